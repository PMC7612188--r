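# Protofilament end morphology: traced contours -> deviation paths, taper
# lengths, end census.

#' Traced protofilament contours at one MT end
#'
#' Each contour is an ordered point path (nm) along one protofilament; the
#' first two points define the straight MT wall segment, later points trace
#' the pf as it curves away from the lattice. Contours are ordered from the
#' MT body outward (the last point is the pf tip).
#'
#' @param contours list of n x 3 matrices (>= 2 points each)
#' @param end_id identifier
#' @param filament_id id of the parent filament
#' @param end_side "path_start" or "path_end": which end of the filament
#' @param max_wall_angle invariant check: maximum pairwise angle between the
#'   wall segments, degrees
#' @return object of class `end_contours`
#' @export
end_contours <- function(contours, end_id = 0L, filament_id = 0L,
                         end_side = c("path_end", "path_start"),
                         max_wall_angle = 15) {
  end_side <- match.arg(end_side)
  contours <- lapply(contours, as.matrix)
  if (any(vapply(contours, nrow, integer(1)) < 2))
    stop("every contour needs at least 2 points")
  dirs <- t(vapply(contours, function(p) {
    d <- p[2, ] - p[1, ]
    d / sqrt(sum(d^2))
  }, numeric(3)))
  if (nrow(dirs) > 1) {
    angs <- acos(pmin(1, abs(dirs %*% t(dirs)))) * 180 / pi
    if (max(angs) > max_wall_angle)
      stop("wall segments are not near-parallel (max pairwise angle ",
           sprintf("%.1f", max(angs)), " deg)")
  }
  structure(list(contours = contours, end_id = as.integer(end_id),
                 filament_id = as.integer(filament_id), end_side = end_side),
            class = "end_contours")
}

# common axis of an end: mean wall-segment direction, oriented so that the
# contour tips lie ahead of the wall segments (s grows toward the end)
end_axis <- function(end) {
  dirs <- t(vapply(end$contours, function(p) {
    d <- p[2, ] - p[1, ]
    d / sqrt(sum(d^2))
  }, numeric(3)))
  u <- colMeans(dirs)
  u <- u / sqrt(sum(u^2))
  tipward <- mean(vapply(end$contours, function(p)
    sum((p[nrow(p), ] - p[1, ]) * u), numeric(1)))
  if (tipward < 0) u <- -u
  a0 <- colMeans(t(vapply(end$contours, function(p) p[1, ], numeric(3))))
  list(origin = a0, u = u)
}

#' Protofilament deviation paths at an MT end
#'
#' For each contour, emits the points after the straight wall segment whose
#' radial distance from the wall cylinder exceeds `threshold`, as pairs
#' (s = axial advance from the end of the wall segment, d = outward radial
#' deviation), both nm. A contour that never deviates yields an empty path
#' (a straight protofilament), not an error.
#'
#' @param end an [end_contours()]
#' @param threshold radial deviation threshold, nm (~one monomer radius)
#' @return list of data.frames (s, d), one per protofilament
#' @export
pf_deviation_paths <- function(end, threshold = 2) {
  ax <- end_axis(end)
  lapply(end$contours, function(p) {
    rel <- sweep(p, 2, ax$origin)
    s_ax <- as.numeric(rel %*% ax$u)
    rad <- sqrt(pmax(rowSums(rel^2) - s_ax^2, 0))
    r_ref <- mean(rad[1:2])
    s0 <- s_ax[2]                      # end of the modeled wall segment
    dev <- rad - r_ref
    idx <- which(dev > threshold & seq_along(dev) > 2)
    data.frame(s = s_ax[idx] - s0, d = dev[idx])
  })
}

#' Taper length of an MT end
#'
#' Projects each protofilament's terminal point onto the end axis and
#' returns the distance between the longest and the shortest protofilament.
#'
#' @param end an [end_contours()] with >= 2 contours
#' @return taper length, nm (>= 0)
#' @export
taper_length <- function(end) {
  if (length(end$contours) < 2)
    stop("taper length is undefined for a single contour")
  ax <- end_axis(end)
  term <- vapply(end$contours, function(p)
    sum((p[nrow(p), ] - ax$origin) * ax$u), numeric(1))
  max(term) - min(term)
}

#' End census: polarity labels, tapers and group comparisons
#'
#' Combines each end's side with the polarity assignment of its filament
#' ("plus" = plus end at the path end). Ends on filaments with unclear or
#' missing polarity are labeled ND (with a warning when missing). Returns
#' per-end rows plus per-label taper summaries and unpaired two-tailed
#' t-tests between groups.
#'
#' @param ends list of [end_contours()]
#' @param polarity_assignments data.frame(filament_id, assignment) with
#'   assignment in "plus", "minus", "unclear" (filament polarity along path)
#' @return list(census = data.frame, summaries = data.frame, tests = list)
#' @export
end_census <- function(ends, polarity_assignments) {
  rows <- do.call(rbind, lapply(ends, function(e) {
    i <- match(e$filament_id, polarity_assignments$filament_id)
    if (is.na(i)) {
      warning("end ", e$end_id, " on filament ", e$filament_id,
              " absent from polarity table; labeled ND")
      pol <- "ND"
    } else {
      a <- polarity_assignments$assignment[i]
      pol <- if (a == "plus") {
        if (e$end_side == "path_end") "plus" else "minus"
      } else if (a == "minus") {
        if (e$end_side == "path_end") "minus" else "plus"
      } else "ND"
    }
    data.frame(end_id = e$end_id, filament_id = e$filament_id,
               side = e$end_side, polarity_label = pol,
               taper = taper_length(e), n_pf_traced = length(e$contours))
  }))
  labs <- unique(rows$polarity_label)
  summaries <- do.call(rbind, lapply(labs, function(l) {
    t <- rows$taper[rows$polarity_label == l]
    data.frame(polarity_label = l, mean = mean(t),
               sd = if (length(t) > 1) sd(t) else NA_real_, n = length(t))
  }))
  tests <- list()
  pairs <- utils::combn(labs, min(2, length(labs)), simplify = FALSE)
  if (length(labs) >= 2) {
    for (pr in utils::combn(labs, 2, simplify = FALSE)) {
      a <- rows$taper[rows$polarity_label == pr[1]]
      b <- rows$taper[rows$polarity_label == pr[2]]
      if (length(a) >= 2 && length(b) >= 2)
        tests[[paste(pr, collapse = "_vs_")]] <- ttest(a, b, mode = "unpaired")
    }
  }
  list(census = rows, summaries = summaries, tests = tests)
}

#' Generate synthetic end contours with known taper and flare
#'
#' Builds one contour per protofilament: a straight wall segment along the
#' axis followed by a circular-arc flare of given radius in the
#' radial-axial plane, sampled every ~4 nm. The terminal axial coordinates
#' (hence the taper) and the flare curvature radii are returned as ground
#' truth for recovery tests.
#'
#' @param n_pf number of protofilaments
#' @param wall_radius wall radius, nm
#' @param straight_lengths per-pf straight segment length, nm (recycled)
#' @param flare_radii per-pf arc radius, nm; 0 = straight pf (recycled)
#' @param arc_degrees per-pf arc angle, degrees (recycled)
#' @param point_spacing contour sampling, nm
#' @param rotation optional 3x3 rigid rotation applied to all points
#' @param translation optional length-3 offset, nm
#' @param end_side which end of the filament the contours describe
#' @param end_id,filament_id identifiers
#' @return list(end = [end_contours()], truth = data.frame(pf,
#'   terminal_axial, flare_radius, arc_degrees))
#' @export
make_end_contours <- function(n_pf = 13, wall_radius = 10.6,
                              straight_lengths = 24, flare_radii = 20,
                              arc_degrees = 90, point_spacing = 4,
                              rotation = diag(3), translation = c(0, 0, 0),
                              end_side = "path_end", end_id = 0L,
                              filament_id = 0L) {
  straight_lengths <- rep_len(straight_lengths, n_pf)
  flare_radii <- rep_len(flare_radii, n_pf)
  arc_degrees <- rep_len(arc_degrees, n_pf)
  contours <- vector("list", n_pf)
  truth <- data.frame(pf = seq_len(n_pf) - 1L, terminal_axial = NA_real_,
                      flare_radius = flare_radii, arc_degrees = arc_degrees)
  for (j in seq_len(n_pf)) {
    phi <- 2 * pi * (j - 1) / n_pf
    r_hat <- c(cos(phi), sin(phi), 0)
    z_hat <- c(0, 0, 1)
    base <- wall_radius * r_hat
    pts <- rbind(base, base + straight_lengths[j] * z_hat)
    term_ax <- straight_lengths[j]
    if (flare_radii[j] > 0 && arc_degrees[j] > 0) {
      rho <- flare_radii[j]
      a_end <- deg2rad(arc_degrees[j])
      arc_len <- rho * a_end
      n_arc <- max(2, ceiling(arc_len / point_spacing))
      aa <- seq(0, a_end, length.out = n_arc + 1)[-1]
      arc <- t(vapply(aa, function(a)
        pts[2, ] + rho * sin(a) * z_hat + rho * (1 - cos(a)) * r_hat,
        numeric(3)))
      pts <- rbind(pts, arc)
      term_ax <- straight_lengths[j] + rho * sin(a_end)
    }
    truth$terminal_axial[j] <- term_ax
    contours[[j]] <- t(rotation %*% t(pts)) +
      matrix(translation, nrow(pts), 3, byrow = TRUE)
  }
  list(end = end_contours(contours, end_id = end_id,
                          filament_id = filament_id, end_side = end_side),
       truth = truth)
}
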