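# Polarity and protofilament-number classification
#
# Polarity cue: in cross-section projections of an MT average, the tubulin
# subunits appear rotationally sheared ("slewed"); the handedness of the
# shear encodes which end of the MT faces the viewer (clockwise slew =
# viewed from the minus end). slew_sign() measures the handedness as the
# signed angular lag between the angular intensity profiles of the inner and
# outer wall radii. With this package's axis conventions (box z along the
# picking path, cross-section image indexed (x, y), projection by summation
# over z), a counter-clockwise outer-vs-inner lag corresponds to the plus
# end pointing along the path ("plus_along_path"); the mapping is fixed by
# the lattice generator's geometry and locked by round-trip tests.

SLEW_CCW_POLARITY <- "plus_along_path"   # calibrated against the generator

# bilinear sample of a 2D image at fractional (x, y) voxel coordinates
sample2d <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pmin(pmax(x, 1), nx - 1e-9)
  y <- pmin(pmax(y, 1), ny - 1e-9)
  i0 <- pmin(floor(x), nx - 1); j0 <- pmin(floor(y), ny - 1)
  fx <- x - i0; fy <- y - j0
  img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    img[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    img[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    img[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# intensity center of mass of a (positive-contrast) image, voxel coordinates
image_com <- function(img) {
  w <- pmax(img - stats::median(img), 0)
  sw <- sum(w)
  if (sw <= 0) return(c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2))
  c(sum(w * row(img)) / sw, sum(w * col(img)) / sw)
}

# mean intensity around a circle of given radius (nm), 1-degree steps
angular_profile <- function(img, center, radius, voxel_size, band = 1.5,
                            angle_step = 1) {
  th <- deg2rad(seq(0, 360 - angle_step, by = angle_step))
  radii <- seq(radius - band, radius + band, by = voxel_size / 2)
  prof <- rep(0, length(th))
  for (r in radii) {
    prof <- prof + sample2d(img, center[1] + r * cos(th) / voxel_size,
                            center[2] + r * sin(th) / voxel_size)
  }
  prof / length(radii)
}

# mean intensity vs radius, used to locate the wall annulus
radial_profile <- function(img, center, radii, voxel_size) {
  vapply(radii, function(r) {
    th <- deg2rad(seq(0, 358, by = 2))
    mean(sample2d(img, center[1] + r * cos(th) / voxel_size,
                  center[2] + r * sin(th) / voxel_size))
  }, numeric(1))
}

#' Slew handedness of an MT cross-section
#'
#' Unwraps the image to polar coordinates and cross-correlates the angular
#' intensity profile at the inner wall radius against the outer one; the
#' sign of the peak angular lag gives the slew handedness (ccw = outer
#' profile rotated counter-clockwise relative to inner). Off-center images
#' are recentered by intensity center of mass first. Returns "undetermined"
#' when the profile correlation is below the noise floor or the lag is
#' negligible.
#'
#' @param img 2D cross-section (x, y), protein-positive
#' @param r_inner,r_outer sampling radii, nm (straddling the MT wall)
#' @param voxel_size nm per pixel
#' @param max_lag largest angular lag searched, degrees (default: half the
#'   13-pf spacing)
#' @param min_corr correlation noise floor
#' @param min_lag smallest |lag| accepted as determined, degrees
#' @return list(sign = "cw"|"ccw"|"undetermined", score = signed lag in
#'   degrees weighted by nothing, corr = peak profile correlation)
#' @export
slew_sign <- function(img, r_inner = 9, r_outer = 12.5, voxel_size = 1,
                      max_lag = 13, min_corr = 0.25, min_lag = 0.3) {
  ctr <- c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2)
  com <- image_com(img)
  if (sqrt(sum((com - ctr)^2)) > 2) ctr <- com
  pin <- angular_profile(img, ctr, r_inner, voxel_size)
  pout <- angular_profile(img, ctr, r_outer, voxel_size)
  if (sd(pin) < 1e-12 || sd(pout) < 1e-12)
    return(list(sign = "undetermined", score = 0, corr = 0))
  lags <- seq(-max_lag, max_lag, by = 1)
  n <- length(pin)
  cc <- vapply(lags, function(dl) {
    sh <- ((seq_len(n) - 1 + dl) %% n) + 1   # p_out(theta + dl)
    stats::cor(pin, pout[sh])
  }, numeric(1))
  i <- which.max(cc)
  # parabolic refinement of the peak lag
  lag <- lags[i]
  if (i > 1 && i < length(lags)) {
    den <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (abs(den) > 1e-12) lag <- lags[i] - 0.5 * (cc[i + 1] - cc[i - 1]) / den
  }
  if (cc[i] < min_corr || abs(lag) < min_lag)
    return(list(sign = "undetermined", score = lag, corr = cc[i]))
  list(sign = if (lag > 0) "ccw" else "cw", score = lag, corr = cc[i])
}

# polarity of the filament (relative to its picking path) implied by the
# slew sign of a cross-section projected along the box/path axis
slew_to_polarity <- function(sign) {
  if (sign == "undetermined") return("unclear")
  if (sign == "ccw") {
    if (SLEW_CCW_POLARITY == "plus_along_path") "plus" else "minus"
  } else {
    if (SLEW_CCW_POLARITY == "plus_along_path") "minus" else "plus"
  }
}

#' Count protofilaments in a per-MT average
#'
#' Computes the angular power spectrum of the polar-unwrapped wall annulus
#' of the 5-slice cross-section; the protofilament count is the harmonic
#' with maximal power among 11..15. Returns NA ("ND") when the peak-to-
#' runner-up power ratio is below `min_ratio`, or when the average was built
#' from fewer than `min_particles` particles (if `n_particles` is given).
#'
#' @param avg a [volume()] (per-MT average in the common frame) or 2D image
#' @param r_wall wall radius, nm; NULL locates the annulus from the radial
#'   intensity profile
#' @param voxel_size nm per pixel (taken from the volume if available)
#' @param candidates candidate pf counts
#' @param min_ratio peak-to-runner-up power ratio below which the result is ND
#' @param n_particles,min_particles optional quality gate
#' @return integer pf count or NA (ND), with attributes `power` and `ratio`
#' @export
count_pfs <- function(avg, r_wall = NULL, voxel_size = NULL,
                      candidates = 11:15, min_ratio = 1.5,
                      n_particles = NULL, min_particles = 5) {
  img2 <- NULL
  if (is_volume(avg)) {
    if (is.null(voxel_size)) voxel_size <- avg$voxel_size
    img <- project(avg, n_slices = min(5, dim(avg)[3]), axis = "z")
    nz <- dim(avg)[3]
    if (nz >= 19) {
      # independent half-slab cross-sections: a real rotational symmetry
      # appears in both, uncorrelated noise does not. Each half spans one
      # full dimer repeat so the helical stagger does not modulate the
      # harmonic content of a thin slab.
      mid <- (nz + 1) / 2
      w <- min(9, floor((nz - 1) / 2))
      lo <- apply(avg$data[, , floor(mid - w):floor(mid - 1)], 1:2, sum)
      hi <- apply(avg$data[, , ceiling(mid + 1):ceiling(mid + w)], 1:2, sum)
      img2 <- list(lo, hi)
    }
  } else {
    img <- avg
    if (is.null(voxel_size)) voxel_size <- 1
  }
  if (!is.null(n_particles) && n_particles < min_particles)
    return(structure(NA_integer_, power = NULL, ratio = NA_real_))
  ctr <- c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2)
  com <- image_com(img)
  if (sqrt(sum((com - ctr)^2)) > 2) ctr <- com
  if (is.null(r_wall)) {
    radii <- seq(6, 16, by = 0.5)
    rp <- radial_profile(img, ctr, radii, voxel_size)
    r_wall <- radii[which.max(rp)]
  }
  spec_at <- function(im) {
    prof <- angular_profile(im, ctr, r_wall, voxel_size, band = 2.5)
    Mod(fft(prof - mean(prof)))^2
  }
  p <- spec_at(img)
  n <- 360
  harm <- p[candidates + 1]                       # harmonic k at index k+1
  names(harm) <- candidates
  ord <- order(harm, decreasing = TRUE)
  ratio <- harm[ord[1]] / max(harm[ord[2]], .Machine$double.eps)
  # the winning harmonic must also rise above the spectral background of
  # nearby non-candidate harmonics, otherwise noise can win the ratio test
  bg_idx <- setdiff(c(6:10, 16:20), candidates)
  bg <- stats::median(p[bg_idx + 1])
  consistent <- TRUE
  if (!is.null(img2)) {
    win <- vapply(img2, function(im) {
      ph <- spec_at(im)[candidates + 1]
      candidates[which.max(ph)]
    }, numeric(1))
    consistent <- all(win == candidates[ord[1]])
  }
  out <- if (ratio < min_ratio || harm[ord[1]] <= 2.5 * bg || !consistent)
    NA_integer_ else as.integer(candidates[ord[1]])
  structure(out, power = harm, ratio = as.numeric(ratio))
}

#' Multivariate statistical analysis (eigenimage decomposition)
#'
#' Principal components of the masked, aligned subtomograms. With a wedge
#' geometry given, the unmeasured Fourier region of each particle is filled
#' with the particle-set mean spectrum (mean imputation) before
#' decomposition, so the wedge does not masquerade as structural variance.
#'
#' @param stack a [subtomogram_stack()]
#' @param table current aligned table (kept rows enter the decomposition)
#' @param n_components number of components to return (~40 typical)
#' @param mask mask spec (see [alignment_limits()]) or NULL for none
#' @param tilt_range wedge half-range for mean imputation, or NULL to skip
#' @return object of class `eigen_decomp`: orthonormal `components`
#'   (masked-voxel space), `eigenvalues` (non-increasing), per-particle
#'   `coords`, the aligned voxel matrix `M`, selected voxel indices `sel`,
#'   and the contributing `particle_id`s
#' @export
msa <- function(stack, table = stack$table, n_components = 40, mask = NULL,
                tilt_range = NULL) {
  tb <- table[table$keep_flag, , drop = FALSE]
  N <- nrow(tb)
  if (N <= n_components)
    warning("fewer particles than requested components; decomposition is rank-limited")
  M <- aligned_boxes(stack, tb)
  d <- rep(stack$box_size, 3)
  if (!is.null(tilt_range)) {
    kx <- freq_axis(d[1], 1); ky <- freq_axis(d[2], 1); kz <- freq_axis(d[3], 1)
    kg <- cbind(rep(kx, times = d[2] * d[3]),
                rep(rep(ky, each = d[1]), times = d[3]),
                rep(kz, each = d[1] * d[2]))
    p_mask <- function(i) {
      R <- eul2rot(tb$phi[i], tb$theta[i], tb$psi[i])
      kw <- kg %*% t(R)
      m <- atan2(abs(kw[, 3]), abs(kw[, 1])) * 180 / pi <= tilt_range
      m[1] <- TRUE
      m
    }
    # streaming mean imputation: two passes, nothing per-particle retained
    acc <- complex(prod(d)); den <- numeric(prod(d))
    for (i in seq_len(N)) {
      m <- p_mask(i)
      acc <- acc + fft(array(M[, i], d)) * m
      den <- den + m
    }
    Fmean <- acc / pmax(den, 1)
    for (i in seq_len(N)) {
      m <- p_mask(i)
      f <- fft(array(M[, i], d))
      f[!m] <- Fmean[!m]
      M[, i] <- Re(fft(array(f, d), inverse = TRUE)) / prod(d)
    }
  }
  mvec <- as.numeric(mask_volume(mask, stack$box_size, stack$voxel_size))
  sel <- which(mvec > 0.05)
  X <- t(M[sel, , drop = FALSE] * mvec[sel])     # particles x masked voxels
  Xc <- sweep(X, 2, colMeans(X))
  G <- tcrossprod(Xc)
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  k <- max(1L, min(n_components, sum(pos), N - 1))
  flagged <- k < n_components
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  lam <- eg$values[seq_len(k)]
  V <- crossprod(Xc, U)                          # voxels x k
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  coords <- Xc %*% V
  structure(list(components = V, eigenvalues = lam / max(N - 1, 1),
                 coords = coords, M = M, sel = sel, box_size = stack$box_size,
                 voxel_size = stack$voxel_size, particle_id = tb$particle_id,
                 rank_limited = flagged),
            class = "eigen_decomp")
}

# deterministic 1-D 2-means split of a coordinate; returns logical group
split_two_means <- function(x) {
  c0 <- stats::quantile(x, c(0.15, 0.85), names = FALSE)
  if (diff(c0) < 1e-12) c0 <- c0 + c(-1e-6, 1e-6)
  for (it in 1:50) {
    g <- abs(x - c0[1]) <= abs(x - c0[2])
    c1 <- c(mean(x[g]), mean(x[!g]))
    if (any(!is.finite(c1))) break
    if (max(abs(c1 - c0)) < 1e-10) { c0 <- c1; break }
    c0 <- c1
  }
  abs(x - c0[1]) <= abs(x - c0[2])
}

# cross-section for slew measurement: projecting over (at least) one full
# dimer repeat balances the alpha/beta contributions of every
# protofilament, which a thinner slab does not (the 3-start helical rise
# staggers the monomers), giving a much cleaner angular shear
slew_image <- function(vol, dimer_rise = 8) {
  v <- if (is_volume(vol)) vol else volume(vol)
  ns <- min(dim(v$data)[3], round(dimer_rise / v$voxel_size) + 1)
  project(v, n_slices = ns, axis = "z")
}

# class average image (slew window cross-section) from the decomposition matrix
class_avg_image <- function(decomp, members) {
  v <- array(rowMeans(decomp$M[, members, drop = FALSE]),
             rep(decomp$box_size, 3))
  slew_image(volume(v, voxel_size = decomp$voxel_size))
}

#' Find the eigenvector that separates MT polarity
#'
#' Scans the top components: clusters on each coordinate alone (1-D
#' 2-means), averages the two groups, and measures the slew handedness of
#' both class-average cross-sections. Returns the component whose two class
#' averages have opposite slew signs and the largest slew-score separation.
#' When `filament_id` is supplied, the clustering is performed on per-MT
#' mean coordinates (polarity is a per-filament property, so averaging the
#' coordinate over each MT's particles suppresses per-particle noise before
#' the split); otherwise particles are clustered individually.
#'
#' @param decomp an `eigen_decomp` from [msa()]
#' @param filament_id optional per-particle filament ids (same order as the
#'   decomposition's particles)
#' @param n_scan how many leading components to scan (~20)
#' @param r_inner,r_outer slew sampling radii, nm
#' @return list(component = index, groups = logical vector (group A
#'   membership per particle), signs = the two slew signs, scores = the two
#'   slew scores, gap = |score difference|)
#' @export
find_polarity_eigenvector <- function(decomp, filament_id = NULL, n_scan = 20,
                                      r_inner = 9, r_outer = 12.5) {
  n_scan <- min(n_scan, ncol(decomp$coords))
  best <- NULL
  for (j in seq_len(n_scan)) {
    if (is.null(filament_id)) {
      g <- split_two_means(decomp$coords[, j])
    } else {
      mt_mean <- tapply(decomp$coords[, j], filament_id, mean)
      gm <- split_two_means(as.numeric(mt_mean))
      g <- gm[match(filament_id, as.numeric(names(mt_mean)))]
    }
    if (sum(g) < 2 || sum(!g) < 2) next
    sa <- slew_sign(class_avg_image(decomp, which(g)),
                    r_inner, r_outer, decomp$voxel_size)
    sb <- slew_sign(class_avg_image(decomp, which(!g)),
                    r_inner, r_outer, decomp$voxel_size)
    if (sa$sign %in% c("cw", "ccw") && sb$sign %in% c("cw", "ccw") &&
        sa$sign != sb$sign) {
      gap <- abs(sa$score - sb$score)
      if (is.null(best) || gap > best$gap)
        best <- list(component = j, groups = g, signs = c(sa$sign, sb$sign),
                     scores = c(sa$score, sb$score), gap = gap)
    }
  }
  if (is.null(best)) stop("polarity eigenvector not found")
  best
}

# One-round multireference classification with cross-validated references:
# class averages are rebuilt excluding the filament being scored, so a
# filament's own particles never bias its references. Scoring is masked
# normalized correlation in the (wedge-imputed) aligned frame. Returns
# integer labels and the winning cc per particle.
classify_loo <- function(M, mvec, labels, filament_id, rounds = 1) {
  P <- normalize_cols(M, mvec)
  lab <- labels
  cc <- rep(NA_real_, ncol(M))
  for (it in seq_len(rounds)) {
    new_lab <- lab
    for (f in unique(filament_id)) {
      inf <- filament_id == f
      out1 <- lab == 1L & !inf
      out2 <- lab == 2L & !inf
      if (!any(out1)) out1 <- lab == 1L      # tiny cohorts: a class may
      if (!any(out2)) out2 <- lab == 2L      # exist only on this filament
      if (!any(out1) || !any(out2)) next
      refs <- cbind(rowMeans(M[, out1, drop = FALSE]),
                    rowMeans(M[, out2, drop = FALSE]))
      Rn <- normalize_cols(refs, mvec)$mat
      sc <- crossprod(Rn, P$mat[, inf, drop = FALSE])
      new_lab[inf] <- ifelse(sc[1, ] >= sc[2, ], 1L, 2L)
      cc[inf] <- pmax(sc[1, ], sc[2, ])
    }
    lab <- new_lab
  }
  list(labels = lab, cc = pmin(pmax(cc, -1), 1))
}

#' Multireference alignment classification
#'
#' Each round, every kept particle is aligned (within `limits`) against
#' every reference and assigned to the best-correlating one; references are
#' re-averaged from their members between rounds, and particles may switch
#' classes in each round. A class that empties keeps its reference frozen
#' (with a warning).
#'
#' @param stack a [subtomogram_stack()]
#' @param references list of >= 2 volumes/arrays (box-sized)
#' @param rounds number of MRA rounds
#' @param limits an [alignment_limits()]
#' @param table starting table (defaults to the stack's)
#' @return list(table = table with class_label (1-based reference index) and
#'   cc_score, references = final references, proportions = per-filament
#'   class proportion matrix)
#' @export
mra <- function(stack, references, rounds = 1, limits = alignment_limits(),
                table = stack$table) {
  if (length(references) < 2) stop("mra needs at least 2 references")
  refs <- lapply(references, function(r) if (is_volume(r)) r$data else r)
  tb <- table
  for (rd in seq_len(rounds)) {
    aligned <- vector("list", length(refs))
    scores <- matrix(-Inf, nrow(tb), length(refs))
    for (r in seq_along(refs)) {
      ta <- align(stack, refs[[r]], limits, iterations = 1, table = tb)
      aligned[[r]] <- ta
      scores[, r] <- ta$cc_score
    }
    cls <- max.col(scores, ties.method = "first")
    new_tb <- tb
    for (i in seq_len(nrow(tb))) {
      ta <- aligned[[cls[i]]]
      new_tb[i, c("x", "y", "z", "phi", "theta", "psi", "cc_score")] <-
        ta[i, c("x", "y", "z", "phi", "theta", "psi", "cc_score")]
    }
    new_tb$class_label <- as.integer(cls)
    new_tb$keep_flag <- tb$keep_flag
    tb <- new_tb
    for (r in seq_along(refs)) {
      members <- tb$keep_flag & tb$class_label == r
      if (!any(members)) {
        warning("class ", r, " emptied; reference frozen")
        next
      }
      refs[[r]] <- average(stack, tb[members, , drop = FALSE])$data
    }
  }
  props <- prop_by_filament(tb)
  list(table = tb, references = refs, proportions = props)
}

# per-filament class proportion matrix (rows: filament, cols: class)
prop_by_filament <- function(table) {
  tb <- table[table$keep_flag & !is.na(table$class_label), , drop = FALSE]
  if (!nrow(tb)) return(NULL)
  tab <- table(factor(tb$filament_id), factor(tb$class_label))
  sweep(unclass(tab), 1, rowSums(tab), "/")
}

#' Per-filament polarity vote
#'
#' After retaining the best-correlating `pre_clean` fraction of particles in
#' each MT, a filament is assigned a polarity only if strictly more than
#' `threshold` of its particles fall in one (polarity-labeled) class;
#' otherwise it is "unclear". Exactly 70% is unclear: the rule is strict.
#'
#' @param table classified table (class_label set, cc scores present)
#' @param class_polarity character vector mapping class index to "plus" /
#'   "minus" (e.g. `c("plus", "minus")` for classes 1 and 2)
#' @param threshold vote threshold (strict)
#' @param pre_clean cc_clean fraction applied per filament first
#' @return data.frame(filament_id, n, p_major, assignment)
#' @export
vote_polarity <- function(table, class_polarity, threshold = 0.70,
                          pre_clean = 0.80) {
  tb <- cc_clean(table, fraction = pre_clean)
  ids <- sort(unique(table$filament_id))
  out <- data.frame(filament_id = ids, n = 0L, p_major = NA_real_,
                    assignment = "unclear", stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    rows <- tb[tb$filament_id == ids[k] & tb$keep_flag &
                 !is.na(tb$class_label), , drop = FALSE]
    out$n[k] <- nrow(rows)
    if (!nrow(rows)) next
    counts <- table(factor(rows$class_label, levels = seq_along(class_polarity)))
    p <- max(counts) / sum(counts)
    out$p_major[k] <- p
    if (p > threshold)
      out$assignment[k] <- class_polarity[which.max(counts)]
  }
  out
}

# contiguous runs of class labels ordered by arclength, after suppressing
# isolated flips shorter than min_run particles
class_runs <- function(cls, min_run = 3) {
  n <- length(cls)
  if (n == 0) return(NULL)
  smoothed <- cls
  repeat {
    r <- rle(smoothed)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run)
    short <- short[short > 1 & short < length(r$lengths)]
    short <- short[vapply(short, function(s)
      r$values[s - 1] == r$values[s + 1], logical(1))]
    if (!length(short)) break
    s <- short[1]
    i0 <- sum(r$lengths[seq_len(s - 1)]) + 1
    smoothed[i0:(i0 + r$lengths[s] - 1)] <- r$values[s - 1]
  }
  rle(smoothed)
}

#' Assign per-filament protofilament architecture
#'
#' Implements the two-stage rule: filaments with over `auto_threshold` of
#' particles in one class are assigned automatically; otherwise per-class
#' per-MT averages are built and quality-gated with [count_pfs()]. If both
#' class averages pass and each class forms a contiguous run of more than
#' `min_patch` particles, the filament is assigned a transition at the
#' midpoint between the two runs' facing ends; if only one passes, the
#' dominant passing class; if neither, ND.
#'
#' @param result list from [mra()] (table + references)
#' @param stack the stack used for classification (per-class averages)
#' @param class_pf integer vector mapping class index to pf count (e.g.
#'   `c(12, 13)`)
#' @param auto_threshold automatic assignment threshold (strict)
#' @param min_patch minimum particles in a contiguous run (strict >)
#' @param min_run isolated flips shorter than this are suppressed before
#'   patch measurement
#' @return data.frame(filament_id, n, p_major, assignment ("12", "13", "ND",
#'   "transition"), transition_nm)
#' @export
assign_pf <- function(result, stack, class_pf = c(12, 13),
                      auto_threshold = 0.95, min_patch = 20, min_run = 3) {
  tb <- result$table
  ids <- sort(unique(tb$filament_id))
  out <- data.frame(filament_id = ids, n = 0L, p_major = NA_real_,
                    assignment = "ND", transition_nm = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    rows <- tb[tb$filament_id == ids[k] & tb$keep_flag &
                 !is.na(tb$class_label), , drop = FALSE]
    rows <- rows[order(rows$arclength), , drop = FALSE]
    out$n[k] <- nrow(rows)
    if (!nrow(rows)) next
    counts <- table(factor(rows$class_label, levels = seq_along(class_pf)))
    p <- max(counts) / sum(counts)
    out$p_major[k] <- p
    major <- which.max(counts)
    if (p > auto_threshold) {
      out$assignment[k] <- as.character(class_pf[major])
      next
    }
    # quality-gate each class by its per-MT class average
    passes <- vapply(seq_along(class_pf), function(cl) {
      members <- rows$class_label == cl
      if (sum(members) < 2) return(FALSE)
      avg <- average(stack, rows[members, , drop = FALSE])
      # gate on the candidate classes only: the missing wedge modulates the
      # angular profile and throws +/-2 harmonic sidebands (11/15 around a
      # 13-pf ring) that are irrelevant to the 12-vs-13 call
      cnt <- count_pfs(avg, candidates = sort(unique(class_pf)),
                       n_particles = sum(members), min_particles = 2)
      !is.na(cnt) && cnt == class_pf[cl]
    }, logical(1))
    if (all(passes)) {
      runs <- class_runs(rows$class_label, min_run = min_run)
      big <- runs$lengths > min_patch
      cls_big <- unique(runs$values[big])
      if (length(cls_big) == 2) {
        # boundary between the two largest runs of different class
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        cand <- which(big[-length(big)] & big[-1] &
                        runs$values[-length(big)] != runs$values[-1])
        if (length(cand)) {
          j <- cand[which.max(pmin(runs$lengths[cand], runs$lengths[cand + 1]))]
          s_left <- rows$arclength[ends[j]]
          s_right <- rows$arclength[starts[j + 1]]
          out$assignment[k] <- "transition"
          out$transition_nm[k] <- (s_left + s_right) / 2
          next
        }
      }
      out$assignment[k] <- as.character(class_pf[major])
    } else if (any(passes)) {
      out$assignment[k] <- as.character(class_pf[which(passes)[
        which.max(counts[passes])]])
    } # else ND
  }
  out
}
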