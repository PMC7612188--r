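#' Filament model: an ordered 3D polyline
#'
#' The picking path of one filament (microtubule, actin, thick or thin
#' filament), in nm.
#'
#' @param points numeric matrix (n x 3) of ordered x,y,z positions in nm
#' @param filament_id integer id (0-based internally)
#' @param kind one of "MT", "actin", "thick", "thin"
#' @return object of class `filament_model`
#' @export
filament_model <- function(points, filament_id = 0L,
                           kind = c("MT", "actin", "thick", "thin")) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) < 2) stop("a filament model needs at least 2 points")
  if (polyline_length(points) <= 0) stop("filament model has zero arclength")
  structure(list(points = points, filament_id = as.integer(filament_id),
                 kind = kind),
            class = "filament_model")
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("<filament_model> id %d (%s), %d points, %.1f nm\n",
              x$filament_id, x$kind, nrow(x$points), visible_length(x)))
  invisible(x)
}

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# cumulative arclength at each polyline vertex
polyline_cumlen <- function(p) {
  c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))))
}

# point at arclength s (linear interpolation along segments)
polyline_point <- function(p, s) {
  cl <- polyline_cumlen(p)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(i, nrow(p) - 1)
  f <- (s - cl[i]) / pmax(cl[i + 1] - cl[i], .Machine$double.eps)
  p[i, , drop = FALSE] + (p[i + 1, , drop = FALSE] - p[i, , drop = FALSE]) * f
}

#' Visible length of a filament model
#'
#' Polyline arclength of the traced path; called "visible" because a filament
#' may extend beyond the reconstructed volume.
#'
#' @param model a [filament_model()] or an n x 3 point matrix
#' @return arclength in nm
#' @export
visible_length <- function(model) {
  p <- if (inherits(model, "filament_model")) model$points else as.matrix(model)
  if (nrow(p) < 2) stop("visible_length needs at least 2 points")
  polyline_length(p)
}

#' Read a model2point-style filament point file
#'
#' Whitespace-delimited columns `object contour x y z` with 1-based object and
#' contour indices and coordinates in voxels (the output convention of IMOD's
#' model2point -object). One filament model is returned per (object, contour)
#' pair; coordinates are scaled to nm by `voxel_size`.
#'
#' @param path file path
#' @param voxel_size nm per voxel used to scale coordinates
#' @return list of [filament_model()]; empty list for an empty file
#' @export
read_point_model <- function(path, voxel_size = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  fields <- strsplit(trimws(lines), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || ncol != 5)
    stop("point model must have 5 whitespace-delimited columns: object contour x y z")
  m <- matrix(as.numeric(unlist(fields)), ncol = 5, byrow = TRUE)
  if (any(!is.finite(m))) stop("non-numeric values in point model")
  key <- paste(m[, 1], m[, 2])
  out <- list()
  id <- 0L
  for (k in unique(key)) {
    pts <- m[key == k, 3:5, drop = FALSE] * voxel_size
    if (nrow(pts) < 2) {
      warning("skipping contour with fewer than 2 points (object/contour ", k, ")")
      next
    }
    out[[length(out) + 1]] <- filament_model(pts, filament_id = id)
    id <- id + 1L
  }
  out
}

#' Write filament models as model2point-style text
#'
#' @param models list of [filament_model()]
#' @param path output path
#' @param voxel_size nm per voxel: coordinates are written in voxels
#' @return `path`, invisibly
#' @export
write_point_model <- function(models, path, voxel_size = 1) {
  rows <- lapply(seq_along(models), function(i) {
    p <- models[[i]]$points / voxel_size
    cbind(i, 1, p)   # one object per filament, single contour
  })
  m <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%6d %5d %11.3f %11.3f %11.3f",
                     m[, 1], m[, 2], m[, 3], m[, 4], m[, 5]), con)
  invisible(path)
}
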