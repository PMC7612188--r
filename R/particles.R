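# Particle tables (the motive-list equivalent)
#
# A data.frame with one row per subtomogram position:
#   particle_id   unique integer
#   filament_id   integer id of the source filament
#   tomogram_id   integer id of the source tomogram
#   x, y, z       position in nm (tomogram frame)
#   phi, theta, psi  Z-X-Z intrinsic Euler angles, degrees (box -> tomogram);
#                    psi is the in-plane (spin) angle about the filament axis
#   cc_score      constrained cross-correlation score in [-1, 1] (NA before alignment)
#   class_label   integer class from classification (NA before)
#   keep_flag     logical, FALSE for dropped/flagged particles
#   arclength     nm along the source filament (extraction bookkeeping)

PARTICLE_COLS <- c("particle_id", "filament_id", "tomogram_id",
                   "x", "y", "z", "phi", "theta", "psi",
                   "cc_score", "class_label", "keep_flag", "arclength")

#' Construct a particle table
#'
#' @param ... columns; missing optional columns are filled with defaults
#' @return data.frame of class `particle_table`
#' @export
particle_table <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$cc_score)) df$cc_score <- NA_real_
  if (is.null(df$class_label)) df$class_label <- NA_integer_
  if (is.null(df$keep_flag)) df$keep_flag <- TRUE
  if (is.null(df$arclength)) df$arclength <- NA_real_
  if (is.null(df$tomogram_id)) df$tomogram_id <- 0L
  missing <- setdiff(PARTICLE_COLS, names(df))
  if (length(missing)) stop("particle table missing column(s): ",
                            paste(missing, collapse = ", "))
  df <- df[PARTICLE_COLS]
  validate_particle_table(df)
  class(df) <- c("particle_table", "data.frame")
  df
}

validate_particle_table <- function(df) {
  if (anyDuplicated(df$particle_id)) stop("particle_id values must be unique")
  cc <- df$cc_score[!is.na(df$cc_score)]
  if (length(cc) && (any(cc < -1 - 1e-9) || any(cc > 1 + 1e-9)))
    stop("cc_score outside [-1, 1]")
  th <- df$theta[!is.na(df$theta)]
  if (length(th) && (any(th < 0) || any(th > 180)))
    stop("theta outside [0, 180]")
  invisible(df)
}

as_particle_table <- function(df) {
  df <- df[PARTICLE_COLS]
  validate_particle_table(df)
  class(df) <- c("particle_table", "data.frame")
  df
}

#' Write a particle table as TSV
#'
#' Tab-separated with a '#'-prefixed header line; diff-able and language
#' neutral. Floating-point columns are written with fixed formatting so a
#' second write of the same table is byte-identical.
#'
#' @param table particle table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(table, path) {
  df <- as.data.frame(table)[PARTICLE_COLS]
  num <- c("x", "y", "z", "phi", "theta", "psi", "cc_score", "arclength")
  out <- df
  for (cn in num) out[[cn]] <- sprintf("%.6f", df[[cn]])
  out$keep_flag <- as.integer(df$keep_flag)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(PARTICLE_COLS, collapse = "\t")), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a particle table written by [write_table()]
#'
#' @param path file path
#' @return particle table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty particle table file: ", path)
  header <- sub("^#", "", lines[1])
  cols <- strsplit(header, "\t")[[1]]
  missing <- setdiff(PARTICLE_COLS, cols)
  if (length(missing)) stop("particle table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (length(lines) == 1) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  } else {
    df <- read.table(text = lines[-1], sep = "\t", col.names = cols)
  }
  df$keep_flag <- as.logical(df$keep_flag)
  int <- c("particle_id", "filament_id", "tomogram_id", "class_label")
  for (cn in int) df[[cn]] <- as.integer(df[[cn]])
  suppressWarnings(df$cc_score[is.nan(df$cc_score)] <- NA_real_)
  as_particle_table(df)
}

#' Write a particle table as a minimal STAR file
#'
#' A single `data_particles` block whose `loop_` columns mirror the TSV
#' schema (rln-style `_amt<Column>` tags).
#'
#' @param table particle table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_star <- function(table, path) {
  df <- as.data.frame(table)[PARTICLE_COLS]
  df$keep_flag <- as.integer(df$keep_flag)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_particles", "", "loop_"), con)
  writeLines(sprintf("_amt%s #%d", PARTICLE_COLS, seq_along(PARTICLE_COLS)), con)
  num <- c("x", "y", "z", "phi", "theta", "psi", "cc_score", "arclength")
  out <- df
  for (cn in num) out[[cn]] <- sprintf("%.6f", df[[cn]])
  writeLines(do.call(paste, c(unname(as.list(out)), sep = " ")), con)
  invisible(path)
}

#' Read a STAR particle table written by [write_star()]
#' @param path file path
#' @return particle table
#' @export
read_star <- function(path) {
  lines <- readLines(path)
  tags <- grep("^_amt", lines)
  if (!length(tags)) stop("no _amt loop_ tags in STAR file: ", path)
  cols <- sub("^_amt(\\S+).*$", "\\1", lines[tags])
  body <- lines[(max(tags) + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  df <- read.table(text = body, col.names = cols)
  df$keep_flag <- as.logical(df$keep_flag)
  for (cn in c("particle_id", "filament_id", "tomogram_id", "class_label"))
    df[[cn]] <- as.integer(df[[cn]])
  as_particle_table(df)
}
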