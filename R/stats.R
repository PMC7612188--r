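# Measurement arithmetic and statistics: peak-to-peak diameters, layer-line
# spectra, density conversions, summary statistics and t-tests. All
# internals keep full precision; rounding to 2-3 significant figures happens
# only at the report layer.

#' Summary statistic (mean, SD with n-1 denominator, n)
#' @param x numeric vector (n >= 1)
#' @return list(mean, sd, n); sd is NA for n = 1
#' @export
summary_stat <- function(x) {
  if (!length(x)) stop("summary_stat needs at least one value")
  list(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
       n = length(x))
}

# parabolic sub-voxel refinement of a local maximum at index i
refine_peak <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(den) < 1e-300) return(i)
  i - 0.5 * (y[i + 1] - y[i - 1]) / den
}

#' Peak-to-peak diameter from a 1D intensity profile
#'
#' Locates the two dominant intensity peaks (walls of a tube or membrane
#' leaflets) with parabolic sub-voxel interpolation and returns their
#' separation.
#'
#' @param profile numeric vector: intensity across the structure
#' @param voxel_size nm per sample
#' @param noise_floor peaks must exceed `mean + noise_floor * sd` of the
#'   profile
#' @return diameter, nm
#' @export
diameter_peak_to_peak <- function(profile, voxel_size = 1, noise_floor = 0.5) {
  n <- length(profile)
  if (n < 3) stop("profile too short")
  is_max <- c(FALSE, profile[2:(n - 1)] > profile[1:(n - 2)] &
                profile[2:(n - 1)] >= profile[3:n], FALSE)
  thr <- mean(profile) + noise_floor * sd(profile)
  peaks <- which(is_max & profile > thr)
  if (length(peaks) < 2)
    stop("fewer than 2 peaks above the noise floor: diameter undefined")
  ord <- peaks[order(profile[peaks], decreasing = TRUE)][1:2]
  p1 <- refine_peak(profile, min(ord))
  p2 <- refine_peak(profile, max(ord))
  abs(p2 - p1) * voxel_size
}

#' Layer-line spectrum of a filament image
#'
#' 2D Fourier power of an image with the filament axis along the rows
#' (dimension 1). Reports the axial frequency of the strongest off-equator
#' layer line as a real-space spacing in nm, or NA when no line rises more
#' than 3 SD above the spectral background.
#'
#' @param img 2D matrix, filament axis along dim 1
#' @param voxel_size nm per pixel
#' @param min_spacing,max_spacing search window for the repeat, nm
#' @return list(spacing_nm, power = data.frame(freq, power), significant)
#' @export
layer_line_spectrum <- function(img, voxel_size = 1, min_spacing = 3.5,
                                max_spacing = 20) {
  # axial Hann window suppresses leakage from the filament's finite extent
  n_ax <- nrow(img)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_ax) - 1) / (n_ax - 1))
  P <- Mod(fft((img - mean(img)) * hann))^2
  f_ax <- freq_axis(n_ax, voxel_size)
  pos <- which(f_ax > 0)
  # layer lines live off the meridian: drop the low lateral-frequency
  # columns, which carry the filament envelope
  n_lat <- ncol(img)
  lat_bin <- c(0:floor((n_lat - 1) / 2), -(ceiling((n_lat - 1) / 2):1))
  keep_lat <- abs(lat_bin) >= 3
  s <- rowSums(P[, keep_lat, drop = FALSE])[pos]
  f <- f_ax[pos]
  win <- f >= 1 / max_spacing & f <= 1 / min_spacing
  if (!any(win)) stop("no frequencies inside the spacing window")
  # spectral background: frequencies beyond the search window but away from
  # the strong low-frequency envelope of the filament itself
  bg <- s[!win & f > 1 / max_spacing]
  if (length(bg) < 5) bg <- s[!win]
  thr <- mean(bg) + 3 * sd(bg)
  i <- which(win)[which.max(s[win])]
  significant <- s[i] > thr && s[i] > 3 * stats::median(s[win])
  spacing <- if (significant) 1 / f[i] else NA_real_
  list(spacing_nm = spacing, power = data.frame(freq = f, power = s),
       significant = significant)
}

#' Linear and areal densities with report-layer rounding
#'
#' @param count number of features (e.g. plus ends)
#' @param length_um surveyed length, micrometer
#' @param width_um effective width, micrometer (for the areal conversion)
#' @return list(per_um, per_um2, report = c(per_um, per_um2) rounded to 2
#'   significant figures)
#' @export
densities <- function(count, length_um, width_um) {
  stopifnot(length_um > 0, width_um > 0)
  per_um <- count / length_um
  per_um2 <- per_um / width_um
  list(per_um = per_um, per_um2 = per_um2,
       report = c(per_um = signif(per_um, 2), per_um2 = signif(per_um2, 2)))
}

#' Student's t-test (pooled variance), two-tailed
#'
#' Thin wrapper over the classic t-test: unpaired uses the pooled-variance
#' (equal-variance) form, paired requires equal lengths. The degenerate case
#' of zero variance in both groups with equal means returns p = 1 with a
#' flag instead of erroring.
#'
#' @param a,b numeric vectors (n >= 2 each)
#' @param mode "unpaired" or "paired"
#' @param tails only two-tailed tests are provided
#' @return list(t, df, p, flagged)
#' @export
ttest <- function(a, b, mode = c("unpaired", "paired"), tails = 2) {
  mode <- match.arg(mode)
  if (tails != 2) stop("only two-tailed tests are provided")
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (mode == "paired" && length(a) != length(b))
    stop("paired test requires equal group sizes")
  degenerate <- if (mode == "paired") all(a - b == (a - b)[1]) &&
    (a - b)[1] == 0 else
    (sd(a) == 0 && sd(b) == 0)
  if (degenerate && isTRUE(all.equal(mean(a), mean(b)))) {
    df <- if (mode == "paired") length(a) - 1 else length(a) + length(b) - 2
    return(list(t = 0, df = df, p = 1, flagged = TRUE))
  }
  res <- t.test(a, b, paired = (mode == "paired"), var.equal = TRUE,
                alternative = "two.sided")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, flagged = FALSE)
}

#' Wall-thickness ratio with per-tomogram pairing
#'
#' Per-tomogram ratio of two structures' wall widths (e.g. vault shell vs
#' adjacent lipid bilayer), the cohort mean ratio, and a paired two-tailed
#' t-test on the per-tomogram means.
#'
#' @param widths_a,widths_b per-tomogram mean widths (paired by position)
#' @return list(ratios, mean_ratio, test (NULL when only one pair))
#' @export
wall_thickness_ratio <- function(widths_a, widths_b) {
  if (length(widths_a) != length(widths_b))
    stop("paired per-tomogram means required")
  ratios <- widths_a / widths_b
  test <- if (length(widths_a) >= 2) ttest(widths_a, widths_b, mode = "paired")
          else NULL
  list(ratios = ratios, mean_ratio = mean(ratios), test = test)
}

#' Protofilament-architecture census percentages
#'
#' Report-layer percentages for a census of MT architectures (e.g. 12-pf,
#' 13-pf, ND): percentages are computed from the counts and rounded to
#' whole percent at the report layer only.
#'
#' @param counts named integer vector of per-class counts
#' @return data.frame(class, n, percent)
#' @export
pf_census <- function(counts) {
  total <- sum(counts)
  data.frame(class = names(counts), n = as.integer(counts),
             percent = round(100 * as.integer(counts) / total))
}

#' Neurite-level architecture census
#'
#' Classifies each neurite by the protofilament architectures of its MTs:
#' "all_12" / "all_13" when every MT is clearly one architecture, "mixed"
#' when MTs of different architecture coexist (including neurites that also
#' contain undetermined MTs), and "ND" when the determined MTs are
#' consistent but one or more MTs could not be determined.
#'
#' @param df data.frame with columns neurite_id and pf (12, 13, or NA for ND)
#' @return data.frame(neurite_id, call)
#' @export
neurite_census <- function(df) {
  out <- do.call(rbind, lapply(split(df, df$neurite_id), function(d) {
    pf <- d$pf
    known <- pf[!is.na(pf)]
    call <- if (length(unique(known)) > 1) "mixed"
    else if (any(is.na(pf))) "ND"
    else if (all(known == 12)) "all_12"
    else if (all(known == 13)) "all_13"
    else "ND"
    data.frame(neurite_id = d$neurite_id[1], call = call)
  }))
  rownames(out) <- NULL
  out
}
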