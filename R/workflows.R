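# End-to-end workflows: reference construction, polarity determination,
# per-MT inspection measurements, and pf-number transition mapping.

#' Render a synthetic MT reference in the particle frame
#'
#' A straight microtubule along the box z axis (the filament axis in the
#' particle frame), rendered noiselessly from the lattice generator. Used as
#' the initial alignment reference and as the 12-/13-pf references for
#' multireference classification.
#'
#' @param pf_number protofilament count
#' @param box_size box edge, voxels (odd)
#' @param voxel_size nm per voxel
#' @param lattice base [lattice_spec()]; pf geometry is scaled from it
#' @param polarity lattice polarity along +z
#' @param phase0 lattice phase, degrees
#' @return a [volume()]
#' @export
render_mt_reference <- function(pf_number = 13, box_size = 33, voxel_size = 1,
                                lattice = lattice_spec(),
                                polarity = "plus_along_path", phase0 = 0) {
  ext <- box_size * voxel_size
  L <- ext + 48
  spec <- lattice_spec(pf_number = pf_number,
                       wall_radius = lattice$wall_radius * pf_number /
                         lattice$pf_number,
                       dimer_rise = lattice$dimer_rise,
                       monomer_offset = lattice$monomer_offset,
                       monomer_sigma = lattice$monomer_sigma,
                       slew_tilt = lattice$slew_tilt)
  fl <- filament_spec(rbind(c(0, 0, -L / 2), c(0, 0, L / 2)),
                      polarity = polarity,
                      pf_segments = data.frame(s0 = 0, s1 = L,
                                               pf = as.integer(pf_number)),
                      phase0 = phase0)
  pts <- build_lattice_points(spec, fl)
  ctr <- (box_size - 1) / 2 * voxel_size
  xyz <- as.matrix(pts[, c("x", "y", "z")])   # path is centered on the box
  amps <- ifelse(pts$monomer == "alpha", 1.12, 0.88)
  dat <- cpp_render_blobs(rep(box_size, 3L), voxel_size,
                          rep(-ctr, 3), xyz,
                          amps, rep(spec$monomer_sigma, nrow(xyz)))
  volume(dat, voxel_size = voxel_size, origin = rep(-ctr, 3))
}

#' Pool per-MT stacks into one stack
#'
#' @param stacks list of [subtomogram_stack()] with identical box geometry
#' @return pooled stack (particle ids reassigned to stay unique)
#' @export
pool_stacks <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  bs <- unique(vapply(stacks, function(s) s$box_size, integer(1)))
  vs <- unique(vapply(stacks, function(s) s$voxel_size, numeric(1)))
  if (length(bs) != 1 || length(vs) != 1)
    stop("stacks must share box size and voxel size")
  boxes <- do.call(cbind, lapply(stacks, function(s) s$boxes))
  tb <- do.call(rbind, lapply(stacks, function(s) as.data.frame(s$table)))
  tb$particle_id <- seq_len(nrow(tb)) - 1L
  subtomogram_stack(boxes, bs, vs, as_particle_table(tb))
}

#' Determine MT polarity by MSA + one-round MRA classification
#'
#' The automated polarity pipeline: align all particles to a common
#' reference (in-plane search), run the eigenimage decomposition, find the
#' component separating polarity (opposite slew signs of the two
#' 1-D-clustered class averages), run one round of multireference alignment
#' with the two class averages, clean to the best 80% per MT, and assign
#' polarity where strictly more than 70% of an MT's particles agree.
#'
#' @param stack pooled [subtomogram_stack()] over all MTs
#' @param lattice the [lattice_spec()] describing the expected geometry
#' @param tilt_range wedge half-range of the data, degrees (for MSA wedge
#'   imputation); NULL if no wedge
#' @param align_rounds initial alignment rounds
#' @param n_components,n_scan MSA size and eigenvector scan depth
#' @param vote_threshold,pre_clean vote parameters (0.70 strict, 0.80)
#' @return list(assignments, table, component, class_polarity, decomp)
#' @export
determine_polarity <- function(stack, lattice = lattice_spec(),
                               tilt_range = 60, align_rounds = 1,
                               n_components = 40, n_scan = 20,
                               vote_threshold = 0.70, pre_clean = 0.80) {
  wr <- lattice$wall_radius
  tube <- list(type = "gaussian_tube", radius = wr, sigma = 4)
  # initial phase/register lock against an achiral reference (slew tilt 0):
  # a chirality-bearing reference would imprint its own handedness on every
  # noisy particle and mask the polarity signal
  lat0 <- lattice_spec(pf_number = lattice$pf_number,
                       wall_radius = lattice$wall_radius,
                       dimer_rise = lattice$dimer_rise,
                       monomer_offset = lattice$monomer_offset,
                       skew_per_pf = lattice$skew_per_pf,
                       monomer_sigma = lattice$monomer_sigma,
                       slew_tilt = 0)
  ref <- render_mt_reference(lattice$pf_number, stack$box_size,
                             stack$voxel_size, lat0)
  lim_align <- alignment_limits(max_inplane = 180, inplane_step = 2,
                                max_axial_shift = lattice$dimer_rise / 2,
                                shift_step = stack$voxel_size,
                                mask = tube)
  tb <- align(stack, ref, lim_align, iterations = align_rounds)
  decomp <- msa(stack, tb, n_components = n_components, mask = tube,
                tilt_range = tilt_range)
  tbk <- tb[tb$keep_flag, , drop = FALSE]
  pe <- find_polarity_eigenvector(decomp, filament_id = tbk$filament_id,
                                  n_scan = n_scan,
                                  r_inner = wr - 1.6, r_outer = wr + 1.9)
  # one round of multireference classification: class references from the
  # eigenvector split, rebuilt per filament excluding that filament's own
  # particles (cross-validated references), scored by masked normalized
  # correlation in the wedge-imputed aligned frame
  mvec <- as.numeric(mask_volume(tube, stack$box_size, stack$voxel_size))
  cls <- classify_loo(decomp$M, mvec, ifelse(pe$groups, 1L, 2L),
                      tbk$filament_id, rounds = 1)
  tbk$class_label <- cls$labels
  tbk$cc_score <- cls$cc
  class_polarity <- vapply(1:2, function(k) {
    members <- which(cls$labels == k)
    if (length(members) < 2) return("unclear")
    img <- class_avg_image(decomp, members)
    slew_to_polarity(slew_sign(img, wr - 1.6, wr + 1.9,
                               stack$voxel_size)$sign)
  }, character(1))
  if (any(class_polarity == "unclear") ||
      class_polarity[1] == class_polarity[2]) {
    # fall back to the eigenvector-scan class labels
    class_polarity <- vapply(pe$signs, slew_to_polarity, character(1))
  }
  votes <- vote_polarity(tbk, class_polarity,
                         threshold = vote_threshold, pre_clean = pre_clean)
  # per-MT slew reading from the same (wedge-imputed, aligned) particles:
  # the automated stand-in for per-MT visual inspection
  slew_route <- do.call(rbind, lapply(sort(unique(tbk$filament_id)),
    function(f) {
      ss <- slew_sign(class_avg_image(decomp, which(tbk$filament_id == f)),
                      wr - 1.6, wr + 1.9, stack$voxel_size)
      data.frame(filament_id = f, slew = ss$sign, lag_deg = ss$score,
                 assignment = slew_to_polarity(ss$sign))
    }))
  decomp$M <- NULL      # the aligned voxel matrix is large; drop it
  list(assignments = votes, table = tbk, component = pe$component,
       class_polarity = class_polarity, slew_route = slew_route,
       decomp = decomp)
}

#' Per-MT polarity by slew inspection of individual averages
#'
#' The visual-inspection-equivalent route: average each MT's particles,
#' project the cross-section, and read the polarity from the slew
#' handedness.
#'
#' @param stack a [subtomogram_stack()]
#' @param table current table
#' @param lattice expected lattice geometry
#' @return data.frame(filament_id, slew, assignment)
#' @export
mt_polarity_by_slew <- function(stack, table = stack$table,
                                lattice = lattice_spec()) {
  wr <- lattice$wall_radius
  ids <- sort(unique(table$filament_id))
  rows <- lapply(ids, function(f) {
    sub <- table[table$filament_id == f & table$keep_flag, , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(filament_id = f, slew = "undetermined",
                        assignment = "unclear"))
    avg <- average(stack, sub)
    img <- slew_image(avg)
    ss <- slew_sign(img, wr - 1.6, wr + 1.9, stack$voxel_size)
    data.frame(filament_id = f, slew = ss$sign,
               assignment = slew_to_polarity(ss$sign))
  })
  do.call(rbind, rows)
}

#' Per-MT protofilament counts from individual averages
#'
#' @param stack a [subtomogram_stack()]
#' @param table current table
#' @param min_particles averages from fewer particles are ND
#' @return data.frame(filament_id, n, pf)
#' @export
mt_pf_counts <- function(stack, table = stack$table, min_particles = 5) {
  ids <- sort(unique(table$filament_id))
  rows <- lapply(ids, function(f) {
    sub <- table[table$filament_id == f & table$keep_flag, , drop = FALSE]
    if (nrow(sub) < min_particles)
      return(data.frame(filament_id = f, n = nrow(sub), pf = NA_integer_))
    avg <- average(stack, sub)
    cnt <- count_pfs(avg, n_particles = nrow(sub),
                     min_particles = min_particles)
    data.frame(filament_id = f, n = nrow(sub), pf = as.integer(cnt))
  })
  do.call(rbind, rows)
}

#' Map protofilament-number transitions by 3-round MRA
#'
#' Aligns particles to a common reference, then runs three rounds of
#' multireference alignment against rendered 12- and 13-pf references and
#' applies the assignment rule: >95% majority assigns automatically; MTs
#' with two quality-gated classes in contiguous runs of more than 20
#' particles are called transitions, localized at the midpoint between the
#' facing run ends.
#'
#' @param stack a [subtomogram_stack()]
#' @param lattice base lattice geometry
#' @param rounds MRA rounds
#' @param class_pf pf numbers of the two references
#' @param auto_threshold,min_patch assignment-rule constants
#' @param prealign_rounds initial common-reference alignment rounds
#' @return list(assignments (from [assign_pf()]), table)
#' @export
detect_pf_transitions <- function(stack, lattice = lattice_spec(),
                                  rounds = 3, class_pf = c(12, 13),
                                  auto_threshold = 0.95, min_patch = 20,
                                  prealign_rounds = 1) {
  tube <- list(type = "gaussian_tube", radius = lattice$wall_radius,
               sigma = 4.5)
  refs <- lapply(class_pf, function(p)
    render_mt_reference(p, stack$box_size, stack$voxel_size, lattice))
  tb <- stack$table
  if (prealign_rounds > 0) {
    lim0 <- alignment_limits(max_inplane = 180, inplane_step = 4,
                             max_axial_shift = lattice$dimer_rise / 2,
                             shift_step = stack$voxel_size, mask = tube)
    ref0 <- refs[[which(class_pf == 13)[1]]]
    for (r in seq_len(prealign_rounds))
      tb <- align(stack, ref0, lim0, iterations = 1, table = tb)
  }
  lim <- alignment_limits(max_inplane = 16, inplane_step = 2,
                          max_axial_shift = 2.2,
                          shift_step = stack$voxel_size / 2, mask = tube)
  res <- mra(stack, refs, rounds = rounds, limits = lim, table = tb)
  assignments <- assign_pf(res, stack, class_pf = class_pf,
                           auto_threshold = auto_threshold,
                           min_patch = min_patch)
  list(assignments = assignments, table = res$table)
}
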