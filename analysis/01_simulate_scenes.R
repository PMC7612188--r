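#!/usr/bin/env Rscript
# Builds a small gallery of ground-truth scenes (13-pf MT with luminal
# particles, a 12->13 pf transition, an actin filament) and writes the
# on-disk artifacts every later stage consumes: MRC volumes, point models
# and JSON manifests under results/scenes/.
library(axonmt)
out <- "results/scenes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- make_mt_scene(length_nm = 400, snr = 1, tilt_range = 60, seed = 101,
                    mip_rate = 72)
write_mrc(sc$volume, file.path(out, "mt13_snr1.mrc"), invert_contrast = TRUE)
write_manifest(sc$manifest, file.path(out, "mt13_snr1.json"))
write_point_model(list(sc$model), file.path(out, "mt13_snr1.pts"),
                  voxel_size = sc$volume$voxel_size)
cat(sprintf("13-pf MT: %d planted MIPs over %.2f um\n",
            length(sc$manifest$mip_positions[[1]]),
            visible_length(sc$model) / 1000))

tr <- make_mt_scene(length_nm = 600,
                    pf_segments = data.frame(s0 = c(0, 300), s1 = c(300, 600),
                                             pf = c(12L, 13L)),
                    snr = 0.5, tilt_range = 60, seed = 102)
write_mrc(tr$volume, file.path(out, "mt_transition.mrc"), invert_contrast = TRUE)
write_manifest(tr$manifest, file.path(out, "mt_transition.json"))
cat("12->13 transition MT rendered (true site at 300 nm)\n")

fl <- filament_spec(rbind(c(24, 10, 24), c(24, 210, 24)), kind = "actin",
                    pf_segments = data.frame(s0 = 0, s1 = 200, pf = 13L))
man <- scene_manifest(list(fl), seed = 103)
act <- render_scene(man, dim = c(48, 224, 48), voxel_size = 1)
write_mrc(act, file.path(out, "actin.mrc"), invert_contrast = TRUE)
img <- t(project(act, n_slices = 15, axis = "z"))
cat(sprintf("actin layer line: %.2f nm\n",
            layer_line_spectrum(img, 1)$spacing_nm))
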