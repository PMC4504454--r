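#!/usr/bin/env Rscript
# Step 3 — the volume-corrected intracellular Mg2+ index.
#
# Demonstrates on rendered z-stacks that (a) the raw projection mean grows
# with branch calibre at fixed concentration while the /d-corrected index
# does not, (b) the index is linear in the planted concentration, and
# (c) the simplified projection estimator tracks the full numerical
# integral.

suppressMessages(library(mgsynapse))
dir.create("results", showWarnings = FALSE)

single_branch <- function(d, conc = 100, noise = TRUE) {
  br <- data.frame(x0 = 6, y0 = 6, angle = pi / 7, L = 8, d = d, mg = conc,
                   z_c = 0)
  scene_config(field_um = 12, branches = br, terminal_density = 0,
               mito_density = 0, branch_z_jitter_um = 0,
               background = if (noise) 20 else 0,
               poisson_scale = if (noise) 1 else 0,
               read_sd = if (noise) 1.5 else 0)
}

# (a) diameter series at fixed concentration, with measured diameters
rows <- lapply(c(0.5, 1, 1.5, 2, 2.5, 3), function(d) {
  sc <- build_scene(single_branch(d), seed = 1)
  st <- render_zstack(sc, "MgGrn")
  mask <- scene_branch_mask(sc, 1)
  proj <- max_project(st)
  ax <- with(sc$branches[1, ],
             c(x0 - cos(angle) * L / 2, y0 - sin(angle) * L / 2,
               x0 + cos(angle) * L / 2, y0 + sin(angle) * L / 2))
  d_meas <- measure_diameter(render_zstack(sc, "DIC"), ax)
  data.frame(d_true = d, d_measured = d_meas,
             raw_mean = mean(proj$data[mask]) -
               median(proj$data[!mask]),
             mg_index = mg_index_simple(proj, mask, d_meas,
                                        background = "auto"),
             mg_index_full = mg_index_full(st, mask, d_meas,
                                           background = "auto"))
})
dia <- do.call(rbind, rows)
write.csv(dia, "results/mg_diameter_series.csv", row.names = FALSE)
cv <- function(x) sd(x) / mean(x)
message("diameter series (fixed concentration):")
print(dia, digits = 3)
message(sprintf(
  "raw projection mean spans %.1f-fold across d; corrected index CV = %.1f %% (full: %.1f %%)",
  max(dia$raw_mean) / min(dia$raw_mean), 100 * cv(dia$mg_index),
  100 * cv(dia$mg_index_full)))

# (b) concentration series
cs <- c(25, 50, 100, 150, 200)
lin <- vapply(cs, function(conc) {
  sc <- build_scene(single_branch(1.2, conc), seed = 2)
  mg_index_simple(max_project(render_zstack(sc, "MgGrn")),
                  scene_branch_mask(sc, 1), 1.2, background = "auto")
}, numeric(1))
fit <- linfit(cs, lin)
write.csv(data.frame(concentration = cs, mg_index = lin),
          "results/mg_linearity.csv", row.names = FALSE)
message(sprintf("linearity: slope %.3f a.u. per concentration unit, R^2 = %.4f",
                fit$slope, fit$r_squared))

# (c) simple vs full estimator across a mixed-calibre AOI
cfg <- scene_config(field_um = 20, n_branches = 10, terminal_density = 0,
                    mito_density = 0, mg_concentration = c(40, 200))
sc <- build_scene(cfg, seed = 11)
st <- render_zstack(sc, "MgGrn")
masks <- lapply(seq_len(nrow(sc$branches)), function(i) scene_branch_mask(sc, i))
keep <- vapply(masks, function(m) sum(m) > 50, logical(1))
bm <- branch_measures(st, masks[keep], sc$branches$d[keep], background = "auto")
write.csv(bm, "results/mg_branch_measures.csv", row.names = FALSE)
message(sprintf("simple vs full estimator: Pearson r = %.4f over %d branches",
                cor(bm$mg_index, bm$mg_index_full), nrow(bm)))
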