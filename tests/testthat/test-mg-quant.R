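# Volume-corrected intracellular Mg2+ estimation.

test_that("indices are zero on empty signal and validate their inputs", {
  st <- image_stack(array(0, dim = c(30, 30, 6)))
  mask <- matrix(FALSE, 30, 30); mask[10:20, 10:20] <- TRUE
  expect_identical(mg_index_full(st, mask, d = 1), 0)
  expect_identical(mg_index_simple(max_project(st), mask, d = 1), 0)
  expect_error(mg_index_full(st, matrix(FALSE, 30, 30), 1),
               class = "mgsynapse_validation_error")
  expect_error(mg_index_full(st, mask, d = 0),
               class = "mgsynapse_validation_error")
  expect_error(mg_index_full(max_project(st), mask, 1),
               class = "mgsynapse_validation_error")
})

test_that("the index is linear in the planted concentration", {
  idx <- vapply(c(50, 100, 200), function(conc) {
    sc <- build_scene(single_branch_config(1, conc = conc), seed = 1)
    st <- render_zstack(sc, "MgGrn")
    mask <- scene_branch_mask(sc, 1)
    c(mg_index_simple(max_project(st), mask, 1), mg_index_full(st, mask, 1))
  }, numeric(2))
  expect_equal(idx[1, 2] / idx[1, 1], 2, tolerance = 0.01)
  expect_equal(idx[2, 3] / idx[2, 2], 2, tolerance = 0.01)
  fit <- linfit(c(50, 100, 200), idx[1, ])
  expect_gt(fit$r_squared, 0.99)
  expect_lt(abs(fit$intercept) / (fit$slope * 100), 0.02)
})

test_that("the /d correction removes the diameter dependence the raw mean has", {
  ds <- c(0.5, 1, 1.5, 2, 2.5, 3)
  res <- vapply(ds, function(d) {
    sc <- build_scene(single_branch_config(d), seed = 1)
    st <- render_zstack(sc, "MgGrn")
    mask <- scene_branch_mask(sc, 1)
    proj <- max_project(st)
    c(simple = mg_index_simple(proj, mask, d),
      full = mg_index_full(st, mask, d),
      raw = mean(proj$data[mask]))
  }, numeric(3))
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(res["simple", ]), 0.10)
  expect_lt(cv(res["full", ]), 0.10)
  # the uncorrected projection mean varies strongly and monotonically with d
  expect_gt(max(res["raw", ]) / min(res["raw", ]), 2)
  expect_true(all(diff(res["raw", ]) > 0))
})

test_that("simple and full estimators agree up to one global scale", {
  cfg <- scene_config(field_um = 20, n_branches = 10, terminal_density = 0,
                      mito_density = 0, mg_concentration = c(40, 200),
                      background = 0, poisson_scale = 0, read_sd = 0)
  sc <- build_scene(cfg, seed = 11)
  st <- render_zstack(sc, "MgGrn")
  masks <- lapply(seq_len(nrow(sc$branches)),
                  function(i) scene_branch_mask(sc, i))
  keep <- vapply(masks, function(m) sum(m) > 50, logical(1))
  bm <- branch_measures(st, masks[keep], sc$branches$d[keep])
  expect_gt(cor(bm$mg_index, bm$mg_index_full), 0.98)
  scale_fit <- lm(mg_index ~ 0 + mg_index_full, data = bm)
  expect_lt(max(abs(resid(scale_fit)) / bm$mg_index), 0.05)
})

test_that("axial profile check flags non-Gaussian profiles and demands planes", {
  sc <- build_scene(single_branch_config(1.5), seed = 1)
  st <- render_zstack(sc, "MgGrn")
  mask <- scene_branch_mask(sc, 1)
  ap <- axial_profile_check(st, mask)
  expect_gt(ap$r_squared, 0.99)
  expect_false(ap$flagged)
  # flat (un-blurred) profile: a slab with no axial PSF is model-violating
  flat <- image_stack(array(rep(c(0, 0, 1, 1, 1, 1, 1, 1, 1, 0, 0),
                                each = 900), dim = c(30, 30, 11)))
  apf <- axial_profile_check(flat, matrix(TRUE, 30, 30))
  expect_true(apf$flagged)
  thin <- image_stack(array(1, dim = c(10, 10, 3)))
  expect_error(axial_profile_check(thin, matrix(TRUE, 10, 10)),
               class = "mgsynapse_validation_error")
})

test_that("branch diameter is measured from the DIC image within tolerance", {
  for (d in c(1.0, 2.0)) {
    sc <- build_scene(single_branch_config(d, noise = TRUE), seed = 2)
    dm <- measure_diameter(render_zstack(sc, "DIC"), branch_axis_of(sc))
    expect_lt(abs(dm - d), if (d < 1.5) 0.15 else 0.2)
  }
  # zero-contrast image errors
  flat <- image_stack(matrix(10, 150, 150))
  expect_error(measure_diameter(flat, c(1, 1, 6, 6)),
               class = "mgsynapse_contrast_error")
  sc <- build_scene(single_branch_config(1), seed = 2)
  expect_error(measure_diameter(render_zstack(sc, "DIC"), c(-5, 0, 50, 50)),
               class = "mgsynapse_validation_error")
})

test_that("AOI level is the unweighted branch mean and errors when empty", {
  expect_identical(aoi_mg_level(c(1, 2, 3)), 2)
  expect_identical(aoi_mg_level(c(5)), 5)
  expect_error(aoi_mg_level(numeric(0)), class = "mgsynapse_validation_error")
  bm <- data.frame(mg_index = c(2, 4))
  expect_identical(aoi_mg_level(bm), 3)
})

test_that("AOIs planted at C and 2C recover a mean-index ratio of 2", {
  aoi_index <- function(conc, seed) {
    cfg <- scene_config(field_um = 16, n_branches = 8, terminal_density = 0,
                        mito_density = 0, mg_concentration = conc,
                        d_range = c(0.5, 2.5))
    sc <- build_scene(cfg, seed = seed)
    st <- render_zstack(sc, "MgGrn")
    masks <- lapply(seq_len(nrow(sc$branches)),
                    function(i) scene_branch_mask(sc, i))
    keep <- vapply(masks, function(m) sum(m) > 50, logical(1))
    bm <- branch_measures(st, masks[keep], sc$branches$d[keep],
                          background = "auto")
    aoi_mg_level(bm)
  }
  r <- vapply(1:3, function(s) {
    aoi_index(200, 800 + s) / aoi_index(100, 800 + s)
  }, numeric(1))
  expect_equal(mean(r), 2, tolerance = 0.05)
})
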