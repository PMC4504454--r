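# The scene generator: determinism, degenerate cases, sampling laws, and
# the physical normalizations downstream estimators rely on.

test_that("identical config and seed give identical scenes and pixels", {
  cfg <- scene_config(field_um = 10)
  s1 <- build_scene(cfg, seed = 7)
  s2 <- build_scene(cfg, seed = 7)
  expect_identical(s1$terminals, s2$terminals)
  expect_identical(s1$mitochondria, s2$mitochondria)
  i1 <- render_zstack(s1, "MAP2")
  i2 <- render_zstack(s2, "MAP2")
  expect_identical(i1$data, i2$data)
  p1 <- render_fm_pair(s1, protocol_5ap(), "5AP")
  p2 <- render_fm_pair(s2, protocol_5ap(), "5AP")
  expect_identical(p1$F1$data, p2$F1$data)
  expect_false(identical(build_scene(cfg, seed = 8)$terminals, s1$terminals))
})

test_that("degenerate terminal settings behave as configured", {
  cfg0 <- scene_config(field_um = 10, terminal_density = 0)
  expect_identical(nrow(build_scene(cfg0, seed = 1)$terminals), 0L)

  cfg1 <- scene_config(field_um = 14, terminal_density = 1.5, p_fun = 1)
  sc <- build_scene(cfg1, seed = 2)
  expect_gt(nrow(sc$terminals), 100)
  expect_true(all(sc$terminals$functional))

  cfgp0 <- scene_config(field_um = 14, terminal_density = 1.5, p_fun = 0)
  expect_false(any(build_scene(cfgp0, seed = 2)$terminals$functional))
})

test_that("invalid configurations are rejected with validation errors", {
  expect_error(scene_config(field_um = -5), class = "mgsynapse_validation_error")
  expect_error(scene_config(theta = 0), class = "mgsynapse_validation_error")
  expect_error(scene_config(p_fun = 1.4), class = "mgsynapse_validation_error")
  expect_error(scene_config(terminal_density = -1),
               class = "mgsynapse_validation_error")
  expect_error(scene_config(d_range = c(-0.1, 2)),
               class = "mgsynapse_validation_error")
})

test_that("terminal counts follow the planted Poisson law", {
  cfg <- scene_config(field_um = 14, terminal_density = 1.38)
  counts <- areas <- numeric(120)
  for (s in seq_len(120)) {
    sc <- build_scene(cfg, seed = 9000 + s)
    counts[s] <- nrow(sc$terminals)
    areas[s] <- sc$dendrite_area_um2
  }
  lambda <- 1.38 * areas
  # each draw within 4 sd of its own mean; the pooled mean within 4 se
  expect_true(all(abs(counts - lambda) < 4 * sqrt(lambda) + 3))
  z <- sum(counts - lambda) / sqrt(sum(lambda))
  expect_lt(abs(z), 4)
})

test_that("terminals lie on the dendrite footprint and quantities are positive", {
  cfg <- scene_config(field_um = 14)
  sc <- build_scene(cfg, seed = 4)
  t <- sc$terminals
  px <- pmin(pmax(round(t$x_um / cfg$theta) + 1, 1), sc$nx)
  py <- pmin(pmax(round(t$y_um / cfg$theta) + 1, 1), sc$ny)
  on_mask <- sc$dendrite_mask[cbind(py, px)]
  expect_gt(mean(on_mask), 0.95)  # sub-pixel jitter can cross an edge pixel
  expect_true(all(t$pool > 0))
  expect_true(all(t$q_SYP > 0))
  expect_true(all(sc$mitochondria$true_ratio > 0))
})

test_that("rendered punctum fluorescence conserves the planted quantity", {
  img <- planted_spot_image(c(3, 7, 5), c(3, 4, 8), q = c(500, 2000, 1200))
  expect_equal(sum(img$data), 3700, tolerance = 0.01)
  # per-spot, via photometry on the clean image
  p <- detect_puncta(img, threshold_k = 3)
  expect_identical(nrow(p), 3L)
  expect_equal(sort(p$F), sort(c(500, 2000, 1200)), tolerance = 0.05)
})

test_that("a zero-branch scene renders MgGrn as pure noise about baseline", {
  cfg <- scene_config(field_um = 8, n_branches = 0, terminal_density = 0,
                      mito_density = 0)
  sc <- build_scene(cfg, seed = 1)
  st <- render_zstack(sc, "MgGrn")
  expect_equal(mean(st$data), cfg$background, tolerance = 0.05)
  expect_lt(sd(st$data), 3 * sqrt(cfg$background))
})

test_that("unknown channels are rejected with the valid channel list", {
  sc <- build_scene(scene_config(field_um = 8), seed = 1)
  err <- tryCatch(render_zstack(sc, "GFP"), error = function(e) e)
  expect_s3_class(err, "mgsynapse_channel_error")
  expect_match(conditionMessage(err), "MgGrn")
  expect_error(render_zstack(sc, "IF:NotAProtein"),
               class = "mgsynapse_channel_error")
})

test_that("noiseless cylinder axial profile is Gaussian with shared shape", {
  profs <- list()
  for (d in c(0.5, 1.5, 3)) {
    sc <- build_scene(single_branch_config(d), seed = 1)
    st <- render_zstack(sc, "MgGrn")
    ap <- axial_profile_check(st, scene_branch_mask(sc, 1))
    expect_gt(ap$r_squared, 0.99)
    profs[[as.character(d)]] <- ap$profile / max(ap$profile)
  }
  # normalized profiles of different calibres overlap
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(max(abs(profs[[i]] - profs[[j]])), 0.1)
  }
})

test_that("total integrated fluorescence scales with cylinder volume (d^2 L)", {
  tot <- vapply(c(0.5, 2.0), function(d) {
    sc <- build_scene(single_branch_config(d), seed = 1)
    sum(render_zstack(sc, "MgGrn")$data)
  }, numeric(1))
  expect_equal(tot[2] / tot[1], (2.0 / 0.5)^2, tolerance = 0.05)
})

test_that("FM pairs carry releasable signal only for responding terminals", {
  cfg <- scene_config(field_um = 16, p_fun = 0)
  sc <- build_scene(cfg, seed = 3)
  pr <- render_fm_pair(sc, protocol_5ap(), "5AP")
  df <- delta_f(pr$F1, pr$F2)
  # noise only: the deltaF image carries no punctum-scale signal
  expect_identical(nrow(detect_puncta(df, threshold_k = 6)), 0L)
  expect_lt(mean(df$data), 3 * sqrt(2 * cfg$background))
  # same scene under maximal stimulation: every releasable terminal visible
  pr6 <- render_fm_pair(sc, protocol_600ap(), "600AP")
  p6 <- detect_puncta(delta_f(pr6$F1, pr6$F2))
  # the dimmest tail of the lognormal pool sits near the detection limit
  expect_gt(recovery_rate(p6, sc$terminals$x_um, sc$terminals$y_um), 0.95)
})

test_that("the 5AP-responding fraction follows the planted Bernoulli law", {
  cfg <- scene_config(field_um = 18, p_fun = 0.5, terminal_density = 1.5)
  hits <- trials <- 0
  for (s in 1:3) {
    sc <- build_scene(cfg, seed = 600 + s)
    trials <- trials + nrow(sc$terminals)
    hits <- hits + sum(sc$terminals$functional)
  }
  expect_gt(trials, 400)
  p_hat <- hits / trials
  expect_lt(abs(p_hat - 0.5), 2.5 * sqrt(0.25 / trials))
})

test_that("EM fields have Poisson-planted counts and render empty at zero", {
  f0 <- render_em_field(0, 4.2, seed = 1)
  expect_identical(f0$true_count, 0L)
  expect_identical(count_em_mitochondria(f0$image), 0L)
  counts <- vapply(1:150, function(s) {
    render_em_field(0.37, 4.2, seed = s)$true_count
  }, integer(1))
  lambda <- 0.37 * 4.2
  expect_lt(abs(mean(counts) - lambda) / (sqrt(lambda / 150)), 4)
})

test_that("scene ground truth serializes to JSON and reads back", {
  sc <- build_scene(scene_config(field_um = 8), seed = 5)
  path <- tempfile(fileext = ".json")
  write_scene_json(sc, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$dendrite_area_um2, sc$dendrite_area_um2)
  expect_equal(length(back$terminals$x_um), nrow(sc$terminals))
  expect_equal(back$theta, sc$config$theta)
})
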