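# Shared imaging primitives: projection, punctum detection, MAP2 area,
# registration, punctum matching.

test_that("max projection matches a brute-force per-pixel loop", {
  set.seed(1)
  arr <- array(runif(20 * 18 * 6), dim = c(20, 18, 6))
  st <- image_stack(arr, theta = 0.1)
  proj <- max_project(st)
  brute <- matrix(0, 20, 18)
  for (i in 1:20) for (j in 1:18) brute[i, j] <- max(arr[i, j, ])
  expect_identical(proj$data, brute)

  cst <- image_stack(array(0.7, dim = c(5, 5, 3)))
  expect_true(all(max_project(cst)$data == 0.7))

  one <- array(0, dim = c(6, 6, 4)); one[, , 3] <- matrix(runif(36), 6)
  expect_identical(max_project(image_stack(one))$data, one[, , 3])

  expect_warning(p2 <- max_project(proj), "identity")
  expect_identical(p2$data, proj$data)
})

test_that("planted well-separated spots are recovered exactly with subpixel centroids", {
  xs <- c(2, 5, 8, 3, 7); ys <- c(2, 3, 5, 7.5, 8)
  img <- planted_spot_image(xs, ys, q = rep(2000, 5), noise_sd = 3.2, seed = 2)
  # k = 5.5: on a mostly empty field the expected maximum of smoothed noise
  # approaches 4-5 robust SDs, so the routine threshold would admit a few
  # noise maxima by design
  p <- detect_puncta(img, threshold_k = 5.5)
  expect_identical(nrow(p), 5L)
  truth <- puncta_set(xs, ys, F = 1, area_um2 = 0.1)
  m <- match_puncta(truth, p, radius = 0.2)
  expect_identical(nrow(m$pairs), 5L)
  expect_true(all(m$pairs$dist_um < 0.05754))  # within 1 px
})

test_that("detection count is monotone non-increasing in the threshold", {
  set.seed(3)
  img <- planted_spot_image(runif(30, 1, 9), runif(30, 1, 9),
                            q = rlnorm(30, log(1200), 0.5), noise_sd = 3, seed = 3)
  ns <- vapply(c(2, 3, 4, 6, 9), function(k) {
    nrow(detect_puncta(img, threshold_k = k))
  }, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("empty and degenerate detection inputs behave", {
  z <- image_stack(matrix(0, 80, 80), theta = 0.1)
  expect_identical(nrow(detect_puncta(z)), 0L)
  expect_identical(nrow(detect_puncta(image_stack(matrix(5, 60, 60)))), 0L)
  expect_error(detect_puncta(z, min_sigma = -1),
               class = "mgsynapse_validation_error")
  expect_error(detect_puncta(z, min_sigma = 0.4, max_sigma = 0.2),
               class = "mgsynapse_validation_error")
})

test_that("MAP2 area is accurate, equalization-invariant and safe on empty input", {
  sc <- build_scene(scene_config(field_um = 14), seed = 11)
  img <- render_zstack(sc, "MAP2")
  A <- measure_map2_area(img)
  mask <- attr(A, "mask")
  truth <- sc$dendrite_mask
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gt(iou, 0.8)
  expect_lt(abs(as.numeric(A) - sc$dendrite_area_um2) / sc$dendrite_area_um2,
            0.15)
  # gain invariance: doubling intensities leaves the area unchanged
  img2 <- image_stack(img$data * 2, theta = img$theta)
  expect_equal(as.numeric(measure_map2_area(img2)), as.numeric(A),
               tolerance = 1e-8)
  expect_warning(A0 <- measure_map2_area(image_stack(matrix(0, 50, 50))),
                 "area = 0")
  expect_identical(as.numeric(A0), 0)
})

test_that("rigid registration recovers planted shifts and rotations", {
  sc <- build_scene(scene_config(field_um = 14), seed = 21)
  ref <- render_zstack(sc, "DIC")
  n <- nrow(ref$data); ctr <- c((n - 1) / 2, (n - 1) / 2)
  tf_plant <- transform2d(angle = 1.5 * pi / 180, t = c(3.4, -2.1),
                          center = ctr, theta = ref$theta)
  mov <- apply_transform(ref, tf_plant)
  tf <- register(ref, mov, "rigid")
  # estimate inverts the planted map: compose and measure residual
  gpx <- seq(40, n - 40, by = 25); pts <- expand.grid(x = gpx, y = gpx)
  q1 <- mgsynapse:::transform_coords(tf, pts$x, pts$y)
  q2 <- mgsynapse:::transform_coords(tf_plant, q1$x, q1$y)
  rms <- sqrt(mean((q2$x - pts$x)^2 + (q2$y - pts$y)^2))
  expect_lt(rms, 0.5)
  expect_lt(abs(abs(tf$angle) - 1.5 * pi / 180), 0.2 * pi / 180)

  # identity case
  tf0 <- register(ref, ref, "rigid")
  expect_lt(sqrt(sum(tf0$t^2)), 0.1)
  expect_lt(abs(tf0$angle), 0.05 * pi / 180)
})

test_that("featureless images are rejected as unregistrable", {
  flat <- image_stack(matrix(1, 120, 120))
  expect_error(register(flat, flat, "rigid"),
               class = "mgsynapse_registration_error")
  set.seed(1)
  noise <- image_stack(matrix(rnorm(120^2), 120))
  shifted <- image_stack(matrix(rnorm(120^2), 120))
  expect_error(register(noise, shifted, "rigid"),
               class = "mgsynapse_registration_error")
})

test_that("elastic registration recovers a planted smooth warp", {
  sc <- build_scene(scene_config(field_um = 18, n_branches = 16), seed = 40)
  ref <- render_zstack(sc, "DIC")
  n <- nrow(ref$data)
  gx <- seq(0, n - 1, length.out = 12); gy <- gx
  disp <- list(gx = gx, gy = gy,
               dx = outer(sin(gy / n * 2 * pi), cos(gx / n * 2 * pi)) * 2,
               dy = outer(cos(gy / n * 2 * pi), sin(gx / n * 2 * pi)) * 2)
  tf_plant <- transform2d(t = c(3, -2), center = c((n - 1) / 2, (n - 1) / 2),
                          theta = ref$theta, disp = disp)
  mov <- apply_transform(ref, tf_plant)
  gpx <- seq(40, n - 40, by = 20); pts <- expand.grid(x = gpx, y = gpx)
  resid <- function(tf) {
    q1 <- mgsynapse:::transform_coords(tf, pts$x, pts$y)
    q2 <- mgsynapse:::transform_coords(tf_plant, q1$x, q1$y)
    sqrt(mean((q2$x - pts$x)^2 + (q2$y - pts$y)^2))
  }
  r_rigid <- resid(register(ref, mov, "rigid"))
  r_elast <- resid(register(ref, mov, "elastic"))
  expect_lt(r_elast, 0.75)
  expect_lt(r_elast, r_rigid)
})

test_that("punctum matching is mutual, symmetric and jitter-tolerant", {
  set.seed(5)
  A <- puncta_set(runif(100, 0, 40), runif(100, 0, 40), F = 1, area_um2 = .1)
  expect_identical(nrow(match_puncta(A, A)$pairs), 100L)
  expect_true(all(match_puncta(A, A)$pairs$dist_um == 0))

  none <- match_puncta(puncta_set(), A)
  expect_identical(nrow(none$pairs), 0L)
  expect_identical(none$unmatched_b, 1:100)

  B <- A
  B$x_um <- B$x_um + rnorm(100, 0, 0.1 / sqrt(2))
  B$y_um <- B$y_um + rnorm(100, 0, 0.1 / sqrt(2))
  mAB <- match_puncta(A, B, radius = 0.5)
  expect_gte(nrow(mAB$pairs), 98L)
  # brute-force oracle: mutual nearest neighbours by direct search
  d2 <- outer(A$x_um, B$x_um, "-")^2 + outer(A$y_um, B$y_um, "-")^2
  oracle <- sum(vapply(seq_len(100), function(i) {
    j <- which.min(d2[i, ])
    which.min(d2[, j]) == i && d2[i, j] <= 0.25
  }, logical(1)))
  expect_identical(nrow(mAB$pairs), as.integer(oracle))
  # symmetry
  mBA <- match_puncta(B, A, radius = 0.5)
  expect_identical(nrow(mBA$pairs), nrow(mAB$pairs))
  expect_identical(mBA$pairs$i, sort(mAB$pairs$j))

  expect_error(match_puncta(A, B, radius = 0),
               class = "mgsynapse_validation_error")
})
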