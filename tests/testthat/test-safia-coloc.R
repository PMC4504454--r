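# SAFIA multi-round colocalization and the Q/sum-Q indices.

# One imaging session of a scene: DIC landmark + protein channels, rigidly
# offset to emulate re-mounting between staining rounds.
make_round <- function(scene, chans, shift = c(0, 0), rot = 0) {
  dic <- render_zstack(scene, "DIC")
  n <- nrow(dic$data)
  tf <- transform2d(angle = rot * pi / 180, t = shift,
                    center = c((n - 1) / 2, (n - 1) / 2), theta = dic$theta)
  imgs <- c(list(dic),
            lapply(chans, function(ch) render_zstack(scene, paste0("IF:", ch))))
  if (rot != 0 || any(shift != 0)) imgs <- lapply(imgs, apply_transform, tf = tf)
  list(dic = imgs[[1L]], channels = setNames(imgs[-1L], chans))
}

safia_scene <- function(seed = 50, coupling = 1, field = 18) {
  build_scene(scene_config(field_um = field, terminal_density = 1.0,
                           p_fun = 0.6,
                           nonfunctional_protein_factor = coupling),
              seed = seed)
}

test_that("round sets validate channel uniqueness and pixel size", {
  sc <- safia_scene()
  r1 <- make_round(sc, c("SYP", "SYT1"))
  expect_error(round_set(list(r1, make_round(sc, c("SYT1", "RIM1")))),
               class = "mgsynapse_validation_error")
  bad <- make_round(sc, "RIM1")
  bad$channels$RIM1$theta <- 0.1
  expect_error(round_set(list(r1, bad)), class = "mgsynapse_validation_error")
})

test_that("a single round aligns to itself with an identity transform", {
  sc <- safia_scene()
  rs <- align_rounds(round_set(list(make_round(sc, c("SYP", "SYT1")))))
  tf <- rs$rounds[[1L]]$transform
  expect_lt(sqrt(sum(tf$t^2)), 0.1)
  expect_lt(abs(tf$angle), 0.05 * pi / 180)
})

test_that("planted inter-round shifts are corrected to sub-pixel punctum error", {
  sc <- safia_scene(seed = 51)
  rs <- round_set(list(
    make_round(sc, c("SYP", "SYT1")),
    make_round(sc, c("RIM1", "Munc13-1"), shift = c(4, -3), rot = 1.0),
    make_round(sc, c("ELKS", "Syntaxin1"), shift = c(-3, 5), rot = -0.7)))
  al <- align_rounds(rs)
  # puncta detected on aligned channels should sit on the true positions
  for (ch in c("SYT1", "RIM1", "Syntaxin1")) {
    img <- mgsynapse:::all_channels(al)[[ch]]
    p <- detect_puncta(img)
    truth <- puncta_set(sc$terminals$x_um, sc$terminals$y_um, F = 1,
                        area_um2 = .1)
    m <- match_puncta(truth, p, radius = 0.3)
    expect_gt(nrow(m$pairs) / nrow(truth), 0.9)
    rms_px <- sqrt(mean(m$pairs$dist_um^2)) / img$theta
    expect_lt(rms_px, 0.75)
  }
})

test_that("an unregistrable round is reported by index", {
  sc <- safia_scene()
  r1 <- make_round(sc, c("SYP", "SYT1"))
  r2 <- make_round(sc, "RIM1")
  r2$dic <- image_stack(matrix(1, nrow(r2$dic$data), ncol(r2$dic$data)),
                        theta = r2$dic$theta)
  err <- tryCatch(align_rounds(round_set(list(r1, r2))), error = function(e) e)
  expect_s3_class(err, "mgsynapse_registration_error")
  expect_match(conditionMessage(err), "round 2")
})

test_that("terminal tables recover planted per-terminal quantities", {
  sc <- safia_scene(seed = 52)
  rs <- align_rounds(round_set(list(
    make_round(sc, c("SYP", "SYT1")),
    make_round(sc, c("RIM1", "ELKS"), shift = c(3, -2)))))
  pr5 <- render_fm_pair(sc, protocol_5ap(), "5AP")
  tab <- build_terminal_table(rs, "SYP",
                              fm = list(FM5AP = delta_f(pr5$F1, pr5$F2)))
  expect_s3_class(tab, "TerminalTable")
  expect_true(all(c("q_SYT1", "q_RIM1", "q_ELKS", "fm_FM5AP", "label") %in%
                    names(tab)))
  truth <- puncta_set(sc$terminals$x_um, sc$terminals$y_um, F = 1,
                      area_um2 = .1)
  rows <- puncta_set(tab$x_um, tab$y_um, F = 1, area_um2 = .1)
  m <- match_puncta(truth, rows, radius = 0.35)
  expect_gt(nrow(m$pairs), 100)
  for (ch in c("SYT1", "RIM1", "ELKS")) {
    r <- cor(sc$terminals[[paste0("q_", ch)]][m$pairs$i],
             tab[[paste0("q_", ch)]][m$pairs$j])
    expect_gt(r, 0.9)
  }
  expect_true(all(
    tab$functional[m$pairs$j] == sc$terminals$functional[m$pairs$i]) ||
      mean(tab$functional[m$pairs$j] ==
             sc$terminals$functional[m$pairs$i]) > 0.95)
  expect_error(build_terminal_table(rs, "VGLUT1"),
               class = "mgsynapse_validation_error")
})

test_that("permuting the IF rounds leaves the terminal table identical", {
  sc <- safia_scene(seed = 53, field = 12)
  r1 <- make_round(sc, c("SYP", "SYT1"))
  r2 <- make_round(sc, c("RIM1", "ELKS"), shift = c(2, 1))
  r3 <- make_round(sc, c("Rab3a", "Syntaxin1"), shift = c(-2, 3))
  t123 <- build_terminal_table(align_rounds(round_set(list(r1, r2, r3))),
                               "SYP")
  t132 <- build_terminal_table(align_rounds(round_set(list(r1, r3, r2))),
                               "SYP")
  expect_identical(sort(names(t123)), sort(names(t132)))
  expect_identical(t123[sort(names(t123))], t132[sort(names(t132))])
})

test_that("Q normalization is exact for the control group", {
  ctrl <- rbind(c(SYP = 10, SYT1 = 4), c(SYP = 14, SYT1 = 8))
  cm <- colMeans(ctrl)
  q1 <- protein_q(ctrl[1, ], cm); q2 <- protein_q(ctrl[2, ], cm)
  expect_equal(unname((q1 + q2) / 2), c(1, 1))
  expect_equal(protein_q(cm, cm), c(SYP = 1, SYT1 = 1))
  expect_error(protein_q(c(SYP = 1), c(SYT1 = 2)),
               class = "mgsynapse_validation_error")
  expect_error(protein_q(c(SYP = 1), c(SYP = 0)),
               class = "mgsynapse_validation_error")
})

test_that("sum-Q adds exactly the six Ca2+-sensitivity proteins", {
  q <- c(SYT1 = 1, Rab3a = 1, RIM1 = 1, `Munc13-1` = 1, ELKS = 1,
         Syntaxin1 = 1, SYP = 2, Bassoon = 7)
  s <- sum_q(q)
  expect_identical(s$sum_q, 6)
  expect_identical(s$ratio_to_syp, 3)
  expect_identical(sum_q(rev(q))$sum_q, 6)
  err <- tryCatch(sum_q(q[-1]), error = function(e) e)
  expect_s3_class(err, "mgsynapse_validation_error")
  expect_match(conditionMessage(err), "SYT1")
  expect_true(is.na(sum_q(q[names(q) != "SYP"])$ratio_to_syp))
})

test_that("the end-to-end sum-Q vs planted mitochondrial density slope is recovered", {
  res <- run_pipeline(list(stages = "safia",
                           scene = list(field_um = 14),
                           safia = list(n_scenes = 6L,
                                        mito_density_range = c(0.15, 0.45),
                                        protein_mito_slope = 2.0)),
                      out_dir = file.path(tempdir(), "safia_e2e"), seed = 3)
  expect_identical(res$status, 0L)
  s <- res$summary$safia$sumq_vs_planted
  expect_lt(abs(s$slope - s$planted_coefficient) / s$planted_coefficient,
            0.15)
  expect_gt(s$r_squared, 0.8)
})

test_that("a planted functionality-protein coupling is detected and the null is calibrated", {
  # statistical behaviour is tested on directly constructed tables
  make_table <- function(n, coupling, seed) {
    set.seed(seed)
    fun <- runif(n) < 0.6
    tab <- data.frame(terminal = seq_len(n), x_um = runif(n), y_um = runif(n),
                      F_structural = rlnorm(n, 7, 0.3), check.names = FALSE)
    for (p in ca_sensitivity_proteins()) {
      q <- rlnorm(n, log(2000), 0.35)
      q[!fun] <- q[!fun] * coupling
      tab[[paste0("q_", p)]] <- q
    }
    tab$functional <- fun
    tab$label <- ifelse(fun, "functional", "nonfunctional")
    class(tab) <- c("TerminalTable", "data.frame")
    tab
  }
  planted <- profile_nonfunctional(make_table(300, 0.5, 1))
  expect_true(all(planted$summary$p_value < 0.05))
  expect_true(all(planted$summary$mean_nonfunctional <
                    planted$summary$mean_functional))
  # null calibration on the total Ca2+-protein content: no coupling ->
  # no significant sum-Q difference in at least 90% of seeds
  sumq_sig <- vapply(1:50, function(s) {
    tab <- make_table(300, 1, 100 + s)
    tot <- rowSums(tab[, paste0("q_", ca_sensitivity_proteins())])
    compare_groups(tot[tab$functional], tot[!tab$functional], "t")$p_value <
      0.05
  }, logical(1))
  expect_gte(mean(!sumq_sig), 0.9)
  # all-functional table flags the absent class
  all_fun <- make_table(50, 1, 3)
  all_fun$label <- "functional"; all_fun$functional <- TRUE
  pf <- profile_nonfunctional(all_fun)
  expect_identical(pf$absent_class, "nonfunctional")
  expect_null(pf$summary)
})
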