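test_that("reference bank has cycle/TR standardised lagged models", {
  d <- test_design()
  bank <- build_reference_models(d)
  expect_equal(bank$n_lags, 25)
  expect_equal(dim(bank$models), c(182L, 25L))
  expect_equal(colMeans(bank$models), rep(0, 25), tolerance = 1e-10)
  expect_equal(apply(bank$models, 2, sd), rep(1, 25), tolerance = 1e-10)
  d_bad <- d
  d_bad$tr_seconds <- 4 # 50 s cycle / 4 s TR is not an integer lag count
  expect_error(build_reference_models(d_bad), "divisible")

  # self-alignment: each lag-k model wins lag k when fed back as data
  zz <- crosscorrelate(t(bank$models[, c(1, 6, 25)]), bank)
  expect_equal(max.col(zz$z) - 1L, c(0L, 5L, 24L))
})

test_that("crosscorrelate computes Fisher z with documented conventions", {
  d <- test_design()
  bank <- build_reference_models(d)
  # atanh closed form: construct data correlating 0.5 with a model
  m <- bank$models[, 3]
  set.seed(4)
  resid <- residuals(lm(rnorm(length(m)) ~ m))
  x <- 0.5 * m + sqrt(1 - 0.25) * resid / sd(resid) # exact r = 0.5 after scaling
  x <- x * 1 # voxel time course
  cm <- crosscorrelate(rbind(x), bank)
  expect_equal(cm$r[1, 3], 0.5, tolerance = 1e-10)
  expect_equal(cm$z[1, 3], atanh(0.5), tolerance = 1e-10) # 0.5493
  # constant voxel -> z = 0 everywhere
  cm0 <- crosscorrelate(rbind(rep(7, 182)), bank)
  expect_true(all(cm0$z == 0))
  # length mismatch rejected
  expect_error(crosscorrelate(matrix(0, 2, 100), bank), "does not match")
  # Monte-Carlo null: mean z per lag ~ 0 (scaled to 4000 noise voxels)
  set.seed(9)
  zn <- crosscorrelate(matrix(rnorm(4000 * 182), 4000), bank)$z
  se <- apply(zn, 2, sd) / sqrt(4000)
  expect_true(all(abs(colMeans(zn)) < 3 * se))
})

test_that("winner-take-all finger maps recover noiseless ground truth", {
  d <- test_design()
  bank <- build_reference_models(d)
  su <- test_subject(sigma = 0)
  maps <- lapply(su$tw_runs, crosscorrelate, bank = bank)
  fmap <- combine_runs_to_fingers(maps, d)
  hand <- hand_mask(su)
  acc <- mean(fmap$winner_finger[hand] == su$truth$preferred_finger[hand])
  expect_gte(acc, 0.99)

  # somatotopic gradient axis ordering reproduced
  idx <- arrayInd(seq_len(prod(su$truth$grid_shape)), su$truth$grid_shape)
  mean_x <- tapply(idx[hand, 1], fmap$winner_finger[hand], mean)
  expect_true(all(diff(mean_x) > 0))

  # direction equivalence: forward-only and backward-only winner maps agree
  # on noiseless data (the onset-centred lag grouping makes single-direction
  # assignment unbiased)
  dirs <- vapply(maps, function(m) m$direction, "")
  f_only <- combine_runs_to_fingers(maps[dirs == "forward"], d)
  b_only <- combine_runs_to_fingers(maps[dirs == "backward"], d)
  expect_gte(mean(f_only$winner_finger[hand] == b_only$winner_finger[hand]), 0.99)

  # argmax and duplication idempotence
  toy <- list(structure(list(z = rbind(c(rep(3, 5), rep(1, 5), rep(0, 15))),
                             r = NULL, direction = "forward"),
                        class = "lag_correlation_map"))
  fm1 <- combine_runs_to_fingers(toy, d)
  expect_equal(fm1$winner_finger, 1L)
  fm2 <- combine_runs_to_fingers(c(toy, toy), d)
  expect_equal(fm2$finger_z, fm1$finger_z)
  expect_error(combine_runs_to_fingers(list(), d), "at least one")
})

test_that("lag winner map aligns backward runs onto forward phase", {
  d <- test_design()
  bank <- build_reference_models(d)
  su <- test_subject(sigma = 0)
  maps <- lapply(su$tw_runs, crosscorrelate, bank = bank)
  dirs <- vapply(maps, function(m) m$direction, "")
  lw <- lag_winner_map(maps[dirs == "forward"], maps[dirs == "backward"])
  hand <- hand_mask(su)
  # finger-1 voxels win a lag in the first finger's (cyclic, onset-centred)
  # lag group {23, 24, 0, 1, 2}
  v1 <- hand & su$truth$preferred_finger == 1
  expect_true(all(lw$winner_lag[v1] %in% c(23, 24, 0, 1, 2)))
  # lag winners increase along the somatotopic gradient
  pf <- su$truth$preferred_finger[hand]
  expect_true(all(diff(tapply(lw$winner_lag[hand], pf, mean)) > 0))

  # all-equal input: deterministic lag-0 winner, tie flagged
  zmap <- function(z) structure(list(z = z, direction = "forward"),
                                class = "lag_correlation_map")
  z0 <- matrix(0, 2, 25)
  lw0 <- lag_winner_map(list(zmap(z0)), list(zmap(z0)))
  expect_equal(lw0$winner_lag, c(0L, 0L))
  expect_true(all(lw0$tie_flag))
  expect_error(lag_winner_map(list(), list(zmap(z0))), "forward")
})

test_that("FDR thresholding controls false positives and matches BH", {
  d <- test_design()
  su <- test_subject(sigma = 0)
  bank <- build_reference_models(d)
  fmap <- combine_runs_to_fingers(lapply(su$tw_runs, crosscorrelate, bank = bank), d)
  expect_error(fdr_threshold(fmap, q = 0.05, n_eff = 182,
                             mask = rep(FALSE, 240)), "empty")
  fm <- fdr_threshold(fmap, q = 0.05, n_eff = 182, mask = hand_mask(su))
  expect_true(all(fm$significant[hand_mask(su)])) # noiseless: everything survives
  expect_true(all(!fm$significant[!hand_mask(su)]))

  # CSF null control: average significant fraction <= q over noise maps
  set.seed(21)
  n_sims <- 60
  fp <- replicate(n_sims, {
    z <- matrix(rnorm(300 * 25, sd = 1 / sqrt(179)), 300, 25)
    m <- structure(list(z = z, direction = "forward"), class = "lag_correlation_map")
    f <- combine_runs_to_fingers(list(m), d)
    mean(fdr_threshold(f, q = 0.05, n_eff = 182)$significant)
  })
  # winner-z selection makes the test conservative relative to a plain BH on
  # one test per voxel; the false-positive proportion must stay below q
  expect_lte(mean(fp), 0.05 + 3 * sd(fp) / sqrt(n_sims))
})

test_that("probability maps count subjects per finger and voxel", {
  d <- test_design()
  su <- test_subject(sigma = 0)
  bank <- build_reference_models(d)
  fm <- combine_runs_to_fingers(lapply(su$tw_runs, crosscorrelate, bank = bank), d)
  fm <- z_threshold(fm, 2, n_eff = 182, mask = hand_mask(su))
  pm <- probability_map(rep(list(fm), 18), group = "control")
  expect_true(all(pm$counts %in% c(0L, 18L)))
  expect_equal(pm$n_subjects, 18)
  # single subject: counts equal the binarised map
  pm1 <- probability_map(list(fm))
  for (f in 1:5) {
    expect_equal(pm1$counts[, f] == 1, fm$significant & fm$winner_finger == f)
  }
  # disjoint maps from 2 subjects: max count 1 (fixed-point-free relabelling)
  fm2 <- fm
  fm2$winner_finger <- c(2L, 3L, 4L, 5L, 1L)[fm$winner_finger]
  expect_lte(max(probability_map(list(fm, fm2))$counts), 1L)
  # grid mismatch rejected
  fm3 <- fm
  fm3$winner_finger <- fm$winner_finger[1:10]
  expect_error(probability_map(list(fm, fm3)), "grid")
})

test_that("winner accuracy degrades monotonically in deterioration", {
  d <- test_design()
  bank <- build_reference_models(d)
  accs <- sapply(c(0, 0.5, 1), function(dl) {
    mean(sapply(1:3, function(s) {
      cfg <- test_config(sigma = 0.5)
      tr <- ground_truth_map(cfg$grid_shape, tuning_width = cfg$tuning_width)
      grp <- if (dl == 0) "control" else if (dl == 1) "one_hander" else "sci"
      sp <- subject_spec(grp, dl, years_since_sci = if (grp == "sci") 17 else NA)
      runs <- lapply(c("forward", "backward"), function(dir) {
        m <- simulate_run(sp, tr, tw_run_descriptor(d, dir), d,
                          noise = list(sigma = 0.5), seed = s * 10 + (dir == "forward"))
        attr(m, "direction") <- dir
        m
      })
      fm <- combine_runs_to_fingers(lapply(runs, crosscorrelate, bank = bank), d)
      hand <- tr$roi == "hand_S1"
      mean(fm$winner_finger[hand] == tr$preferred_finger[hand])
    }))
  })
  expect_true(all(diff(accs) <= 0))
  expect_gt(accs[1], 0.9)
  expect_lt(accs[3], 0.5)
})

test_that("lattice smoothing preserves constants and reduces roughness", {
  set.seed(2)
  x <- rnorm(10 * 6 * 4)
  s <- smooth_lattice(x, c(10, 6, 4), fwhm = 2)
  expect_lt(var(s), var(x))
  expect_equal(smooth_lattice(rep(3, 240), c(10, 6, 4), 2), rep(3, 240),
               tolerance = 1e-12)
})
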