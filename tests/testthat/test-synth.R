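test_that("design invariants hold and bad designs are rejected", {
  d <- test_design()
  expect_equal(d$tw_volumes_per_run * d$tr_seconds, 364) # 6 min 4 s
  expect_equal(d$bd_volumes_per_run * d$tr_seconds, 254) # 4 min 14 s
  expect_equal(d$tw_cycle_seconds, 5 * d$tw_block_on)
  expect_equal(d$baseline_pad_seconds, 14)
  expect_error(design_spec(tw_block_off = 35), "5 x")
  expect_error(design_spec(tw_volumes_per_run = 100), "too small")
})

test_that("blocked run orders are counterbalanced and distinct across seeds", {
  d <- test_design()
  o1 <- blocked_run_order(d, 1)
  o2 <- blocked_run_order(d, 2)
  expect_equal(sort(unique(o1)), sort(d$bd_conditions))
  expect_true(all(table(o1) == d$bd_repeats_per_condition))
  expect_true(all(table(o2) == d$bd_repeats_per_condition))
  expect_false(identical(o1, o2))
  expect_identical(o1, blocked_run_order(d, 1))
  expect_error(bd_run_descriptor(d, rep("finger1", 30)), "exactly")
})

test_that("HRF kernels have canonical shape and exact decimation", {
  g <- make_hrf("gamma", dt = 0.1)
  peak_t <- (which.max(g) - 1) * 0.1
  expect_gte(peak_t, 5); expect_lte(peak_t, 7)
  expect_equal(max(g), 1, tolerance = 1e-6)

  dg <- make_hrf("double_gamma", dt = 0.1)
  expect_lt(min(dg), 0) # undershoot
  expect_gt(sum(dg) * 0.1, 0)

  coarse <- make_hrf("double_gamma", dt = 2)
  fine <- make_hrf("double_gamma", dt = 0.1)
  expect_lt(max(abs(coarse - fine[seq(1, length(fine), by = 20)])), 1e-6)

  expect_error(make_hrf("boxcar", dt = 0.1), "arg")
  expect_error(make_hrf("gamma", dt = 0), "positive")
})

test_that("simulate_run matches its construction in the noiseless limit", {
  d <- test_design()
  su <- test_subject(sigma = 0)
  rd <- tw_run_descriptor(d, "forward")
  y <- simulate_run(su$spec, su$truth, rd, d, noise = list(sigma = 0), seed = 1)
  expect_equal(dim(y), c(240, d$tw_volumes_per_run))

  # a finger-3 voxel is maximal during finger-3 blocks (+ ~6 s HRF delay)
  v3 <- which(hand_mask(su) & su$truth$preferred_finger == 3)[1]
  t_peak <- (which.max(y[v3, ]) - 1) * d$tr_seconds
  within_cycle <- (t_peak - d$baseline_pad_seconds) %% d$tw_cycle_seconds
  expect_gte(within_cycle, 20)        # finger 3 cued at 20-30 s
  expect_lte(within_cycle, 30 + 8)    # plus haemodynamic delay

  # zero amplitude -> flat baseline
  tr0 <- su$truth
  tr0$amplitude[] <- 0
  y0 <- simulate_run(su$spec, tr0, rd, d, noise = list(sigma = 0), seed = 1)
  expect_true(all(y0 == 100))

  # determinism: identical inputs give identical matrices; seed changes noise
  yn1 <- simulate_run(su$spec, su$truth, rd, d, noise = list(sigma = 1), seed = 5)
  yn2 <- simulate_run(su$spec, su$truth, rd, d, noise = list(sigma = 1), seed = 5)
  yn3 <- simulate_run(su$spec, su$truth, rd, d, noise = list(sigma = 1), seed = 6)
  expect_identical(yn1, yn2)
  expect_false(identical(yn1, yn3))
})

test_that("tuning is monotone in finger distance and deterioration mixes it away", {
  d <- test_design()
  su <- test_subject(sigma = 0)
  # widely spaced single blocks (rest in between) so block responses do not
  # contaminate each other; descriptor built directly to allow the spacing
  ord <- rep("rest", 30)
  ord[c(1, 7, 13, 19, 25)] <- paste0("finger", 1:5)
  rd <- list(type = "bd", order = ord, n_vol = d$bd_volumes_per_run)
  y <- simulate_run(su$spec, su$truth, rd, d, noise = list(sigma = 0), seed = 1)

  # block-averaged response strictly decreasing in |cued - preferred|
  v <- which(hand_mask(su) & su$truth$preferred_finger == 1)[1]
  resp <- vapply(1:5, function(f) {
    b <- which(ord == paste0("finger", f))
    t0 <- d$baseline_pad_seconds + (b - 1) * d$bd_block_seconds
    vols <- floor(t0 / d$tr_seconds) + 3:7 # 4-12 s after onset
    mean(y[v, vols]) - 100
  }, 0)
  expect_true(all(diff(resp) < 0)) # finger 1 voxel: response falls with distance

  # delta = 1: all five finger conditions evoke identical noiseless responses
  sp1 <- subject_spec("one_hander", 1)
  y1 <- simulate_run(sp1, su$truth, rd, d, noise = list(sigma = 0), seed = 1)
  p1 <- tuning_profile_for_test(su$truth, 1)
  expect_lt(max(apply(p1[hand_mask(su), ], 1, function(r) diff(range(r)))), 1e-12)
})

test_that("deterioration shrinks pattern variance but preserves net activity", {
  su <- test_subject(sigma = 0)
  hand <- hand_mask(su)
  deltas <- c(0, 0.25, 0.5, 0.75, 1)
  profs <- lapply(deltas, function(dl) tuning_profile_for_test(su$truth, dl))
  pat_var <- vapply(profs, function(p) mean(apply(p[hand, ], 1, stats::var)), 0)
  net <- vapply(profs, function(p) mean(rowMeans(p[hand, ])), 0)
  expect_true(all(diff(pat_var) < 0))             # strictly decreasing in delta
  expect_lt(max(abs(net - net[1])), 1e-12)        # mean response constant
})

test_that("cohort generation is deterministic with correct structure", {
  cfg <- test_config(sigma = 0.5)
  co <- generate_cohort(2, 2, 1, cfg, seed = 11)
  expect_equal(nrow(co$manifest), 5)
  expect_equal(as.vector(table(co$manifest$group)[c("control", "sci", "one_hander")]),
               c(2, 2, 1))
  expect_length(co$subjects[[1]]$tw_runs, 4)
  expect_length(co$subjects[[1]]$bd_runs, 4)
  dirs <- vapply(co$subjects[[1]]$tw_runs, attr, "", "direction")
  expect_equal(sum(dirs == "forward"), 2)
  expect_equal(sum(dirs == "backward"), 2)

  co2 <- generate_cohort(2, 2, 1, cfg, seed = 11)
  expect_identical(co, co2) # byte-identical under one seed

  # SCI deterioration strictly increasing in years since injury; controls 0,
  # one-handers 1 with no tuned voxels
  man <- co$manifest
  sci <- man[man$group == "sci", ]
  expect_true(all(order(sci$years_since_sci) == order(sci$deterioration)))
  expect_true(all(man$deterioration[man$group == "control"] == 0))
  expect_true(all(man$deterioration[man$group == "one_hander"] == 1))
  oh <- which(man$group == "one_hander")
  expect_true(all(is.na(co$subjects[[oh]]$truth$preferred_finger)))

  # empty cohort is allowed
  expect_equal(nrow(generate_cohort(0, 0, 0, cfg, seed = 1)$manifest), 0)
})

test_that("ground truth layout: gradient, disjoint ROIs, silent CSF", {
  tr <- ground_truth_map(c(10, 6, 4))
  expect_equal(levels(tr$roi), c("hand_S1", "CSF", "background"))
  expect_false(any(tr$roi == "hand_S1" & tr$roi == "CSF"))
  expect_true(all(is.na(tr$preferred_finger[tr$roi != "hand_S1"])))
  expect_true(all(tr$amplitude[tr$roi == "CSF"] == 0))
  # monotone thumb->little gradient along x
  idx <- arrayInd(seq_len(prod(tr$grid_shape)), tr$grid_shape)
  hand <- tr$roi == "hand_S1"
  pf <- tapply(tr$preferred_finger[hand], idx[hand, 1], unique)
  expect_true(all(diff(as.numeric(pf)) >= 0))
  expect_equal(range(tr$preferred_finger[hand]), c(1L, 5L))
  expect_error(ground_truth_map(c(6, 4, 2),
                                hand_extent = list(x = c(1, 6), y = c(1, 4), z = c(1, 2)),
                                csf_extent = list(x = c(1, 1), y = c(1, 1), z = c(1, 1))),
               "disjoint")
})
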