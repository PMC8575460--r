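test_that("noise model satisfies its whitening identities", {
  set.seed(5)
  E <- lapply(1:4, function(i) matrix(rnorm(200 * 10), 200, 10))
  nm <- estimate_noise_model(E, lambda = 0.1)
  P <- ncol(nm$sigma)
  expect_lt(max(abs(nm$whitener %*% nm$sigma %*% t(nm$whitener) - diag(P))), 1e-8)
  # i.i.d. unit noise, large T: sigma ~ I
  expect_lt(max(abs(nm$sigma - diag(P))), 0.25)
  # lambda = 1: whitening is exactly diag(1/SD)
  nm1 <- estimate_noise_model(E, lambda = 1)
  expect_equal(nm1$whitener, diag(1 / sqrt(diag(nm1$sigma))), tolerance = 1e-12)
  # singular covariance rejected with guidance
  E_sing <- matrix(rnorm(4 * 10), 4, 10) # T < P
  expect_error(estimate_noise_model(E_sing, lambda = 0), "raise lambda")
  expect_error(estimate_noise_model(matrix(rnorm(10), 1, 10)), "more than one")
})

test_that("crossnobis matches closed forms and the fold-pair oracle", {
  # noiseless patterns differing by v: d = |v|^2 / P for every run pair
  set.seed(6)
  P <- 6
  v <- rnorm(P)
  b <- rbind(finger1 = rep(0, P), finger2 = v)
  rdm <- crossnobis(list(b, b, b))
  expect_equal(rdm[1, 2], sum(v^2) / P, tolerance = 1e-12)
  expect_equal(rdm[2, 1], rdm[1, 2])
  expect_equal(diag(rdm), c(finger1 = 0, finger2 = 0))

  # brute-force fold-pair oracle on 3-run, 4-voxel, 5-condition toys
  for (i in 1:5) {
    betas <- lapply(1:3, function(r) matrix(rnorm(20), 5, 4))
    expect_equal(unclass(crossnobis(betas)), crossnobis_oracle(betas),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # whitening route agrees with oracle on prewhitened patterns
  E <- lapply(1:3, function(i) matrix(rnorm(100 * 4), 100, 4))
  nm <- estimate_noise_model(E, lambda = 0.2)
  betas <- lapply(1:3, function(r) matrix(rnorm(20), 5, 4))
  white <- lapply(betas, function(bb) bb %*% nm$whitener)
  expect_equal(unclass(crossnobis(betas, nm)), crossnobis_oracle(white),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(crossnobis(betas[1]), "at least 2")
})

test_that("crossnobis is unbiased under the null and positive under signal", {
  set.seed(61)
  n_sims <- 1500 # scaled from the nominal 10,000 (full scale in acceptance)
  d0 <- replicate(n_sims, {
    b <- lapply(1:4, function(r) matrix(rnorm(2 * 30), 2, 30))
    crossnobis(b)[1, 2]
  })
  expect_lt(abs(mean(d0)), 3 * sd(d0) / sqrt(n_sims))
  d1 <- replicate(300, {
    pat <- rbind(rep(0, 30), rnorm(30, sd = 0.5))
    b <- lapply(1:4, function(r) pat + matrix(rnorm(2 * 30), 2, 30))
    crossnobis(b)[1, 2]
  })
  expect_gt(mean(d1), 3 * sd(d1) / sqrt(300))
})

test_that("RDM structure invariances hold", {
  set.seed(62)
  betas <- lapply(1:4, function(r) matrix(rnorm(5 * 12), 5, 12))
  rdm <- crossnobis(betas)
  expect_equal(length(rdm_unique_values(rdm)), 10)
  expect_equal(unclass(rdm), t(unclass(rdm)))
  # voxel permutation invariance
  perm <- sample(12)
  rdm_p <- crossnobis(lapply(betas, function(b) b[, perm]))
  expect_equal(unclass(rdm_p), unclass(rdm), tolerance = 1e-12)
  # scaling patterns by c scales distances by c^2
  rdm_s <- crossnobis(lapply(betas, function(b) 3 * b))
  expect_equal(unclass(rdm_s), 9 * unclass(rdm), tolerance = 1e-12)
})

test_that("separability is the mean unique distance with null expectation 0", {
  rdm0 <- structure(matrix(0, 5, 5), class = c("rdm", "matrix"))
  expect_equal(separability(rdm0), 0)
  rdm2 <- structure(matrix(2, 5, 5) - diag(2, 5), class = c("rdm", "matrix"))
  expect_equal(separability(rdm2), 2)
  set.seed(63)
  s0 <- replicate(500, { # scaled null (full scale in acceptance)
    pat <- rnorm(30)
    b <- lapply(1:4, function(r) sweep(matrix(rnorm(5 * 30), 5, 30), 2, pat, `+`))
    separability(crossnobis(b))
  })
  expect_lt(abs(mean(s0)), 3 * sd(s0) / sqrt(500))
})

test_that("hand ROI separates fingers while CSF does not", {
  d <- test_design()
  su <- test_subject(sigma = 1)
  fits <- fit_subject_glms(su, d)
  ctl <- csf_control(fits, hand_mask(su), csf_mask(su))
  expect_gt(ctl$hand, ctl$csf)
  expect_gt(ctl$hand, 0)
  expect_lt(abs(ctl$csf), 0.5) # pure noise ROI stays near zero
  # identical ROI twice -> identical scores
  ctl2 <- csf_control(fits, hand_mask(su), hand_mask(su))
  expect_equal(ctl2$hand, ctl2$csf)
  expect_error(csf_control(fits, hand_mask(su), rep(FALSE, 240)), "non-empty")

  # one-hander: both ROIs uninformative
  su1 <- test_subject(sigma = 1, n_controls = 0, n_onehanders = 1, seed = 2)
  ctl1 <- csf_control(fit_subject_glms(su1, d), hand_mask(su1), csf_mask(su1))
  expect_lt(abs(ctl1$hand), 0.5)
})

test_that("typicality behaves as a rank correlation with Fisher z", {
  canon <- canonical_rdm(test_config())
  expect_equal(typicality(canon, canon)$rho, 1)
  # rank-reversed canonical (negated distances) -> rho = -1
  tp <- typicality(structure(-unclass(canon), class = c("rdm", "matrix")), canon)
  expect_equal(tp$rho, -1)
  expect_true(is.finite(typicality(canon * 2, canon)$fisher_z))
  # zero-variance ranks flagged undefined
  flat <- structure(matrix(1, 5, 5) - diag(5), class = c("rdm", "matrix"))
  expect_warning(t0 <- typicality(flat, canon), "zero-variance")
  expect_true(is.na(t0$rho))
})

test_that("typicality decreases with deterioration across the cohort", {
  d <- test_design()
  cfg <- test_config(sigma = 1)
  co <- generate_cohort(4, 5, 3, cfg, seed = 5)
  canon <- canonical_rdm(cfg)
  g <- co$manifest$group
  typ <- vapply(co$subjects, function(su) {
    typicality(subject_rdm(fit_subject_glms(su, d), hand_mask(su)), canon)$fisher_z
  }, 0)
  # typicality falls monotonically with deterioration across the cohort
  expect_lt(cor(typ, co$manifest$deterioration, method = "spearman"), -0.5)
  expect_gt(mean(typ[g == "control"]), mean(typ[g == "one_hander"]))
  # years-since-SCI ordering tracks deterioration by construction
  sci <- g == "sci"
  expect_lt(cor(typ[sci], co$manifest$years_since_sci[sci], method = "spearman"), 0)
})

test_that("MDS embeds RDMs and Procrustes removes rotations", {
  canon <- canonical_rdm(test_config())
  e <- classical_mds(canon)
  expect_equal(dim(e$points), c(5L, 2L))
  expect_false(e$flagged)
  # identical configurations: zero disparity
  pa <- somatomap:::procrustes_align(e$points, e$points)
  expect_lt(pa$disparity, 1e-16)
  # 90-degree rotation removed by alignment
  Rot <- matrix(c(0, -1, 1, 0), 2, 2)
  pa2 <- somatomap:::procrustes_align(e$points %*% Rot, e$points)
  expect_lt(pa2$disparity, 1e-16)
  # embedding fidelity: 2-D distances track the RDM
  cfgd <- as.matrix(dist(e$points))^2
  expect_gt(cor(rdm_unique_values(structure(cfgd, class = c("rdm", "matrix"))),
                rdm_unique_values(canon), method = "spearman"), 0.9)
  # group alignment returns mean and SE on aligned configs
  rdms <- list(canon, canon * 1.1, canon * 0.9)
  mp <- mds_procrustes(rdms)
  expect_length(mp$configs, 3)
  expect_equal(dim(mp$mean_config), c(5L, 2L))
  expect_true(all(is.finite(mp$se_config)))
  expect_error(mds_procrustes(list()), "at least one")
})
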