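# Shared fixtures: small lattices so full travelling-wave + blocked cohorts
# stay fast; the timing/design parameters themselves are never scaled.

test_design <- function() design_spec()

# 10 x 6 x 4 lattice: 240 voxels, 80-voxel hand slab (16 per finger), CSF row.
test_config <- function(sigma = 1, ...) {
  cohort_config(design = test_design(), grid_shape = c(10, 6, 4),
                sigma_noise = sigma, ...)
}

test_subject <- function(sigma = 0, seed = 1, n_controls = 1, n_sci = 0,
                         n_onehanders = 0, ...) {
  co <- generate_cohort(n_controls, n_sci, n_onehanders,
                        test_config(sigma = sigma, ...), seed = seed)
  co$subjects[[1]]
}

hand_mask <- function(subject) subject$truth$roi == "hand_S1"
csf_mask <- function(subject) subject$truth$roi == "CSF"

# internal noiseless response profile, used as the generator oracle
tuning_profile_for_test <- function(truth, delta) {
  somatomap:::tuning_profile(truth, delta)
}

# Independent brute-force crossnobis oracle: explicit loops over run pairs,
# conditions and voxels; whitening applied outside if wanted.
crossnobis_oracle <- function(betas_by_run) {
  R <- length(betas_by_run)
  nc <- nrow(betas_by_run[[1]])
  P <- ncol(betas_by_run[[1]])
  rdm <- matrix(0, nc, nc)
  for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
    acc <- 0; np <- 0
    for (r in 1:(R - 1)) for (s in (r + 1):R) {
      dr <- betas_by_run[[r]][i, ] - betas_by_run[[r]][j, ]
      ds <- betas_by_run[[s]][i, ] - betas_by_run[[s]][j, ]
      acc <- acc + sum(dr * ds)
      np <- np + 1
    }
    rdm[i, j] <- rdm[j, i] <- acc / (np * P)
  }
  rdm
}

# Independent Benjamini-Hochberg oracle: literal step-up definition.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}
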