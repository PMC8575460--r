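#' Multivariate noise model from GLM residuals
#'
#' Pools the voxel-by-voxel residual covariance over runs, shrinks it toward
#' its diagonal with weight \code{lambda}, and computes the symmetric inverse
#' square root used to spatially prewhiten condition patterns. With
#' \code{lambda = 1} the whitening reduces to univariate scaling by
#' \code{1/SD} per voxel.
#'
#' @param residuals_list list of time x voxel residual matrices (one per run),
#'   or a single matrix.
#' @param lambda shrinkage weight toward the diagonal in [0, 1] (default 0.1).
#' @param df optional residual degrees of freedom per run (default: rows - 1).
#' @return object of class \code{"noise_model"}: list with \code{sigma}
#'   (shrunk covariance), \code{whitener} (W with W Sigma W' = I),
#'   \code{lambda}.
#' @export
estimate_noise_model <- function(residuals_list, lambda = 0.1, df = NULL) {
  if (is.matrix(residuals_list)) residuals_list <- list(residuals_list)
  stopifnot(lambda >= 0, lambda <= 1)
  P <- ncol(residuals_list[[1]])
  S <- matrix(0, P, P)
  for (E in residuals_list) {
    if (nrow(E) < 2) stop("residuals need more than one time point")
    d <- if (is.null(df)) nrow(E) - 1 else df
    S <- S + crossprod(E) / d
  }
  S <- S / length(residuals_list)
  Ssh <- (1 - lambda) * S + lambda * diag(diag(S), P)
  eig <- eigen(Ssh, symmetric = TRUE)
  if (min(eig$values) <= 1e-10 * max(eig$values)) {
    stop("shrunk covariance is numerically singular; raise lambda ",
         "(e.g. lambda = 1 for univariate whitening) or supply more time points")
  }
  W <- eig$vectors %*% diag(1 / sqrt(eig$values), P) %*% t(eig$vectors)
  structure(list(sigma = Ssh, whitener = W, lambda = lambda),
            class = "noise_model")
}

# 10 x 5 pair-contrast matrix over 5 conditions: row k encodes pair (i, j),
# i < j, as +1 / -1.
pair_contrasts <- function(n_cond = 5) {
  pairs <- utils::combn(n_cond, 2)
  C <- matrix(0, ncol(pairs), n_cond)
  for (k in seq_len(ncol(pairs))) {
    C[k, pairs[1, k]] <- 1
    C[k, pairs[2, k]] <- -1
  }
  attr(C, "pairs") <- t(pairs)
  C
}

#' Cross-validated Mahalanobis (crossnobis) distances between conditions
#'
#' Prewhitens each run's condition patterns with the noise model and computes,
#' for every condition pair (i, j), the crossnobis distance: the pattern
#' difference of one run projected on the pattern difference of an
#' independent run, averaged over all unordered run pairs and normalised by
#' the voxel count,
#' \deqn{d_{ij} = \frac{2}{R(R-1)P} \sum_{r<s} (u_{i,r}-u_{j,r})^\top
#'   (u_{i,s}-u_{j,s}).}
#' Cross-validation makes the estimate unbiased: its expected value is 0 when
#' the true patterns are identical (individual estimates may be negative) and
#' positive when they differ.
#'
#' @param betas_by_run list (length >= 2) of condition x voxel beta matrices,
#'   one per run, sharing conditions and voxels.
#' @param noise a \code{\link{estimate_noise_model}} result, or \code{NULL}
#'   for no prewhitening (identity noise).
#' @return object of class \code{"rdm"}: a symmetric condition x condition
#'   matrix of distances with zero diagonal and attributes \code{n_runs},
#'   \code{n_voxels}.
#' @export
crossnobis <- function(betas_by_run, noise = NULL) {
  R <- length(betas_by_run)
  if (R < 2) stop("crossnobis needs at least 2 runs (cross-validation folds)")
  dims <- vapply(betas_by_run, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all runs must share conditions and voxels")
  n_cond <- dims[1, 1]
  P <- dims[2, 1]
  U <- betas_by_run
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    U <- lapply(U, function(b) b %*% noise$whitener)
  }
  C <- pair_contrasts(n_cond)
  D <- lapply(U, function(u) C %*% u) # pair-differences per run
  acc <- numeric(nrow(C))
  n_pairs <- 0
  for (r in 1:(R - 1)) for (s in (r + 1):R) {
    acc <- acc + rowSums(D[[r]] * D[[s]])
    n_pairs <- n_pairs + 1
  }
  d <- acc / (n_pairs * P)
  rdm <- matrix(0, n_cond, n_cond)
  pairs <- attr(C, "pairs")
  rdm[pairs] <- d
  rdm <- rdm + t(rdm)
  lab <- rownames(betas_by_run[[1]]) %||% paste0("finger", seq_len(n_cond))
  dimnames(rdm) <- list(lab, lab)
  structure(rdm, class = c("rdm", "matrix"), n_runs = R, n_voxels = P)
}

#' Unique off-diagonal values of an RDM
#'
#' @param rdm a symmetric condition x condition distance matrix.
#' @return numeric vector of the upper-triangle values (10 for 5 conditions),
#'   ordered as pairs (1,2), (1,3), ..., (4,5).
#' @export
rdm_unique_values <- function(rdm) {
  rdm <- unclass(rdm)
  stopifnot(is.matrix(rdm), nrow(rdm) == ncol(rdm))
  t(rdm)[lower.tri(rdm)]
}

#' Finger separability
#'
#' The mean of the unique off-diagonal RDM values: the overall strength of
#' the finger representation. Because the distances are cross-validated, the
#' expected separability is 0 when the ROI carries no finger information.
#'
#' @param rdm an \code{\link{crossnobis}} RDM.
#' @return scalar separability score.
#' @export
separability <- function(rdm) mean(rdm_unique_values(rdm))

#' Hand-versus-CSF separability control
#'
#' Recomputes the representational analysis in a cerebrospinal-fluid ROI that
#' cannot contain finger information and returns both scores for a paired
#' comparison; a real finger representation should give hand >> CSF while the
#' CSF score stays near 0.
#'
#' @param fits list of per-run \code{\link{fit_glm}} results on the full grid.
#' @param hand_mask,csf_mask non-empty logical voxel masks.
#' @param lambda shrinkage for the per-ROI noise models.
#' @return list with \code{hand}, \code{csf} (separability scores) and the
#'   two RDMs.
#' @export
csf_control <- function(fits, hand_mask, csf_mask, lambda = 0.1) {
  if (!any(hand_mask) || !any(csf_mask)) stop("both ROIs must be non-empty")
  roi_rdm <- function(mask) {
    betas <- lapply(fits, function(f) {
      b <- t(f$betas[mask, f$dm$condition_cols, drop = FALSE])
      rownames(b) <- paste0("finger", 1:5)
      b
    })
    res <- lapply(fits, function(f) f$residuals[, mask, drop = FALSE])
    noise <- estimate_noise_model(res, lambda = lambda)
    crossnobis(betas, noise)
  }
  hand_rdm <- roi_rdm(hand_mask)
  csf_rdm <- roi_rdm(csf_mask)
  list(hand = separability(hand_rdm), csf = separability(csf_rdm),
       hand_rdm = hand_rdm, csf_rdm = csf_rdm)
}

#' Somatotopic typicality of an RDM
#'
#' Spearman correlation between a subject's 10 unique inter-finger distances
#' and those of a canonical (normative) RDM, with the Fisher r-to-z transform
#' used for inference (the raw rho is kept for visualisation). With 10 rank
#' pairs the largest attainable correlation below 1 is about 0.988 (Fisher z
#' 2.54), so for the transform rho is clamped to |rho| <= 0.99: perfect rank
#' agreement maps to the finite z = 2.65 just beyond the scale's resolution
#' instead of infinity.
#'
#' @param rdm subject RDM (5 x 5).
#' @param canonical canonical RDM (5 x 5).
#' @return list with \code{rho} (unclamped), \code{fisher_z}.
#' @export
typicality <- function(rdm, canonical) {
  a <- rdm_unique_values(rdm)
  b <- rdm_unique_values(canonical)
  if (length(a) != length(b)) stop("RDMs must have the same number of conditions")
  if (stats::sd(rank(a)) == 0 || stats::sd(rank(b)) == 0) {
    warning("typicality undefined: zero-variance ranks")
    return(list(rho = NA_real_, fisher_z = NA_real_))
  }
  rho <- stats::cor(a, b, method = "spearman")
  z <- atanh(max(min(rho, 0.99), -0.99))
  list(rho = rho, fisher_z = z)
}

#' Canonical inter-finger RDM from the noise-free control template
#'
#' The package has no access to the normative 7T dataset a canonical RDM
#' would usually come from, so the default canonical is synthetic: the exact
#' (noise-free) squared Euclidean inter-finger distances of the generator's
#' intact control template, computed over one instance of the hand-area
#' tuning layout. A user-supplied canonical can be loaded from a delimited
#' table instead (\code{\link{read_rdm_csv}}).
#'
#' @param config a \code{\link{cohort_config}} describing the template.
#' @return 5 x 5 \code{rdm} matrix.
#' @export
canonical_rdm <- function(config = cohort_config()) {
  truth <- ground_truth_map(config$grid_shape, config$hand_extent,
                            config$csf_extent, config$tuning_width,
                            config$amplitude)
  hand <- truth$roi == "hand_S1"
  prof <- tuning_profile(truth, 0)[hand, ] # voxels x 5, noiseless
  P <- sum(hand)
  d <- as.matrix(stats::dist(t(prof)))^2 / P
  dimnames(d) <- list(paste0("finger", 1:5), paste0("finger", 1:5))
  structure(d, class = c("rdm", "matrix"), n_runs = NA_integer_, n_voxels = P)
}

#' Subject-level RSA from blocked-run fits
#'
#' Extracts the five finger-versus-rest betas and residuals under a mask,
#' estimates the noise model, and returns the crossnobis RDM.
#'
#' @param fits list of per-run \code{\link{fit_glm}} results.
#' @param mask logical voxel mask (e.g. the hand ROI).
#' @param lambda covariance shrinkage weight.
#' @param univariate if \code{TRUE}, use per-voxel variance scaling only
#'   (equivalent to \code{lambda = 1}).
#' @return an \code{rdm}.
#' @export
subject_rdm <- function(fits, mask, lambda = 0.1, univariate = FALSE) {
  if (!any(mask)) stop("mask is empty")
  if (univariate) lambda <- 1
  betas <- lapply(fits, function(f) {
    b <- t(f$betas[mask, f$dm$condition_cols, drop = FALSE])
    rownames(b) <- paste0("finger", 1:5)
    b
  })
  res <- lapply(fits, function(f) f$residuals[, mask, drop = FALSE])
  noise <- estimate_noise_model(res, lambda = lambda)
  crossnobis(betas, noise)
}
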