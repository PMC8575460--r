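#' Blocked-design GLM design matrix
#'
#' Builds the time-by-regressor matrix for one blocked run: the five finger
#' conditions convolved with the double-gamma HRF (unit peak per run), their
#' temporal derivatives (boxcar convolved with the HRF's first derivative),
#' a discrete-cosine high-pass basis up to the cut-off period, and an
#' intercept. High-pass filtering is applied by inclusion of the drift basis
#' as nuisance columns (an equivalent projection to pre-filtering).
#'
#' @param design a \code{\link{design_spec}}.
#' @param run_order character vector of blocked condition labels, each of the
#'   six conditions exactly \code{bd_repeats_per_condition} times.
#' @param hrf_kind HRF for the condition regressors (default
#'   \code{"double_gamma"}).
#' @param highpass_cutoff high-pass cut-off period in seconds (default 100, the
#'   blocked-design value; use 90 for travelling-wave data).
#' @return object of class \code{"design_matrix"}: list with \code{X}
#'   (volumes x p), \code{labels}, index vectors \code{condition_cols},
#'   \code{derivative_cols}, \code{drift_cols}, \code{intercept_col}, and the
#'   run order.
#' @export
build_design_matrix <- function(design, run_order, hrf_kind = "double_gamma",
                                highpass_cutoff = 100) {
  stopifnot(inherits(design, "design_spec"))
  if (!all(run_order %in% design$bd_conditions)) stop("unknown condition label in run order")
  tab <- table(factor(run_order, levels = design$bd_conditions))
  if (!all(tab == design$bd_repeats_per_condition)) {
    stop("invalid run order: each condition (including rest) must appear exactly ",
         design$bd_repeats_per_condition, " times")
  }
  key <- paste("dm", hrf_kind, highpass_cutoff, design$tr_seconds,
               design$baseline_pad_seconds, paste(run_order, collapse = ""),
               sep = "|")
  cached <- .reg_cache[[key]]
  if (!is.null(cached)) return(cached)
  n_vol <- design$bd_volumes_per_run
  tr <- design$tr_seconds
  rd <- bd_run_descriptor(design, run_order)
  fo <- finger_onsets(design, rd)
  dt <- 0.1
  hrf_k <- make_hrf(hrf_kind, dt = dt)
  dhrf_k <- make_hrf_derivative(hrf_kind, dt = dt)
  cond <- matrix(0, n_vol, 5)
  deriv <- matrix(0, n_vol, 5)
  for (f in 1:5) {
    ons <- fo$onsets[[f]]
    cond[, f] <- convolve_boxcar(ons, rep(fo$duration, length(ons)), n_vol, tr,
                                 kernel = hrf_k)
    deriv[, f] <- convolve_boxcar(ons, rep(fo$duration, length(ons)), n_vol, tr,
                                  kernel = dhrf_k, normalise = FALSE)
    pk <- max(abs(deriv[, f]))
    if (pk > 0) deriv[, f] <- deriv[, f] / pk
  }
  total <- n_vol * tr
  n_dct <- max(0L, floor(2 * total / highpass_cutoff))
  t_idx <- 0:(n_vol - 1)
  drift <- if (n_dct > 0) {
    sapply(seq_len(n_dct), function(k) cos(pi * k * (t_idx + 0.5) / n_vol))
  } else matrix(0, n_vol, 0)
  X <- cbind(cond, deriv, drift, 1)
  labels <- c(paste0("finger", 1:5), paste0("finger", 1:5, "_deriv"),
              if (n_dct > 0) paste0("dct", seq_len(n_dct)), "intercept")
  colnames(X) <- labels
  out <- structure(list(X = X, labels = labels,
                 condition_cols = 1:5, derivative_cols = 6:10,
                 drift_cols = if (n_dct > 0) 10 + seq_len(n_dct) else integer(0),
                 intercept_col = ncol(X),
                 run_order = run_order, design = design),
            class = "design_matrix")
  .reg_cache[[key]] <- out
  out
}

#' Fit an ordinary-least-squares GLM to a run
#'
#' Per-voxel OLS fit of the blocked-design model. Prewhitening against local
#' autocorrelation is deliberately not applied (betas stay unbiased; variance
#' estimates are nominal); an optional single-pass Cochrane-Orcutt AR(1)
#' correction is available.
#'
#' @param run_matrix voxel x time matrix.
#' @param dm a \code{\link{build_design_matrix}} result.
#' @param ar1_correct if \code{TRUE}, estimate a common AR(1) coefficient from
#'   the pooled OLS residuals and refit on quasi-differenced data.
#' @return object of class \code{"glm_fit"}: list with \code{betas}
#'   (voxel x p), \code{residuals} (time x voxel), \code{sigma2} (per voxel),
#'   \code{df}, and the design matrix.
#' @export
fit_glm <- function(run_matrix, dm, ar1_correct = FALSE) {
  stopifnot(inherits(dm, "design_matrix"))
  X <- dm$X
  if (ncol(run_matrix) != nrow(X)) stop("time dimensions of data and design differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(run_matrix) # time x voxel
  if (ar1_correct) {
    B0 <- qr.coef(qrX, Y)
    E0 <- Y - X %*% B0
    rho <- sum(E0[-1, ] * E0[-nrow(E0), ]) / sum(E0[-nrow(E0), ]^2)
    Ys <- Y[-1, ] - rho * Y[-nrow(Y), ]
    Xs <- X[-1, ] - rho * X[-nrow(X), ]
    qrX <- qr(Xs)
    betas <- qr.coef(qrX, Ys)
    resid <- Ys - Xs %*% betas
    df <- nrow(Xs) - ncol(Xs)
  } else {
    betas <- qr.coef(qrX, Y)
    resid <- Y - X %*% betas
    df <- nrow(X) - ncol(X)
  }
  sigma2 <- colSums(resid^2) / df
  structure(list(betas = t(betas), residuals = resid, sigma2 = sigma2,
                 df = df, dm = dm,
                 voxel_mean = colMeans(Y)),
            class = "glm_fit")
}

#' Contrast estimate from a GLM fit
#'
#' @param fit a \code{\link{fit_glm}} result.
#' @param weights numeric contrast vector over the full design (or a named
#'   shortcut: \code{"fingerK_vs_rest"} or \code{"all_vs_rest"}). Rest is the
#'   implicit baseline, so finger-vs-rest is the finger's beta and
#'   all-vs-rest averages the five finger betas.
#' @return per-voxel contrast estimates (numeric vector).
#' @export
contrast_estimate <- function(fit, weights = "all_vs_rest") {
  p <- ncol(fit$betas)
  if (is.character(weights)) {
    w <- numeric(p)
    if (weights == "all_vs_rest") {
      w[fit$dm$condition_cols] <- 1 / 5
    } else if (grepl("^finger[1-5]_vs_rest$", weights)) {
      f <- as.integer(substr(weights, 7, 7))
      w[fit$dm$condition_cols[f]] <- 1
    } else stop("unknown contrast shortcut: ", weights)
    weights <- w
  }
  stopifnot(length(weights) == p)
  as.vector(fit$betas %*% weights)
}

#' Percent signal change in an ROI
#'
#' Scales the all-movement-versus-rest (or any) contrast to percent of each
#' voxel's baseline signal (the intercept beta; plain mean-signal scaling, no
#' regressor-height convention) and averages over ROI voxels and runs.
#'
#' @param fits list of \code{\link{fit_glm}} results (one per run) or a single
#'   fit.
#' @param roi_mask logical voxel mask (non-empty).
#' @param contrast contrast specification passed to
#'   \code{\link{contrast_estimate}}.
#' @return list with \code{psc} (scalar mean percent signal change),
#'   \code{per_voxel}, \code{n_voxels}, \code{n_runs}.
#' @export
percent_signal_change <- function(fits, roi_mask, contrast = "all_vs_rest") {
  if (inherits(fits, "glm_fit")) fits <- list(fits)
  if (!any(roi_mask)) stop("ROI is empty")
  per_run <- sapply(fits, function(fit) {
    ce <- contrast_estimate(fit, contrast)
    base <- fit$betas[, fit$dm$intercept_col]
    100 * ce[roi_mask] / base[roi_mask]
  })
  per_voxel <- rowMeans(as.matrix(per_run))
  list(psc = mean(per_voxel), per_voxel = per_voxel,
       n_voxels = sum(roi_mask), n_runs = length(fits))
}

#' Fit all blocked runs of a subject
#'
#' Convenience wrapper: builds each run's design matrix from its stored block
#' order and fits the OLS GLM, returning per-run fits for downstream
#' percent-signal-change and representational analyses.
#'
#' @param subject one element of a \code{\link{generate_cohort}}'s
#'   \code{subjects} list.
#' @param design a \code{\link{design_spec}}.
#' @param ... passed to \code{\link{fit_glm}}.
#' @return list of \code{glm_fit} objects, one per blocked run.
#' @export
fit_subject_glms <- function(subject, design, ...) {
  lapply(subject$bd_runs, function(run) {
    dm <- build_design_matrix(design, attr(run, "order"))
    fit_glm(run, dm, ...)
  })
}
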