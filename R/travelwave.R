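#' Build the bank of lagged travelling-wave reference models
#'
#' The base reference model is a gamma-HRF-convolved boxcar with the design's
#' on/off structure (10 s on, 40 s off by default), tiled over the run's
#' movement cycles and aligned to the first cycle onset (the initial baseline
#' pad carries no task). The model is then shifted in time by one TR at a
#' time over the full movement cycle, giving cycle/TR lagged models (25 for a
#' 50 s cycle at TR 2 s). Each model is standardised to zero mean and unit
#' variance over the run.
#'
#' @param design a \code{\link{design_spec}}.
#' @param hrf_kind HRF used for the reference response (default
#'   \code{"gamma"}).
#' @return object of class \code{"reference_bank"}: list with \code{models}
#'   (volumes x n_lags matrix, lag k in column k+1 = base model delayed by
#'   k TR within the cycle), \code{n_lags}, \code{lag_step} and the design.
#' @export
build_reference_models <- function(design, hrf_kind = "gamma") {
  stopifnot(inherits(design, "design_spec"))
  tr <- design$tr_seconds
  cyc <- design$tw_cycle_seconds
  if (abs(cyc %% tr) > 1e-9) stop("cycle length must be divisible by TR")
  n_lags <- as.integer(round(cyc / tr))
  n_vol <- design$tw_volumes_per_run
  pad <- design$baseline_pad_seconds
  on <- design$tw_block_on
  models <- matrix(0, n_vol, n_lags)
  kernel <- make_hrf(hrf_kind, dt = 0.1)
  for (k in 0:(n_lags - 1)) {
    # lag-k neural window: on during [k*TR, k*TR + on) within each cycle
    # (circular within the cycle)
    shift <- k * tr
    onsets <- numeric(0)
    durs <- numeric(0)
    for (c_i in seq_len(design$tw_cycles_per_run)) {
      cyc0 <- pad + (c_i - 1) * cyc
      a <- shift
      b <- shift + on
      if (b <= cyc) {
        onsets <- c(onsets, cyc0 + a); durs <- c(durs, on)
      } else { # wraps around the cycle boundary
        onsets <- c(onsets, cyc0 + a, cyc0)
        durs <- c(durs, cyc - a, b - cyc)
      }
    }
    m <- convolve_boxcar(onsets, durs, n_vol, tr, kernel = kernel,
                         normalise = FALSE)
    models[, k + 1] <- (m - mean(m)) / stats::sd(m)
  }
  structure(list(models = models, n_lags = n_lags, lag_step = tr,
                 design = design, hrf_kind = hrf_kind),
            class = "reference_bank")
}

#' Cross-correlate voxel time courses with the reference bank
#'
#' Computes, for every voxel, the Pearson correlation with each lagged
#' reference model (the lag lives in the bank, so each correlation is at zero
#' temporal offset) and Fisher r-to-z transforms the result. Constant voxel
#' time courses yield z = 0 by convention; correlations are clamped to
#' |r| <= 1 - 1e-7 so z stays finite on noiseless data.
#'
#' @param run_matrix voxel x time matrix.
#' @param bank a \code{\link{build_reference_models}} result.
#' @param direction \code{"forward"} or \code{"backward"} tag stored with the
#'   map (defaults to the matrix's \code{direction} attribute, else forward).
#' @return object of class \code{"lag_correlation_map"}: list with \code{z}
#'   (voxel x n_lags Fisher-z matrix), \code{r}, and \code{direction}.
#' @export
crosscorrelate <- function(run_matrix, bank,
                           direction = attr(run_matrix, "direction") %||% "forward") {
  stopifnot(inherits(bank, "reference_bank"))
  if (ncol(run_matrix) != nrow(bank$models)) {
    stop("time dimension (", ncol(run_matrix), ") does not match the reference bank (",
         nrow(bank$models), " volumes)")
  }
  sds <- apply(run_matrix, 1, stats::sd)
  r <- matrix(0, nrow(run_matrix), bank$n_lags)
  ok <- sds > 0
  if (any(ok)) {
    r[ok, ] <- suppressWarnings(stats::cor(t(run_matrix[ok, , drop = FALSE]),
                                           bank$models))
  }
  r[is.na(r)] <- 0
  z <- atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
  structure(list(z = z, r = r, direction = match.arg(direction, c("forward", "backward"))),
            class = "lag_correlation_map")
}

# Default lag->finger assignment: with lags-per-finger L = n_lags/5, the
# g-th cued finger owns the L consecutive (cyclic) lags centred on its cue
# onset lag (g-1)L. Centring matters: the reference model already carries
# the HRF delay, so a voxel's correlation profile peaks exactly at its cue
# lag and falls off symmetrically; an uncentred grouping (onset at the group
# edge) spills half of each finger's correlation mass into the cyclically
# previous group and biases single-run winner maps in opposite directions
# for forward and backward sequences.
lag_groups <- function(n_lags) {
  L <- n_lags / 5
  if (L != round(L)) stop("number of lags must be divisible by 5")
  half <- floor(L / 2)
  lapply(1:5, function(g) ((g - 1) * L + (-half:(L - 1 - half))) %% n_lags)
}

#' Combine lag correlation maps into a finger-selectivity map
#'
#' Per run, the Fisher-z values of the lags belonging to each cued finger are
#' averaged (the lags are partitioned into five consecutive cyclic groups of
#' five, each centred on a finger's cue-onset lag; group g maps to the g-th
#' finger in that run's cue sequence, so backward runs are remapped through
#' the reversed sequence). Finger-wise z-values are then
#' averaged across runs and a winner-take-all assignment picks the finger
#' with the maximum z per voxel. Ties go deterministically to the lowest
#' finger index, flagged in \code{tie_flag}.
#'
#' @param maps list of \code{\link{crosscorrelate}} results (>= 1), each
#'   carrying its run \code{direction}.
#' @param design a \code{\link{design_spec}}.
#' @return object of class \code{"finger_map"}: list with \code{finger_z}
#'   (voxel x 5), \code{winner_finger}, \code{winner_z}, \code{tie_flag},
#'   \code{significant} (NA until thresholded), \code{n_runs}.
#' @export
combine_runs_to_fingers <- function(maps, design) {
  if (length(maps) < 1) stop("at least one run is required")
  stopifnot(all(vapply(maps, inherits, TRUE, "lag_correlation_map")))
  n_lags <- ncol(maps[[1]]$z)
  groups <- lag_groups(n_lags)
  acc <- 0
  for (m in maps) {
    seqs <- if (m$direction == "forward") design$tw_forward_sequence
            else design$tw_backward_sequence
    fz <- matrix(0, nrow(m$z), 5)
    for (g in 1:5) {
      fz[, seqs[g]] <- rowMeans(m$z[, groups[[g]] + 1, drop = FALSE])
    }
    acc <- acc + fz
  }
  finger_z <- acc / length(maps)
  winner <- max.col(finger_z, ties.method = "first")
  winner_z <- finger_z[cbind(seq_len(nrow(finger_z)), winner)]
  ties <- apply(finger_z, 1, function(v) sum(v == max(v)) > 1)
  structure(list(finger_z = finger_z, winner_finger = winner,
                 winner_z = winner_z, tie_flag = ties,
                 significant = rep(NA, nrow(finger_z)),
                 n_runs = length(maps)),
            class = "finger_map")
}

#' Lag-specificity (phase) winner map
#'
#' Backward runs' lag-z vectors are lag-reversed and averaged with the
#' forward runs per voxel and lag; the winner is the lag with the maximum
#' combined z. Time-reversal maps an ON window starting at lag k to one
#' starting at \code{cycle - window - k}, so the remap is
#' \code{(n_lags - n_lags/5 - k) mod n_lags}: plain reversal plus a
#' block-width correction, which aligns each finger's backward lags onto its
#' forward lag group (validated by noiseless ground-truth recovery).
#' All-equal z vectors win lag 0 with \code{tie_flag} set.
#'
#' @param forward_maps,backward_maps lists of \code{\link{crosscorrelate}}
#'   results (>= 1 of each).
#' @return list with \code{winner_lag} (0-based), \code{winner_z},
#'   \code{combined_z} (voxel x n_lags), \code{tie_flag}.
#' @export
lag_winner_map <- function(forward_maps, backward_maps) {
  if (length(forward_maps) < 1 || length(backward_maps) < 1) {
    stop("at least one forward and one backward run are required")
  }
  n_lags <- ncol(forward_maps[[1]]$z)
  rev_idx <- ((n_lags - n_lags / 5 - 0:(n_lags - 1)) %% n_lags) + 1
  all_z <- c(lapply(forward_maps, function(m) m$z),
             lapply(backward_maps, function(m) m$z[, rev_idx, drop = FALSE]))
  combined <- Reduce(`+`, all_z) / length(all_z)
  winner <- max.col(combined, ties.method = "first")
  ties <- apply(combined, 1, function(v) sum(v == max(v)) > 1)
  list(winner_lag = winner - 1L,
       winner_z = combined[cbind(seq_len(nrow(combined)), winner)],
       combined_z = combined, tie_flag = ties)
}

#' FDR-threshold a finger-selectivity map
#'
#' Converts each voxel's winner z to a two-sided p-value under the nominal
#' null z ~ N(0, 1/(n_eff - 3)) (the Fisher-z variance for a correlation on
#' n_eff samples; temporal autocorrelation is ignored, so n_eff is nominal
#' and configurable) and applies Benjamini-Hochberg step-up control across
#' the in-mask voxels.
#'
#' @param fmap a \code{\link{combine_runs_to_fingers}} result.
#' @param q FDR level in (0, 1) (default 0.05).
#' @param n_eff effective sample size for the z null (default: volumes per
#'   run; must be > 3).
#' @param mask logical vector of voxels to test (default all). Out-of-mask
#'   voxels are never significant.
#' @return the map with \code{significant}, \code{p} and \code{q} filled in.
#' @export
fdr_threshold <- function(fmap, q = 0.05, n_eff, mask = NULL) {
  stopifnot(inherits(fmap, "finger_map"), q > 0, q < 1, n_eff > 3)
  n_vox <- length(fmap$winner_z)
  if (is.null(mask)) mask <- rep(TRUE, n_vox)
  if (!any(mask)) stop("mask is empty")
  p <- rep(NA_real_, n_vox)
  p[mask] <- 2 * stats::pnorm(-abs(fmap$winner_z[mask]) * sqrt(n_eff - 3))
  sig <- rep(FALSE, n_vox)
  sig[mask] <- bh_fdr(p[mask], q)$reject
  fmap$significant <- sig
  fmap$p <- p
  fmap$q <- q
  fmap
}

#' Threshold a finger map by a minimal z criterion
#'
#' Marks voxels whose standardised winner statistic exceeds \code{z_thresh}
#' (the minimal Z > 2 criterion used for split-half overlap analysis) as
#' significant. The standardised statistic is the winner's Fisher z scaled by
#' \code{sqrt(n_eff - 3)}, its nominal null SD being 1 (the same conversion
#' \code{\link{fdr_threshold}} uses); with \code{n_eff = NULL} the raw Fisher
#' z is thresholded instead.
#'
#' @param fmap a \code{\link{combine_runs_to_fingers}} result.
#' @param z_thresh z cut-off (default 2).
#' @param n_eff nominal sample size behind each correlation (volumes per run);
#'   \code{NULL} thresholds raw Fisher z.
#' @param mask optional logical voxel mask.
#' @return the map with \code{significant} filled in.
#' @export
z_threshold <- function(fmap, z_thresh = 2, n_eff = NULL, mask = NULL) {
  stopifnot(inherits(fmap, "finger_map"))
  n_vox <- length(fmap$winner_z)
  if (is.null(mask)) mask <- rep(TRUE, n_vox)
  scale <- if (is.null(n_eff)) 1 else sqrt(n_eff - 3)
  fmap$significant <- mask & fmap$winner_z * scale > z_thresh
  fmap
}

#' Group probability map of finger selectivity
#'
#' For each finger and voxel, counts the subjects whose thresholded map
#' assigns that voxel significantly to that finger.
#'
#' @param maps list of thresholded \code{finger_map}s on one grid.
#' @param group optional group label stored with the result.
#' @return object of class \code{"probability_map"}: list with \code{counts}
#'   (voxel x 5 integer matrix), \code{n_subjects}, \code{group}.
#' @export
probability_map <- function(maps, group = NA_character_) {
  if (length(maps) < 1) stop("at least one map is required")
  n_vox <- length(maps[[1]]$winner_finger)
  if (!all(vapply(maps, function(m) length(m$winner_finger), 0L) == n_vox)) {
    stop("all maps must share one voxel grid")
  }
  counts <- matrix(0L, n_vox, 5)
  for (m in maps) {
    if (all(is.na(m$significant))) stop("maps must be thresholded first")
    for (f in 1:5) {
      counts[, f] <- counts[, f] + as.integer(m$significant & m$winner_finger == f)
    }
  }
  structure(list(counts = counts, n_subjects = length(maps), group = group),
            class = "probability_map")
}

#' Optional lattice Gaussian smoothing
#'
#' Separable Gaussian smoothing of a per-voxel statistic on the 3-D lattice,
#' mirroring the volumetric spatial smoothing of a typical preprocessing
#' stream. FWHM is given in voxel units; default off in the pipeline.
#'
#' @param values numeric vector over the lattice (column-major).
#' @param grid_shape integer length-3 lattice dimensions.
#' @param fwhm full-width-at-half-maximum in voxels.
#' @return smoothed numeric vector.
#' @export
smooth_lattice <- function(values, grid_shape, fwhm) {
  stopifnot(length(values) == prod(grid_shape), fwhm > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  a <- array(values, grid_shape)
  smooth1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
  }
  for (d in 1:3) {
    perm <- c(d, setdiff(1:3, d))
    b <- aperm(a, perm)
    b <- array(apply(b, c(2, 3), smooth1), dim(b))
    a <- aperm(b, order(perm))
  }
  as.vector(a)
}
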