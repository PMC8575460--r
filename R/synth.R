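#' Voxel grid with somatotopic ground truth
#'
#' Lays out a 3-D voxel lattice containing a contiguous "hand area" slab in
#' which each voxel carries a preferred finger, Gaussian tuning width and
#' response amplitude, plus a disjoint cerebrospinal-fluid (CSF) block with no
#' task response and a background of silent voxels. Preferred fingers form a
#' monotone gradient along the first lattice axis: thumb (finger 1) at one end
#' through to the little finger (finger 5) at the other, emulating the
#' lateral-to-medial progression of the S1 hand map.
#'
#' @param grid_shape integer length-3 lattice dimensions (default
#'   \code{c(20, 20, 10)}).
#' @param hand_extent list with integer ranges \code{x}, \code{y}, \code{z}
#'   delimiting the hand slab; default fills most of the grid. The finger
#'   gradient runs along \code{x}.
#' @param csf_extent like \code{hand_extent}, for the CSF block; must be
#'   disjoint from the hand slab.
#' @param tuning_width base Gaussian tuning SD in finger units (default 0.8).
#' @param amplitude base response amplitude at the preferred finger, percent
#'   signal (default 1).
#' @param magnification if \code{TRUE} (default), emulate cortical
#'   magnification of the radial fingers: tuning sharpens and response gain
#'   grows from the little finger towards the thumb (width 0.7-1.3 x and
#'   amplitude 1.2-0.8 x the base values along fingers 1..5). This gives the
#'   template representational structure well-separated inter-finger
#'   distances instead of the near-ties a homogeneous Gaussian map produces.
#' @return object of class \code{"ground_truth"}: a list with \code{grid_shape},
#'   per-voxel vectors \code{preferred_finger} (NA outside the hand slab),
#'   \code{tuning_width}, \code{amplitude}, and \code{roi} (factor with levels
#'   \code{hand_S1}, \code{CSF}, \code{background}). Voxels are in
#'   column-major order of the lattice.
#' @export
ground_truth_map <- function(grid_shape = c(20, 20, 10),
                             hand_extent = NULL,
                             csf_extent = NULL,
                             tuning_width = 0.8,
                             amplitude = 1,
                             magnification = TRUE) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2))
  if (is.null(hand_extent)) {
    hand_extent <- list(x = c(1, grid_shape[1]),
                        y = c(1, max(1, grid_shape[2] - 2)),
                        z = c(1, max(1, grid_shape[3] - 2)))
  }
  if (is.null(csf_extent)) {
    csf_extent <- list(x = c(1, grid_shape[1]),
                       y = c(grid_shape[2], grid_shape[2]),
                       z = c(grid_shape[3], grid_shape[3]))
  }
  n <- prod(grid_shape)
  idx <- arrayInd(seq_len(n), grid_shape)
  in_ext <- function(ext) {
    idx[, 1] >= ext$x[1] & idx[, 1] <= ext$x[2] &
      idx[, 2] >= ext$y[1] & idx[, 2] <= ext$y[2] &
      idx[, 3] >= ext$z[1] & idx[, 3] <= ext$z[2]
  }
  hand <- in_ext(hand_extent)
  csf <- in_ext(csf_extent)
  if (any(hand & csf)) stop("hand and CSF extents must be disjoint")
  roi <- rep("background", n)
  roi[hand] <- "hand_S1"
  roi[csf] <- "CSF"
  # thumb at low x, little finger at high x: 5 equal bins along the slab
  pref <- rep(NA_integer_, n)
  xr <- hand_extent$x
  relx <- (idx[hand, 1] - xr[1]) / max(1e-9, (xr[2] - xr[1] + 1))
  pref[hand] <- pmin(5L, as.integer(floor(relx * 5)) + 1L)
  amp <- numeric(n)
  amp[hand] <- amplitude
  width <- rep(tuning_width, n)
  if (magnification) {
    # widths and gains are fixed properties of the cortical site (indexed by
    # the voxel's original map position), so later preferred-finger scatter
    # does not alter a voxel's net responsiveness
    width[hand] <- tuning_width * (0.55 + 0.15 * pref[hand])
    amp[hand] <- amplitude * (1.3 - 0.1 * pref[hand])
  }
  structure(list(
    grid_shape = as.integer(grid_shape),
    preferred_finger = pref,
    tuning_width = width,
    amplitude = amp,
    roi = factor(roi, levels = c("hand_S1", "CSF", "background"))
  ), class = "ground_truth")
}

#' Subject specification for the synthetic cohort
#'
#' @param group one of \code{"control"}, \code{"sci"}, \code{"one_hander"}.
#' @param deterioration scalar in [0, 1]; 0 = intact somatotopy, 1 = fully
#'   mixed (no finger information). Controls must have 0 and one-handers 1.
#' @param years_since_sci simulated years since injury (SCI only).
#' @param covariates named numeric vector of simulated clinical covariates.
#' @param rng_seed integer seed for this subject's randomness.
#' @return object of class \code{"subject_spec"}.
#' @export
subject_spec <- function(group = c("control", "sci", "one_hander"),
                         deterioration = 0,
                         years_since_sci = NA_real_,
                         covariates = c(motor_score = NA_real_,
                                        sensory_score = NA_real_,
                                        tissue_bridges = NA_real_,
                                        cord_area = NA_real_),
                         rng_seed = 1L) {
  group <- match.arg(group)
  if (deterioration < 0 || deterioration > 1) stop("deterioration must be in [0, 1]")
  if (group == "control" && deterioration != 0) stop("controls must have deterioration 0")
  if (group == "one_hander" && deterioration != 1) stop("one-handers must have deterioration 1")
  structure(list(group = group, deterioration = deterioration,
                 years_since_sci = years_since_sci, covariates = covariates,
                 rng_seed = as.integer(rng_seed)),
            class = "subject_spec")
}

# Per-voxel condition response profile (5 values per voxel, percent signal).
# Gaussian tuning over finger distance, rescaled so every tuned voxel's mean
# response over the five fingers equals the mean tuning of a mid-map
# (finger-3) voxel; deterioration then mixes toward that constant mean with
# weight delta (so the between-finger pattern variance shrinks as
# (1 - delta)^2), and preferred-finger scatter (SD 3*delta fingers)
# reorganises the map. The finger-mean response is exactly invariant in
# delta and in scatter: net activity preserved, somatotopy degraded. Voxels
# with no preferred finger but positive amplitude (one-handers, delta = 1)
# respond uniformly at the same mean level.
tuning_profile <- function(truth, delta) {
  n <- length(truth$amplitude)
  prof <- matrix(0, n, 5)
  w <- truth$tuning_width
  fingers <- 1:5
  active <- truth$amplitude > 0
  for (f in fingers) {
    g <- exp(-0.5 * ((f - truth$preferred_finger) / w)^2)
    prof[, f] <- g
  }
  prof[is.na(prof)] <- 0
  ref <- rowMeans(sapply(fingers, function(f) exp(-0.5 * ((f - 3) / w)^2)))
  m <- rowMeans(prof)
  tuned <- !is.na(truth$preferred_finger)
  prof[tuned, ] <- prof[tuned, , drop = FALSE] * (ref[tuned] / m[tuned])
  untuned <- active & !tuned
  if (any(untuned)) prof[untuned, ] <- ref[untuned]
  prof <- (1 - delta) * prof + delta * matrix(ref, n, 5)
  prof * truth$amplitude
}

# Apply deterioration-dependent preferred-finger scatter to a ground truth:
# each tuned voxel's preferred finger is jittered by a rounded Gaussian with
# SD 3*delta finger units, clipped to 1..5 (seeded). The scatter is the
# primary deterioration mechanism (see tuning_profile).
scatter_preferences <- function(truth, delta, seed) {
  if (delta <= 0) return(truth)
  tuned <- !is.na(truth$preferred_finger)
  jit <- with_seed(seed, round(stats::rnorm(sum(tuned), 0, 3 * delta)))
  truth$preferred_finger[tuned] <-
    pmin(5L, pmax(1L, truth$preferred_finger[tuned] + as.integer(jit)))
  truth
}

#' Travelling-wave and blocked run descriptors
#'
#' @param design a \code{\link{design_spec}}.
#' @param direction \code{"forward"} or \code{"backward"}.
#' @return run descriptor list (\code{type}, \code{sequence}/\code{order},
#'   \code{n_vol}).
#' @export
tw_run_descriptor <- function(design, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  seqs <- if (direction == "forward") design$tw_forward_sequence else design$tw_backward_sequence
  list(type = "tw", direction = direction, sequence = seqs,
       n_vol = design$tw_volumes_per_run)
}

#' @rdname tw_run_descriptor
#' @param order character vector of blocked condition labels (one per block);
#'   see \code{\link{blocked_run_order}}.
#' @export
bd_run_descriptor <- function(design, order) {
  tab <- table(factor(order, levels = design$bd_conditions))
  if (!all(tab == design$bd_repeats_per_condition)) {
    stop("blocked run order must contain each condition exactly ",
         design$bd_repeats_per_condition, " times")
  }
  list(type = "bd", order = order, n_vol = design$bd_volumes_per_run)
}

# Finger onset times (s) for a run descriptor. Returns a list of numeric
# onset vectors, one per finger 1..5 (rest blocks produce no onsets).
finger_onsets <- function(design, run) {
  pad <- design$baseline_pad_seconds
  if (run$type == "tw") {
    on <- design$tw_block_on
    onsets <- vector("list", 5)
    for (c_i in seq_len(design$tw_cycles_per_run)) {
      cyc0 <- pad + (c_i - 1) * design$tw_cycle_seconds
      for (k in seq_along(run$sequence)) {
        f <- run$sequence[k]
        onsets[[f]] <- c(onsets[[f]], cyc0 + (k - 1) * on)
      }
    }
    list(onsets = onsets, duration = on)
  } else {
    bl <- design$bd_block_seconds
    onsets <- vector("list", 5)
    for (k in seq_along(run$order)) {
      lab <- run$order[k]
      if (lab == "rest") next
      f <- as.integer(sub("finger", "", lab))
      onsets[[f]] <- c(onsets[[f]], pad + (k - 1) * bl)
    }
    list(onsets = onsets, duration = bl)
  }
}

# Unit-peak HRF-convolved regressor per finger for one run: n_vol x 5 matrix.
# Memoised: travelling-wave regressors are shared across all subjects and a
# blocked order recurs across analyses of the same run.
.reg_cache <- new.env(parent = emptyenv())

finger_regressors <- function(design, run, hrf_kind) {
  key <- paste(hrf_kind, design$tr_seconds, design$baseline_pad_seconds,
               run$type, run$n_vol,
               paste(if (run$type == "tw") run$sequence else run$order,
                     collapse = ""), sep = "|")
  cached <- .reg_cache[[key]]
  if (!is.null(cached)) return(cached)
  fo <- finger_onsets(design, run)
  out <- sapply(1:5, function(f) {
    if (length(fo$onsets[[f]]) == 0) return(numeric(run$n_vol))
    convolve_boxcar(fo$onsets[[f]], rep(fo$duration, length(fo$onsets[[f]])),
                    run$n_vol, design$tr_seconds, hrf_kind = hrf_kind)
  })
  if (length(.reg_cache) > 512) rm(list = ls(.reg_cache), envir = .reg_cache)
  .reg_cache[[key]] <- out
  out
}

#' Simulate one BOLD run
#'
#' Generates a voxel-by-time matrix in percent-signal units (baseline 100).
#' Each voxel's noiseless response is its deterioration-mixed Gaussian finger
#' tuning profile (see Details) driven by unit-peak HRF-convolved finger
#' regressors; Gaussian (optionally AR(1)) noise is added.
#'
#' @details With tuning profile \eqn{g_v(f) = \exp(-(f - p_v)^2 / 2w_v^2)} and
#' deterioration \eqn{\delta}, the simulated response to finger \eqn{f} is
#' \eqn{a_v[(1-\delta) g_v(f) + \delta \bar g_v]} where \eqn{\bar g_v} is the
#' voxel's mean tuning over the five fingers. The finger-mean response is thus
#' independent of \eqn{\delta} (net activity preserved) while between-finger
#' differences shrink linearly (pattern variance shrinks as
#' \eqn{(1-\delta)^2}).
#'
#' @param subject a \code{\link{subject_spec}}.
#' @param truth a \code{\link{ground_truth_map}} (already scattered if desired).
#' @param run a run descriptor (\code{\link{tw_run_descriptor}} /
#'   \code{\link{bd_run_descriptor}}).
#' @param design a \code{\link{design_spec}}.
#' @param noise list with \code{sigma} (SD, percent signal) and optional
#'   \code{ar1} coefficient (0 = white).
#' @param seed integer seed; identical inputs reproduce the identical matrix.
#' @param hrf_kind HRF used to generate the response (\code{"gamma"} for
#'   travelling-wave runs, \code{"double_gamma"} for blocked runs by default).
#' @return voxel x time numeric matrix.
#' @export
simulate_run <- function(subject, truth, run, design,
                         noise = list(sigma = 0.5, ar1 = 0),
                         seed = 1L,
                         hrf_kind = if (run$type == "tw") "gamma" else "double_gamma") {
  stopifnot(inherits(subject, "subject_spec"), inherits(truth, "ground_truth"))
  n_vox <- prod(truth$grid_shape)
  regs <- finger_regressors(design, run, hrf_kind)   # n_vol x 5
  prof <- tuning_profile(truth, subject$deterioration) # n_vox x 5
  y <- 100 + prof %*% t(regs)                        # n_vox x n_vol
  sigma <- noise$sigma %||% 0
  rho <- noise$ar1 %||% 0
  if (sigma > 0) {
    eps <- with_seed(seed, matrix(stats::rnorm(n_vox * run$n_vol), n_vox, run$n_vol))
    if (rho != 0) {
      eps <- t(apply(eps, 1, function(e) stats::filter(e, rho, method = "recursive")))
      eps <- eps * sqrt(1 - rho^2) # restore unit marginal variance
    }
    y <- y + sigma * eps
  }
  dimnames(y) <- NULL
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort generation configuration
#'
#' @param design a \code{\link{design_spec}}.
#' @param grid_shape,hand_extent,csf_extent,tuning_width,amplitude passed to
#'   \code{\link{ground_truth_map}}.
#' @param sigma_noise Gaussian noise SD in percent signal (default 1).
#' @param ar1 AR(1) noise coefficient (default 0, white noise).
#' @param max_years_sci maximum simulated years since SCI; deterioration is
#'   \code{years / max_years_sci} clipped to [0, 1] (default 35).
#' @return list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(design = design_spec(),
                          grid_shape = c(20, 20, 10),
                          hand_extent = NULL, csf_extent = NULL,
                          tuning_width = 0.8, amplitude = 1,
                          sigma_noise = 1, ar1 = 0,
                          max_years_sci = 35) {
  structure(list(design = design, grid_shape = grid_shape,
                 hand_extent = hand_extent, csf_extent = csf_extent,
                 tuning_width = tuning_width, amplitude = amplitude,
                 sigma_noise = sigma_noise, ar1 = ar1,
                 max_years_sci = max_years_sci),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Simulates a full cohort (default mirrors the target study: 18 able-bodied
#' controls, 14 spinal-cord-injury patients, 13 congenital one-handers as a
#' no-hand-representation reference), each subject with the complete set of
#' travelling-wave and blocked runs, a ground-truth map, and simulated
#' clinical covariates. SCI deterioration is tied to years since injury
#' (\eqn{\delta = \mathrm{years}/35}, clipped), motor and sensory scores
#' decline with deterioration plus noise, and tissue bridges / cord area are
#' generated independent of deterioration.
#'
#' @param n_controls,n_sci,n_onehanders group sizes (>= 0).
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer cohort seed; fully determines the output.
#' @return object of class \code{"synthetic_cohort"}: list with
#'   \code{design}, \code{config}, \code{manifest} (data.frame of subject,
#'   group, deterioration and covariates) and \code{subjects}, each subject a
#'   list with \code{spec}, \code{truth}, \code{tw_runs} (list of matrices +
#'   direction attribute) and \code{bd_runs} (list of matrices + block order).
#' @export
generate_cohort <- function(n_controls = 18, n_sci = 14, n_onehanders = 13,
                            config = cohort_config(), seed = 1L) {
  stopifnot(n_controls >= 0, n_sci >= 0, n_onehanders >= 0)
  design <- config$design
  groups <- c(rep("control", n_controls), rep("sci", n_sci),
              rep("one_hander", n_onehanders))
  n_sub <- length(groups)
  subjects <- vector("list", n_sub)
  man <- list()
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    sseed <- derive_seed(seed, 1L, i)
    years <- NA_real_
    if (g == "sci") {
      years <- with_seed(derive_seed(seed, 2L, i),
                         stats::runif(1, 1, config$max_years_sci))
      delta <- min(1, years / config$max_years_sci)
    } else {
      delta <- if (g == "one_hander") 1 else 0
    }
    cov_seed <- derive_seed(seed, 3L, i)
    covs <- with_seed(cov_seed, c(
      motor_score = max(0, 50 * (1 - delta) + stats::rnorm(1, 0, 4)),
      sensory_score = max(0, 40 * (1 - delta) + stats::rnorm(1, 0, 4)),
      tissue_bridges = abs(stats::rnorm(1, 2, 1)),
      cord_area = stats::rnorm(1, 70, 8)
    ))
    spec <- subject_spec(g, deterioration = delta, years_since_sci = years,
                         covariates = covs, rng_seed = sseed)
    truth <- ground_truth_map(config$grid_shape, config$hand_extent,
                              config$csf_extent, config$tuning_width,
                              config$amplitude)
    if (g == "one_hander") {
      truth$preferred_finger[] <- NA_integer_   # no tuned voxels
    } else if (delta > 0) {
      truth <- scatter_preferences(truth, delta, derive_seed(seed, 4L, i))
    }
    noise <- list(sigma = config$sigma_noise, ar1 = config$ar1)
    tw_runs <- vector("list", length(design$tw_runs))
    for (r in seq_along(design$tw_runs)) {
      rd <- tw_run_descriptor(design, design$tw_runs[r])
      m <- simulate_run(spec, truth, rd, design, noise,
                        seed = derive_seed(sseed, 10L, r))
      attr(m, "direction") <- rd$direction
      tw_runs[[r]] <- m
    }
    bd_runs <- vector("list", design$bd_runs)
    for (r in seq_len(design$bd_runs)) {
      ord <- blocked_run_order(design, derive_seed(sseed, 20L, r))
      rd <- bd_run_descriptor(design, ord)
      m <- simulate_run(spec, truth, rd, design, noise,
                        seed = derive_seed(sseed, 30L, r))
      attr(m, "order") <- ord
      bd_runs[[r]] <- m
    }
    id <- sprintf("S%02d", i)
    subjects[[i]] <- list(id = id, spec = spec, truth = truth,
                          tw_runs = tw_runs, bd_runs = bd_runs)
    man[[i]] <- data.frame(subject = id, group = g, deterioration = delta,
                           years_since_sci = years, t(covs))
  }
  manifest <- if (n_sub > 0) do.call(rbind, man) else
    data.frame(subject = character(), group = character(),
               deterioration = numeric(), years_since_sci = numeric())
  structure(list(design = design, config = config,
                 manifest = manifest, subjects = subjects),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("Synthetic finger-mapping cohort: %d subjects (%s)\n",
              nrow(x$manifest),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("  grid %s, sigma_noise %g, tuning width %g\n",
              paste(x$config$grid_shape, collapse = "x"),
              x$config$sigma_noise, x$config$tuning_width))
  invisible(x)
}
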