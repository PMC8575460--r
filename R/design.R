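#' Experimental design specification
#'
#' Bundles the timing parameters of the two finger-movement fMRI designs the
#' package simulates and analyses: a travelling-wave (phase-encoded) design in
#' which the five fingers are cued in a fixed cycle, and a blocked design with
#' five finger-movement conditions plus rest.
#'
#' Defaults encode the protocol this package targets: TR 2 s; travelling-wave
#' runs of 182 volumes (6 min 4 s) holding seven 50 s cycles of 10 s-on /
#' 40 s-off finger blocks, two forward (thumb-to-little) and two backward
#' runs; blocked runs of 127 volumes (4 min 14 s) with 8 s blocks, each of the
#' six conditions (five fingers + rest) repeated five times per run, four runs.
#' The cycle structure accounts for 350 s and the blocks for 240 s; the
#' remaining 14 s per run is modelled as an initial rest baseline
#' (\code{baseline_pad_seconds}), a stated assumption of the design.
#'
#' @param tr_seconds repetition time in seconds.
#' @param tw_block_on,tw_block_off travelling-wave on/off durations (s) for a
#'   single finger within one cycle; their sum is the cycle length.
#' @param tw_cycles_per_run number of movement cycles per travelling-wave run.
#' @param tw_volumes_per_run volumes acquired per travelling-wave run.
#' @param tw_runs character vector of run directions, in acquisition order.
#' @param bd_block_seconds blocked-design block duration (s).
#' @param bd_repeats_per_condition repeats of each condition per blocked run.
#' @param bd_volumes_per_run volumes acquired per blocked run.
#' @param bd_runs number of blocked runs.
#' @param baseline_pad_seconds initial rest baseline per run (s).
#' @return An object of class \code{"design_spec"} (a list) with the above
#'   fields plus \code{fingers} (labels 1..5), \code{tw_forward_sequence},
#'   \code{tw_backward_sequence}, \code{tw_cycle_seconds} and
#'   \code{bd_conditions}.
#' @examples
#' d <- design_spec()
#' d$tw_cycle_seconds          # 50
#' d$tw_volumes_per_run * d$tr_seconds  # 364 s = 6 min 4 s
#' @export
design_spec <- function(tr_seconds = 2,
                        tw_block_on = 10,
                        tw_block_off = 40,
                        tw_cycles_per_run = 7,
                        tw_volumes_per_run = 182,
                        tw_runs = c("forward", "backward", "forward", "backward"),
                        bd_block_seconds = 8,
                        bd_repeats_per_condition = 5,
                        bd_volumes_per_run = 127,
                        bd_runs = 4,
                        baseline_pad_seconds = NULL) {
  cycle <- tw_block_on + tw_block_off
  if (abs(cycle - 5 * tw_block_on) > 1e-9) {
    stop("travelling-wave cycle must equal 5 x the per-finger 'on' duration (5 fingers)")
  }
  if (!all(tw_runs %in% c("forward", "backward"))) {
    stop("tw_runs must be 'forward' or 'backward'")
  }
  tw_task <- tw_cycles_per_run * cycle
  tw_total <- tw_volumes_per_run * tr_seconds
  if (is.null(baseline_pad_seconds)) baseline_pad_seconds <- tw_total - tw_task
  if (baseline_pad_seconds < 0) {
    stop("tw_volumes_per_run too small for the requested cycle structure")
  }
  if (abs(tw_total - (tw_task + baseline_pad_seconds)) > 1e-9) {
    stop("travelling-wave run duration does not match volumes x TR")
  }
  bd_task <- 6 * bd_repeats_per_condition * bd_block_seconds
  bd_total <- bd_volumes_per_run * tr_seconds
  if (abs(bd_total - (bd_task + baseline_pad_seconds)) > 1e-9) {
    stop("blocked run duration (blocks + baseline pad) does not match volumes x TR")
  }
  fingers <- 1:5
  structure(list(
    tr_seconds = tr_seconds,
    tw_block_on = tw_block_on,
    tw_block_off = tw_block_off,
    tw_cycle_seconds = cycle,
    tw_cycles_per_run = tw_cycles_per_run,
    tw_volumes_per_run = tw_volumes_per_run,
    tw_runs = tw_runs,
    tw_forward_sequence = fingers,
    tw_backward_sequence = rev(fingers),
    bd_block_seconds = bd_block_seconds,
    bd_conditions = c(paste0("finger", fingers), "rest"),
    bd_repeats_per_condition = bd_repeats_per_condition,
    bd_volumes_per_run = bd_volumes_per_run,
    bd_runs = bd_runs,
    baseline_pad_seconds = baseline_pad_seconds,
    fingers = fingers
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Finger-mapping design specification\n")
  cat(sprintf("  TR: %g s\n", x$tr_seconds))
  cat(sprintf("  travelling wave: %d runs (%s), %d volumes, %d x %g s cycles, %g s pad\n",
              length(x$tw_runs), paste(x$tw_runs, collapse = "/"),
              x$tw_volumes_per_run, x$tw_cycles_per_run, x$tw_cycle_seconds,
              x$baseline_pad_seconds))
  cat(sprintf("  blocked: %d runs, %d volumes, %g s blocks, %d repeats/condition\n",
              x$bd_runs, x$bd_volumes_per_run, x$bd_block_seconds,
              x$bd_repeats_per_condition))
  invisible(x)
}

#' Generate a counterbalanced blocked-run condition order
#'
#' Each of the six conditions (five fingers + rest) appears exactly
#' \code{design$bd_repeats_per_condition} times, in a seeded random order, so
#' every run can use a distinct order.
#'
#' @param design a \code{\link{design_spec}}.
#' @param seed integer seed.
#' @return character vector of condition labels, one per block.
#' @export
blocked_run_order <- function(design, seed) {
  stopifnot(inherits(design, "design_spec"))
  base <- rep(design$bd_conditions, design$bd_repeats_per_condition)
  with_seed(seed, sample(base))
}

# Evaluate an expression under a temporary RNG state so that seeded helpers do
# not disturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Counter-based child-seed derivation: reproducible per (stream, index)
# without overlapping streams for the cohort sizes used here.
derive_seed <- function(seed, stream, index = 0L) {
  s <- (as.double(seed) * 2654435761 + stream * 97 + index * 1009) %% 2147483647
  as.integer(s) + 1L
}
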