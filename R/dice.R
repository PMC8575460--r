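#' Dice overlap coefficient between two binary maps
#'
#' \deqn{DOC = 2|A \cap B| / (|A| + |B|)}, ranging from 0 (no spatial
#' overlap) to 1 (perfect overlap). If both masks are empty the coefficient
#' is undefined and \code{NA} is returned (excluded from category means).
#'
#' @param a,b logical vectors on the same voxel grid.
#' @return scalar in [0, 1], or \code{NA} if both masks are empty.
#' @examples
#' a <- c(TRUE, TRUE, FALSE, FALSE)
#' dice(a, a)                        # 1
#' dice(a, rev(a))                   # 0
#' @export
dice <- function(a, b) {
  if (length(a) != length(b)) stop("masks must share one voxel grid")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

#' Split four travelling-wave runs into two analysis halves
#'
#' Half 1 is the finger map from the first forward plus the first backward
#' run; half 2 from the second of each. Each half is processed exactly like
#' the full pipeline (cross-correlation, finger-wise z averaging,
#' winner-take-all).
#'
#' @param runs list of exactly four voxel x time run matrices, each with a
#'   \code{direction} attribute; two forward and two backward.
#' @param design a \code{\link{design_spec}}.
#' @param bank optional precomputed \code{\link{build_reference_models}} bank.
#' @return list of two \code{finger_map}s (\code{half1}, \code{half2}).
#' @export
split_halves <- function(runs, design, bank = NULL) {
  dirs <- vapply(runs, function(r) attr(r, "direction") %||% NA_character_, "")
  if (length(runs) != 4 || sum(dirs == "forward") != 2 || sum(dirs == "backward") != 2) {
    stop("split-half analysis requires exactly 2 forward + 2 backward runs")
  }
  if (is.null(bank)) bank <- build_reference_models(design)
  fwd <- which(dirs == "forward")
  bwd <- which(dirs == "backward")
  half <- function(ix) {
    maps <- lapply(runs[ix], crosscorrelate, bank = bank)
    combine_runs_to_fingers(maps, design)
  }
  list(half1 = half(c(fwd[1], bwd[1])), half2 = half(c(fwd[2], bwd[2])))
}

# Binary per-finger masks from a thresholded winner-take-all map restricted
# to an ROI: voxel belongs to finger f's mask iff it is significant, in the
# ROI, and f is its winner.
finger_masks <- function(fmap, roi_mask = NULL) {
  n <- length(fmap$winner_finger)
  if (is.null(roi_mask)) roi_mask <- rep(TRUE, n)
  if (all(is.na(fmap$significant))) stop("threshold the map first (z_threshold or fdr_threshold)")
  lapply(1:5, function(f) roi_mask & fmap$significant & fmap$winner_finger == f)
}

#' Split-half Dice table over finger-pair neighbourhood categories
#'
#' Computes the Dice overlap between every finger i mask of half 1 and finger
#' j mask of half 2 (25 cross-half pairs), classifies each pair by
#' |i - j| (0 = same finger, 1 = neighbouring fingers, >= 2 =
#' non-neighbouring; no wraparound), and averages per category. Pairs where
#' both masks are empty are undefined and excluded from the means.
#'
#' @param half1,half2 thresholded \code{finger_map}s (same rule for both; the
#'   minimal Z > 2 criterion by default upstream).
#' @param roi_mask logical S1 mask restricting the comparison.
#' @return object of class \code{"dice_table"}: list with \code{pairs}
#'   (data.frame finger_a, finger_b, category, doc) and \code{category_means}
#'   (named numeric: same, neighbour, non_neighbour).
#' @export
category_doc <- function(half1, half2, roi_mask = NULL) {
  m1 <- finger_masks(half1, roi_mask)
  m2 <- finger_masks(half2, roi_mask)
  grid <- expand.grid(finger_a = 1:5, finger_b = 1:5)
  grid$doc <- mapply(function(i, j) dice(m1[[i]], m2[[j]]),
                     grid$finger_a, grid$finger_b)
  d <- abs(grid$finger_a - grid$finger_b)
  grid$category <- factor(ifelse(d == 0, "same",
                          ifelse(d == 1, "neighbour", "non_neighbour")),
                          levels = c("same", "neighbour", "non_neighbour"))
  means <- tapply(grid$doc, grid$category, mean, na.rm = TRUE)
  structure(list(pairs = grid, category_means = c(means)), class = "dice_table")
}

#' @export
print.dice_table <- function(x, ...) {
  cat("Split-half Dice overlap by finger-pair category:\n")
  print(round(x$category_means, 3))
  invisible(x)
}
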