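#' Classical multidimensional scaling of a (possibly non-Euclidean) RDM
#'
#' Double-centres the squared-distance matrix into a Gram matrix and embeds
#' the top positive eigen-directions. Crossnobis distances may be negative,
#' so the matrix need not be embeddable: negative eigenvalues are truncated
#' and the configuration is flagged when the truncated mass exceeds 10% of
#' the total absolute eigenvalue mass.
#'
#' @param rdm condition x condition distance matrix (crossnobis values, i.e.
#'   already squared distances).
#' @param k embedding dimension (default 2).
#' @return list with \code{points} (conditions x k), \code{eigenvalues},
#'   \code{truncated_mass} (proportion), \code{flagged} (logical).
#' @export
classical_mds <- function(rdm, k = 2) {
  D <- unclass(rdm)
  n <- nrow(D)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% D %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- pmax(eig$values, 0)
  tot <- sum(abs(eig$values))
  trunc_mass <- if (tot > 0) sum(abs(pmin(eig$values, 0))) / tot else 0
  pts <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), k)
  rownames(pts) <- rownames(D)
  list(points = pts, eigenvalues = eig$values,
       truncated_mass = trunc_mass, flagged = trunc_mass > 0.1)
}

# Orthogonal Procrustes: rotate/reflect (no scaling by default) X onto ref
# after centring; returns aligned X and the residual disparity.
procrustes_align <- function(X, ref, scale = FALSE) {
  cx <- colMeans(X); cr <- colMeans(ref)
  Xc <- sweep(X, 2, cx)
  Rc <- sweep(ref, 2, cr)
  sv <- svd(crossprod(Rc, Xc))
  Q <- sv$v %*% t(sv$u)
  s <- if (scale) sum(sv$d) / sum(Xc^2) else 1
  aligned <- s * Xc %*% Q
  aligned <- sweep(aligned, 2, cr, `+`)
  list(aligned = aligned, rotation = Q, scale = s,
       disparity = sum((aligned - ref)^2))
}

#' Per-subject MDS with generalised Procrustes group alignment
#'
#' Embeds each subject's RDM in 2-D, removes the arbitrary rotation/reflection
#' of each embedding by Procrustes alignment to a common reference, and
#' returns the aligned configurations with the group mean and between-subject
#' standard errors per condition. The reference is iterated (generalised
#' Procrustes: align all, re-average, repeat until the mean configuration is
#' stable to 1e-8 or 10 iterations).
#'
#' @param rdms list of condition x condition RDMs (>= 1).
#' @param reference optional fixed conditions x 2 reference configuration
#'   (e.g. the control-group mean); if \code{NULL}, the iterated group mean.
#' @param k embedding dimension (default 2).
#' @return object of class \code{"mds_configuration"}: list with
#'   \code{configs} (list of aligned conditions x k matrices),
#'   \code{mean_config}, \code{se_config}, \code{flagged} (per subject).
#' @export
mds_procrustes <- function(rdms, reference = NULL, k = 2) {
  if (length(rdms) < 1) stop("at least one RDM is required")
  emb <- lapply(rdms, classical_mds, k = k)
  configs <- lapply(emb, function(e) e$points)
  flagged <- vapply(emb, function(e) e$flagged, TRUE)
  ref <- reference %||% configs[[1]]
  for (it in 1:10) {
    configs <- lapply(configs, function(X) procrustes_align(X, ref)$aligned)
    new_ref <- Reduce(`+`, configs) / length(configs)
    if (!is.null(reference)) { ref <- reference; break }
    if (sum((new_ref - ref)^2) < 1e-8) { ref <- new_ref; break }
    ref <- new_ref
  }
  mean_config <- Reduce(`+`, configs) / length(configs)
  se_config <- if (length(configs) > 1) {
    arr <- simplify2array(configs)
    apply(arr, c(1, 2), stats::sd) / sqrt(length(configs))
  } else matrix(NA_real_, nrow(mean_config), k)
  structure(list(configs = configs, mean_config = mean_config,
                 se_config = se_config, flagged = flagged),
            class = "mds_configuration")
}
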