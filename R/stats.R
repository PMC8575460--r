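#' Crawford-Howell single-case t-test
#'
#' Compares a single case against a control sample, inflating the standard
#' error to account for the control sample's finite size:
#' \deqn{t = \frac{x - \bar{c}}{s_c \sqrt{(n + 1)/n}}, \quad df = n - 1,}
#' with a two-sided p-value. As \eqn{n \to \infty} this converges to the
#' one-sample z-test.
#'
#' @param x the single case's score.
#' @param controls numeric vector of control scores (n >= 2, SD > 0).
#' @return list with \code{t}, \code{df}, \code{p} (two-sided), \code{n},
#'   \code{control_mean}, \code{control_sd}.
#' @examples
#' crawford_howell(6, 1:5)  # t ~= 1.732, df = 4
#' @export
crawford_howell <- function(x, controls) {
  n <- length(controls)
  if (n < 2) stop("need at least 2 controls")
  s <- stats::sd(controls)
  if (s == 0) stop("control sample has zero variance")
  t_stat <- (x - mean(controls)) / (s * sqrt((n + 1) / n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p, n = n,
       control_mean = mean(controls), control_sd = s)
}

#' Bootstrap distribution of a sample mean
#'
#' With-replacement resampling of the mean with a percentile-type confidence
#' interval, used to infer group population means and to classify a single
#' case as inside or outside a group's interval. The default interval is the
#' expanded percentile (quantile levels widened by the t-versus-normal ratio,
#' Hesterberg's small-sample correction), because the plain percentile
#' interval undercovers at the group sizes used here (n around 15-20);
#' \code{type = "percentile"} gives the uncorrected interval.
#'
#' @param sample non-empty numeric vector.
#' @param n_reps number of bootstrap replicates (default 10000).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed (reproducible).
#' @param type \code{"expanded"} (default) or \code{"percentile"}.
#' @return object of class \code{"bootstrap_mean"}: list with \code{means}
#'   (replicate means), \code{ci} (interval bounds, always within the
#'   resample range), \code{observed_mean}, \code{n_reps}, \code{seed}.
#' @export
bootstrap_mean <- function(sample, n_reps = 10000, ci_level = 0.95, seed = 1L,
                           type = c("expanded", "percentile")) {
  if (length(sample) < 1) stop("sample is empty")
  if (n_reps < 1) stop("n_reps must be >= 1")
  type <- match.arg(type)
  n <- length(sample)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n_reps)
    rowMeans(matrix(sample[idx], nrow = n_reps))
  })
  alpha <- 1 - ci_level
  lo <- alpha / 2
  if (type == "expanded" && n > 1) {
    lo <- stats::pnorm(stats::qt(alpha / 2, n - 1) * sqrt(n / (n - 1)))
  }
  ci <- unname(stats::quantile(means, c(lo, 1 - lo), type = 7))
  structure(list(means = means, ci = ci, observed_mean = mean(sample),
                 n_reps = n_reps, seed = seed, ci_level = ci_level,
                 type = type),
            class = "bootstrap_mean")
}

#' Is a value inside a bootstrap confidence interval?
#'
#' @param boot a \code{\link{bootstrap_mean}} result.
#' @param x scalar to classify.
#' @return logical.
#' @export
in_bootstrap_ci <- function(boot, x) x >= boot$ci[1] & x <= boot$ci[2]

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure: sort the m p-values, find the largest k with
#' p_(k) <= k q / m, and reject the k smallest. Also returns monotone
#' BH-adjusted p-values.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with \code{reject} (logical, input order), \code{p_adjusted},
#'   \code{n_rejected}.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  ranked <- pvalues[o]
  crit <- seq_len(m) * q / m
  k <- suppressWarnings(max(which(ranked <= crit)))
  reject <- rep(FALSE, m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  adj <- rev(cummin(rev(ranked * m / seq_len(m))))
  adj <- pmin(adj, 1)
  p_adj <- numeric(m)
  p_adj[o] <- adj
  list(reject = reject, p_adjusted = p_adj, n_rejected = sum(reject))
}

#' Spearman correlations of typicality with clinical covariates
#'
#' Correlates per-subject (Fisher-z) typicality scores with each covariate,
#' two-sided and uncorrected (the correlational analysis is exploratory).
#'
#' @param scores numeric vector of typicality scores (Fisher z).
#' @param covariates data.frame of covariates, rows matching \code{scores}.
#' @return data.frame with covariate, rho, p, n (rows with missing values
#'   dropped pairwise); covariates with no variance yield NA and a warning.
#' @export
correlate_typicality <- function(scores, covariates) {
  stopifnot(nrow(covariates) == length(scores))
  out <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    ok <- stats::complete.cases(scores, v)
    if (sum(ok) < 3) stop("need at least 3 paired observations for ", nm)
    if (stats::sd(v[ok]) == 0) {
      warning("covariate ", nm, " is constant; correlation undefined")
      return(data.frame(covariate = nm, rho = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(scores[ok], v[ok], method = "spearman",
                                           exact = FALSE))
    data.frame(covariate = nm, rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  do.call(rbind, out)
}

#' Rank-based group comparisons
#'
#' Two groups: Mann-Whitney U (or paired Wilcoxon signed-rank); three or more:
#' Kruskal-Wallis. All tests two-sided.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param paired for exactly two groups of equal length, use the paired
#'   signed-rank test.
#' @return list with \code{method}, \code{statistic}, \code{p},
#'   \code{n_groups}.
#' @export
group_compare <- function(values, groups, paired = FALSE) {
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2) stop("need >= 2 non-empty groups")
  if (nlevels(groups) == 2) {
    sp <- split(values, groups)
    ht <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]], paired = paired,
                                              exact = FALSE))
    list(method = if (paired) "wilcoxon_signed_rank" else "mann_whitney_u",
         statistic = unname(ht$statistic), p = ht$p.value, n_groups = 2L)
  } else {
    ht <- stats::kruskal.test(values, groups)
    list(method = "kruskal_wallis", statistic = unname(ht$statistic),
         p = ht$p.value, n_groups = nlevels(groups))
  }
}

#' Seeded permutation test for a group-by-factor interaction
#'
#' Substitute for a robust mixed ANOVA on a two-factor design with one
#' between-subject factor (group) and one within-subject factor (e.g. finger
#' pair category): the observed interaction F from a standard cell-means
#' decomposition is compared against its distribution under random
#' permutation of group labels across subjects (which preserves the
#' within-subject structure under the null of no group effect).
#'
#' @param value numeric response.
#' @param group between-subject factor.
#' @param within within-subject factor.
#' @param subject subject identifier.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param effect \code{"interaction"} or \code{"group"}.
#' @return list with \code{statistic} (observed F), \code{p}, \code{n_perm},
#'   \code{effect}.
#' @export
permutation_group_test <- function(value, group, within, subject,
                                   n_perm = 10000, seed = 1L,
                                   effect = c("interaction", "group")) {
  effect <- match.arg(effect)
  group <- factor(group); within <- factor(within); subject <- factor(subject)
  sub_group <- tapply(as.character(group), subject, `[`, 1)
  stat <- function(g_by_sub) {
    g <- factor(g_by_sub[as.character(subject)], levels = levels(group))
    fit <- stats::aov(value ~ g * within + Error(subject))
    sm <- summary(fit)
    tab <- sm[["Error: Within"]][[1]]
    if (effect == "interaction") {
      tab["g:within", "F value"]
    } else {
      tb <- sm[["Error: subject"]][[1]]
      tb["g", "F value"]
    }
  }
  obs <- stat(sub_group)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- sub_group
      names(g) <- sample(names(sub_group))
      stat(g[levels(subject)])
    }, numeric(1))
  })
  p <- (1 + sum(perms >= obs)) / (n_perm + 1)
  list(statistic = obs, p = p, n_perm = n_perm, effect = effect)
}

#' Exploratory forward stepwise regression
#'
#' Thin forward-selection utility (flagged exploratory): adds, one at a time,
#' the predictor whose partial F-test p-value is smallest, while below
#' \code{enter_p}.
#'
#' @param y response vector.
#' @param predictors data.frame of candidate predictors.
#' @param enter_p inclusion threshold (default 0.05).
#' @return list with \code{selected} (names in entry order), \code{model}
#'   (final \code{lm}), \code{r_squared}.
#' @export
stepwise_forward <- function(y, predictors, enter_p = 0.05) {
  remaining <- names(predictors)
  selected <- character(0)
  dat <- cbind(data.frame(.y = y), predictors)
  repeat {
    if (length(remaining) == 0) break
    ps <- vapply(remaining, function(nm) {
      f <- stats::as.formula(paste(".y ~", paste(c(selected, nm), collapse = "+")))
      fit <- stats::lm(f, data = dat)
      ct <- summary(fit)$coefficients
      ct[nm, "Pr(>|t|)"]
    }, numeric(1))
    best <- names(which.min(ps))
    if (ps[best] >= enter_p) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  f <- if (length(selected)) paste(".y ~", paste(selected, collapse = "+")) else ".y ~ 1"
  model <- stats::lm(stats::as.formula(f), data = dat)
  list(selected = selected, model = model,
       r_squared = summary(model)$r.squared)
}
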