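#' Pipeline configuration
#'
#' Single serialisable document driving the end-to-end analysis: cohort
#' sizes, design and noise parameters, thresholds, RSA settings, bootstrap
#' repetitions and the one global seed from which all per-subject and per-run
#' seeds are derived (so any subset of the cohort is independently
#' reproducible).
#'
#' @param n_controls,n_sci,n_onehanders cohort sizes (defaults 18 / 14 / 13).
#' @param grid_shape voxel lattice dimensions.
#' @param tuning_width,amplitude,sigma_noise,ar1,max_years_sci generator
#'   parameters, see \code{\link{cohort_config}}.
#' @param fdr_q FDR level for winner-map thresholding.
#' @param dice_z minimal z threshold for split-half masks.
#' @param lambda RSA covariance shrinkage.
#' @param bootstrap_reps bootstrap replicates (default 10000).
#' @param seed global integer seed.
#' @param smooth_fwhm optional spatial smoothing FWHM in voxels (0 = off,
#'   the default for synthetic data).
#' @return named list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(n_controls = 18, n_sci = 14, n_onehanders = 13,
                            grid_shape = c(20, 20, 10),
                            tuning_width = 0.8, amplitude = 1,
                            sigma_noise = 1, ar1 = 0, max_years_sci = 35,
                            fdr_q = 0.05, dice_z = 2, lambda = 0.1,
                            bootstrap_reps = 10000, seed = 1L,
                            smooth_fwhm = 0) {
  structure(list(n_controls = n_controls, n_sci = n_sci,
                 n_onehanders = n_onehanders, grid_shape = grid_shape,
                 tuning_width = tuning_width, amplitude = amplitude,
                 sigma_noise = sigma_noise, ar1 = ar1,
                 max_years_sci = max_years_sci, fdr_q = fdr_q,
                 dice_z = dice_z, lambda = lambda,
                 bootstrap_reps = bootstrap_reps, seed = seed,
                 smooth_fwhm = smooth_fwhm),
            class = "pipeline_config")
}

validate_config <- function(config) {
  with(config, {
    stopifnot(n_controls >= 0, n_sci >= 0, n_onehanders >= 0,
              length(grid_shape) == 3, all(grid_shape >= 2),
              tuning_width > 0, sigma_noise >= 0, abs(ar1) < 1,
              fdr_q > 0, fdr_q < 1, lambda >= 0, lambda <= 1,
              bootstrap_reps >= 1)
  })
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation, travelling-wave mapping (winner
#' maps, lag maps, FDR thresholding, group probability maps), split-half Dice
#' analysis, blocked-design GLM with percent-signal-change extraction,
#' crossnobis RSA (separability, CSF control, typicality, MDS), and the
#' statistical battery (group comparisons, covariate correlations, single-case
#' tests against both reference groups, bootstrap intervals). All tables are
#' written as CSV, summaries as JSON, and a manifest records an MD5 hash of
#' every output file.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   \code{c("simulate","travelwave","dice","glm","rsa","stats")} (the
#'   downstream stages require the earlier ones and pull them in
#'   automatically).
#' @param verbose print stage progress.
#' @return object of class \code{"run_manifest"}: list with \code{stages},
#'   \code{files} (data.frame path/md5), \code{config}, \code{results} (all
#'   in-memory stage outputs), \code{version}, \code{timestamp}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("somatomap_"),
                         stages = c("simulate", "travelwave", "dice", "glm",
                                    "rsa", "stats"),
                         verbose = FALSE) {
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list()
  design <- design_spec()
  ccfg <- cohort_config(design = design, grid_shape = config$grid_shape,
                        tuning_width = config$tuning_width,
                        amplitude = config$amplitude,
                        sigma_noise = config$sigma_noise, ar1 = config$ar1,
                        max_years_sci = config$max_years_sci)

  say("stage simulate: %d + %d + %d subjects, grid %s, sigma %g",
      config$n_controls, config$n_sci, config$n_onehanders,
      paste(config$grid_shape, collapse = "x"), config$sigma_noise)
  cohort <- generate_cohort(config$n_controls, config$n_sci,
                            config$n_onehanders, ccfg, seed = config$seed)
  res$cohort <- cohort
  utils::write.csv(cohort$manifest, file.path(out_dir, "cohort_manifest.csv"),
                   row.names = FALSE)
  n_sub <- nrow(cohort$manifest)
  groups <- cohort$manifest$group
  hand <- if (n_sub > 0) cohort$subjects[[1]]$truth$roi == "hand_S1" else logical(0)
  csf <- if (n_sub > 0) cohort$subjects[[1]]$truth$roi == "CSF" else logical(0)

  bank <- NULL
  n_eff <- design$tw_volumes_per_run
  if ("travelwave" %in% stages && n_sub > 0) {
    say("stage travelwave: %d lagged reference models", 25)
    bank <- build_reference_models(design)
    tw <- lapply(cohort$subjects, function(su) {
      maps <- lapply(su$tw_runs, crosscorrelate, bank = bank)
      fmap <- combine_runs_to_fingers(maps, design)
      if (config$smooth_fwhm > 0) {
        for (f in 1:5) fmap$finger_z[, f] <-
          smooth_lattice(fmap$finger_z[, f], config$grid_shape, config$smooth_fwhm)
        fmap$winner_finger <- max.col(fmap$finger_z, ties.method = "first")
        fmap$winner_z <- fmap$finger_z[cbind(seq_along(fmap$winner_finger),
                                             fmap$winner_finger)]
      }
      fmap <- fdr_threshold(fmap, q = config$fdr_q, n_eff = n_eff, mask = hand)
      fwd <- maps[vapply(maps, function(m) m$direction == "forward", TRUE)]
      bwd <- maps[vapply(maps, function(m) m$direction == "backward", TRUE)]
      list(maps = maps, fmap = fmap, lagmap = lag_winner_map(fwd, bwd))
    })
    res$travelwave <- tw
    wt <- data.frame(subject = rep(cohort$manifest$subject, each = length(hand)),
                     voxel = rep(seq_along(hand), n_sub),
                     winner = unlist(lapply(tw, function(x) x$fmap$winner_finger)),
                     winner_z = unlist(lapply(tw, function(x) x$fmap$winner_z)),
                     significant = unlist(lapply(tw, function(x) x$fmap$significant)))
    utils::write.csv(wt, file.path(out_dir, "winner_maps.csv"), row.names = FALSE)
    for (g in unique(groups)) {
      pm <- probability_map(lapply(tw[groups == g], function(x) x$fmap), group = g)
      utils::write.csv(data.frame(voxel = seq_len(nrow(pm$counts)), pm$counts),
                       file.path(out_dir, paste0("probability_map_", g, ".csv")),
                       row.names = FALSE)
      res$probability[[g]] <- pm
    }
  }

  if ("dice" %in% stages && n_sub > 0) {
    say("stage dice: split-half overlap, Z > %g", config$dice_z)
    if (is.null(bank)) bank <- build_reference_models(design)
    dice_rows <- lapply(seq_len(n_sub), function(i) {
      halves <- split_halves(cohort$subjects[[i]]$tw_runs, design, bank = bank)
      h1 <- z_threshold(halves$half1, config$dice_z, n_eff = n_eff, mask = hand)
      h2 <- z_threshold(halves$half2, config$dice_z, n_eff = n_eff, mask = hand)
      dt <- category_doc(h1, h2, roi_mask = hand)
      data.frame(subject = cohort$manifest$subject[i], group = groups[i],
                 t(dt$category_means))
    })
    res$dice <- do.call(rbind, dice_rows)
    utils::write.csv(res$dice, file.path(out_dir, "dice_table.csv"), row.names = FALSE)
  }

  if (any(c("glm", "rsa", "stats") %in% stages) && n_sub > 0) {
    say("stage glm: OLS blocked-design fits, PSC in hand ROI")
    fits <- lapply(cohort$subjects, fit_subject_glms, design = design)
    res$psc <- data.frame(
      subject = cohort$manifest$subject, group = groups,
      psc = vapply(fits, function(f) percent_signal_change(f, hand)$psc, 0))
    utils::write.csv(res$psc, file.path(out_dir, "psc.csv"), row.names = FALSE)

    if (any(c("rsa", "stats") %in% stages)) {
      say("stage rsa: crossnobis RDMs, separability, typicality, MDS")
      canon <- canonical_rdm(ccfg)
      write_rdm_csv(canon, file.path(out_dir, "canonical_rdm.csv"))
      rdms <- lapply(fits, subject_rdm, mask = hand, lambda = config$lambda)
      ctrl <- lapply(fits, function(f) csf_control(f, hand, csf, lambda = config$lambda))
      typ <- lapply(rdms, typicality, canonical = canon)
      res$rsa <- data.frame(
        subject = cohort$manifest$subject, group = groups,
        separability_hand = vapply(ctrl, function(x) x$hand, 0),
        separability_csf = vapply(ctrl, function(x) x$csf, 0),
        typicality_rho = vapply(typ, function(x) x$rho, 0),
        typicality_z = vapply(typ, function(x) x$fisher_z, 0))
      utils::write.csv(res$rsa, file.path(out_dir, "rsa_scores.csv"), row.names = FALSE)
      rdm_long <- do.call(rbind, lapply(seq_along(rdms), function(i) {
        pr <- attr(pair_contrasts(5), "pairs")
        data.frame(subject = cohort$manifest$subject[i], group = groups[i],
                   finger_a = pr[, 1], finger_b = pr[, 2],
                   distance = rdm_unique_values(rdms[[i]]))
      }))
      utils::write.csv(rdm_long, file.path(out_dir, "rdms.csv"), row.names = FALSE)
      ctrl_idx <- which(groups == "control")
      mds_ref <- if (length(ctrl_idx) > 0) {
        mds_procrustes(rdms[ctrl_idx])$mean_config
      } else NULL
      mds <- mds_procrustes(rdms, reference = mds_ref)
      res$mds <- mds
      mds_df <- do.call(rbind, lapply(seq_along(mds$configs), function(i) {
        data.frame(subject = cohort$manifest$subject[i], group = groups[i],
                   finger = 1:5, dim1 = mds$configs[[i]][, 1],
                   dim2 = mds$configs[[i]][, 2])
      }))
      utils::write.csv(mds_df, file.path(out_dir, "mds_coordinates.csv"),
                       row.names = FALSE)
    }
  }

  if ("stats" %in% stages && n_sub > 0) {
    say("stage stats: group comparisons, correlations, single-case tests")
    battery <- list()
    rsa_tab <- res$rsa
    have <- function(g) any(groups == g)
    if (all(vapply(c("control", "sci", "one_hander"), have, TRUE))) {
      battery$typicality_kruskal <- group_compare(rsa_tab$typicality_z, groups)
      pair <- function(g1, g2) {
        sel <- groups %in% c(g1, g2)
        group_compare(rsa_tab$typicality_z[sel], groups[sel])
      }
      ps <- c(control_vs_onehander = pair("control", "one_hander")$p,
              sci_vs_onehander = pair("sci", "one_hander")$p,
              control_vs_sci = pair("control", "sci")$p)
      battery$typicality_pairwise <- list(p = ps, bh = bh_fdr(ps, config$fdr_q))
    }
    if (have("sci") && sum(groups == "sci") >= 3) {
      sci <- groups == "sci"
      covs <- cohort$manifest[sci, c("years_since_sci", "motor_score",
                                     "sensory_score", "tissue_bridges",
                                     "cord_area")]
      battery$typicality_correlations <-
        correlate_typicality(rsa_tab$typicality_z[sci], covs)
    }
    if (have("control") && sum(groups == "control") >= 2) {
      ctrl_scores <- rsa_tab$typicality_z[groups == "control"]
      battery$bootstrap_controls <- bootstrap_mean(
        ctrl_scores, n_reps = config$bootstrap_reps,
        seed = derive_seed(config$seed, 90L))
      if (have("one_hander") && sum(groups == "one_hander") >= 2) {
        oh_scores <- rsa_tab$typicality_z[groups == "one_hander"]
        battery$bootstrap_onehanders <- bootstrap_mean(
          oh_scores, n_reps = config$bootstrap_reps,
          seed = derive_seed(config$seed, 91L))
        sci_scores <- rsa_tab$typicality_z[groups == "sci"]
        # single-case tests need variance in the reference samples; tiny
        # degenerate cohorts (all reference scores identical, e.g. rank-
        # saturated typicality) skip them with a warning
        if (stats::sd(ctrl_scores) > 0 && stats::sd(oh_scores) > 0) {
          battery$single_case <- lapply(seq_along(sci_scores), function(i) {
            list(subject = rsa_tab$subject[groups == "sci"][i],
                 vs_controls = crawford_howell(sci_scores[i], ctrl_scores),
                 vs_onehanders = crawford_howell(sci_scores[i], oh_scores),
                 in_control_ci = in_bootstrap_ci(battery$bootstrap_controls, sci_scores[i]),
                 in_onehander_ci = in_bootstrap_ci(battery$bootstrap_onehanders, sci_scores[i]))
          })
        } else {
          warning("single-case tests skipped: a reference group has zero variance")
        }
      }
      if (have("sci")) {
        battery$psc_group <- group_compare(
          res$psc$psc[groups %in% c("control", "sci")],
          groups[groups %in% c("control", "sci")])
        battery$separability_vs_csf <- group_compare(
          c(rsa_tab$separability_hand, rsa_tab$separability_csf),
          rep(c("hand", "csf"), each = n_sub), paired = TRUE)
      }
    }
    res$stats <- battery
    summ <- list(
      typicality_kruskal = battery$typicality_kruskal,
      typicality_pairwise_p = battery$typicality_pairwise$p,
      correlations = battery$typicality_correlations,
      bootstrap_control_ci = battery$bootstrap_controls$ci,
      bootstrap_onehander_ci = battery$bootstrap_onehanders$ci,
      psc_group = battery$psc_group,
      separability_vs_csf = battery$separability_vs_csf)
    jsonlite::write_json(summ, file.path(out_dir, "stats_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }

  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  manifest <- structure(list(
    stages = stages,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files))),
    config = config,
    results = res,
    version = as.character(utils::packageVersion("somatomap")),
    timestamp = format(Sys.time(), tz = "UTC"),
    out_dir = out_dir
  ), class = "run_manifest")
  jsonlite::write_json(
    list(stages = stages, files = manifest$files, config = unclass(config),
         version = manifest$version, timestamp = manifest$timestamp),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' Verify output hashes recorded in a run manifest
#'
#' Recomputes the MD5 hash of every file listed in a \code{run_manifest} (or
#' a written \code{manifest.json}) and reports mismatches, so tampered or
#' truncated intermediates are detected before a resumed analysis trusts
#' them.
#'
#' @param manifest a \code{run_manifest} or path to a \code{manifest.json}.
#' @param out_dir directory holding the outputs (defaults to the manifest's).
#' @return character vector of mismatching file names (empty if intact).
#' @export
verify_manifest <- function(manifest, out_dir = NULL) {
  if (is.character(manifest)) {
    md <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    files <- md$files
    if (is.null(out_dir)) out_dir <- dirname(manifest)
  } else {
    files <- manifest$files
    if (is.null(out_dir)) out_dir <- manifest$out_dir
  }
  files <- files[files$path != "manifest.json", , drop = FALSE]
  cur <- unname(tools::md5sum(file.path(out_dir, files$path)))
  files$path[is.na(cur) | cur != files$md5]
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("somatomap run manifest\n")
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  cat("  outputs:", nrow(x$files), "files in", x$out_dir, "\n")
  cat("  version:", x$version, " time:", x$timestamp, "\n")
  invisible(x)
}
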