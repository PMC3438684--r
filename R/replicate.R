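# End-to-end scenario replication: simulate -> phase I -> classifiers ->
# validation curves -> phase II -> selected-model validation metrics.

# Per-r validation metric curves at T = 1 from a prediction-statistic tibble.
metric_curve <- function(stats, da) {
  n <- max(stats$subject)
  r_use <- max(stats$r)
  pred <- matrix(stats$log_c1 > 0, n, r_use)   # predict 2 iff C1 > 1
  case <- da == 2
  sens <- colMeans(pred[case, , drop = FALSE])
  spec <- colMeans(!pred[!case, , drop = FALSE])
  tibble::tibble(
    r = seq_len(r_use),
    sensitivity = sens, specificity = spec,
    accuracy = (sens * sum(case) + spec * sum(!case)) / length(case),
    mean_sens_spec = (sens + spec) / 2)
}

#' Replicate a simulation scenario end to end
#'
#' Simulates `n_replicates` studies under a scenario, runs the pleiotropic
#' and/or naive phase-I search on each discovery set, builds the nested
#' classifiers, computes per-`r` validation metric curves at the Bayesian
#' threshold `T = 1`, and (optionally) runs the phase-II cross-validation
#' to select `r*` and evaluates the selected classifier on the validation
#' set at `T = 1` and at the cross-validation Youden threshold `T*`.
#'
#' @param scenario a scenario name (see [scenario_names()]) or a
#'   [scenario_config()].
#' @param n_replicates number of independent simulated studies.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param n_snps_total optional override of the scenario's assay size (the
#'   causal structure is unchanged), for desk-scale runs.
#' @param methods any of `"conditional"`, `"marginal"`, `"naive"`.
#' @param r_max largest nested set size examined.
#' @param run_cv run phase II (`FALSE` computes peak metrics only).
#' @param k cross-validation folds.
#' @param variant `"single"` or `"ensemble"` classifiers.
#' @return Tibble with one row per (replicate, method): the number of
#'   retained SNPs `t`, peak validation metrics over `r`, and when
#'   `run_cv = TRUE` the selected `r_star` with validation metrics there.
#' @export
replicate_scenario <- function(scenario, n_replicates = 1, seed = 1,
                               n_snps_total = NULL,
                               methods = c("conditional", "marginal",
                                           "naive"),
                               r_max = 200, run_cv = TRUE, k = 10,
                               variant = "single") {
  cfg <- if (is.character(scenario)) scenario_preset(scenario) else scenario
  stopifnot(inherits(cfg, "scenario_config"))
  methods <- match.arg(methods, c("conditional", "marginal", "naive"),
                       several.ok = TRUE)
  if (!is.null(n_snps_total)) {
    cfg$n_snps_total <- as.integer(n_snps_total)
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)
  purrr::map_dfr(seq_len(n_replicates), function(i) {
    sim <- simulate_study(cfg, seed = rep_seeds[2L * i - 1L])
    disc <- sim$discovery; val <- sim$validation
    da_val <- as.integer(val$phenotypes$da)
    need_pleio <- any(methods != "naive")
    out <- list()
    if (need_pleio) {
      scan_p <- pleio_scan(disc$genotypes, disc$phenotypes)
      clf_p <- fit_classifiers(scan_p, disc$genotypes, disc$phenotypes)
    }
    if ("naive" %in% methods) {
      scan_n <- naive_scan(disc$genotypes, disc$phenotypes)
      clf_n <- fit_classifiers(scan_n, disc$genotypes, disc$phenotypes)
    }
    curves <- lapply(setNames(methods, methods), function(mth) {
      clf <- if (mth == "naive") clf_n else clf_p
      if (clf$t == 0L) return(NULL)
      st <- prediction_statistic(
        clf, val$genotypes, kind = mth, variant = variant,
        db = if (mth == "conditional") val$phenotypes$db else NULL,
        r_max = r_max)
      metric_curve(st, da_val)
    })
    cv <- if (run_cv) {
      cross_validate(disc$genotypes, disc$phenotypes, methods = methods,
                     r_max = r_max, k = k, seed = rep_seeds[2L * i],
                     variant = variant)
    }
    purrr::map_dfr(methods, function(mth) {
      cv_row <- curve <- NULL
      curve <- curves[[mth]]
      t_ <- if (mth == "naive") scan_n$t else scan_p$t
      row <- tibble::tibble(
        replicate = i, method = mth, t = t_,
        peak_accuracy = NA_real_, peak_mean_sens_spec = NA_real_,
        peak_accuracy_r = NA_integer_, peak_mean_sens_spec_r = NA_integer_)
      if (!is.null(curve)) {
        row$peak_accuracy <- max(curve$accuracy)
        row$peak_accuracy_r <- which.max(curve$accuracy)
        row$peak_mean_sens_spec <- max(curve$mean_sens_spec)
        row$peak_mean_sens_spec_r <- which.max(curve$mean_sens_spec)
      }
      if (run_cv) {
        row$r_star <- NA_integer_
        row$accuracy_rstar <- row$mean_sens_spec_rstar <- NA_real_
        row$accuracy_rstar_tstar <- row$mean_sens_spec_rstar_tstar <- NA_real_
        aucs <- dplyr::filter(cv$metrics, .data$method == mth)$auc
        if (any(!is.na(aucs)) && !is.null(curve)) {
          rstar <- min(select_r(aucs), nrow(curve))
          row$r_star <- rstar
          row$accuracy_rstar <- curve$accuracy[rstar]
          row$mean_sens_spec_rstar <- curve$mean_sens_spec[rstar]
          # validation metrics at the cross-validation Youden threshold
          sc <- cv$stats[[mth]][, rstar]
          ok <- !is.na(sc)
          tstar <- select_threshold_youden(sc[ok], cv$labels[ok])
          clf <- if (mth == "naive") clf_n else clf_p
          st <- prediction_statistic(
            clf, val$genotypes, kind = mth, variant = variant,
            db = if (mth == "conditional") val$phenotypes$db else NULL,
            r_max = rstar)
          sr <- st$log_c1[st$r == rstar]
          cm <- confusion_metrics(ifelse(sr > tstar, 2L, 1L), da_val)
          row$accuracy_rstar_tstar <- cm$accuracy
          row$mean_sens_spec_rstar_tstar <- cm$mean_sens_spec
        }
      }
      row
    })
  })
}
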