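# Phase II: cross-validated selection of the SNP-set size r* (AUC-optimal)
# and optionally of the decision threshold (Youden-optimal).

#' Build a (stratified) cross-validation fold plan
#'
#' @param n number of subjects.
#' @param k number of folds, or `"loo"` for leave-one-out.
#' @param strata optional per-subject stratum (e.g. joint phenotype class);
#'   fold class counts then differ by at most 1 per stratum.
#' @param seed optional integer seed for the fold shuffle.
#' @return Integer vector of fold indices in `1..k`.
#' @export
make_folds <- function(n, k = 10, strata = NULL, seed = NULL) {
  if (identical(k, "loo")) k <- n
  k <- as.integer(k)
  if (n < k) stop("`n` must be at least the number of folds")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strata)) strata <- rep(1L, n)
  if (length(strata) != n) stop("`strata` length must equal `n`")
  fold <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < k && k < n) {
      warning("stratum ", s, " has fewer members (", length(idx),
              ") than folds; spreading as evenly as possible")
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Build a pleio_classifier directly from training genotype counts of the
# ranked SNPs (C: [3, K, t] with K = 4 joint classes or 2 Da classes).
classifier_from_counts <- function(ranking, C, method, log_prior) {
  K <- dim(C)[2]
  t_ <- nrow(ranking)
  logcpt <- array(0, c(K, 3L, t_))
  if (t_ > 0L) {
    if (K == 2L) {
      logcpt <- log(cpt_from_counts(C, 2L))
    } else {
      for (mod in intersect(c("Ma", "Mb", "Mab"), unique(ranking$model))) {
        sel <- which(ranking$model == mod)
        groups <- switch(mod, Ma = MA_GROUPS, Mb = MB_GROUPS, Mab = MAB_GROUPS)
        p <- log(cpt_from_counts(
          collapse_rows(C[, , sel, drop = FALSE], groups), length(groups)))
        expand <- switch(mod, Ma = c(1L, 1L, 2L, 2L), Mb = c(1L, 2L, 1L, 2L),
                         Mab = 1:4)
        logcpt[, , sel] <- p[expand, , , drop = FALSE]
      }
    }
  }
  structure(
    list(ranking = ranking, method = method, K = K, logcpt = logcpt,
         log_prior = log_prior, prior = "uniform", t = t_),
    class = "pleio_classifier")
}

#' Cross-validated classifier evaluation over nested set sizes
#'
#' For each fold, the full phase-I model search is repeated on the training
#' subjects only, classifiers are fitted on the training counts, and the
#' held-out subjects are scored for every nested set size
#' `r = 1..min(r_max, t_fold)`.  Out-of-fold statistics are pooled across
#' folds, and sensitivity, specificity (at `T = 1`) and the Mann-Whitney
#' AUC are reported per `r` and method.
#'
#' @param geno,pheno discovery data.
#' @param methods any of `"conditional"`, `"marginal"`, `"naive"`.
#' @param r_max largest nested set size evaluated (default 200).
#' @param k folds (default 10) or `"loo"`.
#' @param seed seed for the fold plan.
#' @param variant `"single"` or `"ensemble"` classifiers.
#' @param bf_threshold phase-I `ln BF` retention threshold.
#' @param alpha optional fixed scoring pseudo-count (see [pleio_scan()]).
#' @return A `pleio_cv` object; `tidy()` gives the per-(method, r) metric
#'   table, `glance()` the selected `r*` and AUC per method.
#' @export
cross_validate <- function(geno, pheno,
                           methods = c("conditional", "marginal", "naive"),
                           r_max = 200, k = 10, seed = NULL,
                           variant = "single", bf_threshold = 1,
                           alpha = NULL) {
  methods <- match.arg(methods, c("conditional", "marginal", "naive"),
                       several.ok = TRUE)
  variant <- match.arg(variant, c("single", "ensemble"))
  geno <- as_genotype_matrix(geno)
  need_db <- any(methods != "naive")
  pheno <- check_phenotypes(pheno, n = nrow(geno), need_db = need_db)
  n <- nrow(geno)
  da <- as.integer(pheno$da)
  has_db <- "db" %in% names(pheno)
  cls <- if (has_db) joint_class(da, as.integer(pheno$db)) else da
  K <- if (has_db) 4L else 2L
  fold <- make_folds(n, k, strata = cls, seed = seed)
  F <- max(fold)
  Cf <- .count_geno_folds(geno, cls, K, fold, F)       # [3, K, F, m]
  Ctot <- .count_geno(geno, cls, K)
  m <- ncol(geno)
  stats <- lapply(methods, function(x) matrix(NA_real_, n, r_max))
  names(stats) <- methods
  log_fold_t <- integer(F)
  for (f in seq_len(F)) {
    test <- which(fold == f)
    Ctr <- Ctot - array(Cf[, , f, ], c(3L, K, m))
    lp4 <- rep(-log(4), 4)
    if (any(methods != "naive")) {
      rk <- rank_snps(scan_from_counts(Ctr, "pleiotropic", bf_threshold,
                                       alpha, colnames(geno)))
      log_fold_t[f] <- nrow(rk)
      if (nrow(rk) > 0L) {
        clf <- classifier_from_counts(rk, Ctr[, , rk$snp_index, drop = FALSE],
                                      "pleiotropic", lp4)
        for (mth in intersect(methods, c("conditional", "marginal"))) {
          st <- prediction_statistic(
            clf, geno[test, , drop = FALSE], kind = mth, variant = variant,
            db = if (mth == "conditional") pheno$db[test] else NULL,
            r_max = r_max)
          stats[[mth]][cbind(test[st$subject], st$r)] <- st$log_c1
        }
      }
    }
    if ("naive" %in% methods) {
      Cna <- if (K == 4L) collapse_rows(Ctr, MA_GROUPS) else Ctr
      rkn <- rank_snps(scan_from_counts(Cna, "naive", bf_threshold,
                                        alpha, colnames(geno)))
      if (K == 2L) log_fold_t[f] <- nrow(rkn)
      if (nrow(rkn) > 0L) {
        clfn <- classifier_from_counts(
          rkn, Cna[, , rkn$snp_index, drop = FALSE], "naive", rep(-log(2), 2))
        st <- prediction_statistic(clfn, geno[test, , drop = FALSE],
                                   kind = "naive", variant = variant,
                                   r_max = r_max)
        stats[["naive"]][cbind(test[st$subject], st$r)] <- st$log_c1
      }
    }
  }
  metrics <- purrr::map_dfr(methods, function(mth) {
    S <- stats[[mth]]
    purrr::map_dfr(seq_len(r_max), function(r) {
      sc <- S[, r]
      ok <- !is.na(sc)
      if (!any(ok) || length(unique(da[ok])) < 2L) {
        return(tibble::tibble(method = mth, r = r, n = sum(ok),
                              sensitivity = NA_real_, specificity = NA_real_,
                              auc = NA_real_))
      }
      cm <- confusion_metrics(ifelse(sc[ok] > 0, 2L, 1L), da[ok])
      tibble::tibble(method = mth, r = r, n = sum(ok),
                     sensitivity = cm$sensitivity,
                     specificity = cm$specificity,
                     auc = auc_mann_whitney(sc[ok], da[ok]))
    })
  })
  structure(
    list(metrics = metrics, stats = stats, labels = da,
         db = if (has_db) as.integer(pheno$db) else NULL,
         fold = fold, fold_t = log_fold_t, methods = methods,
         variant = variant, r_max = r_max, bf_threshold = bf_threshold,
         seed = seed),
    class = "pleio_cv")
}

#' @export
print.pleio_cv <- function(x, ...) {
  cat("Phase-II cross-validation (", max(x$fold), " folds, ", x$variant,
      " classifiers)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Select the AUC-optimal nested set size
#'
#' The smallest `r` attaining the maximal pooled out-of-fold AUC.
#'
#' @param cv a `pleio_cv`, or a numeric AUC curve indexed by `r`.
#' @param method method to select for (required when `cv` holds several).
#' @return The selected `r*`.
#' @export
#' @examples
#' select_r(c(0.6, 0.7, 0.7, 0.65))  # 2
select_r <- function(cv, method = NULL) {
  if (is.numeric(cv)) {
    auc <- cv
  } else {
    stopifnot(inherits(cv, "pleio_cv"))
    if (is.null(method)) {
      if (length(cv$methods) > 1L) stop("specify `method`")
      method <- cv$methods
    }
    auc <- cv$metrics$auc[cv$metrics$method == method][order(
      cv$metrics$r[cv$metrics$method == method])]
  }
  ok <- which(!is.na(auc))
  if (length(ok) == 0L) stop("no defined AUC values to select from")
  ok[which.max(auc[ok])]
}

#' Youden-optimal decision threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` (predicting class 2 when
#' the score strictly exceeds the threshold) over the midpoints between
#' consecutive distinct sorted scores, plus a below-minimum and an
#' above-maximum candidate; the smallest maximizing threshold is returned
#' on ties.
#'
#' @param scores numeric prediction scores.
#' @param labels classes in `{1, 2}`, 2 = case.
#' @return The selected threshold `T*`.
#' @export
#' @examples
#' select_threshold_youden(c(0.1, 0.9), c(1, 2))  # 0.5
select_threshold_youden <- function(scores, labels) {
  case <- labels == 2
  if (!any(case) || all(case)) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  j <- vapply(cand, function(th) {
    mean(scores[case] > th) + mean(scores[!case] <= th) - 1
  }, 0)
  cand[which.max(j)]   # which.max takes the first (smallest) maximizer
}

#' Summarise a cross-validation at the selected size
#'
#' For each method: the AUC-optimal `r*`, the pooled AUC there, and the
#' Youden-optimal decision threshold `T*` computed from the pooled
#' out-of-fold statistics at `r*` (reported on the odds scale).
#'
#' @param x a `pleio_cv`.
#' @param ... unused.
#' @export
glance.pleio_cv <- function(x, ...) {
  purrr::map_dfr(x$methods, function(mth) {
    rstar <- select_r(x, mth)
    sc <- x$stats[[mth]][, rstar]
    ok <- !is.na(sc)
    tstar <- exp(select_threshold_youden(sc[ok], x$labels[ok]))
    met <- dplyr::filter(x$metrics, .data$method == mth, .data$r == rstar)
    tibble::tibble(method = mth, r_star = rstar, auc = met$auc,
                   sensitivity = met$sensitivity,
                   specificity = met$specificity, t_star = tstar)
  })
}

#' @rdname cross_validate
#' @param x a `pleio_cv`.
#' @param ... unused.
#' @export
tidy.pleio_cv <- function(x, ...) x$metrics
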