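# Phase I model search: per-SNP Bayesian model selection and ranking.

# Score single-phenotype models on a joint-class count array C [3, 4, m].
# Returns, for each of the 8 (phenotype x mode) models, the log marginal
# likelihood of the model and of the matched null (same inheritance coding),
# and their difference (ln BF).  `alpha_fun(q)` gives the per-cell
# pseudo-count for a q-row model.
score_single_models <- function(C, alpha_fun, modes = INHERITANCE_MODES) {
  m <- dim(C)[3]
  Cma <- collapse_rows(C, MA_GROUPS)
  Cmb <- collapse_rows(C, MB_GROUPS)
  C0  <- collapse_rows(C, M0_GROUPS)
  phen <- rep(c("Ma", "Mb"), each = length(modes))
  mode <- rep(modes, 2L)
  lnml <- matrix(NA_real_, m, 2L * length(modes))
  lnml_null <- matrix(NA_real_, m, length(modes), dimnames = list(NULL, modes))
  for (k in seq_along(modes)) {
    md <- modes[k]
    lnml_null[, k] <- lnml_counts(collapse_mode(C0, md), alpha_fun(1L))
    lnml[, k] <- lnml_counts(collapse_mode(Cma, md), alpha_fun(2L))
    lnml[, k + length(modes)] <- lnml_counts(collapse_mode(Cmb, md),
                                             alpha_fun(2L))
  }
  lnbf <- lnml - lnml_null[, rep(seq_along(modes), 2L)]
  list(lnml = lnml, lnml_null = lnml_null, lnbf = lnbf,
       phen = phen, mode = mode)
}

# Full phase-I search on a joint-class count array (K = 4 for the
# pleiotropic search, K = 2 classes by Da for the naive search).
scan_from_counts <- function(C, method, threshold, alpha, snp_ids) {
  alpha_fun <- if (is.null(alpha)) function(q) 4 / q else function(q) alpha
  m <- dim(C)[3]
  if (method == "pleiotropic") {
    sc <- score_single_models(C, alpha_fun)
  } else {
    # naive: only Ma-type models; C has 2 classes (by Da)
    modes <- INHERITANCE_MODES
    C0 <- collapse_rows(C, list(1:2))
    lnml <- matrix(NA_real_, m, length(modes))
    lnml_null <- matrix(NA_real_, m, length(modes))
    for (k in seq_along(modes)) {
      lnml_null[, k] <- lnml_counts(collapse_mode(C0, modes[k]), alpha_fun(1L))
      lnml[, k] <- lnml_counts(collapse_mode(C, modes[k]), alpha_fun(2L))
    }
    sc <- list(lnml = lnml, lnml_null = lnml_null, lnbf = lnml - lnml_null,
               phen = rep("Ma", length(modes)), mode = modes)
  }
  best <- max.col(sc$lnbf, ties.method = "first")
  idx2 <- cbind(seq_len(m), best)
  best_bf <- sc$lnbf[idx2]
  n_obs <- colSums(C, dims = 2L)
  keep <- which(best_bf > threshold & n_obs > 0L)
  if (length(keep) == 0L) {
    return(empty_assignments())
  }
  fp_model <- sc$phen[best[keep]]
  fp_mode  <- sc$mode[best[keep]]
  model    <- fp_model
  mode     <- fp_mode
  ln_bf    <- best_bf[keep]
  if (method == "pleiotropic") {
    # second pass: pleiotropic model under the first-pass winning mode,
    # upgraded only on a strictly larger marginal likelihood
    lnml_fp   <- sc$lnml[idx2][keep]
    lnml_null <- sc$lnml_null[cbind(keep, match(fp_mode, INHERITANCE_MODES))]
    lnml_ab   <- rep(NA_real_, length(keep))
    Cab <- C[, , keep, drop = FALSE]
    for (md in unique(fp_mode)) {
      sel <- which(fp_mode == md)
      lnml_ab[sel] <- lnml_counts(
        collapse_mode(Cab[, , sel, drop = FALSE], md), alpha_fun(4L))
    }
    up <- lnml_ab > lnml_fp
    model[up] <- "Mab"
    ln_bf[up] <- lnml_ab[up] - lnml_null[up]
  }
  tibble::tibble(
    snp_id = snp_ids[keep], snp_index = keep, model = model, mode = mode,
    ln_bf = ln_bf, first_pass_model = fp_model, first_pass_ln_bf = best_bf[keep])
}

empty_assignments <- function() {
  tibble::tibble(snp_id = character(), snp_index = integer(),
                 model = character(), mode = character(), ln_bf = double(),
                 first_pass_model = character(), first_pass_ln_bf = double())
}

#' Rank SNP model assignments by Bayes factor
#'
#' Stable descending sort on `ln_bf`; ties keep the input (genomic) order.
#' The nested SNP set of size `r` is the first `r` rows of the result.
#'
#' @param assignments tibble with at least an `ln_bf` column.
#' @return The tibble sorted by descending `ln_bf` with a `rank` column.
#' @export
rank_snps <- function(assignments) {
  stopifnot(is.data.frame(assignments), "ln_bf" %in% names(assignments))
  out <- assignments[order(-assignments$ln_bf, seq_len(nrow(assignments))), ,
                     drop = FALSE]
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(tibble::as_tibble(out), "rank")
}

#' Phase-I Bayesian model search over all SNPs
#'
#' First pass: every SNP is scored against the matched null under the
#' single-phenotype models `Ma` and `Mb` crossed with the four inheritance
#' codings (8 models; 4 `Ma` models for the naive search), and the model
#' with the largest Bayes factor is selected.  SNPs whose best
#' `ln BF` exceeds `threshold` (default 1) are retained.  Second pass
#' (pleiotropic search only): the pleiotropic model `Mab` is evaluated under
#' the first-pass winning inheritance mode and selected iff its marginal
#' likelihood strictly exceeds the first-pass model's.  Retained SNPs are
#' ranked by descending `ln BF` of the selected model versus the null, ties
#' broken by genomic order.
#'
#' @param geno genotype matrix (see [as_genotype_matrix()]).
#' @param pheno tibble with `da` and (for the pleiotropic search) `db`.
#' @param method `"pleiotropic"` (both phenotypes, Mab tested) or `"naive"`
#'   (`da` only).
#' @param threshold first-pass significance threshold on `ln BF`.
#' @param alpha optional fixed per-cell pseudo-count; default `4/q` per model.
#' @return A `pleio_scan` object; `tidy()` returns the ranking table with
#'   columns `rank`, `snp_id`, `model`, `mode`, `ln_bf`.
#' @export
#' @examples
#' sim <- simulate_study(scenario_config(n_discovery = 400, n_snps_total = 60,
#'                                       n_pleiotropic = 3, n_da_only = 3,
#'                                       n_db_only = 3, or_a = c(3, 4),
#'                                       or_b = c(3, 4)), seed = 1)
#' scan <- pleio_scan(sim$discovery$genotypes, sim$discovery$phenotypes)
#' head(tidy(scan))
pleio_scan <- function(geno, pheno, method = c("pleiotropic", "naive"),
                       threshold = 1, alpha = NULL) {
  method <- match.arg(method)
  geno <- as_genotype_matrix(geno)
  pheno <- check_phenotypes(pheno, n = nrow(geno),
                            need_db = method == "pleiotropic")
  da <- as.integer(pheno$da)
  degenerate <- any(tabulate(da, 2L) < 2L) ||
    (method == "pleiotropic" && any(tabulate(as.integer(pheno$db), 2L) < 2L))
  if (degenerate) {
    warning("fewer than 2 subjects in a phenotype class; scan is degenerate ",
            "and no SNPs were scored")
    ranking <- rank_snps(empty_assignments())
  } else {
    if (method == "pleiotropic") {
      cls <- joint_class(da, as.integer(pheno$db)); K <- 4L
    } else {
      cls <- da; K <- 2L
    }
    C <- .count_geno(geno, cls, K)
    ranking <- rank_snps(
      scan_from_counts(C, method, threshold, alpha, colnames(geno)))
  }
  structure(
    list(ranking = ranking, t = nrow(ranking), method = method,
         threshold = threshold, alpha = alpha, n_snps = ncol(geno),
         n_subjects = nrow(geno)),
    class = "pleio_scan")
}

#' Naive single-phenotype model search
#'
#' Ranks SNPs using the first phenotype only (models `Ma` under the four
#' inheritance codings); no pleiotropic pass.  Equivalent to
#' `pleio_scan(geno, pheno, method = "naive")`.
#'
#' @inheritParams pleio_scan
#' @param da per-subject phenotype values in `{1, 2}`, or a tibble with a
#'   `da` column.
#' @export
naive_scan <- function(geno, da, threshold = 1, alpha = NULL) {
  pheno <- if (is.data.frame(da)) da else tibble::tibble(da = da)
  pleio_scan(geno, pheno, method = "naive", threshold = threshold,
             alpha = alpha)
}

#' Extract a nested SNP set
#'
#' @param scan a `pleio_scan`.
#' @param r set size, `0 <= r <= t`.
#' @return The first `r` rows of the ranking.
#' @export
nested_set <- function(scan, r) {
  stopifnot(inherits(scan, "pleio_scan"))
  if (r < 0 || r > scan$t) stop("`r` must be between 0 and t = ", scan$t)
  head(scan$ranking, r)
}

#' @export
print.pleio_scan <- function(x, ...) {
  cat("Phase-I ", x$method, " model search: ", x$t, " of ", x$n_snps,
      " SNPs retained (ln BF > ", format(x$threshold), ")\n", sep = "")
  if (x$t > 0L) print(head(x$ranking, 10L))
  invisible(x)
}

#' @rdname pleio_scan
#' @param x a `pleio_scan` object.
#' @param ... unused.
#' @export
tidy.pleio_scan <- function(x, ...) {
  dplyr::select(x$ranking, "rank", "snp_id", "model", "mode", "ln_bf",
                "first_pass_model", "first_pass_ln_bf")
}

#' @rdname pleio_scan
#' @export
glance.pleio_scan <- function(x, ...) {
  tibble::tibble(method = x$method, t = x$t, n_snps = x$n_snps,
                 n_subjects = x$n_subjects, threshold = x$threshold)
}
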