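# Smoothed conditional probability tables and Bayesian risk prediction.

#' Smoothed conditional probability table of a SNP
#'
#' Bayesian estimate of `P(S = s | D = d, M)` from a genotypic (3-category)
#' contingency table: entry `(j, s) = (n_js + av) / (n_j. + 3 av)` with the
#' smoothing pseudo-count `av = 4/q`, `q` the number of phenotype rows of
#' the SNP's model.  Rows sum to 1 exactly and all entries are in (0, 1).
#' Prediction always uses the genotypic coding, whatever inheritance mode
#' the model search selected.
#'
#' @param table a genotypic `pleio_ct` (from [build_contingency_table()]).
#' @return Matrix `q x 3` of conditional probabilities, class `pleio_cpt`,
#'   with the smoothing constant in `attr(, "av")`.
#' @export
#' @examples
#' ct <- build_contingency_table(recode_genotypes(c(0, 0, 1), "genotypic"),
#'                               tibble::tibble(da = c(1, 2, 2)), "Ma")
#' fit_cpt(ct)
fit_cpt <- function(table) {
  stopifnot(inherits(table, "pleio_ct"))
  if (table$mode != "genotypic" || table$c != 3L) {
    stop("prediction tables require the genotypic (3-category) coding")
  }
  av <- 4 / table$q
  p <- (table$counts + av) / (table$row_sums + 3 * av)
  structure(p, av = av, class = c("pleio_cpt", class(p)))
}

# Smoothed CPT entries from a count array [3, q, m]: returns [q, 3, m]
# probability array (rows over phenotype classes of the model).
cpt_from_counts <- function(A, q) {
  av <- 4 / q
  tot <- colSums(A)                                  # [q, m]
  p <- sweep(aperm(A + av, c(2L, 1L, 3L)), c(1L, 3L),
             array(tot + 3 * av, c(q, dim(A)[3])), "/")
  p
}

#' Fit the nested Bayesian classifier series
#'
#' For every ranked SNP of a phase-I scan, fits the smoothed genotypic
#' conditional probability table under the SNP's selected model, and stores
#' the per-class log-probabilities needed for prediction.  For the
#' pleiotropic search the classifier works over the four joint phenotype
#' classes (a SNP with model `Ma` contributes the same probabilities to both
#' `db` values, and symmetrically for `Mb`); the naive series works over the
#' two `da` classes.
#'
#' @param scan a `pleio_scan`.
#' @param geno,pheno the discovery data the scan was run on.
#' @param prior `"uniform"` (default) over the phenotype classes, or
#'   `"empirical"` (training class frequencies).
#' @return A `pleio_classifier` with the ranking, the log-CPT array and the
#'   class prior.
#' @export
fit_classifiers <- function(scan, geno, pheno,
                            prior = c("uniform", "empirical")) {
  stopifnot(inherits(scan, "pleio_scan"))
  prior <- match.arg(prior)
  geno <- as_genotype_matrix(geno)
  pheno <- check_phenotypes(pheno, n = nrow(geno),
                            need_db = scan$method == "pleiotropic")
  rk <- scan$ranking
  da <- as.integer(pheno$da)
  if (scan$method == "pleiotropic") {
    cls <- joint_class(da, as.integer(pheno$db)); K <- 4L
  } else {
    cls <- da; K <- 2L
  }
  t_ <- nrow(rk)
  logcpt <- array(0, c(K, 3L, t_))
  if (t_ > 0L) {
    C <- .count_geno(geno[, rk$snp_index, drop = FALSE], cls, K)
    if (K == 2L) {
      logcpt <- aperm(log(cpt_from_counts(C, 2L)), c(1L, 2L, 3L))
    } else {
      for (mod in intersect(c("Ma", "Mb", "Mab"), unique(rk$model))) {
        sel <- which(rk$model == mod)
        groups <- switch(mod, Ma = MA_GROUPS, Mb = MB_GROUPS, Mab = MAB_GROUPS)
        A <- collapse_rows(C[, , sel, drop = FALSE], groups)
        p <- log(cpt_from_counts(A, length(groups)))    # [q, 3, nsel]
        # expand model rows to the 4 joint classes
        expand <- switch(mod, Ma = c(1L, 1L, 2L, 2L), Mb = c(1L, 2L, 1L, 2L),
                         Mab = 1:4)
        logcpt[, , sel] <- p[expand, , , drop = FALSE]
      }
    }
  }
  log_prior <- if (prior == "uniform") rep(-log(K), K) else
    log(tabulate(cls, K) / length(cls))
  structure(
    list(ranking = rk, method = scan$method, K = K, logcpt = logcpt,
         log_prior = log_prior, prior = prior, t = t_),
    class = "pleio_classifier")
}

#' @export
print.pleio_classifier <- function(x, ...) {
  cat("Nested Bayesian classifier series (", x$method, "): ", x$t,
      " ranked SNPs, ", x$prior, " prior over ",
      if (x$K == 4L) "4 joint" else "2", " phenotype classes\n", sep = "")
  invisible(x)
}

#' Joint phenotype posterior for one genetic profile
#'
#' `p(D = d | s, Sigma_r)` is proportional to the class prior times the
#' product over the top `r` ranked SNPs of the smoothed genotype
#' probabilities; SNPs with missing genotype in the profile are skipped.
#'
#' @param classifier a `pleio_classifier`.
#' @param profile genotype vector (0/1/2/NA) named by SNP id, or covering
#'   the classifier's ranked SNPs in ranking order.
#' @param r nested set size, `0 <= r <= t` (`r = 0` returns the prior).
#' @return Named probability vector over the phenotype classes, summing to 1.
#' @export
joint_posterior <- function(classifier, profile, r) {
  stopifnot(inherits(classifier, "pleio_classifier"))
  if (r < 0 || r > classifier$t) stop("`r` must be in [0, t]")
  lp <- classifier$log_prior
  if (r > 0) {
    g <- if (!is.null(names(profile))) {
      as.integer(profile[classifier$ranking$snp_id[seq_len(r)]])
    } else as.integer(profile[seq_len(r)])
    for (i in seq_len(r)) {
      if (!is.na(g[i])) lp <- lp + classifier$logcpt[, g[i] + 1L, i]
    }
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  names(p) <- if (classifier$K == 4L) JOINT_CLASS_LABELS else c("Da=1", "Da=2")
  p
}

# log-sum-exp of two matrices
lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Prediction statistics over all nested set sizes
#'
#' Computes, for each subject and each nested classifier `Sigma_r`
#' (`r = 1..r_max`), the odds-form prediction statistic `C1` for predicting
#' `Da = 2`:
#'
#' * `kind = "marginal"`: `p(Da=2 | s, Sigma_r) / p(Da=1 | s, Sigma_r)`,
#'   the unknown `Db` summed out (pleiotropic series only);
#' * `kind = "conditional"`: `p(Da=2, db | s) / p(Da=1, db | s)` with the
#'   subject's known `db` (pleiotropic series only);
#' * `kind = "naive"`: the two-class posterior odds of a naive series.
#'
#' `variant = "single"` uses the classifier built on `Sigma_r`;
#' `variant = "ensemble"` averages the normalized class posteriors of the
#' classifiers built on `Sigma_1 .. Sigma_r` before taking the ratio.
#'
#' @param classifier a `pleio_classifier`.
#' @param geno genotype matrix of the subjects to classify.
#' @param kind one of `"marginal"`, `"conditional"`, `"naive"`.
#' @param variant `"single"` or `"ensemble"`.
#' @param db known secondary phenotype values (length 1 or one per subject);
#'   required for `kind = "conditional"`.
#' @param r_max largest nested set size (capped at the series length `t`).
#' @return Tibble with columns `subject`, `r`, `kind`, `variant`, `log_c1`,
#'   `c1`.
#' @export
prediction_statistic <- function(classifier, geno, kind, variant = "single",
                                 db = NULL, r_max = classifier$t) {
  stopifnot(inherits(classifier, "pleio_classifier"))
  kind <- match.arg(kind, c("marginal", "conditional", "naive"))
  variant <- match.arg(variant, c("single", "ensemble"))
  geno <- as_genotype_matrix(geno)
  if (kind == "naive" && classifier$method != "naive") {
    stop("naive prediction requires a naive-trained classifier series")
  }
  if (kind != "naive" && classifier$method != "pleiotropic") {
    stop(kind, " prediction requires a pleiotropic classifier series")
  }
  r_use <- min(r_max, classifier$t)
  if (r_use < 1L) stop("classifier series is empty (t = 0)")
  n <- nrow(geno)
  if (kind == "conditional") {
    if (is.null(db)) stop("conditional prediction requires `db`")
    db <- rep_len(as.integer(db), n)
    if (!all(db %in% c(1L, 2L))) stop("`db` values must be 1 or 2")
  }
  ids <- classifier$ranking$snp_id[seq_len(r_use)]
  missing_ids <- setdiff(ids, colnames(geno))
  if (length(missing_ids) > 0L) {
    stop("genotype matrix lacks ranked SNP(s): ",
         paste(head(missing_ids, 3L), collapse = ", "))
  }
  G <- geno[, ids, drop = FALSE]
  LP <- .cum_logpost(classifier$logcpt[, , seq_len(r_use), drop = FALSE],
                     G, classifier$log_prior)          # [n, r, K]
  log_c1 <- stat_from_logpost(LP, kind, variant, db, classifier$K)
  tibble::tibble(
    subject = rep(seq_len(n), times = r_use),
    r = rep(seq_len(r_use), each = n),
    kind = kind, variant = variant,
    log_c1 = as.vector(log_c1), c1 = exp(as.vector(log_c1)))
}

# Extract class slab k of an [n, r, K] array as an [n, r] matrix without
# dimension dropping surprises.
slab <- function(LP, k) matrix(LP[, , k], dim(LP)[1], dim(LP)[2])

row_cumsum <- function(X) {
  if (ncol(X) > 1L) for (j in 2:ncol(X)) X[, j] <- X[, j - 1L] + X[, j]
  X
}

# Per-subject per-db selection of a class slab: rows with db = 1 take class
# `k1`, rows with db = 2 take class `k2`.
db_slab <- function(A, db, k1, k2) {
  out <- slab(A, k1)
  if (any(db == 2L)) out[db == 2L, ] <- slab(A, k2)[db == 2L, , drop = FALSE]
  out
}

# LP: [n, r, K] cumulative log posteriors (unnormalized).  Returns [n, r]
# matrix of log C1.
stat_from_logpost <- function(LP, kind, variant, db, K) {
  n <- dim(LP)[1]; r <- dim(LP)[2]
  if (variant == "single") {
    if (K == 2L) return(slab(LP, 2L) - slab(LP, 1L))
    if (kind == "marginal") {
      return(lse2(slab(LP, 3L), slab(LP, 4L)) -
               lse2(slab(LP, 1L), slab(LP, 2L)))
    }
    # conditional: classes (2, db) vs (1, db); joint index (da-1)*2 + db
    return(db_slab(LP, db, 3L, 4L) - db_slab(LP, db, 1L, 2L))
  }
  # ensemble: normalize posteriors at each k, then cumulative-mean over k
  mx <- slab(LP, 1L)
  for (k in seq_len(K)[-1L]) mx <- pmax(mx, slab(LP, k))
  P <- vector("list", K)
  tot <- matrix(0, n, r)
  for (k in seq_len(K)) {
    P[[k]] <- exp(slab(LP, k) - mx)
    tot <- tot + P[[k]]
  }
  denom <- matrix(seq_len(r), n, r, byrow = TRUE)
  A <- array(NA_real_, c(n, r, K))   # running mean of P(class | Sigma_k)
  for (k in seq_len(K)) A[, , k] <- row_cumsum(P[[k]] / tot) / denom
  if (K == 2L) return(log(slab(A, 2L)) - log(slab(A, 1L)))
  if (kind == "marginal") {
    return(log(slab(A, 3L) + slab(A, 4L)) - log(slab(A, 1L) + slab(A, 2L)))
  }
  log(db_slab(A, db, 3L, 4L)) - log(db_slab(A, db, 1L, 2L))
}

#' Bayesian classification decision
#'
#' Predicts class 2 iff the odds-form statistic strictly exceeds the
#' threshold `T` (default 1, the Bayesian classification rule under
#' balanced priors and 0-1 loss).
#'
#' @param c1 prediction statistic value(s) (`>= 0`).
#' @param threshold positive decision threshold `T`.
#' @return Integer vector of predicted classes in `{1, 2}`.
#' @export
#' @examples
#' decide(c(1.5, 1.0, 0.2), threshold = 1)  # 2 1 1
decide <- function(c1, threshold = 1) {
  if (!is.numeric(threshold) || threshold <= 0) stop("`threshold` must be > 0")
  ifelse(c1 > threshold, 2L, 1L)
}

#' Predict phenotypes for new subjects
#'
#' @param object a `pleio_classifier`.
#' @param geno genotype matrix of the subjects to classify.
#' @param r nested set size to use.
#' @param kind,variant,db see [prediction_statistic()].
#' @param threshold decision threshold `T`.
#' @param ... unused.
#' @return Tibble with one row per subject: `subject`, `r`, `kind`,
#'   `variant`, `c1`, `predicted` (in `{1, 2}`).
#' @export
predict.pleio_classifier <- function(object, geno, r = object$t,
                                     kind = c("marginal", "conditional",
                                              "naive"),
                                     variant = "single", db = NULL,
                                     threshold = 1, ...) {
  kind <- match.arg(kind)
  if (object$method == "naive") kind <- "naive"
  r_use <- min(r, object$t)
  stats <- prediction_statistic(object, geno, kind = kind, variant = variant,
                                db = db, r_max = r_use)
  out <- stats[stats$r == r_use, , drop = FALSE]
  out$predicted <- ifelse(out$log_c1 > log(threshold), 2L, 1L)
  dplyr::select(out, "subject", "r", "kind", "variant", "c1", "predicted")
}

#' @rdname fit_classifiers
#' @param x a `pleio_classifier`.
#' @param ... unused.
#' @export
tidy.pleio_classifier <- function(x, ...) {
  if (x$t == 0L) {
    return(tibble::tibble(rank = integer(), snp_id = character(),
                          class = character(), genotype = integer(),
                          prob = double()))
  }
  classes <- if (x$K == 4L) JOINT_CLASS_LABELS else c("1", "2")
  tibble::tibble(
    rank = rep(seq_len(x$t), each = x$K * 3L),
    snp_id = rep(x$ranking$snp_id, each = x$K * 3L),
    class = rep(rep(classes, 3L), x$t),
    genotype = rep(rep(0:2, each = x$K), x$t),
    prob = exp(as.vector(x$logcpt)))
}

#' @rdname fit_classifiers
#' @export
glance.pleio_classifier <- function(x, ...) {
  tibble::tibble(method = x$method, t = x$t, classes = x$K, prior = x$prior)
}
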