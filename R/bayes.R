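#' Dirichlet-multinomial marginal likelihood of a contingency table
#'
#' Each phenotype row of the table is modelled as a multinomial draw whose
#' category probabilities carry a symmetric Dirichlet prior with
#' pseudo-count `alpha` per cell.  Integrating the probabilities out gives
#' the compound (Polya) marginal likelihood; rows are independent, so the
#' table's log marginal likelihood is the sum over rows of
#' \deqn{\ln\Gamma(c\alpha) - \ln\Gamma(n_{j\cdot} + c\alpha) +
#'       \sum_s [\ln\Gamma(n_{js} + \alpha) - \ln\Gamma(\alpha)]}
#' with `c` the number of genotype categories.
#'
#' The default pseudo-count is `4/q`, with `q` the number of phenotype rows
#' of the model being scored, the same convention the smoothed prediction
#' tables use; the null model (`q = 1`) therefore gets `alpha = 4`.
#'
#' @param table a `pleio_ct` from [build_contingency_table()].
#' @param alpha positive per-cell pseudo-count; default `4/q`.
#' @return Log (natural) marginal likelihood; finite and `<= 0`.
#' @export
log_marginal_likelihood <- function(table, alpha = 4 / table$q) {
  stopifnot(inherits(table, "pleio_ct"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a single positive number")
  }
  n <- table$counts
  if (any(n < 0) || any(n != round(n))) {
    stop("contingency table counts must be non-negative integers")
  }
  cc <- table$c
  sum(lgamma(cc * alpha) - lgamma(rowSums(n) + cc * alpha) +
        rowSums(lgamma(n + alpha)) - cc * lgamma(alpha))
}

#' Log Bayes factor of an association model against its null
#'
#' `ln BF = ln p(S | D, M) - ln p(S | M0)`, both marginal likelihoods
#' computed under the same inheritance coding so that the two models see the
#' identical data representation.  The model table is scored with
#' pseudo-count `4/q` (its own row count) and the null with `4` unless
#' overridden.
#'
#' @param model_table,null_table `pleio_ct` tables for the same SNP and the
#'   same inheritance mode; `null_table` must be an `M0` table.
#' @param alpha_model,alpha_null per-cell pseudo-counts.
#' @return The natural-log Bayes factor.
#' @export
log_bayes_factor <- function(model_table, null_table,
                             alpha_model = 4 / model_table$q,
                             alpha_null = 4) {
  stopifnot(inherits(model_table, "pleio_ct"), inherits(null_table, "pleio_ct"))
  if (model_table$mode != null_table$mode) {
    stop("model and null tables use different inheritance modes (",
         model_table$mode, " vs ", null_table$mode, ")")
  }
  if (null_table$model != "M0") stop("`null_table` must be an M0 table")
  log_marginal_likelihood(model_table, alpha_model) -
    log_marginal_likelihood(null_table, alpha_null)
}

# ---- vectorized scoring on genotype count arrays --------------------------
#
# C: integer array [3 genotype categories, K phenotype classes, m SNPs] of
# class-conditional genotype counts.  All phase-I scoring reduces to sums of
# lgamma terms over such arrays, vectorized across SNPs.

# Collapse genotypic counts [3, q, m] to the counts of a given inheritance
# coding; returns [c, q, m].
collapse_mode <- function(C3, mode) {
  if (mode == "genotypic") return(C3)
  d <- dim(C3)
  out <- array(0L, c(2L, d[2], d[3]))
  switch(mode,
    dominant = {
      out[1L, , ] <- C3[1L, , ]
      out[2L, , ] <- C3[2L, , ] + C3[3L, , ]
    },
    recessive = {
      out[1L, , ] <- C3[1L, , ] + C3[2L, , ]
      out[2L, , ] <- C3[3L, , ]
    },
    allelic = {
      out[1L, , ] <- 2L * C3[1L, , ] + C3[2L, , ]
      out[2L, , ] <- C3[2L, , ] + 2L * C3[3L, , ]
    },
    stop("unknown mode: ", mode))
  out
}

# Log marginal likelihood per SNP for a count array [c, q, m]; returns m-vector.
lnml_counts <- function(A, alpha) {
  d <- dim(A)
  cc <- d[1]; q <- d[2]
  row_tot <- colSums(A)                       # [q, m]
  if (q == 1L) dim(row_tot) <- c(1L, d[3])
  cell_term <- colSums(lgamma(A + alpha))     # [q, m]
  if (q == 1L) dim(cell_term) <- c(1L, d[3])
  colSums(cell_term - lgamma(row_tot + cc * alpha)) +
    q * (lgamma(cc * alpha) - cc * lgamma(alpha))
}

# Per-model row groupings of the joint-class axis (K = 4, order
# (1,1),(1,2),(2,1),(2,2)).
collapse_rows <- function(C, groups) {
  m <- dim(C)[3]
  out <- array(0L, c(3L, length(groups), m))
  for (j in seq_along(groups)) {
    gj <- groups[[j]]
    out[, j, ] <- if (length(gj) == 1L) C[, gj, ] else
      Reduce(`+`, lapply(gj, function(k) C[, k, ]))
  }
  out
}

MA_GROUPS <- list(c(1L, 2L), c(3L, 4L))   # rows by Da
MB_GROUPS <- list(c(1L, 3L), c(2L, 4L))   # rows by Db
M0_GROUPS <- list(1:4)
MAB_GROUPS <- list(1L, 2L, 3L, 4L)
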