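# Independent oracles used to pin down expected values.

# All distinct orderings of a category count vector.
all_orderings <- function(counts) {
  seqs <- list(integer(0))
  for (dummy in seq_len(sum(counts))) {
    seqs <- do.call(c, lapply(seqs, function(s) {
      used <- tabulate(s, nbins = length(counts))
      lapply(which(counts - used > 0L), function(k) c(s, k))
    }))
  }
  seqs
}

# Sequential Polya-urn probability of one ordered category sequence.
polya_sequence_prob <- function(seq_cats, c, alpha) {
  seen <- rep(0, c)
  p <- 1
  for (i in seq_along(seq_cats)) {
    k <- seq_cats[i]
    p <- p * (seen[k] + alpha) / (i - 1 + c * alpha)
    seen[k] <- seen[k] + 1
  }
  p
}

# Enumeration oracle for the Dirichlet-multinomial log marginal likelihood
# of a table: per row, every ordering must give the same sequence
# probability; the table's log marginal is the sum of row logs.
polya_table_log_marginal <- function(counts, alpha) {
  sum(apply(counts, 1, function(row) {
    if (sum(row) == 0) return(0)
    probs <- vapply(all_orderings(row), polya_sequence_prob, 0,
                    c = length(row), alpha = alpha)
    stopifnot(diff(range(probs)) < 1e-12 * max(probs))
    log(probs[1])
  }))
}

# Pair-counting AUC oracle.
auc_pairs <- function(scores, labels) {
  x <- scores[labels == 2]; y <- scores[labels == 1]
  pairs <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Trapezoidal area under the empirical ROC curve.
auc_trapezoid <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[labels == 2] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Brute-force Youden maximization over a dense candidate set.
youden_brute <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- sort(c(u - 1e-9, u + 1e-9, u[1] - 1, u[length(u)] + 1,
                 if (length(u) > 1) (u[-1] + u[-length(u)]) / 2))
  j <- vapply(cand, function(t) {
    mean(scores[labels == 2] > t) + mean(scores[labels == 1] <= t) - 1
  }, 0)
  list(threshold = cand[which.max(j)], j = max(j))
}

# Draw one SNP column given per-subject joint classes and a 4 x 3 class
# genotype frequency matrix.
draw_snp <- function(cls, freqs) {
  vapply(cls, function(k) sample(0:2, 1, prob = freqs[k, ]), 0L)
}

# Small fully-specified study: per-class counts, causal freq matrices.
make_geno <- function(n_per_class, freq_list) {
  cls <- rep(1:4, n_per_class)
  G <- vapply(freq_list, function(f) draw_snp(cls, f),
              integer(sum(n_per_class)))
  colnames(G) <- paste0("s", seq_along(freq_list))
  list(geno = G,
       pheno = tibble::tibble(da = ifelse(cls >= 3, 2L, 1L),
                              db = ifelse(cls %% 2 == 0, 2L, 1L)),
       cls = cls)
}

hwe_freqs <- function(maf) {
  matrix(rep(c((1 - maf)^2, 2 * maf * (1 - maf), maf^2), each = 4), 4, 3)
}
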