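# Smoothed CPTs, joint posteriors, prediction statistics and decisions.

test_that("smoothed CPT entries follow the (n + av)/(n. + 3 av) formula", {
  ph <- tibble::tibble(da = c(2L, 2L, 2L))
  ct <- build_contingency_table(recode_genotypes(c(0L, 0L, 0L), "genotypic"),
                                ph, "Ma")
  p <- fit_cpt(ct)   # q = 2, av = 2; empty Da=1 row is uniform
  expect_equal(unname(p["Da=1", ]), rep(1 / 3, 3))
  expect_equal(unname(p["Da=2", ]), c(5 / 9, 2 / 9, 2 / 9))
  expect_equal(attr(p, "av"), 2)
  # row counts (10, 0, 0) with q = 2
  ct2 <- build_contingency_table(
    recode_genotypes(rep(0L, 10), "genotypic"),
    tibble::tibble(da = rep(1L, 10)), "Ma")
  expect_equal(unname(fit_cpt(ct2)[1, ]), c(0.75, 0.125, 0.125))
  # q = 4 (Mab): av = 1, row (1,1,1) -> uniform
  ph4 <- tibble::tibble(da = rep(1L, 3), db = rep(1L, 3))
  ct4 <- build_contingency_table(recode_genotypes(c(0L, 1L, 2L), "genotypic"),
                                 ph4, "Mab")
  expect_equal(unname(fit_cpt(ct4)[1, ]), rep(1 / 3, 3))
  expect_equal(rowSums(fit_cpt(ct4)), setNames(rep(1, 4),
                                               rownames(ct4$counts)))
})

test_that("non-genotypic tables are rejected for prediction", {
  ct <- build_contingency_table(recode_genotypes(c(0L, 1L), "dominant"),
                                tibble::tibble(da = c(1L, 2L)), "Ma")
  expect_error(fit_cpt(ct), "genotypic")
})

make_classifier <- function(logcpt, method = "pleiotropic",
                            log_prior = rep(-log(dim(logcpt)[1]),
                                            dim(logcpt)[1])) {
  t_ <- dim(logcpt)[3]
  structure(list(
    ranking = tibble::tibble(snp_id = paste0("s", seq_len(t_)),
                             snp_index = seq_len(t_),
                             model = rep("Mab", t_), rank = seq_len(t_)),
    method = method, K = dim(logcpt)[1], logcpt = logcpt,
    log_prior = log_prior, prior = "uniform", t = t_),
    class = "pleio_classifier")
}

test_that("joint posterior matches hand enumeration", {
  cpt <- rbind(c(0.8, 0.1, 0.1), c(0.6, 0.2, 0.2),
               c(0.2, 0.4, 0.4), c(0.1, 0.45, 0.45))
  logcpt <- array(log(cpt), c(4, 3, 1))
  clf <- make_classifier(logcpt)
  post <- joint_posterior(clf, c(s1 = 0L), r = 1)
  expect_equal(unname(post), c(0.8, 0.6, 0.2, 0.1) / 1.7)
  # r = 0 returns the prior; uniform CPTs return the prior too
  expect_equal(unname(joint_posterior(clf, c(s1 = 0L), r = 0)), rep(0.25, 4))
  unif <- make_classifier(array(log(1 / 3), c(4, 3, 2)))
  expect_equal(unname(joint_posterior(unif, c(s1 = 1L, s2 = 2L), r = 2)),
               rep(0.25, 4))
  expect_error(joint_posterior(clf, c(s1 = 0L), r = 5), "\\[0, t\\]")
})

test_that("posteriors normalize and missing profile SNPs are skipped", {
  set.seed(41)
  for (rep_i in 1:5) {
    t_ <- 4L
    cpt <- array(runif(4 * 3 * t_), c(4, 3, t_))
    for (i in seq_len(t_)) cpt[, , i] <- cpt[, , i] / rowSums(cpt[, , i])
    clf <- make_classifier(log(cpt))
    prof <- setNames(sample(c(0:2, NA), t_, TRUE), paste0("s", 1:t_))
    for (r in 0:t_) {
      expect_equal(sum(joint_posterior(clf, prof, r)), 1, tolerance = 1e-12)
    }
    # a missing genotype contributes nothing: equals dropping the SNP
    prof2 <- prof; prof2[2] <- NA
    p_skip <- joint_posterior(clf, prof2, 2)
    cpt1 <- cpt[, , c(1, 1), drop = FALSE]  # duplicate SNP1, ignore slot 2
    clf1 <- make_classifier(log(cpt1))
    prof3 <- setNames(c(prof2[1], NA), c("s1", "s2"))
    expect_equal(p_skip, joint_posterior(clf1, prof3, 2))
  }
})

test_that("prediction statistics reduce correctly in structured cases", {
  # uniform CPTs and uniform prior: every statistic is 1
  unif <- make_classifier(array(log(1 / 3), c(4, 3, 3)))
  G <- matrix(sample(0:2, 15, TRUE), 5, 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  for (kind in c("marginal", "conditional")) {
    for (variant in c("single", "ensemble")) {
      st <- prediction_statistic(unif, G, kind, variant,
                                 db = rep(1:2, length.out = 5))
      expect_equal(st$c1, rep(1, nrow(st)))
    }
  }
  # r = 1: ensemble equals single for every kind
  set.seed(42)
  cpt <- array(runif(4 * 3 * 3), c(4, 3, 3))
  for (i in 1:3) cpt[, , i] <- cpt[, , i] / rowSums(cpt[, , i])
  clf <- make_classifier(log(cpt))
  for (kind in c("marginal", "conditional")) {
    s1 <- prediction_statistic(clf, G, kind, "single", db = rep(1L, 5))
    s2 <- prediction_statistic(clf, G, kind, "ensemble", db = rep(1L, 5))
    expect_equal(s1$log_c1[s1$r == 1], s2$log_c1[s2$r == 1])
  }
})

test_that("Ma-only series makes conditional equal marginal", {
  # when no SNP depends on Db, knowing db cannot change the Da odds
  set.seed(43)
  cpt2 <- array(runif(2 * 3 * 4), c(2, 3, 4))
  for (i in 1:4) cpt2[, , i] <- cpt2[, , i] / rowSums(cpt2[, , i])
  logcpt <- array(NA_real_, c(4, 3, 4))
  logcpt[1, , ] <- logcpt[2, , ] <- log(cpt2[1, , ])  # rows by Da only
  logcpt[3, , ] <- logcpt[4, , ] <- log(cpt2[2, , ])
  clf <- make_classifier(logcpt)
  G <- matrix(sample(0:2, 24, TRUE), 6, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  sm <- prediction_statistic(clf, G, "marginal")
  for (dbv in 1:2) {
    sc <- prediction_statistic(clf, G, "conditional", db = rep(dbv, 6))
    expect_equal(sc$log_c1, sm$log_c1, tolerance = 1e-12)
  }
  # and the statistic is invariant to SNP order within the set
  perm <- c(3, 1, 4, 2)
  clf_p <- make_classifier(logcpt[, , perm])
  sm_p <- prediction_statistic(clf_p, G[, perm, drop = FALSE]
                               |> `colnames<-`(paste0("s", 1:4)), "marginal")
  expect_equal(sm_p$log_c1[sm_p$r == 4], sm$log_c1[sm$r == 4],
               tolerance = 1e-12)
})

test_that("ensemble averages normalized posteriors across nested sets", {
  set.seed(44)
  cpt <- array(runif(4 * 3 * 3), c(4, 3, 3))
  for (i in 1:3) cpt[, , i] <- cpt[, , i] / rowSums(cpt[, , i])
  clf <- make_classifier(log(cpt))
  prof <- setNames(sample(0:2, 3, TRUE), paste0("s", 1:3))
  G <- matrix(prof, 1, dimnames = list(NULL, names(prof)))
  post <- vapply(1:3, function(k) joint_posterior(clf, prof, k), numeric(4))
  for (r in 1:3) {
    avg <- rowMeans(post[, 1:r, drop = FALSE])
    want <- unname(log((avg[3] + avg[4]) / (avg[1] + avg[2])))
    st <- prediction_statistic(clf, G, "marginal", "ensemble", r_max = r)
    expect_equal(st$log_c1[st$r == r], want, tolerance = 1e-12)
  }
})

test_that("the Bayesian decision rule is strict at the threshold", {
  expect_equal(decide(c(1.5, 1.0, 0.2), 1), c(2L, 1L, 1L))
  expect_equal(decide(0.2, 0.1), 2L)
  expect_error(decide(1, threshold = 0), "> 0")
  # with T = 1 and uniform prior: class 2 iff posterior P(Da = 2) > 1/2
  set.seed(45)
  for (i in 1:20) {
    cpt <- array(runif(4 * 3 * 2), c(4, 3, 2))
    for (k in 1:2) cpt[, , k] <- cpt[, , k] / rowSums(cpt[, , k])
    clf <- make_classifier(log(cpt))
    prof <- setNames(sample(0:2, 2, TRUE), c("s1", "s2"))
    post <- joint_posterior(clf, prof, 2)
    G <- matrix(prof, 1, dimnames = list(NULL, names(prof)))
    st <- prediction_statistic(clf, G, "marginal", r_max = 2)
    expect_equal(decide(st$c1[st$r == 2], 1) == 2L,
                 post[3] + post[4] > 0.5, ignore_attr = TRUE)
  }
})

test_that("kind/series mismatches and bad db are errors", {
  unif4 <- make_classifier(array(log(1 / 3), c(4, 3, 1)))
  unif2 <- make_classifier(array(log(1 / 3), c(2, 3, 1)), method = "naive")
  G <- matrix(0L, 2, 1, dimnames = list(NULL, "s1"))
  expect_error(prediction_statistic(unif4, G, "naive"), "naive-trained")
  expect_error(prediction_statistic(unif2, G, "marginal"), "pleiotropic")
  expect_error(prediction_statistic(unif4, G, "conditional"), "db")
  expect_error(prediction_statistic(unif4, G, "conditional", db = c(0, 3)),
               "1 or 2")
})
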