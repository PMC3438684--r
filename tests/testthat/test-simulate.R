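# GWAS simulator: causal draws, class frequencies, study generation,
# scenario presets.

test_that("causal specs respect counts, bounds and degenerate ORs", {
  cfg <- scenario_config(n_discovery = 100, n_snps_total = 500,
                         n_pleiotropic = 50, n_da_only = 50, n_db_only = 50,
                         or_a = c(2, 2), or_b = c(2, 2))
  set.seed(71)
  sp <- draw_causal_specs(cfg)
  expect_equal(as.vector(table(sp$target)[c("both", "Da", "Db")]),
               c(50L, 50L, 50L))
  expect_true(all(sp$or_a[sp$target %in% c("both", "Da")] == 2))
  expect_true(all(sp$or_a[sp$target == "Db"] == 1))
  expect_true(all(sp$maf > 0.05 & sp$maf < 0.5))
  expect_error(draw_causal_specs(cfg, maf_pool = numeric(0)), "empty")
  expect_error(draw_causal_specs(cfg, maf_pool = c(0.2, 0.04)), "> 0.05")
})

test_that("mode and allele draws are uniform in the long run", {
  cfg <- scenario_config(n_discovery = 100, n_snps_total = 20000,
                         n_pleiotropic = 10000, n_da_only = 0, n_db_only = 0,
                         or_a = c(1.5, 2.5))
  set.seed(72)
  sp <- draw_causal_specs(cfg)
  expect_true(all(abs(table(sp$mode) / 10000 - 1 / 3) < 0.02))
  expect_true(all(abs(table(sp$disease_allele) / 10000 - 1 / 2) < 0.02))
  expect_true(all(sp$or_a >= 1.5 & sp$or_a <= 2.5))
})

test_that("class genotype frequencies implement the odds tilts", {
  # OR = 1: Hardy-Weinberg everywhere
  f <- class_genotype_freqs(0.3, "B", 1, 1, "dominant")
  expect_equal(unname(f), matrix(rep(c(0.49, 0.42, 0.09), each = 4), 4, 3))
  # dominant with carrier probability 0.5: affected carrier prob = 2/3
  maf <- 1 - sqrt(0.5)   # P(carrier of B) = 1 - (1-maf)^2 = 0.5
  fd <- class_genotype_freqs(maf, "B", or_a = 2, mode = "dominant")
  expect_equal(sum(fd["2,1", c("AB", "BB")]), 2 / 3)
  expect_equal(sum(fd["1,1", c("AB", "BB")]), 1 / 2)
  # additive: homozygote OR equals the full OR, heterozygote its square root
  fa <- class_genotype_freqs(0.25, "B", or_a = 4, mode = "additive")
  or_hom <- (fa["2,1", "BB"] / fa["2,1", "AA"]) /
    (fa["1,1", "BB"] / fa["1,1", "AA"])
  or_het <- (fa["2,1", "AB"] / fa["2,1", "AA"]) /
    (fa["1,1", "AB"] / fa["1,1", "AA"])
  expect_equal(or_hom, 4)
  expect_equal(or_het, 2)
  # disease allele A flips the risk direction
  fr <- class_genotype_freqs(0.2, "A", or_a = 3, mode = "recessive")
  or_AA <- (fr["2,1", "AA"] / fr["2,1", "BB"]) /
    (fr["1,1", "AA"] / fr["1,1", "BB"])
  expect_equal(or_AA, 3)
  # pleiotropic weights multiply in the doubly-affected class
  fp <- class_genotype_freqs(0.3, "B", or_a = 2, or_b = 3, mode = "dominant")
  odds <- function(row) sum(fp[row, c("AB", "BB")]) / fp[row, "AA"]
  expect_equal(odds("2,2") / odds("1,1"), 6, tolerance = 1e-12)
  expect_true(all(abs(rowSums(fp) - 1) < 1e-15))
  expect_error(class_genotype_freqs(0.3, "B", or_a = 0.5), ">= 1")
})

test_that("simulated studies have exact class counts and are seeded", {
  cfg <- scenario_config(n_discovery = 40, n_validation = 20,
                         counts_discovery = c(25, 5, 8, 2),
                         counts_validation = c(5, 5, 5, 5),
                         n_snps_total = 30, n_pleiotropic = 2,
                         n_da_only = 2, n_db_only = 2,
                         or_a = c(2, 3), or_b = c(2, 3))
  s1 <- simulate_study(cfg, seed = 9)
  s2 <- simulate_study(cfg, seed = 9)
  expect_identical(s1$discovery$genotypes, s2$discovery$genotypes)
  expect_identical(s1$truth, s2$truth)
  ph <- s1$discovery$phenotypes
  cls <- (ph$da - 1) * 2 + ph$db
  expect_equal(as.vector(table(factor(cls, 1:4))), c(25, 5, 8, 2))
  expect_equal(nrow(s1$validation$phenotypes), 20)
  expect_equal(sum(s1$truth$target != "none"), 6)
  expect_equal(ncol(s1$discovery$genotypes), 30)
})

test_that("the generator recovers assigned odds ratios at large n", {
  n <- 100000
  for (mode in c("dominant", "recessive", "additive")) {
    set.seed(73)
    f <- class_genotype_freqs(0.3, "B", or_a = 2, mode = mode)
    cls <- rep(c(1L, 3L), each = n)   # Da = 1 vs Da = 2, Db = 1
    cum <- array(0, c(2, 4, 1))
    cum[1, , 1] <- f[, 1]; cum[2, , 1] <- f[, 1] + f[, 2]
    G <- pleiobayes:::.gen_genotypes(cum, cls, 4L, 1L)
    tab <- table(factor(G[cls == 1, 1], 0:2), dnn = NULL)
    tab2 <- table(factor(G[cls == 3, 1], 0:2), dnn = NULL)
    emp_or <- switch(mode,
      dominant = (sum(tab2[2:3]) / tab2[1]) / (sum(tab[2:3]) / tab[1]),
      recessive = (tab2[3] / sum(tab2[1:2])) / (tab[3] / sum(tab[1:2])),
      additive = (tab2[3] / tab2[1]) / (tab[3] / tab[1]))
    expect_equal(as.numeric(emp_or), 2, tolerance = 0.1)
  }
})

test_that("null SNPs stay at Hardy-Weinberg independent of class", {
  cfg <- scenario_config(n_discovery = 20000, n_validation = 4,
                         n_snps_total = 5, n_pleiotropic = 0, n_da_only = 0,
                         n_db_only = 0, or_a = c(1, 1))
  sim <- simulate_study(cfg, seed = 74)
  G <- sim$discovery$genotypes
  for (j in 1:5) {
    maf <- sim$truth$maf[j]
    want <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    emp <- as.vector(table(factor(G[, j], 0:2))) / nrow(G)
    expect_true(all(abs(emp - want) < 0.015))
  }
})

test_that("non-causal SNPs pass a chi-square screen at the nominal rate", {
  cfg <- scenario_config(n_discovery = 4000, n_validation = 4,
                         n_snps_total = 2500, n_pleiotropic = 0,
                         n_da_only = 0, n_db_only = 0, or_a = c(1, 1))
  sim <- simulate_study(cfg, seed = 75)
  G <- sim$discovery$genotypes
  da <- sim$discovery$phenotypes$da
  p <- vapply(seq_len(ncol(G)), function(j) {
    suppressWarnings(stats::chisq.test(table(G[, j], da))$p.value)
  }, 0)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("scenario presets encode the documented study designs", {
  s5 <- scenario_preset("set2_scenario5")
  expect_equal(s5$or_a, c(2.0, 2.5))
  expect_equal(s5$or_b, c(1.5, 2.0))
  expect_equal(s5$counts_discovery, c(450L, 450L, 50L, 50L))
  expect_equal(s5$counts_validation, c(1800L, 1800L, 200L, 200L))
  s41 <- scenario_preset("set4_scenario1")
  expect_equal(s41$n_discovery, 4000)
  expect_equal(s41$or_a, c(1.1, 2.5))
  s3 <- scenario_preset("set3_moderate")
  expect_equal(c(s3$n_pleiotropic, s3$n_da_only, s3$n_db_only),
               c(0L, 75L, 75L))
  # scenario names carry the sample size (odd 1500, even 4000)
  expect_equal(scenario_preset("set1_scenario6")$n_discovery, 4000)
  expect_equal(scenario_preset("set1_scenario6")$or_a, c(1.75, 2.5))
  expect_equal(scenario_preset("set1_scenario1")$n_discovery, 1500)
  expect_equal(scenario_preset("set1_scenario1")$counts_discovery,
               c(375L, 375L, 375L, 375L))
  for (nm in scenario_names()) {
    cfg <- scenario_preset(nm)
    expect_equal(cfg$n_snps_total, 500150L)
    expect_equal(cfg$n_validation, 4000)
  }
  expect_error(scenario_preset("set9_bogus"))
})
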