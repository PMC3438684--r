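# Case-control GWAS simulator with two dichotomous phenotypes.
#
# Each study draws per-causal-SNP parameters (MAF, disease allele, odds
# ratio(s), inheritance mode), converts them to genotype frequencies per
# joint phenotype class (Hardy-Weinberg in unaffected classes, odds-tilted
# in affected ones), assigns subjects to phenotype classes with exact
# scenario counts, and draws every genotype independently given class.

#' Build a simulation scenario configuration
#'
#' @param n_discovery number of discovery subjects.
#' @param n_validation number of validation subjects (default 4000).
#' @param counts_discovery,counts_validation subject counts for the four
#'   joint phenotype classes in the order (1,1), (1,2), (2,1), (2,2);
#'   default balanced.
#' @param n_snps_total total SNPs on the simulated assay (default 500150).
#' @param n_pleiotropic,n_da_only,n_db_only causal SNP counts by type.
#' @param or_a,or_b `c(min, max)` odds-ratio bounds per trait (`min >= 1`).
#' @param name scenario label carried along for reporting.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_discovery,
                            n_validation = 4000,
                            counts_discovery = NULL,
                            counts_validation = NULL,
                            n_snps_total = 500150,
                            n_pleiotropic = 50, n_da_only = 50,
                            n_db_only = 50,
                            or_a = c(1.1, 2.5), or_b = or_a,
                            name = "custom") {
  balanced <- function(n) {
    base <- rep(n %/% 4, 4)
    base + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
  }
  if (is.null(counts_discovery)) counts_discovery <- balanced(n_discovery)
  if (is.null(counts_validation)) counts_validation <- balanced(n_validation)
  stopifnot(sum(counts_discovery) == n_discovery,
            sum(counts_validation) == n_validation,
            n_pleiotropic + n_da_only + n_db_only <= n_snps_total,
            or_a[1] >= 1, or_a[2] >= or_a[1],
            or_b[1] >= 1, or_b[2] >= or_b[1])
  structure(
    list(name = name, n_discovery = n_discovery, n_validation = n_validation,
         counts_discovery = as.integer(counts_discovery),
         counts_validation = as.integer(counts_validation),
         n_snps_total = as.integer(n_snps_total),
         n_pleiotropic = as.integer(n_pleiotropic),
         n_da_only = as.integer(n_da_only), n_db_only = as.integer(n_db_only),
         or_a = as.numeric(or_a), or_b = as.numeric(or_b)),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario ", x$name, ": n_discovery=", x$n_discovery,
      " (classes ", paste(x$counts_discovery, collapse = "/"),
      "), n_validation=", x$n_validation, ", SNPs=", x$n_snps_total,
      ", causal ", x$n_pleiotropic, "/", x$n_da_only, "/", x$n_db_only,
      " (pleio/Da/Db), OR_a [", x$or_a[1], ", ", x$or_a[2],
      "], OR_b [", x$or_b[1], ", ", x$or_b[2], "]\n", sep = "")
  invisible(x)
}

#' Preset simulation scenarios
#'
#' The 16 documented study scenarios.  Set 1: six balanced case-control
#' scenarios crossing sample size (odd scenarios 1500, even 4000 — the
#' scenario names are authoritative) with odds-ratio ranges
#' (1.10-1.50), (1.25-2.00), (1.75-2.50), 50/50/50 causal SNPs.
#' Set 2: 1000 discovery subjects with unbalanced Da (10% cases; joint
#' counts 450/450/50/50, validation 1800/1800/200/200) and six OR-range
#' pairs.  Set 3: no pleiotropic SNPs (75/75/0), moderate (1.25-2.0) or
#' strong (1.75-2.5) effects.  Set 4: wide OR range 1.1-2.5 with 4000 or
#' 1500 discovery subjects.  All presets carry a 500150-SNP assay and a
#' 4000-subject validation set.
#'
#' @param name e.g. `"set1_scenario6"`, `"set2_scenario5"`,
#'   `"set3_moderate"`, `"set3_strong"`, `"set4_scenario1"`.
#' @return A [scenario_config()].
#' @export
#' @examples
#' scenario_preset("set2_scenario5")
scenario_preset <- function(name) {
  name <- match.arg(name, scenario_names())
  or1 <- list(c(1.10, 1.50), c(1.10, 1.50), c(1.25, 2.00),
              c(1.25, 2.00), c(1.75, 2.50), c(1.75, 2.50))
  set2_a <- list(c(1.1, 1.5), c(1.1, 1.5), c(1.5, 2.0),
                 c(1.5, 2.0), c(2.0, 2.5), c(2.0, 2.5))
  set2_b <- list(c(1.5, 2.0), c(2.0, 2.5), c(1.5, 2.0),
                 c(2.0, 2.5), c(1.5, 2.0), c(1.5, 2.5))
  if (grepl("^set1", name)) {
    i <- as.integer(sub("set1_scenario", "", name))
    scenario_config(n_discovery = if (i %% 2 == 1) 1500 else 4000,
                    or_a = or1[[i]], name = name)
  } else if (grepl("^set2", name)) {
    i <- as.integer(sub("set2_scenario", "", name))
    scenario_config(n_discovery = 1000,
                    counts_discovery = c(450, 450, 50, 50),
                    counts_validation = c(1800, 1800, 200, 200),
                    or_a = set2_a[[i]], or_b = set2_b[[i]], name = name)
  } else if (grepl("^set3", name)) {
    scenario_config(n_discovery = 4000,
                    n_pleiotropic = 0, n_da_only = 75, n_db_only = 75,
                    or_a = if (name == "set3_moderate") c(1.25, 2.0)
                           else c(1.75, 2.5),
                    name = name)
  } else {
    i <- as.integer(sub("set4_scenario", "", name))
    scenario_config(n_discovery = if (i == 1) 4000 else 1500,
                    or_a = c(1.1, 2.5), name = name)
  }
}

#' @rdname scenario_preset
#' @export
scenario_names <- function() {
  c(paste0("set1_scenario", 1:6), paste0("set2_scenario", 1:6),
    "set3_moderate", "set3_strong", paste0("set4_scenario", 1:2))
}

SIM_MODES <- c("dominant", "recessive", "additive")

#' Draw causal SNP specifications
#'
#' Independent uniform draws per causal SNP: minor allele frequency from
#' `maf_pool` (default `Uniform(0.05, 0.5)`), disease allele from
#' `{A, B}`, odds ratio(s) uniform within the scenario bounds, and mode of
#' inheritance from `{dominant, recessive, additive}`.
#'
#' @param config a [scenario_config()].
#' @param maf_pool optional numeric vector of allowed MAFs (all `> 0.05`),
#'   e.g. from a genotyping-array manifest.
#' @return Tibble with one row per causal SNP: `target`
#'   (`"both"/"Da"/"Db"`), `maf`, `disease_allele`, `or_a`, `or_b`, `mode`.
#' @export
draw_causal_specs <- function(config, maf_pool = NULL) {
  if (!is.null(maf_pool)) {
    if (length(maf_pool) == 0L) stop("`maf_pool` is empty")
    if (any(maf_pool <= 0.05)) stop("all `maf_pool` entries must be > 0.05")
  }
  n <- config$n_pleiotropic + config$n_da_only + config$n_db_only
  target <- rep(c("both", "Da", "Db"),
                c(config$n_pleiotropic, config$n_da_only, config$n_db_only))
  maf <- if (is.null(maf_pool)) runif(n, 0.05, 0.5) else
    sample(maf_pool, n, replace = TRUE)
  or_a <- ifelse(target %in% c("both", "Da"),
                 runif(n, config$or_a[1], config$or_a[2]), 1)
  or_b <- ifelse(target %in% c("both", "Db"),
                 runif(n, config$or_b[1], config$or_b[2]), 1)
  tibble::tibble(
    target = target, maf = maf,
    disease_allele = sample(c("A", "B"), n, replace = TRUE),
    or_a = or_a, or_b = or_b,
    mode = sample(SIM_MODES, n, replace = TRUE))
}

#' Genotype frequencies per joint phenotype class
#'
#' Baseline frequencies are Hardy-Weinberg for allele-B frequency `maf`
#' (so `AA, AB, BB` have frequencies `(1-maf)^2, 2 maf (1-maf), maf^2`).
#' Classes unaffected for a trait keep the baseline.  Affected classes are
#' tilted by genotype risk weights and renormalized:
#' dominant/recessive weight `OR` on the carrier/homozygote risk set, and
#' the additive mode weights `sqrt(OR)^x` with `x` the disease-allele
#' count, so the homozygote-vs-homozygote odds ratio equals the full `OR`.
#' For pleiotropic SNPs the two traits' weights multiply in the
#' doubly-affected class (additive on the log-odds scale).
#'
#' @param maf allele-B frequency in `(0, 0.5]`.
#' @param disease_allele `"A"` or `"B"`.
#' @param or_a,or_b odds ratios (`>= 1`; 1 = not associated with the trait).
#' @param mode `"dominant"`, `"recessive"` or `"additive"`.
#' @return A `4 x 3` matrix of genotype frequencies, rows the joint classes
#'   (1,1), (1,2), (2,1), (2,2), each row summing to 1.
#' @export
class_genotype_freqs <- function(maf, disease_allele, or_a = 1, or_b = 1,
                                 mode = "dominant") {
  mode <- match.arg(mode, SIM_MODES)
  stopifnot(maf > 0, maf <= 0.5, disease_allele %in% c("A", "B"))
  if (or_a < 1 || or_b < 1) {
    stop("odds ratios must be >= 1; protective effects are encoded by the ",
         "disease allele")
  }
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  x <- if (disease_allele == "B") 0:2 else 2:0   # disease-allele count
  w <- function(or) {
    switch(mode,
           dominant = or^(x >= 1),
           recessive = or^(x == 2),
           additive = sqrt(or)^x)
  }
  wa <- w(or_a); wb <- w(or_b)
  out <- rbind(hwe,                 # (1,1)
               hwe * wb,            # (1,2): affected for Db only
               hwe * wa,            # (2,1): affected for Da only
               hwe * wa * wb)       # (2,2): both effects, log-odds additive
  out <- out / rowSums(out)
  dimnames(out) <- list(JOINT_CLASS_LABELS, c("AA", "AB", "BB"))
  out
}

#' Simulate a two-phenotype case-control GWAS study
#'
#' Subjects are assigned joint phenotype classes with exactly the counts in
#' the configuration; genotypes are then drawn independently per SNP given
#' the class, from [class_genotype_freqs()] for causal SNPs and from
#' Hardy-Weinberg frequencies (class-independent) for null SNPs.  Causal
#' SNPs are placed at seeded-random positions on the assay.
#'
#' @param config a [scenario_config()].
#' @param specs optional causal specification tibble (from
#'   [draw_causal_specs()]); drawn automatically if `NULL`.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param maf_pool optional MAF pool passed to [draw_causal_specs()] and
#'   used for null SNP frequencies.
#' @return A list with `discovery` and `validation` (each
#'   `list(genotypes, phenotypes)`), `truth` (per-SNP tibble with `snp_id`,
#'   `target`, and the causal parameters), and `config`.
#' @export
simulate_study <- function(config, specs = NULL, seed = NULL,
                           maf_pool = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(specs)) specs <- draw_causal_specs(config, maf_pool)
  n_causal <- config$n_pleiotropic + config$n_da_only + config$n_db_only
  if (nrow(specs) != n_causal) {
    stop("`specs` has ", nrow(specs), " rows but the scenario requires ",
         n_causal, " causal SNPs")
  }
  m <- config$n_snps_total
  snp_ids <- sprintf("snp%06d", seq_len(m))
  causal_idx <- sort(sample.int(m, n_causal))
  # per-SNP per-class cumulative genotype probabilities [2, 4, m]
  null_maf <- if (is.null(maf_pool)) runif(m, 0.05, 0.5) else
    sample(maf_pool, m, replace = TRUE)
  p0 <- (1 - null_maf)^2
  p01 <- p0 + 2 * null_maf * (1 - null_maf)
  cum <- array(0, c(2L, 4L, m))
  cum[1L, , ] <- rep(p0, each = 4L)
  cum[2L, , ] <- rep(p01, each = 4L)
  for (i in seq_len(n_causal)) {
    f <- class_genotype_freqs(specs$maf[i], specs$disease_allele[i],
                              specs$or_a[i], specs$or_b[i], specs$mode[i])
    cum[1L, , causal_idx[i]] <- f[, 1L]
    cum[2L, , causal_idx[i]] <- f[, 1L] + f[, 2L]
  }
  draw_set <- function(counts) {
    cls <- rep(1:4, counts)
    G <- .gen_genotypes(cum, cls, 4L, m)
    colnames(G) <- snp_ids
    da <- ifelse(cls >= 3L, 2L, 1L)
    db <- ifelse(cls %% 2L == 0L, 2L, 1L)
    list(genotypes = G,
         phenotypes = tibble::tibble(subject = seq_along(cls),
                                     da = da, db = db))
  }
  truth <- tibble::tibble(snp_id = snp_ids, target = "none",
                          maf = null_maf, disease_allele = NA_character_,
                          or_a = 1, or_b = 1, mode = NA_character_)
  truth$target[causal_idx] <- specs$target
  truth$maf[causal_idx] <- specs$maf
  truth$disease_allele[causal_idx] <- specs$disease_allele
  truth$or_a[causal_idx] <- specs$or_a
  truth$or_b[causal_idx] <- specs$or_b
  truth$mode[causal_idx] <- specs$mode
  list(discovery = draw_set(config$counts_discovery),
       validation = draw_set(config$counts_validation),
       truth = truth, config = config)
}
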