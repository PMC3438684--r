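#' Genotype and phenotype containers
#'
#' Genotypes are held as an integer matrix with one row per subject and one
#' column per SNP, coded by the count of the A2 ("B") allele: `0` = AA
#' (homozygous A1), `1` = AB, `2` = BB, `NA` = missing.  Column names are the
#' SNP identifiers.  Phenotypes travel in a tibble with one row per subject
#' and columns `da` and (optionally) `db`, each taking values in `{1, 2}`
#' with 2 the affected ("case") class.
#'
#' `as_genotype_matrix()` normalises input: it accepts an integer/numeric
#' matrix of 0/1/2/NA or a character matrix of `"AA"/"AB"/"BB"` (missing as
#' `NA`, `""` or `"00"`), checks ranges and uniqueness of SNP ids, and
#' returns the canonical integer form.
#'
#' @param x matrix of genotypes (subjects x SNPs).
#' @param snp_ids optional character vector of SNP identifiers; defaults to
#'   existing column names or `snp1..snpM`.
#' @return An integer matrix of 0/1/2/NA with unique column names.
#' @export
as_genotype_matrix <- function(x, snp_ids = NULL) {
  if (!is.matrix(x)) stop("`x` must be a matrix (subjects x SNPs)")
  if (is.character(x)) {
    codes <- c(AA = 0L, AB = 1L, BA = 1L, BB = 2L)
    g <- codes[x]
    bad <- !is.na(x) & x != "" & x != "00" & is.na(g)
    if (any(bad)) {
      stop("unknown genotype symbol(s): ",
           paste(unique(x[bad]), collapse = ", "))
    }
    x <- matrix(g, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  if (!is.numeric(x) && !is.integer(x)) stop("genotypes must be coded 0/1/2")
  if (!is.integer(x)) storage.mode(x) <- "integer"
  if (!.geno_codes_ok(x)) {
    stop("genotype codes must be 0 (AA), 1 (AB), 2 (BB) or NA")
  }
  if (is.null(snp_ids)) snp_ids <- colnames(x)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(x)))
  if (anyDuplicated(snp_ids)) stop("SNP ids must be unique")
  # avoid duplicating large matrices that already carry the right names
  if (ncol(x) > 0L && !identical(colnames(x), snp_ids)) colnames(x) <- snp_ids
  x
}

check_phenotypes <- function(pheno, n = NULL, need_db = FALSE) {
  if (!is.data.frame(pheno) || !"da" %in% names(pheno)) {
    stop("`pheno` must be a data frame with a `da` column")
  }
  if (need_db && !"db" %in% names(pheno)) {
    stop("this analysis requires both phenotypes; `pheno` has no `db` column")
  }
  cols <- intersect(c("da", "db"), names(pheno))
  for (cl in cols) {
    v <- pheno[[cl]]
    if (!all(v %in% c(1L, 2L))) stop("phenotype `", cl, "` must be 1 or 2")
  }
  if (!is.null(n) && nrow(pheno) != n) {
    stop("phenotype table has ", nrow(pheno), " rows but there are ", n,
         " subjects")
  }
  pheno
}

INHERITANCE_MODES <- c("genotypic", "allelic", "dominant", "recessive")

#' Recode genotypes under an inheritance mode
#'
#' Maps the three genotype categories onto the categories used by each
#' single-SNP association model.  Under the recessive mode the SNP is
#' treated as binary with `1 = {AA | AB}` and `2 = {BB}`; dominant uses
#' `1 = {AA}`, `2 = {AB | BB}`; the genotypic mode keeps three categories
#' `1 = AA`, `2 = AB`, `3 = BB`; and the allelic mode emits two allele
#' observations per genotype (`AA -> 1,1`; `AB -> 1,2`; `BB -> 2,2`).
#' Missing genotypes are dropped (both alleles under the allelic mode).
#'
#' @param snp vector of genotypes (0/1/2/NA integer codes, or
#'   `"AA"/"AB"/"BB"` strings).
#' @param mode one of `"genotypic"`, `"allelic"`, `"dominant"`,
#'   `"recessive"`.
#' @return A list with `code` (integer categories in `1..c`), `subject`
#'   (index of the originating subject for every observation) and
#'   `categories` (`c`, 3 for genotypic, 2 otherwise).
#' @export
#' @examples
#' recode_genotypes(c("AA", "AB", "BB"), "recessive")$code  # 1 1 2
recode_genotypes <- function(snp, mode) {
  mode <- match.arg(mode, INHERITANCE_MODES)
  g <- drop(as_genotype_matrix(matrix(snp, ncol = 1), snp_ids = "s"))
  keep <- which(!is.na(g))
  g <- g[keep]
  out <- switch(mode,
    genotypic = list(code = g + 1L, subject = keep, categories = 3L),
    dominant  = list(code = ifelse(g == 0L, 1L, 2L), subject = keep,
                     categories = 2L),
    recessive = list(code = ifelse(g == 2L, 2L, 1L), subject = keep,
                     categories = 2L),
    allelic   = {
      # each genotype contributes its two alleles as separate observations
      code <- rbind(ifelse(g == 0L, 1L, ifelse(g == 1L, 1L, 2L)),
                    ifelse(g == 0L, 1L, 2L))
      list(code = as.integer(code), subject = rep(keep, each = 2L),
           categories = 2L)
    })
  out$mode <- mode
  out
}

ASSOCIATION_MODELS <- c("M0", "Ma", "Mb", "Mab")

model_rows <- function(model) {
  switch(model, M0 = 1L, Ma = 2L, Mb = 2L, Mab = 4L,
         stop("unknown association model: ", model))
}

#' Build a phenotype-by-genotype contingency table
#'
#' Tallies recoded SNP observations into the contingency table required by an
#' association model: the null model `M0` pools all subjects into one row;
#' `Ma` and `Mb` split rows by the first or second phenotype; the pleiotropic
#' model `Mab` uses the four joint classes in the fixed order
#' (1,1), (1,2), (2,1), (2,2).
#'
#' @param coded result of [recode_genotypes()].
#' @param pheno phenotype tibble with columns `da` and, for `Mb`/`Mab`, `db`.
#' @param model one of `"M0"`, `"Ma"`, `"Mb"`, `"Mab"`.
#' @return An object of class `pleio_ct`: list with integer `counts`
#'   (q rows x c categories), `row_sums`, `model`, `mode`, `q`, `c`.
#' @export
build_contingency_table <- function(coded, pheno, model) {
  model <- match.arg(model, ASSOCIATION_MODELS)
  check_phenotypes(pheno, need_db = model %in% c("Mb", "Mab"))
  cc <- coded$categories
  if (any(coded$code < 1L | coded$code > cc)) {
    stop("coded categories outside the mode's range 1..", cc)
  }
  row_of <- switch(model,
    M0  = rep(1L, length(coded$subject)),
    Ma  = as.integer(pheno$da[coded$subject]),
    Mb  = as.integer(pheno$db[coded$subject]),
    Mab = joint_class(as.integer(pheno$da[coded$subject]),
                      as.integer(pheno$db[coded$subject])))
  q <- model_rows(model)
  counts <- matrix(0L, q, cc)
  for (j in seq_len(q)) {
    counts[j, ] <- tabulate(coded$code[row_of == j], nbins = cc)
  }
  rownames(counts) <- switch(model,
    M0 = "all", Ma = c("Da=1", "Da=2"), Mb = c("Db=1", "Db=2"),
    Mab = JOINT_CLASS_LABELS)
  structure(
    list(counts = counts, row_sums = rowSums(counts), model = model,
         mode = coded$mode, q = q, c = cc),
    class = "pleio_ct")
}

#' @export
print.pleio_ct <- function(x, ...) {
  cat("Contingency table (", x$model, ", ", x$mode, " coding)\n", sep = "")
  print(x$counts)
  invisible(x)
}
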