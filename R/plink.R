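# PLINK 1 binary (bed/bim/fam) reader and writer, SNP-major.
#
# 2-bit codes per the PLINK 1 specification: 00 = homozygous A1 (coded 0),
# 01 = missing, 10 = heterozygous (1), 11 = homozygous A2 (2); subjects are
# packed 4 per byte, lowest bits first, each SNP padded to a whole byte.

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))

#' Read a PLINK 1 binary fileset
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @return List with `genotypes` (subjects x SNPs integer matrix, columns
#'   named by SNP id), `bim` and `fam` tibbles.
#' @export
read_plink1 <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim <- tibble::as_tibble(read.table(
    paste0(prefix, ".bim"), col.names = c("chr", "snp_id", "cm", "pos",
                                          "a1", "a2"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character")))
  fam <- tibble::as_tibble(read.table(
    paste0(prefix, ".fam"), col.names = c("fid", "iid", "pat", "mat",
                                          "sex", "pheno"),
    colClasses = c("character", "character", "character", "character",
                   "integer", "numeric")))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], PLINK_MAGIC)) {
    stop("not a PLINK 1 .bed file: expected magic bytes 0x6c 0x1b")
  }
  if (raw[3L] == as.raw(0x00)) {
    stop("sample-major .bed files are not supported; re-export in SNP-major ",
         "mode (mode byte 0x01)")
  }
  if (raw[3L] != as.raw(0x01)) stop("unknown .bed mode byte: ", raw[3L])
  bps <- ceiling(n / 4)                      # bytes per SNP record
  if (length(raw) != 3L + bps * m) {
    stop(".bed file is truncated or inconsistent with .bim/.fam: expected ",
         3 + bps * m, " bytes, found ", length(raw))
  }
  body <- as.integer(raw[-(1:3)])
  # decode 4 subjects per byte: 2-bit fields, lowest first
  codes <- c(0L, NA_integer_, 1L, 2L)        # 00, 01, 10, 11
  G <- matrix(NA_integer_, n, m)
  shift <- c(1L, 4L, 16L, 64L)
  for (s in 1:4) {
    if (s > n) next
    sub_idx <- seq.int(s, n, by = 4L)
    byte_idx <- rep((seq_len(m) - 1L) * bps, each = length(sub_idx)) +
      rep(ceiling(sub_idx / 4), m)
    two_bits <- (body[byte_idx] %/% shift[s]) %% 4L
    G[sub_idx, ] <- codes[two_bits + 1L]
  }
  colnames(G) <- bim$snp_id
  rownames(G) <- fam$iid
  list(genotypes = G, bim = bim, fam = fam)
}

#' Write a PLINK 1 binary fileset
#'
#' Writes a SNP-major `.bed` plus matching `.bim`/`.fam`.  The fam
#' phenotype column is set to missing (`-9`); two-trait phenotypes are
#' carried in a separate phenotype table (see [write_phenotypes()]).
#'
#' @param geno genotype matrix (see [as_genotype_matrix()]).
#' @param prefix output path prefix.
#' @param bim,fam optional tibbles; defaults are generated (chromosome 1,
#'   positions by column index, alleles A/B, FID=IID=row name or index).
#' @return `prefix`, invisibly.
#' @export
write_plink1 <- function(geno, prefix, bim = NULL, fam = NULL) {
  geno <- as_genotype_matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(bim)) {
    bim <- tibble::tibble(chr = "1", snp_id = colnames(geno), cm = 0,
                          pos = seq_len(max(m, 1L))[seq_len(m)], a1 = "A",
                          a2 = "B")
  }
  if (is.null(fam)) {
    ids <- if (!is.null(rownames(geno))) rownames(geno) else
      sprintf("subj%05d", seq_len(n))
    fam <- tibble::tibble(fid = ids, iid = ids, pat = "0", mat = "0",
                          sex = 0L, pheno = -9)
  }
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # encode: 0 -> 00, 1 -> 10, 2 -> 11, NA -> 01
  enc <- c(0L, 2L, 3L)
  bps <- ceiling(n / 4)
  pad_n <- bps * 4L
  out <- matrix(0L, pad_n, max(m, 1L))[, seq_len(m), drop = FALSE]
  if (m > 0L && n > 0L) {
    vals <- enc[geno + 1L]
    vals[is.na(vals)] <- 1L
    out[seq_len(n), ] <- vals
  }
  dim(out) <- c(4L, bps * m)
  bytes <- as.raw(out[1L, ] + 4L * out[2L, ] + 16L * out[3L, ] +
                    64L * out[4L, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(PLINK_MAGIC, as.raw(0x01), bytes), con)
  invisible(prefix)
}

#' Read or write a two-trait phenotype table
#'
#' Tab-separated with header `FID IID Da Db` (`Db` optional), phenotype
#' values in `{1, 2}`.
#'
#' @param pheno tibble with `da` and optionally `db` (plus optional `fid`,
#'   `iid`).
#' @param path file path.
#' @return `read_phenotypes()` returns a tibble with `fid`, `iid`, `da`
#'   and, when present, `db`.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- data.frame(
    FID = if ("fid" %in% names(pheno)) pheno$fid else seq_len(nrow(pheno)),
    IID = if ("iid" %in% names(pheno)) pheno$iid else seq_len(nrow(pheno)),
    Da = pheno$da)
  if ("db" %in% names(pheno)) out$Db <- pheno$db
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  x <- tibble::as_tibble(read.table(path, header = TRUE))
  names(x) <- tolower(names(x))
  check_phenotypes(x)
}
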