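#' Genotype panel
#'
#' In-memory container for a samples x variants dosage matrix plus the sample
#' and variant metadata the rest of the pipeline needs.  Autosomal and female
#' X dosages are allele counts in \{0, 1, 2\}; male X dosages are raw
#' hemizygous values in \{0, 1\}.  Missing genotypes are `NA`.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns.
#' @param sex integer vector, one per sample: 1 = male (XY), 2 = female (XX).
#' @param map data.frame with one row per variant and columns `chrom`
#'   (integers; the X chromosome is coded 23), `id`, `pos`, `a1`, `a2`.
#'   Optional logical column `biallelic` (default `TRUE`).
#' @param fid,iid character vectors of family/individual ids; default
#'   `"F1".."Fn"` / `"I1".."In"`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, sex, map, fid = NULL, iid = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (n < 1L || m < 1L) stop_invalid("panel must have >= 1 sample and >= 1 variant")
  sex <- as.integer(sex)
  if (length(sex) != n || !all(sex %in% c(1L, 2L))) {
    stop_invalid("'sex' must have one entry per sample, coded 1 (male) / 2 (female)")
  }
  need <- c("chrom", "id", "pos", "a1", "a2")
  if (!is.data.frame(map) || nrow(map) != m || !all(need %in% names(map))) {
    stop_invalid("'map' must be a data.frame with %d rows and columns %s",
                 m, paste(need, collapse = ", "))
  }
  if (is.null(map$biallelic)) map$biallelic <- TRUE
  if (is.null(iid)) iid <- paste0("I", seq_len(n))
  if (is.null(fid)) fid <- paste0("F", seq_len(n))
  rownames(dosage) <- iid
  colnames(dosage) <- map$id
  structure(list(dosage = dosage,
                 fam = data.frame(fid = as.character(fid),
                                  iid = as.character(iid),
                                  sex = sex, stringsAsFactors = FALSE),
                 map = map),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples (%d male, %d female) x %d variants (%d autosomal, %d X)\n",
              nrow(x$dosage), sum(x$fam$sex == 1L), sum(x$fam$sex == 2L),
              ncol(x$dosage), sum(!is_x_chrom(x$map$chrom)),
              sum(is_x_chrom(x$map$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing entries: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_panel
#' @param x a `genotype_panel`.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname genotype_panel
#' @export
n_variants <- function(x) ncol(x$dosage)

#' Subset a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param samples sample selector (indices, logical mask, or iid characters).
#' @param variants variant selector (indices, logical mask, or id characters).
#' @return A `genotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  si <- seq_len(n_samples(panel))
  vi <- seq_len(n_variants(panel))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, panel$fam$iid) else si[samples]
    if (anyNA(si)) stop_invalid("unknown sample id in 'samples'")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, panel$map$id) else vi[variants]
    if (anyNA(vi)) stop_invalid("unknown variant id in 'variants'")
  }
  genotype_panel(panel$dosage[si, vi, drop = FALSE],
                 sex = panel$fam$sex[si],
                 map = panel$map[vi, , drop = FALSE],
                 fid = panel$fam$fid[si], iid = panel$fam$iid[si])
}

# Per-variant allele frequency of a1 on a sample subset.  Males contribute one
# allele on the X (hemizygous), two elsewhere.
allele_freq <- function(panel, samples = seq_len(n_samples(panel))) {
  d <- panel$dosage[samples, , drop = FALSE]
  sex <- panel$fam$sex[samples]
  xv <- is_x_chrom(panel$map$chrom)
  obs <- !is.na(d)
  ploidy <- matrix(2, nrow(d), ncol(d))
  if (any(xv) && any(sex == 1L)) ploidy[sex == 1L, xv] <- 1
  num <- colSums(d * obs, na.rm = TRUE)
  den <- colSums(ploidy * obs)
  ifelse(den > 0, num / den, NA_real_)
}

#' Write / read a plain dosage TSV
#'
#' Variants in rows, samples in columns, with leading columns `chrom`, `id`,
#' `pos`, `a1`, `a2`; a companion `<file>.fam` TSV stores fid/iid/sex.
#'
#' @param panel a `genotype_panel`.
#' @param file path of the dosage TSV to write (the sample sheet goes to
#'   `<file>.fam`).
#' @export
write_dosage_tsv <- function(panel, file) {
  tab <- cbind(panel$map[, c("chrom", "id", "pos", "a1", "a2")],
               as.data.frame(t(panel$dosage)))
  names(tab)[-(1:5)] <- panel$fam$iid
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$fam, paste0(file, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage_tsv
#' @param file path of a dosage TSV written by [write_dosage_tsv()].
#' @return `read_dosage_tsv` returns the reconstructed `genotype_panel`.
#' @export
read_dosage_tsv <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(file, ".fam"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  map <- tab[, 1:5]
  dosage <- t(as.matrix(tab[, -(1:5), drop = FALSE]))
  genotype_panel(dosage, sex = fam$sex, map = map, fid = fam$fid, iid = fam$iid)
}

#' PLINK 1 binary triplet I/O
#'
#' Writes/reads the `.bed`/`.bim`/`.fam` triplet (SNP-major bed).  Sex is
#' stored in `.fam` column 5 (1 = male, 2 = female) and the X chromosome is
#' coded 23.  Male X genotypes are stored as PLINK homozygote codes and
#' converted back to raw \{0, 1\} values on read using the `.fam` sex column.
#'
#' @param panel a `genotype_panel`.
#' @param prefix path prefix (without extension).
#' @return `write_plink` returns `prefix` invisibly; `read_plink` returns a
#'   `genotype_panel`.
#' @export
write_plink <- function(panel, prefix) {
  n <- n_samples(panel)
  m <- n_variants(panel)
  fam <- data.frame(panel$fam$fid, panel$fam$iid, 0L, 0L, panel$fam$sex, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(panel$map$chrom, panel$map$id, 0, panel$map$pos,
                    panel$map$a1, panel$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  xv <- is_x_chrom(panel$map$chrom)
  male <- panel$fam$sex == 1L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  # two-bit codes per genotype (count of a1): 0 -> 11b(3), 1 -> 10b(2),
  # 2 -> 00b(0), NA -> 01b(1); male X: 0 -> 3, 1 -> 0 (homozygote codes)
  nbytes <- ceiling(n / 4)
  for (j in seq_len(m)) {
    g <- panel$dosage[, j]
    if (xv[j]) g[male] <- 2 * g[male]
    code <- integer(n)
    code[is.na(g)] <- 1L
    code[!is.na(g) & g == 0] <- 3L
    code[!is.na(g) & g == 1] <- 2L
    code[!is.na(g) & g == 2] <- 0L
    code <- c(code, integer(nbytes * 4L - n))
    idx <- matrix(code, nrow = 4L)
    bytes <- idx[1, ] + idx[2, ] * 4L + idx[3, ] * 16L + idx[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b || raw[3] != 0x01) {
    stop_invalid("'%s.bed' is not a SNP-major PLINK1 bed file", prefix)
  }
  body <- as.integer(raw[-(1:3)])
  nbytes <- ceiling(n / 4)
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  dim(codes) <- c(4L * nbytes, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_real_, n, m)
  dosage[codes == 3L] <- 0
  dosage[codes == 2L] <- 1
  dosage[codes == 0L] <- 2
  xv <- is_x_chrom(bim$chrom)
  male <- fam[[5]] == 1L
  if (any(xv) && any(male)) {
    sub <- dosage[male, xv, drop = FALSE]
    if (any(sub == 1, na.rm = TRUE)) {
      warning("heterozygous male X genotypes set to NA on read")
      sub[sub == 1] <- NA_real_
    }
    dosage[male, xv] <- sub / 2
  }
  genotype_panel(dosage, sex = fam[[5]],
                 map = bim[, c("chrom", "id", "pos", "a1", "a2")],
                 fid = fam[[1]], iid = fam[[2]])
}
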