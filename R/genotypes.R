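#' Construct a genotype matrix
#'
#' Wraps an accession-by-marker dosage matrix (counts of the alternate
#' allele: 0, 1, 2, or `NA` for missing) together with per-marker alternate
#' allele frequencies computed over non-missing calls. Row names are
#' accession ids, column names are marker ids; both must be unique.
#'
#' @param dosages numeric matrix, accessions in rows, markers in columns,
#'   entries in `[0, 2]` or `NA`. Imputed (non-integer) dosages are allowed.
#' @return an object of class `genotype_matrix` with elements `dosages`
#'   (the matrix) and `allele_freq` (named vector of alternate-allele
#'   frequencies).
#' @export
genotype_matrix <- function(dosages) {
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stop("`dosages` must be a numeric matrix")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("`dosages` must have accession row names and marker column names")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate accession ids in genotype matrix")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate marker ids in genotype matrix")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosage values must lie in [0, 2]")
  structure(
    list(dosages = dosages, allele_freq = colMeans(dosages, na.rm = TRUE) / 2),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosages
  cat(sprintf(
    "<genotype_matrix> %d accessions x %d markers (%.2f%% missing)\n",
    nrow(d), ncol(d), 100 * mean(is.na(d))
  ))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`
#' @export
accession_ids <- function(g) rownames(g$dosages)

#' @rdname genotype_matrix
#' @export
marker_ids <- function(g) colnames(g$dosages)

#' Read genotypes from VCF or a dosage TSV
#'
#' For VCF input, only biallelic SNP records with a GT field are used;
#' multi-allelic or non-SNP records are skipped with a warning giving the
#' count. Phased (`|`) and unphased (`/`) separators are both accepted;
#' any call containing `.` (including half-missing calls such as `./1`)
#' is treated as missing. Dosage is the count of the alternate allele.
#'
#' The dosage TSV layout is: header row of marker ids, first column
#' `accession_id`, remaining cells dosages with `NA` for missing.
#'
#' @param path file path
#' @param format `"vcf"` or `"dosage-tsv"`; default guessed from the
#'   file extension (`.vcf` vs anything else).
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage-tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage-tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_vcf_genotypes(path) else read_dosage_tsv(path)
}

read_vcf_genotypes <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  ref <- VariantAnnotation::ref(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  is_snp <- n_alt == 1L &
    nchar(as.character(ref)) == 1L &
    nchar(vapply(as(alt, "CharacterList"), function(a) a[[1]], "")) == 1L
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    warning(sprintf("skipped %d non-biallelic-SNP VCF record(s)", n_skip))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[is_snp, , drop = FALSE]
  if (nrow(gt) == 0) stop("no usable biallelic SNP records in VCF")
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  out <- t(dos)  # accessions x markers
  genotype_matrix(out)
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || grepl("\\.", gt)) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2L) return(NA_real_)
  sum(alleles == "1")
}

read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "accession_id")
    stop("dosage TSV must have an `accession_id` first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  if (ncol(m) == 0) stop("no markers in dosage TSV")
  genotype_matrix(m)
}

#' Write a genotype matrix as a dosage TSV
#'
#' @param g a [genotype_matrix()]
#' @param path output path
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(accession_id = accession_ids(g),
                   g$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits diploid GT calls on synthetic coordinates (one chromosome,
#' positions = marker index, REF/ALT fixed to A/G). Dosages must be
#' integer 0/1/2 or missing; imputed fractional dosages cannot be
#' represented as genotype calls.
#'
#' @param g a [genotype_matrix()]
#' @param path output path
#' @export
write_vcf <- function(g, path) {
  d <- g$dosages
  if (any(!is.na(d) & d != round(d)))
    stop("cannot write fractional (imputed) dosages as VCF genotype calls")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gsei",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accession_ids(g)), collapse = "\t")
  ), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(d))) {
    calls <- ifelse(is.na(d[, j]), "./.", gt_code[as.character(d[, j])])
    writeLines(paste(c("1", j, colnames(d)[j], "A", "G", ".", "PASS", ".",
                       "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Filter markers on missingness and minor allele frequency
#'
#' Retains markers whose missing-call fraction is at most `max_missing`
#' and whose minor allele frequency (computed over non-missing calls
#' across all accessions in the matrix) is at least `min_maf`; i.e. only
#' markers strictly below the MAF threshold are removed. Defaults match
#' the 5% missingness / 2.5% MAF screen used for the 3K rice panel.
#'
#' @param g a [genotype_matrix()]
#' @param max_missing maximum tolerated missing fraction per marker
#' @param min_maf minimum minor allele frequency
#' @param verbose message the per-rule removal counts
#' @return the filtered [genotype_matrix()]
#' @export
filter_markers <- function(g, max_missing = 0.05, min_maf = 0.025,
                           verbose = TRUE) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  d <- g$dosages
  miss <- colMeans(is.na(d))
  maf <- pmin(g$allele_freq, 1 - g$allele_freq)
  fail_miss <- miss > max_missing
  fail_maf <- is.na(maf) | maf < min_maf
  keep <- !fail_miss & !fail_maf
  if (verbose)
    message(sprintf(
      "filter_markers: removed %d marker(s) for missingness > %g, %d for MAF < %g; %d of %d retained",
      sum(fail_miss), max_missing, sum(fail_maf & !fail_miss), min_maf,
      sum(keep), length(keep)
    ))
  if (!any(keep)) stop("all markers removed by filtering")
  genotype_matrix(d[, keep, drop = FALSE])
}

#' Impute missing dosages with the per-marker mean
#'
#' Each missing call is replaced by the marker's mean dosage over
#' non-missing calls (a continuous value). This stands in for the
#' haplotype-based imputation used in the original study; per-marker
#' allele frequencies are preserved exactly.
#'
#' @param g a [genotype_matrix()]
#' @return a complete [genotype_matrix()]
#' @export
impute_mean <- function(g) {
  d <- g$dosages
  if (!anyNA(d)) return(g)
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing))
    stop("marker(s) with all calls missing; run filter_markers() first: ",
         paste(utils::head(colnames(d)[all_missing], 5), collapse = ", "))
  means <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- means[idx[, 2]]
  genotype_matrix(d)
}

#' Compute the VanRaden genomic relationship matrix
#'
#' Method-1 GRM without shrinkage: each marker column is centered by twice
#' its observed alternate allele frequency, `W = dosages - 2p`, and
#' `G = W W' / (2 * sum(p * (1 - p)))`. Frequencies are those observed in
#' the supplied matrix (as in `rrBLUP::A.mat`). The matrix must be
#' complete (impute first) and free of monomorphic markers.
#'
#' @param g a complete [genotype_matrix()]
#' @return an object of class `grm`: the symmetric positive-semidefinite
#'   relationship matrix with accession ids as dimnames.
#' @export
compute_grm <- function(g) {
  d <- g$dosages
  if (anyNA(d)) stop("genotype matrix has missing dosages; run impute_mean() first")
  p <- g$allele_freq
  if (any(p <= 0 | p >= 1))
    stop("monomorphic marker(s) present (allele frequency 0 or 1); run filter_markers() first")
  W <- sweep(d, 2, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  G <- (G + t(G)) / 2
  structure(G, class = c("grm", "matrix"))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d x %d, mean diagonal %.3f\n",
              nrow(x), ncol(x), mean(diag(unclass(x)))))
  invisible(x)
}

#' Write / read a GRM as labelled TSV
#'
#' @param G a [compute_grm()] result (or plain labelled matrix)
#' @param path file path
#' @export
write_grm_tsv <- function(G, path) {
  df <- data.frame(accession_id = rownames(G), unclass(G), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m <- (m + t(m)) / 2
  structure(m, class = c("grm", "matrix"))
}

# Inverse of a GRM with the ridge rule used throughout: if the smallest
# eigenvalue is below 1e-8 (duplicated accessions make G singular), add a
# 1e-6 ridge to the diagonal before inverting.
grm_solve <- function(G) {
  G <- unclass(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) G <- G + diag(1e-6, nrow(G))
  out <- tryCatch(chol2inv(chol(G)), error = function(e)
    stop("GRM is singular even after ridge adjustment"))
  dimnames(out) <- dimnames(G)
  out
}
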