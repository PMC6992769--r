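#' Diploid GBS genotype container
#'
#' A `gbs_geno` object holds a biallelic SNP call set: a site table
#' (chromosome, 1-based position, REF/ALT alleles, optional marker id), a
#' sites-by-accessions alt-allele dosage matrix (0 = hom-ref, 1 = het,
#' 2 = hom-alt, `NA` = missing), and an optional read-depth matrix of the
#' same shape. Phase is deliberately discarded: every downstream statistic
#' (MAF, heterozygosity, IBS, admixture) is a function of dosage only.
#'
#' @param sites A data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id`. Positions are 1-based; within each chromosome sites
#'   must be strictly increasing.
#' @param dosage Integer matrix, `nrow(sites)` x accessions, values in
#'   `{0, 1, 2, NA}`. Column names are the accession names.
#' @param depth Optional non-negative integer matrix of identical shape, or
#'   `NULL` when depths are unknown.
#' @param chrom_info Optional data frame with columns `name`, `length_bp`
#'   giving chromosome sizes.
#'
#' @return An object of class `gbs_geno`.
#' @export
gbs_geno <- function(sites, dosage, depth = NULL, chrom_info = NULL) {
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (!"id" %in% names(sites)) {
    sites$id <- paste0(sites$chrom, "_", sites$pos)
  }
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(sites)) {
    abort("`dosage` must have one row per site.")
  }
  if (is.null(colnames(dosage))) {
    abort("`dosage` must carry accession names as column names.")
  }
  if (anyDuplicated(colnames(dosage))) {
    abort("Accession names must be unique.")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) abort("Dosage values must be 0, 1, 2 or NA.")
  if (any(sites$pos < 1)) abort("Positions must be >= 1.")
  if (any(sites$ref == sites$alt)) abort("REF and ALT must differ.")
  ok_nt <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% ok_nt) || !all(sites$alt %in% ok_nt)) {
    abort("Alleles must be single nucleotides in {A,C,G,T}.")
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      abort(paste0("Sites on ", ch, " must be strictly increasing by position."))
    }
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(dosage))) {
      abort("`depth` must match the dosage matrix shape.")
    }
    if (any(depth < 0, na.rm = TRUE)) abort("Depths must be non-negative.")
    colnames(depth) <- colnames(dosage)
  }
  if (!is.null(chrom_info)) {
    chrom_info <- as_tibble(chrom_info)
    stopifnot(all(c("name", "length_bp") %in% names(chrom_info)))
    if (any(chrom_info$length_bp <= 0)) abort("Chromosome lengths must be positive.")
    len <- setNames(chrom_info$length_bp, chrom_info$name)
    known <- sites$chrom %in% names(len)
    if (any(known) && any(sites$pos[known] > len[sites$chrom[known]])) {
      abort("A site position exceeds its chromosome length.")
    }
  }
  structure(
    list(sites = sites, dosage = dosage, depth = depth, chrom_info = chrom_info),
    class = "gbs_geno"
  )
}

#' @export
print.gbs_geno <- function(x, ...) {
  cat("<gbs_geno> ", nrow(x$sites), " sites x ", ncol(x$dosage),
      " accessions", if (!is.null(x$depth)) " (with depths)", "\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$sites$chrom), collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$dosage)) * 100
  cat(sprintf("  missing calls: %.2f%%\n", miss))
  invisible(x)
}

#' @export
dim.gbs_geno <- function(x) dim(x$dosage)

#' Accession names of a genotype set
#' @param gm A `gbs_geno` object.
#' @return Character vector of accession names.
#' @export
accessions <- function(gm) colnames(gm$dosage)

#' Subset a genotype set by site index and/or accession
#'
#' @param gm A `gbs_geno` object.
#' @param sites Integer or logical index over sites (default: all).
#' @param accessions Character, integer or logical index over accessions.
#' @return A `gbs_geno` with the selected sites/accessions.
#' @export
subset_geno <- function(gm, sites = NULL, accessions = NULL) {
  i <- if (is.null(sites)) seq_len(nrow(gm$sites)) else sites
  j <- if (is.null(accessions)) seq_len(ncol(gm$dosage)) else accessions
  gbs_geno(
    gm$sites[i, , drop = FALSE],
    gm$dosage[i, j, drop = FALSE],
    depth = if (!is.null(gm$depth)) gm$depth[i, j, drop = FALSE],
    chrom_info = gm$chrom_info
  )
}

#' Long tidy view of the calls
#'
#' @param gm A `gbs_geno` object.
#' @return A tibble with one row per site x accession: site columns,
#'   `accession`, `dosage`, and `depth` when available.
#' @export
geno_tidy <- function(gm) {
  long <- tibble(
    site = rep(seq_len(nrow(gm$sites)), times = ncol(gm$dosage)),
    accession = rep(colnames(gm$dosage), each = nrow(gm$sites)),
    dosage = as.vector(gm$dosage)
  )
  if (!is.null(gm$depth)) long$depth <- as.vector(gm$depth)
  dplyr::bind_cols(gm$sites[long$site, ], long[-1])
}
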