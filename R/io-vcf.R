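#' Read a multi-sample VCF into a genotype container
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and keeps only biallelic SNP
#' records. Multi-allelic records and indels are dropped and counted;
#' genotypes other than `0/0`, `0/1`, `1/0`, `1/1` (phased or unphased) are
#' mapped to missing. Per-genotype read depth is taken from `FORMAT/DP`
#' when present.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param chrom_info Optional chromosome-size table (`name`, `length_bp`);
#'   if `NULL`, contig lengths are recovered from `##contig` header lines
#'   when present.
#'
#' @return A [gbs_geno] object. The number of excluded records is attached
#'   as `attr(x, "excluded")`, a tibble with columns `reason` and `n`.
#' @export
read_vcf <- function(path, chrom_info = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(fix) == 0) abort("VCF contains no variant records.")
  if (ncol(vcf@gt) < 2) abort("VCF contains no sample columns.")

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  nonacgt <- !multi & !indel &
    (!(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T")))
  keep <- !(multi | indel | nonacgt)
  excluded <- tibble(
    reason = c("multiallelic", "indel", "non_acgt"),
    n = c(sum(multi), sum(indel), sum(nonacgt))
  )
  if (!any(keep)) abort("No biallelic SNP records in VCF.")

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = list(NULL, colnames(gt)))
  dos[gt_clean %in% "0/0"] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean %in% "1/1"] <- 2L

  depth <- NULL
  fmt <- vcf@gt[, 1]
  if (any(grepl("\\bDP\\b", fmt))) {
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    depth <- dp[keep, , drop = FALSE]
    storage.mode(depth) <- "integer"
    dimnames(depth) <- list(NULL, colnames(dp))
  }

  id <- fix[keep, "ID"]
  id[is.na(id) | id == "."] <- NA_character_
  sites <- tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    id = ifelse(is.na(id), paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"]), id)
  )

  if (is.null(chrom_info)) {
    meta <- vcf@meta
    ctg <- grep("^##contig=", meta, value = TRUE)
    if (length(ctg)) {
      nm <- sub(".*ID=([^,>]+).*", "\\1", ctg)
      ln <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
      if (!anyNA(ln)) chrom_info <- tibble(name = nm, length_bp = ln)
    }
  }

  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  gm <- gbs_geno(sites[ord, ], dos[ord, , drop = FALSE],
                 depth = if (!is.null(depth)) depth[ord, , drop = FALSE],
                 chrom_info = chrom_info)
  attr(gm, "excluded") <- excluded
  gm
}

#' Write a genotype container to a VCF 4.2 file
#'
#' Emits one biallelic SNP record per site with `GT` (and `DP` when depths
#' are present) per sample. Dosage 0/1/2 maps to `0/0`, `0/1`, `1/1`;
#' missing calls to `./.`.
#'
#' @param gm A [gbs_geno] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) abort(paste0("Cannot open ", path, " for writing."))
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gbsland",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  has_dp <- !is.null(gm$depth)
  if (has_dp) {
    header <- c(header,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  if (!is.null(gm$chrom_info)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                gm$chrom_info$name,
                                as.integer(gm$chrom_info$length_bp)))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT",
                              colnames(gm$dosage)), collapse = "\t"))
  writeLines(header, con)

  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_map[gm$dosage + 1L], nrow = nrow(gm$dosage))
  gt[is.na(gm$dosage)] <- "./."
  if (has_dp) {
    dp <- matrix(as.character(gm$depth), nrow = nrow(gm$depth))
    dp[is.na(gm$depth)] <- "."
    gt <- matrix(paste(gt, dp, sep = ":"), nrow = nrow(gt))
  }
  lines <- paste(
    gm$sites$chrom, gm$sites$pos, gm$sites$id, gm$sites$ref, gm$sites$alt,
    ".", ".", ".", if (has_dp) "GT:DP" else "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}

#' Rename chromosomes via an alias map
#'
#' Assemblies label the same pseudomolecules differently (e.g. `Pp01` vs
#' `chr1` vs scaffold names); this remaps site and chromosome-info names so
#' that a VCF, GFF3 and FASTA agree before annotation.
#'
#' @param gm A [gbs_geno] object.
#' @param alias Named character vector, `old_name = "new_name"`.
#' @return The renamed `gbs_geno`.
#' @export
rename_chroms <- function(gm, alias) {
  hit <- gm$sites$chrom %in% names(alias)
  gm$sites$chrom[hit] <- unname(alias[gm$sites$chrom[hit]])
  if (!is.null(gm$chrom_info)) {
    hit <- gm$chrom_info$name %in% names(alias)
    gm$chrom_info$name[hit] <- unname(alias[gm$chrom_info$name[hit]])
  }
  gm
}
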