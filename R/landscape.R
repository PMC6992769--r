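#' Transition/transversion substitution spectrum
#'
#' Assigns each biallelic SNP to one of the six unordered substitution
#' classes; A/G and C/T are transitions (purine-purine, pyrimidine-
#' pyrimidine), the other four classes transversions.
#'
#' @param sites A site table with `ref` and `alt` columns (e.g.
#'   `gm$sites`), or a [gbs_geno].
#' @return A tibble with one row per class: `class`, `n`, `percent`,
#'   `type` ("transition"/"transversion"); totals and the Ts/Tv ratio are
#'   attached as attributes `ts`, `tv`, `ts_tv_ratio` (ratio is `NA` when
#'   there are no transversions).
#' @export
substitution_spectrum <- function(sites) {
  if (inherits(sites, "gbs_geno")) sites <- sites$sites
  pair <- paste(pmin(sites$ref, sites$alt), pmax(sites$ref, sites$alt), sep = "/")
  classes <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
  n <- vapply(classes, function(cl) sum(pair == cl), integer(1))
  stopifnot(sum(n) == nrow(sites))
  out <- tibble(
    class = classes, n = unname(n),
    percent = 100 * unname(n) / sum(n),
    type = ifelse(classes %in% c("A/G", "C/T"), "transition", "transversion")
  )
  ts <- sum(out$n[out$type == "transition"])
  tv <- sum(out$n[out$type == "transversion"])
  attr(out, "ts") <- ts
  attr(out, "tv") <- tv
  attr(out, "ts_tv_ratio") <- if (tv == 0) NA_real_ else ts / tv
  out
}

#' Per-accession heterozygosity
#'
#' @param gm A [gbs_geno] object.
#' @return A tibble `accession`, `n_het`, `n_called`, `het_percent`
#'   (100 x het calls / non-missing calls). Accessions with no calls get
#'   `NA` with a warning.
#' @export
heterozygosity_percent <- function(gm) {
  n_het <- colSums(gm$dosage == 1L, na.rm = TRUE)
  n_called <- colSums(!is.na(gm$dosage))
  if (any(n_called == 0)) {
    warn(paste0("Accession(s) with no called genotypes: ",
                paste(names(n_called)[n_called == 0], collapse = ", ")))
  }
  tibble(
    accession = colnames(gm$dosage),
    n_het = unname(n_het), n_called = unname(n_called),
    het_percent = ifelse(n_called == 0, NA_real_, 100 * n_het / n_called)
  )
}

#' Chromosome coverage and maximum-gap summary
#'
#' Reproduces a per-chromosome marker-coverage table: first/last SNP
#' positions, covered span (last - first), span as a fraction of the
#' chromosome, bp per SNP over the covered span, and the largest gap
#' between consecutive SNPs with its flanking positions.
#'
#' @param positions Sorted 1-based SNP positions on one chromosome, or a
#'   [gbs_geno] (then all chromosomes are summarised).
#' @param chrom_info For the vector form, a list/row with `name` and
#'   `length_bp`; ignored for the `gbs_geno` form (its own `chrom_info`
#'   is used).
#' @return A tibble with one row per chromosome: `chrom`, `size_bp`,
#'   `n_snps`, `first_pos`, `last_pos`, `span_bp`, `span_fraction`,
#'   `bp_per_snp`, `max_gap_bp`, `gap_before`, `gap_after`.
#' @export
chromosome_coverage <- function(positions, chrom_info = NULL) {
  if (inherits(positions, "gbs_geno")) {
    gm <- positions
    out <- lapply(unique(gm$sites$chrom), function(ch) {
      info <- if (!is.null(gm$chrom_info)) {
        gm$chrom_info[gm$chrom_info$name == ch, ]
      }
      chromosome_coverage(gm$sites$pos[gm$sites$chrom == ch],
                          chrom_info = if (!is.null(info) && nrow(info)) {
                            list(name = ch, length_bp = info$length_bp)
                          } else list(name = ch, length_bp = NA_real_))
    })
    return(bind_rows(out))
  }
  pos <- as.numeric(positions)
  stopifnot(!is.unsorted(pos))
  name <- if (!is.null(chrom_info)) chrom_info$name else NA_character_
  size <- if (!is.null(chrom_info)) as.numeric(chrom_info$length_bp) else NA_real_
  n <- length(pos)
  if (n < 2) {
    return(tibble(chrom = name, size_bp = size, n_snps = n,
                  first_pos = if (n) pos[1] else NA_real_,
                  last_pos = if (n) pos[n] else NA_real_,
                  span_bp = NA_real_, span_fraction = NA_real_,
                  bp_per_snp = NA_real_, max_gap_bp = NA_real_,
                  gap_before = NA_real_, gap_after = NA_real_))
  }
  gaps <- diff(pos)
  gi <- which.max(gaps)
  span <- pos[n] - pos[1]
  tibble(
    chrom = name, size_bp = size, n_snps = n,
    first_pos = pos[1], last_pos = pos[n],
    span_bp = span,
    span_fraction = span / size,
    bp_per_snp = span / n,
    max_gap_bp = gaps[gi],
    gap_before = pos[gi], gap_after = pos[gi + 1]
  )
}

#' Windowed SNP density tracks
#'
#' Tiles each chromosome with non-overlapping windows (default 1 Mb) and
#' counts SNPs per window, optionally per accession group. A site counts
#' toward a group only if it is polymorphic within that group (MAF > 0
#' among the group's accessions): a site fixed within a group carries no
#' information for it.
#'
#' @param gm A [gbs_geno] with `chrom_info`.
#' @param groups Optional tibble `accession`, `group`; when supplied one
#'   track per group is returned in addition to the "all" track.
#' @param window Window size in bp (default 1e6).
#' @param sliding If `TRUE`, windows advance by `step` instead of tiling.
#' @param step Step for sliding windows (default `window %/% 2`).
#' @return A tibble `group`, `chrom`, `start`, `end` (1-based closed),
#'   `count`.
#' @export
density_track <- function(gm, groups = NULL, window = 1e6,
                          sliding = FALSE, step = window %/% 2) {
  if (is.null(gm$chrom_info)) abort("density_track needs chrom_info.")
  if (!is.null(groups)) {
    groups <- as_tibble(groups)
    missing_acc <- setdiff(groups$accession, colnames(gm$dosage))
    if (length(missing_acc)) {
      abort(paste0("Grouped accession(s) not in genotype set: ",
                   paste(missing_acc, collapse = ", ")))
    }
  }
  site_sets <- list(all = rep(TRUE, nrow(gm$sites)))
  if (!is.null(groups)) {
    for (g in unique(groups$group)) {
      acc <- groups$accession[groups$group == g]
      sub <- gm$dosage[, acc, drop = FALSE]
      maf <- site_maf(sub)
      site_sets[[g]] <- !is.na(maf) & maf > 0
    }
  }
  out <- list()
  for (gname in names(site_sets)) {
    sel <- site_sets[[gname]]
    for (ci in seq_len(nrow(gm$chrom_info))) {
      ch <- gm$chrom_info$name[ci]
      len <- gm$chrom_info$length_bp[ci]
      starts <- if (sliding) seq(1, max(1, len - 1), by = step) else seq(1, len, by = window)
      ends <- pmin(starts + window - 1, len)
      pos <- gm$sites$pos[sel & gm$sites$chrom == ch]
      counts <- vapply(seq_along(starts),
                       function(w) sum(pos >= starts[w] & pos <= ends[w]),
                       integer(1))
      out[[length(out) + 1]] <- tibble(group = gname, chrom = ch,
                                       start = as.integer(starts),
                                       end = as.integer(ends), count = counts)
    }
  }
  bind_rows(out)
}

#' Windowed gene density
#'
#' Counts gene starts per tiling window, mirroring [density_track()].
#'
#' @param models A [gene_models] object.
#' @param chrom_info Tibble `name`, `length_bp`.
#' @param window Window size in bp.
#' @return A tibble `chrom`, `start`, `end`, `count`.
#' @export
gene_density <- function(models, chrom_info, window = 1e6) {
  genes <- gene_table(models)
  out <- list()
  for (ci in seq_len(nrow(chrom_info))) {
    ch <- chrom_info$name[ci]; len <- chrom_info$length_bp[ci]
    starts <- seq(1, len, by = window)
    ends <- pmin(starts + window - 1, len)
    gpos <- genes$start[genes$chrom == ch]
    counts <- vapply(seq_along(starts),
                     function(w) sum(gpos >= starts[w] & gpos <= ends[w]),
                     integer(1))
    out[[length(out) + 1]] <- tibble(chrom = ch, start = as.integer(starts),
                                     end = as.integer(ends), count = counts)
  }
  bind_rows(out)
}

#' Cross-reference the call set with SNP-array manifests
#'
#' Exact (chromosome, position) intersection between the call set and an
#' array manifest on the same assembly.
#'
#' @param sites Site table (or [gbs_geno]).
#' @param manifest Manifest tibble from [read_array_manifest()].
#' @param assembly Assembly name of the call set; if both this and the
#'   manifest declare assemblies and they differ, the function refuses.
#' @return A tibble of matches: `marker_id`, `chrom`, `pos`, `id` (call-set
#'   site id); the match count is `nrow()`.
#' @export
cross_reference_arrays <- function(sites, manifest, assembly = NULL) {
  if (inherits(sites, "gbs_geno")) sites <- sites$sites
  man_asm <- attr(manifest, "assembly")
  if (!is.null(assembly) && !is.na(assembly) &&
      !is.null(man_asm) && !is.na(man_asm) && assembly != man_asm) {
    abort(sprintf("Manifest assembly '%s' differs from call-set assembly '%s'.",
                  man_asm, assembly))
  }
  dplyr::inner_join(
    manifest, sites[c("chrom", "pos", "id")],
    by = c("chrom", "pos")
  )
}

#' Genotype concordance between two accessions
#'
#' @param gm A [gbs_geno] object.
#' @param accession_a,accession_b Accession names.
#' @return Fraction of jointly non-missing sites with identical dosage,
#'   with the joint-support size as attribute `n_joint`. Errors when no
#'   site is jointly called.
#' @export
duplicate_concordance <- function(gm, accession_a, accession_b) {
  stopifnot(accession_a %in% colnames(gm$dosage),
            accession_b %in% colnames(gm$dosage))
  a <- gm$dosage[, accession_a]
  b <- gm$dosage[, accession_b]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) abort("No jointly non-missing site; concordance undefined.")
  out <- mean(a[ok] == b[ok])
  attr(out, "n_joint") <- sum(ok)
  out
}

#' Chi-square homogeneity test of SNP region distributions
#'
#' Pearson chi-square comparing counts of SNPs per region category (e.g.
#' exon/intron/UTR/intergenic) across accession groups.
#'
#' @param counts A groups x categories matrix or data frame of non-negative
#'   integer counts with row and column names.
#' @return A tibble `statistic`, `df`, `p_value`. Zero rows/columns are
#'   dropped with a warning.
#' @export
region_distribution_chisq <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) abort("Counts must be non-negative integers.")
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warn("Dropping all-zero row(s)/column(s) from the contingency table.")
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) abort("Need at least 2 groups and 2 categories.")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value))
}
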