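#' Genomic-context classification of SNPs
#'
#' Classifies each site as CDS, 5'UTR, 3'UTR, intron, or intergenic against
#' a set of gene models. When several transcripts overlap a position, the
#' reported context follows the severity precedence
#' `cds > utr5 > utr3 > intron`. Intergenic sites within the promoter
#' window upstream of any transcription start site (strand-aware: lower
#' coordinates on `+`, higher on `-`) are flagged `promoter`; promoter
#' sites remain a subset of intergenic.
#'
#' @param sites Site table with `chrom`, `pos` (or a [gbs_geno]).
#' @param models A [gene_models] object.
#' @param promoter_window Promoter window in bp upstream of the TSS.
#' @return A tibble: site columns plus `context`, `promoter_flag`,
#'   `gene_id`, `transcript_id` (`NA` for intergenic sites).
#' @export
classify_context <- function(sites, models, promoter_window = 1000) {
  if (inherits(sites, "gbs_geno")) sites <- sites$sites
  sites <- as_tibble(sites)
  sites <- sites[setdiff(names(sites), c("context", "promoter_flag",
                                         "gene_id", "transcript_id"))]
  n <- nrow(sites)
  tx_gr <- GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$tx_start, models$tx_end))
  site_gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(site_gr, tx_gr)

  rank <- c(cds = 1, utr5 = 2, utr3 = 3, intron = 4)
  context <- rep("intergenic", n)
  best <- rep(5, n)
  gene_id <- rep(NA_character_, n)
  tx_id <- rep(NA_character_, n)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (h in seq_along(qh)) {
    i <- qh[h]; k <- sh[h]
    pos <- sites$pos[i]
    lab <- tx_region(pos, models[k, ])
    if (rank[lab] < best[i]) {
      best[i] <- rank[lab]
      context[i] <- lab
      gene_id[i] <- models$gene_id[k]
      tx_id[i] <- models$transcript_id[k]
    }
  }

  prom_start <- ifelse(models$strand == "+",
                       pmax(models$tx_start - promoter_window, 1),
                       models$tx_end + 1)
  prom_end <- ifelse(models$strand == "+",
                     models$tx_start - 1,
                     models$tx_end + promoter_window)
  okp <- prom_end >= prom_start
  prom_gr <- GenomicRanges::GRanges(
    models$chrom[okp], IRanges::IRanges(prom_start[okp], prom_end[okp]))
  in_prom <- GenomicRanges::countOverlaps(site_gr, prom_gr) > 0
  promoter_flag <- context == "intergenic" & in_prom

  dplyr::bind_cols(sites, tibble(context = context,
                                 promoter_flag = promoter_flag,
                                 gene_id = gene_id, transcript_id = tx_id))
}

# Region of one position within one transcript (the position is known to
# fall in [tx_start, tx_end]).
tx_region <- function(pos, tx) {
  if (iv_point_in(pos, tx$cds[[1]])) return("cds")
  if (iv_point_in(pos, tx$utr5[[1]])) return("utr5")
  if (iv_point_in(pos, tx$utr3[[1]])) return("utr3")
  "intron"
}

#' Brute-force per-base context labels
#'
#' Labels every position of a chromosome by scanning all transcripts
#' linearly, without interval indexes — an independent oracle for
#' [classify_context()] on small genomes.
#'
#' @param chrom Chromosome name.
#' @param length_bp Chromosome length.
#' @param models A [gene_models] object.
#' @param promoter_window Promoter window (bp).
#' @return Character vector of length `length_bp` with values in
#'   `c("cds", "utr5", "utr3", "intron", "promoter", "intergenic")`
#'   (promoter reported in place of flagged intergenic).
#' @export
context_scan <- function(chrom, length_bp, models, promoter_window = 1000) {
  lab <- rep("intergenic", length_bp)
  rank <- c(cds = 1, utr5 = 2, utr3 = 3, intron = 4, promoter = 5, intergenic = 6)
  best <- rep(rank[["intergenic"]], length_bp)
  put <- function(ivm, what) {
    for (r in seq_len(nrow(ivm))) {
      span <- max(1L, ivm[r, 1]):min(length_bp, ivm[r, 2])
      upd <- rank[[what]] < best[span]
      lab[span][upd] <<- what
      best[span][upd] <<- rank[[what]]
    }
  }
  mm <- models[models$chrom == chrom, ]
  for (k in seq_len(nrow(mm))) {
    tx <- mm[k, ]
    put(iv(tx$tx_start, tx$tx_end), "intron")  # gene body default
    put(tx$utr3[[1]], "utr3")
    put(tx$utr5[[1]], "utr5")
    put(tx$cds[[1]], "cds")
  }
  # promoters never override gene-body labels
  for (k in seq_len(nrow(mm))) {
    tx <- mm[k, ]
    pr <- if (tx$strand == "+") {
      c(tx$tx_start - promoter_window, tx$tx_start - 1L)
    } else {
      c(tx$tx_end + 1L, tx$tx_end + promoter_window)
    }
    if (pr[2] >= pr[1]) put(iv(max(1L, pr[1]), min(length_bp, pr[2])), "promoter")
  }
  lab
}
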