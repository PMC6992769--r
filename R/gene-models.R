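#' Transcript-level gene models
#'
#' A `gene_models` object is a tibble with one row per transcript and
#' interval list-columns, the in-memory form of a GFF3 gene annotation.
#' Intervals are 1-based closed, stored as two-column integer matrices
#' (`start`, `end`) sorted by start. UTRs are derived as exon minus CDS and
#' assigned to the 5'/3' side strand-aware. A transcript whose total CDS
#' length is not divisible by three is flagged `incomplete` and excluded
#' from codon-level effect prediction.
#'
#' @param tx A data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), and list-columns `exons` and `cds` of
#'   two-column matrices.
#' @return A `gene_models` tibble with added `tx_start`, `tx_end`, `utr5`,
#'   `utr3`, `cds_len`, `incomplete` columns.
#' @export
gene_models <- function(tx) {
  tx <- as_tibble(tx)
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand",
                  "exons", "cds") %in% names(tx)))
  if (!all(tx$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  tx$exons <- lapply(tx$exons, iv_normalize)
  tx$cds <- lapply(tx$cds, iv_normalize)
  for (k in seq_len(nrow(tx))) {
    ex <- tx$exons[[k]]
    if (nrow(ex) == 0) abort(paste0(tx$transcript_id[k], " has no exons."))
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
      abort(paste0("Overlapping/unsorted exons in ", tx$transcript_id[k]))
    }
    cds <- tx$cds[[k]]
    if (nrow(cds) && !iv_contains(ex, cds)) {
      abort(paste0("CDS outside exons in ", tx$transcript_id[k]))
    }
  }
  tx$tx_start <- vapply(tx$exons, function(m) min(m[, 1]), integer(1))
  tx$tx_end <- vapply(tx$exons, function(m) max(m[, 2]), integer(1))
  tx$cds_len <- vapply(tx$cds, iv_width, integer(1))
  tx$incomplete <- tx$cds_len == 0L | tx$cds_len %% 3L != 0L
  utr <- lapply(seq_len(nrow(tx)), function(k) {
    non_cds <- iv_setdiff(tx$exons[[k]], tx$cds[[k]])
    if (nrow(tx$cds[[k]]) == 0 || nrow(non_cds) == 0) {
      return(list(utr5 = empty_iv(), utr3 = empty_iv()))
    }
    cds_lo <- min(tx$cds[[k]][, 1]); cds_hi <- max(tx$cds[[k]][, 2])
    lo <- non_cds[non_cds[, 2] < cds_lo, , drop = FALSE]
    hi <- non_cds[non_cds[, 1] > cds_hi, , drop = FALSE]
    if (tx$strand[k] == "+") list(utr5 = lo, utr3 = hi)
    else list(utr5 = hi, utr3 = lo)
  })
  tx$utr5 <- lapply(utr, `[[`, "utr5")
  tx$utr3 <- lapply(utr, `[[`, "utr3")
  bad_gene <- tx %>%
    group_by(.data$gene_id) %>%
    summarise(ok = dplyr::n_distinct(.data$chrom) == 1 &&
                dplyr::n_distinct(.data$strand) == 1) %>%
    filter(!.data$ok)
  if (nrow(bad_gene)) {
    abort(paste0("Transcripts of gene(s) ",
                 paste(bad_gene$gene_id, collapse = ", "),
                 " disagree on chrom/strand."))
  }
  class(tx) <- c("gene_models", class(tx))
  tx
}

#' Per-gene summary of a gene-model set
#'
#' @param models A [gene_models] object.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (span over all transcripts), `n_transcripts`.
#' @export
gene_table <- function(models) {
  models %>%
    as_tibble() %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$tx_start), end = max(.data$tx_end),
      n_transcripts = n(), .groups = "drop"
    ) %>%
    arrange(match(.data$chrom, unique(.data$chrom)), .data$start)
}

# ---- interval helpers (1-based closed, 2-col matrices) ----------------------

empty_iv <- function() matrix(integer(0), ncol = 2,
                              dimnames = list(NULL, c("start", "end")))

iv <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (any(m[, 2] < m[, 1])) abort("Interval end < start.")
  m
}

iv_normalize <- function(m) {
  if (is.null(m) || length(m) == 0) return(empty_iv())
  m <- matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1]), , drop = FALSE]
}

iv_width <- function(m) {
  if (nrow(m) == 0) return(0L)
  as.integer(sum(m[, 2] - m[, 1] + 1L))
}

iv_contains <- function(outer, inner) {
  ir_o <- IRanges::IRanges(outer[, 1], outer[, 2])
  ir_i <- IRanges::IRanges(inner[, 1], inner[, 2])
  length(IRanges::setdiff(ir_i, ir_o)) == 0
}

iv_setdiff <- function(a, b) {
  ir <- IRanges::setdiff(IRanges::IRanges(a[, 1], a[, 2]),
                         IRanges::IRanges(b[, 1], b[, 2]))
  iv_normalize(cbind(IRanges::start(ir), IRanges::end(ir)))
}

iv_point_in <- function(pos, m) {
  nrow(m) > 0 && any(pos >= m[, 1] & pos <= m[, 2])
}
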