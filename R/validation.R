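#' Reconstruct a marker position set from a coverage summary
#'
#' Builds a strictly increasing vector of `n_snps` positions on one
#' chromosome that is consistent with a published coverage summary: it
#' starts at `first_pos`, ends at `last_pos`, and its single largest
#' inter-marker gap is exactly `gap_after - gap_before`. The remaining
#' markers are spread evenly on both sides of the gap, densely enough
#' that no filler spacing exceeds the reported maximum gap. Running
#' [chromosome_coverage()] on the result must reproduce the summary's
#' derived columns (span, span fraction, bp per SNP, maximum gap and its
#' flanks) exactly.
#'
#' @param n_snps Number of markers.
#' @param first_pos,last_pos Positions of the first and last marker (bp).
#' @param gap_before,gap_after Markers flanking the maximum gap (bp).
#' @return Integer-valued numeric vector of length `n_snps`.
#' @export
reconstruct_marker_positions <- function(n_snps, first_pos, last_pos,
                                         gap_before, gap_after) {
  stopifnot(first_pos <= gap_before, gap_before < gap_after,
            gap_after <= last_pos, n_snps >= 4)
  n_snps <- as.numeric(n_snps)
  left_len <- as.numeric(gap_before) - as.numeric(first_pos)
  right_len <- as.numeric(last_pos) - as.numeric(gap_after)
  n_left <- max(2, round(n_snps * left_len / (left_len + right_len)))
  n_left <- min(n_left, n_snps - 2)
  left <- round(seq(first_pos, gap_before, length.out = n_left))
  right <- round(seq(gap_after, last_pos, length.out = n_snps - n_left))
  pos <- c(left, right)
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("Cannot reconstruct: summary too dense for distinct positions.")
  }
  gap <- gap_after - gap_before
  if (max(diff(pos)) != gap) {
    abort("Cannot reconstruct: filler spacing exceeds the reported maximum gap.")
  }
  pos
}

#' Bundled per-pseudomolecule GBS SNP coverage summary
#'
#' A published per-pseudomolecule summary of a high-quality GBS SNP set on
#' the eight peach (Peach v2.0) pseudomolecules: SNP counts, first/last
#' marker positions, the maximum inter-marker gap with its flanking
#' markers, and the derived coverage columns as reported. Used to validate
#' the coverage statistics against independently published arithmetic.
#'
#' @return A tibble with one row per pseudomolecule.
#' @export
peach_snp_summary <- function() {
  path <- system.file("extdata", "peach_gbs_pseudomolecule_summary.csv",
                      package = "gbsland", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Bundled GBS substitution-class counts
#'
#' Counts of the six unordered nucleotide substitution classes reported
#' for the same peach GBS SNP set; companion to [peach_snp_summary()].
#'
#' @return A tibble `class`, `n`.
#' @export
peach_substitution_counts <- function() {
  tibble(
    class = c("C/T", "A/G", "A/T", "A/C", "G/T", "C/G"),
    n = c(13639L, 13597L, 5497L, 4697L, 4394L, 3558L)
  )
}
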