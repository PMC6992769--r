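#' Quality-filter configuration
#'
#' Defaults reproduce a standard GBS filtering cascade: per-genotype depth
#' >= 6, site present in at least 80% of accessions, site missingness below
#' 5%, and minor allele frequency strictly above 0.05. The presence and
#' missingness thresholds coexist because real pipelines apply them at
#' different stages (initial calling vs final selection); both are applied
#' here sequentially and are individually configurable.
#'
#' @param min_depth Minimum per-genotype read depth (calls below are masked).
#' @param min_presence_fraction Minimum fraction of accessions with a call.
#' @param max_missing_fraction Maximum fraction of missing calls
#'   (strictly-less-than rule).
#' @param min_maf Minimum minor allele frequency (strictly-greater-than rule).
#' @param biallelic_only Keep only biallelic SNPs (always true for
#'   [gbs_geno] input; kept for report symmetry).
#' @param unknown_depth_passes When no depth is recorded for a call, does it
#'   pass the depth filter? Default `FALSE` (conservative: unknown fails).
#' @param site_mean_depth Use the site-mean depth instead of per-genotype
#'   masking.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 6,
                          min_presence_fraction = 0.80,
                          max_missing_fraction = 0.05,
                          min_maf = 0.05,
                          biallelic_only = TRUE,
                          unknown_depth_passes = FALSE,
                          site_mean_depth = FALSE) {
  stopifnot(min_depth >= 0,
            min_presence_fraction >= 0, min_presence_fraction <= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_maf >= 0, min_maf <= 0.5)
  structure(as.list(environment()), class = "filter_config")
}

#' Mask low-depth genotype calls
#'
#' Sets every call whose read depth is below `min_depth` to missing. The
#' boundary is inclusive: a call at exactly `min_depth` is kept. With no
#' depth matrix, behaviour follows `unknown_depth_passes`.
#'
#' @param gm A [gbs_geno] object.
#' @param min_depth Depth threshold (default 6).
#' @param unknown_depth_passes Whether calls with unknown depth survive.
#' @param site_mean If `TRUE`, drop whole sites whose mean depth over
#'   non-missing calls is below the threshold instead of masking calls.
#' @return The masked `gbs_geno`.
#' @export
apply_depth_mask <- function(gm, min_depth = 6, unknown_depth_passes = FALSE,
                             site_mean = FALSE) {
  if (min_depth <= 0) return(gm)
  if (is.null(gm$depth)) {
    if (unknown_depth_passes) return(gm)
    gm$dosage[] <- NA_integer_
    return(gm)
  }
  if (site_mean) {
    md <- rowMeans(gm$depth, na.rm = TRUE)
    return(subset_geno(gm, sites = which(md >= min_depth)))
  }
  low <- !is.na(gm$depth) & gm$depth < min_depth
  if (!unknown_depth_passes) low <- low | is.na(gm$depth)
  gm$dosage[low] <- NA_integer_
  gm
}

#' Minor allele frequency of one site
#'
#' MAF = min(p, 1 - p) with p = alt-dosage sum / (2 x non-missing calls);
#' missing calls are excluded from the denominator.
#'
#' @param calls Integer vector of dosages (0, 1, 2, NA).
#' @return MAF in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) abort("MAF undefined: all calls missing.")
  p <- sum(calls[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

site_maf <- function(dosage) {
  nn <- rowSums(!is.na(dosage))
  p <- rowSums(dosage, na.rm = TRUE) / (2 * nn)
  ifelse(nn == 0, NA_real_, pmin(p, 1 - p))
}

#' Filter sites by presence, missingness and MAF
#'
#' Applies the site-level rules in a fixed, accountable order:
#' biallelic -> presence >= `min_presence_fraction` -> missingness <
#' `max_missing_fraction` -> MAF > `min_maf` (both inequalities strict as
#' stated). Surviving sites keep their original order. Apply
#' [apply_depth_mask()] first; this function does not touch depths.
#'
#' @param gm A [gbs_geno] object (depth-masked).
#' @param cfg A [filter_config].
#' @return A list: `gm` (filtered [gbs_geno]) and `report`, a tibble of
#'   per-rule removal counts in application order plus input/output totals
#'   as attributes `input_sites` / `output_sites`.
#' @export
filter_sites <- function(gm, cfg = filter_config()) {
  n_in <- nrow(gm$sites)
  keep <- rep(TRUE, n_in)
  removed <- c(biallelic = 0L, presence = 0L, missingness = 0L, maf = 0L)

  # gbs_geno is biallelic by construction; the rule is a no-op kept for the
  # report's sake.
  n_acc <- ncol(gm$dosage)
  present <- rowSums(!is.na(gm$dosage)) / n_acc

  fail <- keep & present < cfg$min_presence_fraction
  removed["presence"] <- sum(fail); keep <- keep & !fail

  fail <- keep & (1 - present) >= cfg$max_missing_fraction
  removed["missingness"] <- sum(fail); keep <- keep & !fail

  maf <- site_maf(gm$dosage)
  fail <- keep & (is.na(maf) | maf <= cfg$min_maf)
  removed["maf"] <- sum(fail); keep <- keep & !fail

  if (!any(keep)) warn("All sites removed by filtering.")
  out <- subset_geno(gm, sites = which(keep))
  report <- tibble(rule = names(removed), removed = as.integer(removed))
  attr(report, "input_sites") <- n_in
  attr(report, "output_sites") <- sum(keep)
  stopifnot(n_in == sum(keep) + sum(removed))
  list(gm = out, report = report)
}

#' One-call quality filtering
#'
#' Convenience wrapper: depth mask then site filters.
#'
#' @param gm A [gbs_geno] object.
#' @param cfg A [filter_config].
#' @return As [filter_sites()].
#' @export
filter_genotypes <- function(gm, cfg = filter_config()) {
  gm <- apply_depth_mask(gm, cfg$min_depth,
                         unknown_depth_passes = cfg$unknown_depth_passes,
                         site_mean = cfg$site_mean_depth)
  filter_sites(gm, cfg)
}
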