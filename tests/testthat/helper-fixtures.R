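# Shared fixtures, built once per test run and cached.

.fx <- new.env()

fx_genome <- function() {
  if (is.null(.fx$gen)) .fx$gen <- generate_genome(genome_spec(rng_seed = 7))
  .fx$gen
}

fx_planted <- function() {
  if (is.null(.fx$pv)) {
    .fx$pv <- plant_variants(
      fx_genome(),
      requested = c(synonymous = 80, missense = 80, stop_gained = 40,
                    stop_lost = 20, start_lost = 20, splice_donor = 25,
                    splice_acceptor = 25, intron = 60, utr5 = 40, utr3 = 40,
                    promoter = 50, intergenic = 60),
      rng_seed = 3
    )
  }
  .fx$pv
}

# Balding-Nichols panel used by the admixture-recovery checks: the
# simulation seed is fixed (it defines the study conditions); fit seeds
# vary per test.
fx_bn_panel <- function() {
  if (is.null(.fx$bn)) {
    .fx$bn <- simulate_genotypes(population_spec(
      K = 3, fst = 0.15, n_loci = 500,
      n_per_population = c(0, 0, 0), n_hybrids = 0, n_admixed = 30,
      dirichlet_alpha = 0.05, n_duplicates = 0, missing_rate = 0,
      rng_seed = 1))
  }
  .fx$bn
}

# small genotype container from a dosage matrix (sites on one chromosome)
make_gm <- function(dosage, depth = NULL, chrom_len = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("acc", seq_len(ncol(dosage)))
  }
  L <- nrow(dosage)
  sites <- tibble::tibble(chrom = "c1", pos = seq_len(L) * 10L,
                          ref = "A", alt = "G")
  ci <- if (!is.null(chrom_len)) tibble::tibble(name = "c1", length_bp = chrom_len)
  gbs_geno(sites, dosage, depth = depth, chrom_info = ci)
}

# map from planted truth_effect names to predictor effect names
TRUTH_EFFECT_MAP <- c(
  synonymous = "synonymous_variant", missense = "missense_variant",
  stop_gained = "stop_gained", stop_lost = "stop_lost",
  start_lost = "start_lost", splice_donor = "splice_donor_variant",
  splice_acceptor = "splice_acceptor_variant"
)
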