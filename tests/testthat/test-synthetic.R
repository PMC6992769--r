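test_that("generated genomes are deterministic and structurally sound", {
  gen <- fx_genome()
  gen2 <- generate_genome(genome_spec(rng_seed = 7))
  expect_identical(gen$genome, gen2$genome)
  expect_identical(gen$models$exons, gen2$models$exons)

  spec <- genome_spec(n_chromosomes = 1, n_genes_per_chromosome = 2,
                      rng_seed = 99)
  small <- generate_genome(spec)
  expect_identical(nrow(gene_table(small$models)), 2L)
  expect_true(all(small$models$cds_len %% 3L == 0L))

  # FASTA/GFF3 emission is byte-identical across runs with one seed
  f1 <- tempfile(fileext = ".fa"); g1 <- tempfile(fileext = ".gff3")
  f2 <- tempfile(fileext = ".fa"); g2 <- tempfile(fileext = ".gff3")
  write_genome(generate_genome(spec), f1, g1)
  write_genome(generate_genome(spec), f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
})

test_that("every generated CDS translates cleanly (brute-force codon loop)", {
  gen <- fx_genome()
  code <- Biostrings::GENETIC_CODE
  for (k in seq_len(nrow(gen$models))) {
    tx <- gen$models[k, ]
    cds <- tx$cds[[1]]
    pos <- sort(unlist(lapply(seq_len(nrow(cds)), function(r) cds[r, 1]:cds[r, 2])))
    chars <- strsplit(gen$genome[[tx$chrom]], "")[[1]][pos]
    if (tx$strand == "-") chars <- rev(chartr("ACGT", "TGCA", chars))
    n_cod <- length(chars) / 3
    aas <- vapply(seq_len(n_cod), function(i) {
      code[[paste(chars[(3 * i - 2):(3 * i)], collapse = "")]]
    }, character(1))
    expect_identical(aas[1], "M")
    expect_identical(aas[n_cod], "*")
    expect_false(any(aas[-n_cod] == "*"))
  }
})

test_that("planted variants carry provable truth labels", {
  gen <- fx_genome()
  pv <- fx_planted()
  counts <- table(pv$truth_effect)
  expect_identical(unname(counts[["stop_gained"]]), 40L)
  expect_identical(unname(counts[["splice_donor"]]), 25L)
  expect_identical(sum(pv$truth_context == "promoter"), 50L)
  expect_identical(sum(pv$truth_context == "intergenic"), 60L)
  expect_false(anyDuplicated(paste(pv$chrom, pv$pos)) > 0)

  # both strands are exercised by coding plants
  strands <- gen$models$strand[match(pv$transcript_id[!is.na(pv$transcript_id)],
                                     gen$models$transcript_id)]
  expect_setequal(unique(strands), c("+", "-"))

  # codon-table oracle: re-derive the amino-acid change of every coding
  # plant directly from the genome sequence
  code <- Biostrings::GENETIC_CODE
  coding <- pv[pv$truth_context == "cds", ]
  for (r in seq_len(nrow(coding))) {
    v <- coding[r, ]
    tx <- gen$models[gen$models$transcript_id == v$transcript_id, ]
    cds <- tx$cds[[1]]
    pos <- sort(unlist(lapply(seq_len(nrow(cds)), function(x) cds[x, 1]:cds[x, 2])))
    chars <- strsplit(gen$genome[[tx$chrom]], "")[[1]][pos]
    alt_chars <- chars
    alt_chars[pos == v$pos] <- v$alt
    if (tx$strand == "-") {
      chars <- rev(chartr("ACGT", "TGCA", chars))
      alt_chars <- rev(chartr("ACGT", "TGCA", alt_chars))
      ci <- length(pos) - which(pos == v$pos) + 1
    } else {
      ci <- which(pos == v$pos)
    }
    k <- (ci - 1) %/% 3
    ref_cod <- paste(chars[(3 * k + 1):(3 * k + 3)], collapse = "")
    alt_cod <- paste(alt_chars[(3 * k + 1):(3 * k + 3)], collapse = "")
    ok <- switch(v$truth_effect,
      synonymous = code[[ref_cod]] == code[[alt_cod]],
      missense = code[[ref_cod]] != code[[alt_cod]] && code[[alt_cod]] != "*",
      stop_gained = code[[alt_cod]] == "*" && code[[ref_cod]] != "*",
      stop_lost = code[[ref_cod]] == "*" && code[[alt_cod]] != "*",
      start_lost = ref_cod == "ATG" && alt_cod != "ATG")
    expect_true(ok, info = paste(v$id, v$truth_effect, ref_cod, alt_cod))
  }

  # splice plants sit in the first/last two intron bases; promoter plants
  # within 1 kb upstream of the TSS, strand-aware
  for (r in which(pv$truth_effect %in% c("splice_donor", "splice_acceptor"))) {
    v <- pv[r, ]
    tx <- gen$models[gen$models$transcript_id == v$transcript_id, ]
    ex <- tx$exons[[1]]
    intr <- cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L)
    hit <- which(v$pos >= intr[, 1] & v$pos <= intr[, 2])
    expect_length(hit, 1)
    edge_lo <- v$pos <= intr[hit, 1] + 1L
    edge_hi <- v$pos >= intr[hit, 2] - 1L
    expect_true(edge_lo || edge_hi)
    donor <- (tx$strand == "+") == edge_lo
    expect_identical(v$truth_effect,
                     if (donor) "splice_donor" else "splice_acceptor")
  }
  for (r in which(pv$truth_context == "promoter")) {
    v <- pv[r, ]
    tx <- gen$models[gen$models$transcript_id == v$transcript_id, ]
    if (tx$strand == "+") {
      expect_true(v$pos >= tx$tx_start - 1000 && v$pos < tx$tx_start)
    } else {
      expect_true(v$pos > tx$tx_end && v$pos <= tx$tx_end + 1000)
    }
  }
})

test_that("plant_variants reports impossible categories as capacity errors", {
  spec <- genome_spec(n_chromosomes = 1, n_genes_per_chromosome = 1,
                      exons_per_transcript = c(1, 1), rng_seed = 5)
  gen <- generate_genome(spec)   # single-exon gene: no introns
  expect_error(plant_variants(gen, requested = c(splice_donor = 1)),
               "capacity")
})

test_that("simulated genotypes follow the admixture model", {
  # F1 hybrids carry membership exactly (0.5, 0.5)
  sim <- simulate_genotypes(population_spec(
    K = 2, fst = 0.4, n_loci = 200, n_per_population = c(4, 4),
    n_hybrids = 2, n_admixed = 0, n_duplicates = 0, missing_rate = 0.05,
    rng_seed = 3))
  hyb <- sim$truth$accession[sim$truth$group == "hybrid"]
  expect_equal(unname(as.matrix(sim$truth[sim$truth$group == "hybrid",
                                          c("Q1", "Q2")])),
               matrix(0.5, length(hyb), 2))

  # duplicates are exact copies on jointly non-missing sites
  sim_d <- simulate_genotypes(population_spec(rng_seed = 11))
  dups <- sim_d$truth[!is.na(sim_d$truth$duplicate_of), ]
  for (r in seq_len(nrow(dups))) {
    expect_identical(
      duplicate_concordance(sim_d$gm, dups$accession[r], dups$duplicate_of[r]),
      1, ignore_attr = TRUE)
  }

  # determinism
  s2a <- simulate_genotypes(population_spec(rng_seed = 8))
  s2b <- simulate_genotypes(population_spec(rng_seed = 8))
  expect_identical(s2a$gm$dosage, s2b$gm$dosage)
})

test_that("population divergence matches the Balding-Nichols expectation", {
  # E[(f1 - f2)^2] = 2 * Fst * p(1-p) for two populations with the same
  # Fst around ancestral frequency p ~ U(0.1, 0.9): average over loci.
  fst <- 0.15
  sim <- simulate_genotypes(population_spec(
    K = 2, fst = fst, n_loci = 5000, n_per_population = c(2, 2),
    n_hybrids = 0, n_admixed = 0, n_duplicates = 0, missing_rate = 0,
    rng_seed = 13))
  Fmat <- sim$F
  obs <- mean((Fmat[1, ] - Fmat[2, ])^2)
  # E[p(1-p)] for p ~ U(0.1, 0.9): integrate -> 0.5 - (0.9^3-0.1^3)/(3*0.8)
  epq <- 0.5 - (0.9^3 - 0.1^3) / (3 * 0.8)
  expected <- 2 * fst * epq
  expect_lt(abs(obs - expected) / expected, 0.1)

  # fst -> 0 limit: population frequencies collapse onto the ancestral ones
  sim0 <- simulate_genotypes(population_spec(
    K = 3, fst = 0.001, n_loci = 2000, n_per_population = c(2, 2, 2),
    n_hybrids = 0, n_admixed = 0, n_duplicates = 0, missing_rate = 0,
    rng_seed = 14))
  eh <- rowMeans(2 * sim0$F * (1 - sim0$F))  # expected heterozygosity per pop
  expect_lt(max(eh) - min(eh), 0.01)
})
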