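# hand-built single-gene genome: 10 bp lead-in, 5 bp 5'UTR, CDS
# ATG CAA GAA TAA, 5 bp 3'UTR, 5 bp tail
hand_genome <- function(strand = "+") {
  fwd <- paste0("AAAAACCCCC", "GGTCC", "ATGCAAGAATAA", "GGACC", "TTTTT")
  if (strand == "+") {
    genome <- c(c1 = fwd)
    tx <- tibble::tibble(transcript_id = "t1", gene_id = "g1", chrom = "c1",
                         strand = "+",
                         exons = list(iv(11, 32)), cds = list(iv(16, 27)))
  } else {
    chars <- rev(chartr("ACGT", "TGCA", strsplit(fwd, "")[[1]]))
    genome <- c(c1 = paste(chars, collapse = ""))
    L <- nchar(fwd)
    tx <- tibble::tibble(transcript_id = "t1", gene_id = "g1", chrom = "c1",
                         strand = "-",
                         exons = list(iv(L - 32 + 1, L - 11 + 1)),
                         cds = list(iv(L - 27 + 1, L - 16 + 1)))
  }
  list(genome = genome, models = gene_models(tx))
}

test_that("context classification applies region and promoter rules", {
  hg <- hand_genome()
  sites <- tibble::tibble(chrom = "c1",
                          pos = c(20L, 12L, 30L, 5L, 35L),
                          ref = "A", alt = "G")
  ctx <- classify_context(sites, hg$models, promoter_window = 8)
  expect_identical(ctx$context, c("cds", "utr5", "utr3", "intergenic",
                                  "intergenic"))
  # position 5 is 6 bp upstream of the TSS (11) on a plus strand
  expect_identical(ctx$promoter_flag, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(ctx$gene_id, c("g1", "g1", "g1", NA, NA))

  # severity precedence across transcripts: cds in one transcript beats
  # intron in another
  tx2 <- tibble::tibble(
    transcript_id = c("a", "b"), gene_id = "g", chrom = "c1", strand = "+",
    exons = list(iv(100, 160), rbind(c(100L, 110L), c(150L, 160L))),
    cds = list(iv(100, 159), rbind(c(100L, 110L), c(150L, 159L)))
  )
  m2 <- gene_models(tx2)
  ctx2 <- classify_context(tibble::tibble(chrom = "c1", pos = 130L,
                                          ref = "A", alt = "G"), m2)
  expect_identical(ctx2$context, "cds")
  expect_identical(ctx2$transcript_id, "a")
})

test_that("codon-level effect calls match the genetic code", {
  for (strand in c("+", "-")) {
    hg <- hand_genome(strand)
    L <- nchar(hg$genome[[1]])
    flip <- function(p) if (strand == "+") p else L - p + 1L
    base_at <- function(p) substr(hg$genome[[1]], p, p)
    cmp <- function(b) if (strand == "+") b else chartr("ACGT", "TGCA", b)

    # CAA -> TAA in frame: stop gained, high impact
    p1 <- flip(19L)
    s1 <- tibble::tibble(chrom = "c1", pos = p1, ref = base_at(p1),
                         alt = cmp("T"), id = "v1")
    e1 <- predict_effects(s1, hg$models, hg$genome)
    expect_identical(e1$effect, "stop_gained")
    expect_identical(e1$impact, "high")
    expect_identical(e1$codon_ref, "CAA")
    expect_identical(e1$codon_alt, "TAA")

    # GAA -> GAG: synonymous (Glu -> Glu), low impact
    p2 <- flip(24L)
    s2 <- tibble::tibble(chrom = "c1", pos = p2, ref = base_at(p2),
                         alt = cmp("G"), id = "v2")
    e2 <- predict_effects(s2, hg$models, hg$genome)
    expect_identical(e2$effect, "synonymous_variant")
    expect_identical(e2$aa_ref, "E")
    expect_identical(e2$aa_alt, "E")

    # ATG -> CTG: start lost
    p3 <- flip(16L)
    s3 <- tibble::tibble(chrom = "c1", pos = p3, ref = base_at(p3),
                         alt = cmp("C"), id = "v3")
    expect_identical(predict_effects(s3, hg$models, hg$genome)$effect,
                     "start_lost")
  }
})

test_that("ref-mismatch sites are recorded and skipped", {
  hg <- hand_genome()
  sites <- tibble::tibble(chrom = "c1", pos = c(20L, 21L),
                          ref = c(substr(hg$genome[[1]], 20, 20), "T"),
                          alt = c("G", "C"), id = c("ok", "bad"))
  # ensure the planted mismatch really mismatches
  stopifnot(substr(hg$genome[[1]], 21, 21) != "T")
  eff <- predict_effects(sites, hg$models, hg$genome)
  expect_false("bad" %in% eff$id)
  mm <- attr(eff, "ref_mismatch")
  expect_identical(mm$id, "bad")
})

test_that("upstream/downstream/intergenic records are strand-aware", {
  tx <- tibble::tibble(transcript_id = "t", gene_id = "g", chrom = "c1",
                       strand = "-",
                       exons = list(iv(5000, 5099)), cds = list(iv(5000, 5099)))
  m <- gene_models(tx)
  genome <- c(c1 = paste(rep("A", 20000), collapse = ""))
  sites <- tibble::tibble(chrom = "c1", pos = c(4000L, 6000L, 15000L),
                          ref = "A", alt = "G",
                          id = c("low", "high", "far"))
  eff <- predict_effects(sites, m, genome)
  # minus strand: upstream = higher coordinates
  expect_identical(eff$effect[eff$id == "high"], "upstream_gene_variant")
  expect_identical(eff$effect[eff$id == "low"], "downstream_gene_variant")
  expect_identical(eff$effect[eff$id == "far"], "intergenic_variant")
  expect_true(all(eff$impact == "modifier"))
})

test_that("amino-acid property classes partition the 20 residues", {
  cls <- aa_property_classes()
  expect_identical(sort(names(cls)), sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_identical(as.vector(table(cls)[c("acidic", "basic", "nonpolar", "polar")]),
                   c(2L, 3L, 9L, 6L))

  expect_identical(classify_aa_change("K", "E")$pattern, "basic to acidic")
  expect_identical(classify_aa_change("L", "V")$pattern, "nonpolar to nonpolar")
  expect_identical(classify_aa_change("S", "A")$pattern, "polar to nonpolar")
  expect_error(classify_aa_change("K", "*"), "Stop")
})

test_that("per-SNP summarization uses severity precedence", {
  # one SNP, coding in transcript a, intronic in transcript b
  tx <- tibble::tibble(
    transcript_id = c("a", "b"), gene_id = "g", chrom = "c1", strand = "+",
    exons = list(iv(101, 112), rbind(c(95L, 100L), c(120L, 130L))),
    cds = list(iv(101, 112), empty_iv())
  )
  m <- gene_models(tx)
  genome <- c(c1 = paste0(paste(rep("A", 100), collapse = ""),
                          "ATGCAAGAATAA",
                          paste(rep("A", 100), collapse = "")))
  s <- tibble::tibble(chrom = "c1", pos = 104L, ref = "C", alt = "T", id = "v")
  eff <- predict_effects(s, m, genome)
  expect_identical(nrow(eff), 2L)
  smry <- summarize_effects(eff)
  expect_identical(nrow(smry$per_snp), 1L)
  expect_identical(smry$per_snp$effect, "stop_gained")
  expect_identical(smry$by_impact$impact, "high")
})

test_that("variants_per_gene averages genic SNPs over genes hit", {
  ctx <- tibble::tibble(
    id = sprintf("s%d", 1:7),
    context = c("cds", "cds", "intron", "utr5", "intergenic", "cds", "utr3"),
    gene_id = c("g1", "g1", "g1", "g2", NA, "g3", "g3")
  )
  v <- variants_per_gene(ctx)
  expect_identical(nrow(v$per_gene), 3L)
  expect_equal(v$mean_per_gene, 6 / 3)
})

test_that("high-impact report lists genotype states against the reference", {
  hg <- hand_genome()
  sites <- tibble::tibble(chrom = "c1", pos = 19L,
                          ref = substr(hg$genome[[1]], 19, 19), alt = "T",
                          id = "c1_19")
  dos <- matrix(c(0L, 1L, 2L, NA), 1, 4,
                dimnames = list(NULL, c("w", "x", "y", "z")))
  gm <- gbs_geno(sites, dos)
  eff <- predict_effects(sites, hg$models, hg$genome)
  ctx <- classify_context(sites, hg$models)
  rep <- high_impact_report(eff, gm, contexts = ctx)
  expect_identical(nrow(rep), 4L)
  expect_true(all(rep$effect == "stop_gained"))
  expect_identical(rep$genotype, c("ref/ref", "ref/alt", "alt/alt", "missing"))
  expect_identical(unique(rep$context), "cds")
})

test_that("effect calls are invariant under reverse-complementing the genome", {
  gen <- fx_genome()
  pv <- fx_planted()
  pv_sub <- pv[seq(1, nrow(pv), by = 7), ]   # spot-check a spread of plants

  # mirror the genome: reverse-complement every chromosome, flip strands
  lens <- setNames(nchar(gen$genome), names(gen$genome))
  rc_genome <- vapply(gen$genome, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1))
  flip_iv <- function(m, L) {
    if (nrow(m) == 0) return(empty_iv())
    iv(L - m[, 2] + 1L, L - m[, 1] + 1L)
  }
  tx <- tibble::as_tibble(gen$models)[
    c("transcript_id", "gene_id", "chrom", "strand", "exons", "cds")]
  for (k in seq_len(nrow(tx))) {
    L <- lens[[tx$chrom[k]]]
    tx$exons[[k]] <- flip_iv(tx$exons[[k]], L)
    tx$cds[[k]] <- flip_iv(tx$cds[[k]], L)
    tx$strand[k] <- if (tx$strand[k] == "+") "-" else "+"
  }
  m_rc <- gene_models(tx)
  pv_rc <- pv_sub
  pv_rc$pos <- as.integer(lens[pv_rc$chrom] - pv_rc$pos + 1L)
  pv_rc$ref <- chartr("ACGT", "TGCA", pv_rc$ref)
  pv_rc$alt <- chartr("ACGT", "TGCA", pv_rc$alt)

  e1 <- summarize_effects(predict_effects(pv_sub, gen$models, gen$genome))$per_snp
  e2 <- summarize_effects(predict_effects(pv_rc, m_rc, rc_genome))$per_snp
  expect_identical(e1$effect[match(pv_sub$id, e1$id)],
                   e2$effect[match(pv_rc$id, e2$id)])
})
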