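EFFECT_LEVELS <- c("synonymous_variant", "missense_variant", "stop_gained",
                   "stop_lost", "start_lost", "splice_donor_variant",
                   "splice_acceptor_variant", "intron_variant",
                   "utr5_variant", "utr3_variant", "upstream_gene_variant",
                   "downstream_gene_variant", "intergenic_variant")

IMPACT_MAP <- c(
  synonymous_variant = "low",
  missense_variant = "moderate",
  stop_gained = "high", stop_lost = "high", start_lost = "high",
  splice_donor_variant = "high", splice_acceptor_variant = "high",
  intron_variant = "modifier", utr5_variant = "modifier",
  utr3_variant = "modifier", upstream_gene_variant = "modifier",
  downstream_gene_variant = "modifier", intergenic_variant = "modifier"
)

IMPACT_RANK <- c(high = 1, moderate = 2, low = 3, modifier = 4)

#' Predict variant effects against gene models
#'
#' SnpEff-style per-transcript effect calls. For a SNP inside a
#' transcript: positions in the first/last two bases of an intron (in
#' transcript orientation) are splice donor/acceptor variants; CDS
#' positions are located in the transcript reading frame (strand-aware,
#' reverse-complemented on `-`) and classified by codon comparison —
#' same amino acid: synonymous; different: missense; alternate codon a
#' stop: stop gained; reference codon a stop and alternate not: stop lost;
#' the initiator ATG destroyed: start lost. UTR and intron interiors give
#' modifier-class records. When no transcript overlaps, the SNP gets one
#' upstream/downstream record if within `updown_window` of the nearest
#' gene (strand-aware), else an intergenic record. Impact classes follow
#' the fixed map modifier/low/moderate/high. Transcripts flagged
#' incomplete (CDS length not divisible by three) are excluded from
#' codon-level calls.
#'
#' The reference allele of each SNP is validated against the genome; a
#' mismatching site is skipped from effect calls and listed in the
#' `ref_mismatch` attribute of the result.
#'
#' @param sites Site table with `chrom`, `pos`, `ref`, `alt` (or a
#'   [gbs_geno]).
#' @param models A [gene_models] object.
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param updown_window Upstream/downstream window in bp (default 5000).
#' @return A tibble with one row per SNP x transcript (plus single
#'   intergenic/upstream/downstream rows): site columns, `gene_id`,
#'   `transcript_id`, `effect`, `impact`, `codon_ref`, `codon_alt`,
#'   `aa_ref`, `aa_alt`.
#' @export
predict_effects <- function(sites, models, genome, updown_window = 5000) {
  if (inherits(sites, "gbs_geno")) sites <- sites$sites
  sites <- as_tibble(sites)
  if (!"id" %in% names(sites)) sites$id <- paste0(sites$chrom, "_", sites$pos)
  genome <- normalize_genome(genome)

  # reference-allele validation
  gref <- vapply(seq_len(nrow(sites)), function(i) {
    substr(genome[[sites$chrom[i]]], sites$pos[i], sites$pos[i])
  }, character(1))
  mismatch <- gref != sites$ref
  mm_tbl <- sites[mismatch, c("chrom", "pos", "id", "ref")]
  mm_tbl$genome_base <- gref[mismatch]
  ok_sites <- sites[!mismatch, , drop = FALSE]

  tx_gr <- GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$tx_start, models$tx_end))
  site_gr <- GenomicRanges::GRanges(ok_sites$chrom,
                                    IRanges::IRanges(ok_sites$pos, ok_sites$pos))
  hits <- GenomicRanges::findOverlaps(site_gr, tx_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  maps <- new.env()
  get_map <- function(k) {
    key <- as.character(k)
    if (is.null(maps[[key]])) maps[[key]] <- coding_map(genome, models[k, ])
    maps[[key]]
  }

  rows <- vector("list", length(qh))
  for (h in seq_along(qh)) {
    i <- qh[h]; k <- sh[h]
    rows[[h]] <- effect_one(ok_sites[i, ], models[k, ], get_map, k)
  }
  covered <- unique(qh[!vapply(rows, is.null, logical(1))])
  genes <- gene_table(models)
  orphan_rows <- lapply(setdiff(seq_len(nrow(ok_sites)), covered), function(i) {
    effect_nearest(ok_sites[i, ], genes, updown_window)
  })
  out <- bind_rows(c(rows, orphan_rows))
  out <- out[order(match(out$id, sites$id)), ]
  attr(out, "ref_mismatch") <- mm_tbl
  out
}

normalize_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.list(genome)) {
    unlist(genome)
  } else genome
}

effect_row <- function(site, gene_id, tx_id, effect,
                       codon_ref = NA_character_, codon_alt = NA_character_,
                       aa_ref = NA_character_, aa_alt = NA_character_) {
  tibble(chrom = site$chrom, pos = site$pos, id = site$id,
         ref = site$ref, alt = site$alt,
         gene_id = gene_id, transcript_id = tx_id,
         effect = effect, impact = unname(IMPACT_MAP[effect]),
         codon_ref = codon_ref, codon_alt = codon_alt,
         aa_ref = aa_ref, aa_alt = aa_alt)
}

effect_one <- function(site, tx, get_map, k) {
  pos <- site$pos
  intr <- tx_introns(tx)
  if (nrow(intr)) {
    for (r in seq_len(nrow(intr))) {
      if (pos >= intr[r, 1] && pos <= intr[r, 2]) {
        lo2 <- pos <= intr[r, 1] + 1L
        hi2 <- pos >= intr[r, 2] - 1L
        if (lo2 || hi2) {
          donor <- (tx$strand == "+") == lo2
          return(effect_row(site, tx$gene_id, tx$transcript_id,
                            if (donor) "splice_donor_variant"
                            else "splice_acceptor_variant"))
        }
        return(effect_row(site, tx$gene_id, tx$transcript_id, "intron_variant"))
      }
    }
  }
  if (iv_point_in(pos, tx$utr5[[1]])) {
    return(effect_row(site, tx$gene_id, tx$transcript_id, "utr5_variant"))
  }
  if (iv_point_in(pos, tx$utr3[[1]])) {
    return(effect_row(site, tx$gene_id, tx$transcript_id, "utr3_variant"))
  }
  if (iv_point_in(pos, tx$cds[[1]])) {
    if (tx$incomplete) return(NULL)  # no codon-level call possible
    map <- get_map(k)
    ci <- which(map$pos == pos)
    cod_i <- (ci - 1L) %/% 3L + 1L
    idx <- (3L * cod_i - 2L):(3L * cod_i)
    ref_cod <- paste(map$base[idx], collapse = "")
    off <- ci - idx[1] + 1L
    alt_base <- if (tx$strand == "+") site$alt else comp_char(site$alt)
    alt_cod <- ref_cod
    substr(alt_cod, off, off) <- alt_base
    aa_r <- codon_aa(ref_cod); aa_a <- codon_aa(alt_cod)
    effect <-
      if (cod_i == 1L && ref_cod == "ATG" && alt_cod != "ATG") "start_lost"
      else if (!(ref_cod %in% STOPS) && alt_cod %in% STOPS) "stop_gained"
      else if (ref_cod %in% STOPS && !(alt_cod %in% STOPS)) "stop_lost"
      else if (aa_r == aa_a) "synonymous_variant"
      else "missense_variant"
    return(effect_row(site, tx$gene_id, tx$transcript_id, effect,
                      codon_ref = ref_cod, codon_alt = alt_cod,
                      aa_ref = aa_r, aa_alt = aa_a))
  }
  # inside the transcript span but in none of the regions: exonic gap —
  # cannot happen for well-formed models; fall back to intron.
  effect_row(site, tx$gene_id, tx$transcript_id, "intron_variant")
}

effect_nearest <- function(site, genes, updown_window) {
  g <- genes[genes$chrom == site$chrom, ]
  if (nrow(g) == 0) return(effect_row(site, NA_character_, NA_character_,
                                      "intergenic_variant"))
  dist <- pmax(g$start - site$pos, site$pos - g$end, 0)
  j <- which.min(dist)
  if (dist[j] > updown_window || dist[j] == 0) {
    return(effect_row(site, NA_character_, NA_character_, "intergenic_variant"))
  }
  before <- site$pos < g$start[j]
  upstream <- (g$strand[j] == "+") == before
  effect_row(site, g$gene_id[j], NA_character_,
             if (upstream) "upstream_gene_variant" else "downstream_gene_variant")
}

#' Amino-acid property classes
#'
#' The default partition of the 20 standard amino acids into
#' nonpolar/polar/acidic/basic, configurable for alternative conventions
#' (histidine is assigned to basic, glycine to nonpolar).
#'
#' @return Named character vector mapping one-letter codes to classes.
#' @export
aa_property_classes <- function() {
  c(G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
    I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
    W = "nonpolar",
    S = "polar", T = "polar", C = "polar", Y = "polar", N = "polar",
    Q = "polar",
    D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic")
}

#' Classify an amino-acid substitution by property change
#'
#' @param aa_ref,aa_alt One-letter amino-acid codes (vectorized).
#' @param classes Property partition, by default [aa_property_classes()].
#' @return A tibble `aa_ref`, `aa_alt`, `from_class`, `to_class`,
#'   `pattern` (e.g. `"basic to acidic"`).
#' @export
classify_aa_change <- function(aa_ref, aa_alt, classes = aa_property_classes()) {
  stopifnot(sort(names(classes)) == sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  if (any(aa_ref == "*") || any(aa_alt == "*")) {
    abort("Stop codons have no property class; filter stop changes first.")
  }
  bad <- !(aa_ref %in% names(classes)) | !(aa_alt %in% names(classes))
  if (any(bad)) abort("Non-standard amino acid in input.")
  from <- unname(classes[aa_ref]); to <- unname(classes[aa_alt])
  tibble(aa_ref = aa_ref, aa_alt = aa_alt, from_class = from, to_class = to,
         pattern = paste(from, "to", to))
}

#' Collapse per-transcript effects to one effect per SNP
#'
#' Reports the most severe effect across transcripts (impact rank
#' high > moderate > low > modifier; ties broken by the fixed effect
#' order), plus tallies by effect and by impact class.
#'
#' @param effects Output of [predict_effects()].
#' @return A list: `per_snp` (one row per SNP with its summarized effect),
#'   `by_effect` and `by_impact` tally tibbles.
#' @export
summarize_effects <- function(effects) {
  eff <- effects %>%
    mutate(
      .imp_rank = IMPACT_RANK[.data$impact],
      .eff_rank = match(.data$effect, EFFECT_LEVELS)
    ) %>%
    group_by(.data$id) %>%
    arrange(.data$.imp_rank, .data$.eff_rank, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(-".imp_rank", -".eff_rank")
  eff <- eff[order(match(eff$id, unique(effects$id))), ]
  list(
    per_snp = eff,
    by_effect = eff %>% count(.data$effect, name = "n") %>%
      mutate(percent = 100 * .data$n / sum(.data$n)),
    by_impact = eff %>% count(.data$impact, name = "n") %>%
      mutate(percent = 100 * .data$n / sum(.data$n))
  )
}

#' Report high-impact SNPs with per-accession genotype states
#'
#' @param effects Output of [predict_effects()].
#' @param gm The [gbs_geno] the effects were computed on.
#' @param contexts Optional output of [classify_context()] supplying the
#'   location category per SNP.
#' @return A tidy tibble: one row per high-impact SNP x accession with
#'   `chrom`, `pos`, `id`, `gene_id`, `effect`, `context`, `accession`,
#'   `genotype` (`"ref/ref"`, `"ref/alt"`, `"alt/alt"`, `"missing"`).
#' @export
high_impact_report <- function(effects, gm, contexts = NULL) {
  per_snp <- summarize_effects(effects)$per_snp
  hi <- per_snp %>% filter(.data$impact == "high")
  if (!is.null(contexts)) {
    hi <- left_join(hi, contexts[c("id", "context")], by = "id")
  } else {
    hi$context <- NA_character_
  }
  if (nrow(hi) == 0) {
    return(tibble(chrom = character(), pos = integer(), id = character(),
                  gene_id = character(), effect = character(),
                  context = character(), accession = character(),
                  genotype = character()))
  }
  idx <- match(hi$id, gm$sites$id)
  gt_lab <- c("ref/ref", "ref/alt", "alt/alt")
  out <- lapply(seq_len(nrow(hi)), function(r) {
    dos <- gm$dosage[idx[r], ]
    tibble(chrom = hi$chrom[r], pos = hi$pos[r], id = hi$id[r],
           gene_id = hi$gene_id[r], effect = hi$effect[r],
           context = hi$context[r],
           accession = colnames(gm$dosage),
           genotype = unname(ifelse(is.na(dos), "missing", gt_lab[dos + 1L])))
  })
  bind_rows(out)
}

#' Variants per gene
#'
#' @param contexts Output of [classify_context()].
#' @return A list: `per_gene` tibble (`gene_id`, `n_snps`) over genic SNPs
#'   and `mean_per_gene` (genic SNPs / genes hit).
#' @export
variants_per_gene <- function(contexts) {
  genic <- contexts %>% filter(.data$context != "intergenic")
  per_gene <- genic %>% count(.data$gene_id, name = "n_snps")
  list(per_gene = per_gene,
       mean_per_gene = if (nrow(per_gene)) nrow(genic) / nrow(per_gene) else NA_real_)
}
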