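#' Run the full post-variant-calling pipeline
#'
#' Orchestrates filter -> landscape statistics -> annotation -> diversity
#' on a call set, writing all artifacts under `outdir` and returning a run
#' report. Every stage is deterministic given `seed`; output tables carry
#' a header comment with the seed.
#'
#' @param vcf Path to the input VCF (or a [gbs_geno] object directly).
#' @param gff Path to the GFF3 gene annotation (or a [gene_models]).
#' @param fasta Path to the reference FASTA (or a named character vector
#'   of sequences).
#' @param outdir Output directory (created if absent).
#' @param groups Optional accession-group tibble or CSV path
#'   (`accession`, `group`).
#' @param arrays Optional named list of array-manifest paths or tibbles.
#' @param filter_cfg A [filter_config].
#' @param promoter_window,updown_window Annotation windows (bp).
#' @param density_window Density window (bp).
#' @param k_range,replicates,threshold Diversity settings.
#' @param seed Integer seed for the admixture stage.
#' @return A list of class `gbs_run`: `report` (named list of per-stage
#'   counts and summaries) and the main result objects (`gm`, `contexts`,
#'   `effects`, `tree`, `pca`, `deltak`, `assignments`).
#' @export
run_pipeline <- function(vcf, gff, fasta, outdir,
                         groups = NULL, arrays = NULL,
                         filter_cfg = filter_config(),
                         promoter_window = 1000, updown_window = 5000,
                         density_window = 1e6,
                         k_range = 1:6, replicates = 10, threshold = 0.80,
                         seed = 1) {
  for (p in list(vcf, gff, fasta)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      abort(paste0("Input file not found: ", p))
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  gm0 <- if (inherits(vcf, "gbs_geno")) vcf else read_vcf(vcf)
  models <- if (inherits(gff, "gene_models")) gff else read_gff3(gff)
  genome <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    normalize_genome(Biostrings::readDNAStringSet(fasta))
  } else normalize_genome(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(groups) && length(groups) == 1) {
    groups <- as_tibble(read.csv(groups, stringsAsFactors = FALSE))
  }

  filt <- filter_genotypes(gm0, filter_cfg)
  gm <- filt$gm
  write_vcf(gm, file.path(outdir, "filtered.vcf"))

  spec <- substitution_spectrum(gm)
  het <- heterozygosity_percent(gm)
  cov <- chromosome_coverage(gm)
  dens <- if (!is.null(gm$chrom_info)) {
    density_track(gm, groups = groups, window = density_window)
  }
  if (!is.null(dens)) {
    for (g in unique(dens$group)) {
      write_bedgraph(dens[dens$group == g, ],
                     file.path(outdir, paste0("density_", g, ".bedGraph")),
                     name = paste0("snp_density_", g))
    }
  }
  matches <- NULL
  if (!is.null(arrays)) {
    matches <- lapply(arrays, function(a) {
      man <- if (is.character(a)) read_array_manifest(a) else a
      cross_reference_arrays(gm, man)
    })
  }

  contexts <- classify_context(gm, models, promoter_window = promoter_window)
  effects <- predict_effects(gm, models, genome, updown_window = updown_window)
  eff_sum <- summarize_effects(effects)
  vpg <- variants_per_gene(contexts)
  hi <- high_impact_report(effects, gm, contexts = contexts)

  dm <- ibs_distance(gm)
  tree <- upgma(dm)
  write_newick(tree, file.path(outdir, "tree.nwk"))
  pca <- pca_genotypes(gm)
  dk <- select_k(gm, k_range = k_range, replicates = replicates, seed = seed)
  best <- if (!is.na(dk$selected_k)) dk$fits[[as.character(dk$selected_k)]]
  assignments <- if (!is.null(best)) assign_memberships(best, threshold = threshold)

  hdr <- sprintf("# gbsland run, seed=%d", seed)
  write_tsv_with_header <- function(df, file) {
    con <- file(file.path(outdir, file), "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_tsv_with_header(spec, "spectrum.tsv")
  write_tsv_with_header(het, "heterozygosity.tsv")
  write_tsv_with_header(cov, "coverage.tsv")
  write_tsv_with_header(contexts, "contexts.tsv")
  write_tsv_with_header(effects, "effects.tsv")
  write_tsv_with_header(hi, "high_impact.tsv")
  if (!is.null(assignments)) write_tsv_with_header(assignments, "assignments.tsv")
  if (!is.null(best)) {
    qtab <- dplyr::bind_cols(tibble(accession = rownames(best$Q)),
                             as_tibble(as.data.frame(best$Q)))
    write_tsv_with_header(qtab, "q_matrix.tsv")
  }
  write_tsv_with_header(tidy(dk), "deltaK.tsv")

  ctx_tally <- contexts %>%
    mutate(label = ifelse(.data$promoter_flag, "promoter", .data$context)) %>%
    count(.data$label, name = "n")
  report <- list(
    seed = seed,
    input_sites = nrow(gm0$sites),
    filtered_sites = nrow(gm$sites),
    filter_report = filt$report,
    ts_tv_ratio = attr(spec, "ts_tv_ratio"),
    context_tally = ctx_tally,
    impact_tally = eff_sum$by_impact,
    mean_variants_per_gene = vpg$mean_per_gene,
    n_high_impact = sum(eff_sum$per_snp$impact == "high"),
    selected_k = dk$selected_k,
    array_matches = if (!is.null(matches)) vapply(matches, nrow, integer(1))
  )
  jsonlite::write_json(report[c("seed", "input_sites", "filtered_sites",
                                "ts_tv_ratio", "mean_variants_per_gene",
                                "n_high_impact", "selected_k")],
                       file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(report = report, gm = gm, contexts = contexts,
                 effects = effects, spectrum = spec, coverage = cov,
                 heterozygosity = het, tree = tree, pca = pca,
                 deltak = dk, assignments = assignments),
            class = "gbs_run")
}

#' @export
print.gbs_run <- function(x, ...) {
  r <- x$report
  cat("<gbs_run>\n")
  cat(sprintf("  sites: %d in, %d after filtering\n", r$input_sites, r$filtered_sites))
  cat(sprintf("  Ts/Tv ratio: %.2f\n", r$ts_tv_ratio))
  cat(sprintf("  mean variants per gene: %.2f\n", r$mean_variants_per_gene))
  cat(sprintf("  high-impact SNPs: %d; selected K: %s\n",
              r$n_high_impact, r$selected_k))
  invisible(x)
}
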