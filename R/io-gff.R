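#' Read gene models from a GFF3 file
#'
#' Imports `gene`/`mRNA`/`exon`/`CDS` features (via \pkg{rtracklayer}) and
#' assembles strand-aware [gene_models]: UTRs are derived as exon minus CDS
#' and assigned 5'/3' by strand; transcripts whose CDS length is not a
#' multiple of three are flagged incomplete.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parent_of <- function(x) {
    p <- x$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }
  mrna <- gr[type %in% c("mRNA", "transcript")]
  if (length(mrna) == 0) abort("GFF3 contains no mRNA/transcript features.")
  sub <- gr[type %in% c("exon", "CDS")]
  sub_parent <- parent_of(sub)
  orphan <- setdiff(unique(sub_parent[as.character(sub$type) == "CDS"]),
                    c(mrna$ID, NA))
  if (length(orphan)) {
    abort(paste0("CDS feature(s) with no parent mRNA: ",
                 paste(orphan, collapse = ", ")))
  }
  tx <- tibble(
    transcript_id = mrna$ID,
    gene_id = parent_of(mrna),
    chrom = as.character(GenomicRanges::seqnames(mrna)),
    strand = as.character(GenomicRanges::strand(mrna))
  )
  tx$gene_id[is.na(tx$gene_id)] <- tx$transcript_id[is.na(tx$gene_id)]
  pick <- function(id, what) {
    sel <- sub[sub_parent == id & as.character(sub$type) == what]
    iv_normalize(cbind(GenomicRanges::start(sel), GenomicRanges::end(sel)))
  }
  tx$exons <- lapply(tx$transcript_id, pick, what = "exon")
  tx$cds <- lapply(tx$transcript_id, pick, what = "CDS")
  # transcripts without explicit exon features: treat CDS as the exons
  no_ex <- vapply(tx$exons, nrow, integer(1)) == 0
  tx$exons[no_ex] <- tx$cds[no_ex]
  gene_models(tx)
}

#' Write gene models to a GFF3 file
#'
#' @param models A [gene_models] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  genes <- gene_table(models)
  esc <- function(x) x
  lines <- character(0)
  for (g in seq_len(nrow(genes))) {
    ge <- genes[g, ]
    lines <- c(lines, paste(ge$chrom, "gbsland", "gene", ge$start, ge$end,
                            ".", ge$strand, ".",
                            paste0("ID=", esc(ge$gene_id)), sep = "\t"))
    txs <- models[models$gene_id == ge$gene_id, ]
    for (t in seq_len(nrow(txs))) {
      tr <- txs[t, ]
      lines <- c(lines, paste(tr$chrom, "gbsland", "mRNA", tr$tx_start,
                              tr$tx_end, ".", tr$strand, ".",
                              paste0("ID=", tr$transcript_id,
                                     ";Parent=", ge$gene_id), sep = "\t"))
      ex <- tr$exons[[1]]
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, paste(tr$chrom, "gbsland", "exon", ex[k, 1],
                                ex[k, 2], ".", tr$strand, ".",
                                paste0("Parent=", tr$transcript_id), sep = "\t"))
      }
      cds <- tr$cds[[1]]
      ph <- cds_phases(cds, tr$strand)
      for (k in seq_len(nrow(cds))) {
        lines <- c(lines, paste(tr$chrom, "gbsland", "CDS", cds[k, 1],
                                cds[k, 2], ".", tr$strand, ph[k],
                                paste0("ID=", tr$transcript_id, ".cds",
                                       ";Parent=", tr$transcript_id), sep = "\t"))
      }
    }
  }
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) abort(paste0("Cannot open ", path, " for writing."))
  on.exit(close(con))
  writeLines(c("##gff-version 3", lines), con)
  invisible(path)
}

# GFF3 phase column for CDS segments, in translation order
cds_phases <- function(cds, strand) {
  if (nrow(cds) == 0) return(integer(0))
  ord <- if (strand == "+") order(cds[, 1]) else order(-cds[, 1])
  w <- cds[ord, 2] - cds[ord, 1] + 1L
  ph <- integer(length(w))
  done <- 0L
  for (k in seq_along(w)) {
    ph[k] <- (3L - done %% 3L) %% 3L
    done <- done + w[k]
  }
  ph[order(ord)]
}
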