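#' Plant variants with provable truth labels on a synthetic genome
#'
#' For each requested category, places exactly that many single-nucleotide
#' variants whose genomic context and coding effect are provable from the
#' generated gene models: e.g. a `stop_gained` variant's alternate codon is
#' in {TAA, TAG, TGA} in the transcript reading frame (reverse-complemented
#' on the minus strand), a `splice_donor` variant lies in the first two
#' intron bases in transcript orientation, a `promoter` variant lies within
#' the promoter window upstream of a TSS, strand-aware. Coding categories
#' are planted only in single-transcript genes so every truth label is
#' unambiguous under cross-transcript severity collapse.
#'
#' @param gen Result of [generate_genome()].
#' @param requested Named integer vector of counts; names from
#'   `c("synonymous", "missense", "stop_gained", "stop_lost", "start_lost",
#'   "splice_donor", "splice_acceptor", "intron", "utr5", "utr3",
#'   "promoter", "intergenic")`.
#' @param promoter_window Promoter window in bp (default 1000).
#' @param rng_seed Integer seed.
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `truth_context`, `truth_effect`, `truth_aa_ref`, `truth_aa_alt`,
#'   `gene_id`, `transcript_id`.
#' @export
plant_variants <- function(gen,
                           requested = c(synonymous = 5, missense = 5,
                                         stop_gained = 3, stop_lost = 2,
                                         start_lost = 2, splice_donor = 3,
                                         splice_acceptor = 3, intron = 5,
                                         utr5 = 3, utr3 = 3, promoter = 4,
                                         intergenic = 5),
                           promoter_window = 1000,
                           rng_seed = 1) {
  known <- c("synonymous", "missense", "stop_gained", "stop_lost",
             "start_lost", "splice_donor", "splice_acceptor", "intron",
             "utr5", "utr3", "promoter", "intergenic")
  if (!all(names(requested) %in% known)) {
    abort(paste0("Unknown category: ",
                 paste(setdiff(names(requested), known), collapse = ", ")))
  }
  models <- gen$models
  single <- models %>%
    as_tibble() %>%
    group_by(.data$gene_id) %>%
    filter(n() == 1) %>%
    ungroup() %>%
    filter(!.data$incomplete)
  if (nrow(single) == 0) abort("No single-transcript genes to plant in.")

  with_seed(rng_seed, {
    used <- character(0)
    rows <- list()
    take <- function(row) {
      key <- paste(row$chrom, row$pos)
      if (key %in% used) return(FALSE)
      used <<- c(used, key)
      rows[[length(rows) + 1]] <<- row
      TRUE
    }
    genome <- gen$genome
    maps <- lapply(seq_len(nrow(single)), function(k) coding_map(genome, single[k, ]))

    for (cat in names(requested)) {
      need <- requested[[cat]]
      placed <- 0L
      order_tx <- sample(nrow(single))
      tries <- 0L
      while (placed < need) {
        tries <- tries + 1L
        if (tries > 60L * need) {
          abort(sprintf("Cannot place %d '%s' variants in the generated genome (capacity).",
                        need, cat))
        }
        k <- order_tx[((tries - 1L) %% length(order_tx)) + 1L]
        tx <- single[k, ]
        row <- switch(
          cat,
          synonymous = ,
          missense = ,
          stop_gained = ,
          stop_lost = ,
          start_lost = plant_coding(cat, tx, maps[[k]], genome),
          splice_donor = ,
          splice_acceptor = plant_splice(cat, tx, genome),
          intron = plant_intron(tx, genome),
          utr5 = plant_utr(tx, genome, "utr5"),
          utr3 = plant_utr(tx, genome, "utr3"),
          promoter = plant_promoter(tx, genome, promoter_window),
          intergenic = NULL
        )
        if (cat == "intergenic") {
          row <- plant_intergenic(gen, promoter_window, used)
        }
        if (!is.null(row) && take(row)) placed <- placed + 1L
      }
    }
    out <- bind_rows(rows)
    out$id <- sprintf("pv%04d", seq_len(nrow(out)))
    # construction-time verification: REF must match the genome base
    refs <- vapply(seq_len(nrow(out)), function(i) {
      substr(genome[[out$chrom[i]]], out$pos[i], out$pos[i])
    }, character(1))
    stopifnot(identical(refs, out$ref))
    out[c("chrom", "pos", "id", "ref", "alt", "truth_context", "truth_effect",
          "truth_aa_ref", "truth_aa_alt", "gene_id", "transcript_id")]
  })
}

shuffle <- function(x) x[sample.int(length(x))]
pick1 <- function(v) if (length(v) == 1) v else sample(v, 1)

# Coding positions and bases of a transcript in translation order.
coding_map <- function(genome, tx) {
  cds <- tx$cds[[1]]
  pos <- unlist(lapply(seq_len(nrow(cds)), function(k) cds[k, 1]:cds[k, 2]))
  pos <- sort(pos)
  chars <- strsplit(substring_multi(genome[[tx$chrom]], pos), "")[[1]]
  if (tx$strand == "-") {
    pos <- rev(pos)
    chars <- rc_chars(chars)
  }
  list(pos = pos, base = chars)
}

substring_multi <- function(s, pos) {
  paste(vapply(pos, function(p) substr(s, p, p), character(1)), collapse = "")
}

variant_row <- function(tx, pos, ref, alt, context, effect,
                        aa_ref = NA_character_, aa_alt = NA_character_) {
  tibble(chrom = tx$chrom, pos = as.integer(pos), id = NA_character_,
         ref = ref, alt = alt, truth_context = context, truth_effect = effect,
         truth_aa_ref = aa_ref, truth_aa_alt = aa_alt,
         gene_id = tx$gene_id, transcript_id = tx$transcript_id)
}

plant_coding <- function(cat, tx, map, genome) {
  n_cod <- length(map$base) %/% 3L
  ks <- switch(cat,
    start_lost = 1L,
    stop_lost = n_cod,
    shuffle(setdiff(seq_len(n_cod), c(1L, n_cod)))
  )
  for (k in ks) {
    idx <- (3L * k - 2L):(3L * k)
    cod <- paste(map$base[idx], collapse = "")
    for (off in shuffle(1:3)) {
      for (b in shuffle(setdiff(BASES, map$base[idx[off]]))) {
        new <- cod
        substr(new, off, off) <- b
        ok <- switch(cat,
          synonymous = codon_aa(new) == codon_aa(cod) && !(new %in% STOPS),
          missense = codon_aa(new) != codon_aa(cod) && !(new %in% STOPS) &&
            codon_aa(cod) != "*",
          stop_gained = new %in% STOPS,
          stop_lost = cod %in% STOPS && !(new %in% STOPS),
          start_lost = cod == "ATG"
        )
        if (isTRUE(ok)) {
          gpos <- map$pos[idx[off]]
          gref <- substr(genome[[tx$chrom]], gpos, gpos)
          galt <- if (tx$strand == "+") b else comp_char(b)
          return(variant_row(tx, gpos, gref, galt, "cds", cat,
                             aa_ref = codon_aa(cod), aa_alt = codon_aa(new)))
        }
      }
    }
  }
  NULL
}

tx_introns <- function(tx) {
  ex <- tx$exons[[1]]
  if (nrow(ex) < 2) return(empty_iv())
  iv(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L)
}

plant_splice <- function(cat, tx, genome) {
  intr <- tx_introns(tx)
  if (nrow(intr) == 0) return(NULL)
  k <- pick1(seq_len(nrow(intr)))
  donor_side <- (cat == "splice_donor") == (tx$strand == "+")
  # donor = transcript-5' end of the intron; on "+" that is the low-coord end
  gpos <- if (donor_side) intr[k, 1] + sample(0:1, 1) else intr[k, 2] - sample(0:1, 1)
  gref <- substr(genome[[tx$chrom]], gpos, gpos)
  variant_row(tx, gpos, gref, pick1(setdiff(BASES, gref)), "intron", cat)
}

plant_intron <- function(tx, genome) {
  intr <- tx_introns(tx)
  if (nrow(intr) == 0) return(NULL)
  wide <- intr[intr[, 2] - intr[, 1] + 1L >= 9L, , drop = FALSE]
  if (nrow(wide) == 0) return(NULL)
  k <- pick1(seq_len(nrow(wide)))
  gpos <- pick1((wide[k, 1] + 2L):(wide[k, 2] - 2L))
  gref <- substr(genome[[tx$chrom]], gpos, gpos)
  variant_row(tx, gpos, gref, pick1(setdiff(BASES, gref)), "intron", "none")
}

plant_utr <- function(tx, genome, which_utr) {
  m <- tx[[which_utr]][[1]]
  if (nrow(m) == 0) return(NULL)
  pos_all <- unlist(lapply(seq_len(nrow(m)), function(k) m[k, 1]:m[k, 2]))
  gpos <- pick1(pos_all)
  gref <- substr(genome[[tx$chrom]], gpos, gpos)
  variant_row(tx, gpos, gref, pick1(setdiff(BASES, gref)), which_utr, "none")
}

plant_promoter <- function(tx, genome, window) {
  rng <- if (tx$strand == "+") {
    c(tx$tx_start - window, tx$tx_start - 1L)
  } else {
    c(tx$tx_end + 1L, tx$tx_end + window)
  }
  rng[1] <- max(rng[1], 1L)
  rng[2] <- min(rng[2], nchar(genome[[tx$chrom]]))
  if (rng[1] > rng[2]) return(NULL)
  gpos <- pick1(rng[1]:rng[2])
  gref <- substr(genome[[tx$chrom]], gpos, gpos)
  variant_row(tx, gpos, gref, pick1(setdiff(BASES, gref)),
              "promoter", "none")
}

plant_intergenic <- function(gen, window, used) {
  genes <- gene_table(gen$models)
  ch <- pick1(names(gen$genome))
  len <- nchar(gen$genome[[ch]])
  g <- genes[genes$chrom == ch, ]
  for (try_i in 1:50) {
    gpos <- sample(len, 1)
    in_gene <- any(gpos >= g$start & gpos <= g$end)
    in_prom <- any(ifelse(g$strand == "+",
                          gpos >= g$start - window & gpos < g$start,
                          gpos > g$end & gpos <= g$end + window))
    if (!in_gene && !in_prom && !(paste(ch, gpos) %in% used)) {
      gref <- substr(gen$genome[[ch]], gpos, gpos)
      return(tibble(chrom = ch, pos = as.integer(gpos), id = NA_character_,
                    ref = gref, alt = pick1(setdiff(BASES, gref)),
                    truth_context = "intergenic", truth_effect = "none",
                    truth_aa_ref = NA_character_, truth_aa_alt = NA_character_,
                    gene_id = NA_character_, transcript_id = NA_character_))
    }
  }
  NULL
}
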