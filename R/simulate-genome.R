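#' Specification for a synthetic reference genome
#'
#' Defaults emulate an eight-pseudomolecule plant genome at toy scale:
#' short chromosomes carrying non-overlapping protein-coding genes on both
#' strands, each with a 5'UTR, a CDS that starts at ATG and ends at a stop
#' codon, canonical GT..AG introns, and a 3'UTR. Genes are separated by at
#' least twice the promoter window so that planted promoter and intergenic
#' labels are unambiguous by construction.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length_bp Length of each chromosome (bp).
#' @param n_genes_per_chromosome Genes placed per chromosome.
#' @param exons_per_transcript Integer range `c(min, max)` of exon counts.
#' @param transcripts_per_gene Integer range `c(min, max)`; extra
#'   transcripts are structural duplicates of the primary isoform.
#' @param strand_mix Fraction of genes on the minus strand.
#' @param cds_codons Range of CDS length in codons (excluding the stop).
#' @param utr_len Range of UTR lengths (bp), used for both UTRs.
#' @param intron_len Range of intron lengths (bp); minimum 10.
#' @param promoter_window Promoter window (bp upstream of the TSS).
#' @param rng_seed Integer seed; the generator is fully deterministic.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 3,
                        chromosome_length_bp = 60000,
                        n_genes_per_chromosome = 6,
                        exons_per_transcript = c(1, 4),
                        transcripts_per_gene = c(1, 1),
                        strand_mix = 0.5,
                        cds_codons = c(40, 120),
                        utr_len = c(30, 150),
                        intron_len = c(20, 200),
                        promoter_window = 1000,
                        rng_seed = 1) {
  stopifnot(n_chromosomes >= 1, chromosome_length_bp > 0,
            n_genes_per_chromosome >= 1, intron_len[1] >= 10,
            strand_mix >= 0, strand_mix <= 1)
  structure(as.list(environment()), class = "genome_spec")
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

rc_chars <- function(x) rev(chartr("ACGT", "TGCA", x))
comp_char <- function(x) chartr("ACGT", "TGCA", x)

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)

#' Generate a toy reference genome with gene models
#'
#' Every transcript's CDS begins with ATG, ends with a stop codon, and
#' contains no internal stop in frame (sense codons are drawn directly);
#' introns carry canonical GT/AG dinucleotides at the donor/acceptor ends
#' in transcript orientation. Minus-strand genes are built in transcript
#' space and reverse-complemented into the chromosome.
#'
#' @param spec A [genome_spec].
#' @return A list with `genome` (named character vector of chromosome
#'   sequences), `models` (a [gene_models]) and `chrom_info` (tibble
#'   `name`, `length_bp`).
#' @export
generate_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$rng_seed, {
    genome <- list()
    tx_rows <- list()
    for (ci in seq_len(spec$n_chromosomes)) {
      chrom <- sprintf("chr%02d", ci)
      seq_chars <- sample(BASES, spec$chromosome_length_bp, replace = TRUE)
      cursor <- spec$promoter_window
      for (gi in seq_len(spec$n_genes_per_chromosome)) {
        gene_id <- sprintf("%s.g%02d", chrom, gi)
        strand <- if (runif(1) < spec$strand_mix) "-" else "+"
        reg <- build_gene_region(spec)
        gap <- 2L * spec$promoter_window + rint(c(200L, 1200L))
        start <- cursor + gap
        end <- start + reg$len - 1L
        if (end + spec$promoter_window > spec$chromosome_length_bp) {
          abort(sprintf(
            "Chromosome %s too short for %d genes (capacity reached at gene %d).",
            chrom, spec$n_genes_per_chromosome, gi))
        }
        if (strand == "+") {
          seq_chars[start:end] <- reg$chars
          shift_iv <- function(m) iv(m[, 1] + start - 1L, m[, 2] + start - 1L)
          exons <- shift_iv(reg$exons); cds <- shift_iv(reg$cds)
        } else {
          seq_chars[start:end] <- rc_chars(reg$chars)
          flip <- function(m) {
            if (nrow(m) == 0) return(empty_iv())
            iv_normalize(cbind(start + reg$len - m[, 2], start + reg$len - m[, 1]))
          }
          exons <- flip(reg$exons); cds <- flip(reg$cds)
        }
        n_tx <- rint(spec$transcripts_per_gene)
        for (t in seq_len(n_tx)) {
          tx_rows[[length(tx_rows) + 1]] <- tibble(
            transcript_id = sprintf("%s.t%d", gene_id, t),
            gene_id = gene_id, chrom = chrom, strand = strand,
            exons = list(exons), cds = list(cds)
          )
        }
        cursor <- end
      }
      genome[[chrom]] <- paste(seq_chars, collapse = "")
    }
    list(
      genome = unlist(genome),
      models = gene_models(bind_rows(tx_rows)),
      chrom_info = tibble(name = names(genome),
                          length_bp = spec$chromosome_length_bp)
    )
  })
}

# Build one gene in transcript orientation; returns region chars and
# exon/CDS intervals in 1-based region coordinates.
build_gene_region <- function(spec) {
  n_cod <- rint(spec$cds_codons)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOPS)
  cds_seq <- c("ATG",
               sample(sense, n_cod - 1L, replace = TRUE),
               sample(STOPS, 1))
  cds_chars <- strsplit(paste(cds_seq, collapse = ""), "")[[1]]
  u5 <- sample(BASES, rint(spec$utr_len), replace = TRUE)
  u3 <- sample(BASES, rint(spec$utr_len), replace = TRUE)
  tx_chars <- c(u5, cds_chars, u3)
  tx_len <- length(tx_chars)
  n_ex <- rint(spec$exons_per_transcript)
  n_ex <- min(n_ex, tx_len %/% 12L)   # keep exons a sane minimum size
  n_ex <- max(n_ex, 1L)
  cuts <- if (n_ex > 1) {
    sort(sample(seq(6L, tx_len - 6L), n_ex - 1L))
  } else integer(0)
  ex_tx <- cbind(c(1L, cuts + 1L), c(cuts, tx_len))  # transcript coords
  region <- character(0)
  ex_region <- empty_iv()
  offset <- 0L  # cumulative intron length inserted so far
  for (k in seq_len(n_ex)) {
    s <- ex_tx[k, 1]; e <- ex_tx[k, 2]
    ex_region <- rbind(ex_region, c(s + offset, e + offset))
    region <- c(region, tx_chars[s:e])
    if (k < n_ex) {
      ilen <- rint(spec$intron_len)
      intr <- c("G", "T", sample(BASES, ilen - 4L, replace = TRUE), "A", "G")
      region <- c(region, intr)
      offset <- offset + ilen
    }
  }
  colnames(ex_region) <- c("start", "end")
  # CDS occupies transcript coords [len(u5)+1, len(u5)+cds_len]
  cds_lo <- length(u5) + 1L
  cds_hi <- length(u5) + length(cds_chars)
  cds_region <- empty_iv()
  for (k in seq_len(n_ex)) {
    s <- max(ex_tx[k, 1], cds_lo); e <- min(ex_tx[k, 2], cds_hi)
    if (s <= e) {
      off <- ex_region[k, 1] - ex_tx[k, 1]
      cds_region <- rbind(cds_region, c(s + off, e + off))
    }
  }
  colnames(cds_region) <- c("start", "end")
  list(chars = region, exons = iv_normalize(ex_region),
       cds = iv_normalize(cds_region), len = length(region))
}

#' Write a genome's FASTA and GFF3 to disk
#'
#' @param gen Result of [generate_genome()].
#' @param fasta,gff Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_genome <- function(gen, fasta, gff) {
  dna <- Biostrings::DNAStringSet(gen$genome)
  Biostrings::writeXStringSet(dna, fasta)
  write_gff3(gen$models, gff)
  invisible(list(fasta = fasta, gff = gff))
}
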