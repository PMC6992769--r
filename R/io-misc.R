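#' Write a tree in Newick format
#'
#' @param tree A `phylo` object (e.g. from [upgma()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ok <- try(ape::write.tree(tree, file = path), silent = TRUE)
  if (inherits(ok, "try-error")) abort(paste0("Cannot write tree to ", path))
  invisible(path)
}

#' Write a density track as bedGraph
#'
#' Internal coordinates are 1-based closed; bedGraph is 0-based half-open,
#' so a window `[start, end]` is emitted as `start-1, end`.
#'
#' @param track A density-track tibble with columns `chrom`, `start`, `end`
#'   (1-based closed) and `count` (see [density_track()]).
#' @param path Output file path.
#' @param name Track name written into the bedGraph header line.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, name = "snp_density") {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) abort(paste0("Cannot open ", path, " for writing."))
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  if (nrow(track)) {
    writeLines(paste(track$chrom, track$start - 1L, track$end, track$count,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a SNP-array manifest
#'
#' Manifests are CSVs with columns `marker_id`, `chrom`, `pos` (1-based,
#' same assembly as the call set). An optional comment header line
#' `# assembly=<name>` declares the assembly; [cross_reference_arrays()]
#' refuses manifests whose declared assembly differs from the call set's.
#'
#' @param path Path to the CSV manifest.
#' @return A tibble `marker_id`, `chrom`, `pos` with attribute `assembly`
#'   (or `NA` when undeclared).
#' @export
read_array_manifest <- function(path) {
  first <- readLines(path, n = 1)
  assembly <- NA_character_
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("assembly=([^ ,]+)", first))[[1]]
    if (length(m) == 2) assembly <- m[2]
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(df)))
  out <- as_tibble(df[c("marker_id", "chrom", "pos")])
  out$pos <- as.integer(out$pos)
  attr(out, "assembly") <- assembly
  out
}
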