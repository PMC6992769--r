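#' Specification for a simulated population sample
#'
#' Defaults emulate the design of a diverse rootstock germplasm panel:
#' three diverged populations (subgenera) of unequal size, a handful of F1
#' hybrids with exactly 50/50 membership between two populations, a few
#' freely admixed accessions with Dirichlet-distributed membership, and
#' duplicated accessions that are exact genotype copies with independent
#' missingness. Population allele-frequency divergence follows the
#' Balding-Nichols F-model.
#'
#' @param K Number of ancestral populations.
#' @param fst Per-population divergence parameter(s); recycled to length `K`.
#' @param n_loci Number of unlinked biallelic loci.
#' @param n_per_population Accessions drawn purely from each population
#'   (recycled to length `K`).
#' @param n_hybrids F1 hybrids between populations 1 and 2 (membership
#'   exactly 0.5/0.5).
#' @param n_admixed Accessions with Dirichlet(`dirichlet_alpha`) membership.
#' @param dirichlet_alpha Concentration for admixed memberships.
#' @param n_duplicates Number of pure accessions re-sampled as duplicates.
#' @param missing_rate Per-call missing probability (MCAR).
#' @param depth_mean,depth_size Negative-binomial read-depth model
#'   (mean and size/dispersion); depths are independent of genotype.
#' @param rng_seed Integer seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(K = 3, fst = 0.15, n_loci = 500,
                            n_per_population = c(12, 8, 5),
                            n_hybrids = 3, n_admixed = 2,
                            dirichlet_alpha = 0.5, n_duplicates = 2,
                            missing_rate = 0.03,
                            depth_mean = 20, depth_size = 5,
                            rng_seed = 1) {
  stopifnot(K >= 1, all(fst > 0), all(fst < 1), n_loci >= 1)
  fst <- rep_len(fst, K)
  n_per_population <- rep_len(n_per_population, K)
  structure(as.list(environment()), class = "population_spec")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate diploid genotypes under an admixture model
#'
#' Ancestral allele frequencies are drawn per locus from Uniform(0.1, 0.9);
#' each population's frequency is Beta-distributed around the ancestral one
#' with Balding-Nichols parameters `a = p(1-F)/F`, `b = (1-p)(1-F)/F`. Each
#' accession's genotype at locus `l` is Binomial(2, sum_k q_k f_kl); loci
#' are unlinked. Duplicates copy a pure accession's genotypes exactly and
#' then apply independent missingness.
#'
#' @param spec A [population_spec].
#' @param sites Optional site table (`chrom`, `pos`, `ref`, `alt`, `id`)
#'   with `nrow(sites) == n_loci`; when `NULL`, placeholder sites on a
#'   single synthetic chromosome are created.
#' @return A list with `gm` (a [gbs_geno]), `truth` (tibble `accession`,
#'   `group`, membership columns `Q1..QK`, `duplicate_of`) and `F`
#'   (K x n_loci population allele-frequency matrix).
#' @export
simulate_genotypes <- function(spec = population_spec(), sites = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  K <- spec$K
  L <- spec$n_loci
  if (!is.null(sites) && nrow(sites) != L) {
    abort("`sites` must have exactly n_loci rows.")
  }
  with_seed(spec$rng_seed, {
    p_anc <- runif(L, 0.1, 0.9)
    Fmat <- matrix(NA_real_, K, L)
    for (k in seq_len(K)) {
      fk <- spec$fst[k]
      Fmat[k, ] <- rbeta(L, p_anc * (1 - fk) / fk, (1 - p_anc) * (1 - fk) / fk)
    }
    # membership vectors
    Q <- NULL; labels <- character(0); groups <- character(0)
    for (k in seq_len(K)) {
      nk <- spec$n_per_population[k]
      if (nk > 0) {
        qk <- matrix(0, nk, K); qk[, k] <- 1
        Q <- rbind(Q, qk)
        labels <- c(labels, sprintf("pop%d_%02d", k, seq_len(nk)))
        groups <- c(groups, rep(sprintf("pop%d", k), nk))
      }
    }
    if (spec$n_hybrids > 0) {
      qh <- matrix(0, spec$n_hybrids, K)
      qh[, 1] <- 0.5; qh[, min(2, K)] <- qh[, min(2, K)] + 0.5
      Q <- rbind(Q, qh)
      labels <- c(labels, sprintf("hybrid_%02d", seq_len(spec$n_hybrids)))
      groups <- c(groups, rep("hybrid", spec$n_hybrids))
    }
    if (spec$n_admixed > 0) {
      qa <- t(vapply(seq_len(spec$n_admixed),
                     function(i) rdirichlet1(rep(spec$dirichlet_alpha, K)),
                     numeric(K)))
      Q <- rbind(Q, qa)
      labels <- c(labels, sprintf("admixed_%02d", seq_len(spec$n_admixed)))
      groups <- c(groups, rep("admixed", spec$n_admixed))
    }
    n <- nrow(Q)
    expected <- Q %*% Fmat                       # n x L allele-1 probability
    dosage <- matrix(rbinom(n * L, 2, t(expected)), nrow = L)  # L x n
    colnames(dosage) <- labels

    dup_of <- rep(NA_character_, n)
    if (spec$n_duplicates > 0) {
      pure_idx <- which(groups %in% sprintf("pop%d", seq_len(K)))
      src <- pure_idx[seq_len(min(spec$n_duplicates, length(pure_idx)))]
      for (s in src) {
        dosage <- cbind(dosage, dosage[, s])
        Q <- rbind(Q, Q[s, ])
        labels <- c(labels, paste0(labels[s], "_dup"))
        colnames(dosage) <- labels
        groups <- c(groups, groups[s])
        dup_of <- c(dup_of, labels[s])
      }
      n <- ncol(dosage)
    }
    if (spec$missing_rate > 0) {
      drop <- matrix(runif(L * n) < spec$missing_rate, L, n)
      dosage[drop] <- NA_integer_
    }
    depth <- matrix(rnbinom(L * n, size = spec$depth_size, mu = spec$depth_mean),
                    L, n, dimnames = list(NULL, labels))
    if (is.null(sites)) {
      pos <- sort(sample.int(1e7, L))
      ref <- sample(BASES, L, replace = TRUE)
      alt <- vapply(ref, function(r) pick1(setdiff(BASES, r)), character(1))
      sites <- tibble(chrom = "sim01", pos = pos, ref = ref, alt = unname(alt),
                      id = sprintf("sim01_%d", pos))
    }
    truth <- as_tibble(as.data.frame(Q))
    names(truth) <- sprintf("Q%d", seq_len(K))
    truth <- dplyr::bind_cols(
      tibble(accession = labels, group = groups), truth,
      tibble(duplicate_of = dup_of)
    )
    gm <- gbs_geno(sites, dosage, depth = depth)
    list(gm = gm, truth = truth, F = Fmat)
  })
}
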