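#' Identity-by-state genetic distance
#'
#' `d(i, j) = 1 - IBS`, where IBS is the mean over jointly non-missing
#' sites of the shared-allele fraction: dosage pairs differing by 0, 1, 2
#' share 2, 1, 0 alleles. Equivalently `d = mean(|g_i - g_j|) / 2`.
#'
#' @param gm A [gbs_geno] object (>= 2 accessions).
#' @param on_empty What to do for a pair with no jointly called site:
#'   `"error"` (default) or `"na"`.
#' @return A symmetric numeric matrix in `[0, 1]` with zero diagonal and
#'   accession dimnames.
#' @export
ibs_distance <- function(gm, on_empty = c("error", "na")) {
  on_empty <- match.arg(on_empty)
  X <- gm$dosage
  n <- ncol(X)
  if (n < 2) abort("Need at least two accessions.")
  d <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      if (!any(ok)) {
        if (on_empty == "error") {
          abort(sprintf("No joint support for pair (%s, %s).",
                        colnames(X)[i], colnames(X)[j]))
        }
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- mean(abs(X[ok, i] - X[ok, j])) / 2
      }
    }
  }
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering; the resulting tree is
#' ultrametric with each merge at height d/2 (so leaf-to-leaf path lengths
#' reproduce the input distances whenever the input is ultrametric). For
#' reproducibility under tied distances, rows/columns are ordered
#' lexicographically by accession name before clustering.
#'
#' @param dm Symmetric distance matrix with dimnames (e.g. from
#'   [ibs_distance()]).
#' @return A rooted `phylo` tree (ape).
#' @export
upgma <- function(dm) {
  if (nrow(dm) < 2) abort("Need at least two accessions.")
  ord <- order(rownames(dm))
  hc <- hclust(as.dist(dm[ord, ord]), method = "average")
  ape::as.phylo(hc)
}

#' Principal components of the genotype matrix
#'
#' Accession-by-site dosage matrix with missing entries imputed by the
#' per-site mean and sites centered by their mean (no unit-variance
#' scaling); eigendecomposition via `prcomp`.
#'
#' @param gm A [gbs_geno] object (>= 2 accessions and sites).
#' @param scale. Optionally also scale sites to unit variance.
#' @return An object of class `gbs_pca`: list with `scores` (tibble,
#'   `accession` + `PC1..`), `var_explained` (fractions, non-increasing).
#' @export
pca_genotypes <- function(gm, scale. = FALSE) {
  X <- t(gm$dosage)
  if (nrow(X) < 2 || ncol(X) < 2) abort("Need >= 2 accessions and >= 2 sites.")
  mu <- colMeans(X, na.rm = TRUE)
  for (l in seq_len(ncol(X))) X[is.na(X[, l]), l] <- mu[l]
  keep <- apply(X, 2, stats::var) > 0
  if (!any(keep)) abort("Genotype matrix has zero variance.")
  if (scale.) X <- X[, keep, drop = FALSE] else X <- X[, , drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x)
  structure(
    list(scores = dplyr::bind_cols(tibble(accession = rownames(X)), scores),
         var_explained = ve),
    class = "gbs_pca"
  )
}

#' @export
print.gbs_pca <- function(x, ...) {
  cat("<gbs_pca> ", nrow(x$scores), " accessions\n", sep = "")
  ve <- utils::head(x$var_explained, 3) * 100
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(ve), ve), collapse = ", ")))
  invisible(x)
}

#' Maximum-likelihood admixture model fit
#'
#' Fits per-accession membership vectors Q (n x K, rows on the simplex)
#' and per-population allele frequencies F (K x L) by maximizing the
#' binomial admixture log-likelihood
#' `sum_il [ g_il log(p_il) + (2 - g_il) log(1 - p_il) ]`,
#' `p_il = sum_k q_ik f_kl`, over non-missing entries, with
#' expectation-maximization updates. The log-likelihood is non-decreasing
#' at every iteration; frequencies are clamped to `[1e-6, 1 - 1e-6]` to
#' keep it finite. `K = 1` uses the closed form `f_l = mean dosage / 2`.
#'
#' @param gm A [gbs_geno] object (or an L x n dosage matrix).
#' @param K Number of ancestral populations.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum EM iterations (default 2000).
#' @param tol Relative log-likelihood change for convergence (default 1e-8;
#'   membership estimates keep drifting after the likelihood has nearly
#'   plateaued, so the default is deliberately tight).
#' @return An object of class `admixture_fit`: `K`, `Q` (n x K, accession
#'   rownames), `F` (K x L), `loglik`, `loglik_trace`, `iterations`,
#'   `converged`, `seed`.
#' @export
fit_admixture <- function(gm, K, seed = 1, max_iter = 2000, tol = 1e-8) {
  stopifnot(K >= 1)
  G <- if (inherits(gm, "gbs_geno")) gm$dosage else gm
  X <- t(G)                                   # n x L
  n <- nrow(X); L <- ncol(X)
  W <- !is.na(X)
  Xf <- X; Xf[!W] <- 0
  eps <- 1e-6

  if (K == 1) {
    f <- colSums(Xf) / pmax(2 * colSums(W), 1)
    f <- pmin(pmax(f, eps), 1 - eps)
    P <- matrix(f, n, L, byrow = TRUE)
    ll <- sum((Xf * log(P) + (2 - X) * log(1 - P))[W])
    return(structure(list(
      K = 1L, Q = matrix(1, n, 1, dimnames = list(rownames(X), "Q1")),
      F = matrix(f, 1, L), loglik = ll, loglik_trace = ll,
      iterations = 0L, converged = TRUE, seed = seed
    ), class = "admixture_fit"))
  }

  with_seed(seed, {
    Q <- t(vapply(seq_len(n), function(i) rdirichlet1(rep(1, K)), numeric(K)))
    p_hat <- colSums(Xf) / pmax(2 * colSums(W), 1)
    F <- t(vapply(seq_len(K), function(k) {
      pmin(pmax(p_hat + runif(L, -0.1, 0.1), eps), 1 - eps)
    }, numeric(L)))
    dim(F) <- c(K, L)

    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      P <- Q %*% F
      P <- pmin(pmax(P, eps), 1 - eps)
      ll <- sum((Xf * log(P) + (2 - X) * log(1 - P))[W])
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      R1 <- (Xf / P); R1[!W] <- 0
      R0 <- ((2 - Xf) / (1 - P)); R0[!W] <- 0
      A <- (R1 %*% t(F)) * Q
      B <- (R0 %*% t(1 - F)) * Q
      Qn <- A + B
      Q <- Qn / rowSums(Qn)
      Nf <- F * (t(Q) %*% R1)
      Df <- Nf + (1 - F) * (t(Q) %*% R0)
      F <- pmin(pmax(Nf / pmax(Df, .Machine$double.xmin), eps), 1 - eps)
    }
    rownames(Q) <- rownames(X)
    colnames(Q) <- sprintf("Q%d", seq_len(K))
    structure(list(K = as.integer(K), Q = Q, F = F,
                   loglik = ll_trace[length(ll_trace)],
                   loglik_trace = ll_trace, iterations = it,
                   converged = converged, seed = seed),
              class = "admixture_fit")
  })
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, %d accessions, logLik = %.2f (%s, %d iter)\n",
              x$K, nrow(x$Q), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Evanno delta-K model selection over a range of K
#'
#' Fits the admixture model for each K with several replicate seeds and
#' computes the Evanno statistic
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`
#' over replicate log-likelihoods; the selected K maximizes deltaK over
#' interior K values with positive replicate standard deviation.
#'
#' @param gm A [gbs_geno] object.
#' @param k_range Integer vector of K values (default 1:6).
#' @param replicates Replicate fits per K (>= 2).
#' @param seed Base seed; replicate `r` at `K` uses
#'   `seed + 1000 * K + r`.
#' @param max_iter,tol Passed to [fit_admixture()].
#' @return An object of class `deltak`: `table` (tibble `K`, `mean_ll`,
#'   `sd_ll`, `delta_k`), `selected_k`, `fits` (best-likelihood fit per K).
#' @export
select_k <- function(gm, k_range = 1:6, replicates = 10, seed = 1,
                     max_iter = 300, tol = 1e-5) {
  stopifnot(replicates >= 2)
  k_range <- sort(unique(as.integer(k_range)))
  ll <- matrix(NA_real_, length(k_range), replicates,
               dimnames = list(as.character(k_range), NULL))
  best <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    for (r in seq_len(replicates)) {
      fit <- fit_admixture(gm, K, seed = seed + 1000L * K + r,
                           max_iter = max_iter, tol = tol)
      ll[ki, r] <- fit$loglik
      if (is.null(best[[ki]]) || fit$loglik > best[[ki]]$loglik) best[[ki]] <- fit
    }
  }
  mean_ll <- rowMeans(ll)
  sd_ll <- apply(ll, 1, sd)
  delta_k <- evanno_delta_k(k_range, mean_ll, sd_ll)
  if (all(is.na(delta_k))) {
    warn("deltaK undefined for every interior K (zero replicate variance?).")
    selected <- NA_integer_
  } else {
    selected <- k_range[which.max(delta_k)]
  }
  structure(list(
    table = tibble(K = k_range, mean_ll = mean_ll, sd_ll = sd_ll,
                   delta_k = delta_k),
    selected_k = selected,
    fits = setNames(best, as.character(k_range)),
    replicate_ll = ll
  ), class = "deltak")
}

#' @export
print.deltak <- function(x, ...) {
  cat("<deltak> selected K =", x$selected_k, "\n")
  print(x$table)
  invisible(x)
}

#' Evanno delta-K statistic
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' defined only for interior K values (consecutive neighbors present) with
#' positive replicate standard deviation.
#'
#' @param k Sorted integer vector of K values.
#' @param mean_ll,sd_ll Replicate mean and standard deviation of the
#'   log-likelihood at each K.
#' @return Numeric vector of deltaK values (`NA` where undefined).
#' @export
evanno_delta_k <- function(k, mean_ll, sd_ll) {
  stopifnot(length(k) == length(mean_ll), length(k) == length(sd_ll))
  delta_k <- rep(NA_real_, length(k))
  for (ki in seq_along(k)) {
    if (ki == 1 || ki == length(k)) next
    if (k[ki + 1] - k[ki] != 1 || k[ki] - k[ki - 1] != 1) next
    if (!is.finite(sd_ll[ki]) || sd_ll[ki] <= 0) next
    delta_k[ki] <- abs(mean_ll[ki + 1] - 2 * mean_ll[ki] + mean_ll[ki - 1]) / sd_ll[ki]
  }
  delta_k
}

#' Assign accessions to populations by membership threshold
#'
#' An accession is assigned to its maximum-membership population when that
#' membership is at least `threshold` (boundary inclusive); otherwise it
#' is labeled `"admixed"`.
#'
#' @param fit An `admixture_fit` (or a Q matrix with accession rownames).
#' @param threshold Membership threshold (default 0.80).
#' @param labels Optional population labels (length K).
#' @return A tibble `accession`, `assignment`, `max_membership`.
#' @export
assign_memberships <- function(fit, threshold = 0.80, labels = NULL) {
  Q <- if (inherits(fit, "admixture_fit")) fit$Q else as.matrix(fit)
  stopifnot(all(abs(rowSums(Q) - 1) < 1e-6))
  if (is.null(labels)) labels <- sprintf("pop%d", seq_len(ncol(Q)))
  amax <- apply(Q, 1, which.max)
  qmax <- Q[cbind(seq_len(nrow(Q)), amax)]
  tibble(
    accession = rownames(Q) %||% sprintf("acc%d", seq_len(nrow(Q))),
    assignment = ifelse(qmax >= threshold, labels[amax], "admixed"),
    max_membership = qmax
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align an estimated Q matrix to a reference under label switching
#'
#' Tries all column permutations and returns the one minimizing the mean
#' absolute error against the reference memberships.
#'
#' @param Q_est,Q_ref n x K membership matrices.
#' @return A list: `Q` (permuted estimate), `perm`, `mae`.
#' @export
q_align <- function(Q_est, Q_ref) {
  K <- ncol(Q_est)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q_est))
  perms <- all_perms(K)
  best <- NULL
  for (p in perms) {
    mae <- mean(abs(Q_est[, p, drop = FALSE] - Q_ref))
    if (is.null(best) || mae < best$mae) best <- list(Q = Q_est[, p, drop = FALSE],
                                                      perm = p, mae = mae)
  }
  best
}

all_perms <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (rest in all_perms(K - 1)) {
      tail <- seq_len(K)[-i][rest]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}
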