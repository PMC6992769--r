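test_that("IBS distance matches its definition and a per-site loop", {
  dos <- cbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L), c = c(2L, NA, 0L))
  d <- ibs_distance(make_gm(dos))
  expect_identical(d["a", "b"], 0)
  expect_identical(d["a", "c"], 1)   # all joint sites are opposite homozygotes
  expect_identical(diag(d), c(a = 0, b = 0, c = 0))

  withr::with_seed(12, {
    x <- sample(c(0:2, NA), 200, replace = TRUE)
    y <- sample(c(0:2, NA), 200, replace = TRUE)
  })
  gm <- make_gm(cbind(a = x, b = y))
  d2 <- ibs_distance(gm)
  acc <- 0; nn <- 0
  for (l in 1:200) {
    if (!is.na(x[l]) && !is.na(y[l])) {
      shared <- 2 - abs(x[l] - y[l])
      acc <- acc + shared / 2; nn <- nn + 1
    }
  }
  expect_equal(d2["a", "b"], 1 - acc / nn, tolerance = 1e-12)

  expect_error(ibs_distance(make_gm(cbind(a = c(0L, NA), b = c(NA, 1L)))),
               "joint")
})

test_that("IBS distance is a metric on complete data", {
  withr::with_seed(22, {
    dos <- matrix(sample(0:2, 100 * 8, replace = TRUE), 100, 8,
                  dimnames = list(NULL, paste0("a", 1:8)))
  })
  d <- ibs_distance(make_gm(dos))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("UPGMA joins the closest pair and halves the merge height", {
  d <- matrix(0.4, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.1
  tr <- upgma(d)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["A", "B"], 0.1)    # merged at height 0.05
  expect_equal(cp["A", "C"], 0.4)
  expect_equal(cp["B", "C"], 0.4)

  # ultrametric input is reproduced exactly by the cophenetic distances
  um <- matrix(0.5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(um) <- 0
  um["A", "B"] <- um["B", "A"] <- 0.2
  um["C", "D"] <- um["D", "C"] <- 0.3
  tr2 <- upgma(um)
  expect_equal(ape::cophenetic.phylo(tr2)[LETTERS[1:4], LETTERS[1:4]], um,
               tolerance = 1e-12)
})

test_that("simulated populations form monophyletic clades", {
  sim <- simulate_genotypes(population_spec(
    K = 3, fst = 0.15, n_loci = 500, n_per_population = c(10, 10, 5),
    n_hybrids = 0, n_admixed = 0, n_duplicates = 0, missing_rate = 0,
    rng_seed = 1))
  tr <- upgma(ibs_distance(sim$gm))
  for (g in unique(sim$truth$group)) {
    tips <- sim$truth$accession[sim$truth$group == g]
    expect_true(ape::is.monophyletic(tr, tips), info = g)
  }
})

test_that("PCA gives duplicated accessions identical scores", {
  withr::with_seed(33, {
    dos <- matrix(sample(0:2, 120 * 6, replace = TRUE), 120, 6)
  })
  dos <- cbind(dos, dos[, 1])
  colnames(dos) <- c(paste0("a", 1:6), "a1_dup")
  pca <- pca_genotypes(make_gm(dos))
  s <- pca$scores
  expect_equal(unlist(s[s$accession == "a1", -1]),
               unlist(s[s$accession == "a1_dup", -1]), tolerance = 1e-10)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-12)

  # variance fractions match the eigenvalues of the centered covariance
  X <- t(dos)
  X <- sweep(X, 2, colMeans(X))
  ev <- eigen(X %*% t(X), symmetric = TRUE)$values
  ev <- ev[ev > 1e-9]
  expect_equal(pca$var_explained[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-8)

  expect_error(pca_genotypes(make_gm(matrix(1L, 5, 3,
    dimnames = list(NULL, c("x", "y", "z"))))), "variance")
})

test_that("K = 1 admixture has the analytic solution", {
  withr::with_seed(44, {
    dos <- matrix(sample(c(0:2, NA), 200 * 8, replace = TRUE), 200, 8,
                  dimnames = list(NULL, paste0("a", 1:8)))
  })
  gm <- make_gm(dos)
  fit <- fit_admixture(gm, 1)
  f_hand <- vapply(seq_len(nrow(dos)), function(l) {
    x <- dos[l, ]; sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
  }, numeric(1))
  expect_equal(as.vector(fit$F), pmin(pmax(f_hand, 1e-6), 1 - 1e-6),
               tolerance = 1e-12)
  ll_hand <- 0
  for (l in seq_len(nrow(dos))) for (i in 1:8) {
    g <- dos[l, i]
    if (!is.na(g)) {
      p <- fit$F[1, l]
      ll_hand <- ll_hand + g * log(p) + (2 - g) * log(1 - p)
    }
  }
  expect_equal(unname(fit$loglik), unname(ll_hand), tolerance = 1e-8)
  expect_true(all(fit$Q == 1))
})

test_that("EM log-likelihood is monotone and the fit is seed-deterministic", {
  sim <- simulate_genotypes(population_spec(
    K = 2, fst = 0.2, n_loci = 150, n_per_population = c(6, 6),
    n_hybrids = 0, n_admixed = 2, n_duplicates = 0, missing_rate = 0.02,
    rng_seed = 6))
  fit <- fit_admixture(sim$gm, 2, seed = 9)
  expect_true(all(diff(fit$loglik_trace) >= -1e-7))
  fit2 <- fit_admixture(sim$gm, 2, seed = 9)
  expect_identical(fit$Q, fit2$Q)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("an F1 between fixed-difference populations recovers Q = (0.5, 0.5)", {
  L <- 100
  dos <- cbind(matrix(0L, L, 6), matrix(2L, L, 6), matrix(1L, L, 1))
  colnames(dos) <- c(paste0("p1_", 1:6), paste0("p2_", 1:6), "f1")
  gm <- make_gm(dos)
  fit <- fit_admixture(gm, 2, seed = 3)
  expect_lt(max(abs(fit$Q["f1", ] - 0.5)), 0.02)

  # grid-search oracle: with population frequencies fixed at the pure-pop
  # estimates, the F1's likelihood is maximized at q = 0.5
  f1 <- rep(1e-6, L); f2 <- rep(1 - 1e-6, L)
  ll_q <- function(q) sum(log(q * f1 + (1 - q) * f2) +
                          log(1 - (q * f1 + (1 - q) * f2)))
  qs <- seq(0.01, 0.99, by = 0.001)
  expect_equal(qs[which.max(vapply(qs, ll_q, numeric(1)))], 0.5,
               tolerance = 5e-3)

  expect_identical(
    assign_memberships(fit)$assignment[colnames(dos) == "f1"], "admixed")
})

test_that("the Evanno statistic matches a hand evaluation", {
  dk <- evanno_delta_k(1:4, c(-100, -50, -45, -44), rep(1, 4))
  expect_identical(dk, c(NA, 45, 4, NA))
  # undefined where the replicate sd is zero or K values not consecutive
  expect_true(all(is.na(evanno_delta_k(1:3, c(-3, -2, -1), c(0, 0, 0)))))
  expect_true(all(is.na(evanno_delta_k(c(1, 3, 5), c(-3, -2, -1), rep(1, 3)))))
})

test_that("membership assignment applies the 0.80 threshold inclusively", {
  Q <- rbind(a = c(0.9, 0.05, 0.05), b = c(0.5, 0.5, 0),
             c = c(0.8, 0.2, 0), d = c(0.1, 0.15, 0.75))
  asg <- assign_memberships(Q, threshold = 0.80)
  expect_identical(asg$assignment, c("pop1", "admixed", "pop1", "admixed"))
  expect_equal(asg$max_membership, c(0.9, 0.5, 0.8, 0.75))
})

test_that("q_align undoes label switching", {
  withr::with_seed(55, Q <- t(vapply(1:20, function(i) {
    x <- stats::rgamma(3, 0.3); x / sum(x)
  }, numeric(3))))
  perm <- c(3, 1, 2)
  al <- q_align(Q[, perm], Q)
  expect_lt(al$mae, 1e-12)
  expect_identical(Q[, perm][, al$perm], Q)
})

test_that("tidy/glance/autoplot methods return the expected shapes", {
  sim <- simulate_genotypes(population_spec(
    K = 2, fst = 0.3, n_loci = 80, n_per_population = c(4, 4),
    n_hybrids = 0, n_admixed = 0, n_duplicates = 0, missing_rate = 0,
    rng_seed = 2))
  fit <- fit_admixture(sim$gm, 2, seed = 1)
  td <- tidy(fit)
  expect_identical(nrow(td), 16L)
  expect_equal(sum(td$membership), 8)
  expect_identical(glance(fit)$K, 2L)
  expect_s3_class(autoplot(fit), "ggplot")

  pca <- pca_genotypes(sim$gm)
  expect_identical(nrow(tidy(pca)), 8L)
  expect_s3_class(autoplot(pca, colour_by = sim$truth[, c("accession", "group")]),
                  "ggplot")
})
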