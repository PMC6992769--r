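#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_tile
#'   labs theme_minimal facet_wrap scale_fill_brewer coord_flip
#' @export
ggplot2::autoplot

#' Tidy an admixture fit: one row per accession x population
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return A tibble `accession`, `population`, `membership`.
#' @export
tidy.admixture_fit <- function(x, ...) {
  Q <- x$Q
  tibble(
    accession = rep(rownames(Q) %||% sprintf("acc%d", seq_len(nrow(Q))),
                    times = ncol(Q)),
    population = rep(colnames(Q), each = nrow(Q)),
    membership = as.vector(Q)
  )
}

#' @rdname tidy.admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, iterations = x$iterations,
         converged = x$converged, seed = x$seed)
}

#' Tidy a PCA of genotypes
#'
#' @param x A `gbs_pca`.
#' @param ... Unused.
#' @return The score tibble with one row per accession.
#' @export
tidy.gbs_pca <- function(x, ...) x$scores

#' @rdname tidy.gbs_pca
#' @export
glance.gbs_pca <- function(x, ...) {
  tibble(n_components = length(x$var_explained),
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' Tidy a delta-K table
#'
#' @param x A `deltak` object.
#' @param ... Unused.
#' @return The per-K tibble (`K`, `mean_ll`, `sd_ll`, `delta_k`).
#' @export
tidy.deltak <- function(x, ...) x$table

#' @rdname tidy.deltak
#' @export
glance.deltak <- function(x, ...) {
  tibble(selected_k = x$selected_k,
         k_min = min(x$table$K), k_max = max(x$table$K))
}

#' Membership bar plot of an admixture fit
#'
#' @param object An `admixture_fit`.
#' @param ... Unused.
#' @return A ggplot: stacked membership bars per accession.
#' @export
autoplot.admixture_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$accession, y = .data$membership,
                 fill = .data$population)) +
    geom_col(width = 1) +
    labs(x = NULL, y = "Membership", fill = "Population") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Scatter plot of the first two principal components
#'
#' @param object A `gbs_pca`.
#' @param colour_by Optional tibble `accession`, `group` for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbs_pca <- function(object, colour_by = NULL, ...) {
  sc <- object$scores
  ve <- object$var_explained * 100
  if (!is.null(colour_by)) sc <- left_join(sc, colour_by, by = "accession")
  p <- ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) +
    labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
         y = sprintf("PC2 (%.1f%%)", ve[2])) +
    theme_minimal()
  if (!is.null(colour_by)) p + geom_point(aes(colour = .data$group))
  else p + geom_point()
}

#' Delta-K profile plot
#'
#' @param object A `deltak` object.
#' @param ... Unused.
#' @return A ggplot of deltaK against K.
#' @export
autoplot.deltak <- function(object, ...) {
  ggplot(object$table, aes(x = .data$K, y = .data$delta_k)) +
    geom_point() + ggplot2::geom_line() +
    labs(y = expression(Delta * K)) +
    theme_minimal()
}

#' Substitution spectrum bar plot
#'
#' @param spectrum Output of [substitution_spectrum()].
#' @return A ggplot of counts per substitution class, colored by Ts/Tv.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot(spectrum, aes(x = stats::reorder(.data$class, -.data$n), y = .data$n,
                       fill = .data$type)) +
    geom_col() +
    labs(x = "Substitution class", y = "SNPs", fill = NULL) +
    theme_minimal()
}

#' Heterozygosity bar plot
#'
#' @param het Output of [heterozygosity_percent()].
#' @return A ggplot of per-accession heterozygosity.
#' @export
plot_heterozygosity <- function(het) {
  ggplot(het, aes(x = stats::reorder(.data$accession, .data$het_percent),
                  y = .data$het_percent)) +
    geom_col() + coord_flip() +
    labs(x = NULL, y = "Heterozygous calls (%)") +
    theme_minimal()
}
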