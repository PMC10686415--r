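#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-protein model fits
#'
#' One row per protein x group with the least-squares mean (log2).
#'
#' @param x A `protein_fits` object.
#' @param ... Unused.
#' @return Tibble: `protein`, `group`, `lsmean`, `sigma2`, `df`, `testable`.
#' @exportS3Method generics::tidy
tidy.protein_fits <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    lsm <- x$lsmeans[[i]]
    tibble::tibble(protein = x$protein[i], group = names(lsm),
                   lsmean = unname(lsm), sigma2 = x$sigma2[i],
                   df = x$df[i], testable = x$testable[i])
  })
}

#' @rdname tidy.protein_fits
#' @exportS3Method generics::glance
glance.protein_fits <- function(x, ...) {
  tibble::tibble(n_proteins = nrow(x),
                 n_testable = sum(x$testable),
                 n_groups = length(attr(x, "groups")),
                 median_sigma2 = median(x$sigma2, na.rm = TRUE),
                 median_df = median(x$df))
}

#' Tidy a profile PCA
#'
#' @param x A `profile_pca`.
#' @param matrix `"scores"` (default), `"loadings"`, or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble of the requested component.
#' @exportS3Method generics::tidy
tidy.profile_pca <- function(x, matrix = c("scores", "loadings",
                                           "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
         scores = x$scores,
         loadings = x$loadings,
         eigenvalues = tibble::tibble(component = seq_along(x$var_frac),
                                      sdev = x$sdev,
                                      var_frac = x$var_frac))
}

#' @rdname tidy.profile_pca
#' @exportS3Method generics::glance
glance.profile_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$var_frac),
                 pc1_var_frac = x$var_frac[1],
                 pc2_var_frac = ifelse(length(x$var_frac) > 1,
                                       x$var_frac[2], NA_real_),
                 n_dropped = x$n_dropped, n_imputed = x$n_imputed)
}

#' Tidy module-trait correlations
#'
#' @param x A `module_trait` object.
#' @param ... Unused.
#' @return Tibble: `module`, `trait`, `r`, `p`.
#' @exportS3Method generics::tidy
tidy.module_trait <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$r, stringsAsFactors = FALSE)) %>%
    setNames(c("module", "trait", "r")) %>%
    dplyr::mutate(p = as.data.frame.table(x$p)$Freq)
}

#' Tidy a network model
#'
#' @param x A `conet` object.
#' @param ... Unused.
#' @return Tibble of module assignments: `protein`, `module`.
#' @exportS3Method generics::tidy
tidy.conet <- function(x, ...) {
  tibble::tibble(protein = names(x$labels), module = unname(x$labels))
}

#' @rdname tidy.conet
#' @exportS3Method generics::glance
glance.conet <- function(x, ...) {
  tibble::tibble(n_proteins = x$n_proteins, n_filtered = x$n_filtered,
                 n_modules = length(setdiff(unique(x$labels), 0L)),
                 n_unassigned = sum(x$labels == 0),
                 n_edges = nrow(x$edges), beta = x$beta)
}

#' Tidy a negative-pair screen
#'
#' @param x A `pair_screen`.
#' @param ... Unused.
#' @return The per-pair result tibble.
#' @exportS3Method generics::tidy
tidy.pair_screen <- function(x, ...) x$pairs

#' @rdname tidy.pair_screen
#' @exportS3Method generics::glance
glance.pair_screen <- function(x, ...) {
  tibble::tibble(n_screened = nrow(x$pairs),
                 n_significant_negative = sum(x$pairs$significant_negative),
                 n_excluded = x$n_excluded, alpha = x$alpha,
                 adjust = x$adjust)
}

#' Tidy a variance partition
#'
#' @param x A `variance_partition`.
#' @param ... Unused.
#' @return Long tibble: `protein`, `covariate`, `fraction`.
#' @exportS3Method generics::tidy
tidy.variance_partition <- function(x, ...) {
  tidyr::pivot_longer(x$fractions, -"protein", names_to = "covariate",
                      values_to = "fraction")
}

#' Tidy a complex co-regulation result
#'
#' @param x A `complex_coregulation`.
#' @param ... Unused.
#' @return Long tibble of pair correlations: `pair_class`, `r`.
#' @exportS3Method generics::tidy
tidy.complex_coregulation <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(pair_class = "complex", r = x$complex_r),
    tibble::tibble(pair_class = "random", r = x$random_r))
}

#' @rdname tidy.complex_coregulation
#' @exportS3Method generics::glance
glance.complex_coregulation <- function(x, ...) {
  tibble::tibble(median_complex_r = x$median_complex,
                 median_random_r = x$median_random,
                 p_permutation = x$p_permutation,
                 n_pairs_complex = x$n_pairs_complex,
                 n_pairs_random = x$n_pairs_random)
}
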