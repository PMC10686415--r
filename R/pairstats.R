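#' Protein-complex co-regulation versus random pairs
#'
#' Pearson correlations across synapse types for all pairs of proteins
#' annotated to the same complex, against a null distribution of randomly
#' sampled cross-protein pairs (within-complex pairs excluded from the
#' null). Significance of the within-complex median is assessed by
#' permutation: resampled random-pair sets of the same size as the complex
#' pair set, p = fraction of null medians at least as large as the observed
#' complex median (add-one correction).
#'
#' @param pm A `profile_matrix`, normally type-averaged.
#' @param complexes Tibble (`complex_id`, `protein`); members absent from
#'   the matrix are dropped (count reported).
#' @param n_random Random pairs in the null sample; default 10000 (capped
#'   at the number of available pairs).
#' @param n_perm Resampled null sets for the permutation p; default 1000.
#' @param min_obs Minimum complete paired observations per pair; default 4.
#' @param seed RNG seed.
#' @return Object of class `complex_coregulation`: `complex_r`, `random_r`
#'   (numeric vectors), `median_complex`, `median_random`, `p_permutation`,
#'   `n_dropped_members`.
#' @export
complex_coregulation <- function(pm, complexes, n_random = 10000,
                                 n_perm = 1000, min_obs = 4, seed = 1) {
  stopifnot(inherits(pm, "profile_matrix"))
  assert_columns(complexes, c("complex_id", "protein"), "complexes")
  vals <- pm$values
  present <- complexes$protein %in% rownames(vals)
  n_dropped <- sum(!present)
  cx <- complexes[present, ]
  sizes <- table(cx$complex_id)
  cx <- cx[cx$complex_id %in% names(sizes)[sizes >= 2], ]
  if (nrow(cx) == 0) stop_input("no complex has >= 2 quantified members")

  pair_r <- function(a, b) {
    x <- vals[a, ]; y <- vals[b, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_obs) return(NA_real_)
    suppressWarnings(cor(x[ok], y[ok]))
  }
  cpx_pairs <- cx %>%
    dplyr::group_by(.data$complex_id) %>%
    dplyr::reframe({
      pr <- t(combn(sort(unique(.data$protein)), 2))
      tibble::tibble(protein_a = pr[, 1], protein_b = pr[, 2])
    }) %>%
    dplyr::distinct(.data$protein_a, .data$protein_b)
  complex_r <- mapply(pair_r, cpx_pairs$protein_a, cpx_pairs$protein_b)
  complex_r <- complex_r[is.finite(complex_r)]
  if (length(complex_r) == 0) stop_input("no complex pair has enough shared observations")

  prot <- rownames(vals)
  np <- length(prot)
  in_complex <- paste(cpx_pairs$protein_a, cpx_pairs$protein_b, sep = "\r")
  with_seed(seed, {
    total_pairs <- np * (np - 1) / 2
    n_random <- min(n_random, total_pairs - length(in_complex))
    seen <- character(0)
    random_r <- numeric(0)
    while (length(random_r) < n_random) {
      if (length(seen) >= total_pairs - length(in_complex)) break
      need <- n_random - length(random_r)
      i <- sample.int(np, 2 * need, replace = TRUE)
      j <- sample.int(np, 2 * need, replace = TRUE)
      ok <- i != j
      a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
      key <- paste(prot[a], prot[b], sep = "\r")
      fresh <- !(key %in% seen) & !(key %in% in_complex) & !duplicated(key)
      take_n <- min(need, sum(fresh))
      if (take_n == 0) next
      a <- a[fresh][seq_len(take_n)]
      b <- b[fresh][seq_len(take_n)]
      seen <- c(seen, paste(prot[a], prot[b], sep = "\r"))
      rr <- unlist(mapply(pair_r, prot[a], prot[b], SIMPLIFY = FALSE))
      random_r <- c(random_r, rr[is.finite(rr)])
    }
    med_c <- median(complex_r)
    med_r <- median(random_r)
    null_medians <- vapply(seq_len(n_perm), function(b) {
      median(sample(random_r, length(complex_r), replace = TRUE))
    }, numeric(1))
    p_perm <- (1 + sum(null_medians >= med_c)) / (n_perm + 1)
    structure(list(complex_r = unname(complex_r), random_r = random_r,
                   median_complex = med_c, median_random = med_r,
                   p_permutation = p_perm, n_pairs_complex = length(complex_r),
                   n_pairs_random = length(random_r),
                   n_dropped_members = n_dropped),
              class = "complex_coregulation")
  })
}

#' @export
print.complex_coregulation <- function(x, ...) {
  cat(sprintf("<complex_coregulation> median r: complex %.3f vs random %.3f | permutation p = %.4g\n",
              x$median_complex, x$median_random, x$p_permutation))
  invisible(x)
}

#' Screen protein pairs for significant negative correlation
#'
#' Pearson correlation across synapse types for each candidate pair, a
#' two-sided t test (df = n - 2), and Benjamini-Hochberg adjustment across
#' all screened pairs. The significant-negative subset satisfies r < 0 and
#' adjusted p < alpha (raw p via `adjust = "none"`).
#'
#' @param pm A `profile_matrix`, normally type-averaged.
#' @param candidate_pairs Tibble (`protein_a`, `protein_b`), or `NULL` to
#'   derive candidates from `families`.
#' @param families Named list of protein families; candidates are all
#'   within-family pairs.
#' @param all_pairs Screen every protein pair (quadratic; only sensible
#'   for small matrices). Default `FALSE`.
#' @param alpha Significance threshold; default 0.05.
#' @param adjust `"BH"` (default) or `"none"`.
#' @param min_obs Minimum complete paired observations; default 4.
#' @return Object of class `pair_screen`: tibble `pairs` (`protein_a`,
#'   `protein_b`, `r`, `n`, `p`, `adj_p`, `direction`, `significant_negative`)
#'   plus `n_excluded` (constant or under-observed pairs).
#' @export
screen_negative_pairs <- function(pm, candidate_pairs = NULL, families = NULL,
                                  all_pairs = FALSE, alpha = 0.05,
                                  adjust = c("BH", "none"), min_obs = 4) {
  stopifnot(inherits(pm, "profile_matrix"))
  adjust <- match.arg(adjust)
  vals <- pm$values
  if (is.null(candidate_pairs)) {
    if (!is.null(families)) {
      candidate_pairs <- purrr::map_dfr(families, function(members) {
        members <- intersect(unique(members), rownames(vals))
        if (length(members) < 2) return(NULL)
        pr <- t(combn(sort(members), 2))
        tibble::tibble(protein_a = pr[, 1], protein_b = pr[, 2])
      })
    } else if (all_pairs) {
      if (nrow(vals) > 5000) {
        warn("all-pairs screen on > 5000 proteins is quadratic; this may be slow")
      }
      # Vectorized whole-matrix path: correlation and shared-observation
      # counts for every pair at once.
      ord <- sort(rownames(vals))
      v <- vals[ord, , drop = FALSE]
      C <- suppressWarnings(cor(t(v), use = "pairwise.complete.obs"))
      N <- tcrossprod(!is.na(v) * 1)
      ut <- which(upper.tri(C), arr.ind = TRUE)
      r <- C[ut]; n <- N[ut]
      bad <- !is.finite(r) | n < min_obs
      tstat <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1e-300, 1 - r^2))
      res <- tibble::tibble(protein_a = ord[ut[, 1]], protein_b = ord[ut[, 2]],
                            r = r, n = n, p = 2 * pt(-abs(tstat), pmax(n - 2, 1)))
      res$r[bad] <- NA_real_
      res$p[bad] <- NA_real_
      n_excluded <- sum(bad)
      res <- dplyr::filter(res, !is.na(.data$r))
      res$adj_p <- if (adjust == "BH") p.adjust(res$p, "BH") else res$p
      res$direction <- ifelse(res$r < 0, "negative", "positive")
      res$significant_negative <- res$r < 0 & res$adj_p < alpha
      return(structure(list(pairs = res, n_excluded = n_excluded,
                            alpha = alpha, adjust = adjust),
                       class = "pair_screen"))
    } else {
      stop_input("supply candidate_pairs, families, or all_pairs = TRUE")
    }
  }
  candidate_pairs <- dplyr::distinct(candidate_pairs,
                                     .data$protein_a, .data$protein_b)
  known <- candidate_pairs$protein_a %in% rownames(vals) &
    candidate_pairs$protein_b %in% rownames(vals)
  candidate_pairs <- candidate_pairs[known, ]

  res <- purrr::pmap_dfr(candidate_pairs, function(protein_a, protein_b) {
    x <- vals[protein_a, ]; y <- vals[protein_b, ]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_obs || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(protein_a = protein_a, protein_b = protein_b,
                            r = NA_real_, n = n, p = NA_real_))
    }
    r <- cor(x[ok], y[ok])
    tstat <- r * sqrt(n - 2) / sqrt(max(1e-300, 1 - r^2))
    tibble::tibble(protein_a = protein_a, protein_b = protein_b, r = r,
                   n = n, p = 2 * pt(-abs(tstat), n - 2))
  })
  n_excluded <- sum(is.na(res$r)) + sum(!known)
  res <- dplyr::filter(res, !is.na(.data$r))
  res$adj_p <- if (adjust == "BH") p.adjust(res$p, "BH") else res$p
  res$direction <- ifelse(res$r < 0, "negative", "positive")
  res$significant_negative <- res$r < 0 & res$adj_p < alpha
  structure(list(pairs = res, n_excluded = n_excluded, alpha = alpha,
                 adjust = adjust), class = "pair_screen")
}

#' @export
print.pair_screen <- function(x, ...) {
  cat(sprintf("<pair_screen> %d pairs screened | %d significant negative (alpha %.2g, %s) | %d excluded\n",
              nrow(x$pairs), sum(x$pairs$significant_negative), x$alpha,
              x$adjust, x$n_excluded))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric enrichment of a query set against
#' user-supplied gene sets (e.g. read with [read_gmt()]), each intersected
#' with the quantified universe, with Benjamini-Hochberg adjustment across
#' sets.
#'
#' @param query Character vector; must be a subset of `universe`.
#' @param universe Character vector of all eligible identifiers.
#' @param gene_sets Named list of character vectors.
#' @return Tibble: `set`, `n_set` (after intersection), `overlap`,
#'   `expected`, `p`, `adj_p`.
#' @export
hypergeometric_ora <- function(query, universe, gene_sets) {
  query <- unique(query); universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad) > 0) {
    stop_input(sprintf("query identifiers outside the universe: %s",
                       paste(head(bad, 5), collapse = ", ")))
  }
  res <- purrr::imap_dfr(gene_sets, function(members, nm) {
    s <- intersect(unique(members), universe)
    k <- length(intersect(query, s))
    p <- if (length(s) == 0) 1 else {
      phyper(k - 1, length(s), length(universe) - length(s), length(query),
             lower.tail = FALSE)
    }
    tibble::tibble(set = nm, n_set = length(s), overlap = k,
                   expected = length(query) * length(s) / length(universe),
                   p = p)
  })
  res$adj_p <- p.adjust(res$p, "BH")
  dplyr::arrange(res, .data$p)
}
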