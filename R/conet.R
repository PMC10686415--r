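#' Biweight midcorrelation
#'
#' Robust correlation built from median/MAD-based biweights with tuning
#' constant 9: observations further than nine (unscaled) median absolute
#' deviations from the median get zero weight, and weights decay smoothly
#' as `(1 - u^2)^2` inside that window. A vector with zero MAD falls back
#' to the Pearson (mean/centering) form for that vector; the fallback is
#' recorded on the result.
#'
#' @param x,y Numeric vectors of equal length with at least 4 paired finite
#'   observations (incomplete pairs are dropped).
#' @param tuning Biweight tuning constant; default 9.
#' @return Correlation in \[-1, 1\], with attribute `fallback` naming the
#'   arguments (if any) that used the Pearson fallback.
#' @examples
#' bicor(1:5, c(1, 2, 4, 8, 16))
#' @export
bicor <- function(x, y, tuning = 9) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4) stop_input("bicor needs at least 4 paired finite observations")
  x <- x[ok]; y <- y[ok]
  wx <- bicor_transform(x, tuning)
  wy <- bicor_transform(y, tuning)
  r <- sum(wx$v * wy$v)
  fb <- c(if (wx$fallback) "x", if (wy$fallback) "y")
  structure(max(-1, min(1, r)), fallback = fb)
}

# Normalized biweight pseudo-observations: returns unit-norm deviations.
bicor_transform <- function(x, tuning = 9) {
  med <- median(x)
  madx <- median(abs(x - med))
  if (madx == 0) {
    v <- x - mean(x)
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(list(v = rep(0, length(x)), fallback = TRUE))
    return(list(v = v / nv, fallback = TRUE))
  }
  u <- (x - med) / (tuning * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  v <- (x - med) * w
  list(v = v / sqrt(sum(v^2)), fallback = FALSE)
}

#' Biweight midcorrelation matrix of protein profiles
#'
#' Row-wise bicor of a complete (no missing values) proteins x types
#' matrix.
#'
#' @param mat Numeric matrix, rows = proteins; >= 4 columns, no `NA`.
#' @param tuning Biweight tuning constant; default 9.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `n_fallback` counts rows that used the Pearson fallback (zero MAD).
#' @export
bicor_matrix <- function(mat, tuning = 9) {
  if (ncol(mat) < 4) stop_input("bicor needs at least 4 observations (columns)")
  if (anyNA(mat)) stop_input("bicor_matrix requires complete profiles; filter missing values first")
  tr <- apply(mat, 1, function(r) {
    b <- bicor_transform(r, tuning)
    c(b$v, b$fallback)
  })
  V <- t(tr[seq_len(ncol(mat)), , drop = FALSE])
  fallback <- as.logical(tr[ncol(mat) + 1, ])
  r <- tcrossprod(V)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(mat), rownames(mat))
  structure(r, n_fallback = sum(fallback))
}

#' Signed-hybrid soft-threshold adjacency
#'
#' `a_ij = cor_ij ^ beta` for positive correlations, 0 otherwise: negative
#' co-abundance never contributes edge weight, and soft thresholding
#' suppresses weak positive correlations.
#'
#' @param corr Symmetric correlation matrix in \[-1, 1\].
#' @param beta Soft power, > 0; default 6.
#' @return Adjacency matrix in \[0, 1\].
#' @export
adjacency_signed_hybrid <- function(corr, beta = 6) {
  if (beta <= 0) stop_input("soft power beta must be > 0")
  a <- ifelse(corr > 0, corr^beta, 0)
  dimnames(a) <- dimnames(corr)
  a
}

#' Topological overlap matrix
#'
#' Neighborhood-sharing similarity:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivities `k_i = sum_u a_iu` (diagonal excluded) and
#' `TOM_ii = 1`.
#'
#' @param adjacency Symmetric adjacency in \[0, 1\].
#' @return Symmetric TOM matrix in \[0, 1\].
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-abundance modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity (1 - TOM by
#' default), a static cut, a minimum-size filter (small clusters get label
#' 0, the "unassigned" convention), and iterative merging of modules whose
#' eigenproteins correlate above `merge_threshold`. Surviving modules are
#' relabeled 1, 2, ... by decreasing size.
#'
#' @param dissimilarity Square dissimilarity matrix (e.g. `1 - TOM`).
#' @param profiles The proteins x types profile matrix used for
#'   eigenprotein-based merging (rows must match the dissimilarity).
#' @param min_module_size Minimum module size; default 20.
#' @param cut_height Static cut height; by default (`NULL`) placed in the
#'   middle of the largest gap between consecutive merge heights in the
#'   upper half of the dendrogram, which separates tight clusters from the
#'   diffuse top-level merges without a data-scale-specific constant.
#' @param merge_threshold Eigenprotein correlation above which modules are
#'   merged; default 0.75.
#' @return Integer vector of module labels (0 = unassigned), named by
#'   protein, with attribute `cut_height`.
#' @export
detect_modules <- function(dissimilarity, profiles, min_module_size = 20,
                           cut_height = NULL, merge_threshold = 0.75) {
  stopifnot(nrow(dissimilarity) == ncol(dissimilarity))
  tree <- hclust(as.dist(dissimilarity), method = "average")
  if (is.null(cut_height)) cut_height <- largest_gap_height(tree)
  labels <- cutree(tree, h = cut_height)
  tab <- table(labels)
  labels[labels %in% as.integer(names(tab)[tab < min_module_size])] <- 0L

  labels <- merge_close_modules(labels, profiles, merge_threshold)

  kept <- sort(table(labels[labels != 0]), decreasing = TRUE)
  relabel <- setNames(seq_along(kept), names(kept))
  labels <- ifelse(labels == 0, 0L, as.integer(relabel[as.character(labels)]))
  if (all(labels == 0)) warn("no module passed the size filter; all proteins unassigned")
  names(labels) <- rownames(dissimilarity)
  structure(labels, cut_height = unname(cut_height))
}

# Default static cut: midpoint of the largest gap between consecutive
# merge heights in the upper half of the dendrogram.
largest_gap_height <- function(tree) {
  h <- sort(tree$height)
  top <- h[h >= median(h)]
  if (length(top) < 2) return(max(h))
  gaps <- diff(top)
  i <- which.max(gaps)
  (top[i] + top[i + 1]) / 2
}

merge_close_modules <- function(labels, profiles, merge_threshold) {
  repeat {
    mods <- setdiff(unique(labels), 0L)
    if (length(mods) < 2) break
    eig <- eigenproteins(profiles, labels)
    ec <- cor(t(eig))
    diag(ec) <- -Inf
    if (max(ec) <= merge_threshold) break
    idx <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    m_from <- as.integer(sub("^M", "", rownames(ec)[idx[1]]))
    m_to <- as.integer(sub("^M", "", rownames(ec)[idx[2]]))
    labels[labels == m_from] <- m_to
  }
  labels
}

#' Module eigenproteins
#'
#' The first principal component of each module's standardized member
#' profiles: a representative abundance profile across synapse types,
#' scaled to unit variance and sign-aligned so it correlates non-negatively
#' with the module's mean profile. Missing member values are imputed by the
#' protein-wise mean (count recorded as attribute `n_imputed`).
#'
#' @param profiles Proteins x types matrix.
#' @param labels Module labels aligned with the rows (0 ignored).
#' @return Matrix modules x types (rownames `M<label>`), unit variance per
#'   row.
#' @export
eigenproteins <- function(profiles, labels) {
  mods <- setdiff(sort(unique(labels)), 0L)
  if (length(mods) == 0) stop_input("no modules to summarize")
  n_imputed <- 0L
  eig <- t(vapply(mods, function(m) {
    X <- profiles[labels == m, , drop = FALSE]
    if (nrow(X) < 2) stop_input(sprintf("module %s has fewer than 2 proteins", m))
    if (anyNA(X)) {
      rm_ <- rowMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- rm_[idx[, 1]]
      n_imputed <<- n_imputed + nrow(idx)
    }
    Xs <- t(scale(t(X)))
    Xs[!is.finite(Xs)] <- 0
    sv <- svd(Xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (sd(e) > 0) e <- e / sd(e)
    mean_prof <- colMeans(Xs)
    if (sum(e * mean_prof) < 0) e <- -e
    e
  }, numeric(ncol(profiles))))
  dimnames(eig) <- list(paste0("M", mods), colnames(profiles))
  structure(eig, n_imputed = n_imputed)
}

#' Correlate module eigenproteins with synapse-type traits
#'
#' Pearson correlation of each eigenprotein with each trait across synapse
#' types, with two-sided p values from the t distribution with n - 2
#' degrees of freedom. Categorical traits are one-hot encoded; constant
#' traits give missing correlations.
#'
#' @param eig Eigenprotein matrix (modules x types) from [eigenproteins()].
#' @param traits Tibble with a `type` column and one column per trait.
#' @return Object of class `module_trait`: matrices `r` and `p`
#'   (modules x traits).
#' @export
module_trait_correlation <- function(eig, traits) {
  assert_columns(traits, "type", "traits")
  if (ncol(eig) < 4) stop_input("need at least 4 types for module-trait correlation")
  tr <- traits[match(colnames(eig), traits$type), , drop = FALSE]
  if (anyNA(tr$type)) stop_input("traits table does not cover all profiled types")
  tv <- tr[setdiff(names(tr), "type")]
  cols <- list()
  for (nm in names(tv)) {
    v <- tv[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      for (lev in sort(unique(v))) cols[[paste(nm, lev, sep = ".")]] <-
          as.numeric(v == lev)
    }
  }
  n <- ncol(eig)
  r <- p <- matrix(NA_real_, nrow(eig), length(cols),
                   dimnames = list(rownames(eig), names(cols)))
  for (j in seq_along(cols)) {
    v <- cols[[j]]
    if (sd(v) == 0) next
    for (i in seq_len(nrow(eig))) {
      ri <- cor(eig[i, ], v)
      r[i, j] <- ri
      tstat <- ri * sqrt(n - 2) / sqrt(max(1e-300, 1 - ri^2))
      p[i, j] <- 2 * pt(-abs(tstat), n - 2)
    }
  }
  structure(list(r = r, p = p, n = n), class = "module_trait")
}

#' @export
print.module_trait <- function(x, ...) {
  cat(sprintf("<module_trait> %d modules x %d traits (n = %d types)\n",
              nrow(x$r), ncol(x$r), x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' Export a thresholded edge list
#'
#' Undirected edges (`i < j`) with adjacency weight strictly above the
#' cutoff, annotated with the endpoints' module labels.
#'
#' @param adjacency Symmetric adjacency matrix.
#' @param weight_cutoff Strict weight threshold; default 0.3.
#' @param labels Optional module labels named by protein.
#' @return Tibble: `source`, `target`, `weight`, `module_source`,
#'   `module_target`.
#' @export
export_network <- function(adjacency, weight_cutoff = 0.3, labels = NULL) {
  prot <- rownames(adjacency)
  if (is.null(prot)) prot <- as.character(seq_len(nrow(adjacency)))
  keep <- which(upper.tri(adjacency) & adjacency > weight_cutoff, arr.ind = TRUE)
  lab <- function(p) {
    if (is.null(labels)) rep(NA_integer_, length(p)) else unname(labels[p])
  }
  tibble::tibble(
    source = prot[keep[, 1]], target = prot[keep[, 2]],
    weight = adjacency[keep],
    module_source = lab(prot[keep[, 1]]),
    module_target = lab(prot[keep[, 2]])) %>%
    dplyr::arrange(dplyr::desc(.data$weight))
}

#' Build a weighted correlation network over synapse-type profiles
#'
#' The full network stage: restricts to proteins with complete profiles
#' (count reported), computes the biweight midcorrelation matrix, raises
#' positive correlations to the soft power (signed hybrid), derives the
#' topological overlap, detects modules, summarizes them as eigenproteins
#' and correlates the eigenproteins with type-level traits.
#'
#' @param pm A `profile_matrix`, normally type-averaged
#'   ([average_by_type()]).
#' @param traits Optional trait tibble (`type` + trait columns).
#' @param beta Soft power; default 6.
#' @param min_module_size,cut_height,merge_threshold See [detect_modules()].
#' @param weight_cutoff Edge-list threshold; default 0.3.
#' @param use_tom Cluster on `1 - TOM` (default) or `1 - adjacency`.
#' @return Object of class `conet`: correlation, adjacency and TOM
#'   matrices, `labels`, `eigenproteins`, `module_trait` (or `NULL`),
#'   `edges`, and filtering counts.
#' @export
build_network <- function(pm, traits = NULL, beta = 6, min_module_size = 20,
                          cut_height = NULL, merge_threshold = 0.75,
                          weight_cutoff = 0.3, use_tom = TRUE) {
  stopifnot(inherits(pm, "profile_matrix"))
  vals <- pm$values
  complete <- !apply(is.na(vals), 1, any)
  n_filtered <- sum(!complete)
  inform(sprintf("network restricted to %d proteins with complete profiles (%d filtered)",
                 sum(complete), n_filtered))
  vals <- vals[complete, , drop = FALSE]
  corr <- bicor_matrix(vals)
  adj <- adjacency_signed_hybrid(corr, beta = beta)
  tom <- topological_overlap(adj)
  diss <- if (use_tom) 1 - tom else 1 - adj
  labels <- detect_modules(diss, vals, min_module_size = min_module_size,
                           cut_height = cut_height,
                           merge_threshold = merge_threshold)
  eig <- if (any(labels != 0)) eigenproteins(vals, labels) else NULL
  mt <- if (!is.null(eig) && !is.null(traits)) {
    module_trait_correlation(eig, traits)
  } else NULL
  edges <- export_network(adj, weight_cutoff = weight_cutoff, labels = labels)
  structure(list(correlation = corr, adjacency = adj, tom = tom,
                 labels = labels, eigenproteins = eig, module_trait = mt,
                 edges = edges, beta = beta, weight_cutoff = weight_cutoff,
                 n_filtered = n_filtered, n_proteins = sum(complete)),
            class = "conet")
}

#' @export
print.conet <- function(x, ...) {
  cat(sprintf("<conet> %d proteins | beta %g | %d modules | %d edges > %g\n",
              x$n_proteins, x$beta, length(setdiff(unique(x$labels), 0L)),
              nrow(x$edges), x$weight_cutoff))
  invisible(x)
}
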