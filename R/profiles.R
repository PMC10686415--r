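#' Build the matched-pair log2 fold-change profile matrix
#'
#' For every matched pair of runs (one sorted run and the control run of
#' the same animal and region), computes the per-protein normalized
#' log2(sorted/control): the median over shared features of the per-feature
#' log2 ratio (equivalently, the difference of the two runs' feature-centered
#' median abundances). Proteins absent in either run of a pair are missing
#' in that column. Per-run constant offsets cancel in the ratio, so the
#' matrix is invariant to run-level normalization shifts.
#'
#' @param x A [feature_table], normally after [normalize_runs()].
#' @return Object of class `profile_matrix`: list with `values` (proteins x
#'   pairs matrix of log2 fold-changes) and `col_data` (tibble: `pair`,
#'   `animal`, `cell_type`, `region`, `type`, plus `sex`/`age`/`batch` when
#'   annotated).
#' @export
build_profile_matrix <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  runs <- x$runs
  sorted <- dplyr::filter(runs, .data$fraction == "sorted")
  control <- dplyr::filter(runs, .data$fraction == "control")
  key <- function(df) paste(df$animal, df$region, sep = "\r")
  ctrl_by_key <- split(control$run, key(control))
  orphans <- sorted$run[!key(sorted) %in% names(ctrl_by_key)]
  if (length(orphans) > 0) {
    stop_input(sprintf("sorted run(s) without a matched control: %s",
                       paste(orphans, collapse = ", ")))
  }
  multi <- names(ctrl_by_key)[lengths(ctrl_by_key) > 1]
  if (length(multi) > 0) {
    stop_input("more than one control run matches a sorted run; pairing is ambiguous")
  }
  pairs <- sorted %>%
    dplyr::mutate(control_run = unlist(ctrl_by_key[key(sorted)]),
                  pair = .data$animal)

  feats <- x$features
  feats$log2i <- log2(feats$intensity)
  prot <- sort(unique(feats$protein))
  vals <- matrix(NA_real_, length(prot), nrow(pairs),
                 dimnames = list(prot, pairs$pair))
  by_run <- split(feats[c("protein", "feature", "log2i")], feats$run)
  for (j in seq_len(nrow(pairs))) {
    s <- by_run[[pairs$run[j]]]
    c_ <- by_run[[pairs$control_run[j]]]
    if (is.null(s) || is.null(c_)) next
    m <- dplyr::inner_join(s, c_, by = c("protein", "feature"),
                           suffix = c("_s", "_c"))
    if (nrow(m) == 0) next
    ratio <- m$log2i_s - m$log2i_c
    med <- tapply(ratio, m$protein, median)
    vals[names(med), j] <- as.numeric(med)
  }
  col_data <- pairs %>%
    dplyr::mutate(type = paste(.data$region, .data$cell_type, sep = ".")) %>%
    dplyr::select(dplyr::any_of(c("pair", "animal", "cell_type", "region",
                                  "type", "sex", "age", "batch")))
  structure(list(values = vals, col_data = col_data), class = "profile_matrix")
}

#' Construct a profile matrix from values
#'
#' Wraps an existing proteins x columns matrix of matched-pair log2
#' fold-changes (or latent profiles) as a `profile_matrix`, e.g. for
#' feeding ground-truth abundances straight into the network stage.
#'
#' @param values Numeric matrix with protein rownames.
#' @param col_data Tibble with one row per column; must contain `pair`
#'   matching `colnames(values)` (built from them if absent) and ideally
#'   `type`, `cell_type`, `region`.
#' @return A `profile_matrix`.
#' @export
profile_matrix <- function(values, col_data = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (is.null(col_data)) {
    col_data <- tibble::tibble(pair = colnames(values),
                               type = colnames(values))
  }
  col_data <- tibble::as_tibble(col_data)
  if (!"pair" %in% names(col_data)) col_data$pair <- colnames(values)
  stopifnot(nrow(col_data) == ncol(values))
  structure(list(values = values, col_data = col_data),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d proteins x %d columns | %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Average profile columns by synapse type
#'
#' Collapses the per-sample matched-pair matrix to one column per synapse
#' type (cell type x region), averaging over animals with `na.rm = TRUE`.
#'
#' @param pm A `profile_matrix`.
#' @return A `profile_matrix` with one column per type.
#' @export
average_by_type <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  types <- unique(pm$col_data$type)
  vals <- vapply(types, function(tt) {
    cols <- pm$col_data$type == tt
    rowMeans(pm$values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(pm$values)))
  vals[is.nan(vals)] <- NA_real_
  colnames(vals) <- types
  col_data <- pm$col_data %>%
    dplyr::distinct(.data$type, .data$cell_type, .data$region) %>%
    dplyr::mutate(pair = .data$type) %>%
    dplyr::relocate("pair")
  structure(list(values = vals, col_data = col_data), class = "profile_matrix")
}

#' @exportS3Method tibble::as_tibble
as_tibble.profile_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$values, stringsAsFactors = FALSE)) %>%
    setNames(c("protein", "pair", "log2fc")) %>%
    dplyr::left_join(x$col_data, by = "pair")
}

# Impute missing entries by the protein-wise mean, dropping proteins whose
# missing fraction exceeds the threshold. Returns matrix + bookkeeping.
impute_profiles <- function(vals, max_missing_frac = 0.3) {
  frac <- rowMeans(is.na(vals))
  keep <- frac <= max_missing_frac
  vals <- vals[keep, , drop = FALSE]
  n_imputed <- sum(is.na(vals))
  if (n_imputed > 0) {
    rm_ <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm_[idx[, 1]]
  }
  list(values = vals, n_dropped = sum(!keep), n_imputed = n_imputed)
}

#' Principal component analysis of profile columns
#'
#' Samples (columns) are the observations, proteins the variables.
#' Proteins with more than `max_missing_frac` missing values are dropped;
#' remaining gaps are imputed by the protein-wise mean (counts recorded as
#' attributes). Columns are centered per protein, optionally unit-scaled,
#' and decomposed by SVD. Each component's sign is fixed so its
#' largest-magnitude protein loading is positive.
#'
#' @param pm A `profile_matrix`.
#' @param scale Unit-scale protein profiles? Default `FALSE`.
#' @param n_components Components to return; truncated to the rank with a
#'   warning if too many are requested. Default `min(dim)`.
#' @param max_missing_frac Maximum tolerated per-protein missing fraction;
#'   default 0.3.
#' @return Object of class `profile_pca`: `scores` (tibble, one row per
#'   column with annotation), `loadings` (tibble), `var_frac` (numeric,
#'   sums to 1 over the full rank), `sdev`.
#' @export
run_pca <- function(pm, scale = FALSE, n_components = NULL,
                    max_missing_frac = 0.3) {
  stopifnot(inherits(pm, "profile_matrix"))
  imp <- impute_profiles(pm$values, max_missing_frac)
  vals <- imp$values
  constant <- apply(vals, 1, function(r) sd(r) == 0 || !is.finite(sd(r)))
  if (scale) vals <- vals[!constant, , drop = FALSE]
  pc <- prcomp(t(vals), center = TRUE, scale. = scale)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warn(sprintf("requested %d components but rank is %d; truncating",
                 n_components, rank))
    n_components <- rank
  }
  # Deterministic sign: largest |loading| entry positive per component.
  for (k in seq_len(n_components)) {
    l <- pc$rotation[, k]
    if (l[which.max(abs(l))] < 0) {
      pc$rotation[, k] <- -l
      pc$x[, k] <- -pc$x[, k]
    }
  }
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE]) %>%
    dplyr::mutate(pair = rownames(pc$x)) %>%
    dplyr::left_join(pm$col_data, by = "pair") %>%
    dplyr::relocate("pair")
  loadings <- tibble::as_tibble(pc$rotation[, seq_len(n_components), drop = FALSE]) %>%
    dplyr::mutate(protein = rownames(pc$rotation)) %>%
    dplyr::relocate("protein")
  structure(list(scores = scores, loadings = loadings,
                 var_frac = var_frac, sdev = pc$sdev,
                 n_dropped = imp$n_dropped, n_imputed = imp$n_imputed),
            class = "profile_pca")
}

#' @export
print.profile_pca <- function(x, ...) {
  cat(sprintf("<profile_pca> %d components | PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$var_frac), 100 * x$var_frac[1],
              100 * ifelse(length(x$var_frac) > 1, x$var_frac[2], NA)))
  invisible(x)
}

#' Partition per-protein profile variance across covariates
#'
#' For every protein, fits a linear model of its profile on the requested
#' categorical covariates and attributes sums of squares to each covariate
#' by sequential (type-I) decomposition averaged over all covariate
#' orderings — exact and order-free for up to four covariates. Fractions
#' lie in \[0, 1\] and sum to at most 1; the remainder is residual.
#' Covariates aliased with earlier ones (no rank contribution) are flagged
#' with an undefined fraction. The summary compares the per-protein
#' fraction distributions of every covariate pair by a two-sided paired
#' t test.
#'
#' @param pm A `profile_matrix` (per-sample columns).
#' @param covariates Character vector of `col_data` columns; default
#'   `c("cell_type", "region", "sex", "age")` intersected with what is
#'   available and non-constant.
#' @return Object of class `variance_partition`: `fractions` (tibble,
#'   protein x covariate + residual), `summary` (mean fraction per
#'   covariate), `tests` (pairwise t tests), `aliased`.
#' @export
partition_variance <- function(pm, covariates = c("cell_type", "region",
                                                  "sex", "age")) {
  stopifnot(inherits(pm, "profile_matrix"))
  cd <- pm$col_data
  covariates <- covariates[covariates %in% names(cd)]
  usable <- vapply(covariates, function(cv) {
    f <- factor(cd[[cv]])
    nlevels(f) >= 2 && all(table(f) >= 2)
  }, logical(1))
  aliased_pre <- covariates[!usable]
  covariates <- covariates[usable]
  if (length(covariates) == 0) stop_input("no usable covariates (need >= 2 levels with >= 2 columns each)")
  if (length(covariates) > 4) stop_input("at most 4 covariates supported by the exact all-orderings decomposition")

  n <- nrow(cd)
  facs <- lapply(covariates, function(cv) factor(cd[[cv]]))
  names(facs) <- covariates

  perms <- all_permutations(length(covariates))

  # Projection bases for every needed covariate prefix set, computed once
  # and shared across proteins with the same missingness pattern.
  prefix_sets <- unique(unlist(lapply(seq_len(nrow(perms)), function(i) {
    lapply(seq_len(ncol(perms)), function(k) sort(perms[i, seq_len(k)]))
  }), recursive = FALSE))
  set_key <- vapply(prefix_sets, paste, character(1), collapse = ",")

  vals <- pm$values
  pattern <- apply(!is.na(vals), 1, paste, collapse = "")
  out_frac <- matrix(NA_real_, nrow(vals), length(covariates) + 1,
                     dimnames = list(rownames(vals), c(covariates, "residual")))
  aliased_any <- setNames(rep(FALSE, length(covariates)), covariates)

  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    obs <- which(!is.na(vals[rows[1], ]))
    if (length(obs) < length(covariates) + 2) next
    X_of_set <- lapply(prefix_sets, function(ss) {
      mm <- stats::model.matrix(
        stats::reformulate(covariates[ss]),
        data = as.data.frame(lapply(facs, function(f) f[obs])))
      qr_ <- qr(mm)
      list(Q = qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE], rank = qr_$rank)
    })
    names(X_of_set) <- set_key
    Y <- t(vals[rows, obs, drop = FALSE])
    Yc <- sweep(Y, 2, colMeans(Y))
    tot <- colSums(Yc^2)
    fit_ss <- lapply(X_of_set, function(b) colSums((t(b$Q) %*% Y)^2))
    # SS explained beyond the intercept for each covariate prefix set.
    ss0 <- colSums((rep(1 / sqrt(length(obs)), length(obs)) %*% Y)^2)
    expl <- lapply(fit_ss, function(s) s - ss0)

    acc <- matrix(0, length(rows), length(covariates))
    for (i in seq_len(nrow(perms))) {
      prev_key <- NULL
      prev_expl <- 0
      prev_rank <- 1L
      for (k in seq_len(ncol(perms))) {
        ss_now <- sort(perms[i, seq_len(k)])
        keyk <- paste(ss_now, collapse = ",")
        e_now <- expl[[keyk]]
        rank_now <- X_of_set[[keyk]]$rank
        cv <- perms[i, k]
        if (rank_now == prev_rank) aliased_any[covariates[cv]] <- TRUE
        acc[, cv] <- acc[, cv] + (e_now - prev_expl)
        prev_expl <- e_now
        prev_rank <- rank_now
      }
    }
    acc <- acc / nrow(perms)
    frac <- sweep(acc, 1, tot, "/")
    frac[tot <= 0, ] <- NA_real_
    out_frac[rows, seq_len(length(covariates))] <- frac
    out_frac[rows, "residual"] <- 1 - rowSums(frac)
  }
  for (cv in names(aliased_any)) {
    if (aliased_any[cv]) out_frac[, cv] <- NA_real_
  }

  fractions <- tibble::as_tibble(out_frac) %>%
    dplyr::mutate(protein = rownames(vals)) %>%
    dplyr::relocate("protein")
  summary_tb <- tibble::tibble(
    covariate = c(covariates, "residual"),
    mean_fraction = colMeans(out_frac, na.rm = TRUE),
    median_fraction = apply(out_frac, 2, median, na.rm = TRUE))
  tests <- NULL
  if (length(covariates) >= 2) {
    cmb <- combn(covariates, 2)
    tests <- purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
      a <- out_frac[, cmb[1, i]]; b <- out_frac[, cmb[2, i]]
      okp <- is.finite(a) & is.finite(b)
      if (sum(okp) < 3) {
        return(tibble::tibble(covariate_a = cmb[1, i], covariate_b = cmb[2, i],
                              mean_diff = NA_real_, t = NA_real_, p = NA_real_))
      }
      tt <- tryCatch(stats::t.test(a[okp], b[okp], paired = TRUE),
                     error = function(e) NULL)
      if (is.null(tt)) {
        return(tibble::tibble(covariate_a = cmb[1, i], covariate_b = cmb[2, i],
                              mean_diff = mean(a[okp] - b[okp]), t = NA_real_,
                              p = NA_real_))
      }
      tibble::tibble(covariate_a = cmb[1, i], covariate_b = cmb[2, i],
                     mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                     p = tt$p.value)
    })
  }
  structure(list(fractions = fractions, summary = summary_tb, tests = tests,
                 aliased = c(aliased_pre, covariates[aliased_any[covariates]])),
            class = "variance_partition")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
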