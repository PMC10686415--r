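#' Equalize run medians
#'
#' Median normalization on the log2 scale: every run's median log2
#' intensity is shifted to the global median (the median of all observed
#' log2 intensities), removing per-run loading and instrument-response
#' offsets. Missing measurements are untouched.
#'
#' @param x A [feature_table].
#' @return A [feature_table] with normalized intensities.
#' @examples
#' ft <- feature_table(
#'   tibble::tibble(protein = "P1", feature = "f1",
#'                  run = c("r1", "r2"), intensity = c(100, 200)),
#'   tibble::tibble(run = c("r1", "r2"), animal = c("a1", "a1"),
#'                  region = "CX", cell_type = "Camk2a",
#'                  fraction = c("sorted", "control")))
#' normalize_runs(ft)
#' @export
normalize_runs <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  empty <- setdiff(x$runs$run, unique(x$features$run))
  if (length(empty) > 0) {
    stop_input(sprintf("run(s) with zero observed intensities: %s",
                       paste(empty, collapse = ", ")))
  }
  li <- log2(x$features$intensity)
  global_med <- median(li)
  run_med <- tapply(li, x$features$run, median)
  shift <- global_med - run_med[x$features$run]
  x$features$intensity <- 2^(li + as.numeric(shift))
  x
}

#' Testability of a protein for a two-condition comparison
#'
#' A protein is testable when it carries at least `min_features` distinct
#' features (precursor and fragment ions combined) and at least
#' `min_measurements` observed measurements in each compared condition.
#'
#' @param slice Tibble of one protein's records with columns `feature` and
#'   a condition column.
#' @param condition Name of the condition column; default `"fraction"`.
#' @param min_features Minimum distinct features; default 6.
#' @param min_measurements Minimum measurements per condition; default 12.
#' @return One-row tibble: `n_features`, per-condition counts,
#'   `testable`.
#' @export
filter_testability <- function(slice, condition = "fraction",
                               min_features = 6, min_measurements = 12) {
  assert_columns(slice, c("feature", condition), "protein slice")
  counts <- table(slice[[condition]])
  n_feat <- dplyr::n_distinct(slice$feature)
  tibble::tibble(
    n_features = n_feat,
    n_conditions = length(counts),
    min_condition_measurements = if (length(counts)) min(counts) else 0L,
    testable = n_feat >= min_features && length(counts) >= 2 &&
      min(counts) >= min_measurements)
}

# Build the LS-mean parameterization: group cell means plus sum-to-zero
# feature effects, so group coefficients are least-squares means at the
# average feature response.
lsmean_model_matrix <- function(feature, group) {
  gf <- factor(group)
  ff <- factor(feature)
  # Build the group block by hand: single-level factors trip model.matrix's
  # contrast machinery.
  G <- vapply(levels(gf), function(l) as.numeric(gf == l),
              numeric(length(gf)))
  G <- matrix(G, nrow = length(gf),
              dimnames = list(NULL, paste0("g:", levels(gf))))
  if (nlevels(ff) > 1) {
    Fm <- stats::contr.sum(nlevels(ff))[as.integer(ff), , drop = FALSE]
    colnames(Fm) <- paste0("f", seq_len(ncol(Fm)))
    X <- cbind(G, Fm)
  } else {
    X <- G
  }
  attr(X, "groups") <- levels(gf)
  X
}

#' Fit per-protein feature + group models
#'
#' For every protein, fits the fixed-effects two-way model
#' `log2(intensity) ~ feature + group` (no interaction) to its observed
#' feature-level measurements, yielding group least-squares means, a pooled
#' residual variance and residual degrees of freedom
#' `N - (n_features + n_groups - 1)`. With one biological replicate per run
#' and no technical replicates this is the fixed-effects reduction of the
#' usual feature-level mixed model. Features observed in fewer than two
#' runs are dropped (counted per protein); rank-deficient designs fall back
#' to a pivoted fit in which unestimable feature levels are dropped.
#'
#' Proteins sharing an identical observation pattern are solved through one
#' QR decomposition (multi-response least squares), which makes large
#' simulated datasets fast.
#'
#' @param x A [feature_table], normally after [normalize_runs()].
#' @param group Either the name of a run-annotation column, or a named
#'   character vector mapping run id to group label.
#' @param min_features,min_measurements Testability thresholds recorded on
#'   each fit (defaults 6 and 12).
#' @return Object of class `protein_fits`: a tibble with one row per
#'   protein (`protein`, `n_features`, `n_features_dropped`, `n_obs`,
#'   `sigma2`, `df`, `testable`) and list-columns `lsmeans` (named numeric),
#'   `vcov_unscaled` (unscaled covariance of the LS-means) and `n_per_group`.
#' @export
fit_protein_models <- function(x, group = "fraction",
                               min_features = 6, min_measurements = 12) {
  stopifnot(inherits(x, "feature_table"))
  if (is.character(group) && length(group) == 1 && group %in% names(x$runs)) {
    gmap <- setNames(as.character(x$runs[[group]]), x$runs$run)
  } else if (!is.null(names(group))) {
    gmap <- setNames(as.character(group), names(group))
  } else {
    stop_input("group must be a run-annotation column name or a named run->group vector")
  }
  feats <- x$features
  feats$group <- gmap[feats$run]
  if (anyNA(feats$group)) stop_input("some runs have no group assignment")
  feats$log2i <- log2(feats$intensity)

  # Drop features observed in < 2 runs (uninformative for group contrasts).
  feats <- feats %>%
    dplyr::add_count(.data$protein, .data$feature, name = ".n_runs")
  dropped <- feats %>%
    dplyr::filter(.data$.n_runs < 2) %>%
    dplyr::distinct(.data$protein, .data$feature) %>%
    dplyr::count(.data$protein, name = "n_features_dropped")
  feats_all <- feats %>% dplyr::distinct(.data$protein, .data$feature) %>%
    dplyr::count(.data$protein, name = "n_features_total")
  feats <- dplyr::filter(feats, .data$.n_runs >= 2)

  split_idx <- split(seq_len(nrow(feats)), feats$protein)
  all_groups <- sort(unique(feats$group))

  # Group proteins by identical (feature-rank x run x group) pattern so one
  # QR serves many proteins.
  pattern_of <- vapply(split_idx, function(ix) {
    f <- feats$feature[ix]
    fr <- match(f, unique(f))
    paste(paste0(fr, "|", feats$run[ix], "|", feats$group[ix]), collapse = ";")
  }, character(1))

  out <- vector("list", length(split_idx))
  names(out) <- names(split_idx)
  for (pat in unique(pattern_of)) {
    prots <- names(split_idx)[pattern_of == pat]
    ix1 <- split_idx[[prots[1]]]
    X <- lsmean_model_matrix(match(feats$feature[ix1], unique(feats$feature[ix1])),
                             feats$group[ix1])
    grps <- attr(X, "groups")
    qrX <- qr(X)
    rank_ok <- qrX$rank == ncol(X)
    Y <- vapply(prots, function(p) feats$log2i[split_idx[[p]]],
                numeric(length(ix1)))
    Y <- matrix(Y, nrow = length(ix1))
    if (rank_ok) {
      coefs <- qr.coef(qrX, Y)
      res <- Y - X %*% coefs
      dfres <- nrow(X) - ncol(X)
      # qr.R columns are pivoted; undo the pivot before indexing group columns.
      piv <- qrX$pivot
      XtXinv <- chol2inv(qr.R(qrX))
      unpiv <- matrix(0, ncol(X), ncol(X))
      unpiv[piv, piv] <- XtXinv
      gi <- match(paste0("g:", grps), colnames(X))
      Vg <- unpiv[gi, gi, drop = FALSE]
      dimnames(Vg) <- list(grps, grps)
      for (k in seq_along(prots)) {
        rss <- sum(res[, k]^2)
        sigma2 <- if (dfres > 0) rss / dfres else NA_real_
        lsm <- setNames(coefs[gi, k], grps)
        out[[prots[k]]] <- list(lsmeans = lsm, vcov_unscaled = Vg,
                                sigma2 = sigma2, df = dfres,
                                n_obs = nrow(X),
                                groups_present = grps,
                                n_per_group = table(feats$group[ix1]))
      }
    } else {
      for (p in prots) {
        out[[p]] <- fit_protein_single(feats[split_idx[[p]], ])
      }
    }
  }

  res <- tibble::tibble(
    protein = names(out),
    n_obs = unname(vapply(out, function(o) o$n_obs, numeric(1))),
    sigma2 = unname(vapply(out, function(o) o$sigma2, numeric(1))),
    df = unname(vapply(out, function(o) o$df, numeric(1))),
    lsmeans = lapply(out, function(o) o$lsmeans),
    vcov_unscaled = lapply(out, function(o) o$vcov_unscaled),
    n_per_group = lapply(out, function(o) o$n_per_group))
  res <- res %>%
    dplyr::left_join(feats_all, by = "protein") %>%
    dplyr::left_join(dropped, by = "protein") %>%
    dplyr::mutate(
      n_features_dropped = dplyr::coalesce(.data$n_features_dropped, 0L),
      n_features = .data$n_features_total - .data$n_features_dropped) %>%
    dplyr::select(-"n_features_total")
  res$testable <- res$n_features >= min_features & res$df >= 1 &
    is.finite(res$sigma2) & res$sigma2 > 0 &
    vapply(res$n_per_group, function(np) {
      length(np) >= 2 && min(np) >= min_measurements
    }, logical(1))
  structure(res, class = c("protein_fits", class(res)),
            groups = all_groups,
            min_features = min_features, min_measurements = min_measurements)
}

# Rank-deficient fallback: drop unestimable feature levels via a pivoted
# lm fit, keeping whatever group means remain estimable.
fit_protein_single <- function(slice) {
  ff <- factor(match(slice$feature, unique(slice$feature)))
  gf <- factor(slice$group)
  X <- lsmean_model_matrix(ff, gf)
  grps <- attr(X, "groups")
  fit <- stats::lm.fit(X, slice$log2i)
  keep <- !is.na(fit$coefficients)
  Xk <- X[, keep, drop = FALSE]
  qrk <- qr(Xk)
  coefs <- qr.coef(qrk, slice$log2i)
  resid <- slice$log2i - Xk %*% coefs
  dfres <- nrow(Xk) - qrk$rank
  sigma2 <- if (dfres > 0) sum(resid^2) / dfres else NA_real_
  XtXinv <- chol2inv(qr.R(qrk))
  unpiv <- matrix(NA_real_, ncol(Xk), ncol(Xk))
  piv <- qrk$pivot
  unpiv[piv, piv] <- XtXinv
  gi <- match(paste0("g:", grps), colnames(Xk))
  est <- !is.na(gi)
  lsm <- setNames(rep(NA_real_, length(grps)), grps)
  lsm[est] <- coefs[gi[est]]
  Vg <- matrix(NA_real_, length(grps), length(grps), dimnames = list(grps, grps))
  Vg[est, est] <- unpiv[gi[est], gi[est]]
  list(lsmeans = lsm, vcov_unscaled = Vg, sigma2 = sigma2, df = dfres,
       n_obs = nrow(slice), groups_present = grps[est],
       n_per_group = table(slice$group))
}

#' Contrast testing on fitted protein models
#'
#' Computes `log2FC = sum(weights * lsmeans)` for a zero-sum contrast over
#' the fitted groups, its standard error from the pooled residual variance
#' and the design, and a two-sided p value from the t distribution with the
#' fit's residual degrees of freedom. A zero statistic with positive
#' variance reports p = 1.
#'
#' @param fits A `protein_fits` object.
#' @param contrast Named numeric vector of group weights summing to zero,
#'   e.g. `c(sorted = 1, control = -1)`.
#' @param label Contrast label recorded in the result; default built from
#'   the weights.
#' @return Tibble (one row per protein): `protein`, `contrast`, `log2fc`,
#'   `se`, `df`, `t`, `p`, `testable`.
#' @export
compare_groups <- function(fits, contrast, label = NULL) {
  stopifnot(inherits(fits, "protein_fits"))
  if (abs(sum(contrast)) > 1e-12) stop_input("contrast weights must sum to 0")
  groups <- attr(fits, "groups")
  missing_g <- setdiff(names(contrast), groups)
  if (length(missing_g) > 0) {
    stop_input(sprintf("contrast references group(s) absent from the fit: %s",
                       paste(missing_g, collapse = ", ")))
  }
  if (is.null(label)) {
    pos <- names(contrast)[contrast > 0]
    neg <- names(contrast)[contrast < 0]
    label <- paste(paste(pos, collapse = "+"), "vs", paste(neg, collapse = "+"))
  }
  w <- contrast[abs(contrast) > 0]
  min_meas <- attr(fits, "min_measurements")
  n <- nrow(fits)
  log2fc <- se <- tt <- p <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    lsm <- fits$lsmeans[[i]]
    if (!all(names(w) %in% names(lsm)) || anyNA(lsm[names(w)])) next
    V <- fits$vcov_unscaled[[i]][names(w), names(w), drop = FALSE]
    if (anyNA(V)) next
    est <- sum(w * lsm[names(w)])
    log2fc[i] <- est
    np <- fits$n_per_group[[i]]
    enough <- all(names(w) %in% names(np)) && all(np[names(w)] >= min_meas)
    ok[i] <- fits$testable[i] && enough
    if (is.finite(fits$sigma2[i]) && fits$sigma2[i] > 0 && fits$df[i] >= 1) {
      se_i <- sqrt(fits$sigma2[i] * as.numeric(t(w) %*% V %*% w))
      se[i] <- se_i
      tt[i] <- est / se_i
      p[i] <- 2 * pt(-abs(tt[i]), fits$df[i])
    }
  }
  tibble::tibble(protein = fits$protein, contrast = label, log2fc = log2fc,
                 se = se, df = fits$df, t = tt, p = p,
                 testable = ok & !is.na(p))
}

#' Benjamini-Hochberg with a fold-change gate, and significance calls
#'
#' Applies Benjamini-Hochberg adjustment to the p values of the proteins
#' whose absolute fold-change exceeds the cutoff (`|log2FC| > log2(fc_cutoff)`,
#' strict); proteins outside the gate get no adjusted p and cannot be
#' called. Calls: `enriched` when gated, adjusted p < alpha and log2FC > 0;
#' `de-enriched` symmetric; `not testable` for untestable fits; otherwise
#' `not significant`. `bh_scope = "all"` gives the conventional
#' all-protein adjustment instead.
#'
#' @param results Contrast results from [compare_groups()] (one contrast;
#'   multiple contrasts are adjusted within contrast).
#' @param fc_cutoff Linear fold-change cutoff; default 1.1.
#' @param alpha Adjusted-p threshold; default 0.05.
#' @param bh_scope `"fc_gated"` (default) or `"all"`.
#' @return The input tibble with `adj_p` and `call` columns.
#' @export
adjust_and_call <- function(results, fc_cutoff = 1.1, alpha = 0.05,
                            bh_scope = c("fc_gated", "all")) {
  bh_scope <- match.arg(bh_scope)
  assert_columns(results, c("protein", "contrast", "log2fc", "p", "testable"),
                 "results")
  results %>%
    dplyr::group_by(.data$contrast) %>%
    dplyr::group_modify(function(df, key) {
      gate <- df$testable & !is.na(df$p) &
        (if (bh_scope == "fc_gated") abs(df$log2fc) > log2(fc_cutoff) else TRUE)
      adj <- rep(NA_real_, nrow(df))
      if (any(gate)) adj[gate] <- p.adjust(df$p[gate], method = "BH")
      call <- dplyr::case_when(
        !df$testable ~ "not testable",
        gate & !is.na(adj) & adj < alpha & df$log2fc > 0 &
          abs(df$log2fc) > log2(fc_cutoff) ~ "enriched",
        gate & !is.na(adj) & adj < alpha & df$log2fc < 0 &
          abs(df$log2fc) > log2(fc_cutoff) ~ "de-enriched",
        TRUE ~ "not significant")
      df$adj_p <- adj
      df$call <- call
      df
    }) %>%
    dplyr::ungroup() %>%
    dplyr::relocate("protein")
}
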