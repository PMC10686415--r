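#' Run the membership workflow on simulated data and score recovery
#'
#' Simulates (or accepts) a paired sorting experiment, runs normalization,
#' per-region model fitting, sorted-vs-control calling and membership
#' calling for every synapse type, and scores the calls against the
#' noise-free expected mixtures:
#'
#' * **sensitivity** — fraction of *testable* proteins with expected
#'   sorted/control fold-change at least `enriched_margin` that are called
#'   enriched. Conditioning on testability separates the calling
#'   procedure's performance from the feature-count lottery (proteins
#'   drawn with fewer than the minimum number of features can never be
#'   called, by design of the filter).
#' * **precision** — one minus the share of called proteins whose expected
#'   fold-change is at most `null_margin` (truly non-enriched). Proteins in
#'   the indeterminate band between the margins count for neither.
#'
#' @param truth A `ground_truth`.
#' @param scenario A `sorting_scenario`.
#' @param ft Optional pre-simulated [feature_table] (skips simulation).
#' @param fc_cutoff,alpha,min_features,min_measurements Calling settings.
#' @param enriched_margin Expected log2FC above which a protein counts as
#'   planted-enriched; default `log2(1.5)`.
#' @param null_margin Expected log2FC at or below which a protein counts
#'   as truly non-enriched; default 0.
#' @return One-row tibble: `sensitivity`, `precision`, `n_truly_enriched`,
#'   `n_called`, plus the full `calls` tibble as an attribute.
#' @export
membership_recovery <- function(truth, scenario, ft = NULL,
                                fc_cutoff = 1.1, alpha = 0.05,
                                min_features = 6, min_measurements = 12,
                                enriched_margin = log2(1.5),
                                null_margin = 0) {
  if (is.null(ft)) ft <- simulate_experiment(truth, scenario)
  ft <- normalize_runs(ft)
  mix <- expected_mixtures(truth, scenario)
  runs <- ft$runs
  runs$type <- paste(runs$region, runs$cell_type, sep = ".")
  sens_n <- sens_d <- fp <- n_called <- 0
  all_calls <- list()
  for (rg in unique(runs$region)) {
    rr <- runs[runs$region == rg, ]
    gmap <- setNames(ifelse(rr$fraction == "sorted", rr$type,
                            paste0(rg, ".P2")), rr$run)
    sub <- structure(list(
      features = dplyr::filter(ft$features, .data$run %in% rr$run),
      runs = rr), class = "feature_table")
    fits <- fit_protein_models(sub, group = gmap,
                               min_features = min_features,
                               min_measurements = min_measurements)
    for (tt in sort(unique(rr$type[rr$fraction == "sorted"]))) {
      res <- compare_groups(fits, setNames(c(1, -1), c(tt, paste0(rg, ".P2")))) %>%
        adjust_and_call(fc_cutoff = fc_cutoff, alpha = alpha)
      calls <- call_proteome(res, type = tt)
      all_calls[[tt]] <- calls
      efc <- mix$log2fc[, tt]
      testable <- res$protein[res$testable]
      truly <- intersect(names(efc)[efc >= enriched_margin], testable)
      nontrue <- names(efc)[efc <= null_margin]
      called <- calls$protein[calls$status == "enriched"]
      sens_n <- sens_n + length(intersect(called, truly))
      sens_d <- sens_d + length(truly)
      fp <- fp + length(intersect(called, nontrue))
      n_called <- n_called + length(called)
    }
  }
  out <- tibble::tibble(sensitivity = sens_n / sens_d,
                        precision = 1 - fp / n_called,
                        n_truly_enriched = sens_d, n_called = n_called)
  attr(out, "calls") <- dplyr::bind_rows(all_calls)
  out
}

#' Calibration and power of the enrichment-calling procedure
#'
#' `enrichment_calibration()` simulates independent null two-group
#' contrasts (no planted enrichment) and reports the realized false-call
#' fraction among tested, fold-change-passing proteins.
#' `enrichment_power()` plants a fold-change and reports the fraction of
#' planted proteins called enriched.
#'
#' @param n_contrasts Independent null contrasts to simulate; default 200.
#' @param n_proteins Proteins per contrast; default 1000.
#' @param n_per_group Runs per group; default 5.
#' @param n_features Features per protein; default 6.
#' @param replicate_cv Replicate CV; default 0.2.
#' @param fc_cutoff,alpha Calling settings.
#' @param seed Master seed (one per-contrast seed is derived per contrast).
#' @return `enrichment_calibration()`: one-row tibble `false_call_fraction`,
#'   `n_fc_passing`, `n_false_calls`, `binomial_se`.
#' @export
enrichment_calibration <- function(n_contrasts = 200, n_proteins = 1000,
                                   n_per_group = 5, n_features = 6,
                                   replicate_cv = 0.2, fc_cutoff = 1.1,
                                   alpha = 0.05, seed) {
  if (missing(seed)) stop_input("enrichment_calibration() requires a seed")
  n_pass <- n_false <- 0
  for (b in seq_len(n_contrasts)) {
    ft <- simulate_two_group(n_proteins = n_proteins, n_enriched = 0,
                             n_per_group = n_per_group,
                             n_features = n_features,
                             replicate_cv = replicate_cv,
                             seed = derive_seed(seed, b))
    fits <- fit_protein_models(ft, group = "cell_type")
    called <- adjust_and_call(compare_groups(fits, c(G1 = 1, G2 = -1)),
                              fc_cutoff = fc_cutoff, alpha = alpha)
    gated <- called$testable & !is.na(called$adj_p)
    n_pass <- n_pass + sum(gated)
    n_false <- n_false + sum(called$call %in% c("enriched", "de-enriched"))
  }
  tibble::tibble(false_call_fraction = n_false / n_pass,
                 n_fc_passing = n_pass, n_false_calls = n_false,
                 binomial_se = sqrt(alpha * (1 - alpha) / n_pass))
}

#' @rdname enrichment_calibration
#' @param n_enriched Planted enriched proteins; default 200.
#' @param log2fc Planted effect; default 1 (2-fold).
#' @export
enrichment_power <- function(n_proteins = 1000, n_enriched = 200, log2fc = 1,
                             n_per_group = 5, n_features = 6,
                             replicate_cv = 0.2, fc_cutoff = 1.1,
                             alpha = 0.05, seed) {
  if (missing(seed)) stop_input("enrichment_power() requires a seed")
  ft <- simulate_two_group(n_proteins = n_proteins, n_enriched = n_enriched,
                           log2fc = log2fc, n_per_group = n_per_group,
                           n_features = n_features,
                           replicate_cv = replicate_cv, seed = seed)
  fits <- fit_protein_models(ft, group = "cell_type")
  called <- adjust_and_call(compare_groups(fits, c(G1 = 1, G2 = -1)),
                            fc_cutoff = fc_cutoff, alpha = alpha)
  planted <- sprintf("P%05d", seq_len(n_enriched))
  tibble::tibble(
    sensitivity = mean(called$call[match(planted, called$protein)] == "enriched"),
    n_planted = n_enriched)
}
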