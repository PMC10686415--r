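small_truth <- function(seed = 1, ...) {
  args <- list(n_proteins = 120, n_modules = 3, module_size = 15,
               complex_spec = list(n_complexes = 2, size = 3),
               pair_spec = list(n_pairs = 3, loading = 0.95),
               marker_spec = list(n_per_type = 2, amplitude = 2),
               seed = seed)
  do.call(ground_truth, utils::modifyList(args, list(...), keep.null = TRUE))
}

test_that("ground truth satisfies its structural invariants", {
  gt <- small_truth()
  expect_false(anyNA(gt$true_abundance))
  expect_true(all(gt$proteins$module %in% 0:3))
  expect_equal(nrow(gt$proteins), 120)
  # complexes are subsets of single modules
  mods <- gt$proteins$module[match(gt$complexes$protein, gt$proteins$protein)]
  per_cpx <- tapply(mods, gt$complexes$complex_id, function(m) length(unique(m)))
  expect_true(all(per_cpx == 1))
  # planted negative pairs anti-correlate by construction
  for (i in seq_len(nrow(gt$negative_pairs))) {
    r <- cor(gt$true_abundance[gt$negative_pairs$protein_a[i], ],
             gt$true_abundance[gt$negative_pairs$protein_b[i], ])
    expect_lte(r, -0.8)
  }
  expect_error(ground_truth(n_proteins = 10, n_modules = 2, module_size = 20,
                            seed = 1),
               "configuration error")
})

test_that("degenerate noise settings give exact planted correlations", {
  gt <- small_truth(member_loading = 1, n_modules = 1, module_size = 20,
                    pair_spec = NULL, complex_spec = NULL, marker_spec = NULL)
  members <- gt$proteins$protein[gt$proteins$module == 1]
  cm <- cor(t(gt$true_abundance[members, ]))
  expect_equal(unname(cm), matrix(1, 20, 20), tolerance = 1e-12)

  gt2 <- small_truth(pair_spec = list(n_pairs = 2, loading = 1),
                     complex_spec = NULL, marker_spec = NULL)
  for (i in 1:2) {
    r <- cor(gt2$true_abundance[gt2$negative_pairs$protein_a[i], ],
             gt2$true_abundance[gt2$negative_pairs$protein_b[i], ])
    expect_equal(r, -1, tolerance = 1e-12)
  }
})

test_that("within-module correlation exceeds between-module correlation", {
  gt <- ground_truth(seed = 7)  # full defaults: 15 types, 14 modules
  ab <- gt$true_abundance
  lab <- gt$proteins$module
  cm <- cor(t(ab[lab > 0, ]))
  ll <- lab[lab > 0]
  same <- outer(ll, ll, "==") & upper.tri(cm)
  diff <- outer(ll, ll, "!=") & upper.tri(cm)
  expect_gt(mean(abs(cm[same])), mean(abs(cm[diff])))
})

test_that("mixture limits are exact at extreme purity with noise disabled", {
  gt <- small_truth()
  for (p in c(1, 0)) {
    sc <- sorting_scenario(purity = p, seed = 2)
    mix <- expected_mixtures(gt, sc)
    tt <- gt$types$type[1]
    if (p == 1) {
      expect_equal(log2(mix$sorted[, tt]), gt$true_abundance[, tt],
                   tolerance = 1e-12)
    } else {
      # purity 0: the sorted run is exactly the background mixture
      region <- gt$types$region[1]
      others <- gt$types$type[gt$types$region == region & gt$types$type != tt]
      w <- mix$prevalence[others] / sum(mix$prevalence[others])
      bg <- 0.9 * as.numeric(2^gt$true_abundance[, others] %*% w) +
        0.1 * mix$contaminant
      expect_equal(unname(mix$sorted[, tt]), bg, tolerance = 1e-12)
    }
  }
})

test_that("expected sorted/control ratio is monotone in purity for enriched proteins", {
  gt <- small_truth()
  tt <- gt$types$type[1]
  grid <- seq(0.2, 1, by = 0.2)
  fc <- sapply(grid, function(p) {
    expected_mixtures(gt, sorting_scenario(purity = p, seed = 2))$log2fc[, tt]
  })
  # proteins genuinely enriched in the target type: target latent abundance
  # above the sorted-run background (= the purity-0 sorted mixture)
  bg <- expected_mixtures(gt, sorting_scenario(purity = 0, seed = 2))$sorted[, tt]
  enriched0 <- 2^gt$true_abundance[, tt] > bg
  deltas <- t(apply(fc[enriched0, ], 1, diff))
  expect_true(all(deltas > -1e-9))
})

test_that("realized replicate CV matches the scenario target", {
  ft <- simulate_two_group(n_proteins = 3000, n_per_group = 8,
                           n_features = 8, replicate_cv = 0.2, seed = 5)
  totals <- as_tibble(ft) %>%
    dplyr::group_by(.data$protein, .data$run, .data$fraction) %>%
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")
  cvs <- totals %>%
    dplyr::group_by(.data$protein, .data$fraction) %>%
    dplyr::summarise(cv = sd(.data$total) / mean(.data$total), .groups = "drop")
  expect_gt(median(cvs$cv), 0.18)
  expect_lt(median(cvs$cv), 0.22)
})

test_that("dropout is non-increasing in latent log intensity", {
  gt <- small_truth()
  sc <- sorting_scenario(n_animals = 4,
                         missingness = list(midpoint = 19, slope = 1),
                         seed = 3)
  ft <- simulate_experiment(gt, sc)
  # expected measurements per protein in sorted runs vs observed
  mix <- expected_mixtures(gt, sc)
  obs <- ft$features %>%
    dplyr::count(.data$protein, name = "n_obs")
  lat <- tibble::tibble(protein = rownames(mix$sorted),
                        latent = gt$proteins$baseline)
  m <- dplyr::left_join(lat, obs, by = "protein") %>%
    dplyr::mutate(n_obs = dplyr::coalesce(.data$n_obs, 0L),
                  bin = cut(.data$latent, quantile(.data$latent, 0:4 / 4),
                            include.lowest = TRUE))
  # observed record counts rise with latent abundance (missingness falls)
  byb <- m %>% dplyr::group_by(.data$bin) %>%
    dplyr::summarise(mean_obs = mean(.data$n_obs), .groups = "drop")
  expect_true(all(diff(byb$mean_obs) > 0))
})

test_that("generation and simulation are deterministic in their seeds", {
  gt1 <- small_truth(seed = 11)
  gt2 <- small_truth(seed = 11)
  expect_identical(gt1$true_abundance, gt2$true_abundance)
  sc <- sorting_scenario(n_animals = 2, seed = 12)
  ft1 <- simulate_experiment(gt1, sc)
  ft2 <- simulate_experiment(gt2, sc)
  expect_identical(ft1$features, ft2$features)
  expect_false(identical(
    simulate_experiment(gt1, sorting_scenario(n_animals = 2, seed = 13))$features,
    ft1$features))
})

test_that("truth bundles round-trip losslessly", {
  gt <- small_truth(seed = 4)
  sc <- sorting_scenario(n_animals = 3, seed = 5)
  dir <- withr::local_tempdir()
  write_truth_bundle(gt, sc, dir, overwrite = TRUE)
  expect_error(write_truth_bundle(gt, sc, dir), "overwrite")
  back <- read_truth_bundle(dir)
  expect_equal(back$truth$true_abundance, gt$true_abundance)
  expect_equal(back$truth$complexes, gt$complexes)
  expect_equal(back$truth$negative_pairs, gt$negative_pairs)
  expect_equal(back$truth$traits, gt$traits)
  expect_equal(back$scenario$purity, sc$purity, tolerance = 1e-12)
  expect_equal(back$scenario$seed, sc$seed)

  # empty complex spec -> header-only complexes file
  gt0 <- small_truth(seed = 6, complex_spec = NULL)
  dir0 <- withr::local_tempdir()
  write_truth_bundle(gt0, NULL, dir0, overwrite = TRUE)
  lines <- readLines(file.path(dir0, "complexes.tsv"))
  expect_length(lines, 1)
  expect_match(lines, "complex_id")
})
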