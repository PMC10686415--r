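test_that("normalization equalizes run medians and removes constant offsets", {
  runs <- make_runs(c("r1", "r2"), "G1", c("sorted", "control"))
  m <- matrix(c(10, 12, 14, 11, 13, 15), nrow = 3,
              dimnames = list(paste0("f", 1:3), c("r1", "r2")))
  ft <- ft_from_log2(m, runs)
  norm <- normalize_runs(ft)
  li <- log2(norm$features$intensity)
  meds <- tapply(li, norm$features$run, median)
  expect_equal(unname(diff(meds)), 0, tolerance = 1e-12)
  # the +1 offset between the two runs is removed exactly
  by_feat <- tidyr::pivot_wider(
    dplyr::mutate(norm$features, log2i = log2(.data$intensity)),
    id_cols = "feature", names_from = "run", values_from = "log2i")
  expect_equal(by_feat$r1, by_feat$r2, tolerance = 1e-12)

  # random table: all run medians equal the global median after normalization
  ft2 <- simulate_two_group(n_proteins = 30, n_per_group = 3, n_features = 4,
                            seed = 2)
  n2 <- normalize_runs(ft2)
  li2 <- log2(n2$features$intensity)
  meds2 <- tapply(li2, n2$features$run, median)
  expect_true(all(abs(meds2 - median(li2)) < 1e-9))

  # run annotated but without observations is an error naming the run
  ft3 <- ft2
  ft3$features <- dplyr::filter(ft3$features, .data$run != "G1_r1")
  expect_error(normalize_runs(ft3), "G1_r1")
})

test_that("single-run tables are unchanged up to the median convention", {
  runs <- make_runs("r1", "G1", "sorted")
  m <- matrix(c(10, 12, 14), nrow = 3,
              dimnames = list(paste0("f", 1:3), "r1"))
  norm <- normalize_runs(ft_from_log2(m, runs))
  expect_equal(sort(log2(norm$features$intensity)), c(10, 12, 14),
               tolerance = 1e-12)
})

test_that("testability needs 6 features and 12 measurements per condition", {
  slice <- function(n_feat, n1, n2) {
    tibble::tibble(
      feature = c(rep(paste0("f", seq_len(n_feat)), length.out = n1),
                  rep(paste0("f", seq_len(n_feat)), length.out = n2)),
      fraction = c(rep("sorted", n1), rep("control", n2)))
  }
  expect_true(filter_testability(slice(6, 12, 12))$testable)
  expect_false(filter_testability(slice(5, 24, 24))$testable)
  expect_false(filter_testability(slice(6, 12, 11))$testable)
})

test_that("noiseless fits are exact and flagged untestable at zero variance", {
  runs <- make_runs(paste0("r", 1:4), c("G1", "G1", "G2", "G2"),
                    c("sorted", "sorted", "control", "control"))
  m <- matrix(c(10, 12, 10, 12, 9, 11, 9, 11), nrow = 2,
              dimnames = list(c("fA", "fB"), paste0("r", 1:4)))
  fits <- fit_protein_models(ft_from_log2(m, runs), group = "cell_type",
                             min_features = 1, min_measurements = 2)
  expect_equal(unname(diff(rev(fits$lsmeans[[1]]))), 1, tolerance = 1e-12)
  expect_equal(fits$sigma2[[1]], 0, tolerance = 1e-12)
  expect_false(fits$testable[1])
})

test_that("balanced-design LS-mean difference matches the normal-equations oracle", {
  withr::local_seed(42)
  for (rep in 1:5) {
    n_feat <- sample(3:6, 1)
    n_run <- 4
    runs <- make_runs(paste0("r", 1:(2 * n_run)),
                      rep(c("G1", "G2"), each = n_run),
                      rep(c("sorted", "control"), each = n_run))
    m <- matrix(rnorm(n_feat * 2 * n_run, 20, 1), nrow = n_feat,
                dimnames = list(paste0("f", 1:n_feat), runs$run))
    ft <- ft_from_log2(m, runs)
    fits <- fit_protein_models(ft, group = "cell_type",
                               min_features = 1, min_measurements = 2)
    long <- as_tibble(ft)
    oracle <- lsdiff_oracle(long$feature, long$cell_type,
                            log2(long$intensity))
    got <- fits$lsmeans[[1]][["G1"]] - fits$lsmeans[[1]][["G2"]]
    expect_equal(got, unname(oracle), tolerance = 1e-10)
    # and equals the difference of simple group means of feature-centered values
    centered <- long %>%
      dplyr::group_by(.data$feature) %>%
      dplyr::mutate(c = log2(.data$intensity) - mean(log2(.data$intensity))) %>%
      dplyr::ungroup()
    simple <- with(centered, mean(c[cell_type == "G1"]) - mean(c[cell_type == "G2"]))
    expect_equal(got, simple, tolerance = 1e-10)
  }
})

test_that("fits recover a planted unit difference within 3 SE under noise", {
  withr::local_seed(7)
  runs <- make_runs(paste0("r", 1:12), rep(c("G1", "G2"), each = 6),
                    rep(c("sorted", "control"), each = 6))
  base <- matrix(rep(c(10, 12, 11, 13, 9, 10), 12), nrow = 6)
  base[, 1:6] <- base[, 1:6] + 1
  m <- base + rnorm(length(base), 0, 0.1)
  dimnames(m) <- list(paste0("f", 1:6), runs$run)
  fits <- fit_protein_models(ft_from_log2(m, runs), group = "cell_type")
  res <- compare_groups(fits, c(G1 = 1, G2 = -1))
  expect_true(res$testable[1])
  expect_lt(abs(res$log2fc[1] - 1), 3 * res$se[1])
  expect_equal(res$df[1], 12 * 6 - (6 + 2 - 1))
})

test_that("contrasts compute estimates, exact zeros and t-distribution p values", {
  # identical groups with positive residual variance: log2FC 0, p 1
  runs <- make_runs(paste0("r", 1:4), c("G1", "G1", "G2", "G2"),
                    c("sorted", "sorted", "control", "control"))
  m <- matrix(c(10, 12, 11, 11, 10, 12, 11, 11), nrow = 2,
              dimnames = list(c("fA", "fB"), paste0("r", 1:4)))
  fits <- fit_protein_models(ft_from_log2(m, runs), group = "cell_type",
                             min_features = 1, min_measurements = 2)
  res <- compare_groups(fits, c(G1 = 1, G2 = -1))
  expect_equal(res$log2fc[1], 0, tolerance = 1e-12)
  expect_gt(fits$sigma2[1], 0)
  expect_equal(res$p[1], 1)

  # contrast on LS-means (10, 9) gives exactly 1
  expect_equal(sum(c(1, -1) * c(10, 9)), 1)

  # p values come from the t distribution with the residual df
  expect_equal(2 * pt(-2.704, 13), 0.018, tolerance = 1e-2)
  ok <- !is.na(res$p)
  expect_equal(res$p[ok], 2 * pt(-abs(res$t[ok]), res$df[ok]))

  expect_error(compare_groups(fits, c(G1 = 1, G9 = -1)), "absent")
  expect_error(compare_groups(fits, c(G1 = 1, G2 = -0.5)), "sum to 0")
})

test_that("fold-change-gated BH matches the step-up oracle and gates calls", {
  res <- tibble::tibble(
    protein = paste0("P", 1:5), contrast = "A vs B",
    log2fc = c(0.5, -0.4, 0.3, 0.6, 0.10), se = 0.1, df = 10,
    t = 5, p = c(0.01, 0.02, 0.03, 0.04, 1e-9), testable = TRUE)
  out <- adjust_and_call(res)
  # the log2FC = 0.10 protein sits below log2(1.1) ~ 0.1375: no adjusted p,
  # never called despite p = 1e-9
  expect_true(is.na(out$adj_p[out$protein == "P5"]))
  expect_equal(out$call[out$protein == "P5"], "not significant")
  gated <- out[out$protein != "P5", ]
  expect_equal(sort(gated$adj_p), rep(0.04, 4), tolerance = 1e-12)
  expect_equal(gated$adj_p, bh_oracle(gated$p))
  expect_setequal(gated$call[gated$log2fc > 0], "enriched")
  expect_equal(gated$call[gated$log2fc < 0], "de-enriched")

  # single FC-passing protein keeps its raw p
  one <- adjust_and_call(res[c(1, 5), ])
  expect_equal(one$adj_p[one$protein == "P1"], 0.01)

  # empty FC-passing set: everything not significant
  none <- adjust_and_call(dplyr::mutate(res, log2fc = 0.01))
  expect_true(all(none$call == "not significant"))

  # all-protein scope is available behind the flag
  allbh <- adjust_and_call(res, bh_scope = "all")
  expect_equal(allbh$adj_p, bh_oracle(res$p))
})

test_that("gated BH equals the brute-force step-up on random p-vectors", {
  withr::local_seed(99)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    res <- tibble::tibble(protein = paste0("P", seq_len(m)), contrast = "c",
                          log2fc = runif(m, -1, 1), se = 0.1, df = 5, t = 1,
                          p = p, testable = TRUE)
    out <- adjust_and_call(res)
    gate <- abs(res$log2fc) > log2(1.1)
    expect_equal(out$adj_p[gate], bh_oracle(p[gate]))
    expect_true(all(is.na(out$adj_p[!gate])))
  }
})

test_that("results are invariant to per-run constant shifts", {
  ft <- simulate_two_group(n_proteins = 40, n_per_group = 3, n_features = 6,
                           seed = 31)
  shifted <- ft
  pick <- shifted$features$run == "G1_r2"
  shifted$features$intensity[pick] <- shifted$features$intensity[pick] * 2^1.7
  r1 <- compare_groups(fit_protein_models(normalize_runs(ft), "cell_type"),
                       c(G1 = 1, G2 = -1))
  r2 <- compare_groups(fit_protein_models(normalize_runs(shifted), "cell_type"),
                       c(G1 = 1, G2 = -1))
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})
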