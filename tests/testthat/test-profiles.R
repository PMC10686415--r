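two_pair_table <- function(sorted_shift = 0) {
  runs <- tibble::tibble(
    run = c("s1", "c1", "s2", "c2"),
    animal = c("a1", "a1", "a2", "a2"),
    region = "CX", cell_type = "Camk2a",
    fraction = c("sorted", "control", "sorted", "control"))
  m <- matrix(c(10, 12, 10, 12, 10.5, 12.5, 10.5, 12.5), nrow = 2,
              dimnames = list(c("f1", "f2"), runs$run))
  m[, c("s1", "s2")] <- m[, c("s1", "s2")] + sorted_shift
  ft_from_log2(m, runs)
}

test_that("matched-pair values are exact log2 ratios", {
  # sorted identical to control: all zero
  pm0 <- build_profile_matrix(two_pair_table(0))
  expect_equal(unname(pm0$values), matrix(0, 1, 2), tolerance = 1e-12)
  # sorted 2x higher on every feature: exactly 1
  pm1 <- build_profile_matrix(two_pair_table(1))
  expect_equal(unname(pm1$values), matrix(1, 1, 2), tolerance = 1e-12)
})

test_that("orphan sorted runs are reported by name", {
  ft <- two_pair_table()
  ft$runs <- ft$runs[ft$runs$run != "c2", ]
  ft$features <- dplyr::filter(ft$features, .data$run != "c2")
  expect_error(build_profile_matrix(ft), "s2")
})

test_that("profiles are invariant to per-run constant offsets", {
  ft <- simulate_two_group(n_proteins = 25, n_per_group = 3, n_features = 5,
                           seed = 41)
  # re-annotate as matched pairs: G1_rk sorted vs G2_rk control per animal
  ft$runs$animal <- rep(paste0("a", 1:3), 2)
  pm1 <- build_profile_matrix(ft)
  shifted <- ft
  pick <- shifted$features$run == "G1_r1"
  shifted$features$intensity[pick] <- shifted$features$intensity[pick] * 2^0.8
  pm2 <- build_profile_matrix(normalize_runs(shifted))
  pm1n <- build_profile_matrix(normalize_runs(ft))
  expect_equal(pm1n$values, pm2$values, tolerance = 1e-9)
})

test_that("profile columns track the expected latent contrast", {
  gt <- ground_truth(n_proteins = 300, n_modules = 4, module_size = 25,
                     complex_spec = NULL, pair_spec = NULL,
                     marker_spec = list(n_per_type = 5, amplitude = 2),
                     seed = 42)
  sc <- sorting_scenario(n_animals = 3, seed = 43)
  pm <- build_profile_matrix(normalize_runs(simulate_experiment(gt, sc)))
  pmt <- average_by_type(pm)
  mix <- expected_mixtures(gt, sc)
  rs <- sapply(colnames(pmt$values), function(tt) {
    v <- pmt$values[, tt]
    ok <- is.finite(v)
    cor(v[ok], mix$log2fc[rownames(pmt$values)[ok], tt])
  })
  expect_true(all(rs >= 0.9))
})

test_that("PCA conserves variance, deduplicates columns and separates clusters", {
  withr::local_seed(44)
  vals <- matrix(rnorm(60 * 10), 60, 10,
                 dimnames = list(paste0("P", 1:60), paste0("S", 1:10)))
  vals[, 10] <- vals[, 9]  # duplicated column
  pm <- profile_matrix(vals)
  pca <- run_pca(pm)
  expect_equal(sum(pca$var_frac), 1, tolerance = 1e-9)
  s9 <- as.numeric(pca$scores[pca$scores$pair == "S9", paste0("PC", 1:5)])
  s10 <- as.numeric(pca$scores[pca$scores$pair == "S10", paste0("PC", 1:5)])
  expect_equal(s9, s10, tolerance = 1e-9)

  # full-rank reconstruction
  X <- t(scale(t(vals), center = FALSE, scale = FALSE))
  ctr <- rowMeans(vals)
  L <- as.matrix(pca$loadings[, -1])
  S <- as.matrix(pca$scores[, paste0("PC", seq_len(ncol(L)))])
  recon <- t(S %*% t(L)) + ctr
  expect_lt(norm(recon - vals, "F") / norm(vals, "F"), 1e-8)

  # two clusters of columns shifted by a mean offset separate on PC1
  shift <- rnorm(60)
  clean <- matrix(rnorm(60 * 12, sd = 0.1 * sd(shift)), 60, 12)
  clean[, 7:12] <- clean[, 7:12] + shift
  rownames(clean) <- paste0("P", 1:60)
  pca2 <- run_pca(profile_matrix(clean))
  pc1 <- pca2$scores$PC1
  expect_true(max(pc1[1:6]) < min(pc1[7:12]) ||
                min(pc1[1:6]) > max(pc1[7:12]))
})

test_that("requesting more components than the rank truncates with a warning", {
  vals <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(paste0("P", 1:10), NULL))
  expect_warning(run_pca(profile_matrix(vals), n_components = 10),
                 "truncating")
})

test_that("variance partitioning is exact for pure covariate signals", {
  cd <- tibble::tibble(pair = paste0("S", 1:12),
                       type = rep(c("A", "B"), 6),
                       cell_type = rep(c("Camk2a", "Gad2"), 6),
                       sex = rep(c("F", "F", "M", "M"), 3))
  ctv <- ifelse(cd$cell_type == "Camk2a", 1, -1)
  vals <- matrix(rep(ctv, each = 5), nrow = 5,
                 dimnames = list(paste0("P", 1:5), cd$pair))
  vp <- partition_variance(profile_matrix(vals, cd),
                           covariates = c("cell_type", "sex"))
  expect_equal(vp$fractions$cell_type, rep(1, 5), tolerance = 1e-9)
  expect_equal(vp$fractions$sex, rep(0, 5), tolerance = 1e-9)
  expect_equal(vp$fractions$residual, rep(0, 5), tolerance = 1e-9)
})

test_that("null profiles give near-df-share variance fractions", {
  withr::local_seed(45)
  n_col <- 24
  cd <- tibble::tibble(pair = paste0("S", 1:n_col),
                       type = rep(c("A", "B", "C"), 8),
                       cell_type = rep(c("Camk2a", "Gad2"), 12),
                       region = rep(rep(c("CX", "HC"), each = 2), 6))
  vals <- matrix(rnorm(800 * n_col), 800, n_col,
                 dimnames = list(paste0("P", 1:800), cd$pair))
  vp <- partition_variance(profile_matrix(vals, cd),
                           covariates = c("cell_type", "region"))
  med <- apply(vp$fractions[c("cell_type", "region")], 2, median)
  expect_true(all(med <= 1 / (n_col - 1) + 0.05))
  sums <- rowSums(vp$fractions[c("cell_type", "region", "residual")])
  expect_equal(sums, rep(1, 800), tolerance = 1e-9)
})

test_that("permuting a covariate drives its fraction to the null level", {
  withr::local_seed(46)
  n_col <- 24
  cd <- tibble::tibble(pair = paste0("S", 1:n_col),
                       type = "A",
                       cell_type = rep(c("Camk2a", "Gad2"), 12),
                       region = rep(rep(c("CX", "HC"), each = 2), 6))
  sig <- ifelse(cd$cell_type == "Camk2a", 0.5, -0.5)
  vals <- matrix(rnorm(600 * n_col), 600, n_col) +
    matrix(rep(sig, each = 600), 600)
  dimnames(vals) <- list(paste0("P", 1:600), cd$pair)
  vp <- partition_variance(profile_matrix(vals, cd),
                           covariates = c("cell_type", "region"))
  cd_perm <- cd
  cd_perm$cell_type <- sample(cd$cell_type)
  vp_perm <- partition_variance(profile_matrix(vals, cd_perm),
                                covariates = c("cell_type", "region"))
  null_level <- 1 / (n_col - 1)
  expect_gt(median(vp$fractions$cell_type), 0.1)
  expect_lt(abs(median(vp_perm$fractions$cell_type) - null_level), 0.02)
})

test_that("cell-type-driven modules dominate region in the covariate comparison", {
  gt <- ground_truth(n_proteins = 400, n_modules = 4, module_size = 40,
                     trait_spec = tibble::tibble(module = 1:4,
                                                 trait = c("vGat", "VGlut1",
                                                           "vGat", "VGlut1"),
                                                 loading = 0.9),
                     complex_spec = NULL, pair_spec = NULL,
                     marker_spec = NULL, seed = 47)
  sc <- sorting_scenario(n_animals = 3, missingness = NULL, seed = 48)
  pm <- build_profile_matrix(normalize_runs(simulate_experiment(gt, sc)))
  vp <- partition_variance(pm, covariates = c("cell_type", "region", "sex"))
  tt <- vp$tests[vp$tests$covariate_a == "cell_type" &
                   vp$tests$covariate_b == "region", ]
  expect_gt(tt$mean_diff, 0)
  expect_lt(tt$p, 0.001)
})
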