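test_that("bicor satisfies its defining identities and matches the formula oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 2, 4, 8, 16)
  expect_equal(as.numeric(bicor(x, x)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(bicor(x, -x)), -1, tolerance = 1e-12)
  expect_equal(as.numeric(bicor(x, y)), bicor_oracle(x, y), tolerance = 1e-12)

  withr::local_seed(3)
  for (i in 1:100) {
    a <- rnorm(sample(5:20, 1))
    b <- rnorm(length(a)) + 0.3 * a
    expect_equal(as.numeric(bicor(a, b)), bicor_oracle(a, b),
                 tolerance = 1e-9)
  }
  expect_error(bicor(1:3, 1:3), "at least 4")
})

test_that("bicor is invariant under positive affine transforms", {
  withr::local_seed(4)
  for (i in 1:20) {
    a <- rnorm(12)
    b <- rnorm(12)
    r0 <- as.numeric(bicor(a, b))
    expect_equal(as.numeric(bicor(2.5 * a + 7, b)), r0, tolerance = 1e-9)
    expect_equal(as.numeric(bicor(a, 0.1 * b - 3)), r0, tolerance = 1e-9)
  }
  # exact on the Pearson fallback path (zero MAD)
  cst <- c(1, 1, 1, 1, 2, 1, 1, 1)  # MAD 0
  b <- rnorm(8)
  expect_equal(as.numeric(bicor(3 * cst + 1, b)),
               as.numeric(bicor(cst, b)), tolerance = 1e-12)
  expect_equal(attr(bicor(cst, b), "fallback"), "x")
})

test_that("bicor_matrix agrees with the scalar version", {
  withr::local_seed(9)
  m <- matrix(rnorm(8 * 10), 8, 10,
              dimnames = list(paste0("P", 1:8), NULL))
  cm <- bicor_matrix(m)
  expect_equal(cm, t(cm))
  for (i in 1:7) {
    expect_equal(cm[i, i + 1], as.numeric(bicor(m[i, ], m[i + 1, ])),
                 tolerance = 1e-12)
  }
})

test_that("signed-hybrid adjacency zeroes negatives and powers positives", {
  corr <- matrix(c(1, -0.5, 0.9, -0.5, 1, 0.3, 0.9, 0.3, 1), 3, 3)
  a <- adjacency_signed_hybrid(corr, beta = 6)
  expect_equal(a[1, 2], 0)
  expect_equal(a[1, 3], 0.531441, tolerance = 1e-12)  # 0.9^6
  expect_equal(a[1, 1], 1)
  expect_error(adjacency_signed_hybrid(corr, beta = 0), "beta")
})

test_that("raising beta increases adjacency sparsity at any fixed cutoff", {
  withr::local_seed(10)
  m <- matrix(rnorm(30 * 12), 30, 12, dimnames = list(paste0("P", 1:30), NULL))
  corr <- bicor_matrix(m)
  for (cutoff in c(0.05, 0.2, 0.5)) {
    n_edges <- sapply(c(2, 4, 6, 9), function(b) {
      sum(adjacency_signed_hybrid(corr, b)[upper.tri(corr)] > cutoff)
    })
    expect_true(all(diff(n_edges) <= 0))
  }
})

test_that("topological overlap matches the fixture and the brute-force oracle", {
  # 4-node toy adjacency, TOM worked out by hand:
  # a12=0.5, a13=0.5, a23=0.5, node 4 isolated.
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 0.5
  a[1, 3] <- a[3, 1] <- 0.5
  a[2, 3] <- a[3, 2] <- 0.5
  diag(a) <- 1
  tom <- topological_overlap(a)
  # TOM_12 = (a13*a32 + a12) / (min(k1,k2) + 1 - a12) = (0.25 + 0.5) / 1.5
  expect_equal(tom[1, 2], 0.75 / 1.5, tolerance = 1e-12)
  expect_equal(tom[1, 4], 0)  # no shared neighbours, no edge
  expect_equal(tom, tom_oracle(a), tolerance = 1e-12)

  # identical fully-connected rows with a_ij = 1 give TOM 1
  b <- matrix(1, 3, 3)
  expect_equal(topological_overlap(b)[1, 2], 1, tolerance = 1e-12)

  # random 20-node graphs against the double loop
  withr::local_seed(11)
  for (i in 1:5) {
    r <- matrix(runif(400), 20, 20)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    expect_equal(topological_overlap(r), tom_oracle(r), tolerance = 1e-12)
  }
})

test_that("module detection separates clean blocks and drops singletons", {
  withr::local_seed(13)
  t_ <- 15
  f1 <- rnorm(t_); f2 <- rnorm(t_)
  block <- rbind(matrix(rep(f1, 25), 25, byrow = TRUE),
                 matrix(rep(f2, 25), 25, byrow = TRUE))
  rownames(block) <- paste0("P", 1:50)
  corr <- suppressWarnings(bicor_matrix(block))
  tom <- topological_overlap(adjacency_signed_hybrid(corr))
  labels <- detect_modules(1 - tom, block, min_module_size = 10)
  expect_equal(length(setdiff(unique(labels), 0L)), 2)
  expect_equal(sum(labels == 0), 0)
  expect_equal(length(unique(labels[1:25])), 1)
  expect_equal(length(unique(labels[26:50])), 1)

  # an uncorrelated singleton stays unassigned
  single <- rbind(block, P51 = rnorm(t_))
  corr2 <- suppressWarnings(bicor_matrix(single))
  tom2 <- topological_overlap(adjacency_signed_hybrid(corr2))
  labels2 <- detect_modules(1 - tom2, single, min_module_size = 10)
  expect_equal(unname(labels2["P51"]), 0L)
})

test_that("eigenproteins are unit-variance, sign-aligned factor estimates", {
  withr::local_seed(14)
  t_ <- 15
  f <- as.numeric(scale(rnorm(t_)))
  X <- 0.9 * matrix(rep(f, 50), 50, byrow = TRUE) +
    sqrt(1 - 0.81) * matrix(rnorm(50 * t_), 50)
  rownames(X) <- paste0("P", 1:50)
  labels <- setNames(rep(1L, 50), rownames(X))
  eig <- eigenproteins(X, labels)
  expect_equal(sd(eig[1, ]), 1, tolerance = 1e-9)
  expect_gte(cor(eig[1, ], colMeans(t(scale(t(X))))), 0)
  expect_gte(abs(cor(eig[1, ], f)), 0.95)

  ident <- matrix(rep(f, 3), 3, byrow = TRUE,
                  dimnames = list(paste0("Q", 1:3), NULL))
  eig2 <- eigenproteins(ident, setNames(rep(1L, 3), rownames(ident)))
  expect_equal(abs(cor(eig2[1, ], f)), 1, tolerance = 1e-9)
})

test_that("module-trait correlation uses the exact t distribution", {
  t_ <- 15
  withr::local_seed(15)
  eig <- matrix(rnorm(2 * t_), 2, t_,
                dimnames = list(c("M1", "M2"), paste0("T", 1:t_)))
  eig[1, ] <- eig[1, ] / sd(eig[1, ])
  traits <- tibble::tibble(type = paste0("T", 1:t_),
                           same = eig[1, ],
                           ortho = residuals(lm(rnorm(t_) ~ eig[1, ])))
  mt <- module_trait_correlation(eig, traits)
  expect_equal(mt$r["M1", "same"], 1, tolerance = 1e-9)
  expect_equal(mt$r["M1", "ortho"], 0, tolerance = 1e-9)
  r <- mt$r["M2", "same"]
  t_stat <- r * sqrt(t_ - 2) / sqrt(1 - r^2)
  expect_equal(mt$p["M2", "same"], 2 * pt(-abs(t_stat), t_ - 2),
               tolerance = 1e-12)
  # r = 0.6 at n = 15 corresponds to p ~ 0.018
  expect_equal(2 * pt(-0.6 * sqrt(13) / sqrt(1 - 0.36), 13), 0.018,
               tolerance = 1e-2)
})

test_that("edge export applies a strict cutoff once per pair", {
  a <- matrix(0, 3, 3, dimnames = list(paste0("P", 1:3), paste0("P", 1:3)))
  a[1, 2] <- a[2, 1] <- 0.31
  a[1, 3] <- a[3, 1] <- 0.29
  diag(a) <- 1
  edges <- export_network(a, weight_cutoff = 0.3)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$source, "P1")
  expect_equal(edges$target, "P2")
  expect_equal(nrow(export_network(a, weight_cutoff = 2)), 0)

  # brute-force: every unordered above-cutoff pair appears exactly once
  withr::local_seed(16)
  r <- matrix(runif(100), 10, 10); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("P", 1:10), paste0("P", 1:10))
  edges2 <- export_network(r, weight_cutoff = 0.5)
  want <- 0
  for (i in 1:9) for (j in (i + 1):10) if (r[i, j] > 0.5) want <- want + 1
  expect_equal(nrow(edges2), want)
  expect_false(any(duplicated(paste(pmin(edges2$source, edges2$target),
                                    pmax(edges2$source, edges2$target)))))
})

test_that("planted modules and their trait links are recovered end to end", {
  aris <- c()
  vgat_top <- c()
  for (s in 1:3) {
    gt <- ground_truth(n_proteins = 300, n_modules = 5, module_size = 50,
                       complex_spec = NULL, pair_spec = NULL,
                       marker_spec = NULL, seed = s)
    pm <- profile_matrix(gt$true_abundance,
                         tibble::tibble(pair = gt$types$type,
                                        type = gt$types$type,
                                        cell_type = gt$types$cell_type,
                                        region = gt$types$region))
    net <- suppressMessages(build_network(pm, traits = gt$traits))
    aris <- c(aris, mclust::adjustedRandIndex(
      gt$proteins$module, net$labels[gt$proteins$protein]))
    mt <- net$module_trait
    best <- rownames(mt$r)[which.max(abs(mt$r[, "vGat"]))]
    members <- names(net$labels)[net$labels == as.integer(sub("M", "", best))]
    planted <- gt$proteins$protein[gt$proteins$module == 1]
    vgat_top <- c(vgat_top, mean(planted %in% members) > 0.5)
  }
  expect_true(all(aris >= 0.8))
  expect_true(all(vgat_top))
})
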