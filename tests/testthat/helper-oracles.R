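suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Independent oracles, deliberately written as naive direct translations of
# the defining formulas, separate from the package implementations.

# Benjamini-Hochberg by the textbook step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Biweight midcorrelation straight from the published definition, with
# unscaled MAD and tuning constant 9.
bicor_oracle <- function(x, y) {
  wvec <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    u <- (v - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  a <- wvec(x)
  b <- wvec(y)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# Topological overlap by an explicit double loop over shared neighbors.
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      out[i, j] <- out[j, i] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# Explicit normal-equations least squares for the feature + group model,
# returning the group-mean difference G1 - G2 at average feature effect.
lsdiff_oracle <- function(feature, group, y) {
  ff <- factor(feature)
  gf <- factor(group)
  Fm <- stats::contr.sum(nlevels(ff))[as.integer(ff), , drop = FALSE]
  G <- sapply(levels(gf), function(l) as.numeric(gf == l))
  X <- cbind(G, Fm)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  beta[1] - beta[2]
}

# Compact builders -----------------------------------------------------------

make_runs <- function(run, cell_type, fraction, animal = NULL,
                      region = "CX") {
  if (is.null(animal)) animal <- run
  tibble::tibble(run = run, animal = animal, region = region,
                 cell_type = cell_type, fraction = fraction)
}

# A feature table for one protein from a feature x run intensity matrix
# given on the log2 scale.
ft_from_log2 <- function(mat, runs, protein = "P1") {
  df <- as.data.frame.table(mat, stringsAsFactors = FALSE)
  names(df) <- c("feature", "run", "log2i")
  df <- df[!is.na(df$log2i), ]
  feature_table(
    tibble::tibble(protein = protein, feature = df$feature, run = df$run,
                   intensity = 2^df$log2i),
    runs)
}
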