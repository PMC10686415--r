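#' @importFrom rlang abort warn inform .data
#' @importFrom dplyr %>%
#' @importFrom stats median mad sd var cor pt qt phyper setNames rnorm runif rpois rbinom quantile prcomp hclust cutree as.dist p.adjust plogis complete.cases
#' @importFrom utils combn head
NULL

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seeds below 2^31, derived from a master seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) * 7L + 11L
}

stop_input <- function(msg, class = "fassprot_input_error") {
  abort(msg, class = class)
}

assert_columns <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_input(sprintf("%s is missing required column(s): %s",
                       what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# Convert a linear-scale coefficient of variation into the matching
# log2-normal standard deviation: CV = sqrt(exp(sigma_ln^2) - 1).
cv_to_sdlog2 <- function(cv) {
  sqrt(log(1 + cv^2)) / log(2)
}

sdlog2_to_cv <- function(sdlog2) {
  sqrt(exp((sdlog2 * log(2))^2) - 1)
}
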