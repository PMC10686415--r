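#' Sample random cross-section areas of a sphere
#'
#' Random planes through a sphere of radius `R`, drawn by sampling the
#' plane's offset from the equator uniformly: `X ~ Uniform(0, R)`, the
#' section's radius `Y` solving `X^2 + Y^2 = R^2`, so the section area is
#' `pi * (R^2 - X^2)`. The expected area is `(2/3) * pi * R^2`.
#'
#' @param radius Sphere radius, > 0.
#' @param n Number of sections, >= 1.
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n` section areas (squared radius units).
#' @examples
#' mean(sample_cross_sections(1, 1e4, seed = 1)) # close to 2*pi/3
#' @export
sample_cross_sections <- function(radius, n, seed = NULL) {
  if (radius <= 0) stop_input("radius must be > 0")
  if (n < 1) stop_input("n must be >= 1")
  draw <- function() {
    x <- runif(n, 0, radius)
    pi * (radius^2 - x^2)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Build a diameter-to-mean-section-area calibration curve
#'
#' For each diameter on the grid, averages `n_repeats` independent means of
#' `n_sections` sampled cross-section areas (emulating repeated simulated
#' samples of 30 sections each). An analytic mode replaces sampling with
#' the closed-form expectation `(2/3) * pi * (d/2)^2`. Sampling noise can
#' invert adjacent grid points; the curve is monotonized by isotonic
#' regression before use (adjustment recorded).
#'
#' @param diameters Sorted positive diameter grid (length >= 2), in the
#'   caller's units.
#' @param n_sections Sections per repeat; default 30.
#' @param n_repeats Repeats per diameter; default 4.
#' @param analytic Use the closed-form expectation instead of sampling.
#' @param seed RNG seed (sampled mode).
#' @return Object of class `sphere_calibration`: tibble `curve`
#'   (`diameter`, `mean_area`, `sd_area`), flags `analytic`, `monotonized`.
#' @export
build_calibration <- function(diameters, n_sections = 30, n_repeats = 4,
                              analytic = FALSE, seed = NULL) {
  if (length(diameters) < 2) stop_input("diameter grid needs at least 2 points")
  if (is.unsorted(diameters, strictly = TRUE)) {
    stop_input("diameter grid must be sorted and strictly increasing")
  }
  if (any(diameters <= 0)) stop_input("diameters must be positive")
  if (analytic) {
    mean_area <- (2 / 3) * pi * (diameters / 2)^2
    sd_area <- rep(0, length(diameters))
  } else {
    sim <- function() {
      vapply(diameters, function(d) {
        reps <- vapply(seq_len(n_repeats), function(i) {
          mean(sample_cross_sections(d / 2, n_sections))
        }, numeric(1))
        c(mean(reps), sd(reps))
      }, numeric(2))
    }
    res <- if (is.null(seed)) sim() else with_seed(seed, sim())
    mean_area <- res[1, ]
    sd_area <- res[2, ]
  }
  monotonized <- is.unsorted(mean_area)
  if (monotonized) {
    mean_area <- stats::isoreg(diameters, mean_area)$yf
    inform("sampled calibration curve was non-monotone; isotonic adjustment applied")
  }
  structure(list(curve = tibble::tibble(diameter = diameters,
                                        mean_area = mean_area,
                                        sd_area = sd_area),
                 n_sections = n_sections, n_repeats = n_repeats,
                 analytic = analytic, monotonized = monotonized, seed = seed),
            class = "sphere_calibration")
}

#' @export
print.sphere_calibration <- function(x, ...) {
  cat(sprintf("<sphere_calibration> %d diameters in [%g, %g] | %s%s\n",
              nrow(x$curve), min(x$curve$diameter), max(x$curve$diameter),
              if (x$analytic) "analytic" else
                sprintf("%d sections x %d repeats", x$n_sections, x$n_repeats),
              if (x$monotonized) " | monotonized" else ""))
  invisible(x)
}

#' Estimate sphere diameter from a mean cross-section area
#'
#' Inverts the calibration curve by monotone linear interpolation. Areas
#' outside the calibrated range raise an error rather than extrapolating.
#'
#' @param mean_area Observed mean cross-section area(s), same area units as
#'   the curve.
#' @param calibration A `sphere_calibration`.
#' @return Estimated diameter(s) in the grid's units.
#' @examples
#' cal <- build_calibration(seq(100, 1000, by = 50), analytic = TRUE)
#' estimate_diameter((2 / 3) * pi * (600 / 2)^2, cal) # 600
#' @export
estimate_diameter <- function(mean_area, calibration) {
  stopifnot(inherits(calibration, "sphere_calibration"))
  cv <- calibration$curve
  if (any(mean_area < min(cv$mean_area) | mean_area > max(cv$mean_area))) {
    stop_input(sprintf(
      "observed area outside the calibrated range [%.4g, %.4g]; extend the diameter grid",
      min(cv$mean_area), max(cv$mean_area)))
  }
  stats::approx(cv$mean_area, cv$diameter, xout = mean_area,
                ties = "ordered")$y
}
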