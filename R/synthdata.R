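#' Default synapse-type layout
#'
#' Fifteen cell-type x brain-region combinations emulating a multi-region
#' Cre-line sorting design: cortex (Camk2a, Gad2, Syn1, PV, SST),
#' hippocampus (Camk2a, Gad2, Syn1), striatum (Drd1, Drd2, Dat),
#' cerebellum (Gad2, Syn1) and thalamus (Gad2, Syn1).
#'
#' @param n_types Number of synapse types. The curated 15-type layout is
#'   returned for `n_types = 15`; other values cycle Camk2a/Gad2/Syn1 across
#'   generic regions.
#' @return Tibble with columns `type`, `cell_type`, `region`.
#' @export
default_type_layout <- function(n_types = 15) {
  if (n_types == 15) {
    tibble::tibble(
      region = c(rep("CX", 5), rep("HC", 3), rep("ST", 3), rep("CB", 2), rep("TH", 2)),
      cell_type = c("Camk2a", "Gad2", "Syn1", "PV", "SST",
                    "Camk2a", "Gad2", "Syn1",
                    "Drd1", "Drd2", "Dat",
                    "Gad2", "Syn1",
                    "Gad2", "Syn1")
    ) %>%
      dplyr::mutate(type = paste(.data$region, .data$cell_type, sep = ".")) %>%
      dplyr::select("type", "cell_type", "region")
  } else {
    ct <- rep(c("Camk2a", "Gad2", "Syn1"), length.out = n_types)
    rg <- paste0("R", rep(seq_len(ceiling(n_types / 3)), each = 3))[seq_len(n_types)]
    tibble::tibble(type = paste(rg, ct, sep = "."), cell_type = ct, region = rg)
  }
}

# Identity-class score per cell type used to derive the default
# immunofluorescence-like traits (inhibitory vGat-like, excitatory
# VGlut1-like markers).
cell_type_trait_base <- function(cell_type) {
  inh <- c(Gad2 = 0.9, PV = 0.9, SST = 0.9, Drd1 = 0.8, Drd2 = 0.8,
           Camk2a = 0.1, Syn1 = 0.5, Dat = 0.1)
  exc <- c(Camk2a = 0.9, Syn1 = 0.6, Dat = 0.15,
           Gad2 = 0.1, PV = 0.1, SST = 0.1, Drd1 = 0.1, Drd2 = 0.1)
  vg <- unname(inh[cell_type]); vl <- unname(exc[cell_type])
  vg[is.na(vg)] <- 0.5; vl[is.na(vl)] <- 0.5
  list(vGat = vg, VGlut1 = vl)
}

#' Generate a ground-truth synapse-type proteome
#'
#' Builds the latent (noise-free) protein x synapse-type log2 abundance
#' matrix with planted structure that the downstream pipeline must recover:
#' co-abundance modules driven by type-level factors linearly tied to
#' immunofluorescence-like traits, protein complexes nested inside modules,
#' anti-correlated protein pairs, and per-type marker proteins.
#'
#' Member profiles follow
#' `abundance = baseline + amplitude * (loading * F_m + sqrt(1 - loading^2) * eps)`
#' where `F_m` is the module's standardized type-level factor. Setting
#' `member_loading = 1` removes idiosyncratic noise, making within-module
#' correlations exactly 1. A planted negative pair couples its two members
#' to a private factor with opposite loading signs, so the latent
#' correlation is -loading^2 (<= -0.8 at the default 0.95).
#'
#' @param n_types Number of synapse types (>= 3); default 15.
#' @param n_proteins Number of proteins; default 1000.
#' @param n_modules Number of planted co-abundance modules; default 14.
#' @param module_size Proteins per module; default 30.
#' @param trait_spec Tibble (`module`, `trait`, `loading`) linking module
#'   factors to traits; modules not listed get independent factors.
#'   Default ties module 1 to `vGat` and module 2 to `VGlut1` (loading 0.9).
#' @param complex_spec List `n_complexes`, `size`: complexes are random
#'   subsets of single modules. Default 10 complexes of size 4.
#' @param pair_spec List `n_pairs`, `loading`: planted anti-correlated
#'   pairs. Default 10 pairs, loading 0.95.
#' @param marker_spec List `n_per_type`, `amplitude`: proteins elevated by
#'   `amplitude` log2 units in exactly one type. Default 20 per type, +2.
#' @param member_loading Loading of module members on their factor (0.9).
#' @param amplitude Module effect amplitude, log2 units (1).
#' @param idio_sd Idiosyncratic cross-type s.d. of unstructured proteins,
#'   log2 units (0.5).
#' @param baseline_mean,baseline_sd Per-protein baseline log2 abundance
#'   distribution (20, 2), emulating DIA intensity scales.
#' @param types Optional custom type layout tibble (`type`, `cell_type`,
#'   `region`); overrides `n_types`.
#' @param seed RNG seed (required).
#' @return Object of class `ground_truth`.
#' @examples
#' gt <- ground_truth(n_proteins = 200, n_modules = 4, seed = 1)
#' gt
#' @export
ground_truth <- function(n_types = 15, n_proteins = 1000, n_modules = 14,
                         module_size = 30,
                         trait_spec = NULL,
                         complex_spec = list(n_complexes = 10, size = 4),
                         pair_spec = list(n_pairs = 10, loading = 0.95),
                         marker_spec = list(n_per_type = 20, amplitude = 2),
                         member_loading = 0.9, amplitude = 1, idio_sd = 0.5,
                         baseline_mean = 20, baseline_sd = 2,
                         types = NULL, seed) {
  if (missing(seed)) stop_input("ground_truth() requires an explicit seed")
  if (is.null(types)) types <- default_type_layout(n_types)
  types <- tibble::as_tibble(types)
  n_types <- nrow(types)
  if (n_types < 3) stop_input("need at least 3 synapse types")
  if (n_modules < 1) stop_input("need at least 1 module")
  n_pairs <- if (is.null(pair_spec)) 0L else pair_spec$n_pairs
  n_markers <- if (is.null(marker_spec)) 0L else marker_spec$n_per_type * n_types
  need <- n_modules * module_size + 2L * n_pairs + n_markers
  if (need > n_proteins) {
    stop_input(sprintf(
      "configuration error: %d proteins required for modules/pairs/markers but n_proteins = %d",
      need, n_proteins))
  }
  if (is.null(trait_spec)) {
    trait_spec <- tibble::tibble(
      module = c(1L, 2L)[seq_len(min(2L, n_modules))],
      trait = c("vGat", "VGlut1")[seq_len(min(2L, n_modules))],
      loading = 0.9)
  }

  with_seed(seed, {
    tb <- cell_type_trait_base(types$cell_type)
    traits <- tibble::tibble(
      type = types$type,
      vGat = pmin(1, pmax(0, tb$vGat + rnorm(n_types, 0, 0.05))),
      VGlut1 = pmin(1, pmax(0, tb$VGlut1 + rnorm(n_types, 0, 0.05))))

    # Type-level module factors, standardized; tied to traits where specified.
    factors <- matrix(0, n_modules, n_types,
                      dimnames = list(paste0("M", seq_len(n_modules)), types$type))
    for (m in seq_len(n_modules)) {
      row <- trait_spec[trait_spec$module == m, ]
      if (nrow(row) == 1 && !is.na(row$trait)) {
        z <- as.numeric(scale(traits[[row$trait]]))
        f <- row$loading * z + sqrt(1 - row$loading^2) * rnorm(n_types)
      } else {
        f <- rnorm(n_types)
      }
      factors[m, ] <- as.numeric(scale(f))
    }

    proteins <- tibble::tibble(
      protein = sprintf("P%05d", seq_len(n_proteins)),
      baseline = rnorm(n_proteins, baseline_mean, baseline_sd),
      module = 0L, marker_type = NA_character_)

    pool <- sample(seq_len(n_proteins))
    take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }

    dev <- matrix(rnorm(n_proteins * n_types, 0, idio_sd), n_proteins, n_types,
                  dimnames = list(proteins$protein, types$type))

    s_noise <- sqrt(max(0, 1 - member_loading^2))
    for (m in seq_len(n_modules)) {
      idx <- take(module_size)
      proteins$module[idx] <- m
      eps <- matrix(rnorm(module_size * n_types), module_size, n_types)
      dev[idx, ] <- amplitude *
        (member_loading * matrix(factors[m, ], module_size, n_types, byrow = TRUE) +
           s_noise * eps)
    }

    negative_pairs <- tibble::tibble(pair_id = character(), protein_a = character(),
                                     protein_b = character(), loading = numeric())
    if (n_pairs > 0) {
      pl <- pair_spec$loading
      ps <- sqrt(max(0, 1 - pl^2))
      for (q in seq_len(n_pairs)) {
        idx <- take(2L)
        g <- as.numeric(scale(rnorm(n_types)))
        dev[idx[1], ] <- amplitude * (pl * g + ps * rnorm(n_types))
        dev[idx[2], ] <- amplitude * (-pl * g + ps * rnorm(n_types))
        negative_pairs <- dplyr::bind_rows(negative_pairs, tibble::tibble(
          pair_id = paste0("NP", q),
          protein_a = proteins$protein[idx[1]],
          protein_b = proteins$protein[idx[2]], loading = pl))
      }
    }

    if (n_markers > 0) {
      for (t in seq_len(n_types)) {
        idx <- take(marker_spec$n_per_type)
        proteins$marker_type[idx] <- types$type[t]
        dev[idx, t] <- dev[idx, t] + marker_spec$amplitude
      }
    }

    complexes <- tibble::tibble(complex_id = character(), protein = character())
    if (!is.null(complex_spec) && complex_spec$n_complexes > 0) {
      donor_modules <- rep(seq_len(n_modules), length.out = complex_spec$n_complexes)
      for (cc in seq_len(complex_spec$n_complexes)) {
        members <- proteins$protein[proteins$module == donor_modules[cc]]
        if (length(members) < complex_spec$size) {
          stop_input("configuration error: complex size exceeds module size")
        }
        complexes <- dplyr::bind_rows(complexes, tibble::tibble(
          complex_id = sprintf("CPX%02d", cc),
          protein = sample(members, complex_spec$size)))
      }
    }

    true_abundance <- proteins$baseline + dev
    dimnames(true_abundance) <- list(proteins$protein, types$type)

    structure(list(
      types = types, traits = traits, proteins = proteins,
      true_abundance = true_abundance, module_factors = factors,
      trait_spec = trait_spec, complexes = complexes,
      negative_pairs = negative_pairs, seed = seed,
      params = list(n_types = n_types, n_proteins = n_proteins,
                    n_modules = n_modules, module_size = module_size,
                    member_loading = member_loading, amplitude = amplitude,
                    idio_sd = idio_sd, baseline_mean = baseline_mean,
                    baseline_sd = baseline_sd, marker_spec = marker_spec)),
      class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d proteins x %d types | %d modules | %d complexes | %d negative pairs\n",
              nrow(x$true_abundance), ncol(x$true_abundance),
              max(x$proteins$module), dplyr::n_distinct(x$complexes$complex_id),
              nrow(x$negative_pairs)))
  invisible(x)
}

#' Describe a sorting scenario
#'
#' Parameters of the simulated paired sorting experiment: sort purity
#' (fraction of sorted-particle signal originating from the target type,
#' anchored on the ~80-95% purities of calibrated sorts), per-type
#' prevalence within the unsorted precursor (labeled populations span
#' roughly 0.5% to 50% of a region's crude synaptosome pool), replicate
#' count, feature-count model, target replicate coefficient of variation,
#' and intensity-dependent dropout.
#'
#' Prevalences default to a log-uniform draw from \[0.005, 0.5\] per type;
#' if the drawn values plus the fixed contaminant fraction would exceed 1,
#' they are rescaled proportionally (ratios preserved).
#'
#' @param purity Sorted-signal purity in \[0, 1\]; default 0.9.
#' @param prevalence Named numeric vector of per-type prevalences in (0, 1\],
#'   or `NULL` to draw defaults from the scenario seed.
#' @param n_animals Biological replicates (animals) per type, >= 2; default 4.
#' @param features_per_protein List `min`, `mean` of the shifted-Poisson
#'   feature-count model (default min 1, mean 8).
#' @param replicate_cv Target median coefficient of variation of
#'   protein-level intensities among biological replicates; default 0.2.
#' @param feature_response_sd Log2 s.d. of the multiplicative per-feature
#'   response; default 1.
#' @param missingness List `midpoint`, `slope` of the logistic dropout in
#'   log2 intensity, or `NULL` to disable. Default midpoint 17, slope 1.
#' @param contaminant_fraction Fixed contaminant share of a sorted run's
#'   background pseudo-proteome; default 0.1.
#' @param seed RNG seed (required).
#' @return Object of class `sorting_scenario`.
#' @export
sorting_scenario <- function(purity = 0.9, prevalence = NULL, n_animals = 4,
                             features_per_protein = list(min = 1, mean = 8),
                             replicate_cv = 0.2, feature_response_sd = 1,
                             missingness = list(midpoint = 17, slope = 1),
                             contaminant_fraction = 0.1, seed) {
  if (missing(seed)) stop_input("sorting_scenario() requires an explicit seed")
  if (purity < 0 || purity > 1) stop_input("purity must lie in [0, 1]")
  if (n_animals < 2) stop_input("n_animals must be >= 2")
  if (!is.null(prevalence) && (any(prevalence <= 0) || any(prevalence > 1))) {
    stop_input("prevalences must lie in (0, 1]")
  }
  structure(list(purity = purity, prevalence = prevalence, n_animals = n_animals,
                 features_per_protein = features_per_protein,
                 replicate_cv = replicate_cv,
                 feature_response_sd = feature_response_sd,
                 missingness = missingness,
                 contaminant_fraction = contaminant_fraction, seed = seed),
            class = "sorting_scenario")
}

#' @export
print.sorting_scenario <- function(x, ...) {
  cat(sprintf("<sorting_scenario> purity %.2f | %d animals/type | replicate CV %.2f | seed %d\n",
              x$purity, x$n_animals, x$replicate_cv, x$seed))
  invisible(x)
}

# Draw (or validate) the per-type prevalence vector for a truth/scenario
# combination. Rescales proportionally if the total would leave no room for
# the contaminant remainder of the unsorted pool.
resolve_prevalence <- function(truth, scenario) {
  tn <- truth$types$type
  if (is.null(scenario$prevalence)) {
    prev <- with_seed(derive_seed(scenario$seed, 71L), {
      exp(runif(length(tn), log(0.005), log(0.5)))
    })
    names(prev) <- tn
  } else {
    prev <- scenario$prevalence[tn]
    if (anyNA(prev)) stop_input("prevalence vector does not cover all synapse types")
    if (sum(prev) > 1) {
      stop_input("configuration error: prevalences sum to > 1, leaving no contaminant remainder")
    }
  }
  # Per region the labeled types plus contaminant must fit into the pool.
  for (r in unique(truth$types$region)) {
    tr <- tn[truth$types$region == r]
    cap <- 1 - scenario$contaminant_fraction
    if (sum(prev[tr]) > cap) prev[tr] <- prev[tr] * cap / sum(prev[tr])
  }
  prev
}

# Per-feature CV that makes the median protein-level (summed-intensity)
# replicate CV equal the scenario target, given each protein's feature
# weights w: CV_protein = feature_cv * sqrt(sum(w^2)) / sum(w).
calibrate_feature_cv <- function(replicate_cv, weights_by_protein) {
  phi <- vapply(weights_by_protein,
                function(w) sqrt(sum(w^2)) / sum(w), numeric(1))
  replicate_cv / median(phi)
}

#' Noise-free expected run composition
#'
#' Linear-scale mixture expectations of sorted and control runs for every
#' synapse type, plus the implied expected sorted-vs-control log2
#' fold-change. Used to define recoverable truth for calibration studies.
#'
#' @param truth A `ground_truth`.
#' @param scenario A `sorting_scenario`.
#' @return List with matrices `sorted`, `control` (linear scale, proteins x
#'   types), `log2fc` (expected sorted/control log2 ratio), the resolved
#'   `prevalence` vector and the `contaminant` linear profile.
#' @export
expected_mixtures <- function(truth, scenario) {
  lin <- 2^truth$true_abundance
  prev <- resolve_prevalence(truth, scenario)
  contam_dev <- with_seed(derive_seed(scenario$seed, 37L), {
    rnorm(nrow(lin), 0, 1.5)
  })
  contaminant <- 2^(truth$proteins$baseline + contam_dev)
  tn <- truth$types$type
  sorted <- control <- matrix(NA_real_, nrow(lin), length(tn),
                              dimnames = list(rownames(lin), tn))
  cf <- scenario$contaminant_fraction
  for (t in seq_along(tn)) {
    region <- truth$types$region[t]
    others <- tn[truth$types$region == region & tn != tn[t]]
    bg <- if (length(others) > 0) {
      w <- prev[others] / sum(prev[others])
      as.numeric(lin[, others, drop = FALSE] %*% w)
    } else {
      contaminant
    }
    bg <- (1 - cf) * bg + cf * contaminant
    sorted[, t] <- scenario$purity * lin[, tn[t]] + (1 - scenario$purity) * bg
    in_region <- tn[truth$types$region == region]
    control[, t] <- as.numeric(lin[, in_region, drop = FALSE] %*% prev[in_region]) +
      (1 - sum(prev[in_region])) * contaminant
  }
  list(sorted = sorted, control = control,
       log2fc = log2(sorted) - log2(control),
       prevalence = prev, contaminant = contaminant)
}

#' Simulate the paired sorting experiment
#'
#' For each synapse type and animal, emits one sorted run (a linear-scale
#' mixture `purity * target + (1 - purity) * background`, the background
#' being the prevalence-weighted mean of the region's other types plus a
#' fixed contaminant pseudo-proteome) and one matched unsorted control run
#' (the region's types at their prevalences, remainder contaminant).
#' Per-protein features carry a log-normal multiplicative response;
#' measurement noise is log-normal per feature and run, calibrated so the
#' median protein-level replicate CV matches the scenario target; dropout
#' follows the scenario's logistic model in log2 intensity.
#'
#' @param truth A `ground_truth`.
#' @param scenario A `sorting_scenario`.
#' @return A [feature_table] with run annotations (animal, sex, age,
#'   region, cell_type, fraction, batch).
#' @examples
#' gt <- ground_truth(n_proteins = 60, n_modules = 2, module_size = 10,
#'                    complex_spec = NULL, pair_spec = NULL,
#'                    marker_spec = NULL, seed = 1)
#' sc <- sorting_scenario(n_animals = 2, seed = 2)
#' simulate_experiment(gt, sc)
#' @export
simulate_experiment <- function(truth, scenario) {
  stopifnot(inherits(truth, "ground_truth"), inherits(scenario, "sorting_scenario"))
  mix <- expected_mixtures(truth, scenario)
  tn <- truth$types$type
  n_prot <- nrow(truth$true_abundance)

  with_seed(derive_seed(scenario$seed, 1L), {
    fpp <- scenario$features_per_protein
    n_feat <- fpp$min + rpois(n_prot, max(0, fpp$mean - fpp$min))
    feat <- tibble::tibble(
      pidx = rep(seq_len(n_prot), n_feat),
      protein = rep(rownames(truth$true_abundance), n_feat),
      feature = unlist(lapply(seq_len(n_prot), function(i) {
        sprintf("%s_f%02d", rownames(truth$true_abundance)[i], seq_len(n_feat[i]))
      })),
      offset = rnorm(sum(n_feat), 0, scenario$feature_response_sd))

    w_by_protein <- split(2^feat$offset, feat$pidx)
    feature_cv <- calibrate_feature_cv(scenario$replicate_cv, w_by_protein)
    sd_meas <- cv_to_sdlog2(feature_cv)

    runs <- tidyr::expand_grid(
      t = seq_along(tn), a = seq_len(scenario$n_animals),
      fraction = c("sorted", "control")) %>%
      dplyr::mutate(
        type = tn[.data$t],
        cell_type = truth$types$cell_type[.data$t],
        region = truth$types$region[.data$t],
        animal = sprintf("%s_a%d", .data$type, .data$a),
        run = sprintf("%s_%s", .data$animal, .data$fraction),
        sex = ifelse(.data$a %% 2 == 1, "F", "M"),
        age = ifelse(((.data$a - 1) %/% 2) %% 2 == 0, 56L, 70L),
        batch = sprintf("B%d", 1L + (.data$a - 1L) %% 2L))

    recs <- vector("list", nrow(runs))
    for (i in seq_len(nrow(runs))) {
      base_log2 <- if (runs$fraction[i] == "sorted") {
        log2(mix$sorted[, runs$t[i]])
      } else {
        log2(mix$control[, runs$t[i]])
      }
      x <- base_log2[feat$pidx] + feat$offset + rnorm(nrow(feat), 0, sd_meas)
      keep <- rep(TRUE, length(x))
      if (!is.null(scenario$missingness)) {
        p_drop <- plogis(scenario$missingness$slope * (scenario$missingness$midpoint - x))
        keep <- runif(length(x)) >= p_drop
      }
      recs[[i]] <- tibble::tibble(
        protein = feat$protein[keep], feature = feat$feature[keep],
        run = runs$run[i], intensity = 2^x[keep])
    }

    feature_table(
      dplyr::bind_rows(recs),
      dplyr::select(runs, "run", "animal", "sex", "age", "region",
                    "cell_type", "fraction", "batch"))
  })
}

#' Simulate a single two-group comparison
#'
#' A compact generator for calibration and power studies of the per-protein
#' model: two conditions (sorted vs control annotation), a configurable
#' number of planted enriched proteins, log-normal feature responses and
#' measurement noise calibrated as in [simulate_experiment()].
#'
#' @param n_proteins Number of proteins.
#' @param n_enriched Number of proteins planted with `log2fc` enrichment in
#'   the sorted group (the first `n_enriched` proteins).
#' @param log2fc Planted effect, log2 units.
#' @param n_per_group Runs per group; default 5.
#' @param n_features Features per protein; default 6.
#' @param replicate_cv Target protein-level replicate CV; default 0.2.
#' @param feature_response_sd Log2 s.d. of feature responses; default 1.
#' @param missingness Optional logistic dropout list (`midpoint`, `slope`);
#'   default `NULL` (complete data).
#' @param baseline_mean,baseline_sd Baseline log2 abundance distribution.
#' @param seed RNG seed (required).
#' @return A [feature_table] whose two groups are distinguished by the
#'   `fraction` annotation (`sorted` = enriched-side group).
#' @export
simulate_two_group <- function(n_proteins = 1000, n_enriched = 0, log2fc = 1,
                               n_per_group = 5, n_features = 6,
                               replicate_cv = 0.2, feature_response_sd = 1,
                               missingness = NULL,
                               baseline_mean = 20, baseline_sd = 2, seed) {
  if (missing(seed)) stop_input("simulate_two_group() requires an explicit seed")
  with_seed(seed, {
    prot <- sprintf("P%05d", seq_len(n_proteins))
    base <- rnorm(n_proteins, baseline_mean, baseline_sd)
    effect <- c(rep(log2fc, n_enriched), rep(0, n_proteins - n_enriched))

    feat <- tibble::tibble(
      pidx = rep(seq_len(n_proteins), each = n_features),
      protein = rep(prot, each = n_features),
      feature = paste0(rep(prot, each = n_features), "_f",
                       rep(seq_len(n_features), n_proteins)),
      offset = rnorm(n_proteins * n_features, 0, feature_response_sd))
    w_by_protein <- split(2^feat$offset, feat$pidx)
    sd_meas <- cv_to_sdlog2(calibrate_feature_cv(replicate_cv, w_by_protein))

    runs <- tibble::tibble(
      run = c(sprintf("G1_r%d", seq_len(n_per_group)),
              sprintf("G2_r%d", seq_len(n_per_group))),
      animal = c(sprintf("a%d", seq_len(n_per_group)),
                 sprintf("a%d", n_per_group + seq_len(n_per_group))),
      sex = rep(rep(c("F", "M"), length.out = n_per_group), 2),
      age = 56L, region = "CX",
      cell_type = rep(c("G1", "G2"), each = n_per_group),
      fraction = rep(c("sorted", "control"), each = n_per_group),
      batch = "B1")

    recs <- vector("list", nrow(runs))
    for (i in seq_len(nrow(runs))) {
      mu <- base[feat$pidx] + feat$offset +
        if (runs$fraction[i] == "sorted") effect[feat$pidx] else 0
      x <- mu + rnorm(nrow(feat), 0, sd_meas)
      keep <- rep(TRUE, length(x))
      if (!is.null(missingness)) {
        keep <- runif(length(x)) >=
          plogis(missingness$slope * (missingness$midpoint - x))
      }
      recs[[i]] <- tibble::tibble(protein = feat$protein[keep],
                                  feature = feat$feature[keep],
                                  run = runs$run[i], intensity = 2^x[keep])
    }
    feature_table(dplyr::bind_rows(recs), runs)
  })
}

#' Write / read a ground-truth bundle
#'
#' Serializes the ground truth and scenario as plain TSV/YAML files:
#' `types.tsv`, `traits.tsv`, `proteins.tsv`, `true_abundance.tsv` (long),
#' `module_factors.tsv`, `complexes.tsv`, `negative_pairs.tsv`,
#' `trait_spec.tsv`, `scenario.yaml`, `truth_meta.yaml`. Tables round-trip
#' losslessly through [read_truth_bundle()].
#'
#' @param truth A `ground_truth`.
#' @param scenario A `sorting_scenario` (optional; `NULL` skips
#'   `scenario.yaml`).
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite existing files? Default `FALSE`.
#' @return The directory, invisibly.
#' @export
write_truth_bundle <- function(truth, scenario = NULL, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("types.tsv", "traits.tsv", "proteins.tsv",
                            "true_abundance.tsv", "module_factors.tsv",
                            "complexes.tsv", "negative_pairs.tsv",
                            "trait_spec.tsv", "truth_meta.yaml"))
  if (!overwrite && any(file.exists(paths))) {
    stop_input(sprintf("truth bundle exists at %s (use overwrite = TRUE)", dir))
  }
  readr::write_tsv(truth$types, file.path(dir, "types.tsv"))
  readr::write_tsv(truth$traits, file.path(dir, "traits.tsv"))
  readr::write_tsv(truth$proteins, file.path(dir, "proteins.tsv"))
  abun_long <- tibble::as_tibble(as.data.frame.table(truth$true_abundance,
                                                     stringsAsFactors = FALSE)) %>%
    setNames(c("protein", "type", "log2_abundance"))
  readr::write_tsv(abun_long, file.path(dir, "true_abundance.tsv"))
  fac_long <- tibble::as_tibble(as.data.frame.table(truth$module_factors,
                                                    stringsAsFactors = FALSE)) %>%
    setNames(c("module", "type", "factor_value"))
  readr::write_tsv(fac_long, file.path(dir, "module_factors.tsv"))
  readr::write_tsv(truth$complexes, file.path(dir, "complexes.tsv"))
  readr::write_tsv(truth$negative_pairs, file.path(dir, "negative_pairs.tsv"))
  readr::write_tsv(truth$trait_spec, file.path(dir, "trait_spec.tsv"))
  yaml::write_yaml(c(truth$params, list(seed = truth$seed)),
                   file.path(dir, "truth_meta.yaml"), precision = 15L)
  if (!is.null(scenario)) {
    yaml::write_yaml(unclass(scenario), file.path(dir, "scenario.yaml"),
                     precision = 15L)
  }
  invisible(dir)
}

#' @rdname write_truth_bundle
#' @export
read_truth_bundle <- function(dir) {
  rd <- function(f, ct = NULL) readr::read_tsv(file.path(dir, f), col_types = ct,
                                               progress = FALSE)
  types <- rd("types.tsv", "ccc")
  traits <- rd("traits.tsv", "cdd")
  proteins <- rd("proteins.tsv", "cdic")
  abun <- rd("true_abundance.tsv", "ccd")
  fac <- rd("module_factors.tsv", "ccd")
  complexes <- rd("complexes.tsv", "cc")
  pairs <- rd("negative_pairs.tsv", "cccd")
  tspec <- rd("trait_spec.tsv", "icd")
  meta <- yaml::read_yaml(file.path(dir, "truth_meta.yaml"))

  true_abundance <- matrix(NA_real_, nrow(proteins), nrow(types),
                           dimnames = list(proteins$protein, types$type))
  true_abundance[cbind(abun$protein, abun$type)] <- abun$log2_abundance
  mods <- unique(fac$module)
  module_factors <- matrix(NA_real_, length(mods), nrow(types),
                           dimnames = list(mods, types$type))
  module_factors[cbind(fac$module, fac$type)] <- fac$factor_value

  scenario <- NULL
  if (file.exists(file.path(dir, "scenario.yaml"))) {
    sc <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
    if (!is.null(sc$prevalence)) sc$prevalence <- unlist(sc$prevalence)
    scenario <- structure(sc, class = "sorting_scenario")
  }
  truth <- structure(list(
    types = types, traits = traits, proteins = proteins,
    true_abundance = true_abundance, module_factors = module_factors,
    trait_spec = tspec, complexes = complexes, negative_pairs = pairs,
    seed = meta$seed,
    params = meta[setdiff(names(meta), "seed")]), class = "ground_truth")
  list(truth = truth, scenario = scenario)
}
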