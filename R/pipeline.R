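#' Assemble a pipeline configuration
#'
#' One configuration object drives the whole analysis. Defaults equal the
#' standard printed settings of the sorting-proteomics workflow:
#' fold-change cutoff 1.1, alpha 0.05, 6 features / 12 measurements,
#' soft power 6, edge-weight cutoff 0.3. Every random stage receives a seed
#' derived deterministically from the master seed.
#'
#' @param mode `"synthetic"` (generate data from a ground truth) or
#'   `"tables"` (read TSV inputs).
#' @param out_dir Output directory for the artifact bundle.
#' @param seed Master seed.
#' @param truth,scenario Named lists of [ground_truth()] /
#'   [sorting_scenario()] arguments (synthetic mode; seeds are derived).
#' @param paths Named list of input paths (tables mode): `tables_stem`
#'   (feature-table stem for [read_feature_table()]), optional `traits`,
#'   `complexes`, `families` TSVs.
#' @param fc_cutoff,alpha,min_features,min_measurements,beta,weight_cutoff
#'   Analysis cutoffs.
#' @param min_module_size,merge_threshold,cut_height Module-detection
#'   settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "tables"), out_dir, seed,
                            truth = list(), scenario = list(), paths = list(),
                            fc_cutoff = 1.1, alpha = 0.05, min_features = 6,
                            min_measurements = 12, beta = 6,
                            weight_cutoff = 0.3, min_module_size = 20,
                            merge_threshold = 0.75, cut_height = NULL) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
              truth = truth, scenario = scenario, paths = paths,
              fc_cutoff = fc_cutoff, alpha = alpha,
              min_features = min_features,
              min_measurements = min_measurements, beta = beta,
              weight_cutoff = weight_cutoff,
              min_module_size = min_module_size,
              merge_threshold = merge_threshold, cut_height = cut_height)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file holding the configuration fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(cfg$mode %in% c("synthetic", "tables"), "mode must be synthetic or tables")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a single integer")
  chk(cfg$fc_cutoff > 1, "fc_cutoff must exceed 1")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  chk(cfg$beta > 0, "beta must be > 0")
  chk(cfg$min_features >= 1 && cfg$min_measurements >= 1,
      "testability thresholds must be >= 1")
  if (cfg$mode == "tables") {
    chk(!is.null(cfg$paths$tables_stem), "tables mode requires paths$tables_stem")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid pipeline configuration:\n",
                 paste("-", problems, collapse = "\n")),
          class = "fassprot_validation_error")
  }
  invisible(cfg)
}

#' Validate pipeline input tables
#'
#' Schema, uniqueness, pairing and annotation checks on a raw feature /
#' run-annotation pair, reported as one row per violation with the
#' offending record indices.
#'
#' @param features Long feature tibble (`protein`, `feature`, `run`,
#'   `intensity`).
#' @param runs Run-annotation tibble.
#' @return Tibble: `rule`, `detail`, `rows` (comma-separated offending row
#'   numbers of `features`, or `NA`). Zero rows = clean.
#' @export
validate_inputs <- function(features, runs) {
  v <- list()
  add <- function(rule, detail, rows = NA_character_) {
    v[[length(v) + 1]] <<- tibble::tibble(rule = rule, detail = detail,
                                          rows = rows)
  }
  need_f <- setdiff(c("protein", "feature", "run", "intensity"), names(features))
  if (length(need_f) > 0) add("schema", paste("features missing columns:",
                                              paste(need_f, collapse = ", ")))
  need_r <- setdiff(c("run", "animal", "region", "cell_type", "fraction"),
                    names(runs))
  if (length(need_r) > 0) add("schema", paste("runs missing columns:",
                                              paste(need_r, collapse = ", ")))
  if (length(need_f) == 0) {
    key <- paste(features$protein, features$feature, features$run)
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    if (length(dup) > 0) {
      add("duplicate record", "duplicated (protein, feature, run)",
          paste(head(dup, 20), collapse = ","))
    }
    bad <- which(!is.na(features$intensity) & features$intensity <= 0)
    if (length(bad) > 0) {
      add("nonpositive intensity", "intensities must be > 0 where present",
          paste(head(bad, 20), collapse = ","))
    }
    if (length(need_r) == 0) {
      orphan <- which(!features$run %in% runs$run)
      if (length(orphan) > 0) {
        add("unknown run", paste("runs not annotated:",
                                 paste(head(unique(features$run[orphan]), 5),
                                       collapse = ", ")),
            paste(head(orphan, 20), collapse = ","))
      }
    }
  }
  if (length(need_r) == 0) {
    badf <- setdiff(unique(runs$fraction), c("sorted", "control"))
    if (length(badf) > 0) add("bad fraction", paste("unknown fraction label:",
                                                    paste(badf, collapse = ", ")))
    s <- runs[runs$fraction == "sorted", ]
    ckey <- paste(runs$animal[runs$fraction == "control"],
                  runs$region[runs$fraction == "control"])
    unpaired <- s$run[!paste(s$animal, s$region) %in% ckey]
    if (length(unpaired) > 0) {
      add("unpaired sorted run", paste("no matched control for:",
                                       paste(head(unpaired, 10), collapse = ", ")))
    }
  }
  if (length(v) == 0) {
    tibble::tibble(rule = character(), detail = character(), rows = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesize/ingest, validation, normalization, per-region
#' model fitting and contrast calling, membership calling, profile-matrix
#' construction with PCA and variance partitioning, network construction,
#' and pair statistics, writing a TSV artifact bundle plus a JSON manifest
#' (stage list, output md5 hashes, derived seeds). Re-running with the
#' same configuration and master seed reproduces the bundle byte for byte.
#'
#' @param config A `pipeline_config` (or path to its YAML form).
#' @return Invisibly, a list with the in-memory stage results
#'   (`feature_table`, `contrasts`, `calls`, `partitions`, `profile_matrix`,
#'   `profile_types`, `pca`, `varpart`, `network`, `complex_stats`,
#'   `pair_screen`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seeds <- list(truth = derive_seed(config$seed, 1L),
                scenario = derive_seed(config$seed, 2L),
                pairstats = derive_seed(config$seed, 3L))
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out, name)
    readr::write_tsv(df, p)
    written <<- c(written, p)
    p
  }

  truth <- scenario <- NULL
  traits <- complexes <- families <- NULL
  if (config$mode == "synthetic") {
    truth <- do.call(ground_truth, c(config$truth, list(seed = seeds$truth)))
    scenario <- do.call(sorting_scenario,
                        c(config$scenario, list(seed = seeds$scenario)))
    ft <- simulate_experiment(truth, scenario)
    write_truth_bundle(truth, scenario, file.path(out, "truth"),
                       overwrite = TRUE)
    write_feature_table(ft, file.path(out, "input"), overwrite = TRUE)
    written <- c(written, list.files(file.path(out, "truth"),
                                     full.names = TRUE),
                 paste0(file.path(out, "input"), c("_features.tsv", "_runs.tsv")))
    traits <- truth$traits
    complexes <- truth$complexes
    families <- split(
      c(truth$negative_pairs$protein_a, truth$negative_pairs$protein_b),
      rep(truth$negative_pairs$pair_id, 2))
  } else {
    ft <- read_feature_table(config$paths$tables_stem)
    if (!is.null(config$paths$traits)) {
      traits <- readr::read_tsv(config$paths$traits, show_col_types = FALSE)
    }
    if (!is.null(config$paths$complexes)) {
      complexes <- readr::read_tsv(config$paths$complexes, show_col_types = FALSE)
    }
    if (!is.null(config$paths$families)) {
      fam <- readr::read_tsv(config$paths$families, show_col_types = FALSE)
      families <- split(fam$protein, fam$family)
    }
  }

  viol <- validate_inputs(ft$features, ft$runs)
  emit(viol, "validation.tsv")
  if (nrow(viol) > 0) {
    abort(sprintf("input validation failed with %d violation(s); see validation.tsv",
                  nrow(viol)),
          class = "fassprot_validation_error")
  }

  ft <- normalize_runs(ft)

  # Per-region fits: sorted runs grouped by synapse type, controls pooled
  # per region.
  runs <- ft$runs
  runs$type <- paste(runs$region, runs$cell_type, sep = ".")
  contrasts <- list()
  calls <- list()
  partitions <- list()
  for (rg in unique(runs$region)) {
    rr <- runs[runs$region == rg, ]
    gmap <- ifelse(rr$fraction == "sorted", rr$type, paste0(rg, ".P2"))
    names(gmap) <- rr$run
    sub <- structure(list(
      features = dplyr::filter(ft$features, .data$run %in% rr$run),
      runs = rr), class = "feature_table")
    fits <- fit_protein_models(sub, group = gmap,
                               min_features = config$min_features,
                               min_measurements = config$min_measurements)
    types <- sort(unique(rr$type[rr$fraction == "sorted"]))
    ctl <- paste0(rg, ".P2")
    vs_control <- list()
    for (tt in types) {
      res <- compare_groups(fits, setNames(c(1, -1), c(tt, ctl)),
                            label = paste(tt, "vs", ctl)) %>%
        adjust_and_call(fc_cutoff = config$fc_cutoff, alpha = config$alpha)
      vs_control[[tt]] <- res
      contrasts[[length(contrasts) + 1]] <- res
    }
    direct <- list()
    if (length(types) >= 2) {
      for (i in seq_len(length(types) - 1)) {
        for (j in seq(i + 1, length(types))) {
          res <- compare_groups(fits, setNames(c(1, -1), c(types[i], types[j])),
                                label = paste(types[i], "vs", types[j])) %>%
            adjust_and_call(fc_cutoff = config$fc_cutoff, alpha = config$alpha)
          direct[[paste(types[i], types[j], sep = "|")]] <- res
          contrasts[[length(contrasts) + 1]] <- res
        }
      }
    }
    for (tt in types) {
      others <- setdiff(types, tt)[seq_len(min(2, length(types) - 1))]
      getd <- function(other) {
        if (is.na(other)) return(NULL)
        key <- paste(sort(c(tt, other))[1], sort(c(tt, other))[2], sep = "|")
        d <- direct[[key]]
        if (is.null(d)) return(NULL)
        # Orient so positive log2FC = enriched in the target type.
        if (sort(c(tt, other))[1] != tt) {
          d$log2fc <- -d$log2fc
          d$t <- -d$t
          d$call <- dplyr::recode(d$call, enriched = "de-enriched",
                                  `de-enriched` = "enriched")
        }
        d
      }
      vb <- if (length(others) >= 1) getd(others[1]) else NULL
      vc <- if (length(others) >= 2) getd(others[2]) else NULL
      calls[[tt]] <- call_proteome(vs_control[[tt]], vb, vc, type = tt)
    }
    if (length(types) >= 2) {
      for (i in seq_len(length(types) - 1)) {
        for (j in seq(i + 1, length(types))) {
          key <- paste(types[i], types[j], sep = "|")
          part <- partition_shared(vs_control[[types[i]]],
                                   vs_control[[types[j]]],
                                   direct[[key]],
                                   labels = c(types[i], types[j]))
          part$pair_types <- key
          partitions[[key]] <- part
        }
      }
    }
  }
  contrasts_tb <- dplyr::bind_rows(contrasts)
  calls_tb <- dplyr::bind_rows(calls)
  partitions_tb <- if (length(partitions)) dplyr::bind_rows(partitions) else
    tibble::tibble()
  emit(contrasts_tb, "contrasts.tsv")
  emit(calls_tb, "calls.tsv")
  if (nrow(partitions_tb) > 0) emit(partitions_tb, "partitions.tsv")

  pm <- build_profile_matrix(ft)
  pmt <- average_by_type(pm)
  emit(as_tibble.profile_matrix(pm), "profiles.tsv")
  emit(as_tibble.profile_matrix(pmt), "profiles_type.tsv")

  pca <- run_pca(pm)
  emit(pca$scores, "pca_scores.tsv")

  vp <- tryCatch(partition_variance(pm), fassprot_input_error = function(e) NULL)
  if (!is.null(vp)) emit(vp$fractions, "varpart.tsv")

  network <- NULL
  if (ncol(pmt$values) >= 4) {
    network <- build_network(pmt, traits = traits, beta = config$beta,
                             min_module_size = config$min_module_size,
                             cut_height = config$cut_height,
                             merge_threshold = config$merge_threshold,
                             weight_cutoff = config$weight_cutoff)
    emit(tibble::tibble(protein = names(network$labels),
                        module = unname(network$labels)), "modules.tsv")
    emit(network$edges, "edges.tsv")
    if (!is.null(network$module_trait)) {
      mt <- network$module_trait
      mt_tb <- tibble::as_tibble(as.data.frame.table(mt$r,
                                                     stringsAsFactors = FALSE)) %>%
        setNames(c("module", "trait", "r"))
      mt_tb$p <- as.data.frame.table(mt$p)$Freq
      emit(mt_tb, "module_trait.tsv")
    }
  }

  complex_stats <- NULL
  if (!is.null(complexes) && nrow(complexes) > 0) {
    complex_stats <- tryCatch(
      complex_coregulation(pmt, complexes, seed = seeds$pairstats),
      fassprot_input_error = function(e) NULL)
    if (!is.null(complex_stats)) {
      emit(tibble::tibble(median_complex_r = complex_stats$median_complex,
                          median_random_r = complex_stats$median_random,
                          p_permutation = complex_stats$p_permutation,
                          n_pairs_complex = complex_stats$n_pairs_complex,
                          n_pairs_random = complex_stats$n_pairs_random),
           "complex_stats.tsv")
    }
  }

  screen <- NULL
  if (!is.null(families) && length(families) > 0) {
    screen <- screen_negative_pairs(pmt, families = families,
                                    alpha = config$alpha)
    emit(screen$pairs, "pairs.tsv")
  }

  summary_tb <- tibble::tibble(
    stage = c("input", "calls", "profiles", "network"),
    detail = c(
      sprintf("%d proteins, %d runs", dplyr::n_distinct(ft$features$protein),
              nrow(ft$runs)),
      sprintf("%d enriched, %d de-enriched, %d not significant",
              sum(calls_tb$status == "enriched"),
              sum(calls_tb$status == "de-enriched"),
              sum(calls_tb$status == "not significant")),
      sprintf("%d proteins x %d pairs", nrow(pm$values), ncol(pm$values)),
      if (is.null(network)) "skipped (< 4 types)" else
        sprintf("%d modules, %d edges",
                length(setdiff(unique(network$labels), 0L)),
                nrow(network$edges))))
  emit(summary_tb, "summary.tsv")

  manifest <- list(
    package = "fassprot",
    version = as.character(utils::packageVersion("fassprot")),
    mode = config$mode, master_seed = config$seed, derived_seeds = seeds,
    settings = config[c("fc_cutoff", "alpha", "min_features",
                        "min_measurements", "beta", "weight_cutoff")],
    outputs = lapply(sort(unique(written)), function(p) {
      rel <- if (startsWith(p, out)) {
        sub("^/+", "", substring(p, nchar(out) + 1))
      } else p
      list(file = rel, md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(feature_table = ft, truth = truth, scenario = scenario,
                 contrasts = contrasts_tb, calls = calls_tb,
                 partitions = partitions_tb, profile_matrix = pm,
                 profile_types = pmt, pca = pca, varpart = vp,
                 network = network, complex_stats = complex_stats,
                 pair_screen = screen, manifest = manifest))
}
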