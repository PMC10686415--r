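#' Construct a feature-level quantification table
#'
#' The universal input of the pipeline: long-format feature-level intensities
#' (one row per protein group x feature x run) joined to a run-annotation
#' table describing each mass-spectrometry run (animal, sex, age, brain
#' region, cell type / Cre line, fraction, batch). Fractions follow the
#' sorting nomenclature: `"sorted"` for the sorted synaptosome gate and
#' `"control"` for the unsorted control gate.
#'
#' @param features Tibble with columns `protein`, `feature`, `run`,
#'   `intensity`. Intensities must be strictly positive where present;
#'   missing measurements are simply absent rows (or `NA` intensities, which
#'   are dropped on construction).
#' @param runs Tibble with columns `run`, `animal`, `region`, `cell_type`,
#'   `fraction` and optionally `sex`, `age`, `batch`.
#' @return An object of class `feature_table`: a list with tibbles
#'   `$features` and `$runs`.
#' @examples
#' ft <- feature_table(
#'   tibble::tibble(protein = "P1", feature = "f1", run = c("r1", "r2"),
#'                  intensity = c(100, 120)),
#'   tibble::tibble(run = c("r1", "r2"), animal = "a1", region = "CX",
#'                  cell_type = "Camk2a", fraction = c("sorted", "control"))
#' )
#' ft
#' @export
feature_table <- function(features, runs) {
  features <- tibble::as_tibble(features)
  runs <- tibble::as_tibble(runs)
  assert_columns(features, c("protein", "feature", "run", "intensity"), "features")
  assert_columns(runs, c("run", "animal", "region", "cell_type", "fraction"), "runs")
  features <- dplyr::filter(features, !is.na(.data$intensity))
  if (any(features$intensity <= 0)) {
    stop_input("feature intensities must be strictly positive where present")
  }
  dup <- features %>%
    dplyr::count(.data$protein, .data$feature, .data$run) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_input(sprintf("duplicated (protein, feature, run) records, e.g. %s/%s/%s",
                       dup$protein[1], dup$feature[1], dup$run[1]))
  }
  orphan <- setdiff(unique(features$run), runs$run)
  if (length(orphan) > 0) {
    stop_input(sprintf("runs present in features but not annotated: %s",
                       paste(head(orphan, 5), collapse = ", ")))
  }
  bad_frac <- setdiff(unique(runs$fraction), c("sorted", "control"))
  if (length(bad_frac) > 0) {
    stop_input(sprintf("fraction must be 'sorted' or 'control'; found: %s",
                       paste(bad_frac, collapse = ", ")))
  }
  structure(list(features = features, runs = runs), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d records | %d proteins | %d runs (%d sorted, %d control)\n",
              nrow(x$features), dplyr::n_distinct(x$features$protein),
              nrow(x$runs), sum(x$runs$fraction == "sorted"),
              sum(x$runs$fraction == "control")))
  invisible(x)
}

#' Flatten a feature table to one annotated tibble
#'
#' Joins the run annotation onto the feature records, giving the long tidy
#' form used by most downstream verbs.
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return A tibble with one row per measurement and the run annotation
#'   columns appended.
#' @exportS3Method tibble::as_tibble
as_tibble.feature_table <- function(x, ...) {
  dplyr::left_join(x$features, x$runs, by = "run")
}

#' Read / write feature tables as TSV
#'
#' `write_feature_table()` writes the two component tables
#' (`<stem>_features.tsv`, `<stem>_runs.tsv`); `read_feature_table()` reads
#' them back. Plain UTF-8 TSV with a header row.
#'
#' @param x A `feature_table`.
#' @param stem Path stem (without suffix) for the two files.
#' @param overwrite Overwrite existing files? Default `FALSE`.
#' @return `write_feature_table()` returns the written paths invisibly;
#'   `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(x, stem, overwrite = FALSE) {
  paths <- paste0(stem, c("_features.tsv", "_runs.tsv"))
  if (!overwrite && any(file.exists(paths))) {
    stop_input(sprintf("output exists (use overwrite = TRUE): %s",
                       paths[file.exists(paths)][1]))
  }
  readr::write_tsv(x$features, paths[1])
  readr::write_tsv(x$runs, paths[2])
  invisible(paths)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(stem) {
  feats <- readr::read_tsv(paste0(stem, "_features.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  runs <- readr::read_tsv(paste0(stem, "_runs.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  feature_table(feats, runs)
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) character(0) else unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
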