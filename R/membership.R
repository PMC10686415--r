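#' Call synapse-type proteome membership
#'
#' Applies the three-criterion membership rule for a target type A against
#' its unsorted control and up to two sibling types from the same brain
#' region. A protein belongs to the type-A proteome when it satisfies at
#' least one of:
#'
#' * **I** — enriched in the sorted-vs-control comparison and not
#'   significantly different in the direct A-vs-B comparison;
#' * **II** — significantly enriched in the direct A-over-B comparison and
#'   carrying a positive fold-change vs control;
#' * **III** — as II for the direct A-over-C comparison.
#'
#' "Not significantly different" means: not in the adjusted-significant set
#' of the direct comparison (whether gated out by fold-change, p-failing,
#' untestable, or absent). Criteria II/III additionally require the
#' vs-control comparison to be testable; proteins failing only that clause
#' are flagged. Proteins quantified only vs control are eligible via
#' criterion I.
#'
#' @param vs_control Called results ([adjust_and_call()]) for sorted A vs
#'   control.
#' @param vs_typeB Called results for the direct A vs B comparison
#'   (positive log2FC = enriched in A), or `NULL`.
#' @param vs_typeC As `vs_typeB` for a third type, or `NULL`.
#' @param type Label recorded in the output; default `"A"`.
#' @return Tibble (one row per protein seen in any input): `protein`,
#'   `type`, `status` (`enriched` / `de-enriched` / `not significant` /
#'   `not quantified`), `criterion` (`I`/`II`/`III`/`none`) and `flag`.
#' @export
call_proteome <- function(vs_control, vs_typeB = NULL, vs_typeC = NULL,
                          type = "A") {
  assert_columns(vs_control, c("protein", "log2fc", "call", "testable"),
                 "vs_control")
  prot <- unique(c(vs_control$protein,
                   if (!is.null(vs_typeB)) vs_typeB$protein,
                   if (!is.null(vs_typeC)) vs_typeC$protein))
  ctl <- vs_control[match(prot, vs_control$protein), ]
  getb <- function(cmp) {
    if (is.null(cmp)) {
      list(call = rep(NA_character_, length(prot)))
    } else {
      list(call = cmp$call[match(prot, cmp$protein)])
    }
  }
  b <- getb(vs_typeB); cc <- getb(vs_typeC)

  ctl_call <- ctl$call
  ctl_quant <- !is.na(ctl_call)
  ctl_testable <- !is.na(ctl$testable) & ctl$testable
  ctl_pos <- ctl_quant & !is.na(ctl$log2fc) & ctl$log2fc > 0

  not_sig_direct <- function(call) is.na(call) | !(call %in% c("enriched", "de-enriched"))
  enriched_over <- function(call) !is.na(call) & call == "enriched"

  crit1 <- ctl_quant & ctl_call == "enriched" & not_sig_direct(b$call)
  crit2_core <- enriched_over(b$call) & ctl_pos
  crit3_core <- enriched_over(cc$call) & ctl_pos
  crit2 <- crit2_core & ctl_testable
  crit3 <- crit3_core & ctl_testable
  flag <- dplyr::case_when(
    (crit2_core | crit3_core) & !ctl_testable ~ "direct-enriched but vs-control not testable",
    (enriched_over(b$call) | enriched_over(cc$call)) & !ctl_quant ~
      "direct-enriched but absent vs control",
    TRUE ~ NA_character_)

  criterion <- dplyr::case_when(crit1 ~ "I", crit2 ~ "II", crit3 ~ "III",
                                TRUE ~ "none")
  status <- dplyr::case_when(
    criterion != "none" ~ "enriched",
    ctl_quant & ctl_call == "de-enriched" ~ "de-enriched",
    !ctl_quant ~ "not quantified",
    TRUE ~ "not significant")
  tibble::tibble(protein = prot, type = type, status = status,
                 criterion = criterion, flag = flag)
}

#' Partition two type proteomes into type-enriched and shared
#'
#' Shared proteins are significantly enriched in both types against their
#' unsorted controls and not significantly different in the direct A-vs-B
#' comparison. A protein significant in the direct comparison is labeled
#' A-enriched (positive side) or B-enriched (negative side) regardless of
#' control status; everything else is unassigned.
#'
#' @param callsA,callsB Called sorted-vs-control results
#'   ([adjust_and_call()]) for types A and B.
#' @param direct Called results of the direct A vs B comparison (positive
#'   log2FC = higher in A).
#' @param labels Length-2 character vector naming the partitions; default
#'   `c("A", "B")`.
#' @return Tibble: `protein`, `partition` (`A-enriched`, `B-enriched`,
#'   `shared`, `unassigned`).
#' @export
partition_shared <- function(callsA, callsB, direct, labels = c("A", "B")) {
  prot <- unique(c(callsA$protein, callsB$protein, direct$protein))
  ca <- callsA$call[match(prot, callsA$protein)]
  cb <- callsB$call[match(prot, callsB$protein)]
  cd <- direct$call[match(prot, direct$protein)]
  both_sig_direct <- !is.na(cd) & cd %in% c("enriched", "de-enriched")
  enr <- function(x) !is.na(x) & x == "enriched"
  partition <- dplyr::case_when(
    !is.na(cd) & cd == "enriched" ~ paste0(labels[1], "-enriched"),
    !is.na(cd) & cd == "de-enriched" ~ paste0(labels[2], "-enriched"),
    enr(ca) & enr(cb) & !both_sig_direct ~ "shared",
    TRUE ~ "unassigned")
  tibble::tibble(protein = prot, partition = partition)
}

#' Sorting-enrichment interaction between two subfields
#'
#' Difference-of-differences contrast inside one joint per-protein fit of
#' the four groups:
#' `(A_sorted - A_control) - (B_sorted - B_control)`,
#' with the standard error propagated from the joint design. This asks
#' whether sorting enrichment differs between the two subfields rather
#' than whether either is enriched.
#'
#' @param fits `protein_fits` over all four groups.
#' @param a_sorted,a_control,b_sorted,b_control Group labels in `fits`.
#' @param label Contrast label; default descriptive.
#' @return A [compare_groups()] result tibble.
#' @export
interaction_contrast <- function(fits, a_sorted, a_control,
                                 b_sorted, b_control, label = NULL) {
  if (is.null(label)) {
    label <- sprintf("(%s - %s) - (%s - %s)", a_sorted, a_control,
                     b_sorted, b_control)
  }
  w <- setNames(c(1, -1, -1, 1), c(a_sorted, a_control, b_sorted, b_control))
  compare_groups(fits, w, label = label)
}

#' Overlap of a member set with a reference annotation
#'
#' Fraction of called members carrying the reference annotation, with a
#' hypergeometric enrichment p value against the quantified universe.
#'
#' @param members Character vector of member proteins (must be non-empty
#'   and a subset of `universe`).
#' @param universe Character vector of all quantified proteins.
#' @param reference Character vector of reference-annotated proteins
#'   (intersected with the universe).
#' @return One-row tibble: `n_members`, `n_reference`, `overlap`,
#'   `fraction`, `p`.
#' @export
overlap_with_reference <- function(members, universe, reference) {
  members <- unique(members)
  if (length(members) == 0) stop_input("member set is empty; overlap fraction undefined")
  bad <- setdiff(members, universe)
  if (length(bad) > 0) {
    stop_input(sprintf("members outside the universe: %s",
                       paste(head(bad, 5), collapse = ", ")))
  }
  ref <- intersect(unique(reference), universe)
  k <- length(intersect(members, ref))
  tibble::tibble(
    n_members = length(members), n_reference = length(ref), overlap = k,
    fraction = k / length(members),
    p = phyper(k - 1, length(ref), length(universe) - length(ref),
               length(members), lower.tail = FALSE))
}
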