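#' Filter 1: specificity above Cre-negative background
#'
#' Classifies proteins as cell-type specific from construct-minus-control
#' contrasts: a protein is retained for a construct when its log2 fold
#' change is positive and its BH q-value is below `q_max`. Nonspecific bead
#' binders and endogenously biotinylated proteins have no Cre+/Cre-
#' difference and are discarded here. The input must consist of contrasts
#' against the named control condition; anything else is an error, guarding
#' against running the specificity filter on the wrong comparison.
#'
#' @param contrasts A `tmt_contrasts` tibble of `construct - control`
#'   comparisons (one or several constructs).
#' @param control The Cre-negative control condition name.
#' @param q_max Significance cutoff on the BH q-value.
#' @param lfc_min Enrichment direction cutoff (strict; default 0).
#' @return A `filter1_result` tibble: one row per accession with
#'   `specific_in` (list of constructs passing), `n_passed`, `retained`.
#'   The per-contrast detail, with a discard reason per failing row, is in
#'   `attr(., "report")`.
#' @export
filter1_specific <- function(contrasts, control = "CTRL", q_max = 0.05,
                             lfc_min = 0) {
  labels <- unique(contrasts$contrast)
  parts <- parse_contrast_labels(labels)
  if (any(parts[, 2] != control)) {
    abort(sprintf(
      "filter 1 expects contrasts against control '%s'; got: %s", control,
      paste(labels[parts[, 2] != control], collapse = ", ")),
      class = "apexquant_validation_error")
  }
  report <- contrasts |>
    mutate(
      condition = parse_contrast_labels(.data$contrast)[, 1],
      passed = .data$log2fc > lfc_min & .data$q < q_max,
      reason = case_when(
        .data$log2fc > lfc_min & .data$q < q_max ~ NA_character_,
        .data$log2fc <= lfc_min ~ "not_enriched",
        TRUE ~ "not_significant"
      )
    ) |>
    select("accession", "condition", "log2fc", "q", "passed", "reason")
  out <- report |>
    group_by(.data$accession) |>
    summarise(
      specific_in = list(.data$condition[.data$passed]),
      n_passed = sum(.data$passed)
    ) |>
    mutate(retained = .data$n_passed > 0)
  attr(out, "report") <- report
  class(out) <- c("filter1_result", class(tibble::tibble()))
  out
}

#' Read a contaminant accession list
#'
#' Plain text, one accession per line; `#tag` comment lines set the
#' provenance tag of the entries that follow (e.g. `#keratin`).
#'
#' @param path Path to the list file.
#' @param default_tag Tag for entries before any `#tag` line.
#' @return A `contaminant_list` tibble with `accession` and `tag`.
#' @export
read_contaminant_list <- function(path, default_tag = "contaminant") {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines <- lines[lines != ""]
  tag <- default_tag
  acc <- character(); tags <- character()
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      tag <- sub("^#\\s*", "", ln)
    } else {
      acc <- c(acc, ln); tags <- c(tags, tag)
    }
  }
  out <- tibble::tibble(accession = acc, tag = tags) |> distinct()
  class(out) <- c("contaminant_list", class(tibble::tibble()))
  out
}

#' Build a contaminant list in code
#' @param accessions Character vector.
#' @param tag Provenance tag applied to all entries.
#' @return A `contaminant_list` tibble.
#' @export
contaminant_list <- function(accessions, tag = "contaminant") {
  out <- tibble::tibble(accession = unique(accessions), tag = tag)
  class(out) <- c("contaminant_list", class(tibble::tibble()))
  out
}

#' Remove contaminant accessions
#'
#' Set difference against one or more contaminant lists (nonspecific bead
#' binders, keratins, off-target cell-type markers, ...). Removals are
#' attributed to every list tag that matches, so overlapping lists are
#' reported per provenance.
#'
#' @param x Character vector of accessions, or a data frame with an
#'   `accession` column.
#' @param ... `contaminant_list` objects (or plain character vectors).
#' @return `x` without the contaminants; `attr(., "removal_report")` holds
#'   per-tag counts and the removed accessions.
#' @export
remove_contaminants <- function(x, ...) {
  lists <- lapply(list(...), function(l) {
    if (inherits(l, "data.frame")) l else contaminant_list(l)
  })
  all_lists <- bind_rows(lists)
  acc <- if (is.data.frame(x)) x$accession else x
  removed <- intersect(acc, all_lists$accession)
  per_tag <- all_lists |>
    filter(.data$accession %in% removed) |>
    count(.data$tag, name = "n_removed")
  out <- if (is.data.frame(x)) {
    x[!x$accession %in% removed, , drop = FALSE]
  } else {
    setdiff(acc, removed)
  }
  attr(out, "removal_report") <- list(
    n_removed = length(removed), removed = sort(removed), by_tag = per_tag
  )
  out
}

#' Filter 2: subcellular compartment assignment
#'
#' Assigns compartments from nuclear-reference contrasts among proteins that
#' passed the specificity filter. A protein is called `nucleus` when its
#' `H2B - NES` contrast is significantly positive (`q < q_max`,
#' `log2fc > 0`). In three-construct mode (a membrane construct present) a
#' protein is called `membrane` when its `H2B - LCK` contrast is
#' significantly negative; remaining proteins are `unassigned`. In
#' two-compartment mode, proteins that are not nucleus-called are
#' `cytosol_nonH2B`. The two calls are mutually exclusive: a significant
#' negative `H2B - LCK` sign takes the protein to the membrane side.
#'
#' @param h2b_vs_nes A `tmt_contrasts` tibble for the nuclear-vs-cytosol
#'   contrast (`H2B - NES` orientation).
#' @param h2b_vs_lck Optional `tmt_contrasts` for `H2B - LCK`; enables
#'   membrane calls.
#' @param q_max Significance cutoff.
#' @param accessions Optional restriction (e.g. the Filter-1-retained set).
#' @param mode `"auto"` (three-construct iff an LCK table is given),
#'   `"two_compartment"`, or `"three_construct"`.
#' @return A `compartment_calls` tibble: `accession`, `compartment`, the
#'   basis contrasts' `log2fc`/`q`, a human-readable `basis` string, and
#'   `flagged` for proteins missing from the nuclear table.
#' @export
filter2_compartment <- function(h2b_vs_nes, h2b_vs_lck = NULL, q_max = 0.05,
                                accessions = NULL,
                                mode = c("auto", "two_compartment",
                                         "three_construct")) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (is.null(h2b_vs_lck)) "two_compartment" else "three_construct"
  }
  if (mode == "three_construct" && is.null(h2b_vs_lck)) {
    abort("three-construct mode needs an H2B - LCK contrast table",
          class = "apexquant_validation_error")
  }
  nes <- h2b_vs_nes |>
    select("accession", lfc_nes = "log2fc", q_nes = "q",
           nes_contrast = "contrast")
  out <- if (!is.null(h2b_vs_lck)) {
    lck <- h2b_vs_lck |>
      select("accession", lfc_lck = "log2fc", q_lck = "q",
             lck_contrast = "contrast")
    full_join(nes, lck, by = "accession")
  } else {
    nes |> mutate(lfc_lck = NA_real_, q_lck = NA_real_,
                  lck_contrast = NA_character_)
  }
  if (!is.null(accessions)) out <- out |> filter(.data$accession %in% accessions)

  nucleus <- !is.na(out$q_nes) & out$q_nes < q_max & out$lfc_nes > 0
  membrane <- !is.na(out$q_lck) & out$q_lck < q_max & out$lfc_lck < 0
  other <- if (mode == "two_compartment") "cytosol_nonH2B" else "unassigned"
  compartment <- ifelse(membrane, "membrane",
                        ifelse(nucleus, "nucleus", other))
  basis <- character(nrow(out))
  basis[nucleus & !membrane] <- sprintf(
    "%s: log2FC=%.3g, q=%.3g", out$nes_contrast[nucleus & !membrane],
    out$lfc_nes[nucleus & !membrane], out$q_nes[nucleus & !membrane])
  basis[membrane] <- sprintf(
    "%s: log2FC=%.3g, q=%.3g", out$lck_contrast[membrane],
    out$lfc_lck[membrane], out$q_lck[membrane])
  flagged <- is.na(out$lfc_nes)
  if (any(flagged)) {
    warn(sprintf(
      "%d protein(s) absent from the nuclear contrast table; called from the available basis",
      sum(flagged)))
  }
  res <- tibble::tibble(
    accession = out$accession,
    compartment = compartment,
    log2fc_nes = out$lfc_nes, q_nes = out$q_nes,
    log2fc_lck = out$lfc_lck, q_lck = out$q_lck,
    basis = basis, flagged = flagged
  ) |> arrange(.data$accession)
  class(res) <- c("compartment_calls", class(tibble::tibble()))
  attr(res, "mode") <- mode
  res
}

#' Alternative enrichment cutoffs
#'
#' Rank-based or static alternatives to the q-value cutoff: the top `k`
#' proteins by log2 fold change, or all proteins at or above a fold-change
#' threshold. Ties are broken deterministically by (log2fc descending, q
#' ascending, accession ascending).
#'
#' @param contrasts A `tmt_contrasts` tibble (a single contrast).
#' @param mode `"rank_top_k"` or `"static_log2fc"`.
#' @param k Number of proteins to keep in rank mode.
#' @param threshold Inclusive log2FC threshold in static mode.
#' @return Character vector of retained accessions (in cutoff order).
#' @export
alt_cutoff <- function(contrasts, mode = c("rank_top_k", "static_log2fc"),
                       k = NULL, threshold = NULL) {
  mode <- match.arg(mode)
  ord <- contrasts |>
    arrange(desc(.data$log2fc), .data$q, .data$accession)
  if (mode == "rank_top_k") {
    stopifnot(!is.null(k))
    if (k > nrow(ord)) {
      warn(sprintf("k = %d exceeds the %d available proteins; returning all",
                   k, nrow(ord)))
      k <- nrow(ord)
    }
    ord$accession[seq_len(k)]
  } else {
    stopifnot(!is.null(threshold))
    ord$accession[ord$log2fc >= threshold]
  }
}

#' Single-PSM rescue reporting
#'
#' Proteins quantified by exactly one high-confidence unique feature are
#' excluded from inferential testing but reported descriptively: their
#' normalized log2 reporter values per sample (no summarization needed) pass
#' through the same reference-channel batch correction as the main matrix,
#' and per-condition counts of quantified samples are attached (the "n" of
#' the descriptive report).
#'
#' @param psms The filtered `psm_tbl` the partition was computed from.
#' @param design The experiment design.
#' @param rescue Character vector of rescued accessions (from
#'   [partition_quantifiable()]).
#' @param reference_normalize Apply reference-channel correction.
#' @return A long tibble `accession, sample, run, condition, log2_abundance`
#'   with per-condition quantification counts in `attr(., "condition_n")`.
#' @export
rescue_single_psm <- function(psms, design, rescue,
                              reference_normalize = TRUE) {
  design <- as_tmt_design(design)
  if (length(rescue) == 0) {
    out <- tibble::tibble(accession = character(), sample = character(),
                          run = character(), condition = character(),
                          log2_abundance = numeric())
    attr(out, "condition_n") <- tibble::tibble(accession = character(),
                                               condition = character(),
                                               n_quantified = integer())
    return(out)
  }
  pm <- summarize_proteins(psms, design, proteins = sort(rescue))
  if (reference_normalize) pm <- normalize_reference(pm, design)
  long <- tidy(pm) |> filter(!is.na(.data$log2_abundance))
  out <- long |>
    select("accession", "sample", "run", "condition", "log2_abundance")
  n_tbl <- long |>
    filter(!.data$is_reference) |>
    count(.data$accession, .data$condition, name = "n_quantified")
  # conditions with no quantified sample still appear with n = 0
  n_tbl <- tidyr::complete(
    n_tbl, accession = sort(rescue),
    condition = unique(design$condition[!design$is_reference]),
    fill = list(n_quantified = 0L)
  )
  attr(out, "condition_n") <- n_tbl
  out
}
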