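#' Tukey median polish of a two-way table
#'
#' Alternating row/column median sweeps (row sweep first; even-length medians
#' use the midpoint of the two central order statistics) until the largest
#' applied shift falls below `tol`. Missing cells are skipped in every
#' median; all-missing columns stay missing. The fitted channel abundance is
#' the overall effect plus the column effect.
#'
#' @param x Numeric matrix (features x channels), `NA` allowed.
#' @param tol Convergence tolerance on the largest effect change.
#' @param max_iter Iteration cap.
#' @return List with `overall`, `row`, `col`, `fitted` (overall + column
#'   effects), `iterations`, `converged`.
#' @export
median_polish <- function(x, tol = 1e-9, max_iter = 200) {
  stopifnot(is.matrix(x))
  storage.mode(x) <- "double"
  out <- .medpolish_cpp(x, tol = tol, maxit = as.integer(max_iter))
  names(out$fitted) <- colnames(x)
  out
}

#' Global peptide-level median normalization
#'
#' Equalizes reporter loading across run x channel slots: each slot's log2
#' PSM intensities are shifted by (grand median of all slot medians − the
#' slot's median). Applied at the PSM level, before protein summarization.
#' With `enabled = FALSE` the table passes through unchanged, matching
#' workflows that keep construct-level enrichment differences.
#'
#' @param psms A `psm_tbl`.
#' @param design The experiment design.
#' @param enabled Logical switch; `FALSE` returns the input unchanged.
#' @return The adjusted `psm_tbl`.
#' @export
normalize_peptide_medians <- function(psms, design, enabled = TRUE) {
  if (!enabled) return(psms)
  design <- as_tmt_design(design)
  channels <- intersect(unique(design$channel), names(psms))
  runs <- unique(psms$run)
  med <- matrix(NA_real_, length(runs), length(channels),
                dimnames = list(runs, channels))
  for (r in runs) {
    rows <- psms$run == r
    for (ch in design_channels(design, r)) {
      v <- psms[[ch]][rows]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        warn(sprintf("no observed PSM intensities in run %s channel %s; left unshifted",
                     r, ch))
        next
      }
      med[r, ch] <- median(log2(v))
    }
  }
  grand <- median(med, na.rm = TRUE)
  out <- psms
  for (r in runs) {
    rows <- psms$run == r
    for (ch in channels) {
      if (is.na(med[r, ch])) next
      out[[ch]][rows] <- psms[[ch]][rows] * 2^(grand - med[r, ch])
    }
  }
  attr(out, "ingest_log") <- attr(psms, "ingest_log")
  attr(out, "filter_log") <- attr(psms, "filter_log")
  class(out) <- class(psms)
  out
}

#' Summarize PSM intensities to protein x sample log2 abundances
#'
#' For each protein and run, the log2 intensities of its unique PSMs (pooled
#' across fractions) form a PSM x channel matrix that is decomposed by
#' two-way median polish; the protein's abundance in a channel is the
#' overall effect plus that channel's column effect. Channels with no data
#' stay missing; proteins absent from a run are missing in that run's
#' samples.
#'
#' @param psms A filtered `psm_tbl`.
#' @param design The experiment design.
#' @param proteins Accessions to summarize; defaults to the `quantifiable`
#'   set of [partition_quantifiable()] when `partition` is given, else every
#'   accession with unique PSMs.
#' @param partition Optional `quant_partition` restricting to quantifiable
#'   proteins.
#' @param tol,max_iter Median-polish convergence controls.
#' @return A `protein_matrix` tagged `"summarized"`, with per-(protein, run)
#'   PSM counts in `pm_psm_support()`.
#' @export
summarize_proteins <- function(psms, design, proteins = NULL,
                               partition = NULL, tol = 1e-9,
                               max_iter = 200) {
  design <- as_tmt_design(design)
  if (is.null(proteins)) {
    proteins <- if (!is.null(partition)) partition$quantifiable else
      sort(unique(psms$accession[psms$is_unique]))
  }
  uniq <- psms |> filter(.data$is_unique, .data$accession %in% proteins)
  if (nrow(uniq) == 0) {
    abort("no unique PSMs for the requested proteins",
          class = "apexquant_validation_error")
  }
  channels <- intersect(unique(design$channel), names(uniq))
  x <- log2(as.matrix(uniq[, channels, drop = FALSE]))

  prot_f <- factor(uniq$accession, levels = proteins)
  run_levels <- unique(design$run)
  run_f <- factor(uniq$run, levels = run_levels)
  group <- (as.integer(prot_f) - 1L) * length(run_levels) +
    as.integer(run_f)
  ngroups <- length(proteins) * length(run_levels)
  fitted <- .summarize_groups_cpp(x, group, ngroups, tol = tol,
                                  maxit = as.integer(max_iter))

  # map (protein, run, channel) abundances onto samples
  values <- matrix(NA_real_, length(proteins), nrow(design),
                   dimnames = list(proteins, design$sample))
  for (i in seq_len(nrow(design))) {
    g_rows <- (seq_along(proteins) - 1L) * length(run_levels) +
      match(design$run[i], run_levels)
    values[, i] <- fitted[cbind(g_rows, match(design$channel[i], channels))]
  }
  support <- uniq |>
    count(.data$accession, .data$run, name = "n_psms") |>
    rename(accession = "accession")
  new_protein_matrix(values, design, support, "summarized")
}

#' Reference-channel batch correction
#'
#' Corrects between-plex (TMT batch) effects protein-by-protein: for each
#' protein and run, abundances are shifted by (that run's mean reference
#' abundance − the protein's grand mean of reference abundances across
#' runs). After correction a protein's reference values are identical across
#' the runs where they were observed; within-run differences between
#' channels are untouched. Runs where a protein lacks a reference value are
#' left unshifted and flagged.
#'
#' @param pm A `protein_matrix` of per-run summarized abundances.
#' @param design The design; every run must contain a reference channel.
#' @return The corrected `protein_matrix`, tagged `"reference_normalized"`;
#'   unanchored (protein, run) pairs are listed in `attr(., "flags")`.
#' @export
normalize_reference <- function(pm, design = pm_design(pm)) {
  design <- as_tmt_design(design, require_reference = TRUE)
  values <- pm_values(pm)
  runs <- unique(design$run)
  ref_means <- matrix(NA_real_, nrow(values), length(runs),
                      dimnames = list(rownames(values), runs))
  for (r in runs) {
    ref_samples <- design$sample[design$run == r & design$is_reference]
    ref_means[, r] <- rowMeans(values[, ref_samples, drop = FALSE],
                               na.rm = TRUE)
  }
  ref_means[is.nan(ref_means)] <- NA_real_
  grand <- rowMeans(ref_means, na.rm = TRUE)
  shifts <- ref_means - grand
  out <- values
  for (r in runs) {
    cols <- design$sample[design$run == r]
    sh <- shifts[, r]
    sh[is.na(sh)] <- 0 # unanchored: leave unshifted
    out[, cols] <- values[, cols] - sh
  }
  unanchored <- which(is.na(ref_means) &
                        !is.na(grand), arr.ind = TRUE)
  flags <- tibble::tibble(
    accession = rownames(values)[unanchored[, 1]],
    run = runs[unanchored[, 2]],
    flag = "no_reference_value"
  )
  replace_values(pm, out, "reference_normalized", flags = flags)
}

#' Protein-level median normalization
#'
#' Aligns the median protein abundance across samples: each column is
#' shifted by (its median − the median of all column medians). Idempotent;
#' afterwards every column's observed median is equal.
#'
#' @param pm A `protein_matrix`.
#' @return The normalized `protein_matrix`, tagged `"median_normalized"`.
#' @export
normalize_protein_medians <- function(pm) {
  values <- pm_values(pm)
  col_med <- apply(values, 2, median, na.rm = TRUE)
  if (anyNA(col_med)) {
    abort(sprintf("column(s) with no observed values: %s",
                  paste(colnames(values)[is.na(col_med)], collapse = ", ")),
          class = "apexquant_validation_error")
  }
  target <- median(col_med)
  out <- sweep(values, 2, col_med - target, `-`)
  replace_values(pm, out, "median_normalized")
}
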