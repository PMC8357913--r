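#' Column-name dialects for PSM tables
#'
#' PSM exports from different quantification tools name the same fields
#' differently. A dialect maps the tool's column names onto the fields the
#' package needs; reporter-intensity columns are located by a channel prefix
#' (`"<prefix><channel id>"`).
#'
#' Two presets ship: `"native"`, the package's own plain schema
#' (`run, fraction, accessions, peptide, charge, search_q, coisolation_pct`
#' plus one column per channel id), and `"pd"`, matching Proteome
#' Discoverer-style PSM exports.
#'
#' @param preset `"native"` or `"pd"`, or omit and supply fields directly.
#' @param ... Field overrides: `run`, `fraction`, `accessions`, `peptide`,
#'   `charge`, `search_q`, `coisolation_pct`, `channel_prefix`.
#' @return A named list of class `psm_dialect`.
#' @export
psm_dialect <- function(preset = "native", ...) {
  base <- switch(
    preset,
    native = list(run = "run", fraction = "fraction",
                  accessions = "accessions", peptide = "peptide",
                  charge = "charge", search_q = "search_q",
                  coisolation_pct = "coisolation_pct", channel_prefix = ""),
    pd = list(run = "File ID", fraction = NULL,
              accessions = "Master Protein Accessions",
              peptide = "Annotated Sequence", charge = "Charge",
              search_q = "Percolator q-Value",
              coisolation_pct = "Isolation Interference [%]",
              channel_prefix = "Abundance: "),
    abort(sprintf("unknown dialect preset: %s", preset),
          class = "apexquant_parameter_error")
  )
  overrides <- list(...)
  base[names(overrides)] <- overrides
  structure(base, class = "psm_dialect")
}

#' Read a PSM-level quantification table
#'
#' Reads a TSV/CSV export of peptide-spectrum matches with per-channel
#' reporter intensities, standardizes the columns through a [psm_dialect()],
#' and validates the reporter channels against the experiment design. Zero or
#' negative reporter intensities are undefined on the log2 scale and are
#' converted to missing (counted in the ingest log).
#'
#' @param path Path to a tab- or comma-separated PSM table.
#' @param design A `tmt_design` tibble; reporter columns must correspond to
#'   channels present in the design.
#' @param dialect A [psm_dialect()] describing the file's column names.
#' @return A `psm_tbl` tibble: one row per PSM with standardized metadata
#'   columns, `accession`/`is_unique` derived from the accession list, and one
#'   numeric intensity column per channel. The attached `"ingest_log"`
#'   attribute counts rows read and values converted to missing.
#' @export
read_psm_table <- function(path, design, dialect = psm_dialect("native")) {
  if (!file.exists(path)) {
    abort(sprintf("PSM table not found: %s", path),
          class = "apexquant_schema_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, name_repair = "minimal")
  n_parse_fail <- nrow(readr::problems(raw))
  if (n_parse_fail > 0) {
    warn(sprintf("%d cell(s) failed to parse and were set missing",
                 n_parse_fail))
  }
  standardize_psms(raw, design, dialect, n_parse_fail = n_parse_fail)
}

standardize_psms <- function(raw, design, dialect, n_parse_fail = 0) {
  needed <- c(dialect$run, dialect$accessions, dialect$peptide,
              dialect$charge, dialect$search_q, dialect$coisolation_pct)
  check_required_columns(raw, needed, "PSM table")

  all_channels <- unique(design$channel)
  chan_cols <- paste0(dialect$channel_prefix, all_channels)
  found <- chan_cols %in% names(raw)
  if (!any(found)) {
    abort("no reporter-intensity columns matching the design's channels",
          class = "apexquant_schema_error")
  }
  # intensity-like columns that are not design channels are an error: they
  # indicate a design/table mismatch rather than an extra metadata field
  if (nzchar(dialect$channel_prefix)) {
    stray <- setdiff(grep(paste0("^", dialect$channel_prefix), names(raw),
                          value = TRUE), chan_cols)
    if (length(stray) > 0) {
      abort(sprintf("reporter column(s) not in the design: %s",
                    paste(stray, collapse = ", ")),
            class = "apexquant_schema_error")
    }
  }

  accessions <- as.character(raw[[dialect$accessions]])
  acc_split <- stringr::str_split(accessions, ";\\s*")
  is_unique <- lengths(acc_split) == 1L

  psms <- tibble::tibble(
    psm_id = seq_len(nrow(raw)),
    run = as.character(raw[[dialect$run]]),
    fraction = if (!is.null(dialect$fraction) &&
                   dialect$fraction %in% names(raw)) {
      as.character(raw[[dialect$fraction]])
    } else NA_character_,
    accessions = stringr::str_replace_all(accessions, ";\\s*", ";"),
    accession = ifelse(is_unique, vapply(acc_split, `[`, "", 1L),
                       NA_character_),
    is_unique = is_unique,
    peptide = as.character(raw[[dialect$peptide]]),
    charge = as.integer(raw[[dialect$charge]]),
    search_q = as.numeric(raw[[dialect$search_q]]),
    coisolation_pct = as.numeric(raw[[dialect$coisolation_pct]])
  )
  if (any(psms$search_q < 0 | psms$search_q > 1, na.rm = TRUE)) {
    abort("search_q outside [0, 1]", class = "apexquant_validation_error")
  }
  if (any(psms$coisolation_pct < 0 | psms$coisolation_pct > 100,
          na.rm = TRUE)) {
    abort("coisolation_pct outside [0, 100]",
          class = "apexquant_validation_error")
  }
  bad_run <- setdiff(unique(psms$run), unique(design$run))
  if (length(bad_run) > 0) {
    abort(sprintf("PSM run(s) absent from the design: %s",
                  paste(bad_run, collapse = ", ")),
          class = "apexquant_validation_error")
  }

  n_zero <- 0L
  n_offdesign <- 0L
  for (i in seq_along(all_channels)) {
    col <- chan_cols[i]
    vals <- if (col %in% names(raw)) as.numeric(raw[[col]]) else
      rep(NA_real_, nrow(raw))
    zero <- !is.na(vals) & vals <= 0
    n_zero <- n_zero + sum(zero)
    vals[zero] <- NA_real_
    # blank out channels the design does not include for a row's run
    run_has <- psms$run %in% design$run[design$channel == all_channels[i]]
    n_offdesign <- n_offdesign + sum(!is.na(vals) & !run_has)
    vals[!run_has] <- NA_real_
    psms[[all_channels[i]]] <- vals
  }
  if (n_offdesign > 0) {
    warn(sprintf(
      "%d intensity value(s) in channels outside their run's design were dropped",
      n_offdesign))
  }
  attr(psms, "ingest_log") <- list(
    n_rows = nrow(psms), n_parse_failed = n_parse_fail,
    n_nonpositive_to_missing = n_zero,
    n_off_design_dropped = n_offdesign
  )
  class(psms) <- c("psm_tbl", class(tibble::tibble()))
  psms
}

#' Write a PSM table in the native dialect
#' @param psms A `psm_tbl`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms |> select(-any_of(c("psm_id", "accession", "is_unique")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

psm_channel_cols <- function(psms) {
  intersect(names(psms),
            c(tmt_channels(16), tmt_channels(11), tmt_channels(10)))
}

#' Retrieve the machine-readable ingest/filter log of a PSM table
#' @param psms A `psm_tbl`.
#' @return A named list of counts.
#' @export
ingest_log <- function(psms) attr(psms, "ingest_log")

#' Filter PSMs on identification confidence, co-isolation, and uniqueness
#'
#' Retains PSMs with co-isolation interference at or below
#' `coisolation_max` percent, search q-value strictly below `q_max`, and
#' (optionally) a single protein accession. The comparison conventions —
#' inclusive for co-isolation, strict for the q-value — follow the usual
#' reporting of these thresholds; both are configurable. PSMs with a missing
#' value in a filtered field are removed.
#'
#' @param psms A `psm_tbl`.
#' @param coisolation_max Maximum tolerated co-isolation interference (%).
#' @param q_max Upper (exclusive) bound on the search q-value.
#' @param unique_only Keep only PSMs mapping to exactly one protein.
#' @return The retained `psm_tbl`, input order preserved, with a
#'   `"filter_log"` attribute counting removals per criterion.
#' @export
filter_psms <- function(psms, coisolation_max = 70, q_max = 0.01,
                        unique_only = TRUE) {
  ok_coiso <- !is.na(psms$coisolation_pct) &
    psms$coisolation_pct <= coisolation_max
  ok_q <- !is.na(psms$search_q) & psms$search_q < q_max
  ok_unique <- !unique_only | psms$is_unique
  keep <- ok_coiso & ok_q & ok_unique
  out <- psms[keep, , drop = FALSE]
  attr(out, "ingest_log") <- attr(psms, "ingest_log")
  attr(out, "filter_log") <- list(
    n_in = nrow(psms), n_retained = sum(keep),
    n_fail_coisolation = sum(!ok_coiso),
    n_fail_q = sum(!ok_q),
    n_fail_unique = sum(!ok_unique),
    coisolation_max = coisolation_max, q_max = q_max,
    unique_only = unique_only
  )
  if (nrow(out) == 0) warn("no PSMs retained after filtering")
  class(out) <- class(psms)
  out
}

#' Partition proteins by quantifiability
#'
#' A protein enters protein-level summarization only with at least
#' `min_unique_psms` unique features, where a feature is a distinct
#' (peptide, charge) combination of its unique peptides: a protein with one
#' unique peptide therefore needs PSMs at two different charge states.
#' Features are counted per protein over all retained PSMs, across fractions
#' and runs. Proteins with exactly one unique feature are set aside for
#' descriptive single-PSM rescue reporting rather than dropped; accessions
#' observed only in shared (multi-protein) PSMs are dropped outright.
#'
#' @param psms A filtered `psm_tbl` (see [filter_psms()]).
#' @param min_unique_psms Minimum distinct unique features for quantification.
#' @return A `quant_partition` list with character vectors `quantifiable` and
#'   `single_psm_rescue`, and a tibble `dropped` (`accession`, `reason`).
#'   The three sets are disjoint and jointly cover every accession seen.
#' @export
partition_quantifiable <- function(psms, min_unique_psms = 2) {
  uniq <- psms |> filter(.data$is_unique)
  counts <- uniq |>
    distinct(.data$accession, .data$peptide, .data$charge) |>
    count(.data$accession, name = "n_features")
  quantifiable <- counts$accession[counts$n_features >= min_unique_psms]
  rescue <- counts$accession[counts$n_features == 1L]
  mid <- counts$accession[counts$n_features > 1L &
                            counts$n_features < min_unique_psms]
  shared_acc <- unique(unlist(
    stringr::str_split(psms$accessions[!psms$is_unique], ";")
  ))
  shared_only <- setdiff(shared_acc, counts$accession)
  dropped <- bind_rows(
    tibble::tibble(accession = mid, reason = "below_min_unique_features"),
    tibble::tibble(accession = shared_only, reason = "shared_psms_only")
  )
  structure(
    list(quantifiable = sort(quantifiable),
         single_psm_rescue = sort(rescue),
         dropped = arrange(dropped, .data$accession),
         min_unique_psms = min_unique_psms),
    class = "quant_partition"
  )
}

#' @export
print.quant_partition <- function(x, ...) {
  cat(sprintf(
    "<quant_partition> %d quantifiable, %d single-PSM rescue, %d dropped\n",
    length(x$quantifiable), length(x$single_psm_rescue), nrow(x$dropped)))
  invisible(x)
}

#' @export
tidy.quant_partition <- function(x, ...) {
  bind_rows(
    tibble::tibble(accession = x$quantifiable, set = "quantifiable"),
    tibble::tibble(accession = x$single_psm_rescue,
                   set = "single_psm_rescue"),
    tibble::tibble(accession = x$dropped$accession, set = "dropped",
                   reason = if (nrow(x$dropped)) x$dropped$reason else
                     character())
  )
}
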