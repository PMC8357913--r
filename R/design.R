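#' Construct and validate a TMT experiment design
#'
#' An experiment design maps every `(run, channel)` slot of a multiplexed TMT
#' experiment to a sample, its biological condition, a replicate index, and a
#' flag marking pooled reference channels used for between-plex batch
#' correction.
#'
#' @param df Data frame with columns `run`, `channel`, `sample`, `condition`,
#'   `replicate`, `is_reference`.
#' @param require_reference If `TRUE`, every run must contain at least one
#'   reference channel (needed before reference normalization).
#' @return A validated design tibble of class `tmt_design`.
#' @export
as_tmt_design <- function(df, require_reference = FALSE) {
  check_required_columns(
    df, c("run", "channel", "sample", "condition", "replicate", "is_reference"),
    "experiment design"
  )
  design <- tibble::as_tibble(df) |>
    mutate(
      run = as.character(.data$run),
      channel = as.character(.data$channel),
      sample = as.character(.data$sample),
      condition = as.character(.data$condition),
      replicate = as.integer(.data$replicate),
      is_reference = as.logical(.data$is_reference)
    )
  dup <- design |> count(.data$run, .data$channel) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(
      sprintf("duplicate (run, channel) pairs in design: %s",
              paste(dup$run, dup$channel, sep = "/", collapse = ", ")),
      class = "apexquant_validation_error"
    )
  }
  if (anyDuplicated(design$sample)) {
    abort("sample ids must be unique", class = "apexquant_validation_error")
  }
  bad_cond <- design |> filter(!.data$is_reference,
                               is.na(.data$condition) | .data$condition == "")
  if (nrow(bad_cond) > 0) {
    abort("every non-reference sample needs a condition label",
          class = "apexquant_validation_error")
  }
  if (anyNA(design$is_reference)) {
    abort("is_reference must be TRUE/FALSE", class = "apexquant_validation_error")
  }
  if (require_reference) {
    no_ref <- design |> group_by(.data$run) |>
      summarise(has_ref = any(.data$is_reference)) |> filter(!.data$has_ref)
    if (nrow(no_ref) > 0) {
      abort(
        sprintf("run(s) without a reference channel: %s",
                paste(no_ref$run, collapse = ", ")),
        class = "apexquant_validation_error"
      )
    }
  }
  class(design) <- c("tmt_design", class(tibble::tibble()))
  design
}

#' Read an experiment design CSV
#'
#' Expects columns `run,channel,sample,condition,replicate,is_reference`.
#'
#' @inheritParams as_tmt_design
#' @param path Path to a CSV file.
#' @return A `tmt_design` tibble.
#' @export
read_design <- function(path, require_reference = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("design file not found: %s", path),
          class = "apexquant_schema_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_tmt_design(df, require_reference = require_reference)
}

#' Write an experiment design CSV
#' @param design A `tmt_design` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_csv(design, path, progress = FALSE)
  invisible(path)
}

design_channels <- function(design, run) {
  design$channel[design$run == run]
}

# ---- canned synthetic study designs -----------------------------------------

build_design <- function(runs) {
  bind_rows(runs) |> as_tmt_design()
}

fill_run <- function(run_id, channels, conditions, is_reference) {
  tibble::tibble(
    run = run_id,
    channel = channels,
    condition = conditions,
    is_reference = is_reference
  )
}

#' Synthetic study designs
#'
#' Canned designs mirroring the three study layouts the analysis supports:
#'
#' * `design_compartment()`: two TMT-10 plexes; Cre-negative control (n = 6)
#'   and the three APEX constructs H2B, NES, LCK (n = 4 each) plus one pooled
#'   reference channel per run.
#' * `design_celltype()`: two TMT-10 plexes crossing two Cre driver lines
#'   (D1, A2a) with H2B and NES constructs (n = 4 each), a small Cre-negative
#'   control (n = 2) and one reference channel per run.
#' * `design_activity()`: two TMT-11 plexes for the chemogenetic-activation
#'   layout: hM3Dq_H2B (n = 7), mCherry_H2B (n = 7), NES (n = 3), CTRL
#'   (n = 3), one reference channel per run.
#' * `design_twogroup()`: a minimal two-condition layout (plus per-run
#'   reference channels) for null simulations and operating-characteristic
#'   checks.
#'
#' Samples are balanced across runs so every condition spans both plexes.
#'
#' @return A `tmt_design` tibble.
#' @export
design_compartment <- function() {
  ch <- tmt_channels(10)
  r1 <- fill_run("run1", ch,
                 c("REF", "CTRL", "CTRL", "CTRL", "H2B", "H2B",
                   "NES", "NES", "LCK", "LCK"),
                 c(TRUE, rep(FALSE, 9)))
  r2 <- fill_run("run2", ch,
                 c("REF", "CTRL", "CTRL", "CTRL", "H2B", "H2B",
                   "NES", "NES", "LCK", "LCK"),
                 c(TRUE, rep(FALSE, 9)))
  finalize_design(bind_rows(r1, r2))
}

#' @rdname design_compartment
#' @export
design_celltype <- function() {
  ch <- tmt_channels(10)
  r1 <- fill_run("run1", ch,
                 c("REF", "CTRL", "D1_H2B", "D1_H2B", "D1_NES", "D1_NES",
                   "A2a_H2B", "A2a_H2B", "A2a_NES", "A2a_NES"),
                 c(TRUE, rep(FALSE, 9)))
  r2 <- fill_run("run2", ch,
                 c("REF", "CTRL", "D1_H2B", "D1_H2B", "D1_NES", "D1_NES",
                   "A2a_H2B", "A2a_H2B", "A2a_NES", "A2a_NES"),
                 c(TRUE, rep(FALSE, 9)))
  finalize_design(bind_rows(r1, r2))
}

#' @rdname design_compartment
#' @export
design_activity <- function() {
  ch <- tmt_channels(11)
  r1 <- fill_run("run1", ch,
                 c("REF", "hM3Dq_H2B", "hM3Dq_H2B", "hM3Dq_H2B", "hM3Dq_H2B",
                   "mCherry_H2B", "mCherry_H2B", "mCherry_H2B",
                   "NES", "NES", "CTRL"),
                 c(TRUE, rep(FALSE, 10)))
  r2 <- fill_run("run2", ch,
                 c("REF", "hM3Dq_H2B", "hM3Dq_H2B", "hM3Dq_H2B",
                   "mCherry_H2B", "mCherry_H2B", "mCherry_H2B", "mCherry_H2B",
                   "NES", "CTRL", "CTRL"),
                 c(TRUE, rep(FALSE, 10)))
  finalize_design(bind_rows(r1, r2))
}

#' @rdname design_compartment
#' @param conditions Two condition labels.
#' @param n_per_group Biological replicates per condition (split across runs).
#' @param n_runs Number of TMT plexes.
#' @export
design_twogroup <- function(conditions = c("A", "B"), n_per_group = 4,
                            n_runs = 2) {
  stopifnot(length(conditions) == 2, n_per_group >= 1, n_runs >= 1)
  per_run <- ceiling(n_per_group / n_runs)
  rows <- list()
  left <- setNames(rep(n_per_group, 2), conditions)
  for (r in seq_len(n_runs)) {
    conds <- "REF"
    for (cond in conditions) {
      take <- min(per_run, left[[cond]])
      left[[cond]] <- left[[cond]] - take
      conds <- c(conds, rep(cond, take))
    }
    ch <- tmt_channels(if (length(conds) <= 10) 10 else 11)[seq_along(conds)]
    rows[[r]] <- fill_run(paste0("run", r), ch, conds,
                          c(TRUE, rep(FALSE, length(conds) - 1)))
  }
  finalize_design(bind_rows(rows))
}

# Assign sample ids and replicate indices to a (run, channel, condition,
# is_reference) frame.
finalize_design <- function(df) {
  df <- df |>
    mutate(condition = ifelse(.data$is_reference, "REF", .data$condition)) |>
    group_by(.data$condition) |>
    mutate(replicate = seq_len(n())) |>
    ungroup() |>
    mutate(sample = paste0(.data$condition, "_", .data$replicate)) |>
    select("run", "channel", "sample", "condition", "replicate",
           "is_reference")
  as_tmt_design(df)
}
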