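# The protein x sample abundance container.
#
# Stored as a tibble (accession + one numeric column per sample) so it prints
# and joins like any other table; the experiment design, per-(protein, run)
# PSM support and a provenance stage tag ride along as attributes. Use
# pm_values() for the numeric matrix and tidy() for the long form. dplyr
# verbs return plain tibbles; rebuild with as_protein_matrix() if needed.

new_protein_matrix <- function(values, design, psm_support, stage_tag,
                               flags = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  out <- tibble::as_tibble(values, rownames = "accession")
  attr(out, "design") <- design
  attr(out, "psm_support") <- psm_support
  attr(out, "stage_tag") <- stage_tag
  attr(out, "flags") <- flags
  class(out) <- c("protein_matrix", class(tibble::tibble()))
  out
}

#' Build a protein abundance matrix from a tidy or wide table
#'
#' @param df Data frame with an `accession` column and one numeric column per
#'   sample in `design`.
#' @param design The `tmt_design` the columns belong to.
#' @param stage_tag Provenance label of the last transform.
#' @return A `protein_matrix`.
#' @export
as_protein_matrix <- function(df, design, stage_tag = "imported") {
  design <- as_tmt_design(design)
  check_required_columns(df, c("accession", design$sample), "protein matrix")
  values <- as.matrix(df[, design$sample, drop = FALSE])
  rownames(values) <- df$accession
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) {
    abort("protein abundances must be finite where present",
          class = "apexquant_validation_error")
  }
  new_protein_matrix(values, design, attr(df, "psm_support"), stage_tag)
}

#' Extract the numeric proteins-by-samples matrix
#' @param pm A `protein_matrix`.
#' @return Numeric matrix with accession rownames and sample colnames.
#' @export
pm_values <- function(pm) {
  design <- pm_design(pm)
  values <- as.matrix(pm[, design$sample, drop = FALSE])
  rownames(values) <- pm$accession
  values
}

#' @rdname pm_values
#' @export
pm_design <- function(pm) attr(pm, "design")

#' @rdname pm_values
#' @export
pm_stage <- function(pm) attr(pm, "stage_tag")

#' @rdname pm_values
#' @export
pm_psm_support <- function(pm) attr(pm, "psm_support")

replace_values <- function(pm, values, stage_tag, flags = NULL) {
  new_protein_matrix(values, pm_design(pm), pm_psm_support(pm), stage_tag,
                     flags = flags %||% attr(pm, "flags"))
}

#' @export
tidy.protein_matrix <- function(x, ...) {
  design <- pm_design(x)
  tidyr::pivot_longer(tibble::as_tibble(x), cols = -"accession",
                      names_to = "sample",
                      values_to = "log2_abundance") |>
    left_join(design, by = "sample")
}

#' @export
glance.protein_matrix <- function(x, ...) {
  v <- pm_values(x)
  tibble::tibble(
    n_proteins = nrow(v), n_samples = ncol(v),
    frac_missing = mean(is.na(v)), stage_tag = pm_stage(x)
  )
}

#' Write a protein matrix as wide TSV plus a JSON sidecar
#'
#' The TSV holds `accession` plus one column per sample; the sidecar records
#' the provenance stage tag and per-(protein, run) PSM support.
#'
#' @param pm A `protein_matrix`.
#' @param path Output TSV path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_protein_matrix <- function(pm, path) {
  readr::write_tsv(tibble::as_tibble(pm), path, progress = FALSE)
  sidecar <- list(stage_tag = pm_stage(pm),
                  samples = pm_design(pm)$sample,
                  psm_support = pm_psm_support(pm))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
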