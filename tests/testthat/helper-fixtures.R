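# In-code fixtures shared across test files.

# A hand-buildable PSM table in the native wide layout.
make_psms <- function(rows, design) {
  df <- dplyr::bind_rows(rows)
  defaults <- list(fraction = NA_character_, charge = 2L,
                   search_q = 0.001, coisolation_pct = 0)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  for (ch in unique(design$channel)) {
    if (!ch %in% names(df)) df[[ch]] <- NA_real_
  }
  df$psm_id <- seq_len(nrow(df))
  df$accession <- ifelse(grepl(";", df$accessions), NA_character_,
                         df$accessions)
  df$is_unique <- !grepl(";", df$accessions)
  class(df) <- c("psm_tbl", class(tibble::tibble()))
  df
}

# Two runs x 3 channels (1 reference + condition X/Y), for tiny examples.
tiny_design <- function() {
  as_tmt_design(tibble::tibble(
    run = rep(c("r1", "r2"), each = 3),
    channel = rep(c("126", "127N", "127C"), 2),
    sample = c("REF_1", "X_1", "Y_1", "REF_2", "X_2", "Y_2"),
    condition = rep(c("REF", "X", "Y"), 2),
    replicate = c(1, 1, 1, 2, 2, 2),
    is_reference = rep(c(TRUE, FALSE, FALSE), 2)
  ))
}

# Protein matrix built directly from a values matrix.
make_pm <- function(values, design) {
  df <- tibble::as_tibble(values, rownames = "accession")
  as_protein_matrix(df, design, stage_tag = "test")
}

# Minimal contrast tibble for classification tests.
make_contrasts <- function(accession, contrast, log2fc, q,
                           p = q, n_features = 2L) {
  out <- tibble::tibble(accession = accession, contrast = contrast,
                        log2fc = log2fc, se = 0.1, df = 10, t = log2fc / 0.1,
                        p = p, q = q, n_features = n_features)
  class(out) <- c("tmt_contrasts", class(tibble::tibble()))
  out
}
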