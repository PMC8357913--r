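# Shared internal helpers.

# TMT reporter channel layouts by plex width.
tmt_channels <- function(plex = 10) {
  base <- c("126", "127N", "127C", "128N", "128C",
            "129N", "129C", "130N", "130C", "131")
  if (plex == 10) return(base)
  if (plex == 11) return(c(base, "131C"))
  if (plex == 16) {
    return(c("126", paste0(rep(127:133, each = 2), c("N", "C")), "134N"))
  }
  abort(sprintf("unsupported plex width: %s", plex))
}

# Map a condition label onto the APEX construct it implies. Labels containing
# H2B/NES/LCK (case-insensitive) are targeted constructs; recognised control
# spellings are Cre-negative; anything else is an untargeted full-capture
# condition (used for plain two-group designs with no compartment structure).
parse_construct <- function(condition) {
  cond <- toupper(condition)
  out <- rep("neutral", length(cond))
  out[grepl("H2B", cond)] <- "H2B"
  out[grepl("NES", cond)] <- "NES"
  out[grepl("LCK", cond)] <- "LCK"
  ctrl <- grepl("^CTRL$|^CONTROL$|CRE-|CRENEG", cond)
  out[ctrl] <- "control"
  out
}

check_required_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "apexquant_schema_error"
    )
  }
  invisible(df)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name),
          class = "apexquant_parameter_error")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be nonnegative", name),
          class = "apexquant_parameter_error")
  }
  invisible(x)
}

# Parse "A - B" contrast labels into a two-column matrix.
parse_contrast_labels <- function(x) {
  parts <- stringr::str_split_fixed(x, stringr::fixed(" - "), 2)
  if (any(parts == "")) {
    abort("contrast labels must have the form \"A - B\"",
          class = "apexquant_validation_error")
  }
  parts
}

contrast_label <- function(a, b) paste(a, "-", b)
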