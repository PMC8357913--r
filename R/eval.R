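# Scoring of classification output against simulated ground truth.

#' Score compartment calls against simulation truth
#'
#' Compares [filter2_compartment()] calls with the dominant compartment of
#' each simulated protein. A protein is scorable for sensitivity when it is
#' an ordinary protein (not a background binder or endogenously biotinylated),
#' its dominant compartment weight reaches `min_dominance`, and its true
#' noise-free contrast for the compartment's defining comparison has
#' magnitude at least `min_true_log2fc` (dual-localized proteins with weak
#' compartment contrast are excluded, since no compartment label is the
#' right answer for them). Specificity for a compartment is scored over
#' ordinary dominant proteins of the *other* compartments whose true
#' contrast does not itself cross `min_true_log2fc` in the call direction:
#' a cytosol-dominant protein genuinely captured 2-fold more by the
#' membrane construct has no single correct label, and is excluded the same
#' way weak-contrast positives are.
#'
#' @param universe Accessions eligible for scoring (e.g. the quantified
#'   proteins the filters operated on); defaults to every simulated protein.
#'
#' @param calls A `compartment_calls` tibble.
#' @param truth A `sim_truth`.
#' @param nuclear_contrast Condition pair defining the nucleus call.
#' @param membrane_contrast Condition pair defining the membrane call (its
#'   true contrast is negative for membrane proteins), or `NULL`.
#' @param min_dominance Minimum dominant mixture weight.
#' @param min_true_log2fc Minimum true contrast magnitude for sensitivity
#'   scoring.
#' @return Tibble with one row per scored compartment: `compartment`,
#'   `sensitivity`, `specificity`, `n_positive`, `n_negative`.
#' @export
score_compartment_calls <- function(calls, truth, universe = NULL,
                                    nuclear_contrast = c("H2B", "NES"),
                                    membrane_contrast = NULL,
                                    min_dominance = 0.5,
                                    min_true_log2fc = 1) {
  pr <- truth$proteins
  mix <- cbind(nucleus = pr$mix_nucleus, cytosol = pr$mix_cytosol,
               membrane = pr$mix_membrane)
  dom_idx <- max.col(mix, ties.method = "first")
  dominant <- colnames(mix)[dom_idx]
  dominant[mix[cbind(seq_len(nrow(mix)), dom_idx)] < min_dominance] <- "mixed"
  ordinary <- !pr$is_background & !pr$is_endogenous_biotin
  if (!is.null(universe)) ordinary <- ordinary & pr$accession %in% universe

  lfc_nuc <- sim_expected_log2fc(truth, nuclear_contrast[1],
                                 nuclear_contrast[2])$log2fc_true
  lfc_mem <- if (!is.null(membrane_contrast)) {
    sim_expected_log2fc(truth, membrane_contrast[1],
                        membrane_contrast[2])$log2fc_true
  } else NULL

  called <- setNames(rep("absent", nrow(pr)), pr$accession)
  called[calls$accession] <- calls$compartment

  score_one <- function(compartment, true_lfc, call_direction) {
    pos <- ordinary & dominant == compartment &
      abs(true_lfc) >= min_true_log2fc
    neg <- ordinary & dominant %in% setdiff(colnames(mix), compartment) &
      call_direction * true_lfc < min_true_log2fc
    hit <- called[pr$accession] == compartment
    tibble::tibble(
      compartment = compartment,
      sensitivity = if (any(pos)) mean(hit[pos]) else NA_real_,
      specificity = if (any(neg)) mean(!hit[neg]) else NA_real_,
      n_positive = sum(pos), n_negative = sum(neg)
    )
  }
  out <- score_one("nucleus", lfc_nuc, call_direction = 1)
  if (!is.null(lfc_mem)) {
    out <- bind_rows(out, score_one("membrane", lfc_mem,
                                    call_direction = -1))
  }
  out
}
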