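#' Parameters of the synthetic proximity-labeling TMT experiment generator
#'
#' The generator produces PSM-level reporter tables with the statistical
#' structure the downstream analysis assumes: additive log2 effects
#' (baseline + peptide ionization offset + compartment capture + differential
#' expression + TMT batch + channel + noise), pooled reference channels, a
#' deterministic detection floor plus uniform missingness, and ground-truth
#' class labels for every protein.
#'
#' Protein compartment mixtures over \{nucleus, cytosol, membrane\} are drawn
#' from a Dirichlet distribution. Each APEX construct captures compartments
#' according to `construct_capture` plus a nonspecific `background_leak`; the
#' capture term for construct *k* and protein *p* is
#' `enrichment_scale_log2 * log2(sum(capture_k * mixture_p) + leak)`.
#' Cre-negative controls see only the leak. Nonspecific bead binders and
#' endogenously biotinylated proteins are captured at full strength in every
#' condition (construct-independent), so their Cre+/Cre- difference is zero.
#'
#' @param n_proteins Number of simulated proteins.
#' @param frac_background_binders Fraction of nonspecific bead binders.
#' @param frac_endogenous_biotin Fraction of endogenously biotinylated
#'   proteins.
#' @param frac_celltype_de Fraction of ordinary proteins carrying a cell-type
#'   effect (applied to `A2a*` conditions).
#' @param frac_activity_de Fraction of nucleus-dominant ordinary proteins
#'   carrying an activity effect (applied to `hM3Dq*` conditions).
#' @param compartment_concentration Dirichlet concentration over
#'   (nucleus, cytosol, membrane).
#' @param construct_capture Named list of per-construct capture weight
#'   vectors over (nucleus, cytosol, membrane).
#' @param background_leak Nonspecific capture weight added for every
#'   construct and for Cre-negative controls.
#' @param enrichment_scale_log2 Multiplier on the log2 capture term.
#' @param effect_size_log2 List `(mean, sd, sign)` for differential-effect
#'   magnitudes; `sign` is `"both"` (random sign) or `"up"`.
#' @param psm_count List `(size, mu)`: PSMs per protein per run are
#'   `1 + NegBinom(size, mu)`.
#' @param peptides_per_protein Mean number of distinct tryptic peptides per
#'   protein (`1 + Poisson(mean - 1)`).
#' @param baseline_log2 Mean and sd of protein baseline log2 abundance.
#' @param peptide_sd_log2 SD of per-peptide ionization offsets.
#' @param noise_sd_log2 Measurement noise SD (log2).
#' @param batch_sd_log2 SD of per-run (TMT batch) shifts.
#' @param channel_sd_log2 SD of per-(run, channel) shifts.
#' @param detection_floor_log2 Log2 intensity below which a value is missing.
#' @param mcar_rate Uniform missing-completely-at-random rate.
#' @param frac_fail_q,frac_fail_coisolation,frac_shared Fractions of PSMs
#'   whose metadata violate each ingest filter (drawn independently of
#'   intensity; their only role is exercising the filters).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_proteins = 3000,
                       frac_background_binders = 0.10,
                       frac_endogenous_biotin = 0.05,
                       frac_celltype_de = 0.10,
                       frac_activity_de = 0.05,
                       compartment_concentration =
                         c(nucleus = 0.4, cytosol = 0.6, membrane = 0.35),
                       construct_capture = list(
                         H2B = c(nucleus = 1, cytosol = 0.05, membrane = 0.02),
                         NES = c(nucleus = 0.05, cytosol = 1, membrane = 0.05),
                         LCK = c(nucleus = 0.02, cytosol = 0.05, membrane = 1)),
                       background_leak = 0.02,
                       enrichment_scale_log2 = 1,
                       effect_size_log2 = list(mean = 0.8, sd = 0.2,
                                               sign = "both"),
                       psm_count = list(size = 2, mu = 1.5),
                       peptides_per_protein = 2,
                       baseline_log2 = c(mean = 16, sd = 2),
                       peptide_sd_log2 = 1,
                       noise_sd_log2 = 0.25,
                       batch_sd_log2 = 0.5,
                       channel_sd_log2 = 0.05,
                       detection_floor_log2 = 6,
                       mcar_rate = 0.02,
                       frac_fail_q = 0.05,
                       frac_fail_coisolation = 0.05,
                       frac_shared = 0.05,
                       seed = 1L) {
  check_fraction(frac_background_binders, "frac_background_binders")
  check_fraction(frac_endogenous_biotin, "frac_endogenous_biotin")
  check_fraction(frac_celltype_de, "frac_celltype_de")
  check_fraction(frac_activity_de, "frac_activity_de")
  check_fraction(mcar_rate, "mcar_rate")
  check_fraction(frac_fail_q, "frac_fail_q")
  check_fraction(frac_fail_coisolation, "frac_fail_coisolation")
  check_fraction(frac_shared, "frac_shared")
  if (frac_background_binders + frac_endogenous_biotin > 1) {
    abort("protein class fractions sum to more than 1",
          class = "apexquant_parameter_error")
  }
  check_nonnegative(noise_sd_log2, "noise_sd_log2")
  check_nonnegative(batch_sd_log2, "batch_sd_log2")
  check_nonnegative(channel_sd_log2, "channel_sd_log2")
  check_nonnegative(peptide_sd_log2, "peptide_sd_log2")
  check_nonnegative(compartment_concentration, "compartment_concentration")
  for (k in names(construct_capture)) {
    check_nonnegative(construct_capture[[k]],
                      paste0("construct_capture$", k))
  }
  check_nonnegative(background_leak, "background_leak")
  params <- as.list(environment())
  structure(params, class = "sim_params")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  # guard against all-zero gamma draws at tiny concentrations
  bad <- !is.finite(rowSums(sw))
  if (any(bad)) sw[bad, ] <- 1 / length(alpha)
  sw
}

#' Draw the ground truth of a synthetic experiment
#'
#' Samples per-protein compartment mixtures, class flags (background binder,
#' endogenous biotin), differential effects, baselines and peptide counts,
#' plus per-run batch shifts and per-(run, channel) shifts for the given
#' design. Deterministic given `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param design A `tmt_design`; supplies the runs/channels that receive
#'   batch and channel shifts.
#' @return A `sim_truth` list: tibble `proteins`, tibble `batch`, tibble
#'   `channel`, and the generating `params`.
#' @export
simulate_truth <- function(params, design) {
  stopifnot(inherits(params, "sim_params"))
  design <- as_tmt_design(design)
  withr::with_seed(params$seed, {
    n <- params$n_proteins
    mix <- rdirichlet(n, params$compartment_concentration)
    colnames(mix) <- c("nucleus", "cytosol", "membrane")
    cls <- runif(n)
    is_bg <- cls < params$frac_background_binders
    is_endo <- !is_bg & cls < params$frac_background_binders +
      params$frac_endogenous_biotin
    ordinary <- !is_bg & !is_endo

    eff <- params$effect_size_log2
    draw_effect <- function(active) {
      mag <- abs(rnorm(n, eff$mean, eff$sd))
      sgn <- if (identical(eff$sign, "up")) 1 else
        sample(c(-1, 1), n, replace = TRUE)
      ifelse(active, mag * sgn, 0)
    }
    ct_active <- ordinary & runif(n) < params$frac_celltype_de
    nuc_dom <- mix[, "nucleus"] >= 0.5
    act_active <- ordinary & nuc_dom & runif(n) < params$frac_activity_de
    celltype_fc <- draw_effect(ct_active)
    activity_fc <- draw_effect(act_active)

    proteins <- tibble::tibble(
      accession = sprintf("SIM%05d", seq_len(n)),
      mix_nucleus = mix[, "nucleus"],
      mix_cytosol = mix[, "cytosol"],
      mix_membrane = mix[, "membrane"],
      is_background = is_bg,
      is_endogenous_biotin = is_endo,
      celltype_log2fc = celltype_fc,
      activity_log2fc = activity_fc,
      baseline_log2 = rnorm(n, params$baseline_log2[["mean"]],
                            params$baseline_log2[["sd"]]),
      n_peptides = 1L + rpois(n, max(params$peptides_per_protein - 1, 0))
    )
    runs <- unique(design$run)
    batch <- tibble::tibble(
      run = runs,
      batch_shift = rnorm(length(runs), 0, params$batch_sd_log2)
    )
    channel <- design |>
      distinct(.data$run, .data$channel) |>
      mutate(channel_shift = rnorm(n(), 0, params$channel_sd_log2))
    structure(list(proteins = proteins, batch = batch, channel = channel,
                   params = params, design = design),
              class = "sim_truth")
  })
}

# Expected biological log2 signal of every protein under each condition
# (baseline + capture + DE terms; no batch/channel/noise).
sim_condition_means <- function(truth, conditions) {
  p <- truth$params
  pr <- truth$proteins
  mix <- cbind(pr$mix_nucleus, pr$mix_cytosol, pr$mix_membrane)
  full_capture <- log2(1 + p$background_leak)
  mu <- matrix(0, nrow(pr), length(conditions),
               dimnames = list(pr$accession, conditions))
  for (j in seq_along(conditions)) {
    constr <- parse_construct(conditions[j])
    capture <- if (constr %in% names(p$construct_capture)) {
      p$enrichment_scale_log2 *
        log2(drop(mix %*% p$construct_capture[[constr]]) + p$background_leak)
    } else if (constr == "control") {
      rep(p$enrichment_scale_log2 * log2(p$background_leak), nrow(pr))
    } else {
      rep(0, nrow(pr)) # untargeted condition: full capture, no compartment term
    }
    capture[pr$is_background | pr$is_endogenous_biotin] <- full_capture
    de <- rep(0, nrow(pr))
    if (grepl("^A2A", toupper(conditions[j]))) de <- de + pr$celltype_log2fc
    if (grepl("HM3DQ", toupper(conditions[j]))) de <- de + pr$activity_log2fc
    mu[, j] <- pr$baseline_log2 + capture + de
  }
  mu
}

#' Expected (noise-free) log2 fold change between two conditions
#'
#' Computes, from the simulation truth alone, the analytic log2 contrast
#' every protein would show between two condition labels. Used for scoring
#' recovered effects against the truth.
#'
#' @param truth A `sim_truth` object.
#' @param condition_a,condition_b Condition labels.
#' @return Tibble with `accession` and `log2fc_true`.
#' @export
sim_expected_log2fc <- function(truth, condition_a, condition_b) {
  mu <- sim_condition_means(truth, c(condition_a, condition_b))
  tibble::tibble(accession = rownames(mu),
                 log2fc_true = unname(mu[, 1] - mu[, 2]))
}

#' Generate a synthetic PSM-level reporter table
#'
#' Emits one PSM row per (protein, run, spectrum) with raw reporter
#' intensities `2^(log2 signal)` per channel, where the log2 signal is the
#' sum of the protein baseline, a per-peptide ionization offset, the
#' construct capture and differential-effect terms of the channel's
#' condition, the run's batch shift, the channel shift, and Normal noise.
#' Reference channels carry the per-protein average of all study samples'
#' expected signal. Values below the detection floor, or hit by uniform
#' missingness, are missing. PSM metadata (charge, search q-value,
#' co-isolation, shared accessions) are drawn so configurable fractions
#' violate each ingest filter.
#'
#' @param truth A `sim_truth` from [simulate_truth()].
#' @param design The experiment design (defaults to the one truth was drawn
#'   for).
#' @param params Generator parameters (defaults to `truth$params`).
#' @return A `psm_tbl` tibble in the native dialect.
#' @export
simulate_psm_table <- function(truth, design = truth$design,
                               params = truth$params) {
  stopifnot(inherits(truth, "sim_truth"))
  design <- as_tmt_design(design)
  p <- params
  pr <- truth$proteins
  n_prot <- nrow(pr)
  runs <- unique(design$run)
  channels <- unique(design$channel)

  study <- design |> filter(!.data$is_reference)
  conditions <- unique(study$condition)
  mu_cond <- sim_condition_means(truth, conditions)
  # pooled reference: per-protein mean over every study sample's expectation
  mu_ref <- rowMeans(mu_cond[, match(study$condition, conditions),
                             drop = FALSE])
  mu_all <- cbind(mu_cond, REFPOOL = mu_ref)

  # condition index per (run, channel); 0 = slot absent from the run
  cond_idx <- matrix(0L, length(runs), length(channels),
                     dimnames = list(runs, channels))
  for (i in seq_len(nrow(design))) {
    ci <- if (design$is_reference[i]) ncol(mu_all) else
      match(design$condition[i], conditions)
    cond_idx[design$run[i], design$channel[i]] <- ci
  }
  batch <- setNames(truth$batch$batch_shift, truth$batch$run)
  chs <- truth$channel
  ch_shift <- matrix(0, length(runs), length(channels),
                     dimnames = list(runs, channels))
  ch_shift[cbind(match(chs$run, runs), match(chs$channel, channels))] <-
    chs$channel_shift

  withr::with_seed(p$seed + 1L, {
    counts <- matrix(
      1L + rnbinom(n_prot * length(runs), size = p$psm_count$size,
                   mu = p$psm_count$mu),
      n_prot, length(runs))
    prot_i <- rep(rep(seq_len(n_prot), length(runs)), as.vector(counts))
    run_i <- rep(rep(seq_along(runs), each = n_prot), as.vector(counts))
    n_psm <- length(prot_i)

    n_pep <- pr$n_peptides
    pep_off_all <- rnorm(sum(n_pep), 0, p$peptide_sd_log2)
    pep_start <- cumsum(c(0L, n_pep[-n_prot]))
    pep_local <- 1L + as.integer(floor(runif(n_psm) * n_pep[prot_i]))
    pep_offset <- pep_off_all[pep_start[prot_i] + pep_local]

    charge <- sample(2:4, n_psm, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    fail_q <- runif(n_psm) < p$frac_fail_q
    search_q <- ifelse(fail_q, runif(n_psm, 0.01, 0.05),
                       runif(n_psm, 0, 0.0099))
    fail_co <- runif(n_psm) < p$frac_fail_coisolation
    coiso <- ifelse(fail_co, runif(n_psm, 70.001, 100), runif(n_psm, 0, 70))
    shared <- runif(n_psm) < p$frac_shared

    acc <- pr$accession[prot_i]
    accessions <- ifelse(shared, paste0(acc, ";SHARED_BG"), acc)

    inten <- matrix(NA_real_, n_psm, length(channels),
                    dimnames = list(NULL, channels))
    for (j in seq_along(channels)) {
      ci <- cond_idx[cbind(run_i, j)]
      present <- ci > 0L
      if (!any(present)) next
      mu <- mu_all[cbind(prot_i[present], ci[present])]
      x <- mu + pep_offset[present] + batch[runs[run_i[present]]] +
        ch_shift[cbind(run_i[present], j)] +
        rnorm(sum(present), 0, p$noise_sd_log2)
      x[x < p$detection_floor_log2] <- NA_real_
      if (p$mcar_rate > 0) {
        x[runif(length(x)) < p$mcar_rate] <- NA_real_
      }
      inten[present, j] <- 2^x
    }

    psms <- tibble::tibble(
      psm_id = seq_len(n_psm),
      run = runs[run_i],
      fraction = NA_character_,
      accessions = accessions,
      accession = ifelse(shared, NA_character_, acc),
      is_unique = !shared,
      peptide = paste0(acc, "_pep", pep_local),
      charge = charge,
      search_q = search_q,
      coisolation_pct = coiso
    )
    for (j in seq_along(channels)) psms[[channels[j]]] <- inten[, j]
    attr(psms, "ingest_log") <- list(n_rows = n_psm, n_parse_failed = 0L,
                                     n_nonpositive_to_missing = 0L,
                                     n_off_design_dropped = 0L)
    class(psms) <- c("psm_tbl", class(tibble::tibble()))
    psms
  })
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper drawing the truth and the PSM table for one design.
#'
#' @inheritParams simulate_truth
#' @return A list with `truth`, `psms`, and `design`.
#' @export
simulate_experiment <- function(params, design) {
  truth <- simulate_truth(params, design)
  psms <- simulate_psm_table(truth)
  list(truth = truth, psms = psms, design = truth$design)
}

#' Write a simulated experiment to disk
#'
#' Writes the native-dialect PSM TSV, the ground-truth TSV, the design CSV,
#' and the generator parameters as JSON.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_psm_table(sim$psms, file.path(dir, "psms.tsv"))
  readr::write_tsv(sim$truth$proteins, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  write_design(sim$design, file.path(dir, "design.csv"))
  par <- sim$truth$params
  par$construct_capture <- lapply(par$construct_capture, as.list)
  jsonlite::write_json(unclass(par), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
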