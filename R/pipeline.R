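#' Pipeline configuration
#'
#' Assembles and validates the staged-analysis configuration: ingest filter
#' thresholds, the normalization switches of the experiment (peptide-level
#' global median normalization, reference-channel batch correction,
#' protein-level median normalization), the specificity (Filter 1) setup
#' naming the Cre-negative control, the compartment (Filter 2) contrasts,
#' contaminant lists, the differential-expression contrasts with their
#' significance rules, and the QC settings.
#'
#' Three presets encode the supported experiment styles:
#' `config_compartment()` (three constructs vs control, no global median
#' normalization, three-construct compartment calls),
#' `config_celltype()` (two Cre lines x two constructs, global median
#' normalization, contaminant removal, p-rule cell-type contrasts per
#' stratum), and `config_activity()` (chemogenetic activation, q-rule
#' case-control contrast in the nuclear stratum, single-PSM rescue on).
#'
#' @param filters Ingest thresholds (see [filter_psms()],
#'   [partition_quantifiable()]).
#' @param normalization Switches `global_median`, `reference`,
#'   `protein_median`.
#' @param specificity `NULL`, or `list(control=, constructs=, q_max=)`.
#' @param compartment `NULL`, or `list(nuclear = list of contrasts,
#'   membrane = contrast or NULL, q_max=, mode=)`.
#' @param contaminants List of `contaminant_list` objects or file paths.
#' @param de List of entries `list(contrast=, alpha_rule=, alpha=,
#'   strata=NULL, renormalize=FALSE)`.
#' @param rescue Report single-PSM rescue proteins.
#' @param qc `list(mds_top_n=)`.
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filters = list(coisolation_max = 70,
                                           q_max = 0.01,
                                           unique_only = TRUE,
                                           min_unique_psms = 2),
                            normalization = list(global_median = FALSE,
                                                 reference = TRUE,
                                                 protein_median = FALSE),
                            specificity = NULL,
                            compartment = NULL,
                            contaminants = list(),
                            de = list(),
                            rescue = FALSE,
                            qc = list(mds_top_n = 500),
                            seed = 1L) {
  cfg <- list(filters = filters, normalization = normalization,
              specificity = specificity, compartment = compartment,
              contaminants = contaminants, de = de, rescue = rescue,
              qc = qc, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
config_compartment <- function() {
  pipeline_config(
    normalization = list(global_median = FALSE, reference = TRUE,
                         protein_median = FALSE),
    specificity = list(control = "CTRL", constructs = c("H2B", "NES", "LCK"),
                       q_max = 0.05),
    compartment = list(nuclear = list(c("H2B", "NES")),
                       membrane = c("H2B", "LCK"),
                       q_max = 0.05, mode = "three_construct")
  )
}

#' @rdname pipeline_config
#' @export
config_celltype <- function() {
  pipeline_config(
    normalization = list(global_median = TRUE, reference = TRUE,
                         protein_median = TRUE),
    specificity = NULL, # background handled through the contaminant list
    compartment = list(nuclear = list(c("D1_H2B", "D1_NES"),
                                      c("A2a_H2B", "A2a_NES")),
                       membrane = NULL, q_max = 0.05,
                       mode = "two_compartment"),
    de = list(
      list(contrast = c("A2a_H2B", "D1_H2B"), alpha_rule = "p",
           alpha = 0.05, strata = "nucleus"),
      list(contrast = c("A2a_NES", "D1_NES"), alpha_rule = "p",
           alpha = 0.05, strata = "cytosol_nonH2B")
    )
  )
}

#' @rdname pipeline_config
#' @export
config_activity <- function() {
  pipeline_config(
    normalization = list(global_median = TRUE, reference = TRUE,
                         protein_median = TRUE),
    specificity = list(control = "CTRL",
                       constructs = c("hM3Dq_H2B", "mCherry_H2B", "NES"),
                       q_max = 0.05),
    compartment = list(nuclear = list(c("hM3Dq_H2B", "NES"),
                                      c("mCherry_H2B", "NES")),
                       membrane = NULL, q_max = 0.05,
                       mode = "two_compartment"),
    de = list(
      list(contrast = c("hM3Dq_H2B", "mCherry_H2B"), alpha_rule = "q",
           alpha = 0.05, strata = "nucleus", renormalize = TRUE)
    ),
    rescue = TRUE
  )
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file path (`.yml`/`.yaml`/`.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(config, design) {
  conds <- unique(design$condition[!design$is_reference])
  refer <- function(x) {
    bad <- setdiff(x, conds)
    if (length(bad) > 0) {
      abort(sprintf("config references condition(s) absent from the design: %s",
                    paste(bad, collapse = ", ")),
            class = "apexquant_validation_error")
    }
  }
  if (!is.null(config$specificity)) {
    refer(config$specificity$control)
    refer(config$specificity$constructs)
    if (parse_construct(config$specificity$control) != "control") {
      abort("the specificity control must be a Cre-negative control condition",
            class = "apexquant_validation_error")
    }
  }
  if (!is.null(config$compartment)) {
    for (ct in config$compartment$nuclear) refer(unlist(ct))
    if (!is.null(config$compartment$membrane)) {
      refer(unlist(config$compartment$membrane))
    }
  }
  for (entry in config$de) refer(unlist(entry$contrast))
  invisible(config)
}

as_contrast_pair <- function(ct) {
  if (is.character(ct) && length(ct) == 1) drop(parse_contrast_labels(ct))
  else unlist(ct)
}

# Merge compartment calls from several nuclear-reference contrasts:
# membrane wins, then nucleus from any contrast, then the residual class.
merge_compartment_calls <- function(calls_list) {
  all_calls <- bind_rows(calls_list)
  other <- setdiff(unique(all_calls$compartment),
                   c("nucleus", "membrane"))[1]
  merged <- all_calls |>
    group_by(.data$accession) |>
    summarise(
      compartment = if (any(.data$compartment == "membrane")) "membrane"
      else if (any(.data$compartment == "nucleus")) "nucleus"
      else other,
      basis = paste(unique(.data$basis[.data$basis != ""]), collapse = " | "),
      flagged = any(.data$flagged)
    )
  class(merged) <- c("compartment_calls", class(tibble::tibble()))
  merged
}

#' Run the staged analysis on in-memory tables
#'
#' Executes ingest filtering, quantifiability partition, the configured
#' normalizations, protein summarization, moderated-t contrasts, the
#' two-filter classification, stratified differential expression, optional
#' single-PSM rescue, and QC, in that order. Any stage failure aborts with
#' the stage name.
#'
#' @param psms A `psm_tbl` (see [read_psm_table()] / [simulate_psm_table()]).
#' @param design The experiment design.
#' @param config A `pipeline_config`.
#' @return A named list with `psms_filtered`, `partition`, `matrix`
#'   (`protein_matrix`), `specificity_contrasts`, `filter1`,
#'   `compartment_contrasts`, `calls`, `de` (list of tibbles), `rescue`,
#'   `qc` (list), and `events` (stage log).
#' @export
run_experiment <- function(psms, design, config = pipeline_config()) {
  design <- as_tmt_design(design,
                          require_reference = isTRUE(config$normalization$reference))
  validate_pipeline_config(config, design)
  events <- list()
  note <- function(stage, ...) {
    events[[length(events) + 1]] <<- c(list(stage = stage), list(...))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "apexquant_stage_error", parent = e)
    })
  }

  f <- config$filters
  filtered <- run_stage("ingest_filter", filter_psms(
    psms, coisolation_max = f$coisolation_max %||% 70,
    q_max = f$q_max %||% 0.01, unique_only = f$unique_only %||% TRUE))
  note("ingest_filter", log = attr(filtered, "filter_log"))

  partition <- run_stage("partition", partition_quantifiable(
    filtered, min_unique_psms = f$min_unique_psms %||% 2))
  note("partition", n_quantifiable = length(partition$quantifiable),
       n_rescue = length(partition$single_psm_rescue))

  if (isTRUE(config$normalization$global_median)) {
    filtered <- run_stage("peptide_median_normalization",
                          normalize_peptide_medians(filtered, design))
    note("peptide_median_normalization")
  }

  pm <- run_stage("summarize",
                  summarize_proteins(filtered, design,
                                     partition = partition))
  note("summarize", n_proteins = nrow(pm))

  if (isTRUE(config$normalization$reference)) {
    pm <- run_stage("reference_normalization", normalize_reference(pm))
    note("reference_normalization")
  }

  if (length(config$contaminants) > 0) {
    lists <- lapply(config$contaminants, function(l) {
      if (is.character(l) && length(l) == 1 && file.exists(l)) {
        read_contaminant_list(l)
      } else if (inherits(l, "data.frame")) l else contaminant_list(l)
    })
    keep <- run_stage("contaminant_removal",
                      do.call(remove_contaminants,
                              c(list(pm$accession), lists)))
    report <- attr(keep, "removal_report")
    pm2 <- pm[pm$accession %in% keep, , drop = FALSE]
    attr(pm2, "design") <- pm_design(pm)
    attr(pm2, "psm_support") <- pm_psm_support(pm)
    attr(pm2, "stage_tag") <- pm_stage(pm)
    class(pm2) <- class(pm)
    pm <- pm2
    note("contaminant_removal", n_removed = report$n_removed)
  }

  if (isTRUE(config$normalization$protein_median)) {
    pm <- run_stage("protein_median_normalization",
                    normalize_protein_medians(pm))
    note("protein_median_normalization")
  }

  fit <- run_stage("fit", fit_proteins(pm, design))
  result <- list(psms_filtered = filtered, partition = partition,
                 matrix = pm, fit = fit)

  retained <- pm$accession
  if (!is.null(config$specificity)) {
    sp <- config$specificity
    ctrl <- sp$control
    spec_contrasts <- run_stage("specificity_contrasts", moderated_contrasts(
      fit, lapply(sp$constructs, function(k) c(k, ctrl))))
    f1 <- run_stage("filter1", filter1_specific(
      spec_contrasts, control = ctrl, q_max = sp$q_max %||% 0.05))
    retained <- f1$accession[f1$retained]
    note("filter1", n_retained = length(retained))
    result$specificity_contrasts <- spec_contrasts
    result$filter1 <- f1
  }

  if (!is.null(config$compartment)) {
    cp <- config$compartment
    nuclear_pairs <- lapply(cp$nuclear, as_contrast_pair)
    nes_tables <- run_stage("compartment_contrasts", lapply(
      nuclear_pairs, function(pair) moderated_contrasts(fit, list(pair))))
    lck_table <- NULL
    if (!is.null(cp$membrane)) {
      lck_table <- run_stage("compartment_contrasts", moderated_contrasts(
        fit, list(as_contrast_pair(cp$membrane))))
    }
    calls_list <- run_stage("filter2", lapply(nes_tables, function(tb) {
      filter2_compartment(tb, h2b_vs_lck = lck_table,
                          q_max = cp$q_max %||% 0.05,
                          accessions = retained,
                          mode = cp$mode %||% "auto")
    }))
    calls <- if (length(calls_list) == 1) calls_list[[1]] else
      merge_compartment_calls(calls_list)
    note("filter2", n_nucleus = sum(calls$compartment == "nucleus"),
         n_membrane = sum(calls$compartment == "membrane"))
    result$compartment_contrasts <- c(nes_tables, list(lck = lck_table))
    result$calls <- calls
  }

  if (length(config$de) > 0) {
    calls <- result$calls
    de_res <- run_stage("stratified_de", lapply(config$de, function(entry) {
      use_calls <- calls
      if (!is.null(entry$strata) && !is.null(calls)) {
        use_calls <- calls |> filter(.data$compartment %in% entry$strata)
      }
      if (is.null(use_calls)) {
        use_calls <- tibble::tibble(accession = pm$accession,
                                    compartment = "all")
      }
      stratified_de(pm, design, use_calls,
                    contrast = as_contrast_pair(entry$contrast),
                    alpha_rule = entry$alpha_rule %||% "q",
                    alpha = entry$alpha %||% 0.05,
                    renormalize = isTRUE(entry$renormalize))
    }))
    note("stratified_de", n_tables = length(de_res))
    result$de <- de_res
  }

  if (isTRUE(config$rescue)) {
    result$rescue <- run_stage("rescue", rescue_single_psm(
      filtered, design, partition$single_psm_rescue,
      reference_normalize = isTRUE(config$normalization$reference)))
    note("rescue", n_proteins = length(partition$single_psm_rescue))
  }

  result$qc <- run_stage("qc", list(
    mds = tryCatch(qc_mds(pm, top_n = config$qc$mds_top_n %||% 500),
                   error = function(e) NULL),
    cv = qc_cv(pm, design),
    replicate_correlation = qc_replicate_correlation(pm)
  ))
  result$events <- events
  result
}

#' Run the pipeline from files into a run directory
#'
#' File-level front end of [run_experiment()]: reads the design and PSM
#' table, runs the staged analysis, and writes result tables (TSV), QC
#' summaries (JSON) and a manifest recording package version, parameters,
#' input digests and the seed into `out_dir`. Identical inputs and
#' configuration reproduce byte-identical result tables. On a stage error
#' the partial outputs are kept and the manifest is marked `"incomplete"`.
#'
#' @param config A `pipeline_config`.
#' @param psm_path,design_path Input files.
#' @param out_dir Run directory (created).
#' @param dialect PSM table dialect (see [psm_dialect()]).
#' @return Invisibly, the [run_experiment()] result list.
#' @export
run_pipeline <- function(config, psm_path, design_path, out_dir,
                         dialect = psm_dialect("native")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- read_design(design_path)
  psms <- read_psm_table(psm_path, design, dialect = dialect)
  manifest <- list(
    package = "apexquant",
    version = as.character(utils::packageVersion("apexquant")),
    seed = config$seed,
    inputs = list(
      psm_path = psm_path, psm_md5 = unname(tools::md5sum(psm_path)),
      design_path = design_path,
      design_md5 = unname(tools::md5sum(design_path))
    ),
    config = unclass(config),
    status = "incomplete"
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  write_manifest()
  result <- tryCatch(
    run_experiment(psms, design, config),
    error = function(e) {
      manifest$status <<- "incomplete"
      manifest$error <<- conditionMessage(e)
      write_manifest()
      abort(conditionMessage(e), class = "apexquant_stage_error")
    }
  )
  write_protein_matrix(result$matrix, file.path(out_dir, "protein_matrix.tsv"))
  if (!is.null(result$specificity_contrasts)) {
    write_contrasts(result$specificity_contrasts,
                    file.path(out_dir, "specificity_contrasts.tsv"))
  }
  if (!is.null(result$calls)) {
    readr::write_tsv(result$calls, file.path(out_dir, "compartment_calls.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$de)) {
    for (i in seq_along(result$de)) {
      readr::write_tsv(result$de[[i]],
                       file.path(out_dir, sprintf("de_%02d.tsv", i)),
                       progress = FALSE)
    }
  }
  if (!is.null(result$rescue)) {
    readr::write_tsv(result$rescue, file.path(out_dir, "rescue.tsv"),
                     progress = FALSE)
    readr::write_tsv(attr(result$rescue, "condition_n"),
                     file.path(out_dir, "rescue_condition_n.tsv"),
                     progress = FALSE)
  }
  qc_out <- list(
    cv_summary = attr(result$qc$cv, "summary"),
    events = result$events
  )
  jsonlite::write_json(qc_out, file.path(out_dir, "qc_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(result$qc$mds)) {
    readr::write_tsv(tibble::as_tibble(result$qc$mds),
                     file.path(out_dir, "qc_mds.tsv"), progress = FALSE)
  }
  manifest$status <- "complete"
  manifest$stages <- vapply(result$events, function(e) e$stage, "")
  write_manifest()
  invisible(result)
}
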