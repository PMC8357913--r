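#' Differential expression within compartment strata
#'
#' Runs moderated t contrasts separately inside each compartment stratum
#' (nuclear and cytosolic proteomes are tested as independent families, each
#' with its own variance prior and BH adjustment), then flags significance
#' by the configured rule: nominal `p` for exploratory comparisons with
#' modest effect sizes, or BH `q` for FDR-controlled calls.
#'
#' @param pm A normalized `protein_matrix`.
#' @param design The experiment design.
#' @param calls A `compartment_calls` tibble (see [filter2_compartment()]).
#' @param contrast A 2-vector `c(A, B)` or string `"A - B"`.
#' @param alpha_rule `"q"` or `"p"`.
#' @param alpha Significance level.
#' @param renormalize Re-align sample medians within each stratum before
#'   testing (per-stratum protein-median renormalization).
#' @return A tibble of per-stratum contrast results with columns of
#'   [moderated_contrasts()] plus `stratum` and `significant`;
#'   `attr(., "summary")` counts up/down calls per stratum.
#' @export
stratified_de <- function(pm, design = pm_design(pm), calls, contrast,
                          alpha_rule = c("q", "p"), alpha = 0.05,
                          renormalize = FALSE) {
  alpha_rule <- match.arg(alpha_rule)
  design <- as_tmt_design(design)
  values <- pm_values(pm)
  strata <- split(calls$accession, calls$compartment)
  res <- purrr::imap(strata, function(acc, stratum) {
    acc <- intersect(acc, rownames(values))
    if (length(acc) == 0) {
      warn(sprintf("stratum '%s' has no quantified proteins", stratum))
      return(NULL)
    }
    sub <- pm[pm$accession %in% acc, , drop = FALSE]
    attr(sub, "design") <- design
    attr(sub, "psm_support") <- pm_psm_support(pm)
    attr(sub, "stage_tag") <- pm_stage(pm)
    class(sub) <- class(pm)
    if (renormalize) sub <- normalize_protein_medians(sub)
    fit <- fit_proteins(sub, design)
    ct <- moderated_contrasts(fit, list(contrast))
    ct$stratum <- stratum
    ct
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    warn("no stratum produced results")
    return(out)
  }
  crit <- if (alpha_rule == "q") out$q else out$p
  out$significant <- crit < alpha
  attr(out, "summary") <- out |>
    group_by(.data$stratum) |>
    summarise(n_tested = n(),
              n_up = sum(.data$significant & .data$log2fc > 0),
              n_down = sum(.data$significant & .data$log2fc < 0))
  attr(out, "alpha_rule") <- alpha_rule
  attr(out, "alpha") <- alpha
  out
}

#' Merge transcriptomic DEG reference lists
#'
#' Builds the reference set of differentially expressed transcripts from one
#' or more source tables (columns `gene`, `log2fc`, `adj_p`, `source`,
#' optional `cluster`). A gene qualifies in a source when
#' `adj_p < adj_p_max` and `|log2fc| > abs_log2fc_min`, or when it carries a
#' cluster label (sources that publish cluster memberships instead of
#' statistics). Qualifying records are merged across sources and
#' de-duplicated by gene symbol; genes whose sources disagree on direction
#' keep both records and are flagged. An optional two-column gene-accession
#' mapping attaches protein accessions; unmapped genes are reported.
#'
#' @param tables A data frame with a `source` column, or a named list of
#'   data frames (names become sources).
#' @param adj_p_max,abs_log2fc_min Qualification thresholds.
#' @param mapping Optional data frame with columns `gene`, `accession`.
#' @return Tibble `gene, accession, log2fc, adj_p, sources, conflict`;
#'   unmapped genes in `attr(., "unmapped")`.
#' @export
merge_transcript_degs <- function(tables, adj_p_max = 0.05,
                                  abs_log2fc_min = 1, mapping = NULL) {
  if (is.data.frame(tables)) {
    check_required_columns(tables, c("gene", "log2fc", "adj_p", "source"),
                           "DEG table")
    all_tab <- tibble::as_tibble(tables)
  } else {
    all_tab <- purrr::imap(tables, function(df, src) {
      df <- tibble::as_tibble(df)
      if (!"source" %in% names(df)) df$source <- src
      df
    }) |> bind_rows()
    check_required_columns(all_tab, c("gene", "log2fc", "adj_p", "source"),
                           "DEG table")
  }
  if (!"cluster" %in% names(all_tab)) all_tab$cluster <- NA_character_
  qualified <- all_tab |>
    filter(
      (!is.na(.data$adj_p) & .data$adj_p < adj_p_max &
         !is.na(.data$log2fc) & abs(.data$log2fc) > abs_log2fc_min) |
        (!is.na(.data$cluster) & .data$cluster != "")
    )
  merged <- qualified |>
    group_by(.data$gene) |>
    group_modify(function(g, key) {
      signs <- unique(sign(g$log2fc[!is.na(g$log2fc) & g$log2fc != 0]))
      conflict <- length(signs) > 1
      if (conflict) {
        g |> mutate(sources = .data$source, conflict = TRUE) |>
          select("log2fc", "adj_p", "sources", "conflict")
      } else {
        tibble::tibble(
          log2fc = mean(g$log2fc, na.rm = TRUE),
          adj_p = suppressWarnings(min(g$adj_p, na.rm = TRUE)),
          sources = paste(sort(unique(g$source)), collapse = ";"),
          conflict = FALSE
        )
      }
    }) |>
    ungroup() |>
    mutate(adj_p = ifelse(is.infinite(.data$adj_p), NA_real_, .data$adj_p),
           log2fc = ifelse(is.nan(.data$log2fc), NA_real_, .data$log2fc))
  unmapped <- character()
  if (!is.null(mapping)) {
    check_required_columns(mapping, c("gene", "accession"), "gene mapping")
    merged <- merged |>
      left_join(distinct(tibble::as_tibble(mapping)), by = "gene")
    unmapped <- unique(merged$gene[is.na(merged$accession)])
    if (length(unmapped) > 0) {
      inform(sprintf("%d gene(s) had no accession mapping",
                     length(unmapped)))
    }
  } else {
    merged$accession <- NA_character_
  }
  out <- merged |>
    select("gene", "accession", "log2fc", "adj_p", "sources", "conflict") |>
    arrange(.data$gene)
  attr(out, "unmapped") <- unmapped
  out
}

#' Proteome-transcriptome fold-change correlation
#'
#' Pearson correlation between protein and transcript log2 fold changes over
#' the accessions shared by the two tables, with the two-sided p-value from
#' the t transform of r.
#'
#' @param protein_fc Data frame with `accession` and `log2fc`.
#' @param transcript_fc Data frame with `accession` and `log2fc`.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
proteogenomic_correlation <- function(protein_fc, transcript_fc) {
  check_required_columns(protein_fc, c("accession", "log2fc"),
                         "protein fold-change table")
  check_required_columns(transcript_fc, c("accession", "log2fc"),
                         "transcript fold-change table")
  merged <- inner_join(
    protein_fc |> select("accession", protein = "log2fc"),
    transcript_fc |> select("accession", transcript = "log2fc"),
    by = "accession"
  ) |> filter(!is.na(.data$protein), !is.na(.data$transcript))
  if (nrow(merged) < 3) {
    abort("need at least 3 shared accessions for a correlation",
          class = "apexquant_validation_error")
  }
  ct <- cor.test(merged$protein, merged$transcript, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(merged))
}

#' Read a GMT annotation collection
#'
#' Tab-separated: term id, description, then member identifiers.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with `term`, `description`, and list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split(lines, "\t")
  tibble::tibble(
    term = vapply(parts, `[`, "", 1L),
    description = vapply(parts, `[`, "", 2L),
    members = lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  )
}

#' Annotation-set enrichment against the identified-protein background
#'
#' Hypergeometric upper-tail enrichment of a protein foreground (e.g. the
#' nucleus-called set) against a background of all identified proteins, per
#' annotation term. Term memberships are intersected with the background
#' before testing; fold enrichment is
#' `(overlap / |foreground|) / (term size / |background|)`. BH adjustment
#' across terms.
#'
#' @param foreground Character vector; must be a subset of `background`.
#' @param background Character vector (the identified-protein universe).
#' @param sets Annotation collection from [read_gmt()] (or any tibble with
#'   `term`, `description`, `members`).
#' @return Tibble `term, description, n_term, n_overlap, fold_enrichment,
#'   p, q` sorted by p.
#' @export
annotation_enrichment <- function(foreground, background, sets) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0) {
    abort("empty foreground", class = "apexquant_validation_error")
  }
  if (!all(foreground %in% background)) {
    abort("foreground must be a subset of the background",
          class = "apexquant_validation_error")
  }
  N <- length(background)
  n <- length(foreground)
  res <- purrr::pmap(sets, function(term, description, members, ...) {
    in_bg <- intersect(members, background)
    K <- length(in_bg)
    k <- length(intersect(in_bg, foreground))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
    tibble::tibble(term = term, description = description,
                   n_term = K, n_overlap = k, fold_enrichment = fold, p = p)
  }) |> bind_rows()
  res$q <- bh_adjust(res$p)
  arrange(res, .data$p)
}

#' Multidimensional scaling of samples on leading log-fold-changes
#'
#' QC ordination: the distance between two samples is the root-mean-square
#' of the `top_n` largest absolute log2 differences among proteins complete
#' in every sample (the "leading log-fold-change", selected per pair),
#' embedded in two dimensions by classical (Torgerson) MDS. The sign of each
#' dimension is fixed by forcing its largest-magnitude coordinate positive,
#' so embeddings are reproducible.
#'
#' @param pm A `protein_matrix`.
#' @param top_n Number of leading fold changes per pair.
#' @param dims Embedding dimensions.
#' @return A `qc_mds` tibble: `sample`, `condition`, `mds1`, `mds2`; the
#'   pairwise distance matrix is in `attr(., "dist")`.
#' @export
qc_mds <- function(pm, top_n = 500, dims = 2) {
  values <- pm_values(pm)
  if (ncol(values) < 3) {
    abort("MDS needs at least 3 samples", class = "apexquant_validation_error")
  }
  complete <- values[stats::complete.cases(values), , drop = FALSE]
  if (nrow(complete) < 3) {
    abort("fewer than 3 proteins without missing values",
          class = "apexquant_validation_error")
  }
  if (nrow(complete) < top_n) {
    warn(sprintf("only %d complete proteins available (top_n = %d); using all",
                 nrow(complete), top_n))
    top_n <- nrow(complete)
  }
  S <- ncol(complete)
  d <- matrix(0, S, S, dimnames = list(colnames(complete),
                                       colnames(complete)))
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      d2 <- sort((complete[, i] - complete[, j])^2, decreasing = TRUE)
      d[i, j] <- d[j, i] <- sqrt(mean(d2[seq_len(top_n)]))
    }
  }
  coords <- cmdscale(d, k = dims)
  for (k in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, k])), k] < 0) {
      coords[, k] <- -coords[, k]
    }
  }
  design <- pm_design(pm)
  out <- tibble::tibble(
    sample = colnames(complete),
    condition = design$condition[match(colnames(complete), design$sample)]
  )
  for (k in seq_len(ncol(coords))) out[[paste0("mds", k)]] <- coords[, k]
  attr(out, "dist") <- d
  attr(out, "n_proteins") <- nrow(complete)
  class(out) <- c("qc_mds", class(tibble::tibble()))
  out
}

#' Percent coefficient of variation per condition
#'
#' Per protein and condition, `100 * sd / mean` over the observed log2
#' abundances of the condition's replicates (the conventional reporting
#' scale for TMT QC). Conditions with a single replicate are skipped with a
#' warning; proteins with non-positive mean log2 abundance have no defined
#' %CV and are excluded (counted).
#'
#' @param pm A `protein_matrix`.
#' @param design The experiment design.
#' @param scale `"log2"` (default) or `"linear"` (CV of `2^x`).
#' @return A `qc_cv` tibble `accession, condition, cv`; per-condition means
#'   and exclusion counts in `attr(., "summary")`.
#' @export
qc_cv <- function(pm, design = pm_design(pm), scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  design <- as_tmt_design(design)
  values <- pm_values(pm)
  if (scale == "linear") values <- 2^values
  conds <- unique(design$condition[!design$is_reference])
  rows <- purrr::map(conds, function(cond) {
    cols <- design$sample[design$condition == cond & !design$is_reference]
    if (length(cols) < 2) {
      warn(sprintf("condition '%s' has a single replicate; %%CV skipped",
                   cond))
      return(NULL)
    }
    sub <- values[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, sd, na.rm = TRUE)
    ok <- n >= 2 & m > 0
    tibble::tibble(accession = rownames(sub)[ok], condition = cond,
                   cv = unname(100 * s[ok] / m[ok]),
                   n_excluded_nonpositive = sum(n >= 2 & m <= 0))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    warn("no condition had two or more replicates; empty %CV table")
    out <- tibble::tibble(accession = character(), condition = character(),
                          cv = numeric())
    class(out) <- c("qc_cv", class(tibble::tibble()))
    return(out)
  }
  summary <- out |>
    group_by(.data$condition) |>
    summarise(mean_cv = mean(.data$cv),
              n_proteins = n(),
              n_excluded = .data$n_excluded_nonpositive[1])
  out <- out |> select("accession", "condition", "cv")
  attr(out, "summary") <- summary
  class(out) <- c("qc_cv", class(tibble::tibble()))
  out
}

#' Pairwise replicate correlation
#'
#' Pearson correlation of log2 protein abundances for every sample pair,
#' over pairwise-complete proteins. Pairs sharing fewer than 3 proteins get
#' a missing value and are flagged.
#'
#' @param pm A `protein_matrix`.
#' @return Long tibble `sample_x, sample_y, r, n_shared`; the full
#'   correlation matrix is in `attr(., "matrix")`.
#' @export
qc_replicate_correlation <- function(pm) {
  values <- pm_values(pm)
  if (ncol(values) < 2) {
    abort("need at least 2 samples", class = "apexquant_validation_error")
  }
  r <- suppressWarnings(cor(values, use = "pairwise.complete.obs"))
  obs <- !is.na(values)
  shared <- t(obs) %*% obs
  few <- shared < 3
  if (any(few & upper.tri(few))) {
    warn("some sample pairs share fewer than 3 proteins; correlations set missing")
  }
  r[few] <- NA_real_
  diag(r) <- 1
  out <- tibble::as_tibble(r, rownames = "sample_x") |>
    tidyr::pivot_longer(-"sample_x", names_to = "sample_y",
                        values_to = "r") |>
    left_join(
      tibble::as_tibble(shared, rownames = "sample_x") |>
        tidyr::pivot_longer(-"sample_x", names_to = "sample_y",
                            values_to = "n_shared"),
      by = c("sample_x", "sample_y")
    )
  attr(out, "matrix") <- r
  class(out) <- c("qc_correlation", class(tibble::tibble()))
  out
}
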