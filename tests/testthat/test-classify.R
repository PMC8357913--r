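test_that("filter 1 retains positively enriched significant proteins only", {
  ct <- make_contrasts(
    accession = c("P1", "P2", "P3", "P4"),
    contrast = "H2B - CTRL",
    log2fc = c(0.5, -1.0, 2.0, 0.8),
    q = c(0.01, 1e-6, 0.2, 0.04)
  )
  f1 <- filter1_specific(ct)
  retained <- f1$accession[f1$retained]
  expect_setequal(retained, c("P1", "P4"))
  report <- attr(f1, "report")
  expect_equal(report$reason[report$accession == "P2"], "not_enriched")
  expect_equal(report$reason[report$accession == "P3"], "not_significant")

  # wrong contrast orientation is refused
  expect_error(filter1_specific(make_contrasts("P1", "H2B - NES", 1, 0.01)),
               class = "apexquant_validation_error")

  # multi-construct input: specific_in collects the passing constructs
  multi <- dplyr::bind_rows(
    make_contrasts("P1", "H2B - CTRL", 1.0, 0.01),
    make_contrasts("P1", "NES - CTRL", 0.6, 0.03),
    make_contrasts("P1", "LCK - CTRL", 0.2, 0.50)
  )
  f1m <- filter1_specific(multi)
  expect_setequal(f1m$specific_in[[1]], c("H2B", "NES"))
})

test_that("contaminant removal reports per-tag attributions", {
  kept <- remove_contaminants(c("P1", "P2", "P3"),
                              contaminant_list("P2", tag = "keratin"))
  expect_equal(strip_attrs(kept), c("P1", "P3"))
  expect_equal(attr(kept, "removal_report")$n_removed, 1)

  # empty list: identity
  same <- remove_contaminants(c("P1", "P2"), contaminant_list(character()))
  expect_equal(strip_attrs(same), c("P1", "P2"))

  # overlapping lists: removal attributed to both tags
  both <- remove_contaminants(
    c("P1", "P2", "P3"),
    contaminant_list("P2", tag = "nonspecific-binder"),
    contaminant_list(c("P2", "P3"), tag = "astrocyte-enriched"))
  expect_equal(strip_attrs(both), "P1")
  rep_tags <- attr(both, "removal_report")$by_tag
  expect_equal(rep_tags$n_removed[rep_tags$tag == "nonspecific-binder"], 1)
  expect_equal(rep_tags$n_removed[rep_tags$tag == "astrocyte-enriched"], 2)
})

test_that("contaminant lists parse provenance tags from comment lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#keratin", "K1", "K2", "#astrocyte-enriched", "A1"), path)
  cl <- read_contaminant_list(path)
  expect_equal(cl$tag, c("keratin", "keratin", "astrocyte-enriched"))
  expect_equal(cl$accession, c("K1", "K2", "A1"))
})

test_that("filter 2 assigns compartments by the sign-and-significance rules", {
  nes <- make_contrasts(c("N1", "C1", "M1"), "H2B - NES",
                        log2fc = c(1.2, 0.1, -0.3), q = c(0.001, 0.2, 0.2))
  lck <- make_contrasts(c("N1", "C1", "M1"), "H2B - LCK",
                        log2fc = c(1.0, 0.0, -0.9), q = c(0.01, 0.9, 0.004))

  # three-construct mode
  calls3 <- filter2_compartment(nes, lck)
  expect_equal(calls3$compartment[calls3$accession == "N1"], "nucleus")
  expect_equal(calls3$compartment[calls3$accession == "M1"], "membrane")
  expect_equal(calls3$compartment[calls3$accession == "C1"], "unassigned")
  expect_true(all(calls3$basis[calls3$compartment != "unassigned"] != ""))

  # two-compartment mode: the residual class is the cytosolic proteome
  calls2 <- filter2_compartment(nes)
  expect_equal(calls2$compartment[calls2$accession == "C1"],
               "cytosol_nonH2B")
  expect_equal(calls2$compartment[calls2$accession == "M1"],
               "cytosol_nonH2B")

  # restriction to the filter-1-retained set
  restr <- filter2_compartment(nes, lck, accessions = c("N1", "M1"))
  expect_setequal(restr$accession, c("N1", "M1"))
})

test_that("no protein is ever both nucleus- and membrane-called", {
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- 80
      acc <- paste0("P", seq_len(n))
      nes <- make_contrasts(acc, "H2B - NES", rnorm(n), runif(n)^2)
      lck <- make_contrasts(acc, "H2B - LCK", rnorm(n), runif(n)^2)
      calls <- filter2_compartment(nes, lck)
      expect_equal(anyDuplicated(calls$accession), 0)
      expect_true(all(calls$compartment %in%
                        c("nucleus", "membrane", "unassigned")))
      # purity: identical inputs give identical output
      expect_identical(calls, filter2_compartment(nes, lck))
    }
  })
})

test_that("alternative cutoffs use the documented total order", {
  ct <- make_contrasts(paste0("P", 1:4), "H2B - NES",
                       log2fc = c(2.0, 1.5, 1.0, 0.5),
                       q = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(alt_cutoff(ct, "rank_top_k", k = 3), c("P1", "P2", "P3"))
  expect_equal(alt_cutoff(ct, "static_log2fc", threshold = 1.0),
               c("P1", "P2", "P3")) # ties at the threshold included
  expect_warning(res <- alt_cutoff(ct, "rank_top_k", k = 10))
  expect_equal(length(res), 4)

  # rank-boundary ties break by (log2fc desc, q asc, accession asc)
  tied <- make_contrasts(c("B", "A", "C"), "H2B - NES",
                         log2fc = c(1, 1, 1), q = c(0.02, 0.02, 0.01))
  expect_equal(alt_cutoff(tied, "rank_top_k", k = 2), c("C", "A"))
})

test_that("single-PSM rescue reports per-condition quantification counts", {
  des <- design_activity()
  par <- sim_params(n_proteins = 120, seed = 62)
  sim <- simulate_experiment(par, des)
  ps <- filter_psms(sim$psms)
  part <- partition_quantifiable(ps)
  expect_gt(length(part$single_psm_rescue), 3)
  resc <- rescue_single_psm(ps, des, part$single_psm_rescue)
  n_tbl <- attr(resc, "condition_n")
  expect_setequal(unique(n_tbl$condition),
                  unique(des$condition[!des$is_reference]))
  # counts never exceed the design's replicate numbers
  max_n <- table(des$condition[!des$is_reference])
  for (cond in names(max_n)) {
    expect_true(all(n_tbl$n_quantified[n_tbl$condition == cond] <=
                      max_n[[cond]]))
  }
  # rescue values equal the reference-normalized single-PSM log2 intensities
  one <- part$single_psm_rescue[1]
  pm_one <- normalize_reference(summarize_proteins(ps, des, proteins = one))
  manual <- tidy(pm_one) |> dplyr::filter(!is.na(.data$log2_abundance))
  got <- resc |> dplyr::filter(.data$accession == one)
  expect_equal(got$log2_abundance,
               manual$log2_abundance[match(got$sample, manual$sample)],
               tolerance = 1e-12)
})
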