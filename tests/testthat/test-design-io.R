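test_that("designs round-trip through CSV and validate their invariants", {
  design <- design_compartment()
  expect_s3_class(design, "tmt_design")
  expect_equal(length(unique(design$run)), 2)
  expect_equal(nrow(design), 20)

  path <- withr::local_tempfile(fileext = ".csv")
  write_design(design, path)
  back <- read_design(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(design))

  dup <- dplyr::bind_rows(design, design[1, ])
  expect_error(as_tmt_design(dup), class = "apexquant_validation_error")

  no_ref <- design |> dplyr::mutate(is_reference = FALSE)
  expect_error(as_tmt_design(no_ref, require_reference = TRUE),
               class = "apexquant_validation_error")
  expect_silent(as_tmt_design(no_ref, require_reference = FALSE))

  missing_col <- design |> dplyr::select(-"condition")
  expect_error(as_tmt_design(missing_col), class = "apexquant_schema_error")
})

test_that("PSM tables are read, standardized, and cleaned of invalid intensities", {
  design <- tiny_design()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    run = c("r1", "r1", "r2"),
    fraction = NA_character_,
    accessions = c("P1", "P1; P2", "P3"),
    peptide = c("AAAK", "CCCK", "DDDK"),
    charge = c(2L, 2L, 3L),
    search_q = c(0.001, 0.002, 0.003),
    coisolation_pct = c(0, 10, 20),
    `126` = c(100, 200, 0),      # zero -> missing
    `127N` = c(150, NA, 300),    # empty cell stays missing
    `127C` = c(120, 210, 310)
  ), path)
  psms <- read_psm_table(path, design)
  expect_equal(nrow(psms), 3)
  expect_equal(psms$is_unique, c(TRUE, FALSE, TRUE))
  expect_equal(psms$accession, c("P1", NA, "P3"))
  expect_equal(psms$accessions[2], "P1;P2")
  expect_true(is.na(psms$`126`[3]))
  expect_true(is.na(psms$`127N`[2]))
  expect_equal(ingest_log(psms)$n_nonpositive_to_missing, 1)

  # unknown run is a validation error
  readr::write_tsv(tibble::tibble(
    run = "r9", fraction = NA, accessions = "P1", peptide = "K", charge = 2,
    search_q = 0.001, coisolation_pct = 0, `126` = 1, `127N` = 1, `127C` = 1
  ), path)
  expect_error(read_psm_table(path, design),
               class = "apexquant_validation_error")
})

test_that("the Proteome Discoverer dialect maps vendor columns onto the schema", {
  design <- tiny_design()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    `File ID` = c("r1", "r2"),
    `Master Protein Accessions` = c("P1", "P2; P3"),
    `Annotated Sequence` = c("AAAK", "CCCR"),
    Charge = c(2L, 3L),
    `Percolator q-Value` = c(0.001, 0.004),
    `Isolation Interference [%]` = c(5, 12),
    `Abundance: 126` = c(1000, 2000),
    `Abundance: 127N` = c(1100, NA),
    `Abundance: 127C` = c(900, 1800)
  ), path)
  psms <- read_psm_table(path, design, dialect = psm_dialect("pd"))
  expect_equal(psms$run, c("r1", "r2"))
  expect_equal(psms$is_unique, c(TRUE, FALSE))
  expect_equal(psms$search_q, c(0.001, 0.004))
  expect_equal(psms$coisolation_pct, c(5, 12))
  expect_equal(psms$`126`, c(1000, 2000))

  # a reporter column outside the design is a schema error
  readr::write_tsv(tibble::tibble(
    `File ID` = "r1", `Master Protein Accessions` = "P1",
    `Annotated Sequence` = "K", Charge = 2L, `Percolator q-Value` = 0.001,
    `Isolation Interference [%]` = 0,
    `Abundance: 126` = 1, `Abundance: 131` = 5
  ), path)
  expect_error(read_psm_table(path, design, dialect = psm_dialect("pd")),
               class = "apexquant_schema_error")
})

test_that("shipped example annotation files parse", {
  cl <- read_contaminant_list(
    system.file("extdata", "contaminants_example.txt",
                package = "apexquant"))
  expect_setequal(unique(cl$tag),
                  c("nonspecific-binder", "keratin", "astrocyte-enriched"))
  gmt <- read_gmt(
    system.file("extdata", "go_cc_example.gmt", package = "apexquant"))
  expect_equal(nrow(gmt), 3)
  expect_equal(lengths(gmt$members), c(5L, 3L, 4L))
})

test_that("PSM filtering applies the three predicates with the stated conventions", {
  design <- tiny_design()
  psms <- make_psms(tibble::tibble(
    run = "r1",
    accessions = c("P1", "P2", "P3", "P4;P5", "P6"),
    peptide = paste0("PEP", 1:5),
    search_q = c(0.001, 0.02, 0.001, 0.001, 0.001),
    coisolation_pct = c(0, 0, 80, 0, 0),
    `126` = 100
  ), design)
  kept <- filter_psms(psms)
  expect_equal(kept$accessions, c("P1", "P6")) # hand-applied predicates
  expect_equal(attr(kept, "filter_log")$n_fail_q, 1)
  expect_equal(attr(kept, "filter_log")$n_fail_coisolation, 1)
  expect_equal(attr(kept, "filter_log")$n_fail_unique, 1)

  # boundary conventions: co-isolation inclusive at 70, q strict at 0.01
  edge <- make_psms(tibble::tibble(
    run = "r1", accessions = c("A", "B", "C", "D"),
    peptide = paste0("E", 1:4),
    search_q = c(0.001, 0.01, 0.0099, 0.001),
    coisolation_pct = c(70, 0, 0, 75),
    `126` = 10
  ), design)
  expect_equal(filter_psms(edge)$accessions, c("A", "C"))
})

test_that("filtering is idempotent and monotone in its thresholds", {
  design <- tiny_design()
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- 40
      psms <- make_psms(tibble::tibble(
        run = sample(c("r1", "r2"), n, TRUE),
        accessions = ifelse(runif(n) < 0.2, "X;Y",
                            sample(LETTERS, n, TRUE)),
        peptide = paste0("P", seq_len(n)),
        search_q = runif(n, 0, 0.03),
        coisolation_pct = runif(n, 0, 100),
        `126` = runif(n, 10, 1000)
      ), design)
      once <- filter_psms(psms)
      twice <- filter_psms(once)
      expect_equal(twice$psm_id, once$psm_id)
      tighter <- suppressWarnings(
        filter_psms(psms, coisolation_max = 50, q_max = 0.005))
      expect_true(all(tighter$psm_id %in% once$psm_id))
    }
  })
})

test_that("quantifiability partition follows the unique-feature rules", {
  design <- tiny_design()
  psms <- make_psms(tibble::tibble(
    run = "r1",
    accessions = c("TWOPEP", "TWOPEP",      # two unique peptides
                   "CHARGES", "CHARGES",    # one peptide, charges 2 and 3
                   "SINGLE",                # one unique PSM
                   "SAMECHG", "SAMECHG",    # one peptide, both charge 2
                   "SH1;SH2"),              # shared only
    peptide = c("AK", "BK", "CK", "CK", "DK", "EK", "EK", "FK"),
    charge = c(2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L),
    `126` = 100
  ), design)
  part <- partition_quantifiable(psms)
  expect_setequal(part$quantifiable, c("TWOPEP", "CHARGES"))
  expect_setequal(part$single_psm_rescue, c("SINGLE", "SAMECHG"))
  expect_setequal(part$dropped$accession, c("SH1", "SH2"))

  # disjoint and exhaustive over all accessions seen
  all_seen <- unique(unlist(strsplit(psms$accessions, ";")))
  sets <- list(part$quantifiable, part$single_psm_rescue,
               part$dropped$accession)
  expect_equal(sum(lengths(sets)), length(all_seen))
  expect_setequal(unlist(sets), all_seen)
})
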