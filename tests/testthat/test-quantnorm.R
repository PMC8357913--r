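test_that("median polish matches hand-derivable cases", {
  # constant matrix: every channel abundance equals the constant
  const <- matrix(7, 3, 4)
  expect_equal(unname(median_polish(const)$fitted), rep(7, 4))

  # a single PSM row fixes the column abundances at the row's values
  row1 <- matrix(c(5, 6, 8, NA), 1, 4)
  expect_equal(unname(median_polish(row1)$fitted), c(5, 6, 8, NA))

  # purely additive 2x3 matrix m[f, c] = a_f + b_c, a = (0, 2), b = (0, 1, 3)
  additive <- outer(c(0, 2), c(0, 1, 3), `+`)
  expect_equal(unname(median_polish(additive)$fitted), c(1, 2, 4))
})

test_that("median polish agrees with the independent iterative oracle", {
  withr::with_seed(21, {
    for (i in 1:200) {
      nr <- sample(1:6, 1)
      nc <- sample(3:10, 1)
      x <- matrix(rnorm(nr * nc, 10, 2), nr, nc)
      x[runif(nr * nc) < 0.1] <- NA
      if (all(is.na(x))) next
      expect_equal(unname(median_polish(x)$fitted),
                   unname(oracle_median_polish(x)), tolerance = 1e-8)
    }
  })
})

test_that("additive matrices are recovered exactly with near-zero residual medians", {
  withr::with_seed(22, {
    for (i in 1:25) {
      a <- rnorm(4); b <- rnorm(6)
      x <- outer(a, b, `+`) + 12
      mp <- median_polish(x)
      expect_equal(unname(mp$fitted), unname(12 + median(a) + b),
                   tolerance = 1e-9)
    }
  })
})

test_that("peptide-level global median normalization aligns channel medians", {
  design <- tiny_design()
  psms <- make_psms(tibble::tibble(
    run = rep("r1", 4),
    accessions = paste0("P", 1:4), peptide = paste0("PEP", 1:4),
    `126` = 2^c(10, 10.5, 9.5, 10.2),
    `127N` = 2^c(12, 12.5, 11.5, 12.2),
    `127C` = 2^c(11, 11.5, 10.5, 11.2)
  ), design)

  expect_identical(normalize_peptide_medians(psms, design, enabled = FALSE),
                   psms)

  out <- normalize_peptide_medians(psms, design)
  meds <- vapply(c("126", "127N", "127C"),
                 function(ch) median(log2(out[[ch]]), na.rm = TRUE), 0)
  # brute-force target: the grand median of the original channel medians
  orig <- vapply(c("126", "127N", "127C"),
                 function(ch) median(log2(psms[[ch]]), na.rm = TRUE), 0)
  expect_equal(unname(meds), rep(median(orig), 3), tolerance = 1e-12)
  # channels at log2 medians 10.1 and 12.1 move by +1 and -1
  expect_equal(log2(out$`126`) - log2(psms$`126`), rep(+1, 4))
  expect_equal(log2(out$`127N`) - log2(psms$`127N`), rep(-1, 4))
})

test_that("protein summarization maps polished channel effects onto samples", {
  design <- tiny_design()
  psms <- make_psms(tibble::tibble(
    run = c("r1", "r1", "r2"),
    accessions = c("P1", "P1", "P1"),
    peptide = c("AK", "BK", "AK"), charge = c(2L, 3L, 2L),
    `126` = 2^c(10, 12, 11),
    `127N` = 2^c(11, 13, 12),
    `127C` = 2^c(13, 15, 10)
  ), design)
  pm <- summarize_proteins(psms, design)
  v <- pm_values(pm)
  # run 1 is additive with row effects (0, 2): abundances 11, 12, 14
  expect_equal(unname(v["P1", c("REF_1", "X_1", "Y_1")]), c(11, 12, 14))
  # run 2 is a single PSM: abundances are the raw log2 values
  expect_equal(unname(v["P1", c("REF_2", "X_2", "Y_2")]), c(11, 12, 10))
  sup <- pm_psm_support(pm)
  expect_equal(sup$n_psms[sup$run == "r1"], 2)
})

test_that("reference normalization equalizes references and preserves within-run contrasts", {
  design <- tiny_design()
  v <- rbind(P1 = c(10, 11, 12, 12, 13, 14),
             P2 = c(8, 9, 9.5, 8.4, 9.2, 9.9))
  colnames(v) <- design$sample
  pm <- make_pm(v, design)
  out <- pm_values(normalize_reference(pm))
  # worked example: refs at 10 and 12 -> run-2 shift is -1 toward grand mean 11
  expect_equal(unname(out["P1", ]), c(11, 12, 13, 11, 12, 13))
  # references agree across runs for every protein
  expect_equal(out[, "REF_1"], out[, "REF_2"])
  # within-run channel differences are invariant
  expect_equal(out[, "X_1"] - out[, "Y_1"], v[, "X_1"] - v[, "Y_1"])
  expect_equal(out[, "X_2"] - out[, "REF_2"], v[, "X_2"] - v[, "REF_2"])

  # single-run study: identity
  one_run <- as_tmt_design(design[design$run == "r1", ])
  pm1 <- make_pm(v[, 1:3], one_run)
  expect_equal(pm_values(normalize_reference(pm1)), v[, 1:3])

  # no reference channels at all: error
  no_ref <- design |> dplyr::mutate(is_reference = FALSE) |> as_tmt_design()
  pm2 <- make_pm(v, no_ref)
  expect_error(normalize_reference(pm2, no_ref),
               class = "apexquant_validation_error")
})

test_that("injected batch shifts are removed exactly for fully observed proteins", {
  des <- design_compartment()
  par <- sim_params(n_proteins = 60, batch_sd_log2 = 1.0, mcar_rate = 0,
                    seed = 31)
  sim <- simulate_experiment(par, des)
  pm <- normalize_reference(summarize_proteins(filter_psms(sim$psms), des))
  v <- pm_values(pm)
  refs <- v[, des$sample[des$is_reference], drop = FALSE]
  complete <- stats::complete.cases(refs)
  expect_gt(sum(complete), 10)
  expect_equal(refs[complete, 1], refs[complete, 2], tolerance = 1e-12)
})

test_that("protein-level median normalization aligns columns and is idempotent", {
  design <- tiny_design()
  withr::with_seed(41, {
    v <- matrix(rnorm(60, 10), 10, 6,
                dimnames = list(paste0("P", 1:10), design$sample))
    v[sample(60, 12)] <- NA
    v[1, ] <- 10 # keep every column non-empty
    pm <- make_pm(v, design)
    out <- pm_values(normalize_protein_medians(pm))
    meds <- apply(out, 2, median, na.rm = TRUE)
    target <- median(apply(v, 2, median, na.rm = TRUE))
    expect_equal(unname(meds), rep(target, 6), tolerance = 1e-12)
    # idempotent
    again <- pm_values(normalize_protein_medians(
      normalize_protein_medians(pm)))
    expect_equal(again, out, tolerance = 1e-12)
    # empty column errors
    v2 <- v; v2[, 2] <- NA
    expect_error(normalize_protein_medians(make_pm(v2, design)),
                 class = "apexquant_validation_error")
  })
})
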