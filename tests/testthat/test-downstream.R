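test_that("DEG merging applies thresholds, cluster labels, and de-duplication", {
  tabs <- list(
    trap = tibble::tibble(gene = c("Drd1", "Pde1b", "Adora2a"),
                          log2fc = c(1.5, 0.5, -2.0),
                          adj_p = c(0.01, 0.01, 0.001)),
    sc = tibble::tibble(gene = c("Drd1", "Gpr6"),
                        log2fc = c(1.8, -1.4),
                        adj_p = c(0.02, 0.03)),
    clusters = tibble::tibble(gene = "Tac1", log2fc = NA_real_,
                              adj_p = NA_real_, cluster = "D1-MSN")
  )
  mapping <- tibble::tibble(gene = c("Drd1", "Adora2a", "Gpr6", "Tac1"),
                            accession = c("Q1", "Q2", "Q3", "Q4"))
  degs <- merge_transcript_degs(tabs, mapping = mapping)
  expect_setequal(degs$gene, c("Drd1", "Adora2a", "Gpr6", "Tac1"))
  expect_false("Pde1b" %in% degs$gene)         # fails |log2FC| > 1
  drd1 <- degs[degs$gene == "Drd1", ]
  expect_equal(drd1$sources, "sc;trap")        # one entry, both source tags
  expect_false(drd1$conflict)
  expect_equal(degs$accession[degs$gene == "Tac1"], "Q4")

  # conflicting directions across sources keep both records, flagged
  conflicted <- merge_transcript_degs(list(
    a = tibble::tibble(gene = "Gng7", log2fc = 1.5, adj_p = 0.01),
    b = tibble::tibble(gene = "Gng7", log2fc = -1.5, adj_p = 0.01)
  ))
  expect_equal(nrow(conflicted), 2)
  expect_true(all(conflicted$conflict))
})

test_that("proteogenomic correlation matches the covariance oracle", {
  fc <- function(acc, v) tibble::tibble(accession = acc, log2fc = v)
  acc <- paste0("P", 1:4)
  same <- proteogenomic_correlation(fc(acc, 1:4), fc(acc, 1:4))
  expect_equal(same$r, 1)
  neg <- proteogenomic_correlation(fc(acc, 1:4), fc(acc, -(1:4)))
  expect_equal(neg$r, -1)

  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  got <- proteogenomic_correlation(fc(acc, x), fc(acc, y))
  expect_equal(got$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(got$n, 4)
  expect_equal(got$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  expect_error(proteogenomic_correlation(fc(acc[1:2], 1:2), fc(acc[1:2], 1:2)),
               class = "apexquant_validation_error")
})

test_that("annotation enrichment uses the hypergeometric tail on the stated background", {
  sets <- tibble::tibble(
    term = c("T1", "T2"),
    description = c("in", "out"),
    members = list(paste0("P", 1:20), paste0("X", 1:5))
  )
  bg <- paste0("P", 1:100)
  fg <- c(paste0("P", 1:8), paste0("P", 50:51))

  res <- annotation_enrichment(fg, bg, sets)
  t1 <- res[res$term == "T1", ]
  expect_equal(t1$n_overlap, 8)
  expect_equal(t1$fold_enrichment, (8 / 10) / (20 / 100)) # fold = 4
  expect_equal(t1$p, oracle_hyper_tail(8, 20, 100, 10), tolerance = 1e-12)
  # disjoint term: fold 0, p 1
  t2 <- res[res$term == "T2", ]
  expect_equal(t2$n_overlap, 0)
  expect_equal(t2$p, 1)

  # foreground == background: every overlap is forced, p = 1, fold = 1
  all_res <- annotation_enrichment(bg, bg, sets[1, ])
  expect_equal(all_res$fold_enrichment, 1)
  expect_equal(all_res$p, 1)

  expect_error(annotation_enrichment(character(), bg, sets),
               class = "apexquant_validation_error")
  expect_error(annotation_enrichment("Z9", bg, sets),
               class = "apexquant_validation_error")
})

test_that("enrichment p-values are conservative-uniform under random foregrounds", {
  withr::with_seed(71, {
    bg <- paste0("P", 1:200)
    sets <- tibble::tibble(term = "T", description = "",
                           members = list(paste0("P", 1:40)))
    ps <- replicate(400, {
      annotation_enrichment(sample(bg, 30), bg, sets)$p
    })
    # discrete uniformity: P(p <= a) <= a at several cutpoints
    for (a in c(0.05, 0.1, 0.25, 0.5)) {
      expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 400))
    }
  })
})

test_that("GMT collections round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:1\tnuc\tP1\tP2\tP3", "GO:2\tmem\tP4"), path)
  gmt <- read_gmt(path)
  expect_equal(gmt$term, c("GO:1", "GO:2"))
  expect_equal(gmt$members[[1]], c("P1", "P2", "P3"))
})

test_that("leading log-fold-change MDS embeds samples faithfully", {
  design <- tiny_design()
  withr::with_seed(72, {
    v <- matrix(rnorm(600, 12), 100, 6,
                dimnames = list(paste0("P", 1:100), design$sample))
    v[, "X_2"] <- v[, "X_1"] # duplicated sample
    pm <- make_pm(v, design)
    expect_warning(mds <- qc_mds(pm, top_n = 500), "complete proteins")
    d <- attr(mds, "dist")
    expect_equal(d["X_1", "X_2"], 0)
    expect_equal(d, t(d))

    # permutation equivariance of the distances
    perm <- sample(ncol(v))
    pm_perm <- make_pm(v[, perm], as_tmt_design(design[perm, ]))
    d2 <- attr(suppressWarnings(qc_mds(pm_perm, top_n = 500)), "dist")
    expect_equal(d2[colnames(d), colnames(d)], d)
  })

  # three samples: a 2-D embedding reproduces the distances exactly
  d3 <- as_tmt_design(tiny_design()[1:3, ])
  withr::with_seed(73, {
    v3 <- matrix(rnorm(30, 10), 10, 3,
                 dimnames = list(paste0("Q", 1:10), d3$sample))
    mds3 <- suppressWarnings(qc_mds(make_pm(v3, d3), top_n = 10))
    emb <- as.matrix(mds3[, c("mds1", "mds2")])
    emb_d <- as.matrix(dist(emb))
    expect_equal(unname(emb_d), unname(attr(mds3, "dist")),
                 tolerance = 1e-9)
  })
  two_design <- as_tmt_design(tiny_design()[1:2, ])
  two_mat <- matrix(as.numeric(1:4), 2, 2,
                    dimnames = list(c("a", "b"), two_design$sample))
  expect_error(qc_mds(make_pm(two_mat, two_design)),
               class = "apexquant_validation_error")
})

test_that("%CV summaries follow the hand oracle", {
  design <- as_tmt_design(tibble::tibble(
    run = "r1", channel = as.character(1:5),
    sample = c("A_1", "A_2", "A_3", "B_1", "C_1"),
    condition = c("A", "A", "A", "B", "C"),
    replicate = c(1, 2, 3, 1, 1), is_reference = FALSE
  ))
  v <- matrix(c(10, 10, 10, 5, 5,
                9, 10, 11, 5, 5), 2, 5, byrow = TRUE,
              dimnames = list(c("FLAT", "VAR"), design$sample))
  pm <- make_pm(v, design)
  expect_warning(expect_warning(cv <- qc_cv(pm), "single replicate"),
                 "single replicate")
  expect_equal(cv$cv[cv$accession == "FLAT"], 0)
  expect_equal(cv$cv[cv$accession == "VAR"], 10.0) # sd 1, mean 10
  expect_false(any(cv$condition %in% c("B", "C")))
})

test_that("replicate correlation reflects the simulated signal-to-noise ratio", {
  withr::with_seed(74, {
    rs <- replicate(25, {
      base <- rnorm(2000, 14, 2)
      x <- base + rnorm(2000, 0, 0.25)
      y <- base + rnorm(2000, 0, 0.25)
      design <- as_tmt_design(tibble::tibble(
        run = "r1", channel = c("1", "2"), sample = c("A_1", "A_2"),
        condition = "A", replicate = 1:2, is_reference = FALSE
      ))
      v <- cbind(A_1 = x, A_2 = y)
      rownames(v) <- paste0("P", 1:2000)
      qcc <- qc_replicate_correlation(make_pm(v, design))
      attr(qcc, "matrix")["A_1", "A_2"]
    })
    expected <- 4 / (4 + 0.25^2) # variance-ratio oracle
    expect_lt(abs(mean(rs) - expected), 3 * sd(rs) / sqrt(25) + 1e-3)
    expect_gt(mean(rs), 0.9)
  })
})

test_that("stratified DE keeps strata as separate inference families", {
  withr::with_seed(75, {
    des <- design_twogroup(n_per_group = 6)
    sim <- simulate_experiment(
      sim_params(n_proteins = 300, seed = 75), des)
    pm <- normalize_reference(summarize_proteins(filter_psms(sim$psms), des))
    calls <- tibble::tibble(
      accession = pm$accession,
      compartment = rep(c("nucleus", "cytosol_nonH2B"),
                        length.out = nrow(pm)))
    de <- stratified_de(pm, calls = calls, contrast = c("A", "B"),
                        alpha_rule = "q")
    expect_setequal(unique(de$stratum), c("nucleus", "cytosol_nonH2B"))
    # q-values are computed within stratum: re-adjusting reproduces them
    for (st in unique(de$stratum)) {
      sub <- de[de$stratum == st, ]
      expect_equal(sub$q, bh_adjust(sub$p))
    }
    smry <- attr(de, "summary")
    expect_setequal(names(smry), c("stratum", "n_tested", "n_up", "n_down"))
    # all-null simulations: the q rule flags nothing in the large majority
    zero_flags <- vapply(1:8, function(i) {
      s <- simulate_experiment(sim_params(n_proteins = 300, seed = 750 + i),
                               des)
      m <- normalize_reference(summarize_proteins(filter_psms(s$psms), des))
      cl <- tibble::tibble(accession = m$accession, compartment = "all")
      d <- stratified_de(m, calls = cl, contrast = c("A", "B"),
                         alpha_rule = "q")
      sum(d$significant) == 0
    }, logical(1))
    expect_gte(mean(zero_flags), 0.75)
  })
})
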