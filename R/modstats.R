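#' Per-protein group-means fit
#'
#' Fits the standard per-protein cell-means model on log2 abundances:
#' condition means over observed values, and a pooled within-condition
#' residual variance with `sum(n_g - 1)` degrees of freedom (conditions with
#' fewer than two observations contribute none). Proteins observed in no
#' sample are skipped and counted.
#'
#' @param pm A normalized `protein_matrix`.
#' @param design The experiment design.
#' @param conditions Conditions to model; defaults to every non-reference
#'   condition in the design.
#' @return A `protein_fit` object: per-protein condition means and counts,
#'   pooled variance `s2`, residual df `df`, and PSM support.
#' @export
fit_proteins <- function(pm, design = pm_design(pm), conditions = NULL) {
  design <- as_tmt_design(design)
  if (is.null(conditions)) {
    conditions <- unique(design$condition[!design$is_reference])
  }
  values <- pm_values(pm)
  G <- length(conditions)
  P <- nrow(values)
  means <- n_obs <- matrix(NA_real_, P, G,
                           dimnames = list(rownames(values), conditions))
  ss <- matrix(0, P, G)
  for (g in seq_len(G)) {
    cols <- design$sample[design$condition == conditions[g] &
                            !design$is_reference]
    if (length(cols) == 0) {
      abort(sprintf("condition not in design: %s", conditions[g]),
            class = "apexquant_validation_error")
    }
    sub <- values[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[n == 0] <- NA_real_
    means[, g] <- m
    n_obs[, g] <- n
    ss[, g] <- rowSums((sub - m)^2, na.rm = TRUE)
  }
  df <- rowSums(pmax(n_obs - 1, 0))
  s2 <- ifelse(df > 0, rowSums(ss) / df, NA_real_)
  observed <- rowSums(n_obs) > 0
  if (any(!observed)) {
    inform(sprintf("%d protein(s) observed in no sample were skipped",
                   sum(!observed)))
  }
  support <- pm_psm_support(pm)
  n_features <- if (!is.null(support)) {
    sup <- support |> group_by(.data$accession) |>
      summarise(n = sum(.data$n_psms))
    setNames(sup$n, sup$accession)[rownames(values)]
  } else {
    setNames(rep(NA_integer_, P), rownames(values))
  }
  structure(
    list(accession = rownames(values)[observed],
         means = means[observed, , drop = FALSE],
         n_obs = n_obs[observed, , drop = FALSE],
         s2 = s2[observed], df = df[observed],
         conditions = conditions,
         n_features = n_features[observed]),
    class = "protein_fit"
  )
}

#' @export
tidy.protein_fit <- function(x, ...) {
  tibble::as_tibble(x$means, rownames = "accession") |>
    tidyr::pivot_longer(-"accession", names_to = "condition",
                        values_to = "mean_log2") |>
    left_join(
      tibble::as_tibble(x$n_obs, rownames = "accession") |>
        tidyr::pivot_longer(-"accession", names_to = "condition",
                            values_to = "n_obs"),
      by = c("accession", "condition")
    )
}

#' @export
glance.protein_fit <- function(x, ...) {
  tibble::tibble(n_proteins = length(x$accession),
                 n_conditions = length(x$conditions),
                 median_s2 = median(x$s2, na.rm = TRUE),
                 median_df = median(x$df))
}

# Newton inversion of the trigamma function (solves trigamma(x) = y, y > 0).
trigamma_inverse <- function(y) {
  stopifnot(all(y > 0))
  x <- ifelse(y > 1e7, 1 / sqrt(y), 0.5 + 1 / y)
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Empirical-Bayes prior on protein variances
#'
#' Method-of-moments fit of a scaled inverse-chi-squared prior to the
#' observed protein variances, working on `z = log(s2)`: the mean and spread
#' of `z`, corrected with digamma/trigamma terms for the sampling
#' distribution of a variance on `df` degrees of freedom, identify the prior
#' degrees of freedom `d0` and prior variance `s0_sq`. When the observed
#' spread does not exceed the chi-squared prediction the prior is degenerate
#' (`d0 = Inf`) and every variance shrinks fully to `s0_sq`.
#'
#' @param fit A `protein_fit`, or a data frame with columns `s2` and `df`.
#' @return An `eb_prior` list: `d0`, `s0_sq`, `n_used`.
#' @export
estimate_prior <- function(fit) {
  if (inherits(fit, "protein_fit")) {
    s2 <- fit$s2; df <- fit$df
  } else {
    check_required_columns(fit, c("s2", "df"), "variance table")
    s2 <- fit$s2; df <- fit$df
  }
  ok <- !is.na(s2) & s2 > 0 & df >= 1
  if (sum(ok) < 2) {
    abort(paste("fewer than 2 positive variances with df >= 1;",
                "run moderated_contrasts(moderate = FALSE) instead"),
          class = "apexquant_validation_error")
  }
  s2 <- s2[ok]; df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = n), class = "eb_prior")
}

#' @export
glance.eb_prior <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, n_used = x$n_used)
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf("<eb_prior> d0 = %s, s0_sq = %.6g (n = %d)\n",
              format(x$d0), x$s0_sq, x$n_used))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped
#' at 1, returned in input order (a thin, validated front for
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order and length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values",
          class = "apexquant_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Moderated t contrasts between conditions
#'
#' For each protein and contrast `A - B`, computes the difference of
#' condition means, a moderated standard error using the shrunken variance
#' `s~2 = (d0*s0_sq + df*s2) / (d0 + df)` (the limit `s0_sq` when `d0` is
#' infinite; proteins with no residual df shrink fully to the prior), the
#' moderated t statistic on `df + d0` degrees of freedom, a two-sided
#' p-value (normal reference when the df are infinite), and BH q-values.
#' By default the BH family is each named contrast across its tested
#' proteins.
#'
#' @param fit A `protein_fit`.
#' @param contrasts List of 2-vectors `c(A, B)` and/or strings `"A - B"`.
#' @param prior An `eb_prior`; estimated from `fit` when `NULL` and
#'   `moderate = TRUE`.
#' @param moderate If `FALSE`, the ordinary pooled two-sample t-test is used
#'   (no variance shrinkage); proteins without residual df are skipped.
#' @param adjust_by BH family: per `"contrast"` (default), `"global"` across
#'   all contrasts, or `"none"`.
#' @return A `tmt_contrasts` tibble: `accession`, `contrast`, `log2fc`,
#'   `se`, `df`, `t`, `p`, `q`, `n_features`.
#' @export
moderated_contrasts <- function(fit, contrasts, prior = NULL,
                                moderate = TRUE,
                                adjust_by = c("contrast", "global", "none")) {
  adjust_by <- match.arg(adjust_by)
  stopifnot(inherits(fit, "protein_fit"))
  if (moderate && is.null(prior)) prior <- estimate_prior(fit)
  d0 <- if (moderate) prior$d0 else 0
  s0 <- if (moderate) prior$s0_sq else 0

  contrasts <- lapply(contrasts, function(ct) {
    if (is.character(ct) && length(ct) == 1) {
      drop(parse_contrast_labels(ct))
    } else ct
  })
  rows <- purrr::map(contrasts, function(ct) {
    a <- ct[1]; b <- ct[2]
    if (!all(c(a, b) %in% fit$conditions)) {
      abort(sprintf("contrast %s involves conditions absent from the fit",
                    contrast_label(a, b)),
            class = "apexquant_validation_error")
    }
    na <- fit$n_obs[, a]; nb <- fit$n_obs[, b]
    keep <- na >= 1 & nb >= 1
    if (!moderate) keep <- keep & fit$df > 0
    lfc <- fit$means[keep, a] - fit$means[keep, b]
    df <- fit$df[keep]
    s2 <- fit$s2[keep]
    if (moderate) {
      s2t <- ifelse(is.infinite(d0), s0,
                    (d0 * s0 + ifelse(df > 0, df * s2, 0)) / (d0 + df))
    } else {
      s2t <- s2
    }
    df_tot <- df + d0
    se <- sqrt(s2t) * sqrt(1 / na[keep] + 1 / nb[keep])
    t <- lfc / se
    t[se == 0 & lfc == 0] <- 0
    p <- ifelse(is.infinite(df_tot), 2 * pnorm(-abs(t)),
                2 * pt(-abs(t), df = df_tot))
    tibble::tibble(
      accession = rownames(fit$means)[keep],
      contrast = contrast_label(a, b),
      log2fc = unname(lfc), se = unname(se), df = unname(df_tot),
      t = unname(t), p = unname(p),
      n_features = unname(fit$n_features[keep])
    )
  })
  out <- bind_rows(rows)
  out$q <- switch(adjust_by,
                  none = NA_real_,
                  global = bh_adjust(out$p),
                  contrast = {
                    q <- rep(NA_real_, nrow(out))
                    for (ct in unique(out$contrast)) {
                      i <- out$contrast == ct
                      q[i] <- bh_adjust(out$p[i])
                    }
                    q
                  })
  out <- out[, c("accession", "contrast", "log2fc", "se", "df", "t", "p",
                 "q", "n_features")]
  class(out) <- c("tmt_contrasts", class(tibble::tibble()))
  attr(out, "prior") <- if (moderate) prior else NULL
  out
}

#' Write a contrast table as TSV
#'
#' Stable columns `accession, contrast, log2FC, SE, df, t, p, q, n_features`.
#'
#' @param contrasts A `tmt_contrasts` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contrasts <- function(contrasts, path) {
  out <- contrasts |>
    rename(log2FC = "log2fc", SE = "se")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
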