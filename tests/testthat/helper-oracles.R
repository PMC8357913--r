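# Independently coded reference implementations used as oracles. These stay
# deliberately naive (direct transcriptions of the definitions) and are never
# called by package code.

# Iterative two-way median polish: row sweep, re-centre column effects,
# column sweep, re-centre row effects; midpoint medians; NA skipped. The
# stopping rule (largest applied shift < tol, capped sweeps) is part of the
# algorithm's definition and therefore shared with the implementation.
oracle_median_polish <- function(x, tol = 1e-9, max_iter = 200) {
  t_eff <- 0
  r_eff <- rep(0, nrow(x))
  c_eff <- rep(0, ncol(x))
  z <- x
  col_has <- colSums(!is.na(x)) > 0
  for (it in seq_len(max_iter)) {
    delta <- 0
    rm_ <- apply(z, 1, median, na.rm = TRUE)
    rm_[is.na(rm_)] <- 0
    z <- z - rm_
    r_eff <- r_eff + rm_
    delta <- max(delta, max(abs(rm_)))
    d <- median(c_eff[col_has])
    if (is.finite(d)) {
      c_eff[col_has] <- c_eff[col_has] - d
      t_eff <- t_eff + d
      delta <- max(delta, abs(d))
    }
    cm <- apply(z, 2, median, na.rm = TRUE)
    cm[is.na(cm)] <- 0
    z <- sweep(z, 2, cm)
    c_eff <- c_eff + cm
    delta <- max(delta, max(abs(cm)))
    d <- median(r_eff)
    r_eff <- r_eff - d
    t_eff <- t_eff + d
    delta <- max(delta, abs(d))
    if (delta < tol) break
  }
  fitted <- t_eff + c_eff
  fitted[!col_has] <- NA_real_
  fitted
}

# O(m^2) step-up definition: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  sp <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(sp[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  num / den
}

# Hypergeometric upper tail by exhaustive summation.
oracle_hyper_tail <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

strip_attrs <- function(x) {
  attributes(x) <- NULL
  x
}

# Pooled-variance two-sample t-test (no moderation).
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  se <- sqrt(s2 * (1 / na + 1 / nb))
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}
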