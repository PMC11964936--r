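# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: ranks are computed by pairwise comparison counting, the
# normal CDF by numeric integration, BH by stats::p.adjust.

# average-tie rank of x[i] within x (NAs excluded)
oracle_rank_one <- function(v, x) {
  sum(x < v, na.rm = TRUE) + (sum(x == v, na.rm = TRUE) + 1) / 2
}

# the full correlate -> rank (NA -> median) -> symmetrize -> standardize
# pipeline, written with explicit loops
oracle_network <- function(values) {
  n <- nrow(values)
  cc <- suppressWarnings(stats::cor(t(values)))
  rk <- matrix(NA_real_, n, n)
  for (i in 1:n) {
    row <- cc[i, setdiff(1:n, i)]
    r <- rep(NA_real_, n - 1)
    for (j in seq_along(row)) {
      if (!is.na(row[j])) r[j] <- oracle_rank_one(row[j], row)
    }
    if (any(is.na(r))) {
      defined <- sort(r[!is.na(r)])
      med <- if (length(defined) == 0) n / 2 else {
        k <- length(defined)
        if (k %% 2 == 1) defined[(k + 1) / 2] else
          (defined[k / 2] + defined[k / 2 + 1]) / 2
      }
      r[is.na(r)] <- med
    }
    rk[i, setdiff(1:n, i)] <- r
  }
  s <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j) s[i, j] <- (rk[i, j] + rk[j, i]) / 2
  }
  s / max(s, na.rm = TRUE)
}

# standard-normal upper tail by numeric integration of the density
oracle_norm_p_two_sided <- function(z) {
  upper <- stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                            abs(z), Inf, rel.tol = 1e-12)$value
  2 * upper
}

oracle_bh <- function(p) stats::p.adjust(p, method = "BH")

# direct restatement of the four classification rules as quoted thresholds
oracle_classify <- function(coexpr, m, s) {
  if (coexpr > 0.9 && m < 1 && s < 1) return("I")
  if (coexpr > 0.9 && m >= 1 && s < 1) return("II")
  if (coexpr > 0.9 && m >= 1 && s >= 1) return("III")
  if (coexpr < 0.5 && m >= 1 && s >= 1) return("IV")
  "none"
}
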