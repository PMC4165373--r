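#' Pseudocounts for the expression-ratio test
#'
#' For a pair of clusters (a, b) the test works on per-condition aggregate
#' counts
#' \deqn{X_{ai} = 1 + \sum_j (r_{aij} + 0.5\, r_{abij})}
#' where `r_aij` counts fragments mapping to `a` but *not* shared with `b`
#' (replicate j of condition i) and `r_abij` the fragments shared by both.
#' Each shared fragment thus contributes one half to either side, avoiding
#' double counting, and the +1 offset keeps every X strictly positive.
#'
#' @param r_a,r_b numeric vectors, per-replicate fragment counts unique to
#'   cluster a (resp. b), one entry per sample.
#' @param r_ab numeric vector, per-replicate shared fragment counts.
#' @param condition character/factor vector of condition labels, parallel to
#'   the count vectors.
#' @return list of class `pair_counts` with per-condition vectors `X_a`,
#'   `X_b` (ordered by sorted condition label) and `n_conditions`.
#' @seealso [condition_counts()] returns *inclusive* per-sample counts; use
#'   [pair_counts_from_store()] to go from a store to `pair_counts` directly.
#' @export
pseudocounts <- function(r_a, r_b, r_ab, condition) {
  if (any(r_a < 0) || any(r_b < 0) || any(r_ab < 0))
    stop("negative fragment counts")
  stopifnot(length(r_a) == length(condition),
            length(r_b) == length(condition),
            length(r_ab) == length(condition))
  condition <- as.character(condition)
  lev <- csort(unique(condition))
  X_a <- 1 + vapply(lev, function(l) sum(r_a[condition == l] + 0.5 * r_ab[condition == l]),
                    numeric(1L))
  X_b <- 1 + vapply(lev, function(l) sum(r_b[condition == l] + 0.5 * r_ab[condition == l]),
                    numeric(1L))
  structure(list(X_a = X_a, X_b = X_b, n_conditions = length(lev)),
            class = "pair_counts")
}

#' Pair counts for two clusters straight from the store
#'
#' Convenience wrapper: pulls inclusive per-sample counts via
#' [condition_counts()], converts them to exclusive counts (`r_a - r_ab`) and
#' applies [pseudocounts()].
#'
#' @inheritParams condition_counts
#' @return a `pair_counts` object.
#' @export
pair_counts_from_store <- function(store, a, b, design) {
  cc <- condition_counts(store, a, b, design)
  pseudocounts(cc$r_a - cc$r_ab, cc$r_b - cc$r_ab, cc$r_ab, cc$condition)
}

#' Poisson likelihood-ratio statistic for a constant expression ratio
#'
#' Models the per-condition counts as `X_ai ~ Pois(f_i * mu_bi)`,
#' `X_bi ~ Pois(mu_bi)` and tests H0: `f_i = f` (the ratio of expression
#' between the two clusters is the same in every condition) against H1 with a
#' free `f_i` per condition.  The statistic is `D = -2 (ln l0 - ln l1)`,
#' asymptotically chi-square on `n_conditions - 1` degrees of freedom.
#'
#' Both maxima are available in closed form.  Under H1 the fitted means equal
#' the observations.  Under H0, with `f^ = sum(X_a) / sum(X_b)` and
#' `T_i = X_ai + X_bi`, the fitted means are `E_bi = T_i / (1 + f^)` and
#' `E_ai = f^ E_bi`, giving
#' \deqn{D = 2 \sum_i [ X_{ai} \log(X_{ai}/E_{ai}) + X_{bi} \log(X_{bi}/E_{bi}) ].}
#' `D` is symmetric in (a, b).  With a single condition there is no contrast:
#' `df = 0`, `D = 0` and the test never rejects.
#'
#' @param pc a `pair_counts` object (all X >= 1 by construction).
#' @param threshold rejection threshold on D, e.g. from [d_threshold()].
#' @return list of class `ratio_test_result` with fields `D`, `df`,
#'   `threshold`, `reject`.
#' @export
lrt_statistic <- function(pc, threshold = d_threshold(pc$n_conditions)) {
  stopifnot(inherits(pc, "pair_counts"))
  X_a <- pc$X_a; X_b <- pc$X_b
  if (any(X_a <= 0) || any(X_b <= 0)) stop("pair counts must be positive")
  n <- pc$n_conditions
  if (n == 1L) {
    D <- 0
  } else {
    f_hat <- sum(X_a) / sum(X_b)
    E_b <- (X_a + X_b) / (1 + f_hat)
    E_a <- f_hat * E_b
    D <- 2 * sum(X_a * log(X_a / E_a) + X_b * log(X_b / E_b))
    D <- max(D, 0)  # guard tiny negative round-off
  }
  df <- n - 1L
  structure(list(D = D, df = df, threshold = threshold,
                 reject = (df >= 1L && D > threshold)),
            class = "ratio_test_result")
}

#' Rejection threshold on the likelihood-ratio statistic
#'
#' At the default P-value of 1e-5 and fewer than 10 conditions the threshold
#' uses the linear parameterisation `15 + 2.5 * n_conditions`, a cheap
#' approximation of the chi-square upper quantile that is adequate in that
#' range.  For 10 or more conditions, or any non-default P-value, the exact
#' chi-square upper quantile on `n_conditions - 1` degrees of freedom is
#' returned.  With one condition the test has no degrees of freedom and the
#' threshold is `Inf` (never reject).
#'
#' @param n_conditions number of condition groups (>= 1).
#' @param p_value tail probability in (0, 1); default 1e-5, chosen for the
#'   heavy multiple testing across all contig pairs of a transcriptome.
#' @return a single numeric threshold.
#' @export
d_threshold <- function(n_conditions, p_value = 1e-5) {
  stopifnot(n_conditions >= 1)
  if (p_value <= 0 || p_value >= 1) stop("p_value must be in (0, 1)")
  if (n_conditions == 1) return(Inf)
  default_p <- isTRUE(all.equal(p_value, 1e-5))
  if (default_p && n_conditions < 10)
    return(15 + 2.5 * n_conditions)
  stats::qchisq(p_value, df = n_conditions - 1, lower.tail = FALSE)
}

#' @export
print.ratio_test_result <- function(x, ...) {
  cat(sprintf("ratio test: D = %.4g on %d df (threshold %.4g) -> %s\n",
              x$D, x$df, x$threshold, if (x$reject) "reject" else "accept"))
  invisible(x)
}
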