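#' Spearman rank correlation with exact permutation p-value
#'
#' Computes Spearman's rho with average-rank tie handling. The two-sided
#' p-value is, by default, the exact permutation p for small samples
#' (`n <= exact_max`, full enumeration of all `n!` orderings of one vector)
#' and the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom otherwise. A Monte-Carlo permutation mode draws
#' `n_mc` random permutations and applies the add-one estimator.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param method `"auto"` (exact for small n, else approximation),
#'   `"exact"`, `"approx"`, or `"mc"`.
#' @param exact_max largest n for which `"auto"` enumerates (default 9).
#' @param n_mc Monte-Carlo permutation count.
#' @return List with `estimate` (rho), `p.value`, `method` and `n`.
#' @export
spearman_test <- function(x, y, method = c("auto", "exact", "approx", "mc"),
                          exact_max = 9, n_mc = 1e5) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("Spearman correlation needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho is undefined when a vector has zero variance")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "auto") method <- if (n <= exact_max) "exact" else "approx"
  p <- switch(method,
    exact = {
      perms <- perm_matrix(n)
      rho_all <- perm_rho(rx, ry, perms)
      mean(abs(rho_all) >= abs(rho) - 1e-12)
    },
    approx = {
      t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
      2 * stats::pt(-abs(t_stat), df = n - 2)
    },
    mc = {
      hits <- 0L
      for (b in seq_len(n_mc)) {
        r <- stats::cor(rx, ry[sample.int(n)])
        if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (n_mc + 1)
    })
  list(estimate = rho, p.value = min(1, p), method = method, n = n)
}

# all permutations of 1..n as an (n! x n) integer matrix, by insertion
perm_matrix <- function(n) {
  p <- matrix(1L, 1L, 1L)
  if (n == 1L) return(p)
  for (k in 2:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * m + 1L):(j * m)
      if (j > 1L) out[rows, seq_len(j - 1L)] <- p[, seq_len(j - 1L), drop = FALSE]
      out[rows, j] <- k
      if (j < k) out[rows, (j + 1L):k] <- p[, j:(k - 1L), drop = FALSE]
    }
    p <- out
  }
  p
}

perm_rho <- function(rx, ry, perms) {
  n <- length(rx)
  ry_p <- matrix(ry[perms], nrow(perms), n)
  num <- ry_p %*% rx - n * mean(rx) * mean(ry)
  as.numeric(num) / ((n - 1) * stats::sd(rx) * stats::sd(ry))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (the classic Wilcoxon convention, not Pratt). The null
#' distribution is exact (via the signed-rank distribution) when the
#' effective n is at most `exact_max` and the absolute differences are
#' untied; otherwise a normal approximation with continuity and tie
#' correction is used. When every difference is zero the test is degenerate
#' and reported as such with `p = 1`.
#'
#' @param x,y numeric vectors of equal length (site-1 and site-2 values).
#' @param exact_max largest effective n for the exact null distribution.
#' @return List with `statistic` (the smaller of the positive/negative rank
#'   sums), `w_plus`, `w_minus`, `p.value`, `n_effective`, `method` and
#'   `degenerate`.
#' @export
wilcoxon_paired <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, w_plus = 0, w_minus = 0, p.value = 1,
                n_effective = 0L, method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= exact_max && !ties) {
    v <- w_plus
    p <- if (v > n * (n + 1) / 4)
      2 * stats::psignrank(v - 1, n, lower.tail = FALSE)
    else
      2 * stats::psignrank(v, n)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = min(w_plus, w_minus), w_plus = w_plus, w_minus = w_minus,
       p.value = min(1, p), n_effective = n, method = method,
       degenerate = FALSE)
}
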