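# Spearman rank correlation with a two-sided test.
#
# rho is Pearson's product-moment correlation computed on average ranks
# (ties share their mean rank).  The two-sided p-value uses the
# t-distribution approximation with n - 2 degrees of freedom for n >= 10;
# below that the approximation degrades, so an exact permutation p-value is
# computed instead by enumerating all n! permutations of one rank vector.

perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  p <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- all_permutations(n - 1L)
    m <- nrow(sub)
    out <- matrix(0L, m * n, n)
    for (i in seq_len(n)) {
      rows <- ((i - 1L) * m + 1L):(i * m)
      out[rows, i] <- n
      out[rows, -i] <- sub
    }
    out
  }
  if (n <= 9L) perm_cache[[key]] <- p
  p
}

#' Two-sided Spearman rank correlation test
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, neither constant.
#' @param exact_max_n largest n for which the exact permutation p-value is
#'   used (default 9; above this the t approximation with `n - 2` degrees of
#'   freedom is applied, as in standard statistical routines).
#' @return list with elements `rho`, `p_value`, `n`, `method`.
#' @examples
#' spearman_two_sided(1:4, c(10, 20, 30, 40))$rho   # 1
#' spearman_two_sided(1:4, c(40, 30, 20, 10))$rho   # -1
#' @export
spearman_two_sided <- function(x, y, exact_max_n = 9L) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop_config("x and y must not contain NA")
  n <- length(x)
  if (n < 3) stop_config("need at least 3 paired observations, got ", n)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_config("correlation undefined: at least one variable is constant")
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    p <- spearman_exact_p(rx, ry, rho)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  P <- all_permutations(n)
  # rho is affine in the cross-sum of ranks, so enumerate cross-sums only
  cross <- as.vector(matrix(ry[P], nrow(P), n) %*% rx)
  rho_all <- (cross - n * mean(rx) * mean(ry)) /
    ((n - 1) * stats::sd(rx) * stats::sd(ry))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}
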