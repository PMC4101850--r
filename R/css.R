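#' Fractional ranks
#'
#' Ascending ranks (ties share the average rank) rescaled to lie strictly
#' inside (0, 1): `rank(x) / (n + 1)`, giving values from `1/(n+1)` through
#' `n/(n+1)`.  Larger statistic values must already mean stronger evidence
#' of selection in the SELECTED group; missing values must be resolved
#' before ranking (see [compose_css()]).
#'
#' @param x numeric vector, length at least 2, no missing values.
#' @return numeric vector in `(0, 1)`.
#' @export
fractional_ranks <- function(x) {
  if (anyNA(x)) stop("missing values must be resolved before ranking")
  n <- length(x)
  if (n < 2L) stop("need at least 2 values to rank")
  rank(x, ties.method = "average") / (n + 1)
}

#' Normal scores from fractional ranks
#'
#' Elementwise standard-normal quantile of values strictly inside (0, 1).
#'
#' @param fracs numeric vector in (0, 1).
#' @return numeric vector of z-scores.
#' @export
z_scores <- function(fracs) {
  if (any(!is.finite(fracs)) || any(fracs <= 0 | fracs >= 1)) {
    stop("fractional ranks must lie strictly in (0, 1)")
  }
  qnorm(fracs)
}

#' Composite p-values from a matrix of normal scores
#'
#' With m constituent tests, the per-SNP mean score \eqn{\bar Z_j} has null
#' distribution \eqn{N(0, 1/m)}; the composite upper-tail p-value is
#' \eqn{p_j = 1 - \Phi(\sqrt{m}\,\bar Z_j)} and the composite selection
#' signal is \eqn{-\log_{10} p_j}.
#'
#' @param z matrix of normal scores, one row per SNP, one column per test.
#' @return list with vectors `zbar`, `p` and `css`.
#' @export
composite_p <- function(z) {
  z <- as.matrix(z)
  m <- ncol(z)
  if (m < 1L) stop("need at least one test")
  zbar <- rowMeans(z)
  p <- pnorm(sqrt(m) * zbar, lower.tail = FALSE)
  list(zbar = zbar, p = p, css = -log10(p))
}

#' Compose constituent statistics into the composite selection signal
#'
#' For each test column: fractional ranks (ascending, average ties), then
#' standard-normal quantiles; missing constituent scores (e.g. undefined
#' XP-EHH log-ratios) are assigned the median fractional rank 0.5 so the
#' SNP count stays identical across tests.  The per-SNP mean z and
#' upper-tail composite p follow as in [composite_p()].  Being rank-based,
#' the result is invariant to any strictly monotone transform of any
#' constituent statistic.
#'
#' @param stats numeric matrix or data frame, one row per SNP and one
#'   column per constituent test, oriented so that large values indicate
#'   selection in the SELECTED group.
#' @return list with matrices `fracs` and `z` (n x m) plus vectors `zbar`,
#'   `p`, `css`.
#' @export
compose_css <- function(stats) {
  stats <- as.matrix(stats)
  if (nrow(stats) < 2L) stop("need at least 2 SNPs")
  if (ncol(stats) < 1L) stop("need at least one constituent test")
  fr <- apply(stats, 2L, function(x) {
    na <- !is.finite(x)
    if (all(na)) stop("a constituent test has no finite values")
    f <- rep(0.5, length(x))
    f[!na] <- fractional_ranks(x[!na])
    f
  })
  z <- z_scores(fr)
  dim(z) <- dim(fr)
  colnames(z) <- colnames(fr) <- colnames(stats)
  c(list(fracs = fr, z = z), composite_p(z))
}
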