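#' Recalibrate empirical p-values
#'
#' Projects the empirical distribution of the p-values onto the class of
#' ideal empirical p-value distributions -- CDFs that are non-decreasing,
#' concave and anchored at (0,0) and (1,1), so that the null portion is
#' uniform while any excess of small p-values (signal) is preserved -- and
#' transports each p-value to that projected CDF.  Concretely, the least
#' concave majorant M of the empirical CDF (anchored at the endpoints) is
#' computed, and the i-th smallest p-value is mapped to
#' \eqn{M^{-1}(i/(n+1))}.  Already-ideal inputs (uniform, or a valid
#' signal-plus-uniform mixture) pass through essentially unchanged;
#' conservative (super-uniform) inputs are pulled back to uniformity.  The
#' map is order-preserving: calibrated ranks equal raw ranks, tied inputs
#' stay tied.
#'
#' @param p vector of p-values strictly inside (0, 1).
#' @return calibrated p-values in (0, 1]; with fewer than 100 values the
#'   calibration is skipped (identity, with a warning).
#' @export
calibrate_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0 | p >= 1)) {
    stop("p-values must lie strictly in (0, 1)")
  }
  n <- length(p)
  if (n < 100L) {
    warning("fewer than 100 p-values; calibration skipped")
    return(p)
  }
  o <- order(p)
  ps <- p[o]
  yy <- seq_len(n) / (n + 1)
  # one point per distinct p (max ecdf value), plus the anchors
  last <- c(ps[-1L] != ps[-n], TRUE)
  px <- c(0, ps[last], 1)
  py <- c(0, yy[last], 1)
  hull <- upper_hull(px, py)
  cal_sorted <- approx(hull$y, hull$x, xout = yy, rule = 2, ties = "ordered")$y
  # tied raw p-values must share one calibrated value
  if (!all(last)) cal_sorted <- stats::ave(cal_sorted, match(ps, ps), FUN = mean)
  out <- numeric(n)
  out[o] <- cal_sorted
  pmin(pmax(out, .Machine$double.xmin), 1)
}

# Upper convex hull (least concave majorant) of points sorted by x.
upper_hull <- function(x, y) {
  n <- length(x)
  hx <- numeric(n)
  hy <- numeric(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      cross <- (hx[k] - hx[k - 1L]) * (y[i] - hy[k - 1L]) -
        (hy[k] - hy[k - 1L]) * (x[i] - hx[k - 1L])
      if (cross < 0) break   # clockwise turn: keep for upper hull
      k <- k - 1L
    }
    k <- k + 1L
    hx[k] <- x[i]
    hy[k] <- y[i]
  }
  list(x = hx[seq_len(k)], y = hy[seq_len(k)])
}

#' Tail-area false discovery rates (q-values)
#'
#' Estimates the null proportion `eta0` from the p-values above their 75th
#' percentile -- the ratio of the observed to the expected uniform mass on
#' that range -- and attaches the tail-area q-value
#' \eqn{q(p_j) = \min_{p_{(k)} \ge p_j} \; \eta_0 \, n \, p_{(k)} / k}
#' (step-up enforcement of monotonicity, clipped to (0, 1]).  With
#' `eta0 = 1` this reduces exactly to Benjamini--Hochberg adjusted
#' p-values.  With fewer than 20 values the `eta0` estimate is unreliable
#' and is fixed at the conservative value 1.
#'
#' @param p calibrated p-values in (0, 1].
#' @param eta0 optional null-proportion override in (0, 1].
#' @return object of class `fdr_result`: list with `calibrated_p`,
#'   `q_value` and `eta0`.
#' @export
q_values <- function(p, eta0 = NULL) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  n <- length(p)
  if (is.null(eta0)) {
    if (n < 20L) {
      eta0 <- 1
    } else {
      t75 <- quantile(p, 0.75, names = FALSE)
      eta0 <- if (t75 >= 1) 1 else sum(p > t75) / ((1 - t75) * n)
      eta0 <- min(1, max(eta0, 1 / n))
    }
  }
  if (eta0 <= 0 || eta0 > 1) stop("eta0 must lie in (0, 1]")
  o <- order(p)
  q <- eta0 * n * p[o] / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  structure(list(calibrated_p = p, q_value = out, eta0 = eta0),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("fdr_result: %d p-values, eta0 = %.3f, %d with q <= 0.05\n",
              length(x$q_value), x$eta0, sum(x$q_value <= 0.05)))
  invisible(x)
}

#' Summarize FDR inside and outside called regions
#'
#' For each region: the total number of SNPs inside its boundaries and the
#' count and percentage with q-value at or below `alpha`; a final
#' `outside_regions` row gives the same figures for all SNPs not covered
#' by any region.
#'
#' @param q per-SNP q-values aligned to `map` (vector or `fdr_result`).
#' @param regions region data frame from [call_clusters()].
#' @param map validated SNP map.
#' @param alpha FDR threshold (default 0.05).
#' @return data frame with columns `region_id`, `chrom`, `region_start_bp`,
#'   `region_end_bp`, `n_snps`, `n_q_le_alpha`, `pct_q_le_alpha`.
#' @export
region_fdr_summary <- function(q, regions, map, alpha = 0.05) {
  if (inherits(q, "fdr_result")) q <- q$q_value
  if (length(q) != nrow(map)) stop("q-values and map disagree on SNP count")
  covered <- rep(FALSE, nrow(map))
  rows <- lapply(seq_len(nrow(regions)), function(r) {
    inside <- as.character(map$chrom) == regions$chrom[r] &
      map$pos_bp >= regions$region_start_bp[r] &
      map$pos_bp <= regions$region_end_bp[r]
    covered[inside] <<- TRUE
    n <- sum(inside)
    ns <- sum(q[inside] <= alpha)
    data.frame(region_id = regions$core_snp_id[r], chrom = regions$chrom[r],
               region_start_bp = regions$region_start_bp[r],
               region_end_bp = regions$region_end_bp[r],
               n_snps = n, n_q_le_alpha = ns,
               pct_q_le_alpha = if (n > 0) 100 * ns / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  n_out <- sum(!covered)
  out_row <- data.frame(region_id = "outside_regions", chrom = NA_character_,
                        region_start_bp = NA_integer_, region_end_bp = NA_integer_,
                        n_snps = n_out, n_q_le_alpha = sum(q[!covered] <= alpha),
                        pct_q_le_alpha = if (n_out > 0)
                          100 * sum(q[!covered] <= alpha) / n_out else NA_real_,
                        stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(out_row)))
}
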