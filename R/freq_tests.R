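#' Per-group ALT allele frequencies
#'
#' @param panel [hap_panel()].
#' @param groups group assignment data frame.
#' @return list with `f_sel`, `f_ref` (ALT-allele frequency per SNP in each
#'   group) and the haplotype counts `n_hap_sel`, `n_hap_ref`.
#' @export
group_freqs <- function(panel, groups) {
  groups <- group_assignment(groups$sample_id, groups$group)
  rs <- hap_rows(panel, groups$sample_id[groups$group == "SELECTED"])
  rr <- hap_rows(panel, groups$sample_id[groups$group == "REFERENCE"])
  if (length(rs) < 2L || length(rr) < 2L) stop("each group needs at least one sample")
  list(f_sel = colMeans(panel$alleles[rs, , drop = FALSE]),
       f_ref = colMeans(panel$alleles[rr, , drop = FALSE]),
       n_hap_sel = length(rs), n_hap_ref = length(rr))
}

#' SNP-wise fixation index between two groups
#'
#' The default estimator is the unweighted two-population Wright/Nei form:
#' with \eqn{\bar p = (f_1 + f_2)/2}, total heterozygosity
#' \eqn{H_T = 2 \bar p (1 - \bar p)}, mean within-group heterozygosity
#' \eqn{H_S = [2 f_1 (1 - f_1) + 2 f_2 (1 - f_2)]/2}, and
#' \eqn{F_{ST} = (H_T - H_S)/H_T}, set to 0 where \eqn{H_T = 0} (jointly
#' monomorphic for the same allele).  Unweighted \eqn{\bar p} keeps the
#' statistic a pure frequency contrast when group sizes are very unbalanced.
#' `estimator = "wc"` gives the sample-size-weighted Weir--Cockerham
#' estimator (may be negative), for which the haplotype counts are required.
#'
#' @param f_sel,f_ref ALT allele frequency vectors for the two groups.
#' @param estimator `"nei"` (default) or `"wc"`.
#' @param n_sel,n_ref haplotype counts per group (only for `"wc"`).
#' @return numeric vector; in `[0, 1]` for the default estimator.
#' @export
fst_per_snp <- function(f_sel, f_ref, estimator = c("nei", "wc"),
                        n_sel = NULL, n_ref = NULL) {
  estimator <- match.arg(estimator)
  if (estimator == "nei") {
    pbar <- (f_sel + f_ref) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * f_sel * (1 - f_sel) + 2 * f_ref * (1 - f_ref)) / 2
    ifelse(ht == 0, 0, (ht - hs) / ht)
  } else {
    if (is.null(n_sel) || is.null(n_ref)) stop("Weir-Cockerham needs haplotype counts")
    n1 <- n_sel; n2 <- n_ref; nt <- n1 + n2
    pw <- (n1 * f_sel + n2 * f_ref) / nt
    msp <- n1 * (f_sel - pw)^2 + n2 * (f_ref - pw)^2          # r - 1 = 1
    msg <- (n1 * f_sel * (1 - f_sel) + n2 * f_ref * (1 - f_ref)) / (nt - 2)
    nc <- nt - (n1^2 + n2^2) / nt
    den <- msp + (nc - 1) * msg
    ifelse(den == 0, 0, (msp - msg) / den)
  }
}

#' Change in derived allele frequency between groups
#'
#' The derived allele is the non-ancestral one: its frequency is
#' `f_alt` where the ancestral allele is REF and `1 - f_alt` where it is
#' ALT.  Returns derived frequency in the selected group minus derived
#' frequency in the reference group; positive values indicate an excess of
#' the derived allele in the selected group.  SNPs with unknown ancestral
#' state yield `NA` (callers fall back to [delta_saf()]); if the ancestral
#' state is unknown everywhere, an error is raised.
#'
#' @param f_sel,f_ref ALT allele frequencies per group.
#' @param ancestral character vector, `"REF"`, `"ALT"` or `NA` per SNP.
#' @return numeric vector in `[-1, 1]` with `NA` where ancestral is unknown.
#' @export
delta_daf <- function(f_sel, f_ref, ancestral) {
  if (all(is.na(ancestral))) stop("ancestral unknown")
  d_s <- ifelse(ancestral == "REF", f_sel, 1 - f_sel)
  d_ns <- ifelse(ancestral == "REF", f_ref, 1 - f_ref)
  out <- d_s - d_ns
  out[is.na(ancestral)] <- NA_real_
  out
}

#' Change in selected-group major allele frequency
#'
#' Ancestral-allele-free surrogate for [delta_daf()]: let A be the major
#' allele of the SELECTED group (frequency >= 0.5; the tie at exactly 0.5
#' resolves to ALT).  Returns `f_A(selected) - f_A(reference)`.
#'
#' @param f_sel,f_ref ALT allele frequencies per group.
#' @return numeric vector in `[-1, 1]`.
#' @export
delta_saf <- function(f_sel, f_ref) {
  alt_major <- f_sel >= 0.5
  ifelse(alt_major, f_sel - f_ref, (1 - f_sel) - (1 - f_ref))
}

#' Derived-allele contrast with per-SNP fallback
#'
#' Uses [delta_daf()] where the ancestral allele is annotated and
#' [delta_saf()] elsewhere, so a partially annotated map still yields one
#' statistic per SNP.
#'
#' @inheritParams delta_daf
#' @return numeric vector; attribute `"stat_used"` records `"daf"`/`"saf"`
#'   per SNP.
#' @export
daf_or_saf <- function(f_sel, f_ref, ancestral) {
  known <- !is.na(ancestral)
  out <- delta_saf(f_sel, f_ref)
  if (any(known)) {
    out[known] <- delta_daf(f_sel[known], f_ref[known], ancestral[known])
  }
  attr(out, "stat_used") <- ifelse(known, "daf", "saf")
  out
}

#' Standardize scores to zero mean and unit variance
#'
#' Centers and scales by the population-style standard deviation
#' (denominator n) of the finite entries of the genome-wide vector; `NA`
#' entries pass through unchanged.  Idempotent up to floating point.
#'
#' @param x numeric vector with at least two finite values.
#' @return standardized vector of the same length.
#' @export
standardize_scores <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("need at least 2 finite values to standardize")
  m <- mean(x[ok])
  s <- sqrt(mean((x[ok] - m)^2))
  if (s == 0) stop("zero variance input")
  (x - m) / s
}
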