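#' Extended haplotype homozygosity over an interval
#'
#' Probability that two haplotypes drawn at random without replacement from
#' `haps` carry identical alleles over the whole closed SNP interval between
#' `core_index` and `boundary_index`.  With class sizes \eqn{k_c} of the
#' partition of the K haplotypes by their allele string, this is
#' \eqn{\sum_c \binom{k_c}{2} / \binom{K}{2}}.
#'
#' @param haps 0/1 matrix, one row per haplotype, one column per SNP of a
#'   single chromosome; at least two rows.
#' @param core_index,boundary_index column indices delimiting the interval
#'   (inclusive, either order).
#' @return number in `[0, 1]`.
#' @export
ehh_at <- function(haps, core_index, boundary_index) {
  haps <- as.matrix(haps)
  K <- nrow(haps)
  if (K < 2L) stop("EHH is undefined for fewer than 2 haplotypes")
  idx <- seq(min(core_index, boundary_index), max(core_index, boundary_index))
  id <- apply(haps[, idx, drop = FALSE], 1L, paste, collapse = "")
  k <- tabulate(match(id, unique(id)))
  sum(k * (k - 1)) / (K * (K - 1))
}

# One-sided EHH decay curve from a core SNP.  Offset 0 carries EHH = 1 by
# definition (degenerate interval); each further point is ehh_at() over the
# closed interval from the core to that SNP.  Extension stops after the
# first point with EHH < truncation, past max_extension_bp, or at the
# chromosome end.  Returns a two-column matrix (offset_bp, ehh).
ehh_side <- function(haps, core_index, pos, side, truncation, max_extension_bp) {
  K <- nrow(haps)
  offs <- 0
  ehhs <- 1
  id <- as.character(haps[, core_index])
  b <- core_index + side
  while (b >= 1L && b <= length(pos)) {
    off <- abs(pos[b] - pos[core_index])
    if (off > max_extension_bp) break
    id <- paste0(id, haps[, b])
    k <- tabulate(match(id, unique(id)))
    e <- sum(k * (k - 1)) / (K * (K - 1))
    offs <- c(offs, off)
    ehhs <- c(ehhs, e)
    if (e < truncation) break
    b <- b + side
  }
  cbind(offset_bp = offs, ehh = ehhs)
}

#' EHH decay curve around a core SNP
#'
#' @inheritParams ehh_at
#' @param pos physical positions (bp) of the SNP columns of `haps`.
#' @param truncation stop a side after the first point with EHH below this
#'   value (default 0.05).
#' @param max_extension_bp maximum extension per side in bp (default 1 Mb).
#' @return data frame with columns `side` (-1 left, +1 right), `offset_bp`
#'   and `ehh`; each side starts at (0, 1).
#' @export
ehh_decay <- function(haps, core_index, pos, truncation = 0.05,
                      max_extension_bp = 1e6) {
  haps <- as.matrix(haps)
  if (nrow(haps) < 2L) stop("EHH is undefined for fewer than 2 haplotypes")
  left <- ehh_side(haps, core_index, pos, -1L, truncation, max_extension_bp)
  right <- ehh_side(haps, core_index, pos, +1L, truncation, max_extension_bp)
  data.frame(side = rep(c(-1L, 1L), c(nrow(left), nrow(right))),
             offset_bp = c(left[, 1], right[, 1]),
             ehh = c(left[, 2], right[, 2]))
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))
}

#' Integrated EHH around a core SNP
#'
#' Trapezoid-rule integral of the EHH decay against physical distance, over
#' both sides of the core; EHH is taken as 0 beyond the stopping point of
#' each side (see [ehh_decay()]).  Units: bp (probability-weighted length).
#'
#' @inheritParams ehh_decay
#' @return non-negative number; 0 when fewer than 2 haplotypes are supplied.
#' @export
integrated_ehh <- function(haps, core_index, pos, truncation = 0.05,
                           max_extension_bp = 1e6) {
  haps <- as.matrix(haps)
  if (nrow(haps) < 2L) return(0)
  left <- ehh_side(haps, core_index, pos, -1L, truncation, max_extension_bp)
  right <- ehh_side(haps, core_index, pos, +1L, truncation, max_extension_bp)
  trapezoid(left[, 1], left[, 2]) + trapezoid(right[, 1], right[, 2])
}

# chromosome block id (1, 2, ...) per SNP of a validated map
chrom_block_id <- function(map) {
  runs <- rle(as.character(map$chrom))
  rep(seq_along(runs$lengths), runs$lengths)
}

#' Cross-population EHH log-ratio at one core SNP (reference path)
#'
#' Computes `ln(I_sel / I_ref)` where `I_sel` and `I_ref` are the
#' integrated EHH of the SELECTED and REFERENCE haplotypes over identical
#' integration boundaries: the extension extent is determined once on the
#' pooled panel (truncation and maximum extension applied to the pooled
#' EHH), then both groups are integrated over exactly those SNPs.  Positive
#' values indicate longer haplotype homozygosity in the selected group.
#'
#' This is the plain-R reference implementation used for validation;
#' [xpehh_scan()] computes the same quantity for all SNPs at once in
#' compiled code.
#'
#' @param panel [hap_panel()].
#' @param groups group assignment data frame.
#' @param map validated SNP map.
#' @param core_index SNP index into `map`.
#' @inheritParams ehh_decay
#' @return raw log-ratio, or `NA` when either integral is zero (flagged
#'   SNPs receive the median fractional rank downstream).
#' @export
xpehh_per_snp <- function(panel, groups, map, core_index, truncation = 0.05,
                          max_extension_bp = 1e6) {
  groups <- group_assignment(groups$sample_id, groups$group)
  blocks <- chrom_block_id(map)
  on_chrom <- which(blocks == blocks[core_index])
  pos <- map$pos_bp[on_chrom]
  core <- match(core_index, on_chrom)
  rs <- hap_rows(panel, groups$sample_id[groups$group == "SELECTED"])
  rr <- hap_rows(panel, groups$sample_id[groups$group == "REFERENCE"])
  hs <- panel$alleles[rs, on_chrom, drop = FALSE]
  hr <- panel$alleles[rr, on_chrom, drop = FALSE]
  hp <- rbind(hs, hr)

  i_sel <- i_ref <- 0
  for (side in c(-1L, 1L)) {
    pooled <- ehh_side(hp, core, pos, side, truncation, max_extension_bp)
    n_pts <- nrow(pooled) - 1L   # steps taken beyond the core
    if (n_pts < 1L) next
    offs <- pooled[, 1]
    es <- er <- c(1, numeric(n_pts))
    for (k in seq_len(n_pts)) {
      b <- core + side * k
      es[k + 1L] <- ehh_at(hs, core, b)
      er[k + 1L] <- ehh_at(hr, core, b)
    }
    i_sel <- i_sel + trapezoid(offs, es)
    i_ref <- i_ref + trapezoid(offs, er)
  }
  if (i_sel <= 0 || i_ref <= 0) return(NA_real_)
  log(i_sel / i_ref)
}

#' Genome-wide XP-EHH scan
#'
#' Raw XP-EHH log-ratio (see [xpehh_per_snp()]) at every SNP, computed in
#' compiled code with incremental haplotype-partition refinement.
#'
#' @inheritParams xpehh_per_snp
#' @return numeric vector of raw log-ratios aligned to `map`; `NA` where
#'   the score is undefined.
#' @export
xpehh_scan <- function(panel, groups, map, truncation = 0.05,
                       max_extension_bp = 1e6) {
  groups <- group_assignment(groups$sample_id, groups$group)
  if (ncol(panel$alleles) != nrow(map)) stop("panel and map disagree on SNP count")
  rs <- hap_rows(panel, groups$sample_id[groups$group == "SELECTED"])
  rr <- hap_rows(panel, groups$sample_id[groups$group == "REFERENCE"])
  cpp_xpehh_scan(panel$alleles, as.numeric(map$pos_bp),
                 as.integer(chrom_block_id(map)),
                 as.integer(rs), as.integer(rr),
                 truncation, max_extension_bp)
}
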