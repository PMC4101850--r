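#' Sliding-window and region-calling parameters
#'
#' Defaults reproduce the scan's standard constants: 1 Mb windows centred
#' at each SNP (`half_width_bp` 500 kb each side), windows with fewer than
#' 5 SNPs discarded, top 0.1% of smoothed scores significant, clusters
#' closer than 1 Mb merged, at least 3 member SNPs per cluster, and 0.5 Mb
#' of flank added on each side of a cluster to form its candidate region.
#'
#' @param half_width_bp window half width in bp.
#' @param min_snps minimum SNPs per retained window.
#' @param top_fraction significant fraction of retained smoothed scores.
#' @param cluster_merge_gap_bp merge same-chromosome clusters closer than
#'   this gap.
#' @param region_pad_bp flank added to cluster bounds to form the region.
#' @param min_cluster_snps minimum member SNPs per reported cluster.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(half_width_bp = 500000, min_snps = 5,
                        top_fraction = 0.001, cluster_merge_gap_bp = 1000000,
                        region_pad_bp = 500000, min_cluster_snps = 3) {
  spec <- list(half_width_bp = half_width_bp, min_snps = min_snps,
               top_fraction = top_fraction,
               cluster_merge_gap_bp = cluster_merge_gap_bp,
               region_pad_bp = region_pad_bp,
               min_cluster_snps = min_cluster_snps)
  if (any(unlist(spec) <= 0)) stop("all window parameters must be positive")
  structure(spec, class = "window_spec")
}

#' Smooth per-SNP scores over sliding windows
#'
#' For SNP j at position x, the window holds every SNP on the same
#' chromosome with `|pos - x| <= half_width_bp` (closed interval, centre
#' SNP included); the smoothed value is the arithmetic mean of the scores
#' in the window (`NA` scores are dropped from the mean).  Windows holding
#' fewer than `min_snps` SNPs are pruned: their smoothed value is `NA` and
#' they are excluded from all downstream thresholds.
#'
#' @param values per-SNP score vector aligned to `map`.
#' @param map validated SNP map.
#' @param spec [window_spec()].
#' @return list with `smoothed` (NA where pruned) and `n_in_window`
#'   (total SNP count per window).
#' @export
smooth_scores <- function(values, map, spec = window_spec()) {
  if (length(values) != nrow(map)) stop("values and map disagree on SNP count")
  n <- length(values)
  smoothed <- rep(NA_real_, n)
  n_in <- integer(n)
  blocks <- chrom_block_id(map)
  for (blk in unique(blocks)) {
    idx <- which(blocks == blk)
    p <- as.numeric(map$pos_bp[idx])
    v <- values[idx]
    lo <- findInterval(p - spec$half_width_bp - 0.5, p) + 1L
    hi <- findInterval(p + spec$half_width_bp, p)
    def <- !is.na(v)
    cs <- c(0, cumsum(ifelse(def, v, 0)))
    cd <- c(0L, cumsum(def))
    tot <- hi - lo + 1L
    nd <- cd[hi + 1L] - cd[lo]
    sm <- ifelse(nd > 0, (cs[hi + 1L] - cs[lo]) / nd, NA_real_)
    sm[tot < spec$min_snps] <- NA_real_
    smoothed[idx] <- sm
    n_in[idx] <- tot
  }
  list(smoothed = smoothed, n_in_window = n_in)
}

#' Significant SNPs at the top of the smoothed distribution
#'
#' Returns the indices of the top `ceiling(top_fraction * n_retained)`
#' smoothed values, where `n_retained` counts non-pruned windows.  Ties at
#' the cutoff are broken by genome (chromosome, position) order so the
#' count is exact; at least one SNP is always returned.
#'
#' @param smoothed smoothed score vector (NA = pruned window).
#' @param spec [window_spec()].
#' @return sorted integer vector of SNP indices, with attribute
#'   `"threshold_count"`.
#' @export
significant_snps <- function(smoothed, spec = window_spec()) {
  retained <- which(!is.na(smoothed))
  n_ret <- length(retained)
  if (n_ret == 0L) stop("no retained windows")
  if (n_ret < 1000L) {
    warning("only ", n_ret, " retained windows; top-fraction threshold floored at 1 SNP")
  }
  k <- max(1L, as.integer(ceiling(spec$top_fraction * n_ret)))
  ord <- retained[order(-smoothed[retained], retained)]
  out <- sort(ord[seq_len(k)])
  attr(out, "threshold_count") <- k
  out
}

#' Call clusters of significant SNPs and their candidate regions
#'
#' Greedy seeding by descending smoothed score: the unassigned significant
#' SNP with the largest smoothed value becomes a cluster core and captures
#' every unassigned significant SNP on its chromosome within
#' `half_width_bp`; this repeats until all significant SNPs are assigned.
#' Same-chromosome clusters whose boundary gap is smaller than
#' `cluster_merge_gap_bp` are then merged (the more extreme core wins),
#' clusters with fewer than `min_cluster_snps` members are dropped, and
#' each surviving cluster is padded by `region_pad_bp` on both sides
#' (floored at position 1) to form its candidate region.
#'
#' @param sig integer vector of significant SNP indices (from
#'   [significant_snps()]).
#' @param smoothed smoothed score vector used for seeding and peaks.
#' @param map validated SNP map.
#' @param spec [window_spec()].
#' @return data frame with one row per region: `chrom`,
#'   `cluster_start_bp`, `cluster_end_bp`, `region_start_bp`,
#'   `region_end_bp`, `core_snp_id`, `core_index`, `peak_css`, `n_members`,
#'   `member_snp_ids` (comma separated) and list column `member_index`.
#' @export
call_clusters <- function(sig, smoothed, map, spec = window_spec()) {
  empty <- data.frame(chrom = character(), cluster_start_bp = integer(),
                      cluster_end_bp = integer(), region_start_bp = integer(),
                      region_end_bp = integer(), core_snp_id = character(),
                      core_index = integer(), peak_css = numeric(),
                      n_members = integer(), member_snp_ids = character(),
                      stringsAsFactors = FALSE)
  empty$member_index <- list()
  if (length(sig) == 0L) return(empty)
  sig <- sort(unique(as.integer(sig)))
  pos <- map$pos_bp
  chrom <- as.character(map$chrom)

  assigned <- rep(FALSE, length(sig))
  order_by_peak <- order(-smoothed[sig], sig)
  clusters <- list()
  for (k in order_by_peak) {
    if (assigned[k]) next
    core <- sig[k]
    grab <- !assigned & chrom[sig] == chrom[core] &
      abs(pos[sig] - pos[core]) <= spec$half_width_bp
    members <- sig[grab]
    assigned[grab] <- TRUE
    clusters[[length(clusters) + 1L]] <- list(
      chrom = chrom[core], core = core, members = members,
      start = min(pos[members]), end = max(pos[members]))
  }

  # merge neighbouring clusters on the same chromosome
  ord <- order(vapply(clusters, `[[`, "", "chrom"),
               vapply(clusters, `[[`, 0, "start"))
  clusters <- clusters[ord]
  merged <- list(clusters[[1L]])
  for (cl in clusters[-1L]) {
    cur <- merged[[length(merged)]]
    if (cl$chrom == cur$chrom && (cl$start - cur$end) < spec$cluster_merge_gap_bp) {
      cur$members <- sort(union(cur$members, cl$members))
      cur$start <- min(cur$start, cl$start)
      cur$end <- max(cur$end, cl$end)
      if (smoothed[cl$core] > smoothed[cur$core]) cur$core <- cl$core
      merged[[length(merged)]] <- cur
    } else {
      merged[[length(merged) + 1L]] <- cl
    }
  }
  merged <- Filter(function(cl) length(cl$members) >= spec$min_cluster_snps, merged)
  if (length(merged) == 0L) return(empty)

  out <- data.frame(
    chrom = vapply(merged, `[[`, "", "chrom"),
    cluster_start_bp = vapply(merged, function(cl) as.integer(cl$start), 0L),
    cluster_end_bp = vapply(merged, function(cl) as.integer(cl$end), 0L),
    stringsAsFactors = FALSE)
  out$region_start_bp <- pmax(1L, out$cluster_start_bp - as.integer(spec$region_pad_bp))
  out$region_end_bp <- out$cluster_end_bp + as.integer(spec$region_pad_bp)
  out$core_snp_id <- vapply(merged, function(cl) map$snp_id[cl$core], "")
  out$core_index <- vapply(merged, function(cl) as.integer(cl$core), 0L)
  out$peak_css <- vapply(merged, function(cl) smoothed[cl$core], 0)
  out$n_members <- vapply(merged, function(cl) length(cl$members), 0L)
  out$member_snp_ids <- vapply(merged, function(cl)
    paste(map$snp_id[cl$members], collapse = ","), "")
  out$member_index <- lapply(merged, `[[`, "members")
  out
}

#' Count per-test significant SNPs inside each region
#'
#' For every region and every constituent test, counts the test's
#' significant SNPs whose position falls within the closed interval
#' `[region_start_bp, region_end_bp]` on the region's chromosome.
#'
#' @param regions region data frame from [call_clusters()].
#' @param per_test_sig named list of integer index vectors (one per test,
#'   e.g. from applying [smooth_scores()] + [significant_snps()] to each
#'   test's statistic).
#' @param map validated SNP map.
#' @return `regions` with one `n_sig_<test>` column appended per test.
#' @export
count_concordance <- function(regions, per_test_sig, map) {
  for (test in names(per_test_sig)) {
    idx <- per_test_sig[[test]]
    regions[[paste0("n_sig_", test)]] <- vapply(seq_len(nrow(regions)), function(r) {
      sum(as.character(map$chrom[idx]) == regions$chrom[r] &
            map$pos_bp[idx] >= regions$region_start_bp[r] &
            map$pos_bp[idx] <= regions$region_end_bp[r])
    }, 0L)
  }
  regions
}
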