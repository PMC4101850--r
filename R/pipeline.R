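#' Run the full composite selection-signal scan
#'
#' Chains the whole pipeline on in-memory inputs: pooled MAF filter,
#' constituent statistics (fixation index; derived/selected allele
#' frequency contrast, standardized; XP-EHH, standardized), rank-based
#' composition into the composite selection signal, 1 Mb sliding-window
#' smoothing with low-density pruning, top-fraction significance, cluster
#' and region calling with per-test concordance counts, and tail-area FDR
#' on the recalibrated non-smoothed composite p-values.
#'
#' @param panel [hap_panel()].
#' @param map matching SNP map (validated on entry).
#' @param groups group assignment data frame.
#' @param tests constituent tests to combine; subset of
#'   `c("fst", "dafdiff", "xpehh")`.
#' @param min_maf pooled minor-allele-frequency threshold (default 0.01).
#' @param window [window_spec()].
#' @param fst_estimator `"nei"` (default) or `"wc"`, see [fst_per_snp()].
#' @param truncation,max_extension_bp XP-EHH extension controls, see
#'   [ehh_decay()].
#' @param alpha FDR threshold for the region summary.
#' @return object of class `css_scan`: list with `scores` (per-SNP table),
#'   `regions`, `region_summary`, `sig_index` (per-test significant SNP
#'   indices), `eta0`, `counts` (bookkeeping) and the call parameters.
#' @export
css_scan <- function(panel, map, groups,
                     tests = c("fst", "dafdiff", "xpehh"),
                     min_maf = 0.01, window = window_spec(),
                     fst_estimator = c("nei", "wc"),
                     truncation = 0.05, max_extension_bp = 1e6,
                     alpha = 0.05) {
  tests <- match.arg(tests, several.ok = TRUE)
  fst_estimator <- match.arg(fst_estimator)
  map <- validate_snp_map(map)
  groups <- group_assignment(groups$sample_id, groups$group)
  if (!all(panel$sample_ids %in% groups$sample_id)) {
    stop("every panel sample must be assigned to a group")
  }
  groups <- groups[groups$sample_id %in% panel$sample_ids, , drop = FALSE]
  n_input <- nrow(map)

  flt <- apply_maf_filter(panel, map, min_maf)
  map <- flt$map
  panel <- flt$panel
  n_snps <- nrow(map)
  if (n_snps < 2L) stop("fewer than 2 SNPs survive the MAF filter")

  fq <- group_freqs(panel, groups)
  stat_list <- list()
  if ("fst" %in% tests) {
    stat_list$fst <- fst_per_snp(fq$f_sel, fq$f_ref, fst_estimator,
                                 n_sel = fq$n_hap_sel, n_ref = fq$n_hap_ref)
  }
  if ("dafdiff" %in% tests) {
    raw <- daf_or_saf(fq$f_sel, fq$f_ref, map$ancestral)
    stat_list$dafdiff <- standardize_scores(as.numeric(raw))
  }
  if ("xpehh" %in% tests) {
    raw <- xpehh_scan(panel, groups, map, truncation, max_extension_bp)
    n_undef <- sum(is.na(raw))
    if (n_undef > 0) {
      message(n_undef, " SNP(s) with undefined XP-EHH assigned the median rank")
    }
    stat_list$xpehh <- standardize_scores(raw)
  }
  stats <- do.call(cbind, stat_list)
  cmp <- compose_css(stats)

  sm <- smooth_scores(cmp$css, map, window)
  sig_css <- significant_snps(sm$smoothed, window)
  per_test_sig <- lapply(stat_list, function(v) {
    significant_snps(smooth_scores(v, map, window)$smoothed, window)
  })

  regions <- call_clusters(sig_css, sm$smoothed, map, window)
  if (nrow(regions) > 0) {
    regions <- count_concordance(regions, c(list(css = sig_css), per_test_sig), map)
  }

  cal <- calibrate_p(cmp$p)
  fdr <- q_values(cal)
  region_summary <- region_fdr_summary(fdr, regions, map, alpha)

  blank <- rep(NA_real_, n_snps)
  scores <- data.frame(
    snp_id = map$snp_id, chrom = map$chrom, pos_bp = map$pos_bp,
    fst = if (is.null(stat_list$fst)) blank else stat_list$fst,
    dafdiff = if (is.null(stat_list$dafdiff)) blank else stat_list$dafdiff,
    xpehh = if (is.null(stat_list$xpehh)) blank else stat_list$xpehh,
    z_fst = blank, z_dafdiff = blank, z_xpehh = blank,
    zbar = cmp$zbar, p = cmp$p, css = cmp$css,
    css_smoothed = sm$smoothed, n_snps_window = sm$n_in_window,
    q_value = fdr$q_value, stringsAsFactors = FALSE)
  for (test in names(stat_list)) scores[[paste0("z_", test)]] <- cmp$z[, test]

  structure(list(
    scores = scores, regions = regions, region_summary = region_summary,
    sig_index = c(list(css = sig_css), per_test_sig),
    eta0 = fdr$eta0, tests = names(stat_list), window = window,
    counts = list(n_input = n_input, n_after_maf = n_snps,
                  n_retained_windows = sum(!is.na(sm$smoothed)),
                  n_significant = length(sig_css),
                  n_regions = nrow(regions))),
    class = "css_scan")
}

#' @export
print.css_scan <- function(x, ...) {
  cat("Composite selection-signal scan\n")
  cat(sprintf("  tests combined : %s (m = %d)\n",
              paste(x$tests, collapse = " + "), length(x$tests)))
  cat(sprintf("  SNPs           : %d in, %d after MAF filter, %d retained windows\n",
              x$counts$n_input, x$counts$n_after_maf, x$counts$n_retained_windows))
  cat(sprintf("  significant    : %d SNPs (top %.2g%% of smoothed CSS)\n",
              x$counts$n_significant, 100 * x$window$top_fraction))
  cat(sprintf("  regions        : %d called; eta0 = %.3f\n",
              x$counts$n_regions, x$eta0))
  invisible(x)
}

#' File-level scan driver
#'
#' Reads haplotypes (THAP pair or phased VCF) and a group file, runs
#' [css_scan()], and writes `scores.tsv`, `regions.tsv` and
#' `region_summary.tsv` under `out_dir`.  Per-stage SNP counts are
#' reported via `message()`.
#'
#' @param groups_file sample-to-group file, see [read_group_file()].
#' @param out_dir output directory (created if absent).
#' @param hap,map THAP haplotype/map file pair, or
#' @param vcf phased VCF (exactly one input form must be given).
#' @param ... further arguments passed to [css_scan()].
#' @return the `css_scan` object, invisibly.
#' @export
run_scan <- function(groups_file, out_dir, hap = NULL, map = NULL,
                     vcf = NULL, ...) {
  if (!file.exists(groups_file)) stop("group file not found: ", groups_file)
  groups <- read_group_file(groups_file)
  input <- if (!is.null(vcf)) {
    read_phased_vcf(vcf, groups)
  } else if (!is.null(hap) && !is.null(map)) {
    read_thap(hap, map, groups)
  } else {
    stop("supply either vcf= or both hap= and map=")
  }
  message("loaded ", nrow(input$map), " SNPs, ",
          length(input$panel$sample_ids), " samples")
  scan <- css_scan(input$panel, input$map, groups, ...)
  message("after MAF filter: ", scan$counts$n_after_maf, " SNPs; ",
          scan$counts$n_retained_windows, " retained windows; ",
          scan$counts$n_significant, " significant SNPs; ",
          scan$counts$n_regions, " regions")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_scores(scan$scores, file.path(out_dir, "scores.tsv"))
  write_regions(scan$regions, file.path(out_dir, "regions.tsv"))
  write.table(scan$region_summary, file.path(out_dir, "region_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(scan)
}

#' Manhattan-style plot of smoothed composite selection signals
#'
#' Smoothed CSS per SNP, coloured by chromosome, with the top-fraction
#' significance threshold drawn as a dashed line.  Cosmetic companion to
#' [css_scan()].
#'
#' @param scan `css_scan` object.
#' @param ... passed to [graphics::plot()].
#' @return the threshold value, invisibly.
#' @export
plot_css <- function(scan, ...) {
  s <- scan$scores
  keep <- !is.na(s$css_smoothed)
  blocks <- chrom_block_id(s)
  offs <- c(0, cumsum(tapply(as.numeric(s$pos_bp), blocks, max)))
  x <- as.numeric(s$pos_bp) + offs[blocks]
  thr <- min(s$css_smoothed[scan$sig_index$css])
  graphics::plot(x[keep], s$css_smoothed[keep], pch = 16, cex = 0.4,
                 col = blocks[keep] %% 2 + 1,
                 xlab = "genome position (bp)", ylab = "smoothed CSS", ...)
  graphics::abline(h = thr, lty = 2, col = "red")
  invisible(thr)
}
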