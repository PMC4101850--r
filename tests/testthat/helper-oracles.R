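# Independent oracles and fixture builders used across the suite.

# EHH by direct enumeration over all haplotype pairs: count pairs identical
# over the closed interval, divided by the number of pairs.
brute_ehh <- function(haps, core, boundary) {
  idx <- seq(min(core, boundary), max(core, boundary))
  K <- nrow(haps)
  hits <- 0L
  for (a in seq_len(K - 1L)) {
    for (b in seq(a + 1L, K)) {
      if (all(haps[a, idx] == haps[b, idx])) hits <- hits + 1L
    }
  }
  hits / (K * (K - 1L) / 2L)
}

# Integrated EHH recomputed from scratch: step outward SNP by SNP calling
# brute_ehh at every boundary, accumulate trapezoids, stop after the first
# point below the truncation, past the maximum extension, or at the ends.
brute_integrated_ehh <- function(haps, core, pos, truncation = 0.05,
                                 max_extension_bp = 1e6) {
  if (nrow(haps) < 2L) return(0)
  total <- 0
  for (side in c(-1L, 1L)) {
    prev_off <- 0
    prev_e <- 1
    b <- core + side
    while (b >= 1L && b <= length(pos)) {
      off <- abs(pos[b] - pos[core])
      if (off > max_extension_bp) break
      e <- brute_ehh(haps, core, b)
      total <- total + 0.5 * (prev_e + e) * (off - prev_off)
      prev_off <- off
      prev_e <- e
      if (e < truncation) break
      b <- b + side
    }
  }
  total
}

# O(n^2) window mean: for each SNP, average values of all SNPs on the same
# chromosome within the closed +/- half-width window; NA when the window
# holds fewer than min_snps SNPs.
brute_smooth <- function(values, chrom, pos, half_width = 5e5, min_snps = 5) {
  n <- length(values)
  out <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    w <- which(chrom == chrom[j] & abs(pos - pos[j]) <= half_width)
    if (length(w) >= min_snps) out[j] <- mean(values[w], na.rm = TRUE)
  }
  out
}

# random phased panel: n_hap haplotypes x n_snp SNPs of Bernoulli(freq)
random_haps <- function(n_hap, n_snp, freq = 0.5) {
  matrix(rbinom(n_hap * n_snp, 1L, freq), nrow = n_hap)
}

# two-sample group assignment helper
two_groups <- function(n_sel, n_ref) {
  group_assignment(c(sprintf("S%02d", seq_len(n_sel)), sprintf("R%02d", seq_len(n_ref))),
                   rep(c("SELECTED", "REFERENCE"), c(n_sel, n_ref)))
}

# small, fast sweep scenario for pipeline-level tests
small_scenario <- function(seed = 7, sweep_final_freq = 0.9) {
  sweep_scenario(n_snps = 2500, n_chrom = 2, chrom_length_bp = 2.5e7,
                 n_samples_sel = 30, n_samples_ref = 30,
                 sweep_chrom = "chr2", sweep_pos_bp = 1.25e7,
                 sweep_final_freq = sweep_final_freq, seed = seed)
}

# write a minimal phased VCF; gt is an n_snp x n_sample matrix of "a|b"
# strings, aa an optional vector of ancestral bases for the INFO field
write_test_vcf <- function(path, chrom, pos, id, ref, alt, gt, samples,
                           aa = NULL) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  info <- if (is.null(aa)) rep(".", length(pos)) else
    ifelse(is.na(aa), ".", paste0("AA=", aa))
  for (j in seq_along(pos)) {
    writeLines(paste(c(chrom[j], pos[j], id[j], ref[j], alt[j], ".", "PASS",
                       info[j], "GT", gt[j, ]), collapse = "\t"), con)
  }
  close(con)
  path
}
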