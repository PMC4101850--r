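#' Define a two-population hard-sweep scenario
#'
#' Two diploid populations share ancestral (derived-allele) frequencies
#' drawn from a Beta distribution; each population's frequency is jittered
#' independently (truncated Gaussian noise), emulating neutral divergence
#' between phenotypically contrasting multi-breed groups.  Haplotypes are
#' drawn as independent Bernoulli alleles (linkage-equilibrium background).
#' In the SELECTED population a single fixed "sweep haplotype" -- carrying
#' the derived allele at the sweep position -- replaces the background
#' alleles over the sweep interval with probability `sweep_final_freq` per
#' haplotype, producing both the frequency differentiation and the extended
#' haplotype homozygosity that a partial/complete hard sweep leaves behind.
#'
#' The default sizes give 20,000 SNPs on 5 chromosomes of 200 Mb, i.e.
#' about 20 SNPs per 1 Mb window, matching the density of the 50K
#' genotyping chips this kind of scan is run on.
#'
#' @param n_snps total SNP count.
#' @param n_chrom number of chromosomes (`chr1` ... `chrN`).
#' @param chrom_length_bp chromosome length in bp.
#' @param n_samples_sel,n_samples_ref diploid sample counts per group.
#' @param base_freq_shape1,base_freq_shape2 Beta shape parameters of the
#'   ancestral derived-allele frequency distribution.
#' @param divergence_sd per-SNP, per-population frequency jitter (Gaussian
#'   sd, truncated to `[0, 1]`).
#' @param sweep_chrom,sweep_pos_bp sweep locus.
#' @param sweep_final_freq frequency of the sweep haplotype among SELECTED
#'   haplotypes (0 = null scenario).
#' @param sweep_core_halfwidth_bp extent of the shared haplotype on each
#'   side of the sweep position.
#' @param seed RNG seed; identical seeds give bit-identical panels.
#' @return list of class `sweep_scenario`.
#' @export
sweep_scenario <- function(n_snps = 20000, n_chrom = 5, chrom_length_bp = 2e8,
                           n_samples_sel = 100, n_samples_ref = 100,
                           base_freq_shape1 = 0.5, base_freq_shape2 = 0.5,
                           divergence_sd = 0.05,
                           sweep_chrom = "chr3", sweep_pos_bp = 1e8,
                           sweep_final_freq = 0.9,
                           sweep_core_halfwidth_bp = 300000, seed = 1) {
  sc <- list(n_snps = n_snps, n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
             n_samples_sel = n_samples_sel, n_samples_ref = n_samples_ref,
             base_freq_shape1 = base_freq_shape1, base_freq_shape2 = base_freq_shape2,
             divergence_sd = divergence_sd, sweep_chrom = sweep_chrom,
             sweep_pos_bp = sweep_pos_bp, sweep_final_freq = sweep_final_freq,
             sweep_core_halfwidth_bp = sweep_core_halfwidth_bp, seed = seed)
  if (!(sweep_chrom %in% paste0("chr", seq_len(n_chrom)))) {
    stop("sweep_chrom must be one of chr1..chr", n_chrom)
  }
  if (sweep_pos_bp < 1 || sweep_pos_bp > chrom_length_bp) {
    stop("sweep_pos_bp outside the chromosome")
  }
  if (sweep_final_freq < 0 || sweep_final_freq > 1) {
    stop("sweep_final_freq must lie in [0, 1]")
  }
  if (n_samples_sel < 1 || n_samples_ref < 1) stop("both groups need samples")
  structure(sc, class = "sweep_scenario")
}

#' Null (no-sweep) copy of a scenario
#'
#' @param scenario [sweep_scenario()].
#' @return the same scenario with `sweep_final_freq = 0`.
#' @export
null_scenario <- function(scenario) {
  scenario$sweep_final_freq <- 0
  scenario
}

#' Simulate a two-population phased panel with a known sweep
#'
#' @param scenario [sweep_scenario()].
#' @return list with `map` (including the per-SNP `ancestral` annotation),
#'   `panel` ([hap_panel()]), `groups`, `scenario`, and `truth`: the sweep
#'   chromosome/position, the forced-haplotype interval, and the realized
#'   sweep-haplotype frequency in each group (`is_null = TRUE` when
#'   `sweep_final_freq` is 0).
#' @export
simulate_sweep_panel <- function(scenario = sweep_scenario()) {
  if (!inherits(scenario, "sweep_scenario")) stop("need a sweep_scenario")
  set.seed(scenario$seed)
  n <- scenario$n_snps
  n_chr <- scenario$n_chrom
  per <- rep(n %/% n_chr, n_chr)
  if (n %% n_chr) per[seq_len(n %% n_chr)] <- per[seq_len(n %% n_chr)] + 1L
  chroms <- paste0("chr", seq_len(n_chr))

  pos_list <- lapply(seq_len(n_chr), function(k) {
    p <- sort(sample.int(scenario$chrom_length_bp, per[k]))
    if (chroms[k] == scenario$sweep_chrom && !(scenario$sweep_pos_bp %in% p)) {
      p[which.min(abs(p - scenario$sweep_pos_bp))] <- scenario$sweep_pos_bp
      p <- sort(unique(p))
    }
    p
  })
  chrom <- rep(chroms, lengths(pos_list))
  pos <- unlist(pos_list, use.names = FALSE)
  n <- length(pos)  # rarely one less after the sweep-position splice

  d <- rbeta(n, scenario$base_freq_shape1, scenario$base_freq_shape2)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  d_sel <- clamp01(d + rnorm(n, 0, scenario$divergence_sd))
  d_ref <- clamp01(d + rnorm(n, 0, scenario$divergence_sd))
  ancestral <- ifelse(runif(n) < 0.5, "REF", "ALT")
  p_alt_sel <- ifelse(ancestral == "REF", d_sel, 1 - d_sel)
  p_alt_ref <- ifelse(ancestral == "REF", d_ref, 1 - d_ref)

  nh_s <- 2L * scenario$n_samples_sel
  nh_r <- 2L * scenario$n_samples_ref
  a_sel <- matrix(rbinom(nh_s * n, 1L, rep(p_alt_sel, each = nh_s)), nrow = nh_s)
  a_ref <- matrix(rbinom(nh_r * n, 1L, rep(p_alt_ref, each = nh_r)), nrow = nh_r)

  core <- which(chrom == scenario$sweep_chrom & pos == scenario$sweep_pos_bp)
  interval <- which(chrom == scenario$sweep_chrom &
                      abs(pos - scenario$sweep_pos_bp) <= scenario$sweep_core_halfwidth_bp)
  realized_sel <- 0
  realized_ref <- 0
  if (scenario$sweep_final_freq > 0) {
    sweep_hap <- rbinom(length(interval), 1L, p_alt_sel[interval])
    derived_code <- if (ancestral[core] == "REF") 1L else 0L
    sweep_hap[match(core, interval)] <- derived_code
    carriers <- runif(nh_s) < scenario$sweep_final_freq
    if (any(carriers)) {
      a_sel[carriers, interval] <- matrix(sweep_hap, nrow = sum(carriers),
                                          ncol = length(interval), byrow = TRUE)
    }
    realized_sel <- mean(carriers)
    match_ref <- rowSums(a_ref[, interval, drop = FALSE] ==
                           matrix(sweep_hap, nrow = nh_r, ncol = length(interval),
                                  byrow = TRUE)) == length(interval)
    realized_ref <- mean(match_ref)
  }

  sample_ids <- c(sprintf("S%04d", seq_len(scenario$n_samples_sel)),
                  sprintf("R%04d", seq_len(scenario$n_samples_ref)))
  groups <- group_assignment(sample_ids,
                             rep(c("SELECTED", "REFERENCE"),
                                 c(scenario$n_samples_sel, scenario$n_samples_ref)))
  map <- validate_snp_map(data.frame(
    snp_id = paste0(chrom, "_", pos), chrom = chrom, pos_bp = pos,
    ancestral = ancestral, stringsAsFactors = FALSE))
  panel <- hap_panel(rbind(a_sel, a_ref), sample_ids)

  truth <- list(sweep_chrom = scenario$sweep_chrom,
                sweep_pos_bp = scenario$sweep_pos_bp,
                interval_start_bp = min(pos[interval]),
                interval_end_bp = max(pos[interval]),
                sweep_freq_sel = realized_sel,
                sweep_freq_ref = realized_ref,
                is_null = scenario$sweep_final_freq == 0)
  list(map = map, panel = panel, groups = groups, truth = truth,
       scenario = scenario)
}

#' Write a simulated panel in the THAP dialect
#'
#' Produces `<prefix>.hap`, `<prefix>.map`, `<prefix>.groups` and
#' `<prefix>.truth.tsv` under `dir`, loadable with [read_thap()] /
#' [read_group_file()] and the `scan` subcommand of the command-line tool.
#'
#' @param sim output of [simulate_sweep_panel()].
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_thap <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(hap = file.path(dir, paste0(prefix, ".hap")),
             map = file.path(dir, paste0(prefix, ".map")),
             groups = file.path(dir, paste0(prefix, ".groups")),
             truth = file.path(dir, paste0(prefix, ".truth.tsv")))
  write.table(t(sim$panel$alleles), paths["hap"], sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  anc <- sim$map$ancestral
  anc[is.na(anc)] <- "NA"
  write.table(data.frame(sim$map$snp_id, sim$map$chrom, sim$map$pos_bp, anc),
              paths["map"], sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$groups, paths["groups"], sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(sim$truth), paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
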