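#' Validate a SNP map
#'
#' A SNP map is a data frame with one row per SNP and columns `snp_id`
#' (unique), `chrom`, `pos_bp` (1-based physical position) and optionally
#' `ancestral` (`"REF"`, `"ALT"` or `NA` for unknown).  Chromosomes must
#' form contiguous blocks and positions must increase strictly within each
#' chromosome; duplicate (chrom, pos) pairs are rejected.
#'
#' @param map data frame to validate.
#' @return The validated map (with an `ancestral` column added if absent),
#'   invisibly usable in place of the input.
#' @export
validate_snp_map <- function(map) {
  if (!is.data.frame(map)) stop("snp map must be a data frame")
  req <- c("snp_id", "chrom", "pos_bp")
  miss <- setdiff(req, names(map))
  if (length(miss)) stop("snp map is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  if (is.null(map$ancestral)) map$ancestral <- rep(NA_character_, nrow(map))
  bad <- !(map$ancestral %in% c("REF", "ALT")) & !is.na(map$ancestral)
  if (any(bad)) stop("ancestral allele must be 'REF', 'ALT' or NA")
  runs <- rle(as.character(map$chrom))
  if (anyDuplicated(runs$values)) {
    stop("map not sorted: chromosome blocks are not contiguous")
  }
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    p <- map$pos_bp[starts[k]:stops[k]]
    if (any(p < 1)) stop("positions must be >= 1 bp")
    if (length(p) > 1L && is.unsorted(p, strictly = TRUE)) {
      stop("map not sorted: positions must increase strictly on ", runs$values[k])
    }
  }
  map
}

#' Construct a phased haplotype panel
#'
#' @param alleles matrix of 0/1 alleles, one row per haplotype and one
#'   column per SNP; 0 = REF, 1 = ALT.  Each diploid sample owns two
#'   consecutive rows (`2s - 1` and `2s` for sample `s`).
#' @param sample_ids character vector of sample identifiers; its length must
#'   be half the number of haplotype rows.
#' @return An object of class `hap_panel` (list with elements `alleles` and
#'   `sample_ids`).
#' @export
hap_panel <- function(alleles, sample_ids) {
  alleles <- as.matrix(alleles)
  if (anyNA(alleles)) stop("missing alleles: phased, imputed input is required")
  if (!all(alleles == 0L | alleles == 1L)) stop("invalid allele code: alleles must be 0 or 1")
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- NULL
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (nrow(alleles) != 2L * length(sample_ids)) {
    stop("each sample must own exactly two haplotype rows")
  }
  structure(list(alleles = alleles, sample_ids = sample_ids), class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d haplotypes (%d samples) x %d SNPs\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles)))
  invisible(x)
}

# haplotype row indices of the given samples (two consecutive rows each)
hap_rows <- function(panel, samples) {
  s <- match(samples, panel$sample_ids)
  if (anyNA(s)) stop("sample(s) not in panel: ", paste(samples[is.na(s)], collapse = ", "))
  as.vector(rbind(2L * s - 1L, 2L * s))
}

#' Construct / validate a group assignment
#'
#' Assigns every sample to either the putatively `SELECTED` group or the
#' `REFERENCE` group.  Both groups must be non-empty.
#'
#' @param sample_id character vector of sample ids.
#' @param group character vector, `"SELECTED"` or `"REFERENCE"`.
#' @return data frame with columns `sample_id` and `group`.
#' @export
group_assignment <- function(sample_id, group) {
  g <- data.frame(sample_id = as.character(sample_id),
                  group = as.character(group),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$sample_id)) stop("sample assigned to more than one group")
  if (!all(g$group %in% c("SELECTED", "REFERENCE"))) {
    stop("group must be 'SELECTED' or 'REFERENCE'")
  }
  if (!all(c("SELECTED", "REFERENCE") %in% g$group)) {
    stop("both SELECTED and REFERENCE groups must be non-empty")
  }
  g
}

#' Read a sample-to-group assignment file
#'
#' Whitespace-separated text with two columns, `sample_id` and `group`
#' (`SELECTED` or `REFERENCE`); lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return data frame as from [group_assignment()].
#' @export
read_group_file <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("sample_id", "group"),
                    colClasses = "character")
  group_assignment(tab$sample_id, tab$group)
}

#' Read a transposed haplotype (THAP) file pair
#'
#' The THAP dialect holds one SNP per line with `2 * n_samples`
#' whitespace-separated 0/1 tokens; the two columns of a sample are adjacent
#' and samples appear in the order of the group file.  The companion map
#' file has columns `snp_id chrom pos_bp` and optionally a fourth ancestral
#' column (`REF`, `ALT` or `NA`); `#` comment lines are ignored in both.
#'
#' @param path_hap haplotype file.
#' @param path_map map file.
#' @param groups group assignment data frame (defines sample ids and order).
#' @return list with elements `map` (validated SNP map) and `panel`
#'   ([hap_panel()]).
#' @export
read_thap <- function(path_hap, path_map, groups) {
  groups <- group_assignment(groups$sample_id, groups$group)
  map <- read.table(path_map, header = FALSE, comment.char = "#",
                    colClasses = "character", fill = TRUE)
  if (ncol(map) < 3L) stop("map file needs at least 3 columns (snp_id chrom pos_bp)")
  anc <- if (ncol(map) >= 4L) map[[4L]] else rep(NA_character_, nrow(map))
  anc[anc %in% c("NA", ".", "")] <- NA_character_
  map <- data.frame(snp_id = map[[1L]], chrom = map[[2L]],
                    pos_bp = as.integer(map[[3L]]), ancestral = anc,
                    stringsAsFactors = FALSE)
  map <- validate_snp_map(map)

  hap <- as.matrix(read.table(path_hap, header = FALSE, comment.char = "#"))
  if (nrow(hap) != nrow(map)) {
    stop("haplotype file has ", nrow(hap), " SNP rows but map has ", nrow(map))
  }
  n_col_expect <- 2L * nrow(groups)
  if (ncol(hap) != n_col_expect) {
    stop("row length mismatch: expected ", n_col_expect,
         " allele columns for ", nrow(groups), " samples, found ", ncol(hap))
  }
  if (!all(hap == 0 | hap == 1)) stop("invalid allele code: tokens must be 0 or 1")
  panel <- hap_panel(t(hap), groups$sample_id)
  list(map = map, panel = panel)
}

#' Read phased biallelic SNPs from a VCF
#'
#' Requires phased GT (`a|b`) for every assigned sample.  The optional INFO
#' key `AA` sets the ancestral allele when it matches the REF or ALT base;
#' otherwise the ancestral state is recorded as unknown.  In strict mode
#' (default) any unphased/missing genotype or multiallelic record is an
#' error; in lenient mode offending SNPs are skipped with a message.
#'
#' @param path VCF file (plain or bgzipped).
#' @param groups group assignment data frame; every listed sample must be
#'   present in the VCF.  The panel is restricted to these samples, in
#'   group-file order.
#' @param strict reject (TRUE, default) or skip (FALSE) offending records.
#' @return list with elements `map` and `panel`, as [read_thap()].
#' @export
read_phased_vcf <- function(path, groups, strict = TRUE) {
  groups <- group_assignment(groups$sample_id, groups$group)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  absent <- setdiff(groups$sample_id, colnames(gt))
  if (length(absent)) {
    stop("sample(s) in group file absent from VCF: ", paste(absent, collapse = ", "))
  }
  gt <- gt[, groups$sample_id, drop = FALSE]

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) | is.na(fix[, "ALT"]) | fix[, "ALT"] == "."
  phased_ok <- matrix(grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  row_ok <- rowSums(!phased_ok) == 0L
  if (strict) {
    if (any(multi)) stop("multiallelic record at ", fix[which(multi)[1], "CHROM"],
                         ":", fix[which(multi)[1], "POS"])
    if (any(!row_ok)) stop("unphased genotype at ", fix[which(!row_ok)[1], "CHROM"],
                           ":", fix[which(!row_ok)[1], "POS"])
    keep <- rep(TRUE, nrow(gt))
  } else {
    keep <- row_ok & !multi
    n_drop <- sum(!keep)
    if (n_drop > 0) message("skipped ", n_drop, " SNP(s) with unphased/multiallelic records")
  }
  if (!any(keep)) stop("no usable SNP records in VCF")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  aa <- vcfR::extract.info(v, element = "AA")
  aa <- if (is.null(aa)) rep(NA_character_, length(keep)) else as.character(aa)
  aa <- aa[keep]
  anc <- rep(NA_character_, nrow(fix))
  anc[!is.na(aa) & aa == fix[, "REF"]] <- "REF"
  anc[!is.na(aa) & aa == fix[, "ALT"]] <- "ALT"

  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  map <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                    pos_bp = as.integer(fix[, "POS"]), ancestral = anc,
                    stringsAsFactors = FALSE)
  map <- validate_snp_map(map)

  n_samp <- nrow(groups)
  left <- t(matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt)))
  right <- t(matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt)))
  alleles <- matrix(0L, nrow = 2L * n_samp, ncol = nrow(map))
  alleles[seq(1L, 2L * n_samp, by = 2L), ] <- left
  alleles[seq(2L, 2L * n_samp, by = 2L), ] <- right
  list(map = map, panel = hap_panel(alleles, groups$sample_id))
}

#' Remove low minor-allele-frequency SNPs
#'
#' The minor allele frequency is computed over the pooled haplotypes of
#' both groups; SNPs with pooled MAF less than or equal to `min_maf` are
#' removed from map and panel, preserving order.  Pooled (rather than
#' per-group) filtering keeps SNPs monomorphic in one group but segregating
#' in the other -- exactly the differentiation signal the scan looks for.
#'
#' @param panel [hap_panel()].
#' @param map matching SNP map.
#' @param min_maf retention threshold in `[0, 0.5)`; default 0.01.
#' @return list with filtered `map` and `panel`.
#' @export
apply_maf_filter <- function(panel, map, min_maf = 0.01) {
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must lie in [0, 0.5)")
  if (ncol(panel$alleles) != nrow(map)) stop("panel and map disagree on SNP count")
  f <- colMeans(panel$alleles)
  keep <- pmin(f, 1 - f) > min_maf
  list(map = map[keep, , drop = FALSE],
       panel = hap_panel(panel$alleles[, keep, drop = FALSE], panel$sample_ids))
}

score_columns <- c("snp_id", "chrom", "pos_bp", "fst", "dafdiff", "xpehh",
                   "z_fst", "z_dafdiff", "z_xpehh", "zbar", "p", "css",
                   "css_smoothed", "n_snps_window", "q_value")

#' Write / read a per-SNP score table
#'
#' Tab-separated, one row per SNP, fixed column set
#' `snp_id chrom pos_bp fst dafdiff xpehh z_fst z_dafdiff z_xpehh zbar p css
#' css_smoothed n_snps_window q_value`; SNPs in pruned windows carry the
#' literal token `NA` in the smoothed columns.
#'
#' @param scores data frame holding (at least) the score columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  miss <- setdiff(score_columns, names(scores))
  if (length(miss)) stop("score table is missing column(s): ", paste(miss, collapse = ", "))
  write.table(scores[, score_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(snp_id = "character", chrom = "character"))
}

#' Write called regions as a BED-like table
#'
#' Columns: `chrom`, 0-based `start` (`region_start_bp - 1`), `end`
#' (`region_end_bp`), `core_snp_id`, peak smoothed CSS, member count, and the
#' per-test significant-SNP counts inside the region.
#'
#' @param regions region data frame from [call_clusters()] /
#'   [count_concordance()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  cnt <- grep("^n_sig_", names(regions), value = TRUE)
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$region_start_bp - 1L,
                    end = regions$region_end_bp,
                    core_snp_id = regions$core_snp_id,
                    peak_css = regions$peak_css,
                    n_members = regions$n_members,
                    regions[, cnt, drop = FALSE],
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
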