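toy_map <- function(pos, chrom = "chr1") {
  data.frame(snp_id = paste0(chrom, "_", pos), chrom = chrom, pos_bp = pos)
}

test_that("window smoothing matches a brute-force double loop", {
  set.seed(1)
  pos <- sort(sample.int(2e7, 1000))
  map <- toy_map(pos)
  v <- rnorm(1000)
  out <- smooth_scores(v, map, window_spec())
  expect_equal(out$smoothed, brute_smooth(v, map$chrom, pos))
  # window counts include the centre SNP
  expect_true(all(out$n_in_window >= 1))
})

test_that("smoothing a constant reproduces the constant and prunes sparse windows", {
  map <- toy_map(c(1e6, 2e6, 2.2e6, 2.4e6, 2.5e6, 2.6e6))
  out <- smooth_scores(rep(3.5, 6), map, window_spec())
  # SNP 1 sits alone in its window (< 5 SNPs) -> pruned
  expect_true(is.na(out$smoothed[1]))
  expect_equal(out$smoothed[3], 3.5)
  # a 4-SNP chromosome can never fill a window of 5
  map2 <- rbind(map, toy_map(c(10, 20, 30, 40), chrom = "chr2"))
  out2 <- smooth_scores(rep(1, 10), map2, window_spec())
  expect_true(all(is.na(out2$smoothed[7:10])))
  expect_equal(out2$n_in_window[7:10], rep(4L, 4))
})

test_that("smoothing preserves the mean on a dense interior stretch", {
  set.seed(2)
  pos <- seq(1e6, 5e7, by = 2.5e4)  # 40 SNPs per window
  map <- toy_map(pos)
  v <- rnorm(length(pos))
  out <- smooth_scores(v, map, window_spec())
  interior <- pos > 2e6 & pos < 4.8e7
  expect_equal(mean(out$smoothed[interior]), mean(v), tolerance = 0.05)
})

test_that("top-fraction selection is exact and matches a full sort", {
  set.seed(3)
  x <- rnorm(1e4)
  sig <- significant_snps(x, window_spec())
  expect_identical(attr(sig, "threshold_count"), 10L)
  expect_setequal(sig, order(-x)[1:10])

  # degenerate ties: the first k SNPs in genome order win
  y <- rep(1, 5000)
  tied <- significant_snps(y, window_spec())
  expect_identical(as.integer(tied), 1:5)

  # pruned entries leave the count basis
  x[1:2000] <- NA
  sig2 <- significant_snps(x, window_spec())
  expect_identical(attr(sig2, "threshold_count"), 8L)
  expect_warning(significant_snps(rnorm(500), window_spec()), "retained windows")
})

test_that("clusters form around peaks, merge across small gaps, and pad regions", {
  # three significant SNPs at 10.0, 10.2, 10.4 Mb: one cluster, padded region
  pos <- c(1e6, 10e6, 10.2e6, 10.4e6, 30e6)
  map <- toy_map(pos)
  sm <- c(1, 5, 6, 5.5, 2)
  cl <- call_clusters(2:4, sm, map, window_spec())
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$cluster_start_bp, 10e6)
  expect_equal(cl$cluster_end_bp, 10.4e6)
  expect_equal(cl$region_start_bp, 9.5e6)
  expect_equal(cl$region_end_bp, 10.9e6)
  expect_identical(cl$core_snp_id, map$snp_id[3])
  expect_identical(cl$n_members, 3L)

  # clusters ending at 5.0 Mb and starting at 5.8 Mb merge (gap 0.8 < 1 Mb)
  pos <- c(4.6e6, 4.8e6, 5.0e6, 5.8e6, 6.0e6, 6.2e6)
  map <- toy_map(pos)
  sm <- c(4, 5, 4.5, 3, 3.6, 3.2)
  cl <- call_clusters(1:6, sm, map, window_spec())
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$cluster_start_bp, 4.6e6)
  expect_equal(cl$cluster_end_bp, 6.2e6)
  expect_identical(cl$n_members, 6L)
  expect_identical(cl$core_snp_id, map$snp_id[2])

  # two isolated significant SNPs 10 Mb apart: below the 3-member minimum
  map <- toy_map(c(1e6, 11e6))
  expect_identical(nrow(call_clusters(1:2, c(2, 3), map, window_spec())), 0L)
})

test_that("merged clusters keep at least the merge gap between them", {
  set.seed(4)
  for (rep in 1:10) {
    pos <- sort(sample.int(1e8, 600))
    map <- toy_map(pos)
    sm <- rnorm(600)
    sig <- suppressWarnings(
      significant_snps(ifelse(seq_along(sm) %% 7 == 0, sm + 3, sm),
                       window_spec(top_fraction = 0.05)))
    cl <- call_clusters(sig, sm, map, window_spec(min_cluster_snps = 1))
    if (nrow(cl) > 1) {
      gaps <- cl$cluster_start_bp[-1] - cl$cluster_end_bp[-nrow(cl)]
      expect_true(all(gaps >= 1e6))
    }
    # every member is significant
    expect_true(all(unlist(cl$member_index) %in% sig))
  }
})

test_that("per-test concordance counts equal a brute interval scan", {
  set.seed(5)
  pos <- sort(sample.int(5e7, 400))
  map <- toy_map(pos)
  sm <- rnorm(400)
  sig <- suppressWarnings(significant_snps(sm, window_spec(top_fraction = 0.02)))
  cl <- call_clusters(sig, sm, map, window_spec())
  expect_gt(nrow(cl), 0)
  sets <- list(fst = sample(400, 30), xpehh = integer(0))
  out <- count_concordance(cl, sets, map)
  for (r in seq_len(nrow(out))) {
    hand <- sum(pos[sets$fst] >= out$region_start_bp[r] &
                  pos[sets$fst] <= out$region_end_bp[r])
    expect_identical(out$n_sig_fst[r], hand)
  }
  expect_true(all(out$n_sig_xpehh == 0L))
})

test_that("enlarging the top fraction never drops a called core", {
  set.seed(6)
  pos <- sort(sample.int(1e8, 2000))
  map <- toy_map(pos)
  v <- rnorm(2000)
  v[900:940] <- v[900:940] + 2.5
  sm <- smooth_scores(v, map, window_spec())$smoothed
  small <- call_clusters(significant_snps(sm, window_spec(top_fraction = 0.002)),
                         sm, map, window_spec(top_fraction = 0.002))
  big <- call_clusters(significant_snps(sm, window_spec(top_fraction = 0.01)),
                       sm, map, window_spec(top_fraction = 0.01))
  expect_gt(nrow(small), 0)
  expect_true(all(small$core_snp_id %in% unlist(strsplit(big$member_snp_ids, ","))))
})
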