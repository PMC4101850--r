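test_that("EHH closed forms hold on hand-built panels", {
  h <- matrix(0L, 4, 3)           # four identical haplotypes
  expect_equal(ehh_at(h, 2, 2), 1)
  expect_equal(ehh_at(h, 1, 3), 1)

  h <- rbind(c(0, 0), c(0, 0), c(0, 1))  # classes {2, 1} of 3
  expect_equal(ehh_at(h, 1, 2), 1 / 3)

  h <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))  # all four strings distinct
  expect_equal(ehh_at(h, 1, 2), 0)
  expect_error(ehh_at(h[1, , drop = FALSE], 1, 2), "fewer than 2")
})

test_that("EHH equals brute-force pair enumeration on random panels", {
  set.seed(10)
  for (rep in 1:200) {
    K <- sample(2:10, 1)
    n_snp <- sample(2:20, 1)
    h <- random_haps(K, n_snp, freq = runif(1, 0.2, 0.8))
    core <- sample(n_snp, 1)
    boundary <- sample(n_snp, 1)
    expect_equal(ehh_at(h, core, boundary), brute_ehh(h, core, boundary))
  }
})

test_that("EHH decay is non-increasing and invariant to row order and relabeling", {
  set.seed(11)
  for (rep in 1:25) {
    h <- random_haps(8, 15)
    core <- sample(15, 1)
    right <- core:15
    e <- vapply(right, function(b) ehh_at(h, core, b), 0)
    expect_true(all(diff(e) <= 1e-12))
    b <- sample(right, 1)
    expect_equal(ehh_at(h[sample(8), ], core, b), ehh_at(h, core, b))
    expect_equal(ehh_at(1L - h, core, b), ehh_at(h, core, b))
  }
})

test_that("integrated EHH matches constant and hand-computed decays", {
  # identical haplotypes to both chromosome ends: EHH = 1 throughout,
  # integral equals the spanned distance on each side
  pos <- c(1000, 3000, 6000, 10000)
  h <- matrix(1L, 5, 4)
  expect_equal(integrated_ehh(h, 2, pos, truncation = 0.05),
               (3000 - 1000) + (10000 - 3000))

  # single-sided decay 1 -> 0.5 over 1000 bp: trapezoid area 750
  h <- cbind(rep(0L, 4), c(0L, 0L, 0L, 1L))  # classes {3,1}: EHH = 0.5
  expect_equal(integrated_ehh(h, 1, c(100, 1100), truncation = 0.05), 750)

  # fewer than two haplotypes: zero by convention
  expect_equal(integrated_ehh(matrix(0L, 1, 3), 1, c(1, 2, 3)), 0)
})

test_that("integrated EHH equals an independent trapezoid oracle", {
  set.seed(12)
  for (rep in 1:60) {
    K <- sample(4:8, 1)
    n_snp <- sample(5:20, 1)
    h <- random_haps(K, n_snp, freq = runif(1, 0.3, 0.7))
    pos <- sort(sample.int(5e5, n_snp))
    core <- sample(n_snp, 1)
    trunc <- runif(1, 0.02, 0.3)
    expect_equal(integrated_ehh(h, core, pos, trunc, 2e5),
                 brute_integrated_ehh(h, core, pos, trunc, 2e5))
  }
})

test_that("cross-population log-ratio is zero for identical groups and antisymmetric", {
  set.seed(13)
  block <- random_haps(8, 30)
  g <- two_groups(4, 4)
  panel <- hap_panel(rbind(block, block), g$sample_id)
  map <- data.frame(snp_id = paste0("s", 1:30), chrom = "chr1",
                    pos_bp = sort(sample.int(3e6, 30)))
  raw <- xpehh_scan(panel, g, map)
  expect_true(all(abs(raw[!is.na(raw)]) < 1e-12))

  sim <- simulate_sweep_panel(small_scenario(seed = 21))
  swapped <- sim$groups
  swapped$group <- ifelse(swapped$group == "SELECTED", "REFERENCE", "SELECTED")
  a <- xpehh_scan(sim$panel, sim$groups, sim$map)
  b <- xpehh_scan(sim$panel, swapped, sim$map)
  expect_equal(a, -b)
})

test_that("compiled genome scan agrees with the plain-R per-SNP path", {
  set.seed(14)
  sc <- sweep_scenario(n_snps = 120, n_chrom = 2, chrom_length_bp = 3e6,
                       n_samples_sel = 6, n_samples_ref = 6,
                       sweep_chrom = "chr1", sweep_pos_bp = 1.5e6, seed = 31)
  sim <- simulate_sweep_panel(sc)
  fast <- xpehh_scan(sim$panel, sim$groups, sim$map, 0.05, 8e5)
  slow <- vapply(seq_len(nrow(sim$map)), function(j) {
    xpehh_per_snp(sim$panel, sim$groups, sim$map, j, 0.05, 8e5)
  }, 0)
  expect_equal(fast, slow)
})

test_that("sweep haplotypes raise the raw log-ratio around the sweep locus", {
  sim <- simulate_sweep_panel(small_scenario(seed = 17))
  raw <- xpehh_scan(sim$panel, sim$groups, sim$map)
  near <- sim$map$chrom == sim$truth$sweep_chrom &
    abs(sim$map$pos_bp - sim$truth$sweep_pos_bp) <= 1e5
  expect_gt(mean(raw[near], na.rm = TRUE), mean(raw, na.rm = TRUE))
})
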