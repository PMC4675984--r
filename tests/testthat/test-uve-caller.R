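paired_from_counts <- function(mock, uv, bin_width = 250, chrom = "chr1") {
  compute_fuv(toy_track(mock, bin_width, total = max(sum(mock), 1), chrom),
              toy_track(uv, bin_width, total = max(sum(uv), 1), chrom))
}

test_that("UV read fractions treat each read as a Bernoulli trial", {
  p <- paired_from_counts(c(8, 3, 3, 0), c(0, 3, 9, 0))
  expect_equal(p$fuv, c(0, 0.5, 0.75, NA))
  expect_equal(p$n, c(8, 6, 12, 0))
  expect_equal(p$k, c(0, 3, 9, 0))
  # fractional scaled counts are rounded half-up
  p2 <- paired_from_counts(c(2.5), c(3.5))
  expect_equal(p2$k, 4)
  expect_equal(p2$n, 7)
  expect_error(
    compute_fuv(toy_track(c(1, 2), 250), toy_track(c(1, 2, 3), 250)),
    "grid")
})

test_that("UVR training pools deep gene-body bins of expressed genes", {
  # 30-kb gene: qualifying bins sit > 20 kb downstream of the TSS
  mock <- numeric(160)
  uv <- numeric(160)
  # gene A: [0, 30000) on '+': deep bins at [20000, 30000)
  mock[1:120] <- 5
  uv[(20000 / 250 + 1):(30000 / 250)] <- 0   # start clean
  # place (uv, mock) = (1, 9) and (3, 7) in two deep bins
  mock[81] <- 9; uv[81] <- 1
  mock[82] <- 7; uv[82] <- 3
  paired <- paired_from_counts(mock, uv)
  genes <- gene_set(tibble::tibble(
    gene_id = c("gA", "gShort", "gWeak"), chrom = "chr1",
    start = c(0, 31000, 34000), end = c(30000, 33000, 39500),
    strand = "+"))
  mock_track <- toy_track(mock, total = 1000)
  # gA RPKM = sum(mock in gene)/ (30 kb * 1e-3 M) -> comfortably over 0.25;
  # gShort is under 20 kb; gWeak has no reads
  cfg <- uve_config()
  tr <- collect_training_fuv(paired, genes, mock_track, cfg)
  expect_equal(tr$gene_id, "gA")
  # pooled over ALL deep bins of gA: uv 4 out of (4 + 16 + 5*38 zero-uv bins)
  deep <- which(paired$start >= 20000 & paired$end <= 30000)
  expect_equal(tr$fuv, sum(uv[deep]) / sum(uv[deep] + mock[deep]))

  # the two curated bins alone pool to 4/20
  two <- paired[81:82, ]
  expect_equal(sum(two$uv) / sum(two$uv + two$mock), 0.2)

  # an expression filter of 0.25 RPKM excludes weak genes
  weak_mock <- mock
  weak_mock[1:120] <- 0.01
  expect_error(
    collect_training_fuv(paired_from_counts(weak_mock, uv), genes,
                         toy_track(weak_mock, total = 1e6), cfg),
    "cannot train")
})

test_that("beta moment matching inverts mean and variance", {
  mk <- function(m, v, n = 64) {
    raw <- rep(c(-1, 1), n / 2)
    m + (raw - mean(raw)) * sqrt(v / var(raw))
  }
  p1 <- fit_beta_by_moments(mk(0.5, 0.025))
  expect_equal(p1$alpha, 4.5, tolerance = 1e-9)
  expect_equal(p1$beta, 4.5, tolerance = 1e-9)

  p2 <- fit_beta_by_moments(mk(0.2, 0.016))
  expect_equal(p2$alpha, 1.8, tolerance = 1e-9)
  expect_equal(p2$beta, 7.2, tolerance = 1e-9)
  # round-trip: the fitted beta reproduces the sample moments
  expect_equal(p2$alpha / (p2$alpha + p2$beta), 0.2, tolerance = 1e-9)

  expect_error(fit_beta_by_moments(rep(0.4, 5)), "variance")
  expect_error(fit_beta_by_moments(c(0.01, 0.99, 0.01, 0.99)),
               "Bernoulli")
  expect_error(fit_beta_by_moments(c(0, 0.5, 0.7)), "strictly")
})

test_that("beta parameters recover from seeded draws within 5%", {
  set.seed(9)
  fit <- fit_beta_by_moments(rbeta(1e5, 3, 7))
  expect_lt(abs(fit$alpha - 3) / 3, 0.05)
  expect_lt(abs(fit$beta - 7) / 7, 0.05)
})

test_that("reflection swaps shapes and is an involution", {
  p <- beta_params(1.8, 7.2)
  r <- reflect_beta(p)
  expect_equal(r$alpha, 7.2)
  expect_equal(r$beta, 1.8)
  expect_equal(reflect_beta(r), p)
  sym <- beta_params(4.5, 4.5)
  expect_equal(reflect_beta(sym), sym)
})

test_that("beta-binomial log-pmf is exact, normalized, and reflective", {
  # alpha = beta = 1 makes the counts uniform on 0..n
  expect_equal(beta_binomial_log_pmf(1, 2, beta_params(1, 1)), log(1 / 3))
  expect_equal(beta_binomial_log_pmf(0, 0, beta_params(1.8, 7.2)), 0)
  expect_error(beta_binomial_log_pmf(3, 2, beta_params(1, 1)), "k <= n")

  p <- beta_params(1.8, 7.2)
  expect_equal(sum(exp(beta_binomial_log_pmf(0:12, 12, p))), 1,
               tolerance = 1e-12)

  # normalization and reflection identity over a parameter grid, n <= 30
  for (a in c(0.3, 1, 2.7)) {
    for (b in c(0.5, 1, 8)) {
      prm <- beta_params(a, b)
      for (n in c(1, 7, 30)) {
        k <- 0:n
        expect_equal(sum(exp(beta_binomial_log_pmf(k, n, prm))), 1,
                     tolerance = 1e-10)
        expect_equal(beta_binomial_log_pmf(k, n, reflect_beta(prm)),
                     beta_binomial_log_pmf(n - k, n, prm),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("two-state Viterbi attains the exhaustively enumerated optimum", {
  set.seed(19)
  for (rep in 1:60) {
    L <- sample(1:10, 1)
    le <- matrix(rnorm(2 * L), ncol = 2)
    p <- runif(1, 0.001, 0.4)
    path <- bruuv:::viterbi_two_state(le, p)
    expect_equal(score_two_state_path(path, le, p),
                 enumerate_two_state_max(le, p), tolerance = 1e-9)
  }
})

test_that("segmentation recovers planted high-fraction blocks as peaks", {
  uvr <- beta_params(1.8, 7.2)
  uve <- reflect_beta(uvr)

  # background at the UVR mean: no peaks at all
  set.seed(29)
  n <- rep(20, 40)
  k_bg <- rbinom(40, 20, 0.2)
  bg <- paired_from_counts(20 - k_bg, k_bg)
  seg0 <- segment_uve(bg, uvr, uve, 0.005)
  expect_equal(nrow(seg0$peaks), 0)

  # a 10-bin block at f = 0.9 on that background: one peak, exact extent
  k2 <- k_bg
  k2[16:25] <- 18
  blk <- paired_from_counts(20 - k2, k2)
  seg1 <- segment_uve(blk, uvr, uve, 0.005)
  expect_equal(nrow(seg1$peaks), 1)
  expect_equal(seg1$peaks$start, 15 * 250)
  expect_equal(seg1$peaks$end, 25 * 250)
  expect_equal(seg1$peaks$n_bins, 10)
  expect_gt(seg1$peaks$mean_fuv, 0.8)

  # matches brute-force decoding over all 2^L paths on a short instance
  sub <- blk[10:25, ]
  le <- cbind(beta_binomial_log_pmf(sub$k, sub$n, uvr),
              beta_binomial_log_pmf(sub$k, sub$n, uve))
  path <- bruuv:::viterbi_two_state(le, 0.005)
  expect_equal(score_two_state_path(path, le, 0.005),
               enumerate_two_state_max(le, 0.005), tolerance = 1e-9)

  # two blocks separated by background: two disjoint peaks
  k3 <- k_bg
  k3[5:8] <- 19
  k3[20:24] <- 19
  two <- paired_from_counts(20 - k3, k3)
  seg2 <- segment_uve(two, uvr, uve, 0.005)
  expect_equal(nrow(seg2$peaks), 2)
  expect_true(all(seg2$peaks$end[-nrow(seg2$peaks)] <=
                    seg2$peaks$start[-1]))
})

test_that("zero-coverage bins never enter peaks", {
  uvr <- beta_params(1.8, 7.2)
  uve <- reflect_beta(uvr)
  mock <- c(rep(2, 5), rep(0, 6), rep(2, 5))
  uv <- c(rep(18, 5), rep(0, 6), rep(18, 5))
  seg <- segment_uve(paired_from_counts(mock, uv), uvr, uve, 0.005)
  expect_equal(nrow(seg$peaks), 2)
  expect_true(all(seg$peaks$n_bins == 5))
})

test_that("swapping the sample labels complements the segmentation", {
  uvr <- beta_params(1.8, 7.2)
  uve <- reflect_beta(uvr)
  set.seed(37)
  k <- rbinom(60, 25, rep(c(0.2, 0.8), each = 30))
  fwd <- segment_uve(paired_from_counts(25 - k, k), uvr, uve, 0.005)
  # same state distributions on the relabelled pair: states flip
  swp <- segment_uve(paired_from_counts(k, 25 - k), uvr, uve, 0.005)
  expect_equal(fwd$states$state == "UVE", swp$states$state == "UVR")
  # relabelling AND reflecting both distributions restores the original
  dbl <- segment_uve(paired_from_counts(k, 25 - k),
                     reflect_beta(uvr), reflect_beta(uve), 0.005)
  expect_equal(dbl$states$state, fwd$states$state)
})

test_that("intergenic filtering uses half-open single-base overlap", {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(1000, 50000, 7999),
                          end = c(1500, 50500, 8500))
  genes <- tibble::tibble(chrom = "chr1", start = c(500, 8499),
                          end = c(2000, 9000))
  out <- filter_intergenic(peaks, genes)
  expect_equal(out$intergenic, c(FALSE, TRUE, FALSE))
  # exactly one shared base (peak end 8500 vs gene start 8499) counts
  expect_false(out$intergenic[3])
  only <- filter_intergenic(peaks, genes, intergenic_only = TRUE)
  expect_equal(nrow(only), 1)
})

test_that("the full pair pipeline trains, segments and annotates peaks", {
  genome <- sim_genome(n_genes = 30, n_enhancers = 10, seed = 51)
  sim <- simulate_paired_tracks(genome, lesion_model(dose_J = 25),
                                depth_mock = 4e5, depth_uv = 4e5, seed = 52)
  fit <- call_uve_peaks(sim$mock, sim$uv, genome$genes)
  gl <- glance(fit)
  expect_gt(gl$n_training_genes, 5)
  expect_lt(gl$mean_fuv_uvr, 0.2)
  peaks <- tidy(fit)
  expect_true(all(peaks$start %% 250 == 0))
  expect_true(all(diff(peaks$start[peaks$chrom == peaks$chrom[1]]) > 0))
  # every true enhancer centre falls inside an intergenic peak
  hit <- vapply(genome$enhancers$center, function(cc) {
    any(peaks$intergenic & peaks$start <= cc & peaks$end > cc)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
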