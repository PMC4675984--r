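# three long '+' genes with flat per-gene coverage; per-bin RPKMs differ
# by gene so medians and heat-map scalings are hand-checkable
profile_fixture <- function(levels = c(10, 20, 90), len = 70000,
                            gap = 10000, bin = 250) {
  n <- length(levels)
  span <- len + gap
  nbins <- (n * span + 20000) / bin
  counts <- numeric(nbins)
  genes <- tibble::tibble(
    gene_id = sprintf("p%d", seq_len(n)), chrom = "chrP",
    start = 10000 + (seq_len(n) - 1) * span,
    end = 10000 + (seq_len(n) - 1) * span + len, strand = "+")
  for (i in seq_len(n)) {
    b <- (genes$start[i] %/% bin):((genes$end[i] - 1) %/% bin)
    counts[b + 1] <- levels[i]
  }
  list(track = toy_track(counts, bin, total = 1e6, chrom = "chrP"),
       genes = gene_set(genes))
}

test_that("aggregate profiles take per-bin medians and unit self-normalization", {
  fx <- profile_fixture()
  # against itself the normalized profile is 1 everywhere the reference is
  self <- aggregate_tss_profile(fx$track, fx$genes, min_rpkm = 0.1)
  inside <- self$offset >= 0 & self$offset < 60000
  expect_true(all(abs(self$value[inside] - 1) < 1e-9))
  expect_equal(attr(self, "n_regions"), 3)

  # unnormalized: median of per-gene per-bin RPKM; bins carry {10,20,90}
  raw <- aggregate_tss_profile(fx$track, fx$genes, min_rpkm = 0.1,
                               normalize = FALSE)
  expected <- 20 / ((250 / 1000) * (1e6 / 1e6))   # median count as RPKM
  expect_equal(raw$value[raw$offset == 10000], expected)

  # a 50-kb gene is excluded under the 60-kb default
  short <- profile_fixture(levels = c(10, 20), len = 50000)
  expect_error(aggregate_tss_profile(short$track, short$genes,
                                     min_rpkm = 0.1), "filters")
})

test_that("heat-map rows are min-max scaled and sorted by first-5-kb signal", {
  fx <- profile_fixture()
  hm <- heatmap_matrix(fx$track, fx$genes, min_rpkm = 0.1, bin = 1000)
  expect_true(all(hm$values >= 0 & hm$values <= 1))
  expect_setequal(hm$genes$gene_id, fx$genes$gene_id)

  # flat-coverage genes all scale identically here; perturb one gene to a
  # promoter-skewed shape and it must sort first
  counts <- fx$track$count
  g1 <- fx$genes[1, ]
  b <- (g1$start %/% 1000):((g1$start + 4000) %/% 1000)
  counts[(b * 4) + 1] <- 500   # boost first 5 kb of gene 1 (250-bp bins)
  trk2 <- toy_track(counts, 250, total = 1e6, chrom = "chrP")
  hm2 <- heatmap_matrix(trk2, fx$genes, reference = fx$track,
                        min_rpkm = 0.1, bin = 1000)
  expect_equal(hm2$genes$gene_id[1], "p1")
  expect_equal(min(hm2$values[1, ]), 0)
  expect_equal(max(hm2$values[1, ]), 1)

  # constant rows degrade to zero and sort last
  counts3 <- fx$track$count
  g3 <- fx$genes[3, ]
  sel <- fx$track$start >= g3$start - 2000 & fx$track$start < g3$end
  counts3[sel] <- 7
  trk3 <- toy_track(counts3, 250, total = 1e6, chrom = "chrP")
  hm3 <- heatmap_matrix(trk3, fx$genes, reference = fx$track,
                        min_rpkm = 0.1, bin = 1000)
  expect_equal(hm3$genes$gene_id[nrow(hm3$genes)], "p3")
  expect_true(all(hm3$values[nrow(hm3$values), ] == 0))
})

test_that("first-5-kb fold changes follow the pseudocount definition", {
  fx <- profile_fixture()
  same <- fold_change_first_5kb(fx$track, fx$track, fx$genes)
  expect_true(all(same$fold == 1))

  # doubling counts and totals together leaves RPKM and folds unchanged
  dbl <- fx$track
  dbl$count <- dbl$count * 2
  attr(dbl, "total_reads") <- 2e6
  expect_true(all(fold_change_first_5kb(fx$track, dbl, fx$genes)$fold == 1))

  # rpkm_a = 1.75, rpkm_b = 48.75, c = 0.25 -> fold = 49 / 2 = 24.5
  a <- toy_track(rep(1.75 * 5 / 20, 20), 250, total = 1e6)
  b <- toy_track(rep(48.75 * 5 / 20, 20), 250, total = 1e6)
  g5 <- gene_set(tibble::tibble(gene_id = "g", chrom = "chr1", start = 0,
                                end = 5000, strand = "+"))
  fc <- fold_change_first_5kb(a, b, g5)
  expect_equal(fc$rpkm_a, 1.75)
  expect_equal(fc$rpkm_b, 48.75)
  expect_equal(fc$fold, 24.5)

  # antisymmetry under swapping tracks (exact with the shared pseudocount)
  other <- fx$track
  other$count <- rev(other$count) + 3
  fc_ab <- fold_change_first_5kb(fx$track, other, fx$genes)
  fc_ba <- fold_change_first_5kb(other, fx$track, fx$genes)
  expect_equal(fc_ab$fold, 1 / fc_ba$fold)

  # genes shorter than the span fall back to full length and are flagged
  gshort <- gene_set(tibble::tibble(gene_id = "s", chrom = "chrP",
                                    start = 10000, end = 13000,
                                    strand = "+"))
  expect_true(fold_change_first_5kb(fx$track, fx$track, gshort)$short)
})

test_that("peaks are assigned to the gene with the nearest TSS", {
  genes <- gene_set(tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(10000, 50000), end = c(30000, 70000), strand = "+"))
  peaks <- tibble::tibble(chrom = "chr1", start = c(10500, 29000),
                          end = c(11500, 31000))
  out <- nearest_gene_assignment(peaks, genes)
  expect_equal(out$gene_id, c("gA", "gA"))
  expect_equal(out$distance[1], 1000)

  # equidistant: lexicographically smaller gene id wins
  mid <- tibble::tibble(chrom = "chr1", start = 29999, end = 30001)
  expect_equal(nearest_gene_assignment(mid, genes)$gene_id, "gA")

  # a peak inside gA's body but nearer gB's TSS goes to gB
  inner <- tibble::tibble(chrom = "chr1", start = 29000, end = 36000)
  expect_equal(nearest_gene_assignment(inner, genes)$gene_id, "gB")

  expect_error(nearest_gene_assignment(peaks, genes[0, ]), "empty")
})

test_that("eRNA/gene change correlation is plain Pearson with guards", {
  x <- c(0.3, -1.2, 2.0, 0.1, 0.9, -0.5, 1.4, -2.2, 0.0, 0.7)
  expect_equal(erna_gene_change_correlation(x, x), 1)
  expect_equal(erna_gene_change_correlation(x, -x), -1)
  y <- c(0.5, -0.9, 1.4, 0.6, 1.2, -0.1, 0.8, -1.9, 0.2, 0.4)
  # frozen from an independent computation of the product-moment formula
  expect_equal(erna_gene_change_correlation(x, y), 0.9549909441,
               tolerance = 1e-8)
  # invariant under affine rescaling
  expect_equal(erna_gene_change_correlation(2 * x + 3, y),
               erna_gene_change_correlation(x, y))
  expect_error(erna_gene_change_correlation(x, rep(1, 10)), "variance")
  expect_error(erna_gene_change_correlation(1:2, 1:2), "3 paired")
})

test_that("downsampling CV is zero at full depth and shrinks with depth", {
  gc <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                       count = rep(c(2000L, 150L, 30L, 0L), 10),
                       length = rep(c(60000, 20000, 8000, 10000), 10))
  total <- 500000
  cv <- downsampling_cv(gc, total, depths = c(20000, 100000, total),
                        reps = 10, seed = 8)
  full <- cv[cv$depth == total, ]
  expect_true(all(full$cv == 0))
  # the zero-count genes never yield reads: dropped at every depth
  expect_false(any(cv$gene_id %in% sprintf("g%02d", seq(4, 40, 4))))
  expect_gt(attr(cv, "n_dropped"), 0)
  med <- tapply(cv$cv, cv$depth, median)
  expect_gt(med[["20000"]], med[["1e+05"]])
  expect_error(downsampling_cv(gc, total, depths = total + 1), "exceeds")
})
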