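# strand-oriented anchor windows: bin with offset o covers
#   '+' : [tss + o, tss + o + w)      '-' : [tss + 1 - o - w, tss + 1 - o)
# so offsets increase 5'->3' along the gene; off-chromosome bins are
# zero-filled and the row flagged
window_matrix <- function(track, genes, offsets, w) {
  sizes <- chrom_sizes(track)
  rows <- purrr::pmap(
    list(genes$chrom, genes$tss, genes$strand),
    function(chrom, tss, strand) {
      s <- if (strand == "+") tss + offsets else tss + 1 - offsets - w
      e <- s + w
      inside <- s >= 0 & e <= sizes[[chrom]]
      vals <- numeric(length(offsets))
      if (any(inside)) {
        vals[inside] <- region_mass(track, chrom, s[inside], e[inside])
      }
      list(vals = vals, clipped = any(!inside))
    })
  values <- do.call(rbind, purrr::map(rows, "vals"))
  rownames(values) <- genes$tss_id
  list(values = values, clipped = purrr::map_lgl(rows, "clipped"))
}

filter_profile_genes <- function(genes, reference, min_gene_len, min_rpkm) {
  keep <- (genes$end - genes$start) >= min_gene_len
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) > 0) {
    genes <- genes[compute_rpkm(reference, genes) >= min_rpkm, , drop = FALSE]
  }
  assert_that(nrow(genes) > 0, "no gene passes the length/expression filters")
  genes
}

#' TSS-anchored aggregate signal profile
#'
#' Long, expressed genes (length and RPKM filters applied on the
#' reference/mock track) are aligned by their annotated TSS; for every bin
#' offset the median across genes of the per-gene per-bin RPKM is
#' reported, optionally divided bin-wise by the same profile of the
#' reference track — so the reference normalized against itself is the
#' unit profile.
#'
#' @param track [bruuv_track()] to profile.
#' @param genes a [gene_set()].
#' @param reference [bruuv_track()] used for gene selection and (when
#'   `normalize = TRUE`) bin-wise normalization; defaults to `track`.
#' @param span_up,span_down window extent around the TSS, bp.
#' @param bin profile bin width, bp.
#' @param min_gene_len,min_rpkm gene filters (defaults 60 kb and 1 RPKM,
#'   evaluated on the reference track over the whole gene).
#' @param normalize divide by the reference profile bin-wise.
#' @return A `bruuv_profile` tibble (`offset`, `value`) with attributes
#'   `n_regions` and `normalized`; has an [autoplot()] method.
#' @export
aggregate_tss_profile <- function(track, genes, reference = track,
                                  span_up = 2000, span_down = 60000,
                                  bin = 250, min_gene_len = 60000,
                                  min_rpkm = 1, normalize = TRUE) {
  genes <- filter_profile_genes(genes, reference, min_gene_len, min_rpkm)
  offsets <- seq(-span_up, span_down - bin, by = bin)
  to_rpkm <- function(trk) {
    window_matrix(trk, genes, offsets, bin)$values /
      ((bin / 1000) * (total_reads(trk) / 1e6))
  }
  prof <- apply(to_rpkm(track), 2, median)
  if (normalize) {
    ref_prof <- apply(to_rpkm(reference), 2, median)
    prof <- ifelse(ref_prof > 0, prof / ref_prof, NA_real_)
  }
  out <- tibble(offset = offsets, value = prof)
  attr(out, "n_regions") <- nrow(genes)
  attr(out, "normalized") <- normalize
  class(out) <- c("bruuv_profile", class(out))
  out
}

#' Per-gene TSS-anchored heat-map matrix
#'
#' Applies the same gene filters as [aggregate_tss_profile()], min-max
#' scales each gene's row to `[0, 1]` (constant rows become all zeros) and
#' sorts rows in decreasing order of the summed scaled signal over the
#' first 5 kb downstream of the TSS, so the most promoter-concentrated
#' genes come first.
#'
#' @inheritParams aggregate_tss_profile
#' @param bin heat-map bin width, bp (coarser than the profile default).
#' @return A `bruuv_heatmap` object: list with `values` (genes x bins,
#'   sorted), `bin_offsets` and `genes` (in display order). Has an
#'   [autoplot()] method.
#' @export
heatmap_matrix <- function(track, genes, reference = track,
                           span_up = 2000, span_down = 60000, bin = 1000,
                           min_gene_len = 60000, min_rpkm = 1) {
  genes <- filter_profile_genes(genes, reference, min_gene_len, min_rpkm)
  offsets <- seq(-span_up, span_down - bin, by = bin)
  vals <- window_matrix(track, genes, offsets, bin)$values
  scaled <- t(apply(vals, 1, function(r) {
    rng <- diff(range(r))
    if (rng == 0) rep(0, length(r)) else (r - min(r)) / rng
  }))
  first5 <- offsets >= 0 & offsets < 5000
  ord <- order(rowSums(scaled[, first5, drop = FALSE]), decreasing = TRUE)
  structure(list(values = scaled[ord, , drop = FALSE],
                 bin_offsets = offsets,
                 genes = genes[ord, , drop = FALSE]),
            class = "bruuv_heatmap")
}

#' First-5-kb fold change between two samples
#'
#' Measures each gene's RPKM over the strand-aware first `span` bp
#' downstream of the TSS in both tracks and reports
#' `fold = (rpkm_b + pseudocount) / (rpkm_a + pseudocount)` — the
#' promoter-proximal surrogate for whole-gene expression change that the
#' UV-redistributed signal supports. Genes shorter than `span` fall back
#' to their full length and are flagged. `whole_gene = TRUE` uses the full
#' gene interval instead (the conventional nascent-RNA measure, for the
#' non-UV side of a comparison).
#'
#' @param track_a,track_b [bruuv_track()]s (e.g. control and treated).
#' @param genes a [gene_set()].
#' @param pseudocount RPKM added to both sides to stabilize low-expression
#'   ratios.
#' @param span bp measured downstream of the TSS.
#' @param whole_gene measure over the whole gene instead.
#' @return Tibble: `gene_id`, `tss_id`, `rpkm_a`, `rpkm_b`, `fold`,
#'   `short` (gene shorter than `span`).
#' @export
fold_change_first_5kb <- function(track_a, track_b, genes,
                                  pseudocount = 0.25, span = 5000,
                                  whole_gene = FALSE) {
  g <- as_tibble(genes)
  if (whole_gene) {
    iv <- select(g, "chrom", "start", "end")
    short <- rep(FALSE, nrow(g))
  } else {
    len <- g$end - g$start
    short <- len < span
    eff <- pmin(span, len)
    iv <- tibble(chrom = g$chrom,
                 start = ifelse(g$strand == "+", g$tss, g$tss + 1 - eff),
                 end = ifelse(g$strand == "+", g$tss + eff, g$tss + 1))
  }
  rpkm_a <- compute_rpkm(track_a, iv)
  rpkm_b <- compute_rpkm(track_b, iv)
  tibble(gene_id = g$gene_id, tss_id = g$tss_id,
         rpkm_a = rpkm_a, rpkm_b = rpkm_b,
         fold = (rpkm_b + pseudocount) / (rpkm_a + pseudocount),
         short = short)
}

#' Assign peaks to their nearest gene
#'
#' Distance is measured from the peak midpoint to the gene TSS on the same
#' chromosome, strand-agnostic (the biological claim summarized is
#' eRNA-promoter pairing, so the promoter is the anchor, not the gene-body
#' edge). Ties go to the lexicographically smaller `gene_id`; peaks on
#' chromosomes without genes get `NA`.
#'
#' @param peaks tibble with `chrom`, `start`, `end`.
#' @param genes a [gene_set()].
#' @return `peaks` with `gene_id` and `distance` columns appended.
#' @export
nearest_gene_assignment <- function(peaks, genes) {
  assert_that(nrow(genes) > 0, "empty gene set")
  mid <- (peaks$start + peaks$end) / 2
  hits <- purrr::map2(peaks$chrom, mid, function(chrom, m) {
    cand <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(list(gene_id = NA_character_, distance = NA_real_))
    }
    d <- abs(m - cand$tss)
    best <- order(d, cand$gene_id)[1]
    list(gene_id = cand$gene_id[best], distance = d[best])
  })
  peaks %>%
    mutate(gene_id = purrr::map_chr(hits, "gene_id"),
           distance = purrr::map_dbl(hits, "distance"))
}

#' Correlation between eRNA and gene expression changes
#'
#' Plain Pearson correlation of paired per-peak and per-(nearest-)gene
#' changes, typically log2 fold changes from [fold_change_first_5kb()]
#' after [nearest_gene_assignment()].
#'
#' @param peak_change,gene_change paired numeric vectors (length >= 3,
#'   both with positive variance); `NA` pairs are dropped.
#' @return The Pearson correlation coefficient.
#' @export
erna_gene_change_correlation <- function(peak_change, gene_change) {
  assert_that(length(peak_change) == length(gene_change),
              "inputs must be paired")
  ok <- is.finite(peak_change) & is.finite(gene_change)
  peak_change <- peak_change[ok]
  gene_change <- gene_change[ok]
  assert_that(length(peak_change) >= 3, "need at least 3 paired values")
  assert_that(var(peak_change) > 0 && var(gene_change) > 0,
              "zero variance in one of the variables")
  cor(peak_change, gene_change, method = "pearson")
}

# multivariate hypergeometric draw: subsample `depth` reads without
# replacement from categories with integer counts `counts` (sum >= depth)
rmvhyper <- function(counts, depth) {
  pool <- sum(counts)
  out <- integer(length(counts))
  remaining <- depth
  for (i in seq_along(counts)) {
    if (remaining == 0) break
    pool <- pool - counts[i]
    out[i] <- rhyper(1, counts[i], pool, remaining)
    remaining <- remaining - out[i]
  }
  out
}

#' Quantification stability under downsampling
#'
#' Subsamples the library without replacement to each requested depth
#' (`reps` independent draws per depth), recomputes per-gene RPKM over
#' each gene's effective length, and reports the coefficient of variation
#' (standard deviation / mean) across replicates per gene and depth.
#' Reads not assigned to any gene are carried as an unassigned category so
#' the subsampling acts on the whole library. At the full library depth
#' every draw returns the library itself and the CV is exactly 0.
#'
#' @param gene_counts tibble with `gene_id`, `count` (integer reads
#'   assigned to the gene's quantified region) and `length` (bp of that
#'   region: whole gene for steady-state-style input, first 5 kb for
#'   UV-redistributed input).
#' @param total_reads library size; must be at least `sum(count)` and at
#'   least every requested depth.
#' @param depths read depths to simulate.
#' @param reps subsamples per depth.
#' @param seed optional RNG seed.
#' @return Tibble `depth`, `gene_id`, `cv`; genes with zero reads in all
#'   replicates at a depth are dropped (their number is in attribute
#'   `n_dropped`).
#' @export
downsampling_cv <- function(gene_counts, total_reads, depths, reps = 10,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.integer(gene_counts$count)
  assert_that(all(counts >= 0) && total_reads >= sum(counts),
              "`total_reads` must be >= the assigned read total")
  assert_that(all(depths <= total_reads), "depth exceeds library size")
  all_counts <- c(counts, total_reads - sum(counts))
  dropped <- 0L
  out <- purrr::map(depths, function(d) {
    draws <- replicate(reps, {
      x <- rmvhyper(all_counts, d)[seq_along(counts)]
      x / ((gene_counts$length / 1000) * (d / 1e6))   # RPKM
    })
    if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
    mu <- rowMeans(draws)
    keep <- mu > 0
    dropped <<- dropped + sum(!keep)
    tibble(depth = d, gene_id = gene_counts$gene_id[keep],
           cv = apply(draws[keep, , drop = FALSE], 1, sd) / mu[keep])
  }) %>% bind_rows()
  attr(out, "n_dropped") <- dropped
  out
}
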