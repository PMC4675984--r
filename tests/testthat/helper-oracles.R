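# Independent oracles and small builders used across the suite.

# best monotone path by explicit enumeration of all n+1 candidates,
# ties broken toward the most upstream switch (smallest state-1 prefix)
enumerate_monotone_best <- function(obs, params, p) {
  n <- length(obs)
  ll1 <- dnorm(obs, params$state1[["mean"]], params$state1[["sd"]], log = TRUE)
  ll2 <- dnorm(obs, params$state2[["mean"]], params$state2[["sd"]], log = TRUE)
  best <- -Inf
  best_k <- NA
  for (k in 0:n) {
    sc <- sum(ll1[seq_len(k)]) + sum(ll2[seq_len(n - k) + k]) +
      (if (k < n) k * log1p(-p) + log(p) else n * log1p(-p))
    if (sc > best + 1e-12) {
      best <- sc
      best_k <- k
    }
  }
  rep(c(1L, 2L), times = c(best_k, n - best_k))
}

# cache of all binary state paths of length L (rows = paths, entries 1/2)
.path_cache <- new.env(parent = emptyenv())
all_paths <- function(L) {
  key <- as.character(L)
  if (is.null(.path_cache[[key]])) {
    m <- as.matrix(expand.grid(rep(list(1:2), L)))
    dimnames(m) <- NULL
    .path_cache[[key]] <- m
  }
  .path_cache[[key]]
}

# max log-probability over all 2^L paths of a symmetric 2-state HMM
enumerate_two_state_max <- function(log_emissions, p, log_init = log(c(0.5, 0.5))) {
  L <- nrow(log_emissions)
  P <- all_paths(L)
  score <- log_init[P[, 1]] +
    rowSums((P == 1) * matrix(log_emissions[, 1], nrow(P), L, byrow = TRUE) +
              (P == 2) * matrix(log_emissions[, 2], nrow(P), L, byrow = TRUE))
  if (L > 1) {
    switches <- rowSums(P[, -1, drop = FALSE] != P[, -L, drop = FALSE])
    score <- score + switches * log(p) + (L - 1 - switches) * log1p(-p)
  }
  max(score)
}

score_two_state_path <- function(path, log_emissions, p,
                                 log_init = log(c(0.5, 0.5))) {
  L <- length(path)
  s <- log_init[path[1]] + sum(log_emissions[cbind(seq_len(L), path)])
  if (L > 1) {
    sw <- sum(path[-1] != path[-L])
    s <- s + sw * log(p) + (L - 1 - sw) * log1p(-p)
  }
  s
}

# reference quantile normalization written independently of the package
naive_quantile_normalize <- function(mat) {
  ref <- rowMeans(apply(mat, 1, sort))
  t(apply(mat, 1, function(r) {
    out <- numeric(length(r))
    for (v in unique(r)) {
      idx <- which(r == v)
      rnk <- which(sort(r) == v)
      out[idx] <- mean(ref[rnk])
    }
    out
  }))
}

# read mass of a track over a set of intervals
region_mass_of <- function(track, iv) {
  purrr::pmap_dbl(list(iv$chrom, iv$start, iv$end),
                  function(c, s, e) bruuv:::region_mass(track, c, s, e))
}

# one-chromosome track from a bare count vector
toy_track <- function(counts, bin_width = 250, total = sum(counts),
                      chrom = "chr1") {
  bruuv_track(setNames(list(counts), chrom), bin_width, total_reads = total)
}

# evenly spaced single-TSS genes for caller tests
toy_gene_panel <- function(n, spacing = 20000, len = 12000, start0 = 100000,
                           chrom = "chrT", strand = "+") {
  gene_set(tibble::tibble(
    gene_id = sprintf("t%03d", seq_len(n)),
    tss_id = sprintf("t%03d", seq_len(n)),
    chrom = chrom,
    start = start0 + (seq_len(n) - 1) * spacing,
    end = start0 + (seq_len(n) - 1) * spacing + len,
    strand = strand))
}

# probe pair of isoform TSSs d apart plus a background gene population,
# with the caller's resolution measured as "both probe TSSs active"
resolution_both_active <- function(d, seed, n_bg = 60, baseline = 20,
                                   effect_sd = 5) {
  bg <- tibble::tibble(
    gene_id = sprintf("b%03d", seq_len(n_bg)),
    tss_id = sprintf("b%03d", seq_len(n_bg)),
    chrom = "chrT", start = 100000 + (seq_len(n_bg) - 1) * 20000,
    end = 100000 + (seq_len(n_bg) - 1) * 20000 + 12000, strand = "+")
  iso <- tibble::tibble(gene_id = "gA", tss_id = c("i1", "i2"),
                        chrom = "chrT", start = c(10000, 10000 + d),
                        end = 80000, strand = "+")
  merged <- merge_isoform_tss(gene_set(dplyr::bind_rows(iso, bg)))
  if (sum(merged$gene_id == "gA") < 2) return(FALSE)
  merged$active <- merged$gene_id == "gA" | (seq_len(nrow(merged)) %% 2 == 0)
  trk <- simulate_tss_step_track(merged, effect_sd = effect_sd,
                                 baseline = baseline, seed = seed)
  calls <- tidy(call_active_tss(trk, dplyr::select(merged, -"active")))
  sum(calls$active[calls$gene_id == "gA"]) == 2
}
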