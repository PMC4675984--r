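#' Configuration of the UV-enhancement HMM
#'
#' @param bin_width analysis bin width, bp.
#' @param rpkm_min minimum mock-sample gene RPKM for a gene to contribute
#'   training bins for the UV-repressed state.
#' @param tss_exclusion_bp genic bins closer than this to the TSS are
#'   excluded from training (the UV-enhanced region hugs the TSS).
#' @param p_transition symmetric per-step probability of switching between
#'   the UVR and UVE states.
#' @param training `"pooled"` (default: per-gene cumulative UV fraction,
#'   summed UV reads over summed totals) or `"per_bin_mean"` (mean of the
#'   gene's per-bin fractions).
#' @param smooth_level wavelet decomposition depth passed to
#'   [smooth_track()]; `NULL` picks it automatically.
#' @return A `bruuv_uve_config` list.
#' @export
uve_config <- function(bin_width = 250, rpkm_min = 0.25,
                       tss_exclusion_bp = 20000, p_transition = 0.005,
                       training = c("pooled", "per_bin_mean"),
                       smooth_level = NULL) {
  cfg <- list(bin_width = bin_width, rpkm_min = rpkm_min,
              tss_exclusion_bp = tss_exclusion_bp,
              p_transition = p_transition,
              training = match.arg(training),
              smooth_level = smooth_level)
  assert_that(p_transition > 0 && p_transition < 1,
              "`p_transition` must lie in (0, 1)")
  class(cfg) <- "bruuv_uve_config"
  cfg
}

#' Per-bin UV read fraction of a depth-matched track pair
#'
#' With both libraries at common depth, each read in a bin is a Bernoulli
#' trial for "came from the UV sample"; `fuv = uv / (uv + mock)` on the
#' scaled counts is its empirical success fraction. Scaled counts are
#' rounded half-up to integers (`k` UV successes out of `n` trials) for
#' the beta-binomial emissions; bins with zero total carry no trials and
#' `fuv` is missing there.
#'
#' @param mock,uv [bruuv_track()]s on identical bin grids, already
#'   smoothed and scaled to common depth (see [smooth_track()],
#'   [scale_pair_to_common_depth()]).
#' @return A `bruuv_paired` tibble: `chrom`, `start`, `end`, `mock`, `uv`,
#'   `fuv`, `k`, `n`, with the pair's `bin_width` as an attribute.
#' @export
compute_fuv <- function(mock, uv) {
  assert_that(bin_width(mock) == bin_width(uv) &&
                identical(chrom_sizes(mock), chrom_sizes(uv)),
              "mock and uv tracks must share their bin grid")
  assert_that(identical(mock$chrom, uv$chrom) &&
                identical(mock$start, uv$start),
              "mock and uv tracks must share their bin grid")
  mock_c <- mock$count
  uv_c <- uv$count
  total <- mock_c + uv_c
  paired <- tibble(chrom = mock$chrom, start = mock$start, end = mock$end,
                   mock = mock_c, uv = uv_c,
                   fuv = ifelse(total > 0, uv_c / total, NA_real_),
                   k = round_half_up(uv_c),
                   n = round_half_up(uv_c) + round_half_up(mock_c))
  attr(paired, "bin_width") <- bin_width(mock)
  class(paired) <- c("bruuv_paired", class(paired))
  paired
}

#' Cumulative UV read fraction in the presumptive UV-repressed gene bodies
#'
#' For every gene expressed at `rpkm_min` or more in the mock sample and
#' longer than `tss_exclusion_bp`, pools the bins lying fully inside the
#' gene and more than `tss_exclusion_bp` downstream of the TSS
#' (strand-aware) and returns the pooled fraction
#' `sum(uv) / sum(uv + mock)` per gene — the training observable for the
#' UVR state. Genes without qualifying read mass are dropped.
#'
#' @param paired output of [compute_fuv()].
#' @param genes a [gene_set()].
#' @param mock_track the unsmoothed mock [bruuv_track()] used for the
#'   RPKM expression filter.
#' @param cfg a [uve_config()].
#' @return Tibble with `gene_id` and `fuv` (plus `n_bins` pooled).
#' @export
collect_training_fuv <- function(paired, genes, mock_track,
                                 cfg = uve_config()) {
  w <- attr(paired, "bin_width")
  long_enough <- (genes$end - genes$start) > cfg$tss_exclusion_bp
  genes <- genes[long_enough, , drop = FALSE]
  if (nrow(genes) > 0) {
    rpkm <- compute_rpkm(mock_track, genes)
    genes <- genes[rpkm >= cfg$rpkm_min, , drop = FALSE]
  }
  out <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$start, genes$end,
         genes$strand, genes$tss),
    function(gene_id, chrom, start, end, strand, tss) {
      if (strand == "+") {
        lo <- tss + cfg$tss_exclusion_bp
        hi <- end
      } else {
        lo <- start
        hi <- tss + 1 - cfg$tss_exclusion_bp
      }
      sel <- paired$chrom == chrom & paired$start >= lo & paired$end <= hi
      if (!any(sel)) return(NULL)
      uv <- paired$uv[sel]
      tot <- paired$uv[sel] + paired$mock[sel]
      if (sum(tot) <= 0) return(NULL)
      f <- if (cfg$training == "pooled") {
        sum(uv) / sum(tot)
      } else {
        mean(paired$fuv[sel], na.rm = TRUE)
      }
      tibble(gene_id = gene_id, fuv = f, n_bins = sum(sel))
    })
  out <- bind_rows(purrr::compact(out))
  assert_that(nrow(out) > 0,
              "cannot train UVR state: no qualifying gene")
  out
}

#' Beta parameters by moment matching
#'
#' Inverts the beta mean/variance relations: with sample mean `m` and
#' variance `v`, `c = m(1-m)/v - 1`, `alpha = m*c`, `beta = (1-m)*c`.
#' Requires `0 < v < m(1-m)` (overdispersion cannot exceed the Bernoulli
#' bound).
#'
#' @param values numeric vector in (0, 1), length >= 3.
#' @return List with `alpha` and `beta` (class `bruuv_beta`).
#' @examples
#' fit_beta_by_moments(c(0.45, 0.5, 0.55))
#' @export
fit_beta_by_moments <- function(values) {
  assert_that(length(values) >= 3, "need at least 3 values")
  assert_that(all(values > 0 & values < 1),
              "values must lie strictly in (0, 1)")
  m <- mean(values)
  v <- var(values)
  if (v == 0) abort("zero variance: cannot fit a beta distribution")
  if (v >= m * (1 - m)) abort("variance exceeds Bernoulli bound m(1-m)")
  cc <- m * (1 - m) / v - 1
  beta_params(alpha = m * cc, beta = (1 - m) * cc)
}

#' @rdname fit_beta_by_moments
#' @param alpha,beta positive shape parameters.
#' @export
beta_params <- function(alpha, beta) {
  assert_that(alpha > 0 && beta > 0, "beta shape parameters must be positive")
  structure(list(alpha = alpha, beta = beta), class = "bruuv_beta")
}

#' Reflect a beta distribution about 1/2
#'
#' Returns the parameters of `1 - X` for `X ~ Beta(alpha, beta)`, i.e.
#' swaps the shapes. Applied to the fitted UVR distribution it yields the
#' UVE emission distribution: bins highly probable under UVR become
#' improbable under UVE and vice versa. The operation is an involution.
#'
#' @param params a [beta_params()].
#' @export
reflect_beta <- function(params) {
  beta_params(alpha = params$beta, beta = params$alpha)
}

#' Beta-binomial log probability mass
#'
#' `log P(K = k | n, alpha, beta)` computed via log-gamma:
#' `lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)`.
#' A bin with no trials (`n = 0`) has probability 1 of zero successes, so
#' its log-pmf is 0 under any parameters — such bins are uninformative for
#' state decoding. Vectorized over `k` and `n`.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 0`.
#' @param params a [beta_params()].
#' @export
beta_binomial_log_pmf <- function(k, n, params) {
  assert_that(all(n >= 0) && all(k >= 0) && all(k <= n),
              "need 0 <= k <= n")
  out <- lchoose(n, k) + lbeta(k + params$alpha, n - k + params$beta) -
    lbeta(params$alpha, params$beta)
  out[n == 0] <- 0
  out
}

# generic 2-state Viterbi in log space; emissions: n x 2 matrix
viterbi_two_state <- function(log_emissions, p_transition,
                              log_init = log(c(0.5, 0.5))) {
  n <- nrow(log_emissions)
  lstay <- log1p(-p_transition)
  lswitch <- log(p_transition)
  delta <- matrix(-Inf, n, 2)
  psi <- matrix(1L, n, 2)
  delta[1, ] <- log_init + log_emissions[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (s in 1:2) {
        # cand[j] = delta[t-1, j] + log A[j, s]
        cand <- c(delta[t - 1, 1] + (if (s == 1) lstay else lswitch),
                  delta[t - 1, 2] + (if (s == 2) lstay else lswitch))
        psi[t, s] <- which.max(cand)
        delta[t, s] <- cand[psi[t, s]] + log_emissions[t, s]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  path
}

#' Segment paired coverage into UVR/UVE states and extract peaks
#'
#' Runs a two-state Viterbi per chromosome with symmetric transition
#' probability and uniform initial distribution; emissions are the
#' beta-binomial log-pmf of the bin's rounded UV successes out of rounded
#' total trials under the UVR and UVE (reflected) parameters. Bins with no
#' trials are uninformative and inherit their state from the transition
#' prior; peaks are reported as maximal runs of UVE-state bins that carry
#' data (`n > 0`), so zero-coverage stretches never appear inside a peak.
#'
#' @param paired output of [compute_fuv()].
#' @param uvr,uve [beta_params()] for the two states.
#' @param p_transition symmetric switching probability.
#' @return List with `states` (the paired tibble plus a `state` column,
#'   `"UVR"`/`"UVE"`) and `peaks` (tibble: `chrom`, `start`, `end`,
#'   `n_bins`, `mean_fuv`), peaks disjoint, bin-aligned and ordered.
#' @export
segment_uve <- function(paired, uvr, uve, p_transition = 0.005) {
  paired$state <- NA_character_
  peaks <- list()
  for (chr in unique(paired$chrom)) {
    idx <- which(paired$chrom == chr)
    le <- cbind(beta_binomial_log_pmf(paired$k[idx], paired$n[idx], uvr),
                beta_binomial_log_pmf(paired$k[idx], paired$n[idx], uve))
    path <- viterbi_two_state(le, p_transition)
    paired$state[idx] <- c("UVR", "UVE")[path]
    informative_uve <- path == 2 & paired$n[idx] > 0
    r <- rle(informative_uve)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    for (j in keep) {
      sel <- idx[starts[j]:ends[j]]
      peaks[[length(peaks) + 1]] <- tibble(
        chrom = chr,
        start = paired$start[sel[1]],
        end = paired$end[sel[length(sel)]],
        n_bins = length(sel),
        mean_fuv = mean(paired$fuv[sel], na.rm = TRUE))
    }
  }
  peaks <- if (length(peaks) > 0) {
    bind_rows(peaks) %>% arrange(.data$chrom, .data$start)
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           n_bins = integer(), mean_fuv = numeric())
  }
  list(states = paired, peaks = peaks)
}

#' Flag peaks overlapping genes or transcription units
#'
#' A peak is intergenic when it overlaps no exclusion interval by even a
#' single base (half-open coordinates). Exclusion intervals are typically
#' the gene annotation plus independently determined transcription units.
#'
#' @param peaks peak tibble (`chrom`, `start`, `end`, ...).
#' @param exclusion tibble of intervals (`chrom`, `start`, `end`).
#' @param intergenic_only drop non-intergenic peaks instead of flagging.
#' @return The peak tibble with an `intergenic` logical column.
#' @export
filter_intergenic <- function(peaks, exclusion, intergenic_only = FALSE) {
  if (nrow(peaks) == 0) {
    peaks$intergenic <- logical(0)
    return(peaks)
  }
  if (is.null(exclusion) || nrow(exclusion) == 0) {
    peaks$intergenic <- TRUE
  } else {
    hits <- GenomicRanges::countOverlaps(as_granges0(peaks),
                                         as_granges0(exclusion),
                                         minoverlap = 1L)
    peaks$intergenic <- hits == 0
  }
  if (intergenic_only) peaks <- peaks[peaks$intergenic, , drop = FALSE]
  peaks
}

#' Call UV-enhancement peaks from a mock/UV track pair
#'
#' The full pipeline: wavelet-smooth each track, scale the pair to common
#' depth, form per-bin UV read fractions, train the UVR beta-binomial on
#' the deep bodies of expressed genes ([collect_training_fuv()] /
#' [fit_beta_by_moments()]), reflect it for the UVE state, Viterbi-segment
#' every chromosome ([segment_uve()]), and annotate peaks with RPKM and
#' intergenic status. Gene annotations are used only for training, so
#' peaks can be detected anywhere in the genome.
#'
#' @param mock,uv [bruuv_track()]s on the same grid (raw binned counts).
#' @param genes a [gene_set()] used for training and as exclusion
#'   intervals.
#' @param cfg a [uve_config()].
#' @param exclude optional extra exclusion intervals (tibble `chrom`,
#'   `start`, `end`), e.g. Bru-seq transcription units.
#' @return A `bruuv_uve_fit` object. [tidy()] returns the peak table;
#'   [glance()] the fitted parameters; [autoplot()] the UV-fraction track
#'   with peaks shaded.
#' @export
call_uve_peaks <- function(mock, uv, genes, cfg = uve_config(),
                           exclude = NULL) {
  mock_s <- smooth_track(mock, level = cfg$smooth_level)
  uv_s <- smooth_track(uv, level = cfg$smooth_level)
  pair <- scale_pair_to_common_depth(mock_s, uv_s)
  paired <- compute_fuv(pair$mock, pair$uv)
  training <- collect_training_fuv(paired, genes, mock, cfg)
  degenerate <- training$fuv <= 0 | training$fuv >= 1
  if (any(degenerate)) {
    warn(sprintf(
      "%d training gene(s) with UV fraction exactly 0 or 1 dropped before the beta fit",
      sum(degenerate)))
    training <- training[!degenerate, , drop = FALSE]
  }
  uvr <- fit_beta_by_moments(training$fuv)
  uve <- reflect_beta(uvr)
  seg <- segment_uve(paired, uvr, uve, cfg$p_transition)
  peaks <- seg$peaks
  if (nrow(peaks) > 0) {
    peaks$rpkm_mock <- compute_rpkm(pair$mock, peaks)
    peaks$rpkm_uv <- compute_rpkm(pair$uv, peaks)
  } else {
    peaks$rpkm_mock <- numeric(0)
    peaks$rpkm_uv <- numeric(0)
  }
  exclusion <- bind_rows(
    select(as_tibble(genes), "chrom", "start", "end"),
    if (!is.null(exclude)) select(as_tibble(exclude), "chrom", "start", "end"))
  peaks <- filter_intergenic(peaks, exclusion)
  structure(list(peaks = peaks, states = seg$states,
                 params = list(uvr = uvr, uve = uve),
                 training = training, p0 = pair$p0, cfg = cfg),
            class = "bruuv_uve_fit")
}

#' @export
print.bruuv_uve_fit <- function(x, ...) {
  cat(sprintf(
    "<bruuv_uve_fit> %d UVE peaks (%d intergenic); UVR ~ Beta(%.3g, %.3g) from %d genes\n",
    nrow(x$peaks), sum(x$peaks$intergenic),
    x$params$uvr$alpha, x$params$uvr$beta, nrow(x$training)))
  invisible(x)
}

#' @export
tidy.bruuv_uve_fit <- function(x, ...) {
  as_tibble(x$peaks)
}

#' @export
glance.bruuv_uve_fit <- function(x, ...) {
  tibble(alpha_uvr = x$params$uvr$alpha, beta_uvr = x$params$uvr$beta,
         mean_fuv_uvr = with(x$params$uvr, alpha / (alpha + beta)),
         n_training_genes = nrow(x$training),
         n_peaks = nrow(x$peaks),
         n_intergenic = sum(x$peaks$intergenic),
         p_transition = x$cfg$p_transition)
}
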