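#' Configuration of the TSS-activity HMM
#'
#' The default mode analyses 250-bp bins spanning 5 kb either side of each
#' annotated (merged) TSS; emission parameters for the pre-TSS state
#' (state 1) and post-TSS state (state 2) are trained on the 5-2 kb
#' upstream and 2-5 kb downstream flanks respectively, the single allowed
#' 1-to-2 transition carries probability 1e-5, and a TSS is "active" when
#' the Viterbi switch starts within 500 bp of it. The `grocap` mode keeps
#' the identical code path with parameters suited to the narrow peaks of
#' 5'-capped run-on data: a 500-bp window of 50-bp bins with training
#' flanks at -500..-100 and 0..+500 bp.
#'
#' @param mode `"default"` or `"grocap"` preset.
#' @param upstream_bp,downstream_bp window extent around the TSS, bp.
#' @param bin_width bin width, bp; must divide both extents.
#' @param train_state1,train_state2 `c(lo, hi)` offset ranges (bp,
#'   half-open, negative = upstream) whose fully contained bins train the
#'   two emission distributions.
#' @param p_transition probability of the single 1-to-2 transition.
#' @param activity_window_bp maximum |switch offset| for an active call.
#' @param sd_floor lower bound on emission standard deviations, in
#'   normalized-signal units; prevents degenerate likelihood spikes when a
#'   training flank is constant.
#' @param pooled_emissions train one emission pair on all windows jointly
#'   instead of per window.
#' @param gamma_mode normalization passed to [gamma_z_transform()].
#' @return A `bruuv_tss_config` list.
#' @export
tss_config <- function(mode = c("default", "grocap"),
                       upstream_bp = NULL, downstream_bp = NULL,
                       bin_width = NULL,
                       train_state1 = NULL, train_state2 = NULL,
                       p_transition = 1e-5, activity_window_bp = 500,
                       sd_floor = 0.1, pooled_emissions = FALSE,
                       gamma_mode = c("gamma_z", "plain_z")) {
  mode <- match.arg(mode)
  preset <- if (mode == "default") {
    list(up = 5000, down = 5000, w = 250,
         t1 = c(-5000, -2000), t2 = c(2000, 5000))
  } else {
    list(up = 500, down = 500, w = 50,
         t1 = c(-500, -100), t2 = c(0, 500))
  }
  cfg <- list(
    mode = mode,
    upstream_bp = upstream_bp %||% preset$up,
    downstream_bp = downstream_bp %||% preset$down,
    bin_width = bin_width %||% preset$w,
    train_state1 = train_state1 %||% preset$t1,
    train_state2 = train_state2 %||% preset$t2,
    p_transition = p_transition,
    activity_window_bp = activity_window_bp,
    sd_floor = sd_floor,
    pooled_emissions = pooled_emissions,
    gamma_mode = match.arg(gamma_mode))
  assert_that(cfg$p_transition > 0 && cfg$p_transition < 1,
              "`p_transition` must lie in (0, 1)")
  assert_that(cfg$upstream_bp %% cfg$bin_width == 0 &&
                cfg$downstream_bp %% cfg$bin_width == 0,
              "`bin_width` must divide the window extents")
  assert_that(cfg$train_state1[1] >= -cfg$upstream_bp &&
                cfg$train_state2[2] <= cfg$downstream_bp,
              "training ranges must lie inside the window")
  class(cfg) <- "bruuv_tss_config"
  cfg
}

window_offsets <- function(cfg) {
  seq(-cfg$upstream_bp, cfg$downstream_bp - cfg$bin_width, by = cfg$bin_width)
}

training_bins <- function(cfg, range) {
  off <- window_offsets(cfg)
  which(off >= range[1] & off + cfg$bin_width <= range[2])
}

#' Extract TSS-anchored signal windows
#'
#' Builds one row per gene-set entry, covering `upstream_bp` to
#' `downstream_bp` around the TSS in `bin_width` bins oriented 5' to 3'
#' along the gene (upstream bins first; on the minus strand bins are read
#' right to left along the genome). Bins extending past a chromosome end
#' are zero-filled and the row is flagged `clipped`; entries on
#' chromosomes absent from the track are skipped with a warning.
#'
#' @param track a [bruuv_track()].
#' @param genes a [gene_set()] (typically TSS-merged).
#' @param cfg a [tss_config()].
#' @return A `bruuv_windows` object: list with `values` (matrix, one row
#'   per entry), `bin_offsets` (bp, strand-oriented), `genes` (the rows
#'   kept) and `clipped` (logical per row). Has a [tidy()] method.
#' @export
extract_tss_windows <- function(track, genes, cfg = tss_config()) {
  off <- window_offsets(cfg)
  known <- genes$chrom %in% names(chrom_sizes(track))
  if (any(!known)) {
    warn(sprintf("%d gene(s) on chromosomes absent from the track; skipped",
                 sum(!known)))
    genes <- genes[known, , drop = FALSE]
  }
  assert_that(nrow(genes) > 0, "no gene left to extract windows for")
  wm <- window_matrix(track, genes, off, cfg$bin_width)
  structure(list(values = wm$values, bin_offsets = off, genes = genes,
                 clipped = wm$clipped, cfg = cfg),
            class = "bruuv_windows")
}

#' @export
print.bruuv_windows <- function(x, ...) {
  cat(sprintf("<bruuv_windows> %d windows x %d bins (%d bp), offsets %d..%d\n",
              nrow(x$values), ncol(x$values), x$cfg$bin_width,
              min(x$bin_offsets), max(x$bin_offsets) + x$cfg$bin_width))
  invisible(x)
}

#' @export
tidy.bruuv_windows <- function(x, ...) {
  tibble(tss_id = rep(rownames(x$values), each = ncol(x$values)),
         offset = rep(x$bin_offsets, nrow(x$values)),
         value = as.vector(t(x$values)))
}

#' Train Gaussian emissions from the window flanks
#'
#' State means and standard deviations are the sample moments of the bins
#' fully contained in the two training ranges; standard deviations are
#' floored at `cfg$sd_floor`.
#'
#' @param window_row normalized signal vector over the window bins.
#' @param cfg a [tss_config()].
#' @return List with `state1` and `state2`, each `c(mean, sd)`.
#' @export
fit_state_emissions <- function(window_row, cfg = tss_config()) {
  i1 <- training_bins(cfg, cfg$train_state1)
  i2 <- training_bins(cfg, cfg$train_state2)
  assert_that(length(i1) >= 2 && length(i2) >= 2,
              "each training region must contain at least 2 bins")
  moments <- function(v) c(mean = mean(v), sd = max(sd(v), cfg$sd_floor))
  list(state1 = moments(window_row[i1]), state2 = moments(window_row[i2]))
}

#' Viterbi decoding of the monotone two-state chain
#'
#' The chain starts in state 1 (a pre-TSS state necessarily precedes the
#' TSS) and may switch to the absorbing state 2 exactly once, with
#' probability `p_transition` per step; staying in state 1 costs
#' `log(1 - p_transition)` per step and state 2 is absorbing. The best of
#' the `n + 1` monotone paths is found in closed form from cumulative
#' emission log-likelihood sums. Ties are broken toward the most upstream
#' switch.
#'
#' @param obs numeric observation vector (normalized signal).
#' @param params emission parameters from [fit_state_emissions()].
#' @param p_transition 1-to-2 transition probability per step.
#' @return Integer vector over `{1, 2}`, non-decreasing.
#' @export
viterbi_monotone_two_state <- function(obs, params, p_transition) {
  n <- length(obs)
  assert_that(n >= 1, "`obs` must be non-empty")
  assert_that(all(is.finite(obs)), "non-finite observation")
  ll1 <- stats::dnorm(obs, params$state1[["mean"]], params$state1[["sd"]],
                      log = TRUE)
  ll2 <- stats::dnorm(obs, params$state2[["mean"]], params$state2[["sd"]],
                      log = TRUE)
  lp <- log(p_transition)
  lq <- log1p(-p_transition)
  # path k (k = 0..n): first k bins in state 1, rest in state 2; a switch
  # after k state-1 bins costs k stay-terms then one transition (a path
  # starting in state 2 spends the transition before the first emission)
  c1 <- c(0, cumsum(ll1))
  c2 <- rev(c(0, cumsum(rev(ll2))))
  k <- 0:n
  score <- c1 + c2 + ifelse(k < n, k * lq + lp, n * lq)
  k_best <- k[which.max(score)]   # which.max takes the first (most upstream)
  rep(c(1L, 2L), times = c(k_best, n - k_best))
}

#' Call active TSSs with the monotone two-state HMM
#'
#' Runs the full pipeline over a merged gene set: extract TSS-anchored
#' windows, quantile-normalize across windows, gamma-z-transform each row,
#' train per-window (or pooled) Gaussian emissions on the two flanks,
#' Viterbi-decode the monotone chain, and call a TSS active when the first
#' state-2 bin starts within `activity_window_bp` of the TSS. All-zero
#' windows are reported inactive rather than erroring.
#'
#' @param track a [bruuv_track()] (conventionally the UV sample, built on
#'   the gene's strand or combined).
#' @param genes a [gene_set()], TSS-merged (see [merge_isoform_tss()]).
#' @param cfg a [tss_config()].
#' @return A `bruuv_tss_fit` object. [tidy()] returns the per-TSS call
#'   table (`gene_id`, `tss_id`, `chrom`, `tss`, `strand`, `active`,
#'   `transition_offset`, `n_active_tss_for_gene`); [glance()] summarises
#'   the fit; [autoplot()] shows the switch-offset distribution.
#' @export
call_active_tss <- function(track, genes, cfg = tss_config()) {
  wins <- extract_tss_windows(track, genes, cfg)
  raw <- wins$values
  norm <- quantile_normalize(raw)
  degenerate <- apply(norm, 1, function(r) var(r) == 0 || all(r == 0))
  z <- norm
  z[] <- NA_real_
  for (i in which(!degenerate)) {
    z[i, ] <- gamma_z_transform(norm[i, ], mode = cfg$gamma_mode)
  }
  pooled <- if (cfg$pooled_emissions && any(!degenerate)) {
    zz <- z[!degenerate, , drop = FALSE]
    i1 <- training_bins(cfg, cfg$train_state1)
    i2 <- training_bins(cfg, cfg$train_state2)
    moments <- function(v) c(mean = mean(v), sd = max(sd(v), cfg$sd_floor))
    list(state1 = moments(as.vector(zz[, i1])),
         state2 = moments(as.vector(zz[, i2])))
  } else NULL
  off <- wins$bin_offsets

  res <- purrr::map(seq_len(nrow(z)), function(i) {
    if (degenerate[i]) {
      return(list(active = FALSE, transition_offset = NA_real_))
    }
    params <- if (cfg$pooled_emissions) pooled else
      fit_state_emissions(z[i, ], cfg)
    path <- viterbi_monotone_two_state(z[i, ], params, cfg$p_transition)
    sw <- match(2L, path)
    if (is.na(sw)) {
      list(active = FALSE, transition_offset = NA_real_)
    } else {
      o <- off[sw]
      list(active = abs(o) <= cfg$activity_window_bp, transition_offset = o)
    }
  })

  calls <- wins$genes %>%
    mutate(active = purrr::map_lgl(res, "active"),
           transition_offset = purrr::map_dbl(res, "transition_offset"),
           clipped = wins$clipped) %>%
    group_by(.data$gene_id) %>%
    mutate(n_active_tss_for_gene = sum(.data$active)) %>%
    ungroup()

  structure(list(calls = calls, windows = wins, normalized = z,
                 cfg = cfg), class = "bruuv_tss_fit")
}

#' @export
print.bruuv_tss_fit <- function(x, ...) {
  cat(sprintf("<bruuv_tss_fit> %d TSS entries, %d active (%s mode)\n",
              nrow(x$calls), sum(x$calls$active), x$cfg$mode))
  invisible(x)
}

#' @export
tidy.bruuv_tss_fit <- function(x, ...) {
  select(x$calls, "gene_id", "tss_id", "chrom", "tss", "strand",
         "active", "transition_offset", "n_active_tss_for_gene")
}

#' @export
glance.bruuv_tss_fit <- function(x, ...) {
  per_gene <- x$calls %>%
    group_by(.data$gene_id) %>%
    summarise(k = sum(.data$active), .groups = "drop") %>%
    filter(.data$k > 0)
  tibble(n_tss = nrow(x$calls),
         n_active = sum(x$calls$active),
         n_genes = length(unique(x$calls$gene_id)),
         n_expressed_genes = nrow(per_gene),
         prop_single_active_tss =
           if (nrow(per_gene) > 0) mean(per_gene$k == 1) else NA_real_,
         p_transition = x$cfg$p_transition,
         mode = x$cfg$mode)
}
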