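#' UV transcription-blocking lesion model
#'
#' UVC irradiation induces on average 1 transcription-blocking lesion (a
#' CPD or 6-4 photoproduct) per 100 kb of transcribed strand per J/m^2,
#' i.e. a homogeneous Poisson process of intensity
#' `rate_per_bp_per_J * dose_J` per bp — 1 lesion per 5 kb at 20 J/m^2.
#'
#' @param rate_per_bp_per_J lesions per bp per J/m^2 (default 1e-5).
#' @param dose_J UVC dose in J/m^2.
#' @return A `bruuv_lesion_model` list with a derived `lambda`
#'   (lesions/bp).
#' @export
lesion_model <- function(rate_per_bp_per_J = 1e-5, dose_J = 20) {
  assert_that(rate_per_bp_per_J > 0, "lesion rate must be positive")
  assert_that(dose_J >= 0, "dose must be non-negative")
  structure(list(rate_per_bp_per_J = rate_per_bp_per_J, dose_J = dose_J,
                 lambda = rate_per_bp_per_J * dose_J),
            class = "bruuv_lesion_model")
}

#' Place lesions along a transcribed strand
#'
#' Draws a Poisson(`length * lambda`) lesion count and i.i.d. uniform
#' positions, returned sorted. A zero dose yields no lesions.
#'
#' @param length strand length, bp.
#' @param model a [lesion_model()].
#' @param seed optional RNG seed.
#' @return Sorted numeric positions in `[0, length)`.
#' @examples
#' length(place_lesions(1e6, lesion_model(dose_J = 20), seed = 1))  # ~200
#' @export
place_lesions <- function(length, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_that(length > 0, "`length` must be positive")
  if (model$lambda == 0) return(numeric(0))
  n <- rpois(1, length * model$lambda)
  sort(runif(n, 0, length))
}

#' Lay out a synthetic genome of genes and intergenic enhancers
#'
#' Genes are placed sequentially on one chromosome with intergenic gaps,
#' alternating strands, with log-normal expression weights; enhancers sit
#' at gap midpoints, so they are intergenic by construction. Each
#' enhancer has a base amplitude (eRNA is weakly transcribed in untreated
#' cells) and a stabilization factor `s >= 1` multiplying its signal in
#' the UV sample, standing in for the exosome protection of polymerase-
#' associated transcripts.
#'
#' @param n_genes,n_enhancers how many of each (enhancers are capped at
#'   `n_genes` gaps).
#' @param gene_len_range,gap_range uniform sampling ranges, bp.
#' @param expr_sdlog log-normal sd of gene expression weights (meanlog 0).
#' @param enhancer_base_amp peak eRNA density relative to the average
#'   genic density of 1.
#' @param stabilization UV stabilization factor `s` applied to every
#'   enhancer.
#' @param kernel_halfwidth_bp half-width of the triangular eRNA signal
#'   kernel, bp.
#' @param element_halfwidth_bp half-width of the enhancer element proper
#'   (the truth interval), bp.
#' @param chrom chromosome name.
#' @param seed optional RNG seed.
#' @return A `bruuv_sim_genome` list: `genes` (a [gene_set()] with an
#'   `expression` column), `enhancers` (tibble with `center`, `base_amp`,
#'   `stabilization` and the truth interval), `chrom_sizes`.
#' @export
sim_genome <- function(n_genes = 60, n_enhancers = 25,
                       gene_len_range = c(20000, 120000),
                       gap_range = c(30000, 80000),
                       expr_sdlog = 0.5,
                       enhancer_base_amp = 0.5,
                       stabilization = 5,
                       kernel_halfwidth_bp = 1000,
                       element_halfwidth_bp = 500,
                       chrom = "chrS", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_that(n_genes >= 1, "need at least one gene")
  lens <- round(runif(n_genes, gene_len_range[1], gene_len_range[2]))
  gaps <- round(runif(n_genes, gap_range[1], gap_range[2]))
  starts <- cumsum(gaps) + c(0, cumsum(lens))[seq_len(n_genes)]
  ends <- starts + lens
  strand <- rep(c("+", "-"), length.out = n_genes)
  genes <- gene_set(tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = chrom, start = starts, end = ends, strand = strand))
  genes$expression <- exp(stats::rnorm(n_genes, 0, expr_sdlog))

  n_enhancers <- min(n_enhancers, n_genes - 1)
  enh <- tibble(
    enhancer_id = sprintf("e%03d", seq_len(n_enhancers)),
    chrom = chrom,
    # midpoint of the gap following gene i: comfortably away from genes
    center = round((ends[seq_len(n_enhancers)] +
                      starts[seq_len(n_enhancers) + 1]) / 2),
    base_amp = enhancer_base_amp,
    stabilization = stabilization) %>%
    mutate(start = .data$center - element_halfwidth_bp,
           end = .data$center + element_halfwidth_bp)

  structure(list(genes = genes, enhancers = enh,
                 kernel_halfwidth_bp = kernel_halfwidth_bp,
                 chrom_sizes = setNames(max(ends) + max(gaps), chrom)),
            class = "bruuv_sim_genome")
}

# expected genic read mass per bin; survival form: density at
# strand-oriented offset x is e_g * exp(-lambda * x), integrated per bin
genic_bin_mass <- function(gene_start, gene_end, strand, expression,
                           lambda, bin_starts, w, first_lesion = Inf) {
  # strand-oriented offsets of bin boundaries within the gene
  len <- gene_end - gene_start
  lo <- pmax(bin_starts, gene_start)
  hi <- pmin(bin_starts + w, gene_end)
  ok <- hi > lo
  x0 <- if (strand == "+") lo - gene_start else gene_end - hi
  x1 <- x0 + (hi - lo)
  x1 <- pmin(x1, first_lesion)
  x0 <- pmin(x0, first_lesion)
  mass <- numeric(length(bin_starts))
  if (lambda == 0) {
    mass[ok] <- expression * (x1 - x0)[ok]
  } else {
    mass[ok] <- expression *
      ((exp(-lambda * x0) - exp(-lambda * x1)) / lambda)[ok]
  }
  mass
}

#' Simulate a paired mock/UV track set with ground truth
#'
#' Expected genic read density at strand-oriented offset `x` from a TSS is
#' `e_g * exp(-lambda * x)`: the survival probability of an elongating
#' polymerase past Poisson lesions at intensity `lambda`, marginalized
#' over lesion placements. The mock sample uses dose 0 (uniform genic
#' density). Each enhancer adds a symmetric triangular kernel of
#' half-width `kernel_halfwidth_bp` with amplitude `base_amp` in mock and
#' `base_amp * s` in UV (stabilization requires stalled polymerases, so a
#' zero dose leaves the UV enhancer amplitude at baseline and the model
#' collapses to the mock model). Reads are drawn multinomially to the requested
#' depths, so track totals match the depths exactly.
#' `mode = "explicit"` instead conditions each gene on one drawn lesion
#' realization (reads uniform up to the first lesion), whose expectation
#' over lesion draws equals the survival form.
#'
#' @param genome a [sim_genome()].
#' @param model a [lesion_model()] giving the UV dose.
#' @param depth_mock,depth_uv reads per track.
#' @param bin_width bp.
#' @param mode `"marginal"` (analytic expectation) or `"explicit"`.
#' @param seed optional RNG seed.
#' @return A list: `mock` and `uv` ([bruuv_track()]s), `truth` (list of
#'   `tss`, `enhancers`, `lesions` tibbles), and the expected per-bin
#'   intensities `intensity_mock`/`intensity_uv` for validation.
#' @export
simulate_paired_tracks <- function(genome, model = lesion_model(dose_J = 25),
                                   depth_mock = 1e6, depth_uv = 1e6,
                                   bin_width = 250,
                                   mode = c("marginal", "explicit"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  assert_that(depth_mock > 0 && depth_uv > 0, "depths must be positive")
  genes <- genome$genes
  assert_that(nrow(genes) > 0, "empty genome")
  chrom <- names(genome$chrom_sizes)[1]
  L <- genome$chrom_sizes[[1]]
  nb <- as.integer(ceiling(L / bin_width))
  bs <- (seq_len(nb) - 1) * bin_width

  lesions <- purrr::pmap(
    list(genes$gene_id, genes$start, genes$end),
    function(id, s, e) {
      pos <- place_lesions(e - s, model)
      if (length(pos) == 0) return(NULL)
      tibble(gene_id = id, offset = pos)
    }) %>% purrr::compact() %>% bind_rows()
  if (nrow(lesions) == 0) {
    lesions <- tibble(gene_id = character(), offset = numeric())
  }

  imock <- numeric(nb)
  iuv <- numeric(nb)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    imock <- imock + genic_bin_mass(g$start, g$end, g$strand, g$expression,
                                    0, bs, bin_width)
    fl <- if (mode == "explicit") {
      off <- lesions$offset[lesions$gene_id == g$gene_id]
      if (length(off) == 0) Inf else min(off)
    } else Inf
    iuv <- iuv + genic_bin_mass(g$start, g$end, g$strand, g$expression,
                                if (mode == "marginal") model$lambda else 0,
                                bs, bin_width, first_lesion = fl)
  }
  mid <- bs + bin_width / 2
  for (i in seq_len(nrow(genome$enhancers))) {
    e <- genome$enhancers[i, ]
    kern <- pmax(0, 1 - abs(mid - e$center) / genome$kernel_halfwidth_bp) *
      bin_width
    # stabilization needs stalled polymerases, so it acts only under UV
    s_eff <- if (model$dose_J > 0) e$stabilization else 1
    imock <- imock + e$base_amp * kern
    iuv <- iuv + e$base_amp * s_eff * kern
  }

  draw <- function(intensity, depth) {
    as.numeric(rmultinom(1, depth, intensity / sum(intensity)))
  }
  mock <- bruuv_track(setNames(list(draw(imock, depth_mock)), chrom),
                      bin_width, total_reads = depth_mock,
                      chrom_sizes = genome$chrom_sizes)
  uv <- bruuv_track(setNames(list(draw(iuv, depth_uv)), chrom),
                    bin_width, total_reads = depth_uv,
                    chrom_sizes = genome$chrom_sizes)
  list(mock = mock, uv = uv,
       truth = list(
         tss = select(as_tibble(genes), "gene_id", "tss_id", "chrom",
                      "tss", "strand"),
         enhancers = select(genome$enhancers, "enhancer_id", "chrom",
                            "start", "end", "center", "stabilization"),
         lesions = lesions),
       intensity_mock = imock, intensity_uv = iuv)
}

#' Simulate a step-signal track for TSS-caller validation
#'
#' Builds the canonical test signal for the monotone TSS HMM: Poisson
#' noise at a baseline level everywhere, plus — for each entry flagged
#' `active` — an additional `effect_sd` baseline-standard-deviations of
#' intensity over the gene body downstream of its TSS. Entries sharing a
#' gene produce cumulative steps, mimicking nested alternative TSSs.
#'
#' @param genes a [gene_set()]; an optional logical `active` column marks
#'   which entries carry a step (default all).
#' @param effect_sd step height in units of the baseline Poisson sd.
#' @param baseline expected background reads per bin.
#' @param bin_width bp.
#' @param chrom_sizes optional named chromosome lengths.
#' @param seed optional RNG seed.
#' @return A [bruuv_track()] of Poisson counts.
#' @export
simulate_tss_step_track <- function(genes, effect_sd = 5, baseline = 20,
                                    bin_width = 250, chrom_sizes = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  active <- if ("active" %in% names(genes)) genes$active else
    rep(TRUE, nrow(genes))
  chrom_sizes <- chrom_sizes %||% {
    sizes <- as_tibble(genes) %>%
      group_by(.data$chrom) %>%
      summarise(size = max(.data$end) + 10000, .groups = "drop")
    setNames(sizes$size, sizes$chrom)
  }
  step <- effect_sd * sqrt(baseline)
  counts <- purrr::imap(chrom_sizes, function(size, chr) {
    nb <- as.integer(ceiling(size / bin_width))
    bs <- (seq_len(nb) - 1) * bin_width
    intensity <- rep(baseline, nb)
    sel <- which(genes$chrom == chr & active)
    for (i in sel) {
      s <- if (genes$strand[i] == "+") genes$tss[i] else genes$start[i]
      e <- if (genes$strand[i] == "+") genes$end[i] else genes$tss[i] + 1
      frac <- overlap_width(bs, bs + bin_width, s, e) / bin_width
      intensity <- intensity + step * frac
    }
    rpois(nb, intensity)
  })
  trk <- bruuv_track(counts, bin_width, total_reads = sum(unlist(counts)),
                     chrom_sizes = chrom_sizes)
  trk
}

#' Write a deterministic simulated fixture to disk
#'
#' Generates a genome and paired tracks and writes `mock.bedGraph`,
#' `uv.bedGraph`, `genes.bed12`, `truth_tss.bed` and
#' `truth_enhancers.bed` under `dir`. Given the same seed the files are
#' byte-identical, and they round-trip through [read_bedgraph()] /
#' [read_gene_annotation()].
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed driving genome and reads.
#' @param genome optional pre-built [sim_genome()].
#' @param model a [lesion_model()].
#' @param depth_mock,depth_uv reads per track.
#' @param bin_width bp.
#' @param ... further arguments to [sim_genome()].
#' @return Invisibly, a named list of the five file paths plus the
#'   simulation object.
#' @export
make_fixture <- function(dir, seed = 1, genome = NULL,
                         model = lesion_model(dose_J = 25),
                         depth_mock = 1e6, depth_uv = 1e6,
                         bin_width = 250, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- genome %||% sim_genome(seed = seed, ...)
  sim <- simulate_paired_tracks(genome, model, depth_mock, depth_uv,
                                bin_width, seed = seed + 1)
  paths <- list(
    mock = file.path(dir, "mock.bedGraph"),
    uv = file.path(dir, "uv.bedGraph"),
    genes = file.path(dir, "genes.bed12"),
    truth_tss = file.path(dir, "truth_tss.bed"),
    truth_enhancers = file.path(dir, "truth_enhancers.bed"))
  write_bedgraph(sim$mock, paths$mock)
  write_bedgraph(sim$uv, paths$uv)
  g <- as_tibble(genome$genes)
  readr::write_tsv(
    tibble(chrom = g$chrom, start = as.integer(g$start),
           end = as.integer(g$end), name = g$gene_id, score = 0L,
           strand = g$strand, thickStart = as.integer(g$start),
           thickEnd = as.integer(g$end), itemRgb = "0", blockCount = 1L,
           blockSizes = paste0(as.integer(g$end - g$start), ","),
           blockStarts = "0,"),
    paths$genes, col_names = FALSE)
  readr::write_tsv(
    tibble(chrom = g$chrom, start = as.integer(g$tss),
           end = as.integer(g$tss) + 1L, name = g$tss_id, score = 0L,
           strand = g$strand),
    paths$truth_tss, col_names = FALSE)
  e <- genome$enhancers
  readr::write_tsv(
    tibble(chrom = e$chrom, start = as.integer(e$start),
           end = as.integer(e$end), name = e$enhancer_id,
           score = as.integer(e$stabilization), strand = "."),
    paths$truth_enhancers, col_names = FALSE)
  invisible(c(paths, list(sim = sim, genome = genome)))
}
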