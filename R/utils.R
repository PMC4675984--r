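`%||%` <- function(x, y) if (is.null(x)) y else x

# round-half-up (not banker's rounding): used when scaled fractional counts
# must become integral trial counts for the beta-binomial
round_half_up <- function(x) floor(x + 0.5)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# 0-based half-open tibble -> GRanges (1-based closed)
as_granges0 <- function(df, strand = NULL) {
  s <- strand %||% (if ("strand" %in% names(df)) df$strand else "*")
  s[s == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = s
  )
}

# half-open interval overlap width, vectorised
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
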