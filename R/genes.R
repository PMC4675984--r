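#' Gene sets with strand-aware TSS coordinates
#'
#' A `bruuv_genes` object is a tibble with one row per TSS entry (an
#' isoform before merging, a merged-TSS cluster after): columns `gene_id`
#' (the gene an entry belongs to), `tss_id` (unique entry identifier),
#' `chrom`, `start`, `end` (0-based half-open), `strand` (`+`/`-`), `tss`
#' (strand-aware start: `start` on `+`, `end - 1` on `-`) and
#' `source_isoforms` (comma-joined ids of the isoforms behind the entry).
#'
#' @param genes data frame with at least `gene_id`, `chrom`, `start`,
#'   `end`, `strand`; `tss`, `tss_id` and `source_isoforms` are filled in
#'   when absent.
#' @return A `bruuv_genes` tibble.
#' @export
gene_set <- function(genes) {
  g <- as_tibble(genes)
  needed <- c("gene_id", "chrom", "start", "end", "strand")
  assert_that(all(needed %in% names(g)),
              paste("gene set needs columns:", paste(needed, collapse = ", ")))
  assert_that(all(g$strand %in% c("+", "-")),
              "every gene record must carry a '+' or '-' strand")
  assert_that(all(g$start >= 0 & g$end > g$start),
              "gene intervals must satisfy 0 <= start < end")
  if (!"tss" %in% names(g)) {
    g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  }
  assert_that(all(g$tss >= g$start & g$tss < g$end),
              "tss must lie inside the gene interval")
  if (!"tss_id" %in% names(g)) g$tss_id <- g$gene_id
  if (!"source_isoforms" %in% names(g)) g$source_isoforms <- g$tss_id
  assert_that(!anyDuplicated(g$tss_id),
              "`tss_id` must be unique within a gene set")
  g <- select(g, "gene_id", "tss_id", "chrom", "start", "end",
              "strand", "tss", "source_isoforms")
  class(g) <- c("bruuv_genes", class(g))
  g
}

#' Read gene models from GTF or BED
#'
#' Produces one entry per isoform; TSSs are computed strand-aware and all
#' coordinates are normalized to the internal 0-based half-open convention
#' (GTF's 1-based closed coordinates are converted on read, BED is native).
#' For GTF, entries are grouped into genes by the `gene_id` attribute; for
#' BED, the `name` field serves as both isoform and gene identifier (so
#' records meant to be merged as alternative TSSs of one gene should share
#' a name). Records without a strand are rejected. Use
#' [merge_isoform_tss()] afterwards to apply the TSS-merging rules.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gtf"`, or `"bed"`
#'   (BED6/BED12).
#' @return A [gene_set()] tibble, one row per isoform.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) abort(sprintf("failed to parse %s as %s: %s",
                                      path, format, conditionMessage(e))))
  if (format == "gtf") {
    meta <- S4Vectors::mcols(gr)
    if ("type" %in% names(meta) && any(meta$type == "transcript")) {
      gr <- gr[meta$type == "transcript"]
      meta <- S4Vectors::mcols(gr)
    }
    iso <- as.character(meta$transcript_id %||% meta$gene_id)
    gid <- as.character(meta$gene_id %||% iso)
  } else {
    iso <- as.character(gr$name %||% paste0("iso", seq_along(gr)))
    gid <- iso
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) abort("annotation record without a strand")
  g <- tibble(gene_id = gid, tss_id = iso,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1,
              end = as.numeric(GenomicRanges::end(gr)),
              strand = strand)
  if (format == "gtf" && !is.null(S4Vectors::mcols(gr)$type)) {
    # exon-only GTFs: take the transcript extent as the exon span
    g <- g %>%
      group_by(.data$gene_id, .data$tss_id, .data$chrom, .data$strand) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
  }
  g$tss_id <- make.unique(g$tss_id, sep = "#")
  gene_set(g)
}

#' Merge isoforms by TSS proximity
#'
#' Within each gene (same `gene_id` and strand), isoforms with identical
#' TSSs collapse to one entry, and TSSs closer than `merge_distance`
#' (default 1 kb, strict inequality: starts exactly 1 kb apart stay
#' distinct) are single-linkage clustered; each cluster becomes one merged
#' entry carrying the most upstream member TSS (smallest coordinate on
#' `+`, largest on `-`) and the union of the member intervals. The
#' operation is idempotent.
#'
#' @param genes a [gene_set()].
#' @param merge_distance clustering distance in bp.
#' @return A merged [gene_set()]; multi-cluster genes get `tss_id`s of the
#'   form `<gene_id>.<k>` numbered in genomic order.
#' @examples
#' g <- gene_set(tibble::tibble(
#'   gene_id = "g1", tss_id = c("a", "b"), chrom = "chr1",
#'   start = c(10000, 10800), end = c(20000, 21000), strand = "+"))
#' merge_isoform_tss(g)$tss  # 10000: the most upstream of the pair
#' @export
merge_isoform_tss <- function(genes, merge_distance = 1000) {
  assert_that(nrow(genes) > 0, "cannot merge an empty gene set")
  merged <- genes %>%
    group_by(.data$gene_id, .data$strand, .data$chrom) %>%
    group_modify(function(d, key) {
      ord <- order(d$tss)
      d <- d[ord, , drop = FALSE]
      cl <- cumsum(c(1, diff(d$tss) >= merge_distance))
      d %>%
        mutate(.cl = cl) %>%
        group_by(.data$.cl) %>%
        summarise(
          start = min(.data$start), end = max(.data$end),
          tss = if (key$strand == "+") min(.data$tss) else max(.data$tss),
          source_isoforms = paste(
            sort(unique(unlist(strsplit(.data$source_isoforms, ",")))),
            collapse = ","),
          .groups = "drop") %>%
        select(-".cl")
    }) %>%
    ungroup() %>%
    group_by(.data$gene_id, .data$strand) %>%
    mutate(tss_id = if (n() == 1) .data$gene_id
           else paste0(.data$gene_id, ".", rank(.data$tss))) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$tss)
  out <- gene_set(merged)
  attr(out, "merge_distance") <- merge_distance
  out
}
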