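# Splice-junction model and the seven-category hierarchical classifier.
#
# A junction spans an intron gap between two exonic anchor blocks: the
# left block [S, S + MOL) and the right block [E - MOR, E), where S/E are
# the junction's genomic start/end and MOL/MOR are the maximal overhangs
# of the reads supporting it. In TopHat's junctions.bed dialect these are
# chromStart/chromEnd and the two blockSizes; score carries the read
# support. On the plus strand S is the 5' side; on the minus strand the
# 5'/3' designations swap but genomic order S < E is kept.

JUNCTION_CATEGORIES <- c(
  "annotated", "exon_skipping", "only_one_side", "intra_exonic",
  "different_transcripts", "trans_splicing", "intronic_intergenic"
)

#' Load splice junctions from a TopHat-style BED12
#'
#' Each record must carry exactly two blocks; records with a different
#' block count, or whose blocks overlap, are rejected with a warning.
#' Duplicate junctions (same chromosome, start, end and strand) are
#' merged with their supports summed.
#'
#' @param path junctions.bed file (BED12, two blocks, score = number of
#'   supporting reads).
#' @return Tibble with one row per junction: `junction_id`, `chrom`,
#'   `start` (S), `end` (E), `strand`, `support`, `mol`, `mor` and the
#'   block intervals `l_start`, `l_end`, `r_start`, `r_end`.
#' @export
read_junctions <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) abort(paste0("BED parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  mc <- S4Vectors::mcols(gr)
  if (length(gr) == 0) return(empty_junctions())
  if (!"blocks" %in% names(mc)) abort("junction file is not BED12 (no blocks)")
  nb <- S4Vectors::elementNROWS(mc$blocks)
  if (any(nb != 2)) {
    warn(sprintf("rejected %d junction record(s) with blockCount != 2",
                 sum(nb != 2)))
  }
  keep <- nb == 2
  gr <- gr[keep]
  if (length(gr) == 0) return(empty_junctions())
  blocks <- S4Vectors::mcols(gr)$blocks
  mol <- vapply(blocks, function(b) IRanges::width(b)[1], integer(1))
  mor <- vapply(blocks, function(b) IRanges::width(b)[2], integer(1))
  x <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    support = as.integer(S4Vectors::mcols(gr)$score %||% 0L),
    mol = mol, mor = mor
  )
  bad <- x$start + x$mol > x$end - x$mor
  if (any(bad)) {
    warn(sprintf("rejected %d junction record(s) with overlapping blocks",
                 sum(bad)))
    x <- x[!bad, ]
  }
  x |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    summarise(support = sum(.data$support), mol = .data$mol[1],
              mor = .data$mor[1], .groups = "drop") |>
    finish_junctions()
}

empty_junctions <- function() {
  tibble(junction_id = character(), chrom = character(), start = integer(),
         end = integer(), strand = character(), support = integer(),
         mol = integer(), mor = integer(), l_start = integer(),
         l_end = integer(), r_start = integer(), r_end = integer())
}

finish_junctions <- function(x) {
  x |>
    arrange(.data$chrom, .data$start, .data$end) |>
    mutate(junction_id = sprintf("JUNC%05d", dplyr::row_number()),
           l_start = .data$start, l_end = .data$start + .data$mol,
           r_start = .data$end - .data$mor, r_end = .data$end) |>
    select("junction_id", "chrom", "start", "end", "strand", "support",
           "mol", "mor", "l_start", "l_end", "r_start", "r_end")
}

#' Filter junctions on read support
#'
#' @param junctions Junction tibble.
#' @param min_reads Minimum supporting reads (default 3, the usual
#'   high-confidence cutoff).
#' @return Filtered junction tibble.
#' @export
filter_junctions <- function(junctions, min_reads = 3) {
  filter(junctions, .data$support >= min_reads)
}

#' Overlap a block with annotated exons
#'
#' Every (gene, transcript, exon) whose exon overlaps a query block by at
#' least one base (intersectBed-style half-open overlap), with the
#' overlap length.
#'
#' @param blocks Interval tibble (`chrom`, `start`, `end`); extra columns
#'   are kept.
#' @param ann A `tx_annotation`.
#' @return Tibble: one row per (block, exon) overlap, with the block's
#'   columns plus `gene_id`, `gene_name`, `transcript_id`,
#'   `exon_genomic_index`, `exon_rank`, `exon_start`, `exon_end`,
#'   `tx_strand`, `overlap_bp`.
#' @export
block_exon_hits <- function(blocks, ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  check_intervals(blocks, "blocks")
  if (nrow(blocks) == 0 || nrow(ann$exons) == 0) {
    return(dplyr::bind_cols(blocks[0, ], hit_cols_proto()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(blocks),
                                      as_granges0(ann$exons))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ex <- ann$exons[si, ]
  dplyr::bind_cols(
    blocks[qi, ],
    tibble(
      gene_id = ex$gene_id, gene_name = ex$gene_name,
      transcript_id = ex$transcript_id,
      exon_genomic_index = ex$genomic_index, exon_rank = ex$exon_rank,
      exon_start = ex$start, exon_end = ex$end, tx_strand = ex$strand,
      overlap_bp = pmin(blocks$end[qi], ex$end) - pmax(blocks$start[qi], ex$start)
    )
  )
}

hit_cols_proto <- function() {
  tibble(gene_id = character(), gene_name = character(),
         transcript_id = character(), exon_genomic_index = integer(),
         exon_rank = integer(), exon_start = integer(),
         exon_end = integer(), tx_strand = character(),
         overlap_bp = integer())
}

#' Classify splice junctions against an annotation
#'
#' Assigns each junction the first category it satisfies in the fixed
#' hierarchy:
#'
#' 1. `annotated` — left and right blocks overlap consecutive exons
#'    (adjacent in genomic order) of one transcript;
#' 2. `exon_skipping` — blocks overlap non-consecutive exons (gap of two
#'    or more genomic ranks) of one transcript;
#' 3. `only_one_side` — exactly one block overlaps an exon;
#' 4. `intra_exonic` — both blocks overlap the same single exon;
#' 5. `different_transcripts` — blocks overlap exons of two different
#'    transcripts of the same gene, with no single transcript covering
#'    both;
#' 6. `trans_splicing` — blocks overlap exons of two different genes;
#' 7. `intronic_intergenic` — neither block overlaps any exon.
#'
#' Overlap means >= 1 bp (strand-blind); a junction whose strand differs
#' from the matched transcript's strand is flagged, not vetoed.
#' Categories 2-7 are evidence of transcripts absent from the
#' annotation.
#'
#' @param junctions Junction tibble ([read_junctions()] /
#'   [simulate_junctions()]), usually after [filter_junctions()].
#' @param ann A `tx_annotation`.
#' @return An object of class `junction_calls` with elements `calls`
#'   (one row per junction: `category`, `category_name`, `evidence`,
#'   `strand_mismatch`, plus the junction columns), `gene_summary`
#'   (counts per gene symbol per category) and `config`. [tidy()]
#'   returns the calls, [glance()] the per-category histogram.
#' @export
classify_junctions <- function(junctions, ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  jx <- as_tibble(junctions)
  if (nrow(jx) == 0) {
    calls <- mutate(jx, category = integer(), category_name = character(),
                    evidence = character(), genes = character(),
                    strand_mismatch = logical())
    return(new_junction_calls(calls))
  }
  lh <- block_exon_hits(
    tibble(jid = jx$junction_id, chrom = jx$chrom,
           start = jx$l_start, end = jx$l_end), ann)
  rh <- block_exon_hits(
    tibble(jid = jx$junction_id, chrom = jx$chrom,
           start = jx$r_start, end = jx$r_end), ann)
  calls_extra <- purrr::map(seq_len(nrow(jx)), function(i) {
    classify_one(jx[i, ],
                 lh[lh$jid == jx$junction_id[i], ],
                 rh[rh$jid == jx$junction_id[i], ])
  }) |> dplyr::bind_rows()
  calls <- dplyr::bind_cols(jx, calls_extra)
  new_junction_calls(calls)
}

# Hierarchy for a single junction, given its per-block exon hits.
classify_one <- function(j, lh, rh) {
  pairs <- dplyr::inner_join(
    lh |> select("gene_id", "gene_name", "transcript_id", "tx_strand",
                 l_index = "exon_genomic_index"),
    rh |> select("transcript_id", r_index = "exon_genomic_index"),
    by = "transcript_id", relationship = "many-to-many"
  ) |> mutate(diff = .data$r_index - .data$l_index)

  res <- function(category, evidence, genes, tx_strands) {
    tibble(category = category,
           category_name = JUNCTION_CATEGORIES[category],
           evidence = evidence,
           genes = if (length(genes) == 0) NA_character_ else
             paste(unique(genes), collapse = ","),
           strand_mismatch = length(tx_strands) > 0 &&
             !(j$strand %in% c(".", "*")) && !(j$strand %in% tx_strands))
  }
  if (any(pairs$diff == 1)) {
    hit <- pairs[pairs$diff == 1, ][1, ]
    return(res(1L, sprintf("%s:exon%d>exon%d", hit$transcript_id,
                           hit$l_index, hit$r_index),
               hit$gene_name, hit$tx_strand))
  }
  if (any(pairs$diff >= 2)) {
    hit <- pairs[pairs$diff >= 2, ][1, ]
    return(res(2L, sprintf("%s:exon%d>exon%d (skips %d)", hit$transcript_id,
                           hit$l_index, hit$r_index, hit$diff - 1L),
               hit$gene_name, hit$tx_strand))
  }
  has_l <- nrow(lh) > 0
  has_r <- nrow(rh) > 0
  if (xor(has_l, has_r)) {
    hit <- if (has_l) lh[1, ] else rh[1, ]
    side <- if (has_l) "L" else "R"
    return(res(3L, sprintf("%s:%s:exon%d", side, hit$transcript_id,
                           hit$exon_genomic_index),
               hit$gene_name, hit$tx_strand))
  }
  if (any(pairs$diff == 0)) {
    hit <- pairs[pairs$diff == 0, ][1, ]
    return(res(4L, sprintf("%s:exon%d", hit$transcript_id, hit$l_index),
               hit$gene_name, hit$tx_strand))
  }
  if (!has_l && !has_r) {
    return(res(7L, NA_character_, character(0), character(0)))
  }
  cross <- dplyr::inner_join(
    lh |> select("gene_id", "gene_name", l_tx = "transcript_id",
                 l_strand = "tx_strand", l_index = "exon_genomic_index"),
    rh |> select("gene_id", r_tx = "transcript_id",
                 r_index = "exon_genomic_index"),
    by = "gene_id", relationship = "many-to-many"
  ) |> filter(.data$l_tx != .data$r_tx)
  if (nrow(cross) > 0) {
    hit <- cross[1, ]
    return(res(5L, sprintf("%s:%s:exon%d|%s:exon%d", hit$gene_id, hit$l_tx,
                           hit$l_index, hit$r_tx, hit$r_index),
               hit$gene_name, hit$l_strand))
  }
  # remaining case: both sides hit exons but never within one gene,
  # so the anchors lie in two different genes
  lg <- lh[1, ]; rg <- rh[1, ]
  res(6L, sprintf("%s>%s", lg$gene_id, rg$gene_id),
      c(lg$gene_name, rg$gene_name), c(lg$tx_strand, rg$tx_strand))
}

new_junction_calls <- function(calls) {
  gene_summary <- calls |>
    filter(!is.na(.data$genes)) |>
    tidyr::separate_rows("genes", sep = ",") |>
    count(gene = .data$genes, .data$category, .data$category_name,
          name = "n") |>
    mutate(novel = .data$category >= 2L)
  structure(list(calls = calls, gene_summary = gene_summary),
            class = "junction_calls")
}

#' @export
print.junction_calls <- function(x, ...) {
  cat(sprintf("<junction_calls> %d junction(s); %d with evidence of unannotated isoforms (categories 2-7)\n",
              nrow(x$calls), sum(x$calls$category >= 2L)))
  tab <- table(factor(x$calls$category, levels = 1:7,
                      labels = JUNCTION_CATEGORIES))
  print(tab)
  invisible(x)
}

#' Tidy junction calls
#'
#' @param x A `junction_calls` object.
#' @param ... Unused.
#' @return One row per junction with its assigned category and evidence.
#' @method tidy junction_calls
#' @export
tidy.junction_calls <- function(x, ...) as_tibble(x$calls)

#' One-row summary of junction calls
#'
#' @param x A `junction_calls` object.
#' @param ... Unused.
#' @return Tibble with total junction count, per-category counts
#'   (`n_annotated`, ..., `n_intronic_intergenic`) and `n_novel`
#'   (categories 2-7).
#' @method glance junction_calls
#' @export
glance.junction_calls <- function(x, ...) {
  counts <- as.integer(table(factor(x$calls$category, levels = 1:7)))
  out <- tibble(n_junctions = nrow(x$calls))
  for (i in 1:7) out[[paste0("n_", JUNCTION_CATEGORIES[i])]] <- counts[i]
  out$n_novel <- sum(counts[2:7])
  out
}

#' Category histogram plot of junction calls
#'
#' @param object A `junction_calls` object.
#' @param ... Unused.
#' @return A ggplot bar chart of junctions per category.
#' @method autoplot junction_calls
#' @export
autoplot.junction_calls <- function(object, ...) {
  d <- object$calls |>
    mutate(category_name = factor(.data$category_name,
                                  levels = JUNCTION_CATEGORIES))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category_name,
                                  fill = .data$category >= 2)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey50",
                                          `TRUE` = "#D55E00"),
                               labels = c("annotated", "novel evidence"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "junctions") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write junction-call artifacts
#'
#' TSV of calls, per-gene summary TSV, and a BED of category 2-7
#' junction spans for browser inspection.
#'
#' @param calls A `junction_calls` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_junction_outputs <- function(calls, dir) {
  stopifnot(inherits(calls, "junction_calls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "junction_calls.tsv")
  readr::write_tsv(tidy(calls), p1, progress = FALSE)
  p2 <- file.path(dir, "gene_summary.tsv")
  readr::write_tsv(calls$gene_summary, p2, progress = FALSE)
  p3 <- file.path(dir, "novel_junctions.bed")
  novel <- calls$calls |> filter(.data$category >= 2L)
  write_bed(novel, p3, name = "junction_id", score = "support",
            strand = "strand")
  invisible(c(p1, p2, p3))
}

#' Write junctions as TopHat-style BED12
#'
#' @param junctions Junction tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  j <- sort_intervals(junctions)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t2\t%d,%d\t0,%d",
    j$chrom, j$start, j$end, j$junction_id, j$support, j$strand,
    j$start, j$end, j$mol, j$mor, j$r_start - j$start
  )
  writeLines(lines, path)
  invisible(path)
}
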