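# Read-position ingestion and per-window counting.

#' Load uniquely mapped read placements
#'
#' Reads coordinate-sorted BED (or BAM, via Rsamtools) into a tibble of
#' placements. From BAM, secondary alignments and records with mapping
#' quality 0 are dropped as multi-mapped, and the number dropped is
#' reported.
#'
#' @param path BED (`.bed`) or BAM (`.bam`) file, sorted by
#'   chromosome/start.
#' @param chroms Optional character vector: keep placements on these
#'   chromosomes only.
#' @return Tibble `chrom`, `start`, `end`, `strand` in coordinate order.
#' @export
read_reads <- function(path, chroms = NULL) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    reads <- read_reads_bam(path)
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bed"),
      error = function(e) abort(paste0("BED parse error in ", path, ": ",
                                       conditionMessage(e)))
    )
    reads <- as_tibble0(gr)
    reads$strand <- as.character(GenomicRanges::strand(gr))
  }
  if (!is.null(chroms)) reads <- filter(reads, .data$chrom %in% chroms)
  if (nrow(reads) > 1) {
    blocks <- rle(reads$chrom)$values
    within_sorted <- reads |>
      group_by(.data$chrom) |>
      summarise(ok = !is.unsorted(.data$start), .groups = "drop")
    if (anyDuplicated(blocks) > 0 || !all(within_sorted$ok)) {
      abort(paste0(path, " is not coordinate-sorted; sort by chromosome and ",
                   "start first (e.g. `sort -k1,1 -k2,2n`)"))
    }
  }
  check_intervals(reads, "reads")
  reads
}

read_reads_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading BAM requires the Rsamtools package")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "mapq", "flag")
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  multi <- keep & (bitwAnd(b$flag, 256L) > 0L | (!is.na(b$mapq) & b$mapq == 0L))
  n_dropped <- sum(multi)
  keep <- keep & !multi
  if (n_dropped > 0) {
    inform(sprintf("dropped %d multi-mapped record(s) (secondary or MAPQ 0)",
                   n_dropped))
  }
  tibble(
    chrom = as.character(b$rname[keep]),
    start = b$pos[keep] - 1L,
    end = b$pos[keep] - 1L + b$qwidth[keep],
    strand = as.character(b$strand[keep])
  )
}

#' Count reads per window
#'
#' A read falls in the (unique) window containing its start coordinate
#' (its 5'-most genomic base), so every read is counted at most once even
#' when it straddles a window edge; strand is ignored. With
#' `method = "overlap"` a read is instead counted in every window it
#' overlaps by at least one base.
#'
#' @param windows Window tibble from [make_windows()] (sorted, disjoint
#'   within a compartment).
#' @param reads Placement tibble from [read_reads()] or
#'   [simulate_reads()].
#' @param method `"start"` (default) or `"overlap"`.
#' @return `windows` with a `count` column added.
#' @export
count_reads_in_windows <- function(windows, reads, method = c("start", "overlap")) {
  method <- match.arg(method)
  check_intervals(reads, "reads")
  if (nrow(windows) == 0) return(mutate(windows, count = integer()))
  win_gr <- as_granges0(windows)
  if (nrow(reads) == 0) return(mutate(windows, count = 0L))
  qry <- if (method == "start") {
    tibble(chrom = reads$chrom, start = reads$start, end = reads$start + 1L)
  } else {
    reads
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(qry), win_gr)
  mutate(windows, count = tabulate(S4Vectors::subjectHits(hits),
                                   nbins = nrow(windows)))
}
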