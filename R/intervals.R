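# Interval algebra over tibbles of 0-based half-open intervals.
# GRanges (1-based closed) is used internally for the set operations;
# every public surface speaks tibble(chrom, start, end).

#' Validate an interval tibble
#'
#' Checks that `x` has `chrom`, `start`, `end` columns with
#' `0 <= start < end` (0-based half-open convention used throughout).
#'
#' @param x A data frame of intervals.
#' @param what Label used in error messages.
#' @return `x` invisibly, or an error.
#' @keywords internal
check_intervals <- function(x, what = "interval set") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0)) abort(paste0(what, ": negative start coordinate"))
    bad <- which(x$start >= x$end)
    if (length(bad) > 0) {
      abort(sprintf("%s: start >= end at row %d (intervals are half-open, length > 0)",
                    what, bad[1]))
    }
  }
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> tibble, restoring 0-based half-open coordinates
as_tibble0 <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
}

sort_intervals <- function(x) dplyr::arrange(x, .data$chrom, .data$start, .data$end)

# Union (merge overlapping/adjacent) of an interval tibble.
interval_union <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  as_tibble0(GenomicRanges::reduce(as_granges0(x))) |> sort_intervals()
}

# Set difference a \ b, per base.
interval_setdiff <- function(a, b) {
  check_intervals(a, "minuend")
  check_intervals(b, "subtrahend")
  if (nrow(a) == 0) return(interval_union(a))
  if (nrow(b) == 0) return(interval_union(a))
  gra <- GenomicRanges::reduce(as_granges0(a))
  grb <- GenomicRanges::reduce(as_granges0(b))
  lvl <- union(GenomeInfoDb::seqlevels(gra), GenomeInfoDb::seqlevels(grb))
  GenomeInfoDb::seqlevels(gra) <- lvl
  GenomeInfoDb::seqlevels(grb) <- lvl
  as_tibble0(GenomicRanges::setdiff(gra, grb)) |> sort_intervals()
}

# Complement of x within [0, chrom_size) for every chromosome in chrom_sizes.
interval_complement <- function(x, chrom_sizes) {
  check_intervals(x)
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  whole <- tibble(chrom = chrom_sizes$chrom, start = 0L, end = chrom_sizes$size)
  if (nrow(x) > 0) {
    over <- dplyr::left_join(x, chrom_sizes, by = "chrom")
    if (anyNA(over$size)) {
      abort(paste0("interval on chromosome absent from chrom_sizes: ",
                   over$chrom[which(is.na(over$size))[1]]))
    }
    if (any(over$end > over$size)) {
      abort("interval exceeds chromosome size")
    }
  }
  interval_setdiff(whole, x)
}

# Total number of bases covered.
interval_bp <- function(x) {
  u <- interval_union(x)
  sum(as.numeric(u$end - u$start))
}
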