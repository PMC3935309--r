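# Genomic compartments: intronic, intergenic, genic; background-eligible
# subsets; fixed-width window tiling.

#' Derive the intronic compartment
#'
#' A base is intronic when it is covered by at least one transcript span
#' and by no exon of any transcript. This locus-wide definition (rather
#' than per-isoform introns) guarantees that intronic windows never
#' overlap an annotated exon, which is what a search for unannotated
#' transcription requires.
#'
#' @param ann A `tx_annotation` object.
#' @return Tibble of disjoint intervals `chrom`, `start`, `end`.
#' @export
derive_introns <- function(ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  interval_setdiff(ann$transcripts, ann$exons)
}

#' Derive the intergenic compartment
#'
#' The complement of the union of gene spans within `[0, chrom_size)`;
#' bases inside any gene are never intergenic, so overlapping genes are
#' handled conservatively.
#'
#' @param ann A `tx_annotation` object.
#' @return Tibble of disjoint intervals `chrom`, `start`, `end`.
#' @export
derive_intergenic <- function(ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  interval_complement(ann$genes, ann$chrom_sizes)
}

#' Derive all three compartments at once
#'
#' @param ann A `tx_annotation` object.
#' @return Tibble `chrom`, `start`, `end`, `compartment` with compartment
#'   one of `"intronic"`, `"intergenic"`, `"genic"`. Genic and intergenic
#'   partition every chromosome; intronic is a subset of genic.
#' @export
derive_compartments <- function(ann) {
  dplyr::bind_rows(
    derive_introns(ann) |> mutate(compartment = "intronic"),
    derive_intergenic(ann) |> mutate(compartment = "intergenic"),
    interval_union(ann$genes) |> mutate(compartment = "genic")
  )
}

#' Select background-eligible regions for rate estimation
#'
#' The background (no-signal) intensity is estimated from long intervals
#' kept clear of annotation edges: intergenic intervals longer than 1 Mb
#' trimmed 10 kb at both ends, and intronic intervals longer than 300 kb
#' trimmed 1 kb at both ends (defaults). Length eligibility is measured
#' on the untrimmed interval.
#'
#' @param compartments Output of [derive_compartments()] (or any tibble
#'   with `chrom`, `start`, `end`, `compartment`).
#' @param intergenic_min_len,intergenic_trim Minimum (strict) untrimmed
#'   length and symmetric end trim for intergenic intervals, in bp.
#' @param intronic_min_len,intronic_trim Same for intronic intervals.
#' @return Tibble `chrom`, `start`, `end`, `compartment` restricted to
#'   `intronic`/`intergenic`; possibly zero rows.
#' @export
select_background_regions <- function(compartments,
                                      intergenic_min_len = 1e6,
                                      intergenic_trim = 1e4,
                                      intronic_min_len = 3e5,
                                      intronic_trim = 1e3) {
  check_intervals(compartments, "compartments")
  stopifnot("compartment" %in% names(compartments))
  if (intergenic_trim * 2 >= intergenic_min_len || intronic_trim * 2 >= intronic_min_len) {
    abort("trim must be smaller than half the corresponding minimum length")
  }
  pick <- function(comp, min_len, trim) {
    compartments |>
      filter(.data$compartment == comp, .data$end - .data$start > min_len) |>
      mutate(start = .data$start + as.integer(trim),
             end = .data$end - as.integer(trim))
  }
  dplyr::bind_rows(
    pick("intronic", intronic_min_len, intronic_trim),
    pick("intergenic", intergenic_min_len, intergenic_trim)
  ) |>
    select("chrom", "start", "end", "compartment") |>
    sort_intervals()
}

#' Tile regions into fixed-width windows
#'
#' Each region is tiled left to right with consecutive `width`-bp tiles;
#' a final partial tile shorter than `width` is kept and carries its true
#' length in the `width` column (`window_size` holds the nominal width).
#' Tiles never span two regions.
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optionally
#'   `compartment` (propagated to the windows).
#' @param width Nominal window width in bp (>= 1).
#' @return Tibble `chrom`, `start`, `end`, `compartment`, `window_size`
#'   (nominal), `width` (true tile length), ordered and disjoint within a
#'   compartment.
#' @export
make_windows <- function(regions, width) {
  check_intervals(regions, "regions")
  stopifnot(length(width) == 1, width >= 1)
  width <- as.integer(width)
  if (!"compartment" %in% names(regions)) regions$compartment <- NA_character_
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  compartment = character(), window_size = integer(),
                  width = integer()))
  }
  len <- regions$end - regions$start
  n_tiles <- as.integer(ceiling(len / width))
  idx <- rep(seq_len(nrow(regions)), n_tiles)
  off <- unlist(lapply(n_tiles, function(k) seq_len(k) - 1L), use.names = FALSE)
  start <- regions$start[idx] + off * width
  end <- pmin(start + width, regions$end[idx])
  tibble(
    chrom = regions$chrom[idx],
    start = as.integer(start),
    end = as.integer(end),
    compartment = regions$compartment[idx],
    window_size = width,
    width = as.integer(end - start)
  ) |>
    arrange(.data$compartment, .data$chrom, .data$start)
}

#' Write intervals as BED
#'
#' Writes BED3 by default; supplying `name`/`score`/`strand` column names
#' extends to BED4-BED6.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @param path Output file.
#' @param name,score,strand Optional column names in `x` for BED fields
#'   4-6.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name = NULL, score = NULL, strand = NULL) {
  check_intervals(x)
  x <- sort_intervals(x)
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(name)) cols <- c(cols, list(x[[name]]))
  if (!is.null(score)) cols <- c(cols, list(x[[score]]))
  if (!is.null(strand)) cols <- c(cols, list(x[[strand]]))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write window counts as BEDGRAPH
#'
#' One line per window with its read count, suitable for genome-browser
#' coverage tracks.
#'
#' @param windows Window tibble with a `count` column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(windows, path) {
  stopifnot("count" %in% names(windows))
  w <- sort_intervals(windows)
  writeLines(sprintf("%s\t%d\t%d\t%d", w$chrom, w$start, w$end, w$count), path)
  invisible(path)
}
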