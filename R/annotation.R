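# Gene annotation container: genes -> transcripts -> ordered exons.
# All coordinates are 0-based half-open; GTF input (1-based closed) is
# converted on read, BED12 is read natively.

#' Build an annotation index from an exon table
#'
#' Constructs the gene/transcript/exon index used by every other part of
#' the toolkit from a flat exon table. Transcript and gene spans are
#' derived from their exons. Exons are ranked twice: `genomic_index`
#' (left-to-right genomic order within the transcript) and `exon_rank`
#' (transcription order: identical to `genomic_index` on the plus strand,
#' reversed on the minus strand).
#'
#' @param exons Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`, `-` or `*`), `gene_id`, `transcript_id`,
#'   and optionally `gene_name` (defaults to `gene_id`).
#' @param chrom_sizes Data frame with columns `chrom` and `size`, or the
#'   path to a two-column chrom.sizes file.
#' @return An object of class `tx_annotation`: a list of tibbles
#'   `genes`, `transcripts`, `exons`, `chrom_sizes`.
#' @export
annotation_index <- function(exons, chrom_sizes) {
  check_intervals(exons, "exon table")
  needed <- setdiff(c("gene_id", "transcript_id", "strand"), names(exons))
  if (length(needed) > 0) {
    abort(paste0("exon table lacks column(s): ", paste(needed, collapse = ", ")))
  }
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  chrom_sizes <- as_tibble(chrom_sizes)
  if (!all(c("chrom", "size") %in% names(chrom_sizes))) {
    abort("chrom_sizes needs columns `chrom` and `size`")
  }
  exons <- as_tibble(exons)
  if (!"gene_name" %in% names(exons)) exons$gene_name <- exons$gene_id
  exons <- exons |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$transcript_id, .data$start)
  if (nrow(exons) == 0) {
    exons <- mutate(exons, genomic_index = integer(), exon_rank = integer())
    span_proto <- tibble(gene_id = character(), gene_name = character(),
                         transcript_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer())
    return(structure(
      list(genes = mutate(select(span_proto, -"transcript_id"),
                          n_transcripts = integer()),
           transcripts = mutate(span_proto, n_exons = integer()),
           exons = exons, chrom_sizes = chrom_sizes),
      class = "tx_annotation"))
  }

  # structural invariant: exons of one transcript are disjoint
  overlap_prev <- exons |>
    group_by(.data$transcript_id) |>
    summarise(bad = any(.data$start < dplyr::lag(.data$end, default = -1L)),
              .groups = "drop")
  if (any(overlap_prev$bad)) {
    abort(sprintf("overlapping exons within transcript %s",
                  overlap_prev$transcript_id[which(overlap_prev$bad)[1]]))
  }
  one_strand <- exons |>
    group_by(.data$transcript_id) |>
    summarise(n = dplyr::n_distinct(.data$strand),
              g = dplyr::n_distinct(.data$gene_id), .groups = "drop")
  if (any(one_strand$n > 1)) abort("transcript with exons on both strands")
  if (any(one_strand$g > 1)) abort("transcript assigned to more than one gene")

  exons <- exons |>
    group_by(.data$transcript_id) |>
    mutate(genomic_index = dplyr::row_number(),
           exon_rank = if (isTRUE(.data$strand[1] == "-")) rev(dplyr::row_number())
                       else dplyr::row_number()) |>
    ungroup()

  transcripts <- exons |>
    group_by(.data$gene_id, .data$gene_name, .data$transcript_id,
             .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_exons = dplyr::n(), .groups = "drop")
  genes <- transcripts |>
    group_by(.data$gene_id, .data$gene_name, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_transcripts = dplyr::n(), .groups = "drop")

  missing_chrom <- setdiff(unique(exons$chrom), chrom_sizes$chrom)
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome absent from chrom_sizes: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  over <- dplyr::left_join(genes, chrom_sizes, by = "chrom")
  if (any(over$end > over$size)) abort("gene span exceeds chromosome size")

  structure(
    list(genes = sort_intervals(genes),
         transcripts = sort_intervals(transcripts),
         exons = sort_intervals(exons),
         chrom_sizes = chrom_sizes),
    class = "tx_annotation"
  )
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("<tx_annotation> %d gene(s), %d transcript(s), %d exon(s) on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              nrow(x$chrom_sizes)))
  invisible(x)
}

#' Read a chrom.sizes table
#'
#' @param path Two-column whitespace-separated file: chromosome, length.
#' @return Tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       col_types = "ci", progress = FALSE)
  if (nrow(x) == 0 || anyNA(x$size)) abort("malformed chrom.sizes file")
  x
}

#' Load a gene annotation from GTF or BED12
#'
#' GTF is read as GENCODE-dialect (exon features carrying `gene_id`,
#' `transcript_id` and optionally `gene_name` attributes) in 1-based
#' closed coordinates, converted internally to 0-based half-open. BED12
#' encodes one transcript per line; blocks become exons.
#'
#' @param path GTF (`.gtf`) or BED12 (`.bed`) file.
#' @param chrom_sizes Data frame with `chrom`/`size` columns, or path to a
#'   chrom.sizes file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return A [annotation_index()] object.
#' @export
read_annotation <- function(path, chrom_sizes, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  exons <- if (format == "gtf") read_gtf_exons(path) else read_bed12_exons(path)
  annotation_index(exons, chrom_sizes)
}

read_gtf_exons <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) abort(paste0("GTF parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  df <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df)) abort("GTF lacks a feature-type column")
  ex <- df |> filter(.data$type == "exon")
  if (nrow(ex) == 0) abort("GTF contains no exon features")
  for (col in c("gene_id", "transcript_id")) {
    if (!col %in% names(ex) || anyNA(ex[[col]])) {
      bad <- if (!col %in% names(ex)) 1L else which(is.na(ex[[col]]))[1]
      abort(sprintf("exon record %d lacks a %s attribute (exon without parent)",
                    bad, col))
    }
  }
  tibble(
    chrom = as.character(ex$seqnames),
    start = ex$start - 1L,   # 1-based closed -> 0-based half-open
    end = ex$end,
    strand = as.character(ex$strand),
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    gene_name = if ("gene_name" %in% names(ex)) {
      dplyr::coalesce(ex$gene_name, ex$gene_id)
    } else ex$gene_id
  )
}

read_bed12_exons <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) abort(paste0("BED parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (!"blocks" %in% names(S4Vectors::mcols(gr))) {
    abort("BED file is not BED12 (no block structure)")
  }
  blocks <- S4Vectors::mcols(gr)$blocks  # block coords relative to chromStart, 1-based
  n <- S4Vectors::elementNROWS(blocks)
  flat <- BiocGenerics::unlist(blocks)
  chrom_start <- rep(GenomicRanges::start(gr) - 1L, n)
  name <- S4Vectors::mcols(gr)$name
  if (is.null(name)) name <- paste0("tx", seq_along(gr))
  tibble(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), n),
    start = chrom_start + IRanges::start(flat) - 1L,
    end = chrom_start + IRanges::end(flat),
    strand = rep(as.character(GenomicRanges::strand(gr)), n),
    gene_id = rep(name, n),
    transcript_id = rep(name, n),
    gene_name = rep(name, n)
  )
}

#' Write an annotation as GENCODE-dialect GTF
#'
#' Emits gene, transcript and exon features with `gene_id`,
#' `transcript_id` and `gene_name` attributes, converting internal
#' 0-based half-open coordinates to GTF 1-based closed.
#'
#' @param ann A `tx_annotation` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "tx_annotation"))
  fmt <- function(df, feature, attr) {
    sprintf("%s\tnovotx\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$chrom, feature, df$start + 1L, df$end, df$strand, attr)
  }
  g <- ann$genes |> arrange(.data$chrom, .data$start, .data$gene_id)
  t <- ann$transcripts |> arrange(.data$chrom, .data$start, .data$transcript_id)
  e <- ann$exons |> arrange(.data$chrom, .data$start, .data$transcript_id)
  lines <- c(
    fmt(g, "gene", sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)),
    fmt(t, "transcript",
        sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                t$gene_id, t$transcript_id, t$gene_name)),
    fmt(e, "exon",
        sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d"; gene_name "%s";',
                e$gene_id, e$transcript_id, e$exon_rank, e$gene_name))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a chrom.sizes table
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(sprintf("%s\t%d", chrom_sizes$chrom, chrom_sizes$size), path)
  invisible(path)
}
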