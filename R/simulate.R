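# Synthetic data with known ground truth: annotation, uniquely mapped
# read positions with planted intronic/intergenic transcription, and
# splice junctions planted one hierarchy category at a time. Everything
# downstream is testable against the truth tables without any download.

#' Simulation configuration
#'
#' Defaults describe a desk-scale chromosome that still exercises the
#' full method with its production constants: a 10 Mb chromosome whose
#' gene layout guarantees intergenic intervals longer than 1 Mb and two
#' intronic intervals longer than 300 kb (so the default
#' background-eligibility rules select non-empty region sets), a uniform
#' Poisson background of 0.01 reads/bp (representative of a deeply
#' sequenced library restricted to one chromosome), and 20 planted transcribed
#' regions at 10-fold enrichment spanning 3-10 windows each.
#'
#' @param seed Integer seed; the same configuration always reproduces
#'   identical outputs.
#' @param chrom,chrom_length Chromosome name and length (bp).
#' @param n_genes Number of non-overlapping genes.
#' @param exons_per_transcript Inclusive range of exon counts.
#' @param exon_length,intron_length Inclusive bp ranges for exon and
#'   ordinary intron lengths.
#' @param large_intron_length Length of the single large intron given to
#'   each of the first two genes (keeps intronic background estimable
#'   under the >300 kb rule).
#' @param n_alt_genes Number of genes given a second isoform that skips
#'   one internal exon and adds one alternative exon (enables the
#'   different-transcripts junction category).
#' @param background_rate Background read-start rate, reads per bp.
#' @param read_length Simulated read length (bp); counting assigns reads
#'   by start, so this only affects file realism.
#' @param n_signal_regions Number of planted enriched regions, split
#'   evenly between intronic and intergenic compartments.
#' @param signal_fold Fold enrichment of planted regions over background
#'   (> 1).
#' @param signal_length_windows Inclusive range of planted-region
#'   lengths, in units of the compartment's window width.
#' @param junctions_per_category Junctions planted per category (scalar
#'   or length-7 vector, categories 1-7).
#' @param junction_support Inclusive range of supporting-read counts.
#' @param junction_block Block (maximal overhang) length in bp.
#' @param intronic_window,intergenic_window Window widths (bp) the
#'   planted regions are sized against.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom = "chrS", chrom_length = 10e6,
                              n_genes = 8,
                              exons_per_transcript = c(4, 8),
                              exon_length = c(120, 300),
                              intron_length = c(2000, 8000),
                              large_intron_length = 4e5,
                              n_alt_genes = 2,
                              background_rate = 0.01,
                              read_length = 50,
                              n_signal_regions = 20,
                              signal_fold = 10,
                              signal_length_windows = c(3, 10),
                              junctions_per_category = 2,
                              junction_support = c(3, 12),
                              junction_block = 20,
                              intronic_window = 200,
                              intergenic_window = 500) {
  stopifnot(signal_fold > 1 || n_signal_regions == 0,
            n_signal_regions >= 0, chrom_length > 0, n_genes >= 0,
            junction_block >= 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

rint <- function(n, range) {
  if (range[1] >= range[2]) rep(as.integer(range[1]), n)
  else as.integer(sample(seq(range[1], range[2]), n, replace = TRUE))
}

#' Simulate a gene annotation
#'
#' Lays out non-overlapping multi-exon genes on one chromosome with
#' alternating strands. The first two genes carry one large intron each;
#' the first intergenic gap and a mid-chromosome gap exceed 1 Mb, so the
#' default background-eligibility rules apply unchanged. `n_alt_genes`
#' genes receive a second isoform (one internal exon skipped, one
#' alternative exon added inside a different intron).
#'
#' @param cfg A [simulation_config()].
#' @return A `tx_annotation`; the alternative-isoform structure is
#'   recorded in `attr(, "alt_genes")` (tibble with the skipped and
#'   added exon coordinates per gene).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, simulate_annotation_impl(cfg))
}

simulate_annotation_impl <- function(cfg) {
  chrom_sizes <- tibble(chrom = cfg$chrom, size = as.integer(cfg$chrom_length))
  if (cfg$n_genes == 0) {
    ann <- annotation_index(
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             transcript_id = character(), gene_name = character()),
      chrom_sizes)
    attr(ann, "alt_genes") <- tibble(gene_id = character(),
                                     skip_start = integer(),
                                     skip_end = integer(),
                                     alt_start = integer(),
                                     alt_end = integer())
    return(ann)
  }
  n <- cfg$n_genes
  large_idx <- head(seq_len(n), 2)
  alt_idx <- if (cfg$n_alt_genes > 0 && n > 2) {
    head(setdiff(seq_len(n), large_idx), cfg$n_alt_genes)
  } else integer(0)

  gaps <- rint(n, c(5e4, 1.5e5))
  gaps[1] <- 1.5e6
  if (n >= 3) gaps[ceiling(n / 2)] <- 1.2e6

  exon_rows <- list()
  alt_rows <- list()
  cursor <- 0L
  for (i in seq_len(n)) {
    cursor <- cursor + gaps[i]
    k <- max(rint(1, cfg$exons_per_transcript),
             if (i %in% alt_idx) 5L else 2L)
    el <- rint(k, cfg$exon_length)
    il <- rint(k - 1, cfg$intron_length)
    if (i %in% large_idx) il[ceiling((k - 1) / 2)] <- as.integer(cfg$large_intron_length)
    starts <- cursor + cumsum(c(0L, head(el, -1) + il))
    ends <- starts + el
    strand <- if (i %% 2 == 1) "+" else "-"
    gid <- sprintf("G%02d", i); gname <- sprintf("GENE%02d", i)
    base <- tibble(chrom = cfg$chrom, start = starts, end = ends,
                   strand = strand, gene_id = gid,
                   transcript_id = paste0(gid, ".1"), gene_name = gname)
    exon_rows[[length(exon_rows) + 1]] <- base
    if (i %in% alt_idx) {
      # isoform 2: skip genomic exon 2, add an alternative exon centred
      # in the intron between genomic exons 4 and 5
      alt_len <- 150L
      mid <- (ends[4] + starts[5]) %/% 2L
      alt_start <- mid - alt_len %/% 2L
      alt <- tibble(chrom = cfg$chrom, start = alt_start,
                    end = alt_start + alt_len, strand = strand,
                    gene_id = gid, transcript_id = paste0(gid, ".2"),
                    gene_name = gname)
      iso2 <- dplyr::bind_rows(
        base[-2, ] |> mutate(transcript_id = paste0(gid, ".2")), alt)
      exon_rows[[length(exon_rows) + 1]] <- iso2
      alt_rows[[length(alt_rows) + 1]] <- tibble(
        gene_id = gid,
        skip_start = starts[2], skip_end = ends[2],
        alt_start = alt_start, alt_end = alt_start + alt_len)
    }
    cursor <- ends[k]
  }
  if (cursor >= cfg$chrom_length) {
    abort("infeasible packing: genes exceed the chromosome; enlarge chrom_length")
  }
  ann <- annotation_index(dplyr::bind_rows(exon_rows), chrom_sizes)
  attr(ann, "alt_genes") <- dplyr::bind_rows(alt_rows)
  ann
}

#' Simulate uniquely mapped reads with planted transcription
#'
#' Read starts are drawn Poisson-uniformly at the background rate across
#' the whole chromosome, plus an extra `(fold - 1) x background` rate
#' inside each planted region, so the local rate inside a planted region
#' is exactly `fold x background`. Planted regions are placed inside
#' intronic and intergenic intervals (alternating), at least one window
#' width away from compartment edges and at least two window widths away
#' from each other, and are recorded in a truth table.
#'
#' @param cfg A [simulation_config()].
#' @param ann The annotation from [simulate_annotation()].
#' @return List with `reads` (placement tibble, coordinate-sorted) and
#'   `truth` (tibble `region_id`, `chrom`, `start`, `end`,
#'   `compartment`, `fold`, `window_size`).
#' @export
simulate_reads <- function(cfg, ann) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(ann, "tx_annotation"))
  withr::with_seed(cfg$seed + 1L, simulate_reads_impl(cfg, ann))
}

simulate_reads_impl <- function(cfg, ann) {
  comp <- derive_compartments(ann)
  window_of <- c(intronic = cfg$intronic_window,
                 intergenic = cfg$intergenic_window)

  truth <- plant_regions(cfg, comp, window_of)

  n_bg <- rpois(1, cfg$background_rate * cfg$chrom_length)
  starts <- as.integer(floor(runif(n_bg, 0, cfg$chrom_length)))
  if (nrow(truth) > 0) {
    extra_n <- rpois(nrow(truth),
                     (cfg$signal_fold - 1) * cfg$background_rate *
                       (truth$end - truth$start))
    extra <- unlist(purrr::map(seq_len(nrow(truth)), function(i) {
      as.integer(floor(runif(extra_n[i], truth$start[i], truth$end[i])))
    }), use.names = FALSE)
    starts <- c(starts, extra)
  }
  starts <- sort(pmin(starts, as.integer(cfg$chrom_length) - 1L))
  reads <- tibble(
    chrom = cfg$chrom,
    start = starts,
    end = pmin(starts + as.integer(cfg$read_length),
               as.integer(cfg$chrom_length)),
    strand = sample(c("+", "-"), length(starts), replace = TRUE)
  )
  list(reads = reads, truth = truth)
}

# Greedy placement of planted regions into compartment intervals,
# keeping a margin of one window from interval edges and two windows
# between plantings (so two planted regions can never merge into one
# peak).
plant_regions <- function(cfg, comp, window_of) {
  if (cfg$n_signal_regions == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  compartment = character(), fold = double(),
                  window_size = integer()))
  }
  comps <- rep(c("intronic", "intergenic"),
               length.out = cfg$n_signal_regions)
  free <- lapply(c(intronic = "intronic", intergenic = "intergenic"),
                 function(cc) {
                   w <- window_of[[cc]]
                   comp |>
                     filter(.data$compartment == cc,
                            .data$end - .data$start > 2 * w) |>
                     mutate(start = .data$start + w, end = .data$end - w)
                 })
  rows <- vector("list", cfg$n_signal_regions)
  for (i in seq_len(cfg$n_signal_regions)) {
    cc <- comps[i]
    w <- window_of[[cc]]
    len <- rint(1, cfg$signal_length_windows) * w
    sep <- 2L * w
    cand <- which(free[[cc]]$end - free[[cc]]$start >= len)
    if (length(cand) == 0) {
      abort(sprintf("planted region %d (%s, %d bp) not placeable; enlarge the genome or reduce n_signal_regions",
                    i, cc, len))
    }
    seg_len <- free[[cc]]$end[cand] - free[[cc]]$start[cand]
    pick <- cand[sample.int(length(cand), 1, prob = seg_len)]
    seg <- free[[cc]][pick, ]
    s <- as.integer(floor(runif(1, seg$start, seg$end - len + 1)))
    rows[[i]] <- tibble(chrom = seg$chrom, start = s, end = s + len,
                        compartment = cc, fold = cfg$signal_fold,
                        window_size = w)
    left <- seg |> mutate(end = s - sep)
    right <- seg |> mutate(start = s + len + sep)
    free[[cc]] <- dplyr::bind_rows(
      free[[cc]][-pick, ],
      filter(left, .data$end - .data$start > 0),
      filter(right, .data$end - .data$start > 0)
    )
  }
  dplyr::bind_rows(rows) |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = sprintf("REG%03d", dplyr::row_number()), .before = 1)
}

#' Simulate splice junctions of every category
#'
#' Constructs junctions guaranteed, by the structure of the simulated
#' annotation, to satisfy exactly one category of the classification
#' hierarchy; the intended category is recorded in a truth table.
#' Category 5 (different transcripts) needs alternative-isoform genes
#' (`n_alt_genes >= 1`), category 6 (trans-splicing) needs at least two
#' genes; an unsatisfiable request errors naming the category.
#'
#' @param cfg A [simulation_config()].
#' @param ann The annotation from [simulate_annotation()].
#' @return List with `junctions` (junction tibble in the
#'   [read_junctions()] layout) and `truth` (tibble `junction_id`,
#'   `category`, `category_name`).
#' @export
simulate_junctions <- function(cfg, ann) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(ann, "tx_annotation"))
  withr::with_seed(cfg$seed + 2L, simulate_junctions_impl(cfg, ann))
}

simulate_junctions_impl <- function(cfg, ann) {
  n_per <- rep(cfg$junctions_per_category, length.out = 7)
  B <- as.integer(cfg$junction_block)
  ex <- ann$exons
  introns <- derive_introns(ann)
  intergenic <- derive_intergenic(ann)
  take <- function(cat, cand) {
    if (nrow(cand) < n_per[cat]) {
      abort(sprintf("cannot construct %d junction(s) of category %d (%s): only %d candidate site(s) in this annotation",
                    n_per[cat], cat, JUNCTION_CATEGORIES[cat], nrow(cand)))
    }
    if (n_per[cat] == 0) return(cand[0, ])
    cand[sample.int(nrow(cand), n_per[cat]), ]
  }
  # transcripts containing an exon with exactly these coordinates
  txs_with <- function(s, e) {
    ex$transcript_id[ex$start == s & ex$end == e]
  }
  jrow <- function(chrom, l_start, l_end, r_start, r_end, strand, cat) {
    tibble(chrom = chrom, start = l_start, end = r_end, strand = strand,
           support = rint(1, cfg$junction_support), mol = l_end - l_start,
           mor = r_end - r_start, category = cat)
  }

  out <- list()
  # candidate adjacent / skipped exon pairs per transcript
  pairs <- ex |>
    arrange(.data$transcript_id, .data$genomic_index) |>
    group_by(.data$transcript_id, .data$strand, .data$chrom) |>
    reframe(l_start = head(.data$start, -1), l_end = head(.data$end, -1),
            r_start = tail(.data$start, -1), r_end = tail(.data$end, -1))
  if (any(n_per[1] > 0)) {
    out$c1 <- purrr::pmap_dfr(take(1, pairs), function(transcript_id, strand,
                                                       chrom, l_start, l_end,
                                                       r_start, r_end) {
      jrow(chrom, l_end - B, l_end, r_start, r_start + B, strand, 1L)
    })
  }
  if (n_per[2] > 0) {
    skip2 <- ex |>
      arrange(.data$transcript_id, .data$genomic_index) |>
      group_by(.data$transcript_id, .data$strand, .data$chrom) |>
      reframe(l_start = head(.data$start, -2), l_end = head(.data$end, -2),
              r_start = tail(.data$start, -2), r_end = tail(.data$end, -2)) |>
      rowwise() |>
      filter({
        # unambiguous: in every transcript containing both exons the
        # genomic-index gap is >= 2
        tl <- txs_with(.data$l_start, .data$l_end)
        tr <- txs_with(.data$r_start, .data$r_end)
        common <- intersect(tl, tr)
        length(common) > 0 && all(vapply(common, function(tt) {
          ee <- ex[ex$transcript_id == tt, ]
          abs(ee$genomic_index[ee$start == .data$r_start] -
                ee$genomic_index[ee$start == .data$l_start]) >= 2
        }, logical(1)))
      }) |>
      ungroup()
    out$c2 <- purrr::pmap_dfr(take(2, skip2), function(transcript_id, strand,
                                                       chrom, l_start, l_end,
                                                       r_start, r_end) {
      jrow(chrom, l_end - B, l_end, r_start, r_start + B, strand, 2L)
    })
  }
  if (n_per[3] > 0) {
    # left anchor inside an exon, right block in the locus-wide intronic
    # compartment to its right
    cand3 <- dplyr::inner_join(
      ex |> select("chrom", "strand", exon_end = "end"),
      introns |> filter(.data$end - .data$start >= B + 60) |>
        select("chrom", i_start = "start", i_end = "end"),
      by = "chrom", relationship = "many-to-many"
    ) |> filter(.data$i_start >= .data$exon_end) |>
      distinct(.data$chrom, .data$strand, .data$exon_end,
               .keep_all = TRUE)
    out$c3 <- purrr::pmap_dfr(take(3, cand3), function(chrom, strand,
                                                       exon_end, i_start,
                                                       i_end) {
      m <- (i_start + i_end) %/% 2L
      jrow(chrom, exon_end - B, exon_end, m, m + B, strand, 3L)
    })
  }
  if (n_per[4] > 0) {
    cand4 <- ex |> filter(.data$end - .data$start >= 2 * B + 50) |>
      distinct(.data$chrom, .data$start, .data$end, .keep_all = TRUE)
    out$c4 <- purrr::pmap_dfr(
      take(4, cand4 |> select("chrom", "strand", "start", "end")),
      function(chrom, strand, start, end) {
        jrow(chrom, start + 10L, start + 10L + B,
             start + 20L + B, start + 20L + 2L * B, strand, 4L)
      })
  }
  if (n_per[5] > 0) {
    alt <- attr(ann, "alt_genes")
    if (is.null(alt) || nrow(alt) == 0) {
      abort("cannot construct category 5 (different_transcripts): the annotation has no alternative-isoform gene")
    }
    alt <- dplyr::left_join(alt,
                            ann$genes |> select("gene_id", "chrom", "strand"),
                            by = "gene_id")
    out$c5 <- purrr::pmap_dfr(take(5, alt), function(gene_id, skip_start,
                                                     skip_end, alt_start,
                                                     alt_end, chrom, strand) {
      jrow(chrom, skip_end - B, skip_end, alt_start + 10L,
           alt_start + 10L + B, strand, 5L)
    })
  }
  if (n_per[6] > 0) {
    g <- ann$genes |> arrange(.data$chrom, .data$start)
    if (nrow(g) < 2) {
      abort("cannot construct category 6 (trans_splicing): need at least two genes")
    }
    cand6 <- tibble(
      chrom = head(g$chrom, -1), strand = head(g$strand, -1),
      l_gene = head(g$gene_id, -1), r_gene = tail(g$gene_id, -1),
      same_chrom = head(g$chrom, -1) == tail(g$chrom, -1)
    ) |> filter(.data$same_chrom)
    cand6 <- cand6 |>
      rowwise() |>
      mutate(l_exon_end = max(ex$end[ex$gene_id == .data$l_gene]),
             r_exon_start = min(ex$start[ex$gene_id == .data$r_gene])) |>
      ungroup()
    out$c6 <- purrr::pmap_dfr(
      take(6, cand6 |> select("chrom", "strand", "l_exon_end",
                              "r_exon_start")),
      function(chrom, strand, l_exon_end, r_exon_start) {
        jrow(chrom, l_exon_end - B, l_exon_end,
             r_exon_start, r_exon_start + B, strand, 6L)
      })
  }
  if (n_per[7] > 0) {
    cand7 <- intergenic |> filter(.data$end - .data$start >= 2000)
    out$c7 <- purrr::pmap_dfr(
      take(7, cand7 |> select("chrom", "start", "end")),
      function(chrom, start, end) {
        m <- (start + end) %/% 2L
        jrow(chrom, m, m + B, m + B + 300L, m + 2L * B + 300L, "+", 7L)
      })
  }
  all <- dplyr::bind_rows(out) |>
    arrange(.data$chrom, .data$start, .data$end) |>
    mutate(junction_id = sprintf("JUNC%05d", dplyr::row_number()))
  junctions <- all |>
    select(-"category") |>
    mutate(l_start = .data$start, l_end = .data$start + .data$mol,
           r_start = .data$end - .data$mor, r_end = .data$end) |>
    select("junction_id", "chrom", "start", "end", "strand", "support",
           "mol", "mor", "l_start", "l_end", "r_start", "r_end")
  truth <- all |>
    select("junction_id", "category") |>
    mutate(category_name = JUNCTION_CATEGORIES[.data$category])
  list(junctions = junctions, truth = truth)
}

#' Write simulated reads as sorted BED
#'
#' @param reads Placement tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  r <- sort_intervals(reads)
  writeLines(sprintf("%s\t%d\t%d\tread%d\t0\t%s",
                     r$chrom, r$start, r$end, seq_len(nrow(r)), r$strand),
             path)
  invisible(path)
}
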