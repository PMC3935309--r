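# Junction parsing, support filtering, block overlap, and the
# seven-category hierarchy.

test_that("TopHat BED12 junction records parse into blocks", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr21\t100\t500\tJUNC1\t7\t+\t100\t500\t0\t2\t20,30\t0,370",
    "chr21\t600\t900\tJUNC2\t4\t-\t600\t900\t0\t3\t20,30,10\t0,100,290"
  ), bed)
  expect_warning(j <- read_junctions(bed), "blockCount")
  expect_equal(nrow(j), 1L)   # the 3-block record is rejected
  expect_equal(j$start, 100L)
  expect_equal(j$end, 500L)
  expect_equal(j$mol, 20L)
  expect_equal(j$mor, 30L)
  expect_equal(j$support, 7L)
  expect_equal(c(j$l_start, j$l_end), c(100L, 120L))
  expect_equal(c(j$r_start, j$r_end), c(470L, 500L))

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(read_junctions(empty)), 0L)
})

test_that("duplicate junctions merge with summed support", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t500\tJa\t3\t+\t100\t500\t0\t2\t20,30\t0,370",
    "chr1\t100\t500\tJb\t4\t+\t100\t500\t0\t2\t20,30\t0,370"
  ), bed)
  j <- read_junctions(bed)
  expect_equal(nrow(j), 1L)
  expect_equal(j$support, 7L)
})

test_that("support filtering is monotone and keeps >= min_reads", {
  j <- dplyr::bind_rows(purrr::map(1:4, function(s) {
    make_junction(0L, 20L, 100L, 120L, support = s,
                  junction_id = paste0("J", s))
  }))
  expect_equal(nrow(filter_junctions(j, 3)), 2L)
  expect_equal(filter_junctions(j, 0), j)
  expect_equal(nrow(filter_junctions(j, 99)), 0L)
  expect_true(all(filter_junctions(j, 3)$junction_id %in%
                    filter_junctions(j, 2)$junction_id))
})

test_that("block-exon overlap is >= 1 bp, half-open, and matches brute force", {
  ann <- toy_annotation()
  h <- block_exon_hits(tibble::tibble(chrom = "toy", start = 80L, end = 100L),
                       ann)
  expect_equal(nrow(h), 1L)
  expect_equal(h$overlap_bp, 20L)
  # half-open adjacency is not an overlap
  h2 <- block_exon_hits(tibble::tibble(chrom = "toy", start = 100L, end = 120L),
                        ann)
  expect_equal(nrow(h2), 0L)
  # a block spanning two exons of one transcript yields two hits
  h3 <- block_exon_hits(tibble::tibble(chrom = "toy", start = 90L, end = 210L),
                        ann)
  expect_equal(nrow(h3), 2L)
  expect_equal(sort(h3$exon_genomic_index), c(1L, 2L))

  # brute-force cross-check on random toy genomes
  for (seed in 1:6) {
    rann <- random_toy_annotation(seed)
    withr::with_seed(seed * 1000, {
      starts <- sample(0:(rann$chrom_sizes$size - 30), 40)
      blocks <- tibble::tibble(chrom = "rtoy", start = starts,
                               end = starts + sample(5:30, 40, replace = TRUE))
    })
    got <- block_exon_hits(blocks, rann) |>
      dplyr::count(.data$start, .data$end, name = "hits") |>
      dplyr::arrange(.data$start, .data$end)
    want <- purrr::pmap_dfr(blocks, function(chrom, start, end) {
      n <- sum(vapply(seq_len(nrow(rann$exons)), function(i) {
        any(seq(start, end - 1) >= rann$exons$start[i] &
              seq(start, end - 1) < rann$exons$end[i])
      }, logical(1)))
      tibble::tibble(start = start, end = end, hits = n)
    }) |>
      dplyr::filter(.data$hits > 0) |>
      dplyr::arrange(.data$start, .data$end)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 info = paste("seed", seed))
  }
})

test_that("the hierarchy assigns the documented category on the toy annotation", {
  ann <- toy_annotation()
  cases <- list(
    list(80L, 100L, 200L, 220L, 1L),    # e1 -> e2 consecutive
    list(80L, 100L, 400L, 420L, 2L),    # e1 -> e3 skipping
    list(80L, 100L, 150L, 170L, 3L),    # right side in an intron
    list(10L, 30L, 60L, 80L, 4L),       # both inside e1
    list(480L, 500L, 1000L, 1020L, 6L), # G1 -> G2
    list(120L, 140L, 150L, 170L, 7L)    # both sides intronic
  )
  jx <- dplyr::bind_rows(purrr::imap(cases, function(cs, i) {
    make_junction(cs[[1]], cs[[2]], cs[[3]], cs[[4]],
                  junction_id = sprintf("J%02d", i))
  }))
  calls <- tidy(classify_junctions(jx, ann))
  expect_equal(calls$category[match(sprintf("J%02d", 1:6), calls$junction_id)],
               c(1L, 2L, 3L, 4L, 6L, 7L))
})

test_that("different-transcripts requires two isoforms of one gene", {
  # gene with isoform A (exons a1, a2) and isoform B (exons b1 inside
  # a1-a2 intron); left block in a1 (A only below), right in b1 (B only)
  exons <- tibble::tibble(
    chrom = "toy",
    start = c(0L, 600L, 300L),
    end = c(100L, 700L, 400L),
    strand = "+",
    gene_id = "G1",
    transcript_id = c("TA", "TA", "TB"),
    gene_name = "G1")
  ann <- annotation_index(exons, tibble::tibble(chrom = "toy", size = 1000L))
  j <- make_junction(80L, 100L, 320L, 340L)
  calls <- tidy(classify_junctions(j, ann))
  expect_equal(calls$category, 5L)
  expect_match(calls$evidence, "TA")
  expect_match(calls$evidence, "TB")
})

test_that("hierarchy regression: annotated in one transcript wins over skipping in another", {
  # T1 has exons e1, e2, e3; T2 skips e2, so e1 -> e3 is adjacent in T2
  exons <- tibble::tibble(
    chrom = "toy",
    start = c(0L, 200L, 400L, 0L, 400L),
    end = c(100L, 300L, 500L, 100L, 500L),
    strand = "+",
    gene_id = "G1",
    transcript_id = c("T1", "T1", "T1", "T2", "T2"),
    gene_name = "G1")
  ann <- annotation_index(exons, tibble::tibble(chrom = "toy", size = 1000L))
  j <- make_junction(80L, 100L, 400L, 420L)
  calls <- tidy(classify_junctions(j, ann))
  expect_equal(calls$category, 1L)      # category 1 always tested first
  expect_match(calls$evidence, "T2")
})

test_that("strand mismatches are flagged, not vetoed", {
  ann <- toy_annotation()                # plus-strand transcripts
  j <- make_junction(80L, 100L, 200L, 220L, strand = "-")
  calls <- tidy(classify_junctions(j, ann))
  expect_equal(calls$category, 1L)
  expect_true(calls$strand_mismatch)
})

test_that("classification summarises per gene and handles empties", {
  ann <- toy_annotation()
  empty <- classify_junctions(make_junction(0L, 20L, 60L, 80L)[0, ], ann)
  expect_equal(nrow(tidy(empty)), 0L)
  expect_equal(nrow(empty$gene_summary), 0L)

  jx <- dplyr::bind_rows(
    make_junction(80L, 100L, 200L, 220L, junction_id = "J1"),
    make_junction(80L, 100L, 400L, 420L, junction_id = "J2"),
    make_junction(480L, 500L, 1000L, 1020L, junction_id = "J3"))
  calls <- classify_junctions(jx, ann)
  g <- glance(calls)
  expect_equal(g$n_junctions, 3L)
  expect_equal(g$n_annotated, 1L)
  expect_equal(g$n_exon_skipping, 1L)
  expect_equal(g$n_trans_splicing, 1L)
  expect_equal(g$n_novel, 2L)
  gs <- calls$gene_summary
  expect_true(all(c("G1", "G2") %in% gs$gene))
  # every junction gets exactly one category
  expect_true(all(table(tidy(calls)$junction_id) == 1))
})
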