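# Independent brute-force oracles and small fixtures shared by the test
# files. The oracles deliberately avoid the code paths they check:
# per-base mark arrays instead of interval algebra, direct pmf summation
# instead of distribution functions, an explicit step-up loop instead of
# p.adjust.

# P(X >= k) for X ~ Poisson(mu) by direct summation of the pmf below k.
oracle_poisson_upper <- function(k, mu) {
  if (k == 0) return(1)
  terms <- exp(-mu) * cumprod(c(1, rep(mu, k - 1)) / c(1, seq_len(k - 1)))
  max(1 - sum(terms), 0)
}

# Step-up BH by the definition q_(i) = min_{j>=i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Per-base compartment membership over a toy chromosome: 1 byte per base.
# genic = inside some gene span; exonic = inside some exon; intronic =
# inside some transcript span and not exonic; intergenic = not genic.
oracle_compartments <- function(ann) {
  size <- ann$chrom_sizes$size[1]
  exonic <- logical(size)
  txspan <- logical(size)
  genespan <- logical(size)
  for (i in seq_len(nrow(ann$exons))) {
    exonic[(ann$exons$start[i] + 1):ann$exons$end[i]] <- TRUE
  }
  for (i in seq_len(nrow(ann$transcripts))) {
    txspan[(ann$transcripts$start[i] + 1):ann$transcripts$end[i]] <- TRUE
  }
  for (i in seq_len(nrow(ann$genes))) {
    genespan[(ann$genes$start[i] + 1):ann$genes$end[i]] <- TRUE
  }
  list(intronic = txspan & !exonic, intergenic = !genespan)
}

# Convert a logical per-base mask (index b = base b-1) to 0-based
# half-open intervals.
mask_to_intervals <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(chrom = chrom, start = starts[r$values],
                 end = ends[r$values])
}

# Spec'd toy annotation used throughout the junction tests:
# gene G1 / transcript T1 with exons [0,100), [200,300), [400,500);
# gene G2 / transcript T2 with exon [1000,1100).
toy_annotation <- function(chrom_size = 2000) {
  exons <- tibble::tibble(
    chrom = "toy",
    start = c(0L, 200L, 400L, 1000L),
    end = c(100L, 300L, 500L, 1100L),
    strand = "+",
    gene_id = c("G1", "G1", "G1", "G2"),
    transcript_id = c("T1", "T1", "T1", "T2"),
    gene_name = c("G1", "G1", "G1", "G2")
  )
  annotation_index(exons, tibble::tibble(chrom = "toy",
                                         size = as.integer(chrom_size)))
}

# A junction tibble from explicit block coordinates.
make_junction <- function(l_start, l_end, r_start, r_end, chrom = "toy",
                          strand = "+", support = 5L,
                          junction_id = "JTEST") {
  tibble::tibble(
    junction_id = junction_id, chrom = chrom, start = l_start, end = r_end,
    strand = strand, support = support,
    mol = l_end - l_start, mor = r_end - r_start,
    l_start = l_start, l_end = l_end, r_start = r_start, r_end = r_end
  )
}

# Random small genome for the interval-algebra property tests; genes may
# have two isoforms with one exon dropped, so locus-wide intron logic is
# exercised. Everything fits in <= 10 kb.
random_toy_annotation <- function(seed) {
  withr::with_seed(seed, {
    size <- sample(2000:10000, 1)
    n_genes <- sample(0:3, 1)
    rows <- list()
    cursor <- sample(0:200, 1)
    for (g in seq_len(n_genes)) {
      n_ex <- sample(1:4, 1)
      el <- sample(20:120, n_ex, replace = TRUE)
      il <- if (n_ex > 1) sample(30:250, n_ex - 1, replace = TRUE) else integer(0)
      starts <- cursor + cumsum(c(0L, utils::head(el, -1) + il))
      ends <- starts + el
      if (max(ends) >= size) break
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("g%d", g)
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = "rtoy", start = starts, end = ends, strand = strand,
        gene_id = gid, transcript_id = paste0(gid, ".1"), gene_name = gid)
      if (n_ex >= 3 && stats::runif(1) < 0.5) {
        drop <- sample(2:(n_ex - 1), 1)
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = "rtoy", start = starts[-drop], end = ends[-drop],
          strand = strand, gene_id = gid,
          transcript_id = paste0(gid, ".2"), gene_name = gid)
      }
      cursor <- max(ends) + sample(50:400, 1)
    }
    exons <- if (length(rows) == 0) {
      tibble::tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), gene_id = character(),
                     transcript_id = character(), gene_name = character())
    } else {
      dplyr::bind_rows(rows)
    }
    annotation_index(exons, tibble::tibble(chrom = "rtoy", size = size))
  })
}
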