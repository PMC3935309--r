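# Background model, Poisson test, BH correction, merging, flank scan.

test_that("poisson_upper_tail matches direct pmf summation", {
  expect_equal(poisson_upper_tail(0, 1), 1)
  expect_equal(poisson_upper_tail(3, 1), oracle_poisson_upper(3, 1),
               tolerance = 1e-12)
  # frozen oracle values: 1 - e^-1 (1 + 1 + 1/2) and the k = 10 tail
  expect_equal(poisson_upper_tail(3, 1), 0.0803014, tolerance = 1e-6)
  expect_equal(poisson_upper_tail(10, 1), 1.1142e-07, tolerance = 1e-4)
  for (mu in c(0.1, 0.7, 2, 9.5, 31, 50)) {
    for (k in c(0:6, 20, 87, 200)) {
      expect_lt(abs(poisson_upper_tail(k, mu) - oracle_poisson_upper(k, mu)),
                1e-10)
    }
  }
  expect_error(poisson_upper_tail(3, 0), "mu")
  expect_error(poisson_upper_tail(-1, 1), "k")
})

test_that("p is monotone: decreasing in k, increasing in mu", {
  p_k <- poisson_upper_tail(0:30, 2)
  expect_true(all(diff(p_k) < 0))
  mus <- seq(0.5, 20, by = 0.5)
  p_mu <- poisson_upper_tail(rep(5, length(mus)), mus)
  expect_true(all(diff(p_mu) > 0))
})

test_that("bh_adjust equals the brute-force step-up oracle and is order-invariant", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(c(0.04, 0.5, 1.0)), c(0.12, 0.75, 1.0))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  withr::with_seed(99, {
    for (i in 1:20) {
      p <- runif(sample(c(1, 5, 100, 1000), 1))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
      perm <- sample.int(length(p))
      expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
    }
  })
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
})

test_that("lambda is the MLE rate: background reads over background bp", {
  reads <- tibble::tibble(chrom = "c", start = seq(0L, by = 200L,
                                                   length.out = 500),
                          end = seq(0L, by = 200L, length.out = 500) + 50L,
                          strand = "+")
  bg <- tibble::tibble(chrom = "c", start = 0L, end = 100000L)
  expect_equal(estimate_lambda(reads, bg), 0.005)
  # reads starting outside the background do not count
  far <- dplyr::mutate(reads, start = start + 500000L, end = end + 500000L)
  expect_equal(estimate_lambda(far, bg), 0)
  expect_error(estimate_lambda(reads, bg[0, ]), "empty background")
})

test_that("lambda estimate is consistent on Poisson-simulated coverage", {
  withr::with_seed(5, {
    rate <- 0.01
    n <- rpois(1, rate * 1e6)
    reads <- tibble::tibble(chrom = "c",
                            start = sort(as.integer(floor(runif(n, 0, 1e6)))),
                            end = 0L, strand = "+")
    reads$end <- reads$start + 50L
    lam <- estimate_lambda(reads, tibble::tibble(chrom = "c", start = 0L,
                                                 end = 1000000L))
    se <- sqrt(rate / 1e6)
    expect_lt(abs(lam - rate), 3 * se)
  })
})

test_that("fit_background falls back and pseudocounts degenerate compartments", {
  comp <- tibble::tibble(chrom = "c", start = c(0L, 5000L),
                         end = c(4000L, 9000L),
                         compartment = c("intronic", "intergenic"))
  bg <- comp[0, ]  # nothing is background-eligible
  reads <- tibble::tibble(chrom = "c", start = c(100L, 200L, 6000L),
                          end = c(150L, 250L, 6050L), strand = "+")
  w <- capture_warnings(
    m <- fit_background(reads, bg, compartments = comp, fallback_buffer = 100))
  expect_match(w, "whole compartment", all = TRUE)
  expect_true(all(m$fallback))
  expect_equal(m$lambda[m$compartment == "intronic"], 2 / 3800)
  # zero reads in a compartment: pseudocount of one read
  none <- reads[reads$start < 5000, ]
  m2 <- suppressWarnings(fit_background(none, bg, compartments = comp,
                                        fallback_buffer = 100))
  expect_equal(m2$lambda[m2$compartment == "intergenic"], 1 / 3800)
  expect_true(m2$pseudocount[m2$compartment == "intergenic"])
  expect_error(suppressWarnings(fit_background(reads, bg, fallback = FALSE)),
               "background-eligible")
})

test_that("call_windows scales mu by true width and corrects per compartment", {
  windows <- tibble::tibble(
    chrom = "c", start = c(0L, 200L, 400L), end = c(200L, 400L, 450L),
    compartment = "intronic", window_size = 200L,
    width = c(200L, 200L, 50L), count = c(1L, 0L, 0L))
  model <- tibble::tibble(compartment = c("intronic", "intergenic"),
                          lambda = c(0.005, 0.001))
  out <- call_windows(windows, model)
  expect_equal(out$mu, c(1, 1, 0.25))   # partial tile gets a scaled mean
  expect_equal(out$p[2], 1)             # k = 0 is never enriched
  expect_false(any(out$significant))
  expect_error(call_windows(dplyr::mutate(windows, compartment = "flank"),
                            model), "no background rate")
})

test_that("a strong outlier window is significant among a thousand nulls", {
  withr::with_seed(17, {
    windows <- make_windows(tibble::tibble(chrom = "c", start = 0L,
                                           end = 200000L), 200) |>
      dplyr::mutate(compartment = "intronic",
                    count = rpois(dplyr::n(), 1))
    windows$count[500] <- 50L
    model <- tibble::tibble(compartment = "intronic", lambda = 0.005)
    out <- call_windows(windows, model, fdr = 0.05)
    expect_true(out$significant[500])
    expect_equal(sum(out$significant), 1L)
  })
})

test_that("null windows yield no significant calls after BH", {
  withr::with_seed(23, {
    windows <- make_windows(tibble::tibble(chrom = "c", start = 0L,
                                           end = 2000000L), 200) |>
      dplyr::mutate(compartment = "intronic",
                    count = rpois(dplyr::n(), 0.4))
    model <- tibble::tibble(compartment = "intronic", lambda = 0.002)
    out <- call_windows(windows, model)
    expect_equal(sum(out$significant), 0L)
  })
})

test_that("empirical type-I error matches the discrete Poisson null level", {
  # Poisson p-values are discrete: the attainable fraction below alpha is
  # P(X >= k_alpha), the largest attainable level <= alpha, never more.
  withr::with_seed(31, {
    mu <- 0.4
    n <- 10000
    k <- rpois(n, mu)
    p <- poisson_upper_tail(k, rep(mu, n))
    for (alpha in c(0.01, 0.05)) {
      lvls <- poisson_upper_tail(0:30, rep(mu, 31))
      exact <- max(c(0, lvls[lvls <= alpha]))
      frac <- mean(p <= alpha)
      sigma <- sqrt(exact * (1 - exact) / n)
      expect_lt(abs(frac - exact), 3 * sigma + 1e-12)
      expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / n))
    }
  })
})

test_that("merging follows the gap <= window-size rule", {
  mk <- function(starts, ends, sig = TRUE) {
    tibble::tibble(chrom = "c", start = as.integer(starts),
                   end = as.integer(ends), compartment = "intronic",
                   window_size = 200L, width = as.integer(ends - starts),
                   count = 10L, mu = 1, p = 1e-8, q = 1e-6,
                   significant = sig)
  }
  expect_equal(nrow(merge_hcps(mk(c(0, 200), c(200, 400)))), 1L)
  h <- merge_hcps(mk(c(0, 400), c(200, 600)))   # gap 200 = window size
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 600L))
  h2 <- merge_hcps(mk(c(0, 500), c(200, 700)))  # gap 300 > window size
  expect_equal(nrow(h2), 2L)
  # summaries: member count, total reads, min q
  expect_equal(h$n_windows, 2L)
  expect_equal(h$total_reads, 20L)
  expect_equal(h$min_q, 1e-6)
  # windows of different compartments never merge
  w <- dplyr::bind_rows(mk(0, 200),
                        dplyr::mutate(mk(200, 400), compartment = "intergenic"))
  expect_equal(nrow(merge_hcps(w)), 2L)
  expect_equal(nrow(merge_hcps(dplyr::mutate(w, significant = FALSE))), 0L)
})

test_that("flank windows are strand-aware and flagged near edges and exons", {
  exons <- tibble::tibble(
    chrom = "c", start = c(10000L, 12000L, 19000L, 19900L),
    end = c(10500L, 12500L, 19500L, 20000L),
    strand = c("+", "+", "-", "-"),
    gene_id = c("gp", "gp", "gm", "gm"),
    transcript_id = c("tp", "tp", "tm", "tm"))
  ann <- annotation_index(exons, tibble::tibble(chrom = "c", size = 20100L))
  model <- tibble::tibble(compartment = c("intronic", "intergenic"),
                          lambda = c(0.001, 0.001))
  reads <- tibble::tibble(chrom = "c", start = 9850L, end = 9900L,
                          strand = "+")
  fl <- scan_flanks(ann, reads, model, widths = c(200))
  plus_up <- fl[fl$transcript_id == "tp" & fl$side == "upstream", ]
  expect_equal(c(plus_up$start, plus_up$end), c(9800L, 10000L))
  minus_up <- fl[fl$transcript_id == "tm" & fl$side == "upstream", ]
  expect_equal(c(minus_up$start, minus_up$end), c(20000L, 20100L))
  expect_true(minus_up$truncated)            # chromosome edge: rescaled
  expect_equal(minus_up$true_width, 100L)
  expect_equal(plus_up$count, 1L)
  minus_down <- fl[fl$transcript_id == "tm" & fl$side == "downstream", ]
  expect_equal(c(minus_down$start, minus_down$end), c(18800L, 19000L))
  # zero reads anywhere -> all p-values exactly 1
  fl0 <- scan_flanks(ann, reads[0, ], model, widths = c(50, 200))
  expect_true(all(fl0$p == 1))
  # a flank overlapping an annotated exon is flagged
  plus_down <- fl[fl$transcript_id == "tp" & fl$side == "downstream", ]
  expect_equal(c(plus_down$start, plus_down$end), c(12500L, 12700L))
  expect_false(plus_down$overlaps_exon)
  fl_wide <- scan_flanks(ann, reads, model, widths = c(7000))
  expect_true(any(fl_wide$overlaps_exon))
})
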