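# High coverage peak (HCP) discovery: Poisson background model per
# compartment, per-window upper-tail test, BH-FDR, merging of significant
# windows, and the variable-width flank scan around transcript ends.

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(mu)`: the enrichment p-value of observing
#' at least `k` reads in a window whose background expectation is `mu`.
#' Equals 1 when `k = 0`.
#'
#' @param k Observed counts (non-negative integers); vectorised.
#' @param mu Expected counts (> 0); vectorised.
#' @return P-values in `(0, 1]`.
#' @export
poisson_upper_tail <- function(k, mu) {
  if (any(k < 0) || any(k != floor(k))) abort("k must be non-negative integers")
  if (any(mu <= 0)) abort("mu must be > 0")
  ppois(k - 1, lambda = mu, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up q-values: `q_(i) = min_(j >= i) p_(j) * m / j`,
#' capped at 1, returned in input order.
#'
#' @param p P-values in `(0, 1]`.
#' @return Q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Maximum-likelihood background rate
#'
#' The Poisson MLE of a homogeneous per-bp rate: reads starting inside
#' the background regions divided by the total background length.
#'
#' @param reads Placement tibble.
#' @param regions Background interval tibble (possibly one compartment of
#'   [select_background_regions()] output).
#' @return Rate in reads per bp (may be 0 if no reads; see
#'   [fit_background()] for the pseudocount policy).
#' @export
estimate_lambda <- function(reads, regions) {
  check_intervals(regions, "background regions")
  bp <- interval_bp(regions)
  if (bp <= 0) {
    abort(paste0("empty background region set; relax the length/trim ",
                 "thresholds or use the whole-compartment fallback in ",
                 "fit_background()"))
  }
  starts <- tibble(chrom = reads$chrom, start = reads$start,
                   end = reads$start + 1L)
  n <- sum(overlaps_any(starts, interval_union(regions)))
  n / bp
}

#' Fit the per-compartment background model
#'
#' Estimates one rate per compartment (intronic and intergenic,
#' independently) from background-eligible regions. If a compartment has
#' no eligible region, and `fallback = TRUE`, the rate is estimated from
#' the whole compartment with `fallback_buffer` bp trimmed from each
#' interval end (a warning notes the fallback). A compartment with zero
#' background reads gets a pseudocount of one read over its background
#' span, with a warning, so that p-values stay defined.
#'
#' @param reads Placement tibble.
#' @param background Output of [select_background_regions()].
#' @param compartments Output of [derive_compartments()]; needed only for
#'   the fallback.
#' @param fallback Use whole-compartment fallback when a compartment has
#'   no eligible background region.
#' @param fallback_buffer Bp trimmed from each interval end in fallback
#'   estimation.
#' @return A `background_model`: tibble `compartment`, `lambda` (reads
#'   per bp), `n_reads`, `total_bp`, `fallback`, `pseudocount`.
#' @export
fit_background <- function(reads, background, compartments = NULL,
                           fallback = TRUE, fallback_buffer = 1e3) {
  one <- function(comp) {
    reg <- filter(background, .data$compartment == comp)
    used_fallback <- FALSE
    if (interval_bp(reg) <= 0) {
      if (!fallback || is.null(compartments)) {
        abort(sprintf(paste0("no background-eligible %s region; supply ",
                             "`compartments` with fallback = TRUE or relax ",
                             "the thresholds"), comp))
      }
      warn(sprintf(paste0("no background-eligible %s region; estimating the ",
                          "rate from the whole compartment minus a %d bp ",
                          "edge buffer"), comp, as.integer(fallback_buffer)))
      reg <- compartments |>
        filter(.data$compartment == comp,
               .data$end - .data$start > 2 * fallback_buffer) |>
        mutate(start = .data$start + as.integer(fallback_buffer),
               end = .data$end - as.integer(fallback_buffer))
      if (interval_bp(reg) <= 0) {
        abort(sprintf("fallback also yielded an empty %s background", comp))
      }
      used_fallback <- TRUE
    }
    bp <- interval_bp(reg)
    lam <- estimate_lambda(reads, reg)
    n <- lam * bp
    pseudo <- FALSE
    if (n == 0) {
      warn(sprintf("zero background reads in %s; applying a pseudocount of 1 read",
                   comp))
      lam <- 1 / bp
      pseudo <- TRUE
    }
    tibble(compartment = comp, lambda = lam, n_reads = round(n),
           total_bp = bp, fallback = used_fallback, pseudocount = pseudo)
  }
  model <- dplyr::bind_rows(lapply(c("intronic", "intergenic"), one))
  class(model) <- c("background_model", class(model))
  model
}

#' Test windows for enrichment over background
#'
#' For each window the expected count is `mu = lambda_compartment x true
#' width`; the p-value is the Poisson upper tail `P(X >= count)`, and BH
#' correction is applied separately within each compartment (the two
#' families have independently estimated rates). `pool = TRUE` corrects
#' across all windows as one family instead.
#'
#' @param windows Window tibble with `count` (from
#'   [count_reads_in_windows()]).
#' @param model A `background_model` from [fit_background()].
#' @param fdr Significance threshold on the q-value.
#' @param pool Pool the BH correction across compartments.
#' @return `windows` with `mu`, `p`, `q`, `significant` columns.
#' @export
call_windows <- function(windows, model, fdr = 0.05, pool = FALSE) {
  stopifnot("count" %in% names(windows))
  lam <- setNames(model$lambda, model$compartment)
  unknown <- setdiff(unique(windows$compartment), names(lam))
  if (length(unknown) > 0) {
    abort(paste0("no background rate for compartment: ",
                 paste(unknown, collapse = ", ")))
  }
  out <- windows |>
    mutate(mu = unname(lam[.data$compartment]) * .data$width,
           p = poisson_upper_tail(.data$count, .data$mu))
  out <- if (pool) {
    mutate(out, q = bh_adjust(.data$p))
  } else {
    out |>
      group_by(.data$compartment) |>
      mutate(q = bh_adjust(.data$p)) |>
      ungroup()
  }
  mutate(out, significant = .data$q <= fdr)
}

#' Merge significant windows into high coverage peaks
#'
#' Consecutive significant windows of the same compartment (and
#' chromosome) are merged when the gap between them is at most the
#' nominal window size. Each HCP records its merged span, the number of
#' member windows, their total read count and the minimum q-value.
#'
#' @param windows Output of [call_windows()].
#' @return Tibble `hcp_id`, `chrom`, `start`, `end`, `compartment`,
#'   `n_windows`, `total_reads`, `min_q`.
#' @export
merge_hcps <- function(windows) {
  stopifnot(all(c("significant", "window_size") %in% names(windows)))
  sig <- windows |>
    filter(.data$significant) |>
    arrange(.data$compartment, .data$chrom, .data$start)
  if (nrow(sig) == 0) {
    return(tibble(hcp_id = character(), chrom = character(), start = integer(),
                  end = integer(), compartment = character(),
                  n_windows = integer(), total_reads = integer(),
                  min_q = double()))
  }
  sig |>
    group_by(.data$compartment, .data$chrom) |>
    mutate(gap = .data$start - dplyr::lag(.data$end, default = NA_integer_),
           new_run = is.na(.data$gap) | .data$gap > .data$window_size,
           run = cumsum(.data$new_run)) |>
    group_by(.data$compartment, .data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = dplyr::n(),
              total_reads = sum(.data$count),
              min_q = min(.data$q), .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    mutate(hcp_id = sprintf("HCP%04d", dplyr::row_number())) |>
    select("hcp_id", "chrom", "start", "end", "compartment",
           "n_windows", "total_reads", "min_q")
}

#' Scan transcript flanks with a ladder of window widths
#'
#' Places windows of each width immediately upstream of every transcript
#' start site and immediately downstream of every transcript end
#' (strand-aware: upstream of a minus-strand transcript extends toward
#' larger coordinates). Reports counts and the Poisson p-value against
#' the intergenic rate; no multiple-testing correction is applied by
#' default because the scan is a coverage assessment, not a test family.
#' Windows truncated at a chromosome edge are rescaled to their true
#' width and flagged; windows overlapping any annotated exon are flagged.
#'
#' @param ann A `tx_annotation` object.
#' @param reads Placement tibble.
#' @param model A `background_model`.
#' @param widths Window-width ladder in bp.
#' @return Tibble keyed by `transcript_id`, `side` and nominal `width`,
#'   with `chrom`, `start`, `end`, `true_width`, `truncated`, `count`,
#'   `mu`, `p`, `overlaps_exon`.
#' @export
scan_flanks <- function(ann, reads, model,
                        widths = c(50, 100, 200, 500, 1000)) {
  stopifnot(inherits(ann, "tx_annotation"))
  lam <- model$lambda[model$compartment == "intergenic"]
  if (length(lam) != 1) abort("model lacks an intergenic rate")
  tx <- ann$transcripts
  grid <- tidyr::expand_grid(
    tx |> select("transcript_id", "gene_id", "chrom", "strand",
                 tx_start = "start", tx_end = "end"),
    width = as.integer(widths),
    side = c("upstream", "downstream")
  )
  fl <- grid |>
    mutate(
      start = dplyr::case_when(
        .data$side == "upstream" & .data$strand != "-" ~ .data$tx_start - .data$width,
        .data$side == "upstream" & .data$strand == "-" ~ .data$tx_end,
        .data$side == "downstream" & .data$strand != "-" ~ .data$tx_end,
        TRUE ~ .data$tx_start - .data$width
      ),
      end = .data$start + .data$width
    ) |>
    dplyr::left_join(ann$chrom_sizes, by = "chrom") |>
    mutate(start_clip = pmax(.data$start, 0L),
           end_clip = pmin(.data$end, .data$size),
           truncated = .data$start_clip != .data$start | .data$end_clip != .data$end,
           start = .data$start_clip, end = .data$end_clip) |>
    filter(.data$end > .data$start) |>
    mutate(true_width = .data$end - .data$start)
  counted <- count_reads_in_windows(
    fl |> select("chrom", "start", "end"), reads
  )
  fl$count <- counted$count
  fl |>
    mutate(mu = lam * .data$true_width,
           p = poisson_upper_tail(.data$count, .data$mu),
           overlaps_exon = overlaps_any(fl, ann$exons)) |>
    select("transcript_id", "gene_id", "side", "width", "chrom", "start",
           "end", "true_width", "truncated", "count", "mu", "p",
           "overlaps_exon")
}

# logical: does each interval in x overlap any interval in y?
overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  GenomicRanges::countOverlaps(as_granges0(x), as_granges0(y)) > 0
}
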