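# End-to-end HCP discovery: reads + annotation -> windows, model, peaks.

#' Discover high coverage peaks
#'
#' Runs the full discovery pipeline: derive intronic and intergenic
#' compartments from the annotation, tile them into windows (200 bp
#' intronic, 500 bp intergenic by default), count uniquely mapped read
#' starts per window, estimate the per-compartment background rate by
#' maximum likelihood on long annotation-distant regions, test each
#' window with a Poisson upper-tail p-value, apply BH-FDR within each
#' compartment, and merge significant windows whose gaps do not exceed
#' the window size into HCPs.
#'
#' @param reads Placement tibble ([read_reads()] / [simulate_reads()]).
#' @param ann A `tx_annotation` ([read_annotation()] /
#'   [simulate_annotation()]).
#' @param intronic_window,intergenic_window Window widths in bp.
#' @param fdr Q-value significance threshold.
#' @param intergenic_min_len,intergenic_trim,intronic_min_len,intronic_trim
#'   Background-eligibility rules (see [select_background_regions()]).
#' @param pool_fdr Pool BH across compartments instead of correcting each
#'   family separately.
#' @param count_method `"start"` or `"overlap"` (see
#'   [count_reads_in_windows()]).
#' @param background_fallback Use the whole-compartment fallback when no
#'   region is background-eligible (see [fit_background()]).
#' @param flank_widths Optional width ladder for [scan_flanks()]; `NULL`
#'   skips the flank scan.
#' @return An object of class `hcp_fit` with elements `hcps`, `windows`,
#'   `model`, `flanks` (or `NULL`) and `config`. Use [tidy()] for the
#'   peak table, [glance()] for a one-row summary and [autoplot()] for a
#'   window-level overview.
#' @export
call_hcp <- function(reads, ann,
                     intronic_window = 200, intergenic_window = 500,
                     fdr = 0.05,
                     intergenic_min_len = 1e6, intergenic_trim = 1e4,
                     intronic_min_len = 3e5, intronic_trim = 1e3,
                     pool_fdr = FALSE, count_method = "start",
                     background_fallback = TRUE, flank_widths = NULL) {
  stopifnot(inherits(ann, "tx_annotation"))
  comp <- derive_compartments(ann)
  bg <- select_background_regions(
    comp,
    intergenic_min_len = intergenic_min_len, intergenic_trim = intergenic_trim,
    intronic_min_len = intronic_min_len, intronic_trim = intronic_trim
  )
  model <- fit_background(reads, bg, compartments = comp,
                          fallback = background_fallback)
  windows <- dplyr::bind_rows(
    make_windows(filter(comp, .data$compartment == "intronic"), intronic_window),
    make_windows(filter(comp, .data$compartment == "intergenic"), intergenic_window)
  ) |>
    count_reads_in_windows(reads, method = count_method) |>
    call_windows(model, fdr = fdr, pool = pool_fdr)
  hcps <- merge_hcps(windows)
  flanks <- if (!is.null(flank_widths)) {
    scan_flanks(ann, reads, model, widths = flank_widths)
  }
  structure(
    list(hcps = hcps, windows = windows, model = model, flanks = flanks,
         config = list(
           intronic_window = intronic_window,
           intergenic_window = intergenic_window, fdr = fdr,
           intergenic_min_len = intergenic_min_len,
           intergenic_trim = intergenic_trim,
           intronic_min_len = intronic_min_len,
           intronic_trim = intronic_trim,
           pool_fdr = pool_fdr, count_method = count_method
         )),
    class = "hcp_fit"
  )
}

#' @export
print.hcp_fit <- function(x, ...) {
  cat(sprintf("<hcp_fit> %d window(s), %d significant at q <= %g, %d HCP(s)\n",
              nrow(x$windows), sum(x$windows$significant), x$config$fdr,
              nrow(x$hcps)))
  lam <- setNames(x$model$lambda, x$model$compartment)
  cat(sprintf("  background rate: intronic %.3g /bp, intergenic %.3g /bp\n",
              lam[["intronic"]], lam[["intergenic"]]))
  invisible(x)
}

#' Tidy the peak table of an HCP fit
#'
#' @param x An `hcp_fit`.
#' @param ... Unused.
#' @return The HCP tibble (one row per merged peak).
#' @method tidy hcp_fit
#' @export
tidy.hcp_fit <- function(x, ...) x$hcps

#' One-row summary of an HCP fit
#'
#' @param x An `hcp_fit`.
#' @param ... Unused.
#' @return Tibble with window/peak counts and background rates.
#' @method glance hcp_fit
#' @export
glance.hcp_fit <- function(x, ...) {
  lam <- setNames(x$model$lambda, x$model$compartment)
  tibble(
    n_windows = nrow(x$windows),
    n_significant = sum(x$windows$significant),
    n_hcps = nrow(x$hcps),
    n_reads_assigned = sum(x$windows$count),
    lambda_intronic = lam[["intronic"]],
    lambda_intergenic = lam[["intergenic"]],
    fdr = x$config$fdr
  )
}

#' Window-level overview plot of an HCP fit
#'
#' Plots per-window enrichment (-log10 q) along the chromosome, faceted
#' by compartment, with merged HCP spans overlaid.
#'
#' @param object An `hcp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hcp_fit
#' @export
autoplot.hcp_fit <- function(object, ...) {
  w <- object$windows |>
    mutate(neglog_q = -log10(pmax(.data$q, 1e-300)),
           mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mid, y = .data$neglog_q)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(object$config$fdr),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_grid(.data$compartment ~ .data$chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10] ~ q),
                  colour = "significant")
  if (nrow(object$hcps) > 0) {
    p <- p + ggplot2::geom_segment(
      data = object$hcps,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
      inherit.aes = FALSE, colour = "#0072B2", linewidth = 2
    )
  }
  p
}

#' Write the artifacts of an HCP fit
#'
#' BED6 of peaks (score = -10 log10(min q), capped at 1000), the full
#' window table and, when present, the flank-scan table as TSV.
#'
#' @param fit An `hcp_fit`.
#' @param dir Output directory (created if needed).
#' @param windows Also write the window-level table.
#' @return Character vector of paths written, invisibly.
#' @export
write_hcp_outputs <- function(fit, dir, windows = FALSE) {
  stopifnot(inherits(fit, "hcp_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  hb <- fit$hcps |>
    mutate(score = pmin(round(-10 * log10(pmax(.data$min_q, 1e-100))), 1000),
           strand = ".")
  p <- file.path(dir, "hcps.bed")
  write_bed(hb, p, name = "hcp_id", score = "score", strand = "strand")
  paths <- c(paths, p)
  if (windows) {
    p <- file.path(dir, "windows.tsv")
    readr::write_tsv(fit$windows, p, progress = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(fit$flanks)) {
    p <- file.path(dir, "flanks.tsv")
    readr::write_tsv(fit$flanks, p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
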