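#' Count CpG dinucleotides per mapped fragment
#'
#' Counts occurrences of the CpG dinucleotide ("CG" on the forward strand)
#' wholly inside each fragment interval. The dinucleotide is its own reverse
#' complement, so forward-strand counting covers both strands without double
#' counting; a CG straddling the fragment end (C at `end - 1`) is not
#' counted. Matching is case-insensitive by default so that soft-masked
#' repeats keep their CpGs; `uppercase_only = TRUE` restricts to unmasked
#' sequence. `N` bases never match.
#'
#' @param fragments A fragment tibble (`chrom`, `start`, `end`).
#' @param genome A [Biostrings::BStringSet] from [read_reference()].
#' @param uppercase_only If `TRUE`, lowercase (soft-masked) bases do not
#'   match.
#' @return `fragments` with an integer `n_cpg` column appended.
#' @export
count_cpgs <- function(fragments, genome, uppercase_only = FALSE) {
  assert_columns(fragments, c("chrom", "start", "end"), "`fragments`")
  n <- nrow(fragments)
  out <- integer(n)
  glen <- setNames(Biostrings::width(genome), names(genome))
  unknown <- setdiff(unique(fragments$chrom), names(genome))
  if (length(unknown)) {
    abort(sprintf("fragments reference sequence(s) absent from genome: %s",
                  paste(unknown, collapse = ", ")))
  }
  oob <- fragments$start < 0 | fragments$end > glen[fragments$chrom] |
    fragments$start >= fragments$end
  if (any(oob)) {
    i <- which(oob)[1]
    abort(sprintf("fragment interval %s:[%d,%d) out of genome bounds",
                  fragments$chrom[i], fragments$start[i], fragments$end[i]))
  }
  for (chr in unique(fragments$chrom)) {
    ix <- which(fragments$chrom == chr)
    at <- IRanges::IRanges(start = fragments$start[ix] + 1L,
                           end = fragments$end[ix])
    seqs <- as.character(Biostrings::extractAt(genome[[chr]], at))
    if (!uppercase_only) seqs <- toupper(seqs)
    out[ix] <- stringr::str_count(seqs, stringr::fixed("CG"))
  }
  mutate(fragments, n_cpg = as.integer(out))
}

#' Fragment CpG-plot histogram
#'
#' The Fragment CpG-plot summarizes the CpG content of the captured
#' fragments: with `F_i` fragments containing exactly `i` CpGs, it depicts
#' the normalized counts `F_i / sum_i(F_i)` as a function of `i`. Mass at
#' `i = 0` is sequence that an MBD cannot have bound through methyl-CpG —
#' its fraction gauges (non)specificity; enrichment at low non-zero `i`
#' gauges sensitivity for sparsely methylated loci.
#'
#' By default duplicates are collapsed first (`dedup = TRUE`), matching the
#' processing convention for these plots; `dedup = FALSE` weights each
#' fragment by its multiplicity instead.
#'
#' @param fragments A fragment tibble; a precomputed `n_cpg` column is used
#'   if present, otherwise `genome` must be supplied.
#' @param genome A [Biostrings::BStringSet]; required when `n_cpg` is absent.
#' @param dedup Collapse duplicates before tallying (default `TRUE`).
#' @param sample_label Label carried into the `sample` column.
#' @param uppercase_only Passed to [count_cpgs()].
#' @return A tibble of class `fragment_cpg_histogram` with columns `sample`,
#'   `i` (0..observed maximum), `count` (`F_i`) and `fraction`
#'   (`F_i / total`); attribute `total`.
#' @export
fragment_cpg_histogram <- function(fragments, genome = NULL, dedup = TRUE,
                                   sample_label = "sample",
                                   uppercase_only = FALSE) {
  assert_columns(fragments, c("chrom", "start", "end"), "`fragments`")
  if (nrow(fragments) == 0L) {
    abort("empty fragment set: the Fragment CpG-plot is undefined")
  }
  if (!"multiplicity" %in% names(fragments)) fragments$multiplicity <- 1L
  if (dedup) {
    counted <- "n_cpg" %in% names(fragments)
    keep <- c("chrom", "start", "end", if (counted) "n_cpg")
    fragments <- distinct(fragments[keep])
    fragments$multiplicity <- 1L
  }
  if (!"n_cpg" %in% names(fragments)) {
    if (is.null(genome)) {
      abort("`genome` is required when `fragments` has no n_cpg column")
    }
    fragments <- count_cpgs(fragments, genome, uppercase_only = uppercase_only)
  }
  total <- sum(fragments$multiplicity)
  i_max <- max(fragments$n_cpg)
  counts <- vapply(0:i_max, function(i) {
    sum(fragments$multiplicity[fragments$n_cpg == i])
  }, numeric(1))
  out <- tibble(sample = sample_label, i = 0:i_max, count = counts,
                fraction = counts / total)
  attr(out, "total") <- total
  class(out) <- c("fragment_cpg_histogram", class(out))
  out
}

#' Write (and re-read) Fragment CpG-plot tables and figures
#'
#' Writes one or more histograms as a tidy TSV (`sample`, `i`, `count`,
#' `fraction`, one row per sample-by-`i`) and, when `figure_path` is given,
#' an overlay line figure of `fraction` versus `i` per sample.
#'
#' @param histograms A `fragment_cpg_histogram` or a list of them.
#' @param table_path Output TSV path.
#' @param figure_path Optional figure path (extension selects the device,
#'   e.g. `.png`, `.svg`, `.pdf`).
#' @param i_max Optional display truncation for the figure x-axis (the table
#'   is never truncated).
#' @return The combined tibble, invisibly.
#' @export
write_cpg_plot <- function(histograms, table_path, figure_path = NULL,
                           i_max = NULL) {
  if (is.data.frame(histograms)) histograms <- list(histograms)
  if (!length(histograms)) abort("at least one histogram is required")
  combined <- bind_rows(lapply(histograms, as_tibble))
  assert_columns(combined, c("sample", "i", "count", "fraction"),
                 "`histograms`")
  readr::write_tsv(combined, table_path)
  if (!is.null(figure_path)) {
    p <- plot_cpg_histograms(combined, i_max = i_max)
    ggplot2::ggsave(figure_path, p, width = 7, height = 4.5, dpi = 150)
  }
  invisible(combined)
}

#' @rdname write_cpg_plot
#' @param path TSV path previously written by [write_cpg_plot()].
#' @export
read_cpg_plot_table <- function(path) {
  out <- readr::read_tsv(path, col_types = "cidd", show_col_types = FALSE)
  class(out) <- c("fragment_cpg_histogram", class(out))
  out
}

plot_cpg_histograms <- function(combined, i_max = NULL) {
  if (!is.null(i_max)) combined <- filter(combined, .data$i <= i_max)
  ggplot2::ggplot(combined,
                  ggplot2::aes(x = .data$i, y = .data$fraction,
                               colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "CpGs per mapped fragment (i)",
                  y = expression(F[i] / Sigma[i] ~ F[i]),
                  colour = NULL, title = "Fragment CpG-plot") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for Fragment CpG-plot histograms
#'
#' @param object A `fragment_cpg_histogram`.
#' @param i_max Optional x-axis truncation.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fragment_cpg_histogram
#' @export
autoplot.fragment_cpg_histogram <- function(object, i_max = NULL, ...) {
  plot_cpg_histograms(as_tibble(object), i_max = i_max)
}

#' @method tidy fragment_cpg_histogram
#' @export
tidy.fragment_cpg_histogram <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "fragment_cpg_histogram")
  out
}

#' @method glance fragment_cpg_histogram
#' @export
glance.fragment_cpg_histogram <- function(x, ...) {
  tibble(sample = unique(x$sample)[1],
         total_fragments = attr(x, "total") %||% sum(x$count),
         i_max = max(x$i),
         fraction_zero_cpg = x$fraction[x$i == 0],
         mode_i = x$i[which.max(x$fraction)],
         mean_cpg = sum(x$i * x$fraction))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
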