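#' Filter a methylation table by coverage
#'
#' Keeps loci whose bisulfite coverage reaches `min_cov`; the conventional
#' resolution threshold for RRBS-style calls is coverage >= 20. Array-like
#' records carry `Inf` coverage and always pass.
#'
#' @param table A methylation tibble from [read_methylation_table()] or the
#'   simulator.
#' @param min_cov Minimum coverage (default 20).
#' @return The filtered tibble; the `source_kind` attribute is preserved.
#' @export
filter_by_coverage <- function(table, min_cov = 20) {
  assert_columns(table, c("chrom", "cpg_pos", "methylation_degree", "coverage"),
                 "`table`")
  if (!is.numeric(min_cov) || length(min_cov) != 1L || min_cov < 0) {
    abort("`min_cov` must be a single non-negative number")
  }
  kind <- attr(table, "source_kind")
  out <- filter(table, .data$coverage >= min_cov)
  attr(out, "source_kind") <- kind
  out
}

#' Assign methylation degrees to bins
#'
#' Bins `[k*w, (k+1)*w)` are half-open with the final bin closed at 1, so a
#' degree exactly on an interior edge goes to the upper bin and degree 1
#' lands in the last bin. Vectorized; 0-based bin indices.
#'
#' @param degree Methylation degrees in `[0, 1]`.
#' @param bin_width Bin width `w`; 0.02 is conventional for RRBS-derived
#'   degrees, 0.05 for array beta values.
#' @return Integer bin indices in `0 .. ceiling(1/w) - 1`.
#' @examples
#' assign_bin(c(0.01, 0.02, 1), 0.02)
#' @export
assign_bin <- function(degree, bin_width) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      bin_width <= 0 || bin_width > 1) {
    abort("`bin_width` must be a single number in (0, 1]")
  }
  if (any(is.na(degree)) || any(degree < 0 | degree > 1)) {
    abort("methylation degrees must lie in [0, 1] and not be NA")
  }
  n_bins <- as.integer(ceiling(1 / bin_width - 1e-9))
  # the 1e-9 nudge keeps exact edges (e.g. 0.06 / 0.02) in the upper bin
  # despite binary floating point
  idx <- floor(degree / bin_width + 1e-9)
  as.integer(pmin(idx, n_bins - 1L))
}

profile_scaffold <- function(bin_width) {
  n_bins <- as.integer(ceiling(1 / bin_width - 1e-9))
  tibble(bin = 0:(n_bins - 1L),
         bin_low = (0:(n_bins - 1L)) * bin_width,
         bin_high = pmin((1:n_bins) * bin_width, 1))
}

new_bin_profile <- function(counts_by_bin, bin_width, kind) {
  prof <- profile_scaffold(bin_width)
  prof$count <- 0
  prof$count[match(counts_by_bin$bin, prof$bin)] <- counts_by_bin$n
  total <- sum(prof$count)
  prof$fraction <- if (total > 0) prof$count / total else NA_real_
  attr(prof, "bin_width") <- bin_width
  attr(prof, "kind") <- kind
  attr(prof, "total_incidences") <- total
  class(prof) <- c("methylation_bin_profile", class(prof))
  prof
}

#' Fraction profile of fragments over binned methylation degrees
#'
#' The yield-independent view of capture behaviour: each mapped fragment is
#' assigned to the methylation-degree bins of the independently assessed
#' CpGs it contains (a CpG is "in" a fragment when its forward-strand C
#' position lies in `[start, end)`), and per-bin incidence counts are
#' normalized to fractions summing to one. A fragment whose assessed CpGs
#' span several bins contributes one incidence to each such bin; fragments
#' containing no assessed CpG contribute nothing.
#'
#' The profiles are CpG-oriented: with the default `semantics = "cpg"` every
#' fragment-CpG containment pair is one incidence, so uniform (nonspecific)
#' capture reproduces the background profile exactly in expectation.
#' `semantics = "set"` instead counts each (fragment, bin) pair once,
#' bounding any fragment's influence by the number of bins — at the cost of
#' depressing bins whose CpGs cluster densely (e.g. fully methylated
#' islands).
#'
#' @param fragments A deduplicated fragment tibble.
#' @param table A coverage-filtered methylation tibble.
#' @param bin_width Bin width (0.02 for RRBS-like, 0.05 for array-like).
#' @param semantics `"cpg"` (default) or `"set"`.
#' @return A `methylation_bin_profile` tibble: `bin`, `bin_low`, `bin_high`,
#'   `count`, `fraction`; attributes `bin_width`, `kind = "kit"`,
#'   `total_incidences`.
#' @export
fragment_bin_fractions <- function(fragments, table, bin_width = 0.02,
                                   semantics = c("cpg", "set")) {
  semantics <- match.arg(semantics)
  assert_columns(fragments, c("chrom", "start", "end"), "`fragments`")
  assert_columns(table, c("chrom", "cpg_pos", "methylation_degree"), "`table`")
  hits <- overlap_fragment_cpgs(fragments, table)
  if (nrow(hits) == 0L) {
    abort(paste0("no assessed CpG falls inside any fragment: ",
                 "check that fragments and methylation table share ",
                 "chromosome names and coordinates"))
  }
  hits$bin <- assign_bin(hits$degree, bin_width)
  if (semantics == "set") {
    hits <- distinct(hits, .data$fragment_id, .data$bin)
  }
  new_bin_profile(count(hits, .data$bin, name = "n"), bin_width, kind = "kit")
}

# fragment x CpG containment pairs via interval overlap, per chromosome
overlap_fragment_cpgs <- function(fragments, table) {
  frag_id <- seq_len(nrow(fragments))
  out <- lapply(intersect(unique(fragments$chrom), unique(table$chrom)),
                function(chr) {
    fi <- which(fragments$chrom == chr)
    ti <- which(table$chrom == chr)
    q <- IRanges::IRanges(start = fragments$start[fi] + 1L,
                          end = fragments$end[fi])
    s <- IRanges::IRanges(start = table$cpg_pos[ti] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(q, s)
    tibble(fragment_id = frag_id[fi][S4Vectors::queryHits(ov)],
           degree = table$methylation_degree[ti][S4Vectors::subjectHits(ov)])
  })
  bind_rows(out)
}

#' Background methylation-degree profile
#'
#' The distribution of all independently assessed methylation degrees — the
#' full pool of loci a capture kit could have drawn from. Each CpG record
#' contributes one incidence to its bin; fractions are normalized to one.
#'
#' @inheritParams fragment_bin_fractions
#' @return A `methylation_bin_profile` with `kind = "background"`.
#' @export
background_profile <- function(table, bin_width = 0.02) {
  assert_columns(table, c("chrom", "cpg_pos", "methylation_degree"), "`table`")
  if (nrow(table) == 0L) abort("empty methylation table: background undefined")
  bins <- assign_bin(table$methylation_degree, bin_width)
  new_bin_profile(count(tibble(bin = bins), .data$bin, name = "n"),
                  bin_width, kind = "background")
}

#' Enrichment ratio of a kit profile over the background profile
#'
#' Divides per-bin kit fractions by background fractions. Bins with zero
#' background fraction get `NA` (not infinity) and are omitted from the
#' onset computation. The enrichment onset — attribute `onset_bin` — is the
#' first bin index from which the ratio is >= 1 in every higher occupied
#' bin; it proxies sensitivity (the lowest methylation degree a kit still
#' enriches for).
#'
#' @param kit A `methylation_bin_profile` from [fragment_bin_fractions()].
#' @param background A `methylation_bin_profile` from [background_profile()]
#'   with identical binning.
#' @return An `enrichment_profile` tibble: `bin`, `bin_low`, `bin_high`,
#'   `kit_fraction`, `background_fraction`, `ratio`; attributes `bin_width`
#'   and `onset_bin` (`NA` if the kit never consistently exceeds
#'   background).
#' @export
enrichment_ratio <- function(kit, background) {
  for (p in list(kit, background)) {
    assert_columns(p, c("bin", "bin_low", "bin_high", "fraction"),
                   "a bin profile")
  }
  wk <- attr(kit, "bin_width")
  wb <- attr(background, "bin_width")
  if (nrow(kit) != nrow(background) ||
      (!is.null(wk) && !is.null(wb) && wk != wb) ||
      any(kit$bin != background$bin)) {
    abort("kit and background profiles must share bin width and edges")
  }
  ratio <- ifelse(background$fraction > 0,
                  kit$fraction / background$fraction, NA_real_)
  out <- tibble(bin = kit$bin, bin_low = kit$bin_low, bin_high = kit$bin_high,
                kit_fraction = kit$fraction,
                background_fraction = background$fraction,
                ratio = ratio)
  occupied <- which(!is.na(ratio))
  onset <- NA_integer_
  if (length(occupied)) {
    ge1 <- ratio[occupied] >= 1
    run_ok <- rev(cumprod(rev(ge1))) == 1   # TRUE where all later occupied bins >= 1
    if (any(run_ok)) onset <- out$bin[occupied[which(run_ok)[1]]]
  }
  attr(out, "bin_width") <- wk %||% wb
  attr(out, "onset_bin") <- onset
  class(out) <- c("enrichment_profile", class(out))
  out
}

#' @method tidy methylation_bin_profile
#' @export
tidy.methylation_bin_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "methylation_bin_profile")
  out
}

#' @method tidy enrichment_profile
#' @export
tidy.enrichment_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "enrichment_profile")
  out
}

#' @method glance enrichment_profile
#' @export
glance.enrichment_profile <- function(x, ...) {
  tibble(n_bins = nrow(x),
         bin_width = attr(x, "bin_width"),
         onset_bin = attr(x, "onset_bin"),
         onset_degree = attr(x, "onset_bin") * attr(x, "bin_width"),
         n_missing_background = sum(is.na(x$ratio)))
}

#' Autoplot methods for methylation-bin and enrichment profiles
#'
#' A `methylation_bin_profile` draws fractions against the bin midpoint. An
#' `enrichment_profile` draws two panels in the conventional layout: kit and
#' background fractions, and their ratio with a reference line at 1.
#'
#' @param object The profile.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot methylation_bin_profile
#' @export
autoplot.methylation_bin_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_low + df$bin_high) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$fraction)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "independent methylation degree",
                  y = "fraction of incidences",
                  title = sprintf("%s profile (bin width %.2f)",
                                  attr(object, "kind") %||% "bin",
                                  attr(object, "bin_width") %||% NA)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.methylation_bin_profile
#' @method autoplot enrichment_profile
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_low + df$bin_high) / 2
  long <- tidyr::pivot_longer(
    df, c("kit_fraction", "background_fraction", "ratio"),
    names_to = "panel", values_to = "value")
  long$panel <- factor(ifelse(long$panel == "ratio", "kit / background",
                              sub("_fraction", "", long$panel)),
                       levels = c("kit", "background", "kit / background"))
  long$facet <- ifelse(long$panel == "kit / background", "ratio", "fractions")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$value,
                                     colour = .data$panel)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(data = data.frame(facet = "ratio", y = 1),
                        ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~facet, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "independent methylation degree", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write an enrichment profile as TSV
#'
#' Columns `bin_low`, `bin_high`, `kit_fraction`, `background_fraction`,
#' `ratio`; missing ratios are written as `NA`.
#'
#' @param profile An `enrichment_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_profile <- function(profile, path) {
  assert_columns(profile, c("bin_low", "bin_high", "kit_fraction",
                            "background_fraction", "ratio"), "`profile`")
  readr::write_tsv(select(as_tibble(profile), "bin_low", "bin_high",
                          "kit_fraction", "background_fraction", "ratio"),
                   path)
  invisible(path)
}
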