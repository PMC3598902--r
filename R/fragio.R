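#' Read paired-end alignments into a tibble of aligned pairs
#'
#' Parses a paired-end alignment stream into one record per read pair, the
#' input to [reconstruct_fragments()]. Two dialects are supported: plain-text
#' SAM (mates located by read name and the first/last-in-pair flag bits) and
#' ten-column BEDPE. Coordinates are returned 0-based half-open; SAM `POS` is
#' converted from 1-based.
#'
#' A mate counts as uniquely mapped when it is mapped, its mapping quality is
#' at least `mapq_threshold`, and no secondary alignment record exists for
#' that mate. For BEDPE the score column stands in for the mapping quality of
#' both mates. `proper_orientation` requires both mates mapped on the same
#' reference sequence, on opposite strands, with the leftmost mate on the
#' forward strand (inward-pointing mates).
#'
#' @param path Path to a SAM or BEDPE text file.
#' @param dialect `"sam"` or `"bedpe"`.
#' @param mapq_threshold Minimum mapping quality for a mate to count as
#'   uniquely mapped. Default 20.
#' @return A tibble with one row per read pair, in input order: `pair_id`,
#'   `chrom` (mate 1), `pos1`, `len1`, `chrom2`, `pos2`, `len2` (0-based
#'   leftmost positions and aligned reference lengths), `unique1`, `unique2`,
#'   `proper_orientation`.
#' @examples
#' bedpe <- tempfile(fileext = ".bedpe")
#' writeLines("chr1\t100\t145\tchr1\t300\t345\tfrag1\t60\t+\t-", bedpe)
#' read_alignment_pairs(bedpe, dialect = "bedpe")
#' @export
read_alignment_pairs <- function(path, dialect = c("sam", "bedpe"),
                                 mapq_threshold = 20) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort(
                        sprintf("unknown alignment dialect: %s",
                                paste(dialect, collapse = "/"))))
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  switch(dialect,
         sam   = read_sam_pairs(path, mapq_threshold),
         bedpe = read_bedpe_pairs(path, mapq_threshold))
}

cigar_reference_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg)) {
      return(NA_integer_)
    }
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

read_sam_pairs <- function(path, mapq_threshold) {
  lines <- readLines(path)
  is_aln <- !startsWith(lines, "@") & nzchar(lines)
  lineno <- which(is_aln)
  if (!length(lineno)) {
    return(tibble(pair_id = character(), chrom = character(),
                  pos1 = integer(), len1 = integer(), chrom2 = character(),
                  pos2 = integer(), len2 = integer(), unique1 = logical(),
                  unique2 = logical(), proper_orientation = logical()))
  }
  fields <- strsplit(lines[is_aln], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    abort(sprintf("malformed SAM record at line %d: expected >= 11 fields, got %d",
                  lineno[which(nf < 11L)[1]], nf[which(nf < 11L)[1]]))
  }
  get <- function(k) vapply(fields, `[[`, character(1), k)
  flag <- suppressWarnings(as.integer(get(2)))
  pos <- suppressWarnings(as.integer(get(4)))
  mapq <- suppressWarnings(as.integer(get(5)))
  bad <- which(is.na(flag) | is.na(pos) | is.na(mapq))
  if (length(bad)) {
    abort(sprintf("malformed SAM record at line %d: non-numeric FLAG/POS/MAPQ",
                  lineno[bad[1]]))
  }
  rec <- tibble(
    lineno = lineno,
    qname = get(1), flag = flag, rname = get(3), pos = pos, mapq = mapq,
    cigar = get(6), seqlen = nchar(get(10)))
  rec$mapped <- bitwAnd(rec$flag, 4L) == 0L
  rec$secondary <- bitwAnd(rec$flag, 0x900L) > 0L
  rec$reverse <- bitwAnd(rec$flag, 16L) > 0L
  rec$first_mate <- bitwAnd(rec$flag, 0x40L) > 0L
  rec$reflen <- cigar_reference_length(rec$cigar)
  rec$reflen <- ifelse(is.na(rec$reflen) | rec$reflen == 0L,
                       pmax(rec$seqlen, 1L), rec$reflen)

  # mates with secondary records anywhere in the file are not uniquely mapped
  sec_first <- unique(rec$qname[rec$secondary & rec$first_mate])
  sec_last <- unique(rec$qname[rec$secondary & !rec$first_mate])

  prim <- rec[!rec$secondary, , drop = FALSE]
  split_idx <- split(seq_len(nrow(prim)), factor(prim$qname,
                                                 levels = unique(prim$qname)))
  n_per <- lengths(split_idx)
  if (any(n_per != 2L)) {
    bad_q <- names(split_idx)[which(n_per != 2L)[1]]
    abort(sprintf(
      "read %s has %d primary alignment record(s); paired-end SAM requires exactly 2",
      bad_q, n_per[which(n_per != 2L)[1]]))
  }
  pairs <- purrr::map(split_idx, function(ix) {
    a <- prim[ix, , drop = FALSE]
    m1 <- a[which(a$first_mate)[1], , drop = FALSE]
    m2 <- a[which(!a$first_mate)[1], , drop = FALSE]
    if (is.na(m1$qname[1]) || is.na(m2$qname[1])) {
      abort(sprintf("read %s lacks a first-in-pair / last-in-pair record",
                    a$qname[1]))
    }
    u1 <- m1$mapped && m1$mapq >= mapq_threshold && !(m1$qname %in% sec_first)
    u2 <- m2$mapped && m2$mapq >= mapq_threshold && !(m2$qname %in% sec_last)
    same_chrom <- m1$mapped && m2$mapped && m1$rname == m2$rname
    proper <- FALSE
    if (same_chrom && (m1$reverse != m2$reverse)) {
      left_fwd <- if (m1$pos <= m2$pos) !m1$reverse else !m2$reverse
      proper <- left_fwd
    }
    tibble(pair_id = m1$qname, chrom = m1$rname, pos1 = m1$pos - 1L,
           len1 = m1$reflen, chrom2 = m2$rname, pos2 = m2$pos - 1L,
           len2 = m2$reflen, unique1 = u1, unique2 = u2,
           proper_orientation = proper)
  })
  dplyr::bind_rows(pairs)
}

read_bedpe_pairs <- function(path, mapq_threshold) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  out <- purrr::map2(fields, lineno, function(f, ln) {
    if (length(f) < 6L) {
      abort(sprintf("malformed BEDPE record at line %d: expected >= 6 fields, got %d",
                    ln, length(f)))
    }
    s1 <- suppressWarnings(as.integer(f[2])); e1 <- suppressWarnings(as.integer(f[3]))
    s2 <- suppressWarnings(as.integer(f[5])); e2 <- suppressWarnings(as.integer(f[6]))
    if (anyNA(c(s1, e1, s2, e2))) {
      abort(sprintf("malformed BEDPE record at line %d: non-numeric coordinates", ln))
    }
    score <- if (length(f) >= 8L) suppressWarnings(as.numeric(f[8])) else NA_real_
    strands <- if (length(f) >= 10L) f[9:10] else c(NA_character_, NA_character_)
    mapped1 <- f[1] != "." && s1 >= 0L
    mapped2 <- f[4] != "." && s2 >= 0L
    uniq <- !is.na(score) && score >= mapq_threshold
    same_chrom <- mapped1 && mapped2 && f[1] == f[4]
    proper <- FALSE
    if (same_chrom) {
      if (anyNA(strands)) {
        proper <- TRUE  # strand-less BEDPE: trust the pairing upstream
      } else if (strands[1] != strands[2]) {
        left_strand <- if (s1 <= s2) strands[1] else strands[2]
        proper <- left_strand == "+"
      }
    }
    tibble(pair_id = if (length(f) >= 7L) f[7] else sprintf("pair%d", ln),
           chrom = f[1], pos1 = s1, len1 = e1 - s1,
           chrom2 = f[4], pos2 = s2, len2 = e2 - s2,
           unique1 = mapped1 && uniq, unique2 = mapped2 && uniq,
           proper_orientation = proper)
  })
  dplyr::bind_rows(out)
}

#' Reconstruct mapped fragments from aligned pairs
#'
#' A mapped fragment is the reference interval spanning both sequenced mate
#' ends and the unsequenced region between them. Pairs are retained only when
#' both mates are uniquely mapped, lie on the same reference sequence in
#' proper (inward) orientation, and the outer span — leftmost mate start to
#' rightmost mate end — does not exceed `max_span`. Filtering is silent
#' failure-free: rejected pairs are tallied per filter and the tally is
#' attached as the `"filter_tally"` attribute (and emitted as a message).
#'
#' @param pairs A tibble from [read_alignment_pairs()].
#' @param max_span Maximum outer fragment span in bp (default 400).
#' @return A tibble of fragments (`chrom`, `start`, `end`, `multiplicity`),
#'   0-based half-open, `multiplicity` 1 for every row, with attribute
#'   `filter_tally`.
#' @export
reconstruct_fragments <- function(pairs, max_span = 400) {
  assert_columns(pairs, c("chrom", "pos1", "len1", "chrom2", "pos2", "len2",
                          "unique1", "unique2", "proper_orientation"),
                 "`pairs`")
  if (!is.numeric(max_span) || length(max_span) != 1L || max_span <= 0) {
    abort("`max_span` must be a single positive number")
  }
  n_input <- nrow(pairs)
  ok_unique <- pairs$unique1 & pairs$unique2
  ok_proper <- ok_unique & pairs$proper_orientation & (pairs$chrom == pairs$chrom2)
  start <- pmin(pairs$pos1, pairs$pos2)
  end <- pmax(pairs$pos1 + pairs$len1, pairs$pos2 + pairs$len2)
  ok_span <- ok_proper & (end - start <= max_span)
  tally <- tibble(
    n_input = n_input,
    non_unique = sum(!ok_unique),
    improper_or_cross_chromosome = sum(ok_unique & !ok_proper),
    over_span = sum(ok_proper & !ok_span),
    kept = sum(ok_span))
  inform(sprintf(
    "reconstruct_fragments: %d pairs in, %d kept (%d non-unique, %d improper/cross-chromosome, %d over %d bp)",
    tally$n_input, tally$kept, tally$non_unique,
    tally$improper_or_cross_chromosome, tally$over_span, max_span))
  out <- tibble(chrom = pairs$chrom[ok_span],
                start = as.integer(start[ok_span]),
                end = as.integer(end[ok_span]),
                multiplicity = 1L)
  attr(out, "filter_tally") <- tally
  out
}

#' Collapse duplicate fragments
#'
#' Fragments sharing exact `(chrom, start, end)` coordinates are presumed PCR
#' copies of a single captured molecule and are collapsed to one record whose
#' `multiplicity` is the copy count. The sum of multiplicities after collapse
#' equals the fragment count before.
#'
#' @param fragments A fragment tibble (`chrom`, `start`, `end`, optionally
#'   `multiplicity`).
#' @return A tibble with one row per distinct interval, sorted by position.
#' @export
deduplicate_fragments <- function(fragments) {
  assert_columns(fragments, c("chrom", "start", "end"), "`fragments`")
  if (!"multiplicity" %in% names(fragments)) fragments$multiplicity <- 1L
  fragments |>
    group_by(.data$chrom, .data$start, .data$end) |>
    summarise(multiplicity = as.integer(sum(.data$multiplicity)),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Sequencing-yield summary
#'
#' Tabulates the yield chain of an enrichment-sequencing library: sequenced
#' fragments, uniquely mapped fragments, and non-duplicate uniquely mapped
#' fragments, with the two percentages conventionally reported alongside
#' (unique as % of sequenced; non-duplicate as % of unique). Percentages are
#' rounded half away from zero to one decimal; a zero denominator yields
#' `NA`.
#'
#' Low yields paired with low non-duplicate percentages point at inefficient
#' capture (few pre-amplification molecules, mostly PCR duplicates); low
#' yields with high non-duplicate percentages point at the sequencing step
#' instead.
#'
#' @param n_sequenced Number of sequenced read pairs (fragments).
#' @param unique_fragments Uniquely mapped fragment count, or the fragment
#'   tibble from [reconstruct_fragments()] (rows are counted).
#' @param dedup_fragments Non-duplicate fragment count, or the tibble from
#'   [deduplicate_fragments()] (rows are counted).
#' @return A one-row tibble: `n_sequenced_fragments`, `n_unique_mapped`,
#'   `n_nonduplicate`, `pct_unique_of_sequenced`, `pct_nondup_of_unique`.
#' @examples
#' yield_summary(11531844, 6632940, 3916243)
#' @export
yield_summary <- function(n_sequenced, unique_fragments, dedup_fragments) {
  as_count <- function(x) if (is.data.frame(x)) nrow(x) else x
  n_seq <- as_count(n_sequenced)
  n_uni <- as_count(unique_fragments)
  n_ddp <- as_count(dedup_fragments)
  for (v in list(n_seq, n_uni, n_ddp)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort("yield counts must be single non-negative numbers")
    }
  }
  if (!(n_ddp <= n_uni && n_uni <= n_seq)) {
    abort(sprintf(
      "counts must satisfy non-duplicate (%s) <= unique (%s) <= sequenced (%s)",
      format(n_ddp, big.mark = ","), format(n_uni, big.mark = ","),
      format(n_seq, big.mark = ",")))
  }
  tibble(
    n_sequenced_fragments = n_seq,
    n_unique_mapped = n_uni,
    n_nonduplicate = n_ddp,
    pct_unique_of_sequenced = percent_1dp(n_uni, n_seq),
    pct_nondup_of_unique = percent_1dp(n_ddp, n_uni))
}

#' Read a reference genome from FASTA
#'
#' Sequences are kept case-preserving (soft-masked lowercase is retained) and
#' validated against the `{A,C,G,T,N}` alphabet in either case. Names are
#' truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::BStringSet] addressable by sequence name.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    abort(sprintf("duplicate sequence name(s) in %s: %s", path,
                  paste(unique(names(seqs)[duplicated(names(seqs))]),
                        collapse = ", ")))
  }
  af <- Biostrings::alphabetFrequency(seqs)  # 256 byte-value columns
  allowed <- as.integer(charToRaw("ACGTNacgtn")) + 1L
  other <- rowSums(af[, -allowed, drop = FALSE])
  if (any(other > 0)) {
    abort(sprintf("sequence %s contains characters outside {A,C,G,T,N}",
                  names(seqs)[which(other > 0)[1]]))
  }
  seqs
}

#' Extract a genomic interval as a character string
#'
#' 0-based half-open coordinates; errors on unknown sequence names or
#' out-of-bounds intervals.
#'
#' @param genome A [Biostrings::BStringSet] from [read_reference()].
#' @param chrom Sequence name.
#' @param start,end 0-based half-open interval.
#' @return The interval sequence (case preserved).
#' @export
genome_interval <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("sequence %s not present in genome", chrom))
  }
  len <- Biostrings::width(genome[chrom])
  if (start < 0 || end > len || start >= end) {
    abort(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                  start, end, chrom, len))
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Read a per-CpG methylation table
#'
#' Two TSV dialects are understood. `rrbs`: columns `chrom`, `pos`, `strand`,
#' `meth_count`, `total_count` — stranded counts from bisulfite sequencing.
#' `array`: columns `chrom`, `pos`, `beta` — array beta values, treated as
#' already strand-combined with effectively unlimited coverage (`Inf`).
#'
#' With `strand_mode = "merge"` (default, `rrbs` only), the forward-strand C
#' record and the reverse-strand G record of one CpG are combined by summing
#' methylated and total counts, keyed to the forward-strand C position
#' (reverse-strand `pos` maps to `pos - 1`). Reverse-strand records with no
#' forward partner are kept as singletons at their C position and reported in
#' a message.
#'
#' @param path TSV path (header row required).
#' @param source_kind `"rrbs"` or `"array"`.
#' @param strand_mode `"merge"` or `"none"`.
#' @return A tibble (`chrom`, `cpg_pos`, `methylation_degree`, `coverage`)
#'   with at most one row per CpG, attribute `source_kind`.
#' @export
read_methylation_table <- function(path, source_kind = c("rrbs", "array"),
                                   strand_mode = c("merge", "none")) {
  source_kind <- match.arg(source_kind)
  strand_mode <- match.arg(strand_mode)
  if (!file.exists(path)) abort(sprintf("methylation table not found: %s", path))
  if (source_kind == "array") {
    raw <- readr::read_tsv(path, show_col_types = FALSE)
    assert_columns(raw, c("chrom", "pos", "beta"), "array methylation table")
    if (any(raw$beta < 0 | raw$beta > 1, na.rm = TRUE)) {
      abort("array beta values must lie in [0, 1]")
    }
    if (anyDuplicated(raw[c("chrom", "pos")])) {
      abort("duplicate (chrom, pos) records in array methylation table")
    }
    out <- tibble(chrom = raw$chrom, cpg_pos = as.integer(raw$pos),
                  methylation_degree = raw$beta, coverage = Inf)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE)
    assert_columns(raw, c("chrom", "pos", "strand", "meth_count", "total_count"),
                   "rrbs methylation table")
    if (strand_mode == "merge") {
      fwd_key <- paste(raw$chrom, raw$pos)
      is_rev <- raw$strand == "-"
      orphan <- is_rev & !(paste(raw$chrom, raw$pos - 1L) %in% fwd_key[!is_rev])
      if (any(orphan)) {
        inform(sprintf(
          "read_methylation_table: %d reverse-strand record(s) without a forward partner kept as singletons",
          sum(orphan)))
      }
      key_pos <- ifelse(is_rev, raw$pos - 1L, raw$pos)
    } else {
      key_pos <- raw$pos
    }
    out <- tibble(chrom = raw$chrom, cpg_pos = as.integer(key_pos),
                  meth = raw$meth_count, total = raw$total_count) |>
      group_by(.data$chrom, .data$cpg_pos) |>
      summarise(meth = sum(.data$meth), total = sum(.data$total),
                .groups = "drop") |>
      mutate(methylation_degree = ifelse(.data$total > 0,
                                         .data$meth / .data$total, NA_real_),
             coverage = .data$total) |>
      select("chrom", "cpg_pos", "methylation_degree", "coverage")
  }
  bad <- !is.na(out$methylation_degree) &
    (out$methylation_degree < 0 | out$methylation_degree > 1)
  if (any(bad)) abort("methylation degrees must lie in [0, 1]")
  out <- arrange(out, .data$chrom, .data$cpg_pos)
  attr(out, "source_kind") <- source_kind
  out
}

#' Write and read fragments as BED
#'
#' Five-column BED with the duplicate multiplicity in the score column;
#' coordinates stay 0-based half-open so a write/read round trip is
#' lossless.
#'
#' @param fragments A fragment tibble.
#' @param path Output path.
#' @return `write_fragments_bed()` returns `path` invisibly;
#'   `read_fragments_bed()` returns the fragment tibble.
#' @export
write_fragments_bed <- function(fragments, path) {
  assert_columns(fragments, c("chrom", "start", "end"), "`fragments`")
  if (!"multiplicity" %in% names(fragments)) fragments$multiplicity <- 1L
  bed <- tibble(chrom = fragments$chrom, start = fragments$start,
                end = fragments$end,
                name = sprintf("frag%d", seq_len(nrow(fragments))),
                score = fragments$multiplicity)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score"),
                         col_types = "ciici", show_col_types = FALSE)
  tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
         multiplicity = bed$score)
}
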