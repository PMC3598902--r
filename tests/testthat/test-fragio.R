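test_that("SAM pairs parse into aligned-pair records with flags intact", {
  pairs <- read_alignment_pairs(sam_fixture_path(), dialect = "sam")
  expect_equal(nrow(pairs), 10L)
  expect_equal(pairs$pair_id, paste0("p", 1:10))  # input order preserved

  p1 <- pairs[1, ]
  expect_equal(p1$chrom, "chr1")
  expect_equal(p1$pos1, 100L)   # SAM 1-based 101 -> 0-based 100
  expect_equal(p1$len1, 45L)
  expect_equal(p1$pos2, 300L)
  expect_true(p1$unique1 && p1$unique2 && p1$proper_orientation)

  expect_false(pairs$unique1[7])             # MAPQ 0 mate
  expect_false(pairs$unique2[8])             # MAPQ 5 mate
  expect_false(pairs$unique1[9])             # unmapped mate
  expect_false(pairs$proper_orientation[10]) # cross-chromosome pair
})

test_that("BEDPE records map directly onto aligned pairs", {
  bedpe <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100\t145\tchr1\t300\t345\tfrag1\t60\t+\t-",
               "chr1\t100\t145\tchr2\t300\t345\tfrag2\t60\t+\t-"),
             bedpe)
  pairs <- read_alignment_pairs(bedpe, dialect = "bedpe")
  expect_equal(pairs$chrom[1], "chr1")
  expect_equal(pairs$pos1[1], 100L)
  expect_equal(pairs$len1[1], 45L)
  expect_equal(pairs$pos2[1], 300L)
  expect_equal(pairs$len2[1], 45L)
  expect_true(pairs$proper_orientation[1])
  expect_false(pairs$proper_orientation[2])  # mates on different chromosomes

  bad <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100\t145\tchr1\t300\t345\tok\t60\t+\t-",
               "chr1\tnot_a_number\t145\tchr1\t300\t345\tbad\t60\t+\t-"), bad)
  expect_error(read_alignment_pairs(bad, dialect = "bedpe"), "line 2")
  expect_error(read_alignment_pairs(bedpe, dialect = "cram"),
               "unknown alignment dialect")
})

test_that("fragment reconstruction filters pairs and conserves counts", {
  pairs <- read_alignment_pairs(sam_fixture_path(), dialect = "sam")
  frags <- quiet(reconstruct_fragments(pairs, max_span = 400))
  # 10 pairs: 3 fail uniqueness, 1 cross-chromosome, 6 fragments remain
  expect_equal(nrow(frags), 6L)
  expect_equal(frags$chrom[1], "chr1")
  expect_equal(frags$start[1], 100L)
  expect_equal(frags$end[1], 345L)   # both 45 bp ends plus the gap
  expect_true(all(frags$multiplicity == 1L))

  tally <- attr(frags, "filter_tally")
  expect_equal(tally$n_input, 10L)
  expect_equal(tally$non_unique, 3L)
  expect_equal(tally$improper_or_cross_chromosome, 1L)
  expect_equal(tally$over_span, 0L)
  expect_equal(tally$n_input,
               tally$kept + tally$non_unique +
                 tally$improper_or_cross_chromosome + tally$over_span)

  # outer span above the limit is dropped, at the limit is kept
  bedpe <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100\t145\tchr1\t300\t345\tnear\t60\t+\t-",
               "chr1\t100\t145\tchr1\t700\t745\tfar\t60\t+\t-"), bedpe)
  f2 <- quiet(reconstruct_fragments(
    read_alignment_pairs(bedpe, dialect = "bedpe"), max_span = 400))
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$end - f2$start, 245L)
  expect_error(reconstruct_fragments(pairs, max_span = 0), "positive")
})

test_that("duplicate collapse keys on coordinates and preserves totals", {
  two <- tibble::tibble(chrom = "chr1", start = c(100L, 100L),
                        end = c(345L, 345L))
  dd <- deduplicate_fragments(two)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$multiplicity, 2L)

  distinct_in <- tibble::tibble(chrom = "chr1", start = 1:50 * 10L,
                                end = 1:50 * 10L + 200L)
  expect_equal(deduplicate_fragments(distinct_in)$multiplicity, rep(1L, 50))

  # 1,000 draws from 200 distinct intervals vs a set-of-tuples oracle
  set.seed(99)
  universe <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                             start = sample.int(10000, 200, TRUE))
  universe$end <- universe$start + sample(50:400, 200, TRUE)
  draws <- universe[sample.int(200, 1000, replace = TRUE), ]
  dd <- deduplicate_fragments(draws)
  oracle_distinct <- length(unique(paste(draws$chrom, draws$start, draws$end)))
  expect_equal(nrow(dd), oracle_distinct)
  expect_equal(sum(dd$multiplicity), 1000L)
})

test_that("yield summaries follow the printed percentage conventions", {
  ys <- yield_summary(100, 100, 100)
  expect_equal(ys$pct_unique_of_sequenced, 100.0)
  expect_equal(ys$pct_nondup_of_unique, 100.0)

  # round-half-away-from-zero at the first decimal
  expect_equal(yield_summary(1000, 575, 155)$pct_unique_of_sequenced, 57.5)
  expect_equal(yield_summary(10000, 5745, 1000)$pct_unique_of_sequenced, 57.5)

  empty <- yield_summary(0, 0, 0)
  expect_true(is.na(empty$pct_unique_of_sequenced))
  expect_true(is.na(empty$pct_nondup_of_unique))

  expect_error(yield_summary(100, 200, 50), "non-duplicate")
  expect_error(yield_summary(100, 50, 60), "non-duplicate")

  # counts may arrive as fragment tables
  frags <- tibble::tibble(chrom = "c", start = c(0L, 0L, 10L),
                          end = c(5L, 5L, 20L))
  ys2 <- yield_summary(4, frags, deduplicate_fragments(frags))
  expect_equal(ys2$n_unique_mapped, 3)
  expect_equal(ys2$n_nonduplicate, 2)
})

test_that("FASTA reading preserves case and enforces bounds", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c some description", "ACGT"), fa)
  g <- read_reference(fa)
  expect_equal(names(g), "c")
  expect_equal(Biostrings::width(g)[[1]], 4L)
  expect_error(genome_interval(g, "c", 2, 6), "out of bounds")
  expect_error(genome_interval(g, "missing", 0, 2), "not present")

  soft <- tempfile(fileext = ".fa")
  writeLines(c(">s", "acgtACGT"), soft)
  gs <- read_reference(soft)
  expect_equal(genome_interval(gs, "s", 0, 4), "acgt")  # soft mask kept

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(read_reference(dup), "duplicate")

  alien <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGU"), alien)
  expect_error(read_reference(alien), "outside")
})

test_that("methylation tables merge strands onto the forward C", {
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", pos = c(10L, 11L), strand = c("+", "-"),
    meth_count = c(8L, 2L), total_count = c(10L, 10L)), tsv)
  tab <- read_methylation_table(tsv, source_kind = "rrbs")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$cpg_pos, 10L)
  expect_equal(tab$methylation_degree, 0.5)   # (8+2)/(10+10)
  expect_equal(tab$coverage, 20)

  # six stranded records forming three CpGs, hand-merged
  tsv6 <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 101L, 200L, 201L, 300L, 301L),
    strand = c("+", "-", "+", "-", "+", "-"),
    meth_count = c(5L, 5L, 0L, 1L, 20L, 18L),
    total_count = c(10L, 10L, 12L, 8L, 20L, 18L)), tsv6)
  tab6 <- read_methylation_table(tsv6, source_kind = "rrbs")
  expect_equal(nrow(tab6), 3L)
  expect_equal(tab6$cpg_pos, c(100L, 200L, 300L))
  expect_equal(tab6$methylation_degree, c(10 / 20, 1 / 20, 38 / 38))
  expect_equal(tab6$coverage, c(20, 20, 38))

  # a fixture where every CpG has both strand records halves exactly
  n <- 20L
  both <- tibble::tibble(
    chrom = "chr1",
    pos = as.integer(rbind(1:n * 50L, 1:n * 50L + 1L)),
    strand = rep(c("+", "-"), n),
    meth_count = 3L, total_count = 6L)
  tsvb <- tempfile(fileext = ".tsv")
  readr::write_tsv(both, tsvb)
  expect_equal(nrow(read_methylation_table(tsvb, "rrbs")), n)

  # reverse-strand orphan is kept as a singleton, with a message
  orph <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 51L, strand = "-",
                                  meth_count = 4L, total_count = 8L), orph)
  expect_message(tabo <- read_methylation_table(orph, "rrbs"), "singleton")
  expect_equal(tabo$cpg_pos, 50L)   # keyed to the forward-strand C
  expect_equal(tabo$methylation_degree, 0.5)
})

test_that("array-like tables carry unlimited coverage and validate betas", {
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 10L, beta = 0.87), tsv)
  tab <- read_methylation_table(tsv, source_kind = "array")
  expect_equal(tab$methylation_degree, 0.87)
  expect_equal(tab$coverage, Inf)
  expect_equal(attr(tab, "source_kind"), "array")

  bad <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 10L, beta = 1.2), bad)
  expect_error(read_methylation_table(bad, source_kind = "array"),
               "\\[0, 1\\]")
})

test_that("fragments written to BED re-read identically", {
  frags <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                          start = c(100L, 400L, 7L),
                          end = c(345L, 610L, 210L),
                          multiplicity = c(3L, 1L, 12L))
  bed <- tempfile(fileext = ".bed")
  write_fragments_bed(frags, bed)
  back <- read_fragments_bed(bed)
  expect_identical(back$chrom, frags$chrom)
  expect_identical(back$start, frags$start)
  expect_identical(back$end, frags$end)
  expect_identical(back$multiplicity, frags$multiplicity)
})
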