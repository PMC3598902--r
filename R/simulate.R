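#' Simulator parameter constructors
#'
#' Three small parameter records drive the synthetic MBD-capture experiment.
#'
#' `genome_model()` describes a genome as background sequence interspersed
#' with CpG islands: a first-order dinucleotide chain whose C-to-G
#' transition probability is elevated inside islands, giving islands their
#' high CpG density. `methylation_model()` describes the methylation
#' landscape: background CpGs are predominantly methylated (a high Beta),
#' while island CpGs follow a bimodal mixture of a mostly-methylated and a
#' mostly-unmethylated component — the versatile island methylation seen in
#' somatic genomes. `kit_archetype()` describes a virtual capture kit by a
#' nonspecific capture floor `epsilon` (methylation-independent pulldown,
#' the specificity axis) and a per-methylated-CpG binding success
#' probability `q` (the sensitivity axis).
#'
#' @param length Genome length in bp.
#' @param island_fraction Fraction of the genome covered by islands.
#' @param bg_cpg_prob,island_cpg_prob C-to-G transition probability outside
#'   / inside islands.
#' @param bg_gc,island_gc GC content outside / inside islands.
#' @param island_len_mean Mean island length (bp).
#' @param island_len_shape Gamma shape of the island length distribution.
#' @return A parameter list of class `genome_model`, `methylation_model` or
#'   `kit_archetype`.
#' @export
genome_model <- function(length = 1e5, island_fraction = 0.15,
                         bg_cpg_prob = 0.05, island_cpg_prob = 0.25,
                         bg_gc = 0.40, island_gc = 0.60,
                         island_len_mean = 1000, island_len_shape = 2) {
  probs <- c(island_fraction, bg_cpg_prob, island_cpg_prob, bg_gc, island_gc)
  if (any(probs < 0 | probs > 1)) {
    abort("genome_model probabilities must lie in [0, 1]")
  }
  if (length < 1000) abort("`length` must be at least 1000 bp")
  structure(list(length = as.integer(length),
                 island_fraction = island_fraction,
                 bg_cpg_prob = bg_cpg_prob, island_cpg_prob = island_cpg_prob,
                 bg_gc = bg_gc, island_gc = island_gc,
                 island_len_mean = island_len_mean,
                 island_len_shape = island_len_shape),
            class = "genome_model")
}

#' @rdname genome_model
#' @param bg_shape1,bg_shape2 Beta parameters of the background degree
#'   distribution (default Beta(9, 1): mostly methylated).
#' @param island_meth_weight Mixture weight `pi_m` of the methylated island
#'   component.
#' @param island_high,island_low Beta parameter pairs of the methylated and
#'   unmethylated island components.
#' @export
methylation_model <- function(bg_shape1 = 9, bg_shape2 = 1,
                              island_meth_weight = 0.3,
                              island_high = c(9, 1), island_low = c(1, 9)) {
  if (any(c(bg_shape1, bg_shape2, island_high, island_low) <= 0)) {
    abort("Beta parameters must be positive")
  }
  if (island_meth_weight < 0 || island_meth_weight > 1) {
    abort("`island_meth_weight` must lie in [0, 1]")
  }
  structure(list(bg_shape1 = bg_shape1, bg_shape2 = bg_shape2,
                 island_meth_weight = island_meth_weight,
                 island_high = island_high, island_low = island_low),
            class = "methylation_model")
}

#' @rdname genome_model
#' @param epsilon Nonspecific capture probability per fragment, in `[0, 1]`.
#' @param q Per-methylated-CpG binding success probability, in `[0, 1]`.
#' @param label Kit label carried into outputs.
#' @export
kit_archetype <- function(epsilon, q, label = sprintf("eps%.3g_q%.3g",
                                                      epsilon, q)) {
  if (any(c(epsilon, q) < 0 | c(epsilon, q) > 1)) {
    abort("`epsilon` and `q` must lie in [0, 1]")
  }
  structure(list(epsilon = epsilon, q = q, label = label),
            class = "kit_archetype")
}

# cumulative transition rows of a first-order chain over A,C,G,T: every row
# is the base-composition vector except the C row, where P(G) is pinned to
# cpg_prob and the remaining mass is spread over A,C,T proportionally
transition_cumsum <- function(gc, cpg_prob) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  m <- matrix(rep(p, each = 4), nrow = 4, dimnames = list(names(p), names(p)))
  rest <- p[c("A", "C", "T")] / sum(p[c("A", "C", "T")]) * (1 - cpg_prob)
  m["C", ] <- c(rest["A"], rest["C"], cpg_prob, rest["T"])
  t(apply(m, 1, cumsum))
}

#' Simulate a genome with CpG-island structure
#'
#' Non-overlapping islands are placed uniformly until `island_fraction` of
#' the genome is covered, then the sequence is generated by a first-order
#' dinucleotide chain switching between the background and island
#' transition matrices. One chromosome named `"sim1"` is produced.
#'
#' @param model A [genome_model()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A list: `genome` (a single-sequence [Biostrings::BStringSet]) and
#'   `islands` (tibble `chrom`, `start`, `end`, 0-based half-open).
#' @export
simulate_genome <- function(model, seed = NULL) {
  stopifnot(inherits(model, "genome_model"))
  maybe_seed(seed)
  L <- model$length
  target <- round(model$island_fraction * L)
  starts <- integer(0); ends <- integer(0)
  covered <- 0L; attempts <- 0L
  while (covered < target && attempts < 10000L) {
    attempts <- attempts + 1L
    len <- max(200L, round(rgamma(1, shape = model$island_len_shape,
                                  scale = model$island_len_mean /
                                    model$island_len_shape)))
    len <- min(len, L %/% 5L)
    s <- floor(runif(1, 0, L - len + 1))
    if (!any(s < ends + 100L & s + len > starts - 100L)) {  # 100 bp spacer
      starts <- c(starts, as.integer(s)); ends <- c(ends, as.integer(s + len))
      covered <- covered + len
    }
  }
  ord <- order(starts)
  islands <- tibble(chrom = "sim1", start = starts[ord], end = ends[ord])
  in_island <- logical(L)
  for (k in seq_len(nrow(islands))) {
    in_island[(islands$start[k] + 1L):islands$end[k]] <- TRUE
  }
  cum_bg <- transition_cumsum(model$bg_gc, model$bg_cpg_prob)
  cum_is <- transition_cumsum(model$island_gc, model$island_cpg_prob)
  u <- runif(L)
  base0 <- c((1 - model$bg_gc) / 2, model$bg_gc / 2, model$bg_gc / 2,
             (1 - model$bg_gc) / 2)
  cb0 <- cumsum(base0)
  # one uniform per position drives the chain; precomputing, per position,
  # the successor for every possible current base turns the sequential pass
  # into a cheap index lookup
  cand <- matrix(1L, nrow = L, ncol = 4)
  for (b in 1:4) {
    for (st in c(FALSE, TRUE)) {
      ix <- if (st) which(in_island) else which(!in_island)
      row <- if (st) cum_is[b, ] else cum_bg[b, ]
      cand[ix, b] <- 1L + (u[ix] > row[1]) + (u[ix] > row[2]) + (u[ix] > row[3])
    }
  }
  v <- integer(L)
  v[1] <- 1L + (u[1] > cb0[1]) + (u[1] > cb0[2]) + (u[1] > cb0[3])
  for (i in 2:L) v[i] <- cand[i, v[i - 1L]]
  seq <- paste(c("A", "C", "G", "T")[v], collapse = "")
  genome <- Biostrings::BStringSet(setNames(seq, "sim1"))
  list(genome = genome, islands = islands)
}

# 0-based forward-strand C positions of every CpG, per sequence
find_cpg_positions <- function(genome) {
  out <- lapply(names(genome), function(chr) {
    s <- toupper(as.character(genome[[chr]]))
    loc <- stringr::str_locate_all(s, stringr::fixed("CG"))[[1]]
    tibble(chrom = chr, cpg_pos = as.integer(loc[, 1] - 1L))
  })
  bind_rows(out)
}

#' Assign true methylation degrees to every CpG
#'
#' Background CpGs draw from the high-methylation Beta. Islands are
#' methylation-coherent units: each island draws one mixture component
#' (methylated with probability `island_meth_weight`), and all its CpGs
#' then draw degrees from that component's Beta — mirroring island-level
#' transcriptional silencing, where a promoter island is hyper- or
#' hypomethylated as a whole. The returned table is the simulation's
#' ground truth and carries `Inf` coverage (degrees known exactly).
#'
#' @param genome A [Biostrings::BStringSet] (or the list returned by
#'   [simulate_genome()]).
#' @param islands Island tibble (`chrom`, `start`, `end`); ignored when
#'   `genome` is a `simulate_genome()` result.
#' @param model A [methylation_model()].
#' @param seed Optional seed.
#' @return A methylation tibble (`chrom`, `cpg_pos`, `methylation_degree`,
#'   `coverage = Inf`, plus `in_island`).
#' @export
assign_methylation <- function(genome, islands = NULL, model, seed = NULL) {
  stopifnot(inherits(model, "methylation_model"))
  if (is.list(genome) && !is.null(genome$genome)) {
    islands <- genome$islands
    genome <- genome$genome
  }
  maybe_seed(seed)
  cpgs <- find_cpg_positions(genome)
  if (nrow(cpgs) == 0L) abort("genome contains no CpG")
  cpgs$island_id <- NA_integer_
  if (!is.null(islands) && nrow(islands)) {
    islands <- islands[order(islands$chrom, islands$start), ]
    islands$id <- seq_len(nrow(islands))
    for (chr in unique(islands$chrom)) {
      isl <- islands[islands$chrom == chr, ]
      ix <- which(cpgs$chrom == chr)
      k <- findInterval(cpgs$cpg_pos[ix], isl$start)
      hit <- k > 0 & cpgs$cpg_pos[ix] < isl$end[pmax(k, 1L)]
      cpgs$island_id[ix[hit]] <- isl$id[k[hit]]
    }
  }
  cpgs$in_island <- !is.na(cpgs$island_id)
  deg <- numeric(nrow(cpgs))
  n_bg <- sum(!cpgs$in_island)
  if (n_bg) deg[!cpgs$in_island] <- rbeta(n_bg, model$bg_shape1, model$bg_shape2)
  if (any(cpgs$in_island)) {
    # one mixture draw per island; per-CpG degrees from that component
    island_ids <- sort(unique(cpgs$island_id[cpgs$in_island]))
    island_methylated <- setNames(runif(length(island_ids)) <
                                    model$island_meth_weight,
                                  island_ids)
    for (id in island_ids) {
      ix <- which(cpgs$island_id == id)
      par <- if (island_methylated[as.character(id)]) model$island_high else
        model$island_low
      deg[ix] <- rbeta(length(ix), par[1], par[2])
    }
  }
  out <- mutate(select(cpgs, -"island_id"),
                methylation_degree = deg, coverage = Inf)
  attr(out, "source_kind") <- "true"
  out
}

#' Per-molecule capture probability of an MBD kit archetype
#'
#' `p(m) = epsilon + (1 - epsilon) * (1 - (1 - q)^m)` for a molecule
#' carrying `m` methylated CpGs: a nonspecific floor plus one independent
#' binding chance per methylated CpG, saturating in `m`.
#'
#' @param m Methylated-CpG counts (vectorized).
#' @param epsilon,q Kit archetype parameters.
#' @return Capture probabilities in `[0, 1]`.
#' @examples
#' capture_probability(5, epsilon = 0.01, q = 0.3)
#' @export
capture_probability <- function(m, epsilon, q) {
  if (any(c(epsilon, q) < 0 | c(epsilon, q) > 1)) {
    abort("`epsilon` and `q` must lie in [0, 1]")
  }
  epsilon + (1 - epsilon) * (1 - (1 - q)^m)
}

#' Simulate affinity capture of sheared molecules
#'
#' Molecules get a uniform random start and a truncated-normal length
#' (default mean 200 bp, sd 50, bounds 50-400 bp — a typical sonication
#' target). Each CpG contained in a molecule is methylated on that molecule
#' with probability equal to its population degree (per-molecule
#' resampling: allelic/cellular heterogeneity), and the molecule is captured
#' with probability [capture_probability()] of its methylated-CpG count.
#'
#' @param genome A [Biostrings::BStringSet] or `simulate_genome()` result.
#' @param methylation True methylation tibble from [assign_methylation()].
#' @param kit A [kit_archetype()].
#' @param n_molecules Number of sheared molecules to offer to the kit.
#' @param frag_len_mean,frag_len_sd,frag_len_bounds Truncated-normal length
#'   parameters (bp).
#' @param seed Optional seed.
#' @return Tibble of captured molecules (`chrom`, `start`, `end`,
#'   `m_methylated`), attributes `n_molecules` and `kit`.
#' @export
simulate_capture <- function(genome, methylation, kit, n_molecules = 50000,
                             frag_len_mean = 200, frag_len_sd = 50,
                             frag_len_bounds = c(50, 400), seed = NULL) {
  stopifnot(inherits(kit, "kit_archetype"))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  if (n_molecules <= 0) abort("`n_molecules` must be positive")
  lo <- frag_len_bounds[1]; hi <- frag_len_bounds[2]
  if (!(lo > 0 && hi > lo)) abort("invalid fragment length bounds")
  if (hi > min(Biostrings::width(genome))) {
    abort("fragment length upper bound exceeds the shortest sequence")
  }
  maybe_seed(seed)
  widths <- Biostrings::width(genome)
  chrom_idx <- if (length(genome) == 1L) rep(1L, n_molecules) else
    sample.int(length(genome), n_molecules, replace = TRUE,
               prob = widths / sum(widths))
  len <- rnorm(n_molecules, frag_len_mean, frag_len_sd)
  bad <- which(len < lo | len > hi)
  while (length(bad)) {
    len[bad] <- rnorm(length(bad), frag_len_mean, frag_len_sd)
    bad <- bad[len[bad] < lo | len[bad] > hi]
  }
  len <- as.integer(round(len))
  start <- as.integer(floor(runif(n_molecules) * (widths[chrom_idx] - len + 1)))
  end <- start + len
  m <- integer(n_molecules)
  for (ci in unique(chrom_idx)) {
    chr <- names(genome)[ci]
    ix <- which(chrom_idx == ci)
    tab <- methylation[methylation$chrom == chr, ]
    tab <- tab[order(tab$cpg_pos), ]
    pos <- tab$cpg_pos
    lo_i <- findInterval(start[ix] - 1L, pos)   # CpGs strictly before start
    hi_i <- findInterval(end[ix] - 1L, pos)     # CpGs before end
    cnt <- hi_i - lo_i
    if (sum(cnt) > 0) {
      cpg_ix <- sequence(cnt) + rep(lo_i, cnt)
      draws <- rbinom(length(cpg_ix), 1L, tab$methylation_degree[cpg_ix])
      sums <- rowsum(draws, group = rep.int(seq_along(ix), cnt))
      m[ix[as.integer(rownames(sums))]] <- as.integer(sums[, 1])
    }
  }
  p <- capture_probability(m, kit$epsilon, kit$q)
  keep <- runif(n_molecules) < p
  out <- tibble(chrom = names(genome)[chrom_idx[keep]],
                start = start[keep], end = end[keep],
                m_methylated = m[keep])
  attr(out, "n_molecules") <- n_molecules
  attr(out, "kit") <- kit
  out
}

#' Simulate sequencing of a captured pool (with PCR duplicates)
#'
#' Draws `n_reads` fragments with replacement from the captured pool — a
#' one-knob proxy for PCR amplification plus flow-cell sampling. Small pools
#' therefore yield high duplicate fractions, the signature of inefficient
#' capture in yield tables.
#'
#' @param pool Captured molecule tibble from [simulate_capture()].
#' @param n_reads Number of sequenced read pairs.
#' @param seed Optional seed.
#' @param read_len Sequenced mate length in bp (default 45).
#' @return Tibble of sequenced fragments, one row per read pair (`chrom`,
#'   `start`, `end`, `molecule_id`, `multiplicity = 1`); attribute
#'   `read_len`.
#' @export
simulate_sequencing <- function(pool, n_reads, seed = NULL, read_len = 45) {
  if (nrow(pool) == 0L) abort("captured pool is empty")
  if (n_reads <= 0) abort("`n_reads` must be positive")
  maybe_seed(seed)
  idx <- sample.int(nrow(pool), n_reads, replace = TRUE)
  out <- tibble(chrom = pool$chrom[idx], start = pool$start[idx],
                end = pool$end[idx], molecule_id = idx, multiplicity = 1L)
  attr(out, "read_len") <- read_len
  out
}

#' Express sequenced fragments as BEDPE mate intervals
#'
#' The first and last `read_len` bp of each fragment become mate 1 (+) and
#' mate 2 (-); fragments shorter than `read_len` yield fully overlapping
#' mates.
#'
#' @param fragments Sequenced fragment tibble.
#' @param read_len Mate length in bp.
#' @return A BEDPE-shaped tibble (10 columns).
#' @export
fragments_to_bedpe <- function(fragments, read_len = 45) {
  assert_columns(fragments, c("chrom", "start", "end"), "`fragments`")
  rl <- pmin(read_len, fragments$end - fragments$start)
  tibble(chrom1 = fragments$chrom, start1 = fragments$start,
         end1 = fragments$start + rl,
         chrom2 = fragments$chrom, start2 = fragments$end - rl,
         end2 = fragments$end,
         name = sprintf("read%d", seq_len(nrow(fragments))),
         score = 60L, strand1 = "+", strand2 = "-")
}

#' @rdname fragments_to_bedpe
#' @param path Output path.
#' @export
write_bedpe <- function(fragments, path, read_len = 45) {
  readr::write_tsv(fragments_to_bedpe(fragments, read_len), path,
                   col_names = FALSE)
  invisible(path)
}

#' Simulate RRBS-like observation of the methylation landscape
#'
#' Per CpG: coverage is Poisson(`mean_coverage`), the methylated read count
#' is Binomial(coverage, true degree), and the observed degree is their
#' ratio. CpGs drawing zero coverage are absent from the output, as they
#' would be from a bisulfite caller's table.
#'
#' @param methylation True methylation tibble.
#' @param mean_coverage Mean sequencing coverage per CpG.
#' @param seed Optional seed.
#' @return An observed methylation tibble (`chrom`, `cpg_pos`,
#'   `methylation_degree`, `coverage`, `meth_count`), attribute
#'   `source_kind = "rrbs"`.
#' @export
simulate_bisulfite <- function(methylation, mean_coverage = 30, seed = NULL) {
  assert_columns(methylation, c("chrom", "cpg_pos", "methylation_degree"),
                 "`methylation`")
  if (mean_coverage <= 0) abort("`mean_coverage` must be positive")
  maybe_seed(seed)
  n <- nrow(methylation)
  cov <- rpois(n, mean_coverage)
  mc <- rbinom(n, cov, methylation$methylation_degree)
  keep <- cov > 0
  out <- tibble(chrom = methylation$chrom[keep],
                cpg_pos = methylation$cpg_pos[keep],
                methylation_degree = mc[keep] / cov[keep],
                coverage = cov[keep],
                meth_count = mc[keep])
  attr(out, "source_kind") <- "rrbs"
  out
}

#' Write a methylation table as TSV
#'
#' `rrbs` dialect writes stranded count columns (`chrom`, `pos`, `strand`,
#' `meth_count`, `total_count`; all records on `+`, already
#' strand-combined); `array` writes (`chrom`, `pos`, `beta`).
#'
#' @param table A methylation tibble.
#' @param path Output TSV path.
#' @param dialect `"rrbs"` or `"array"`.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(table, path, dialect = c("rrbs", "array")) {
  dialect <- match.arg(dialect)
  assert_columns(table, c("chrom", "cpg_pos", "methylation_degree"), "`table`")
  if (dialect == "array") {
    readr::write_tsv(tibble(chrom = table$chrom, pos = table$cpg_pos,
                            beta = table$methylation_degree), path)
  } else {
    cov <- table$coverage %||% rep(NA_real_, nrow(table))
    mc <- if ("meth_count" %in% names(table)) table$meth_count else
      round(table$methylation_degree * cov)
    readr::write_tsv(tibble(chrom = table$chrom, pos = table$cpg_pos,
                            strand = "+", meth_count = as.integer(mc),
                            total_count = as.integer(cov)), path)
  }
  invisible(path)
}

#' Run a full simulated MBD-capture experiment
#'
#' Chains genome generation, methylation assignment, affinity capture,
#' sequencing with duplicates, and RRBS-like observation under one seeded
#' generator, so identical parameters and seed reproduce the experiment
#' bit-exactly.
#'
#' @param genome_model A [genome_model()].
#' @param methylation_model A [methylation_model()].
#' @param kit A [kit_archetype()].
#' @param n_molecules Molecules offered to the kit.
#' @param n_reads Sequenced read pairs.
#' @param mean_coverage RRBS mean coverage.
#' @param seed Master seed for the whole experiment.
#' @param frag_len_mean,frag_len_sd,frag_len_bounds Shearing parameters.
#' @return An object of class `mbd_experiment`: list with `genome`,
#'   `islands`, `methylation_true`, `pool`, `reads`,
#'   `methylation_observed`, `params`.
#' @export
simulate_experiment <- function(genome_model = mbdqc::genome_model(),
                                methylation_model = mbdqc::methylation_model(),
                                kit = kit_archetype(0.05, 0.2),
                                n_molecules = 50000, n_reads = 50000,
                                mean_coverage = 30, seed = 1,
                                frag_len_mean = 200, frag_len_sd = 50,
                                frag_len_bounds = c(50, 400)) {
  set.seed(as.integer(seed))
  gen <- simulate_genome(genome_model, seed = NULL)
  meth <- assign_methylation(gen, model = methylation_model, seed = NULL)
  pool <- simulate_capture(gen$genome, meth, kit, n_molecules = n_molecules,
                           frag_len_mean = frag_len_mean,
                           frag_len_sd = frag_len_sd,
                           frag_len_bounds = frag_len_bounds, seed = NULL)
  reads <- simulate_sequencing(pool, n_reads = n_reads, seed = NULL)
  observed <- simulate_bisulfite(meth, mean_coverage = mean_coverage,
                                 seed = NULL)
  structure(list(genome = gen$genome, islands = gen$islands,
                 methylation_true = meth, pool = pool, reads = reads,
                 methylation_observed = observed,
                 params = list(genome_model = genome_model,
                               methylation_model = methylation_model,
                               kit = kit, n_molecules = n_molecules,
                               n_reads = n_reads,
                               mean_coverage = mean_coverage,
                               frag_len_mean = frag_len_mean,
                               frag_len_sd = frag_len_sd,
                               frag_len_bounds = frag_len_bounds,
                               seed = seed)),
            class = "mbd_experiment")
}

#' @method glance mbd_experiment
#' @export
glance.mbd_experiment <- function(x, ...) {
  dedup <- deduplicate_fragments(x$reads)
  tibble(kit = x$params$kit$label,
         n_molecules = x$params$n_molecules,
         n_captured = nrow(x$pool),
         capture_rate = nrow(x$pool) / x$params$n_molecules,
         n_reads = x$params$n_reads,
         n_nonduplicate = nrow(dedup),
         pct_nondup_of_reads = percent_1dp(nrow(dedup), x$params$n_reads),
         n_cpgs = nrow(x$methylation_true),
         mean_true_degree = mean(x$methylation_true$methylation_degree),
         seed = x$params$seed)
}

#' @method print mbd_experiment
#' @export
print.mbd_experiment <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Simulated MBD-capture experiment (kit %s, seed %s)\n  %s CpGs over %d bp; %s molecules -> %s captured -> %s reads (%s non-duplicate)\n",
    g$kit, g$seed, format(g$n_cpgs, big.mark = ","),
    sum(Biostrings::width(x$genome)), format(g$n_molecules, big.mark = ","),
    format(g$n_captured, big.mark = ","), format(g$n_reads, big.mark = ","),
    format(g$n_nonduplicate, big.mark = ",")))
  invisible(x)
}
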