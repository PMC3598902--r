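# Independent oracles and shared fixtures. Oracles deliberately avoid the
# package's own code paths: explicit loops, closed forms, hand-built records.

.mbdqc_cache <- new.env(parent = emptyenv())

cache_get <- function(name, fn) {
  if (!exists(name, envir = .mbdqc_cache)) {
    assign(name, fn(), envir = .mbdqc_cache)
  }
  get(name, envir = .mbdqc_cache)
}

quiet <- function(expr) suppressMessages(expr)

# --- alignment fixture: 10 pairs, 6 pass, 3 fail uniqueness, 1 cross-chrom --
sam_fixture_path <- function() {
  cache_get("sam_fixture", function() {
    path <- tempfile(fileext = ".sam")
    rec <- function(qname, flag, rname, pos, mapq, cigar = "45M") {
      paste(qname, flag, rname, pos, mapq, cigar, "=", 0, 0, "*", "*",
            sep = "\t")
    }
    lines <- c(
      "@HD\tVN:1.6",
      "@SQ\tSN:chr1\tLN:2000",
      "@SQ\tSN:chr2\tLN:2000",
      # six proper unique pairs within 400 bp
      rec("p1", 99, "chr1", 101, 60), rec("p1", 147, "chr1", 301, 60),
      rec("p2", 99, "chr1", 201, 60), rec("p2", 147, "chr1", 481, 60),
      rec("p3", 99, "chr1", 51, 60), rec("p3", 147, "chr1", 111, 60),
      rec("p4", 99, "chr1", 1001, 60), rec("p4", 147, "chr1", 1101, 60),
      rec("p5", 99, "chr1", 301, 60), rec("p5", 147, "chr1", 471, 60),
      rec("p6", 99, "chr1", 601, 60), rec("p6", 147, "chr1", 641, 60),
      # three uniqueness failures: low MAPQ mate 1, low MAPQ mate 2, unmapped
      rec("p7", 99, "chr1", 701, 0), rec("p7", 147, "chr1", 801, 60),
      rec("p8", 99, "chr1", 901, 60), rec("p8", 147, "chr1", 1001, 5),
      rec("p9", 69, "*", 0, 0, "*"), rec("p9", 137, "chr1", 901, 60),
      # one cross-chromosome pair
      rec("p10", 97, "chr1", 1501, 60), rec("p10", 145, "chr2", 201, 60))
    writeLines(lines, path)
    path
  })
}

# --- random genome as both raw string and package container ----------------
random_genome <- function(len, seed, name = "rg1") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  list(seq = s, genome = Biostrings::BStringSet(stats::setNames(s, name)),
       name = name)
}

# sliding-window CpG count over a 0-based half-open interval
cpg_count_oracle <- function(s, start, end) {
  n <- 0L
  if (end - start >= 2L) {
    for (j in start:(end - 2L)) {
      if (toupper(substr(s, j + 1L, j + 2L)) == "CG") n <- n + 1L
    }
  }
  n
}

# nested-loop per-bin incidence counts (degrees assumed off bin edges, so a
# plain floor needs no floating-point nudge)
bin_counts_oracle <- function(fragments, table, w, semantics = "cpg") {
  n_bins <- as.integer(ceiling(1 / w - 1e-9))
  counts <- numeric(n_bins)
  for (f in seq_len(nrow(fragments))) {
    seen <- integer(0)
    for (t in seq_len(nrow(table))) {
      if (table$chrom[t] == fragments$chrom[f] &&
          table$cpg_pos[t] >= fragments$start[f] &&
          table$cpg_pos[t] < fragments$end[f]) {
        b <- min(floor(table$methylation_degree[t] / w), n_bins - 1)
        if (semantics == "cpg") {
          counts[b + 1L] <- counts[b + 1L] + 1
        } else {
          seen <- union(seen, b)
        }
      }
    }
    if (semantics == "set") {
      for (b in seen) counts[b + 1L] <- counts[b + 1L] + 1
    }
  }
  counts
}

# occupancy of K cells after n draws with replacement: closed-form moments
occupancy_stats <- function(K, n) {
  a <- (1 - 1 / K)^n
  b <- (1 - 2 / K)^n
  m <- K * (1 - a)
  v <- K * a + K * (K - 1) * b - K^2 * a^2
  list(mean = m, sd = sqrt(max(v, 0)))
}

total_variation <- function(p, q) sum(abs(p - q)) / 2

# --- shared small simulated experiment -------------------------------------
sim_fixture <- function() {
  cache_get("sim_fixture", function() {
    exp <- simulate_experiment(
      genome_model = genome_model(length = 30000),
      kit = kit_archetype(0.05, 0.3, "fixture"),
      n_molecules = 10000, n_reads = 10000, mean_coverage = 30, seed = 424242)
    exp$dedup <- deduplicate_fragments(exp$reads)
    exp$table <- filter_by_coverage(exp$methylation_observed, 20)
    exp
  })
}

# --- 100-replicate kit contrast (shared by property and acceptance tests) --
# A: specific & sensitive; B: nonspecific & insensitive; C: like A but a
# higher nonspecific floor (epsilon-rank probe); D: like A but low q
# (onset-shift probe).
kit_contrast_replicates <- function(n_reps = 100) {
  cache_get("kit_contrast", function() {
    kits <- list(A = kit_archetype(0.02, 0.40, "A"),
                 B = kit_archetype(0.30, 0.05, "B"),
                 C = kit_archetype(0.20, 0.40, "C"),
                 D = kit_archetype(0.02, 0.05, "D"))
    one_rep <- function(r) {
      set.seed(52000 + r)
      g <- simulate_genome(genome_model(length = 100000))
      meth <- assign_methylation(g, model = methylation_model())
      obs <- simulate_bisulfite(meth, 30)
      tab <- filter_by_coverage(obs, 20)
      bg <- background_profile(tab)
      pools <- lapply(kits, function(k) {
        deduplicate_fragments(simulate_capture(g$genome, meth, k, 50000))
      })
      f0 <- vapply(pools[c("A", "B", "C")], function(p) {
        fragment_cpg_histogram(p, g$genome)$fraction[1]
      }, numeric(1))
      onset <- vapply(pools[c("A", "B", "D")], function(p) {
        kit <- fragment_bin_fractions(p, tab)
        as.numeric(attr(enrichment_ratio(kit, bg), "onset_bin"))
      }, numeric(1))
      c(f0A = unname(f0["A"]), f0B = unname(f0["B"]), f0C = unname(f0["C"]),
        onsetA = unname(onset["A"]), onsetB = unname(onset["B"]),
        onsetD = unname(onset["D"]))
    }
    as.data.frame(t(vapply(seq_len(n_reps), one_rep, numeric(6))))
  })
}
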