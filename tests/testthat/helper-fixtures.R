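## shared fixtures and independent oracles

DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## write a FASTQ file from sequences (+ optional quality characters)
write_fastq <- function(seqs, path, qual_char = "I", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(seqs))
  qual <- vapply(nchar(seqs), function(n) strrep(qual_char, n), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

## brute-force oracle for the phased-window tail probability: exhaustive
## enumeration of n-position subsets of the 21m window positions, counting
## those with >= k phased positions
phas_pvalue_enum <- function(n, k, m) {
  total <- 21L * m
  phased <- seq_len(m) * 21L - 20L   # one phased position per cycle
  subsets <- utils::combn(total, n)
  hits <- colSums(matrix(subsets %in% phased, nrow = n))
  mean(hits >= k)
}

## independent all-pairs known-miRNA matching oracle (simple nested loops,
## ungapped end-shift alignment)
match_known_oracle <- function(tags, refs, max_mismatch = 0L, max_shift = 2L) {
  out <- rep(NA_character_, length(tags))
  refs <- refs[order(names(refs))]
  for (i in seq_along(tags)) {
    best_mm <- Inf; best_shift <- Inf; best_name <- NA_character_
    for (j in seq_along(refs)) {
      t <- strsplit(tags[i], "")[[1]]; r <- strsplit(refs[[j]], "")[[1]]
      for (o in -max_shift:max_shift) {
        es <- abs(o + length(t) - length(r))
        if (es > max_shift) next
        ti <- max(1, 1 - o):min(length(t), length(r) - o)
        if (!length(ti)) next
        mm <- sum(t[ti] != r[ti + o])
        sh <- abs(o) + es
        if (mm <= max_mismatch &&
            (mm < best_mm || (mm == best_mm && sh < best_shift))) {
          best_mm <- mm; best_shift <- sh; best_name <- names(refs)[j]
        }
      }
    }
    out[i] <- best_name
  }
  out
}

## naive exact-match genome search oracle
map_oracle <- function(tag, gen) {
  hits <- list()
  for (ch in names(gen)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else mirphas::revcomp(tag)
      pos <- gregexpr(pat, gen[[ch]], fixed = TRUE)[[1]]
      ## gregexpr misses overlapping matches; step through manually
      starts <- integer(0); from <- 1L
      while (from <= nchar(gen[[ch]]) - nchar(pat) + 1L) {
        p <- regexpr(pat, substr(gen[[ch]], from, nchar(gen[[ch]])), fixed = TRUE)
        if (p < 0) break
        starts <- c(starts, from + p - 1L)
        from <- from + p
      }
      if (length(starts)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = starts - 1L, end = starts - 1L + nchar(tag),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

## a ground-truthed small scenario reused across tests
demo_scenario <- function(seed = 42L, n_hairpins = 3L, total_reads = 4000L,
                          chrom_len = 30000L) {
  g <- make_genome(1, chrom_len, seed = seed)
  set.seed(seed + 1L)
  for (i in seq_len(n_hairpins)) {
    g <- plant_hairpin(g, mature_len = sample(20:24, 1),
                       arm = sample(c("5p", "3p"), 1),
                       abundance_treatment = 60, abundance_control = 60)
  }
  trig <- random_seq(22)
  g <- plant_phas_locus(g, n_cycles = 12L, trigger_seq = trig,
                        abundance_treatment = 80, abundance_control = 80)
  g <- plant_region(g, "rrna_trna", 300, 50, 50)
  g <- plant_region(g, "exon", 400, 40, 40)
  dir <- file.path(tempdir(), paste0("demo", seed))
  sim <- simulate_libraries(
    g, library_spec("treatment", total_reads, seed = seed + 10L),
    library_spec("control", total_reads, seed = seed + 20L), dir = dir)
  list(genome = g, sim = sim, trigger = trig)
}

## preprocess + collapse both simulated libraries of a scenario
scenario_tags <- function(sc) {
  pre_t <- preprocess_library(sc$sim$fastq_treatment, DEFAULT_ADAPTER)
  pre_c <- preprocess_library(sc$sim$fastq_control, DEFAULT_ADAPTER)
  collapse_tags(pre_t$inserts, pre_c$inserts)
}
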