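test_that("genome generation is seed-deterministic and seed-sensitive", {
  g1 <- make_genome(1, 10000, seed = 1)
  g2 <- make_genome(1, 10000, seed = 1)
  g3 <- make_genome(2, 5000, seed = 2)
  expect_identical(g1$sequences, g2$sequences)
  expect_false(identical(make_genome(2, 5000, seed = 1)$sequences,
                         g3$sequences))
  expect_error(make_genome(0, 10000), "n_chrom")
  expect_error(make_genome(1, 10), "chrom_len")
})

test_that("background sequence composition is uniform", {
  g <- make_genome(1, 100000, seed = 7)
  gc <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(g$sequences), "GC", as.prob = TRUE)[, 1]
  ## binomial bound: sd of GC fraction at 100 kb is ~0.0016
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("planted hairpins satisfy the construction contract", {
  g <- make_genome(1, 20000, seed = 3)
  set.seed(4)
  g <- plant_hairpin(g, mature_len = 21, arm = "5p")
  g <- plant_hairpin(g, mature_len = 24, arm = "3p")
  tr <- g$truth
  expect_equal(nrow(tr), 2L)
  ## the mature and star sit where the truth table says
  for (i in 1:2) {
    chrom <- g$sequences[[tr$chrom[i]]]
    expect_identical(substr(chrom, tr$mature_start[i] + 1, tr$mature_end[i]),
                     tr$mature_seq[i])
    expect_identical(substr(chrom, tr$star_start[i] + 1, tr$star_end[i]),
                     tr$star_seq[i])
    ## star core is the reverse complement of the mature minus its overhang
    L <- nchar(tr$mature_seq[i])
    expect_identical(substr(tr$star_seq[i], 1, L - 2),
                     revcomp(substr(tr$mature_seq[i], 1, L - 2)))
  }
  expect_error(plant_hairpin(g, mature_len = 17), "mature_len")
  expect_error(plant_hairpin(g, mature_len = 26), "mature_len")
})

test_that("planted phased loci encode the cleavage register", {
  g <- make_genome(1, 20000, seed = 5)
  set.seed(6)
  trig <- random_seq(22)
  g <- plant_phas_locus(g, n_cycles = 11, trigger_seq = trig)
  tr <- g$truth[1, ]
  ## the trigger site carries the complement of the trigger
  site <- substr(g$sequences[[tr$chrom]], tr$trigger_site_start + 1,
                 tr$trigger_site_start + 22)
  expect_identical(site, revcomp(trig))
  ## register definition: first phase opposite trigger positions 10/11
  expect_identical(tr$phase_start, cleavage_position(tr$trigger_site_start))
  expect_identical(tr$phase_register, (tr$trigger_site_start + 10L) %% 21L)
  expect_error(plant_phas_locus(g, n_cycles = 5, trigger_seq = trig),
               "n_cycles")
  expect_error(plant_phas_locus(g, n_cycles = 11, trigger_seq = "ACGT"),
               "22 nt")
})

test_that("library simulation conserves totals and is byte-deterministic", {
  sc <- demo_scenario(seed = 101, total_reads = 2000)
  fq <- readLines(sc$sim$fastq_treatment)
  expect_equal(length(fq) / 4L, 2000)
  expect_equal(length(readLines(sc$sim$fastq_control)) / 4L, 2000)
  ## re-simulating with the same specs reproduces the files byte for byte
  dir2 <- file.path(tempdir(), "resim")
  sim2 <- simulate_libraries(
    sc$genome, library_spec("treatment", 2000, seed = 111),
    library_spec("control", 2000, seed = 121), dir = dir2)
  sim3dir <- file.path(tempdir(), "resim3")
  sim3 <- simulate_libraries(
    sc$genome, library_spec("treatment", 2000, seed = 111),
    library_spec("control", 2000, seed = 121), dir = sim3dir)
  expect_identical(readLines(sim2$fastq_treatment),
                   readLines(sim3$fastq_treatment))
  expect_error(library_spec("t", 0), "total_reads")
  expect_error(library_spec("t", 10, adapter_3p = ""), "adapter_3p")
  expect_error(library_spec("t", 10, error_rate = 0.5), "error_rate")
})

test_that("condition-specific features appear only in their library", {
  g <- make_genome(1, 20000, seed = 9)
  set.seed(10)
  g <- plant_hairpin(g, 21, "5p", abundance_treatment = 100,
                     abundance_control = 0)
  dir <- file.path(tempdir(), "condspec")
  sim <- simulate_libraries(g, library_spec("treatment", 1500, seed = 1),
                            library_spec("control", 1500, seed = 2),
                            dir = dir)
  mature <- g$truth$mature_seq[1]
  count_in <- function(fq) {
    seqs <- readLines(fq)[c(FALSE, TRUE, FALSE, FALSE)]
    sum(startsWith(seqs, mature))
  }
  expect_gt(count_in(sim$fastq_treatment), 50)
  expect_equal(count_in(sim$fastq_control), 0)
})

test_that("non-background reads map back to their recorded feature", {
  sc <- demo_scenario(seed = 202, total_reads = 1500)
  fq <- readLines(sc$sim$fastq_treatment)
  ids <- sub("^@\\S+\\s+", "", fq[c(TRUE, FALSE, FALSE, FALSE)])
  seqs <- fq[c(FALSE, TRUE, FALSE, FALSE)]
  tr <- sc$genome$truth
  featured <- ids %in% tr$feature_id
  checked <- 0L
  for (i in which(featured)) {
    row <- tr[tr$feature_id == ids[i], ]
    region <- substr(sc$genome$sequences[[row$chrom]],
                     row$start + 1 - 2, row$end)   # -2: antisense phas offset
    insert <- sub(paste0(substr(DEFAULT_ADAPTER, 1, 8), ".*$"), "", seqs[i])
    found <- grepl(insert, region, fixed = TRUE) ||
      grepl(revcomp(insert), region, fixed = TRUE)
    expect_true(found, info = paste("read", i, "kind", row$kind))
    checked <- checked + 1L
  }
  expect_gt(checked, 100L)
})

test_that("sampled mature counts track the expected abundance", {
  ## Poisson oracle: over 20 seeds the observed count of one planted
  ## mature should stay within 3 sd of its expectation
  g <- make_genome(1, 15000, seed = 11)
  set.seed(12)
  g <- plant_hairpin(g, 21, "5p", abundance_treatment = 80,
                     abundance_control = 80)
  mature <- g$truth$mature_seq[1]
  counts <- vapply(1:20, function(s) {
    dir <- file.path(tempdir(), paste0("pois", s))
    sim <- simulate_libraries(g, library_spec("treatment", 1200, seed = s),
                              library_spec("control", 1200, seed = 1000 + s),
                              dir = dir, star_frac = 0)
    sim$counts$treatment[1]
  }, numeric(1))
  expect_true(all(abs(counts - 80) <= 3 * sqrt(80)))
  ## and the mean over seeds is close to the expectation
  expect_lt(abs(mean(counts) - 80), 3 * sqrt(80 / 20))
})
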