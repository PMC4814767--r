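## construct a hairpin_candidate-shaped list for criterion tests
mock_candidate <- function(mature_len = 21L, mfe = -30, duplex_pairs = 18L,
                           max_bulge = 2L, asymmetry = 1L, loop_span = 12L,
                           flank5 = 25L, flank3 = 25L, copy_number = 1L) {
  structure(list(mature_seq = strrep("A", mature_len), mfe = mfe,
                 duplex_pairs = duplex_pairs, max_bulge = max_bulge,
                 asymmetry = asymmetry, loop_span = loop_span,
                 flank5 = flank5, flank3 = flank3,
                 copy_number = copy_number),
            class = "hairpin_candidate")
}

test_that("hit clustering is strand-aware single linkage with a 200-nt gap", {
  hits <- data.frame(
    sequence = c("a", "b", "c", "d"), chrom = "chr1",
    start = c(100L, 171L, 700L, 100L), end = c(121L, 192L, 721L, 121L),
    strand = c("+", "+", "+", "-"), length = 21L, n_hits = 1L)
  cl <- cluster_hits(hits, max_gap = 200L)
  id_of <- function(s) cl$locus_id[cl$sequence == s]
  expect_equal(id_of("a"), id_of("b"))       # 50 nt apart: one locus
  expect_false(id_of("a") == id_of("c"))     # ~500 nt apart: two loci
  expect_false(id_of("a") == id_of("d"))     # opposite strand: two loci
})

test_that("criterion checklist enforces the stated boundaries", {
  all_pass <- check_criteria(mock_candidate())
  expect_length(all_pass, 11L)
  expect_true(all(all_pass))
  ## exact boundary values pass
  expect_true(all(check_criteria(mock_candidate(
    duplex_pairs = 16L, max_bulge = 4L, asymmetry = 4L, mfe = -18,
    copy_number = 20L, loop_span = 200L))))
  ## one-off violations fail the right flag
  expect_false(check_criteria(mock_candidate(duplex_pairs = 15L))[["duplex_pairs"]])
  expect_false(check_criteria(mock_candidate(mfe = -17.5))[["mfe"]])
  expect_false(check_criteria(mock_candidate(max_bulge = 5L))[["bulge"]])
  expect_false(check_criteria(mock_candidate(asymmetry = 5L))[["asymmetry"]])
  expect_false(check_criteria(mock_candidate(copy_number = 21L))[["copy_number"]])
  expect_false(check_criteria(mock_candidate(loop_span = 201L))[["duplex_space"]])
  expect_false(check_criteria(mock_candidate(mature_len = 17L))[["mature_min_len"]])
  expect_false(check_criteria(mock_candidate(flank5 = 20L))[["flank"]])
  ## reference-length criteria only bind when a reference is supplied
  expect_true(all(check_criteria(mock_candidate(), ref_len = NULL)))
  expect_false(check_criteria(mock_candidate(), ref_len = 24L)[["ref_max_len"]])
  expect_false(check_criteria(mock_candidate(), ref_len = 19L)[["ref_min_len"]])
})

test_that("a planted hairpin re-folds into a candidate passing all criteria", {
  g <- make_genome(1, 20000, seed = 61)
  set.seed(62)
  g <- plant_hairpin(g, 21, "5p", 50, 50)
  tr <- g$truth[1, ]
  hits <- map_to_genome(c(tr$mature_seq, tr$star_seq), g)
  hits$count_treatment <- ifelse(hits$sequence == tr$mature_seq, 50L, 12L)
  hits$count_control <- hits$count_treatment
  cand <- excise_and_fold(hits, g)
  expect_s3_class(cand, "hairpin_candidate")
  expect_lte(cand$mfe, -18)
  expect_true(all(check_criteria(cand)))
  expect_gte(nchar(cand$precursor_seq), 68L)
  expect_lte(nchar(cand$precursor_seq), 293L)
  ## star support: the planted star tag sits at the implied duplex position
  expect_true(detect_star(hits, cand))
  ## without star reads there is no support
  expect_false(detect_star(hits[hits$sequence == tr$mature_seq, ], cand))
  ## a tag offset 5 nt from the implied star position does not count
  shifted <- hits[hits$sequence == tr$star_seq, ]
  shifted$start <- shifted$start + 5L
  shifted$end <- shifted$end + 5L
  expect_false(detect_star(rbind(hits[hits$sequence == tr$mature_seq, ],
                                 shifted), cand))
})

test_that("a weak designed duplex fails the base-pairing criterion", {
  g <- make_genome(1, 20000, seed = 63)
  set.seed(64)
  ## 7 designed mismatches leave ~12 duplex pairs
  g <- plant_hairpin(g, 21, "5p", 50, 50, mismatches = 7L)
  tr <- g$truth[1, ]
  hits <- map_to_genome(tr$mature_seq, g)
  hits$count_treatment <- 50L; hits$count_control <- 50L
  cand <- excise_and_fold(hits, g)
  if (!is.null(cand)) {
    expect_false(check_criteria(cand)[["duplex_pairs"]])
  } else {
    succeed("no stem-loop recovered from the broken duplex")
  }
})

test_that("multi-copy hairpins are rejected by the copy-number criterion", {
  g <- make_genome(1, 80000, seed = 65)
  set.seed(66)
  g <- plant_hairpin(g, 21, "5p", 60, 60, copies = 25L)
  mature <- g$truth$mature_seq[1]
  tags <- collapse_tags(rep(mature, 60), rep(mature, 60))
  out <- predict_novel_mirnas(tags, g)
  expect_equal(nrow(out), 0L)
})

test_that("family clustering respects the 85% identity cutoff", {
  base <- "ACGTACGTACGTACGTACGTA"   # 21 nt
  mutate_at <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- chartr("ACGT", "CGTA", substr(s, p, p))
    s
  }
  three_mm <- mutate_at(base, c(3, 9, 15))   # identity 18/21 ~ 0.857
  four_mm <- mutate_at(base, c(3, 9, 15, 20))  # identity 17/21 ~ 0.81
  fam3 <- cluster_families(c(base, base, three_mm))
  expect_equal(fam3[1], fam3[2])
  expect_equal(fam3[1], fam3[3])
  ## pairwise below the cutoff (single linkage would otherwise chain
  ## through an intermediate, so test the pair in isolation)
  fam4 <- cluster_families(c(base, four_mm))
  expect_false(fam4[1] == fam4[2])
})

test_that("first-nucleotide bias reproduces a planted composition", {
  seqs <- c(rep(paste0("T", random_seq(20, seed = 67)), 5),
            rep(paste0("A", random_seq(23, seed = 68)), 7))
  fb <- first_nt_bias(seqs)
  expect_equal(fb$U[fb$length == 21], 1)
  expect_equal(fb$A[fb$length == 24], 1)
  expect_false(22 %in% fb$length)   # empty length classes are omitted
  expect_equal(nrow(first_nt_bias(character(0))), 0L)
})

test_that("reported novel miRNAs all re-pass the criteria independently", {
  sc <- demo_scenario(seed = 71, n_hairpins = 4, total_reads = 4000)
  tags <- scenario_tags(sc)
  ann <- truth_annotation(sc$genome)
  tags <- annotate_tags(tags, sc$genome, rfam = ann$rfam, exon = ann$exon)
  out <- predict_novel_mirnas(tags, sc$genome)
  expect_gte(nrow(out), 3L)
  for (cand in attr(out, "candidates")) {
    expect_true(all(check_criteria(cand)))
  }
  expect_true(all(pmax(out$count_treatment, out$count_control) >= 10L))
  expect_true(all(out$precursor_len >= 68L & out$precursor_len <= 293L))
  ## planted matures recovered
  planted <- sc$genome$truth$mature_seq[sc$genome$truth$kind == "hairpin_mirna"]
  expect_gte(sum(planted %in% out$mature_seq), 3L)
})
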