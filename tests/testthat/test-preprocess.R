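test_that("quality filtering drops low-quality and ambiguous reads", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@good", "ACGTACGTACGTACGTACGTA", "+", strrep("I", 21),
               "@hasN", "ACGTNCGTACGTACGTACGTA", "+", strrep("I", 21),
               "@lowq", "ACGTACGTACGTACGTACGTA", "+", strrep("#", 21)),
             fq)
  kept <- quality_filter(read_fastq(fq))
  expect_equal(length(kept), 1L)
  expect_equal(names(kept), "good")
  expect_equal(attr(kept, "n_raw"), 3L)
})

test_that("malformed FASTQ errors name the record index", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGT", "+", "III"), fq)   # quality too short
  expect_error(read_fastq(fq), "record at index 2")
})

test_that("adapter trimming assigns discard classes by precedence", {
  adapter <- DEFAULT_ADAPTER
  insert21 <- "GCTCACTGCTCTATCTGTCAC"
  reads <- c(
    paste0(insert21, substr(adapter, 1, 19)),      # clean 21-nt insert
    substr(adapter, 1, 40),                        # adapter at start
    random_seq(40, seed = 31),                     # no adapter
    paste0("GTACG", substr(adapter, 1, 20)),       # 5-nt insert: too short
    paste0(strrep("A", 20), substr(adapter, 1, 20)))  # polyA insert
  fq <- write_fastq(reads, tempfile(fileext = ".fastq"))
  res <- trim_and_categorize(quality_filter(read_fastq(fq)), adapter)
  s <- res$stats
  expect_equal(s$insert_null, 1L)
  expect_equal(s$adapter3_null, 1L)
  expect_equal(s$shorter_than_18, 1L)
  expect_equal(s$polyA, 1L)
  expect_equal(s$clean, 1L)
  expect_equal(as.character(res$inserts[[1]]), insert21)
  ## discard classes partition high-quality reads
  expect_equal(s$high_quality,
               s$adapter3_null + s$insert_null + s$adapter5_contaminant +
                 s$polyA + s$shorter_than_18 + s$clean)
  expect_error(trim_and_categorize(read_fastq(fq), ""), "adapter_3p")
})

test_that("5' adapter contamination is flagged before the polyA check", {
  adapter3 <- DEFAULT_ADAPTER
  adapter5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  read <- paste0("ACGTT", substr(adapter5, 1, 12), "ACGTT",
                 substr(adapter3, 1, 18))
  fq <- write_fastq(c(read), tempfile(fileext = ".fastq"))
  res <- trim_and_categorize(quality_filter(read_fastq(fq)), adapter3,
                             adapter_5p = adapter5)
  expect_equal(res$stats$adapter5_contaminant, 1L)
  expect_equal(res$stats$clean, 0L)
})

test_that("collapse merges libraries into a unique-tag table", {
  t_ins <- c(rep("ACGTACGTACGTACGTAC", 3))
  c_ins <- character(0)
  tags <- collapse_tags(t_ins, c_ins)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$count_treatment, 3L)
  expect_equal(tags$count_control, 0L)
  ## identical multisets give a 100% shared fraction
  both <- collapse_tags(c("AAAACCCCGGGGTTTTAC", "ACGTACGTACGTACGTAC"),
                        c("ACGTACGTACGTACGTAC", "AAAACCCCGGGGTTTTAC"))
  expect_equal(attr(both, "shared_fraction"), 1)
})

test_that("genome mapping matches a naive string-search oracle", {
  g <- make_genome(1, 50000, seed = 21)
  gen <- g$sequences
  set.seed(22)
  tags <- c(
    vapply(1:15, function(i) {
      s <- sample.int(nchar(gen[[1]]) - 25, 1)
      substr(gen[[1]], s, s + sample(18:24, 1))
    }, character(1)),
    vapply(1:10, function(i) {
      s <- sample.int(nchar(gen[[1]]) - 25, 1)
      revcomp(substr(gen[[1]], s, s + 20))
    }, character(1)),
    random_seq(21))   # almost surely unmapped
  hits <- map_to_genome(unique(tags), g)
  for (tag in unique(tags)) {
    ora <- map_oracle(tag, gen)
    got <- hits[hits$sequence == tag, c("chrom", "start", "end", "strand")]
    if (is.null(ora)) {
      expect_equal(nrow(got), 0L)
    } else {
      ora <- ora[order(ora$start, ora$strand), ]
      got <- got[order(got$start, got$strand), ]
      rownames(ora) <- rownames(got) <- NULL
      expect_equal(got, ora)
    }
  }
})

test_that("strand convention stores forward-strand intervals", {
  gen <- c(chrA = paste0(strrep("A", 100), "GCTCACTGCTCTATCTGTCACCG",
                         strrep("A", 100)))
  tag_fwd <- substr(gen[[1]], 101, 121)
  tag_rev <- revcomp(tag_fwd)
  h_fwd <- map_to_genome(tag_fwd, gen)
  h_rev <- map_to_genome(tag_rev, gen)
  expect_equal(h_fwd[1, c("start", "end", "strand")],
               data.frame(start = 100L, end = 121L, strand = "+"),
               ignore_attr = TRUE)
  expect_equal(h_rev[1, c("start", "end", "strand")],
               data.frame(start = 100L, end = 121L, strand = "-"),
               ignore_attr = TRUE)
})

test_that("high-copy tags are reported and flaggable", {
  g <- make_genome(1, 60000, seed = 23)
  set.seed(24)
  g <- plant_hairpin(g, 21, "5p", copies = 25)
  mature <- g$truth$mature_seq[1]
  hits <- map_to_genome(mature, g)
  expect_gte(unique(hits$n_hits), 25L)
  expect_true(mature %in% tags_over_cap(hits, cap = 20))
})

test_that("tag annotation follows the stated precedence", {
  g <- make_genome(1, 30000, seed = 25)
  set.seed(26)
  g <- plant_region(g, "rrna_trna", 200)
  g <- plant_region(g, "exon", 300)
  g <- plant_region(g, "repeat", 300)
  ann <- truth_annotation(g)
  tr <- g$truth
  pick <- function(kind, len = 21L) {
    row <- tr[tr$kind == kind, ][1, ]
    substr(g$sequences[[row$chrom]], row$start + 11, row$start + 10 + len)
  }
  rfam_tag <- pick("rrna_trna")
  exon_tag <- pick("exon")
  rep_tag <- pick("repeat")
  ## a tag 3 mismatches away from the rRNA is no longer an rfam match
  rfam3mm <- rfam_tag
  for (p in c(1L, 8L, 15L)) {   # cyclic base change: always a mismatch
    substr(rfam3mm, p, p) <- chartr("ACGT", "CGTA", substr(rfam3mm, p, p))
  }
  tags <- collapse_tags(c(rfam_tag, exon_tag, rep_tag, rfam3mm,
                          random_seq(21, seed = 27)), character(0))
  tags <- annotate_tags(tags, g, rfam = ann$rfam, exon = ann$exon,
                        repeats = ann$repeats)
  cat_of <- function(s) tags$category[tags$sequence == s]
  expect_equal(cat_of(rfam_tag), "rfam")
  expect_equal(cat_of(exon_tag), "exon")
  expect_equal(cat_of(rep_tag), "repeat")
  expect_false(cat_of(rfam3mm) == "rfam")
  expect_equal(cat_of(random_seq(21, seed = 27)), "unmapped")
  ## idempotence: annotating again gives identical categories
  again <- annotate_tags(tags, g, rfam = ann$rfam, exon = ann$exon,
                         repeats = ann$repeats)
  expect_identical(again$category, tags$category)
  ## interval validation
  expect_error(
    annotate_tags(tags, g, exon = data.frame(chrom = "chr1", start = 0,
                                             end = 1e7)),
    "outside chromosome bounds")
})

test_that("length histogram supports unique and count weighting", {
  tags <- collapse_tags(rep("ACGTACGTACGTACGTACGTACGT", 10), character(0))
  h_u <- length_histogram(tags, "unique")
  h_t <- length_histogram(tags, "total")
  expect_equal(h_u$count[h_u$length == 24], 1L)
  expect_equal(h_t$count[h_t$length == 24], 10L)
  empty <- collapse_tags(character(0), character(0))
  expect_true(all(length_histogram(empty)$count == 0L))
})
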