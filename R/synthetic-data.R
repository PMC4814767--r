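## Synthetic study generator: toy genomes carrying planted miRNA hairpins,
## 21-nt phased siRNA loci, contaminant and exon/repeat regions, read out as
## two adaptered FASTQ libraries with known per-feature abundances. The truth
## table gives every downstream stage its ground truth.

empty_truth <- function() {
  data.frame(feature_id = character(), kind = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             mature_seq = character(), star_seq = character(),
             mature_arm = character(), mature_start = integer(),
             mature_end = integer(), star_start = integer(),
             star_end = integer(), phase_register = integer(),
             phase_start = integer(), trigger_seq = character(),
             trigger_site_start = integer(), n_cycles = integer(),
             abundance_treatment = numeric(), abundance_control = numeric(),
             stringsAsFactors = FALSE)
}

truth_row <- function(genome, ...) {
  fields <- list(...)
  row <- empty_truth()[0, ]
  row[1, ] <- NA
  row$feature_id <- sprintf("feat%04d", nrow(genome$truth) + 1L)
  for (nm in names(fields)) row[[nm]] <- fields[[nm]]
  row
}

#' Create a random background genome
#'
#' Chromosomes are uniform random sequence over A/C/G/T (expected GC 0.5);
#' the truth table starts empty and is filled by the `plant_*` functions.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_len length of each chromosome in nt (>= 1000).
#' @param seed integer RNG seed; fixed seed gives identical genomes.
#' @return an object of class `synthetic_genome`: a list with `sequences`
#'   (named character vector) and `truth` (planted-feature data.frame,
#'   0-based half-open coordinates).
#' @export
make_genome <- function(n_chrom = 1L, chrom_len = 100000L, seed = 1L) {
  if (n_chrom < 1L) stop("n_chrom must be >= 1")
  if (chrom_len < 1000L) stop("chrom_len must be >= 1000")
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i) random_dna(chrom_len),
                 character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  structure(list(sequences = seqs, truth = empty_truth()),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", length(x$sequences), "chromosome(s),",
      sum(nchar(x$sequences)), "nt total;", nrow(x$truth),
      "planted feature(s)\n")
  if (nrow(x$truth)) print(table(x$truth$kind))
  invisible(x)
}

## find a placement slot not overlapping existing features (with a buffer)
find_slot <- function(genome, len, chrom = NULL, buffer = 60L,
                      max_tries = 2000L) {
  chroms <- names(genome$sequences)
  for (i in seq_len(max_tries)) {
    ch <- if (is.null(chrom)) sample(chroms, 1L) else chrom
    clen <- nchar(genome$sequences[[ch]])
    if (clen < len + 2L * buffer) next
    start <- sample.int(clen - len - 2L * buffer, 1L) + buffer
    tr <- genome$truth
    busy <- tr$chrom == ch & tr$start < start + len + buffer &
      tr$end > start - buffer
    if (!any(busy)) return(list(chrom = ch, start = start))
  }
  stop("could not find a free slot of length ", len)
}

insert_seq <- function(genome, chrom, start, seq) {
  s <- genome$sequences[[chrom]]
  substr(s, start + 1L, start + nchar(seq)) <- seq
  genome$sequences[[chrom]] <- s
  genome
}

## star strand of a mature m under the Dicer 2-nt 3' overhang convention:
## star[1..L-2] = revcomp(m[1..L-2]); star[L-1..L] is the unpaired 3' tail.
star_from_mature <- function(mature, mismatches = 0L) {
  L <- nchar(mature)
  core <- revcomp(substr(mature, 1L, L - 2L))
  if (mismatches > 0L) {
    ## a designed mismatch must not pair its mature partner at all,
    ## including G:U wobbles (which a folder would still stack)
    pairs_with <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
    pos <- sample(4:(nchar(core) - 4L), mismatches)
    ch <- strsplit(core, "")[[1]]
    mch <- strsplit(mature, "")[[1]]
    for (p in pos) {
      partner_base <- mch[L - 1L - p]
      ch[p] <- sample(setdiff(DNA_BASES,
                              c(ch[p], pairs_with[[partner_base]])), 1L)
    }
    core <- paste(ch, collapse = "")
  }
  paste0(core, random_dna(2L))
}

#' Plant a miRNA hairpin precursor into a synthetic genome
#'
#' Inserts a stem-loop whose two arms are reverse-complementary apart from
#' up to `mismatches` designed mismatches, with the mature/star duplex
#' carrying a 2-nt 3' overhang on each strand and >= 25 nt of genomic flank
#' on both sides.
#'
#' @param genome a `synthetic_genome`.
#' @param mature_len mature miRNA length, 18-25 nt.
#' @param arm `"5p"` or `"3p"`: which precursor arm carries the mature.
#' @param abundance_treatment,abundance_control expected mature read counts.
#' @param mismatches designed mature/star mismatches (default 0; values > 2
#'   deliberately break the duplex criteria for negative controls).
#' @param loop_len hairpin loop length, 8-40 nt.
#' @param copies number of identical genomic insertions (for copy-number
#'   tests); all copies share one truth entry per insertion.
#' @param chrom optional chromosome name to place the feature on.
#' @param mature_seq optional explicit mature sequence.
#' @return the updated `synthetic_genome`.
#' @export
plant_hairpin <- function(genome, mature_len = 21L, arm = c("5p", "3p"),
                          abundance_treatment = 50, abundance_control = 50,
                          mismatches = 0L, loop_len = 15L, copies = 1L,
                          chrom = NULL, mature_seq = NULL) {
  arm <- match.arg(arm)
  if (mature_len < 18L || mature_len > 25L) {
    stop("mature_len must be in [18, 25]")
  }
  if (loop_len < 8L || loop_len > 40L) stop("loop_len must be in [8, 40]")
  if (abundance_treatment < 0 || abundance_control < 0) {
    stop("abundances must be non-negative")
  }
  mature <- if (is.null(mature_seq)) random_dna(mature_len, gc = 0.55, gc_tol = 0.1)
            else toupper(mature_seq)
  if (nchar(mature) != mature_len) stop("mature_seq length mismatch")
  star <- star_from_mature(mature, mismatches)
  loop <- random_dna(loop_len)
  core <- if (arm == "5p") paste0(mature, loop, star) else paste0(star, loop, mature)
  for (cp in seq_len(copies)) {
    slot <- find_slot(genome, nchar(core), chrom = if (cp == 1L) chrom else NULL)
    genome <- insert_seq(genome, slot$chrom, slot$start, core)
    if (arm == "5p") {
      ms <- slot$start; ss <- slot$start + mature_len + loop_len
    } else {
      ss <- slot$start; ms <- slot$start + nchar(star) + loop_len
    }
    genome$truth <- rbind(genome$truth, truth_row(
      genome, kind = "hairpin_mirna", chrom = slot$chrom,
      start = slot$start, end = slot$start + nchar(core), strand = "+",
      mature_seq = mature, star_seq = star, mature_arm = arm,
      mature_start = ms, mature_end = ms + mature_len,
      star_start = ss, star_end = ss + nchar(star),
      abundance_treatment = if (cp == 1L) abundance_treatment else 0,
      abundance_control = if (cp == 1L) abundance_control else 0))
  }
  genome
}

#' First phased position implied by a trigger site
#'
#' Shared convention between the generator and the trigger search: cleavage
#' guided by a 22-nt small RNA registers the first 21-nt phase at the
#' target-site start plus 10 (0-based).
#'
#' @param site_start 0-based start of the 22-nt target site.
#' @return 0-based first phased position.
#' @export
cleavage_position <- function(site_start) site_start + 10L

#' Plant a 21-nt phased siRNA locus into a synthetic genome
#'
#' Inserts a transcript-like region carrying a site complementary to a 22-nt
#' trigger small RNA, with the downstream sequence producing 21-nt reads in
#' the cleavage register.
#'
#' @param genome a `synthetic_genome`.
#' @param n_cycles number of 21-nt phase cycles (>= 10).
#' @param trigger_seq 22-nt trigger miRNA sequence.
#' @param abundance_treatment,abundance_control expected total phased read
#'   counts per library.
#' @param chrom optional chromosome name.
#' @return the updated `synthetic_genome`.
#' @export
plant_phas_locus <- function(genome, n_cycles = 12L, trigger_seq,
                             abundance_treatment = 60,
                             abundance_control = 60, chrom = NULL) {
  if (n_cycles < 10L) stop("n_cycles must be >= 10")
  trigger_seq <- toupper(trigger_seq)
  if (nchar(trigger_seq) != 22L) stop("trigger_seq must be exactly 22 nt")
  site <- revcomp(trigger_seq)
  pad <- 20L
  body_len <- pad + 22L + 21L * n_cycles
  region <- paste0(random_dna(pad), site,
                   random_dna(body_len - pad - 22L))
  slot <- find_slot(genome, body_len, chrom = chrom)
  genome <- insert_seq(genome, slot$chrom, slot$start, region)
  site_start <- slot$start + pad
  phase_start <- cleavage_position(site_start)
  genome$truth <- rbind(genome$truth, truth_row(
    genome, kind = "phas_locus", chrom = slot$chrom, start = slot$start,
    end = slot$start + body_len, strand = "+",
    phase_register = phase_start %% 21L, phase_start = phase_start,
    trigger_seq = trigger_seq, trigger_site_start = site_start,
    n_cycles = n_cycles,
    abundance_treatment = abundance_treatment,
    abundance_control = abundance_control))
  genome
}

#' Plant a contaminant or structural region
#'
#' Adds an rRNA/tRNA-like, exon or repeat region whose random subsequences
#' are later sampled as reads, exercising the tag-categorisation stages.
#'
#' @param genome a `synthetic_genome`.
#' @param kind `"rrna_trna"`, `"exon"` or `"repeat"`.
#' @param length region length in nt.
#' @param abundance_treatment,abundance_control expected read counts.
#' @param copies identical insertions (repeats are typically multi-copy).
#' @return the updated `synthetic_genome`.
#' @export
plant_region <- function(genome, kind = c("rrna_trna", "exon", "repeat"),
                         length = 300L, abundance_treatment = 100,
                         abundance_control = 100, copies = 1L) {
  kind <- match.arg(kind)
  region <- random_dna(length)
  for (cp in seq_len(copies)) {
    slot <- find_slot(genome, length)
    genome <- insert_seq(genome, slot$chrom, slot$start, region)
    genome$truth <- rbind(genome$truth, truth_row(
      genome, kind = kind, chrom = slot$chrom, start = slot$start,
      end = slot$start + length, strand = "+",
      abundance_treatment = if (cp == 1L) abundance_treatment else 0,
      abundance_control = if (cp == 1L) abundance_control else 0))
  }
  genome
}

#' Library specification for the read simulator
#'
#' @param name library name, conventionally `"treatment"` or `"control"`.
#' @param total_reads total reads to emit.
#' @param adapter_3p 3' adapter sequence ligated to every insert.
#' @param error_rate per-base substitution probability, in [0, 0.1).
#' @param seed per-library RNG seed.
#' @return a `library_spec` list.
#' @export
library_spec <- function(name, total_reads, adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                         error_rate = 0, seed = 1L) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (is.null(adapter_3p) || !nzchar(adapter_3p)) {
    stop("adapter_3p must be a non-empty nucleotide string")
  }
  if (error_rate < 0 || error_rate >= 0.1) stop("error_rate must be in [0, 0.1)")
  structure(list(name = name, total_reads = as.integer(total_reads),
                 adapter_3p = toupper(adapter_3p),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "library_spec")
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                        character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## sample insert sequences for one feature in one library
feature_inserts <- function(genome, feat, n, star_frac = 0.3,
                            minus_frac = 0.3) {
  if (n == 0L) return(character(0))
  chrom_seq <- genome$sequences[[feat$chrom]]
  if (feat$kind == "hairpin_mirna") {
    n_star <- rpois(1L, n * star_frac)
    c(rep(feat$mature_seq, n), rep(feat$star_seq, n_star))
  } else if (feat$kind == "phas_locus") {
    cyc <- sample.int(feat$n_cycles, n, replace = TRUE) - 1L
    starts <- feat$phase_start + 21L * cyc
    plus <- runif(n) >= minus_frac
    ifelse(plus,
           substring(chrom_seq, starts + 1L, starts + 21L),
           revcomp(substring(chrom_seq, starts - 2L + 1L, starts - 2L + 21L)))
  } else {
    len <- sample(18:30, n, replace = TRUE)
    off <- vapply(len, function(l)
      sample.int(feat$end - feat$start - l + 1L, 1L) - 1L, integer(1))
    substring(chrom_seq, feat$start + off + 1L, feat$start + off + len)
  }
}

background_inserts <- function(genome, n, len_range = 18:30) {
  if (n == 0L) return(character(0))
  chroms <- sample(names(genome$sequences), n, replace = TRUE)
  len <- if (length(len_range) == 1L) rep(len_range, n) else {
    sample(len_range, n, replace = TRUE,
           prob = ifelse(len_range == 24, 4, 1))
  }
  starts <- vapply(seq_len(n), function(i)
    sample.int(nchar(genome$sequences[[chroms[i]]]) - len[i], 1L), integer(1))
  substring(genome$sequences[chroms], starts, starts + len - 1L)
}

#' Simulate two adaptered small RNA FASTQ libraries
#'
#' Per-feature read counts are Poisson around the recorded expected
#' abundances; remaining reads are background genome fragments with a 24-nt
#' enriched length distribution. Each read is insert + 3' adapter, padded
#' with adapter sequence to a fixed read length, Phred 40 throughout. A small
#' fraction of sub-18-nt inserts and adapter-free reads is injected so the
#' preprocessing categories are all exercised.
#'
#' @param genome a `synthetic_genome` with at least one planted feature.
#' @param spec_t,spec_c `library_spec` for treatment and control.
#' @param dir output directory for FASTQ / FASTA / truth files.
#' @param read_length raw read length (insert + adapter fill).
#' @param short_frac fraction of reads given a < 18 nt insert.
#' @param adapter_null_frac fraction of reads emitted without the adapter.
#' @param star_frac hairpin star reads as a fraction of mature abundance.
#' @return list with paths (`fastq_treatment`, `fastq_control`,
#'   `genome_fasta`, `truth_tsv`) and `counts`, the per-feature sampled read
#'   counts per library.
#' @export
simulate_libraries <- function(genome, spec_t, spec_c, dir = tempdir(),
                               read_length = 40L, short_frac = 0.01,
                               adapter_null_frac = 0.005, star_frac = 0.3) {
  stopifnot(inherits(spec_t, "library_spec"), inherits(spec_c, "library_spec"))
  if (!nrow(genome$truth)) stop("genome has no planted features")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  counts <- data.frame(feature_id = genome$truth$feature_id,
                       stringsAsFactors = FALSE)
  for (spec in list(spec_t, spec_c)) {
    set.seed(spec$seed)
    ab_col <- if (spec$name == spec_t$name) "abundance_treatment" else "abundance_control"
    n_feat <- rpois(nrow(genome$truth), genome$truth[[ab_col]])
    inserts <- character(0)
    ids <- character(0)
    for (i in seq_len(nrow(genome$truth))) {
      ins <- feature_inserts(genome, genome$truth[i, ], n_feat[i], star_frac)
      inserts <- c(inserts, ins)
      ids <- c(ids, rep(genome$truth$feature_id[i], length(ins)))
    }
    n_short <- round(spec$total_reads * short_frac)
    n_anull <- round(spec$total_reads * adapter_null_frac)
    n_bg <- spec$total_reads - length(inserts) - n_short - n_anull
    if (n_bg < 0) stop("total_reads too small for the planted abundances")
    inserts <- c(inserts, background_inserts(genome, n_bg),
                 background_inserts(genome, n_short, len_range = 12:17))
    ids <- c(ids, rep("background", n_bg), rep("short", n_short))
    adapter_fill <- strrep(spec$adapter_3p,
                           ceiling(read_length / nchar(spec$adapter_3p)) + 1L)
    reads <- substr(paste0(inserts, adapter_fill), 1L, read_length)
    if (n_anull > 0L) {
      reads <- c(reads, background_inserts(genome, n_anull,
                                           len_range = read_length))
      ids <- c(ids, rep("adapter_null", n_anull))
    }
    reads <- apply_errors(reads, spec$error_rate)
    ord <- sample.int(length(reads))
    reads <- reads[ord]; ids <- ids[ord]
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- sprintf("%s_read%07d %s", spec$name, seq_along(reads), ids)
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    fq <- file.path(dir, paste0(spec$name, ".fastq"))
    if (file.exists(fq)) unlink(fq)
    Biostrings::writeXStringSet(dna, fq, format = "fastq", qualities = qual)
    paths[[paste0("fastq_", spec$name)]] <- fq
    counts[[spec$name]] <- as.integer(table(factor(ids, levels = counts$feature_id)))
  }
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), fa)
  tt <- file.path(dir, "truth.tsv")
  write.table(genome$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  c(paths, list(genome_fasta = fa, truth_tsv = tt, counts = counts))
}

#' Annotation inputs derived from a synthetic genome's truth table
#'
#' @param genome a `synthetic_genome`.
#' @return list with `rfam` (character vector of rRNA/tRNA-like region
#'   sequences), `exon` and `repeats` (interval data.frames).
#' @export
truth_annotation <- function(genome) {
  tr <- genome$truth
  sub <- function(kind) tr[tr$kind == kind, , drop = FALSE]
  get_seq <- function(rows) {
    if (!nrow(rows)) return(character(0))
    setNames(substring(genome$sequences[rows$chrom], rows$start + 1L, rows$end),
             rows$feature_id)
  }
  bed <- function(rows) rows[, c("chrom", "start", "end")]
  list(rfam = get_seq(sub("rrna_trna")),
       exon = bed(sub("exon")),
       repeats = bed(sub("repeat")))
}
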