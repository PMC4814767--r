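## Raw FASTQ -> per-library clean inserts -> unique-tag table with category
## labels and library accounting.

#' Percentage of a total, at report precision
#'
#' The rounding convention used throughout the library accounting tables
#' (two decimal places).
#'
#' @param x numerator count(s).
#' @param total denominator count.
#' @return numeric percentage(s), rounded to 2 decimals.
#' @export
percent_of <- function(x, total) round(100 * x / total, 2)

#' Library accounting from class counts
#'
#' Builds the one-row accounting record from raw/high-quality totals and
#' the discarded-class counts: clean reads are the high-quality reads not
#' assigned to any discard class, and every class is expressed as a
#' percentage of high-quality reads.
#'
#' @param total_raw,high_quality read totals.
#' @param adapter3_null,insert_null,adapter5_contaminant,polyA,shorter_than_18
#'   discarded-class counts.
#' @return one-row data.frame with counts and `pct_*` columns.
#' @export
library_accounting <- function(total_raw, high_quality, adapter3_null = 0L,
                               insert_null = 0L, adapter5_contaminant = 0L,
                               polyA = 0L, shorter_than_18 = 0L) {
  clean <- high_quality - (adapter3_null + insert_null +
                             adapter5_contaminant + polyA + shorter_than_18)
  stats <- data.frame(total_raw = total_raw, high_quality = high_quality,
                      adapter3_null = adapter3_null,
                      insert_null = insert_null,
                      adapter5_contaminant = adapter5_contaminant,
                      polyA = polyA, shorter_than_18 = shorter_than_18,
                      clean = clean)
  for (nm in c("adapter3_null", "insert_null", "adapter5_contaminant",
               "polyA", "shorter_than_18", "clean")) {
    stats[[paste0("pct_", nm)]] <- percent_of(stats[[nm]], high_quality)
  }
  stats
}

#' Read a small RNA FASTQ file
#'
#' Wraps [Biostrings::readQualityScaledDNAStringSet()]; on a structurally
#' broken file the 4-line record grid is re-scanned so the error names the
#' first malformed record.
#'
#' @param path FASTQ path (Sanger Phred+33).
#' @return a `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  idx <- seq_len(n %/% 4L)
  ok <- n %% 4L == 0L
  bad <- if (!ok) (n %/% 4L) + 1L else {
    rec_ok <- startsWith(lines[4L * idx - 3L], "@") &
      startsWith(lines[4L * idx - 1L], "+") &
      nchar(lines[4L * idx - 2L]) == nchar(lines[4L * idx])
    if (all(rec_ok)) 0L else which(!rec_ok)[1]
  }
  if (!ok || bad > 0L) {
    stop("malformed FASTQ record at index ", max(bad, 1L), " in ", path,
         call. = FALSE)
  }
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

#' Drop low-quality reads
#'
#' Removes reads whose mean Phred score falls below `min_mean_phred` or that
#' contain any ambiguous (N) base.
#'
#' @param reads a `QualityScaledDNAStringSet` (from [read_fastq()]).
#' @param min_mean_phred mean Phred threshold (default 20).
#' @return the surviving reads, with attribute `n_raw` (input read count).
#' @export
quality_filter <- function(reads, min_mean_phred = 20) {
  q <- methods::as(Biostrings::quality(reads), "IntegerList")
  mean_q <- sum(q) / pmax(lengths(q), 1L)
  has_n <- Biostrings::alphabetFrequency(reads)[, "N"] > 0L
  keep <- mean_q >= min_mean_phred & !has_n
  out <- reads[keep]
  attr(out, "n_raw") <- length(reads)
  out
}

## leftmost 3' adapter start per read: prefix-overlap seed of `min_overlap`
## nt with <= max_mismatch mismatches; NA when no adapter is found
adapter_starts <- function(seqs, adapter_3p, min_overlap = 8L,
                           max_mismatch = 1L) {
  seed <- substr(adapter_3p, 1L, min_overlap)
  m <- Biostrings::vmatchPattern(seed, seqs, max.mismatch = max_mismatch,
                                 fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  vapply(starts, function(v) if (length(v)) min(v) else NA_integer_, integer(1))
}

#' Trim 3' adapters and account for discarded read classes
#'
#' Finds the 3' adapter by seeded prefix match (>= `min_overlap` nt overlap,
#' <= `max_mismatch` mismatches) and assigns each high-quality read to
#' exactly one class, in precedence order: no adapter found
#' (`adapter3_null`), adapter at read start (`insert_null`), 5' adapter
#' present in the insert (`adapter5_contaminant`), insert >= 80% A
#' (`polyA`), insert shorter than 18 nt (`shorter_than_18`); survivors are
#' clean inserts.
#'
#' @param reads `DNAStringSet`/`QualityScaledDNAStringSet` of high-quality
#'   reads.
#' @param adapter_3p 3' adapter sequence (required).
#' @param adapter_5p optional 5' adapter to flag contaminants.
#' @param min_overlap,max_mismatch adapter seed-match parameters.
#' @param min_len minimum insert length (default 18).
#' @param total_raw raw read count before quality filtering (defaults to the
#'   `n_raw` attribute set by [quality_filter()], else to `length(reads)`).
#' @return list with `inserts` (clean `DNAStringSet`) and `stats`, a one-row
#'   data.frame of class counts and their percentages of high-quality reads.
#' @export
trim_and_categorize <- function(reads, adapter_3p, adapter_5p = NULL,
                                min_overlap = 8L, max_mismatch = 1L,
                                min_len = 18L, total_raw = NULL) {
  if (is.null(adapter_3p) || !nzchar(adapter_3p)) {
    stop("adapter_3p must be a non-empty string")
  }
  if (is.null(total_raw)) {
    total_raw <- attr(reads, "n_raw", exact = TRUE)
    if (is.null(total_raw)) total_raw <- length(reads)
  }
  seqs <- suppressWarnings(Biostrings::DNAStringSet(reads))
  S4Vectors::mcols(seqs) <- NULL
  astart <- adapter_starts(seqs, adapter_3p, min_overlap, max_mismatch)
  cls <- rep("clean", length(seqs))
  cls[is.na(astart)] <- "adapter3_null"
  cls[!is.na(astart) & astart == 1L] <- "insert_null"
  ins_len <- ifelse(is.na(astart), 0L, astart - 1L)
  inserts <- Biostrings::subseq(seqs, 1L, ins_len)
  open <- cls == "clean"
  if (!is.null(adapter_5p) && nzchar(adapter_5p)) {
    seed5 <- substr(adapter_5p, 1L, min(nchar(adapter_5p), min_overlap))
    has5 <- Biostrings::vcountPattern(seed5, inserts,
                                      max.mismatch = max_mismatch) > 0L
    cls[open & has5] <- "adapter5_contaminant"
    open <- cls == "clean"
  }
  fracA <- Biostrings::letterFrequency(inserts, "A", as.prob = TRUE)[, 1]
  cls[open & ins_len > 0L & fracA >= 0.8] <- "polyA"
  open <- cls == "clean"
  cls[open & ins_len < min_len] <- "shorter_than_18"
  counts <- table(factor(cls, levels = c("adapter3_null", "insert_null",
                                         "adapter5_contaminant", "polyA",
                                         "shorter_than_18", "clean")))
  stats <- library_accounting(total_raw, length(seqs),
                              counts[["adapter3_null"]],
                              counts[["insert_null"]],
                              counts[["adapter5_contaminant"]],
                              counts[["polyA"]],
                              counts[["shorter_than_18"]])
  list(inserts = inserts[cls == "clean"], stats = stats)
}

#' Preprocess one FASTQ library end to end
#'
#' [read_fastq()] + [quality_filter()] + [trim_and_categorize()].
#'
#' @inheritParams trim_and_categorize
#' @param path FASTQ file.
#' @param min_mean_phred mean Phred threshold for [quality_filter()].
#' @return as [trim_and_categorize()].
#' @export
preprocess_library <- function(path, adapter_3p, adapter_5p = NULL,
                               min_mean_phred = 20, min_overlap = 8L,
                               max_mismatch = 1L, min_len = 18L) {
  reads <- read_fastq(path)
  hq <- quality_filter(reads, min_mean_phred)
  trim_and_categorize(hq, adapter_3p, adapter_5p, min_overlap, max_mismatch,
                      min_len)
}

#' Collapse clean inserts from two libraries into a unique-tag table
#'
#' @param inserts_t,inserts_c clean inserts (`DNAStringSet` or character)
#'   for the treatment and control libraries.
#' @return data.frame (`tag_table`) with `sequence`, `count_treatment`,
#'   `count_control`, `length`; attributes `unique_treatment`,
#'   `unique_control` and `shared_fraction` (fraction of the tag union seen
#'   in both libraries).
#' @export
collapse_tags <- function(inserts_t, inserts_c) {
  st <- as.character(inserts_t); sc <- as.character(inserts_c)
  dt <- data.table::data.table(
    sequence = c(st, sc),
    lib = rep(c("t", "c"), c(length(st), length(sc))))
  agg <- dt[, list(count_treatment = sum(lib == "t"),
                   count_control = sum(lib == "c")), by = "sequence"]
  data.table::setorder(agg, sequence)
  out <- as.data.frame(agg)
  out$length <- nchar(out$sequence)
  attr(out, "unique_treatment") <- sum(out$count_treatment > 0L)
  attr(out, "unique_control") <- sum(out$count_control > 0L)
  attr(out, "shared_fraction") <-
    if (nrow(out)) mean(out$count_treatment > 0L & out$count_control > 0L) else NA_real_
  class(out) <- c("tag_table", "data.frame")
  out
}

#' Map unique tags to a genome by exact full-length match
#'
#' Reports every placement on both strands (mireap-style exact matching;
#' minus-strand hits are stored as their forward-strand interval plus a
#' strand flag). Coordinates are 0-based half-open.
#'
#' @param tags a `tag_table` or character vector of tag sequences.
#' @param genome genome input accepted by the package (a
#'   `synthetic_genome`, `DNAStringSet`, named character vector, or FASTA
#'   path).
#' @return data.frame with `sequence`, `chrom`, `start`, `end`, `strand`,
#'   `length`, `n_hits` (total placements of that tag genome-wide).
#' @export
map_to_genome <- function(tags, genome) {
  seqs <- if (is.data.frame(tags)) tags$sequence else as.character(tags)
  seqs <- unique(seqs)
  gen <- genome_seqs(genome)
  subj <- Biostrings::DNAStringSet(gen)
  res <- list()
  for (w in sort(unique(nchar(seqs)))) {
    sw <- seqs[nchar(seqs) == w]
    fwd <- Biostrings::DNAStringSet(sw)
    rev <- Biostrings::reverseComplement(fwd)
    for (strand in c("+", "-")) {
      pd <- Biostrings::PDict(if (strand == "+") fwd else rev)
      for (ci in seq_along(subj)) {
        m <- Biostrings::matchPDict(pd, subj[[ci]])
        n_per <- lengths(m)
        if (!sum(n_per)) next
        starts <- unlist(Biostrings::startIndex(m), use.names = FALSE)
        res[[length(res) + 1L]] <- data.frame(
          sequence = rep(sw, n_per), chrom = names(gen)[ci],
          start = starts - 1L, end = starts - 1L + w,
          strand = strand, length = w, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(sequence = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      n_hits = integer(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits$n_hits <- as.integer(table(hits$sequence)[hits$sequence])
  hits
}

#' Tags whose genome placement count exceeds the copy-number cap
#'
#' @param hits output of [map_to_genome()].
#' @param cap maximum allowed placements (default 20).
#' @return character vector of over-cap tag sequences.
#' @export
tags_over_cap <- function(hits, cap = 20L) {
  unique(hits$sequence[hits$n_hits > cap])
}

#' Annotate unique tags with sequence categories
#'
#' Precedence: Rfam contaminant (<= 2 mismatches to an rRNA/tRNA/snoRNA
#' reference on either strand), then repeat / exon interval overlap of any
#' genome hit (repeat before exon by default, configurable), then known
#' miRNA (exact match to a mature reference), then `unannotated` for mapped
#' tags and `unmapped` for the rest.
#'
#' @param tags a `tag_table`.
#' @param genome genome input (see [map_to_genome()]).
#' @param rfam optional rRNA/tRNA reference (character, `DNAStringSet` or
#'   FASTA path).
#' @param exon,repeats optional interval data.frames (`chrom`, `start`,
#'   `end`; 0-based half-open) or BED paths.
#' @param known optional known mature miRNA reference set.
#' @param hits optional precomputed [map_to_genome()] output.
#' @param repeat_before_exon interval-overlap precedence switch.
#' @param max_rfam_mismatch mismatch allowance for the Rfam match.
#' @return `tags` with a `category` column and `n_hits`; attribute `hits`
#'   carries the genome-hit table.
#' @export
annotate_tags <- function(tags, genome, rfam = NULL, exon = NULL,
                          repeats = NULL, known = NULL, hits = NULL,
                          repeat_before_exon = TRUE,
                          max_rfam_mismatch = 2L) {
  stopifnot(is.data.frame(tags))
  gen <- genome_seqs(genome)
  exon <- as_intervals(exon); repeats <- as_intervals(repeats)
  if (!is.null(exon)) validate_intervals(exon, gen)
  if (!is.null(repeats)) validate_intervals(repeats, gen)
  if (is.null(hits)) hits <- map_to_genome(tags, genome)
  category <- rep(NA_character_, nrow(tags))

  if (!is.null(rfam) && length(rfam)) {
    ref <- Biostrings::DNAStringSet(as_seq_set(rfam, "rfam"))
    both <- c(ref, Biostrings::reverseComplement(ref))
    is_rfam <- vapply(tags$sequence, function(s) {
      any(Biostrings::vcountPattern(s, both,
                                    max.mismatch = max_rfam_mismatch) > 0L)
    }, logical(1), USE.NAMES = FALSE)
    category[is_rfam] <- "rfam"
  }

  mapped <- tags$sequence %in% hits$sequence
  category[is.na(category) & !mapped] <- "unmapped"

  overlap_tags <- function(iv) {
    if (is.null(iv) || !nrow(iv)) return(character(0))
    gr_hits <- GenomicRanges::GRanges(hits$chrom,
                                      IRanges::IRanges(hits$start + 1L, hits$end))
    gr_iv <- GenomicRanges::GRanges(iv$chrom,
                                    IRanges::IRanges(iv$start + 1L, iv$end))
    ov <- GenomicRanges::findOverlaps(gr_hits, gr_iv)
    unique(hits$sequence[S4Vectors::queryHits(ov)])
  }
  first <- if (repeat_before_exon) repeats else exon
  second <- if (repeat_before_exon) exon else repeats
  lab1 <- if (repeat_before_exon) "repeat" else "exon"
  lab2 <- if (repeat_before_exon) "exon" else "repeat"
  t1 <- overlap_tags(first)
  category[is.na(category) & tags$sequence %in% t1] <- lab1
  t2 <- overlap_tags(second)
  category[is.na(category) & tags$sequence %in% t2] <- lab2

  if (!is.null(known) && length(known)) {
    ref <- as_seq_set(known, "mir")
    category[is.na(category) & tags$sequence %in% ref] <- "known_mirna"
  }
  category[is.na(category)] <- "unannotated"
  tags$category <- category
  tags$n_hits <- ifelse(mapped, hits$n_hits[match(tags$sequence, hits$sequence)], 0L)
  attr(tags, "hits") <- hits
  tags
}

validate_intervals <- function(iv, gen) {
  bad <- !(iv$chrom %in% names(gen)) | iv$start < 0L |
    iv$end > nchar(gen)[match(iv$chrom, names(gen))]
  if (any(bad, na.rm = TRUE)) {
    stop("interval(s) outside chromosome bounds: row ",
         paste(which(bad), collapse = ", "))
  }
  invisible(iv)
}

#' Per-library categorisation summary of unique tags
#'
#' One row per category (clean unique tags, genome-mapped, rfam, repeat,
#' exon, known miRNA, unannotated), counted per library among tags with a
#' non-zero count there, with percentages of that library's unique clean
#' tags.
#'
#' @param tags annotated `tag_table` (from [annotate_tags()]).
#' @return data.frame summary.
#' @export
category_table <- function(tags) {
  stopifnot("category" %in% names(tags))
  one <- function(cnt) {
    present <- cnt > 0L
    n <- sum(present)
    cat_n <- function(k) sum(present & tags$category == k)
    c(clean = n, mapped = sum(present & tags$category != "unmapped"),
      rfam = cat_n("rfam"), repeat_ = cat_n("repeat"), exon = cat_n("exon"),
      known_mirna = cat_n("known_mirna"), unannotated = cat_n("unannotated"))
  }
  tt <- one(tags$count_treatment); cc <- one(tags$count_control)
  data.frame(category = c("clean", "map_to_genome", "rfam", "repeat", "exon",
                          "mirbase", "unannotated"),
             treatment = as.integer(tt), control = as.integer(cc),
             pct_treatment = percent_of(tt, tt[["clean"]]),
             pct_control = percent_of(cc, cc[["clean"]]),
             stringsAsFactors = FALSE)
}

#' Tag length histogram
#'
#' @param tags a `tag_table`.
#' @param weighting `"unique"` (distinct sequences) or `"total"`
#'   (read-count weighted).
#' @param library `"both"`, `"treatment"` or `"control"`.
#' @param lengths length range to tabulate.
#' @return data.frame with `length` and `count`.
#' @export
length_histogram <- function(tags, weighting = c("unique", "total"),
                             library = c("both", "treatment", "control"),
                             lengths = 18:30) {
  weighting <- match.arg(weighting)
  library <- match.arg(library)
  cnt <- switch(library,
                both = tags$count_treatment + tags$count_control,
                treatment = tags$count_treatment,
                control = tags$count_control)
  keep <- cnt > 0L
  w <- if (weighting == "unique") rep(1L, sum(keep)) else cnt[keep]
  tab <- tapply(w, factor(tags$length[keep], levels = lengths), sum)
  data.frame(length = lengths,
             count = as.integer(ifelse(is.na(tab), 0L, tab)))
}

#' Library accounting in printed-report form
#'
#' Combines two [trim_and_categorize()] stats rows into the conventional
#' two-library accounting table (counts with percentages of high-quality
#' reads; clean reads last).
#'
#' @param stats_t,stats_c one-row stats data.frames.
#' @return data.frame with `type`, `treatment`, `control` columns.
#' @export
library_stats_table <- function(stats_t, stats_c) {
  fmt <- function(s) {
    rows <- c("adapter3_null", "insert_null", "adapter5_contaminant",
              "polyA", "shorter_than_18", "clean")
    c(format(s$total_raw, big.mark = ","),
      format(s$high_quality, big.mark = ","),
      vapply(rows, function(r) sprintf("%s (%.2f%%)",
                                       format(s[[r]], big.mark = ","),
                                       s[[paste0("pct_", r)]]), character(1)))
  }
  data.frame(type = c("Total raw reads", "High quality reads",
                      "3'adapter_null", "insert_null",
                      "5'adapter_contaminants", "polyA",
                      "Reads smaller than 18nt", "Clean reads"),
             treatment = fmt(stats_t), control = fmt(stats_c),
             stringsAsFactors = FALSE)
}
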