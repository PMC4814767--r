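#' Run the full paired-library small RNA analysis
#'
#' Convenience wrapper chaining the module stages: per-library
#' preprocessing, tag collapsing and annotation, known-miRNA matching,
#' novel-miRNA prediction, differential expression and PHAS locus
#' detection. Each stage is also available as an exported function for
#' finer control.
#'
#' @param fastq_treatment,fastq_control FASTQ paths.
#' @param genome genome input (see [map_to_genome()]).
#' @param adapter_3p 3' adapter sequence.
#' @param rfam,exon,repeats,known_mature optional annotation inputs (see
#'   [annotate_tags()] and [match_known()]).
#' @param min_reads minimum-abundance rule (default 10).
#' @param engine folding engine for novel-miRNA prediction.
#' @param run_phas whether to run the PHAS scan (default TRUE).
#' @return list with `stats_treatment`, `stats_control`, `tags`, `hits`,
#'   `known`, `novel`, `de`, `phas`.
#' @export
run_srna_pipeline <- function(fastq_treatment, fastq_control, genome,
                              adapter_3p, rfam = NULL, exon = NULL,
                              repeats = NULL, known_mature = NULL,
                              min_reads = 10L,
                              engine = getOption("mirphas.fold_engine",
                                                 "vienna"),
                              run_phas = TRUE) {
  pre_t <- preprocess_library(fastq_treatment, adapter_3p)
  pre_c <- preprocess_library(fastq_control, adapter_3p)
  tags <- collapse_tags(pre_t$inserts, pre_c$inserts)
  tags <- annotate_tags(tags, genome, rfam = rfam, exon = exon,
                        repeats = repeats, known = known_mature)
  hits <- attr(tags, "hits")
  known <- if (!is.null(known_mature)) {
    abundance_filter(match_known(tags, known_mature), min_reads)
  } else NULL
  novel <- predict_novel_mirnas(tags, genome, hits = hits,
                                min_reads = min_reads, engine = engine)
  total_t <- sum(tags$count_treatment)
  total_c <- sum(tags$count_control)
  de_input <- rbind(
    if (!is.null(known) && nrow(known)) {
      data.frame(id = known$name, count_treatment = known$count_treatment,
                 count_control = known$count_control,
                 stringsAsFactors = FALSE)
    },
    if (nrow(novel)) {
      data.frame(id = novel$id, count_treatment = novel$count_treatment,
                 count_control = novel$count_control,
                 stringsAsFactors = FALSE)
    })
  de <- if (!is.null(de_input) && nrow(de_input)) {
    de_table(de_input, total_t, total_c)
  } else NULL
  phas <- if (run_phas) {
    h <- hits
    h$count <- tags$count_treatment[match(h$sequence, tags$sequence)] +
      tags$count_control[match(h$sequence, tags$sequence)]
    phas_scan(h)
  } else NULL
  list(stats_treatment = pre_t$stats, stats_control = pre_c$stats,
       tags = tags, hits = hits, known = known, novel = novel, de = de,
       phas = phas)
}
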