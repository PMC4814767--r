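## Novel miRNA prediction from unannotated genome-mapped tags: locus
## clustering, precursor excision and folding, the 11 hairpin/duplex
## criteria, star detection, 85%-identity family clustering, 5' nucleotide
## bias.

#' Cluster genome hits into candidate loci
#'
#' Strand-aware single-linkage clustering: hits on the same chromosome and
#' strand within `max_gap` nt of each other join one locus.
#'
#' @param hits [map_to_genome()] output.
#' @param max_gap maximum gap in nt (default 200, the maximal allowed
#'   miRNA/miRNA* spacing).
#' @return `hits` with a `locus_id` column.
#' @export
cluster_hits <- function(hits, max_gap = 200L) {
  if (!nrow(hits)) {
    hits$locus_id <- integer(0)
    return(hits)
  }
  ord <- order(hits$chrom, hits$strand, hits$start)
  h <- hits[ord, , drop = FALSE]
  locus <- integer(nrow(h))
  cur <- 0L; cur_end <- -Inf; cur_key <- ""
  for (i in seq_len(nrow(h))) {
    key <- paste0(h$chrom[i], h$strand[i])
    if (key != cur_key || h$start[i] - cur_end > max_gap) {
      cur <- cur + 1L
      cur_end <- h$end[i]
      cur_key <- key
    } else {
      cur_end <- max(cur_end, h$end[i])
    }
    locus[i] <- cur
  }
  h$locus_id <- locus
  rownames(h) <- NULL
  h
}

## window-position <-> genomic mapping for a locus on either strand
window_to_genomic <- function(wstart, wend, strand, lo, hi) {
  ## lo..hi are 1-based inclusive window positions; returns 0-based
  ## half-open forward-strand interval
  if (strand == "+") c(wstart + lo - 1L, wstart + hi)
  else c(wend - hi, wend - lo + 1L)
}

## structural analysis of a folded window with the mature at 1-based
## positions mi..mj; NULL unless the mature sits on one arm of a stem-loop
analyze_window <- function(seq, structure, mfe, mi, mj) {
  partner <- pair_table(structure)
  n <- nchar(seq)
  idx <- mi:mj
  if (!any(partner[idx] > 0L)) return(NULL)
  ## anchor the star on the dominant helix: the longest run of
  ## consecutively paired mature positions. The star interval then follows
  ## from ungapped duplex arithmetic with 2-nt 3' overhangs, which keeps
  ## stray pairs of the overhang/terminal bases (which routinely pair
  ## opportunistically with flanking sequence) from breaking or inflating
  ## the duplex.
  ## helix run: consecutive mature positions whose partners step
  ## antiparallel (partner decreasing by 1), so a run cannot jump arms
  p <- partner[idx]
  runlen <- integer(length(p))
  for (t in seq_along(p)) {
    if (p[t] > 0L) {
      runlen[t] <- if (t > 1L && p[t - 1L] == p[t] + 1L) runlen[t - 1L] + 1L
                   else 1L
    }
  }
  if (max(runlen) < 4L) return(NULL)              # no credible helix
  run_hi <- which.max(runlen)
  run_lo <- run_hi - runlen[run_hi] + 1L
  run_pos <- (mi - 1L + run_lo):(mi - 1L + run_hi)
  pr <- partner[run_pos]
  if (any(pr >= mi & pr <= mj)) return(NULL)      # self-pairing inside mature
  arm <- if (all(pr > mj)) "5p" else "3p"
  p_anchor <- mi - 1L + (run_lo + run_hi) %/% 2L
  q_anchor <- partner[p_anchor]
  s_hi <- min(q_anchor + (p_anchor - mi) + 2L, n)
  s_lo <- max(q_anchor - (mj - 2L - p_anchor), 1L)
  if (s_lo > s_hi) return(NULL)
  if (s_lo <= mj && s_hi >= mi) return(NULL)      # star overlaps mature
  ## duplex-relative pairing: a position counts as paired only when its
  ## partner lies in the opposite element of the duplex
  core_m <- mi:max(mi, mj - 2L)
  core_s <- s_lo:max(s_lo, s_hi - 2L)
  unpaired_m <- !(partner[core_m] >= s_lo & partner[core_m] <= s_hi)
  unpaired_s <- !(partner[core_s] >= mi & partner[core_s] <= mj)
  longest_run <- function(flags) {
    if (!length(flags)) return(0L)
    r <- rle(flags)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  }
  space <- if (arm == "5p") s_lo - mj - 1L else mi - s_hi - 1L
  duplex_pairs <- sum(partner[idx] >= s_lo & partner[idx] <= s_hi)
  list(arm = arm, mature_lo = mi, mature_hi = mj,
       star_lo = s_lo, star_hi = s_hi,
       star_seq = substr(seq, s_lo, s_hi),
       duplex_pairs = duplex_pairs,
       max_bulge = max(longest_run(unpaired_m), longest_run(unpaired_s)),
       asymmetry = abs(sum(unpaired_m) - sum(unpaired_s)),
       loop_span = max(space, 0L),
       flank5 = min(mi, s_lo) - 1L,
       flank3 = n - max(mj, s_hi),
       structure = structure, mfe = mfe, precursor_seq = seq)
}

#' Excise and fold candidate precursors around a locus's dominant tag
#'
#' Takes the locus's most abundant tag as the putative mature (ties prefer
#' the longer, then 5'-most tag), excises windows extending up to
#' `max_space` nt on either side plus `flank` nt of genomic flank, folds
#' each window, and keeps the window whose structure places the mature on
#' one arm of a single stem-loop and best satisfies the duplex criteria;
#' the winning precursor is re-excised tightly around the mature/star
#' duplex plus flanks and re-folded.
#'
#' @param locus_hits genome-hit rows (one locus) joined with tag counts
#'   (`count_treatment`, `count_control`).
#' @param genome genome input.
#' @param flank flanking sequence length (default 25).
#' @param max_space maximal miRNA/miRNA* spacing explored (default 200).
#' @param engine folding engine (see [fold_rna()]).
#' @return a `hairpin_candidate` list, or NULL when no window folds into an
#'   acceptable stem-loop.
#' @export
excise_and_fold <- function(locus_hits, genome, mature_hit = NULL,
                            flank = 25L, max_space = 200L,
                            engine = getOption("mirphas.fold_engine", "vienna")) {
  gen <- genome_seqs(genome)
  h <- locus_hits
  dom <- if (!is.null(mature_hit)) mature_hit else {
    total <- h$count_treatment + h$count_control
    h[order(-total, -h$length, h$start)[1], ]
  }
  chrom_seq <- gen[[dom$chrom]]
  clen <- nchar(chrom_seq)
  exts <- unique(pmin(c(seq(30L, max_space, by = 34L), max_space), max_space))
  windows <- rbind(
    data.frame(ws = pmax(dom$start - exts - flank, 0L),
               we = pmin(dom$end + flank, clen)),
    data.frame(ws = pmax(dom$start - flank, 0L),
               we = pmin(dom$end + exts + flank, clen)))
  windows <- unique(windows)
  wseq <- substring(chrom_seq, windows$ws + 1L, windows$we)
  if (dom$strand == "-") wseq <- revcomp(wseq)
  folded <- tryCatch(fold_rna(wseq, engine = engine), error = function(e) {
    message("folding failed for locus at ", dom$chrom, ":", dom$start,
            "; skipped (", conditionMessage(e), ")")
    NULL
  })
  if (is.null(folded)) return(NULL)
  best <- NULL; best_key <- c(-Inf, Inf)
  for (i in seq_len(nrow(windows))) {
    ws <- windows$ws[i]; we <- windows$we[i]
    if (dom$strand == "+") {
      mi <- dom$start - ws + 1L; mj <- dom$end - ws
    } else {
      mi <- we - dom$end + 1L; mj <- we - dom$start
    }
    a <- analyze_window(wseq[i], folded$structure[i], folded$mfe[i], mi, mj)
    if (is.null(a)) next
    score <- sum(a$duplex_pairs >= 16L, a$max_bulge <= 4L, a$asymmetry <= 4L,
                 a$loop_span <= max_space, a$mfe <= -18)
    if (score > best_key[1] ||
        (score == best_key[1] && a$mfe < best_key[2])) {
      best <- c(a, list(ws = ws, we = we))
      best_key <- c(score, a$mfe)
    }
  }
  if (is.null(best)) return(NULL)
  ## tight re-excision around the duplex
  lo <- min(best$mature_lo, best$star_lo)
  hi <- max(best$mature_hi, best$star_hi)
  giv <- window_to_genomic(best$ws, best$we, dom$strand, lo, hi)
  ps <- max(giv[1] - flank, 0L); pe <- min(giv[2] + flank, clen)
  pseq <- substr(chrom_seq, ps + 1L, pe)
  if (dom$strand == "-") pseq <- revcomp(pseq)
  refold <- fold_rna(pseq, engine = engine)
  if (dom$strand == "+") {
    mi <- dom$start - ps + 1L; mj <- dom$end - ps
  } else {
    mi <- pe - dom$end + 1L; mj <- pe - dom$start
  }
  a <- analyze_window(pseq, refold$structure, refold$mfe, mi, mj)
  if (is.null(a)) return(NULL)
  sgiv <- window_to_genomic(ps, pe, dom$strand, a$star_lo, a$star_hi)
  structure(c(a, list(
    chrom = dom$chrom, start = ps, end = pe, strand = dom$strand,
    mature_seq = dom$sequence, mature_start = dom$start,
    mature_end = dom$end, star_start = sgiv[1], star_end = sgiv[2],
    copy_number = dom$n_hits,
    count_treatment = dom$count_treatment,
    count_control = dom$count_control)),
    class = "hairpin_candidate")
}

#' Evaluate the 11 precursor/duplex criteria
#'
#' The classical plant hairpin-prediction parameter set: mature length in
#' \[18, 25\] (1-2); matched reference mature length in \[20, 23\] when a
#' reference is supplied, else skipped as passing (3-4); at most 20 genomic
#' copies (5); precursor free energy at most -18 kcal/mol (6); at most 200
#' nt between miRNA and miRNA* (7); at least 16 duplex base pairs (8); at
#' most 4 nt of bulge (9); duplex asymmetry at most 4 (10); 25 nt of
#' precursor flank on both sides of the duplex (11).
#'
#' @param candidate a `hairpin_candidate`.
#' @param copy_number genomic placement count of the mature (defaults to the
#'   candidate's own).
#' @param ref_len length of the matched reference mature, or NULL for fully
#'   novel candidates.
#' @param limits named list overriding individual thresholds.
#' @return named logical vector of the 11 flags.
#' @export
check_criteria <- function(candidate, copy_number = candidate$copy_number,
                           ref_len = NULL, limits = list()) {
  lim <- utils::modifyList(list(
    mature_min = 18L, mature_max = 25L, ref_min = 20L, ref_max = 23L,
    max_copy = 20L, max_mfe = -18, max_space = 200L, min_pairs = 16L,
    max_bulge = 4L, max_asymmetry = 4L, flank = 25L), limits)
  mlen <- nchar(candidate$mature_seq)
  c(mature_min_len = mlen >= lim$mature_min,
    mature_max_len = mlen <= lim$mature_max,
    ref_min_len = is.null(ref_len) || ref_len >= lim$ref_min,
    ref_max_len = is.null(ref_len) || ref_len <= lim$ref_max,
    copy_number = copy_number <= lim$max_copy,
    mfe = candidate$mfe <= lim$max_mfe,
    duplex_space = candidate$loop_span <= lim$max_space,
    duplex_pairs = candidate$duplex_pairs >= lim$min_pairs,
    bulge = candidate$max_bulge <= lim$max_bulge,
    asymmetry = candidate$asymmetry <= lim$max_asymmetry,
    flank = candidate$flank5 >= lim$flank && candidate$flank3 >= lim$flank)
}

#' Look for miRNA* (star) read support at a hairpin
#'
#' The star is detected when some tag at the locus maps to the opposite arm
#' at the duplex position implied by the mature under the 2-nt 3' overhang
#' convention, within `tol` nt at each end.
#'
#' @param locus_hits genome-hit rows at the locus.
#' @param candidate a `hairpin_candidate`.
#' @param tol positional tolerance in nt (default 1).
#' @return logical.
#' @export
detect_star <- function(locus_hits, candidate, tol = 1L) {
  h <- locus_hits[locus_hits$sequence != candidate$mature_seq &
                    locus_hits$strand == candidate$strand, , drop = FALSE]
  if (!nrow(h)) return(FALSE)
  any(abs(h$start - candidate$star_start) <= tol &
        abs(h$end - candidate$star_end) <= tol)
}

#' Cluster mature sequences into families at an identity cutoff
#'
#' Single-linkage clustering where pairwise identity is the number of
#' matching positions divided by the global-alignment length.
#'
#' @param seqs character vector of mature sequences.
#' @param identity identity threshold (default 0.85).
#' @return integer family ids, one per input sequence.
#' @export
cluster_families <- function(seqs, identity = 0.85) {
  n <- length(seqs)
  if (!n) return(integer(0))
  uniq <- unique(seqs)
  m <- length(uniq)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (a in seq_len(m)) {
    for (b in seq_len(a - 1L)) {
      if (pair_identity(uniq[a], uniq[b]) >= identity) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  as.integer(factor(roots))[match(seqs, uniq)]
}

pair_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 4, gapExtension = 2)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alen
}

#' 5' first-nucleotide bias by sequence length
#'
#' @param seqs character vector of mature sequences.
#' @return data.frame of per-length frequencies of A/C/G/U at position 1
#'   (lengths absent from the input are omitted).
#' @export
first_nt_bias <- function(seqs) {
  if (!length(seqs)) {
    return(data.frame(length = integer(), A = numeric(), C = numeric(),
                      G = numeric(), U = numeric()))
  }
  first <- chartr("T", "U", substr(seqs, 1L, 1L))
  tab <- table(factor(nchar(seqs)), factor(first, levels = c("A", "C", "G", "U")))
  freq <- prop.table(tab, margin = 1)
  out <- data.frame(length = as.integer(rownames(freq)),
                    as.data.frame.matrix(freq))
  rownames(out) <- NULL
  out
}

#' Predict novel miRNAs from unannotated genome-mapped tags
#'
#' Full pipeline stage: keep unannotated tags, cluster their genome hits
#' into loci, excise and fold a precursor per locus, require all 11
#' criteria plus the minimum-abundance rule, look for star support, and
#' cluster the accepted matures into families.
#'
#' @param tags a `tag_table`, annotated ([annotate_tags()]) or raw.
#' @param genome genome input.
#' @param hits optional precomputed genome hits.
#' @param min_reads minimum mature abundance in at least one library.
#' @param max_gap locus clustering gap (default 200).
#' @param flank precursor flank length (default 25).
#' @param engine folding engine.
#' @param identity family-clustering identity cutoff (default 0.85).
#' @return data.frame of accepted novel miRNAs (one row per locus) with
#'   precursor coordinates, structure, energies, duplex metrics, criterion
#'   flags, star support and family ids; attribute `candidates` holds the
#'   `hairpin_candidate` objects.
#' @export
predict_novel_mirnas <- function(tags, genome, hits = NULL, min_reads = 10L,
                                 max_gap = 200L, flank = 25L,
                                 engine = getOption("mirphas.fold_engine",
                                                    "vienna"),
                                 identity = 0.85) {
  if ("category" %in% names(tags)) {
    tags <- tags[tags$category == "unannotated", , drop = FALSE]
  }
  empty <- data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mature_seq = character(), mature_arm = character(),
                      precursor_len = integer(), mfe = numeric(),
                      duplex_pairs = integer(), max_bulge = integer(),
                      asymmetry = integer(), copy_number = integer(),
                      count_treatment = integer(), count_control = integer(),
                      star_detected = logical(), family_id = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(tags)) return(empty)
  if (is.null(hits)) hits <- map_to_genome(tags, genome)
  if (!nrow(hits)) return(empty)
  hits$count_treatment <- tags$count_treatment[match(hits$sequence, tags$sequence)]
  hits$count_control <- tags$count_control[match(hits$sequence, tags$sequence)]
  hits <- cluster_hits(hits, max_gap)
  out <- list(); cands <- list()
  for (lid in unique(hits$locus_id)) {
    lh <- hits[hits$locus_id == lid, , drop = FALSE]
    ## a locus can hold several abundant tags (e.g. tandem hairpins inside
    ## one read-dense region): try each abundant tag as a putative mature,
    ## most abundant first, skipping tags inside an accepted precursor
    cand_rows <- which(pmax(lh$count_treatment, lh$count_control) >= min_reads)
    if (!length(cand_rows)) next
    cand_rows <- cand_rows[order(-(lh$count_treatment +
                                     lh$count_control)[cand_rows])]
    taken <- NULL   # accepted precursor intervals within this locus
    for (ri in cand_rows) {
      row <- lh[ri, , drop = FALSE]
      if (!is.null(taken) &&
          any(row$start < taken$end & row$end > taken$start)) next
      cand <- excise_and_fold(lh, genome, mature_hit = row, flank = flank,
                              engine = engine)
      if (is.null(cand)) next
      flags <- check_criteria(cand)
      if (!all(flags)) next
      cand$star_detected <- detect_star(lh, cand)
      cand$criterion_flags <- flags
      taken <- rbind(taken, data.frame(start = cand$start, end = cand$end))
      cands[[length(cands) + 1L]] <- cand
      out[[length(out) + 1L]] <- data.frame(
        chrom = cand$chrom, start = cand$start, end = cand$end,
        strand = cand$strand, mature_seq = cand$mature_seq,
        mature_arm = cand$arm, precursor_len = nchar(cand$precursor_seq),
        mfe = cand$mfe, duplex_pairs = cand$duplex_pairs,
        max_bulge = cand$max_bulge, asymmetry = cand$asymmetry,
        copy_number = cand$copy_number,
        count_treatment = cand$count_treatment,
        count_control = cand$count_control,
        star_detected = cand$star_detected, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- cbind(id = sprintf("miRn%04d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  res$family_id <- cluster_families(res$mature_seq, identity)
  attr(res, "candidates") <- cands
  res
}
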