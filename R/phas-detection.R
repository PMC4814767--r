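## Detection of 21-nt phased siRNA (PHAS) loci: phase-adjusted coordinates,
## the hypergeometric window p-value, the phasing score, a sliding-window
## genome scan, and 22-nt trigger assignment.

#' Phase-adjusted 5' coordinate of a read placement
#'
#' Forward-strand reads phase at their 5' start; antisense reads are offset
#' +2 nt (projected onto the forward strand) so that the two strands of a
#' 2-nt 3'-overhang duplex fall into the same 21-nt register.
#'
#' @param start,end 0-based half-open forward-strand interval(s).
#' @param strand `"+"` or `"-"` (vectorised).
#' @return adjusted 0-based coordinate(s).
#' @export
phase_position <- function(start, end, strand) {
  ifelse(strand == "+", start, start + 2L)
}

#' Hypergeometric p-value of phased-read enrichment in a window
#'
#' In a 21m-nt window with m phased positions, n unique 21-nt reads of
#' which k sit at phased positions, the tail probability is
#' `sum_{j=k}^{min(m,n)} C(m, j) C(20m, n-j) / C(21m, n)`, computed in
#' log space and clipped to \[0, 1\].
#'
#' @param n total unique 21-nt reads in the window.
#' @param k unique 21-nt reads at phased positions.
#' @param m number of 21-nt phases in the window (10 for a 210-nt window).
#' @return the tail probability.
#' @export
phas_pvalue <- function(n, k, m) {
  stopifnot(m >= 1)
  if (k > n) stop("k cannot exceed n")
  if (n > 21 * m) stop("n cannot exceed the 21m window positions")
  if (k <= 0) return(1)
  jmax <- min(m, n)
  if (k > jmax) return(0)
  j <- k:jmax
  terms <- lchoose(m, j) + lchoose(20 * m, n - j) - lchoose(21 * m, n)
  min(max(sum(exp(terms)), 0), 1)
}

#' Phasing score of a 210-nt ten-cycle window
#'
#' `(k - 2) * ln(1 + 10 * sum(P) / (1 + sum(U)))`, defined only when more
#' than 3 phase cycles are occupied.
#'
#' @param sum_p total count of 21-nt reads falling in phase.
#' @param sum_u total count of reads out of phase.
#' @param k number of phase cycles occupied by at least one 21-nt read.
#' @return the score, or NA when `k <= 3`.
#' @export
phasing_score <- function(sum_p, sum_u, k) {
  stopifnot(sum_p >= 0, sum_u >= 0)
  if (k <= 3) return(NA_real_)
  (k - 2) * log(1 + 10 * sum_p / (1 + sum_u))
}

#' Scan genome-mapped reads for PHAS windows and loci
#'
#' Slides `21 * m`-nt windows over each chromosome region with 21-nt read
#' coverage, evaluates all 21 possible registers per window, keeps the best
#' register, marks windows with p-value below `p_cut` positive, and merges
#' overlapping positive windows into loci. `n` and the p-value `k` count
#' distinct 21-nt tag placements (unique sequences at an adjusted
#' position); the phasing score uses cycle occupancy and read counts, with
#' non-21-nt reads contributing to the out-of-phase mass in the default
#' lenient mode and ignored entirely in `"strict21"` mode.
#'
#' @param hits read placements: data.frame with `sequence`, `chrom`,
#'   `start`, `end`, `strand`, `length` and (optionally) `count` per-tag
#'   read counts (default 1).
#' @param m phase cycles per window (default 10, i.e. 210-nt windows).
#' @param step window step in nt (default 21; 1 is supported).
#' @param p_cut positive-window cutoff (default 0.001).
#' @param mode `"lenient"` or `"strict21"` handling of non-21-nt reads.
#' @param all_registers when TRUE, return every (window, register) row
#'   rather than the best register per window (used for null calibration).
#' @return list with `windows` (chrom, start, register, n, k, k_cycles,
#'   sum_p, sum_u, pvalue, score, positive) and `loci` (merged positive
#'   windows: chrom, start, end, register, pvalue, score).
#' @export
phas_scan <- function(hits, m = 10L, step = 21L, p_cut = 0.001,
                      mode = c("lenient", "strict21"),
                      all_registers = FALSE) {
  mode <- match.arg(mode)
  win_len <- 21L * m
  if (!"count" %in% names(hits)) hits$count <- 1L
  empty_w <- data.frame(chrom = character(), start = integer(),
                        register = integer(), n = integer(), k = integer(),
                        k_cycles = integer(), sum_p = numeric(),
                        sum_u = numeric(), pvalue = numeric(),
                        score = numeric(), positive = logical(),
                        stringsAsFactors = FALSE)
  empty_l <- data.frame(chrom = character(), start = integer(),
                        end = integer(), register = integer(),
                        pvalue = numeric(), score = numeric(),
                        stringsAsFactors = FALSE)
  if (!nrow(hits)) return(list(windows = empty_w, loci = empty_l))
  hits$phase_pos <- phase_position(hits$start, hits$end, hits$strand)
  rows <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    h21 <- h[h$length == 21L, , drop = FALSE]
    if (!nrow(h21)) next
    ## unique 21-nt tag placements at each adjusted position
    key <- paste(h21$sequence, h21$phase_pos)
    dup <- duplicated(key)
    u_pos <- h21$phase_pos[!dup]
    u_cnt <- h21$count[!dup]
    other <- h[h$length != 21L, , drop = FALSE]
    lo <- min(u_pos); hi <- max(u_pos)
    starts <- seq.int(max(lo - win_len + 21L, 0L), hi, by = step)
    for (ws in starts) {
      we <- ws + win_len
      inw <- u_pos >= ws & u_pos < we
      n <- sum(inw)
      if (n == 0L) next
      pos_in <- u_pos[inw]; cnt_in <- u_cnt[inw]
      cnt21_total <- sum(cnt_in)
      other_cnt <- if (mode == "lenient" && nrow(other)) {
        sum(other$count[other$phase_pos >= ws & other$phase_pos < we])
      } else 0
      res_reg <- lapply(0:20, function(r) {
        phased <- (pos_in - ws - r) %% 21L == 0L
        k <- sum(phased)
        pv <- phas_pvalue(n, k, m)
        cyc <- unique((pos_in[phased] - ws - r) %/% 21L)
        sum_p <- sum(cnt_in[phased])
        sum_u <- cnt21_total - sum_p + other_cnt
        data.frame(chrom = ch, start = ws, register = (ws + r) %% 21L,
                   n = n, k = k, k_cycles = length(cyc), sum_p = sum_p,
                   sum_u = sum_u, pvalue = pv,
                   score = phasing_score(sum_p, sum_u, length(cyc)),
                   stringsAsFactors = FALSE)
      })
      res_reg <- do.call(rbind, res_reg)
      if (all_registers) {
        rows[[length(rows) + 1L]] <- res_reg
      } else {
        rows[[length(rows) + 1L]] <- res_reg[which.min(res_reg$pvalue), ]
      }
    }
  }
  if (!length(rows)) return(list(windows = empty_w, loci = empty_l))
  windows <- do.call(rbind, rows)
  rownames(windows) <- NULL
  windows$positive <- windows$pvalue < p_cut
  pos <- windows[windows$positive, , drop = FALSE]
  if (!nrow(pos)) return(list(windows = windows, loci = empty_l))
  gr <- GenomicRanges::GRanges(pos$chrom,
                               IRanges::IRanges(pos$start + 1L,
                                                pos$start + win_len))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(ov)
  loci <- do.call(rbind, lapply(seq_along(red), function(i) {
    w <- pos[grp == i, , drop = FALSE]
    best <- w[which.min(w$pvalue), ]
    data.frame(chrom = as.character(GenomicRanges::seqnames(red))[i],
               start = GenomicRanges::start(red)[i] - 1L,
               end = GenomicRanges::end(red)[i],
               register = best$register, pvalue = best$pvalue,
               score = suppressWarnings(max(w$score, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  loci$score[!is.finite(loci$score)] <- NA_real_
  list(windows = windows, loci = loci)
}

#' Assign a 22-nt trigger miRNA to a PHAS locus
#'
#' Scans the locus plus `flank` nt on both sides for a target site of a
#' 22-nt miRNA with complementarity expectation at most `cutoff`; the
#' implied cleavage position ([cleavage_position()]) must fall exactly in
#' the locus phase register. The best-scoring qualifying site wins.
#'
#' @param locus one row of [phas_scan()] `loci`.
#' @param mirnas data.frame with `id` and `sequence` columns (any lengths;
#'   only 22-nt entries are considered).
#' @param genome genome input.
#' @param cutoff expectation cutoff for the trigger search (default 4.5,
#'   looser than target prediction because trigger pairing is imperfect).
#' @param flank search flank in nt (default 250).
#' @return one-row data.frame (`mirna_id`, `site_start`, `site_end`,
#'   `cleavage`, `expectation`) or NULL when no trigger qualifies.
#' @export
find_trigger <- function(locus, mirnas, genome, cutoff = 4.5, flank = 250L) {
  mir22 <- mirnas[nchar(mirnas$sequence) == 22L, , drop = FALSE]
  if (!nrow(mir22)) return(NULL)
  gen <- genome_seqs(genome)
  chrom_seq <- gen[[locus$chrom]]
  rs <- max(locus$start - flank, 0L)
  re <- min(locus$end + flank, nchar(chrom_seq))
  region <- substr(chrom_seq, rs + 1L, re)
  best <- NULL
  for (i in seq_len(nrow(mir22))) {
    sites <- scan_transcriptome(
      data.frame(id = mir22$id[i], sequence = mir22$sequence[i],
                 stringsAsFactors = FALSE),
      setNames(region, "region"), expectation_cut = cutoff)
    if (!nrow(sites)) next
    sites$site_start0 <- rs + sites$start - 1L
    sites$cleavage <- cleavage_position(sites$site_start0)
    ok <- sites$cleavage %% 21L == locus$register
    sites <- sites[ok, , drop = FALSE]
    if (!nrow(sites)) next
    top <- sites[which.min(sites$expectation), ]
    if (is.null(best) || top$expectation < best$expectation) {
      best <- data.frame(mirna_id = mir22$id[i],
                         site_start = top$site_start0,
                         site_end = top$site_start0 + 22L,
                         cleavage = top$cleavage,
                         expectation = top$expectation,
                         stringsAsFactors = FALSE)
    }
  }
  best
}
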