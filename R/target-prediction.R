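## Rule-based plant miRNA target prediction: position-weighted
## complementarity expectation scoring, transcriptome scanning, target-site
## accessibility (UPE), cleavage vs translational-inhibition classification.

#' Penalty scheme for complementarity scoring
#'
#' The published plant-target scoring weights: mismatch 1.0, G:U wobble
#' 0.5, each gapped position 2.0, with penalties doubled in the seed
#' (miRNA positions 2-13). Kept in one place so the scheme is auditable
#' and overridable.
#'
#' @param mismatch,wobble,gap position penalties.
#' @param seed_from,seed_to seed region (1-based miRNA positions, 5' end).
#' @param seed_multiplier seed penalty multiplier.
#' @return named list of weights.
#' @export
target_penalties <- function(mismatch = 1.0, wobble = 0.5, gap = 2.0,
                             seed_from = 2L, seed_to = 13L,
                             seed_multiplier = 2.0) {
  list(mismatch = mismatch, wobble = wobble, gap = gap,
       seed_from = seed_from, seed_to = seed_to,
       seed_multiplier = seed_multiplier)
}

## per-position pair class of miRNA vs a same-length target window:
## miRNA position i (5'->3') pairs target position L-i+1
## 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch
pair_classes <- function(mirna_seq, target_subseq) {
  mi <- strsplit(toupper(mirna_seq), "")[[1]]
  ta <- rev(strsplit(toupper(target_subseq), "")[[1]])
  stopifnot(length(mi) == length(ta))
  cls <- rep(2L, length(mi))
  cls[comp_base(mi) == ta] <- 0L
  cls[(mi == "G" & ta == "T") | (mi == "T" & ta == "G") |
        (mi == "G" & ta == "U") | (mi == "U" & ta == "G")] <- 1L
  cls
}

#' Score a miRNA against one candidate target site
#'
#' Ungapped position-wise penalty over the miRNA (5'->3'; position 1 is the
#' miRNA 5' end, pairing the site's 3' end): mismatch 1.0, G:U wobble 0.5,
#' doubled at seed positions 2-13. At most `hspsize` positions are scored;
#' longer matures take their best contiguous `hspsize`-position window.
#'
#' @param mirna_seq mature miRNA sequence.
#' @param target_subseq target site, same length as the miRNA, given
#'   5'->3'.
#' @param penalties a [target_penalties()] list.
#' @param hspsize maximum scored positions (default 19, i.e. "shorter than
#'   20").
#' @return list with `expectation` and `alignment` (three strings: miRNA
#'   3'->5', match line with `|` match / `o` wobble / space mismatch,
#'   target 5'->3').
#' @export
score_site <- function(mirna_seq, target_subseq,
                       penalties = target_penalties(), hspsize = 19L) {
  if (!nzchar(mirna_seq) || !nzchar(target_subseq)) {
    stop("empty sequence")
  }
  if (nchar(mirna_seq) != nchar(target_subseq)) {
    stop("site must have the same length as the miRNA (ungapped scoring)")
  }
  cls <- pair_classes(mirna_seq, target_subseq)
  L <- length(cls)
  pen <- c(0, penalties$wobble, penalties$mismatch)[cls + 1L]
  seed <- seq_len(L) >= penalties$seed_from & seq_len(L) <= penalties$seed_to
  pen[seed] <- pen[seed] * penalties$seed_multiplier
  expectation <- if (L <= hspsize) sum(pen) else {
    cs <- cumsum(c(0, pen))
    min(cs[(hspsize + 1L):(L + 1L)] - cs[1:(L - hspsize + 1L)])
  }
  match_line <- c("|", "o", " ")[cls + 1L]
  alignment <- c(mirna_3to5 = paste(rev(strsplit(mirna_seq, "")[[1]]),
                                    collapse = ""),
                 match = paste(rev(match_line), collapse = ""),
                 target_5to3 = target_subseq)
  list(expectation = expectation, alignment = alignment, classes = cls)
}

#' Scan transcripts for miRNA target sites
#'
#' Exhaustive ungapped window scan of every transcript position for every
#' miRNA, reporting all sites with complementarity expectation at most
#' `expectation_cut`. One transcript may yield several sites and one site
#' several miRNAs.
#'
#' @param mirnas data.frame with `id` and `sequence`, or a named character
#'   vector.
#' @param transcripts transcript set (named character, `DNAStringSet` or
#'   FASTA path).
#' @param expectation_cut maximum reported expectation (default 3.0).
#' @param penalties a [target_penalties()] list.
#' @param hspsize maximum scored positions (default 19).
#' @return data.frame with `mirna_id`, `transcript_id`, `start`, `end`
#'   (1-based inclusive site coordinates), `expectation`, `inhibition`
#'   (`"cleavage"` or `"translation"`).
#' @export
scan_transcriptome <- function(mirnas, transcripts, expectation_cut = 3.0,
                               penalties = target_penalties(),
                               hspsize = 19L) {
  if (!is.data.frame(mirnas)) {
    mirnas <- data.frame(id = names(as_seq_set(mirnas, "mir")),
                         sequence = unname(as_seq_set(mirnas, "mir")),
                         stringsAsFactors = FALSE)
  }
  tx <- as_seq_set(transcripts, "tx")
  out <- list()
  for (ti in seq_along(tx)) {
    tch <- strsplit(toupper(tx[[ti]]), "")[[1]]
    nt <- length(tch)
    for (mi in seq_len(nrow(mirnas))) {
      mseq <- toupper(mirnas$sequence[mi])
      mch <- strsplit(mseq, "")[[1]]
      L <- length(mch)
      if (nt < L) next
      nw <- nt - L + 1L
      pen_mat <- matrix(0, nrow = L, ncol = nw)
      central_mm <- rep(FALSE, nw)
      for (i in seq_len(L)) {
        ## miRNA position i pairs target position (start + L - i)
        tpos <- seq_len(nw) + (L - i)
        tb <- tch[tpos]
        mb <- mch[i]
        match_ <- comp_base(mb) == tb
        wob <- (mb == "G" & tb == "T") | (mb == "T" & tb == "G")
        p <- ifelse(match_, 0, ifelse(wob, penalties$wobble,
                                      penalties$mismatch))
        if (i >= penalties$seed_from && i <= penalties$seed_to) {
          p <- p * penalties$seed_multiplier
        }
        pen_mat[i, ] <- p
        if (i >= 9L && i <= 11L) {
          central_mm <- central_mm | (!match_ & !wob)
        }
      }
      expect <- if (L <= hspsize) colSums(pen_mat) else {
        cs <- apply(pen_mat, 2, cumsum)
        cs <- rbind(0, cs)
        apply(cs[(hspsize + 1L):(L + 1L), , drop = FALSE] -
                cs[1:(L - hspsize + 1L), , drop = FALSE], 2, min)
      }
      keep <- which(expect <= expectation_cut)
      if (!length(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = mirnas$id[mi], transcript_id = names(tx)[ti],
        start = keep, end = keep + L - 1L,
        expectation = expect[keep],
        inhibition = ifelse(central_mm[keep], "translation", "cleavage"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), inhibition = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the inhibition mode of a scored site
#'
#' Translational inhibition when a true mismatch (wobbles do not count)
#' occupies any of miRNA positions 9-11; cleavage otherwise, with the
#' slice site opposite positions 10/11.
#'
#' @param mirna_seq,target_subseq as in [score_site()].
#' @return `"cleavage"` or `"translation"`.
#' @export
classify_inhibition <- function(mirna_seq, target_subseq) {
  cls <- pair_classes(mirna_seq, target_subseq)
  if (any(cls[9:11] == 2L)) "translation" else "cleavage"
}

#' Energy required to open (unpair) a target site
#'
#' Folds the site context (site plus `flank_up` nt upstream and
#' `flank_down` nt downstream) with and without the site constrained
#' unpaired; the UPE is the energy difference (>= 0, kcal/mol scale).
#' Requires the vienna folding engine.
#'
#' @param transcript transcript sequence (character).
#' @param site_start,site_end 1-based inclusive site coordinates.
#' @param flank_up,flank_down context flanks (defaults 17 and 13).
#' @return the UPE value, or NA (with a message) if folding fails.
#' @export
accessibility_upe <- function(transcript, site_start, site_end,
                              flank_up = 17L, flank_down = 13L) {
  nt <- nchar(transcript)
  cs <- max(site_start - flank_up, 1L)
  ce <- min(site_end + flank_down, nt)
  context <- substr(transcript, cs, ce)
  cons <- strrep(".", ce - cs + 1L)
  substr(cons, site_start - cs + 1L, site_end - cs + 1L) <-
    strrep("x", site_end - site_start + 1L)
  tryCatch({
    free <- fold_rna(context, engine = "vienna")$mfe
    open <- fold_rna(context, engine = "vienna", constraint = cons)$mfe
    max(open - free, 0)
  }, error = function(e) {
    message("UPE folding failed: ", conditionMessage(e))
    NA_real_
  })
}
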