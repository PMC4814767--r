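## Known-miRNA identification: match unique tags against a mature miRNA
## reference set, apply the >=10-read abundance rule, summarise families.

#' Parse a miRNA family name from a mature identifier
#'
#' Strips a species prefix (e.g. `sly-`), positional suffixes (`-5p`/`-3p`)
#' and letter/paralogue variants, so `sly-miR171g-3p` and `miR171i` both
#' collapse to `miR171`.
#'
#' @param name character vector of mature identifiers.
#' @return character vector of family names.
#' @export
parse_mir_family <- function(name) {
  x <- sub("^[A-Za-z]{2,5}[-_](?=miR)", "", name, perl = TRUE)
  m <- regmatches(x, regexpr("^miR[0-9]+", x, ignore.case = TRUE))
  fam <- x
  fam[regexpr("^miR[0-9]+", x, ignore.case = TRUE) > 0] <- m
  fam
}

## ungapped tag-vs-reference comparison under an end-shift allowance;
## returns NULL or list(mismatches, shift)
align_shift <- function(tag, ref, max_mismatch, max_shift) {
  lt <- nchar(tag); lr <- nchar(ref)
  tch <- strsplit(tag, "")[[1]]; rch <- strsplit(ref, "")[[1]]
  best <- NULL
  for (o in -max_shift:max_shift) {
    end_shift <- abs(o + lt - lr)
    if (end_shift > max_shift) next
    ti <- max(1L, 1L - o):min(lt, lr - o)
    if (!length(ti)) next
    mm <- sum(tch[ti] != rch[ti + o])
    if (mm > max_mismatch) next
    shift <- abs(o) + end_shift
    if (is.null(best) || mm < best$mm ||
        (mm == best$mm && shift < best$shift)) {
      best <- list(mm = mm, shift = shift)
    }
  }
  best
}

#' Match unique tags against known mature miRNAs
#'
#' A tag is assigned to the reference mature it matches with at most
#' `max_mismatch` substitutions, allowing its ends to shift by at most
#' `max_shift` nt relative to the reference. Ties resolve to the fewest
#' mismatches, then the smallest total end shift, then the
#' lexicographically first reference name (logged via `message`). Counts
#' of all tags assigned to one reference are aggregated.
#'
#' @param tags a `tag_table` (optionally annotated; if a `category` column
#'   is present only mappable tags are considered).
#' @param mature reference mature set (named character, `DNAStringSet` or
#'   FASTA path).
#' @param max_mismatch substitution allowance (default 0).
#' @param max_shift end-shift allowance in nt (default 2).
#' @return data.frame with `name`, `family`, `sequence` (reference mature),
#'   `length`, `count_treatment`, `count_control`, `n_tags`.
#' @export
match_known <- function(tags, mature, max_mismatch = 0L, max_shift = 2L) {
  ref <- as_seq_set(mature, "mir")
  if (!length(ref)) stop("empty mature miRNA reference")
  ref <- toupper(ref)
  cand <- tags
  assign_name <- rep(NA_character_, nrow(cand))
  ord <- order(names(ref))
  ref <- ref[ord]
  for (i in seq_len(nrow(cand))) {
    s <- cand$sequence[i]
    if (abs(nchar(s) - max(nchar(ref))) > 2L * max_shift &&
        abs(nchar(s) - min(nchar(ref))) > 2L * max_shift) next
    best <- NULL; best_names <- character(0)
    for (j in seq_along(ref)) {
      if (abs(nchar(s) - nchar(ref[[j]])) > 2L * max_shift) next
      a <- align_shift(s, ref[[j]], max_mismatch, max_shift)
      if (is.null(a)) next
      if (is.null(best) || a$mm < best$mm ||
          (a$mm == best$mm && a$shift < best$shift)) {
        best <- a; best_names <- names(ref)[j]
      } else if (a$mm == best$mm && a$shift == best$shift) {
        best_names <- c(best_names, names(ref)[j])
      }
    }
    if (!is.null(best)) {
      if (length(best_names) > 1L) {
        message("tag ", s, " matches ", length(best_names),
                " references equally; keeping ", best_names[1])
      }
      assign_name[i] <- best_names[1]
    }
  }
  keep <- !is.na(assign_name)
  if (!any(keep)) {
    return(data.frame(name = character(), family = character(),
                      sequence = character(), length = integer(),
                      count_treatment = integer(), count_control = integer(),
                      n_tags = integer(), stringsAsFactors = FALSE))
  }
  agg <- data.table::data.table(
    name = assign_name[keep],
    count_treatment = cand$count_treatment[keep],
    count_control = cand$count_control[keep])
  agg <- agg[, list(count_treatment = sum(count_treatment),
                    count_control = sum(count_control),
                    n_tags = .N), by = "name"]
  out <- as.data.frame(agg)
  out$sequence <- unname(ref[out$name])
  out$length <- nchar(out$sequence)
  out$family <- parse_mir_family(out$name)
  out[order(out$name),
      c("name", "family", "sequence", "length", "count_treatment",
        "count_control", "n_tags")]
}

#' Apply the minimum-abundance rule
#'
#' Keeps records with at least `min_reads` reads in at least one library.
#'
#' @param records data.frame with `count_treatment` and `count_control`.
#' @param min_reads abundance threshold (default 10).
#' @return the filtered data.frame.
#' @export
abundance_filter <- function(records, min_reads = 10L) {
  records[pmax(records$count_treatment, records$count_control) >= min_reads, ,
          drop = FALSE]
}

#' Summarise miRNA families and the member/abundance correlation
#'
#' @param records output of [match_known()] (optionally
#'   [abundance_filter()]ed).
#' @return list with `families` (data.frame: `family`, `members`,
#'   `total_reads`) and `correlation`, the Spearman rank correlation of
#'   member count with total reads across families (NA with a message when
#'   fewer than 2 families are present).
#' @export
family_summary <- function(records) {
  if (!nrow(records)) {
    return(list(families = data.frame(family = character(),
                                      members = integer(),
                                      total_reads = integer()),
                correlation = NA_real_))
  }
  total <- records$count_treatment + records$count_control
  agg <- data.table::data.table(family = records$family, total = total)
  agg <- agg[, list(members = .N, total_reads = sum(total)), by = "family"]
  fam <- as.data.frame(agg[order(-agg$members)])
  rho <- if (nrow(fam) < 2L) {
    message("fewer than 2 families; correlation undefined")
    NA_real_
  } else {
    suppressWarnings(cor(fam$members, fam$total_reads, method = "spearman"))
  }
  list(families = fam, correlation = rho)
}
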