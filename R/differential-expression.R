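## Count-based differential expression between two unreplicated small RNA
## libraries: RPM normalisation, log2 fold-change, per-tag p-value, calls.

#' Reads-per-million normalisation
#'
#' `count / total * 1e6`.
#'
#' @param count tag read count(s), >= 0.
#' @param total library clean-read total, > 0.
#' @return numeric RPM value(s).
#' @export
rpm_normalize <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / total * 1e6
}

#' Log2 fold-change of treatment over control RPM
#'
#' A zero operand is floored at `zero_floor` RPM before the ratio is taken;
#' records with both RPMs zero are undefined (NA, with a message) and
#' should be dropped by the caller.
#'
#' @param rpm_t,rpm_c treatment and control RPM values.
#' @param zero_floor floor applied to zero operands (default 0.001 RPM).
#' @return numeric log2 fold-change(s).
#' @export
log2_fold_change <- function(rpm_t, rpm_c, zero_floor = 0.001) {
  stopifnot(zero_floor > 0)
  if (any(rpm_t < 0 | rpm_c < 0)) stop("RPM values must be non-negative")
  both0 <- rpm_t == 0 & rpm_c == 0
  if (any(both0)) message(sum(both0), " record(s) with zero RPM in both ",
                          "libraries; fold-change undefined")
  out <- log2(pmax(rpm_t, zero_floor) / pmax(rpm_c, zero_floor))
  out[both0] <- NA_real_
  out
}

#' Significance of a count difference between two libraries
#'
#' Default backend: a two-proportion Z statistic with pooled variance on
#' the per-library proportions (the tag-count test family used for
#' unreplicated digital expression data); `"binom"` gives the exact
#' conditional binomial alternative, testing `count_t` against
#' `Binomial(count_t + count_c, total_t / (total_t + total_c))`. Both are
#' two-sided.
#'
#' @param count_t,count_c per-library tag counts.
#' @param total_t,total_c library clean-read totals.
#' @param backend `"ztest"` (default) or `"binom"`.
#' @return p-value(s) in \[0, 1\].
#' @export
tag_count_pvalue <- function(count_t, count_c, total_t, total_c,
                             backend = c("ztest", "binom")) {
  backend <- match.arg(backend)
  if (any(total_t <= 0 | total_c <= 0)) stop("library totals must be positive")
  n <- max(length(count_t), length(count_c))
  count_t <- rep_len(count_t, n); count_c <- rep_len(count_c, n)
  total_t <- rep_len(total_t, n); total_c <- rep_len(total_c, n)
  if (backend == "ztest") {
    p1 <- count_t / total_t
    p2 <- count_c / total_c
    pool <- (count_t + count_c) / (total_t + total_c)
    se <- sqrt(pool * (1 - pool) * (1 / total_t + 1 / total_c))
    z <- ifelse(se > 0, (p1 - p2) / se, 0)
    2 * pnorm(-abs(z))
  } else {
    vapply(seq_len(n), function(i) {
      k <- count_t[i] + count_c[i]
      if (k == 0L) return(1)
      binom.test(count_t[i], k,
                 p = total_t[i] / (total_t[i] + total_c[i]))$p.value
    }, numeric(1))
  }
}

#' Call differentially expressed records
#'
#' `up` when lfc > `lfc_cut` and p < `p_cut`; `down` when lfc < -`lfc_cut`
#' and p < `p_cut`; `ns` otherwise.
#'
#' @param records data.frame with `lfc` and `pvalue` columns.
#' @param lfc_cut log2 fold-change cutoff (default 2).
#' @param p_cut p-value cutoff (default 0.001).
#' @return `records` with a `call` column.
#' @export
call_de <- function(records, lfc_cut = 2, p_cut = 0.001) {
  call <- rep("ns", nrow(records))
  sig <- !is.na(records$lfc) & !is.na(records$pvalue) & records$pvalue < p_cut
  call[sig & records$lfc > lfc_cut] <- "up"
  call[sig & records$lfc < -lfc_cut] <- "down"
  records$call <- call
  records
}

#' Build the differential-expression table for a set of miRNAs
#'
#' RPM-normalises both libraries, computes log2 fold-changes and per-tag
#' p-values, and calls responsive records. Records with zero counts in both
#' libraries are dropped (logged). A Benjamini-Hochberg adjusted column is
#' included for reference; calls use the raw p-value.
#'
#' @param records data.frame with `count_treatment`, `count_control` and an
#'   id column (`id` or `name`).
#' @param total_t,total_c library clean-read totals.
#' @param lfc_cut,p_cut call thresholds.
#' @param zero_floor see [log2_fold_change()].
#' @param backend see [tag_count_pvalue()].
#' @return data.frame with `id`, counts, `rpm_treatment`, `rpm_control`,
#'   `lfc`, `pvalue`, `padj`, `call`.
#' @export
de_table <- function(records, total_t, total_c, lfc_cut = 2, p_cut = 0.001,
                     zero_floor = 0.001, backend = c("ztest", "binom")) {
  backend <- match.arg(backend)
  id <- if ("id" %in% names(records)) records$id else
    if ("name" %in% names(records)) records$name else
      sprintf("tag%05d", seq_len(nrow(records)))
  keep <- records$count_treatment + records$count_control > 0L
  if (any(!keep)) message(sum(!keep), " record(s) with zero counts in both ",
                          "libraries dropped")
  rec <- records[keep, , drop = FALSE]; id <- id[keep]
  rpm_t <- rpm_normalize(rec$count_treatment, total_t)
  rpm_c <- rpm_normalize(rec$count_control, total_c)
  out <- data.frame(id = id,
                    count_treatment = rec$count_treatment,
                    count_control = rec$count_control,
                    rpm_treatment = rpm_t, rpm_control = rpm_c,
                    lfc = log2_fold_change(rpm_t, rpm_c, zero_floor),
                    pvalue = tag_count_pvalue(rec$count_treatment,
                                              rec$count_control,
                                              total_t, total_c, backend),
                    stringsAsFactors = FALSE)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  call_de(out, lfc_cut, p_cut)
}
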