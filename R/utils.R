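#' @importFrom stats rpois runif cor complete.cases p.adjust pnorm binom.test setNames
#' @importFrom utils head write.table read.table
#' @importFrom data.table data.table setorder .N
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

## random DNA of length n, optionally with a GC fraction window
## (rejection sampling; used to keep planted stems thermodynamically stable)
random_dna <- function(n, gc = NULL, gc_tol = 0.1, max_tries = 200L) {
  if (is.null(gc)) {
    return(paste(sample(DNA_BASES, n, replace = TRUE), collapse = ""))
  }
  for (i in seq_len(max_tries)) {
    s <- sample(DNA_BASES, n, replace = TRUE)
    f <- mean(s %in% c("G", "C"))
    if (abs(f - gc) <= gc_tol) return(paste(s, collapse = ""))
  }
  paste(s, collapse = "")
}

## coerce genome-like input (synthetic_genome, DNAStringSet, named character,
## FASTA path) to a named character vector of chromosome sequences
genome_seqs <- function(genome) {
  if (inherits(genome, "synthetic_genome")) return(genome$sequences)
  if (inherits(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    dss <- Biostrings::readDNAStringSet(genome)
    names(dss) <- sub("\\s.*$", "", names(dss))
    return(setNames(as.character(dss), names(dss)))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(genome)
  }
  stop("cannot interpret `genome`; supply a synthetic_genome, DNAStringSet, ",
       "named character vector or FASTA path")
}

## coerce sequence-set input (DNAStringSet, named character, FASTA path)
as_seq_set <- function(x, what = "sequences") {
  if (inherits(x, "DNAStringSet")) return(setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    dss <- Biostrings::readDNAStringSet(x)
    names(dss) <- sub("\\s.*$", "", names(dss))
    return(setNames(as.character(dss), names(dss)))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0(what, seq_along(x))
    return(x)
  }
  stop("cannot interpret ", what)
}

## intervals argument: data.frame(chrom, start, end) (0-based half-open) or a
## BED file path (imported via rtracklayer when available)
as_intervals <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(x, format = "BED")
      return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE))
    }
    bed <- read.table(x, sep = "\t", stringsAsFactors = FALSE)
    return(data.frame(chrom = bed[[1]], start = as.integer(bed[[2]]),
                      end = as.integer(bed[[3]]), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  x
}
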