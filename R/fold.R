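#' Fold RNA/DNA sequences into secondary structures
#'
#' Pluggable folding contract: a folding engine takes nucleotide sequences and
#' returns, for each, a dot-bracket structure of the same length and a free
#' energy in kcal/mol. The default engine shells out to ViennaRNA's `RNAfold`
#' (thermodynamic nearest-neighbour model); the `"maxpair"` engine is a pure-R
#' Nussinov base-pair maximisation with a fixed -1 kcal/mol-per-pair surrogate
#' energy, intended only for structure-shape checks on short sequences, never
#' for thermodynamic thresholds.
#'
#' @param seqs character vector of sequences (T is read as U).
#' @param engine `"vienna"` (default, requires `RNAfold` on the PATH) or
#'   `"maxpair"`.
#' @param constraint optional single dot-bracket-style constraint string
#'   (`.` free, `x` forced unpaired); only supported by the vienna engine and
#'   only for a single sequence.
#' @return data.frame with columns `sequence`, `structure`, `mfe`.
#' @export
fold_rna <- function(seqs, engine = getOption("mirphas.fold_engine", "vienna"),
                     constraint = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  engine <- match.arg(engine, c("vienna", "maxpair"))
  if (engine == "vienna") {
    fold_vienna(seqs, constraint)
  } else {
    if (!is.null(constraint)) stop("constraints need the vienna engine")
    structs <- vapply(seqs, nussinov_structure, character(1), USE.NAMES = FALSE)
    data.frame(sequence = seqs, structure = structs,
               mfe = -1.0 * vapply(structs, function(s)
                 sum(strsplit(s, "")[[1]] == "("), numeric(1), USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  }
}

fold_vienna <- function(seqs, constraint = NULL) {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold not found on PATH; install ViennaRNA or use engine = 'maxpair'")
  }
  infile <- tempfile(fileext = ".fa")
  on.exit(unlink(infile), add = TRUE)
  args <- c("--noPS")
  if (!is.null(constraint)) {
    stopifnot(length(seqs) == 1L, nchar(constraint) == nchar(seqs))
    writeLines(c(">s1", seqs, constraint), infile)
    args <- c(args, "-C")
  } else {
    writeLines(as.vector(rbind(paste0(">s", seq_along(seqs)), seqs)), infile)
  }
  out <- suppressWarnings(system2("RNAfold", args, stdout = TRUE,
                                  stdin = infile, stderr = FALSE))
  hit <- regmatches(out, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
  keep <- lengths(hit) == 3L
  if (sum(keep) != length(seqs)) {
    stop("RNAfold returned ", sum(keep), " structures for ", length(seqs),
         " sequences")
  }
  data.frame(sequence = seqs,
             structure = vapply(hit[keep], `[`, character(1), 2L),
             mfe = as.numeric(vapply(hit[keep], `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Partner table of a dot-bracket structure
#'
#' @param structure single dot-bracket string.
#' @return integer vector; position i holds the 1-based partner of i, or 0.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure")
  partner
}

can_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G") |
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

## Nussinov base-pair maximisation, min hairpin loop 3.
## O(n^2) vectorised over the bifurcation split; fine for n up to a few hundred.
nussinov_structure <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 5L) return(strrep(".", n))
  M <- matrix(0L, n, n)
  for (span in 4:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- max(M[i + 1L, j], M[i, j - 1L],
                  M[i + 1L, j - 1L] + as.integer(can_pair(ch[i], ch[j])))
      ks <- i:(j - 1L)
      best <- max(best, max(M[i, ks] + M[cbind(ks + 1L, j)]))
      M[i, j] <- best
    }
  }
  struct <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i < 4L) next
    if (M[i, j] == M[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else if (M[i, j] == M[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    } else if (can_pair(ch[i], ch[j]) && M[i, j] == M[i + 1L, j - 1L] + 1L) {
      struct[i] <- "("; struct[j] <- ")"
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
    } else {
      for (k in i:(j - 1L)) {
        if (M[i, j] == M[i, k] + M[k + 1L, j]) {
          stack[[length(stack) + 1L]] <- c(i, k)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  paste(struct, collapse = "")
}
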