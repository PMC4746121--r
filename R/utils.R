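# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODON <- "ATG"

# Fast character-level reverse complement (no Biostrings object overhead);
# for hot inner loops on short strings.
fast_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character strings (IUPAC codes allowed).
#'
#' @param seq A single DNA string.
#' @return A character string.
#' @export
#' @examples
#' reverse_complement("ATGC")
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Substring of a circular sequence; `end` may exceed nchar(seq) and wraps.
circ_substr <- function(seq, start, end) {
  L <- nchar(seq)
  stopifnot(start >= 1, end >= start, end - start + 1 <= 2 * L)
  start <- ((start - 1) %% L) + 1
  end <- start + (end - start)
  if (end <= L) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, L), substr(seq, 1, end - L))
  }
}

# Split a (possibly origin-wrapping) 1-based inclusive interval into 1 or 2
# linear segments within [1, L]. `end` may exceed L (unwrapped convention).
split_circular <- function(start, end, L) {
  stopifnot(start >= 1, start <= L, end >= start)
  if (end <= L) {
    list(c(start, end))
  } else {
    stopifnot(end - L < start) # wraps at most once
    list(c(start, L), c(1L, end - L))
  }
}

# IRanges over [1, L] for a set of features (vectors start, end; end may wrap).
features_as_ranges <- function(start, end, L) {
  segs <- mapply(split_circular, start, end, MoreArgs = list(L = L),
                 SIMPLIFY = FALSE)
  idx <- rep(seq_along(segs), lengths(segs))
  m <- do.call(rbind, unlist(segs, recursive = FALSE))
  if (is.null(m)) {
    return(IRanges::IRanges())
  }
  r <- IRanges::IRanges(start = m[, 1], end = m[, 2])
  S4Vectors::mcols(r)$feature <- idx
  r
}

# Total number of genome positions covered by features (union, wraps handled).
union_width <- function(start, end, L) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(features_as_ranges(start, end, L))))
}

# Overlap (in nt) between two circular intervals given as (start, end) with
# possibly end > L.
circ_overlap <- function(s1, e1, s2, e2, L) {
  a <- split_circular(s1, e1, L)
  b <- split_circular(s2, e2, L)
  ov <- 0L
  for (x in a) for (y in b) {
    ov <- ov + max(0L, min(x[2], y[2]) - max(x[1], y[1]) + 1L)
  }
  ov
}

# Deterministic local RNG: evaluate `expr` under `seed` without touching the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Base composition counts over {A,C,G,T} (N and other codes ignored).
base_counts <- function(seq) {
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                   letters = DNA_BASES)
  setNames(as.integer(f), DNA_BASES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
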