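#' Default baculovirus promoter motif set
#'
#' Late motifs `TTAAG` (consensus late) and `GATA`; early motifs `CAKT` and
#' `TATAWAW` (IUPAC: `K = G/T`, `W = A/T`). The table is user-editable: pass
#' your own data frame with the same columns to [scan_upstream()].
#'
#' @return A data frame with columns `name`, `class`, `pattern`.
#' @export
default_promoter_motifs <- function() {
  data.frame(
    name = c("TTAAG", "GATA", "CAKT", "TATAWAW"),
    class = c("late", "late", "early", "early"),
    pattern = c("TTAAG", "GATA", "CAKT", "TATAWAW"),
    stringsAsFactors = FALSE
  )
}

#' Match an IUPAC-degenerate pattern against a sequence
#'
#' Reports every start position (1-based) at which each pattern symbol's IUPAC
#' code set contains the sequence base. Plain wrapper over
#' [Biostrings::matchPattern()] with `fixed = "subject"` so degeneracy applies
#' to the pattern only.
#'
#' @param pattern IUPAC pattern string.
#' @param seq DNA string.
#' @return Integer vector of 1-based match start positions.
#' @export
#' @examples
#' iupac_match("TATAWAW", "TATAAAT") # 1
#' iupac_match("CAKT", "CACT")       # none
iupac_match <- function(pattern, seq) {
  pat_chars <- strsplit(toupper(pattern), "")[[1]]
  if (length(pat_chars) == 0 ||
      !all(pat_chars %in% names(Biostrings::IUPAC_CODE_MAP))) {
    stop("pattern contains non-IUPAC symbols: ", pattern)
  }
  if (nchar(seq) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                fixed = "subject")
  as.integer(Biostrings::start(m))
}

#' Scan ORF upstream windows for promoter motifs
#'
#' For each ORF the `window_nt` bases 5' of its ATG on the coding strand are
#' extracted (wrapping the origin when needed) and every motif is matched on
#' that window and on its reverse complement (template strand). The reported
#' offset is the number of bases strictly between the motif's 3' end and the A
#' of the ATG (a motif immediately adjacent to the start codon has offset 0).
#' `matched_literal` is the hit substring as it reads on the genome plus
#' strand.
#'
#' @param genome A [circular_genome()].
#' @param annotation A [gene_annotation()].
#' @param motifs Motif table as in [default_promoter_motifs()].
#' @param window_nt Upstream window length (default 120 nt).
#' @return A data frame with columns `orf_serial`, `motif_name`, `motif_class`,
#'   `matched_literal`, `offset_nt`, `strand_of_match` (`coding`/`template`).
#' @export
scan_upstream <- function(genome, annotation, motifs = default_promoter_motifs(),
                          window_nt = 120L) {
  stopifnot(inherits(genome, "circular_genome"))
  if (window_nt < max(nchar(motifs$pattern))) {
    stop("window_nt shorter than the longest motif")
  }
  L <- genome$length
  hits <- list()
  for (i in seq_len(nrow(annotation))) {
    f <- annotation[i, ]
    W <- window_nt
    if (f$strand == "+") {
      # genomic window [start - W, start - 1], wrapped
      ws <- f$start - W
      if (ws < 1) {
        if (!genome$circular) {
          ws <- 1L
          W <- f$start - 1L
          if (W < 1) next
        } else {
          ws <- ws + L
        }
      }
      win <- circ_substr(genome$seq, ws, ws + W - 1L)
      gpos <- function(a, b) (((ws + a - 2L) %% L) + 1L) # genomic start of window pos a
    } else {
      # coding-strand upstream lies genomically downstream of `end`
      es <- (((f$end) %% L)) + 1L # first position after the ORF
      if (!genome$circular) {
        if (es > L) next
        W <- min(W, L - es + 1L)
      }
      win_plus <- circ_substr(genome$seq, es, es + W - 1L)
      win <- reverse_complement(win_plus)
      gpos <- function(a, b) ((((es + (W - b) - 1L)) %% L) + 1L)
    }
    truncated <- nchar(win) < window_nt
    rcwin <- reverse_complement(win)
    for (m in seq_len(nrow(motifs))) {
      pat <- motifs$pattern[m]
      plen <- nchar(pat)
      # coding strand of the window
      for (a in iupac_match(pat, win)) {
        b <- a + plen - 1L
        gs <- gpos(a, b)
        lit <- circ_substr(genome$seq, gs, gs + plen - 1L)
        hits[[length(hits) + 1L]] <- data.frame(
          orf_serial = f$serial, motif_name = motifs$name[m],
          motif_class = motifs$class[m], matched_literal = lit,
          offset_nt = W - b, strand_of_match = "coding",
          truncated_window = truncated, stringsAsFactors = FALSE)
      }
      # template strand: the same genomic window read on the other strand
      for (a in iupac_match(pat, rcwin)) {
        b <- a + plen - 1L
        # corresponding coding-window span
        ca <- W - b + 1L; cb <- W - a + 1L
        gs <- gpos(ca, cb)
        lit <- circ_substr(genome$seq, gs, gs + plen - 1L)
        hits[[length(hits) + 1L]] <- data.frame(
          orf_serial = f$serial, motif_name = motifs$name[m],
          motif_class = motifs$class[m], matched_literal = lit,
          offset_nt = a - 1L, strand_of_match = "template",
          truncated_window = truncated, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(orf_serial = integer(0), motif_name = character(0),
                      motif_class = character(0), matched_literal = character(0),
                      offset_nt = integer(0), strand_of_match = character(0),
                      truncated_window = logical(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$orf_serial, out$offset_nt, out$motif_name), , drop = FALSE]
}
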