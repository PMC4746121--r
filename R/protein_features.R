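# Standard average residue masses (Da), i.e. amino-acid masses minus one
# water; the mass of a peptide is the residue sum plus one water (18.01524).
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Translate an ORF to protein
#'
#' Standard-code translation of the ORF's coding strand (reverse-complemented
#' for minus-strand features, wrapping the origin where needed); a terminal
#' stop codon is removed. An internal stop is an error naming the offending
#' codon position.
#'
#' @param genome A [circular_genome()].
#' @param orf One row of a [gene_annotation()] (or any list with `start`,
#'   `end`, `strand`, and optionally `serial`).
#' @return A list of class `protein_record`: `orf_serial`, `aa_seq` (no stop),
#'   `length_aa`, `mw_da`.
#' @export
translate_orf <- function(genome, orf) {
  stopifnot(inherits(genome, "circular_genome"))
  nt <- circ_substr(genome$seq, orf$start, orf$end)
  if (orf$strand == "-") nt <- reverse_complement(nt)
  if (nchar(nt) %% 3 != 0) {
    stop("ORF span not divisible by 3 (", nchar(nt), " nt)")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           no.init.codon = TRUE))
  ncod <- nchar(aa)
  if (substr(aa, ncod, ncod) == "*") aa <- substr(aa, 1L, ncod - 1L)
  internal <- regexpr("*", aa, fixed = TRUE)
  if (internal > 0) {
    stop("internal stop codon at codon ", internal, " of the ORF")
  }
  structure(list(orf_serial = orf$serial %||% NA_integer_, aa_seq = aa,
                 length_aa = nchar(aa), mw_da = protein_mw(aa)),
            class = "protein_record")
}

#' Translate every ORF of an annotation
#'
#' @param genome A [circular_genome()].
#' @param annotation A [gene_annotation()].
#' @return Named character vector of protein sequences (names = serials);
#'   molecular weights in attribute `mw_da`.
#' @export
orf_proteins <- function(genome, annotation) {
  recs <- lapply(seq_len(nrow(annotation)), function(i) {
    translate_orf(genome, annotation[i, ])
  })
  aa <- vapply(recs, `[[`, character(1), "aa_seq")
  names(aa) <- annotation$serial
  attr(aa, "mw_da") <- vapply(recs, `[[`, numeric(1), "mw_da")
  aa
}

#' Average molecular weight of a protein
#'
#' Sum of standard average residue masses plus one water (18.015 Da). Average
#' (not monoisotopic) masses are used, matching how genome reports quote
#' protein sizes in kDa.
#'
#' @param aa_seq Protein sequence over the 20 standard amino acids. `X` is
#'   allowed only with `allow_x = TRUE` (counted as mass 0).
#' @param allow_x Tolerate `X` residues.
#' @return Mass in daltons.
#' @export
#' @examples
#' protein_mw("G") # 75.07
protein_mw <- function(aa_seq, allow_x = FALSE) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L)
  if (!nzchar(aa_seq)) stop("empty protein sequence")
  res <- strsplit(toupper(aa_seq), "")[[1]]
  known <- res %in% names(AA_RESIDUE_MASS)
  if (!all(known)) {
    bad <- unique(res[!known])
    if (!(allow_x && identical(bad, "X"))) {
      stop("non-standard residue(s): ", paste(bad, collapse = ", "))
    }
  }
  sum(AA_RESIDUE_MASS[res[known]]) + WATER_MASS
}

#' Find six-cysteine chitin-binding (peritrophin-A/CBM_14) motifs
#'
#' Enumerates every sextuple of cysteines whose five inter-cysteine spacers
#' fall in the peritrophin-A ranges
#' `C-x(13,20)-C-x(5,6)-C-x(9,19)-C-x(10,14)-C-x(4,14)-C`. Overlapping hits
#' are kept: a protein with two adjacent CBM_14 domains reports both.
#'
#' @param aa_seq Protein sequence.
#' @param spacer_ranges List of five `c(min, max)` spacer bounds (defaults to
#'   the peritrophin-A pattern above).
#' @return A `data.frame` with columns `start_aa`, `end_aa` (positions of the
#'   first and sixth cysteine, 1-based inclusive) and `spacer1`..`spacer5`.
#' @export
find_cys_motif <- function(aa_seq,
                           spacer_ranges = list(c(13L, 20L), c(5L, 6L),
                                                c(9L, 19L), c(10L, 14L),
                                                c(4L, 14L))) {
  stopifnot(length(spacer_ranges) == 5L)
  cys <- which(strsplit(toupper(aa_seq), "")[[1]] == "C")
  hits <- list()
  recurse <- function(chain) {
    k <- length(chain)
    if (k == 6L) {
      sp <- diff(chain) - 1L
      hits[[length(hits) + 1L]] <<- data.frame(
        start_aa = chain[1], end_aa = chain[6],
        spacer1 = sp[1], spacer2 = sp[2], spacer3 = sp[3],
        spacer4 = sp[4], spacer5 = sp[5])
      return(invisible())
    }
    rng <- spacer_ranges[[k]]
    nxt <- cys[cys - chain[k] - 1L >= rng[1] & cys - chain[k] - 1L <= rng[2]]
    for (p in nxt) recurse(c(chain, p))
  }
  for (c1 in cys) recurse(c1)
  if (length(hits) == 0) {
    return(data.frame(start_aa = integer(0), end_aa = integer(0),
                      spacer1 = integer(0), spacer2 = integer(0),
                      spacer3 = integer(0), spacer4 = integer(0),
                      spacer5 = integer(0)))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start_aa, out$end_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count non-overlapping six-cysteine domains
#'
#' Adjacent CBM_14 domains admit additional "bridge" sextuples that reuse
#' cysteines of both; the domain count reported for a protein is the maximal
#' chain of non-overlapping hits, selected greedily from the N-terminus.
#'
#' @param hits Output of [find_cys_motif()].
#' @return Integer domain count.
#' @export
count_cys_domains <- function(hits) {
  if (nrow(hits) == 0) return(0L)
  hits <- hits[order(hits$start_aa, hits$end_aa), , drop = FALSE]
  n <- 0L
  last_end <- -Inf
  for (i in seq_len(nrow(hits))) {
    if (hits$start_aa[i] > last_end) {
      n <- n + 1L
      last_end <- hits$end_aa[i]
    }
  }
  n
}

#' Find homopolymer runs (e.g. poly-glutamine)
#'
#' Maximal runs of a single residue (or nucleotide) of at least `min_len`.
#'
#' @param seq Protein or DNA string.
#' @param residue Single character to look for (e.g. `"Q"`).
#' @param min_len Minimum run length (>= 2).
#' @return A `data.frame` with columns `start`, `end`, `length` (1-based
#'   inclusive).
#' @export
#' @examples
#' find_homopolymer_runs("AAQQQQA", "Q", 3) # one run, 3..6
find_homopolymer_runs <- function(seq, residue, min_len = 2L) {
  stopifnot(nchar(residue) == 1L, min_len >= 2L)
  x <- strsplit(toupper(seq), "")[[1]] == toupper(residue)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_len
  data.frame(start = starts[sel], end = ends[sel], length = r$lengths[sel])
}
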