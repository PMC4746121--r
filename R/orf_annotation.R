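#' ORF-calling configuration
#'
#' Criteria for de novo ORF identification: methionine-initiated reading
#' frames of at least `min_len_nt` coding nucleotides (50 codons at the
#' default) with minimal overlap between accepted ORFs. Because published
#' genome reports rarely state whether the stop codon counts towards the
#' minimum length, `count_stop_in_min_len` switches between the two readings
#' (default: the coding span ATG..last sense codon must reach `min_len_nt`, so
#' a 50-codon ORF spans 153 nt including its stop).
#'
#' @param min_len_nt Minimum length in nt (default 150).
#' @param count_stop_in_min_len Include the stop codon in the length test.
#' @param overlap_policy Conflict resolution; only `"longest-first"` greedy is
#'   implemented (candidates accepted in decreasing length order).
#' @param max_allowed_overlap_nt Maximum tolerated overlap between two
#'   accepted ORFs (default 30 nt; granulovirus ORFs frequently overlap
#'   slightly).
#' @return A list of class `orf_config`.
#' @export
orf_config <- function(min_len_nt = 150L, count_stop_in_min_len = FALSE,
                       overlap_policy = "longest-first",
                       max_allowed_overlap_nt = 30L) {
  stopifnot(min_len_nt >= 3, max_allowed_overlap_nt >= 0)
  overlap_policy <- match.arg(overlap_policy, "longest-first")
  structure(list(min_len_nt = as.integer(min_len_nt),
                 count_stop_in_min_len = isTRUE(count_stop_in_min_len),
                 overlap_policy = overlap_policy,
                 max_allowed_overlap_nt = as.integer(max_allowed_overlap_nt)),
            class = "orf_config")
}

# Codon start positions and codon strings for one frame of a string.
frame_codons <- function(seq, frame) {
  n <- nchar(seq)
  pos <- seq.int(1L + frame, n - 2L, by = 3L)
  list(pos = pos, codon = substring(seq, pos, pos + 2L))
}

# All maximal ATG..stop ORFs on the plus strand of `seq` (doubled when
# circular). Returns start/end in coordinates of `seq`'s first copy, with
# end possibly > L (wrap). Span includes the stop codon.
orfs_plus_strand <- function(seq, L, circular) {
  s2 <- if (circular) paste0(seq, seq) else seq
  out <- list()
  for (frame in 0:2) {
    fc <- frame_codons(s2, frame)
    if (length(fc$pos) == 0) next
    is_stop <- fc$codon %in% STOP_CODONS
    is_atg <- fc$codon == START_CODON
    stop_idx <- which(is_stop)
    atg_idx <- which(is_atg)
    if (length(stop_idx) == 0 || length(atg_idx) == 0) next
    # for each stop, the 5'-most ATG after the previous stop
    prev_stop <- c(0L, head(stop_idx, -1L))
    for (k in seq_along(stop_idx)) {
      lo <- prev_stop[k] + 1L
      hi <- stop_idx[k] - 1L
      if (hi < lo) next
      cand <- atg_idx[atg_idx >= lo & atg_idx <= hi]
      if (length(cand) == 0) next
      a <- cand[1]
      start <- fc$pos[a]
      end <- fc$pos[stop_idx[k]] + 2L
      if (start > L) next           # duplicate from the second copy
      if (end - start + 1L > L) next # would wrap more than once
      out[[length(out) + 1L]] <- c(start, end)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- unique(do.call(rbind, out))
  data.frame(start = m[, 1], end = m[, 2])
}

#' Enumerate candidate ORFs on both strands of a circular genome
#'
#' Finds every maximal ATG-initiated reading frame in all six frames, with
#' wrap-around across the origin when the genome is circular. For each stop
#' codon only the longest candidate (5'-most in-frame ATG since the previous
#' stop) is retained. Coordinates are genomic plus-strand 1-based inclusive and
#' include the stop codon; origin-wrapping candidates carry `end > length`.
#'
#' @param genome A [circular_genome()].
#' @param config An [orf_config()].
#' @return A `data.frame` with columns `start`, `end`, `strand`, `span`,
#'   `wraps_origin`, filtered to `config$min_len_nt`.
#' @export
enumerate_candidate_orfs <- function(genome, config = orf_config()) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  plus <- orfs_plus_strand(genome$seq, L, genome$circular)
  plus$strand <- rep("+", nrow(plus))
  rc <- reverse_complement(genome$seq)
  minus <- orfs_plus_strand(rc, L, genome$circular)
  if (nrow(minus) > 0) {
    # map [p, p+w-1] on the reverse complement to genomic plus coordinates
    w <- minus$end - minus$start + 1L
    ge <- L - minus$start + 1L
    gs <- ge - w + 1L
    wrap <- gs < 1L
    gs[wrap] <- gs[wrap] + L
    ge[wrap] <- ge[wrap] + L
    minus <- data.frame(start = gs, end = ge, strand = "-")
  } else {
    minus$strand <- character(0)
  }
  cand <- rbind(plus, minus)
  cand$span <- cand$end - cand$start + 1L
  cand$wraps_origin <- cand$end > L
  min_span <- if (config$count_stop_in_min_len) config$min_len_nt else
    config$min_len_nt + 3L
  cand <- cand[cand$span >= min_span, , drop = FALSE]
  cand <- cand[order(cand$start, cand$end, cand$strand), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Select a conflict-free ORF set from candidates
#'
#' Greedy longest-first selection: candidates are sorted by decreasing span
#' (ties: earlier start, then plus strand) and accepted iff their overlap with
#' every already-accepted ORF is at most `max_allowed_overlap_nt`. Serials are
#' then assigned clockwise by start coordinate.
#'
#' @param candidates Output of [enumerate_candidate_orfs()].
#' @param genome The [circular_genome()] the candidates came from.
#' @param config An [orf_config()].
#' @return A [gene_annotation()].
#' @export
select_orfs <- function(candidates, genome, config = orf_config()) {
  L <- genome$length
  if (nrow(candidates) == 0) {
    return(gene_annotation(integer(0), integer(0), character(0), genome = genome))
  }
  ord <- order(-candidates$span, candidates$start,
               match(candidates$strand, c("+", "-")))
  cand <- candidates[ord, , drop = FALSE]
  acc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in acc) {
      ov <- circ_overlap(cand$start[i], cand$end[i],
                         cand$start[j], cand$end[j], L)
      if (ov > config$max_allowed_overlap_nt) { ok <- FALSE; break }
    }
    if (ok) acc <- c(acc, i)
  }
  sel <- cand[acc, , drop = FALSE]
  gene_annotation(sel$start, sel$end, sel$strand, genome = genome)
}

#' Call ORFs on a circular genome
#'
#' Convenience wrapper: [enumerate_candidate_orfs()] followed by
#' [select_orfs()].
#'
#' @inheritParams enumerate_candidate_orfs
#' @return A [gene_annotation()].
#' @export
call_orfs <- function(genome, config = orf_config()) {
  select_orfs(enumerate_candidate_orfs(genome, config), genome, config)
}

#' Orientation split relative to an anchor ORF
#'
#' Counts how many ORFs run in the same orientation as the anchor (the anchor
#' counts itself) versus opposite.
#'
#' @param annotation A [gene_annotation()].
#' @param anchor_serial Serial of the anchor ORF (default 1, the granulin
#'   position under anchored numbering).
#' @return Named integer vector `c(same =, opposite =)`.
#' @export
orientation_split <- function(annotation, anchor_serial = 1L) {
  if (nrow(annotation) == 0) stop("empty annotation")
  k <- match(anchor_serial, annotation$serial)
  if (is.na(k)) stop("anchor serial ", anchor_serial, " not present")
  same <- sum(annotation$strand == annotation$strand[k])
  c(same = same, opposite = nrow(annotation) - same)
}

#' Coding density of an annotated genome
#'
#' Fraction of genome positions covered by the union of all ORF spans (both
#' strands projected onto the genome axis; overlaps counted once).
#'
#' @param genome A [circular_genome()].
#' @param annotation A [gene_annotation()].
#' @return A fraction in `[0, 1]`.
#' @export
coding_density <- function(genome, annotation) {
  if (nrow(annotation) == 0) return(0)
  union_width(annotation$start, annotation$end, genome$length) / genome$length
}

#' Intergenic regions of a circular annotated genome
#'
#' Complementary gaps between consecutive ORF spans on the circle. Zero-length
#' gaps (abutting ORFs) are excluded. AT content is computed over `{A,T}`
#' against `{A,C,G,T}` (N excluded).
#'
#' @param genome A [circular_genome()].
#' @param annotation A [gene_annotation()].
#' @return A `data.frame` with columns `start`, `end` (possibly wrapping, i.e.
#'   `end > length`), `length`, `at_content`, `serial_before`, `serial_after`,
#'   sorted by decreasing length.
#' @export
intergenic_regions <- function(genome, annotation) {
  L <- genome$length
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      at_content = numeric(0), serial_before = integer(0),
                      serial_after = integer(0))
  if (nrow(annotation) == 0) return(empty)
  covered <- IRanges::reduce(features_as_ranges(annotation$start,
                                                annotation$end, L))
  gaps <- IRanges::gaps(covered, start = 1L, end = L)
  gs <- IRanges::start(gaps); ge <- IRanges::end(gaps)
  # stitch the two flanks of the origin into one circular gap
  if (length(gs) >= 2 && gs[1] == 1L && ge[length(ge)] == L &&
      !(length(gs) == 1)) {
    k <- length(gs)
    gs <- c(gs[-c(1, k)], gs[k])
    ge <- c(ge[-c(1, k)], L + ge[1])
  } else if (length(gs) == 1 && gs[1] == 1L && ge[1] == L) {
    # annotation covers nothing? handled above; keep as-is
  }
  if (length(gs) == 0) return(empty)
  res <- data.frame(start = gs, end = ge)
  res$length <- res$end - res$start + 1L
  res$at_content <- vapply(seq_len(nrow(res)), function(i) {
    at_content(circ_substr(genome$seq, res$start[i], res$end[i]))
  }, numeric(1))
  # flanking serials: nearest feature end before the gap / start after it
  ends_mod <- ((annotation$end - 1L) %% L) + 1L
  res$serial_before <- vapply(seq_len(nrow(res)), function(i) {
    d <- (res$start[i] - 1L - ends_mod) %% L
    annotation$serial[which.min(d)]
  }, integer(1))
  res$serial_after <- vapply(seq_len(nrow(res)), function(i) {
    d <- (annotation$start - (((res$end[i] - 1L) %% L) + 1L) - 1L) %% L
    annotation$serial[which.min(d)]
  }, integer(1))
  res[order(-res$length, res$start), , drop = FALSE]
}

#' Longest and shortest ORF of an annotation
#'
#' Amino-acid lengths are `(span - 3) / 3`, excluding the stop codon.
#'
#' @param annotation A [gene_annotation()].
#' @return A list with `longest` and `shortest`, each a one-row data frame
#'   with an added `aa_len` column.
#' @export
extremal_orfs <- function(annotation) {
  if (nrow(annotation) == 0) stop("empty annotation")
  span <- annotation$end - annotation$start + 1L
  aa <- (span - 3L) %/% 3L
  i <- which.max(span); j <- which.min(span)
  longest <- cbind(as.data.frame(annotation[i, , drop = FALSE]), aa_len = aa[i])
  shortest <- cbind(as.data.frame(annotation[j, , drop = FALSE]), aa_len = aa[j])
  list(longest = longest, shortest = shortest)
}
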