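#' Configuration for the synthetic-genome generator
#'
#' The defaults emulate a granulovirus-sized genome: ~112 kb circular, 35.2%
#' GC, 130 ATG-initiated ORFs on both strands (anchor gene at position 1 on
#' the plus strand, a 1162-aa helicase-like gene, ~53% of genes on the anchor
#' strand), planted early/late promoter motifs at known upstream offsets,
#' planted tandem-repeat arrays (coding CAG/CAA arrays with fractional copy
#' numbers and AT-rich noncoding arrays), and six AT-rich cassettes of
#' imperfect palindromes (hrs), the largest sitting in a 757-nt intergenic
#' gap. Every planted feature is recorded in a truth table.
#'
#' @param seed Integer seed; fully determines the genome.
#' @param genome_len Genome length in nt (default 112000).
#' @param gc Target GC fraction (default 0.352).
#' @param n_orfs Number of planted ORFs (default 130).
#' @param orf_len_range Range of ORF lengths in codons excluding the stop
#'   (default 60..404).
#' @param strand_fraction_same Fraction of genes on the anchor strand
#'   (default 0.53).
#' @param promoter_plants Data frame `motif`, `literal`, `offset`, `n`:
#'   how many genes receive each upstream motif at which offset.
#' @param tr_noncoding Data frame `unit_len`, `span` of noncoding tandem
#'   arrays (units are generated AT-rich, stop-seeded, non-multiples of 3).
#' @param hr_palindromes Integer vector: palindromes per hr cassette.
#' @param hr_arm,hr_loop,hr_mismatches Palindrome geometry of planted
#'   cassettes (defaults arm 22, loop 5, 1 mismatch).
#' @param with_protein_plants Plant the six-cysteine (CBM_14) motif pair,
#'   the 13-residue poly-Q run and the fractional CAG array (default TRUE).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_len = 112000L,
                              gc = 0.352,
                              n_orfs = 130L,
                              orf_len_range = c(60L, 404L),
                              strand_fraction_same = 0.53,
                              promoter_plants = data.frame(
                                motif = c("TTAAG", "TATAWAW", "GATA", "CAKT"),
                                literal = c("TTAAG", "TATAAAT", "GATA", "CAGT"),
                                offset = c(8L, 57L, 20L, 30L),
                                n = c(12L, 8L, 6L, 6L),
                                stringsAsFactors = FALSE),
                              tr_noncoding = data.frame(
                                unit_len = c(7L, 11L, 16L, 22L, 25L, 29L, 35L, 38L),
                                span = c(32L, 44L, 56L, 66L, 105L, 87L, 112L, 118L)),
                              hr_palindromes = c(4L, 11L, 3L, 3L, 3L, 3L),
                              hr_arm = 22L, hr_loop = 5L, hr_mismatches = 1L,
                              with_protein_plants = TRUE) {
  stopifnot(genome_len >= 20000, n_orfs >= 0, gc > 0, gc < 1)
  structure(as.list(environment()), class = "simulation_config")
}

# -- low-level sequence builders ---------------------------------------------

sim_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# n sense codons (no stops) at roughly the target GC
sim_sense_codons <- function(n, gc) {
  if (n == 0) return(character(0))
  cod <- apply(matrix(sim_bases(3 * n, gc), nrow = 3), 2, paste, collapse = "")
  bad <- cod %in% STOP_CODONS
  while (any(bad)) {
    cod[bad] <- apply(matrix(sim_bases(3 * sum(bad), gc), nrow = 3), 2,
                      paste, collapse = "")
    bad <- cod %in% STOP_CODONS
  }
  cod
}

# Remove every ATG/CAT whose triplet touches an unprotected position, by
# flipping one unprotected base. Operates on a character vector in place.
sim_scrub <- function(x, protected) {
  n <- length(x)
  if (n < 3) return(x)
  repeat {
    s <- paste(x, collapse = "")
    hits <- c(gregexpr("ATG", s, fixed = TRUE)[[1]],
              gregexpr("CAT", s, fixed = TRUE)[[1]])
    hits <- hits[hits > 0]
    if (length(hits) == 0) return(x)
    fixed_any <- FALSE
    for (h in hits) {
      idx <- h:(h + 2)
      free <- idx[!protected[idx]]
      if (length(free) == 0) next
      # flip the highest-information base available
      i <- free[length(free)]
      x[i] <- sample(setdiff(c("A", "T"), x[i]), 1)
      fixed_any <- TRUE
    }
    if (!fixed_any) return(x) # fully protected occurrences stay
  }
}

# Coding-orientation upstream overlay: guard stop (TAA, in frame) at distance
# d, optional motif with its 3' end `off` bases before the ATG. Returns the
# window (character vector, last element adjacent to the ATG) and its length.
sim_upstream_window <- function(off = 0L, literal = NULL, gc) {
  len <- if (is.null(literal)) 0L else nchar(literal)
  d <- max(6L, as.integer(3 * ceiling((off + len + 3) / 3)))
  win <- sim_bases(d, gc)
  win[1:3] <- c("T", "A", "A") # in-frame guard stop
  if (!is.null(literal)) {
    win[(d - off - len + 1):(d - off)] <- strsplit(literal, "")[[1]]
  }
  prot <- rep(FALSE, d)
  prot[1:3] <- TRUE
  if (!is.null(literal)) prot[(d - off - len + 1):(d - off)] <- TRUE
  win <- sim_scrub(win, prot)
  win
}

# AT-rich tandem unit of length u (not a multiple of 3) containing the stop
# seeds TAA and TTA and free of ATG/CAT.
sim_tr_unit <- function(u) {
  stopifnot(u >= 7, u %% 3 != 0)
  repeat {
    unit <- sim_bases(u, gc = 0.25)
    unit[1:3] <- c("T", "A", "A")
    unit[5:7] <- c("T", "T", "A")
    unit <- sim_scrub(unit, rep(FALSE, u))
    s2 <- paste(c(unit, unit), collapse = "")
    if (!grepl("ATG|CAT", s2)) return(unit)
  }
}

# A noncoding array of `span` nt built from a unit of length u, verified to
# contain no incidental inverted repeat that a genome-scale palindrome scan
# (arm >= 20, <= 2 mismatches) could call: units are resampled until clean.
sim_tr_array <- function(u, span) {
  repeat {
    unit <- sim_tr_unit(u)
    arr <- rep(unit, length.out = span)
    pal <- .scan_palindromes(paste(arr, collapse = ""), 18L, 20L, 2L)
    if (nrow(pal) == 0) {
      # anti-match flanks: the bases adjacent to the array must break the
      # periodicity so detected boundaries match the planted span exactly
      antiL <- setdiff(c("A", "T"), arr[u])[1]
      partnerR <- arr[span - u + 1L]
      last2 <- paste(arr[c(span - 1L, span)], collapse = "")
      antiR <- NA_character_
      for (b in c(setdiff(c("A", "T"), partnerR), "G", "C")) {
        if (b == partnerR) next
        if (last2 == "CA" && b == "T") next # would write CAT
        if (last2 == "AT" && b == "G") next # would write ATG
        antiR <- b
        break
      }
      return(list(unit = unit, arr = c(antiL, arr, antiR), pad = 1L))
    }
  }
}

# One imperfect palindrome: arm + loop + reverse-complemented arm with `mm`
# substitutions in the right arm; ATG/CAT-free.
sim_palindrome <- function(arm, loop, mm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  repeat {
    a <- sim_bases(arm, gc = 0.27)
    lp <- if (loop > 0) sim_bases(loop, gc = 0.27) else character(0)
    right <- rev(unname(comp[a]))
    if (mm > 0) {
      pos <- sample(seq_len(arm - 2), mm) + 1 # keep terminal pairs intact
      for (p in pos) right[p] <- sample(setdiff(DNA_BASES, right[p]), 1)
    }
    pal <- c(a, lp, right)
    if (!grepl("ATG|CAT", paste(pal, collapse = ""))) {
      return(list(seq = pal, arm = arm, loop = loop, mm = mm))
    }
  }
}

# -- gene construction --------------------------------------------------------

# Build one gene's coding string (codons incl ATG and final TAA) plus records
# of protected codon indices and in-gene planted features (gene-local nt
# coordinates, 1-based from the A of ATG).
sim_gene <- function(n_aa, gc, special = NULL) {
  codons <- c("ATG", sim_sense_codons(n_aa - 1L, gc), "TAA")
  protected <- c(1L, length(codons)) # never touch start/stop
  plants <- list()
  if (!is.null(special) && special == "chit") {
    # exactly two six-cysteine motifs and one 13-residue poly-Q run
    stopifnot(n_aa >= 173)
    cys <- c(40, 54, 60, 70, 81, 95, 99, 113, 119, 129, 140, 154)
    isC <- vapply(codons, function(cd) substr(cd, 1, 2) == "TG" &&
                    substr(cd, 3, 3) %in% c("T", "C"), logical(1))
    codons[isC] <- "TCT" # no stray cysteines elsewhere
    codons[cys] <- "TGC"
    codons[155] <- "TTT"
    codons[156:168] <- "CAA"
    codons[169] <- "TCT"
    isQ <- codons %in% c("CAA", "CAG")
    isQ[156:168] <- FALSE
    codons[isQ] <- "AAT" # no stray glutamines
    protected <- c(protected, cys, 155:169)
    plants$cys <- data.frame(start_aa = c(40, 99), end_aa = c(95, 154))
    plants$polyq <- data.frame(start_aa = 156, end_aa = 168)
    plants$tr <- data.frame(start = (156 - 1) * 3 + 1, end = 168 * 3,
                            unit_len = 3, copy_number = 13.0,
                            placement = "coding")
  }
  if (!is.null(special) && special == "tr6") {
    # fractional CAG array: 12 full copies + 1 nt = 12.3 copies
    stopifnot(n_aa >= 115)
    codons[99] <- "TTT"
    codons[100:111] <- "CAG"
    codons[112] <- "CCT"
    protected <- c(protected, 99:112)
    plants$tr <- data.frame(start = (100 - 1) * 3 + 1,
                            end = (100 - 1) * 3 + 37,
                            unit_len = 3, copy_number = 12.3,
                            placement = "coding")
  }
  list(codons = codons, protected_codons = sort(unique(protected)),
       plants = plants)
}

# -- six-frame open-run accounting -------------------------------------------

# Maximal stop-free runs (nt spans, circle-aware via doubling) in all six
# frames. Returns a data.frame: start (1..L), len, strand; start is the first
# nt of the first stop-free codon, in plus coordinates of the first copy.
sim_stop_runs <- function(seqvec, L, min_len) {
  runs <- list()
  s2 <- paste(c(seqvec, seqvec), collapse = "")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") s2 else reverse_complement(s2)
    for (frame in 0:2) {
      fc <- frame_codons(s, frame)
      open <- !(fc$codon %in% STOP_CODONS)
      r <- rle(open)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      sel <- which(r$values & r$lengths * 3L >= min_len)
      for (k in sel) {
        nt_start <- fc$pos[starts[k]]
        nt_len <- r$lengths[k] * 3L
        if (strand == "-") {
          # map to plus coordinates of the doubled sequence
          nt_end_rc <- nt_start + nt_len - 1L
          nt_start <- 2L * L - nt_end_rc + 1L
        }
        s0 <- ((nt_start - 1L) %% L) + 1L
        runs[[length(runs) + 1L]] <- data.frame(start = s0, len = nt_len,
                                                strand = strand)
      }
    }
  }
  if (length(runs) == 0) {
    return(data.frame(start = integer(0), len = integer(0),
                      strand = character(0)))
  }
  unique(do.call(rbind, runs))
}

# Break every non-exempt stop-free run >= min_len by writing a stop codon
# (spacer positions) or substituting a sense codon (gene positions).
sim_repair <- function(seqvec, L, region, gene_tab, gene_prot, min_len = 141L) {
  exempt <- function(run) {
    # the planted genes' own coding runs (which may extend a little into the
    # guard-protected upstream filler) are allowed
    for (g in seq_len(nrow(gene_tab))) {
      if (gene_tab$strand[g] != run$strand) next
      gs <- gene_tab$start[g]; ge <- gene_tab$end[g]
      core <- if (run$strand == "+") c(gs, ge - 3L) else c(gs + 3L, ge)
      # does the run span contain the gene's sense-codon core (circularly)?
      off <- ((core[1] - run$start) %% L)
      if (off + (core[2] - core[1]) <= run$len - 1L) return(TRUE)
    }
    FALSE
  }
  sense <- setdiff(mkAllCodons(), c(STOP_CODONS, "TGT", "TGC", "CAA", "CAG",
                                    "ATG"))
  for (iter in 1:40) {
    runs <- sim_stop_runs(seqvec, L, min_len)
    runs <- runs[runs$len >= min_len, , drop = FALSE]
    if (nrow(runs) > 0) {
      runs <- runs[!vapply(seq_len(nrow(runs)), function(i) exempt(runs[i, ]),
                           logical(1)), , drop = FALSE]
    }
    if (nrow(runs) == 0) return(seqvec)
    for (i in seq_len(nrow(runs))) {
      seqvec <- sim_break_run(seqvec, L, runs[i, ], region, gene_tab,
                              gene_prot, sense)
    }
  }
  stop("open-reading-frame repair did not converge")
}

mkAllCodons <- function() {
  apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = "")
}

# Stop triplets (either strand) whose span overlaps positions `touched`.
sim_local_stops <- function(seqvec, L, touched) {
  qs <- unique(as.vector(vapply(touched, function(p) p - 2:0, numeric(3))))
  qs <- ((qs - 1L) %% L) + 1L
  hits <- character(0)
  for (q in qs) {
    idx <- ((q + 0:2 - 1L) %% L) + 1L
    tri <- paste(seqvec[idx], collapse = "")
    if (tri %in% c(STOP_CODONS, "TTA", "CTA", "TCA")) {
      hits <- c(hits, paste0(q, ":", tri))
    }
  }
  hits
}

# Write one stop into `run`, searching codon-aligned slots outwards from the
# run centre. Repairs must not erase stops already present in other frames
# (which would make the pass oscillate); a destructive write is a last resort.
sim_break_run <- function(seqvec, L, run, region, gene_tab, gene_prot, sense) {
  n_slots <- run$len %/% 3L
  centre <- n_slots %/% 2L
  order_slots <- centre + c(0L, as.vector(rbind(seq_len(n_slots), -seq_len(n_slots))))
  order_slots <- order_slots[order_slots >= 1L & order_slots <= n_slots - 1L]
  fallback <- NULL
  for (k in order_slots) {
    # slot k: codon offset k within the run, in run orientation
    if (run$strand == "+") {
      p <- ((run$start + 3L * k - 1L) %% L) + 1L
    } else {
      p <- ((run$start + run$len - 3L * k - 3L - 1L) %% L) + 1L
    }
    idx <- ((p + 0:2 - 1L) %% L) + 1L
    reg <- region[idx]
    if (all(reg == "spacer")) {
      before <- sim_local_stops(seqvec, L, idx)
      trial <- seqvec
      trial[idx] <- if (run$strand == "+") c("T", "A", "A") else
        c("T", "T", "A")
      after <- sim_local_stops(trial, L, idx)
      if (all(before %in% after)) return(trial)
      if (is.null(fallback)) fallback <- trial
      next
    }
    g <- unique(gene_tab$gene_id[match_gene(idx, gene_tab, L)])
    g <- g[!is.na(g)]
    if (length(g) != 1 || any(reg != "gene")) next
    out <- sim_sub_codon(seqvec, L, gene_tab[gene_tab$gene_id == g, ],
                         gene_prot[[g]], idx, run$strand, sense)
    if (!is.null(out$safe)) return(out$safe)
    if (is.null(fallback) && !is.null(out$any)) fallback <- out$any
  }
  if (!is.null(fallback)) return(fallback)
  stop("no repairable slot in an open run at ", run$start,
       " (strand ", run$strand, ")")
}

match_gene <- function(idx, gene_tab, L) {
  vapply(idx, function(p) {
    hit <- which(((p - gene_tab$start) %% L) <= (gene_tab$end - gene_tab$start))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

# Substitute one (or two) codons of gene `g` so that a stop appears, in the
# run's strand, inside the 3 positions `slot_idx`. Returns the new sequence
# vector or NULL.
sim_sub_codon <- function(seqvec, L, g, protected_codons, slot_idx, run_strand,
                          sense) {
  gi <- function(p) ((p - g$start) %% L) + 1L # gene-local nt index (plus order)
  loc <- gi(slot_idx)
  cods <- sort(unique((loc - 1L) %/% 3L + 1L))
  n_cod <- (g$end - g$start + 1L) %/% 3L
  # protected indices are in coding order; convert for minus-strand genes
  prot_plus <- if (g$strand == "+") protected_codons else
    n_cod - protected_codons + 1L
  cods <- cods[!(cods %in% prot_plus)]
  cods <- cods[cods >= 2L & cods <= n_cod - 1L]
  slot_idx <- ((slot_idx - 1L) %% L) + 1L
  any_fix <- NULL
  for (cd in cods) {
    pos <- ((g$start + (cd - 1L) * 3L + 0:2 - 1L) %% L) + 1L
    cur_plus <- paste(seqvec[pos], collapse = "")
    before <- sim_local_stops(seqvec, L, pos)
    for (repl in sense) {
      # genes on the minus strand are stored reverse-complemented on plus
      new_plus <- if (g$strand == "+") repl else fast_revcomp(repl)
      if (new_plus == cur_plus) next
      newv <- strsplit(new_plus, "")[[1]]
      tri_bases <- vapply(slot_idx, function(p) {
        hit <- match(p, pos)
        if (is.na(hit)) seqvec[p] else newv[hit]
      }, character(1))
      tri <- paste(tri_bases, collapse = "")
      if (run_strand == "-") tri <- fast_revcomp(tri)
      if (tri %in% STOP_CODONS) {
        trial <- seqvec
        trial[pos] <- newv
        if (all(before %in% sim_local_stops(trial, L, pos))) {
          return(list(safe = trial, any = trial))
        }
        if (is.null(any_fix)) any_fix <- trial
      }
    }
  }
  if (is.null(any_fix)) NULL else list(safe = NULL, any = any_fix)
}

COMP_BASE <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Can position p be set to base b without destroying a stop triplet (either
# strand) or creating ATG/CAT?
sim_flip_ok <- function(vec, L, p, b) {
  stops6 <- c(STOP_CODONS, "TTA", "CTA", "TCA")
  for (q in max(1L, p - 2L):min(L - 2L, p)) {
    if (paste(vec[q:(q + 2L)], collapse = "") %in% stops6) return(FALSE)
  }
  old <- vec[p]
  vec[p] <- b
  ok <- TRUE
  for (q in max(1L, p - 2L):min(L - 2L, p)) {
    if (paste(vec[q:(q + 2L)], collapse = "") %in% c("ATG", "CAT")) {
      ok <- FALSE
      break
    }
  }
  vec[p] <- old
  ok
}

# Break every inverted repeat that the genome-scale palindrome scan would
# call but that was not planted: three pairs of the inner arm are mutated so
# that no 18-pair window stays within the mismatch budget. Spacer bases are
# flipped directly; gene bases via sense-codon substitution.
sim_clean_palindromes <- function(vec, region, pal_spans, gene_tab, gene_prot,
                                  L) {
  sense <- setdiff(mkAllCodons(), c(STOP_CODONS, "TGT", "TGC", "CAA", "CAG",
                                    "ATG"))
  for (iter in 1:10) {
    g <- circular_genome(paste(vec, collapse = ""), id = "tmp")
    calls <- find_palindromes(g, min_arm = 18L, max_loop = 20L,
                              max_mismatch = 2L, dedupe = TRUE)
    if (nrow(calls) > 0 && nrow(pal_spans) > 0) {
      keep <- vapply(seq_len(nrow(calls)), function(i) {
        !any(pmin(calls$end[i], pal_spans$end) -
               pmax(calls$start[i], pal_spans$start) + 1 > 0)
      }, logical(1))
      calls <- calls[keep, , drop = FALSE]
    }
    if (nrow(calls) == 0) return(vec)
    for (i in seq_len(nrow(calls))) {
      cl <- calls[i, ]
      broken <- 0L
      for (d in c(4L, 9L, 14L, seq_len(cl$arm_len))) {
        if (broken >= 3L) break
        if (d > cl$arm_len) next
        li <- ((cl$center - d) %% L) + 1L
        ri <- ((cl$center + cl$loop_len + d - 1L) %% L) + 1L
        if (vec[li] != COMP_BASE[vec[ri]]) next # already a mismatch
        done <- FALSE
        for (p in c(li, ri)) {
          other <- if (p == li) ri else li
          bad <- c(vec[p], COMP_BASE[vec[other]])
          for (b in setdiff(DNA_BASES, bad)) {
            if (region[p] == "spacer" && sim_flip_ok(vec, L, p, b)) {
              vec[p] <- b
              done <- TRUE
              break
            }
            if (region[p] == "gene") {
              gid <- match_gene(p, gene_tab, L)
              if (is.na(gid)) next
              gtab <- gene_tab[gid, ]
              out <- sim_gene_flip(vec, L, gtab, gene_prot[[gtab$gene_id]],
                                   p, b, sense)
              if (!is.null(out)) {
                vec <- out
                done <- TRUE
                break
              }
            }
          }
          if (done) break
        }
        if (done) broken <- broken + 1L
      }
    }
  }
  vec
}

# Substitute the sense codon containing plus-position p so that the base at p
# becomes b, preserving local stops. Returns new vector or NULL.
sim_gene_flip <- function(vec, L, g, protected_codons, p, b, sense) {
  loc <- ((p - g$start) %% L) + 1L
  cd <- (loc - 1L) %/% 3L + 1L
  n_cod <- (g$end - g$start + 1L) %/% 3L
  prot_plus <- if (g$strand == "+") protected_codons else
    n_cod - protected_codons + 1L
  if (cd %in% prot_plus || cd < 2L || cd > n_cod - 1L) return(NULL)
  pos <- ((g$start + (cd - 1L) * 3L + 0:2 - 1L) %% L) + 1L
  k <- match(p, pos)
  before <- sim_local_stops(vec, L, pos)
  for (repl in sense) {
    new_plus <- if (g$strand == "+") repl else fast_revcomp(repl)
    newv <- strsplit(new_plus, "")[[1]]
    if (newv[k] != b) next
    trial <- vec
    trial[pos] <- newv
    if (all(before %in% sim_local_stops(trial, L, pos))) return(trial)
  }
  NULL
}

# Nudge the assembled genome to the target GC by flipping free spacer bases.
# A position is eligible only if it is not part of any stop triplet on either
# strand (so the open-run guarantees stay intact) and the flip creates no
# ATG/CAT.
sim_tune_gc <- function(vec, region, target, tol = 0.002) {
  L <- length(vec)
  stops6 <- c(STOP_CODONS, "TTA", "CTA", "TCA")
  tri_at <- function(v, q) paste(v[q:(q + 2L)], collapse = "")
  ok_flip <- function(p, b) {
    for (q in max(1L, p - 2L):min(L - 2L, p)) {
      if (tri_at(vec, q) %in% stops6) return(FALSE)
    }
    old <- vec[p]
    vec[p] <- b
    bad <- FALSE
    for (q in max(1L, p - 2L):min(L - 2L, p)) {
      if (tri_at(vec, q) %in% c("ATG", "CAT")) { bad <- TRUE; break }
    }
    vec[p] <- old
    !bad
  }
  repeat {
    gc_now <- sum(vec %in% c("G", "C")) / L
    delta <- round((target - gc_now) * L)
    if (abs(gc_now - target) <= tol || delta == 0) return(vec)
    src <- if (delta > 0) c("A", "T") else c("G", "C")
    dst <- if (delta > 0) c("G", "C") else c("A", "T")
    cand <- which(region == "spacer" & vec %in% src)
    if (length(cand) == 0) return(vec)
    cand <- sample(cand)
    flipped <- 0L
    for (p in cand) {
      b <- sample(dst, 1)
      if (ok_flip(p, b)) {
        vec[p] <- b
        flipped <- flipped + 1L
        if (flipped >= abs(delta)) break
      }
    }
    if (flipped == 0L) return(vec) # nothing more can move
  }
}

#' Simulate a circular genome with a full truth table
#'
#' Generates a genome under `config` in which every planted feature is
#' recoverable by the corresponding detector: genes are ATG-initiated sense
#' codon runs; intergenic spacers carry an in-frame guard stop upstream of
#' every gene, are free of ATG/CAT outside planted features, and a genome-wide
#' repair pass breaks every non-planted stop-free stretch of 141 nt or more in
#' all six frames, so no spurious ORF of >= 150 coding nt can exist. Promoter
#' motifs, tandem arrays, and palindrome cassettes are written at recorded
#' coordinates. Output is fully determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` ([circular_genome()]), `truth` (list of data
#'   frames: `orfs` as a [gene_annotation()], `motif_hits`, `repeats`,
#'   `palindromes`, `hrs`, `proteins`), and `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, sim_genome_impl(config))
}

sim_genome_impl <- function(cfg) {
  L <- cfg$genome_len
  n <- cfg$n_orfs
  gene_gc <- min(0.95, cfg$gc + 0.012) # spacers run AT-richer than genes

  if (n == 0) {
    vec <- sim_bases(L, cfg$gc)
    region <- rep("spacer", L)
    vec <- sim_repair(vec, L, region,
                      data.frame(gene_id = integer(0), start = integer(0),
                                 end = integer(0), strand = character(0)),
                      list(), min_len = 141L)
    g <- circular_genome(paste(vec, collapse = ""), id = "sim")
    return(list(genome = g,
                truth = list(orfs = gene_annotation(integer(0), integer(0),
                                                    character(0), genome = g)),
                config = cfg))
  }

  # --- gene roster -----------------------------------------------------------
  aa <- sample(seq(cfg$orf_len_range[1], cfg$orf_len_range[2]), n,
               replace = TRUE)
  special <- rep("", n)
  labels <- rep("orf", n)
  labels[1] <- "granulin"; aa[1] <- 248
  if (n >= 10) {
    slots <- sample(2:n, 4)
    special[slots[1]] <- "helicase"; aa[slots[1]] <- 1162
    labels[slots[1]] <- "helicase"
    if (cfg$with_protein_plants) {
      special[slots[2]] <- "chit"; aa[slots[2]] <- 173; labels[slots[2]] <- "chit1"
      special[slots[3]] <- "tr6"; aa[slots[3]] <- 333; labels[slots[3]] <- "hypothetical"
    }
    labels[slots[4]] <- "bro"
    bro2 <- sample(setdiff(2:n, slots), 1)
    labels[bro2] <- "bro"
    core <- core_gene_names()
    core <- setdiff(core, "helicase")
    free <- setdiff(2:n, c(slots, bro2))
    take <- sample(free, min(length(core), length(free)))
    labels[take] <- core[seq_along(take)]
  }
  strands <- c("+", ifelse(runif(n - 1) < cfg$strand_fraction_same, "+", "-"))
  genes <- lapply(seq_len(n), function(i) {
    sp <- if (special[i] %in% c("chit", "tr6")) special[i] else NULL
    sim_gene(aa[i], gene_gc, sp)
  })
  spans <- vapply(genes, function(g) 3L * length(g$codons), integer(1))

  # --- plant assignment ------------------------------------------------------
  pp <- cfg$promoter_plants
  promoter_genes <- list()
  used <- integer(0)
  chit_i <- which(special == "chit")
  if (length(chit_i)) {
    promoter_genes[["TTAAG"]] <- chit_i
    used <- chit_i
  }
  for (r in seq_len(nrow(pp))) {
    want <- pp$n[r] - length(promoter_genes[[pp$motif[r]]])
    if (want <= 0) next
    pool <- setdiff(seq_len(n), used)
    pick <- sample(pool, min(want, length(pool)))
    promoter_genes[[pp$motif[r]]] <- c(promoter_genes[[pp$motif[r]]], pick)
    used <- c(used, pick)
  }

  n_hr <- length(cfg$hr_palindromes)
  hr_spacers <- if (n_hr > 0) {
    round(seq(3, n - 2, length.out = n_hr)) # spacer i sits before gene i
  } else integer(0)
  tr_pool <- setdiff(seq(2, n), hr_spacers)
  tr_spacers <- sample(tr_pool, nrow(cfg$tr_noncoding))

  # --- per-spacer requirements and gap allocation ---------------------------
  # spacer i precedes gene i (spacer 1 wraps: it sits at the genome end)
  ov_right <- vector("list", n) # upstream overlay of gene i (coding orientation)
  for (i in seq_len(n)) {
    lit <- NULL; off <- 0L
    for (m in names(promoter_genes)) {
      if (i %in% promoter_genes[[m]]) {
        r <- which(pp$motif == m)[1]
        lit <- pp$literal[r]; off <- pp$offset[r]
      }
    }
    ov_right[[i]] <- sim_upstream_window(off, lit, gc = 0.29)
  }
  plant_seq <- vector("list", n)
  plant_meta <- vector("list", n)
  for (k in seq_along(tr_spacers)) {
    i <- tr_spacers[k]
    u <- cfg$tr_noncoding$unit_len[k]; spn <- cfg$tr_noncoding$span[k]
    built <- sim_tr_array(u, spn)
    unit <- built$unit
    arr <- built$arr
    plant_seq[[i]] <- c(plant_seq[[i]], list(arr))
    plant_meta[[i]] <- c(plant_meta[[i]], list(list(
      type = "tr", unit_len = u, span = spn, pad = built$pad,
      copy_number = round(spn / u, 1),
      consensus = paste(unit, collapse = ""))))
  }
  hr_truth_local <- vector("list", n)
  for (k in seq_along(hr_spacers)) {
    i <- hr_spacers[k]
    npal <- cfg$hr_palindromes[k]
    gapw <- if (npal >= 8) 14L else 30L
    repeat {
      pieces <- list(); pals <- list(); pos <- 1L
      for (q in seq_len(npal)) {
        pal <- sim_palindrome(cfg$hr_arm, cfg$hr_loop, cfg$hr_mismatches)
        pieces[[length(pieces) + 1L]] <- pal$seq
        pals[[q]] <- data.frame(local_start = pos,
                                local_end = pos + length(pal$seq) - 1L,
                                arm_len = pal$arm, loop_len = pal$loop,
                                mismatches = pal$mm)
        pos <- pos + length(pal$seq)
        if (q < npal) {
          filler <- sim_scrub(sim_bases(gapw, 0.27), rep(FALSE, gapw))
          pieces[[length(pieces) + 1L]] <- filler
          pos <- pos + gapw
        }
      }
      cassette <- unlist(pieces)
      pal_tab <- do.call(rbind, pals)
      # the cassette must yield exactly the planted loci under a stricter
      # scan than the genome-scale one (one deduped call per palindrome)
      chk <- find_palindromes(paste(cassette, collapse = ""), min_arm = 18L,
                              max_loop = 20L, max_mismatch = 2L, dedupe = TRUE)
      if (nrow(chk) == npal &&
          all(abs(sort(chk$start) - pal_tab$local_start) <= 8)) break
    }
    cass_prot <- rep(FALSE, length(cassette))
    for (q in seq_len(nrow(pal_tab))) {
      cass_prot[pal_tab$local_start[q]:pal_tab$local_end[q]] <- TRUE
    }
    plant_seq[[i]] <- c(plant_seq[[i]], list(cassette))
    plant_meta[[i]] <- c(plant_meta[[i]], list(list(
      type = "hr", pals = pal_tab, hr_index = k, prot = cass_prot)))
  }

  margin <- 12L
  req <- vapply(seq_len(n), function(i) {
    left_gene <- if (i == 1) n else i - 1L
    wl <- if (strands[left_gene] == "-") length(ov_right[[left_gene]]) else 0L
    wr <- if (strands[i] == "+") length(ov_right[[i]]) else 0L
    plants <- sum(vapply(plant_seq[[i]], length, integer(1)))
    nplant <- length(plant_seq[[i]])
    wl + wr + plants + margin * (nplant + 2L)
  }, integer(1))
  budget <- L - sum(spans)
  base_gap <- pmax(req, 60L)
  # the hr cassette with the most palindromes sits in a 757-nt gap
  if (n_hr > 0) {
    big <- hr_spacers[which.max(cfg$hr_palindromes)]
    base_gap[big] <- max(base_gap[big], 757L)
  }
  if (budget < sum(base_gap)) {
    stop("infeasible packing: genes + planted features exceed genome_len")
  }
  extra <- budget - sum(base_gap)
  add <- if (extra > 0) {
    tabulate(sample(seq_len(n), extra, replace = TRUE), nbins = n)
  } else rep(0L, n)
  if (n_hr > 0) { # keep the 757-nt gap the designated size
    base_gap <- base_gap + add - (if (extra > 0) 0L else 0L)
    shift <- base_gap[big] - max(757L, req[big])
    if (shift > 0) {
      base_gap[big] <- base_gap[big] - shift
      base_gap[if (big == 1L) 2L else 1L] <-
        base_gap[if (big == 1L) 2L else 1L] + shift
    }
    gaps <- base_gap
  } else {
    gaps <- base_gap + add
  }

  # --- assembly --------------------------------------------------------------
  vec <- character(L)
  region <- character(L)
  gene_start <- integer(n); gene_end <- integer(n)
  truth_repeats <- list(); truth_pals <- list(); truth_hr <- list()
  truth_motifs <- list()
  pos <- 1L
  put <- function(chars, at, what) {
    idx <- ((at + seq_along(chars) - 2L) %% L) + 1L
    vec[idx] <<- chars
    region[idx] <<- what
  }
  for (i in seq_len(n)) {
    # gene i
    gene_plus <- unlist(strsplit(genes[[i]]$codons, ""))
    if (strands[i] == "-") {
      gene_plus <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[gene_plus]))
    }
    gene_start[i] <- pos
    gene_end[i] <- pos + spans[i] - 1L
    put(gene_plus, pos, "gene")
    pos <- pos + spans[i]
    # spacer following gene i = spacer of gene i+1 (spacer 1 is the last one)
    sp_i <- if (i == n) 1L else i + 1L
    Gap <- gaps[sp_i]
    sp <- sim_bases(Gap, 0.27)
    prot <- rep(FALSE, Gap)
    # left overlay: upstream of gene i if it is on the minus strand
    if (strands[i] == "-") {
      w <- ov_right[[i]]
      ov <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[w]))
      sp[seq_along(ov)] <- ov
      prot[seq_along(ov)] <- TRUE
    }
    # right overlay: upstream of gene sp_i if on the plus strand
    nxt <- sp_i
    if (strands[nxt] == "+") {
      w <- ov_right[[nxt]]
      sp[(Gap - length(w) + 1L):Gap] <- w
      prot[(Gap - length(w) + 1L):Gap] <- TRUE
    }
    # plants in the middle
    pl_at <- (if (strands[i] == "-") length(ov_right[[i]]) else 0L) + margin + 1L
    for (k in seq_along(plant_seq[[sp_i]])) {
      chars <- plant_seq[[sp_i]][[k]]
      meta <- plant_meta[[sp_i]][[k]]
      sp[pl_at:(pl_at + length(chars) - 1L)] <- chars
      # protect planted features; hr cassette gap fillers stay repairable
      piece_prot <- if (!is.null(meta$prot)) meta$prot else
        rep(TRUE, length(chars))
      prot[pl_at:(pl_at + length(chars) - 1L)] <- piece_prot
      abs0 <- pos + pl_at - 1L # absolute genome position of plant start
      if (meta$type == "tr") {
        truth_repeats[[length(truth_repeats) + 1L]] <- data.frame(
          start = abs0 + meta$pad, end = abs0 + meta$pad + meta$span - 1L,
          unit_len = meta$unit_len,
          copy_number = meta$copy_number, placement = "noncoding")
      } else {
        p <- meta$pals
        truth_pals[[length(truth_pals) + 1L]] <- data.frame(
          start = abs0 + p$local_start - 1L, end = abs0 + p$local_end - 1L,
          arm_len = p$arm_len, loop_len = p$loop_len,
          mismatches = p$mismatches, hr = meta$hr_index)
        truth_hr[[length(truth_hr) + 1L]] <- data.frame(
          hr = meta$hr_index, start = abs0 + min(p$local_start) - 1L,
          end = abs0 + max(p$local_end) - 1L, n_palindromes = nrow(p))
      }
      pl_at <- pl_at + length(chars) + margin
    }
    sp <- sim_scrub(sp, prot)
    put(sp, pos, "spacer")
    # re-mark plant/overlay positions so the repair pass never touches them
    pr_idx <- ((pos + which(prot) - 2L) %% L) + 1L
    region[pr_idx] <- "plant"
    pos <- pos + Gap
  }
  stopifnot(pos == L + 1L)

  gene_tab <- data.frame(gene_id = seq_len(n), start = gene_start,
                         end = gene_end, strand = strands)
  gene_prot <- lapply(genes, `[[`, "protected_codons")
  vec <- sim_repair(vec, L, region, gene_tab, gene_prot, min_len = 141L)
  pal_spans <- if (length(truth_pals)) {
    do.call(rbind, truth_pals)[, c("start", "end")]
  } else data.frame(start = integer(0), end = integer(0))
  vec <- sim_clean_palindromes(vec, region, pal_spans, gene_tab, gene_prot, L)
  vec <- sim_tune_gc(vec, region, cfg$gc)

  genome <- circular_genome(paste(vec, collapse = ""), id = "sim")
  ann <- gene_annotation(gene_start, gene_end, strands, labels, genome)

  # in-gene planted repeats (gene-local -> genomic coordinates)
  for (i in seq_len(n)) {
    tr <- genes[[i]]$plants$tr
    if (is.null(tr)) next
    if (strands[i] == "+") {
      s0 <- gene_start[i] + tr$start - 1L
      e0 <- gene_start[i] + tr$end - 1L
    } else {
      e0 <- gene_end[i] - tr$start + 1L
      s0 <- gene_end[i] - tr$end + 1L
    }
    truth_repeats[[length(truth_repeats) + 1L]] <- data.frame(
      start = s0, end = e0, unit_len = tr$unit_len,
      copy_number = tr$copy_number, placement = "coding")
  }

  # motif truth (serials == gene index: genes are laid out in start order)
  for (m in names(promoter_genes)) {
    r <- which(pp$motif == m)[1]
    for (i in promoter_genes[[m]]) {
      truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
        orf_serial = i, motif_name = m, matched_literal_coding = pp$literal[r],
        offset_nt = pp$offset[r])
    }
  }

  prot_truth <- list()
  if (cfg$with_protein_plants && any(special == "chit")) {
    ci <- which(special == "chit")
    prot_truth <- list(cys_serial = ci,
                       cys_hits = genes[[ci]]$plants$cys,
                       polyq_serial = ci,
                       polyq = genes[[ci]]$plants$polyq)
  }

  truth <- list(
    orfs = ann,
    motif_hits = if (length(truth_motifs)) do.call(rbind, truth_motifs) else
      data.frame(),
    repeats = if (length(truth_repeats)) {
      x <- do.call(rbind, truth_repeats); x[order(x$start), ]
    } else data.frame(),
    palindromes = if (length(truth_pals)) {
      x <- do.call(rbind, truth_pals); x[order(x$start), ]
    } else data.frame(),
    hrs = if (length(truth_hr)) {
      x <- do.call(rbind, truth_hr); x[order(x$start), ]
    } else data.frame(),
    proteins = prot_truth
  )
  list(genome = genome, truth = truth, config = cfg)
}

core_gene_names <- function() {
  ref <- tryCatch(core_gene_reference(), error = function(e) NULL)
  if (is.null(ref)) return(character(0))
  ref$gene
}

#' Apply gene-order inversions to an annotation
#'
#' Reverses the gene order (and flips strands) within each serial span,
#' repositioning genes over the original coordinate slots so the genome
#' layout stays valid. Used to create known synteny/inversion truth for
#' testing gene-order comparison.
#'
#' @param annotation A [gene_annotation()].
#' @param inversions List of `c(from_serial, to_serial)` spans (inclusive);
#'   spans must not overlap.
#' @return A [gene_annotation()] with attributes `source_serial` (original
#'   serial of each feature, in new serial order) and `truth_blocks` (number
#'   of colinear blocks implied by the inversions).
#' @export
perturb_gene_order <- function(annotation, inversions) {
  n <- nrow(annotation)
  if (length(inversions)) {
    m <- do.call(rbind, lapply(inversions, function(x) sort(as.integer(x))))
    if (any(m[, 1] < 1 | m[, 2] > n)) stop("inversion span out of range")
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2])) {
      stop("overlapping inversion spans")
    }
  }
  ord <- seq_len(n)
  strand <- annotation$strand
  for (iv in inversions) {
    iv <- sort(as.integer(iv))
    seg <- iv[1]:iv[2]
    ord[seg] <- rev(ord[seg])
  }
  # reposition genes over the original slots, preserving gap structure
  L <- attr(annotation, "genome_length")
  lens <- annotation$end - annotation$start + 1L
  gaps <- c(annotation$start[1] - 1L,
            annotation$start[-1] - annotation$end[-n] - 1L)
  new_lens <- lens[ord]
  starts <- integer(n); pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i] + 1L
    starts[i] <- pos
    pos <- pos + new_lens[i] - 1L
  }
  new_strand <- strand[ord]
  for (iv in inversions) {
    seg <- iv[1]:iv[2]
    new_strand[seg] <- ifelse(new_strand[seg] == "+", "-", "+")
  }
  out <- gene_annotation(starts, starts + new_lens - 1L, new_strand,
                         annotation$label[ord], L)
  attr(out, "source_serial") <- annotation$serial[ord]
  attr(out, "truth_blocks") <- if (length(inversions)) {
    m <- do.call(rbind, lapply(inversions, function(x) sort(as.integer(x))))
    m <- m[order(m[, 1]), , drop = FALSE]
    plain <- (m[1, 1] > 1) + (m[nrow(m), 2] < n)
    if (nrow(m) > 1) plain <- plain + sum(m[-1, 1] - m[-nrow(m), 2] > 1)
    nrow(m) + plain
  } else 1L
  out
}

#' Mutate protein sequences by random substitutions
#'
#' Independent per-residue substitutions to a uniformly chosen different
#' standard amino acid, used to build diverged ortholog sets with known
#' pairing truth.
#'
#' @param proteins Named character vector.
#' @param rate Per-residue substitution probability.
#' @param seed Integer seed.
#' @return Named character vector of mutated proteins.
#' @export
mutate_proteins <- function(proteins, rate = 0.1, seed = 1L) {
  aa20 <- names(AA_RESIDUE_MASS)
  with_seed(seed, {
    vapply(proteins, function(p) {
      x <- strsplit(p, "")[[1]]
      hit <- which(runif(length(x)) < rate)
      for (i in hit) x[i] <- sample(setdiff(aa20, x[i]), 1)
      paste(x, collapse = "")
    }, character(1))
  })
}
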