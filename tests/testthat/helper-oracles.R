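# Independent oracles used across the suite. These deliberately use naive,
# transparent algorithms (and third-party code where available) so they share
# nothing with the package implementations they check.

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exhaustive six-frame ORF oracle: for every position and strand, if an ATG
# starts there, walk codon by codon (wrapping when circular) to the first
# stop. Keeps, per stop, the longest candidate; reports plus-strand spans with
# end > L for wrapped ORFs.
oracle_orfs <- function(seq, circular = TRUE, min_coding_nt = 150) {
  L <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(s) {
    s2 <- if (circular) paste0(s, s) else s
    found <- list()
    for (p in 1:L) {
      if (substr(s2, p, p + 2) != "ATG") next
      q <- p
      repeat {
        q <- q + 3
        if (q + 2 > nchar(s2) || q + 2 - p + 1 > L) { q <- NA; break }
        if (substr(s2, q, q + 2) %in% stops) break
      }
      if (is.na(q)) next
      span <- q + 2 - p + 1
      if (span - 3 < min_coding_nt) next
      found[[length(found) + 1]] <- c(p, q + 2)
    }
    if (!length(found)) return(data.frame(start = integer(0), end = integer(0)))
    m <- unique(do.call(rbind, found))
    df <- data.frame(start = m[, 1], end = m[, 2])
    # longest per stop
    df <- df[order(df$end, df$start), ]
    df[!duplicated(df$end), ]
  }
  plus <- scan_strand(seq)
  plus$strand <- rep("+", nrow(plus))
  rc <- revcomp(seq)
  minus <- scan_strand(rc)
  if (nrow(minus)) {
    w <- minus$end - minus$start + 1
    ge <- L - minus$start + 1
    gs <- ge - w + 1
    wrap <- gs < 1
    gs[wrap] <- gs[wrap] + L
    ge[wrap] <- ge[wrap] + L
    minus <- data.frame(start = gs, end = ge, strand = "-")
  } else {
    minus$strand <- character(0)
  }
  out <- rbind(plus, minus)
  out[order(out$start, out$end, out$strand), ]
}

# Brute-force maximal imperfect palindromes over all (centre, loop) pairs,
# via cumulative mismatch counts.
oracle_palindromes <- function(seq, min_arm, max_loop, max_mismatch) {
  x <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(x)
  out <- list()
  for (g in 0:max_loop) {
    for (i in 1:(n - g - 1)) {
      dmax <- min(i, n - i - g)
      if (dmax < min_arm) next
      li <- i - seq_len(dmax) + 1
      ri <- i + g + seq_len(dmax)
      mm <- cumsum(comp[x[li]] != x[ri] | is.na(comp[x[li]]))
      arm <- max(c(0, which(mm <= max_mismatch)))
      if (arm >= min_arm) {
        out[[length(out) + 1]] <- data.frame(
          center = i, arm_len = arm, loop_len = g,
          mismatches = mm[arm], start = i - arm + 1, end = i + g + arm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(center = integer(0), arm_len = integer(0),
                      loop_len = integer(0), mismatches = integer(0),
                      start = integer(0), end = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$loop_len), ]
}

# Expand an IUPAC pattern to a plain regular expression.
iupac_to_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    set <- map[[ch]]
    if (nchar(set) == 1) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

# Positions of all (possibly overlapping) regex matches.
regex_positions <- function(rx, seq) {
  hits <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  as.integer(hits[hits > 0])
}

# Hand-rolled standard-code translation (oracle for Biostrings-based path).
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  # order: TTT TTC TTA TTG TCT ... (first base slowest)
  codons <- c()
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons <- c(codons, paste0(b1, b2, b3))
  }
  stats::setNames(aas, codons)
})

oracle_translate <- function(nt) {
  n <- nchar(nt)
  cods <- substring(nt, seq(1, n - 2, 3), seq(3, n, 3))
  paste(CODON_TABLE[cods], collapse = "")
}

# Six nested loops over cysteine positions: the brute-force CBM_14 oracle.
oracle_cys_motif <- function(aa, ranges = list(c(13, 20), c(5, 6), c(9, 19),
                                               c(10, 14), c(4, 14))) {
  cys <- which(strsplit(aa, "")[[1]] == "C")
  win <- function(prev, k) {
    cys[cys >= prev + ranges[[k]][1] + 1 & cys <= prev + ranges[[k]][2] + 1]
  }
  hits <- list()
  for (c1 in cys) for (c2 in win(c1, 1)) for (c3 in win(c2, 2))
    for (c4 in win(c3, 3)) for (c5 in win(c4, 4)) for (c6 in win(c5, 5)) {
      sp <- c(c2 - c1, c3 - c2, c4 - c3, c5 - c4, c6 - c5) - 1
      hits[[length(hits) + 1]] <- c(c1, c6, sp)
    }
  if (!length(hits)) {
    return(data.frame(start_aa = integer(0), end_aa = integer(0)))
  }
  m <- unique(do.call(rbind, hits))
  df <- data.frame(start_aa = m[, 1], end_aa = m[, 2], spacer1 = m[, 3],
                   spacer2 = m[, 4], spacer3 = m[, 5], spacer4 = m[, 6],
                   spacer5 = m[, 7])
  df[order(df$start_aa, df$end_aa), ]
}

# Exhaustive three-sequence alignment by 3D dynamic programming maximising
# the sum-of-pairs score (BLOSUM62; linear gap cost per residue-gap pair;
# gap-gap pairs free).
oracle_sp3 <- function(s1, s2, s3, gap = -4) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- BLOSUM62
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]; z <- strsplit(s3, "")[[1]]
  n1 <- length(x); n2 <- length(y); n3 <- length(z)
  colscore <- function(a, b, cc) {
    s <- 0
    s <- s + if (!is.na(a) && !is.na(b)) B[a, b] else if (is.na(a) != is.na(b)) gap else 0
    s <- s + if (!is.na(a) && !is.na(cc)) B[a, cc] else if (is.na(a) != is.na(cc)) gap else 0
    s <- s + if (!is.na(b) && !is.na(cc)) B[b, cc] else if (is.na(b) != is.na(cc)) gap else 0
    s
  }
  D <- array(-Inf, dim = c(n1 + 1, n2 + 1, n3 + 1))
  D[1, 1, 1] <- 0
  moves <- expand.grid(0:1, 0:1, 0:1)[-1, ]
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    if (i + j + k == 0) next
    best <- -Inf
    for (m in seq_len(nrow(moves))) {
      di <- moves[m, 1]; dj <- moves[m, 2]; dk <- moves[m, 3]
      if (i - di < 0 || j - dj < 0 || k - dk < 0) next
      prev <- D[i - di + 1, j - dj + 1, k - dk + 1]
      if (!is.finite(prev)) next
      sc <- colscore(if (di) x[i] else NA, if (dj) y[j] else NA,
                     if (dk) z[k] else NA)
      best <- max(best, prev + sc)
    }
    D[i + 1, j + 1, k + 1] <- best
  }
  D[n1 + 1, n2 + 1, n3 + 1]
}

# Sum-of-pairs score of an existing alignment under the oracle's objective.
sp_score <- function(alignment, gap = -4) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- BLOSUM62
  m <- do.call(rbind, strsplit(unclass(alignment), ""))
  total <- 0
  for (c in seq_len(ncol(m))) for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    a <- m[i, c]; b <- m[j, c]
    total <- total + if (a != "-" && b != "-") B[a, b] else
      if (a == "-" && b == "-") 0 else gap
  }
  total
}

# Small synthetic genome used by several integration tests (fast: ~3 s).
small_sim_config <- function(seed = 1) {
  simulation_config(
    seed = seed, genome_len = 30000, n_orfs = 30,
    orf_len_range = c(60L, 200L),
    promoter_plants = data.frame(
      motif = c("TTAAG", "TATAWAW"), literal = c("TTAAG", "TATAAAT"),
      offset = c(8L, 57L), n = c(4L, 3L), stringsAsFactors = FALSE),
    tr_noncoding = data.frame(unit_len = c(7L, 22L), span = c(32L, 66L)),
    hr_palindromes = c(3L, 4L))
}

# A deterministic toy GenBank record (300 nt, two CDS) written to a temp file.
write_toy_genbank <- function(path, wrap_cds = FALSE) {
  seq <- with_toy_seed(300)
  lines <- c(
    "LOCUS       TOY0001                  300 bp    DNA     circular VRL 01-JAN-2020",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "     CDS             10..108",
    '                     /gene="alpha"',
    "     CDS             complement(10..108)",
    '                     /gene="beta"')
  if (wrap_cds) {
    lines <- c(lines,
               "     CDS             join(280..300,1..30)",
               '                     /gene="gamma"')
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1, 300, 60)) {
    chunk <- substring(seq, seq(i, i + 59, 10), seq(i + 9, i + 68, 10))
    lines <- c(lines, sprintf("%9d %s", i, paste(chunk, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  seq
}

with_toy_seed <- function(n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20240101)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
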