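test_that("translation follows the standard code and strips the stop", {
  g <- circular_genome("ATGAAATAACCCCCCCCC", circular = FALSE)
  p <- translate_orf(g, list(start = 1, end = 9, strand = "+", serial = 1L))
  expect_equal(p$aa_seq, "MK")
  expect_equal(p$length_aa, 2L)
})

test_that("translation agrees with a hand-rolled codon-table oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n_cod <- sample(20:120, 1)
    cods <- c("ATG", sample(setdiff(names(CODON_TABLE),
                                    c("TAA", "TAG", "TGA")),
                            n_cod, replace = TRUE), "TAA")
    nt <- paste(cods, collapse = "")
    g <- circular_genome(nt, circular = FALSE)
    p <- translate_orf(g, list(start = 1, end = nchar(nt), strand = "+"))
    want <- sub("\\*$", "", oracle_translate(nt))
    expect_equal(p$aa_seq, want)
  }
})

test_that("minus-strand and origin-wrapping ORFs translate correctly", {
  core <- "ATGGCCAAATAA" # MAK
  g1 <- circular_genome(paste0("CC", reverse_complement(core), "GG"),
                        circular = FALSE)
  p1 <- translate_orf(g1, list(start = 3, end = 14, strand = "-"))
  expect_equal(p1$aa_seq, "MAK")
  # wrap: gene starts near the end of the circle
  pre <- strrep("C", 20)
  g2 <- circular_genome(paste0(substr(core, 7, 12), pre, substr(core, 1, 6)))
  p2 <- translate_orf(g2, list(start = 21 + 6, end = 21 + 6 + 11, strand = "+"))
  expect_equal(p2$aa_seq, "MAK")
})

test_that("internal stops are reported with their codon position", {
  g <- circular_genome("ATGTAAAAATAA", circular = FALSE)
  expect_error(translate_orf(g, list(start = 1, end = 12, strand = "+")),
               "codon 2")
})

test_that("molecular weight matches published residue masses and is additive", {
  expect_equal(protein_mw("G"), 75.07, tolerance = 1e-3)
  expect_error(protein_mw(""), "empty")
  expect_error(protein_mw("GZ"), "non-standard")
  expect_equal(protein_mw("GXG", allow_x = TRUE),
               2 * protein_mw("G") - 18.01524, tolerance = 1e-6)
  set.seed(62)
  aa20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
  a <- paste(sample(aa20, 40, TRUE), collapse = "")
  b <- paste(sample(aa20, 25, TRUE), collapse = "")
  expect_equal(protein_mw(paste0(a, b)),
               protein_mw(a) + protein_mw(b) - 18.01524, tolerance = 1e-9)
})

test_that("molecular weight agrees with the seqinr oracle", {
  skip_if_not_installed("seqinr")
  set.seed(63)
  aa20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
  for (rep in 1:5) {
    p <- paste(sample(aa20, sample(50:300, 1), TRUE), collapse = "")
    expect_equal(protein_mw(p), seqinr::pmw(strsplit(p, "")[[1]]),
                 tolerance = 0.05)
  }
})

test_that("the six-cysteine motif respects its spacer bounds exactly", {
  ok <- paste0("C", strrep("A", 13), "C", strrep("A", 5), "C", strrep("A", 9),
               "C", strrep("A", 10), "C", strrep("A", 4), "C")
  hits <- find_cys_motif(ok)
  expect_equal(nrow(hits), 1L)
  expect_equal(unlist(hits[1, 3:7], use.names = FALSE), c(13L, 5L, 9L, 10L, 4L))
  bad <- sub(strrep("A", 13), strrep("A", 12), ok, fixed = TRUE)
  expect_equal(nrow(find_cys_motif(bad)), 0L)
  expect_equal(nrow(find_cys_motif("MKLVNTAG")), 0L)
})

test_that("motif enumeration equals the six-nested-loop oracle", {
  set.seed(64)
  for (rep in 1:6) {
    # cysteine-enriched random proteins exercise overlapping matches
    p <- paste(sample(c("C", "A", "G", "S", "T"), 250, TRUE,
                      prob = c(0.18, rep(0.205, 4))), collapse = "")
    got <- find_cys_motif(p)
    want <- oracle_cys_motif(p)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("start_aa", "end_aa")],
                 want[, c("start_aa", "end_aa")])
  }
})

test_that("non-overlapping domain counting collapses bridge matches", {
  hits <- data.frame(start_aa = c(40, 95, 99), end_aa = c(95, 154, 154))
  expect_equal(count_cys_domains(hits), 2L)
  expect_equal(count_cys_domains(hits[0, ]), 0L)
})

test_that("homopolymer runs match a regex oracle and the min-length rule", {
  expect_equal(nrow(find_homopolymer_runs("QQQ", "Q", 4)), 0L)
  r <- find_homopolymer_runs("AAQQQQA", "Q", 3)
  expect_equal(c(r$start, r$end, r$length), c(3L, 6L, 4L))
  set.seed(65)
  for (rep in 1:5) {
    p <- paste(sample(c("Q", "A", "S"), 300, TRUE, prob = c(0.4, 0.3, 0.3)),
               collapse = "")
    got <- find_homopolymer_runs(p, "Q", 4)
    m <- gregexpr("Q{4,}", p)[[1]]
    expect_equal(got$start, as.integer(m[m > 0]))
    expect_equal(got$length, attr(m, "match.length")[m > 0])
  }
})
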