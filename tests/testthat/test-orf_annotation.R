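test_that("candidate enumeration handles trivial and constructed cases", {
  # no ATG on either strand (CAT is the minus-strand ATG, also absent)
  g <- circular_genome(strrep("CCCCCCGGG", 30))
  expect_equal(nrow(enumerate_candidate_orfs(g)), 0L)

  # one planted 153-nt ORF in a stop-rich background
  set.seed(21)
  bg1 <- paste(rep("TAA", 40), collapse = "")
  orf <- paste0("ATG", strrep("AAA", 49), "TAA")
  g2 <- circular_genome(paste0(bg1, orf, bg1), circular = FALSE)
  cand <- enumerate_candidate_orfs(g2)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$span, 153L)
  expect_equal(cand$start, 121L)
})

test_that("enumeration equals the exhaustive six-frame oracle on circular sequences", {
  set.seed(22)
  for (rep in 1:5) {
    g <- circular_genome(random_dna(2000, gc = 0.4))
    got <- enumerate_candidate_orfs(g)
    want <- oracle_orfs(g$seq, circular = TRUE)
    expect_equal(got[, c("start", "end", "strand")],
                 want[, c("start", "end", "strand")],
                 ignore_attr = TRUE)
  }
})

test_that("selection breaks ties deterministically and stays conflict-free", {
  # two identical-span candidates on opposite strands -> plus wins
  cand <- data.frame(start = c(1, 1), end = c(150, 150),
                     strand = c("-", "+"), span = c(150, 150),
                     wraps_origin = FALSE)
  g <- circular_genome(strrep("A", 1000))
  sel <- select_orfs(cand, g, orf_config())
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$strand, "+")

  # random candidates: all pairwise overlaps of the selection <= allowance
  set.seed(23)
  g2 <- circular_genome(random_dna(5000))
  cfg <- orf_config(max_allowed_overlap_nt = 30)
  sel2 <- call_orfs(g2, cfg)
  if (nrow(sel2) > 1) {
    for (i in 1:(nrow(sel2) - 1)) for (j in (i + 1):nrow(sel2)) {
      ov <- gvannot:::circ_overlap(sel2$start[i], sel2$end[i],
                                   sel2$start[j], sel2$end[j], g2$length)
      expect_lte(ov, 30)
    }
  }
})

test_that("nested decoy ORFs are rejected in favour of planted genes", {
  sim <- simulate_genome(small_sim_config(seed = 4))
  ann <- call_orfs(sim$genome)
  truth <- sim$truth$orfs
  expect_equal(nrow(ann), nrow(truth))
  expect_equal(ann$start, truth$start)
  expect_equal(ann$end, truth$end)
  expect_equal(ann$strand, truth$strand)
})

test_that("orientation split counts strands relative to the anchor", {
  set.seed(24)
  g <- circular_genome(random_dna(4000))
  strands <- sample(c("+", "-"), 20, replace = TRUE)
  ann <- gene_annotation(start = seq(1, by = 200, length.out = 20),
                         end = seq(1, by = 200, length.out = 20) + 99,
                         strand = strands, genome = g)
  os <- orientation_split(ann, anchor_serial = 1)
  expect_equal(sum(os), 20L)
  expect_equal(unname(os["same"]), sum(strands == strands[1]))
  # all plus with a plus anchor
  ann2 <- gene_annotation(start = c(1, 200), end = c(99, 299),
                          strand = c("+", "+"), genome = g)
  expect_equal(unname(orientation_split(ann2)), c(2L, 0L))
  expect_error(orientation_split(ann2, anchor_serial = 9), "not present")
})

test_that("coding density counts union coverage once and is rotation-invariant", {
  g <- circular_genome(strrep("ACGT", 250))
  empty <- gene_annotation(integer(0), integer(0), character(0), genome = g)
  expect_equal(coding_density(g, empty), 0)
  whole <- gene_annotation(1, 1000, "+", genome = g)
  expect_equal(coding_density(g, whole), 1)
  # overlapping ORFs on both strands counted once
  ann <- gene_annotation(start = c(1, 51, 980), end = c(100, 150, 1009),
                         strand = c("+", "-", "+"), genome = g)
  # union: [1,150] plus [980,1000] (the wrapped tail [1,9] is already covered)
  expect_equal(coding_density(g, ann), (150 + 21) / 1000)
  for (off in c(10, 500, 990)) {
    rot <- rotate_genome(g, ann, offset = off)
    expect_equal(coding_density(rot$genome, rot$annotation),
                 coding_density(g, ann))
  }
})

test_that("intergenic regions recover constructed gaps with AT content", {
  g <- circular_genome(paste0(strrep("A", 500), strrep("G", 500)))
  # genes leaving gaps of 10, 50 and 200 nt on the circle
  ann <- gene_annotation(start = c(11, 121, 421), end = c(110, 370, 800),
                         strand = "+", genome = g)
  ig <- intergenic_regions(g, ann)
  expect_setequal(ig$length, c(10L, 50L, 210L))
  big <- ig[1, ]
  expect_equal(big$length, 210L)
  expect_equal(big$serial_before, 3L)
  expect_equal(big$serial_after, 1L)
  # gap 801..1010 wraps: 200 G + 10 A
  expect_equal(big$at_content, 10 / 210)
  # abutting ORFs produce no zero-length gap
  ann2 <- gene_annotation(start = c(1, 101), end = c(100, 1000),
                          strand = "+", genome = g)
  expect_equal(nrow(intergenic_regions(g, ann2)), 0L)
})

test_that("extremal ORFs report amino-acid lengths excluding the stop", {
  g <- circular_genome(strrep("ACGT", 300))
  ann <- gene_annotation(start = c(1, 201), end = c(153, 1100),
                         strand = "+", genome = g)
  ex <- extremal_orfs(ann)
  expect_equal(ex$shortest$aa_len, 50L)
  expect_equal(ex$longest$aa_len, (900 - 3) / 3)
  one <- gene_annotation(1, 153, "+", genome = g)
  ex1 <- extremal_orfs(one)
  expect_equal(ex1$longest$aa_len, ex1$shortest$aa_len)
})
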