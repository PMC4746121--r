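test_that("a perfect triplet array is called with exact unit and copies", {
  reps <- find_tandem_repeats("ACGACGACG", min_unit = 1, max_unit = 4,
                              min_copies = 3, min_len = 9, min_identity = 1)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$unit_len, 3L)
  expect_equal(reps$copy_number, 3.0)
  expect_equal(reps$consensus_unit, "ACG")
})

test_that("a fractional CAG array inside a coding region is recovered as 12.3 copies", {
  set.seed(51)
  sim <- simulate_genome(small_sim_config(seed = 1))
  ann <- sim$truth$orfs
  reps <- find_tandem_repeats(sim$genome, min_len = 30, min_identity = 0.85)
  reps <- classify_repeat_placement(reps, ann, sim$genome)
  truth <- sim$truth$repeats
  cag <- truth[truth$unit_len == 3 & truth$copy_number == 12.3, ]
  hit <- reps[reps$start <= cag$end & reps$end >= cag$start, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit_len, 3L)
  expect_equal(hit$copy_number, 12.3)
  expect_equal(hit$placement, "coding")
})

test_that("planted arrays in random sequence are recovered; shuffled background is clean", {
  set.seed(52)
  units <- c(7, 15, 26, 41, 60)
  copies <- c(5, 4, 3.5, 3, 3)
  bg <- strsplit(random_dna(5000, gc = 0.4), "")[[1]]
  at <- floor(seq(400, 4400, length.out = 5))
  truth <- list()
  for (k in 1:5) {
    u <- units[k]
    unit <- sample(c("A", "C", "G", "T"), u, replace = TRUE)
    span <- round(u * copies[k])
    arr <- rep(unit, length.out = span)
    # anti-match flanks pin the boundaries
    antiL <- setdiff(c("A", "C"), arr[u])[1]
    antiR <- setdiff(c("A", "C"), arr[span - u + 1])[1]
    bg[at[k] - 1] <- antiL
    bg[at[k] + span] <- antiR
    bg[at[k]:(at[k] + span - 1)] <- arr
    truth[[k]] <- c(at[k], at[k] + span - 1, u, round(span / u, 1))
  }
  seq <- paste(bg, collapse = "")
  reps <- find_tandem_repeats(seq) # defaults: min_len 24, identity 0.8
  for (k in 1:5) {
    tr <- truth[[k]]
    j <- which(reps$start <= tr[2] & reps$end >= tr[1])
    expect_length(j, 1)
    expect_equal(reps$unit_len[j], tr[3])
    expect_lte(abs(reps$copy_number[j] - tr[4]), 0.2)
  }
  # i.i.d. shuffle of the same sequence: no repeat structure left
  shuffled <- paste(sample(bg), collapse = "")
  expect_equal(nrow(find_tandem_repeats(shuffled)), 0L)
})

test_that("placement classification matches an interval oracle", {
  g <- circular_genome(strrep("ACGT", 500))
  ann <- gene_annotation(start = c(101, 501), end = c(300, 800),
                         strand = "+", genome = g)
  reps <- data.frame(start = c(150, 250, 320, 1990),
                     end = c(200, 350, 450, 2030),
                     unit_len = 5, copy_number = 10, consensus_unit = "AAAAA",
                     percent_identity = 1, placement = NA_character_)
  out <- classify_repeat_placement(reps, ann, g)
  expect_equal(out$placement, c("coding", "both", "noncoding", "noncoding"))
})

test_that("genome fraction uses the union of repeat spans", {
  g <- circular_genome(strrep("A", 112000))
  expect_equal(repeat_genome_fraction(gvannot:::empty_repeat_table(), g), 0)
  reps <- data.frame(start = c(1, 561), end = c(1120, 1120))
  expect_equal(repeat_genome_fraction(reps, g), 1.0)
})

test_that("palindrome trivia behave as documented", {
  p <- find_palindromes("GAATTC", min_arm = 3, max_loop = 0, max_mismatch = 0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$arm_len, 3L)
  expect_equal(c(p$start, p$end), c(1L, 6L))
  expect_equal(nrow(find_palindromes("AAAAAAAA", min_arm = 3, max_loop = 0,
                                     max_mismatch = 0)), 0L)
})

test_that("palindrome calls equal the brute-force oracle on random sequences", {
  set.seed(53)
  for (rep in 1:4) {
    seq <- random_dna(300, gc = 0.35)
    got <- find_palindromes(seq, min_arm = 5, max_loop = 6, max_mismatch = 2)
    want <- oracle_palindromes(seq, min_arm = 5, max_loop = 6, max_mismatch = 2)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("hr clustering finds planted cassettes and respects min_cluster", {
  set.seed(54)
  # 3 cassettes of 4 perfect palindromes, far apart on a 20 kb circle
  bg <- strsplit(random_dna(20000, gc = 0.45), "")[[1]]
  centers <- c(3000, 9000, 16000)
  spans <- list()
  for (cc in centers) {
    pos <- cc
    for (q in 1:4) {
      arm <- sample(c("A", "C", "G", "T"), 24, replace = TRUE)
      rc_arm <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[arm]))
      bg[pos:(pos + 47)] <- c(arm, rc_arm)
      spans[[length(spans) + 1]] <- c(pos, pos + 47)
      pos <- pos + 100
    }
  }
  g <- circular_genome(paste(bg, collapse = ""))
  h <- find_hrs(g, min_arm = 20, max_mismatch = 2)
  expect_equal(nrow(h$regions), 3L)
  expect_equal(h$regions$n_palindromes, c(4L, 4L, 4L))
  # an isolated single palindrome is not an hr under min_cluster = 2
  lone <- find_palindromes(g, min_arm = 20, max_mismatch = 0, dedupe = TRUE)
  one <- lone[1, , drop = FALSE]
  expect_equal(nrow(cluster_hrs(one, g, min_cluster = 2)), 0L)
})

test_that("hr regions stay within bounds and are pairwise disjoint", {
  sim <- simulate_genome(small_sim_config(seed = 3))
  h <- find_hrs(sim$genome)
  r <- h$regions
  expect_true(all(r$start >= 1))
  expect_true(all(r$end - r$start + 1 <= sim$genome$length))
  if (nrow(r) > 1) {
    for (i in 1:(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
      ov <- gvannot:::circ_overlap(r$start[i], r$end[i], r$start[j], r$end[j],
                                   sim$genome$length)
      expect_equal(ov, 0L)
    }
  }
})
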