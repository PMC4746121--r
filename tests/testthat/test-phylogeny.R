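test_that("pairwise alignment trivia behave as expected", {
  a <- progressive_align(c(x = "MKLV", y = "MKLV"))
  expect_false(any(grepl("-", a)))
  b <- progressive_align(c(x = "ACD", y = "AD"))
  expect_equal(nchar(b[["x"]]), 3L)
  expect_equal(b[["x"]], "ACD")
  expect_equal(gsub("-", "", b[["y"]]), "AD")
  expect_error(progressive_align(c(x = "ACD")), "at least 2")
})

test_that("three-sequence alignments reach the exhaustive sum-of-pairs optimum on easy toys", {
  toys <- list(
    c(a = "MKVLIT", b = "MKVLIT", c = "MKVIT"),
    c(a = "ACDEFGHIK", b = "ACDEFGHIK", c = "ACDEGHIK"),
    c(a = "WWKLMNP", b = "WWKLMNP", c = "WWKLMN"))
  for (ts in toys) {
    aln <- progressive_align(ts)
    best <- oracle_sp3(ts[1], ts[2], ts[3])
    expect_lte(sp_score(aln), best)            # the oracle is an upper bound
    expect_equal(sp_score(aln), best)          # and is met on these toys
  }
  # random short triples never beat the exhaustive optimum
  set.seed(81)
  aa20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
  for (rep in 1:3) {
    ts <- setNames(vapply(1:3, function(i) {
      paste(sample(aa20, sample(6:9, 1), TRUE), collapse = "")
    }, character(1)), c("a", "b", "c"))
    aln <- progressive_align(ts)
    expect_lte(sp_score(aln), oracle_sp3(ts[1], ts[2], ts[3]))
  }
})

test_that("marker concatenation is width-additive and name-keyed", {
  m1 <- structure(c(t1 = "ACDE", t2 = "ACDE", t3 = "ACDS"), class = "protein_msa")
  m2 <- structure(c(t3 = "WW", t1 = "WF", t2 = "WF"), class = "protein_msa")
  cc <- concat_markers(list(g1 = m1, g2 = m2))
  expect_equal(unique(nchar(cc)), 6L)
  expect_equal(substr(cc[["t3"]], 5, 6), "WW") # joined by name, not order
  parts <- attr(cc, "partitions")
  expect_equal(parts$end, c(4L, 6L))
  # missing marker -> all-gap partition with a warning
  m3 <- structure(c(t1 = "KK", t2 = "KK"), class = "protein_msa")
  expect_warning(cc2 <- concat_markers(list(m1, m3)), "missing")
  expect_equal(substr(cc2[["t3"]], 5, 6), "--")
  m4 <- structure(c(zz = "AA"), class = "protein_msa")
  expect_error(concat_markers(list(m1, m4)), "no taxa")
})

test_that("distances follow the closed forms under pairwise deletion", {
  aln <- structure(c(a = "AAAAAAAAAA", b = "AAAAAAAACC"), class = "protein_msa")
  expect_equal(distance_matrix(aln, "p")["a", "b"], 0.2)
  expect_equal(distance_matrix(aln, "poisson")["a", "b"], -log(0.8))
  gap <- structure(c(a = "AA--AAAAAAA-", b = "AAAAAAAAAA-C"),
                   class = "protein_msa")
  # gapped columns are deleted pairwise: 8 comparable sites, 0 mismatches
  expect_equal(distance_matrix(gap, "p")["a", "b"], 0)
  same <- structure(c(a = "GG", b = "GG"), class = "protein_msa")
  expect_equal(distance_matrix(same)["a", "b"], 0)
  nogap <- structure(c(a = "-A", b = "A-"), class = "protein_msa")
  expect_error(distance_matrix(nogap), "comparable")
})

test_that("distance computation equals a counting oracle on random alignments", {
  set.seed(82)
  aa <- c(LETTERS[1:20])
  for (rep in 1:3) {
    m <- matrix(sample(c("A", "C", "D", "-"), 5 * 60, TRUE), nrow = 5,
                dimnames = list(paste0("t", 1:5), NULL))
    aln <- structure(apply(m, 1, paste, collapse = ""), class = "protein_msa")
    D <- try(distance_matrix(aln, "p"), silent = TRUE)
    if (inherits(D, "try-error")) next
    i <- sample(5, 1); j <- sample(setdiff(1:5, i), 1)
    ok <- m[i, ] != "-" & m[j, ] != "-"
    expect_equal(D[i, j], mean(m[i, ok] != m[j, ok]))
  }
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("NJ recovers a five-taxon additive matrix exactly", {
  # caterpillar tree ((a:1,b:2):1,(c:3,(d:1,e:1):2):1); distances by hand
  tr0 <- ape::read.tree(text = "((a:1,b:2):1,(c:3,(d:1,e:1):2):1);")
  D <- ape::cophenetic.phylo(tr0)
  tr <- nj_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  expect_s3_class(tr, "phylo")
  expect_false(ape::is.rooted(tr))
})

test_that("NJ is exact on additive matrices from random trees (property)", {
  skip_if_not_installed("phangorn")
  set.seed(83)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    tr0 <- ape::unroot(tr0)
    D <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(D)
    expect_equal(phangorn::RF.dist(tr, tr0), 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("UPGMA is ultrametric, recovers ultrametric matrices and matches hclust", {
  # constructed ultrametric 4-taxon matrix
  D <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- upgma_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]], D,
               tolerance = 1e-9)
  depths <- ape::node.depth.edgelength(tr)[1:4]
  expect_equal(max(D) / 2, unique(round(depths, 9)))
  # random matrices: same merge heights as average-linkage hclust
  set.seed(84)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    M <- matrix(runif(n * n, 1, 10), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tru <- upgma_tree(M)
    hc <- stats::hclust(stats::as.dist(M), method = "average")
    expect_equal(sort(unique(round(ape::branching.times(tru), 8))),
                 sort(round(hc$height / 2, 8)))
    # ultrametricity
    d2r <- ape::node.depth.edgelength(tru)[seq_len(n)]
    expect_lt(diff(range(d2r)), 1e-9)
  }
})

test_that("bootstrap supports are reproducible and order-invariant", {
  set.seed(85)
  aa20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
  base <- paste(sample(aa20, 80, TRUE), collapse = "")
  seqs <- c(a = base,
            b = mutate_proteins(c(x = base), 0.05, seed = 1)[[1]],
            c = mutate_proteins(c(x = base), 0.3, seed = 2)[[1]],
            d = mutate_proteins(c(x = base), 0.35, seed = 3)[[1]])
  aln <- progressive_align(seqs)
  t1 <- bootstrap_support(aln, n_reps = 50, seed = 7, method = "nj")
  t2 <- bootstrap_support(aln, n_reps = 50, seed = 7, method = "nj")
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  shuffled <- aln[c(3, 1, 4, 2)]
  class(shuffled) <- "protein_msa"
  t3 <- bootstrap_support(shuffled, n_reps = 50, seed = 7, method = "nj")
  expect_equal(ape::write.tree(t3), ape::write.tree(t1))
})

test_that("identical sequences give a tree with full support by convention", {
  aln <- structure(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"),
                   class = "protein_msa")
  tr <- bootstrap_support(aln, n_reps = 20, seed = 1, method = "upgma")
  expect_true(all(tr$edge.length >= 0))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 1))
})
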