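toy_annotation <- function(n, L = NULL, strand = rep("+", n)) {
  starts <- seq(1, by = 200, length.out = n)
  gene_annotation(start = starts, end = starts + 99, strand = strand,
                  genome = L %||% (200 * n + 100))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a proteome paired against itself gives the identity at similarity 1", {
  set.seed(71)
  aa20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
  prots <- setNames(vapply(1:8, function(i) {
    paste(sample(aa20, 80, TRUE), collapse = "")
  }, character(1)), as.character(1:8))
  orth <- pair_orthologs(prots, prots)
  expect_equal(nrow(orth), 8L)
  expect_equal(orth$serial_a, orth$serial_b)
  expect_true(all(orth$similarity == 1))
})

test_that("mutated orthologs are recovered one-to-one; disjoint sets pair nothing", {
  set.seed(72)
  aa20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
  a <- setNames(vapply(1:15, function(i) {
    paste(sample(aa20, 120, TRUE), collapse = "")
  }, character(1)), as.character(1:15))
  b <- mutate_proteins(a, rate = 0.1, seed = 9)
  orth <- pair_orthologs(a, b, min_similarity = 0.5)
  expect_equal(nrow(orth), 15L)
  expect_equal(orth$serial_a, orth$serial_b)
  expect_true(all(orth$similarity > 0.75))
  expect_equal(nrow(pair_orthologs(character(0), a)), 0L)
})

test_that("identical gene orders give one same-orientation block covering all pairs", {
  ann <- toy_annotation(10)
  orth <- data.frame(serial_a = 1:10, serial_b = 1:10, similarity = 1)
  blocks <- synteny_blocks(ann, ann, orth, max_gap_genes = 0)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$orientation, "same")
  expect_equal(blocks$n_genes, 10L)
})

test_that("a constructed middle inversion yields exactly three blocks", {
  ann <- toy_annotation(10)
  # B order: 1,2,3, 7',6',5',4', 8,9,10
  b_of_a <- c(1, 2, 3, 7, 6, 5, 4, 8, 9, 10)
  orth <- data.frame(serial_a = 1:10, serial_b = b_of_a, similarity = 1)
  blocks <- synteny_blocks(ann, ann, orth, max_gap_genes = 0)
  expect_equal(nrow(blocks), 3L)
  expect_equal(blocks$orientation, c("same", "inverted", "same"))
  expect_equal(blocks$n_genes, c(3L, 4L, 3L))
})

test_that("random internal inversions are recovered as three blocks (property)", {
  set.seed(73)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    ends <- sort(sample(2:(n - 1), 2))
    if (ends[1] == ends[2]) next
    ann <- toy_annotation(n)
    p <- perturb_gene_order(ann, list(ends))
    src <- attr(p, "source_serial")
    orth <- data.frame(serial_a = seq_len(n), serial_b = order(src)[seq_len(n)],
                       similarity = 1)
    # serial_b of original gene s is its position in the perturbed order
    orth$serial_b <- match(seq_len(n), src)
    blocks <- synteny_blocks(ann, p, orth, max_gap_genes = 0)
    expect_equal(nrow(blocks), attr(p, "truth_blocks"))
    expect_equal(sum(blocks$orientation == "inverted"), 1L)
    # pairs partition: every ortholog pair appears in exactly one block
    all_pairs <- do.call(rbind, blocks$pairs)
    expect_equal(sort(all_pairs[, "a"]), seq_len(n))
  }
})

test_that("the core-gene audit counts planted labels against the 37-name reference", {
  ref <- core_gene_reference()
  expect_equal(nrow(ref), 37L)
  g <- 200 * 40 + 100
  ann <- toy_annotation(37, L = 200 * 37 + 100)
  ann$label <- ref$gene
  audit <- core_gene_audit(ann)
  expect_equal(attr(audit, "n_present"), 37L)
  ann2 <- ann
  ann2$label[11:37] <- "orf"
  audit2 <- core_gene_audit(ann2)
  expect_equal(attr(audit2, "n_present"), 10L)
  expect_equal(sum(!audit2$present), 27L)
  empty <- gene_annotation(integer(0), integer(0), character(0), genome = 1000)
  expect_equal(attr(core_gene_audit(empty), "n_present"), 0L)
  # aliases match case- and punctuation-insensitively
  ann3 <- toy_annotation(2)
  ann3$label <- c("LEF1", "DNA polymerase")
  audit3 <- core_gene_audit(ann3)
  expect_true(all(audit3$present[audit3$gene %in% c("lef-1", "dnapol")]))
})

test_that("repeated gene families are suffixed in serial order", {
  ann <- toy_annotation(6)
  ann$label[c(5, 2)] <- "bro"
  named <- name_repeated_genes(ann, "bro")
  expect_equal(named$label[2], "bro-a")
  expect_equal(named$label[5], "bro-b")
  one <- toy_annotation(1)
  one$label <- "bro"
  expect_equal(name_repeated_genes(one, "bro")$label, "bro-a")
  # shuffled: suffixes follow ascending serial regardless of assignment order
  ann2 <- toy_annotation(5)
  ann2$label[c(4, 1, 3)] <- "vef"
  named2 <- name_repeated_genes(ann2, "vef")
  expect_equal(named2$label[c(1, 3, 4)], c("vef-a", "vef-b", "vef-c"))
  expect_error(name_repeated_genes(ann2, "missing"), "no feature")
})
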