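test_that("GenBank parsing handles plain, complement and origin-spanning CDS", {
  gb <- tempfile(fileext = ".gb")
  seq <- write_toy_genbank(gb, wrap_cds = TRUE)
  parsed <- read_genbank(gb)
  expect_equal(parsed$genome$length, 300L)
  expect_true(parsed$genome$circular)
  expect_equal(parsed$genome$seq, seq)
  ann <- parsed$annotation
  expect_equal(nrow(ann), 3L)
  beta <- ann[ann$label == "beta", ]
  expect_equal(beta$strand, "-")
  expect_equal(beta$end - beta$start + 1L, 99L)
  gamma <- ann[ann$label == "gamma", ]
  expect_true(gamma$wraps_origin)
  expect_equal(c(gamma$start, gamma$end), c(280L, 330L)) # unwrapped end > L
})

test_that("a record with no CDS yields an empty annotation, not an error", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       X 30 bp DNA circular",
    "ORIGIN",
    "        1 atgaaataac ccgggtttaa acgtacgtac",
    "//"), gb)
  parsed <- read_genbank(gb)
  expect_equal(nrow(parsed$annotation), 0L)
  expect_equal(parsed$genome$length, 30L)
  expect_equal(parsed$genome$seq, toupper("atgaaataacccgggtttaaacgtacgtac"))
})

test_that("malformed records produce informative errors", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS X 10 bp", "FEATURES", "     CDS             5..x9",
               "ORIGIN", "        1 acgtacgtac", "//"), gb)
  expect_error(read_genbank(gb), "line")
  writeLines(c("LOCUS X 10 bp", "ORIGIN", "//"), gb)
  expect_error(read_genbank(gb), "ORIGIN")
  writeLines(c("DEFINITION no locus"), gb)
  expect_error(read_genbank(gb), "LOCUS")
})

test_that("rotate_to_anchor matches a manual reverse-complement + slice oracle", {
  set.seed(11)
  seq <- random_dna(1000)
  substr(seq, 488, 490) <- "CAT" # the anchor ATG, read on the minus strand
  g <- circular_genome(seq, id = "toy")
  # anchor on the minus strand mid-sequence: plus span 401..490
  ann <- gene_annotation(start = c(10, 401), end = c(108, 490),
                         strand = c("+", "-"), label = c("x", "anchor"),
                         genome = g)
  rot <- rotate_to_anchor(g, ann, "anchor")
  rc <- reverse_complement(seq)
  # anchor ATG on minus strand sits at plus position 490 -> rc position 511
  manual <- paste0(substr(rc, 511, 1000), substr(rc, 1, 510))
  expect_equal(rot$genome$seq, manual)
  anchor_row <- rot$annotation[rot$annotation$label == "anchor", ]
  expect_equal(anchor_row$start, 1L)
  expect_equal(anchor_row$strand, "+")
  expect_equal(anchor_row$serial, 1L)
  expect_equal(substr(rot$genome$seq, 1, 3), "ATG")
})

test_that("rotation is a bijection and the identity when already anchored", {
  set.seed(12)
  g <- circular_genome(random_dna(600))
  ann <- gene_annotation(start = c(1, 200), end = c(99, 340),
                         strand = c("+", "+"), label = c("a", "b"), genome = g)
  id <- rotate_to_anchor(g, ann, "a")
  expect_equal(id$genome$seq, g$seq)
  expect_equal(id$annotation$start, ann$start)
  fwd <- rotate_genome(g, ann, offset = 123)
  back <- rotate_genome(fwd$genome, fwd$annotation, offset = 600 - 123)
  expect_equal(back$genome$seq, g$seq)
  expect_equal(back$annotation$start, ann$start)
  expect_equal(back$annotation$end, ann$end)
})

test_that("anchor errors list candidates and reject ambiguity", {
  g <- circular_genome(strrep("ACGT", 50))
  ann <- gene_annotation(start = c(1, 21), end = c(12, 32),
                         strand = c("+", "+"), label = c("dup", "dup"),
                         genome = g)
  expect_error(rotate_to_anchor(g, ann, "missing"), "labels present")
  expect_error(rotate_to_anchor(g, ann, "dup"), "ambiguous")
})

test_that("GFF3 round-trips coordinates, strands and serials", {
  set.seed(13)
  g <- circular_genome(random_dna(500))
  ann <- gene_annotation(start = c(5, 120, 480), end = c(103, 260, 530),
                         strand = c("+", "-", "+"),
                         label = c("a", "b", "wrapper"), genome = g)
  path <- tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_gff3(path)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$strand, ann$strand)
  expect_equal(back$serial, ann$serial)
  expect_equal(back$wraps_origin, ann$wraps_origin)
})

test_that("origin-wrapping features are written as two segments a second parser groups by ID", {
  skip_if_not_installed("rtracklayer")
  g <- circular_genome(strrep("ACGT", 100))
  ann <- gene_annotation(start = 390, end = 430, strand = "+",
                         label = "wrapper", genome = g)
  path <- tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  gr <- rtracklayer::import(path)
  expect_equal(length(gr), 2L)
  expect_equal(length(unique(gr$ID)), 1L)
  segs <- sort(as.data.frame(gr)$start)
  expect_equal(segs, c(1L, 390L))
  widths <- sum(as.data.frame(gr)$width)
  expect_equal(widths, 41L)
})

test_that("GenBank -> internal -> GFF3 -> internal is the identity on features", {
  gb <- tempfile(fileext = ".gb")
  write_toy_genbank(gb, wrap_cds = TRUE)
  parsed <- read_genbank(gb)
  path <- tempfile(fileext = ".gff3")
  write_gff3(parsed$annotation, path)
  back <- read_gff3(path)
  for (col in c("start", "end", "strand", "serial", "wraps_origin")) {
    expect_equal(back[[col]], parsed$annotation[[col]], label = col)
  }
})

test_that("FASTA writing and reading round-trips a genome", {
  g <- circular_genome(strrep("ACGTT", 30), id = "rt")
  fa <- tempfile(fileext = ".fasta")
  write_fasta(g, fa)
  back <- read_fasta_genome(fa)
  expect_equal(back$seq, g$seq)
  expect_equal(back$id, "rt")
})
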