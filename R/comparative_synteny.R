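#' Pair orthologs between two proteomes by reciprocal best alignment
#'
#' All-vs-all local protein alignment (Smith-Waterman, BLOSUM62, gap open 11 /
#' extend 1 via [Biostrings::pairwiseAlignment()]); pairs that are each
#' other's best-scoring hit and whose similarity (identities / alignment
#' length) reaches `min_similarity` are kept, yielding a one-to-one table.
#'
#' @param proteins_a,proteins_b Named character vectors (names = gene serials)
#'   or `AAStringSet`s.
#' @param min_similarity Minimum identity fraction (default 0.3).
#' @return A `data.frame` with columns `serial_a`, `serial_b`, `similarity`.
#' @export
pair_orthologs <- function(proteins_a, proteins_b, min_similarity = 0.3) {
  a <- as(proteins_a, "AAStringSet")
  b <- as(proteins_b, "AAStringSet")
  empty <- data.frame(serial_a = character(0), serial_b = character(0),
                      similarity = numeric(0))
  if (length(a) == 0 || length(b) == 0) return(empty)
  if (is.null(names(a))) names(a) <- seq_along(a)
  if (is.null(names(b))) names(b) <- seq_along(b)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  scores <- matrix(NA_real_, length(a), length(b))
  sims <- matrix(NA_real_, length(a), length(b))
  for (j in seq_along(b)) {
    aln <- Biostrings::pairwiseAlignment(a, b[[j]], type = "local",
                                         substitutionMatrix = BLOSUM62,
                                         gapOpening = 11, gapExtension = 1)
    scores[, j] <- Biostrings::score(aln)
    sims[, j] <- Biostrings::pid(aln, type = "PID1") / 100
  }
  best_for_a <- max.col(scores, ties.method = "first")
  best_for_b <- max.col(t(scores), ties.method = "first")
  rows <- which(best_for_b[best_for_a] == seq_along(a))
  out <- data.frame(serial_a = names(a)[rows],
                    serial_b = names(b)[best_for_a[rows]],
                    similarity = sims[cbind(rows, best_for_a[rows])],
                    stringsAsFactors = FALSE)
  out <- out[out$similarity >= min_similarity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build syntenic blocks from an ortholog table
#'
#' Walks ortholog pairs in genome-A gene order and grows maximal runs that are
#' monotone in both serials, allowing up to `max_gap_genes` skipped genes on
#' either side between consecutive members. Descending runs in B are reported
#' as `inverted`. Block spans are the hull of member gene coordinates in each
#' genome. Every ortholog pair belongs to exactly one block.
#'
#' @param annot_a,annot_b [gene_annotation()]s of the two genomes.
#' @param orthologs Output of [pair_orthologs()] (one-to-one).
#' @param max_gap_genes Tolerated serial gap (default 2, absorbing
#'   lineage-specific insertions/deletions).
#' @return A `data.frame` with columns `a_start`, `a_end`, `b_start`, `b_end`
#'   (nt hulls), `orientation` (`same`/`inverted`), `n_genes`, and list column
#'   `pairs` of member (a, b) serial matrices.
#' @export
synteny_blocks <- function(annot_a, annot_b, orthologs, max_gap_genes = 2L) {
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), n_genes = integer(0))
  if (nrow(orthologs) == 0) return(empty)
  sa <- as.integer(orthologs$serial_a)
  sb <- as.integer(orthologs$serial_b)
  if (anyDuplicated(sa) || anyDuplicated(sb)) {
    stop("ortholog table is not one-to-one")
  }
  ord <- order(sa)
  sa <- sa[ord]; sb <- sb[ord]
  blocks <- list()
  cur <- list(a = sa[1], b = sb[1], dir = 0L)
  flush <- function(cur) {
    data.frame(n_genes = length(cur$a),
               orientation = if (cur$dir < 0) "inverted" else "same",
               a_first = cur$a[1], a_last = cur$a[length(cur$a)],
               b_first = cur$b[1], b_last = cur$b[length(cur$b)],
               pairs = I(list(cbind(a = cur$a, b = cur$b))))
  }
  if (length(sa) > 1) for (i in 2:length(sa)) {
    da <- sa[i] - cur$a[length(cur$a)]
    db <- sb[i] - cur$b[length(cur$b)]
    dir_ok <- cur$dir == 0L || sign(db) == cur$dir
    if (da <= max_gap_genes + 1L && abs(db) <= max_gap_genes + 1L &&
        db != 0L && dir_ok) {
      cur$a <- c(cur$a, sa[i]); cur$b <- c(cur$b, sb[i])
      if (cur$dir == 0L) cur$dir <- sign(db)
    } else {
      blocks[[length(blocks) + 1L]] <- flush(cur)
      cur <- list(a = sa[i], b = sb[i], dir = 0L)
    }
  }
  blocks[[length(blocks) + 1L]] <- flush(cur)
  out <- do.call(rbind, blocks)
  hull <- function(annot, serials) {
    rows <- match(serials, annot$serial)
    c(min(annot$start[rows]), max(annot$end[rows]))
  }
  spans <- lapply(seq_len(nrow(out)), function(i) {
    p <- out$pairs[[i]]
    c(hull(annot_a, p[, "a"]), hull(annot_b, p[, "b"]))
  })
  m <- do.call(rbind, spans)
  out$a_start <- m[, 1]; out$a_end <- m[, 2]
  out$b_start <- m[, 3]; out$b_end <- m[, 4]
  out[, c("a_start", "a_end", "b_start", "b_end", "orientation", "n_genes",
          "a_first", "a_last", "b_first", "b_last", "pairs")]
}

#' Load the betabaculovirus core-gene reference list
#'
#' A curated 37-name inventory of genes conserved across the Baculoviridae
#' (replication, transcription, packaging/assembly, viral release and oral
#' infectivity factors), shipped with the package; each row carries
#' pipe-separated aliases.
#'
#' @return A `data.frame` with columns `gene`, `aliases`, `category`.
#' @export
core_gene_reference <- function() {
  path <- system.file("extdata", "core_genes.tsv", package = "gvannot")
  if (!nzchar(path)) stop("core-gene reference list missing from the package")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Audit an annotation against the core-gene reference
#'
#' Label-based presence/absence of each of the 37 core genes: a core gene is
#' present when some feature label matches its name or one of its aliases
#' (case-insensitive, punctuation-insensitive).
#'
#' @param annotation A [gene_annotation()] with informative labels.
#' @param reference Reference table; defaults to [core_gene_reference()].
#' @return A `data.frame` with columns `gene`, `present`, `orf_serial`;
#'   attribute `n_present` carries the count.
#' @export
core_gene_audit <- function(annotation, reference = core_gene_reference()) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  labels <- norm(annotation$label)
  res <- lapply(seq_len(nrow(reference)), function(i) {
    names_i <- norm(strsplit(paste(reference$gene[i], reference$aliases[i],
                                   sep = "|"), "\\|")[[1]])
    names_i <- names_i[nzchar(names_i)]
    hit <- which(labels %in% names_i)
    data.frame(gene = reference$gene[i], present = length(hit) > 0,
               orf_serial = if (length(hit)) annotation$serial[hit[1]] else
                 NA_integer_)
  })
  out <- do.call(rbind, res)
  attr(out, "n_present") <- sum(out$present)
  out
}

#' Serially name repeated gene-family members
#'
#' Features carrying `family_label` get suffixes `-a`, `-b`, ... in ascending
#' serial (genomic) order — the convention used for baculovirus repeated ORF
#' (bro) families.
#'
#' @param annotation A [gene_annotation()].
#' @param family_label Label of the family (e.g. `"bro"`).
#' @return The annotation with suffixed labels.
#' @export
name_repeated_genes <- function(annotation, family_label) {
  rows <- which(annotation$label == family_label)
  if (length(rows) == 0) stop("no feature labelled '", family_label, "'")
  rows <- rows[order(annotation$serial[rows])]
  suffix <- vapply(seq_along(rows), function(i) {
    # a, b, ..., z, aa, ab, ... for very large families
    s <- ""
    i <- i - 1L
    repeat {
      s <- paste0(letters[(i %% 26L) + 1L], s)
      i <- i %/% 26L - 1L
      if (i < 0) break
    }
    s
  }, character(1))
  annotation$label[rows] <- paste0(family_label, "-", suffix)
  annotation
}
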