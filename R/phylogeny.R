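#' Progressive multiple alignment of protein sequences
#'
#' Classic progressive scheme: a k-mer distance matrix feeds a UPGMA guide
#' tree, and profiles are merged bottom-up by Needleman-Wunsch profile
#' alignment (BLOSUM62, affine gaps, open 10 / extend 0.5). Column-column
#' scores are the average substitution score over all residue pairs of the two
#' profile columns (gap pairs score 0).
#'
#' @param seqs Named character vector of >= 2 protein sequences.
#' @param gap_open,gap_extend Affine gap penalties (positive; defaults 10 and
#'   0.5).
#' @return A named character vector of equal-length aligned sequences (gap
#'   `-`), class `protein_msa`.
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_extend = 0.5) {
  if (length(seqs) < 2) stop("progressive_align needs at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  if (length(seqs) == 2) {
    rows <- profile_nw(msa_matrix(seqs[1]), msa_matrix(seqs[2]),
                       gap_open, gap_extend)
    return(matrix_msa(rows))
  }
  D <- kmer_distance(seqs)
  guide <- upgma_tree(D)
  merge_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    profs <- lapply(kids, function(k) {
      if (k <= length(seqs)) msa_matrix(seqs[guide$tip.label[k]])
      else merge_node(k)
    })
    out <- profs[[1]]
    for (p in profs[-1]) out <- profile_nw(out, p, gap_open, gap_extend)
    out
  }
  rows <- merge_node(length(seqs) + 1L)
  matrix_msa(rows[names(seqs), , drop = FALSE])
}

# character matrix (rows = sequences) from aligned/unaligned strings
msa_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

matrix_msa <- function(m) {
  out <- apply(m, 1, paste, collapse = "")
  class(out) <- "protein_msa"
  out
}

# k-mer (k = 3, shrinking for very short inputs) distance for guide trees
kmer_distance <- function(seqs) {
  k <- max(1L, min(3L, min(nchar(seqs)) ))
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- sum(pmin(ci[names(cj)], cj)[!is.na(ci[names(cj)])])
    denom <- min(sum(ci), sum(cj))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  D
}

# Needleman-Wunsch alignment of two profiles (character matrices) with affine
# gaps; returns the merged character matrix.
profile_nw <- function(A, B, gap_open, gap_extend) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  alpha <- rownames(BLOSUM62)
  colfreq <- function(M) {
    f <- apply(M, 2, function(col) {
      tab <- tabulate(factor(col, levels = alpha), nbins = length(alpha))
      tab
    })
    matrix(f, nrow = length(alpha)) / nrow(M)
  }
  FA <- colfreq(A); FB <- colfreq(B)
  S <- t(FA) %*% BLOSUM62 %*% FB # wA x wB column-column average scores
  wa <- ncol(A); wb <- ncol(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, wa + 1, wb + 1)
  tM <- tX <- tY <- matrix(0L, wa + 1, wb + 1)
  M[1, 1] <- 0
  for (i in 2:(wa + 1)) {
    prev <- pmax(M[i - 1, 1], X[i - 1, 1])
    X[i, 1] <- max(M[i - 1, 1] - gap_open, X[i - 1, 1] - gap_extend)
    tX[i, 1] <- if (M[i - 1, 1] - gap_open >= X[i - 1, 1] - gap_extend) 1L else 2L
  }
  for (j in 2:(wb + 1)) {
    Y[1, j] <- max(M[1, j - 1] - gap_open, Y[1, j - 1] - gap_extend)
    tY[1, j] <- if (M[1, j - 1] - gap_open >= Y[1, j - 1] - gap_extend) 1L else 3L
  }
  for (i in 2:(wa + 1)) {
    for (j in 2:(wb + 1)) {
      best <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best + S[i - 1, j - 1]
      tM[i, j] <- which.max(c(M[i - 1, j - 1], X[i - 1, j - 1],
                              Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      tX[i, j] <- if (M[i - 1, j] - gap_open >= X[i - 1, j] - gap_extend) 1L else 2L
      Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
      tY[i, j] <- if (M[i, j - 1] - gap_open >= Y[i, j - 1] - gap_extend) 1L else 3L
    }
  }
  # traceback
  i <- wa + 1L; j <- wb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  colsA <- integer(0); colsB <- integer(0) # 0 = gap column
  while (i > 1 || j > 1) {
    if (state == 1L) {
      colsA <- c(i - 1L, colsA); colsB <- c(j - 1L, colsB)
      state <- tM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      colsA <- c(i - 1L, colsA); colsB <- c(0L, colsB)
      state <- tX[i, j]; i <- i - 1L
    } else {
      colsA <- c(0L, colsA); colsB <- c(j - 1L, colsB)
      state <- tY[i, j]; j <- j - 1L
    }
    if (i == 1 && j > 1) state <- 3L
    if (j == 1 && i > 1) state <- 2L
  }
  expand <- function(M, cols) {
    out <- matrix("-", nrow(M), length(cols), dimnames = list(rownames(M), NULL))
    out[, cols != 0] <- M[, cols[cols != 0], drop = FALSE]
    out
  }
  rbind(expand(A, colsA), expand(B, colsB))
}

#' Concatenate per-marker alignments
#'
#' Column-wise concatenation keyed by taxon name. A taxon missing from one
#' marker gets an all-gap row for that partition (with a warning); taxa shared
#' by no marker pair is an error.
#'
#' @param alignments Named list of `protein_msa` objects (one per marker).
#' @return A `protein_msa` with attribute `partitions` (data frame: marker,
#'   start, end).
#' @export
concat_markers <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  taxa <- Reduce(union, lapply(alignments, names))
  common <- Reduce(intersect, lapply(alignments, names))
  if (length(common) == 0) stop("markers share no taxa")
  widths <- vapply(alignments, function(a) nchar(a[[1]]), numeric(1))
  rows <- setNames(rep("", length(taxa)), taxa)
  for (m in seq_along(alignments)) {
    a <- alignments[[m]]
    missing <- setdiff(taxa, names(a))
    if (length(missing)) {
      warning("taxa missing marker ", names(alignments)[m] %||% m, ": ",
              paste(missing, collapse = ", "), "; padded with gaps")
    }
    pad <- strrep("-", widths[m])
    rows <- paste0(rows, ifelse(taxa %in% names(a), a[match(taxa, names(a))],
                                pad))
  }
  names(rows) <- taxa
  class(rows) <- "protein_msa"
  ends <- cumsum(widths)
  attr(rows, "partitions") <- data.frame(
    marker = names(alignments) %||% paste0("marker", seq_along(alignments)),
    start = c(1, head(ends, -1) + 1), end = ends)
  rows
}

#' Pairwise distance matrix from a protein alignment
#'
#' Pairwise deletion: for each taxon pair, columns where either sequence has a
#' gap are dropped; `p` is the mismatch fraction over the remaining sites and
#' the Poisson-corrected distance is `-ln(1 - p)`.
#'
#' @param alignment A `protein_msa` (or named character vector of equal-length
#'   aligned strings).
#' @param model `"poisson"` (default) or `"p"` (raw p-distance).
#' @return A symmetric numeric matrix with zero diagonal and taxon dimnames.
#' @export
distance_matrix <- function(alignment, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- msa_matrix(unclass(alignment))
  if (nrow(m) < 2) stop("need at least 2 taxa")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stop("taxa ", rownames(m)[i], " and ", rownames(m)[j],
                       " share no comparable sites")
    p <- mean(m[i, ok] != m[j, ok])
    d <- if (model == "p") p else {
      if (p >= 1) stop("saturated pair (p = 1): Poisson distance undefined")
      -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

check_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) ||
      max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with the Q-criterion and the standard
#' distance update; ties in Q are broken deterministically by the
#' lexicographically smallest taxon pair (each cluster is represented by its
#' smallest member label). On an additive distance matrix the generating tree
#' (topology and branch lengths) is recovered exactly. The result is unrooted
#' (root trifurcation).
#'
#' @param D Symmetric distance matrix with taxon dimnames.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(D) {
  D <- check_dist(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  nwk <- as.list(labels)          # growing newick fragment per cluster
  rep_label <- labels             # lexicographic representative per cluster
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (n > 3) {
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      q <- (n - 2) * D[i, j] - r[i] - r[j]
      key <- sort(c(rep_label[i], rep_label[j]))
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(q = q, i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", nwk[[i]], fmt(li), nwk[[j]], fmt(lj))
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nwk <- c(nwk[keep], merged)
    rep_label <- c(rep_label[keep], min(best$key))
    n <- n - 1
  }
  # closing trifurcation via the three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[[1]], fmt(la), nwk[[2]], fmt(lb),
                 nwk[[3]], fmt(lc))
  ape::read.tree(text = txt)
}

#' UPGMA tree
#'
#' Average-linkage agglomerative clustering with ultrametric heights (node
#' height = half the average inter-cluster distance); ties are broken by the
#' lexicographically smallest taxon pair. The returned tree is rooted and
#' ultrametric: all root-to-leaf path lengths are equal.
#'
#' @param D Symmetric distance matrix with taxon dimnames.
#' @return A rooted `phylo` object.
#' @export
upgma_tree <- function(D) {
  D <- check_dist(D)
  n <- nrow(D)
  if (n < 2) stop("UPGMA needs at least 2 taxa")
  labels <- rownames(D)
  nwk <- as.list(labels)
  rep_label <- labels
  size <- rep(1L, n)
  height <- rep(0, n)
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (n > 1) {
    best <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      key <- sort(c(rep_label[i], rep_label[j]))
      if (is.null(best) || D[i, j] < best$d - 1e-12 ||
          (abs(D[i, j] - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(d = D[i, j], i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    merged <- sprintf("(%s:%s,%s:%s)", nwk[[i]], fmt(h - height[i]),
                      nwk[[j]], fmt(h - height[j]))
    dk <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nwk <- c(nwk[keep], merged)
    rep_label <- c(rep_label[keep], min(best$key))
    size <- c(size[keep], size[i] + size[j])
    height <- c(height[keep], h)
    n <- n - 1
  }
  ape::read.tree(text = paste0(nwk[[1]], ";"))
}

#' Bootstrap support for a distance tree
#'
#' Nonparametric bootstrap: alignment columns are resampled with replacement
#' `n_reps` times; the support of each internal edge of the full-data tree is
#' the fraction of replicate trees containing the same bipartition (clade).
#' Supports are attached as node labels. Resampling is driven by `seed` only,
#' so results are reproducible and independent of taxon input order.
#'
#' @param alignment A `protein_msa`.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param method `"nj"` or `"upgma"`.
#' @param model Distance model, see [distance_matrix()].
#' @return The full-data `phylo` tree with `node.label` = support fractions
#'   (root label empty).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L,
                              method = c("nj", "upgma"),
                              model = c("poisson", "p")) {
  method <- match.arg(method)
  model <- match.arg(model)
  stopifnot(n_reps >= 1)
  build <- function(aln) {
    D <- distance_matrix(aln, model = model)
    if (method == "nj") nj_tree(D) else upgma_tree(D)
  }
  m <- msa_matrix(unclass(alignment))
  m <- m[order(rownames(m)), , drop = FALSE] # input-order invariance
  full <- build(matrix_msa(m))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      build(matrix_msa(m[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(full, reps, rooted = (method == "upgma"))
  counts[is.na(counts)] <- 0L
  support <- counts / n_reps
  full$node.label <- as.character(support)
  if (!ape::is.rooted(full)) full$node.label[1] <- ""
  attr(full, "n_reps") <- n_reps
  full
}
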