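#' Construct a circular genome object
#'
#' The substrate of every scan in the package: an uppercase DNA sequence over
#' `{A,C,G,T,N}` plus topology. All coordinates in the package are 1-based
#' inclusive (GenBank convention). Features that span the origin of a circular
#' genome are stored "unwrapped", i.e. with `end > length(genome)`, which keeps
#' interval arithmetic linear.
#'
#' @param seq A single DNA string.
#' @param id Accession or name.
#' @param circular Logical; circular topology (default `TRUE`).
#' @return An object of class `circular_genome` with fields `id`, `seq`,
#'   `circular`, `length`.
#' @export
#' @examples
#' g <- circular_genome("ATGAAATAACCC", id = "toy")
#' g$length
circular_genome <- function(seq, id = "genome", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("sequence contains non-ACGTN characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  structure(
    list(id = id, seq = seq, circular = isTRUE(circular), length = nchar(seq)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d nt, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a gene annotation table
#'
#' An ordered table of ORF records. Serials are unique and consecutive from 1,
#' assigned clockwise by start coordinate. `end` may exceed the genome length
#' for features wrapping the origin (flagged by `wraps_origin`).
#'
#' @param start,end 1-based inclusive coordinates (`end` may exceed the genome
#'   length for origin-wrapping features).
#' @param strand `"+"` or `"-"`.
#' @param label Free-text product/gene labels.
#' @param genome A [circular_genome()] (used for bounds checking), or a genome
#'   length.
#' @param wraps_origin Logical; computed from `end > length` when `NULL`.
#' @return A `data.frame` of class `gene_annotation` with columns `serial`,
#'   `start`, `end`, `strand`, `wraps_origin`, `label` and attributes
#'   `genome_id`, `genome_length`.
#' @export
gene_annotation <- function(start, end, strand, label = NULL, genome,
                            wraps_origin = NULL) {
  L <- if (inherits(genome, "circular_genome")) genome$length else as.integer(genome)
  gid <- if (inherits(genome, "circular_genome")) genome$id else "genome"
  n <- length(start)
  stopifnot(length(end) == n)
  strand <- rep_len(as.character(strand), n)
  label <- rep_len(label %||% "orf", n)
  if (n > 0) {
    stopifnot(all(start >= 1), all(start <= L), all(end >= start),
              all(strand %in% c("+", "-")))
    if (any(end - start + 1 > L)) stop("feature longer than the genome")
  }
  wraps_origin <- wraps_origin %||% (end > L)
  ord <- order(start, end)
  ann <- data.frame(
    serial = seq_len(n),
    start = as.integer(start)[ord],
    end = as.integer(end)[ord],
    strand = as.character(strand)[ord],
    wraps_origin = as.logical(wraps_origin)[ord],
    label = as.character(label)[ord],
    stringsAsFactors = FALSE
  )
  attr(ann, "genome_id") <- gid
  attr(ann, "genome_length") <- L
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read a GenBank flat file
#'
#' Minimal parser for GenBank flat files: LOCUS (length, topology), `CDS`
#' features (including `complement()` and origin-spanning `join()` locations)
#' and the ORIGIN sequence. Feature coordinates are returned 1-based inclusive;
#' `join()` locations spanning the origin are flagged `wraps_origin` and stored
#' with unwrapped `end > length`.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with elements `genome` ([circular_genome()]) and `annotation`
#'   ([gene_annotation()]; zero rows if the record has no CDS features).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) stop("malformed GenBank record: no LOCUS line")
  locus <- strsplit(trimws(lines[locus_i[1]]), "[[:space:]]+")[[1]]
  id <- locus[2]
  circular <- any(tolower(locus) == "circular")

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0) stop("malformed GenBank record: no ORIGIN section")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  if (is.na(end_i)) end_i <- length(lines) + 1L
  if (end_i - 1L < origin_i[1] + 1L) {
    stop("empty ORIGIN in GenBank record (line ", origin_i[1], ")")
  }
  seq_lines <- lines[seq(origin_i[1] + 1L, end_i - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq)) stop("empty ORIGIN in GenBank record (line ", origin_i[1], ")")
  genome <- circular_genome(seq, id = id, circular = circular)
  L <- genome$length

  # collect CDS feature blocks
  feat_i <- grep("^FEATURES", lines)
  starts <- ends <- integer(0); strands <- wraps <- logical(0); labels <- character(0)
  if (length(feat_i)) {
    i <- feat_i[1] + 1L
    while (i < origin_i[1]) {
      line <- lines[i]
      if (grepl("^     [A-Za-z]", line)) {
        key <- trimws(substr(line, 1, 20))
        loc <- trimws(substr(line, 21, nchar(line)))
        j <- i + 1L
        # location continuation lines (no qualifier slash)
        while (j < origin_i[1] && grepl("^ {21}", lines[j]) &&
               !grepl("^ *\\/", lines[j]) && grepl("[0-9.,)]$", loc) &&
               grepl("[,(]$|,$", loc)) {
          loc <- paste0(loc, trimws(lines[j]))
          j <- j + 1L
        }
        quals <- character(0)
        while (j < origin_i[1] && grepl("^ {21}", lines[j]) &&
               !grepl("^     [A-Za-z]", lines[j])) {
          quals <- c(quals, trimws(lines[j]))
          j <- j + 1L
        }
        if (key == "CDS") {
          parsed <- tryCatch(parse_genbank_location(loc, L),
                             error = function(e) {
                               stop("malformed CDS location at line ", i, ": ",
                                    conditionMessage(e))
                             })
          lab <- genbank_qualifier(quals, c("gene", "product", "label")) %||% "orf"
          starts <- c(starts, parsed$start)
          ends <- c(ends, parsed$end)
          strands <- c(strands, parsed$strand)
          wraps <- c(wraps, parsed$wraps)
          labels <- c(labels, lab)
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  ann <- gene_annotation(starts, ends, strands, labels, genome,
                         wraps_origin = wraps)
  list(genome = genome, annotation = ann)
}

# Parse a GenBank location string: a..b, complement(...), join(a..L,1..b).
parse_genbank_location <- function(loc, L) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    seg <- lapply(parts, parse_simple_span)
    if (length(seg) == 2 && seg[[1]][2] == L && seg[[2]][1] == 1) {
      # spans the origin: unwrap
      return(list(start = seg[[1]][1], end = L + seg[[2]][2],
                  strand = strand, wraps = TRUE))
    }
    stop("unsupported join() location: ", loc)
  }
  s <- parse_simple_span(loc)
  list(start = s[1], end = s[2], strand = strand, wraps = FALSE)
}

parse_simple_span <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+)\\.\\.([0-9]+)$", trimws(x)))[[1]]
  if (length(m) != 3) stop("cannot parse span '", x, "'")
  c(as.integer(m[2]), as.integer(m[3]))
}

genbank_qualifier <- function(quals, keys) {
  for (k in keys) {
    hit <- grep(paste0("^/", k, "="), quals, value = TRUE)
    if (length(hit)) return(gsub('^/[a-z]+="?|"$', "", hit[1]))
  }
  NULL
}

#' Rotate a circular genome so that an anchor gene starts at position 1
#'
#' Re-anchors the coordinate system at the ATG of the feature carrying
#' `anchor_label` (e.g. granulin), on the plus strand: if the anchor lies on
#' the minus strand the genome is reverse-complemented first. All feature
#' coordinates are remapped, the anchor becomes serial 1 and subsequent serials
#' are assigned clockwise by start coordinate.
#'
#' @param genome A [circular_genome()]; must be circular.
#' @param annotation A [gene_annotation()].
#' @param anchor_label Label carried by exactly one feature.
#' @return A list with rotated `genome` and remapped `annotation`.
#' @export
rotate_to_anchor <- function(genome, annotation, anchor_label) {
  stopifnot(inherits(genome, "circular_genome"))
  if (!genome$circular) stop("rotate_to_anchor requires a circular genome")
  hit <- which(annotation$label == anchor_label)
  if (length(hit) == 0) {
    stop("anchor '", anchor_label, "' not found; labels present: ",
         paste(unique(annotation$label), collapse = ", "))
  }
  if (length(hit) > 1) {
    stop("anchor '", anchor_label, "' is ambiguous (serials ",
         paste(annotation$serial[hit], collapse = ", "), ")")
  }
  anchor <- annotation[hit, ]
  if (anchor$strand == "-") {
    flipped <- flip_genome(genome, annotation)
    genome <- flipped$genome
    annotation <- flipped$annotation
    anchor <- annotation[annotation$label == anchor_label, ]
  }
  rotate_genome(genome, annotation, offset = anchor$start - 1L)
}

#' Rotate a circular genome by a fixed offset
#'
#' Position `offset + 1` of the input becomes position 1 of the output. The
#' inverse rotation is `rotate_genome(..., offset = L - offset)`.
#'
#' @param genome A [circular_genome()].
#' @param annotation Optional [gene_annotation()] to remap.
#' @param offset Number of positions to rotate (0 is the identity).
#' @return A list with `genome` and `annotation` (NULL if none supplied).
#' @export
rotate_genome <- function(genome, annotation = NULL, offset = 0L) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  offset <- ((offset %% L) + L) %% L
  seq2 <- if (offset == 0) genome$seq else
    paste0(substr(genome$seq, offset + 1L, L), substr(genome$seq, 1L, offset))
  g2 <- circular_genome(seq2, id = genome$id, circular = genome$circular)
  ann2 <- NULL
  if (!is.null(annotation) && nrow(annotation) > 0) {
    ns <- ((annotation$start - offset - 1L) %% L) + 1L
    span <- annotation$end - annotation$start
    ann2 <- gene_annotation(ns, ns + span, annotation$strand,
                            annotation$label, g2)
  } else if (!is.null(annotation)) {
    ann2 <- gene_annotation(integer(0), integer(0), character(0), genome = g2)
  }
  list(genome = g2, annotation = ann2)
}

# Reverse-complement a genome and remap the annotation onto the new strand.
flip_genome <- function(genome, annotation) {
  L <- genome$length
  g2 <- circular_genome(reverse_complement(genome$seq), id = genome$id,
                        circular = genome$circular)
  if (nrow(annotation) == 0) {
    return(list(genome = g2,
                annotation = gene_annotation(integer(0), integer(0),
                                             character(0), genome = g2)))
  }
  # plus-strand interval [s, e] (e possibly > L) maps to [L - e + 1, L - s + 1]
  ns <- L - annotation$end + 1L
  ne <- L - annotation$start + 1L
  wrap <- ns < 1L
  ns[wrap] <- ns[wrap] + L
  ne[wrap] <- ne[wrap] + L
  ann2 <- gene_annotation(ns, ne, ifelse(annotation$strand == "+", "-", "+"),
                          annotation$label, g2)
  list(genome = g2, annotation = ann2)
}

#' Write sequences to FASTA
#'
#' @param x A [circular_genome()], a named character vector, or a
#'   `Biostrings::XStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "circular_genome")) {
    x <- setNames(Biostrings::DNAStringSet(x$seq), x$id)
  } else if (is.character(x)) {
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a circular genome
#'
#' @param path FASTA path (first record used).
#' @param circular Topology to assume.
#' @return A [circular_genome()].
#' @export
read_fasta_genome <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path)
  circular_genome(as.character(ss[[1]]),
                  id = strsplit(names(ss)[1], "[[:space:]]")[[1]][1],
                  circular = circular)
}

#' Write an annotation as GFF3
#'
#' Coordinates are written 1-based inclusive (GFF3 convention). A feature that
#' wraps the origin is written as two segments sharing an `ID` attribute.
#'
#' @param annotation A [gene_annotation()].
#' @param path Output path.
#' @param source Column 2 of the GFF3 output.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, source = "gvannot") {
  L <- attr(annotation, "genome_length")
  gid <- attr(annotation, "genome_id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", gid, L)), con)
  for (i in seq_len(nrow(annotation))) {
    f <- annotation[i, ]
    attrs <- sprintf("ID=orf%03d;serial=%d;label=%s", f$serial, f$serial,
                     f$label)
    for (seg in split_circular(f$start, f$end, L)) {
      writeLines(paste(gid, source, "CDS", seg[1], seg[2], ".", f$strand, "0",
                       attrs, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' Reassembles origin-wrapping features from their two same-`ID` segments.
#'
#' @param path GFF3 path.
#' @param genome_length Genome length; taken from the `##sequence-region`
#'   pragma when `NULL`.
#' @return A [gene_annotation()].
#' @export
read_gff3 <- function(path, genome_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  gid <- "genome"
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr)) {
    f <- strsplit(trimws(sr[1]), "[[:space:]]+")[[1]]
    gid <- f[2]
    genome_length <- genome_length %||% as.integer(f[4])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    return(gene_annotation(integer(0), integer(0), character(0),
                           genome = genome_length %||% 1L))
  }
  m <- do.call(rbind, strsplit(body, "\t"))
  if (ncol(m) != 9) stop("malformed GFF3: expected 9 columns in ", path)
  df <- data.frame(start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                   strand = m[, 7],
                   id = sub(".*ID=([^;]+).*", "\\1", m[, 9]),
                   label = sub(".*label=([^;]+).*", "\\1", m[, 9]),
                   stringsAsFactors = FALSE)
  L <- genome_length %||% max(df$end)
  out <- do.call(rbind, lapply(split(df, df$id), function(segs) {
    if (nrow(segs) == 1) return(segs[c("start", "end", "strand", "label")])
    segs <- segs[order(segs$start), ]
    # wrap: segment ending at L pairs with segment starting at 1
    stopifnot(nrow(segs) == 2, segs$start[1] == 1, segs$end[2] == L)
    data.frame(start = segs$start[2], end = L + segs$end[1],
               strand = segs$strand[1], label = segs$label[1],
               stringsAsFactors = FALSE)
  }))
  ann <- gene_annotation(out$start, out$end, out$strand, out$label, L)
  attr(ann, "genome_id") <- gid
  ann
}
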