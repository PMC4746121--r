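#' Configuration for the full annotation pipeline
#'
#' Bundles per-stage parameters. The repeat and hr stages default to a
#' genome-scale specificity profile (tandem repeats: min span 30 nt at 85%
#' identity; palindromes: min arm 20 nt with 2 mismatches) chosen so that the
#' expected number of chance calls on a ~112 kb random background is well
#' below one; the generic scanners keep their own permissive defaults.
#'
#' @param orf An [orf_config()].
#' @param promoter_motifs Motif table ([default_promoter_motifs()]).
#' @param promoter_window Upstream window in nt (default 120).
#' @param tr Tandem-repeat stage parameters (list).
#' @param hr hr stage parameters (list, see [find_hrs()]).
#' @param skew GC-skew window/step (list).
#' @param anchor Label to rotate the genome to before annotation (NULL: keep
#'   coordinates as given).
#' @return A list of class `annotate_config`.
#' @export
annotate_config <- function(orf = orf_config(),
                            promoter_motifs = default_promoter_motifs(),
                            promoter_window = 120L,
                            tr = list(min_unit = 1L, max_unit = 500L,
                                      min_copies = 3, min_len = 30L,
                                      min_identity = 0.85),
                            hr = list(min_arm = 20L, max_loop = 20L,
                                      max_mismatch = 2L, cluster_gap = 1000L,
                                      min_cluster = 2L),
                            skew = list(window_nt = 1000L, step_nt = 100L),
                            anchor = NULL) {
  structure(list(orf = orf, promoter_motifs = promoter_motifs,
                 promoter_window = promoter_window, tr = tr, hr = hr,
                 skew = skew, anchor = anchor),
            class = "annotate_config")
}

#' Run the full genome characterisation pipeline
#'
#' Stages, in dependency order: (optional) rotation to the anchor gene, ORF
#' calling (unless an annotation is supplied), composition and GC skew,
#' promoter-motif scanning, tandem repeats (with placement and genome
#' fraction), palindromes/hrs, and protein features. Stage failures are
#' isolated: an error is recorded under the stage name and later stages still
#' run where possible.
#'
#' @param genome A [circular_genome()] (or path to a FASTA/GenBank file).
#' @param annotation Optional [gene_annotation()]; called de novo when NULL.
#' @param config An [annotate_config()].
#' @return A list of class `genome_report`; every number in it is
#'   recomputable by calling the underlying operation with the parameters
#'   recorded in `$parameters`.
#' @export
run_annotate <- function(genome, annotation = NULL,
                         config = annotate_config()) {
  if (is.character(genome)) {
    genome <- if (grepl("\\.g(b|bk|enbank)$", genome, ignore.case = TRUE)) {
      gb <- read_genbank(genome)
      if (is.null(annotation) && nrow(gb$annotation) > 0) {
        annotation <- gb$annotation
      }
      gb$genome
    } else {
      read_fasta_genome(genome)
    }
  }
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  if (!is.null(config$anchor) && !is.null(annotation)) {
    rot <- stage("rotate", rotate_to_anchor(genome, annotation, config$anchor))
    if (!is.null(rot)) { genome <- rot$genome; annotation <- rot$annotation }
  }
  if (is.null(annotation)) {
    annotation <- stage("orf_calling", call_orfs(genome, config$orf))
  }
  comp <- stage("composition", list(
    gc = gc_content(genome),
    skew = gc_skew_profile(genome, config$skew$window_nt, config$skew$step_nt)))
  orf_stats <- stage("orf_stats", {
    if (nrow(annotation) > 0) {
      ig <- intergenic_regions(genome, annotation)
      list(n_orfs = nrow(annotation),
           orientation = orientation_split(annotation),
           coding_density = coding_density(genome, annotation),
           extremal = extremal_orfs(annotation),
           intergenic = ig,
           largest_intergenic = if (nrow(ig)) ig[1, ] else NULL)
    } else {
      list(n_orfs = 0L, orientation = c(same = 0L, opposite = 0L),
           coding_density = 0, extremal = NULL, intergenic = NULL,
           largest_intergenic = NULL)
    }
  })
  promoters <- stage("promoters",
                     scan_upstream(genome, annotation, config$promoter_motifs,
                                   config$promoter_window))
  repeats <- stage("tandem_repeats", {
    tr <- config$tr
    reps <- find_tandem_repeats(genome, min_unit = tr$min_unit,
                                max_unit = tr$max_unit,
                                min_copies = tr$min_copies,
                                min_len = tr$min_len,
                                min_identity = tr$min_identity)
    reps <- classify_repeat_placement(reps, annotation, genome)
    list(table = reps,
         genome_fraction_pct = repeat_genome_fraction(reps, genome),
         placement_counts = table(factor(reps$placement,
                                         c("coding", "noncoding", "both"))))
  })
  hrs <- stage("hrs", {
    h <- config$hr
    find_hrs(genome, min_arm = h$min_arm, max_loop = h$max_loop,
             max_mismatch = h$max_mismatch, cluster_gap = h$cluster_gap,
             min_cluster = h$min_cluster)
  })
  proteins <- stage("proteins", {
    if (nrow(annotation) == 0) NULL else {
      aa <- orf_proteins(genome, annotation)
      data.frame(
        orf_serial = annotation$serial,
        length_aa = nchar(aa),
        mw_kda = round(attr(aa, "mw_da") / 1000, 2),
        n_cys_motifs = vapply(aa, function(p) {
          count_cys_domains(find_cys_motif(p))
        }, integer(1)),
        longest_polyq = vapply(aa, function(p) {
          r <- find_homopolymer_runs(p, "Q", min_len = 2L)
          if (nrow(r)) max(r$length) else 0L
        }, integer(1)),
        row.names = NULL)
    }
  })
  structure(list(
    genome_id = genome$id,
    parameters = config,
    genome_length = genome$length,
    gc_content = comp$gc,
    skew = comp$skew,
    annotation = annotation,
    orf_stats = orf_stats,
    promoter_hits = promoters,
    repeats = repeats,
    hrs = hrs,
    proteins = proteins,
    errors = errors
  ), class = "genome_report")
}

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf("<genome_report> %s\n", x$genome_id))
  cat(sprintf("  genome: %d nt, GC %.1f%%\n", x$genome_length,
              100 * x$gc_content))
  if (!is.null(x$orf_stats)) {
    os <- x$orf_stats
    cat(sprintf("  ORFs: %d (%d same / %d opposite strand), coding density %.1f%%\n",
                os$n_orfs, os$orientation["same"], os$orientation["opposite"],
                100 * os$coding_density))
    if (!is.null(os$largest_intergenic)) {
      cat(sprintf("  largest intergenic gap: %d nt (AT %.0f%%) between ORF%d and ORF%d\n",
                  os$largest_intergenic$length,
                  100 * os$largest_intergenic$at_content,
                  os$largest_intergenic$serial_before,
                  os$largest_intergenic$serial_after))
    }
  }
  if (!is.null(x$repeats)) {
    cat(sprintf("  tandem repeats: %d calls, %.2f%% of the genome\n",
                nrow(x$repeats$table), x$repeats$genome_fraction_pct))
  }
  if (!is.null(x$hrs)) {
    cat(sprintf("  hrs: %d regions containing %d palindromes\n",
                nrow(x$hrs$regions), sum(x$hrs$regions$n_palindromes)))
  }
  if (length(x$errors)) {
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a genome report to a directory
#'
#' Produces `report.json` (machine-readable summary), `orfs.gff3`,
#' `proteins.faa`, `repeats.tsv`, `hrs.tsv` and `promoter_hits.tsv`.
#'
#' @param report A `genome_report`.
#' @param dir Output directory (created if missing).
#' @param genome The [circular_genome()] used (needed for protein FASTA).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, genome = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    genome_id = report$genome_id,
    genome_length = report$genome_length,
    gc_content = report$gc_content,
    n_orfs = report$orf_stats$n_orfs,
    orientation_same = unname(report$orf_stats$orientation["same"]),
    orientation_opposite = unname(report$orf_stats$orientation["opposite"]),
    coding_density = report$orf_stats$coding_density,
    largest_intergenic_nt = report$orf_stats$largest_intergenic$length,
    n_tandem_repeats = nrow(report$repeats$table),
    repeat_genome_fraction_pct = report$repeats$genome_fraction_pct,
    n_hrs = nrow(report$hrs$regions),
    n_hr_palindromes = sum(report$hrs$regions$n_palindromes),
    parameters = list(
      orf = unclass(report$parameters$orf),
      tr = report$parameters$tr,
      hr = report$parameters$hr,
      promoter_window = report$parameters$promoter_window)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$annotation) && nrow(report$annotation) > 0) {
    write_gff3(report$annotation, file.path(dir, "orfs.gff3"))
  }
  if (!is.null(genome) && !is.null(report$annotation) &&
      nrow(report$annotation) > 0) {
    aa <- orf_proteins(genome, report$annotation)
    write_fasta(setNames(as.character(aa),
                         sprintf("%s_orf%03d", report$genome_id,
                                 report$annotation$serial)),
                file.path(dir, "proteins.faa"))
  }
  wtsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$repeats)) wtsv(report$repeats$table, "repeats.tsv")
  if (!is.null(report$hrs)) wtsv(report$hrs$regions, "hrs.tsv")
  if (!is.null(report$promoter_hits)) wtsv(report$promoter_hits,
                                           "promoter_hits.tsv")
  invisible(dir)
}
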