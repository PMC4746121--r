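#' Find tandem repeats with fractional copy numbers
#'
#' Period-by-period scan: for each candidate unit length `u` the sequence is
#' compared with itself shifted by `u`; maximal high-identity stretches of the
#' match vector (seeded at runs of consecutive matches and extended while the
#' identity stays above `min_identity`) become repeat calls. Copy number is the
#' aligned span divided by the unit length, reported to 0.1 (fractional final
#' copies allowed). Overlapping calls with the same period are merged; nested
#' harmonics (unit `2u` over the same span as unit `u` at no better identity)
#' are suppressed in favour of the smaller unit. On circular genomes the
#' sequence is doubled for scanning and second-copy duplicates discarded, so
#' arrays crossing the origin are found.
#'
#' @param genome A [circular_genome()] or a plain DNA string (treated linear).
#' @param min_unit,max_unit Unit length bounds (defaults 1 and 500 nt).
#' @param min_copies Minimum copy number (default 3).
#' @param min_len Minimum array span in nt (default 24).
#' @param min_identity Minimum fraction of matching positions between the
#'   array and its unit-shifted self (default 0.8).
#' @return A `data.frame` with columns `start`, `end` (1-based inclusive;
#'   `end` may exceed the genome length for origin-crossing arrays),
#'   `unit_len`, `copy_number`, `consensus_unit`, `percent_identity`,
#'   `placement` (`NA` until [classify_repeat_placement()]).
#' @export
find_tandem_repeats <- function(genome, min_unit = 1L, max_unit = 500L,
                                min_copies = 3, min_len = 24L,
                                min_identity = 0.8) {
  if (inherits(genome, "circular_genome")) {
    seq <- genome$seq; L <- genome$length; circular <- genome$circular
  } else {
    seq <- toupper(genome); L <- nchar(seq); circular <- FALSE
  }
  s2 <- if (circular) paste0(seq, seq) else seq
  n <- nchar(s2)
  seed_len <- 5L
  calls <- list()
  for (u in seq.int(min_unit, min(max_unit, floor((n - 1) / 2)))) {
    m <- .period_match(s2, u)
    r <- rle(m)
    k <- length(r$lengths)
    if (k == 0) next
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    seeds <- which(r$values & r$lengths >= seed_len)
    if (length(seeds) == 0) next
    done_until <- 0L
    for (sd in seeds) {
      if (run_start[sd] <= done_until) next
      lo <- hi <- sd
      matches <- r$lengths[sd]
      total <- r$lengths[sd]
      # absorb FALSE+TRUE run pairs while identity stays above threshold
      repeat {
        grew <- FALSE
        if (hi + 2L <= k && r$values[hi + 2L]) {
          add_f <- r$lengths[hi + 1L]; add_t <- r$lengths[hi + 2L]
          if ((matches + add_t) / (total + add_f + add_t) >= min_identity) {
            matches <- matches + add_t; total <- total + add_f + add_t
            hi <- hi + 2L; grew <- TRUE
          }
        }
        if (lo - 2L >= 1L && r$values[lo - 2L]) {
          add_f <- r$lengths[lo - 1L]; add_t <- r$lengths[lo - 2L]
          if ((matches + add_t) / (total + add_f + add_t) >= min_identity) {
            matches <- matches + add_t; total <- total + add_f + add_t
            lo <- lo - 2L; grew <- TRUE
          }
        }
        if (!grew) break
      }
      done_until <- run_end[hi]
      # trim to the best-scoring sub-segment (match +1, mismatch -5): greedy
      # absorption may creep into flanking sequence on chance matches
      seg <- lo:hi
      w <- ifelse(r$values[seg], r$lengths[seg], -5L * r$lengths[seg])
      best <- c(-Inf, 1L, 1L); cur <- 0; cur_lo <- 1L
      for (q in seq_along(w)) {
        if (cur <= 0) { cur <- 0; cur_lo <- q }
        cur <- cur + w[q]
        if (r$values[seg[q]] && cur > best[1]) best <- c(cur, cur_lo, q)
      }
      if (!is.finite(best[1])) next
      lo2 <- seg[best[2]]; hi2 <- seg[best[3]]
      if (!r$values[lo2]) lo2 <- lo2 + 1L # segments start/end on matches
      a <- run_start[lo2]; b <- run_end[hi2]
      matches <- sum(r$lengths[lo2:hi2][r$values[lo2:hi2]])
      span <- b - a + 1L + u
      if (span < min_len) next
      if (span / u < min_copies - 1e-9) next
      identity <- matches / (b - a + 1L)
      if (identity < min_identity) next
      calls[[length(calls) + 1L]] <-
        data.frame(start = a, end = a + span - 1L, unit_len = u,
                   matches = matches, compared = b - a + 1L,
                   percent_identity = identity)
    }
  }
  if (length(calls) == 0) return(empty_repeat_table())
  tab <- do.call(rbind, calls)
  if (circular) {
    tab <- tab[tab$start <= L, , drop = FALSE]
    over <- tab$end - tab$start + 1L > L
    tab$end[over] <- tab$start[over] + L - 1L
    if (nrow(tab) == 0) return(empty_repeat_table())
  }
  # merge overlapping same-period calls
  tab <- do.call(rbind, lapply(split(tab, tab$unit_len), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    out <- g[1, , drop = FALSE]
    if (nrow(g) > 1) for (i in 2:nrow(g)) {
      last <- nrow(out)
      if (g$start[i] <= out$end[last]) {
        w_old <- out$compared[last]; w_new <- g$compared[i]
        out$end[last] <- max(out$end[last], g$end[i])
        out$compared[last] <- out$end[last] - out$start[last] + 1L - out$unit_len[last]
        out$matches[last] <- round(out$percent_identity[last] * w_old +
                                     g$percent_identity[i] * max(0, out$compared[last] - w_old))
        out$percent_identity[last] <- min(1, out$matches[last] / out$compared[last])
      } else {
        out <- rbind(out, g[i, , drop = FALSE])
      }
    }
    out
  }))
  # suppress nested harmonics: drop the larger unit when a smaller-unit call
  # covers (most of) the same span at no worse identity
  tab <- tab[order(tab$unit_len, tab$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(tab))) {
      if (i == j || !keep[j]) next
      if (tab$unit_len[j] <= tab$unit_len[i]) next
      ov <- max(0L, min(tab$end[i], tab$end[j]) -
                  max(tab$start[i], tab$start[j]) + 1L)
      small_span <- min(tab$end[i] - tab$start[i], tab$end[j] - tab$start[j]) + 1L
      if (ov >= 0.8 * small_span &&
          tab$percent_identity[i] >= tab$percent_identity[j] - 0.02) {
        keep[j] <- FALSE
      }
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab$copy_number <- round((tab$end - tab$start + 1L) / tab$unit_len, 1)
  tab$consensus_unit <- vapply(seq_len(nrow(tab)), function(i) {
    consensus_unit(s2, tab$start[i], tab$end[i], tab$unit_len[i])
  }, character(1))
  tab <- tab[order(tab$start, tab$unit_len),
             c("start", "end", "unit_len", "copy_number", "consensus_unit",
               "percent_identity")]
  tab$placement <- NA_character_
  rownames(tab) <- NULL
  tab
}

empty_repeat_table <- function() {
  data.frame(start = integer(0), end = integer(0), unit_len = integer(0),
             copy_number = numeric(0), consensus_unit = character(0),
             percent_identity = numeric(0), placement = character(0))
}

# Majority-vote consensus unit of an array (phase anchored at `start`).
consensus_unit <- function(seq, start, end, u) {
  x <- strsplit(substr(seq, start, end), "")[[1]]
  paste(vapply(seq_len(u), function(k) {
    col <- x[seq.int(k, length(x), by = u)]
    names(which.max(table(col)))
  }, character(1)), collapse = "")
}

#' Classify repeat placement relative to the annotation
#'
#' `coding` when the array lies fully inside some ORF span, `noncoding` when it
#' overlaps no ORF, `both` otherwise.
#'
#' @param repeats Output of [find_tandem_repeats()].
#' @param annotation A [gene_annotation()].
#' @param genome The [circular_genome()] (for circular overlap arithmetic).
#' @return `repeats` with the `placement` column filled.
#' @export
classify_repeat_placement <- function(repeats, annotation, genome) {
  L <- genome$length
  if (nrow(repeats) == 0) return(repeats)
  repeats$placement <- vapply(seq_len(nrow(repeats)), function(i) {
    rl <- repeats$end[i] - repeats$start[i] + 1L
    ov <- vapply(seq_len(nrow(annotation)), function(j) {
      as.numeric(circ_overlap(repeats$start[i], repeats$end[i],
                              annotation$start[j], annotation$end[j], L))
    }, numeric(1))
    if (length(ov) == 0 || all(ov == 0)) "noncoding"
    else if (any(ov == rl)) "coding"
    else {
      cov <- union_width(c(repeats$start[i], annotation$start),
                         c(repeats$end[i], annotation$end), L) -
        union_width(annotation$start, annotation$end, L)
      if (cov == 0) "coding" else "both"
    }
  }, character(1))
  repeats
}

#' Fraction of the genome covered by tandem repeats
#'
#' `100 * |union of repeat spans| / genome length`; overlapping calls are not
#' double-counted.
#'
#' @param repeats Output of [find_tandem_repeats()].
#' @param genome A [circular_genome()].
#' @return A percentage.
#' @export
repeat_genome_fraction <- function(repeats, genome) {
  if (nrow(repeats) == 0) return(0)
  100 * union_width(repeats$start, repeats$end, genome$length) / genome$length
}

#' Find maximal imperfect palindromes
#'
#' Enumerates, for every centre and loop length up to `max_loop`, the maximal
#' inverted repeat whose arms reverse-complement each other with at most
#' `max_mismatch` substitutions; a call is maximal when extending either arm
#' would push the mismatch count past the budget (or run off the sequence).
#' All maximal calls are returned, sorted by position.
#'
#' @param seq A DNA string or a [circular_genome()]. Circular genomes are
#'   scanned across the origin (sequence doubled, duplicates dropped).
#' @param min_arm Minimum arm length (default 8).
#' @param max_loop Maximum loop (spacer) length between the arms (default 20).
#' @param max_mismatch Maximum substitutions between the arms (default 2).
#' @param dedupe Collapse overlapping calls to one per locus, keeping the
#'   longest arm (ties: fewest mismatches, smallest loop). Default `FALSE`.
#' @return A `data.frame` with columns `center` (position of the last base of
#'   the left arm), `arm_len`, `loop_len`, `mismatches`, `start`, `end`.
#' @export
find_palindromes <- function(seq, min_arm = 8L, max_loop = 20L,
                             max_mismatch = 2L, dedupe = FALSE) {
  circular <- FALSE
  if (inherits(seq, "circular_genome")) {
    circular <- seq$circular
    L <- seq$length
    seq <- seq$seq
  } else {
    seq <- toupper(seq)
    L <- nchar(seq)
  }
  s2 <- if (circular) paste0(seq, seq) else seq
  calls <- .scan_palindromes(s2, as.integer(min_arm), as.integer(max_loop),
                             as.integer(max_mismatch))
  if (circular && nrow(calls) > 0) {
    calls <- calls[calls$start >= 1 & calls$start <= L &
                     calls$end - calls$start + 1 <= L, , drop = FALSE]
  } else if (nrow(calls) > 0) {
    calls <- calls[calls$start >= 1, , drop = FALSE]
  }
  calls <- calls[order(calls$start, calls$loop_len), , drop = FALSE]
  rownames(calls) <- NULL
  if (dedupe && nrow(calls) > 1) {
    calls <- calls[order(-calls$arm_len, calls$mismatches, calls$loop_len), ,
                   drop = FALSE]
    keep <- rep(TRUE, nrow(calls))
    for (i in seq_len(nrow(calls))) {
      if (!keep[i]) next
      later <- which(keep & seq_len(nrow(calls)) > i)
      if (length(later) == 0) next
      ov <- pmin(calls$end[later], calls$end[i]) -
        pmax(calls$start[later], calls$start[i]) + 1
      keep[later[ov > 0]] <- FALSE
    }
    calls <- calls[keep, , drop = FALSE]
    calls <- calls[order(calls$start), , drop = FALSE]
    rownames(calls) <- NULL
  }
  calls
}

#' Cluster palindromes into homologous regions (hrs)
#'
#' Single-linkage clustering of palindrome spans along the circle: palindromes
#' whose spans are at most `cluster_gap` apart join the same region; regions
#' with at least `min_cluster` palindromes are reported, numbered `hr1`,
#' `hr2`, ... clockwise from position 1. Baculovirus hrs are AT-rich cassettes
#' of clustered imperfect palindromes acting as transcription enhancers and
#' putative replication origins.
#'
#' @param palindromes Output of [find_palindromes()].
#' @param genome A [circular_genome()] (for AT content and circular gaps).
#' @param cluster_gap Maximum gap in nt between member spans (default 1000).
#' @param min_cluster Minimum palindromes per region (default 2).
#' @return A `data.frame` with columns `id`, `start`, `end`, `n_palindromes`,
#'   `at_content`.
#' @export
cluster_hrs <- function(palindromes, genome, cluster_gap = 1000L,
                        min_cluster = 2L) {
  empty <- data.frame(id = character(0), start = integer(0), end = integer(0),
                      n_palindromes = integer(0), at_content = numeric(0))
  if (nrow(palindromes) == 0) return(empty)
  L <- genome$length
  p <- palindromes[order(palindromes$start), , drop = FALSE]
  reg_start <- p$start[1]; reg_end <- p$end[1]; n <- 1L
  regions <- list()
  flush <- function(s, e, n) data.frame(start = s, end = e, n_palindromes = n)
  if (nrow(p) > 1) for (i in 2:nrow(p)) {
    if (p$start[i] - reg_end - 1 <= cluster_gap) {
      reg_end <- max(reg_end, p$end[i]); n <- n + 1L
    } else {
      regions[[length(regions) + 1L]] <- flush(reg_start, reg_end, n)
      reg_start <- p$start[i]; reg_end <- p$end[i]; n <- 1L
    }
  }
  regions[[length(regions) + 1L]] <- flush(reg_start, reg_end, n)
  reg <- do.call(rbind, regions)
  # circular wrap: last region may join the first across the origin
  if (genome$circular && nrow(reg) > 1) {
    wrap_gap <- (reg$start[1] + L) - reg$end[nrow(reg)] - 1
    if (wrap_gap <= cluster_gap) {
      k <- nrow(reg)
      merged <- data.frame(start = reg$start[k],
                           end = reg$end[1] + L,
                           n_palindromes = reg$n_palindromes[1] +
                             reg$n_palindromes[k])
      reg <- rbind(reg[-c(1, k), , drop = FALSE], merged)
    }
  }
  reg <- reg[reg$n_palindromes >= min_cluster, , drop = FALSE]
  if (nrow(reg) == 0) return(empty)
  reg <- reg[order(((reg$start - 1) %% L) + 1), , drop = FALSE]
  reg$id <- sprintf("hr%d", seq_len(nrow(reg)))
  reg$at_content <- vapply(seq_len(nrow(reg)), function(i) {
    at_content(circ_substr(genome$seq, reg$start[i], reg$end[i]))
  }, numeric(1))
  rownames(reg) <- NULL
  reg[, c("id", "start", "end", "n_palindromes", "at_content")]
}

#' Genome-scale hr detection
#'
#' Convenience wrapper: palindrome scan of the whole (circular) genome at a
#' genome-scale specificity profile, one call per locus, clustered into hrs.
#' The defaults differ from [find_palindromes()]: at 112 kb scale a minimum
#' arm of 20 nt (with 2 mismatches allowed) keeps the expected number of
#' chance palindromes below 0.01 per genome, so every reported locus is a
#' genuine inverted-repeat cassette member.
#'
#' @param genome A [circular_genome()].
#' @param min_arm,max_loop,max_mismatch Palindrome parameters (defaults 20,
#'   20, 2).
#' @param cluster_gap,min_cluster Clustering parameters (defaults 1000, 2).
#' @return A list with `palindromes` (deduplicated calls) and `regions`
#'   (the [cluster_hrs()] table).
#' @export
find_hrs <- function(genome, min_arm = 20L, max_loop = 20L, max_mismatch = 2L,
                     cluster_gap = 1000L, min_cluster = 2L) {
  pal <- find_palindromes(genome, min_arm = min_arm, max_loop = max_loop,
                          max_mismatch = max_mismatch, dedupe = TRUE)
  list(palindromes = pal,
       regions = cluster_hrs(pal, genome, cluster_gap = cluster_gap,
                             min_cluster = min_cluster))
}
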