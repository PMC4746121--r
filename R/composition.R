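#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from both numerator and
#' denominator.
#'
#' @param seq A DNA string, or a [circular_genome()].
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' gc_content("GGCC") # 1
#' gc_content("ATAT") # 0
gc_content <- function(seq) {
  if (inherits(seq, "circular_genome")) seq <- seq$seq
  cnt <- base_counts(seq)
  denom <- sum(cnt)
  if (denom == 0) stop("GC content undefined: no A/C/G/T bases")
  unname((cnt["G"] + cnt["C"]) / denom)
}

#' AT content of a sequence
#'
#' `(A + T) / (A + C + G + T)`, the complement of [gc_content()].
#'
#' @inheritParams gc_content
#' @return A fraction in `[0, 1]`.
#' @export
at_content <- function(seq) {
  1 - gc_content(seq)
}

#' Windowed GC-skew profile of a circular genome
#'
#' Per-window GC content and GC skew `(G - C) / (G + C)` over sliding windows
#' that wrap around the origin, plus the cumulative skew (running sum of
#' per-window `G - C` counts) whose minimum and maximum are reported as
#' candidate replication origin/terminus.
#'
#' @param genome A [circular_genome()].
#' @param window_nt Window size (default 1000).
#' @param step_nt Step between window starts (default 100). The profile has
#'   `ceiling(length / step_nt)` windows.
#' @return An object of class `skew_profile`: list with `window_nt`, `step_nt`,
#'   `values` (data frame: `center`, `gc_content`, `gc_skew`, `gc_zero`,
#'   `cumulative_skew`), `origin_candidate`, `terminus_candidate`. The skew
#'   sign convention is `(G - C)/(G + C)`.
#' @export
gc_skew_profile <- function(genome, window_nt = 1000L, step_nt = 100L) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (window_nt > L) stop("window larger than the genome")
  s2 <- if (genome$circular) paste0(genome$seq,
                                    substr(genome$seq, 1L, window_nt)) else
    genome$seq
  x <- strsplit(s2, "")[[1]]
  cumG <- c(0L, cumsum(x == "G"))
  cumC <- c(0L, cumsum(x == "C"))
  starts <- seq.int(1L, L, by = step_nt)
  ends <- pmin(starts + window_nt - 1L, nchar(s2))
  g <- cumG[ends + 1L] - cumG[starts]
  cc <- cumC[ends + 1L] - cumC[starts]
  gcsum <- g + cc
  skew <- ifelse(gcsum == 0, 0, (g - cc) / pmax(gcsum, 1L))
  gcfrac <- gcsum / (ends - starts + 1L)
  center <- (((starts + (window_nt %/% 2L)) - 1L) %% L) + 1L
  cum <- cumsum(g - cc)
  values <- data.frame(center = center, window_start = starts,
                       gc_content = gcfrac, gc_skew = skew,
                       gc_zero = gcsum == 0, cumulative_skew = cum)
  structure(list(window_nt = as.integer(window_nt),
                 step_nt = as.integer(step_nt),
                 skew_convention = "(G-C)/(G+C)",
                 values = values,
                 origin_candidate = center[which.min(cum)],
                 terminus_candidate = center[which.max(cum)]),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> %d windows of %d nt (step %d); skew %s\n",
              nrow(x$values), x$window_nt, x$step_nt, x$skew_convention))
  cat(sprintf("  cumulative-skew minimum (origin candidate) near %d, maximum (terminus candidate) near %d\n",
              x$origin_candidate, x$terminus_candidate))
  invisible(x)
}
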