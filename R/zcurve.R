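# Z-curve computation and recursive composition segmentation.
#
# The split statistic is the weighted gain in the genome order index
# S(p) = sum_b p_b^2 upon splitting a segment:
#   Delta = n * [ (nL/n) S(pL) + (nR/n) S(pR) - S(p_pooled) ]
#         = n * (nL/n) (nR/n) * ||pL - pR||^2
# which is non-negative, zero iff the two sides share a composition, and
# scales linearly with segment size at fixed contrast, so a single halting
# threshold t0 applies across segment lengths.

#' Compute the Z-curve of a nucleotide sequence
#'
#' The Z-curve is the triple of cumulative base-disparity series
#' x (purine - pyrimidine), y (amino - keto) and z (weak - strong hydrogen
#' bonding): after the first n counted bases,
#' `x_n = (#A + #G) - (#C + #T)`, `y_n = (#A + #C) - (#G + #T)`,
#' `z_n = (#A + #T) - (#G + #C)`. `N` bases are skipped (each series
#' repeats its previous value).
#'
#' @param sequence Uppercase nucleotide string over `{A,C,G,T,N}`.
#' @return A tibble with columns `pos` (1-based base index), `x`, `y`, `z`.
#' @export
compute_zcurve <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) abort("empty sequence")
  b <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(b), NUC_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("illegal base(s): %s", paste(bad, collapse = ", ")))
  }
  dx <- c(A = 1, G = 1, C = -1, T = -1, N = 0)[b]
  dy <- c(A = 1, C = 1, G = -1, T = -1, N = 0)[b]
  dz <- c(A = 1, T = 1, G = -1, C = -1, N = 0)[b]
  tibble(pos = seq_along(b),
         x = cumsum(unname(dx)),
         y = cumsum(unname(dy)),
         z = cumsum(unname(dz)))
}

#' Quadratic divergence between two base-composition distributions
#'
#' Split statistic `Delta = n * [ (nL/n) S(pL) + (nR/n) S(pR) - S(p) ]`
#' where `S(p) = sum_b p_b^2` is the genome order index and `p` is the
#' count-pooled composition. `Delta >= 0`, with equality iff the two
#' distributions coincide; it is symmetric in its arguments.
#'
#' @param left_freqs,right_freqs Base-frequency vectors over `{A,C,G,T}`
#'   (non-negative, summing to 1).
#' @param n_left,n_right Counted (non-N) base totals of the two sides.
#' @return The divergence `Delta` (dimensionless).
#' @export
quadratic_divergence <- function(left_freqs, right_freqs, n_left, n_right) {
  if (n_left < 1 || n_right < 1) abort("zero-length side")
  stopifnot(length(left_freqs) == 4, length(right_freqs) == 4)
  n <- n_left + n_right
  a <- n_left / n
  pooled <- a * left_freqs + (1 - a) * right_freqs
  n * (a * sum(left_freqs^2) + (1 - a) * sum(right_freqs^2) - sum(pooled^2))
}

# Cumulative base-count matrix: row i+1 holds counts of A,C,G,T in seq[1..i].
cumulative_base_counts <- function(sequence) {
  b <- strsplit(sequence, "")[[1]]
  m <- matrix(0L, nrow = length(b) + 1L, ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in 1:4) {
    m[, k] <- c(0L, cumsum(b == c("A", "C", "G", "T")[k]))
  }
  m
}

# Delta for every candidate split of [s, e) (0-based half-open), vectorised.
# Returns NA where a side has zero counted bases.
split_divergences <- function(counts, s, e, candidates) {
  tot <- counts[e + 1L, ] - counts[s + 1L, ]
  n <- sum(tot)
  left <- counts[candidates + 1L, , drop = FALSE] -
    matrix(counts[s + 1L, ], nrow = length(candidates), ncol = 4, byrow = TRUE)
  right <- matrix(tot, nrow = length(candidates), ncol = 4, byrow = TRUE) - left
  nl <- rowSums(left)
  nr <- rowSums(right)
  ok <- nl > 0 & nr > 0
  delta <- rep(NA_real_, length(candidates))
  if (any(ok)) {
    pl <- left[ok, , drop = FALSE] / nl[ok]
    pr <- right[ok, , drop = FALSE] / nr[ok]
    a <- nl[ok] / n
    pooled <- pl * a + pr * (1 - a)
    delta[ok] <- n * (a * rowSums(pl^2) + (1 - a) * rowSums(pr^2) -
                        rowSums(pooled^2))
  }
  delta
}

#' Recursively segment a sequence by composition
#'
#' Recursive binary segmentation: within each segment every split leaving
#' both children at least `min_len` bp is scored with
#' [quadratic_divergence()]; the best split (ties broken by the smallest
#' position) is accepted iff its divergence reaches the halting threshold
#' `t0`, and segmentation recurses into both children. `N` bases are
#' excluded from all counts; a side with only `N`s is never split off.
#'
#' @param sequence Uppercase nucleotide string.
#' @param t0 Halting threshold (dimensionless), default 100.
#' @param min_len Minimum segment length in bp, default 1000.
#' @return An object of class `"zseg_segmentation"` with elements
#'   `breakpoints` (0-based positions where a new segment starts, strictly
#'   increasing), `splits` (tibble: `breakpoint`, `delta`, in acceptance
#'   order), `segments` (tibble: `start`, `end`, `n_counted`, `freq_A` ..
#'   `freq_T`), `params` and `seq_length`.
#' @export
segment_sequence <- function(sequence, t0 = 100, min_len = 1000) {
  stopifnot(t0 > 0, min_len >= 2)
  n_total <- nchar(sequence)
  if (n_total == 0) abort("empty sequence")
  counts <- cumulative_base_counts(sequence)
  breakpoints <- integer(0)
  splits <- list()
  stack <- list(c(0L, n_total))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    s <- seg[1]; e <- seg[2]
    if (e - s < 2L * min_len) next
    cand <- seq.int(s + min_len, e - min_len)
    delta <- split_divergences(counts, s, e, cand)
    if (all(is.na(delta))) next
    best <- which.max(delta)  # first maximum -> smallest position on ties
    if (delta[best] >= t0) {
      bp <- cand[best]
      breakpoints <- c(breakpoints, bp)
      splits[[length(splits) + 1L]] <- tibble(breakpoint = bp,
                                              delta = delta[best])
      # right pushed first so the left child is processed next (depth-first,
      # left-to-right; output order is normalised below anyway)
      stack[[length(stack) + 1L]] <- c(bp, e)
      stack[[length(stack) + 1L]] <- c(s, bp)
    }
  }
  breakpoints <- sort(breakpoints)
  bounds <- c(0L, breakpoints, n_total)
  segs <- purrr::map_dfr(seq_len(length(bounds) - 1L), function(i) {
    s <- bounds[i]; e <- bounds[i + 1L]
    cnt <- counts[e + 1L, ] - counts[s + 1L, ]
    nc <- sum(cnt)
    fr <- if (nc > 0) cnt / nc else rep(NA_real_, 4)
    tibble(start = s, end = e, n_counted = nc,
           freq_A = fr[1], freq_C = fr[2], freq_G = fr[3], freq_T = fr[4])
  })
  structure(
    list(breakpoints = breakpoints,
         splits = if (length(splits)) dplyr::bind_rows(splits) else
           tibble(breakpoint = integer(0), delta = numeric(0)),
         segments = segs,
         params = list(t0 = t0, min_len = min_len),
         seq_length = n_total),
    class = "zseg_segmentation"
  )
}

#' @export
print.zseg_segmentation <- function(x, ...) {
  cat(sprintf(
    "Z-curve segmentation: %d bp, t0 = %g, min_len = %d -> %d breakpoint(s)\n",
    x$seq_length, x$params$t0, x$params$min_len, length(x$breakpoints)))
  if (length(x$breakpoints)) print(x$splits)
  invisible(x)
}

#' @describeIn segment_sequence Segments as a tibble.
#' @param x A `zseg_segmentation`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.zseg_segmentation <- function(x, ...) x$segments

#' @describeIn segment_sequence One-row summary (breakpoint count, max
#'   divergence, parameters).
#' @export
#' @exportS3Method generics::glance
glance.zseg_segmentation <- function(x, ...) {
  tibble(n_breakpoints = length(x$breakpoints),
         max_delta = if (nrow(x$splits)) max(x$splits$delta) else NA_real_,
         t0 = x$params$t0, min_len = x$params$min_len,
         seq_length = x$seq_length)
}

#' @describeIn segment_sequence GC fraction per segment with breakpoints
#'   marked.
#' @param object A `zseg_segmentation`.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.zseg_segmentation <- function(object, ...) {
  segs <- dplyr::mutate(object$segments, gc = .data$freq_G + .data$freq_C)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$gc, yend = .data$gc)) +
    ggplot2::geom_vline(xintercept = object$breakpoints, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "position (bp)", y = "segment GC fraction") +
    ggplot2::theme_minimal()
}

#' Distance from segmentation breakpoints to a locus
#'
#' Reports the nearest-breakpoint distance to a locus interval (0 if a
#' breakpoint falls inside it) and whether any breakpoint lies within
#' `window_bp` of the locus. With no breakpoints the distance is `Inf` and
#' the flag is `FALSE`.
#'
#' @param segresult A [segment_sequence()] result.
#' @param locus One-row tibble (or list) with `start`, `end` (0-based
#'   half-open) on the segmented sequence.
#' @param window_bp Window in bp within which a breakpoint counts as "near".
#' @return One-row tibble: `distance`, `within_window`, `n_breakpoints`,
#'   `window_bp`.
#' @export
scan_locus <- function(segresult, locus, window_bp = 10000) {
  start <- locus$start; end <- locus$end
  if (start < 0 || end > segresult$seq_length || start >= end) {
    abort("locus outside sequence bounds")
  }
  bps <- segresult$breakpoints
  if (length(bps) == 0) {
    return(tibble(distance = Inf, within_window = FALSE,
                  n_breakpoints = 0L, window_bp = window_bp))
  }
  d <- pmax(0, start - bps, bps - end)
  tibble(distance = min(d), within_window = min(d) <= window_bp,
         n_breakpoints = length(bps), window_bp = window_bp)
}
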