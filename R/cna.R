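#' Segment a copy-number log-ratio track
#'
#' Penalized least-squares change-point segmentation by recursive binary
#' splitting: a split is accepted while it reduces the within-segment sum
#' of squares by more than `penalty`. Each chromosome is segmented
#' independently. The per-segment median log ratio is recorded as the
#' segment's smoothing value, the quantity the amplification-labeling rule
#' consumes.
#'
#' The default penalty is `4 * sigma^2 * log(n)` with `sigma` estimated
#' from the median absolute first difference of the track
#' (`median|diff| / (sqrt(2) * qnorm(3/4))`), which is robust to the
#' change points themselves. The factor 4 (rather than the BIC-like 2)
#' compensates for the greedy maximization over candidate split points,
#' which otherwise admits spurious breakpoints.
#'
#' @param track data.frame with columns `chrom`, `pos` (strictly
#'   increasing within chromosome) and `value` (log2 ratio).
#' @param penalty cost per additional breakpoint (default as above).
#' @return object of class `cna_segments`: data.frame with `chrom`,
#'   `start_pos`, `end_pos`, `start_idx`, `end_idx`, `n_probes`, `median`
#'   (smoothing value), `mean`.
#' @export
segment_profile <- function(track, penalty = NULL) {
  need <- c("chrom", "pos", "value")
  if (!is.data.frame(track) || !all(need %in% names(track)))
    .stopf("track needs columns chrom, pos, value")
  if (nrow(track) < 2L) .stopf("need at least 2 probes")
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    if (is.unsorted(sub$pos, strictly = TRUE))
      .stopf("positions not strictly increasing on %s", ch)
    y <- sub$value
    pen <- if (is.null(penalty)) {
      sigma <- stats::median(abs(diff(y))) / (sqrt(2) * stats::qnorm(0.75))
      4 * sigma^2 * log(length(y))
    } else penalty
    bounds <- .binseg(y, pen)
    out[[ch]] <- do.call(rbind, lapply(seq_len(nrow(bounds)), function(i) {
      a <- bounds$start[i]; b <- bounds$end[i]
      data.frame(chrom = ch, start_pos = sub$pos[a], end_pos = sub$pos[b],
                 start_idx = a, end_idx = b, n_probes = b - a + 1L,
                 median = stats::median(y[a:b]), mean = mean(y[a:b]))
    }))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("cna_segments", "data.frame"))
}

# Recursive binary segmentation on a numeric vector; a split at j is kept
# when RSS(whole) - RSS(left) - RSS(right) > penalty. Split costs are
# computed from cumulative sums, O(n) per level.
.binseg <- function(y, penalty) {
  segs <- list(c(1L, length(y)))
  final <- list()
  rss <- function(a, b) {
    v <- y[a:b]
    sum(v^2) - sum(v)^2 / length(v)
  }
  while (length(segs)) {
    seg <- segs[[1L]]; segs <- segs[-1L]
    a <- seg[1L]; b <- seg[2L]
    if (b - a < 1L) { final[[length(final) + 1L]] <- seg; next }
    v <- y[a:b]
    n <- length(v)
    cs <- cumsum(v); cs2 <- cumsum(v^2)
    i <- seq_len(n - 1L)
    left <- cs2[i] - cs[i]^2 / i
    right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
    whole <- rss(a, b)
    gain <- whole - (left + right)
    j <- which.max(gain)
    # absolute slack guards the penalty = 0 case against rounding noise
    if (gain[j] > penalty + 1e-10 * (1 + abs(whole))) {
      segs <- c(segs, list(c(a, a + j - 1L)), list(c(a + j, b)))
    } else {
      final[[length(final) + 1L]] <- seg
    }
  }
  m <- do.call(rbind, final)
  m <- m[order(m[, 1L]), , drop = FALSE]
  data.frame(start = m[, 1L], end = m[, 2L])
}

#' @export
print.cna_segments <- function(x, ...) {
  cat(sprintf("CNA segmentation: %d segment(s) over %d probe(s)\n",
              nrow(x), sum(x$n_probes)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Amplification call at a genomic locus
#'
#' A sample is amplification positive when the smoothing value (per-segment
#' median log ratio) of the segment covering the locus is strictly greater
#' than zero, and negative otherwise.
#'
#' @param segments `cna_segments` from [segment_profile()].
#' @param locus list or vector with `chrom` and `pos`.
#' @return `"positive"` or `"negative"`.
#' @export
amplification_call <- function(segments, locus) {
  stopifnot(inherits(segments, "cna_segments"))
  chrom <- locus$chrom %||% locus[["chrom"]]
  pos <- as.numeric(locus$pos %||% locus[["pos"]])
  hit <- segments$chrom == chrom & segments$start_pos <= pos &
    segments$end_pos >= pos
  if (!any(hit)) .stopf("locus %s:%s not covered by any segment", chrom, pos)
  if (segments$median[which(hit)[1L]] > 0) "positive" else "negative"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
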