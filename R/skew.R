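# Windowed and cumulative nucleotide skews and replication-origin selection.
#
# Sign convention: GC skew is (G - C)/(G + C) and the origin is taken at the
# cumulative minimum, which makes the leading strand G-rich downstream of the
# origin. N bases are excluded from every denominator.

#' Windowed nucleotide skews
#'
#' Computes per-window GC, AT, RY (purine minus pyrimidine) and MK (amino
#' minus keto) skews and their cumulative (prefix-sum) tracks. For a window
#' with base counts a, c, g, t (N excluded): `gc = (g-c)/(g+c)`,
#' `at = (a-t)/(a+t)`, `ry = ((a+g)-(c+t))/(a+c+g+t)`,
#' `mk = ((a+c)-(g+t))/(a+c+g+t)`; a zero denominator yields skew 0. The
#' trailing partial window is included when it spans at least half a window.
#'
#' @param contig A [contig()].
#' @param window Window size, nt (default 1000).
#' @param step Step between window starts, nt (default = `window`).
#' @return An object of class `"skew_profile"`: list with `contig_id`,
#'   `window`, `step`, vectors `start` (0-based window starts) and `width`,
#'   per-window tracks `gc`, `at`, `ry`, `mk`, and cumulative tracks
#'   `cum_gc`, `cum_at`, `cum_ry`, `cum_mk`.
#' @export
windowed_skews <- function(contig, window = 1000L, step = window) {
  n <- contig$length
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be >= 1",
                                     call. = FALSE)
  if (window > n) stop("window larger than contig", call. = FALSE)

  v <- utf8ToInt(contig$seq)
  cum <- function(ch) c(0L, cumsum(v == utf8ToInt(ch)))
  cA <- cum("A"); cC <- cum("C"); cG <- cum("G"); cT <- cum("T")

  starts <- seq.int(0L, n - 1L, by = step)
  widths <- pmin(window, n - starts)
  keep <- widths == window | widths >= window / 2
  starts <- starts[keep]
  widths <- widths[keep]

  cnt <- function(cm) cm[starts + widths + 1L] - cm[starts + 1L]
  a <- cnt(cA); c_ <- cnt(cC); g <- cnt(cG); t <- cnt(cT)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  gc <- safe_div(g - c_, g + c_)
  at <- safe_div(a - t, a + t)
  tot <- a + c_ + g + t
  ry <- safe_div((a + g) - (c_ + t), tot)
  mk <- safe_div((a + c_) - (g + t), tot)

  structure(list(
    contig_id = contig$id, window = window, step = step,
    start = starts, width = widths,
    gc = gc, at = at, ry = ry, mk = mk,
    cum_gc = cumsum(gc), cum_at = cumsum(at),
    cum_ry = cumsum(ry), cum_mk = cumsum(mk)
  ), class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> %s: %d windows of %d nt (step %d)\n",
              x$contig_id, length(x$start), x$window, x$step))
  cat(sprintf("  cumulative GC skew range [%.3f, %.3f], min at window %d\n",
              min(x$cum_gc), max(x$cum_gc), which.min(x$cum_gc)))
  invisible(x)
}

#' Base-graphics plot of cumulative skew tracks
#' @param x A `skew_profile`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.skew_profile <- function(x, ...) {
  m <- cbind(x$cum_gc, x$cum_at, x$cum_ry, x$cum_mk)
  graphics::matplot(x$start + x$width, m, type = "l", lty = 1,
                    col = c("black", "grey50", "steelblue", "tomato"),
                    xlab = "position (nt)", ylab = "cumulative skew", ...)
  graphics::legend("topright", legend = c("GC", "AT", "RY", "MK"), lty = 1,
                   col = c("black", "grey50", "steelblue", "tomato"),
                   bty = "n")
  org <- find_origin(x)
  graphics::abline(v = org$position, lty = 2)
  invisible(x)
}

#' Select a replication origin from the cumulative GC skew
#'
#' Returns the nt position of the boundary following the window where the
#' cumulative GC skew attains its global minimum (ties: leftmost). The other
#' three cumulative tracks corroborate the call when their values at that
#' window fall below their track medians; the flags are advisory, never
#' vetoes.
#'
#' @param profile A `skew_profile` with at least 3 windows.
#' @return Object of class `"origin_call"`: list with `position` (0-based nt),
#'   `window_index`, and named logical `corroboration` (`at`, `ry`, `mk`).
#' @export
find_origin <- function(profile) {
  stopifnot(inherits(profile, "skew_profile"))
  if (length(profile$start) < 3L) {
    stop("need at least 3 windows to call an origin", call. = FALSE)
  }
  i <- which.min(profile$cum_gc)
  structure(list(
    position = profile$start[i] + profile$width[i],
    window_index = i,
    corroboration = c(
      at = unname(profile$cum_at[i] < median(profile$cum_at)),
      ry = unname(profile$cum_ry[i] < median(profile$cum_ry)),
      mk = unname(profile$cum_mk[i] < median(profile$cum_mk)))
  ), class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("<origin_call> position %d (window %d); corroborated by: %s\n",
              x$position, x$window_index,
              if (any(x$corroboration))
                paste(names(x$corroboration)[x$corroboration],
                      collapse = ", ") else "none"))
  invisible(x)
}

#' Candidate origins: the deepest local minima of the cumulative GC skew
#'
#' The published practice selects one local cumulative-skew minimum by
#' inspection; this lists the `n` deepest local minima for manual review.
#'
#' @param profile A `skew_profile`.
#' @param n Number of candidates to report.
#' @return Data frame with columns `position`, `window_index`, `cum_gc`,
#'   ordered by increasing cumulative skew.
#' @export
origin_candidates <- function(profile, n = 3L) {
  v <- profile$cum_gc
  k <- length(v)
  is_min <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || v[i] < v[i - 1L]
    right_ok <- i == k || v[i] <= v[i + 1L]
    left_ok && right_ok
  }, logical(1L))
  idx <- which(is_min)
  idx <- idx[order(v[idx])]
  idx <- head(idx, n)
  data.frame(position = profile$start[idx] + profile$width[idx],
             window_index = idx, cum_gc = v[idx])
}

#' Rotate a circular contig so a position becomes nucleotide +1
#'
#' @param contig A circular [contig()] (rotating a linear contig is an error).
#' @param origin 0-based position that becomes the first base.
#' @return The rotated contig; length preserved; applying the inverse rotation
#'   (`length - origin`) restores the input exactly.
#' @export
rotate_to_origin <- function(contig, origin) {
  stopifnot(is_contig(contig))
  if (contig$topology != "circular") {
    stop("refusing to rotate a non-circular contig ('", contig$id,
         "' has topology ", contig$topology, ")", call. = FALSE)
  }
  origin <- as.integer(origin) %% contig$length
  if (origin == 0L) return(contig)
  n <- contig$length
  rotated <- paste0(substr(contig$seq, origin + 1L, n),
                    substr(contig$seq, 1L, origin))
  out <- contig
  out$seq <- rotated
  out$desc <- trimws(paste(out$desc, sprintf("rotated_origin=%d", origin)))
  out
}
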