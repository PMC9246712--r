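# CRISPR repeat-spacer array detection: a seed-cluster-extend detector.
# Exact k-mers recurring at near-constant period seed candidate repeats,
# which are extended to the maximal repeat consensus by column majority;
# spacers are the inter-repeat gaps.

new_crispr_array <- function(contig_id, repeat_spans, consensus, seqc) {
  n_rep <- nrow(repeat_spans)
  n_sp <- n_rep - 1L
  spacers <- data.frame(id = character(n_sp), array_id = character(n_sp),
                        index_in_array = integer(n_sp),
                        seq = character(n_sp),
                        start = integer(n_sp), end = integer(n_sp),
                        stringsAsFactors = FALSE)
  if (n_sp > 0L) {
    for (i in seq_len(n_sp)) {
      s0 <- repeat_spans[i, 2L]
      e0 <- repeat_spans[i + 1L, 1L]
      spacers$index_in_array[i] <- i - 1L
      spacers$seq[i] <- substr(seqc, s0 + 1L, e0)
      spacers$start[i] <- s0
      spacers$end[i] <- e0
    }
  }
  structure(list(
    id = NA_character_, contig_id = contig_id,
    start = repeat_spans[1L, 1L], end = repeat_spans[n_rep, 2L],
    orientation = "unknown",
    repeat_consensus = consensus,
    repeat_spans = repeat_spans,
    spacers = spacers,
    n_repeats = n_rep
  ), class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %s on %s [%d, %d)  %d repeats, %d spacers\n",
              x$id, x$contig_id, x$start, x$end, x$n_repeats,
              nrow(x$spacers)))
  cat("  repeat consensus: ", x$repeat_consensus, "\n", sep = "")
  invisible(x)
}

# split seed positions into runs with period in [gmin, gmax] and spread <= sp
cluster_positions <- function(pos, gmin, gmax, spread) {
  clusters <- list()
  cur <- pos[1L]
  gaps <- numeric(0L)
  for (p in pos[-1L]) {
    g <- p - cur[length(cur)]
    ok <- g >= gmin && g <= gmax &&
      (length(gaps) == 0L || max(c(gaps, g)) - min(c(gaps, g)) <= spread)
    if (ok) {
      cur <- c(cur, p)
      gaps <- c(gaps, g)
    } else {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- p
      gaps <- numeric(0L)
    }
  }
  clusters[[length(clusters) + 1L]] <- cur
  clusters
}

# fraction of in-range occurrences agreeing on the majority letter at the
# given per-occurrence columns
col_agreement <- function(seqc, n, col) {
  inside <- col >= 1L & col <= n
  if (!sum(inside)) return(0)
  letters <- substring(seqc, col[inside], col[inside])
  max(table(letters)) / sum(inside)
}

# extend a cluster of identical k-mer occurrences into full repeats by
# column majority, then trim edge columns back to near-unanimity: a single
# chance column can clear the extension threshold over few occurrences, and a
# one-column offset would shift every spacer boundary of the array
extend_cluster <- function(seqc, n, P, k, cap, min_agreement,
                           edge_agreement = 0.95) {
  m <- length(P)
  quorum <- max(2L, ceiling(m / 2))
  grow <- function(left_done, side) {
    ext <- 0L
    repeat {
      if (left_done + k + ext >= cap) break
      col <- if (side == "left") P - ext - 1L else P + k + ext
      if (sum(col >= 1L & col <= n) < quorum) break
      if (col_agreement(seqc, n, col) < min_agreement) break
      ext <- ext + 1L
    }
    ext
  }
  left <- grow(0L, "left")
  right <- grow(left, "right")
  while (left > 0L &&
         col_agreement(seqc, n, P - left) < edge_agreement) {
    left <- left - 1L
  }
  while (right > 0L &&
         col_agreement(seqc, n, P + k - 1L + right) < edge_agreement) {
    right <- right - 1L
  }
  c(left = left, right = right)
}

column_majority_consensus <- function(seqc, starts0, len, n) {
  keep <- starts0 >= 0L & starts0 + len <= n
  occ <- substring(seqc, starts0[keep] + 1L, starts0[keep] + len)
  if (!length(occ)) return("")
  mat <- do.call(rbind, strsplit(occ, ""))
  paste(apply(mat, 2L, function(col) names(which.max(table(col)))),
        collapse = "")
}

#' Detect CRISPR repeat-spacer arrays on a contig
#'
#' Algorithm: (1) collect exact k-mers (default k = 13) occurring at least
#' `min_repeats` times; (2) cluster occurrence positions whose successive gaps
#' lie in `[repeat_min + spacer_min, repeat_max + spacer_max]` and are
#' near-constant (spread at most `gap_spread`); (3) extend each clustered seed
#' left and right to the maximal repeat consensus by column majority over
#' occurrences, stopping when column agreement drops below
#' `min_col_agreement`; (4) emit an array when at least `min_repeats` repeats
#' result, spacers being the inter-repeat gaps; (5) merge overlapping
#' candidates keeping the one with more repeats. Truncated boundary repeats
#' (contig ends mid-repeat) count toward the repeat total when at least half
#' the consensus length survives.
#'
#' Array orientation is reported as `"unknown"`: no leader-sequence or repeat
#' polarity inference is attempted.
#'
#' @param contig A [contig()].
#' @param params Configuration list (see [default_config()]).
#' @return List of `crispr_array` objects sorted by contig position (empty
#'   list when nothing is found).
#' @export
detect_arrays <- function(contig, params = default_config()) {
  seqc <- contig$seq
  n <- contig$length
  k <- params$seed_k
  if (n < 3L * params$repeat_min || n < k) return(list())
  gmin <- params$repeat_min + params$spacer_min
  gmax <- params$repeat_max + params$spacer_max

  starts <- seq_len(n - k + 1L)
  kmers <- substring(seqc, starts, starts + k - 1L)
  pos_by_kmer <- split(starts, kmers)
  counts <- lengths(pos_by_kmer)
  cand <- names(counts)[counts >= params$min_repeats]
  cand <- cand[!grepl("N", cand, fixed = TRUE)]
  if (!length(cand)) return(list())
  firstpos <- vapply(pos_by_kmer[cand], `[[`, integer(1L), 1L)
  cand <- cand[order(-counts[cand], firstpos)]

  candidates <- list()
  for (km in cand) {
    P_all <- pos_by_kmer[[km]]
    for (P in cluster_positions(P_all, gmin, gmax, params$gap_spread)) {
      if (length(P) < params$min_repeats) next
      gaps <- diff(P)
      cap <- min(params$repeat_max, min(gaps) - params$spacer_min)
      if (cap < k) next
      ext <- extend_cluster(seqc, n, P, k, cap, params$min_col_agreement,
                            params$repeat_edge_agreement)
      len <- k + ext[["left"]] + ext[["right"]]
      starts0 <- P - 1L - ext[["left"]]  # 0-based repeat starts
      consensus <- column_majority_consensus(seqc, starts0, len, n)
      if (!nzchar(consensus)) next
      spans <- cbind(pmax(starts0, 0L), pmin(starts0 + len, n))
      keep <- (spans[, 2L] - spans[, 1L]) >= 0.5 * len
      spans <- spans[keep, , drop = FALSE]
      if (nrow(spans) < params$min_repeats) next
      candidates[[length(candidates) + 1L]] <-
        new_crispr_array(contig$id, spans, consensus, seqc)
    }
  }
  if (!length(candidates)) return(list())

  # merge overlapping candidates, keeping the one with more repeats
  ord <- order(vapply(candidates, `[[`, integer(1L), "start"),
               -vapply(candidates, `[[`, integer(1L), "n_repeats"))
  candidates <- candidates[ord]
  kept <- list(candidates[[1L]])
  for (a in candidates[-1L]) {
    last <- kept[[length(kept)]]
    if (a$start < last$end) {  # overlap
      if (a$n_repeats > last$n_repeats) kept[[length(kept)]] <- a
    } else {
      kept[[length(kept) + 1L]] <- a
    }
  }
  for (i in seq_along(kept)) {
    kept[[i]]$id <- sprintf("%s_array%d", contig$id, i)
    if (nrow(kept[[i]]$spacers)) {
      kept[[i]]$spacers$array_id <- kept[[i]]$id
      kept[[i]]$spacers$id <- sprintf("%s_sp%02d", kept[[i]]$id,
                                      seq_len(nrow(kept[[i]]$spacers)))
    }
  }
  kept
}

#' Arrays at contig boundaries
#'
#' Returns the detected arrays whose span starts within `edge_window` of
#' position 0 (`"left"`) or ends within `edge_window` of the contig end
#' (`"right"`). An array qualifying at both ends yields two entries.
#'
#' @param contig The [contig()] the arrays were detected on.
#' @param arrays List of `crispr_array` objects from [detect_arrays()].
#' @param edge_window Distance from the contig end, nt (default 500).
#' @return List of entries `list(array = <crispr_array>, end = "left"|"right")`.
#' @export
boundary_arrays <- function(contig, arrays, edge_window = 500L) {
  out <- list()
  for (a in arrays) {
    if (a$contig_id != contig$id) next
    if (a$start <= edge_window) {
      out[[length(out) + 1L]] <- list(array = a, end = "left")
    }
    if (contig$length - a$end <= edge_window) {
      out[[length(out) + 1L]] <- list(array = a, end = "right")
    }
  }
  out
}

#' Collect all spacers from a list of arrays
#'
#' @param arrays List of `crispr_array` objects (possibly across contigs).
#' @return Data frame with columns `id`, `array_id`, `contig_id`,
#'   `index_in_array`, `seq`, `start`, `end`.
#' @export
collect_spacers <- function(arrays) {
  if (!length(arrays)) {
    return(data.frame(id = character(), array_id = character(),
                      contig_id = character(), index_in_array = integer(),
                      seq = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(arrays, function(a) {
    if (!nrow(a$spacers)) return(NULL)
    cbind(a$spacers[, c("id", "array_id")],
          data.frame(contig_id = a$contig_id, stringsAsFactors = FALSE),
          a$spacers[, c("index_in_array", "seq", "start", "end")])
  }))
}
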