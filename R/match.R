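# Spacer-to-protospacer matching under full-query-coverage, bounded-mismatch,
# ungapped semantics: every position (both strands) where the Hamming
# distance between the spacer and the equal-length target window is within
# the mismatch budget is reported. `N` in either sequence counts as a
# mismatch; indels are out of contract.

normalize_spacers <- function(spacers) {
  if (is.data.frame(spacers)) {
    stopifnot(all(c("id", "seq") %in% names(spacers)))
    data.frame(id = as.character(spacers$id),
               seq = toupper(as.character(spacers$seq)),
               stringsAsFactors = FALSE)
  } else if (is.character(spacers)) {
    ids <- names(spacers)
    if (is.null(ids)) ids <- sprintf("spacer_%03d", seq_along(spacers))
    data.frame(id = ids, seq = toupper(unname(spacers)),
               stringsAsFactors = FALSE)
  } else {
    stop("spacers must be a data frame with id/seq or a character vector",
         call. = FALSE)
  }
}

empty_hits <- function() {
  data.frame(spacer_id = character(), target = character(),
             start = integer(), end = integer(), strand = character(),
             mismatches = integer(), full_coverage = logical(),
             stringsAsFactors = FALSE)
}

# padded array exclusion zones per contig id: list of 2-col matrices
exclusion_zones <- function(arrays) {
  zones <- list()
  for (a in arrays) {
    pad <- nchar(a$repeat_consensus)
    zones[[a$contig_id]] <- rbind(zones[[a$contig_id]],
                                  c(max(0L, a$start - pad), a$end + pad))
  }
  zones
}

#' Find protospacer matches for spacers against target contigs
#'
#' Ungapped full-coverage search: for every spacer and every target, every
#' position on both strands where the Hamming distance between the spacer and
#' the equal-length window is at most `max_mismatches` is reported. `N` never
#' matches anything (including `N`). Hits overlapping detected CRISPR arrays
#' on the target (padded by one repeat length) are removed when
#' `exclude_arrays` is `TRUE` -- a spacer trivially matches its own array, and
#' only inter-element hits carry host-virus information.
#'
#' @param spacers Data frame with columns `id` and `seq` (e.g. from
#'   [collect_spacers()]), or a named character vector.
#' @param targets List of [contig()] objects to search.
#' @param max_mismatches Mismatch budget (default 1).
#' @param exclude_arrays Remove hits inside target CRISPR arrays
#'   (default `TRUE`).
#' @param target_arrays Optional list of `crispr_array` objects on the
#'   targets; when `NULL` and `exclude_arrays` is `TRUE`, arrays are detected
#'   with [detect_arrays()].
#' @param params Configuration list (see [default_config()]).
#' @return Data frame with columns `spacer_id`, `target`, `start`, `end`
#'   (0-based half-open on the target forward strand), `strand` (`"+"`/`"-"`),
#'   `mismatches`, `full_coverage` (always `TRUE` under these semantics),
#'   sorted by (target, position).
#' @export
find_hits <- function(spacers, targets, max_mismatches = 1L,
                      exclude_arrays = TRUE, target_arrays = NULL,
                      params = default_config()) {
  sp <- normalize_spacers(spacers)
  if (!nrow(sp)) return(empty_hits())
  if (!length(targets)) stop("no target contigs", call. = FALSE)
  short <- nchar(sp$seq) < params$min_spacer_query
  if (any(short)) {
    stop("spacer(s) shorter than ", params$min_spacer_query,
         " nt are uninformative queries: ",
         paste(sp$id[short], collapse = ", "), call. = FALSE)
  }

  if (exclude_arrays && is.null(target_arrays)) {
    target_arrays <- unlist(lapply(targets, detect_arrays, params = params),
                            recursive = FALSE)
  }
  zones <- if (exclude_arrays) exclusion_zones(target_arrays) else list()

  rows <- list()
  for (tg in targets) {
    # mask N so that it never matches, N vs N included
    subject <- Biostrings::DNAString(gsub("N", "-", tg$seq, fixed = TRUE))
    for (i in seq_len(nrow(sp))) {
      L <- nchar(sp$seq[i])
      if (L > tg$length) next
      for (strand in c("+", "-")) {
        q <- if (strand == "+") sp$seq[i] else revcomp(sp$seq[i])
        m <- Biostrings::matchPattern(Biostrings::DNAString(q), subject,
                                      max.mismatch = max_mismatches,
                                      with.indels = FALSE, fixed = TRUE)
        if (!length(m)) next
        st1 <- Biostrings::start(m)
        mm <- vapply(st1, function(s) {
          hamming(substr(tg$seq, s, s + L - 1L), q)
        }, integer(1L))
        keep <- mm <= max_mismatches
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          spacer_id = sp$id[i], target = tg$id,
          start = st1[keep] - 1L, end = st1[keep] - 1L + L,
          strand = strand, mismatches = mm[keep], full_coverage = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()

  if (nrow(hits) && length(zones)) {
    drop <- logical(nrow(hits))
    for (cid in names(zones)) {
      z <- zones[[cid]]
      sel <- hits$target == cid
      if (!any(sel)) next
      for (r in seq_len(nrow(z))) {
        drop <- drop | (sel & hits$start < z[r, 2L] & hits$end > z[r, 1L])
      }
    }
    hits <- hits[!drop, , drop = FALSE]
  }
  hits <- hits[order(hits$target, hits$start, hits$strand, hits$spacer_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-target linkage summary
#'
#' For each target contig: the number of distinct spacers with at least one
#' zero-mismatch hit, the number of additional distinct spacers whose best hit
#' has exactly one mismatch, and the total number of hit positions. A spacer
#' hitting two contigs counts toward both; the attached `totals` attribute
#' additionally reports the deduplicated convention (distinct spacers and
#' distinct targets over the whole hit set).
#'
#' @param hits Hit table from [find_hits()] (computed with
#'   `max_mismatches >= 1` for the one-mismatch column to be meaningful).
#' @param spacers Optional spacer table (unused counts are not reported, but
#'   ids are validated when given).
#' @return Data frame with columns `target`, `n_exact_spacers`,
#'   `n_one_mm_spacers`, `n_hit_positions`, sorted by target; attribute
#'   `totals` holds the assembly-wide deduplicated counts.
#' @export
summarize_linkage <- function(hits, spacers = NULL) {
  if (!is.null(spacers)) {
    sp <- normalize_spacers(spacers)
    unknown <- setdiff(unique(hits$spacer_id), sp$id)
    if (length(unknown)) {
      stop("hits reference unknown spacer id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (!nrow(hits)) {
    out <- data.frame(target = character(), n_exact_spacers = integer(),
                      n_one_mm_spacers = integer(),
                      n_hit_positions = integer(), stringsAsFactors = FALSE)
    attr(out, "totals") <- list(n_spacers_exact = 0L, n_spacers_any = 0L,
                                n_targets = 0L)
    return(out)
  }
  per_target <- lapply(split(hits, hits$target), function(h) {
    best <- tapply(h$mismatches, h$spacer_id, min)
    data.frame(target = h$target[1L],
               n_exact_spacers = sum(best == 0L),
               n_one_mm_spacers = sum(best == 1L),
               n_hit_positions = nrow(h),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_target)
  out <- out[order(out$target), , drop = FALSE]
  rownames(out) <- NULL
  best_all <- tapply(hits$mismatches, hits$spacer_id, min)
  attr(out, "totals") <- list(
    n_spacers_exact = sum(best_all == 0L),
    n_spacers_any = length(best_all),
    n_targets = length(unique(hits$target)))
  out
}
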