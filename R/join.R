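# Contig joins from shared runs of consecutive boundary spacers.
#
# When two contigs break inside the same CRISPR array, the fragments end in
# partial arrays that share a run of identical consecutive spacers. A
# suffix-of-one / prefix-of-the-other alignment of the boundary spacer lists
# yields the join evidence; spacer identity is exact string equality (spacers
# are the unique evidence), while repeats between them may mismatch up to a
# tolerance. Proposed merges are provisional in-silico evidence, not closure.

# boundary spacer list with partial spacers (< partial_frac of the array's
# median spacer length) dropped from run computation. A partial spacer can
# only arise where the contig end cuts the array mid-spacer, so a spacer is
# dropped only when it is both short and flush with a contig end --
# interior (or full terminal) length variation is genuine evidence
boundary_spacer_seqs <- function(array, contig_len, partial_frac = 0.9) {
  sp <- array$spacers
  if (!nrow(sp)) return(character(0L))
  cutoff <- partial_frac * median(nchar(sp$seq))
  n <- nrow(sp)
  keep <- rep(TRUE, n)
  if (nchar(sp$seq[1L]) < cutoff && sp$start[1L] <= 1L) keep[1L] <- FALSE
  if (nchar(sp$seq[n]) < cutoff && sp$end[n] >= contig_len - 1L) {
    keep[n] <- FALSE
  }
  sp$seq[keep]
}

# longest t with tail(left, t) elementwise identical to head(right, t)
longest_end_run <- function(left, right) {
  kmax <- min(length(left), length(right))
  best <- 0L
  for (t in seq_len(kmax)) {
    if (all(tail(left, t) == head(right, t))) best <- t
  }
  best
}

# spans of an array mirrored onto the reverse complement of its contig
mirror_array_spans <- function(array, contig_len) {
  spans <- array$repeat_spans
  flipped <- cbind(contig_len - spans[, 2L], contig_len - spans[, 1L])
  flipped[rev(seq_len(nrow(flipped))), , drop = FALSE]
}

#' Propose joins between contigs with matching boundary arrays
#'
#' For every pair of boundary arrays on distinct contig ends (self-pairs of
#' one contig's two ends are allowed and flagged as circularisation evidence),
#' and for both orientations of the second contig, computes the longest run of
#' consecutive spacer pairs with identical sequences aligned end-to-end --
#' a suffix of the upstream boundary array against a prefix of the downstream
#' one. A proposal is emitted when the run length reaches `min_k`.
#'
#' @param contigs List of [contig()] objects.
#' @param arrays List of `crispr_array` objects detected on them.
#' @param min_k Minimum shared-run length (default 4).
#' @param params Configuration list (`edge_window`, `partial_spacer_frac`).
#' @return List of `join_proposal` objects sorted by decreasing `k`. Each has
#'   fields `contig_a`, `end_a`, `contig_b`, `end_b`, `orientation_b`
#'   (`"forward"` or `"reverse-complement"`), `k`, `shared_run` (data frame of
#'   spacer id pairs and sequence), `overlap_length` (nt of the duplicated
#'   region), and `circularization` (logical).
#' @export
propose_joins <- function(contigs, arrays, min_k = 4L,
                          params = default_config()) {
  ids <- contig_ids(contigs)
  pfrac <- params$partial_spacer_frac
  bnd <- list()
  for (cid in ids) {
    cg <- get_contig(contigs, cid)
    ca <- Filter(function(a) a$contig_id == cid, arrays)
    bnd[[cid]] <- boundary_arrays(cg, ca, params$edge_window)
  }

  proposals <- list()
  seen <- character(0L)

  for (cid_a in ids) {
    for (ea in bnd[[cid_a]]) {
      for (cid_b in ids) {
        for (eb in bnd[[cid_b]]) {
          for (orient in c("forward", "reverse-complement")) {
            if (cid_a == cid_b) {
              # a contig's own two ends: circularisation, forward only
              if (!(ea$end == "right" && eb$end == "left" &&
                    orient == "forward")) next
              # one array spanning the whole contig would match itself
              # trivially; circularisation needs two distinct boundary arrays
              if (identical(ea$array$id, eb$array$id)) next
            }
            # geometry: upstream partner's array must face the junction at its
            # right end; downstream partner's at its left end (after
            # orientation of b)
            if (ea$end == "right") {
              eb_needed <- if (orient == "forward") "left" else "right"
              if (eb$end != eb_needed) next
              up <- list(contig = cid_a, end = "right", array = ea$array,
                         rc = FALSE)
              down <- list(contig = cid_b, end = eb$end, array = eb$array,
                           rc = orient != "forward")
            } else {
              # junction at a's left end: oriented b precedes a
              eb_needed <- if (orient == "forward") "right" else "left"
              if (eb$end != eb_needed) next
              up <- list(contig = cid_b, end = eb$end, array = eb$array,
                         rc = orient != "forward")
              down <- list(contig = cid_a, end = "left", array = ea$array,
                           rc = FALSE)
            }

            key <- paste(c(sort(c(paste(cid_a, ea$end, ea$array$id),
                                  paste(cid_b, eb$end, eb$array$id))),
                           orient), collapse = "|")
            if (key %in% seen) next

            sp_up <- boundary_spacer_seqs(
              up$array, get_contig(contigs, up$contig)$length, pfrac)
            sp_down <- boundary_spacer_seqs(
              down$array, get_contig(contigs, down$contig)$length, pfrac)
            if (up$rc) sp_up <- rev(vapply(sp_up, revcomp, character(1L)))
            if (down$rc) sp_down <- rev(vapply(sp_down, revcomp,
                                               character(1L)))
            k <- longest_end_run(sp_up, sp_down)
            seen <- c(seen, key)
            if (k < min_k) next

            shared <- data.frame(
              seq = tail(sp_up, k),
              stringsAsFactors = FALSE)
            overlap <- overlap_length_from_arrays(up, down, k, contigs)
            down_len <- get_contig(contigs, down$contig)$length
            dsp <- down$array$spacers[, c("start", "end"), drop = FALSE]
            if (down$rc && nrow(dsp)) {
              dsp <- data.frame(start = down_len - dsp$end,
                                end = down_len - dsp$start)
              dsp <- dsp[rev(seq_len(nrow(dsp))), , drop = FALSE]
            }
            proposals[[length(proposals) + 1L]] <- structure(list(
              contig_a = cid_a, end_a = ea$end,
              contig_b = cid_b, end_b = eb$end,
              orientation_b = orient,
              k = k, shared_run = shared,
              overlap_length = overlap,
              down_spacer_spans = dsp,
              upstream = up[c("contig", "end", "rc")],
              downstream = down[c("contig", "end", "rc")],
              upstream_array_id = up$array$id,
              downstream_array_id = down$array$id,
              circularization = cid_a == cid_b,
              evidence_level = "in_silico"
            ), class = "join_proposal")
          }
        }
      }
    }
  }
  if (length(proposals) > 1L) {
    proposals <- proposals[order(-vapply(proposals, `[[`, integer(1L), "k"),
                                 vapply(proposals, `[[`, character(1L),
                                        "contig_a"))]
  }
  proposals
}

# duplicated-overlap length implied by the shared run: measured on the
# downstream partner (from its oriented start through the repeat following
# the last shared spacer) and cross-checked on the upstream partner
overlap_length_from_arrays <- function(up, down, k, contigs) {
  down_len <- get_contig(contigs, down$contig)$length
  spans_down <- if (down$rc) {
    mirror_array_spans(down$array, down_len)
  } else {
    down$array$repeat_spans
  }
  # shared spacers are the first k of the downstream boundary array; overlap
  # runs through the end of repeat k + 1
  ov_down <- spans_down[k + 1L, 2L]

  up_len <- get_contig(contigs, up$contig)$length
  spans_up <- if (up$rc) {
    mirror_array_spans(up$array, up_len)
  } else {
    up$array$repeat_spans
  }
  n_rep <- nrow(spans_up)
  ov_up <- up_len - spans_up[n_rep - k, 1L]
  min(ov_down, ov_up)
}

#' @export
print.join_proposal <- function(x, ...) {
  cat(sprintf(
    "<join_proposal> %s(%s) -- %s(%s, %s): k=%d shared spacers, overlap %d nt%s\n",
    x$contig_a, x$end_a, x$contig_b, x$end_b, x$orientation_b, x$k,
    x$overlap_length,
    if (x$circularization) " [circularization]" else ""))
  invisible(x)
}

#' Merge two contigs according to a join proposal
#'
#' Concatenates the two contigs in the proposed orientation, collapsing the
#' duplicated shared-spacer region once. The two copies of the overlap must
#' agree exactly at spacer positions; the flanking repeats may disagree at up
#' to `repeat_tol` of their positions (repeat degeneracy at array edges).
#' Beyond that the proposal is rejected with an error. The merge is recorded
#' as provisional (`join_evidence=in_silico`) in the output description: the
#' join is a hypothesis for targeted validation, never a claimed closure.
#'
#' @param proposal A `join_proposal` from [propose_joins()].
#' @param contigs The contig list the proposal refers to.
#' @param repeat_tol Tolerated mismatch fraction over non-spacer overlap
#'   positions (default from `params`).
#' @param params Configuration list.
#' @return The merged [contig()]. Merging the two fragments produced by
#'   [fragment_at_array()] reconstructs the original chromosome exactly.
#' @export
merge_contigs <- function(proposal, contigs, repeat_tol = params$repeat_tol,
                          params = default_config()) {
  stopifnot(inherits(proposal, "join_proposal"))
  up <- proposal$upstream
  down <- proposal$downstream
  up_cg <- get_contig(contigs, up$contig)
  down_cg <- get_contig(contigs, down$contig)
  up_seq <- if (up$rc) revcomp(up_cg$seq) else up_cg$seq
  down_seq <- if (down$rc) revcomp(down_cg$seq) else down_cg$seq

  ov <- proposal$overlap_length
  if (ov < 1L || ov > nchar(up_seq) || ov > nchar(down_seq)) {
    stop("invalid overlap length in proposal", call. = FALSE)
  }
  up_ov <- substr(up_seq, nchar(up_seq) - ov + 1L, nchar(up_seq))
  down_ov <- substr(down_seq, 1L, ov)

  vu <- utf8ToInt(up_ov)
  vd <- utf8ToInt(down_ov)
  mis <- which(vu != vd)

  # spacer positions inside the overlap, in oriented downstream coordinates
  spacer_mask <- rep(FALSE, ov)
  da <- proposal$down_spacer_spans
  if (!is.null(da) && nrow(da)) {
    for (r in seq_len(nrow(da))) {
      s0 <- max(da$start[r], 0L)
      e0 <- min(da$end[r], ov)
      if (e0 > s0) spacer_mask[(s0 + 1L):e0] <- TRUE
    }
  }
  sp_mis <- mis[spacer_mask[mis]]
  rep_mis <- mis[!spacer_mask[mis]]
  allowed <- floor(repeat_tol * sum(!spacer_mask))
  if (length(sp_mis) > 0L || length(rep_mis) > allowed) {
    stop("overlap sequences disagree beyond spacer identity (",
         length(sp_mis), " spacer mismatch(es), ", length(rep_mis),
         " repeat mismatch(es) vs ", allowed, " allowed); proposal rejected",
         call. = FALSE)
  }

  merged_seq <- paste0(up_seq, substr(down_seq, ov + 1L, nchar(down_seq)))
  contig(
    paste0(up$contig, "_", down$contig, "_joined"),
    merged_seq,
    topology = if (proposal$circularization) "circular" else "linear",
    desc = sprintf(
      "join_evidence=in_silico;shared_spacers=%d;overlap=%dnt;%s(%s)+%s(%s)",
      proposal$k, ov, up$contig, if (up$rc) "rc" else "fwd",
      down$contig, if (down$rc) "rc" else "fwd"))
}
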