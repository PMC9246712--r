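# Contig triage: circularity via terminal direct repeats, linear-virus
# signatures via terminal inverted repeats, coverage ratios, and an ordered
# rule set assigning each contig exactly one label with recorded evidence.

new_terminal_repeat <- function(contig_id, kind, length, identity,
                                left_start, left_end, right_start, right_end) {
  structure(list(contig_id = contig_id, kind = kind,
                 length = as.integer(length), identity = identity,
                 left_start = as.integer(left_start),
                 left_end = as.integer(left_end),
                 right_start = as.integer(right_start),
                 right_end = as.integer(right_end)),
            class = "terminal_repeat")
}

#' @export
print.terminal_repeat <- function(x, ...) {
  cat(sprintf("<terminal_repeat> %s on %s: %d nt, identity %.3f\n",
              x$kind, x$contig_id, x$length, x$identity))
  invisible(x)
}

#' Detect circularity as a terminal direct repeat
#'
#' Assemblers emit circular replicons as linear strings whose start is
#' duplicated at the end. This reports the longest prefix of the contig that
#' matches (within `max_mismatch` Hamming mismatches) an equal-length suffix,
#' searched up to half the contig length, provided it reaches `min_overlap`.
#' Candidate overlap lengths are located by matching the first `min_overlap`
#' nt against the contig with the same mismatch budget (complete: any valid
#' overlap has at most `max_mismatch` mismatches in that window), then
#' verified over the full overlap.
#'
#' @param contig A [contig()].
#' @param min_overlap Minimum overlap length, nt (default 20).
#' @param max_mismatch Mismatch budget over the whole overlap (default 0).
#' @return A `terminal_repeat` of kind `"direct"`, or `NULL`.
#' @export
detect_circularity <- function(contig, min_overlap = 20L, max_mismatch = 0L) {
  n <- contig$length
  if (n < 2L * min_overlap) return(NULL)
  prefix <- substr(contig$seq, 1L, min_overlap)
  subject <- Biostrings::DNAString(gsub("N", "-", contig$seq, fixed = TRUE))
  m <- Biostrings::matchPattern(Biostrings::DNAString(prefix), subject,
                                max.mismatch = max_mismatch,
                                with.indels = FALSE, fixed = TRUE)
  if (!length(m)) return(NULL)
  cand_L <- n - (IRanges::start(m) - 1L)      # overlap length implied by each
  cand_L <- cand_L[cand_L >= min_overlap & cand_L <= n %/% 2L]
  if (!length(cand_L)) return(NULL)
  for (L in sort(cand_L, decreasing = TRUE)) {
    mm <- hamming(substr(contig$seq, 1L, L),
                  substr(contig$seq, n - L + 1L, n))
    if (mm <= max_mismatch) {
      return(new_terminal_repeat(contig$id, "direct", L, (L - mm) / L,
                                 0L, L, n - L, n))
    }
  }
  NULL
}

#' Detect terminal inverted repeats (TIRs)
#'
#' Compares the first `max_scan` nt of the contig against the reverse
#' complement of its last `max_scan` nt by ungapped extension from position 0.
#' Extension is scored +1 per match and -3 per mismatch and terminates when
#' the score drops `x_drop` below its running maximum; the reported arm is the
#' longest match-ending prefix attaining the maximal score. The arm is
#' reported when its length reaches `min_len` and its identity reaches
#' `min_identity`.
#'
#' @param contig A [contig()].
#' @param min_len Minimum arm length, nt (default 20).
#' @param min_identity Minimum arm identity fraction (default 0.85).
#' @param max_scan Terminal window compared, nt (default 500).
#' @param x_drop Score drop terminating extension (default 20).
#' @return A `terminal_repeat` of kind `"inverted"`, or `NULL`.
#' @export
detect_tir <- function(contig, min_len = 20L, min_identity = 0.85,
                       max_scan = 500L, x_drop = 20L) {
  n <- contig$length
  if (n < 2L * min_len) return(NULL)
  w <- min(max_scan, n %/% 2L)
  f <- utf8ToInt(substr(contig$seq, 1L, w))
  r <- utf8ToInt(revcomp(substr(contig$seq, n - w + 1L, n)))
  n_int <- utf8ToInt("N")
  match_vec <- f == r & f != n_int & r != n_int
  score <- cumsum(ifelse(match_vec, 1L, -3L))
  run_max <- cummax(score)
  stopped <- which(run_max - score > x_drop)
  upto <- if (length(stopped)) stopped[1L] - 1L else w
  if (upto < 1L) return(NULL)
  smax <- max(score[seq_len(upto)])
  arm <- max(which(score[seq_len(upto)] == smax & match_vec[seq_len(upto)]),
             -Inf)
  if (!is.finite(arm)) return(NULL)
  identity <- sum(match_vec[seq_len(arm)]) / arm
  if (arm < min_len || identity < min_identity) return(NULL)
  new_terminal_repeat(contig$id, "inverted", arm, identity,
                      0L, arm, n - arm, n)
}

#' Depth ratio of a contig relative to the chromosome
#'
#' Elevated depth relative to the host chromosome is a signature of active
#' (e.g. viral) DNA replication.
#'
#' @param contig A [contig()] or contig id.
#' @param chromosome The chromosome [contig()] or its id.
#' @param depths Named numeric vector (contig id -> mean depth), e.g. from
#'   [read_depth_table()].
#' @return Positive real: contig depth divided by chromosome depth.
#' @export
coverage_ratio <- function(contig, chromosome, depths) {
  cid <- if (is_contig(contig)) contig$id else contig
  hid <- if (is_contig(chromosome)) chromosome$id else chromosome
  for (id in c(cid, hid)) {
    if (!id %in% names(depths) || is.na(depths[id])) {
      stop("no depth recorded for contig '", id, "'", call. = FALSE)
    }
  }
  if (depths[hid] <= 0) stop("chromosome depth must be > 0", call. = FALSE)
  unname(depths[cid] / depths[hid])
}

#' Classify contigs into chromosome and mobile-element classes
#'
#' Rules are applied in order; the first match wins:
#' 1. the designated (or longest) contig is the `chromosome`;
#' 2. at least `array_fraction_threshold` of the contig covered by detected
#'    CRISPR arrays: `crispr_fragment`;
#' 3. terminal direct repeat present: `circular_mobile`;
#' 4. terminal inverted repeat present: `linear_tir_mobile`;
#' 5. at least one spacer hit as a target, or coverage ratio at least
#'    `coverage_ratio_threshold`, or a user-supplied mobile-gene annotation:
#'    `mobile_other`;
#' 6. otherwise `unclassified`.
#'
#' Every label except `unclassified` carries the evidence that triggered it.
#' Mobile-gene evidence (integrases, endonucleases, ...) and contaminant
#' overrides enter only through the optional `annotations` table; no gene
#' calling is performed.
#'
#' @param contigs List of [contig()] objects (the assembly).
#' @param arrays List of `crispr_array` objects across the assembly.
#' @param hits Hit table from [find_hits()].
#' @param repeats List of `terminal_repeat` objects.
#' @param depths Optional named depth vector.
#' @param params Configuration list.
#' @param chromosome_id Optional explicit chromosome designation; default is
#'   the longest contig.
#' @param annotations Optional data frame with columns `contig_id`,
#'   `evidence`, and optionally `label_override`.
#' @return Data frame with columns `contig_id`, `label`, `evidence`
#'   (`;`-separated tags).
#' @export
classify <- function(contigs, arrays = list(), hits = NULL, repeats = list(),
                     depths = NULL, params = default_config(),
                     chromosome_id = NULL, annotations = NULL) {
  if (!length(contigs)) stop("empty assembly", call. = FALSE)
  ids <- contig_ids(contigs)
  lens <- vapply(contigs, `[[`, integer(1L), "length")
  if (is.null(chromosome_id)) {
    chromosome_id <- ids[which.max(lens)]
  } else if (!chromosome_id %in% ids) {
    stop("designated chromosome '", chromosome_id, "' not in assembly",
         call. = FALSE)
  }

  array_cov <- vapply(ids, function(cid) {
    spans <- lapply(arrays, function(a) {
      if (a$contig_id == cid) c(a$start, a$end) else NULL
    })
    spans <- do.call(rbind, spans)
    if (is.null(spans)) 0 else
      sum(spans[, 2L] - spans[, 1L]) / lens[match(cid, ids)]
  }, numeric(1L))

  rep_by_contig <- list()
  for (r in repeats) {
    rep_by_contig[[r$contig_id]] <- c(rep_by_contig[[r$contig_id]], list(r))
  }

  out <- data.frame(contig_id = ids, label = "unclassified", evidence = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    cid <- ids[i]
    ev <- character(0L)

    override <- NULL
    ann_ev <- character(0L)
    if (!is.null(annotations) && cid %in% annotations$contig_id) {
      ann <- annotations[annotations$contig_id == cid, , drop = FALSE]
      ann_ev <- sprintf("annotation(%s)", ann$evidence)
      if ("label_override" %in% names(ann) &&
          any(nzchar(ann$label_override) & !is.na(ann$label_override))) {
        override <- ann$label_override[nzchar(ann$label_override)][1L]
      }
    }
    if (!is.null(override)) {
      out$label[i] <- override
      out$evidence[i] <- paste(ann_ev, collapse = ";")
      next
    }

    if (cid == chromosome_id) {
      out$label[i] <- "chromosome"
      out$evidence[i] <- sprintf("designated_chromosome(%dnt)", lens[i])
      next
    }
    if (array_cov[i] >= params$array_fraction_threshold) {
      out$label[i] <- "crispr_fragment"
      out$evidence[i] <- sprintf("array_coverage=%.2f", array_cov[i])
      next
    }
    reps <- rep_by_contig[[cid]]
    direct <- Filter(function(r) r$kind == "direct", reps)
    if (length(direct)) {
      out$label[i] <- "circular_mobile"
      out$evidence[i] <- sprintf("terminal_direct_repeat(%dnt,identity=%.3f)",
                                 direct[[1L]]$length, direct[[1L]]$identity)
      next
    }
    inverted <- Filter(function(r) r$kind == "inverted", reps)
    if (length(inverted)) {
      out$label[i] <- "linear_tir_mobile"
      out$evidence[i] <- sprintf("terminal_inverted_repeat(%dnt,identity=%.3f)",
                                 inverted[[1L]]$length,
                                 inverted[[1L]]$identity)
      next
    }
    n_hits <- if (is.null(hits)) 0L else sum(hits$target == cid)
    if (n_hits > 0L) ev <- c(ev, sprintf("spacer_hits=%d", n_hits))
    if (!is.null(depths) && cid %in% names(depths) &&
        chromosome_id %in% names(depths) && depths[chromosome_id] > 0) {
      ratio <- coverage_ratio(cid, chromosome_id, depths)
      if (ratio >= params$coverage_ratio_threshold) {
        ev <- c(ev, sprintf("coverage_ratio=%.2f", ratio))
      }
    }
    ev <- c(ev, ann_ev)
    if (length(ev)) {
      out$label[i] <- "mobile_other"
      out$evidence[i] <- paste(ev, collapse = ";")
    }
  }
  out
}
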