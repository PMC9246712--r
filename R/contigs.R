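#' Construct a contig record
#'
#' The basic unit consumed by every pipeline stage: a named DNA sequence with
#' optional mean read depth and topology metadata.
#'
#' @param id Character scalar, unique contig identifier.
#' @param seq DNA string over the alphabet `A,C,G,T,N` (case-insensitive;
#'   normalised to upper case).
#' @param mean_depth Optional non-negative mean read depth (reads per base).
#' @param topology One of `"unknown"`, `"linear"`, `"circular"`.
#' @param desc Free-text description (FASTA header text after the first
#'   whitespace is kept here on read).
#'
#' @return An object of class `"contig"`: a list with elements `id`, `seq`,
#'   `length`, `mean_depth`, `topology`, `desc`.
#' @export
#' @examples
#' contig("c1", "acgt")
contig <- function(id, seq,
                   mean_depth = NULL,
                   topology = c("unknown", "linear", "circular"),
                   desc = "") {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) {
    stop("contig '", id, "' has an empty sequence", call. = FALSE)
  }
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1L]])
    stop("contig '", id, "' contains illegal characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(mean_depth)) {
    mean_depth <- as.numeric(mean_depth)
    if (is.na(mean_depth) || mean_depth < 0) {
      stop("mean_depth of contig '", id, "' must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(id = id, seq = seq, length = nchar(seq),
         mean_depth = mean_depth, topology = topology, desc = desc),
    class = "contig"
  )
}

#' @export
print.contig <- function(x, ...) {
  depth <- if (is.null(x$mean_depth)) "NA" else format(x$mean_depth)
  cat(sprintf("<contig> %s  %d nt  topology=%s  depth=%s\n",
              x$id, x$length, x$topology, depth))
  invisible(x)
}

is_contig <- function(x) inherits(x, "contig")

#' Look up a contig by id in a list of contigs
#' @param contigs List of [contig()] objects.
#' @param id Contig identifier.
#' @return The matching contig.
#' @export
get_contig <- function(contigs, id) {
  ids <- vapply(contigs, `[[`, character(1L), "id")
  i <- match(id, ids)
  if (is.na(i)) stop("no contig with id '", id, "'", call. = FALSE)
  contigs[[i]]
}

contig_ids <- function(contigs) vapply(contigs, `[[`, character(1L), "id")

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`. Works on plain character scalars.
#'
#' @param seq DNA string.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Hamming distance between two equal-length DNA strings
#'
#' `N` never matches anything, including another `N` (conservative treatment
#' of ambiguity), so any position where either string carries `N` counts as a
#' mismatch.
#'
#' @param a,b Equal-length DNA strings.
#' @return Integer mismatch count.
#' @export
hamming <- function(a, b) {
  va <- utf8ToInt(a)
  vb <- utf8ToInt(b)
  if (length(va) != length(vb)) {
    stop("hamming() requires equal-length strings", call. = FALSE)
  }
  n_int <- utf8ToInt("N")
  sum(va != vb | va == n_int | vb == n_int)
}

#' Reverse complement of a contig
#'
#' @param x A [contig()].
#' @return A contig with reverse-complemented sequence; the id gains an
#'   `_rc` suffix unless `keep_id = TRUE`.
#' @param keep_id Keep the original id.
#' @export
revcomp_contig <- function(x, keep_id = FALSE) {
  stopifnot(is_contig(x))
  contig(if (keep_id) x$id else paste0(x$id, "_rc"), revcomp(x$seq),
         mean_depth = x$mean_depth, topology = x$topology, desc = x$desc)
}

# Random DNA string; prob is a length-4 vector over A,C,G,T. Uses the current
# RNG state (callers control the seed).
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Mirror a 0-based half-open interval on a contig of length len
# (coordinates on the reverse complement).
mirror_span <- function(start, end, len) {
  c(start = len - end, end = len - start)
}
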