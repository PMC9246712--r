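#' Read an assembly FASTA file
#'
#' One [contig()] per record, order preserved, sequences upper-cased. The
#' record description after the first whitespace is retained in `desc`.
#' Records with empty sequences or duplicated ids are hard errors naming the
#' offending record.
#'
#' @param path FASTA file path.
#' @return List of [contig()] objects.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA record id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  empty <- ids[Biostrings::width(ss) == 0L]
  if (length(empty)) {
    stop("FASTA record(s) with empty sequence: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    out[[i]] <- contig(ids[i], as.character(ss[[i]]), desc = descs[i])
  }
  out
}

#' Write contigs to a FASTA file
#'
#' @param contigs List of [contig()] objects.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(vapply(contigs, `[[`, character(1L), "seq"))
  descs <- vapply(contigs, `[[`, character(1L), "desc")
  ids <- contig_ids(contigs)
  names(seqs) <- ifelse(nzchar(descs), paste(ids, descs), ids)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a per-contig depth table
#'
#' Expects a TSV with header columns `contig_id` and `mean_depth`. Contigs in
#' the table but absent from `contigs` (when supplied) are tolerated with a
#' warning; negative depths are a hard error.
#'
#' @param path TSV file path.
#' @param contigs Optional list of contigs to cross-check ids against.
#' @return Named numeric vector: contig id -> mean depth.
#' @export
read_depth_table <- function(path, contigs = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("contig_id", "mean_depth") %in% names(df))) {
    stop("depth table must have header columns 'contig_id' and 'mean_depth'",
         call. = FALSE)
  }
  depth <- as.numeric(df$mean_depth)
  if (anyNA(depth)) stop("non-numeric mean_depth in depth table", call. = FALSE)
  if (any(depth < 0)) {
    stop("negative mean_depth for contig(s): ",
         paste(df$contig_id[depth < 0], collapse = ", "), call. = FALSE)
  }
  names(depth) <- df$contig_id
  if (!is.null(contigs)) {
    unknown <- setdiff(names(depth), contig_ids(contigs))
    if (length(unknown)) {
      warning("depth table names unknown contig(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  depth
}

#' Write a per-contig depth table
#' @param depths Named numeric vector (contig id -> mean depth).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depths, path) {
  df <- data.frame(contig_id = names(depths), mean_depth = unname(depths),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detected features to GFF3
#'
#' Serialises arrays (`repeat_region`), terminal repeats (`direct_repeat` /
#' `inverted_repeat`, one line per arm) and protospacer hits (`protospacer`).
#' Internal coordinates are 0-based half-open; GFF3 on disk is 1-based
#' inclusive.
#'
#' @param arrays List of `crispr_array` objects (may be empty).
#' @param repeats List of `terminal_repeat` objects (may be empty).
#' @param hits Spacer hit data frame from [find_hits()] (may be `NULL`).
#' @param path Output GFF3 path.
#' @param contigs Optional contig list; when given, any feature extending past
#'   its contig end is a hard error.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(arrays = list(), repeats = list(), hits = NULL,
                                path, contigs = NULL) {
  rows <- list()
  add <- function(seqid, start0, end0, type, strand, id, extra = character()) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = seqid, start = start0, end = end0, type = type,
      strand = strand, ID = id,
      extra = if (length(extra)) paste(extra, collapse = ";") else "",
      stringsAsFactors = FALSE)
  }
  for (a in arrays) {
    add(a$contig_id, a$start, a$end, "repeat_region", "*", a$id,
        sprintf("n_repeats=%d", a$n_repeats))
    for (i in seq_len(nrow(a$repeat_spans))) {
      add(a$contig_id, a$repeat_spans[i, 1L], a$repeat_spans[i, 2L],
          "direct_repeat", "*", sprintf("%s_rep%02d", a$id, i))
    }
    if (nrow(a$spacers)) {
      for (i in seq_len(nrow(a$spacers))) {
        add(a$contig_id, a$spacers$start[i], a$spacers$end[i],
            "spacer", "*", a$spacers$id[i])
      }
    }
  }
  for (r in repeats) {
    type <- if (r$kind == "inverted") "inverted_repeat" else "direct_repeat"
    add(r$contig_id, r$left_start, r$left_end, type, "+",
        paste0(r$contig_id, "_", r$kind, "_L"),
        sprintf("identity=%.4f", r$identity))
    add(r$contig_id, r$right_start, r$right_end, type,
        if (r$kind == "inverted") "-" else "+",
        paste0(r$contig_id, "_", r$kind, "_R"),
        sprintf("identity=%.4f", r$identity))
  }
  if (!is.null(hits) && nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      add(hits$target[i], hits$start[i], hits$end[i], "protospacer",
          hits$strand[i], sprintf("hit_%04d", i),
          c(sprintf("spacer=%s", hits$spacer_id[i]),
            sprintf("mismatches=%d", hits$mismatches[i])))
    }
  }
  if (!length(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  if (!is.null(contigs)) {
    lens <- vapply(contigs, `[[`, integer(1L), "length")
    names(lens) <- contig_ids(contigs)
    over <- df$end > lens[df$seqid]
    if (any(is.na(over)) || any(over)) {
      bad <- df$ID[is.na(over) | over]
      stop("feature(s) extend past contig end or name unknown contigs: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$note <- df$extra
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read features back from a GFF3 file
#'
#' Inverse of [write_features_gff3()] at the coordinate level: returns
#' 0-based half-open spans so that a write/read round trip is the identity.
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `contig_id`, `type`, `start`, `end`
#'   (0-based half-open), `strand`, `ID`.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) {
    return(data.frame(contig_id = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), ID = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = as.character(S4Vectors::mcols(gr)$ID),
    stringsAsFactors = FALSE)
}

#' Mean per-contig depth from a coordinate-sorted BAM file
#'
#' Thin optional adapter: the pipeline itself consumes depth as a TSV
#' ([read_depth_table()]); this helper computes mean depth (aligned bases per
#' reference base) when an alignment file is at hand. Requires the Rsamtools
#' package.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @return Named numeric vector: contig id -> mean depth.
#' @export
depth_from_bam <- function(bam) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("depth_from_bam() requires the Rsamtools package", call. = FALSE)
  }
  bf <- Rsamtools::BamFile(bam)
  lens <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  pp <- Rsamtools::PileupParam(max_depth = 1000000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE)
  p <- Rsamtools::pileup(bf, pileupParam = pp)
  tot <- tapply(p$count, p$seqnames, sum)
  depth <- rep(0, length(lens))
  names(depth) <- names(lens)
  depth[names(tot)] <- as.numeric(tot) / lens[names(tot)]
  depth
}
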