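# Synthetic assemblies with planted ground truth.
#
# The generator emulates the system the pipeline targets: a circular
# chromosome whose cumulative GC skew has a V-shape with a unique minimum at
# the planted replication origin, two CRISPR arrays (same repeat, distinct
# spacers) flanking a marker locus, plain mobile contigs, a circular virus
# represented with a duplicated terminal direct repeat, and a linear virus
# flanked by terminal inverted repeats at elevated depth. Protospacers are
# copies of planted spacers with exactly 0 or exactly 1 substitution, on
# either strand, never inside an array.

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# distinct random spacers with the given lengths
random_spacers <- function(lens, prob = rep(0.25, 4)) {
  out <- character(0L)
  for (len in lens) {
    repeat {
      sp <- random_dna(len, prob)
      if (!sp %in% out) break
    }
    out <- c(out, sp)
  }
  out
}

# substitute exactly one base, position uniform
mutate_one <- function(seq) {
  v <- strsplit(seq, "")[[1L]]
  pos <- sample(length(v), 1L)
  v[pos] <- sample(setdiff(c("A", "C", "G", "T"), v[pos]), 1L)
  paste(v, collapse = "")
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# repeat/spacer interleaving; returns sequence plus 0-based repeat starts
build_array_seq <- function(repeat_seq, spacers) {
  parts <- character(2L * length(spacers) + 1L)
  parts[seq(1L, length(parts), by = 2L)] <- repeat_seq
  parts[seq(2L, length(parts), by = 2L)] <- spacers
  seq <- paste(parts, collapse = "")
  lens <- nchar(parts)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  list(seq = seq, repeat_starts = starts[seq(1L, length(parts), by = 2L)])
}

# sample non-overlapping planting positions in [margin, len - margin - w]
plant_positions <- function(len, widths, margin) {
  taken <- matrix(numeric(0L), ncol = 2L)
  out <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    lo <- margin
    hi <- len - margin - w
    if (hi < lo) stop("target contig too short to plant protospacers",
                      call. = FALSE)
    for (try in 1:1000) {
      s <- sample(lo:hi, 1L)
      if (!nrow(taken) ||
          all(s + w + 10L <= taken[, 1L] | s >= taken[, 2L] + 10L)) {
        taken <- rbind(taken, c(s, s + w))
        out[i] <- s
        break
      }
      if (try == 1000L) stop("could not place protospacers without overlap",
                             call. = FALSE)
    }
  }
  out
}

#' Generate a synthetic assembly with planted ground truth
#'
#' Emits the exact input formats of the pipeline (contigs, depth table) plus a
#' truth set recording every planted feature: origin position, array
#' coordinates and ordered spacers, protospacer sites with strand and planted
#' mismatch count, terminal-repeat lengths, depth multipliers.
#'
#' The chromosome is composed with a per-base G-vs-C excess
#' (`sim_skew_bias`) on the replichore downstream of the planted origin and
#' the mirror bias upstream, so the cumulative GC skew has a unique global
#' minimum at the origin; a weaker A-vs-T excess (`sim_at_bias`) makes the
#' corroborating AT/RY/MK tracks dip there too. Two CRISPR arrays sharing one
#' repeat consensus but carrying mutually distinct spacers flank a marker
#' locus placed on the opposite replichore arc.
#'
#' @param config A [default_config()] list; `sim_*` entries control the
#'   generator.
#' @param seed Integer seed; the same seed reproduces the assembly
#'   byte-identically.
#' @return List with elements `contigs` (list of [contig()]), `truth`
#'   (class `"truth_set"`), and `depths` (named numeric vector).
#' @export
generate_assembly <- function(config = default_config(), seed = config$seed) {
  L <- as.integer(config$sim_chromosome_length)
  if (L < 20000L) stop("chromosome length must be >= 20 kb", call. = FALSE)
  n_spacers <- config$sim_array1_spacers + config$sim_array2_spacers
  n_needed <- config$sim_n_plain_mobile * config$sim_exact_per_plain +
    config$sim_exact_circular + config$sim_exact_linear +
    config$sim_onemm_linear
  if (n_needed > n_spacers) {
    stop("requested protospacers (", n_needed,
         ") exceed available spacers (", n_spacers, ")", call. = FALSE)
  }

  with_local_seed(seed, {
    gc <- config$sim_gc_content
    dg <- config$sim_skew_bias / 2
    da <- config$sim_at_bias / 2
    p_lead <- c(A = (1 - gc) / 2 + da, C = gc / 2 - dg,
                G = gc / 2 + dg, T = (1 - gc) / 2 - da)
    p_lag <- c(A = (1 - gc) / 2 - da, C = gc / 2 + dg,
               G = gc / 2 - dg, T = (1 - gc) / 2 + da)

    ## --- chromosome background with planted skew V-shape -------------------
    origin <- sample(floor(0.15 * L):floor(0.85 * L), 1L)
    half <- L %/% 2L
    pos <- 0:(L - 1L)
    lead <- ((pos - origin) %% L) < half
    bases <- character(L)
    bases[lead] <- sample(names(p_lead), sum(lead), replace = TRUE,
                          prob = p_lead)
    bases[!lead] <- sample(names(p_lag), sum(!lead), replace = TRUE,
                           prob = p_lag)
    background <- paste(bases, collapse = "")

    ## --- CRISPR arrays flanking a marker locus -----------------------------
    # sizes first, so the block can be placed before sequences are drawn:
    # the block is sampled with the bias of its replichore, keeping the
    # composition bias (and hence the skew V-shape) uniform along each arm
    rep_len <- as.integer(config$sim_repeat_length)
    n1 <- config$sim_array1_spacers
    n2 <- config$sim_array2_spacers
    sp_lens <- sample(config$sim_spacer_min:config$sim_spacer_max, n_spacers,
                      replace = TRUE)
    decoy_i1 <- decoy_i2 <- NA_integer_
    if (isTRUE(config$sim_decoy_in_array)) {
      decoy_i1 <- sample(n1, 1L)
      decoy_i2 <- sample(n2, 1L)
      sp_lens[n1 + decoy_i2] <- sp_lens[decoy_i1]
    }
    blen <- (n1 + n2 + 2L) * rep_len + sum(sp_lens) +
      config$sim_marker_length

    margin <- 2L * config$skew_window
    if (origin + margin + blen <= L) {
      bs <- origin + margin + (L - origin - margin - blen) %/% 2L
    } else {
      bs <- (origin - margin - blen) %/% 2L
    }
    bs <- max(bs, 2L * config$edge_window)
    if (bs + blen > L - 2L * config$edge_window ||
        (origin >= bs - margin && origin < bs + blen + margin)) {
      stop("cannot place CRISPR array block away from origin; ",
           "increase chromosome length", call. = FALSE)
    }
    block_lead <- (((bs + blen %/% 2L) - origin) %% L) < half
    p_block <- if (block_lead) p_lead else p_lag

    repeat_seq <- random_dna(rep_len, p_block)
    spacers <- random_spacers(sp_lens, p_block)
    sp1 <- spacers[seq_len(n1)]
    sp2 <- spacers[n1 + seq_len(n2)]
    decoy <- NULL
    if (isTRUE(config$sim_decoy_in_array)) {
      # adversarial mode: one spacer occurs in both arrays, so its hit inside
      # the second array must be removed by the self-hit filter
      sp2[decoy_i2] <- sp1[decoy_i1]
      decoy <- list(array1_index = decoy_i1, array2_index = decoy_i2,
                    seq = sp1[decoy_i1])
    }
    arr1 <- build_array_seq(repeat_seq, sp1)
    arr2 <- build_array_seq(repeat_seq, sp2)
    marker <- random_dna(config$sim_marker_length, p_block)
    block <- paste0(arr1$seq, marker, arr2$seq)
    stopifnot(nchar(block) == blen)
    chrom_seq <- paste0(substr(background, 1L, bs), block,
                        substr(background, bs + blen + 1L, L))

    a1_start <- bs
    a2_start <- bs + nchar(arr1$seq) + config$sim_marker_length
    sp_ids <- function(aid, n) sprintf("%s_sp%02d", aid, seq_len(n))
    arrays <- list(
      list(id = "array1", contig_id = "chromosome",
           start = a1_start, end = a1_start + nchar(arr1$seq),
           repeat_consensus = repeat_seq,
           repeat_len = config$sim_repeat_length,
           repeat_starts = a1_start + arr1$repeat_starts,
           spacers = sp1, spacer_ids = sp_ids("array1", length(sp1))),
      list(id = "array2", contig_id = "chromosome",
           start = a2_start, end = a2_start + nchar(arr2$seq),
           repeat_consensus = repeat_seq,
           repeat_len = config$sim_repeat_length,
           repeat_starts = a2_start + arr2$repeat_starts,
           spacers = sp2, spacer_ids = sp_ids("array2", length(sp2)))
    )
    all_sp_ids <- c(arrays[[1L]]$spacer_ids, arrays[[2L]]$spacer_ids)
    all_sp_seq <- c(sp1, sp2)

    ## --- mobile-element contigs --------------------------------------------
    contigs <- list(contig("chromosome", chrom_seq, topology = "circular",
                           desc = "synthetic chromosome"))
    mobile_specs <- list()
    if (config$sim_n_plain_mobile > 0L) {
      for (i in seq_len(config$sim_n_plain_mobile)) {
        mobile_specs[[length(mobile_specs) + 1L]] <- list(
          id = sprintf("mobile_%d", i), kind = "plain",
          length = config$sim_plain_mobile_length,
          n_exact = config$sim_exact_per_plain, n_onemm = 0L,
          depth_mult = config$sim_plain_depth_multiplier)
      }
    }
    if (config$sim_circular_virus_length > 0L) {
      mobile_specs[[length(mobile_specs) + 1L]] <- list(
        id = "virus_circ", kind = "circular",
        length = config$sim_circular_virus_length,
        n_exact = config$sim_exact_circular, n_onemm = 0L,
        depth_mult = config$sim_circular_depth_multiplier)
    }
    if (config$sim_linear_virus_length > 0L) {
      mobile_specs[[length(mobile_specs) + 1L]] <- list(
        id = "virus_tir", kind = "tir",
        length = config$sim_linear_virus_length,
        n_exact = config$sim_exact_linear, n_onemm = config$sim_onemm_linear,
        depth_mult = config$sim_virus_depth_multiplier)
    }

    pool <- sample(seq_along(all_sp_seq))  # spacer indices, random order
    take <- function(n) {
      idx <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      idx
    }

    proto <- list()
    tir_truth <- NULL
    circ_truth <- NULL
    depth_mult <- c(chromosome = 1.0)

    for (spec in mobile_specs) {
      len <- as.integer(spec$length)
      if (spec$kind == "plain") {
        seqc <- random_dna(len)
        margin_p <- 200L
      } else if (spec$kind == "circular") {
        ov <- as.integer(config$sim_circular_overlap)
        core <- random_dna(len)
        seqc <- paste0(core, substr(core, 1L, ov))
        margin_p <- ov + 200L
        circ_truth <- list(contig_id = spec$id, length = ov)
      } else { # linear virus with terminal inverted repeats
        tl <- as.integer(config$sim_tir_length)
        core <- strsplit(random_dna(len - 2L * tl), "")[[1L]]
        tir <- random_dna(tl)
        right <- strsplit(revcomp(tir), "")[[1L]]
        # sharpen the planted arm boundary: the 4 bases inward of each arm
        # must not complement their counterparts, so the planted TIR length
        # is exactly tl
        nc <- length(core)
        for (j in 1:4) {
          partner <- comp_base(core[nc - j + 1L])
          if (core[j] == partner) {
            core[j] <- sample(setdiff(c("A", "C", "G", "T"), partner), 1L)
          }
        }
        identity <- 1
        left <- strsplit(tir, "")[[1L]]
        if (config$sim_tir_mismatches > 0L) {
          for (m in seq_len(config$sim_tir_mismatches)) {
            p <- sample(5:(tl - 5L), 1L)
            left[p] <- sample(setdiff(c("A", "C", "G", "T"), left[p]), 1L)
          }
          identity <- (tl - config$sim_tir_mismatches) / tl
        }
        seqc <- paste(c(left, core, right), collapse = "")
        margin_p <- tl + 200L
        tir_truth <- list(contig_id = spec$id, length = tl,
                          identity = identity)
      }

      n_sites <- spec$n_exact + spec$n_onemm
      if (n_sites > 0L) {
        idx <- take(n_sites)
        mism <- c(rep(0L, spec$n_exact), rep(1L, spec$n_onemm))
        widths <- nchar(all_sp_seq[idx])
        starts <- plant_positions(nchar(seqc), widths, margin_p)
        for (j in seq_len(n_sites)) {
          sp_seq <- all_sp_seq[idx[j]]
          site <- if (mism[j] == 1L) mutate_one(sp_seq) else sp_seq
          strand <- sample(c("+", "-"), 1L)
          ins <- if (strand == "+") site else revcomp(site)
          substr(seqc, starts[j] + 1L, starts[j] + widths[j]) <- ins
          proto[[length(proto) + 1L]] <- data.frame(
            spacer_id = all_sp_ids[idx[j]], spacer_seq = sp_seq,
            contig_id = spec$id, start = starts[j],
            end = starts[j] + widths[j], strand = strand,
            mismatches = mism[j], stringsAsFactors = FALSE)
        }
      }
      contigs[[length(contigs) + 1L]] <-
        contig(spec$id, seqc, desc = paste0("synthetic ", spec$kind,
                                            " mobile element"))
      depth_mult[spec$id] <- spec$depth_mult
    }

    protospacers <- if (length(proto)) {
      do.call(rbind, proto)
    } else {
      data.frame(spacer_id = character(), spacer_seq = character(),
                 contig_id = character(), start = integer(), end = integer(),
                 strand = character(), mismatches = integer(),
                 stringsAsFactors = FALSE)
    }

    depths <- config$sim_chromosome_depth * depth_mult
    for (i in seq_along(contigs)) {
      contigs[[i]]$mean_depth <- unname(depths[contigs[[i]]$id])
    }

    truth <- structure(list(
      seed = seed,
      origin_position = origin,
      arrays = arrays,
      protospacers = protospacers,
      tir = tir_truth,
      circular_overlap = circ_truth,
      depth_multipliers = depth_mult,
      decoy = decoy,
      join_truth = NULL
    ), class = "truth_set")

    list(contigs = contigs, truth = truth, depths = depths)
  })
}

#' Fragment the chromosome inside a CRISPR array
#'
#' Splits the chromosome into two contigs whose facing boundaries terminate in
#' partial arrays sharing exactly `k_shared` consecutive identical spacers
#' (the duplicated region), emulating how independent assemblies break inside
#' long repeat loci. The correct join is recorded in `join_truth`.
#' Concatenating the left fragment with the right fragment minus the
#' duplicated overlap reconstructs the chromosome exactly.
#'
#' @param chromosome The chromosome [contig()] from [generate_assembly()].
#' @param truth The matching `truth_set`.
#' @param k_shared Number of shared consecutive spacers (default 4).
#' @param seed Integer seed controlling the split position.
#' @return List with `contigs` (two fragments, left then right) and `truth`
#'   (updated with `join_truth`).
#' @export
fragment_at_array <- function(chromosome, truth, k_shared = 4L, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"), k_shared >= 1L)
  n_sp <- vapply(truth$arrays, function(a) length(a$spacers), integer(1L))
  ai <- which(n_sp >= k_shared + 2L)[1L]
  if (is.na(ai)) {
    stop("no array with >= k_shared + 2 spacers; cannot fragment",
         call. = FALSE)
  }
  arr <- truth$arrays[[ai]]
  nsp <- length(arr$spacers)
  valid_i <- 2:(nsp - k_shared)
  with_local_seed(seed, {
    i <- if (length(valid_i) == 1L) valid_i else sample(valid_i, 1L)
    rep_len <- arr$repeat_len
    endA <- arr$repeat_starts[i + k_shared] + rep_len  # 0-based half-open
    startB <- arr$repeat_starts[i]
    L <- chromosome$length
    left <- contig(paste0(chromosome$id, "_left"),
                   substr(chromosome$seq, 1L, endA),
                   topology = "linear", desc = "chromosome fragment (left)")
    right <- contig(paste0(chromosome$id, "_right"),
                    substr(chromosome$seq, startB + 1L, L),
                    topology = "linear", desc = "chromosome fragment (right)")
    truth$join_truth <- list(
      contig_a = left$id, end_a = "right",
      contig_b = right$id, end_b = "left",
      orientation_b = "forward",
      k = as.integer(k_shared),
      array_id = arr$id,
      first_shared_index = i,
      shared_spacers = arr$spacers[i:(i + k_shared - 1L)],
      overlap_length = endA - startB,
      left_boundary_spacers = arr$spacers[seq_len(i + k_shared - 1L)],
      right_boundary_spacers = arr$spacers[i:nsp]
    )
    list(contigs = list(left, right), truth = truth)
  })
}

#' Check the internal consistency of a planted truth set
#'
#' Verifies, against the emitted sequences, that (a) every planted
#' protospacer's spacer id exists in a planted array, (b) a direct recount of
#' mismatches between each planted spacer and its protospacer site equals the
#' recorded count, and (c) array repeat/spacer coordinates reproduce the
#' recorded sequences. Errors on the first violation.
#'
#' @param contigs Contig list from [generate_assembly()].
#' @param truth The matching `truth_set`.
#' @return `TRUE`, invisibly.
#' @export
validate_truth <- function(contigs, truth) {
  ids <- unlist(lapply(truth$arrays, `[[`, "spacer_ids"))
  seqs <- unlist(lapply(truth$arrays, `[[`, "spacers"))
  pt <- truth$protospacers
  if (nrow(pt)) {
    if (!all(pt$spacer_id %in% ids)) {
      stop("protospacer references unknown spacer id", call. = FALSE)
    }
    for (i in seq_len(nrow(pt))) {
      target <- get_contig(contigs, pt$contig_id[i])
      site <- substr(target$seq, pt$start[i] + 1L, pt$end[i])
      query <- if (pt$strand[i] == "+") pt$spacer_seq[i] else
        revcomp(pt$spacer_seq[i])
      if (hamming(site, query) != pt$mismatches[i]) {
        stop("mismatch recount disagrees with recorded count for ",
             pt$spacer_id[i], " on ", pt$contig_id[i], call. = FALSE)
      }
      if (seqs[match(pt$spacer_id[i], ids)] != pt$spacer_seq[i]) {
        stop("protospacer table spacer_seq disagrees with planted array",
             call. = FALSE)
      }
    }
  }
  for (a in truth$arrays) {
    chrom <- get_contig(contigs, a$contig_id)
    for (j in seq_along(a$repeat_starts)) {
      s <- a$repeat_starts[j]
      if (substr(chrom$seq, s + 1L, s + a$repeat_len) != a$repeat_consensus) {
        stop("planted repeat ", j, " of ", a$id,
             " does not match the emitted sequence", call. = FALSE)
      }
    }
    for (j in seq_along(a$spacers)) {
      s0 <- a$repeat_starts[j] + a$repeat_len
      e0 <- a$repeat_starts[j + 1L]
      if (substr(chrom$seq, s0 + 1L, e0) != a$spacers[j]) {
        stop("planted spacer ", j, " of ", a$id,
             " does not match the emitted sequence", call. = FALSE)
      }
    }
  }
  if (!is.null(truth$depth_multipliers) &&
      any(truth$depth_multipliers <= 0)) {
    stop("depth multipliers must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialise a truth set to JSON
#' @param truth A `truth_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$depth_multipliers <- as.list(x$depth_multipliers)  # keep contig names
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", null = "null")
  invisible(path)
}

#' Read a truth set written by [write_truth()]
#' @param path JSON path.
#' @return A list of class `"truth_set"`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list(
    seed = as.integer(x$seed),
    origin_position = as.integer(x$origin_position),
    arrays = lapply(x$arrays, function(a) {
      list(id = a$id, contig_id = a$contig_id,
           start = as.integer(a$start), end = as.integer(a$end),
           repeat_consensus = a$repeat_consensus,
           repeat_len = as.integer(a$repeat_len),
           repeat_starts = as.integer(unlist(a$repeat_starts)),
           spacers = as.character(unlist(a$spacers)),
           spacer_ids = as.character(unlist(a$spacer_ids)))
    }),
    protospacers = if (length(x$protospacers)) {
      do.call(rbind, lapply(x$protospacers, function(r) {
        data.frame(spacer_id = r$spacer_id, spacer_seq = r$spacer_seq,
                   contig_id = r$contig_id, start = as.integer(r$start),
                   end = as.integer(r$end), strand = r$strand,
                   mismatches = as.integer(r$mismatches),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(spacer_id = character(), spacer_seq = character(),
                 contig_id = character(), start = integer(), end = integer(),
                 strand = character(), mismatches = integer(),
                 stringsAsFactors = FALSE)
    },
    tir = if (is.null(x$tir)) NULL else
      list(contig_id = x$tir$contig_id, length = as.integer(x$tir$length),
           identity = as.numeric(x$tir$identity)),
    circular_overlap = if (is.null(x$circular_overlap)) NULL else
      list(contig_id = x$circular_overlap$contig_id,
           length = as.integer(x$circular_overlap$length)),
    depth_multipliers = unlist(x$depth_multipliers),
    decoy = if (is.null(x$decoy)) NULL else x$decoy,
    join_truth = if (is.null(x$join_truth)) NULL else {
      jt <- x$join_truth
      jt$k <- as.integer(jt$k)
      jt$overlap_length <- as.integer(jt$overlap_length)
      jt$shared_spacers <- as.character(unlist(jt$shared_spacers))
      jt$left_boundary_spacers <- as.character(unlist(jt$left_boundary_spacers))
      jt$right_boundary_spacers <-
        as.character(unlist(jt$right_boundary_spacers))
      jt
    })
  structure(out, class = "truth_set")
}
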