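# Independent oracles: deliberately different mechanics from the package
# implementations they check.

# brute-force spacer scan: slide every spacer over every target position on
# both strands, counting mismatches naively (N never matches, N vs N included)
oracle_find_hits <- function(spacers, targets, max_mismatches) {
  n_int <- utf8ToInt("N")
  rows <- list()
  for (tg in targets) {
    ti <- utf8ToInt(tg$seq)
    n <- length(ti)
    for (i in seq_len(nrow(spacers))) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") spacers$seq[i] else revcomp(spacers$seq[i])
        qi <- utf8ToInt(q)
        L <- length(qi)
        if (L > n) next
        nmis <- integer(n - L + 1L)
        for (j in seq_len(L)) {
          tj <- ti[j:(n - L + j)]
          nmis <- nmis + as.integer(tj != qi[j] | tj == n_int | qi[j] == n_int)
        }
        pos <- which(nmis <= max_mismatches)
        if (length(pos)) {
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = spacers$id[i], target = tg$id,
            start = pos - 1L, end = pos - 1L + L, strand = strand,
            mismatches = nmis[pos], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(spacer_id = character(), target = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$target, out$start, out$strand, out$spacer_id), ,
      drop = FALSE]
}

hit_key <- function(h) {
  if (!nrow(h)) return(character(0L))
  sort(paste(h$spacer_id, h$target, h$start, h$strand, h$mismatches,
             sep = "|"))
}

# quadratic scan: longest L with prefix(L) == suffix(L), L <= floor(n/2)
oracle_longest_border <- function(seq, min_overlap, max_mismatch = 0L) {
  n <- nchar(seq)
  if (n %/% 2L < min_overlap) return(0L)
  for (L in seq(n %/% 2L, min_overlap)) {
    if (hamming(substr(seq, 1L, L), substr(seq, n - L + 1L, n)) <=
        max_mismatch) {
      return(L)
    }
  }
  0L
}

# independent per-window recount of all four skews using strsplit counting
oracle_window_skews <- function(seq, window, step) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  starts <- seq.int(0L, n - 1L, by = step)
  widths <- pmin(window, n - starts)
  keep <- widths == window | widths >= window / 2
  starts <- starts[keep]
  widths <- widths[keep]
  out <- data.frame(gc = numeric(0), at = numeric(0), ry = numeric(0),
                    mk = numeric(0))
  for (i in seq_along(starts)) {
    w <- chars[(starts[i] + 1L):(starts[i] + widths[i])]
    a <- sum(w == "A"); c_ <- sum(w == "C")
    g <- sum(w == "G"); t <- sum(w == "T")
    sdiv <- function(x, y) if (y == 0) 0 else x / y
    out <- rbind(out, data.frame(
      gc = sdiv(g - c_, g + c_), at = sdiv(a - t, a + t),
      ry = sdiv((a + g) - (c_ + t), a + c_ + g + t),
      mk = sdiv((a + c_) - (g + t), a + c_ + g + t)))
  }
  out
}

# brute-force longest end-aligned run over two spacer lists: try every t
oracle_longest_run <- function(left, right) {
  best <- 0L
  for (t in seq_len(min(length(left), length(right)))) {
    if (identical(tail(left, t), head(right, t))) best <- t
  }
  best
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# planted-array contig: R + s1 + R + s2 + ... + R with padding around it
planted_array_contig <- function(repeat_seq, spacers, pad = 1500L,
                                 id = "test", seed = 42L) {
  set.seed(seed)
  body <- paste0(paste0(repeat_seq, spacers, collapse = ""), repeat_seq)
  contig(id, paste0(random_seq(pad), body, random_seq(pad)))
}

# synthetic skew profile for origin-selection index arithmetic
fake_profile <- function(cum_gc, window = 1000L) {
  k <- length(cum_gc)
  structure(list(
    contig_id = "fake", window = window, step = window,
    start = (seq_len(k) - 1L) * window, width = rep(window, k),
    gc = diff(c(0, cum_gc)), at = rep(0, k), ry = rep(0, k), mk = rep(0, k),
    cum_gc = cum_gc, cum_at = cumsum(rep(0, k)),
    cum_ry = cumsum(rep(0, k)), cum_mk = cumsum(rep(0, k))
  ), class = "skew_profile")
}
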