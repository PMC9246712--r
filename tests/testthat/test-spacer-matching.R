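test_that("planted forward and reverse-complement protospacers are found", {
  set.seed(41)
  sp <- random_seq(35)
  target_seq <- random_seq(2000)
  substr(target_seq, 101, 135) <- sp
  rc_mut <- revcomp(sp)
  substr(rc_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(rc_mut, 10, 10))[1]
  substr(target_seq, 501, 535) <- rc_mut
  tg <- contig("t1", target_seq)
  hits <- find_hits(data.frame(id = "s1", seq = sp), list(tg),
                    max_mismatches = 1, exclude_arrays = FALSE)
  expect_equal(nrow(hits), 2L)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, 100L)
  expect_equal(fwd$end, 135L)
  expect_equal(fwd$mismatches, 0L)
  rev <- hits[hits$strand == "-", ]
  expect_equal(rev$start, 500L)
  expect_equal(rev$mismatches, 1L)
  expect_true(all(hits$full_coverage))
  expect_true(all(hits$end - hits$start == nchar(sp)))
})

test_that("short spacers are rejected as uninformative queries", {
  tg <- contig("t", random_seq(100, seed = 1))
  expect_error(find_hits(data.frame(id = "s1", seq = "ACGTACGTAC"),
                         list(tg)), "15")
})

test_that("N never matches anything, including N", {
  tg <- contig("t", paste0(strrep("A", 50), "ACGTNACGTACGTACGTACG",
                           strrep("A", 50)))
  sp <- data.frame(id = "q", seq = "ACGTNACGTACGTACGTACG")
  h0 <- find_hits(sp, list(tg), max_mismatches = 0, exclude_arrays = FALSE)
  expect_equal(nrow(h0), 0L)
  h1 <- find_hits(sp, list(tg), max_mismatches = 1, exclude_arrays = FALSE)
  expect_equal(nrow(h1[h1$strand == "+", ]), 1L)
  expect_equal(h1$mismatches[h1$strand == "+"], 1L)  # N-vs-N counts as one
})

test_that("hit set equals the brute-force oracle on a synthetic assembly", {
  g <- generate_assembly(seed = 13)
  sp <- data.frame(
    id = unlist(lapply(g$truth$arrays, `[[`, "spacer_ids")),
    seq = unlist(lapply(g$truth$arrays, `[[`, "spacers")),
    stringsAsFactors = FALSE)
  for (mm in c(0L, 1L)) {
    got <- find_hits(sp, g$contigs, max_mismatches = mm,
                     exclude_arrays = FALSE)
    want <- oracle_find_hits(sp, g$contigs, mm)
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("hit sets are monotone in the mismatch budget and strand-symmetric", {
  g <- generate_assembly(seed = 14)
  sp <- data.frame(
    id = unlist(lapply(g$truth$arrays, `[[`, "spacer_ids")),
    seq = unlist(lapply(g$truth$arrays, `[[`, "spacers")),
    stringsAsFactors = FALSE)
  targets <- g$contigs[-1]
  h0 <- find_hits(sp, targets, max_mismatches = 0, exclude_arrays = FALSE)
  h1 <- find_hits(sp, targets, max_mismatches = 1, exclude_arrays = FALSE)
  expect_true(all(hit_key(h0) %in% hit_key(h1)))

  # reverse-complementing a target mirrors coordinates and flips strand
  tg <- targets[[which(vapply(targets, `[[`, character(1), "id") ==
                         "virus_tir")]]
  h_f <- find_hits(sp, list(tg), max_mismatches = 1, exclude_arrays = FALSE)
  h_r <- find_hits(sp, list(revcomp_contig(tg, keep_id = TRUE)),
                   max_mismatches = 1, exclude_arrays = FALSE)
  expect_equal(nrow(h_f), nrow(h_r))
  mirrored <- data.frame(
    spacer_id = h_r$spacer_id,
    start = tg$length - h_r$end,
    strand = ifelse(h_r$strand == "+", "-", "+"),
    mismatches = h_r$mismatches, stringsAsFactors = FALSE)
  key <- function(d) sort(paste(d$spacer_id, d$start, d$strand, d$mismatches))
  expect_identical(key(h_f), key(mirrored))
})

test_that("self-hits inside arrays are excluded; the in-array decoy is filtered", {
  cfg <- spacerlink_config(sim_decoy_in_array = TRUE)
  g <- generate_assembly(cfg, seed = 15)
  arrays <- detect_arrays(g$contigs[[1]])
  sp <- collect_spacers(arrays)
  decoy_seq <- g$truth$decoy$seq
  decoy_ids <- sp$id[sp$seq == decoy_seq]
  expect_gte(length(decoy_ids), 1L)

  h_excl <- find_hits(sp, g$contigs[1], max_mismatches = 0,
                      exclude_arrays = TRUE, target_arrays = arrays)
  expect_equal(nrow(h_excl), 0L)

  h_raw <- find_hits(sp, g$contigs[1], max_mismatches = 0,
                     exclude_arrays = FALSE)
  # without the filter every spacer hits its own array; the duplicated decoy
  # hits both arrays
  expect_true(all(sp$id %in% h_raw$spacer_id))
  expect_gte(sum(h_raw$spacer_id %in% decoy_ids), 3L)
})

test_that("linkage summary counts distinct spacers per convention", {
  hits <- data.frame(
    spacer_id = c("a", "b", "c", "d", "e", "f"),
    target = "V",
    start = c(0L, 100L, 200L, 300L, 400L, 500L), end = 35L,
    strand = "+",
    mismatches = c(0L, 0L, 0L, 1L, 1L, 1L),
    full_coverage = TRUE, stringsAsFactors = FALSE)
  tab <- summarize_linkage(hits)
  expect_equal(tab$target, "V")
  expect_equal(tab$n_exact_spacers, 3L)
  expect_equal(tab$n_one_mm_spacers, 3L)

  # one spacer hitting twice at 0 mm: one distinct spacer, two positions
  twice <- data.frame(spacer_id = "a", target = "V",
                      start = c(0L, 50L), end = c(35L, 85L), strand = "+",
                      mismatches = 0L, full_coverage = TRUE,
                      stringsAsFactors = FALSE)
  tab2 <- summarize_linkage(twice)
  expect_equal(tab2$n_exact_spacers, 1L)
  expect_equal(tab2$n_one_mm_spacers, 0L)
  expect_equal(tab2$n_hit_positions, 2L)

  # a spacer with both a 0 mm and a 1 mm hit counts once, as exact
  both <- rbind(hits, data.frame(spacer_id = "a", target = "V", start = 600L,
                                 end = 635L, strand = "+", mismatches = 1L,
                                 full_coverage = TRUE))
  tab3 <- summarize_linkage(both)
  expect_equal(tab3$n_exact_spacers, 3L)
  expect_equal(tab3$n_one_mm_spacers, 3L)

  empty <- summarize_linkage(hits[0, ])
  expect_equal(nrow(empty), 0L)
})
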