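frag_setup <- function(gen_seed, frag_seed = 2, k = 4L) {
  g <- generate_assembly(seed = gen_seed)
  fr <- fragment_at_array(g$contigs[[1]], g$truth, k_shared = k,
                          seed = frag_seed)
  arrays <- unlist(lapply(fr$contigs, detect_arrays), recursive = FALSE)
  list(g = g, fr = fr, arrays = arrays)
}

test_that("fragmented chromosomes yield exactly one k=4 join in the correct orientation", {
  s <- frag_setup(22)
  props <- propose_joins(s$fr$contigs, s$arrays, min_k = 4L)
  expect_length(props, 1L)
  p <- props[[1]]
  expect_equal(p$k, 4L)
  expect_false(p$circularization)
  expect_equal(p$upstream$contig, "chromosome_left")
  expect_equal(p$downstream$contig, "chromosome_right")
  expect_false(p$upstream$rc)
  expect_false(p$downstream$rc)
  expect_equal(p$shared_run$seq, s$fr$truth$join_truth$shared_spacers)
  expect_equal(p$overlap_length, s$fr$truth$join_truth$overlap_length)
})

test_that("proposal k agrees with the brute-force offset-scan oracle", {
  s <- frag_setup(23, k = 5L)
  props <- propose_joins(s$fr$contigs, s$arrays, min_k = 2L)
  jt <- s$fr$truth$join_truth
  k_oracle <- oracle_longest_run(jt$left_boundary_spacers,
                                 jt$right_boundary_spacers)
  expect_equal(props[[1]]$k, k_oracle)
  expect_equal(k_oracle, 5L)
})

test_that("contigs with disjoint boundary spacer sets yield no proposals", {
  s1 <- frag_setup(24)
  s2 <- frag_setup(25)
  # left fragment of one assembly vs right fragment of an unrelated one:
  # all spacers differ, so no shared run can exist
  contigs <- list(s1$fr$contigs[[1]], s2$fr$contigs[[2]])
  arrays <- c(Filter(function(a) a$contig_id == "chromosome_left", s1$arrays),
              Filter(function(a) a$contig_id == "chromosome_right", s2$arrays))
  # rename to keep ids unique
  contigs[[2]]$id <- "other_right"
  arrays <- lapply(arrays, function(a) {
    if (a$contig_id == "chromosome_right") {
      a$contig_id <- "other_right"
      a$spacers$array_id <- a$id <- sub("chromosome_right", "other_right", a$id)
    }
    a
  })
  expect_length(propose_joins(contigs, arrays, min_k = 4L), 0L)
})

test_that("merging reconstructs the chromosome byte-for-byte, also with a reversed fragment", {
  s <- frag_setup(26)
  chrom_seq <- s$g$contigs[[1]]$seq
  props <- propose_joins(s$fr$contigs, s$arrays, min_k = 4L)
  merged <- merge_contigs(props[[1]], s$fr$contigs)
  expect_identical(merged$seq, chrom_seq)
  expect_match(merged$desc, "in_silico")

  # reverse-complement the right fragment: the join must be found in the
  # reverse-complement orientation and still reconstruct the chromosome
  flipped <- list(s$fr$contigs[[1]],
                  revcomp_contig(s$fr$contigs[[2]], keep_id = TRUE))
  arrays2 <- unlist(lapply(flipped, detect_arrays), recursive = FALSE)
  props2 <- propose_joins(flipped, arrays2, min_k = 4L)
  expect_length(props2, 1L)
  expect_equal(props2[[1]]$orientation_b, "reverse-complement")
  merged2 <- merge_contigs(props2[[1]], flipped)
  expect_identical(merged2$seq, chrom_seq)
})

test_that("proposals are invariant under exchanging the two contigs", {
  s <- frag_setup(27)
  p_ab <- propose_joins(s$fr$contigs, s$arrays, min_k = 4L)
  p_ba <- propose_joins(rev(s$fr$contigs), s$arrays, min_k = 4L)
  expect_length(p_ab, 1L)
  expect_length(p_ba, 1L)
  expect_equal(p_ab[[1]]$k, p_ba[[1]]$k)
  expect_equal(p_ab[[1]]$overlap_length, p_ba[[1]]$overlap_length)
  expect_setequal(c(p_ab[[1]]$upstream$contig, p_ab[[1]]$downstream$contig),
                  c(p_ba[[1]]$upstream$contig, p_ba[[1]]$downstream$contig))
})

test_that("a corrupted overlap is rejected under zero repeat tolerance", {
  s <- frag_setup(28)
  props <- propose_joins(s$fr$contigs, s$arrays, min_k = 4L)
  p <- props[[1]]
  right <- s$fr$contigs[[2]]
  # mutate 2 nt inside the first repeat of the right fragment's overlap copy
  seqc <- right$seq
  for (pos in c(5L, 9L)) {
    old <- substr(seqc, pos, pos)
    substr(seqc, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  corrupted <- list(s$fr$contigs[[1]],
                    contig(right$id, seqc, topology = "linear"))
  expect_error(merge_contigs(p, corrupted, repeat_tol = 0),
               "disagree|rejected")
  # spacer mismatches are rejected regardless of repeat tolerance
  seqd <- right$seq
  sp1 <- p$down_spacer_spans[1, ]
  mid <- floor((sp1$start + sp1$end) / 2)
  old <- substr(seqd, mid + 1, mid + 1)
  substr(seqd, mid + 1, mid + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  corrupted2 <- list(s$fr$contigs[[1]],
                     contig(right$id, seqd, topology = "linear"))
  expect_error(merge_contigs(p, corrupted2, repeat_tol = 0.5),
               "spacer")
})

test_that("two ends of one contig are flagged as circularization evidence", {
  # build a contig whose two ends carry arrays sharing 4 consecutive spacers,
  # i.e. a circular molecule opened inside its array
  g <- generate_assembly(seed = 29)
  fr <- fragment_at_array(g$contigs[[1]], g$truth, k_shared = 4L, seed = 3)
  jt <- fr$truth$join_truth
  # right fragment followed by left fragment: the original circle opened at a
  # different position, with the shared array split across the two ends
  opened <- contig("opened", paste0(fr$contigs[[2]]$seq,
                                    fr$contigs[[1]]$seq))
  arrays <- detect_arrays(opened)
  props <- propose_joins(list(opened), arrays, min_k = 4L)
  expect_length(props, 1L)
  expect_true(props[[1]]$circularization)
  expect_gte(props[[1]]$k, 4L)
})
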