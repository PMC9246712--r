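test_that("a duplicated terminus is detected as a direct terminal repeat", {
  set.seed(51)
  core <- random_seq(5000)
  ctg <- contig("circ", paste0(core, substr(core, 1, 30)))
  tr <- detect_circularity(ctg)
  expect_false(is.null(tr))
  expect_equal(tr$kind, "direct")
  expect_equal(tr$length, 30L)
  expect_equal(tr$identity, 1)
  expect_equal(c(tr$left_start, tr$left_end), c(0L, 30L))
  expect_equal(c(tr$right_start, tr$right_end), c(5000L, 5030L))
  expect_null(detect_circularity(contig("rand", random_seq(5000))))
})

test_that("detected overlap length matches the quadratic border oracle", {
  set.seed(52)
  for (ov in c(20L, 57L, 300L)) {
    core <- random_seq(4000)
    seqc <- paste0(core, substr(core, 1, ov))
    got <- detect_circularity(contig("c", seqc))
    expect_equal(got$length, oracle_longest_border(seqc, 20L))
    expect_equal(got$length, ov)
  }
  # negative control against the same oracle
  r <- random_seq(3000)
  expect_equal(oracle_longest_border(r, 20L), 0L)
  expect_null(detect_circularity(contig("r", r)))
})

test_that("planted TIRs are recovered at exact length and identity", {
  set.seed(53)
  make_tir_contig <- function(tl, n_mut = 0) {
    core <- strsplit(random_seq(5000), "")[[1]]
    tir <- random_seq(tl)
    nc <- length(core)
    # sharp planted boundary, as in the generator
    for (j in 1:4) {
      partner <- chartr("ACGT", "TGCA", core[nc - j + 1])
      if (core[j] == partner) {
        core[j] <- setdiff(c("A", "C", "G", "T"), partner)[1]
      }
    }
    left <- strsplit(tir, "")[[1]]
    if (n_mut > 0) {
      left[40] <- setdiff(c("A", "C", "G", "T"), left[40])[1]
    }
    contig("tirv", paste(c(left, core, strsplit(revcomp(tir), "")[[1]]),
                         collapse = ""))
  }
  tr <- detect_tir(make_tir_contig(80L))
  expect_equal(tr$kind, "inverted")
  expect_equal(tr$length, 80L)
  expect_equal(tr$identity, 1)

  tr1 <- detect_tir(make_tir_contig(80L, n_mut = 1))
  expect_equal(tr1$length, 80L)
  expect_equal(tr1$identity, 79 / 80)
})

test_that("random sequences yield no TIR across seeds", {
  for (s in 1:25) {
    expect_null(detect_tir(contig("r", random_seq(3000, seed = 100 + s))))
  }
})

test_that("terminal repeat detection is reverse-complement invariant", {
  g <- generate_assembly(seed = 16)
  circ <- get_contig(g$contigs, "virus_circ")
  tirv <- get_contig(g$contigs, "virus_tir")
  d1 <- detect_circularity(circ)
  d2 <- detect_circularity(revcomp_contig(circ, keep_id = TRUE))
  expect_equal(d1$kind, d2$kind)
  expect_equal(d1$length, d2$length)
  t1 <- detect_tir(tirv)
  t2 <- detect_tir(revcomp_contig(tirv, keep_id = TRUE))
  expect_equal(t1$kind, t2$kind)
  expect_equal(t1$length, t2$length)
})

test_that("coverage ratio is depth division with strict error contract", {
  depths <- c(v1 = 70, chr = 20, eq = 20)
  expect_equal(coverage_ratio("v1", "chr", depths), 3.5)
  expect_equal(coverage_ratio("eq", "chr", depths), 1)
  expect_error(coverage_ratio("ghost", "chr", depths), "ghost")
  expect_error(coverage_ratio("v1", "chr", c(v1 = 70, chr = 0)), "> 0")
})

test_that("classification applies rules in order with recorded evidence", {
  g <- generate_assembly(seed = 17)
  run <- run_pipeline(g$contigs, g$depths)
  cls <- run$classifications
  lab <- function(id) cls$label[cls$contig_id == id]
  expect_equal(lab("chromosome"), "chromosome")
  expect_equal(lab("virus_circ"), "circular_mobile")
  expect_equal(lab("virus_tir"), "linear_tir_mobile")
  expect_equal(lab("mobile_1"), "mobile_other")
  expect_equal(lab("mobile_2"), "mobile_other")
  expect_true(all(nzchar(cls$evidence[cls$label != "unclassified"])))
  # labels partition the assembly
  expect_equal(sort(cls$contig_id),
               sort(vapply(g$contigs, `[[`, character(1), "id")))
})

test_that("a contig that is one long array is a crispr_fragment; no signal is unclassified", {
  set.seed(54)
  R <- random_seq(30)
  spacers <- replicate(8, random_seq(38))
  arr_seq <- paste0(paste0(R, spacers, collapse = ""), R)
  frag <- contig("fragment", paste0(random_seq(100), arr_seq,
                                    random_seq(100)))
  chrom <- contig("big", random_seq(20000))
  blank <- contig("blank", random_seq(4000))
  contigs <- list(chrom, frag, blank)
  arrays <- unlist(lapply(contigs, detect_arrays), recursive = FALSE)
  cls <- classify(contigs, arrays)
  expect_equal(cls$label[cls$contig_id == "fragment"], "crispr_fragment")
  expect_equal(cls$label[cls$contig_id == "blank"], "unclassified")
  expect_equal(cls$evidence[cls$contig_id == "blank"], "")
})

test_that("rule order: circularity precedes spacer-hit evidence", {
  set.seed(55)
  core <- random_seq(4000)
  sp <- random_seq(36)
  substr(core, 1001, 1036) <- sp
  circ_hit <- contig("both", paste0(core, substr(core, 1, 25)))
  chrom <- contig("big", random_seq(20000))
  contigs <- list(chrom, circ_hit)
  hits <- find_hits(data.frame(id = "s1", seq = sp), contigs,
                    exclude_arrays = FALSE)
  expect_true(any(hits$target == "both"))
  reps <- list(detect_circularity(circ_hit))
  cls <- classify(contigs, list(), hits, reps)
  expect_equal(cls$label[cls$contig_id == "both"], "circular_mobile")
})

test_that("annotation evidence feeds rule 5 and overrides relabel contaminants", {
  chrom <- contig("big", random_seq(20000, seed = 56))
  plain <- contig("p", random_seq(3000))
  rrna <- contig("r", random_seq(3000))
  ann <- data.frame(contig_id = c("p", "r"),
                    evidence = c("integrase", "rRNA contaminant"),
                    label_override = c("", "unclassified"),
                    stringsAsFactors = FALSE)
  cls <- classify(list(chrom, plain, rrna), annotations = ann)
  expect_equal(cls$label[cls$contig_id == "p"], "mobile_other")
  expect_match(cls$evidence[cls$contig_id == "p"], "integrase")
  expect_equal(cls$label[cls$contig_id == "r"], "unclassified")
})
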