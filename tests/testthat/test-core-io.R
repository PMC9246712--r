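test_that("read_fasta normalises case, preserves order and keeps descriptions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 a plasmid", "acgt", ">c2", "GGTTAACC"), f)
  ctg <- read_fasta(f)
  expect_length(ctg, 2L)
  expect_equal(ctg[[1]]$id, "c1")
  expect_equal(ctg[[1]]$seq, "ACGT")
  expect_equal(ctg[[1]]$length, 4L)
  expect_equal(ctg[[1]]$desc, "a plasmid")
  expect_equal(vapply(ctg, `[[`, character(1), "id"), c("c1", "c2"))
})

test_that("read_fasta rejects duplicate ids naming the record", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), f)
  expect_error(read_fasta(f), "c1")
})

test_that("FASTA write/read round-trips sequences exactly", {
  ctgs <- list(contig("alpha", random_seq(257, seed = 7), desc = "x y"),
               contig("beta", "ACGTN"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ctgs, f)
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, character(1), "seq"),
               vapply(ctgs, `[[`, character(1), "seq"))
  expect_equal(back[[1]]$desc, "x y")
})

test_that("contig constructor enforces the alphabet and empty-sequence rules", {
  expect_error(contig("c", ""), "empty")
  expect_error(contig("c", "ACGU"), "illegal")
  expect_error(contig("c", "ACGT", mean_depth = -1), ">= 0")
})

test_that("depth table reads valid input and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tmean_depth", "chr\t20.0", "v1\t70.0"), f)
  d <- read_depth_table(f)
  expect_equal(d, c(chr = 20, v1 = 70))

  writeLines(c("contig_id\tmean_depth", "chr\t-1"), f)
  expect_error(read_depth_table(f), "negative")

  writeLines(c("chr\t20"), f)
  expect_error(read_depth_table(f), "header")

  writeLines(c("contig_id\tmean_depth", "chr\t20", "ghost\t4"), f)
  expect_warning(read_depth_table(f, list(contig("chr", "ACGT"))), "ghost")
})

test_that("GFF3 output uses 1-based inclusive coordinates and round-trips", {
  ctg <- contig("c1", random_seq(60000, seed = 3))
  arr <- detect_arrays(planted_array_contig(
    random_seq(30, seed = 11),
    replicate(4, random_seq(37)), id = "c1"))[[1]]
  f <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(arrays = list(arr), path = f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  region <- strsplit(body[grepl("repeat_region", body)], "\t")[[1]]
  # 0-based half-open [start, end) serialises as 1-based inclusive
  expect_equal(as.integer(region[4]), arr$start + 1L)
  expect_equal(as.integer(region[5]), arr$end)
  back <- read_features_gff3(f)
  reg <- back[back$type == "repeat_region", ]
  expect_equal(reg$start, arr$start)
  expect_equal(reg$end, arr$end)
  # spacer features round-trip coordinate-exactly too
  sp <- back[back$type == "spacer", ]
  expect_equal(sp$start, arr$spacers$start)
  expect_equal(sp$end, arr$spacers$end)
})

test_that("GFF3 writer handles empty feature sets and strand, rejects overruns", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(path = f)
  expect_equal(readLines(f), "##gff-version 3")

  hits <- data.frame(spacer_id = "s1", target = "c1", start = 10L, end = 45L,
                     strand = "-", mismatches = 0L, stringsAsFactors = FALSE)
  write_features_gff3(hits = hits, path = f)
  body <- grep("^#", readLines(f), value = TRUE, invert = TRUE)
  expect_equal(strsplit(body, "\t")[[1]][7], "-")

  expect_error(
    write_features_gff3(hits = hits, path = f,
                        contigs = list(contig("c1", "ACGT"))),
    "past contig end")
})

test_that("config round-trips losslessly through YAML and rejects unknown keys", {
  cfg <- spacerlink_config(seed = 99L, sim_tir_length = 120L,
                           coverage_ratio_threshold = 2.5)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back, cfg)
  expect_error(spacerlink_config(not_a_knob = 1), "unknown config")
})

test_that("BAM depth adapter agrees with hand-computed aligned-base counts", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  # two reads of 10 bases on c1 (len 100), one of 20 on c2 (len 50)
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:100",
    "@SQ\tSN:c2\tLN:50",
    paste("r1", 0, "c1", 1, 60, "10M", "*", 0, 0,
          strrep("A", 10), strrep("I", 10), sep = "\t"),
    paste("r2", 0, "c1", 51, 60, "10M", "*", 0, 0,
          strrep("A", 10), strrep("I", 10), sep = "\t"),
    paste("r3", 0, "c2", 11, 60, "20M", "*", 0, 0,
          strrep("A", 20), strrep("I", 20), sep = "\t")), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)
  d <- depth_from_bam(bam)
  expect_equal(d[["c1"]], 20 / 100)
  expect_equal(d[["c2"]], 20 / 50)
})
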