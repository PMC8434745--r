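test_that("FASTA reading normalizes case and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), f)
  expect_equal(unname(read_fasta(f)), "ACGT")
  expect_equal(names(read_fasta(f)), "c1")

  writeLines(c(">c1", "acgrn"), f)
  expect_equal(unname(read_fasta(f)), "ACGNN")

  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">c1", "ACGT", ">c2", ""), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA round-trips byte-identically for normalized input", {
  seqs <- setNames(c(rand_dna(143, seed = 1), rand_dna(70, seed = 2)),
                   c("a", "b"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("N-run detection finds maximal runs above threshold", {
  expect_equal(nrow(find_n_runs("ACGT", 1)), 0)
  expect_equal(find_n_runs("ACGTNNNNNNNNNNAC", 10),
               data.frame(start = 4L, end = 14L))
  expect_equal(nrow(find_n_runs("ANNA", 10)), 0)
  # min_run = 1 recovers the exact N count, disjoint and sorted
  set.seed(3)
  for (rep in 1:10) {
    s <- rand_dna(500)
    at <- sample(500, 40)
    sv <- strsplit(s, "")[[1]]
    sv[at] <- "N"
    s <- paste(sv, collapse = "")
    runs <- find_n_runs(s, 1)
    expect_equal(sum(runs$end - runs$start),
                 lengths(regmatches(s, gregexpr("N", s))))
    expect_true(all(diff(runs$start) > 0))
    if (nrow(runs) > 1)
      expect_true(all(runs$start[-1] > runs$end[-nrow(runs)]))
  }
})

test_that("PAF parsing keeps strand and validates geometry", {
  f <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste("q1", 1000, 0, 500, "-", "t1", 2000, 100, 600, 480, 500,
                   60, sep = "\t"), f)
  b <- read_paf_blocks(f)
  expect_equal(b$strand, "-")
  expect_equal(b$target_start, 100)

  writeLines(character(0), f)
  expect_equal(nrow(read_paf_blocks(f)), 0)

  writeLines(paste("q1", 1000, 500, 0, "+", "t1", 2000, 100, 600, 480, 500,
                   60, sep = "\t"), f)
  expect_error(read_paf_blocks(f), "end < start")

  writeLines("q1\t1000\t0", f)
  expect_error(read_paf_blocks(f), "12 columns")
})

test_that("MAF parsing validates block geometry and counts non-gaps", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("a score=1",
               "s cattle.chr1 10 5 + 100 AC-GTT",
               "s goat.chr2 3 6 - 50 ACAGTT"), f)
  blocks <- read_maf(f)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$species, c("cattle", "goat"))
  expect_equal(blocks[[1]]$size, c(5, 6))

  writeLines(c("a", "s cattle.chr1 10 5 + 100 ACGTT",
               "s goat.chr2 3 6 - 50 ACAGTT"), f)
  expect_error(read_maf(f), "width")

  writeLines(c("a", "s cattle.chr1 10 4 + 100 AC-GTT"), f)
  expect_error(read_maf(f), "size")

  # round trip
  writeLines(c("a", "s cattle.chr1 10 5 + 100 AC-GTT",
               "s goat.chr2 3 6 - 50 ACAGTT"), f)
  b1 <- read_maf(f)
  f2 <- withr::local_tempfile(fileext = ".maf")
  write_maf(b1, f2)
  expect_equal(read_maf(f2), b1)
})

test_that("probe hit tables map outfmt-6 columns and derive coverage", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("p1", "chr1", 96.0, 48, 2, 0, 1, 48, 1001, 1048,
                   1e-20, 90, 50, sep = "\t"), f)
  h <- read_probe_hits(f)
  expect_equal(h$identity, 96)
  expect_equal(h$coverage, 100 * 48 / 50)
  expect_equal(h$subject_start, 1000)  # 0-based
  expect_equal(h$subject_end, 1048)

  # no qlen column: probe_lengths required; reversed subject coords ok
  writeLines(paste("p1", "chr1", 96.0, 48, 2, 0, 1, 48, 1048, 1001,
                   1e-20, 90, sep = "\t"), f)
  expect_error(read_probe_hits(f), "probe_lengths")
  h2 <- read_probe_hits(f, probe_lengths = c(p1 = 50))
  expect_equal(h2$subject_start, 1000)
  expect_equal(h2$coverage, 96)
})

test_that("repeat annotations parse from BED+label and RepeatMasker .out", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t9000\tSatellite/centr",
               "chr1\t20000\t20500\tLINE/L1"), f)
  r <- read_repeat_annotations(f)
  expect_equal(r$label[1], "Satellite/centr")
  expect_equal(r$end[1] - r$start[1], 8900)

  f2 <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin  end  (left)   repeat  class/family  begin end (left) ID",
    "",
    "  463  1.3  0.6  1.7  chr1      101    9000  (0)  +  SATREP  Satellite/centr  1 100 (0) 1"), f2)
  r2 <- read_repeat_annotations(f2)
  expect_equal(r2$label, "Satellite/centr")
  expect_equal(r2$start, 100)  # converted to 0-based
  expect_equal(r2$end, 9000)
})

test_that("variant reading extracts genotype classes from a minimal VCF", {
  rows <- data.frame(
    chrom = "chr1", pos1 = c(10, 20, 30, 40),
    ref = c("A", "C", "G", "AT"), alt = c("T", "G", "A", "A"),
    qual = c(50, 50, 5, 50), gt = c("1/1", "0/1", "1/1", "1/1"),
    dp = c(30, 25, 31, 28))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(rows, f)
  v <- read_variants(f)
  expect_equal(v$genotype, c("hom_alt", "het", "hom_alt", "hom_alt"))
  expect_equal(v$pos, c(9, 19, 29, 39))
  expect_equal(v$is_snv, c(TRUE, TRUE, TRUE, FALSE))
})
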