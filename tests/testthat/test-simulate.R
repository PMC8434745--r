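test_that("generators are deterministic given config and seed", {
  cfg <- sim_config(seed = 8, n_autosomes = 2)
  c1 <- simulate_chromosome(cfg, 1)
  c2 <- simulate_chromosome(cfg, 1)
  expect_identical(c1, c2)
  # chromosome substreams: adding chromosomes does not change earlier ones
  cfg3 <- sim_config(seed = 8, n_autosomes = 3)
  expect_identical(simulate_chromosome(cfg3, 1)$seq, c1$seq)

  p1 <- simulate_assembly_pair(n_chrom = 2, chrom_length = 1e6, seed = 9)
  p2 <- simulate_assembly_pair(n_chrom = 2, chrom_length = 1e6, seed = 9)
  expect_identical(p1, p2)

  r1 <- simulate_reads(c(g = rand_dna(5000, seed = 1)), 5, 100, seed = 2)
  r2 <- simulate_reads(c(g = rand_dna(5000, seed = 1)), 5, 100, seed = 2)
  expect_identical(r1, r2)

  m1 <- simulate_maf(n_autosome = 500, n_y = 100, seed = 3)
  m2 <- simulate_maf(n_autosome = 500, n_y = 100, seed = 3)
  expect_identical(m1, m2)
})

test_that("emitted truth tables agree with the emitted sequences", {
  cfg <- sim_config(seed = 12, n_autosomes = 3, complete_chromosomes = 2)
  sim <- simulate_assembly(cfg)
  for (i in 1:3) {
    ch <- paste0("chr", i)
    s <- sim$assembly[[ch]]
    # gap truth equals N-run detection
    runs <- find_n_runs(s, min_run = 10, chrom = ch)
    truth <- sim$gaps[sim$gaps$chrom == ch, , drop = FALSE]
    expect_equal(runs$start, truth$start)
    expect_equal(runs$end, truth$end)
    # satellite truth interval is pure satellite (no telomere motif)
    cen <- sim$repeats[sim$repeats$chrom == ch, ]
    satseq <- substr(s, cen$start + 1, cen$end)
    expect_false(grepl("TTAGGG", satseq, fixed = TRUE))
    expect_false(grepl("CCCTAA", satseq, fixed = TRUE))
    # telomere truth interval is pure motif
    tel <- sim$telomeres[sim$telomeres$chrom == ch, ]
    if (nrow(tel)) {
      telseq <- substr(s, tel$start + 1, tel$end)
      expect_equal(gsub("TTAGGG", "", paste0(telseq, "TTAGGG")), "")
    }
  }
})

test_that("assembly-pair sequences match the emitted block structure", {
  pair <- simulate_assembly_pair(
    n_chrom = 2, chrom_length = 1e6,
    inversions = list(list(chrom = 1, start = 2e5, length = 1e5)),
    translocations = list(list(from = 2, start = 3e5, length = 1e5,
                               to = 1)),
    piece = 5e4, seed = 17)
  blk <- pair$blocks
  for (i in seq_len(nrow(blk))) {
    qseq <- substr(pair$a[[blk$query_chrom[i]]], blk$query_start[i] + 1,
                   blk$query_end[i])
    tseq <- substr(pair$b[[blk$target_chrom[i]]], blk$target_start[i] + 1,
                   blk$target_end[i])
    if (blk$strand[i] == "+") expect_identical(tseq, qseq)
    else expect_identical(tseq, revcomp(qseq))
  }
  # overlapping events are rejected
  expect_error(simulate_assembly_pair(
    n_chrom = 1, chrom_length = 1e6,
    inversions = list(list(chrom = 1, start = 1e5, length = 2e5),
                      list(chrom = 1, start = 2e5, length = 2e5))),
    "overlap")
  expect_error(simulate_assembly_pair(
    n_chrom = 1, chrom_length = 1e6,
    inversions = list(list(chrom = 1, start = 9e5, length = 2e5))),
    "fit")
})

test_that("read simulation honours coverage and error arguments", {
  g <- c(g = rand_dna(20000, seed = 19))
  reads <- simulate_reads(g, coverage = 10, read_length = 100, seed = 20)
  expect_equal(length(reads), 2000)
  expect_true(all(nchar(reads) == 100))
  expect_error(simulate_reads(g, 0), "positive")
  expect_error(simulate_reads(g, 5, read_length = 1e6), "exceeds")
  # error injection: on a homopolymer genome the per-read minority-base
  # fraction equals the error rate (reads are all-A or all-T by strand)
  mono <- c(m = strrep("A", 20000))
  r1 <- simulate_reads(mono, 1, 1000, error_rate = 0.05, seed = 21)
  err_frac <- vapply(r1, function(r) {
    tab <- table(strsplit(r, "")[[1]])
    1 - max(tab) / 1000
  }, numeric(1))
  expect_gt(mean(err_frac), 0.03)
  expect_lt(mean(err_frac), 0.07)
  r0 <- simulate_reads(mono, 1, 1000, error_rate = 0, seed = 21)
  expect_true(all(r0 %in% c(strrep("A", 1000), strrep("T", 1000))))
})

test_that("probe panels carry closed-loop truth labels", {
  pair <- simulate_assembly_pair(
    n_chrom = 3, chrom_length = 3e6,
    inversions = list(list(chrom = 1, start = 1e6, length = 6e5)),
    translocations = list(list(from = 2, start = 5e5, length = 5e5,
                               to = 3)),
    seed = 23)
  panel <- simulate_probe_panel(pair, spacing = 1e5,
                                desert_spans = list(
                                  list(chrom = 3, start = 5e5,
                                       end = 1.8e6)))
  cl <- classify_discrepancies(panel$maps_a, panel$maps_b)
  expect_equal(nrow(cl), nrow(panel$truth))
  # translocated probes are exactly the diff_chr calls
  expect_setequal(cl$probe_id[cl$category == "diff_chr"],
                  panel$truth$probe_id[panel$truth$group == "diff_chr"])
  # the planted desert is recovered
  lens <- setNames(nchar(pair$a), names(pair$a))
  des <- find_probe_deserts(panel$maps_a, lens)
  expect_true(any(des$chrom == "chr3" & des$length > 1e6))
})

test_that("probe spacing wider than the chromosome is rejected", {
  pair <- simulate_assembly_pair(n_chrom = 1, chrom_length = 1e5,
                                 seed = 29)
  expect_error(simulate_probe_panel(pair, spacing = 1e6), "spacing")
})

test_that("MAF simulation responds to branch lengths and multiplier", {
  # zero branch lengths give identical sequences
  z <- simulate_maf(branch_lengths = rep(0, 5), n_autosome = 200,
                    n_y = 50, seed = 27)
  expect_equal(length(unique(as.vector(z$aln_a[1, ]))) > 1, TRUE)
  expect_true(all(z$aln_a[1, ] == z$aln_a[2, ]))
  expect_true(all(z$aln_a[1, ] == z$aln_a[4, ]))
  # null multiplier: fitted ratio near 1
  sim <- simulate_maf(n_autosome = 30000, n_y = 30000,
                      y_rate_multiplier = 1, seed = 28)
  res <- substitution_rate_analysis(sim$maf_y, sim$maf_a, n_starts = 1)
  expect_equal(unname(res$ya_ratio["goat"]), 1, tolerance = 0.1)
  # MAF blocks are valid for the parser
  f <- withr::local_tempfile(fileext = ".maf")
  write_maf(sim$maf_a, f)
  expect_equal(read_maf(f)[[1]]$text, sim$maf_a[[1]]$text)
})
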