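mk_block <- function(qc, qs, qe, tc, ts, te, strand = "+") {
  data.frame(query_chrom = qc, query_len = 1e7, query_start = qs,
             query_end = qe, strand = strand, target_chrom = tc,
             target_len = 1e7, target_start = ts, target_end = te,
             num_matches = qe - qs, block_len = qe - qs, mapq = 60)
}

test_that("chaining groups collinear blocks and splits on breaks", {
  coll <- rbind(mk_block("q", 0, 5e4, "t", 0, 5e4),
                mk_block("q", 5e4, 1e5, "t", 5e4, 1e5),
                mk_block("q", 1e5, 2e5, "t", 1e5, 2e5))
  expect_equal(nrow(chain_blocks(coll)), 1)

  flip <- rbind(mk_block("q", 0, 1e5, "t", 0, 1e5, "+"),
                mk_block("q", 1e5, 2e5, "t", 1e5, 2e5, "-"))
  expect_equal(nrow(chain_blocks(flip)), 2)

  gap <- rbind(mk_block("q", 0, 1e5, "t", 0, 1e5),
               mk_block("q", 3e5, 4e5, "t", 3e5, 4e5))
  expect_equal(nrow(chain_blocks(gap, max_gap = 1e5)), 2)
  expect_equal(nrow(chain_blocks(gap, max_gap = 3e5)), 1)

  # sub-min_block pieces are dropped first
  small <- rbind(coll, mk_block("q", 2e5, 2.05e5, "t", 9e6, 9.05e6))
  expect_equal(nrow(chain_blocks(small, min_block = 1e4)), 1)
})

test_that("planted rearrangements are recovered from synthetic pairs", {
  pair <- simulate_assembly_pair(
    n_chrom = 3, chrom_length = 5e6,
    inversions = list(list(chrom = 1, start = 2e6, length = 2e6)),
    translocations = list(list(from = 3, start = 1e6, length = 1.5e6,
                               to = 2)),
    seed = 5)
  disc <- detect_large_discrepancies(chain_blocks(pair$blocks))
  expect_equal(sort(disc$kind), c("incorrectly_placed", "inverted"))
  inv <- disc[disc$kind == "inverted", ]
  expect_equal(inv$query_chrom, "chr1")
  expect_equal(inv$length, 2e6)
  expect_equal(inv$target_start, 2e6)
  tra <- disc[disc$kind == "incorrectly_placed", ]
  expect_equal(tra$query_chrom, "chr3")
  expect_equal(tra$target_chrom, "chr2")
  expect_equal(tra$length, 1.5e6)

  # identical assemblies: no calls
  p0 <- simulate_assembly_pair(n_chrom = 2, chrom_length = 2e6, seed = 3)
  expect_equal(nrow(detect_large_discrepancies(chain_blocks(p0$blocks))), 0)

  # swapping the two assemblies keeps the inversion inverted and remaps
  # the misplaced region consistently
  swapped <- pair$blocks
  names(swapped)[c(1:4, 6:9)] <- names(swapped)[c(6:9, 1:4)]
  swapped <- swapped[, names(pair$blocks)]
  disc_s <- detect_large_discrepancies(chain_blocks(swapped))
  expect_equal(sort(disc_s$kind), c("incorrectly_placed", "inverted"))
  inv_s <- disc_s[disc_s$kind == "inverted", ]
  expect_equal(inv_s$length, 2e6)
  tra_s <- disc_s[disc_s$kind == "incorrectly_placed", ]
  expect_equal(tra_s$query_chrom, "chr2")
  expect_equal(tra_s$target_chrom, "chr3")
})

test_that("recall is complete for large events over repeated seeds", {
  for (seed in 1:10) {
    pair <- simulate_assembly_pair(
      n_chrom = 2, chrom_length = 4e6,
      inversions = list(list(chrom = 1, start = 1e6, length = 1.2e6)),
      seed = seed)
    disc <- detect_large_discrepancies(chain_blocks(pair$blocks))
    expect_equal(nrow(disc), 1)
    expect_equal(disc$kind, "inverted")
    p0 <- simulate_assembly_pair(n_chrom = 2, chrom_length = 1e6,
                                 seed = seed + 100)
    expect_equal(nrow(detect_large_discrepancies(chain_blocks(p0$blocks))),
                 0)
  }
})

test_that("region span is end minus start", {
  expect_equal(region_span(98973162, 101785323), 2812161)
  expect_equal(region_span(16211458, 22469539), 6258081)
  expect_equal(region_span(5, 5), 0)
  expect_error(region_span(10, 5), "end < start")
})

test_that("discrepancy summaries add up and round half-even", {
  regs <- data.frame(kind = c("inverted", "inverted", "incorrectly_placed"),
                     length = c(1.5e6, 2.5e6, 1.04e6))
  s <- summarize_discrepancies(regs)
  expect_equal(s$count, 3)
  expect_equal(s$total_bp, sum(regs$length))
  expect_equal(unname(s$by_kind["inverted"]), 2)
  expect_equal(s$total_mb, round(sum(regs$length) / 1e6, 1))
  e <- summarize_discrepancies(regs[0, ])
  expect_equal(e$count, 0)
  expect_equal(e$total_bp, 0)
})

test_that("small SV calls classify gap geometry and apply size filters", {
  ins <- rbind(mk_block("q", 0, 5e4, "t", 0, 5e4),
               mk_block("q", 5.05e4, 1e5, "t", 5e4, 9.95e4))
  sv <- call_small_svs(ins)
  expect_equal(sv$type, "insertion")
  expect_equal(sv$size, 500)
  expect_equal(sv$query_gap, 500)
  expect_equal(sv$ref_gap, 0)

  del <- rbind(mk_block("q", 0, 5e4, "t", 0, 5e4),
               mk_block("q", 5e4, 1e5, "t", 5.05e4, 1.005e5))
  expect_equal(call_small_svs(del)$type, "deletion")

  # 30 bp and 15 kb differences are filtered out
  small <- rbind(mk_block("q", 0, 5e4, "t", 0, 5e4),
                 mk_block("q", 50030, 1e5, "t", 5e4, 99970))
  expect_equal(nrow(call_small_svs(small)), 0)
  big <- rbind(mk_block("q", 0, 5e4, "t", 0, 5e4),
               mk_block("q", 65000, 1.2e5, "t", 5e4, 105000))
  expect_equal(nrow(call_small_svs(big)), 0)

  # both gaps positive -> repeat class; anchor overlap -> tandem class
  repx <- rbind(mk_block("q", 0, 5e4, "t", 0, 5e4),
                mk_block("q", 51000, 1e5, "t", 50200, 99200))
  expect_equal(call_small_svs(repx)$type, "repeat_expansion")
  tand <- rbind(mk_block("q", 0, 5e4, "t", 0, 5e4),
                mk_block("q", 50400, 1e5, "t", 49900, 99500))
  expect_equal(call_small_svs(tand)$type, "tandem_expansion")
})
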