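mk_block4 <- function(texts, species = SP4, strand = "+") {
  n <- nchar(gsub("-", "", texts))
  data.frame(species = species, src = paste0(species, ".chr1"),
             start = 0, size = n, strand = strand,
             src_length = n + 10, text = texts)
}

test_that("block filtering keeps only complete four-species blocks", {
  full <- mk_block4(c("ACGT", "ACGT", "ACGT", "ACGT"))
  missing <- full[-2, ]
  expect_length(filter_blocks(list(full, missing)), 1)
  expect_length(filter_blocks(list()), 0)
})

test_that("duplicate removal keeps the consensus-nearest row", {
  b <- rbind(mk_block4(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC",
                         "ACGTACGTAC")),
             data.frame(species = "goat", src = "goat.chr9", start = 0,
                        size = 10, strand = "+", src_length = 20,
                        text = "TTTTACGTAC"))
  out <- dedupe_blocks(list(b))[[1]]
  expect_equal(sum(out$species == "goat"), 1)
  expect_equal(out$src[out$species == "goat"], "goat.chr1")
  # no duplicates: unchanged
  clean <- mk_block4(c("ACGT", "ACGT", "ACGT", "ACGT"))
  expect_equal(dedupe_blocks(list(clean))[[1]], clean)
  # exact tie keeps the first in file order
  tie <- rbind(clean,
               data.frame(species = "goat", src = "goat.chrZ", start = 0,
                          size = 4, strand = "+", src_length = 14,
                          text = "ACGT"))
  out2 <- dedupe_blocks(list(tie))[[1]]
  expect_equal(out2$src[out2$species == "goat"], "goat.chr1")
})

test_that("strand flip is a per-column reverse complement and an involution", {
  b <- mk_block4(c("AC-GT", "ACAGT", "AC-GT", "ACAGT"))
  b$strand <- c("-", "+", "-", "+")
  b$start <- c(3, 0, 2, 1)
  flipped <- flip_to_reference_strand(b, "cattle")
  expect_equal(flipped$text[1], "AC-GT")  # revcomp of AC-GT
  expect_equal(flipped$text[2], "ACTGT")  # revcomp of ACAGT
  expect_equal(flipped$strand, c("+", "-", "+", "-"))
  # coordinates: start' = src_length - start - size
  expect_equal(flipped$start, b$src_length - b$start - b$size)
  # the raw flip is an involution: re-flipping on a now-minus row
  # restores the original block exactly
  expect_equal(flip_to_reference_strand(flipped, "yak"), b)
  # reference already on +: identity (so double application is idempotent)
  expect_equal(flip_to_reference_strand(flipped, "cattle"), flipped)
  expect_equal(flip_to_reference_strand(
    flip_to_reference_strand(b, "cattle"), "cattle"), flipped)
  expect_error(flip_to_reference_strand(b, "pig"), "absent")
})

test_that("zero branch lengths give the stationary-frequency likelihood", {
  m <- gtr_model(base_freqs = c(0.4, 0.1, 0.2, 0.3))
  aln <- matrix("A", 4, 1, dimnames = list(SP4, NULL))
  expect_equal(gtr_loglik(aln, m, rep(0, 5)), log(0.4))
})

test_that("two-taxon reduction matches the Jukes-Cantor closed form", {
  m <- gtr_model(n_rate_categories = 1L)  # equal rates, uniform freqs
  t <- 0.3
  jc_same <- 0.25 + 0.75 * exp(-4 * t / 3)
  jc_diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  same <- matrix(c("A", "A", "-", "-"), 4, 1, dimnames = list(SP4, NULL))
  diff <- matrix(c("A", "G", "-", "-"), 4, 1, dimnames = list(SP4, NULL))
  expect_equal(gtr_loglik(same, m, c(t, 0, 0, 0, 0)),
               log(0.25 * jc_same), tolerance = 1e-10)
  expect_equal(gtr_loglik(diff, m, c(t, 0, 0, 0, 0)),
               log(0.25 * jc_diff), tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration over internal states", {
  set.seed(41)
  for (rep in 1:50) {
    m <- gtr_model(rates = c(runif(5, 0.3, 3), 1),
                   base_freqs = as.numeric(rmultinom(1, 400, rep(1, 4)) + 1)
                   / 404,
                   gamma_shape = runif(1, 0.3, 3))
    bl <- runif(5, 0, 0.4)
    nc <- sample(1:5, 1)
    aln <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * nc, TRUE,
                         prob = c(rep(0.23, 4), 0.08)),
                  4, nc, dimnames = list(SP4, NULL))
    expect_equal(gtr_loglik(aln, m, bl), brute_gtr_loglik(aln, m, bl),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under exchangeability rescaling", {
  aln <- matrix(sample(c("A", "C", "G", "T"), 40, TRUE), 4, 10,
                dimnames = list(SP4, NULL))
  m1 <- gtr_model(rates = c(1.3, 4, 1, 1.2, 4.5, 1),
                  base_freqs = c(0.3, 0.2, 0.2, 0.3), gamma_shape = 1.5)
  m2 <- m1; m2$rates <- m1$rates * 7
  bl <- c(0.05, 0.04, 0.03, 0.06, 0.02)
  expect_equal(gtr_loglik(aln, m1, bl), gtr_loglik(aln, m2, bl))
})

test_that("degenerate fits behave: identical sequences, column order", {
  aln <- matrix(rep(strsplit(rand_dna(300, seed = 42), "")[[1]], each = 4),
                4, 300, dimnames = list(SP4, NULL))
  fit <- fit_gtr(aln, n_rate_categories = 1L, n_starts = 1)
  expect_lt(max(fit$branch_lengths), 1e-3)
  # column permutation leaves the fit unchanged (iid columns)
  sim <- simulate_maf(n_autosome = 2000, n_y = 100, seed = 43)
  a1 <- sim$aln_a
  a2 <- a1[, sample(ncol(a1))]
  f1 <- fit_gtr(a1, n_starts = 1)
  f2 <- fit_gtr(a2, n_starts = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$branch_lengths, f2$branch_lengths, tolerance = 1e-4)
})

test_that("fit agrees with an independent ML implementation", {
  skip_if_not_installed("phangorn")
  sim <- simulate_maf(n_autosome = 20000, n_y = 100, seed = 44)
  fit <- fit_gtr(sim$aln_a, n_starts = 2)
  dat <- phangorn::phyDat(sim$aln_a, type = "DNA")
  tre <- ape::read.tree(text = "((cattle:0.05,yak:0.04):0.02,sheep:0.03,goat:0.06);")
  pml0 <- phangorn::pml(tre, dat, k = 4)
  pfit <- phangorn::optim.pml(pml0, model = "GTR", optGamma = TRUE,
                              optEdge = TRUE, optBf = TRUE, optQ = TRUE,
                              control = phangorn::pml.control(trace = 0))
  expect_equal(fit$loglik, as.numeric(stats::logLik(pfit)),
               tolerance = 1e-4)
  # terminal branch lengths agree closely
  pe <- pfit$tree$edge.length
  tips <- pfit$tree$tip.label
  term <- setNames(pe[pfit$tree$edge[, 2] <= length(tips)],
                   tips[pfit$tree$edge[, 2][pfit$tree$edge[, 2] <=
                                              length(tips)]])
  expect_equal(unname(fit$branch_lengths[names(term)]), unname(term),
               tolerance = 0.02)
})

test_that("male-bias relation inverts exactly and rejects impossible input", {
  expect_equal(ya_ratio_and_alpha(1)$alpha_m, 1)
  expect_equal(ya_ratio_and_alpha(1.55)$alpha_m, 1.55 / 0.45)
  expect_error(ya_ratio_and_alpha(2.0), "alpha undefined")
  expect_error(ya_ratio_and_alpha(1, 0), "positive")
  # round trip: r = 2a/(1+a) recovers a, and alpha is increasing in r
  for (a in c(0.1, 0.5, 1, 2, 3.5, 10)) {
    r <- 2 * a / (1 + a)
    expect_equal(ya_ratio_and_alpha(r)$alpha_m, a, tolerance = 1e-12)
  }
  rs <- seq(0.1, 1.9, by = 0.1)
  alphas <- vapply(rs, function(r) ya_ratio_and_alpha(r)$alpha_m,
                   numeric(1))
  expect_true(all(diff(alphas) > 0))
  expect_lt(ya_ratio_and_alpha(1e-6)$alpha_m, 1e-5)
  expect_warning(ya_ratio_and_alpha(0.5, paper_formula = TRUE),
                 "cannot exceed 1")
})

test_that("the whole MAF-to-alpha pipeline runs end to end", {
  sim <- simulate_maf(n_autosome = 20000, n_y = 8000,
                      y_rate_multiplier = 1.55, seed = 45)
  res <- substitution_rate_analysis(sim$maf_y, sim$maf_a, n_starts = 1)
  expect_true(res$ya_ratio[["goat"]] > 1.2 && res$ya_ratio[["goat"]] < 1.9)
  expect_true(is.finite(res$alpha_m))
})
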