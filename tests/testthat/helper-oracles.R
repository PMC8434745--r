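# Independent oracles and tiny fixture builders shared across tests.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force length of the longest strictly increasing subsequence by
# enumeration over all index subsets (n <= ~15)
brute_lis_len <- function(x) {
  n <- length(x)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    v <- x[idx]
    if (all(diff(v) > 0)) best <- length(idx)
  }
  best
}

# brute-force GTR+gamma log-likelihood on the fixed 4-taxon topology by
# summation over all 16 internal-node state assignments, with dense
# matrix exponentials (eigen on the raw Q, no symmetry tricks)
brute_gtr_loglik <- function(aln, model, bl) {
  Q <- asmqc:::.gtr_q(model)
  pi <- model$base_freqs
  rates <- discrete_gamma_rates(model$gamma_shape, model$n_rate_categories)
  expm_dense <- function(M) {
    e <- eigen(M)
    Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
  }
  B <- c("A", "C", "G", "T")
  tipP <- function(P, x, obs) if (obs %in% B) P[x, match(obs, B)] else 1
  ll <- 0
  for (j in seq_len(ncol(aln))) {
    s <- 0
    for (r in rates) {
      P <- lapply(bl, function(t) expm_dense(Q * t * r))
      for (x in 1:4) for (y in 1:4) {
        s <- s + (1 / length(rates)) * pi[x] * P[[5]][x, y] *
          tipP(P[[1]], x, aln[1, j]) * tipP(P[[2]], x, aln[2, j]) *
          tipP(P[[3]], y, aln[3, j]) * tipP(P[[4]], y, aln[4, j])
      }
    }
    ll <- ll + log(s)
  }
  ll
}

# minimal single-sample VCF writer for read_variants fixtures
write_mini_vcf <- function(rows, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP\t%s:%d",
            r$chrom, r$pos1, r$ref, r$alt, as.character(r$qual), r$gt, r$dp)
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# the fixed four-taxon species order used throughout
SP4 <- c("cattle", "yak", "sheep", "goat")

# study-condition GTR model used by the MAF generator defaults
sim_gtr_model <- function() {
  gtr_model(rates = c(1.3, 4, 1, 1.2, 4.5, 1),
            base_freqs = c(0.3, 0.2, 0.2, 0.3), gamma_shape = 1.5)
}
sim_branch_lengths <- function() c(0.05, 0.04, 0.03, 0.06, 0.02)
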