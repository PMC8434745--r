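# GTR (REV) + discrete-gamma maximum likelihood on the fixed four-taxon
# topology ((cattle,yak),(sheep,goat)), by Felsenstein pruning with
# eigendecomposition-based transition matrices. The unrooted tree has five
# branches: four terminal and one internal.

.BASES <- c("A", "C", "G", "T")

#' Construct a GTR substitution model
#'
#' Exchangeabilities are given in the order AC, AG, AT, CG, CT, GT with GT
#' fixed to 1 for identifiability. The rate matrix is scaled so that one
#' unit of branch length equals one expected substitution per site at
#' stationarity. Rate variation across sites is discrete gamma with
#' `n_rate_categories` equal-probability categories whose rates are the
#' within-bin means (mean 1 overall).
#'
#' @param rates Length-6 positive exchangeabilities (AC, AG, AT, CG, CT,
#'   GT).
#' @param base_freqs Length-4 stationary frequencies (A, C, G, T), summing
#'   to 1.
#' @param gamma_shape Positive gamma shape; `Inf` disables rate variation.
#' @param n_rate_categories Number of discrete gamma categories.
#' @return Object of class `gtr_model`.
#' @export
gtr_model <- function(rates = rep(1, 6), base_freqs = rep(0.25, 4),
                      gamma_shape = Inf, n_rate_categories = 4L) {
  stopifnot(length(rates) == 6, all(rates > 0),
            length(base_freqs) == 4, all(base_freqs > 0),
            gamma_shape > 0)
  base_freqs <- base_freqs / sum(base_freqs)
  structure(list(rates = rates, base_freqs = base_freqs,
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories)),
            class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR model\n  exchangeabilities (AC AG AT CG CT GT):",
      paste(signif(x$rates, 4), collapse = " "), "\n")
  cat("  base frequencies (A C G T):",
      paste(signif(x$base_freqs, 4), collapse = " "), "\n")
  cat("  gamma shape:", signif(x$gamma_shape, 4),
      sprintf("(%d categories)\n", x$n_rate_categories))
  invisible(x)
}

# Scaled GTR rate matrix Q (rows sum to 0, -sum(pi*diag)=1).
.gtr_q <- function(model) {
  s <- model$rates; pi <- model$base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  Q["A", "C"] <- s[1] * pi[2]; Q["A", "G"] <- s[2] * pi[3]
  Q["A", "T"] <- s[3] * pi[4]
  Q["C", "A"] <- s[1] * pi[1]; Q["C", "G"] <- s[4] * pi[3]
  Q["C", "T"] <- s[5] * pi[4]
  Q["G", "A"] <- s[2] * pi[1]; Q["G", "C"] <- s[4] * pi[2]
  Q["G", "T"] <- s[6] * pi[4]
  Q["T", "A"] <- s[3] * pi[1]; Q["T", "C"] <- s[5] * pi[2]
  Q["T", "G"] <- s[6] * pi[3]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Eigendecomposition of Q exploiting time reversibility:
# diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric.
.gtr_eigen <- function(model) {
  Q <- .gtr_q(model)
  pi <- model$base_freqs
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / sp) %*% e$vectors,   # columns: right eigenvectors
       left = t(e$vectors) %*% diag(sp))
  # P(t) = right %*% diag(exp(values*t)) %*% left
}

.gtr_pmat <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0
  P
}

#' Discrete-gamma category rates (within-bin means)
#' @param shape Gamma shape parameter.
#' @param k Number of equal-probability categories.
#' @return Length-`k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  if (!is.finite(shape)) return(rep(1, k))
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  r <- k * diff(pgamma(b, shape = shape + 1, rate = shape))
  r / mean(r)
}

# Convert an alignment (matrix species x sites of A/C/G/T characters, with
# "-"/"N" as missing) to compressed site patterns.
# Returns list(tips = list of 4 x npat 0/1 likelihood matrices per species,
#              weights, npat, nsites).
.compress_patterns <- function(aln, species) {
  miss <- !(aln %in% .BASES)
  codes <- match(aln, .BASES)
  codes[miss] <- 5L
  dim(codes) <- dim(aln)
  rownames(codes) <- rownames(aln)
  codes <- codes[species, , drop = FALSE]
  key <- apply(codes, 2, paste, collapse = ".")
  tab <- table(key)
  pats <- do.call(cbind, strsplit(names(tab), ".", fixed = TRUE))
  storage.mode(pats) <- "integer"
  tips <- lapply(seq_along(species), function(i) {
    M <- matrix(0, 4, ncol(pats))
    for (b in 1:4) M[b, pats[i, ] == b] <- 1
    M[, pats[i, ] == 5L] <- 1   # missing: uninformative
    M
  })
  names(tips) <- species
  list(tips = tips, weights = as.numeric(tab), npat = ncol(pats),
       nsites = ncol(codes))
}

#' Log-likelihood of an alignment under GTR+Gamma on the fixed topology
#'
#' Felsenstein pruning on the unrooted tree `((sp1,sp2),(sp3,sp4))` with
#' five branch lengths (four terminal, one internal), integrating over the
#' discrete gamma rate categories with equal prior weight. Gaps and Ns are
#' treated as missing data.
#'
#' @param aln Character matrix (rows = species, columns = sites) over
#'   `A,C,G,T,-,N`, or a precompressed pattern list (internal use).
#' @param model A `gtr_model`.
#' @param branch_lengths Length-5 non-negative vector: `sp1`, `sp2`,
#'   `sp3`, `sp4`, `internal`.
#' @param species Character vector of 4 species names ordering the tree
#'   tips as `((sp1,sp2),(sp3,sp4))`; defaults to the rownames of `aln`.
#' @return Total log-likelihood.
#' @export
gtr_loglik <- function(aln, model, branch_lengths,
                       species = rownames(aln)) {
  stopifnot(length(branch_lengths) == 5, all(branch_lengths >= 0))
  pat <- if (is.list(aln) && !is.data.frame(aln)) aln
         else .compress_patterns(aln, species)
  eig <- .gtr_eigen(model)
  pi <- model$base_freqs
  rates <- discrete_gamma_rates(model$gamma_shape, model$n_rate_categories)
  sitelik <- numeric(pat$npat)
  for (r in rates) {
    P <- lapply(branch_lengths, function(t) .gtr_pmat(eig, t * r))
    c1 <- (P[[1]] %*% pat$tips[[1]]) * (P[[2]] %*% pat$tips[[2]])
    c2 <- (P[[3]] %*% pat$tips[[3]]) * (P[[4]] %*% pat$tips[[4]])
    root <- c1 * (P[[5]] %*% c2)
    sitelik <- sitelik + as.numeric(pi %*% root) / length(rates)
  }
  if (any(sitelik <= 0) || any(!is.finite(sitelik)))
    stop("non-finite site likelihood")
  sum(pat$weights * log(sitelik))
}

# parameter transform: theta <-> (rates[1:5], pi, shape, branches)
.theta_unpack <- function(theta, ncat, est_shape) {
  rates <- c(exp(theta[1:5]), 1)
  lp <- c(theta[6:8], 0)
  pi <- exp(lp) / sum(exp(lp))
  if (est_shape) {
    shape <- exp(theta[9])
    bl <- exp(theta[10:14])
  } else {
    shape <- Inf
    bl <- exp(theta[9:13])
  }
  list(model = gtr_model(rates, pi, shape, ncat), bl = bl)
}

#' Fit a GTR(+Gamma) model on the fixed four-taxon topology
#'
#' Maximizes the [gtr_loglik()] over the six exchangeabilities (GT fixed
#' to 1), the base frequencies, the gamma shape and the five branch
#' lengths, using bounded quasi-Newton optimisation on log/logit-
#' transformed parameters with multiple jittered starts to avoid local
#' optima. Base frequencies are initialised empirically and branch lengths
#' from pairwise mismatch proportions.
#'
#' @param aln Character matrix (species x sites) over `A,C,G,T,-,N`.
#' @param species Four species names, tree order `((sp1,sp2),(sp3,sp4))`.
#' @param n_rate_categories Discrete gamma categories (1 = no rate
#'   variation, gamma shape not estimated).
#' @param n_starts Number of optimisation starts.
#' @param seed Seed for the start jitter.
#' @return Object of class `gtr_fit`: list with `model`,
#'   `branch_lengths` (named: four species + "internal"), `loglik`,
#'   `nsites`, `npatterns`, `convergence`, `tree` (ape `phylo`, branch
#'   lengths in substitutions/site).
#' @export
fit_gtr <- function(aln, species = rownames(aln), n_rate_categories = 4L,
                    n_starts = 3L, seed = 1L) {
  stopifnot(length(species) == 4)
  pat <- .compress_patterns(aln, species)
  if (pat$nsites < 100)
    warning("fewer than 100 alignment columns; estimates will be noisy")
  est_shape <- n_rate_categories > 1L
  # empirical initialisation
  counts <- Reduce(`+`, lapply(pat$tips, function(M)
    as.numeric(M[, colSums(M) < 4, drop = FALSE] %*%
                 pat$weights[colSums(M) < 4])))
  pi0 <- (counts + 1) / sum(counts + 1)
  pdist <- function(i, j) {
    Ti <- pat$tips[[i]]; Tj <- pat$tips[[j]]
    def <- colSums(Ti) == 1 & colSums(Tj) == 1
    if (!any(def)) return(0.05)
    mism <- colSums(Ti[, def, drop = FALSE] * Tj[, def, drop = FALSE]) == 0
    p <- sum(pat$weights[def] * mism) / sum(pat$weights[def])
    max(p, 1e-4)
  }
  d12 <- pdist(1, 2); d34 <- pdist(3, 4)
  d13 <- pdist(1, 3)
  bl0 <- pmax(c(d12 / 2, d12 / 2, d34 / 2, d34 / 2,
                max(d13 - d12 / 2 - d34 / 2, 1e-3)), 1e-4)
  theta0 <- c(rep(0, 5), log(pi0[1:3] / pi0[4]),
              if (est_shape) log(1) else NULL, log(bl0))
  negll <- function(theta) {
    p <- tryCatch(.theta_unpack(theta, n_rate_categories, est_shape),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- tryCatch(gtr_loglik(pat, p$model, p$bl),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }
  npar <- length(theta0)
  lower <- rep(-12, npar); upper <- rep(12, npar)
  bidx <- (npar - 4):npar
  upper[bidx] <- log(10)   # branch lengths bounded in (0, 10]
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    th <- if (s == 1) theta0 else theta0 + rnorm(npar, 0, 0.3)
    th <- pmin(pmax(th, lower + 0.1), upper - 0.1)
    fit <- tryCatch(
      optim(th, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("GTR optimisation failed on all starts")
  p <- .theta_unpack(best$par, n_rate_categories, est_shape)
  bl <- p$bl
  names(bl) <- c(species, "internal")
  tre <- ape::read.tree(text = sprintf(
    "((%s:%g,%s:%g):%g,%s:%g,%s:%g);",
    species[1], bl[1], species[2], bl[2], bl[5],
    species[3], bl[3], species[4], bl[4]))
  structure(list(model = p$model, branch_lengths = bl,
                 loglik = -best$value, nsites = pat$nsites,
                 npatterns = pat$npat, convergence = best$convergence,
                 species = species, tree = tre),
            class = "gtr_fit")
}

#' @export
print.gtr_fit <- function(x, ...) {
  cat(sprintf("GTR+Gamma fit: logLik %.3f on %d sites (%d patterns)\n",
              x$loglik, x$nsites, x$npatterns))
  cat("  branch lengths (subst/site):\n")
  for (nm in names(x$branch_lengths))
    cat(sprintf("    %-10s %.5f\n", nm, x$branch_lengths[[nm]]))
  print(x$model)
  invisible(x)
}

#' @export
logLik.gtr_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- 5 + 3 + (object$model$n_rate_categories > 1) + 5
  attr(val, "nobs") <- object$nsites
  class(val) <- "logLik"
  val
}

#' @export
coef.gtr_fit <- function(object, ...) {
  c(setNames(object$model$rates,
             paste0("s_", c("AC", "AG", "AT", "CG", "CT", "GT"))),
    setNames(object$model$base_freqs, paste0("pi_", .BASES)),
    gamma_shape = object$model$gamma_shape,
    setNames(object$branch_lengths,
             paste0("bl_", names(object$branch_lengths))))
}

#' Keep only MAF blocks containing all required species
#' @param blocks List of MAF block data.frames (see [read_maf()]).
#' @param required_species Character vector of species that must all be
#'   present.
#' @return Filtered list of blocks.
#' @export
filter_blocks <- function(blocks,
                          required_species = c("cattle", "yak", "sheep",
                                               "goat")) {
  Filter(function(b) all(required_species %in% b$species), blocks)
}

#' Remove duplicate species rows within MAF blocks
#'
#' When a species has several rows in one block (paralogous or duplicated
#' alignments), only the row closest to the column-wise majority consensus
#' of the block is kept; identity is the fraction of matching non-gap
#' positions. Exact ties keep the first row in file order.
#'
#' @param blocks List of MAF block data.frames.
#' @return List of blocks with at most one row per species.
#' @export
dedupe_blocks <- function(blocks) {
  lapply(blocks, function(b) {
    if (!anyDuplicated(b$species)) return(b)
    chars <- do.call(rbind, strsplit(b$text, "", fixed = TRUE))
    consensus <- apply(chars, 2, function(col) {
      col <- col[col != "-"]
      if (length(col) == 0) return("-")
      names(sort(table(col), decreasing = TRUE))[1]
    })
    ident <- vapply(seq_len(nrow(chars)), function(i) {
      nong <- chars[i, ] != "-"
      if (!any(nong)) return(0)
      mean(chars[i, nong] == consensus[nong])
    }, numeric(1))
    keep <- unlist(lapply(split(seq_len(nrow(b)), b$species), function(ix) {
      ix[which.max(ident[ix])]   # which.max keeps the first on ties
    }))
    out <- b[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Flip a MAF block to the positive strand of a reference species
#'
#' If the reference species row is on the minus strand, every row's
#' aligned text is reverse-complemented (gaps preserved), strands are
#' toggled and start coordinates recomputed
#' (`start' = src_length - start - size`). Applying the flip twice is the
#' identity.
#'
#' @param block A MAF block data.frame.
#' @param reference_species Species whose strand defines the orientation.
#' @return The (possibly flipped) block.
#' @export
flip_to_reference_strand <- function(block, reference_species) {
  i <- which(block$species == reference_species)
  if (length(i) == 0) stop("reference species absent from block")
  if (block$strand[i[1]] == "+") return(block)
  block$text <- revcomp(block$text)
  block$start <- block$src_length - block$start - block$size
  block$strand <- ifelse(block$strand == "+", "-", "+")
  block
}

# Stack MAF blocks into one species x sites character matrix.
.maf_alignment <- function(blocks, species) {
  cols <- lapply(blocks, function(b) {
    rows <- b[match(species, b$species), , drop = FALSE]
    do.call(rbind, strsplit(toupper(rows$text), "", fixed = TRUE))
  })
  aln <- do.call(cbind, cols)
  rownames(aln) <- species
  aln
}

#' Y-to-autosome rate ratio and male mutation bias
#'
#' The Y chromosome is transmitted only through males, while autosomes
#' spend equal time in the two germlines, so with male and female per-
#' generation mutation rates `u_m = alpha * u_f` the expected rate ratio is
#' `Y/A = 2*alpha/(1 + alpha)`, giving `alpha = r / (2 - r)` for an
#' observed ratio `r` (undefined for `r >= 2`). Setting
#' `paper_formula = TRUE` instead inverts `Y/A = alpha/(1 + alpha)`, a
#' relation sometimes printed in the literature that cannot exceed 1 and
#' therefore cannot explain observed ratios above 1; it is provided for
#' comparison only and warns when used.
#'
#' @param rate_y,rate_a Substitution rates (e.g. terminal branch lengths)
#'   on the Y and autosomal partitions; or pass `rate_y` as a
#'   precomputed ratio and leave `rate_a = 1`.
#' @param paper_formula Use the `alpha/(1+alpha)` relation instead.
#' @return List with `ya_ratio` and `alpha_m`.
#' @export
ya_ratio_and_alpha <- function(rate_y, rate_a = 1, paper_formula = FALSE) {
  if (rate_a <= 0) stop("autosomal rate must be positive")
  r <- rate_y / rate_a
  if (r <= 0) stop("ya_ratio must be positive")
  if (paper_formula) {
    warning("alpha/(1+alpha) relation cannot exceed 1; ",
            "alpha is undefined for ratios >= 1")
    alpha <- if (r >= 1) NaN else r / (1 - r)
  } else {
    if (r >= 2) stop("alpha undefined: ya_ratio >= 2")
    alpha <- r / (2 - r)
  }
  list(ya_ratio = r, alpha_m = alpha)
}

#' Full substitution-rate analysis from Y and autosomal MAF alignments
#'
#' Applies the filtering pipeline (duplicate-row removal, flip to the
#' reference species' positive strand, retention of blocks with all four
#' species) to each partition, fits GTR+Gamma on the fixed topology
#' `((sp1,sp2),(sp3,sp4))` separately for the Y and autosomal partitions,
#' and derives the per-species Y/A ratio of terminal branch lengths plus
#' the male mutation bias of the focal species.
#'
#' @param maf_y,maf_a MAF block lists (or file paths).
#' @param species Four species names in tree order.
#' @param focal Species whose `alpha_m` is reported.
#' @param reference_species Strand reference (defaults to `species[1]`).
#' @param ... Passed to [fit_gtr()].
#' @return Object of class `rate_result`: list with `fit_y`, `fit_a`,
#'   `ya_ratio` (named per species), `alpha_m`, `focal`.
#' @export
substitution_rate_analysis <- function(maf_y, maf_a,
                                       species = c("cattle", "yak",
                                                   "sheep", "goat"),
                                       focal = "goat",
                                       reference_species = species[1],
                                       ...) {
  prep <- function(maf) {
    blocks <- if (is.character(maf)) read_maf(maf) else maf
    blocks <- dedupe_blocks(blocks)
    blocks <- lapply(blocks, flip_to_reference_strand,
                     reference_species = reference_species)
    blocks <- filter_blocks(blocks, required_species = species)
    if (length(blocks) == 0) stop("no blocks with all four species")
    .maf_alignment(blocks, species)
  }
  fit_y <- fit_gtr(prep(maf_y), species = species, ...)
  fit_a <- fit_gtr(prep(maf_a), species = species, ...)
  ratio <- fit_y$branch_lengths[species] / fit_a$branch_lengths[species]
  alpha <- ya_ratio_and_alpha(unname(ratio[focal]))$alpha_m
  structure(list(fit_y = fit_y, fit_a = fit_a, ya_ratio = ratio,
                 alpha_m = alpha, focal = focal),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat("Y vs autosome substitution rates\n")
  cat("  Y/A per species:",
      paste(sprintf("%s=%.3f", names(x$ya_ratio), x$ya_ratio),
            collapse = ", "), "\n")
  cat(sprintf("  male mutation bias alpha_m (%s): %.2f\n", x$focal,
              x$alpha_m))
  invisible(x)
}
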