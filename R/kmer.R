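#' Canonical k-mer depth histogram
#'
#' Counts every k-mer of the reads in canonical (strand-folded) form — the
#' lexicographic minimum of the k-mer and its reverse complement — and
#' tabulates how many distinct k-mers were seen at each depth. K-mers
#' containing `N` (or any ambiguity code) are skipped.
#'
#' @param reads Character vector of read sequences.
#' @param k K-mer length (odd, 1..31; default 17).
#' @return Object of class `kmer_histogram`: list with `k`, `depth`,
#'   `count` and `kmer_number` (total k-mer instances, `sum(depth*count)`).
#' @export
kmer_histogram <- function(reads, k = 17L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 31L)
  if (k %% 2L == 0L)
    warning("even k cannot distinguish a k-mer from its reverse complement ",
            "in all cases; odd k recommended")
  h <- .kmer_histogram_cpp(as.character(reads), k)
  structure(list(k = k, depth = h$depth, count = h$count,
                 kmer_number = sum(as.numeric(h$depth) * h$count)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k = %d): %s k-mer instances, %s distinct\n",
              x$k, format(x$kmer_number, big.mark = ","),
              format(sum(x$count), big.mark = ",")))
  invisible(x)
}

#' Read a precomputed k-mer histogram from a depth/count TSV
#' @param path Two-column TSV (depth, count), with or without a header.
#' @param k K-mer length the histogram was computed with.
#' @return A `kmer_histogram` object.
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  first <- readLines(path, n = 1)
  header <- grepl("[A-Za-z]", first)
  d <- read.delim(path, header = header)
  names(d)[1:2] <- c("depth", "count")
  structure(list(k = as.integer(k), depth = as.integer(d$depth),
                 count = as.numeric(d$count),
                 kmer_number = sum(as.numeric(d$depth) * d$count)),
            class = "kmer_histogram")
}

#' Identify the characteristic peaks of a k-mer spectrum
#'
#' Smooths the depth counts with a moving average (window 3), takes the
#' first local minimum as the error valley (the trough separating the
#' low-depth sequencing-error k-mers from genomic k-mers), and the global
#' maximum beyond the valley as the homozygous coverage peak. Local maxima
#' near half and double the homozygous depth (within 25%) are flagged as
#' the heterozygous and repeat peaks. A spectrum whose counts only decay
#' (pure error) has no coverage peak and raises an error; a spectrum that
#' rises straight into its peak (error-free data) gets `error_valley = 1`.
#'
#' @param hist A `kmer_histogram` object.
#' @return Object of class `spectrum_peaks`: list with `error_valley`,
#'   `heterozygous_peak` (or NA), `homozygous_peak`, `repeat_peak` (or NA).
#' @export
find_peaks <- function(hist) {
  if (length(hist$depth) == 0) stop("empty histogram")
  depths <- seq_len(max(hist$depth))
  counts <- numeric(length(depths))
  counts[hist$depth] <- hist$count
  # moving average, window 3
  n <- length(counts)
  sm <- counts
  if (n >= 3) {
    sm <- (c(counts[1], counts[-n]) + counts + c(counts[-1], counts[n])) / 3
  }
  if (n < 3) stop("no coverage peak in k-mer spectrum")
  # first local minimum: smallest d with sm[d-1] > sm[d] <= sm[d+1]
  valley <- NA_integer_
  for (d in 2:(n - 1)) {
    if (sm[d - 1] > sm[d] && sm[d] <= sm[d + 1]) { valley <- d; break }
    if (sm[d] > sm[d - 1]) { valley <- 1L; break }  # rises from the start
  }
  if (is.na(valley)) stop("no coverage peak in k-mer spectrum")  # monotone decay
  beyond <- valley:n
  hom <- beyond[which.max(sm[beyond])]
  if (hom == valley && valley > 1L)
    stop("no coverage peak beyond error valley")
  if (valley == 1L && hom == 1L) stop("no coverage peak in k-mer spectrum")
  local_max_near <- function(target) {
    lo <- max(2, floor(target * 0.75)); hi <- min(n - 1, ceiling(target * 1.25))
    if (lo >= hi) return(NA_integer_)
    cand <- lo:hi
    is_max <- sm[cand] >= sm[cand - 1] & sm[cand] >= sm[cand + 1] & sm[cand] > 0
    if (!any(is_max)) return(NA_integer_)
    cand[is_max][which.max(sm[cand[is_max]])]
  }
  het <- local_max_near(hom / 2)
  if (!is.na(het) && (het <= valley || het == hom)) het <- NA_integer_
  rep_pk <- local_max_near(hom * 2)
  if (!is.na(rep_pk) && rep_pk == hom) rep_pk <- NA_integer_
  # sub-integer refinement: Gaussian (quadratic-in-log-counts) fit over a
  # +/- 2*sqrt(peak) window around the mode, iterated once after
  # recentering; the raw mode of a Poisson-wide bump wanders by several
  # depth units when few distinct k-mers populate the histogram
  refined <- hom
  for (it in 1:2) {
    win <- max(3, round(2 * sqrt(refined)))
    ctr <- round(refined)
    sel <- which(depths >= max(valley + 1, ctr - win) &
                   depths <= ctr + win & counts > 0)
    if (length(sel) < 5) break
    d <- depths[sel]
    fit <- lm(log(counts[sel]) ~ d + I(d^2), weights = counts[sel])
    cc <- coef(fit)
    if (anyNA(cc) || cc[3] >= 0) break
    refined <- unname(-cc[2] / (2 * cc[3]))
  }
  if (!is.finite(refined) || refined <= valley) refined <- hom
  structure(list(error_valley = valley, heterozygous_peak = het,
                 homozygous_peak = hom,
                 homozygous_peak_refined = refined,
                 repeat_peak = rep_pk),
            class = "spectrum_peaks")
}

#' @export
print.spectrum_peaks <- function(x, ...) {
  cat(sprintf("spectrum peaks: homozygous %d (valley %d%s%s)\n",
              x$homozygous_peak, x$error_valley,
              if (!is.na(x$heterozygous_peak))
                sprintf(", heterozygous %d", x$heterozygous_peak) else "",
              if (!is.na(x$repeat_peak))
                sprintf(", repeat %d", x$repeat_peak) else ""))
  invisible(x)
}

#' Estimate genome size from a k-mer spectrum
#'
#' `genome_size = kmer_number / peak_depth`, where `peak_depth` is the
#' homozygous coverage peak (the sub-integer refined peak when available,
#' since the true mean k-mer depth is rarely a whole number). By default
#' k-mer instances at depths below the error valley are excluded from
#' `kmer_number` first, so sequencing-error k-mers do not inflate the
#' estimate; `exclude_errors = FALSE` reproduces the raw formula.
#'
#' @param hist A `kmer_histogram`.
#' @param peaks A `spectrum_peaks` (computed with [find_peaks()] if NULL).
#' @param exclude_errors Drop depths below the error valley first.
#' @return Estimated genome size in bp (integer-rounded).
#' @export
estimate_genome_size <- function(hist, peaks = NULL, exclude_errors = TRUE) {
  if (is.null(peaks)) peaks <- find_peaks(hist)
  pk <- peaks$homozygous_peak_refined
  if (is.null(pk)) pk <- peaks$homozygous_peak
  if (is.null(pk) || pk <= 0) stop("undefined or zero peak depth")
  kn <- if (exclude_errors) {
    keep <- hist$depth >= peaks$error_valley
    sum(as.numeric(hist$depth[keep]) * hist$count[keep])
  } else hist$kmer_number
  round(kn / pk)
}
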