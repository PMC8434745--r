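#' Exact telomere hexamer matches
#'
#' All exact occurrences of the vertebrate telomere motif `TTAGGG` on the
#' forward strand and of its reverse complement `CCCTAA` (a minus-strand
#' motif copy) in a sequence. Overlapping occurrences are allowed.
#'
#' @param record A single sequence string.
#' @return data.frame with `pos` (0-based start) and `strand` (`+`/`-`),
#'   sorted by position.
#' @export
scan_hexamer <- function(record) {
  stopifnot(length(record) == 1L)
  # neither motif can overlap itself (no border of TTAGGG is also a
  # suffix), so non-overlapping search already finds every occurrence
  find_all <- function(pat) {
    m <- gregexpr(pat, record, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  }
  fw <- find_all("TTAGGG")
  rv <- find_all("CCCTAA")
  out <- data.frame(pos = c(fw, rv),
                    strand = c(rep("+", length(fw)), rep("-", length(rv))))
  out[order(out$pos), , drop = FALSE]
}

#' DUST low-complexity masking (windowed symmetric score)
#'
#' Slides a window of `window` bp over the sequence and scores each window
#' by the triplet-collision statistic
#' `10 * sum_t c_t(c_t - 1)/2 / (l - 1)`, where `c_t` counts occurrences of
#' 3-mer `t` among the `l` valid triplets of the window (the symmetric-DUST
#' score, identical on a sequence and its reverse complement). Windows
#' scoring above `threshold` are masked; the merged union of masked windows
#' is returned. Random sequence scores around 5 and perfect short-period
#' tandem repeats score far above 20, so the default threshold separates
#' the two cleanly.
#'
#' @param record A single sequence string.
#' @param window Window size in bp (>= 3).
#' @param threshold Score threshold above which a window is masked.
#' @return data.frame of 0-based half-open intervals (`start`, `end`).
#' @export
sdust <- function(record, window = 64L, threshold = 20) {
  stopifnot(length(record) == 1L, window >= 3)
  m <- .dust_intervals_cpp(record, as.integer(window), threshold)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Tandem hexamer seed runs
#'
#' Spans of at least `min_consecutive` telomere-motif copies in tandem
#' (period exactly 6) on one strand. A single interrupting base breaks the
#' run: telomeric DNA is tandem, and requiring exact period 6 is the
#' strictest reading of "consecutive identical 6-mer matches".
#'
#' @param matches data.frame from [scan_hexamer()] (sorted by position).
#' @param min_consecutive Minimum number of tandem copies.
#' @return data.frame of 0-based half-open intervals (`start`, `end`,
#'   `strand`).
#' @export
seed_runs <- function(matches, min_consecutive = 10L) {
  out <- data.frame(start = numeric(0), end = numeric(0),
                    strand = character(0))
  for (st in c("+", "-")) {
    pos <- matches$pos[matches$strand == st]
    if (length(pos) < min_consecutive) next
    pos <- sort(pos)
    brk <- c(0L, which(diff(pos) != 6L), length(pos))
    for (i in seq_len(length(brk) - 1L)) {
      run <- pos[(brk[i] + 1L):brk[i + 1L]]
      if (length(run) >= min_consecutive)
        out <- rbind(out, data.frame(start = run[1], end = run[length(run)] + 6,
                                     strand = st))
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' Detect telomeric repeat regions in a sequence
#'
#' The detection procedure: (1) exact hexamer matches on both strands;
#' (2) tandem seed runs of >= `min_consecutive` copies; (3) each seed run
#' is unioned with every DUST low-complexity interval it intersects;
#' (4) overlapping results merge; (5) regions are retained iff they are at
#' least `min_len` bp long and their hexamer density (motif-covered bases /
#' region length, overlaps on either strand counted once) exceeds
#' `min_density`; (6) each region is labelled proximal/distal/interior by
#' whether it lies within `end_window` bp of a chromosome boundary.
#'
#' If no seed run exists the DUST pass is skipped entirely (no telomere can
#' be called), which makes scanning motif-free sequence cheap.
#'
#' @param record A single sequence string.
#' @param min_len Minimum region length (bp).
#' @param min_density Minimum hexamer density (strict >).
#' @param window,threshold DUST parameters, see [sdust()].
#' @param min_consecutive Seed-run tandem copy threshold.
#' @param end_window Distance from a chromosome boundary within which a
#'   region counts as proximal/distal.
#' @param chrom Optional chromosome name attached to the output.
#' @return data.frame with `start`, `end`, `hexamer_bases`, `density`,
#'   `side` (and `chrom` if given).
#' @export
detect_telomeres <- function(record, min_len = 2000L, min_density = 0.5,
                             window = 64L, threshold = 20,
                             min_consecutive = 10L, end_window = 500000L,
                             chrom = NULL) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      hexamer_bases = numeric(0), density = numeric(0),
                      side = character(0))
  finish <- function(df) {
    if (!is.null(chrom)) {
      df <- cbind(chrom = rep(chrom, nrow(df)), df)
    }
    df
  }
  matches <- scan_hexamer(record)
  seeds <- seed_runs(matches, min_consecutive)
  if (nrow(seeds) == 0) return(finish(empty))
  dust <- sdust(record, window, threshold)
  regions <- seeds[, c("start", "end")]
  if (nrow(dust) > 0) {
    for (i in seq_len(nrow(seeds))) {
      hit <- dust$start < seeds$end[i] & dust$end > seeds$start[i]
      if (any(hit)) {
        regions$start[i] <- min(regions$start[i], dust$start[hit])
        regions$end[i] <- max(regions$end[i], dust$end[hit])
      }
    }
  }
  regions <- .merge_intervals(regions)
  # hexamer coverage: motif intervals merged across strands
  motif_iv <- .merge_intervals(data.frame(start = matches$pos,
                                          end = matches$pos + 6))
  cover <- function(s, e) {
    ov_s <- pmax(motif_iv$start, s)
    ov_e <- pmin(motif_iv$end, e)
    sum(pmax(0, ov_e - ov_s))
  }
  regions$hexamer_bases <- mapply(cover, regions$start, regions$end)
  regions$density <- regions$hexamer_bases / (regions$end - regions$start)
  keep <- (regions$end - regions$start) >= min_len &
    regions$density > min_density
  regions <- regions[keep, , drop = FALSE]
  L <- nchar(record)
  regions$side <- ifelse(regions$start < end_window, "proximal",
                         ifelse(regions$end > L - end_window, "distal",
                                "interior"))
  # a short chromosome can satisfy both; prefer the nearer boundary
  both <- regions$start < end_window & regions$end > L - end_window
  if (any(both)) {
    nearer_distal <- (L - regions$end[both]) < regions$start[both]
    regions$side[both] <- ifelse(nearer_distal, "distal", "proximal")
  }
  rownames(regions) <- NULL
  finish(regions)
}

#' Detect centromeric satellite regions from repeat annotations
#'
#' Keeps annotated intervals whose repeat class/family label is exactly
#' `Satellite/centr` and whose length strictly exceeds `min_len`.
#'
#' @param repeats data.frame from [read_repeat_annotations()] (`chrom`,
#'   `start`, `end`, `label`).
#' @param min_len Minimum length (strict >), default 5000 bp.
#' @return data.frame with `chrom`, `start`, `end`, `label`.
#' @export
detect_centromeres <- function(repeats, min_len = 5000L) {
  keep <- repeats$label == "Satellite/centr" &
    (repeats$end - repeats$start) > min_len
  out <- repeats[keep, c("chrom", "start", "end", "label"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify acrocentric chromosome completeness
#'
#' An acrocentric chromosome is called `near_complete` when it carries a
#' centromeric satellite region starting within `end_window` bp of its
#' proximal end and a telomeric region within `end_window` bp of its distal
#' end; otherwise `partial`.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param telomeres data.frame of telomere regions on this chromosome
#'   (`start`, `end`).
#' @param centromeres data.frame of centromere regions on this chromosome.
#' @param end_window Boundary window in bp.
#' @return One-row data.frame with `chrom`, `has_proximal_centromere`,
#'   `has_distal_telomere`, `status`.
#' @export
classify_completeness <- function(chrom, chrom_length, telomeres,
                                  centromeres, end_window = 500000L) {
  has_cen <- nrow(centromeres) > 0 && any(centromeres$start < end_window)
  has_tel <- nrow(telomeres) > 0 &&
    any(telomeres$end > chrom_length - end_window)
  data.frame(chrom = chrom,
             has_proximal_centromere = has_cen,
             has_distal_telomere = has_tel,
             status = if (has_cen && has_tel) "near_complete" else "partial")
}

#' Completeness calls for a whole assembly
#'
#' Runs [detect_telomeres()] on every sequence, filters the supplied repeat
#' annotations through [detect_centromeres()], and classifies each
#' chromosome with [classify_completeness()].
#'
#' @param assembly Named character vector of sequences.
#' @param repeats Repeat annotation data.frame (may be empty).
#' @param end_window Boundary window in bp.
#' @param ... Passed to [detect_telomeres()].
#' @return List with `telomeres`, `centromeres`, `calls` data.frames.
#' @export
assembly_completeness <- function(assembly, repeats = NULL,
                                  end_window = 500000L, ...) {
  if (is.null(repeats))
    repeats <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), label = character(0))
  cen <- detect_centromeres(repeats)
  tel_list <- lapply(names(assembly), function(ch)
    detect_telomeres(assembly[[ch]], chrom = ch, end_window = end_window, ...))
  tel <- .rbind_all(tel_list)
  if (is.null(tel))
    tel <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), hexamer_bases = numeric(0),
                      density = numeric(0), side = character(0))
  calls <- do.call(rbind, lapply(names(assembly), function(ch)
    classify_completeness(ch, nchar(assembly[[ch]]),
                          tel[tel$chrom == ch, , drop = FALSE],
                          cen[cen$chrom == ch, , drop = FALSE],
                          end_window = end_window)))
  list(telomeres = tel, centromeres = cen, calls = calls)
}
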