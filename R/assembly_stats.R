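#' Ungapped length of a sequence
#'
#' Total length minus the number of `N` bases, regardless of how the Ns are
#' grouped into runs. This is the "ungapped length" convention of
#' chromosome-level assembly reports: every N is excluded, even isolated
#' ones that fall below the gap-run threshold.
#'
#' @param record A single sequence string.
#' @return Integer number of non-N bases.
#' @export
ungapped_length <- function(record) {
  stopifnot(length(record) == 1L)
  nchar(record) - sum(nchar(record) - nchar(gsub("N", "", record, fixed = TRUE)))
}

#' Number of assembly gaps in a sequence
#'
#' A gap is a maximal run of at least `min_gap_run` consecutive Ns (10 by
#' default, the NCBI assembly convention). Shorter N runs are not counted
#' as gaps but are still excluded from [ungapped_length()].
#'
#' @param record A single sequence string.
#' @param min_gap_run Minimum N-run length that counts as a gap.
#' @return Integer gap count.
#' @export
gap_count <- function(record, min_gap_run = 10L) {
  nrow(find_n_runs(record, min_run = min_gap_run))
}

#' Nx length statistic (N50 by default)
#'
#' Smallest length L such that the pieces of length >= L jointly cover at
#' least `x` percent of the total. Invariant under permutation of the
#' input.
#'
#' @param lengths Numeric vector of positive piece lengths.
#' @param x Percent of the total to cover (50 for N50).
#' @return The Nx length.
#' @export
nx <- function(lengths, x = 50) {
  if (length(lengths) == 0) stop("empty length list")
  stopifnot(all(lengths > 0), x > 0, x <= 100)
  s <- sort(unname(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= x / 100 * sum(s))[1]]
}

# Split records at counted gap runs and return contig lengths.
.contig_lengths <- function(seqs, min_gap_run = 10L) {
  unlist(lapply(seq_along(seqs), function(i) {
    runs <- find_n_runs(seqs[[i]], min_run = min_gap_run)
    L <- nchar(seqs[[i]])
    if (nrow(runs) == 0) return(L)
    bounds <- c(0, as.vector(t(as.matrix(runs[, c("start", "end")]))), L)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    lens <- ends - starts
    lens[lens > 0]
  }), use.names = FALSE)
}

#' Per-chromosome and assembly-wide statistics report
#'
#' Computes, per chromosome: total length, ungapped length (all Ns
#' excluded), gap count (N runs >= `min_gap_run`), telomere length
#' (summed over supplied telomere intervals on that chromosome) and
#' completeness flags; plus assembly-wide sums, contig and scaffold N50,
#' the number of chromosomes with fewer than 10 gaps and the number of
#' gapless chromosomes.
#'
#' Alternatively, pre-tabulated rows (a data.frame with columns
#' `chrom`, `ungapped_length`, `gap_count`, `telomere_length`) may be
#' supplied via `rows` to recompute the summary of an existing published
#' table without the sequences.
#'
#' @param assembly Named character vector of sequences (or NULL).
#' @param telomeres Optional data.frame of telomere intervals
#'   (`chrom`, `start`, `end`).
#' @param centromeres Optional data.frame of centromere intervals.
#' @param rows Optional pre-tabulated per-chromosome rows.
#' @param min_gap_run Minimum N-run length that counts as a gap.
#' @return An object of class `assembly_report`: list with `per_chrom`
#'   (data.frame) and `summary` (list of sums and counts).
#' @export
chromosome_report <- function(assembly = NULL, telomeres = NULL,
                              centromeres = NULL, rows = NULL,
                              min_gap_run = 10L) {
  if (is.null(assembly) && is.null(rows))
    stop("supply either an assembly or pre-tabulated rows")
  if (!is.null(rows)) {
    need <- c("chrom", "ungapped_length", "gap_count", "telomere_length")
    if (!all(need %in% names(rows)))
      stop("pre-tabulated rows need columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(rows$chrom)) stop("duplicate chrom ids")
    per <- rows[, need]
    contig_n50 <- scaffold_n50 <- NA_real_
  } else {
    if (length(assembly) == 0) stop("empty assembly")
    if (anyDuplicated(names(assembly))) stop("duplicate chrom ids")
    tel_len <- function(chrom) {
      if (is.null(telomeres) || nrow(telomeres) == 0) return(0)
      sub <- telomeres[telomeres$chrom == chrom, , drop = FALSE]
      sum(sub$end - sub$start)
    }
    per <- data.frame(
      chrom = names(assembly),
      total_length = nchar(assembly),
      ungapped_length = vapply(assembly, ungapped_length, numeric(1)),
      gap_count = vapply(assembly, gap_count, numeric(1),
                         min_gap_run = min_gap_run),
      telomere_length = vapply(names(assembly), tel_len, numeric(1)),
      row.names = NULL)
    scaffold_n50 <- nx(nchar(assembly))
    contig_n50 <- nx(.contig_lengths(assembly, min_gap_run))
  }
  summary <- list(
    ungapped_sum = sum(per$ungapped_length),
    gap_sum = sum(per$gap_count),
    telomere_sum = sum(per$telomere_length),
    n_chrom = nrow(per),
    n_chrom_lt10_gaps = sum(per$gap_count < 10),
    n_gapless = sum(per$gap_count == 0),
    contig_n50 = contig_n50,
    scaffold_n50 = scaffold_n50)
  structure(list(per_chrom = per, summary = summary),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  s <- x$summary
  cat("Assembly report:", s$n_chrom, "sequences\n")
  cat(sprintf("  ungapped length sum: %s bp\n",
              format(s$ungapped_sum, big.mark = ",")))
  cat(sprintf("  gaps: %d (%d chromosomes with <10 gaps, %d gapless)\n",
              s$gap_sum, s$n_chrom_lt10_gaps, s$n_gapless))
  cat(sprintf("  telomere length sum: %s bp\n",
              format(s$telomere_sum, big.mark = ",")))
  if (!is.na(s$contig_n50))
    cat(sprintf("  contig N50: %s bp; scaffold N50: %s bp\n",
                format(s$contig_n50, big.mark = ","),
                format(s$scaffold_n50, big.mark = ",")))
  invisible(x)
}

#' Count substitutions for consensus-quality estimation
#'
#' Counts biallelic homozygous-alternate SNVs passing quality and depth
#' filters. These are the sites where the reads of the sequenced individual
#' homozygously disagree with its own assembly, i.e. putative consensus
#' errors.
#'
#' @param variants data.frame as returned by [read_variants()].
#' @param min_qual Minimum variant QUAL (phred).
#' @param depth_range Either NULL (derive `[mean/3, 2*mean]` from the mean
#'   depth of the variants) or a numeric length-2 vector.
#' @return Integer count of substitution sites.
#' @export
count_substitutions <- function(variants, min_qual = 20,
                                depth_range = NULL) {
  if (nrow(variants) == 0) return(0L)
  if (is.null(depth_range)) {
    md <- mean(variants$depth, na.rm = TRUE)
    depth_range <- if (is.finite(md)) c(md / 3, 2 * md) else c(0, Inf)
  }
  keep <- variants$is_snv &
    variants$genotype %in% "hom_alt" &
    (!is.na(variants$qual) & variants$qual >= min_qual) &
    (!is.na(variants$depth) & variants$depth >= depth_range[1] &
       variants$depth <= depth_range[2])
  sum(keep, na.rm = TRUE)
}

#' Phred-scaled assembly quality value (QV)
#'
#' `QV = -10 * log10(substitution_number / genome_size)`. A substitution
#' count of zero yields `Inf` (no detected consensus error).
#'
#' @param substitution_number Count of substitution sites.
#' @param genome_size Assembly size in bp.
#' @return An object of class `qv_estimate` (list with
#'   `substitution_number`, `genome_size`, `qv`).
#' @export
qv_estimate <- function(substitution_number, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (substitution_number < 0) stop("substitution_number must be >= 0")
  qv <- if (substitution_number == 0) Inf else
    -10 * log10(substitution_number / genome_size)
  structure(list(substitution_number = substitution_number,
                 genome_size = genome_size, qv = qv),
            class = "qv_estimate")
}

#' @export
print.qv_estimate <- function(x, ...) {
  cat(sprintf("QV = %.1f (%s substitutions / %s bp)\n", x$qv,
              format(x$substitution_number, big.mark = ","),
              format(x$genome_size, big.mark = ",")))
  invisible(x)
}

#' Published per-chromosome statistics of the two goat assemblies
#'
#' The chromosome-level comparison table of the Saanen_v1
#' (GCA_015443085.1) and ARS1 (GCA_001704415.1) goat genome assemblies:
#' ungapped length, gap number and telomere length per chromosome for both
#' assemblies. Shipped as a plain TSV under `extdata`.
#'
#' @return data.frame with one row per chromosome (1-29, X, Y) and columns
#'   `chrom`, `saanen_ungapped`, `saanen_gaps`, `saanen_telomere`,
#'   `ars1_ungapped`, `ars1_gaps`, `ars1_telomere`.
#' @export
goat_chrom_stats <- function() {
  f <- system.file("extdata", "goat_saanen_ars1_chrom_stats.tsv",
                   package = "asmqc", mustWork = TRUE)
  read.delim(f, colClasses = c("character", rep("numeric", 6)))
}

#' Published large discrepancy regions between Saanen_v1 and ARS1
#'
#' The eight >1 Mb regions called inverted or incorrectly placed in the
#' ARS1 goat assembly relative to Saanen_v1, with their coordinates on both
#' assemblies (1-based inclusive, as published; the printed length equals
#' `ars1_end - ars1_start`).
#'
#' @return data.frame with columns `name`, `saanen_chrom`, `saanen_start`,
#'   `saanen_end`, `ars1_chrom`, `ars1_start`, `ars1_end`, `length`,
#'   `description`.
#' @export
goat_discrepancy_regions <- function() {
  f <- system.file("extdata", "goat_large_discrepancy_regions.tsv",
                   package = "asmqc", mustWork = TRUE)
  read.delim(f, colClasses = c("character", "character", "numeric", "numeric",
                               "character", "numeric", "numeric", "numeric",
                               "character"))
}
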