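#' @useDynLib asmqc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import stats
#' @import utils
NULL

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# Assemblies are named character vectors of uppercase ACGTN sequences;
# interval tables are data.frames with chrom/start/end columns.

.AMBIG_FROM <- "RYSWKMBDHVU"
.AMBIG_TO   <- "NNNNNNNNNNN"

.normalize_bases <- function(x) {
  x <- toupper(x)
  x <- chartr(.AMBIG_FROM, .AMBIG_TO, x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N} after normalization")
  x
}

#' Read a FASTA file into a named assembly vector
#'
#' Sequences are uppercased and IUPAC ambiguity codes (and any other
#' non-ACGTN letter) are normalized to `N`, so that downstream gap and
#' telomere accounting only ever sees the five-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record, in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgrn"), f)
#' read_fasta(f)  # "ACGNN"
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("malformed FASTA header: empty record id")
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1])
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0)) {
    bad <- ids[nchar(seqs) == 0][1]
    stop("empty sequence for record '", bad, "'")
  }
  seqs <- .normalize_bases(seqs)
  names(seqs) <- ids
  seqs
}

#' Write an assembly to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Locate runs of N in a sequence
#'
#' Returns the maximal runs of consecutive `N` of length at least `min_run`,
#' as 0-based half-open intervals, sorted and non-overlapping. With
#' `min_run = 1` the total interval length equals the N count of the
#' sequence.
#'
#' @param record A single sequence string.
#' @param min_run Minimum run length to report.
#' @param chrom Optional chromosome name to attach to the output.
#' @return data.frame with columns `start`, `end` (and `chrom` if given).
#' @export
find_n_runs <- function(record, min_run = 1L, chrom = NULL) {
  stopifnot(length(record) == 1L, min_run >= 1L)
  m <- gregexpr("N+", record)[[1]]
  if (m[1] == -1L) {
    out <- data.frame(start = integer(0), end = integer(0))
  } else {
    len <- attr(m, "match.length")
    keep <- len >= min_run
    out <- data.frame(start = as.integer(m[keep]) - 1L,
                      end = as.integer(m[keep]) - 1L + len[keep])
  }
  if (!is.null(chrom) && nrow(out) > 0) out <- cbind(chrom = chrom, out)
  else if (!is.null(chrom)) out <- data.frame(chrom = character(0),
                                              start = integer(0),
                                              end = integer(0))
  out
}

#' Read whole-genome alignment blocks from a PAF file
#'
#' Parses the 12 mandatory PAF columns into one alignment block per line.
#' Minus-strand blocks keep ascending target coordinates with the strand
#' flag, per PAF convention.
#'
#' @param path Path to a PAF file (tab separated, >= 12 columns).
#' @return data.frame with columns `query_chrom`, `query_len`,
#'   `query_start`, `query_end`, `strand`, `target_chrom`, `target_len`,
#'   `target_start`, `target_end`, `num_matches`, `block_len`, `mapq`.
#' @export
read_paf_blocks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(query_chrom = character(0), query_len = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      strand = character(0), target_chrom = character(0),
                      target_len = integer(0), target_start = integer(0),
                      target_end = integer(0), num_matches = integer(0),
                      block_len = integer(0), mapq = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("PAF parse error at line ", which(nf < 12)[1], ": fewer than 12 columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  out <- data.frame(
    query_chrom = m[, 1],
    query_len = as.numeric(m[, 2]),
    query_start = as.numeric(m[, 3]),
    query_end = as.numeric(m[, 4]),
    strand = m[, 5],
    target_chrom = m[, 6],
    target_len = as.numeric(m[, 7]),
    target_start = as.numeric(m[, 8]),
    target_end = as.numeric(m[, 9]),
    num_matches = as.numeric(m[, 10]),
    block_len = as.numeric(m[, 11]),
    mapq = as.numeric(m[, 12]))
  bad <- which(out$query_end < out$query_start | out$target_end < out$target_start)
  if (length(bad))
    stop("PAF parse error at line ", bad[1], ": end < start")
  if (!all(out$strand %in% c("+", "-")))
    stop("PAF parse error: strand column must be '+' or '-'")
  out
}

#' Write alignment blocks as PAF
#' @param blocks data.frame as returned by [read_paf_blocks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf_blocks <- function(blocks, path) {
  m <- cbind(blocks$query_chrom, blocks$query_len, blocks$query_start,
             blocks$query_end, blocks$strand, blocks$target_chrom,
             blocks$target_len, blocks$target_start, blocks$target_end,
             blocks$num_matches, blocks$block_len,
             if (is.null(blocks$mapq)) 60L else blocks$mapq)
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a multiple-alignment MAF file
#'
#' Parses `a`/`s` paragraphs. Each block becomes a data.frame with one row
#' per species row: `species` (the part of the MAF src field before the
#' first dot), `src`, `start`, `size`, `strand`, `src_length`, `text`.
#' Validates that all rows of a block have equal aligned width and that the
#' non-gap character count of each row equals its declared size.
#'
#' @param path Path to a MAF file.
#' @return List of block data.frames.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush_block <- function(cur, lineno) {
    if (is.null(cur) || nrow(cur) == 0) return(NULL)
    if (length(unique(nchar(cur$text))) != 1L)
      stop("MAF parse error near line ", lineno,
           ": rows of a block differ in aligned width")
    nongap <- nchar(gsub("-", "", cur$text, fixed = TRUE))
    if (any(nongap != cur$size))
      stop("MAF parse error near line ", lineno,
           ": non-gap character count does not match declared size")
    cur
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "a")) {
      b <- flush_block(cur, i)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- data.frame(species = character(0), src = character(0),
                        start = numeric(0), size = numeric(0),
                        strand = character(0), src_length = numeric(0),
                        text = character(0))
    } else if (startsWith(ln, "s ") || startsWith(ln, "s\t")) {
      if (is.null(cur)) stop("MAF parse error at line ", i, ": 's' before 'a'")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7) stop("MAF parse error at line ", i, ": short 's' line")
      cur <- rbind(cur, data.frame(
        species = sub("\\..*$", "", f[2]), src = f[2],
        start = as.numeric(f[3]), size = as.numeric(f[4]),
        strand = f[5], src_length = as.numeric(f[6]), text = f[7]))
    }
    # other line types (#, i, e, q, blank) are ignored
  }
  b <- flush_block(cur, length(lines))
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write MAF blocks
#' @param blocks List of block data.frames (see [read_maf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a", con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$src, as.integer(b$start),
                       as.integer(b$size), b$strand,
                       as.integer(b$src_length), b$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read probe-to-assembly hits (BLAST outfmt-6 dialect)
#'
#' Expects the 12 standard tabular columns; an optional 13th column is
#' taken as the probe (query) length. Coverage is
#' `100 * alignment_length / probe_length`; when no 13th column is present,
#' probe lengths must be supplied via `probe_lengths`. Subject coordinates
#' are normalized to ascending 0-based half-open intervals.
#'
#' @param path Path to the hit table.
#' @param probe_lengths Optional named vector of probe lengths.
#' @return data.frame with `probe_id`, `subject_chrom`, `subject_start`,
#'   `subject_end`, `identity`, `coverage`, `score`.
#' @export
read_probe_hits <- function(path, probe_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(probe_id = character(0), subject_chrom = character(0),
                      subject_start = numeric(0), subject_end = numeric(0),
                      identity = numeric(0), coverage = numeric(0),
                      score = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("hit table parse error at line ", which(nf < 12)[1],
         ": fewer than 12 columns")
  g <- function(j) vapply(fields, `[`, "", j)
  qid <- g(1)
  alen <- as.numeric(g(4))
  sstart <- as.numeric(g(9)); send <- as.numeric(g(10))
  if (all(nf >= 13)) {
    qlen <- as.numeric(g(13))
  } else {
    if (is.null(probe_lengths))
      stop("no query-length column; supply probe_lengths")
    qlen <- unname(probe_lengths[qid])
    if (anyNA(qlen)) stop("probe length missing for some hits")
  }
  data.frame(
    probe_id = qid,
    subject_chrom = g(2),
    subject_start = pmin(sstart, send) - 1,
    subject_end = pmax(sstart, send),
    identity = as.numeric(g(3)),
    coverage = 100 * alen / qlen,
    score = as.numeric(g(12)))
}

#' Read repeat annotations (RepeatMasker .out or BED + label)
#'
#' Auto-detects the format: a RepeatMasker `.out` table (whitespace
#' separated, with its two header lines) or a 4+ column BED whose fourth
#' column carries the repeat class/family label verbatim (e.g.
#' `Satellite/centr`).
#'
#' @param path Input path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `label`.
#' @export
read_repeat_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0)))
  is_rm <- grepl("^\\s*SW|^\\s*score", lines[1])
  if (is_rm) {
    body <- lines[!grepl("^\\s*(SW|score|$)", lines)]
    body <- body[!grepl("^\\s*perc", body)]
    f <- strsplit(trimws(body), "\\s+")
    nf <- lengths(f)
    if (any(nf < 11))
      stop("RepeatMasker parse error at line ", which(nf < 11)[1])
    data.frame(
      chrom = vapply(f, `[`, "", 5),
      start = as.numeric(vapply(f, `[`, "", 6)) - 1,
      end = as.numeric(vapply(f, `[`, "", 7)),
      label = vapply(f, `[`, "", 11))
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 4))
      stop("BED repeat parse error at line ", which(nf < 4)[1],
           ": need chrom, start, end, label")
    data.frame(
      chrom = vapply(f, `[`, "", 1),
      start = as.numeric(vapply(f, `[`, "", 2)),
      end = as.numeric(vapply(f, `[`, "", 3)),
      label = vapply(f, `[`, "", 4))
  }
}

#' Read single-nucleotide variants from a VCF (minimal subset)
#'
#' Reads CHROM/POS/REF/ALT/QUAL plus the GT and DP fields of the first
#' sample. INFO and other FORMAT fields are ignored. Positions are converted
#' to 0-based.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `genotype`
#'   (`hom_ref`/`het`/`hom_alt`), `qual`, `depth`, `is_snv`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  gt_raw <- tryCatch(vcfR::extract.gt(v, element = "GT")[, 1],
                     error = function(e) rep(NA_character_, nrow(fx)))
  dp_raw <- tryCatch(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1]),
                     error = function(e) rep(NA_real_, nrow(fx)))
  alleles <- gsub("[|]", "/", gt_raw)
  genotype <- rep(NA_character_, length(alleles))
  genotype[alleles %in% "0/0"] <- "hom_ref"
  split_gt <- strsplit(alleles, "/", fixed = TRUE)
  two <- lengths(split_gt) == 2
  a1 <- vapply(split_gt, function(x) x[1], "")
  a2 <- vapply(split_gt, function(x) if (length(x) >= 2) x[2] else NA_character_, "")
  genotype[two & a1 != a2] <- "het"
  genotype[two & a1 == a2 & a1 != "0" & a1 != "."] <- "hom_alt"
  ref <- fx[, "REF"]; alt <- fx[, "ALT"]
  data.frame(
    chrom = fx[, "CHROM"],
    pos = as.numeric(fx[, "POS"]) - 1,
    ref = ref,
    alt = alt,
    genotype = genotype,
    qual = suppressWarnings(as.numeric(fx[, "QUAL"])),
    depth = dp_raw,
    is_snv = nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE))
}

# rbind a list of data.frames; NULL when the list is empty
.rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, make.row.names = FALSE))
}

# Merge a set of intervals (data.frame start/end) into disjoint sorted
# intervals; intervals separated by 0 bp (abutting) merge.
.merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("start", "end")])
  ir <- IRanges::IRanges(start = df$start + 1L, end = df$end)
  red <- IRanges::reduce(ir)
  data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

#' Reverse-complement a DNA string (gaps preserved)
#' @param x Character vector of sequences (may contain `-`).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}
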