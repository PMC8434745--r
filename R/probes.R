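#' Best probe placement per probe on one assembly
#'
#' For each probe, the highest-scoring hit wins; ties break by higher
#' identity, then lexicographically smaller subject chromosome, then
#' smaller start, which makes the choice deterministic. A probe is
#' `mapped` iff its best hit has identity strictly above `min_identity`
#' and coverage strictly above `min_coverage`.
#'
#' @param hits data.frame from [read_probe_hits()].
#' @param min_identity Mapping identity threshold (strict >), percent.
#' @param min_coverage Mapping coverage threshold (strict >), percent.
#' @return data.frame, one row per probe: `probe_id`, `chrom`, `pos`
#'   (0-based hit start on the subject), `identity`, `coverage`, `mapped`.
#' @export
best_mappings <- function(hits, min_identity = 95, min_coverage = 90) {
  if (nrow(hits) == 0)
    return(data.frame(probe_id = character(0), chrom = character(0),
                      pos = numeric(0), identity = numeric(0),
                      coverage = numeric(0), mapped = logical(0)))
  ord <- order(hits$probe_id, -hits$score, -hits$identity,
               hits$subject_chrom, hits$subject_start)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$probe_id), , drop = FALSE]
  data.frame(probe_id = best$probe_id,
             chrom = best$subject_chrom,
             pos = best$subject_start,
             identity = best$identity,
             coverage = best$coverage,
             mapped = best$identity > min_identity &
               best$coverage > min_coverage,
             row.names = NULL)
}

# Longest strictly-increasing subsequence: returns indices of one LIS
# (O(n log n), deterministic: among equal-length solutions it keeps the
# one with smallest tail values, reconstructed through predecessors).
.lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- numeric(0)      # smallest tail value of an LIS of each length
  tails_idx <- integer(0)  # index achieving it
  pred <- integer(n)
  for (i in seq_len(n)) {
    # strictly increasing: find first tail >= x[i]
    j <- findInterval(x[i], tails, left.open = TRUE) + 1L
    if (j > length(tails)) {
      tails <- c(tails, x[i]); tails_idx <- c(tails_idx, i)
    } else {
      tails[j] <- x[i]; tails_idx[j] <- i
    }
    pred[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
  }
  out <- integer(length(tails))
  k <- tails_idx[length(tails)]
  for (j in rev(seq_along(tails))) { out[j] <- k; k <- pred[k] }
  out
}

#' Classify probe positional discrepancies between two assemblies
#'
#' Given one best mapping per probe on each assembly, assigns each probe
#' exactly one category:
#' \itemize{
#'   \item `unmapped_both` — mapped on neither assembly;
#'   \item `unique_to_a` / `unique_to_b` — mapped on only one;
#'   \item `diff_chr` — mapped to different chromosomes (takes precedence
#'     over the rank-order test);
#'   \item `diff_pos` — same chromosome on both, but flagged by the
#'     rank-order procedure: per chromosome, probes are ordered by their
#'     position on A and every probe outside a longest strictly-increasing
#'     subsequence of the B positions is flagged (the minimal set of probes
#'     whose removal restores collinear order);
#'   \item `consistent` — everything else.
#' }
#'
#' @param maps_a,maps_b data.frames from [best_mappings()], one row per
#'   probe, same probe set.
#' @return data.frame with `probe_id` and `category`.
#' @export
classify_discrepancies <- function(maps_a, maps_b) {
  if (anyDuplicated(maps_a$probe_id) || anyDuplicated(maps_b$probe_id))
    stop("duplicate probe_id in mappings")
  ids <- maps_a$probe_id
  if (!setequal(ids, maps_b$probe_id))
    stop("the two assemblies must carry the same probe set")
  b <- maps_b[match(ids, maps_b$probe_id), , drop = FALSE]
  a <- maps_a
  cat_out <- rep(NA_character_, length(ids))
  cat_out[!a$mapped & !b$mapped] <- "unmapped_both"
  cat_out[a$mapped & !b$mapped] <- "unique_to_a"
  cat_out[!a$mapped & b$mapped] <- "unique_to_b"
  both <- a$mapped & b$mapped
  cat_out[both & a$chrom != b$chrom] <- "diff_chr"
  same <- both & a$chrom == b$chrom
  cat_out[same] <- "consistent"
  for (ch in unique(a$chrom[same])) {
    ix <- which(same & a$chrom == ch)
    ix <- ix[order(a$pos[ix], a$probe_id[ix])]
    keep <- .lis_indices(b$pos[ix])
    flagged <- setdiff(seq_along(ix), keep)
    cat_out[ix[flagged]] <- "diff_pos"
  }
  data.frame(probe_id = ids, category = cat_out)
}

#' Find probe deserts on one assembly
#'
#' Intervals longer than `min_len` containing no mapped probe: gaps between
#' adjacent probe positions on a chromosome and, unless
#' `interior_only = TRUE`, the terminal gaps between a chromosome boundary
#' and its outermost probe. Chromosomes in `chrom_lengths` with no mapped
#' probe at all yield one whole-chromosome desert (when long enough).
#'
#' @param maps data.frame from [best_mappings()] (only `mapped` rows used).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param min_len Minimum desert length (strict >), bp.
#' @param interior_only Ignore chromosome-terminal gaps.
#' @return data.frame with `chrom`, `start`, `end`, `length`.
#' @export
find_probe_deserts <- function(maps, chrom_lengths, min_len = 1e6,
                               interior_only = FALSE) {
  maps <- maps[maps$mapped, , drop = FALSE]
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    pos <- sort(maps$pos[maps$chrom == ch])
    if (interior_only) {
      if (length(pos) < 2) next
      bounds_s <- pos[-length(pos)]; bounds_e <- pos[-1]
    } else if (length(pos) == 0) {
      bounds_s <- 0; bounds_e <- L
    } else {
      bounds_s <- c(0, pos); bounds_e <- c(pos, L)
    }
    len <- bounds_e - bounds_s
    keep <- len > min_len
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = bounds_s[keep], end = bounds_e[keep],
        length = len[keep])
  }
  res <- .rbind_all(out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0))
  res
}
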