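#' Chain collinear alignment blocks
#'
#' Groups alignment blocks (query assembly A against target assembly B)
#' into maximal runs that are collinear in both assemblies with a
#' consistent strand. Blocks whose query span is below `min_block` are
#' dropped first; a chain breaks when the query or target gap to the next
#' block exceeds `max_gap`, the target chromosome or strand changes, or
#' the target order is inconsistent with the strand.
#'
#' @param blocks data.frame of alignment blocks (see [read_paf_blocks()]).
#' @param max_gap Maximum within-chain gap on either assembly (bp).
#' @param min_block Minimum block query span (bp).
#' @return data.frame of chains: `query_chrom`, `query_start`, `query_end`,
#'   `target_chrom`, `target_start`, `target_end`, `strand`, `n_blocks`,
#'   plus a `blocks` list-column holding the member block rows.
#' @export
chain_blocks <- function(blocks, max_gap = 1e5, min_block = 1e4) {
  blocks <- blocks[blocks$query_end - blocks$query_start >= min_block, ,
                   drop = FALSE]
  blocks <- blocks[order(blocks$query_chrom, blocks$query_start), ,
                   drop = FALSE]
  chains <- list()
  if (nrow(blocks) > 0) {
    chain_id <- integer(nrow(blocks))
    cid <- 1L
    chain_id[1] <- cid
    for (i in seq_len(nrow(blocks))[-1]) {
      p <- blocks[i - 1L, ]; b <- blocks[i, ]
      ok <- b$query_chrom == p$query_chrom &&
        b$target_chrom == p$target_chrom &&
        b$strand == p$strand &&
        (b$query_start - p$query_end) <= max_gap
      if (ok) {
        if (b$strand == "+") {
          tgap <- b$target_start - p$target_end
        } else {
          tgap <- p$target_start - b$target_end
        }
        ok <- tgap <= max_gap && tgap > -(b$target_end - b$target_start)
      }
      cid <- if (ok) cid else cid + 1L
      chain_id[i] <- cid
    }
    chains <- lapply(split(seq_len(nrow(blocks)), chain_id), function(ix) {
      sub <- blocks[ix, , drop = FALSE]
      data.frame(query_chrom = sub$query_chrom[1],
                 query_start = min(sub$query_start),
                 query_end = max(sub$query_end),
                 target_chrom = sub$target_chrom[1],
                 target_start = min(sub$target_start),
                 target_end = max(sub$target_end),
                 strand = sub$strand[1],
                 n_blocks = nrow(sub))
    })
  }
  out <- .rbind_all(chains)
  if (is.null(out))
    out <- data.frame(query_chrom = character(0), query_start = numeric(0),
                      query_end = numeric(0), target_chrom = character(0),
                      target_start = numeric(0), target_end = numeric(0),
                      strand = character(0), n_blocks = integer(0))
  out <- out[order(out$query_chrom, out$query_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect large inversions and misplacements between two assemblies
#'
#' From chained alignment blocks: a minus-strand chain whose flanking
#' chains (on the same query chromosome) are plus-strand with the same
#' target chromosome is called `inverted`; a chain whose target chromosome
#' differs from that of its flanking context is called
#' `incorrectly_placed`. Only regions whose span on the target (comparison)
#' assembly reaches `min_len` are reported, and lengths are measured on the
#' target interval. Calls are putative: no orthogonal (e.g. Hi-C) evidence
#' is consulted.
#'
#' @param chains data.frame from [chain_blocks()].
#' @param min_len Minimum target-interval span (bp).
#' @return data.frame with `kind` (`inverted`/`incorrectly_placed`),
#'   `query_chrom`, `query_start`, `query_end`, `target_chrom`,
#'   `target_start`, `target_end`, `length`.
#' @export
detect_large_discrepancies <- function(chains, min_len = 1e6) {
  out <- list()
  for (qc in unique(chains$query_chrom)) {
    sub <- chains[chains$query_chrom == qc, , drop = FALSE]
    sub <- sub[order(sub$query_start), , drop = FALSE]
    n <- nrow(sub)
    # dominant partner chromosome of this query chromosome, by query span
    span_by_tgt <- tapply(sub$query_end - sub$query_start,
                          sub$target_chrom, sum)
    dominant <- names(span_by_tgt)[which.max(span_by_tgt)]
    for (i in seq_len(n)) {
      prev <- if (i > 1) sub[i - 1L, ] else NULL
      nxt <- if (i < n) sub[i + 1L, ] else NULL
      if (is.null(prev) && is.null(nxt)) next
      ctx_chrom <- unique(c(if (!is.null(prev)) prev$target_chrom,
                            if (!is.null(nxt)) nxt$target_chrom))
      ctx_strand <- c(if (!is.null(prev)) prev$strand,
                      if (!is.null(nxt)) nxt$strand)
      kind <- NULL
      if (sub$target_chrom[i] != dominant &&
          all(ctx_chrom == dominant)) {
        kind <- "incorrectly_placed"
      } else if (sub$strand[i] == "-" && all(ctx_strand == "+") &&
                 length(ctx_chrom) == 1 &&
                 ctx_chrom == sub$target_chrom[i]) {
        kind <- "inverted"
      }
      if (is.null(kind)) next
      len <- sub$target_end[i] - sub$target_start[i]
      if (len < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        kind = kind,
        query_chrom = sub$query_chrom[i], query_start = sub$query_start[i],
        query_end = sub$query_end[i],
        target_chrom = sub$target_chrom[i],
        target_start = sub$target_start[i], target_end = sub$target_end[i],
        length = len)
    }
  }
  res <- .rbind_all(out)
  if (is.null(res))
    res <- data.frame(kind = character(0), query_chrom = character(0),
                      query_start = numeric(0), query_end = numeric(0),
                      target_chrom = character(0), target_start = numeric(0),
                      target_end = numeric(0), length = numeric(0))
  res
}

#' Span of a genomic interval
#'
#' `end - start` under the half-open convention; identical to the printed
#' length convention of published discrepancy tables, whose "Length" cell
#' equals `end - start` of the printed interval.
#'
#' @param start,end Interval bounds (`end >= start`).
#' @return Span in bp.
#' @export
region_span <- function(start, end) {
  if (any(end < start)) stop("end < start")
  end - start
}

#' Summarize discrepancy regions
#'
#' @param regions data.frame with at least `kind` and `length` columns.
#' @return List with `count`, `by_kind` (named counts), `total_bp`,
#'   `total_mb` (total/1e6 rounded half-even to one decimal).
#' @export
summarize_discrepancies <- function(regions) {
  if (nrow(regions) == 0)
    return(list(count = 0L, by_kind = integer(0), total_bp = 0,
                total_mb = 0))
  total <- sum(regions$length)
  list(count = nrow(regions),
       by_kind = table(regions$kind),
       total_bp = total,
       total_mb = round(total / 1e6, 1))
}

#' Call size-filtered structural variants between two assemblies
#'
#' For each pair of consecutive blocks within a chain, the gap between the
#' aligned anchors is measured on both assemblies (`ref_gap` on the target,
#' `query_gap` on the query) and classified by gap geometry:
#' `insertion`/`deletion` when one side's gap is (near) zero,
#' `repeat_expansion`/`repeat_contraction` when both gaps are positive, and
#' `tandem_expansion`/`tandem_contraction` when the anchors overlap on one
#' side (negative gap). The variant size is `query_gap - ref_gap`. Variants
#' are retained iff `min_size <= |size| <= max_size` and
#' `max(ref_gap, query_gap) > min_gap`.
#'
#' @param blocks data.frame of alignment blocks.
#' @param min_size,max_size Size filter bounds (bp).
#' @param min_gap Retain only events where the larger gap exceeds this.
#' @param max_chain_gap,min_block Chaining parameters, see
#'   [chain_blocks()].
#' @return data.frame with `type`, `query_chrom`, `query_start`,
#'   `query_end`, `target_chrom`, `target_start`, `target_end`,
#'   `ref_gap`, `query_gap`, `size`.
#' @export
call_small_svs <- function(blocks, min_size = 50, max_size = 10000,
                           min_gap = 10, max_chain_gap = 1e5,
                           min_block = 1e4) {
  blocks <- blocks[blocks$query_end - blocks$query_start >= min_block, ,
                   drop = FALSE]
  blocks <- blocks[order(blocks$query_chrom, blocks$query_start), ,
                   drop = FALSE]
  out <- list()
  if (nrow(blocks) >= 2) {
    for (i in seq_len(nrow(blocks) - 1L)) {
      p <- blocks[i, ]; b <- blocks[i + 1L, ]
      if (b$query_chrom != p$query_chrom ||
          b$target_chrom != p$target_chrom ||
          b$strand != p$strand) next
      q_gap <- b$query_start - p$query_end
      if (q_gap > max_chain_gap) next
      r_gap <- if (p$strand == "+") b$target_start - p$target_end
               else p$target_start - b$target_end
      if (r_gap > max_chain_gap) next
      size <- q_gap - r_gap
      if (abs(size) < min_size || abs(size) > max_size) next
      if (max(r_gap, q_gap) <= min_gap) next
      type <- if (min(r_gap, q_gap) < 0) {
        if (size > 0) "tandem_expansion" else "tandem_contraction"
      } else if (min(r_gap, q_gap) <= min_gap) {
        if (size > 0) "insertion" else "deletion"
      } else {
        if (size > 0) "repeat_expansion" else "repeat_contraction"
      }
      tgt <- if (p$strand == "+") c(p$target_end, b$target_start)
             else c(b$target_end, p$target_start)
      out[[length(out) + 1L]] <- data.frame(
        type = type, query_chrom = p$query_chrom,
        query_start = p$query_end, query_end = b$query_start,
        target_chrom = p$target_chrom,
        target_start = min(tgt), target_end = max(tgt),
        ref_gap = r_gap, query_gap = q_gap, size = size)
    }
  }
  res <- .rbind_all(out)
  if (is.null(res))
    res <- data.frame(type = character(0), query_chrom = character(0),
                      query_start = numeric(0), query_end = numeric(0),
                      target_chrom = character(0), target_start = numeric(0),
                      target_end = numeric(0), ref_gap = numeric(0),
                      query_gap = numeric(0), size = numeric(0))
  res
}
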