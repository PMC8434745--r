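#' End-to-end assembly QC report
#'
#' Chains the per-module analyses over one assembly: per-chromosome
#' statistics, telomere detection, centromere filtering, completeness
#' classification, and (when a whole-genome alignment and/or probe hit
#' tables are supplied) large-discrepancy calling, small structural
#' variants and probe classification. All outputs are written as
#' plain-text TSV/BED files under `out_dir` and returned invisibly.
#'
#' @param fasta Path to the assembly FASTA (or a named character vector).
#' @param repeats Optional repeat annotation path (RepeatMasker .out or
#'   BED+label) or data.frame.
#' @param paf Optional PAF path or block data.frame (query = this
#'   assembly, target = comparison assembly).
#' @param hits_a,hits_b Optional probe hit tables (paths or data.frames)
#'   on this and the comparison assembly.
#' @param out_dir Output directory (created if missing).
#' @param min_gap_run Gap definition (minimum N-run).
#' @param end_window Completeness boundary window (bp).
#' @param min_discrepancy_len Minimum large-discrepancy span (bp).
#' @param ... Passed to [detect_telomeres()].
#' @return Invisibly, a list with every computed table.
#' @export
run_report <- function(fasta, repeats = NULL, paf = NULL,
                       hits_a = NULL, hits_b = NULL,
                       out_dir = ".", min_gap_run = 10L,
                       end_window = 500000L,
                       min_discrepancy_len = 1e6, ...) {
  assembly <- if (is.character(fasta) && length(fasta) == 1 &&
                  file.exists(fasta)) read_fasta(fasta) else fasta
  if (is.character(repeats) && length(repeats) == 1)
    repeats <- read_repeat_annotations(repeats)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comp <- assembly_completeness(assembly, repeats,
                                end_window = end_window, ...)
  rep_out <- chromosome_report(assembly, telomeres = comp$telomeres,
                               centromeres = comp$centromeres,
                               min_gap_run = min_gap_run)
  tsv <- function(df, f) write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(rep_out$per_chrom, "chromosome_stats.tsv")
  tsv(comp$calls, "completeness.tsv")
  bed <- function(df, f) {
    if (nrow(df) == 0) {
      file.create(file.path(out_dir, f))
      return(invisible())
    }
    write.table(df[, c("chrom", "start", "end")], file.path(out_dir, f),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  bed(comp$telomeres, "telomeres.bed")
  bed(comp$centromeres, "centromeres.bed")
  out <- list(report = rep_out, completeness = comp)
  if (!is.null(paf)) {
    blocks <- if (is.character(paf)) read_paf_blocks(paf) else paf
    chains <- chain_blocks(blocks)
    disc <- detect_large_discrepancies(chains,
                                       min_len = min_discrepancy_len)
    svs <- call_small_svs(blocks)
    tsv(disc, "large_discrepancies.tsv")
    tsv(svs, "structural_variants.tsv")
    out$discrepancies <- disc
    out$discrepancy_summary <- summarize_discrepancies(disc)
    out$svs <- svs
  }
  if (!is.null(hits_a) && !is.null(hits_b)) {
    ma <- if (is.character(hits_a)) best_mappings(read_probe_hits(hits_a))
          else hits_a
    mb <- if (is.character(hits_b)) best_mappings(read_probe_hits(hits_b))
          else hits_b
    calls <- classify_discrepancies(ma, mb)
    deserts <- find_probe_deserts(ma, setNames(nchar(assembly),
                                               names(assembly)))
    tsv(calls, "probe_categories.tsv")
    tsv(deserts, "probe_deserts.tsv")
    out$probe_calls <- calls
    out$probe_deserts <- deserts
  }
  invisible(out)
}
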