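# Seeded generators for every input the pipeline consumes. All functions
# take an explicit seed and restore the caller's RNG state, so identical
# arguments always give identical output regardless of surrounding code.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

# per-chromosome substream: adding chromosomes never shifts earlier ones
.sub_seed <- function(seed, index) {
  (as.integer(seed) * 1009L + as.integer(index) * 9176L) %% 2147483647L
}

.random_dna <- function(n) .random_dna_cpp(as.integer(n))[1]

# centromeric satellite monomer: fixed 30-mer, free of TTAGGG/CCCTAA on
# both strands (also across tandem junctions), so the telomere detector
# cannot cross-fire on centromeres
.SAT_MONOMER <- "CACGATGGATCAGTTGACCACTAGAGGATG"

.sat_array <- function(len) {
  substr(paste(rep(.SAT_MONOMER, ceiling(len / nchar(.SAT_MONOMER))),
               collapse = ""), 1, len)
}

#' Simulation configuration for synthetic acrocentric assemblies
#'
#' Defaults emulate the architecture the completeness analysis assumes:
#' 29 acrocentric autosomes, each with a proximal centromeric satellite
#' array and a distal telomeric `(TTAGGG)n` tract, random single-copy
#' core sequence, and a few assembly gaps (N runs). `complete_chromosomes`
#' controls how many chromosomes carry a full-length distal telomere
#' tract; the remainder get none.
#'
#' @param seed Master seed; together with the chromosome index it fully
#'   determines every output.
#' @param n_autosomes Number of chromosomes.
#' @param chrom_length Chromosome length (bp).
#' @param telomere_tract Distal telomere tract length (bp).
#' @param centromere_tract Proximal satellite array length (bp).
#' @param complete_chromosomes How many chromosomes get the telomere
#'   tract.
#' @param n_gap_runs,gap_run_length Assembly gaps per chromosome.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_autosomes = 29L, chrom_length = 1e6,
                       telomere_tract = 3000L, centromere_tract = 10000L,
                       complete_chromosomes = n_autosomes,
                       n_gap_runs = 2L, gap_run_length = 100L) {
  stopifnot(chrom_length > 2 * (telomere_tract + centromere_tract),
            complete_chromosomes <= n_autosomes)
  structure(list(seed = as.integer(seed), n_autosomes = as.integer(n_autosomes),
                 chrom_length = chrom_length,
                 telomere_tract = telomere_tract,
                 centromere_tract = centromere_tract,
                 complete_chromosomes = as.integer(complete_chromosomes),
                 n_gap_runs = as.integer(n_gap_runs),
                 gap_run_length = as.integer(gap_run_length)),
            class = "sim_config")
}

#' Simulate one acrocentric chromosome
#'
#' Layout: a short random lead-in, the proximal `Satellite/centr` array,
#' a random single-copy core with planted N gap runs, and (for complete
#' chromosomes) the distal perfect `(TTAGGG)n` tract. Companion truth
#' tables (gaps, repeats, telomere) are returned alongside the sequence.
#'
#' @param config A `sim_config`.
#' @param index Chromosome index (1-based).
#' @return List with `id`, `seq`, and truth data.frames `gaps`,
#'   `repeats` (the satellite interval, labelled `Satellite/centr`),
#'   `telomere` (empty when no tract was planted).
#' @export
simulate_chromosome <- function(config, index) {
  tel_len <- if (index <= config$complete_chromosomes)
    config$telomere_tract else 0L
  L <- config$chrom_length
  lead <- 1000L
  cen_len <- config$centromere_tract
  core_len <- L - lead - cen_len - tel_len
  if (core_len <= 0) stop("tract lengths exceed chromosome length")
  .with_seed(.sub_seed(config$seed, index), {
    core <- .random_dna(core_len)
    # plant gap runs in the middle half of the core
    if (config$n_gap_runs > 0) {
      span <- floor(core_len / 4)
      pos <- sort(sample(floor(seq(span, 3 * span - config$gap_run_length,
                                   length.out = 1000)),
                         config$n_gap_runs))
      # keep runs apart so they stay maximal
      pos <- pos + seq(0, by = 2L * config$gap_run_length,
                       length.out = config$n_gap_runs)
      for (p in pos) {
        substr(core, p + 1, p + config$gap_run_length) <-
          strrep("N", config$gap_run_length)
      }
      gap_truth <- data.frame(start = lead + cen_len + pos,
                              end = lead + cen_len + pos +
                                config$gap_run_length)
    } else {
      gap_truth <- data.frame(start = numeric(0), end = numeric(0))
    }
    seq <- paste0(.random_dna(lead), .sat_array(cen_len), core,
                  if (tel_len > 0) strrep("TTAGGG", ceiling(tel_len / 6))
                  else "")
    seq <- substr(seq, 1, L)
    id <- paste0("chr", index)
    list(id = id, seq = seq,
         gaps = cbind(chrom = id, gap_truth),
         repeats = data.frame(chrom = id, start = lead,
                              end = lead + cen_len,
                              label = "Satellite/centr"),
         telomere = if (tel_len > 0)
           data.frame(chrom = id, start = L - tel_len, end = L)
         else data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0)))
  })
}

#' Simulate a full synthetic assembly with truth tables
#'
#' @param config A `sim_config`.
#' @return List with `assembly` (named character vector), `repeats`,
#'   `gaps`, `telomeres` truth data.frames.
#' @export
simulate_assembly <- function(config) {
  chroms <- lapply(seq_len(config$n_autosomes), simulate_chromosome,
                   config = config)
  assembly <- setNames(vapply(chroms, `[[`, "", "seq"),
                       vapply(chroms, `[[`, "", "id"))
  list(assembly = assembly,
       repeats = do.call(rbind, lapply(chroms, `[[`, "repeats")),
       gaps = do.call(rbind, lapply(chroms, `[[`, "gaps")),
       telomeres = do.call(rbind, lapply(chroms, `[[`, "telomere")))
}

#' Simulate a pair of assemblies differing by planted rearrangements
#'
#' Assembly B is assembly A with planted inversions (segments reverse-
#' complemented in place) and translocations (segments excised from one
#' chromosome and appended to another). The implied alignment-block
#' structure is emitted as PAF (query = A, target = B), split into pieces
#' of `piece` bp, so downstream discrepancy calling is testable without an
#' aligner. Events must not overlap.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length (bp).
#' @param inversions List of `list(chrom =, start =, length =)`.
#' @param translocations List of
#'   `list(from =, start =, length =, to =)`.
#' @param piece Block piece size for the emitted PAF (bp).
#' @param seed Seed.
#' @return List with `a`, `b` (named character vectors), `blocks`
#'   (PAF-style data.frame), `truth` (data.frame of planted events with
#'   B-side coordinates), and `segment_map` (internal probe-lifting map).
#' @export
simulate_assembly_pair <- function(n_chrom = 3L, chrom_length = 5e6,
                                   inversions = list(),
                                   translocations = list(),
                                   piece = 2e5, seed = 1L) {
  for (ev in c(inversions, translocations))
    if (ev$start < 0 || ev$start + ev$length > chrom_length)
      stop("event does not fit its chromosome")
  # check overlap per chromosome
  evs <- rbind(
    do.call(rbind, lapply(inversions, function(e)
      data.frame(chrom = e$chrom, start = e$start, end = e$start + e$length,
                 kind = "inversion", to = e$chrom))),
    do.call(rbind, lapply(translocations, function(e)
      data.frame(chrom = e$from, start = e$start, end = e$start + e$length,
                 kind = "translocation", to = e$to))))
  if (!is.null(evs)) {
    for (ch in unique(evs$chrom)) {
      sub <- evs[evs$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("overlapping planted events on chromosome ", ch)
    }
  }
  a <- .with_seed(seed, {
    setNames(.random_dna_cpp(as.integer(rep(chrom_length, n_chrom))),
             paste0("chr", seq_len(n_chrom)))
  })
  b <- a
  # segment map rows: one collinear A->B segment
  seg <- data.frame(a_chrom = names(a), a_start = 0, a_end = chrom_length,
                    b_chrom = names(a), b_offset = 0, strand = "+",
                    stringsAsFactors = FALSE)
  # b_offset: b_pos = b_offset + (a_pos - a_start) on '+';
  #           b_pos = b_offset + (a_end - a_pos) ... handled per strand below
  split_seg <- function(seg, chrom, s, e) {
    i <- which(seg$a_chrom == chrom & seg$a_start <= s & seg$a_end >= e &
                 seg$strand == "+")
    if (length(i) != 1) stop("event must fall in one unrearranged segment")
    row <- seg[i, ]
    pre <- post <- mid <- NULL
    if (row$a_start < s)
      pre <- transform(row, a_end = s)
    if (row$a_end > e)
      post <- transform(row, a_start = e,
                        b_offset = row$b_offset + (e - row$a_start))
    mid <- transform(row, a_start = s, a_end = e,
                     b_offset = row$b_offset + (s - row$a_start))
    list(seg = rbind(seg[-i, ], pre, post), mid = mid)
  }
  truth <- data.frame(kind = character(0), a_chrom = character(0),
                      a_start = numeric(0), a_end = numeric(0),
                      b_chrom = character(0), b_start = numeric(0),
                      b_end = numeric(0), length = numeric(0))
  for (ev in inversions) {
    ch <- paste0("chr", ev$chrom)
    s <- ev$start; e <- ev$start + ev$length
    sp <- split_seg(seg, ch, s, e)
    mid <- sp$mid
    mid$strand <- "-"
    seg <- rbind(sp$seg, mid)
    bs <- mid$b_offset; be <- mid$b_offset + ev$length
    substr(b[[ch]], bs + 1, be) <- revcomp(substr(a[[ch]], s + 1, e))
    truth <- rbind(truth, data.frame(
      kind = "inverted", a_chrom = ch, a_start = s, a_end = e,
      b_chrom = ch, b_start = bs, b_end = be, length = be - bs))
  }
  for (ev in translocations) {
    ch_from <- paste0("chr", ev$from); ch_to <- paste0("chr", ev$to)
    s <- ev$start; e <- ev$start + ev$length
    sp <- split_seg(seg, ch_from, s, e)
    seg <- sp$seg
    mid <- sp$mid
    ins_at <- nchar(b[[ch_to]])
    moved <- substr(b[[ch_from]], mid$b_offset + 1,
                    mid$b_offset + ev$length)
    b[[ch_from]] <- paste0(substr(b[[ch_from]], 1, mid$b_offset),
                           substr(b[[ch_from]], mid$b_offset + ev$length + 1,
                                  nchar(b[[ch_from]])))
    b[[ch_to]] <- paste0(b[[ch_to]], moved)
    # shift every later segment on the source B chromosome left
    shift <- seg$b_chrom == ch_from & seg$b_offset >= mid$b_offset
    seg$b_offset[shift] <- seg$b_offset[shift] - ev$length
    mid$b_chrom <- ch_to
    mid$b_offset <- ins_at
    seg <- rbind(seg, mid)
    truth <- rbind(truth, data.frame(
      kind = "incorrectly_placed", a_chrom = ch_from, a_start = s,
      a_end = e, b_chrom = ch_to, b_start = ins_at,
      b_end = ins_at + ev$length, length = ev$length))
  }
  seg <- seg[order(seg$a_chrom, seg$a_start), , drop = FALSE]
  rownames(seg) <- NULL
  # emit PAF blocks: each segment split into pieces
  blocks <- list()
  b_len <- nchar(b)
  for (i in seq_len(nrow(seg))) {
    r <- seg[i, ]
    len <- r$a_end - r$a_start
    cuts <- unique(c(seq(0, len, by = piece), len))
    for (j in seq_len(length(cuts) - 1L)) {
      qs <- r$a_start + cuts[j]; qe <- r$a_start + cuts[j + 1L]
      if (r$strand == "+") {
        ts <- r$b_offset + cuts[j]; te <- r$b_offset + cuts[j + 1L]
      } else {
        ts <- r$b_offset + (len - cuts[j + 1L])
        te <- r$b_offset + (len - cuts[j])
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        query_chrom = r$a_chrom, query_len = chrom_length,
        query_start = qs, query_end = qe, strand = r$strand,
        target_chrom = r$b_chrom, target_len = b_len[[r$b_chrom]],
        target_start = ts, target_end = te,
        num_matches = qe - qs, block_len = qe - qs, mapq = 60L)
    }
  }
  blocks <- .rbind_all(blocks)
  list(a = a, b = b, blocks = blocks, truth = truth, segment_map = seg)
}

#' Simulate shotgun reads from a genome
#'
#' Uniform start positions over the concatenated genome, both strands,
#' independent substitution errors at `error_rate` per base. Read count is
#' `ceiling(coverage * genome_length / read_length)`.
#'
#' @param genome Named character vector of sequences (or one string).
#' @param coverage Mean depth.
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution error probability.
#' @param seed Seed.
#' @return Character vector of read sequences.
#' @export
simulate_reads <- function(genome, coverage, read_length = 150L,
                           error_rate = 0, seed = 1L) {
  if (coverage <= 0) stop("coverage must be positive")
  lens <- nchar(genome)
  if (read_length > max(lens)) stop("read_length exceeds genome")
  total <- sum(lens)
  n_reads <- ceiling(coverage * total / read_length)
  .with_seed(seed, {
    chrom <- sample(seq_along(genome), n_reads, replace = TRUE,
                    prob = lens)
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
      L <- lens[chrom[i]]
      s <- sample.int(L - read_length + 1L, 1L)
      r <- substr(genome[[chrom[i]]], s, s + read_length - 1L)
      if (error_rate > 0) {
        ne <- rbinom(1, read_length, error_rate)
        if (ne > 0) {
          at <- sample.int(read_length, ne)
          for (p in at) {
            cur <- substr(r, p, p)
            substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          }
        }
      }
      if (runif(1) < 0.5) r <- revcomp(r)
      reads[i] <- r
    }
    reads
  })
}

#' Simulate a SNP-probe panel over an assembly pair
#'
#' Tiles probes of `probe_len` bp at `spacing` bp along every chromosome
#' of assembly A, lifts each probe to assembly B through the pair's
#' segment map, and emits best-hit tables for both assemblies plus truth
#' labels: probes inside a planted inversion are order-discrepant
#' (`diff_pos` group), probes inside a translocated segment land on
#' another B chromosome (`diff_chr`), all others are `consistent`. Probes
#' falling in `desert_spans` (list of `list(chrom =, start =, end =)` on
#' A) are omitted, creating probe deserts.
#'
#' @param pair Output of [simulate_assembly_pair()].
#' @param spacing Probe spacing (bp).
#' @param probe_len Probe length (bp).
#' @param desert_spans Regions to leave probe-free.
#' @return List with `manifest`, `maps_a`, `maps_b` (in
#'   [best_mappings()] format) and `truth` (probe_id, group).
#' @export
simulate_probe_panel <- function(pair, spacing = 5e4, probe_len = 50L,
                                 desert_spans = list()) {
  seg <- pair$segment_map
  rows <- list()
  for (ch in names(pair$a)) {
    L <- nchar(pair$a[[ch]])
    if (spacing > L) stop("spacing exceeds chromosome length")
    pos <- seq(floor(spacing / 2), L - probe_len, by = spacing)
    for (d in desert_spans) {
      if (paste0("chr", d$chrom) == ch || identical(d$chrom, ch))
        pos <- pos[pos + probe_len <= d$start | pos >= d$end]
    }
    if (length(pos) == 0) next
    rows[[ch]] <- data.frame(
      probe_id = sprintf("%s_p%06d", ch, seq_along(pos)),
      chrom = ch, pos = pos)
  }
  manifest <- .rbind_all(rows)
  # lift to B through the segment map
  lift <- function(ch, p) {
    i <- which(seg$a_chrom == ch & seg$a_start <= p &
                 seg$a_end >= p + probe_len)
    if (length(i) != 1) return(c(NA, NA))   # probe straddles a breakpoint
    r <- seg[i, ]
    if (r$strand == "+") c(r$b_chrom, r$b_offset + (p - r$a_start))
    else c(r$b_chrom, r$b_offset + (r$a_end - p - probe_len))
  }
  lifted <- t(mapply(lift, manifest$chrom, manifest$pos))
  keep <- !is.na(lifted[, 1])
  manifest <- manifest[keep, , drop = FALSE]
  lifted <- lifted[keep, , drop = FALSE]
  mk_maps <- function(chrom, pos) data.frame(
    probe_id = manifest$probe_id, chrom = chrom, pos = as.numeric(pos),
    identity = 99.5, coverage = 100, mapped = TRUE, row.names = NULL)
  maps_a <- mk_maps(manifest$chrom, manifest$pos)
  maps_b <- mk_maps(lifted[, 1], as.numeric(lifted[, 2]))
  group <- rep("consistent", nrow(manifest))
  for (k in seq_len(nrow(pair$truth))) {
    ev <- pair$truth[k, ]
    inside <- manifest$chrom == ev$a_chrom &
      manifest$pos >= ev$a_start & manifest$pos + probe_len <= ev$a_end
    group[inside] <- if (ev$kind == "inverted") "diff_pos" else "diff_chr"
  }
  list(manifest = manifest, maps_a = maps_a, maps_b = maps_b,
       truth = data.frame(probe_id = manifest$probe_id, group = group))
}

#' Simulate Y and autosomal four-species alignments under GTR+Gamma
#'
#' Evolves iid columns down the fixed topology `((sp1,sp2),(sp3,sp4))`:
#' root states drawn from the stationary frequencies, one gamma rate
#' category per column, transitions by the model's matrix exponentials.
#' The Y partition uses the autosomal branch lengths multiplied by
#' `y_rate_multiplier`, emulating the elevated substitution rate of the
#' male-transmitted Y chromosome.
#'
#' The default model and branch lengths are the generator's fixed study
#' conditions: a transition-biased GTR with mildly AT-rich frequencies and
#' moderate gamma rate variation (shape 1.5), with ruminant-scale terminal
#' divergences of a few percent.
#'
#' @param model A `gtr_model`.
#' @param branch_lengths Length-5 autosomal branch lengths
#'   (sp1, sp2, sp3, sp4, internal).
#' @param n_autosome,n_y Column counts for the two partitions.
#' @param y_rate_multiplier Y branch-length scale factor.
#' @param species Four species names in tree order.
#' @param seed Seed.
#' @return List with `maf_a`, `maf_y` (single-block MAF lists) and
#'   `aln_a`, `aln_y` (character matrices).
#' @export
simulate_maf <- function(model = gtr_model(rates = c(1.3, 4, 1, 1.2, 4.5, 1),
                                           base_freqs = c(0.3, 0.2, 0.2, 0.3),
                                           gamma_shape = 1.5),
                         branch_lengths = c(0.05, 0.04, 0.03, 0.06, 0.02),
                         n_autosome = 1e5,
                         n_y = 1e4, y_rate_multiplier = 1.55,
                         species = c("cattle", "yak", "sheep", "goat"),
                         seed = 1L) {
  stopifnot(length(branch_lengths) == 5, all(branch_lengths >= 0))
  evolve <- function(bl, n) {
    eig <- .gtr_eigen(model)
    rates <- discrete_gamma_rates(model$gamma_shape,
                                  model$n_rate_categories)
    cat_of <- sample.int(length(rates), n, replace = TRUE)
    root <- sample.int(4L, n, replace = TRUE, prob = model$base_freqs)
    step <- function(parent, t) {
      child <- integer(length(parent))
      for (r in seq_along(rates)) {
        sel <- cat_of == r
        if (!any(sel)) next
        P <- .gtr_pmat(eig, t * rates[r])
        for (bs in 1:4) {
          idx <- sel & parent == bs
          nidx <- sum(idx)
          if (nidx)
            child[idx] <- sample.int(4L, nidx, replace = TRUE,
                                     prob = P[bs, ])
        }
      }
      child
    }
    n2 <- step(root, bl[5])
    tips <- rbind(step(root, bl[1]), step(root, bl[2]),
                  step(n2, bl[3]), step(n2, bl[4]))
    aln <- matrix(.BASES[tips], nrow = 4,
                  dimnames = list(species, NULL))
    aln
  }
  .with_seed(seed, {
    aln_a <- evolve(branch_lengths, n_autosome)
    aln_y <- evolve(branch_lengths * y_rate_multiplier, n_y)
    as_maf <- function(aln, chrom) {
      n <- ncol(aln)
      list(data.frame(
        species = species,
        src = paste0(species, ".", chrom),
        start = 0, size = n, strand = "+", src_length = n,
        text = apply(aln, 1, paste, collapse = "")))
    }
    list(maf_a = as_maf(aln_a, "chrA"), maf_y = as_maf(aln_y, "chrY"),
         aln_a = aln_a, aln_y = aln_y)
  })
}
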