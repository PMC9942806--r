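#' Simulate HiFi-like reads from a fragmented MAC genome
#'
#' Draws reads from DNA molecules realised on the simulated genome.  For
#' each read a genome point is sampled uniformly (so molecules are sampled
#' in proportion to length), and the molecule containing it is delimited by
#' activating each telomere-addition junction independently with its usage
#' probability (nearest activated `left`-side junction on the left, nearest
#' activated `right`-side junction on the right, else the contig ends).
#'
#' A read of trimmed length L drawn from a molecule of length M covers a
#' molecule end with probability `min(1, 2 L / M)` — the renewal-density
#' rate of molecule ends encountered by random fragments — so the
#' telomere-bearing read fraction converges to `2 * Lbar / M` when molecules
#' are much longer than reads.  Reads covering an end carry a telomeric
#' tract of at least `min_repeats` complete units at random rotation phase
#' (shifted-geometric tract length); reads at least as long as their
#' molecule span it entirely and carry telomeres at both ends.  C-rich
#' repeats face the molecule start on the forward strand, so every read 5'
#' tract is C-rich, as in real telomeric reads.
#'
#' @param genome A [simulate_mac_genome()] result.
#' @param n_reads Number of reads.
#' @param read_len_mean Mean trimmed (telomere-free) read length in bp
#'   (lognormal; default 8000).
#' @param read_len_sdlog Lognormal sdlog (default 0.35).
#' @param read_len_range Truncation range for trimmed read lengths
#'   (default 1--12 kbp, resampled until inside).
#' @param error_rate Per-base substitution rate in `[0, 1)` (default 0,
#'   HiFi-like; no indels).
#' @param telo_geom_p Success probability of the shifted geometric giving
#'   the number of complete telomere units beyond the minimum (default 0.3).
#' @param min_repeats Minimum complete units per simulated tract (default 3).
#' @param unit Telomere repeat unit on the C-rich strand (default
#'   `CCCTAACA`).
#' @param seed Integer seed.
#' @param emit_seq If `FALSE`, skip sequence realisation and return only the
#'   truth table and truth alignments (fast; useful for estimator studies).
#' @return An object of class `sim_reads`: list with `reads` (named
#'   character vector or `NULL`), `truth` (tibble; see Details), `paf`
#'   (tibble of 12-column truth alignments) and `params`.  Truth columns:
#'   `read_id`, `contig`, `mol_start`, `mol_end` (0-based half-open molecule
#'   interval), `start`, `end` (reference interval of the read core),
#'   `strand`, `has_telo_5p`, `has_telo_3p`, `n_repeats_5p`, `n_repeats_3p`,
#'   `core_len`, `read_len`.
#' @export
simulate_reads <- function(genome, n_reads = 1e4,
                           read_len_mean = 8000, read_len_sdlog = 0.35,
                           read_len_range = c(1000, 12000),
                           error_rate = 0,
                           telo_geom_p = 0.3, min_repeats = 3L,
                           unit = "CCCTAACA",
                           seed = 1L, emit_seq = TRUE) {
  stopifnot(inherits(genome, "sim_genome"))
  if (length(genome$contigs) == 0L || sum(nchar(genome$contigs)) == 0L) {
    abort("empty genome.")
  }
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1).")
  if (n_reads < 1L) abort("`n_reads` must be positive.")
  set.seed(seed)
  k <- nchar(unit)
  rc_unit <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  clens <- nchar(genome$contigs)
  cnames <- names(genome$contigs)

  # per-contig junction lookup, split by side
  jl <- lapply(cnames, function(cn) {
    j <- genome$junctions[genome$junctions$contig == cn, ]
    list(lpos = j$pos[j$side == "left"], lu = j$usage[j$side == "left"],
         rpos = j$pos[j$side == "right"], ru = j$usage[j$side == "right"])
  })
  names(jl) <- cnames

  # trimmed read lengths: truncated lognormal
  meanlog <- log(read_len_mean) - read_len_sdlog^2 / 2
  L <- round(rlnorm(n_reads, meanlog, read_len_sdlog))
  bad <- L < read_len_range[1] | L > read_len_range[2]
  while (any(bad)) {
    L[bad] <- round(rlnorm(sum(bad), meanlog, read_len_sdlog))
    bad <- L < read_len_range[1] | L > read_len_range[2]
  }
  L <- as.integer(L)

  ci <- sample.int(length(clens), n_reads, replace = TRUE,
                   prob = clens / sum(clens))
  g <- floor(runif(n_reads) * clens[ci])

  mol_start <- integer(n_reads); mol_end <- integer(n_reads)
  start <- integer(n_reads); end <- integer(n_reads)
  telo_left <- logical(n_reads); telo_right <- logical(n_reads)

  for (i in seq_len(n_reads)) {
    jj <- jl[[ci[i]]]
    len <- clens[ci[i]]
    gi <- g[i]
    # left boundary: nearest activated left-side junction at pos <= g
    lb <- 0L
    cand <- which(jj$lpos <= gi)
    if (length(cand)) {
      ord <- cand[order(jj$lpos[cand], decreasing = TRUE)]
      act <- runif(length(ord)) < jj$lu[ord]
      if (any(act)) lb <- jj$lpos[ord[which(act)[1]]]
    }
    rb <- len
    cand <- which(jj$rpos > gi)
    if (length(cand)) {
      ord <- cand[order(jj$rpos[cand])]
      act <- runif(length(ord)) < jj$ru[ord]
      if (any(act)) rb <- jj$rpos[ord[which(act)[1]]]
    }
    M <- rb - lb
    Li <- L[i]
    if (Li >= M) {
      start[i] <- lb; end[i] <- rb
      telo_left[i] <- TRUE; telo_right[i] <- TRUE
    } else {
      q <- min(1, 2 * Li / M)
      anchored <- runif(1) < q
      if (!anchored) {
        lo <- lb + 1L; hi <- rb - Li - 1L
        if (hi < lo) anchored <- TRUE
        else {
          u <- lo + floor(runif(1) * (hi - lo + 1L))
          start[i] <- u; end[i] <- u + Li
        }
      }
      if (anchored) {
        if (runif(1) < 0.5) {
          start[i] <- lb; end[i] <- lb + Li; telo_left[i] <- TRUE
        } else {
          start[i] <- rb - Li; end[i] <- rb; telo_right[i] <- TRUE
        }
      }
    }
    mol_start[i] <- lb; mol_end[i] <- rb
  }

  nrep_left <- ifelse(telo_left,
                      min_repeats + rgeom(n_reads, telo_geom_p), 0L)
  nrep_right <- ifelse(telo_right,
                       min_repeats + rgeom(n_reads, telo_geom_p), 0L)
  strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
  core_len <- end - start
  read_len <- core_len + k * (nrep_left + nrep_right)
  plus <- strand == "+"
  read_id <- sprintf("read%06d", seq_len(n_reads))

  truth <- tibble(
    read_id = read_id,
    contig = cnames[ci],
    mol_start = mol_start, mol_end = mol_end,
    start = start, end = end,
    strand = strand,
    has_telo_5p = ifelse(plus, telo_left, telo_right),
    has_telo_3p = ifelse(plus, telo_right, telo_left),
    n_repeats_5p = as.integer(ifelse(plus, nrep_left, nrep_right)),
    n_repeats_3p = as.integer(ifelse(plus, nrep_right, nrep_left)),
    core_len = core_len,
    read_len = as.integer(read_len)
  )

  qstart <- as.integer(k * truth$n_repeats_5p)
  paf <- tibble(
    qname = read_id, qlen = truth$read_len,
    qstart = qstart, qend = qstart + core_len,
    strand = strand,
    tname = cnames[ci], tlen = as.integer(clens[ci]),
    tstart = start, tend = end,
    nmatch = core_len, alnlen = core_len, mapq = 60L
  )

  reads <- NULL
  if (emit_seq) {
    phase5 <- sample.int(k, n_reads, replace = TRUE)
    phase3 <- sample.int(k, n_reads, replace = TRUE)
    tract_l <- ifelse(telo_left,
                      substring(strrep(unit, nrep_left + 1L), phase5,
                                phase5 + k * nrep_left - 1L), "")
    tract_r <- ifelse(telo_right,
                      substring(strrep(rc_unit, nrep_right + 1L), phase3,
                                phase3 + k * nrep_right - 1L), "")
    core <- substring(genome$contigs[ci], start + 1L, end)
    if (error_rate > 0) {
      core <- .mutate_bases(core, error_rate)
    }
    seqs <- paste0(tract_l, core, tract_r)
    neg <- which(!plus)
    if (length(neg)) {
      seqs[neg] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg])))
    }
    names(seqs) <- read_id
    reads <- seqs
  }

  structure(
    list(reads = reads, truth = truth, paf = paf,
         params = list(n_reads = n_reads, read_len_mean = read_len_mean,
                       read_len_sdlog = read_len_sdlog,
                       read_len_range = read_len_range,
                       error_rate = error_rate, telo_geom_p = telo_geom_p,
                       min_repeats = min_repeats, unit = unit, seed = seed)),
    class = "sim_reads"
  )
}

# random substitutions at a fixed per-base rate
.mutate_bases <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    nmut <- rbinom(1L, n, rate)
    if (nmut == 0L) return(s)
    pos <- sample.int(n, nmut)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("<sim_reads>", nrow(x$truth), "reads;",
      sum(x$truth$has_telo_5p | x$truth$has_telo_3p), "telomere-bearing\n")
  invisible(x)
}

#' Truth-derived read annotation of a simulation
#'
#' Builds the per-read annotation tibble that [classify_reads()] would
#' produce on error-free reads, directly from the simulation truth.  Useful
#' for estimator studies run with `emit_seq = FALSE`.
#'
#' @param sim A `sim_reads` object.
#' @return Annotation tibble with `read_id`, `read_len`, `cls`,
#'   `telo_5p_end`, `telo_3p_start`, `trimmed_len`.
#' @export
truth_annotation <- function(sim) {
  stopifnot(inherits(sim, "sim_reads"))
  k <- nchar(sim$params$unit)
  tr <- sim$truth
  tibble(
    read_id = tr$read_id,
    read_len = tr$read_len,
    cls = dplyr::case_when(
      tr$has_telo_5p & tr$has_telo_3p ~ "both_ends",
      tr$has_telo_5p ~ "five_prime",
      tr$has_telo_3p ~ "three_prime",
      TRUE ~ "none"),
    telo_5p_end = ifelse(tr$has_telo_5p, k * tr$n_repeats_5p, NA_integer_),
    telo_3p_start = ifelse(tr$has_telo_3p,
                           tr$read_len - k * tr$n_repeats_3p, NA_integer_),
    trimmed_len = tr$core_len
  )
}

#' Truth alignments of a read simulation as an alignment tibble
#'
#' Renames the truth PAF columns of a [simulate_reads()] result to the
#' alignment-record layout used by [call_atas()] (equivalent to writing the
#' PAF with [write_paf()] and re-reading it with [read_paf()]).
#'
#' @param sim A `sim_reads` object.
#' @return Alignment tibble with `read_id`, `qlen`, `qstart`, `qend`,
#'   `strand`, `contig`, `tlen`, `rstart`, `rend`, `nmatch`, `alnlen`,
#'   `mapq`, `is_primary`.
#' @export
truth_alignments <- function(sim) {
  stopifnot(inherits(sim, "sim_reads"))
  p <- sim$paf
  tibble(read_id = p$qname, qlen = p$qlen, qstart = p$qstart,
         qend = p$qend, strand = p$strand, contig = p$tname,
         tlen = p$tlen, rstart = as.integer(p$tstart),
         rend = as.integer(p$tend), nmatch = as.integer(p$nmatch),
         alnlen = as.integer(p$alnlen), mapq = p$mapq, is_primary = TRUE)
}

#' Write simulated reads to FASTQ (constant quality) with truth tables
#'
#' @param sim A [simulate_reads()] result with sequences.
#' @param fastq Output FASTQ path.
#' @param truth_tsv Optional truth TSV path.
#' @param paf Optional truth PAF path.
#' @param qual Constant quality character (default `"~"`, Q93).
#' @return `fastq`, invisibly.
#' @export
write_sim_reads <- function(sim, fastq, truth_tsv = NULL, paf = NULL,
                            qual = "~") {
  stopifnot(inherits(sim, "sim_reads"))
  if (is.null(sim$reads)) abort("simulation was run with emit_seq = FALSE.")
  con <- file(fastq, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(sim$reads), "\n", sim$reads, "\n+\n",
                    strrep(qual, nchar(sim$reads))), con)
  if (!is.null(truth_tsv)) readr::write_tsv(sim$truth, truth_tsv)
  if (!is.null(paf)) write_paf(sim$paf, paf)
  invisible(fastq)
}
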