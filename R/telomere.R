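#' Telomere repeat motif
#'
#' Describes the telomeric repeat unit used for run detection.  In
#' *Blepharisma stoltei* the unit is `CCCTAACA`; a telomeric tract on a read
#' may start at any phase of the repeat, so matching is performed against all
#' cyclic rotations of the unit (C-rich strand) and of its reverse complement
#' (G-rich strand).
#'
#' @param unit Repeat unit, a DNA string over `A`, `C`, `G`, `T`.
#' @param min_repeats Minimum number of complete units for a tract to count
#'   as a telomeric run (default 3, i.e. "at least three consecutive
#'   repeats").
#' @return An object of class `telomere_motif`: a list with elements `unit`,
#'   `min_repeats`, `rotations` (cyclic rotations of `unit`) and
#'   `rc_rotations` (cyclic rotations of the reverse complement).
#' @examples
#' telomere_motif()                      # Blepharisma default
#' telomere_motif("CCCCAA", min_repeats = 3)  # Tetrahymena unit
#' @export
telomere_motif <- function(unit = "CCCTAACA", min_repeats = 3L) {
  unit <- toupper(unit)
  if (!nzchar(unit)) abort("`unit` must be a non-empty DNA string.")
  if (grepl("[^ACGT]", unit)) {
    abort("`unit` may only contain A, C, G, T.")
  }
  min_repeats <- as.integer(min_repeats)
  if (is.na(min_repeats) || min_repeats < 1L) {
    abort("`min_repeats` must be a positive integer.")
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  structure(
    list(
      unit = unit,
      min_repeats = min_repeats,
      rotations = rotations(unit),
      rc_rotations = rotations(rc)
    ),
    class = "telomere_motif"
  )
}

#' @export
print.telomere_motif <- function(x, ...) {
  cat("<telomere_motif> unit:", x$unit,
      " min_repeats:", x$min_repeats,
      " rotations:", length(x$rotations), "\n")
  invisible(x)
}

#' Cyclic rotations of a DNA string
#'
#' @param unit A non-empty DNA string.
#' @return Character vector of all distinct cyclic rotations of `unit`.
#' @examples
#' rotations("CCCTAACA")
#' rotations("AAAA")   # a single rotation
#' @export
rotations <- function(unit) {
  unit <- toupper(unit)
  if (!nzchar(unit)) abort("`unit` must be non-empty.")
  if (grepl("[^ACGT]", unit)) abort("`unit` may only contain A, C, G, T.")
  k <- nchar(unit)
  doubled <- paste0(unit, unit)
  unique(vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L),
                character(1)))
}

# Normalise reads input (character vector, DNAStringSet, or FASTA/FASTQ path)
# to a named uppercase character vector.
.as_read_set <- function(reads) {
  if (inherits(reads, "XStringSet")) {
    out <- as.character(reads)
  } else if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
             grepl("\\.(fa|fasta|fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE)) {
    fq <- grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE)
    ss <- if (fq) Biostrings::readDNAStringSet(reads, format = "fastq")
          else Biostrings::readDNAStringSet(reads)
    out <- as.character(ss)
    # keep only the first token of FASTA/FASTQ headers
    names(out) <- sub("\\s.*$", "", names(out))
  } else if (is.character(reads)) {
    out <- reads
  } else {
    abort("`reads` must be a character vector, an XStringSet, or a FASTA/FASTQ path.")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    names(out) <- paste0("read", seq_along(out))
  }
  # byte-wise case folding: much faster than toupper() on large read sets
  chartr("acgtn", "ACGTN", out)
}

#' Find telomeric repeat runs in a set of reads
#'
#' Locates maximal substrings of each read that are substrings of the
#' infinite repetition of the motif unit (C-rich orientation) or of its
#' reverse complement (G-rich orientation), and reports those containing at
#' least `min_repeats` complete units.  Matching is exact by default; a small
#' mismatch budget can be allowed with `max_mismatch`, which merges
#' phase-consistent runs across isolated mismatched bases.
#'
#' Coordinates are 0-based half-open on the read.  The reported span is the
#' full maximal matched stretch, including flanking partial units;
#' `n_repeats` counts only complete units (`floor(span / unit length)`).
#'
#' @param reads Character vector of sequences (named by read id), a
#'   `DNAStringSet`, or a FASTA/FASTQ file path.
#' @param motif A [telomere_motif()].
#' @param max_mismatch Mismatch budget per run (default 0 = exact matching).
#' @return A tibble with columns `read_id`, `qstart`, `qend`, `n_repeats`,
#'   `orientation` (`"C-rich"` or `"G-rich"`).
#' @examples
#' find_telomere_runs(c(r1 = strrep("CCCTAACA", 4)), telomere_motif())
#' @export
find_telomere_runs <- function(reads, motif = telomere_motif(),
                               max_mismatch = 0L) {
  stopifnot(inherits(motif, "telomere_motif"))
  reads <- .as_read_set(reads)
  if (length(reads) == 0L) {
    return(tibble(read_id = character(), qstart = integer(),
                  qend = integer(), n_repeats = integer(),
                  orientation = character()))
  }
  k <- nchar(motif$unit)
  nch <- unname(nchar(reads))
  big <- paste(reads, collapse = "X")
  start_big <- cumsum(c(1L, nch[-length(nch)] + 1L))
  braw <- charToRaw(big)
  n <- length(braw)

  runs <- .periodic_regions(braw, big, n, k, motif)
  if (motif$min_repeats == 1L) {
    runs <- rbind(runs, .isolated_units(big, k, motif, runs))
  }
  if (max_mismatch > 0L && nrow(runs) > 0L) {
    runs <- .merge_mismatched(runs, big, k, motif, max_mismatch)
  }
  if (nrow(runs) == 0L) {
    return(tibble(read_id = character(), qstart = integer(),
                  qend = integer(), n_repeats = integer(),
                  orientation = character()))
  }
  runs <- runs[floor((runs$end - runs$start + 1L) / k) >= motif$min_repeats, ,
               drop = FALSE]
  if (nrow(runs) == 0L) {
    return(tibble(read_id = character(), qstart = integer(),
                  qend = integer(), n_repeats = integer(),
                  orientation = character()))
  }
  idx <- findInterval(runs$start, start_big)
  tibble(
    read_id = names(reads)[idx],
    qstart = runs$start - start_big[idx],
    qend = runs$end - start_big[idx] + 1L,
    n_repeats = as.integer(floor((runs$end - runs$start + 1L) / k)),
    orientation = runs$orientation
  ) |>
    arrange(.data$read_id, .data$qstart)
}

# Maximal regions with period k whose content matches a motif rotation.
# Within a region of period k every k-window is a cyclic rotation of the
# first window, so a single membership test classifies the whole region.
.periodic_regions <- function(braw, big, n, k, motif) {
  empty <- data.frame(start = integer(), end = integer(),
                      orientation = character())
  if (n <= k) return(empty)
  per <- braw[(k + 1L):n] == braw[1L:(n - k)]
  n2 <- length(per)
  len_min <- max(k * (motif$min_repeats - 1L), 1L)
  if (len_min >= 2L && n2 > len_min) {
    # Long-run detection without enumerating every run: a stretch of
    # len_min consecutive TRUEs adds nothing to cumsum(!per), so equal
    # cumsum values len_min apart mark windows inside qualifying runs.
    cs <- cumsum(!per)
    idx <- which(cs[(len_min + 1L):n2] == cs[1L:(n2 - len_min)])
    if (cs[len_min] == 0L) idx <- c(0L, idx)   # qualifying run at position 1
    if (length(idx) == 0L) return(empty)
    brk <- which(diff(idx) > 1L)
    grp_first <- idx[c(1L, brk + 1L)]
    grp_last <- idx[c(brk, length(idx))]
    a <- grp_first + 1L
    run_end <- grp_last + len_min
  } else {
    r <- rle(per)
    run_end_all <- cumsum(r$lengths)
    keep <- r$values & r$lengths >= len_min
    if (!any(keep)) return(empty)
    a <- (run_end_all - r$lengths + 1L)[keep]    # first TRUE index in `per`
    run_end <- run_end_all[keep]
  }
  region_start <- a                              # 1-based in big
  region_end <- run_end + k                      # inclusive
  win <- substring(big, region_start, region_start + k - 1L)
  ori <- rep(NA_character_, length(win))
  ori[win %in% motif$rotations] <- "C-rich"
  ori[is.na(ori) & win %in% motif$rc_rotations] <- "G-rich"
  ok <- !is.na(ori)
  data.frame(start = region_start[ok], end = region_end[ok],
             orientation = ori[ok])
}

# Single-unit exact matches not already inside a periodic region; only
# relevant when min_repeats == 1.
.isolated_units <- function(big, k, motif, regions) {
  pats <- c(motif$rotations, motif$rc_rotations)
  ori_of <- c(rep("C-rich", length(motif$rotations)),
              rep("G-rich", length(motif$rc_rotations)))
  hits <- lapply(seq_along(pats), function(i) {
    m <- gregexpr(pats[[i]], big, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m), end = as.integer(m) + k - 1L,
               orientation = ori_of[[i]])
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      orientation = character()))
  }
  if (nrow(regions) > 0L) {
    covered <- vapply(seq_len(nrow(hits)), function(i) {
      any(hits$start[i] >= regions$start & hits$end[i] <= regions$end)
    }, logical(1))
    hits <- hits[!covered, , drop = FALSE]
  }
  unique(hits)
}

# Greedy merging of same-orientation runs across isolated mismatches, used
# only when max_mismatch > 0.  Two runs merge when they lie on the same
# global tiling phase of the unit and the gap (every gap base counted as a
# mismatch) fits in the remaining budget.
.merge_mismatched <- function(runs, big, k, motif, budget) {
  runs <- runs[order(runs$start), , drop = FALSE]
  tiling_phase <- function(start, orientation) {
    tab <- if (orientation == "C-rich") motif$rotations else motif$rc_rotations
    r <- match(substring(big, start, start + k - 1L), tab) - 1L
    (r - start + 1L) %% k
  }
  runs$phase <- vapply(seq_len(nrow(runs)), function(i) {
    tiling_phase(runs$start[i], runs$orientation[i])
  }, integer(1))
  out <- list()
  cur <- runs[1, ]
  used <- 0L
  for (i in seq_len(nrow(runs))[-1]) {
    nxt <- runs[i, ]
    gap <- nxt$start - cur$end - 1L
    same_frame <- !is.na(cur$phase) && !is.na(nxt$phase) &&
      nxt$phase == cur$phase
    if (nxt$orientation == cur$orientation && gap >= 0L && same_frame &&
        used + gap <= budget) {
      used <- used + gap
      cur$end <- nxt$end
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
      used <- 0L
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

#' Find telomeric runs in a single sequence
#'
#' Convenience wrapper around [find_telomere_runs()] for one sequence.
#'
#' @param seq A single DNA string.
#' @inheritParams find_telomere_runs
#' @return A tibble of runs with `qstart`/`qend` (0-based half-open),
#'   `n_repeats` and `orientation`.
#' @export
find_runs <- function(seq, motif = telomere_motif(), max_mismatch = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  find_telomere_runs(c(seq1 = seq), motif, max_mismatch = max_mismatch) |>
    select(-"read_id")
}

#' Classify reads by telomere content
#'
#' Assigns each read a class from its telomeric runs: `none`, `five_prime`,
#' `three_prime`, `both_ends`, or `internal_only`.  A run is *terminal* when
#' it starts (ends) within `end_tol` bases of the corresponding read end.  A
#' read is telomere-bearing iff its class is not `none`.
#'
#' @param runs Tibble of runs from [find_telomere_runs()].
#' @param read_lens Named integer vector of read lengths (all reads,
#'   including those without runs).
#' @param end_tol Distance from a read end within which a run counts as
#'   terminal (default 50 bp, allowing for adapter remnants).
#' @return A tibble with one row per read: `read_id`, `read_len`, `cls`,
#'   `n_runs`, `telo_5p_end` (qend of the terminal 5' run, `NA` if none),
#'   `telo_3p_start`, and `trimmed_len` (read length excluding terminal
#'   telomeric spans).
#' @export
classify_reads <- function(runs, read_lens, end_tol = 50L) {
  if (is.null(names(read_lens))) abort("`read_lens` must be named by read id.")
  if (nrow(runs) > 0L) {
    bad <- !(runs$read_id %in% names(read_lens))
    if (any(bad)) abort("runs refer to reads absent from `read_lens`.")
    rl <- read_lens[runs$read_id]
    if (any(runs$qend > rl)) abort("run coordinates exceed read length.")
    per_read <- runs |>
      mutate(rl = rl,
             t5 = .data$qstart <= end_tol,
             t3 = (.data$rl - .data$qend) <= end_tol) |>
      group_by(.data$read_id) |>
      summarise(
        n_runs = n(),
        telo_5p_end = if (any(.data$t5)) max(.data$qend[.data$t5]) else NA_integer_,
        telo_3p_start = if (any(.data$t3)) min(.data$qstart[.data$t3]) else NA_integer_,
        .groups = "drop"
      )
  } else {
    per_read <- tibble(read_id = character(), n_runs = integer(),
                       telo_5p_end = integer(), telo_3p_start = integer())
  }
  ann <- tibble(read_id = names(read_lens),
                read_len = as.integer(unname(read_lens))) |>
    left_join(per_read, by = "read_id") |>
    mutate(
      n_runs = ifelse(is.na(.data$n_runs), 0L, .data$n_runs),
      cls = dplyr::case_when(
        n_runs == 0L ~ "none",
        !is.na(telo_5p_end) & !is.na(telo_3p_start) ~ "both_ends",
        !is.na(telo_5p_end) ~ "five_prime",
        !is.na(telo_3p_start) ~ "three_prime",
        TRUE ~ "internal_only"
      ),
      trimmed_len = pmax(
        0L,
        ifelse(is.na(.data$telo_3p_start), .data$read_len, .data$telo_3p_start) -
          ifelse(is.na(.data$telo_5p_end), 0L, .data$telo_5p_end)
      )
    )
  ann
}

#' Scan reads for telomeres and classify them
#'
#' One-stop wrapper: finds runs with [find_telomere_runs()] and classifies
#' reads with [classify_reads()].
#'
#' @inheritParams find_telomere_runs
#' @inheritParams classify_reads
#' @return A list with elements `annotation` (per-read tibble) and `runs`
#'   (per-run tibble).
#' @export
scan_telomeres <- function(reads, motif = telomere_motif(), end_tol = 50L,
                           max_mismatch = 0L) {
  reads <- .as_read_set(reads)
  runs <- find_telomere_runs(reads, motif, max_mismatch = max_mismatch)
  ann <- classify_reads(runs, setNames(nchar(reads), names(reads)),
                        end_tol = end_tol)
  list(annotation = ann, runs = runs)
}

#' Trim terminal telomeric tracts from reads
#'
#' Removes the full matched span (including partial units) of terminal runs
#' from each read, so that read lengths excluding telomeres can be measured.
#'
#' @param reads Character vector, `DNAStringSet` or FASTA/FASTQ path.
#' @param annotation Per-read annotation from [classify_reads()] /
#'   [scan_telomeres()].
#' @return A tibble with `read_id`, `seq` (trimmed sequence), `left_cut`,
#'   `right_cut` (bases removed at each end); `trimmed length + cuts` equals
#'   the original read length.
#' @export
trim_telomeres <- function(reads, annotation) {
  reads <- .as_read_set(reads)
  ann <- annotation[match(names(reads), annotation$read_id), ]
  if (any(is.na(ann$read_id))) abort("annotation missing for some reads.")
  left <- ifelse(is.na(ann$telo_5p_end), 0L, ann$telo_5p_end)
  right_start <- ifelse(is.na(ann$telo_3p_start), ann$read_len,
                        ann$telo_3p_start)
  right_start <- pmax(right_start, left)
  tibble(
    read_id = names(reads),
    seq = unname(substring(reads, left + 1L, right_start)),
    left_cut = as.integer(left),
    right_cut = as.integer(ann$read_len - right_start)
  )
}
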