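#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns; optional SAM-style tags are scanned
#' for `tp:A:` to distinguish primary (`P`) from secondary/supplementary
#' alignments (records without the tag are taken as primary).
#'
#' @param path Path to a PAF file.
#' @return Tibble of alignment records: `read_id`, `qlen`, `qstart`, `qend`
#'   (0-based half-open on the query), `strand`, `contig`, `tlen`, `rstart`,
#'   `rend` (0-based half-open on the reference), `nmatch`, `alnlen`,
#'   `mapq`, `is_primary`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), qlen = integer(), qstart = integer(),
                  qend = integer(), strand = character(), contig = character(),
                  tlen = integer(), rstart = integer(), rend = integer(),
                  nmatch = integer(), alnlen = integer(), mapq = integer(),
                  is_primary = logical()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    abort(sprintf("PAF line %d has fewer than 12 fields.", which(nf < 12L)[1]))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  is_primary <- vapply(parts, function(p) {
    tags <- p[-(1:12)]
    tp <- tags[startsWith(tags, "tp:A:")]
    if (length(tp) == 0L) TRUE else substring(tp[1], 6, 6) == "P"
  }, logical(1))
  tibble(
    read_id = col(1), qlen = as.integer(col(2)),
    qstart = as.integer(col(3)), qend = as.integer(col(4)),
    strand = col(5), contig = col(6), tlen = as.integer(col(7)),
    rstart = as.integer(col(8)), rend = as.integer(col(9)),
    nmatch = as.integer(col(10)), alnlen = as.integer(col(11)),
    mapq = as.integer(col(12)), is_primary = is_primary
  )
}

#' Write alignments as PAF
#'
#' @param aln Tibble with the columns produced by [simulate_reads()]
#'   (`qname`/`read_id`, `qlen`, `qstart`, `qend`, `strand`,
#'   `tname`/`contig`, `tlen`, `tstart`/`rstart`, `tend`/`rend`, `nmatch`,
#'   `alnlen`, `mapq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  pick <- function(a, b) if (a %in% names(aln)) aln[[a]] else aln[[b]]
  m <- cbind(pick("qname", "read_id"), aln$qlen, aln$qstart, aln$qend,
             aln$strand, pick("tname", "contig"), aln$tlen,
             pick("tstart", "rstart"), pick("tend", "rend"),
             aln$nmatch, aln$alnlen, aln$mapq)
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read alignments from a SAM/BAM file
#'
#' Converts coordinate information from a SAM/BAM file into the alignment
#' tibble used by [call_atas()].  Query coordinates on the original read are
#' recovered from soft/hard clip lengths in the CIGAR string.  Requires the
#' Rsamtools package.
#'
#' @param path Path to a SAM or BAM file.
#' @return Alignment tibble as for [read_paf()].
#' @export
read_aln_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("read_aln_sam() requires the Rsamtools package.")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(b$pos)
  flag <- b$flag[keep]
  cigar <- b$cigar[keep]
  ref_len <- .cigar_ref_len(cigar)
  qcoord <- .cigar_query_span(cigar, bitwAnd(flag, 16L) > 0L)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  tibble(
    read_id = b$qname[keep],
    qlen = qcoord$qlen,
    qstart = qcoord$qstart, qend = qcoord$qend,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    contig = as.character(b$rname[keep]),
    tlen = as.integer(hdr[as.character(b$rname[keep])]),
    rstart = b$pos[keep] - 1L,
    rend = b$pos[keep] - 1L + ref_len,
    nmatch = NA_integer_, alnlen = ref_len,
    mapq = as.integer(b$mapq[keep]),
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  )
}

.cigar_ops <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

.cigar_ref_len <- function(cigar) {
  vapply(.cigar_ops(cigar), function(x) {
    sum(x$len[x$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

# query span of the aligned part on the ORIGINAL read orientation
.cigar_query_span <- function(cigar, is_rev) {
  res <- vapply(.cigar_ops(cigar), function(x) {
    qa <- sum(x$len[x$op %in% c("M", "I", "=", "X")])
    lead <- if (x$op[1] %in% c("S", "H")) x$len[1] else 0L
    last <- length(x$op)
    trail <- if (x$op[last] %in% c("S", "H")) x$len[last] else 0L
    c(qa, lead, trail)
  }, integer(3))
  qlen <- res[1, ] + res[2, ] + res[3, ]
  qstart <- ifelse(is_rev, res[3, ], res[2, ])
  tibble(qlen = as.integer(qlen), qstart = as.integer(qstart),
         qend = as.integer(qstart + res[1, ]))
}

#' Call alternative telomere addition sites (ATASs)
#'
#' For every telomere-bearing read whose terminal telomeric run abuts its
#' aligned query interval (within `junction_tol`), one junction is emitted
#' at the strand-appropriate reference boundary: a 5' telomere on a `+`
#' alignment puts the junction at `rstart` with side `left` (the telomere
#' extends toward decreasing coordinates); on a `-` alignment at `rend`
#' with side `right`; symmetrically for 3' telomeres.  Identical
#' `(contig, pos, side)` junctions are aggregated, and coverage is counted
#' over all qualifying primary alignments spanning the position.  Sites with
#' telomere fraction >= `terminus_frac` lying within `end_margin` of a
#' contig end are flagged as contig termini rather than ATASs.
#'
#' @param annotation Per-read annotation from [classify_reads()] (needs
#'   `read_id`, `cls`, `telo_5p_end`, `telo_3p_start`, `read_len`).
#' @param aln Alignment tibble from [read_paf()] / [read_aln_sam()]; only
#'   primary alignments are used.
#' @param junction_tol Max distance (bp) between the terminal run and the
#'   aligned query interval (default 20).
#' @param min_mapq Minimum mapping quality (default 0).
#' @param end_margin Distance (bp) from a contig end within which a site can
#'   be a contig terminus (default 100).
#' @param terminus_frac Telomere fraction at or above which an end-proximal
#'   site is labelled a terminus (default 0.5).
#' @param contig_lens Optional named vector of contig lengths; taken from
#'   the alignment `tlen` column when absent.
#' @return Tibble of calls: `contig`, `pos` (0-based), `pos1` (1-based, for
#'   human reading), `side`, `n_support`, `n_cover`, `telo_frac`,
#'   `is_contig_end`, `is_terminus`.
#' @export
call_atas <- function(annotation, aln, junction_tol = 20L, min_mapq = 0L,
                      end_margin = 100L, terminus_frac = 0.5,
                      contig_lens = NULL) {
  if (junction_tol < 0L) abort("`junction_tol` must be >= 0.")
  unknown <- setdiff(aln$read_id, annotation$read_id)
  if (length(unknown)) {
    warn(sprintf("%d alignments refer to reads absent from the annotation; skipped.",
                 length(unknown)))
    aln <- aln[aln$read_id %in% annotation$read_id, ]
  }
  aln <- aln[aln$is_primary & aln$mapq >= min_mapq, ]
  if (is.null(contig_lens)) {
    contig_lens <- c(tapply(aln$tlen, aln$contig, max))
  }
  a <- left_join(aln,
                 annotation[, c("read_id", "cls", "telo_5p_end",
                                "telo_3p_start", "read_len")],
                 by = "read_id")

  # 5' telomere junctions
  j5 <- a |>
    filter(!is.na(.data$telo_5p_end),
           abs(.data$qstart - .data$telo_5p_end) <= junction_tol) |>
    mutate(pos = as.integer(ifelse(.data$strand == "+", .data$rstart,
                                   .data$rend)),
           side = as.character(ifelse(.data$strand == "+", "left", "right")))
  # 3' telomere junctions
  j3 <- a |>
    filter(!is.na(.data$telo_3p_start),
           abs(.data$qend - .data$telo_3p_start) <= junction_tol) |>
    mutate(pos = as.integer(ifelse(.data$strand == "+", .data$rend,
                                   .data$rstart)),
           side = as.character(ifelse(.data$strand == "+", "right", "left")))

  jn <- bind_rows(j5, j3)
  if (nrow(jn) == 0L) {
    return(tibble(contig = character(), pos = integer(), pos1 = integer(),
                  side = character(), n_support = integer(),
                  n_cover = integer(), telo_frac = double(),
                  is_contig_end = logical(), is_terminus = logical()))
  }
  calls <- jn |>
    count(.data$contig, .data$pos, .data$side, name = "n_support")

  # coverage: qualifying primary alignments with rstart <= pos <= rend
  calls$n_cover <- 0L
  for (cn in unique(calls$contig)) {
    ii <- which(calls$contig == cn)
    sub <- aln[aln$contig == cn, ]
    cov <- IRanges::countOverlaps(
      IRanges::IRanges(start = calls$pos[ii], width = 1L),
      IRanges::IRanges(start = sub$rstart, end = sub$rend))
    calls$n_cover[ii] <- cov
  }
  calls |>
    mutate(
      telo_frac = .data$n_support / pmax(.data$n_cover, 1L),
      is_contig_end = .data$pos <= end_margin |
        .data$pos >= (as.vector(contig_lens[.data$contig]) - end_margin),
      is_terminus = .data$is_contig_end & .data$telo_frac >= terminus_frac,
      pos1 = .data$pos + 1L
    ) |>
    select("contig", "pos", "pos1", "side", "n_support", "n_cover",
           "telo_frac", "is_contig_end", "is_terminus") |>
    arrange(.data$contig, .data$pos, .data$side)
}

#' Summarise ATAS calls
#'
#' Counts total and singleton (single supporting read) ATASs; contig-end
#' telomere sites (`is_terminus`) are excluded first.
#'
#' @param calls Call tibble from [call_atas()].
#' @return One-row tibble: `n_total`, `n_singleton`, `singleton_frac`
#'   (0 when there are no calls).
#' @export
summarize_atas <- function(calls) {
  calls <- calls[!calls$is_terminus, , drop = FALSE]
  n_total <- nrow(calls)
  n_singleton <- sum(calls$n_support == 1L)
  tibble(n_total = n_total, n_singleton = n_singleton,
         singleton_frac = if (n_total > 0L) n_singleton / n_total else 0)
}

#' Per-contig ATAS density
#'
#' @param calls Call tibble from [call_atas()].
#' @param contig_lens Named vector of contig lengths (bp).
#' @return Tibble: `contig`, `n_atas`, `len_bp`, `per_kbp`.
#' @export
atas_density <- function(calls, contig_lens) {
  calls <- calls[!calls$is_terminus, , drop = FALSE]
  tibble(contig = names(contig_lens),
         len_bp = as.integer(unname(contig_lens))) |>
    left_join(count(calls, .data$contig, name = "n_atas"), by = "contig") |>
    mutate(n_atas = ifelse(is.na(.data$n_atas), 0L, .data$n_atas),
           per_kbp = .data$n_atas / (.data$len_bp / 1000)) |>
    select("contig", "n_atas", "len_bp", "per_kbp")
}

#' Write ATAS calls as BED
#'
#' BED is 0-based half-open; the side is written in the strand column
#' (`left` as `-`, `right` as `+`).
#'
#' @param calls Call tibble from [call_atas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atas_bed <- function(calls, path) {
  m <- cbind(calls$contig, calls$pos, calls$pos + 1L,
             sprintf("ATAS_%s_%d_%s", calls$contig, calls$pos, calls$side),
             calls$n_support, ifelse(calls$side == "left", "-", "+"))
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}
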