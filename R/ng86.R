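#' Build a pairwise codon alignment
#'
#' Validates two equal-length coding sequences, removes codon columns that
#' are gapped or ambiguous in either sequence (complete deletion of gapped
#' codons), and checks that no internal stop codons remain.
#'
#' @param s1,s2 DNA strings of equal length divisible by 3 (gaps `-`
#'   allowed in whole-codon units).
#' @param code A [genetic_code()].
#' @return An object of class `codon_alignment`: list with `s1`, `s2`
#'   (codon character vectors), `n_codons`, `n_dropped`, `code`.
#' @export
codon_alignment <- function(s1, s2, code = genetic_code("standard")) {
  s1 <- toupper(s1); s2 <- toupper(s2)
  if (nchar(s1) != nchar(s2)) abort("sequences must have equal length.")
  if (nchar(s1) %% 3 != 0) abort("alignment length must be divisible by 3.")
  c1 <- .split_codons(s1); c2 <- .split_codons(s2)
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  n_dropped <- sum(!clean)
  c1 <- c1[clean]; c2 <- c2[clean]
  if (any(c1 %in% code$stops) || any(c2 %in% code$stops)) {
    abort("internal stop codon in codon alignment.")
  }
  structure(list(s1 = c1, s2 = c2, n_codons = length(c1),
                 n_dropped = n_dropped, code = code),
            class = "codon_alignment")
}

.split_codons <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites per codon as the synonymous
#' fraction of valid single-nucleotide neighbours (stop codons are excluded
#' from the mutational opportunity), averages site counts across the two
#' sequences, averages observed differences over all minimal mutational
#' pathways that avoid stop codons (equal pathway weighting), and applies
#' the Jukes-Cantor correction `d = -3/4 log(1 - 4 p / 3)` to the
#' proportions.  Proportions at or beyond the JC saturation point (3/4)
#' yield `NA` distances with a saturation flag.
#'
#' @param x A [codon_alignment()], or a DNA string (with `y`).
#' @param y Second DNA string when `x` is a string.
#' @param code A [genetic_code()]; ignored when `x` is a `codon_alignment`.
#' @return One-row tibble: `n_codons`, `N`, `S` (site counts,
#'   `N + S = 3 * n_codons`), `Nd`, `Sd` (pathway-averaged differences),
#'   `pN`, `pS`, `dN`, `dS`, `omega`, `dn_saturated`, `ds_saturated`.
#' @examples
#' cd <- genetic_code("standard")
#' ng86("TTTGCT", "TTCGCT", code = cd)
#' @export
ng86 <- function(x, y = NULL, code = genetic_code("standard")) {
  if (!inherits(x, "codon_alignment")) {
    if (is.null(y)) abort("provide a codon_alignment or two sequences.")
    x <- codon_alignment(x, y, code)
  }
  code <- x$code
  if (x$n_codons == 0L) abort("zero aligned codons.")
  sites <- .ng_sites(code)
  S <- (sum(sites[x$s1]) + sum(sites[x$s2])) / 2
  N <- 3 * x$n_codons - S
  di <- .ng_diffs(code)
  idx <- cbind(match(x$s1, code$sense), match(x$s2, code$sense))
  Nd <- sum(di$nd[idx])
  Sd <- sum(di$sd[idx])
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  dN <- .jc_correct(pN)
  dS <- .jc_correct(pS)
  tibble(
    n_codons = x$n_codons, N = N, S = S, Nd = Nd, Sd = Sd,
    pN = pN, pS = pS, dN = dN, dS = dS,
    omega = omega(dN, dS),
    dn_saturated = is.na(dN), ds_saturated = is.na(dS)
  )
}

.jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' dN/dS ratio with degenerate-case markers
#'
#' @param dN,dS Nonnegative corrected distances (`NA` allowed).
#' @return `dN / dS` when `dS > 0`; `NA` when both are zero (undefined);
#'   `Inf` when `dN > 0` and `dS = 0`.
#' @examples
#' omega(0.02, 0.2)  # 0.1
#' omega(0, 0)       # NA (undefined)
#' omega(0.1, 0)     # Inf
#' @export
omega <- function(dN, dS) {
  if (is.na(dN) || is.na(dS)) return(NA_real_)
  if (dN < 0 || dS < 0) abort("`dN` and `dS` must be >= 0.")
  if (dS > 0) return(dN / dS)
  if (dN == 0) return(NA_real_)
  Inf
}

#' Thread coding sequences through a protein alignment
#'
#' Builds a pairwise codon alignment by placing each sequence's codons at
#' the positions of its residues in the gapped protein alignment
#' (back-translation threading), then dropping columns gapped in either
#' sequence.  A terminal stop codon on the CDS is stripped; under codes
#' where the codon is not a stop (e.g. TGA under `UGA_to_Trp`) it is kept
#' and must match the aligned residue.
#'
#' @param protein_aln Named character vector of two aligned protein
#'   sequences (equal width, `-` gaps).
#' @param cds Named character vector of coding sequences (DNA), names
#'   matching `protein_aln`.
#' @param code A [genetic_code()].
#' @return A [codon_alignment()].
#' @export
back_align <- function(protein_aln, cds, code = genetic_code("standard")) {
  if (length(protein_aln) != 2L) {
    abort("`protein_aln` must contain exactly two sequences.")
  }
  ids <- names(protein_aln)
  if (is.null(ids) || !all(ids %in% names(cds))) {
    abort("sequence ids missing from `cds`.")
  }
  if (nchar(protein_aln[[1]]) != nchar(protein_aln[[2]])) {
    abort("aligned proteins must have equal width.")
  }
  threaded <- lapply(ids, function(id) {
    .thread_one(protein_aln[[id]], cds[[id]], id, code)
  })
  codon_alignment(paste(threaded[[1]], collapse = ""),
                  paste(threaded[[2]], collapse = ""), code)
}

.thread_one <- function(paln, cds, id, code) {
  paln <- toupper(paln); cds <- toupper(cds)
  res <- strsplit(paln, "", fixed = TRUE)[[1]]
  prot <- res[res != "-"]
  lp <- length(prot)
  codons <- .split_codons(cds)
  if (length(codons) == lp + 1L && codons[length(codons)] %in% code$stops) {
    codons <- codons[-length(codons)]
  }
  if (length(codons) != lp) {
    abort(sprintf("CDS length for %s (%d codons) does not match its %d aligned residues.",
                  id, length(codons), lp))
  }
  aa <- unname(code$map[codons])
  bad <- which(!is.na(aa) & aa != prot & prot != "X")
  if (length(bad)) {
    abort(sprintf("translation mismatch for %s at residue %d: codon %s (%s) vs residue %s.",
                  id, bad[1], codons[bad[1]], aa[bad[1]], prot[bad[1]]))
  }
  out <- rep("---", length(res))
  out[res != "-"] <- codons
  out
}

#' Pairwise dN/dS screen against a reference sequence
#'
#' Runs [back_align()] + [ng86()] for each listed sequence against the
#' reference, using a shared multiple protein alignment.  Columns where the
#' pair is entirely gapped are dropped per pair.  Pairs that fail (missing
#' CDS, translation mismatch, saturation at the alignment level) are
#' recorded as `NA` rows.
#'
#' @param reference_id Id of the reference protein (e.g. the catalytically
#'   complete PiggyBac homolog).
#' @param others Character vector of comparison ids.
#' @param protein_aln Named character vector of aligned proteins (must
#'   include the reference and all `others`).
#' @param cds Named character vector of coding sequences.
#' @param code A [genetic_code()].
#' @return Tibble with one row per pair (`id1`, `id2`, then the [ng86()]
#'   columns), in the order of `others`.
#' @export
pairwise_dnds <- function(reference_id, others, protein_aln, cds,
                          code = genetic_code("standard")) {
  if (!reference_id %in% names(protein_aln)) {
    abort("`reference_id` missing from the alignment.")
  }
  rows <- lapply(others, function(id) {
    base <- tibble(id1 = reference_id, id2 = id)
    res <- tryCatch({
      if (!id %in% names(protein_aln)) abort("missing from alignment")
      pair <- protein_aln[c(reference_id, id)]
      ng86(back_align(pair, cds, code))
    }, error = function(e) NULL)
    if (is.null(res)) {
      res <- tibble(n_codons = NA_integer_, N = NA_real_, S = NA_real_,
                    Nd = NA_real_, Sd = NA_real_, pN = NA_real_,
                    pS = NA_real_, dN = NA_real_, dS = NA_real_,
                    omega = NA_real_, dn_saturated = NA, ds_saturated = NA)
    }
    dplyr::bind_cols(base, res)
  })
  bind_rows(rows)
}
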