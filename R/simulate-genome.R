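#' Simulate a fragmented somatic (MAC) genome with telomere-addition junctions
#'
#' Generates an AT-rich assembly of `n_contigs` contigs and plants internal
#' telomere-addition junctions along each contig.  Each junction has a side
#' (`left`: molecules starting at the junction and extending rightwards;
#' `right`: molecules ending at the junction) and a usage probability, the
#' per-molecule chance that the junction delimits the DNA molecule.  Reads
#' simulated from this genome ([simulate_reads()]) then carry telomeres at
#' molecule ends, so junction positions are recoverable as alternative
#' telomere addition sites.
#'
#' @param n_contigs Number of contigs.
#' @param contig_len Contig length(s) in bp (recycled to `n_contigs`).
#' @param junction_density Expected junctions per bp (Poisson); 0 plants no
#'   junctions, leaving only contig-end telomeres.
#' @param n_junctions Optional exact total junction count, allocated to
#'   contigs in proportion to length (overrides the Poisson draw implied by
#'   `junction_density`).
#' @param usage_range Range of per-junction usage probabilities, drawn
#'   uniformly; both ends must lie in (0, 1].
#' @param at_frac Genome AT fraction (default 0.66, typical of ciliate MAC
#'   genomes).
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @return An object of class `sim_genome`: a list with `contigs` (named
#'   character vector of sequences), `junctions` (tibble: `contig`, `pos`
#'   0-based, `side`, `usage`), and `params`.
#' @examples
#' g <- simulate_mac_genome(n_contigs = 2, contig_len = 2e4,
#'                          junction_density = 1e-3, seed = 1)
#' nrow(g$junctions)
#' @export
simulate_mac_genome <- function(n_contigs = 5L,
                                contig_len = 1e5,
                                junction_density = 4e-4,
                                usage_range = c(0.02, 0.3),
                                at_frac = 0.66,
                                n_junctions = NULL,
                                seed = 1L) {
  if (n_contigs < 1L) abort("`n_contigs` must be positive.")
  contig_len <- as.integer(rep_len(contig_len, n_contigs))
  if (any(contig_len <= 0L)) abort("contig lengths must be positive.")
  if (junction_density < 0) abort("`junction_density` must be >= 0.")
  if (any(usage_range <= 0) || any(usage_range > 1)) {
    abort("`usage_range` must lie in (0, 1].")
  }
  if (at_frac < 0 || at_frac > 1) abort("`at_frac` must be in [0, 1].")
  set.seed(seed)
  probs <- c(A = at_frac / 2, T = at_frac / 2,
             C = (1 - at_frac) / 2, G = (1 - at_frac) / 2)
  contig_names <- sprintf("Contig_%d", seq_len(n_contigs))
  contigs <- vapply(contig_len, function(len) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  names(contigs) <- contig_names

  n_fixed <- NULL
  if (!is.null(n_junctions)) {
    alloc <- table(factor(sample.int(n_contigs, n_junctions, replace = TRUE,
                                     prob = contig_len / sum(contig_len)),
                          levels = seq_len(n_contigs)))
    n_fixed <- as.integer(alloc)
  }
  jn <- lapply(seq_len(n_contigs), function(i) {
    len <- contig_len[i]
    n_j <- if (is.null(n_fixed)) rpois(1L, junction_density * len)
           else n_fixed[i]
    n_j <- min(n_j, len - 1L)
    if (n_j == 0L) return(NULL)
    pos <- sort(sample.int(len - 1L, n_j))    # 0-based positions 1..len-1
    tibble(
      contig = contig_names[i],
      pos = pos,
      side = sample(c("left", "right"), n_j, replace = TRUE),
      usage = runif(n_j, usage_range[1], usage_range[2])
    )
  })
  junctions <- dplyr::bind_rows(jn)
  if (nrow(junctions) == 0L) {
    junctions <- tibble(contig = character(), pos = integer(),
                        side = character(), usage = double())
  }
  structure(
    list(contigs = contigs, junctions = junctions,
         params = list(n_contigs = n_contigs, contig_len = contig_len,
                       junction_density = junction_density,
                       usage_range = usage_range, at_frac = at_frac,
                       n_junctions = n_junctions, seed = seed)),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>", length(x$contigs), "contigs,",
      sum(nchar(x$contigs)), "bp,", nrow(x$junctions), "junctions\n")
  invisible(x)
}

#' Write a simulated genome to FASTA and its truth table to TSV
#'
#' @param genome A `sim_genome`.
#' @param fasta Output FASTA path.
#' @param truth_tsv Optional output TSV path for the junction truth table.
#' @return `fasta`, invisibly.
#' @export
write_sim_genome <- function(genome, fasta, truth_tsv = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(truth_tsv)) {
    readr::write_tsv(genome$junctions, truth_tsv)
  }
  invisible(fasta)
}
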