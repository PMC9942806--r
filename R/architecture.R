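#' Telomere-bearing read fraction
#'
#' Counts telomere-bearing reads (class other than `none`) and the mean
#' telomere-trimmed read length.  Under random fragment sampling the
#' fraction `p` converges to `2 * Lbar / M`, where `M` is the mean distance
#' between telomeres (the mean DNA molecule length) — the basis of the
#' spacing estimator in [mean_spacing()].
#'
#' @param annotation Per-read annotation from [classify_reads()].
#' @return One-row tibble: `n_reads`, `n_telo`, `p`, `mean_read_len`
#'   (telomere-trimmed mean over all reads, bp).
#' @export
telo_fraction <- function(annotation) {
  if (nrow(annotation) == 0L) abort("empty annotation.")
  n <- nrow(annotation)
  t <- sum(annotation$cls != "none")
  tibble(n_reads = n, n_telo = t, p = t / n,
         mean_read_len = mean(annotation$trimmed_len))
}

#' Closed-form inter-telomere spacing estimate
#'
#' `linear`: `M = 2 * Lbar / p`.  `poisson`: `M = 2 * Lbar / (-log(1 - p))`,
#' which corrects for reads carrying more than one telomere.
#'
#' @param p Telomere-bearing read fraction, in (0, 1) (`poisson` requires
#'   p < 1).
#' @param mean_read_len Mean telomere-trimmed read length (bp).
#' @param method `"linear"` or `"poisson"`.
#' @return Estimated mean molecule length (bp).
#' @examples
#' spacing_point(0.125, 8125)               # 130000
#' spacing_point(0.125, 8125, "poisson")    # ~121694
#' @export
spacing_point <- function(p, mean_read_len, method = c("linear", "poisson")) {
  method <- match.arg(method)
  if (any(p <= 0)) abort("spacing undefined for p = 0.")
  if (method == "linear") {
    2 * mean_read_len / p
  } else {
    if (any(p >= 1)) abort("poisson spacing undefined for p = 1.")
    2 * mean_read_len / (-log1p(-p))
  }
}

#' Estimate the mean inter-telomere distance from annotated reads
#'
#' Point estimate by [spacing_point()] on the observed telomere fraction and
#' trimmed mean read length, with a seeded nonparametric bootstrap over
#' reads for the confidence interval.
#'
#' @param annotation Per-read annotation from [classify_reads()].
#' @param method `"linear"` or `"poisson"`.
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `spacing_estimate` with fields `m_hat`,
#'   `ci_lower`, `ci_upper`, `method`, `p`, `mean_read_len`, `n_reads`,
#'   `boot` (bootstrap draws).  Has [tidy()]/[glance()] methods.
#' @export
mean_spacing <- function(annotation, method = c("linear", "poisson"),
                         n_boot = 200L, conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  st <- telo_fraction(annotation)
  if (st$p <= 0) abort("no telomere-bearing reads: spacing undefined.")
  if (method == "poisson" && st$p >= 1) {
    abort("all reads telomere-bearing: poisson spacing undefined.")
  }
  m_hat <- spacing_point(st$p, st$mean_read_len, method)
  telo <- annotation$cls != "none"
  lens <- annotation$trimmed_len
  n <- length(telo)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- mean(telo[idx])
    if (pb <= 0 || (method == "poisson" && pb >= 1)) return(NA_real_)
    spacing_point(pb, mean(lens[idx]), method)
  }, double(1))
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  structure(
    list(m_hat = m_hat, ci_lower = unname(qs[1]), ci_upper = unname(qs[2]),
         method = method, p = st$p, mean_read_len = st$mean_read_len,
         n_reads = st$n_reads, conf = conf, n_boot = n_boot, boot = boot),
    class = "spacing_estimate"
  )
}

#' @export
print.spacing_estimate <- function(x, ...) {
  cat(sprintf(
    "<spacing_estimate> M = %.0f bp (%s; %d%% CI %.0f-%.0f)\n  p = %.4f, mean trimmed read length = %.0f bp, n = %d reads\n",
    x$m_hat, x$method, round(100 * x$conf), x$ci_lower, x$ci_upper,
    x$p, x$mean_read_len, x$n_reads))
  invisible(x)
}

#' @export
tidy.spacing_estimate <- function(x, ...) {
  tibble(term = "mean_molecule_length", estimate = x$m_hat,
         conf.low = x$ci_lower, conf.high = x$ci_upper, method = x$method)
}

#' @export
glance.spacing_estimate <- function(x, ...) {
  tibble(m_hat = x$m_hat, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         method = x$method, p = x$p, mean_read_len = x$mean_read_len,
         n_reads = x$n_reads, n_boot = x$n_boot)
}

#' Observed fraction of reads with telomeres at both ends
#'
#' @param annotation Per-read annotation from [classify_reads()].
#' @return Numeric fraction.
#' @export
two_telomere_fraction <- function(annotation) {
  if (nrow(annotation) == 0L) abort("empty annotation.")
  mean(annotation$cls == "both_ends")
}

#' Expected two-telomere read fraction by Monte-Carlo placement
#'
#' Places random fragments on random molecules under the same generative
#' model as [simulate_reads()]: a fragment of length L on a molecule of
#' length M covers an end with probability `min(1, 2 L / M)` and covers both
#' ends iff it is at least as long as the molecule.
#'
#' @param molecule_lens Sample of molecule lengths (bp).
#' @param read_lens Sample of (trimmed) read lengths (bp).
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed Seed.
#' @return Expected fraction of two-telomere reads.
#' @export
expected_two_telomere_fraction <- function(molecule_lens, read_lens,
                                           n_mc = 1e5, seed = 1L) {
  if (length(molecule_lens) == 0L || length(read_lens) == 0L) {
    abort("`molecule_lens` and `read_lens` must be nonempty.")
  }
  set.seed(seed)
  M <- sample(molecule_lens, n_mc, replace = TRUE)
  L <- sample(read_lens, n_mc, replace = TRUE)
  anchored <- runif(n_mc) < pmin(1, 2 * L / M)
  mean(anchored & L >= M)
}

#' Classify a MAC genome architecture
#'
#' Rough classification of somatic DNA molecule architecture:
#' `nanochromosomal` (molecules of a few kbp encoding single genes, as in
#' spirotrichs), `chromosomal` (hundreds of kbp to Mbp, as in
#' oligohymenophorean MAC chromosomes), and `minichromosomal` in between
#' (tens to a few hundred kbp, tens to a few hundred genes).
#'
#' @param median_molecule_len Median molecule length (bp).
#' @param mean_genes_per_molecule Mean genes per molecule.
#' @param nano_max_len,nano_max_genes Upper bounds for the nanochromosomal
#'   call (defaults 10 kbp / 2 genes).
#' @param chrom_min_len Lower bound for the chromosomal call (default
#'   500 kbp).
#' @return One-row tibble: `label`, `median_molecule_len`,
#'   `mean_genes_per_molecule`.
#' @examples
#' classify_architecture(3e3, 1)      # nanochromosomal
#' classify_architecture(130e3, 60)   # minichromosomal
#' classify_architecture(570e3, 300)  # chromosomal
#' @export
classify_architecture <- function(median_molecule_len,
                                  mean_genes_per_molecule,
                                  nano_max_len = 1e4, nano_max_genes = 2,
                                  chrom_min_len = 5e5) {
  if (median_molecule_len <= 0 || mean_genes_per_molecule <= 0) {
    abort("inputs must be positive.")
  }
  label <- if (median_molecule_len <= nano_max_len ||
               mean_genes_per_molecule <= nano_max_genes) {
    "nanochromosomal"
  } else if (median_molecule_len >= chrom_min_len) {
    "chromosomal"
  } else {
    "minichromosomal"
  }
  tibble(label = label, median_molecule_len = median_molecule_len,
         mean_genes_per_molecule = mean_genes_per_molecule)
}

#' Individual heterozygosity
#'
#' Heterozygous SNPs per callable site, `n / L`.  The callable denominator
#' defaults to the assembly length when no explicit callable-site count is
#' available.
#'
#' @param n_het_snps Number of heterozygous SNPs.
#' @param callable_len Callable genome length (bp); must be positive.
#' @return Heterozygosity rate (per bp).
#' @examples
#' heterozygosity(1277, 41460000)    # ~3.08e-5
#' @export
heterozygosity <- function(n_het_snps, callable_len) {
  if (any(callable_len <= 0)) abort("`callable_len` must be positive.")
  if (any(n_het_snps < 0)) abort("`n_het_snps` must be >= 0.")
  n_het_snps / callable_len
}

#' AT fraction of a genome
#'
#' Fraction of A+T over unambiguous (A, C, G, T) bases.
#'
#' @param x FASTA path, `DNAStringSet`, or character vector of sequences.
#' @return AT fraction in `[0, 1]`.
#' @export
at_fraction <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  } else if (is.character(x)) {
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  f <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  tot <- sum(f)
  if (tot == 0) abort("no unambiguous bases.")
  unname((f["A"] + f["T"]) / tot)
}

#' GC fraction of a genome
#'
#' Complement of [at_fraction()] over unambiguous bases.
#' @inheritParams at_fraction
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(x) 1 - at_fraction(x)

#' Intron length summary from a GFF3 annotation
#'
#' Intron lengths are the gaps between consecutive exon features of each
#' transcript; with 1-based inclusive GFF coordinates the length is
#' `next_exon_start - prev_exon_end - 1`.
#'
#' @param gff Path to a GFF3 file.
#' @return Tibble histogram: `length`, `n` (one row per observed intron
#'   length; the `n` column sums to the total intron count).
#' @export
intron_length_summary <- function(gff) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("intron_length_summary() requires the rtracklayer package.")
  }
  gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                 error = function(e) abort(paste("GFF parse error:",
                                                 conditionMessage(e))))
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) {
    return(tibble(length = integer(), n = integer()))
  }
  parent <- vapply(ex$Parent, function(p) {
    if (length(p)) as.character(p[[1]]) else NA_character_
  }, character(1))
  df <- tibble(parent = parent,
               start = BiocGenerics::start(ex),
               end = BiocGenerics::end(ex)) |>
    filter(!is.na(.data$parent)) |>
    arrange(.data$parent, .data$start)
  introns <- df |>
    group_by(.data$parent) |>
    dplyr::reframe(len = if (n() > 1L) .data$start[-1L] - .data$end[-n()] - 1L
                   else integer(0))
  lens <- introns$len
  if (length(lens) == 0L) return(tibble(length = integer(), n = integer()))
  as_tibble(as.data.frame(table(length = lens),
                          stringsAsFactors = FALSE)) |>
    mutate(length = as.integer(.data$length), n = as.integer(.data$Freq)) |>
    select("length", "n")
}
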