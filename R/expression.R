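#' TPM normalisation
#'
#' Transcripts per million: per sample, counts are divided by gene length,
#' and the length-normalised rates are scaled to sum to 1e6.
#'
#' @param counts Tibble (or data frame) with a `gene_id` column and one
#'   numeric column per sample.
#' @param gene_lengths Named numeric vector of gene lengths (bp), or a
#'   tibble with `gene_id` and `length` columns; all lengths must be
#'   positive.
#' @return Tibble of the same shape with TPM values; every sample column
#'   sums to 1e6.
#' @export
tpm <- function(counts, gene_lengths) {
  if (!"gene_id" %in% names(counts)) abort("`counts` needs a `gene_id` column.")
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$length, gene_lengths$gene_id)
  }
  lens <- unname(gene_lengths[counts$gene_id])
  if (anyNA(lens)) abort("missing gene lengths.")
  if (any(lens <= 0)) abort("gene lengths must be positive.")
  samples <- setdiff(names(counts), "gene_id")
  out <- counts
  for (s in samples) {
    rate <- counts[[s]] / lens
    tot <- sum(rate)
    out[[s]] <- if (tot > 0) rate / tot * 1e6 else rate
  }
  out
}

#' Developmental fold-change ranking
#'
#' Ranks genes by the ratio of target-sample expression to the unweighted
#' mean of the baseline samples, with a pseudocount on both terms.  This is
#' the "expression at the new-MAC time point vs the average of starved,
#' gamone-treated and 0 h cells" ranking: a plain ratio ranking, not a
#' differential-expression test.  Ties are broken lexicographically by gene
#' id; ranks are a permutation of `1..n` (1 = highest fold change).
#'
#' @param mat Expression tibble with `gene_id` and sample columns
#'   (normalised values or counts).
#' @param target Name of the target sample column (e.g. `"26h"`).
#' @param baselines Names of the baseline sample columns (e.g. starved,
#'   gamone-treated and 0 h).
#' @param pseudocount Pseudocount added to numerator and denominator
#'   (default 0.5).
#' @return Tibble: `gene_id`, `target`, `baseline_mean`, `fc`, `rank`,
#'   sorted by rank.
#' @export
fold_change <- function(mat, target, baselines, pseudocount = 0.5) {
  miss <- setdiff(c(target, baselines), names(mat))
  if (length(miss)) {
    abort(paste("missing sample columns:", paste(miss, collapse = ", ")))
  }
  if (length(baselines) < 1L) abort("at least one baseline sample required.")
  base <- rowMeans(as.data.frame(mat[baselines]))
  fc <- (mat[[target]] + pseudocount) / (base + pseudocount)
  out <- tibble(gene_id = mat$gene_id,
                target = mat[[target]],
                baseline_mean = base,
                fc = fc)
  ord <- order(-out$fc, out$gene_id)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Annotate top-ranked genes with domain hits
#'
#' Among the `k` highest-ranked genes, reports those with at least one
#' domain hit in the given domain set.
#'
#' @param fc Ranking tibble from [fold_change()].
#' @param hits Domain-hit tibble (needs `gene_id`, `domain_name`), e.g.
#'   from [read_domain_table()].
#' @param k Number of top genes to inspect (default 100; must not exceed
#'   the number of genes).
#' @param domains Domain set (default [TRANSPOSASE_DOMAINS]).
#' @return Tibble of the matching top-`k` genes: `gene_id`, `rank`, `fc`,
#'   `domains` (comma-joined); the number of matching genes is `nrow()` of
#'   the result.  The inspected `k` is kept as attribute `k`.
#' @export
annotate_top <- function(fc, hits, k = 100L, domains = TRANSPOSASE_DOMAINS) {
  if (k > nrow(fc)) abort("`k` exceeds the number of ranked genes.")
  top <- fc[fc$rank <= k, ]
  h <- hits |>
    filter(.data$domain_name %in% domains, .data$gene_id %in% top$gene_id) |>
    group_by(.data$gene_id) |>
    summarise(domains = paste(sort(unique(.data$domain_name)),
                              collapse = ","), .groups = "drop")
  out <- top |>
    dplyr::inner_join(h, by = "gene_id") |>
    select("gene_id", "rank", "fc", "domains") |>
    arrange(.data$rank)
  attr(out, "k") <- as.integer(k)
  out
}

#' Simulate a developmental expression count matrix with planted
#' up-regulation
#'
#' Negative-binomial counts for one target sample (the new-MAC development
#' time point) and several baseline samples; a chosen set of genes is
#' scaled by planted fold changes in the target sample only.
#'
#' @param n_genes Number of genes.
#' @param n_planted Number of planted up-regulated genes (default 100, the
#'   size of the reported top set).
#' @param fc_range Range of planted fold changes, drawn log-uniformly
#'   (default 69--825, the span reported for the top-ranked development
#'   genes); all planted fold changes must exceed 1.
#' @param target Name of the target sample (default `"26h"`).
#' @param baselines Baseline sample names (default starved, gamone-treated
#'   and 0 h).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   must be positive.
#' @param base_mean_meanlog,base_mean_sdlog Lognormal parameters of the
#'   per-gene baseline mean.
#' @param lib_size_factor Per-sample library size factors (recycled;
#'   default 1).
#' @param seed Integer seed.
#' @return Object of class `sim_expression`: list with `counts` (tibble:
#'   `gene_id` + one column per sample), `truth` (tibble: `gene_id`,
#'   `planted`, `fc_true`), `target`, `baselines`, `params`.
#' @export
simulate_expression <- function(n_genes = 5000L, n_planted = 100L,
                                fc_range = c(69, 825),
                                target = "26h",
                                baselines = c("starved", "gamone", "0h"),
                                dispersion = 0.1,
                                base_mean_meanlog = log(50),
                                base_mean_sdlog = 1,
                                lib_size_factor = 1,
                                seed = 1L) {
  if (dispersion <= 0) abort("`dispersion` must be positive.")
  if (length(baselines) < 1L) abort("at least one baseline sample required.")
  if (n_planted > n_genes) abort("`n_planted` exceeds `n_genes`.")
  if (any(fc_range <= 1)) abort("planted fold changes must exceed 1.")
  set.seed(seed)
  samples <- c(baselines, target)
  libf <- rep_len(lib_size_factor, length(samples))
  names(libf) <- samples
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  base_mean <- rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog)
  planted <- sample.int(n_genes, n_planted)
  fc_true <- rep(1, n_genes)
  fc_true[planted] <- exp(runif(n_planted, log(fc_range[1]),
                                log(fc_range[2])))
  size <- 1 / dispersion
  counts <- tibble(gene_id = gene_id)
  for (s in samples) {
    mu <- base_mean * libf[[s]]
    if (s == target) mu <- mu * fc_true
    counts[[s]] <- rnbinom(n_genes, mu = mu, size = size)
  }
  structure(
    list(counts = counts,
         truth = tibble(gene_id = gene_id,
                        planted = seq_len(n_genes) %in% planted,
                        fc_true = fc_true),
         target = target, baselines = baselines,
         params = list(n_genes = n_genes, n_planted = n_planted,
                       fc_range = fc_range, dispersion = dispersion,
                       lib_size_factor = libf, seed = seed)),
    class = "sim_expression"
  )
}

#' @export
print.sim_expression <- function(x, ...) {
  cat("<sim_expression>", nrow(x$counts), "genes,",
      sum(x$truth$planted), "planted up-regulated; target:", x$target, "\n")
  invisible(x)
}
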