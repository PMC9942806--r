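#' Simulate a codon-sequence pair evolved at a chosen dN/dS
#'
#' Evolves a descendant from a random stop-free ancestor under a
#' continuous-time Markov codon process: single-nucleotide exchanges occur
#' at rate 1 when synonymous and at rate `omega_true` when nonsynonymous;
#' pathways into stop codons are forbidden (rate 0).  The generator is
#' scaled so that `t` is the expected number of substitutions per codon
#' (uniform codon usage).  Transition probabilities come from the matrix
#' exponential of the scaled generator, so the process is exact for any
#' `t`.
#'
#' @param n_codons Number of codons.
#' @param omega_true True nonsynonymous/synonymous rate ratio (> 0).
#' @param t Branch length: expected substitutions per codon (>= 0).
#' @param code A [genetic_code()].
#' @param seed Integer seed.
#' @return Object of class `sim_codon_pair`: list with `s1`, `s2` (DNA
#'   strings, no gaps, stop-free under `code`) and `truth`
#'   (`omega_true`, `t`, `n_codons`, `code_id`, `seed`).
#' @examples
#' p <- simulate_codon_pair(100, omega_true = 0.1, t = 0.2, seed = 1)
#' ng86(p$s1, p$s2)$omega
#' @export
simulate_codon_pair <- function(n_codons, omega_true, t,
                                code = genetic_code("standard"), seed = 1L) {
  if (omega_true <= 0) abort("`omega_true` must be > 0.")
  if (t < 0) abort("`t` must be >= 0.")
  if (n_codons < 1L) abort("`n_codons` must be positive.")
  set.seed(seed)
  sense <- code$sense
  anc <- sample(sense, n_codons, replace = TRUE)
  if (t == 0) {
    s <- paste(anc, collapse = "")
    return(structure(
      list(s1 = s, s2 = s,
           truth = list(omega_true = omega_true, t = t, n_codons = n_codons,
                        code_id = code$id, seed = seed)),
      class = "sim_codon_pair"))
  }
  P <- .codon_transition_matrix(code, omega_true, t)
  des <- anc
  for (cd in unique(anc)) {
    ii <- which(anc == cd)
    des[ii] <- sample(sense, length(ii), replace = TRUE,
                      prob = P[cd, ])
  }
  structure(
    list(s1 = paste(anc, collapse = ""), s2 = paste(des, collapse = ""),
         truth = list(omega_true = omega_true, t = t, n_codons = n_codons,
                      code_id = code$id, seed = seed)),
    class = "sim_codon_pair"
  )
}

#' @export
print.sim_codon_pair <- function(x, ...) {
  cat("<sim_codon_pair>", x$truth$n_codons, "codons, omega =",
      x$truth$omega_true, ", t =", x$truth$t, "\n")
  invisible(x)
}

.codon_transition_matrix <- function(code, omega_true, t) {
  sense <- code$sense
  ns <- length(sense)
  Q <- matrix(0, ns, ns, dimnames = list(sense, sense))
  for (cd in sense) {
    nb <- .codon_neighbors(cd)
    nb <- nb[!(nb %in% code$stops)]
    syn <- code$map[nb] == code$map[[cd]]
    Q[cd, nb] <- ifelse(syn, 1, omega_true)
  }
  diag(Q) <- -rowSums(Q)
  rate <- -mean(diag(Q))        # mean substitutions per codon per unit time
  Q <- Q / rate
  as.matrix(Matrix::expm(Q * t))
}

#' Write a simulated codon pair as CDS FASTA
#'
#' @param pair A [simulate_codon_pair()] result.
#' @param path Output FASTA path.
#' @param ids Sequence names (default `c("anc", "des")`).
#' @return `path`, invisibly.
#' @export
write_sim_codon_pair <- function(pair, path, ids = c("anc", "des")) {
  stopifnot(inherits(pair, "sim_codon_pair"))
  ss <- Biostrings::DNAStringSet(setNames(c(pair$s1, pair$s2), ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
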