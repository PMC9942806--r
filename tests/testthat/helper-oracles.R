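# Independent oracles used by the test suite.  These deliberately share no
# code with the package implementation.

# Brute-force telomere-run oracle: a span matches iff it matches the
# periodic tiling of the unit (or its reverse complement) at some global
# offset.  For each orientation and each of the |unit| offsets, a template
# the length of the sequence is built and maximal all-match stretches are
# read off with rle(); stretches with at least min_repeats complete units
# are reported.  Assumes a primitive unit (unique phase per span).
oracle_find_runs <- function(seq, unit = "CCCTAACA", min_repeats = 3L) {
  seq <- toupper(seq)
  k <- nchar(unit)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(unit, "", fixed = TRUE)[[1]]),
                                     collapse = ""))
  out <- list()
  for (ori in c("C-rich", "G-rich")) {
    u <- strsplit(if (ori == "C-rich") unit else rc, "", fixed = TRUE)[[1]]
    for (p in 0:(k - 1L)) {
      tmpl <- u[((seq_len(n) - 1L + p) %% k) + 1L]
      m <- ch == tmpl
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & (r$lengths %/% k) >= min_repeats
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          qstart = starts[keep] - 1L, qend = ends[keep],
          n_repeats = r$lengths[keep] %/% k, orientation = ori)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(qstart = integer(), qend = integer(),
                      n_repeats = integer(), orientation = character()))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$qstart), , drop = FALSE]
}

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# NG86 oracle: per-codon site counts by direct neighbour enumeration and
# difference counts by recursive enumeration of all mutational pathways,
# discarding pathways through stop codons (all retained if none is
# stop-free, as a fallback).
oracle_ng86 <- function(s1, s2, code_id = "standard") {
  gc_map <- Biostrings::GENETIC_CODE
  if (code_id == "UGA_to_Trp") gc_map["TGA"] <- "W"
  stops <- names(gc_map)[gc_map == "*"]
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- split3(toupper(s1)); c2 <- split3(toupper(s2))
  stopifnot(length(c1) == length(c2))

  neighbours <- function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    unlist(lapply(1:3, function(pos) {
      sapply(setdiff(c("A", "C", "G", "T"), ch[pos]), function(b) {
        x <- ch; x[pos] <- b; paste(x, collapse = "")
      })
    }), use.names = FALSE)
  }
  syn_sites <- function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    tot <- 0
    for (pos in 1:3) {
      nb <- sapply(setdiff(c("A", "C", "G", "T"), ch[pos]), function(b) {
        x <- ch; x[pos] <- b; paste(x, collapse = "")
      })
      nb <- nb[!(nb %in% stops)]
      if (length(nb)) tot <- tot + mean(gc_map[nb] == gc_map[[cd]])
    }
    tot
  }
  # recursive pathway enumeration from a to b
  enum_paths <- function(a, b) {
    if (a == b) return(list(c(n = 0, s = 0, ok = 1)))
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    res <- list()
    for (pos in which(ca != cb)) {
      nxt <- ca; nxt[pos] <- cb[pos]
      mid <- paste(nxt, collapse = "")
      step_syn <- gc_map[[a]] == gc_map[[mid]]
      step_ok <- !(mid %in% stops) || mid == b
      for (tailp in enum_paths(mid, b)) {
        res[[length(res) + 1L]] <- c(
          n = unname(tailp["n"]) + !step_syn,
          s = unname(tailp["s"]) + step_syn,
          ok = unname(tailp["ok"]) * step_ok)
      }
    }
    res
  }
  Nd <- 0; Sd <- 0; S <- 0
  for (i in seq_along(c1)) {
    S <- S + (syn_sites(c1[i]) + syn_sites(c2[i])) / 2
    if (c1[i] != c2[i]) {
      pp <- do.call(rbind, enum_paths(c1[i], c2[i]))
      use <- pp[, "ok"] == 1
      if (!any(use)) use <- rep(TRUE, nrow(pp))
      Nd <- Nd + mean(pp[use, "n"])
      Sd <- Sd + mean(pp[use, "s"])
    }
  }
  N <- 3 * length(c1) - S
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dN <- jc(pN); dS <- jc(pS)
  om <- if (is.na(dN) || is.na(dS)) NA_real_
        else if (dS > 0) dN / dS else if (dN == 0) NA_real_ else Inf
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = dN, dS = dS, omega = om)
}

# random sense-codon sequence under a code
random_cds <- function(n_codons, code_id = "standard") {
  gc_map <- Biostrings::GENETIC_CODE
  if (code_id == "UGA_to_Trp") gc_map["TGA"] <- "W"
  sense <- names(gc_map)[gc_map != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
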