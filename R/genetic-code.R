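#' Genetic codes for codon analyses
#'
#' `"standard"` is the standard nuclear code.  `"UGA_to_Trp"` reassigns the
#' UGA (TGA) stop to tryptophan, the alternative nuclear code used by
#' *Blepharisma* (and *Condylostoma*), leaving TAA/TAG as the only stops.
#'
#' @param id `"standard"` or `"UGA_to_Trp"`.
#' @return An object of class `genetic_code`: list with `id`, `map`
#'   (named character vector, 64 codons to amino acids, `*` = stop),
#'   `stops`, and `sense` (non-stop codons).
#' @export
genetic_code <- function(id = c("standard", "UGA_to_Trp")) {
  id <- match.arg(id)
  map <- Biostrings::GENETIC_CODE
  if (id == "UGA_to_Trp") map["TGA"] <- "W"
  structure(
    list(id = id, map = map,
         stops = names(map)[map == "*"],
         sense = names(map)[map != "*"]),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code>", x$id, "-", length(x$sense), "sense codons, stops:",
      paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

.BASES <- c("A", "C", "G", "T")

# the nine single-nucleotide neighbours of a codon
.codon_neighbors <- function(codon) {
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  out <- character(9)
  j <- 0L
  for (pos in 1:3) {
    for (b in .BASES[.BASES != ch[pos]]) {
      j <- j + 1L
      nb <- ch
      nb[pos] <- b
      out[j] <- paste(nb, collapse = "")
    }
  }
  out
}

# package-local cache of per-code NG86 tables
.ng_cache <- new.env(parent = emptyenv())

# Per-codon synonymous site counts: at each position the synonymous fraction
# of valid (non-stop) single-nucleotide neighbours; positions whose three
# neighbours are all stops contribute no synonymous fraction.
.ng_sites <- function(code) {
  key <- paste0("sites_", code$id)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  s <- vapply(code$sense, function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    aa <- code$map[[cd]]
    total <- 0
    for (pos in 1:3) {
      nb <- vapply(.BASES[.BASES != ch[pos]], function(b) {
        x <- ch; x[pos] <- b; paste(x, collapse = "")
      }, character(1))
      valid <- nb[!(nb %in% code$stops)]
      if (length(valid)) {
        total <- total + sum(code$map[valid] == aa) / length(valid)
      }
    }
    total
  }, double(1))
  .ng_cache[[key]] <- s
  s
}

# Pathway-averaged nonsynonymous/synonymous difference counts for every
# ordered pair of sense codons.  All orderings of the differing positions
# are enumerated; orderings passing through a stop codon are discarded
# (when every ordering does, all are kept, steps into stops counting as
# nonsynonymous).
.ng_diffs <- function(code) {
  key <- paste0("diffs_", code$id)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  sense <- code$sense
  ns <- length(sense)
  nd <- matrix(0, ns, ns, dimnames = list(sense, sense))
  sd <- matrix(0, ns, ns, dimnames = list(sense, sense))
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  chars <- strsplit(sense, "", fixed = TRUE)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i >= j) next
      a <- chars[[i]]; b <- chars[[j]]
      dpos <- which(a != b)
      d <- length(dpos)
      if (d == 0L) next
      pm <- perms[[as.character(d)]]
      path_nd <- double(nrow(pm)); path_sd <- double(nrow(pm))
      path_ok <- logical(nrow(pm))
      for (pi in seq_len(nrow(pm))) {
        cur <- a
        n_n <- 0; n_s <- 0; ok <- TRUE
        for (step in seq_len(d)) {
          pos <- dpos[pm[pi, step]]
          nxt <- cur
          nxt[pos] <- b[pos]
          c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
          if (step < d && c2 %in% code$stops) ok <- FALSE
          if (code$map[[c1]] == code$map[[c2]]) n_s <- n_s + 1
          else n_n <- n_n + 1
          cur <- nxt
        }
        path_nd[pi] <- n_n; path_sd[pi] <- n_s; path_ok[pi] <- ok
      }
      use <- if (any(path_ok)) path_ok else rep(TRUE, nrow(pm))
      nd[i, j] <- nd[j, i] <- mean(path_nd[use])
      sd[i, j] <- sd[j, i] <- mean(path_sd[use])
    }
  }
  .ng_cache[[key]] <- list(nd = nd, sd = sd)
  .ng_cache[[key]]
}
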