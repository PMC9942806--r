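#' Read a HMMER per-domain table (domtblout style)
#'
#' Parses whitespace-delimited per-domain output as written by
#' `hmmscan --domtblout` (22 fixed columns plus free-text description, `#`
#' comment lines).  Hits are filtered on the independent E-value.
#'
#' @param path Path to the table.
#' @param max_evalue Keep hits with i-Evalue at or below this threshold
#'   (default 1e-5).
#' @return Tibble of hits: `gene_id` (query), `domain_name` (target model),
#'   `accession`, `i_evalue`, `ali_from`, `ali_to` (1-based on the
#'   protein).
#' @export
read_domain_table <- function(path, max_evalue = 1e-5) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(tibble(gene_id = character(), domain_name = character(),
                  accession = character(), i_evalue = double(),
                  ali_from = integer(), ali_to = integer()))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 22L)) {
    abort(sprintf("malformed domain table line %d: %d fields (expected >= 22).",
                  lineno[which(nf < 22L)[1]], min(nf)))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  hits <- tibble(
    domain_name = col(1), accession = col(2), gene_id = col(4),
    i_evalue = as.numeric(col(13)),
    ali_from = as.integer(col(18)), ali_to = as.integer(col(19))
  )
  if (anyNA(hits$i_evalue) || anyNA(hits$ali_from)) {
    bad <- which(is.na(hits$i_evalue) | is.na(hits$ali_from))[1]
    abort(sprintf("malformed domain table line %d: non-numeric field.",
                  lineno[bad]))
  }
  if (any(hits$ali_from > hits$ali_to)) {
    abort("domain table has ali_from > ali_to.")
  }
  hits |>
    filter(.data$i_evalue <= max_evalue) |>
    select("gene_id", "domain_name", "accession", "i_evalue",
           "ali_from", "ali_to")
}

#' Write hits in domtblout style (round-trip companion of
#' [read_domain_table()])
#'
#' @param hits Tibble with `gene_id`, `domain_name`, `accession`,
#'   `i_evalue`, `ali_from`, `ali_to`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  header <- c("# target name accession tlen query name accession qlen",
              "# domtblout-style per-domain table")
  body <- sprintf(
    "%s %s %d %s - %d %.2g 100.0 0.1 1 1 %.2g %.2g 99.0 0.1 1 %d %d %d %d %d 0.99 -",
    hits$domain_name, hits$accession, hits$ali_to - hits$ali_from + 1L,
    hits$gene_id, 1000L, hits$i_evalue, hits$i_evalue, hits$i_evalue,
    hits$ali_to - hits$ali_from + 1L,
    hits$ali_from, hits$ali_to, hits$ali_from, hits$ali_to)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Transposase PFAM domains named in MAC-encoded ciliate proteins
#'
#' The transposase domain families explicitly discussed for the
#' *Blepharisma* MAC genome: the PiggyBac domain `DDE_Tnp_1_7` (PF13843)
#' and the additional domesticated-transposase domains `DDE_3`,
#' `DDE_Tnp_IS1595`, `MULE`, and `DDE_1`.
#' @export
TRANSPOSASE_DOMAINS <- c("DDE_Tnp_1_7", "DDE_3", "DDE_Tnp_IS1595",
                         "MULE", "DDE_1")

#' Domain presence/absence matrix across species
#'
#' @param hits Tibble of domain hits with a `species` column (plus
#'   `gene_id`, `domain_name`), e.g. several [read_domain_table()] results
#'   bound together with a species label.
#' @param domains Domain whitelist defining the columns (default
#'   [TRANSPOSASE_DOMAINS]).
#' @param species Optional character vector of species defining the rows
#'   (retains all-absent rows); defaults to the species present in `hits`.
#' @return Object of class `presence_matrix`: list with `present` (logical
#'   species x domain matrix) and `count` (supporting gene counts), rows and
#'   columns in lexicographic order.
#' @export
presence_matrix <- function(hits, domains = TRANSPOSASE_DOMAINS,
                            species = NULL) {
  if (length(domains) == 0L) abort("`domains` must be nonempty.")
  if (!"species" %in% names(hits)) abort("`hits` needs a `species` column.")
  if (is.null(species)) species <- unique(hits$species)
  species <- sort(unique(species))
  domains <- sort(unique(domains))
  cnt <- matrix(0L, length(species), length(domains),
                dimnames = list(species, domains))
  h <- hits |>
    filter(.data$domain_name %in% domains, .data$species %in% !!species) |>
    dplyr::distinct(.data$species, .data$domain_name, .data$gene_id) |>
    count(.data$species, .data$domain_name)
  if (nrow(h)) cnt[cbind(h$species, h$domain_name)] <- h$n
  structure(list(present = cnt >= 1L, count = cnt),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix>", nrow(x$present), "species x",
      ncol(x$present), "domains;", sum(x$present), "present cells\n")
  print(x$present)
  invisible(x)
}

#' @export
tidy.presence_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$count, stringsAsFactors = FALSE)) |>
    dplyr::rename(species = "Var1", domain = "Var2", n_genes = "Freq") |>
    mutate(present = .data$n_genes >= 1L)
}

#' Call a PiggyBac catalytic triad (DDD) from a protein alignment
#'
#' Maps three 1-based positions of the reference protein (its aspartate
#' triad) to alignment columns and reads the target residues there.  A
#' target site that is not aspartate but has an aspartate within
#' `max_offset` alignment columns is called `offset` (the D-prime case, an
#' aspartate displaced by one residue).  Status aggregates the three sites:
#' `complete` (DDD), `offset_Dprime` (>= 1 offset aspartate, rest D),
#' `incomplete` (>= 1 site without a nearby D), `absent` (target gapped at
#' all three columns).
#'
#' @param alignment Named character vector of aligned protein sequences.
#' @param reference_id Id of the reference (must have D at the stated
#'   positions).
#' @param reference_triad Three 1-based positions in the *ungapped*
#'   reference.
#' @param target_id Id of the protein to call.
#' @param max_offset Column tolerance for the displaced aspartate
#'   (default 1).
#' @return Object of class `triad_call`: list with `protein_id`, `status`
#'   and `sites` (tibble: `site`, `column`, `target_pos` 1-based unaligned
#'   position or `NA`, `residue`, `call`).  Has a [tidy()] method.
#' @export
call_triad <- function(alignment, reference_id, reference_triad, target_id,
                       max_offset = 1L) {
  if (!reference_id %in% names(alignment)) abort("reference id missing.")
  if (!target_id %in% names(alignment)) abort("target id missing.")
  if (length(reference_triad) != 3L) abort("`reference_triad` needs 3 positions.")
  ref <- strsplit(toupper(alignment[[reference_id]]), "", fixed = TRUE)[[1]]
  tgt <- strsplit(toupper(alignment[[target_id]]), "", fixed = TRUE)[[1]]
  if (length(ref) != length(tgt)) abort("alignment widths differ.")
  ref_upos <- cumsum(ref != "-")
  cols <- vapply(reference_triad, function(p) {
    w <- which(ref_upos == p & ref != "-")
    if (length(w) == 0L) abort("reference position outside the protein.")
    w[1]
  }, integer(1))
  if (any(ref[cols] != "D")) {
    abort("reference residue is not D at a stated triad position.")
  }
  tgt_upos <- cumsum(tgt != "-")
  site_call <- function(cl) {
    if (tgt[cl] == "D") {
      return(list(call = "D", pos = tgt_upos[cl], res = "D", col = cl))
    }
    lo <- max(1L, cl - max_offset); hi <- min(length(tgt), cl + max_offset)
    near <- setdiff(seq(lo, hi), cl)
    near <- near[tgt[near] == "D"]
    if (length(near)) {
      nc <- near[which.min(abs(near - cl))]
      return(list(call = "offset", pos = tgt_upos[nc], res = "D", col = nc))
    }
    if (tgt[cl] == "-") {
      return(list(call = "gap", pos = NA_integer_, res = "-", col = cl))
    }
    list(call = "missing", pos = tgt_upos[cl], res = tgt[cl], col = cl)
  }
  sc <- lapply(cols, site_call)
  calls <- vapply(sc, `[[`, character(1), "call")
  status <- if (all(calls == "D")) "complete"
    else if (all(calls == "gap")) "absent"
    else if (all(calls %in% c("D", "offset"))) "offset_Dprime"
    else "incomplete"
  structure(
    list(protein_id = target_id, status = status,
         sites = tibble(
           site = 1:3,
           column = vapply(sc, function(s) as.integer(s$col), integer(1)),
           target_pos = vapply(sc, function(s) as.integer(s$pos), integer(1)),
           residue = vapply(sc, `[[`, character(1), "res"),
           call = calls)),
    class = "triad_call"
  )
}

#' @export
print.triad_call <- function(x, ...) {
  cat("<triad_call>", x$protein_id, "-", x$status, "\n")
  print(x$sites)
  invisible(x)
}

#' @export
tidy.triad_call <- function(x, ...) {
  mutate(x$sites, protein_id = x$protein_id, status = x$status)
}

#' Find C-terminal cysteine-rich domains (CRDs)
#'
#' Heuristic cysteine-cluster scan for the short, characteristic C-terminal
#' zinc-finger-like domain of PiggyBac homologs: reports maximal windows of
#' at most `window` residues containing at least `min_cys` cysteines,
#' restricted to the C-terminal `cterm_frac` of the protein, together with
#' the inter-cysteine spacing pattern (e.g. `C-x2-C-x10-C`).
#'
#' @param protein A protein sequence (single string, 20-letter alphabet
#'   plus X).
#' @param min_cys Minimum cysteines per window (default 5).
#' @param window Maximum window length in residues (default 60).
#' @param cterm_frac Fraction of the protein (from the C terminus) searched
#'   (default 0.35).
#' @return Tibble of hits: `start`, `end` (1-based inclusive), `n_cys`,
#'   `spacing`.
#' @export
find_crd <- function(protein, min_cys = 5L, window = 60L,
                     cterm_frac = 0.35) {
  protein <- toupper(protein)
  len <- nchar(protein)
  empty <- tibble(start = integer(), end = integer(), n_cys = integer(),
                  spacing = character())
  if (len == 0L) return(empty)
  region_start <- max(1L, len - as.integer(floor(len * cterm_frac)) + 1L)
  cys <- which(strsplit(protein, "", fixed = TRUE)[[1]] == "C")
  cys <- cys[cys >= region_start]
  if (length(cys) < min_cys) return(empty)
  cand <- list()
  for (i in seq_along(cys)) {
    j <- max(which(cys - cys[i] + 1L <= window))
    if (j - i + 1L >= min_cys) {
      cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- unique(do.call(rbind, cand))
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    !any(cand[, 1] <= cand[r, 1] & cand[, 2] >= cand[r, 2] &
           (cand[, 1] != cand[r, 1] | cand[, 2] != cand[r, 2]))
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  tibble(
    start = cys[cand[, 1]],
    end = cys[cand[, 2]],
    n_cys = cand[, 2] - cand[, 1] + 1L,
    spacing = vapply(seq_len(nrow(cand)), function(r) {
      pp <- cys[cand[r, 1]:cand[r, 2]]
      gaps <- diff(pp) - 1L
      paste0("C", paste0(vapply(gaps, function(g) {
        if (g == 0L) "-C" else sprintf("-x%d-C", g)
      }, character(1)), collapse = ""))
    }, character(1))
  ) |>
    arrange(.data$start)
}

#' Recover cysteine positions from a CRD spacing pattern
#'
#' Inverse of the `spacing` string written by [find_crd()].
#'
#' @param spacing Spacing pattern, e.g. `"C-x2-C-x10-C"`.
#' @param start 1-based position of the first cysteine (default 1).
#' @return Integer vector of cysteine positions.
#' @export
crd_spacing_positions <- function(spacing, start = 1L) {
  parts <- strsplit(spacing, "-", fixed = TRUE)[[1]]
  pos <- start
  out <- start
  for (p in parts[-1]) {
    if (p == "C") {
      pos <- pos + 1L
      out <- c(out, pos)
    } else {
      pos <- pos + as.integer(sub("^x", "", p))
    }
  }
  out
}
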