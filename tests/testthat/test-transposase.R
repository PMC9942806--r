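make_domtbl <- function(path, rows) {
  hdr <- c("# target name accession tlen query name ...", "#")
  writeLines(c(hdr, rows), path)
}

dom_row <- function(target = "DDE_Tnp_1_7", acc = "PF13843.8",
                    query = "g1", ievalue = "1e-20",
                    ali_from = 10, ali_to = 150) {
  paste(target, acc, 200, query, "-", 500, "1e-30", 120.0, 0.1, 1, 1,
        "1e-25", ievalue, 118.0, 0.1, 5, 180, ali_from, ali_to,
        ali_from, ali_to, 0.98, "description text", sep = " ")
}

test_that("domain tables parse, filter on E-value and reject bad lines", {
  f <- tempfile()
  make_domtbl(f, character(0))
  expect_equal(nrow(read_domain_table(f)), 0L)

  make_domtbl(f, c(dom_row(query = "g1"),
                   dom_row(query = "g2", target = "DDE_3", acc = "PF13358"),
                   dom_row(query = "g3", ievalue = "0.5")))
  hits <- read_domain_table(f)
  expect_equal(nrow(hits), 2L)             # one hit fails the filter
  expect_setequal(hits$gene_id, c("g1", "g2"))
  expect_equal(hits$ali_from, c(10L, 10L))

  writeLines(c("# ok", "too few fields here"), f)
  expect_error(read_domain_table(f), "line 2")
})

test_that("domain tables round-trip through the writer", {
  f <- tempfile()
  make_domtbl(f, c(dom_row(query = "g1"),
                   dom_row(query = "g2", target = "MULE", acc = "PF10551")))
  hits <- read_domain_table(f)
  f2 <- tempfile()
  write_domain_table(hits, f2)
  again <- read_domain_table(f2)
  expect_equal(again[c("gene_id", "domain_name", "accession",
                       "ali_from", "ali_to")],
               hits[c("gene_id", "domain_name", "accession",
                      "ali_from", "ali_to")])
})

test_that("presence matrix keeps all-absent rows and conserves cell counts", {
  hits <- tibble::tibble(
    species = c("Blepharisma", "Blepharisma", "Tetrahymena"),
    gene_id = c("g1", "g2", "t1"),
    domain_name = c("DDE_Tnp_1_7", "DDE_Tnp_1_7", "DDE_3"))
  pm <- presence_matrix(hits, species = c("Blepharisma", "Tetrahymena",
                                          "Oxytricha"))
  expect_equal(dim(pm$present), c(3L, 5L))
  expect_equal(sum(pm$present), 2L)
  expect_equal(pm$count["Blepharisma", "DDE_Tnp_1_7"], 2L)
  expect_true(all(!pm$present["Oxytricha", ]))
  # lexicographic order
  expect_equal(rownames(pm$present), sort(rownames(pm$present)))

  # duplicated hits: boolean semantics idempotent, counts de-duplicate genes
  pm2 <- presence_matrix(dplyr::bind_rows(hits, hits),
                         species = c("Blepharisma", "Tetrahymena", "Oxytricha"))
  expect_identical(pm2$present, pm$present)
  expect_identical(pm2$count, pm$count)

  td <- tidy(pm)
  expect_equal(sum(td$present), 2L)
})

test_that("triad calling distinguishes complete, offset, incomplete, absent", {
  # reference triad at unaligned positions 3, 6, 9
  ref <- "MADKCDLKDA"
  stopifnot(substr(ref, 3, 3) == "D", substr(ref, 6, 6) == "D",
            substr(ref, 9, 9) == "D")

  # identical target: complete
  tc <- call_triad(c(ref = ref, tgt = ref), "ref", c(3, 6, 9), "tgt")
  expect_equal(tc$status, "complete")
  expect_equal(tc$sites$target_pos, c(3L, 6L, 9L))

  # second site D -> N with a D one column over: offset_Dprime
  aln2 <- c(ref = "MADKCD-LKDA", tgt = "MADKCNDLKDA")
  tc2 <- call_triad(aln2, "ref", c(3, 6, 9), "tgt")
  expect_equal(tc2$status, "offset_Dprime")
  expect_equal(tc2$sites$call[2], "offset")

  # D -> A with no neighbouring D: incomplete
  tc3 <- call_triad(c(ref = ref, tgt = "MADKCALKDA"), "ref", c(3, 6, 9), "tgt")
  expect_equal(tc3$status, "incomplete")

  # target gapped at all three columns: absent
  tc4 <- call_triad(c(ref = ref, tgt = "MA-KC-LK-A"), "ref", c(3, 6, 9), "tgt")
  expect_equal(tc4$status, "absent")

  # reference must carry D at the stated positions
  expect_error(call_triad(c(ref = ref, tgt = ref), "ref", c(1, 6, 9), "tgt"),
               "not D")
  expect_error(call_triad(c(ref = ref), "ref", c(3, 6, 9), "tgt"), "missing")
})

test_that("triad calls ignore unrelated sequences in the alignment", {
  aln <- c(ref = "MADKCD-LKDA", tgt = "MADKCNDLKDA")
  with_extra <- c(aln, junk1 = "MWWWWW-WWWW", junk2 = "-----------")
  a <- call_triad(aln, "ref", c(3, 6, 9), "tgt")
  b <- call_triad(with_extra, "ref", c(3, 6, 9), "tgt")
  expect_equal(a$status, b$status)
  expect_equal(a$sites, b$sites)
})

test_that("CRD detection finds C-terminal cysteine clusters", {
  expect_equal(nrow(find_crd(strrep("A", 200))), 0L)

  crd <- paste0("C", "AA", "C", strrep("A", 10), "C", "AA", "C", "A",
                "C", "AAA", "C")
  prot <- paste0(strrep("A", 100), crd)
  hits <- find_crd(prot, min_cys = 5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_cys, 6L)
  expect_equal(hits$spacing, "C-x2-C-x10-C-x2-C-x1-C-x3-C")

  # the spacing string inverts back to the cysteine positions
  pos <- crd_spacing_positions(hits$spacing, start = hits$start)
  ch <- strsplit(prot, "")[[1]]
  expect_true(all(ch[pos] == "C"))
  expect_equal(length(pos), hits$n_cys)

  # clusters outside the C-terminal fraction are not reported
  nterm <- paste0(crd, strrep("A", 400))
  expect_equal(nrow(find_crd(nterm)), 0L)

  # N-terminal extension that stays outside the window changes nothing
  hits2 <- find_crd(paste0(strrep("G", 50), prot), min_cys = 5)
  expect_equal(hits2$n_cys, hits$n_cys)
  expect_equal(hits2$end - hits2$start, hits$end - hits$start)
  expect_equal(hits2$spacing, hits$spacing)
})
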