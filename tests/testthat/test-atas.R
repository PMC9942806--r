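# helper: one-read annotation + alignment pair for constructed cases
one_read_ann <- function(cls = "five_prime", read_len = 5000L,
                         telo_5p_end = 24L, telo_3p_start = NA_integer_) {
  tibble::tibble(read_id = "r1", read_len = read_len, n_runs = 1L,
                 telo_5p_end = telo_5p_end, telo_3p_start = telo_3p_start,
                 cls = cls, trimmed_len = read_len - 24L)
}

one_aln <- function(strand = "+", rstart = 999L, rend = 3000L,
                    qstart = 24L, qend = 2025L, read_id = "r1",
                    mapq = 60L, is_primary = TRUE) {
  tibble::tibble(read_id = read_id, qlen = 5000L, qstart = qstart,
                 qend = qend, strand = strand, contig = "Contig_1",
                 tlen = 100000L, rstart = rstart, rend = rend,
                 nmatch = 2000L, alnlen = 2000L, mapq = mapq,
                 is_primary = is_primary)
}

test_that("a 5' telomere read yields a left junction at rstart on +", {
  calls <- call_atas(one_read_ann(), one_aln())
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$contig, "Contig_1")
  expect_equal(calls$pos, 999)
  expect_equal(calls$pos1, 1000)
  expect_equal(calls$side, "left")
  expect_equal(calls$n_support, 1L)
  expect_false(calls$is_terminus)
})

test_that("the same read on - strand yields a right junction at rend", {
  calls <- call_atas(one_read_ann(), one_aln(strand = "-"))
  expect_equal(calls$pos, 3000)
  expect_equal(calls$side, "right")
})

test_that("non-telomeric reads contribute to coverage only", {
  ann <- dplyr::bind_rows(
    one_read_ann(),
    tibble::tibble(read_id = "r2", read_len = 5000L, n_runs = 0L,
                   telo_5p_end = NA_integer_, telo_3p_start = NA_integer_,
                   cls = "none", trimmed_len = 5000L))
  aln <- dplyr::bind_rows(one_aln(),
                          one_aln(read_id = "r2", rstart = 500L, rend = 2500L,
                                  qstart = 0L, qend = 2000L))
  calls <- call_atas(ann, aln)
  expect_equal(calls$n_support, 1L)
  expect_equal(calls$n_cover, 2L)
  expect_equal(calls$telo_frac, 0.5)
})

test_that("junction tolerance gates the telomere-alignment abutment", {
  # terminal run ends at 24 but alignment starts at query 60
  calls <- call_atas(one_read_ann(), one_aln(qstart = 60L), junction_tol = 20L)
  expect_equal(nrow(calls), 0L)
  calls2 <- call_atas(one_read_ann(), one_aln(qstart = 60L), junction_tol = 40L)
  expect_equal(nrow(calls2), 1L)
  expect_error(call_atas(one_read_ann(), one_aln(), junction_tol = -1),
               ">= 0")
})

test_that("secondary alignments and low mapq are excluded; support is
           monotone in min_mapq", {
  expect_equal(nrow(call_atas(one_read_ann(),
                              one_aln(is_primary = FALSE))), 0L)
  ann <- one_read_ann()
  a10 <- call_atas(ann, one_aln(mapq = 10L), min_mapq = 0L)
  a60 <- call_atas(ann, one_aln(mapq = 10L), min_mapq = 30L)
  expect_equal(a10$n_support, 1L)
  expect_equal(nrow(a60), 0L)
})

test_that("alignments for unknown reads are skipped with a warning", {
  expect_warning(
    calls <- call_atas(one_read_ann(), one_aln(read_id = "ghost")),
    "absent")
  expect_equal(nrow(calls), 0L)
})

test_that("calling on concatenated batches equals merging per-batch calls", {
  g <- simulate_mac_genome(2, 5e4, junction_density = 4e-4,
                           usage_range = c(0.2, 0.5), seed = 21)
  r1 <- simulate_reads(g, 1500, seed = 22, emit_seq = FALSE)
  r2 <- simulate_reads(g, 1500, seed = 23, emit_seq = FALSE)
  ann1 <- truth_annotation(r1); aln1 <- truth_alignments(r1)
  ann2 <- truth_annotation(r2)
  aln2 <- truth_alignments(r2)
  aln2$read_id <- paste0("b2_", aln2$read_id)
  ann2$read_id <- paste0("b2_", ann2$read_id)

  joint <- call_atas(dplyr::bind_rows(ann1, ann2),
                     dplyr::bind_rows(aln1, aln2))
  c1 <- call_atas(ann1, aln1, contig_lens = nchar(g$contigs))
  c2 <- call_atas(ann2, aln2, contig_lens = nchar(g$contigs))
  merged <- dplyr::bind_rows(c1, c2) |>
    dplyr::group_by(contig, pos, side) |>
    dplyr::summarise(n_support = sum(n_support), .groups = "drop") |>
    dplyr::arrange(contig, pos, side)
  expect_equal(joint[c("contig", "pos", "side", "n_support")],
               merged[c("contig", "pos", "side", "n_support")])
})

test_that("with error-free reads every call sits on a planted junction or
           molecule terminus", {
  g <- simulate_mac_genome(3, 6e4, junction_density = 5e-4,
                           usage_range = c(0.1, 0.4), seed = 31)
  r <- simulate_reads(g, 4000, seed = 32, emit_seq = FALSE)
  calls <- call_atas(truth_annotation(r), truth_alignments(r))
  atas <- calls[!calls$is_terminus, ]
  key <- function(d) paste(d$contig, d$pos, d$side)
  planted <- key(g$junctions)
  ends <- c(paste(names(g$contigs), 0, "left"),
            paste(names(g$contigs), nchar(g$contigs), "right"))
  expect_true(all(key(atas) %in% planted))
  expect_true(all(key(calls[calls$is_terminus, ]) %in% ends))
})

test_that("summaries count singletons and respect edge cases", {
  empty <- call_atas(one_read_ann(), one_aln())[0, ]
  s0 <- summarize_atas(empty)
  expect_equal(s0$n_total, 0L)
  expect_equal(s0$singleton_frac, 0)

  calls <- tibble::tibble(contig = "c", pos = c(10L, 20L, 30L),
                          pos1 = c(11L, 21L, 31L),
                          side = "left", n_support = c(1L, 1L, 5L),
                          n_cover = c(10L, 10L, 10L),
                          telo_frac = 0.1, is_contig_end = FALSE,
                          is_terminus = FALSE)
  s <- summarize_atas(calls)
  expect_equal(s$n_singleton, 2L)
  expect_equal(s$singleton_frac, 2 / 3)

  d <- atas_density(calls, c(c = 10000L))
  expect_equal(d$per_kbp, 0.3)
})

test_that("PAF parsing flags non-primary records and rejects short lines", {
  f <- tempfile(fileext = ".paf")
  writeLines(c(
    "r1\t1000\t0\t900\t+\tc1\t5000\t100\t1000\t900\t900\t60\ttp:A:P",
    "r1\t1000\t0\t400\t-\tc2\t4000\t0\t400\t400\t400\t0\ttp:A:S",
    "r2\t800\t0\t800\t+\tc1\t5000\t2000\t2800\t800\t800\t60"), f)
  aln <- read_paf(f)
  expect_equal(aln$is_primary, c(TRUE, FALSE, TRUE))
  expect_equal(aln$rstart[1], 100L)

  writeLines("r1\t1000\t0", f)
  expect_error(read_paf(f), "fewer than 12")
})

test_that("SAM alignments convert to the same junction coordinates", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:Contig_1\tLN:100000",
    # 24 bp soft-clipped telomere then 2001M, mapped at 1-based 1000
    paste("r1", 0, "Contig_1", 1000, 60, "24S2001M", "*", 0, 0,
          paste(rep("A", 2025), collapse = ""), "*", sep = "\t")), sam)
  aln <- read_aln_sam(sam)
  expect_equal(aln$rstart, 999L)
  expect_equal(aln$qstart, 24L)
  expect_equal(aln$strand, "+")
  calls <- call_atas(one_read_ann(), aln)
  expect_equal(calls$pos, 999)
  expect_equal(calls$side, "left")
})
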