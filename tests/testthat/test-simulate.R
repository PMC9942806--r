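test_that("genome simulation is deterministic and honours its parameters", {
  g1 <- simulate_mac_genome(2, 2e4, junction_density = 5e-4, seed = 5)
  g2 <- simulate_mac_genome(2, 2e4, junction_density = 5e-4, seed = 5)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(g1$junctions, g2$junctions)

  g0 <- simulate_mac_genome(1, 5e4, junction_density = 0, seed = 1)
  expect_equal(nrow(g0$junctions), 0L)

  gx <- simulate_mac_genome(3, 3e4, n_junctions = 40, seed = 2)
  expect_equal(nrow(gx$junctions), 40L)
  expect_true(all(gx$junctions$pos > 0 &
                    gx$junctions$pos < 3e4))
  expect_true(all(gx$junctions$usage > 0 & gx$junctions$usage <= 1))

  expect_error(simulate_mac_genome(1, -5), "positive")
})

test_that("junction counts follow the Poisson rate", {
  counts <- vapply(1:40, function(s) {
    nrow(simulate_mac_genome(1, 1e5, junction_density = 1e-4,
                             seed = s)$junctions)
  }, double(1))
  lambda <- 10
  se <- sqrt(lambda / 40)
  expect_lt(abs(mean(counts) - lambda), 4 * se)
})

test_that("genome AT content matches the requested fraction", {
  g <- simulate_mac_genome(1, 5e4, junction_density = 0, at_frac = 0.66,
                           seed = 3)
  expect_lt(abs(at_fraction(g$contigs) - 0.66), 0.01)
  expect_equal(at_fraction(g$contigs) + gc_fraction(g$contigs), 1)
})

test_that("read simulation is deterministic and truth-consistent", {
  g <- simulate_mac_genome(2, 5e4, junction_density = 2e-4, seed = 1)
  r1 <- simulate_reads(g, 300, seed = 9)
  r2 <- simulate_reads(g, 300, seed = 9)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)

  tr <- r1$truth
  k <- 8L
  expect_true(all(tr$read_len ==
                    tr$core_len + k * (tr$n_repeats_5p + tr$n_repeats_3p)))
  expect_true(all(tr$n_repeats_5p[tr$has_telo_5p] >= 3))
  expect_true(all(!tr$has_telo_5p | tr$n_repeats_5p > 0))
  expect_true(all(tr$start >= tr$mol_start & tr$end <= tr$mol_end))
  expect_true(all(nchar(r1$reads) == tr$read_len[match(names(r1$reads),
                                                       tr$read_id)]))

  # reads covering a molecule 5' end carry a tract; interior reads none
  interior <- tr$start > tr$mol_start & tr$end < tr$mol_end
  expect_true(all(!tr$has_telo_5p[interior] & !tr$has_telo_3p[interior]))

  # read sequences are reconstructible from genome + truth
  i <- which(tr$strand == "+" & !tr$has_telo_5p & !tr$has_telo_3p)[1]
  expect_equal(r1$reads[[tr$read_id[i]]],
               substr(g$contigs[[tr$contig[i]]], tr$start[i] + 1, tr$end[i]))
  j <- which(tr$strand == "-" & !tr$has_telo_5p & !tr$has_telo_3p)[1]
  expect_equal(r1$reads[[tr$read_id[j]]],
               revcomp_chr(substr(g$contigs[[tr$contig[j]]],
                                  tr$start[j] + 1, tr$end[j])))

  expect_error(simulate_reads(g, 100, error_rate = 1), "error_rate")
})

test_that("telomere-bearing read fraction converges to 2*Lbar/M", {
  # molecules are whole 130 kbp contigs (no internal junctions)
  g <- simulate_mac_genome(4, 130e3, junction_density = 0, seed = 2)
  r <- simulate_reads(g, 20000, seed = 3, emit_seq = FALSE)
  ann <- truth_annotation(r)
  st <- telo_fraction(ann)
  expected <- 2 * st$mean_read_len / 130e3
  se <- sqrt(expected * (1 - expected) / st$n_reads)
  expect_lt(abs(st$p - expected), 3 * se)
})

test_that("truth PAF round-trips through the PAF writer/reader", {
  g <- simulate_mac_genome(2, 3e4, junction_density = 3e-4, seed = 4)
  r <- simulate_reads(g, 200, seed = 5, emit_seq = FALSE)
  f <- tempfile(fileext = ".paf")
  write_paf(r$paf, f)
  back <- read_paf(f)
  expect_equal(back$read_id, r$paf$qname)
  expect_equal(back$rstart, as.integer(r$paf$tstart))
  expect_equal(back$rend, as.integer(r$paf$tend))
  expect_equal(back$qstart, as.integer(r$paf$qstart))
  expect_equal(back$strand, r$paf$strand)
  expect_true(all(back$is_primary))
})

test_that("FASTQ output is well-formed and scanner-compatible", {
  g <- simulate_mac_genome(1, 2e4, junction_density = 0, seed = 6)
  r <- simulate_reads(g, 50, seed = 7)
  fq <- tempfile(fileext = ".fastq")
  write_sim_reads(r, fq)
  sc <- scan_telomeres(fq)
  expect_equal(nrow(sc$annotation), 50L)
  expect_setequal(sc$annotation$read_id, r$truth$read_id)
})

test_that("codon pair simulation respects t, omega ordering and the code", {
  p0 <- simulate_codon_pair(200, omega_true = 0.5, t = 0, seed = 1)
  expect_identical(p0$s1, p0$s2)

  p <- simulate_codon_pair(300, omega_true = 0.5, t = 0.2,
                           code = genetic_code("UGA_to_Trp"), seed = 2)
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  expect_false(any(codons(p$s2) %in% c("TAA", "TAG")))
  expect_equal(nchar(p$s2) %% 3, 0)

  # determinism
  q <- simulate_codon_pair(300, omega_true = 0.5, t = 0.2,
                           code = genetic_code("UGA_to_Trp"), seed = 2)
  expect_identical(p$s2, q$s2)

  # omega ordering is preserved by the estimator
  lo <- vapply(1:5, function(s) {
    pp <- simulate_codon_pair(800, 0.05, 0.3, seed = s)
    ng86(pp$s1, pp$s2)$omega
  }, double(1))
  hi <- vapply(1:5, function(s) {
    pp <- simulate_codon_pair(800, 0.5, 0.3, seed = s + 100)
    ng86(pp$s1, pp$s2)$omega
  }, double(1))
  expect_true(all(lo < hi))
})

test_that("expression simulation plants recoverable fold changes", {
  e1 <- simulate_expression(n_genes = 500, n_planted = 20, seed = 3)
  e2 <- simulate_expression(n_genes = 500, n_planted = 20, seed = 3)
  expect_identical(e1$counts, e2$counts)
  expect_true(all(as.matrix(e1$counts[-1]) >= 0))
  expect_true(all(e1$truth$fc_true[e1$truth$planted] > 1))

  # near-zero dispersion: empirical fold change close to the planted one
  e3 <- simulate_expression(n_genes = 400, n_planted = 10,
                            fc_range = c(100, 100.0001),
                            dispersion = 1e-4, base_mean_meanlog = log(500),
                            base_mean_sdlog = 0.2, seed = 4)
  fc <- fold_change(e3$counts, target = "26h",
                    baselines = c("starved", "gamone", "0h"),
                    pseudocount = 0.5)
  got <- fc$fc[match(e3$truth$gene_id[e3$truth$planted], fc$gene_id)]
  expect_true(all(abs(got - 100) / 100 < 0.1))

  # no planted genes: top fold changes cluster near 1
  e4 <- simulate_expression(n_genes = 500, n_planted = 0, dispersion = 0.05,
                            base_mean_meanlog = log(200),
                            base_mean_sdlog = 0.3, seed = 5)
  fc4 <- fold_change(e4$counts, "26h", c("starved", "gamone", "0h"))
  expect_lt(max(fc4$fc), 3)
  expect_lt(abs(median(fc4$fc) - 1), 0.1)

  expect_error(simulate_expression(100, dispersion = 0), "dispersion")
})
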