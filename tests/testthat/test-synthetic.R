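small_cfg <- function(...) {
  generator_config(n_per_family = c("NDBP-short" = 5, "alpha-KTx" = 5,
                                    "DDH-calcin" = 5, "La1-like" = 5,
                                    "ascaris-type-inhibitor" = 5),
                   n_decoys = 5, ...)
}

test_that("the generator is deterministic given a seed and respects counts", {
  cfg <- small_cfg(seed = 101)
  g1 <- generate_precursors(cfg)
  g2 <- generate_precursors(cfg)
  expect_identical(g1, g2)
  t1 <- reverse_transcribe(g1$truth, cfg)
  t2 <- reverse_transcribe(g2$truth, cfg)
  expect_identical(t1, t2)
  expect_identical(synth_proteome(t1$truth, cfg), synth_proteome(t2$truth, cfg))

  empty <- generate_precursors(
    generator_config(n_per_family = c("NDBP-short" = 0), seed = 1))
  expect_identical(nrow(empty$records), 0L)
  expect_identical(nrow(empty$truth), 0L)

  expect_error(generator_config(n_per_family = c(unicorn = 3)), "unknown family")
})

test_that("NDBP precursors obey the antimicrobial-peptide grammar", {
  cfg <- generator_config(n_per_family = c("NDBP-short" = 50), seed = 103)
  g <- generate_precursors(cfg)
  expect_true(all(nchar(g$truth$mature) < 20))
  expect_false(any(grepl("C", g$truth$mature)))
  expect_true(all(g$truth$amidated))
  expect_true(all(nchar(g$truth$signal) %in% 23:24))
  expect_true(all(nchar(g$truth$pro_c) >= 31 & nchar(g$truth$pro_c) <= 46))
  expect_true(all(vapply(g$truth$pro_c,
                         function(p) mean(strsplit(p, "")[[1]] %in% c("D", "E")),
                         numeric(1)) >= 0.25))
})

test_that("reverse transcription round-trips every precursor through the ORF finder", {
  cfg <- small_cfg(seed = 107)
  g <- generate_precursors(cfg)
  rt <- reverse_transcribe(g$truth, cfg)
  expect_identical(nrow(rt$transcripts), nrow(g$truth) + 5L)
  for (i in seq_len(nrow(rt$truth))) {
    tx <- rt$transcripts$seq[rt$transcripts$id == rt$truth$id[i]]
    top <- select_precursor_orf(find_orfs(tx, id = rt$truth$id[i]))
    expect_identical(top$protein, rt$truth$precursor[i])
  }
  # decoys contain no start-anchored ORF at the pipeline threshold
  decoys <- rt$transcripts[startsWith(rt$transcripts$id, "decoy"), ]
  for (d in decoys$seq) expect_identical(nrow(find_orfs(d)), 0L)
})

test_that("a zero-UTR configuration makes the CDS span the whole transcript", {
  cfg <- generator_config(n_per_family = c("alpha-KTx" = 3),
                          utr_len_range = c(0L, 0L), n_decoys = 0, seed = 109)
  g <- generate_precursors(cfg)
  rt <- reverse_transcribe(g$truth, cfg)
  # CDS codons plus the stop codon cover the transcript exactly
  expect_true(all(nchar(rt$transcripts$seq) ==
                    3L * nchar(rt$truth$precursor) + 3L))
})

test_that("noiseless proteome lists are fully recovered at tight tolerance", {
  cfg <- small_cfg(mass_noise_sd = 0, dropout = 0, seed = 113)
  g <- generate_precursors(cfg)
  pm <- synth_proteome(g$truth, cfg)
  expect_identical(nrow(pm), nrow(g$truth))
  rep <- match_masses(
    data.frame(name = g$truth$id, mass = g$truth$mature_mono_da),
    pm, tol_da = 0.01)
  expect_identical(rep$n_exp_matched, nrow(pm))

  none <- synth_proteome(g$truth, small_cfg(dropout = 1, seed = 113))
  expect_identical(nrow(none), 0L)
})

test_that("noisy recovery tracks the normal-tail expectation", {
  cfg <- generator_config(n_per_family = c("NDBP-short" = 1000),
                          mass_noise_sd = 0.5, dropout = 0, seed = 127)
  g <- generate_precursors(cfg)
  pm <- synth_proteome(g$truth, cfg)
  rep <- match_masses(
    data.frame(name = g$truth$id, mass = g$truth$mature_mono_da),
    pm, tol_da = 1.0)
  frac <- rep$n_exp_matched / nrow(pm)
  expected <- stats::pnorm(2) - stats::pnorm(-2)   # |N(0, 0.5)| <= 1.0
  expect_gte(frac, expected - 0.03)
  expect_gte(frac, 0.95)
})
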