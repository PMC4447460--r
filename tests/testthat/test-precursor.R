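test_that("signal cleavage heuristic finds curated sites and rejects junk", {
  fx <- load_precursor_fixture()
  p17 <- fx$precursor[fx$name == "comp17_c0_seq1-4"]
  got <- predict_signal_cleavage(p17)
  expect_identical(got$cut, 23L)
  expect_identical(substr(p17, 1, got$cut), "MKNQFVLLLLAIVFLQLISQSDA")

  expect_null(predict_signal_cleavage(paste0("M", strrep("D", 39))))
  expect_null(predict_signal_cleavage("MAAAA"))            # too short
  expect_null(predict_signal_cleavage(strrep("L", 40)))    # no Met start
  expect_error(predict_signal_cleavage(paste0("M", strrep("L", 30), "Z")),
               "illegal")
})

test_that("signal cleavage is within +-2 of the curated boundary for >=70% of full-length rows", {
  fx <- load_precursor_fixture()
  full <- fx[nchar(fx$signal) >= 15 & substr(fx$precursor, 1, 1) == "M", ]
  pred <- vapply(full$precursor, function(p) {
    s <- predict_signal_cleavage(p)
    if (is.null(s)) NA_integer_ else s$cut
  }, integer(1))
  hit <- !is.na(pred) & abs(pred - nchar(full$signal)) <= 2
  expect_gte(mean(hit), 0.70)
})

test_that("processing motifs are found with the tripeptide kind preferred", {
  fx <- load_precursor_fixture()
  p17 <- fx$precursor[fx$name == "comp17_c0_seq1-4"]
  hits <- find_processing_motifs(p17)
  g <- hits[hits$pos == 36, ]
  expect_identical(g$kind, "G-KR/G-RR")
  expect_identical(g$motif, "GKR")

  expect_identical(nrow(find_processing_motifs("AAAA")), 0L)

  term <- find_processing_motifs("ACYGCSG")
  expect_identical(term$kind[term$pos == 6], "terminal-G")
  di <- find_processing_motifs("AGKA")
  expect_identical(di$kind, "G-K/G-R")
})

test_that("segmentation reproduces curated worked examples", {
  fx <- load_precursor_fixture()
  s17 <- segment_precursor(fx$precursor[fx$name == "comp17_c0_seq1-4"])
  expect_identical(nchar(s17$signal), 23L)
  expect_identical(s17$mature, "ILSAIWSGIKSLF")
  expect_true(s17$amidated)
  expect_identical(s17$pro_c, "GLKNMDKFDELFDGDFSQADLDFLRELTR")
  expect_identical(s17$motif, "GKR")

  # LaIT1-like calcin: acidic N-terminal propeptide ending in ER, then the
  # cysteine-scaffold mature peptide
  s1 <- segment_precursor(fx$precursor[fx$name == "comp10032_c0_seq1"])
  expect_identical(s1$mature, "DLPPSDEYGTCVRPRKCKPHLKCSKAQTCVDPKKGW")
  expect_false(s1$amidated)
  expect_identical(paste0(s1$signal, s1$pro_n),
                   paste0(fx$signal[fx$name == "comp10032_c0_seq1"],
                          fx$pro_n[fx$name == "comp10032_c0_seq1"]))

  # terminal donor glycine after the disulfide scaffold
  s2092 <- segment_precursor(fx$precursor[fx$name == "comp2092_c0_seq1"],
                             signal_override = 25L)
  expect_identical(s2092$mature, "IGGCPIDSMCKSYCKNHKYGSEGKCDGTNCKCSL")
  expect_true(s2092$amidated)
  expect_identical(s2092$amid_gly, "G")

  # no motif, no terminal glycine: everything after the signal is mature
  plain <- paste0("MK", strrep("L", 16), "QNSDA", strrep("NHQ", 10))
  sp <- segment_precursor(plain)
  expect_identical(sp$mature, strrep("NHQ", 10))
  expect_false(sp$amidated)
})

test_that("segment intervals always partition the precursor", {
  set.seed(21)
  fx <- load_precursor_fixture()
  seqs <- c(fx$precursor,
            vapply(sample(25:120, 50, replace = TRUE), rand_peptide,
                   character(1)))
  for (p in seqs) {
    s <- segment_precursor(p)
    expect_identical(
      paste0(s$signal, s$pro_n, s$mature, s$amid_gly, s$basic, s$pro_c), p)
  }
  short <- segment_precursor("MKKLL")
  expect_identical(short$mature, "MKKLL")
  expect_true("too-short" %in% short$method_flags)
})

test_that("amidation flags reproduce the curated annotations exactly", {
  fx <- load_precursor_fixture()
  got <- vapply(fx$precursor,
                function(p) infer_amidation(segment_precursor(p)), logical(1))
  expect_identical(unname(got), fx$amidated)
})

test_that("terminal glycine without an upstream cysteine is not called amidated", {
  # mature peptides that merely end in G (no Cys scaffold at the terminus)
  p <- paste0("MK", strrep("L", 16), "QNSDA", "KYHNQWNPHQNKHSQWNG")
  s <- segment_precursor(p)
  expect_false(s$amidated)
  expect_identical(substr(s$mature, nchar(s$mature), nchar(s$mature)), "G")
})

test_that("duplicate precursors group into a unique-sequence census", {
  expect_identical(nrow(dedupe_unique(character(), character())), 0L)

  ids <- c("t1", "t2", "t3", "t4", "t5")
  seqs <- c("AAA", "BBB", "AAA", "AAA", "BBB")
  g <- dedupe_unique(ids, seqs)
  expect_identical(g$n, c(3L, 2L))
  expect_identical(g$members[1], "t1;t3;t4")

  set.seed(33)
  pool <- vapply(rep(30, 40), rand_peptide, character(1))
  seqs <- sample(pool, 1000, replace = TRUE)
  ids <- sprintf("r%04d", 1:1000)
  g <- dedupe_unique(ids, seqs)
  # brute-force census
  expect_identical(sum(g$n), 1000L)
  expect_identical(nrow(g), length(unique(seqs)))
  for (k in sample(nrow(g), 10)) {
    expect_identical(g$n[k], sum(seqs == g$seq[k]))
  }
})
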