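test_that("FASTA round-trips arbitrary records and preserves order", {
  set.seed(11)
  recs <- data.frame(
    id = sprintf("rec%03d", 1:100),
    desc = ifelse(runif(100) < 0.5, "some description", ""),
    seq = vapply(sample(20:300, 100, replace = TRUE), rand_dna, character(1)),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f, alphabet = "dna")
  expect_identical(back$id, recs$id)
  expect_identical(back$seq, recs$seq)
  expect_identical(back$desc, recs$desc)
})

test_that("FASTA parsing handles empty input and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_identical(nrow(read_fasta(f)), 0L)

  writeLines(c(">a", "ACGT"), f)
  got <- read_fasta(f, alphabet = "dna")
  expect_identical(got$id, "a")
  expect_identical(nchar(got$seq), 4L)

  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">a", "AC!T"), f)
  expect_error(read_fasta(f, alphabet = "dna"), "line 2")
  writeLines(c(">a", "ACGT", ">", "ACGT"), f)
  expect_error(read_fasta(f), "line 3")
})

test_that("proteome mass list loads the packaged venom LC-MS table", {
  pm <- load_proteome_masses(venomtk_extdata("table3_proteome.tsv"))
  expect_identical(nrow(pm), 16L)
  expect_equal(pm$rt_min[1], 13.88)
  expect_equal(pm$mass_da[1], 1433.54)

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rt_min\tmass_da", f)
  expect_identical(nrow(load_proteome_masses(f)), 0L)
  writeLines(c("rt_min\tmass_da", "1.0\t100.0"), f)
  expect_equal(load_proteome_masses(f)$mass_da, 100.0)
  writeLines(c("rt_min\tmass_da", "1.0\tnot-a-mass"), f)
  expect_error(load_proteome_masses(f), "non-numeric")
})

test_that("curated precursor fixture satisfies the reconstruction invariant", {
  fx <- load_precursor_fixture()
  expect_identical(nrow(fx), 68L)
  recon <- paste0(fx$signal, fx$pro_n, fx$mature, fx$amid_gly, fx$basic,
                  fx$pro_c)
  expect_identical(recon, fx$precursor)
  expect_true(all(nzchar(fx$mature)))
  expect_true(all(fx$amid_gly[fx$amidated] == "G"))

  r17 <- fx[fx$name == "comp17_c0_seq1-4", ]
  expect_identical(nchar(r17$signal), 23L)
  expect_identical(r17$mature, "ILSAIWSGIKSLF")
  expect_true(r17$amidated)

  r1991 <- fx[fx$name == "comp1991_c0_seq1-5", ]
  expect_identical(r1991$mature, "KYAPTGGCPLSDALCARYCLKHNYGRSGKCDGSTCKCS")
  expect_identical(r1991$pro_c, "TKLPNIIVL")
  expect_false(r1991$amidated)
})

test_that("empty fixture file loads as an empty table", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    "name\tsignal\tpro_n\tmature\tamid_gly\tbasic\tpro_c\tamidated\tdescription",
    f)
  expect_identical(nrow(load_precursor_fixture(f)), 0L)
})

test_that("N50 follows its definition on trivial and random inputs", {
  expect_identical(assembly_stats(500)$n50, 500)
  expect_identical(assembly_stats(c(2, 2, 2))$n50, 2)
  st <- assembly_stats(c(10, 20, 30, 40))
  expect_identical(st$total_nt, 100)
  expect_identical(st$n_seqs, 4L)
  expect_identical(assembly_stats(numeric())$n50, 0)

  set.seed(42)
  for (i in 1:200) {
    lens <- sample(1:2000, sample(1:40, 1), replace = TRUE)
    expect_equal(assembly_stats(lens)$n50, brute_n50(lens), ignore_attr = TRUE)
  }
})
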