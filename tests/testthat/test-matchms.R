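test_that("published theoretical and experimental columns match as printed", {
  t3 <- table3_fixture()
  theory <- data.frame(name = t3$name, mass = t3$theor_mw_da)
  exper <- load_proteome_masses(venomtk_extdata("table3_proteome.tsv"))

  rep4 <- match_masses(theory, exper, tol_da = 4.0)
  expect_identical(rep4$n_exp_matched, 16L)
  rep1 <- match_masses(theory, exper, tol_da = 1.0)
  expect_identical(rep1$n_exp_matched, 14L)
})

test_that("degenerate inputs give empty reports, not errors", {
  exper <- data.frame(rt_min = 1, mass_da = 100)
  empty_t <- data.frame(name = character(), mass = numeric())
  expect_identical(match_masses(empty_t, exper)$n_exp_matched, 0L)
  expect_identical(
    nrow(match_masses(data.frame(name = "a", mass = 1),
                      data.frame(rt_min = numeric(),
                                 mass_da = numeric()))$matches), 0L)
})

test_that("match counts are monotone in tolerance", {
  set.seed(37)
  theory <- data.frame(name = sprintf("t%d", 1:80),
                       mass = runif(80, 1000, 9000))
  exper <- data.frame(rt_min = runif(60, 10, 50),
                      mass_da = runif(60, 1000, 9000))
  tols <- c(0.1, 1, 5, 25, 100, 1000)
  reps <- lapply(tols, function(tol) match_masses(theory, exper, tol_da = tol))
  ne <- vapply(reps, `[[`, integer(1), "n_exp_matched")
  nt <- vapply(reps, `[[`, integer(1), "n_theory_matched")
  expect_true(all(diff(ne) >= 0))
  expect_true(all(diff(nt) >= 0))
})

test_that("matching is symmetric under an absolute tolerance", {
  set.seed(41)
  a <- runif(50, 1000, 5000)
  b <- runif(50, 1000, 5000)
  fwd <- match_masses(data.frame(name = as.character(1:50), mass = a),
                      data.frame(rt_min = 1:50, mass_da = b), tol_da = 10)
  rev <- match_masses(data.frame(name = as.character(1:50), mass = b),
                      data.frame(rt_min = 1:50, mass_da = a), tol_da = 10)
  expect_identical(nrow(fwd$matches), nrow(rev$matches))
  expect_identical(fwd$n_exp_matched, rev$n_theory_matched)
  expect_identical(fwd$n_theory_matched, rev$n_exp_matched)
})

test_that("reported pairs equal an all-pairs brute force, in Da and ppm", {
  set.seed(43)
  theory <- data.frame(name = sprintf("t%d", 1:200),
                       mass = runif(200, 500, 10000))
  exper <- data.frame(rt_min = runif(150, 0, 60),
                      mass_da = runif(150, 500, 10000))
  rep <- match_masses(theory, exper, tol_da = 8)
  brute <- 0L
  for (i in seq_len(nrow(theory))) {
    for (j in seq_len(nrow(exper))) {
      if (abs(theory$mass[i] - exper$mass_da[j]) <= 8) brute <- brute + 1L
    }
  }
  expect_identical(nrow(rep$matches), brute)
  expect_equal(rep$matches$delta_ppm,
               rep$matches$delta_da * 1e6 / rep$matches$exp_da)

  repp <- match_masses(theory, exper, tol_ppm = 500)
  brute_ppm <- 0L
  for (i in seq_len(nrow(theory))) {
    for (j in seq_len(nrow(exper))) {
      if (abs(theory$mass[i] - exper$mass_da[j]) <=
            500e-6 * exper$mass_da[j]) brute_ppm <- brute_ppm + 1L
    }
  }
  expect_identical(nrow(repp$matches), brute_ppm)
})

test_that("every experimental mass is labeled with its nearest candidate", {
  theory <- data.frame(name = c("a", "b", "c"), mass = c(100, 200, 300.2))
  exper <- data.frame(rt_min = c(1, 2), mass_da = c(299.9, 150))
  rep <- match_masses(theory, exper, tol_da = 1)
  expect_identical(rep$nearest$theory_name, c("c", "a"))  # tie at 150 -> lower index
  expect_equal(rep$nearest$delta_da[1], 0.3, tolerance = 1e-9)
})
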