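test_that("the parser extracts thermochemistry, frequencies and status from a log", {
  log <- c(
    " Entering Gaussian System",
    " Charge = -1 Multiplicity = 1",
    " Frequencies --    -45.1000     55.0000",
    " Frequencies --   1700.1000",
    " Sum of electronic and thermal Free Energies=   -496.100000",
    " Sum of electronic and thermal Free Energies=   -496.123456",
    " Elapsed time:       0 days  0 hours 51 minutes 30.0 seconds.",
    " Normal termination of Gaussian 16"
  )
  r <- parse_gaussian_log(log)
  expect_equal(r$gibbs_free_energy, -496.123456) # last occurrence wins
  expect_equal(r$frequencies[1], -45.1)
  expect_equal(r$frequencies, c(-45.1, 55.0, 1700.1))
  expect_true(r$converged)
  expect_equal(r$wall_time, 51.5)
  expect_null(r$structure)

  truncated <- parse_gaussian_log(log[1:6])
  expect_false(truncated$converged)
  expect_true(is.na(truncated$wall_time))

  expect_error(parse_gaussian_log(" nothing useful here"),
               "no thermochemistry section")
})

test_that("parsing is insensitive to line endings and trailing whitespace", {
  res <- fixture_result("water")
  text <- write_gaussian_log(res, qm_settings("PBEPBE"))
  mangled <- gsub("\n", "  \r\n", text)
  a <- parse_gaussian_log(text)
  b <- parse_gaussian_log(mangled)
  expect_equal(a$gibbs_free_energy, b$gibbs_free_energy)
  expect_equal(a$frequencies, b$frequencies)
  expect_identical(a$structure$elements, b$structure$elements)
})

test_that("synthetic log round trip reproduces structure, energy and status", {
  for (kind in c("acid", "base")) {
    res <- qm_result(build_species(kind, "2-Chlorobenzoic Acid"),
                     gibbs_free_energy = -1492.654321,
                     frequencies = seq(30, 3500, length.out = 12),
                     converged = TRUE, wall_time = 34.25)
    back <- parse_gaussian_log(write_gaussian_log(res, qm_settings()))
    expect_equal(length(back$structure$elements), length(res$structure$elements))
    expect_identical(back$structure$elements, res$structure$elements)
    expect_equal(back$structure$coordinates, res$structure$coordinates,
                 tolerance = 1e-5)
    expect_identical(back$structure$charge, res$structure$charge)
    expect_identical(back$structure$multiplicity, res$structure$multiplicity)
    expect_equal(back$gibbs_free_energy, res$gibbs_free_energy, tolerance = 1e-9)
    expect_equal(back$frequencies, res$frequencies, tolerance = 1e-4)
    expect_equal(back$wall_time, res$wall_time, tolerance = 1e-6)
    expect_true(back$converged)
  }
  unconverged <- fixture_result(converged = FALSE)
  expect_false(parse_gaussian_log(write_gaussian_log(unconverged))$converged)
})

test_that("true-minimum screening rejects imaginary and zero modes", {
  mk <- function(f) qm_result(build_species("water"), -229.1, frequencies = f)
  expect_true(check_true_minimum(mk(c(12.3, 55.0, 1700.1))))
  expect_false(check_true_minimum(mk(c(-45.1, 55.0))))
  expect_false(check_true_minimum(mk(c(0.0, 10.0)))) # boundary is non-minimum
  expect_error(check_true_minimum(qm_result(build_species("water"), -229.1)),
               "frequencies")
})

test_that("input decks carry charge/multiplicity, route keywords and all atoms", {
  deck_lines <- function(s, f) {
    strsplit(write_engine_input(s, qm_settings(f)), "\n")[[1]]
  }
  water <- deck_lines(build_species("water"), "PBEPBE")
  expect_true(any(water == "0 1"))
  hydrox <- deck_lines(build_species("hydroxide"), "TPSSTPSS")
  expect_true(any(hydrox == "-1 1"))
  acid <- deck_lines(build_species("acid", "Benzoic Acid"), "CAM-B3LYP")
  route <- acid[1]
  expect_match(route, "opt")
  expect_match(route, "freq")
  expect_match(route, "smd")
  expect_match(route, "CAM-B3LYP/6-311\\+G\\(d,p\\)")
  # one coordinate line per atom
  expect_equal(sum(grepl("^[A-Z][a-z]? ", acid)), 21L)
  expect_error(write_engine_input(build_species("water"),
                                  qm_settings("M06-2X")),
               "supported")
})

test_that("deck and synthetic log agree on charge, multiplicity, atoms, energy", {
  s <- build_species("base", "Benzoic Acid")
  deck <- strsplit(write_engine_input(s, qm_settings()), "\n")[[1]]
  res <- qm_result(s, -571.22, frequencies = c(10, 20, 30))
  back <- parse_gaussian_log(write_gaussian_log(res, qm_settings()))
  cm <- strsplit(deck[5], " ")[[1]]
  expect_equal(as.integer(cm), c(back$structure$charge,
                                 back$structure$multiplicity))
  expect_equal(sum(grepl("^[A-Z][a-z]? ", deck)),
               length(back$structure$elements))
  expect_equal(back$gibbs_free_energy, -571.22, tolerance = 1e-9)
})

test_that("mock engine serves registered species and rejects unknown ones", {
  eng <- mock_engine()
  st <- qm_settings("CAM-B3LYP")
  acid <- run_engine(eng, build_species("acid", "Benzoic Acid"), st)
  expect_true(acid$converged)
  expect_true(check_true_minimum(acid))
  expect_equal(acid$gibbs_free_energy, -495.0) # the fixed acid gauge constant
  expect_equal(acid$wall_time, 30) # acid share of the 52-minute pair cost
  expect_equal(run_engine(eng, build_species("base", "Benzoic Acid"), st)$wall_time,
               22)
  # frequencies span 3N-6 modes
  expect_length(acid$frequencies, 3 * 21 - 6)

  stranger <- build_species("acid", "Benzoic Acid")
  stranger$compound <- "Unregistered Acid"
  expect_error(run_engine(eng, stranger, st), "no mock energy registered")
})

test_that("mock energies reproduce each target pKa through the thermochemistry", {
  eng <- mock_engine()
  tab <- reference_benchmark()
  for (f in c("CAM-B3LYP", "WB97XD")) {
    st <- qm_settings(f)
    oh <- run_engine(eng, build_species("hydroxide"), st)$gibbs_free_energy
    wat <- run_engine(eng, build_species("water"), st)$gibbs_free_energy
    for (cmpd in c("Benzoic Acid", "2-Chlorobenzoic Acid")) {
      ga <- run_engine(eng, build_species("acid", cmpd), st)$gibbs_free_energy
      gb <- run_engine(eng, build_species("base", cmpd), st)$gibbs_free_energy
      pka <- pka_from_delta_g(delta_g_dep(gb, wat, oh, ga))
      expect_equal(pka, tab[[f]][tab$compound == cmpd], tolerance = 0.005)
    }
  }
})

test_that("a pKa of 15.74 pins the mock reaction free energy at zero", {
  pseudo <- data.frame(compound = "Pseudo Acid", `CAM-B3LYP` = 15.74,
                       check.names = FALSE)
  eng <- mock_engine(pseudo)
  k <- eng$keyfun
  g <- function(kind, cmpd = NA) get(k(kind, cmpd, "CAM-B3LYP"),
                                     envir = eng$energies)
  dg <- delta_g_dep(g("base", "Pseudo Acid"), g("water"),
                    g("hydroxide"), g("acid", "Pseudo Acid"))
  expect_equal(dg, 0, tolerance = 1e-6)
})
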