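test_that("MAE recomputes the published column errors", {
  tab <- reference_benchmark()
  ref <- builtin_compounds()$pka_ref
  expect_equal(round(mae(tab[["CAM-B3LYP"]], ref), 2), 0.23)
  expect_equal(round(mae(tab[["B3PW91"]], ref), 2), 0.38)
  expect_equal(mae(ref, ref), 0)
})

test_that("MAE is nonnegative, zero only for identical columns, permutation-safe", {
  set.seed(5)
  for (rep in 1:5) {
    calc <- stats::runif(8, 1, 6)
    ref <- stats::runif(8, 1, 6)
    m <- mae(calc, ref)
    expect_gte(m, 0)
    perm <- sample(8)
    expect_equal(mae(calc[perm], ref[perm]), m, tolerance = 1e-12)
  }
  expect_error(mae(1:3, 1:4), "lengths differ")
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
})

test_that("signed deviations identify the worst-predicted compound", {
  tab <- reference_benchmark()
  panel <- builtin_compounds()
  d <- delta_pka(tab[["CAM-B3LYP"]], panel$pka_ref, panel$name)
  expect_equal(d$max_abs_compound, "2,6-Dimethylbenzoic Acid")
  expect_equal(d$max_abs_delta, 0.65, tolerance = 1e-12)
  expect_equal(unname(d$delta["Benzoic Acid"]), 0.15, tolerance = 1e-12)
  same <- delta_pka(panel$pka_ref, panel$pka_ref)
  expect_true(all(same$delta == 0))
  single <- delta_pka(4.35, 4.20)
  expect_equal(single$delta, 0.15, tolerance = 1e-12)
})

test_that("regression recovers synthetic linear data and matches the closed form", {
  x <- c(1, 2, 3, 4, 5)
  ideal <- pka_regression(x, x)
  expect_equal(ideal$slope, 1, tolerance = 1e-12)
  expect_equal(ideal$intercept, 0, tolerance = 1e-12)
  expect_equal(ideal$pearson_r, 1, tolerance = 1e-12)
  expect_equal(ideal$cod, 1, tolerance = 1e-12)

  affine <- pka_regression(2 * x + 1, x)
  expect_equal(affine$slope, 2, tolerance = 1e-9)
  expect_equal(affine$intercept, 1, tolerance = 1e-9)
  expect_equal(affine$cod, 1, tolerance = 1e-9)

  set.seed(31)
  for (rep in 1:5) {
    a <- stats::runif(1, 0.5, 2); b <- stats::runif(1, -2, 2)
    xs <- stats::rnorm(9, 4, 1)
    noisy <- a * xs + b + stats::rnorm(9, sd = 0.3)
    got <- pka_regression(noisy, xs)
    want <- ols_oracle(xs, noisy)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-9)
    expect_equal(got$pearson_r, want$pearson_r, tolerance = 1e-9)
    expect_equal(got$cod, want$cod, tolerance = 1e-9)
    # exact recovery without noise
    clean <- pka_regression(a * xs + b, xs)
    expect_equal(clean$slope, a, tolerance = 1e-9)
    expect_equal(clean$intercept, b, tolerance = 1e-9)
  }
  expect_error(pka_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pka_regression(c(1, 2, 3), c(2, 2, 2)), "variance")
})

test_that("the published calc-vs-ref slope for the best functional is near unity", {
  tab <- reference_benchmark()
  ref <- builtin_compounds()$pka_ref
  fit <- pka_regression(tab[["CAM-B3LYP"]], ref)
  want <- ols_oracle(ref, tab[["CAM-B3LYP"]])
  expect_equal(fit$slope, want$slope, tolerance = 1e-9)
  expect_equal(fit$slope, 0.985, tolerance = 0.005)
  expect_equal(fit$n, 11L)
})

test_that("cost accounting sums acid/base pairs and averages over compounds", {
  flat <- expand.grid(compound = paste("acid", 1:11),
                      kind = c("acid", "base"),
                      stringsAsFactors = FALSE)
  flat$functional <- "PBE1PBE"
  flat$minutes <- 10
  expect_equal(unname(cost_summary(flat)), 20)
  single <- data.frame(compound = "Benzoic Acid", functional = "CAM-B3LYP",
                       kind = c("acid", "base"), minutes = c(30, 22))
  expect_equal(unname(cost_summary(single)), 52)
  expect_error(cost_summary(single[1, ]), "unpaired")
  expect_error(cost_summary(data.frame()), "non-empty")
})

test_that("rendered tables keep the published layout and stay self-consistent", {
  panel <- builtin_compounds()
  tab <- reference_benchmark()
  bt <- benchmark_table(panel$name, panel$pka_ref,
                        tab[setdiff(names(tab), "compound")])
  md <- render_benchmark(bt, "markdown")
  benzoic_row <- grep("^\\| Benzoic Acid", strsplit(md, "\n")[[1]], value = TRUE)
  expect_match(benzoic_row, "4.20", fixed = TRUE)
  expect_match(benzoic_row, "4.35", fixed = TRUE)
  lines <- strsplit(md, "\n")[[1]]
  expect_match(lines[length(lines)], "^\\| MAE") # MAE row last
  # MAE row always recomputes from the table's own columns
  expect_equal(unname(bt$mae_row["CAM-B3LYP"]),
               mae(bt$columns[["CAM-B3LYP"]], bt$reference))
  expect_equal(round(unname(bt$mae_row["B3PW91"]), 2), 0.38)

  csv <- render_benchmark(bt, "csv")
  parsed <- utils::read.csv(text = csv, check.names = FALSE)
  expect_equal(parsed$COMPOUND[1:11], panel$name)
  expect_equal(parsed$`CAM-B3LYP`[1], 4.35)

  expect_error(render_benchmark(bt, "html"), "arg")
})

test_that("JSON rendering round-trips the benchmark table", {
  panel <- builtin_compounds()
  tab <- reference_benchmark()
  bt <- benchmark_table(panel$name, panel$pka_ref,
                        tab[setdiff(names(tab), "compound")],
                        cost = reference_costs())
  back <- read_benchmark(render_benchmark(bt, "json"))
  expect_identical(back$compounds, bt$compounds)
  expect_equal(back$reference, bt$reference)
  expect_equal(back$columns, bt$columns)
  expect_equal(back$mae_row, bt$mae_row)
  expect_equal(back$cost, bt$cost)
})

test_that("an empty compound set renders to a header-only table", {
  bt <- benchmark_table(character(0), numeric(0),
                        list(`CAM-B3LYP` = numeric(0)))
  md <- strsplit(render_benchmark(bt, "markdown"), "\n")[[1]]
  expect_length(md, 2L) # header + separator only
  csv <- strsplit(render_benchmark(bt, "csv"), "\n")[[1]]
  expect_length(csv, 1L)
})
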