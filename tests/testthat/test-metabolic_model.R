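test_that("fixture model loads with the documented shape and survives file round-trips", {
  m <- fig1_fixture()
  expect_s3_class(m, "metabolic_model")
  expect_length(m$reactions, 33)
  expect_identical(m$conditions, c("control", "stressed"))
  expect_length(state_metabolites(m), 4)
  expect_length(fitting_targets(m), 11)

  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_metabolic_model(m, path)
    back <- read_metabolic_model(path)
    expect_identical(names(back$reactions), names(m$reactions))
    expect_equal(initial_amounts(back), initial_amounts(m))
    for (rid in names(m$reactions)) {
      expect_equal(back$reactions[[rid]]$vmax, m$reactions[[rid]]$vmax,
                   tolerance = 1e-12)
      expect_equal(back$reactions[[rid]]$substrates$km,
                   m$reactions[[rid]]$substrates$km, tolerance = 1e-12)
    }
  }
})

test_that("invalid model files are rejected with the offending id", {
  m <- two_species_model()
  m$reactions[["R1"]]$substrates$km <- 0
  expect_error(validate_metabolic_model(m), "R1.*km", ignore.case = TRUE)

  m2 <- two_species_model()
  m2$reactions[["R1"]]$products$metabolite <- "Ghost"
  expect_error(validate_metabolic_model(m2), "Ghost")

  path <- withr::local_tempfile(fileext = ".yaml")
  obj <- statevar:::model_to_list(two_species_model())
  obj$schema_version <- 99
  yaml::write_yaml(obj, path)
  expect_error(read_metabolic_model(path), "schema_version")
})

test_that("reaction_rate follows multiplicative Michaelis-Menten kinetics", {
  rx <- reaction_spec("R1", data.frame(metabolite = "A", coef = 1, km = 2),
                      data.frame(metabolite = "B", coef = 1),
                      c(control = 3))
  expect_equal(reaction_rate(rx, c(A = 2, B = 0), 3), 1.5)  # half saturation
  expect_equal(reaction_rate(rx, c(A = 0, B = 0), 3), 0)
  expect_error(reaction_rate(rx, c(A = -1, B = 0), 3), "negative")

  rx2 <- reaction_spec("R2",
                       data.frame(metabolite = c("A", "B"), coef = c(1, 1),
                                  km = c(0.1, 0.2)),
                       data.frame(metabolite = "C", coef = 1),
                       c(control = 5))
  expect_equal(reaction_rate(rx2, c(A = 1e6, B = 1e6, C = 0), 5), 5,
               tolerance = 1e-5)

  # monotone in every substrate amount and bounded by vmax
  set.seed(1)
  for (i in 1:50) {
    a <- runif(2, 0, 10)
    r1 <- reaction_rate(rx2, c(A = a[1], B = a[2], C = 0), 5)
    r2 <- reaction_rate(rx2, c(A = a[1] * 1.5, B = a[2], C = 0), 5)
    r3 <- reaction_rate(rx2, c(A = a[1], B = a[2] * 1.5, C = 0), 5)
    expect_true(r1 <= r2 && r1 <= r3 && r2 <= 5 && r3 <= 5)
  }
})

test_that("non-competitive inhibition multiplies in as Ki/(Ki + I)", {
  rx <- reaction_spec("R1", data.frame(metabolite = "A", coef = 1, km = 1),
                      data.frame(metabolite = "B", coef = 1),
                      c(control = 2),
                      inhibitor = list(metabolite = "I", ki = 0.5))
  expect_equal(reaction_rate(rx, c(A = 1, I = 0), 2), 1)
  expect_equal(reaction_rate(rx, c(A = 1, I = 0.5), 2), 0.5)
})

test_that("condition interpolation is exact at the endpoints and affine", {
  m <- fig1_fixture()
  m0 <- interpolate_vmax(m, 0)
  m1 <- interpolate_vmax(m, 1)
  for (rid in names(m$reactions)) {
    expect_equal(unname(m0$reactions[[rid]]$vmax[[1]]),
                 unname(m$reactions[[rid]]$vmax[["control"]]))
    expect_equal(unname(m1$reactions[[rid]]$vmax[[1]]),
                 unname(m$reactions[[rid]]$vmax[["stressed"]]))
  }
  # midpoint of two lambdas equals the mean of their Vmax sets
  set.seed(4)
  for (i in 1:5) {
    ab <- sort(runif(2))
    va <- vapply(interpolate_vmax(m, ab[1])$reactions, function(r) r$vmax[[1]], numeric(1))
    vb <- vapply(interpolate_vmax(m, ab[2])$reactions, function(r) r$vmax[[1]], numeric(1))
    vm <- vapply(interpolate_vmax(m, mean(ab))$reactions, function(r) r$vmax[[1]], numeric(1))
    expect_equal(vm, (va + vb) / 2, tolerance = 1e-12)
  }
  expect_error(interpolate_vmax(m, -0.1), "lambda")
  expect_error(interpolate_vmax(m, 1.1), "lambda")
})

test_that("overexpress edits exactly one Vmax and round-trips", {
  m <- fig1_fixture()
  m4 <- overexpress(m, "R19", 4.0)
  expect_equal(m4$reactions[["R19"]]$vmax[["control"]],
               4 * m$reactions[["R19"]]$vmax[["control"]])
  expect_equal(m4$reactions[["R19"]]$vmax[["stressed"]],
               m$reactions[["R19"]]$vmax[["stressed"]])
  others <- setdiff(names(m$reactions), "R19")
  expect_equal(lapply(m4$reactions[others], `[[`, "vmax"),
               lapply(m$reactions[others], `[[`, "vmax"))

  expect_equal(overexpress(m, "R19", 1.0), m)
  expect_equal(overexpress(overexpress(m, "R16", 2.5), "R16", 1 / 2.5), m,
               tolerance = 1e-12)
  expect_error(overexpress(m, "R99", 4), "R99")
  expect_error(overexpress(m, "R19", -1), "positive")
})
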