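test_that("null dynamics and unperturbed initial conditions are preserved", {
  m <- two_species_model(vmax = 0)
  tc <- simulate_timecourse(select_condition(m, "control"))
  expect_equal(tc$times, 0:4)
  expect_true(all(tc$amounts[, "A"] == 1))
  expect_true(all(tc$amounts[, "B"] == 0))

  m2 <- select_condition(cycle_model(), "control")
  tc2 <- simulate_timecourse(m2)
  expect_equal(unname(tc2$amounts[1, ]), c(2, 1, 0.5))
})

test_that("two-species decay matches the analytic solution and conserves mass", {
  vmax <- 0.7; km <- 0.4; a0 <- 1.5
  m <- select_condition(two_species_model(vmax, km, a0), "control")
  tc <- simulate_timecourse(m, duration = 4, sample_interval = 0.5)
  a_exact <- analytic_mm_decay(tc$times, vmax, km, a0)
  expect_equal(unname(tc$amounts[, "A"]), a_exact, tolerance = 1e-7)
  expect_true(all(diff(tc$amounts[, "A"]) <= 0))
  expect_true(all(diff(tc$amounts[, "B"]) >= 0))
  expect_equal(unname(rowSums(tc$amounts)), rep(a0, length(tc$times)),
               tolerance = 1e-7)
})

test_that("closed cycles conserve total amount within solver tolerance", {
  m <- select_condition(cycle_model(), "control")
  tc <- simulate_timecourse(m, duration = 10, sample_interval = 1)
  expect_equal(unname(rowSums(tc$amounts)), rep(3.5, 11), tolerance = 1e-7)
})

test_that("perturbations double initial amounts of the named state metabolites", {
  m <- select_condition(cycle_model(), "control")
  tc <- simulate_timecourse(m, perturbation(c("A", "B")))
  expect_equal(unname(tc$amounts[1, ]), c(4, 2, 0.5))
  expect_error(simulate_timecourse(m, perturbation("C")), "state")
})

test_that("enumerate_perturbations counts 2^k subsets in canonical order", {
  perts <- enumerate_perturbations(fig1_fixture())
  expect_length(perts, 16)
  expect_length(perts[[1]]$doubled_set, 0)
  expect_equal(perts[[2]]$doubled_set, state_metabolites(fig1_fixture())[1])
  expect_length(perts[[16]]$doubled_set, 4)
  # all subsets distinct
  keys <- vapply(perts, function(p) paste(sort(p$doubled_set), collapse = "+"),
                 character(1))
  expect_length(unique(keys), 16)

  m1 <- two_species_model()
  expect_length(enumerate_perturbations(m1), 2)
  m0 <- two_species_model()
  m0$metabolites$is_state_metabolite <- FALSE
  expect_error(enumerate_perturbations(m0), "state metabolites")
})

test_that("batch_simulate preserves order, is deterministic, and labels failures", {
  m <- interpolate_vmax(fig1_fixture(), 0)
  perts <- enumerate_perturbations(m)
  runs1 <- batch_simulate(m, perts)
  runs2 <- batch_simulate(m, perts)
  expect_length(runs1, 16)
  expect_identical(lapply(runs1, `[[`, "amounts"),
                   lapply(runs2, `[[`, "amounts"))
  expect_equal(vapply(runs1, `[[`, character(1), "run_label")[1], "none")
  expect_identical(batch_simulate(m, list()), list())
})

test_that("halving tolerances changes sampled amounts by < 0.1% relative", {
  m <- interpolate_vmax(fig1_fixture(), 0.5)
  tc1 <- simulate_timecourse(m, control = solver_control(rtol = 1e-8, atol = 1e-10))
  tc2 <- simulate_timecourse(m, control = solver_control(rtol = 5e-9, atol = 5e-11))
  rel <- abs(tc1$amounts - tc2$amounts) / pmax(abs(tc2$amounts), 1e-8)
  expect_lt(max(rel), 1e-3)
})

test_that("timecourses tidy into the documented CSV layout", {
  m <- select_condition(two_species_model(), "control")
  tc <- simulate_timecourse(m)
  df <- as.data.frame(tc)
  expect_named(df, c("run_label", "time_days", "metabolite_id", "amount"))
  expect_equal(nrow(df), 5 * 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourses_csv(list(tc), path)
  back <- utils::read.csv(path)
  expect_equal(back$amount, df$amount, tolerance = 1e-12)
})
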