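test_that("lambda sweep has 33 consistent rows and a degenerate limit", {
  m <- fig1_fixture()
  sweep <- lambda_sweep(m)
  expect_s3_class(sweep, "lambda_sweep")
  expect_equal(nrow(sweep), 33)
  expect_equal(sweep$lambda, seq(0, 32) / 32)
  expect_true(all(diff(sweep$lambda) > 0))
  expect_true(all(sweep$n_runs == 16))

  # lambda = 0 row equals the standalone control-model experiment
  standalone <- metabolic_state_experiment(interpolate_vmax(m, 0))
  expect_equal(sweep$variation_of_state[1], standalone$variation_of_state)
  expect_equal(sweep$robustness[1], standalone$robustness)

  # a model with identical condition Vmax sets sweeps flat
  flat <- m
  for (i in seq_along(flat$reactions))
    flat$reactions[[i]]$vmax[["stressed"]] <- flat$reactions[[i]]$vmax[["control"]]
  sflat <- lambda_sweep(flat, lambdas = c(0, 0.5, 1))
  expect_equal(sflat$variation_of_state, rep(sflat$variation_of_state[1], 3))
  expect_equal(sflat$robustness, rep(sflat$robustness[1], 3))
})

test_that("the flooded endpoint loses variation of state and robustness", {
  m <- fig1_fixture()
  r0 <- metabolic_state_experiment(interpolate_vmax(m, 0))
  r1 <- metabolic_state_experiment(interpolate_vmax(m, 1))
  expect_lt(r1$variation_of_state, r0$variation_of_state)
  expect_lt(r1$robustness, r0$robustness)
  # frozen regression values from the first verified run of this fixture
  expect_equal(r0$variation_of_state, 2.0, tolerance = 1e-8)
  expect_equal(r0$robustness, 0.75, tolerance = 1e-8)
  expect_equal(r1$variation_of_state, 0.33729007, tolerance = 1e-6)
  expect_equal(r1$robustness, 0, tolerance = 1e-8)
})

test_that("region split at 0.375 gives groups (12, 21) and a rank-sum report", {
  sweep <- lambda_sweep(fig1_fixture())
  rep <- region_median_test(sweep, cut = 0.375)
  expect_equal(rep$n_low, 12)
  expect_equal(rep$n_high, 21)
  expect_gt(rep$median_low, rep$median_high)  # entropy is lost toward lambda = 1
  expect_s3_class(rep$test, "rank_sum_report")
  expect_lt(rep$test$p, 0.05)
  expect_error(region_median_test(sweep, cut = -1), "empty")
})

test_that("over-expression screen covers every reaction and runs both tests", {
  m <- fig1_fixture()
  ann <- read_annotation_csv(system.file("extdata",
                                         "expressed_proteins_synthetic.csv",
                                         package = "statevar"))
  scr <- overexpression_screen(m, factor = 4, annotation = ann)
  expect_equal(nrow(scr$screen), 33)
  expect_setequal(scr$screen$reaction_id, names(m$reactions))
  expect_equal(scr$baseline$label, "control")
  expect_true(all(scr$screen$robustness >= 0 & scr$screen$robustness <= 1))
  # binomial quadrant classification matches a brute-force recount
  base <- scr$baseline
  changed <- scr$screen$expressed &
    (scr$screen$variation_of_state != base$variation_of_state |
       scr$screen$robustness != base$robustness)
  k <- sum(changed & scr$screen$variation_of_state < base$variation_of_state &
             scr$screen$robustness < base$robustness)
  expect_equal(scr$binomial_test$n, sum(changed))
  expect_equal(scr$binomial_test$k, k)
  expect_equal(scr$binomial_test$p,
               binomial_point(sum(changed), k, 0.25))
  expect_s3_class(scr$proportion_test, "proportion_report")
  expect_equal(scr$proportion_test$sided, "one")
})

test_that("PMA experiment runs 256 trajectories per condition and loses entropy", {
  net <- ladder_fixture()
  pma <- pma_experiment(net)
  expect_equal(pma$before$n_runs, 256)
  expect_equal(pma$after$n_runs, 256)
  expect_lt(pma$after$variation_of_state, pma$before$variation_of_state)
  expect_lt(pma$after$robustness, pma$before$robustness)
  expect_equal(pma$percent_of_max,
               percent_of_max(pma$before$variation_of_state,
                              pma$after$variation_of_state, 256))
  # frozen regression values from the first verified run of this fixture
  expect_equal(pma$before$variation_of_state, 3.73611675, tolerance = 1e-6)
  expect_equal(pma$after$variation_of_state, 2.93478401, tolerance = 1e-6)
  expect_equal(pma$before$robustness, 0.25537109, tolerance = 1e-6)
  expect_equal(pma$after$robustness, 0.125, tolerance = 1e-8)
})

test_that("enforced expression dampens (case1) or maintains (case2) variation", {
  net <- ladder_fixture()
  base <- boolean_state_experiment(statevar:::strip_inputs(net), label = "off")
  c1 <- enforced_expression_experiment(net, "case1")
  c2 <- enforced_expression_experiment(net, "case2")
  expect_lt(c1$variation_of_state, base$variation_of_state)
  expect_gte(c2$variation_of_state, base$variation_of_state - 1e-9)
  # frozen regression values from the first verified run of this fixture
  expect_equal(c1$variation_of_state, 1.50595022, tolerance = 1e-6)
  expect_equal(c2$variation_of_state, 4.06586499, tolerance = 1e-6)

  every <- enforced_expression_experiment(net, "case1",
                                          case1_modules = net$modules)
  expect_equal(every$variation_of_state, 0)
  expect_error(enforced_expression_experiment(net, "case3"), "arg")
  expect_error(enforced_expression_experiment(net, "case2",
                                              case2_modules = "Z9"), "Z9")
})

test_that("experiments are pure functions of their inputs", {
  net <- ladder_fixture()
  expect_equal(pma_experiment(net)$after$variation_of_state,
               pma_experiment(net)$after$variation_of_state)
  m <- fig1_fixture()
  s1 <- lambda_sweep(m, lambdas = c(0, 0.5, 1))
  s2 <- lambda_sweep(m, lambdas = c(0, 0.5, 1))
  expect_identical(s1$variation_of_state, s2$variation_of_state)
})
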