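test_that("discretize applies the inclusive 2x accumulation threshold", {
  m <- two_species_model(a0 = 1)
  tc <- structure(list(times = 0:2,
                       amounts = cbind(A = c(1, 2.5, 1.9), B = c(0, 0, 0)),
                       run_label = "r"), class = "timecourse")
  st <- discretize(tc, m)
  expect_equal(unname(st$states[, 1]), c(0L, 1L, 0L))
  # doubled-initial perturbation is accumulated at t = 0 (amount exactly 2x)
  tc$amounts[1, "A"] <- 2
  expect_equal(discretize(tc, m)$states[1, 1], c(A = 1L))
  expect_equal(discretize(tc, m, strict = TRUE)$states[1, 1], c(A = 0L))
  tc$amounts <- tc$amounts[, "B", drop = FALSE]
  expect_error(discretize(tc, m), "state metabolite")
})

test_that("pool_states counts occurrences inside the inclusive window", {
  m <- interpolate_vmax(fig1_fixture(), 0)
  trajs <- lapply(batch_simulate(m, enumerate_perturbations(m)),
                  discretize, model = m)
  dist <- pool_states(trajs, window = c(1, 4))
  expect_equal(dist$total, 64)  # 16 runs x 4 post-initial days
  expect_equal(sum(dist$counts), dist$total)

  one <- state_trajectory(matrix(c(1L, 0L), 1), times = 0)
  d1 <- pool_states(list(one), window = c(0, 0))
  expect_equal(d1$total, 1)
  expect_length(d1$counts, 1)
  expect_error(pool_states(list()), "no trajectories")
  expect_error(pool_states(list(one), window = c(5, 9)), "window")
})

test_that("variation of state reproduces the printed entropy edge cases", {
  u16 <- state_distribution(stats::setNames(rep(1L, 16), sprintf("%04d", 1:16)), 4)
  expect_equal(variation_of_state(u16), 4)
  single <- state_distribution(c("0000" = 10L), 4)
  expect_equal(variation_of_state(single), 0)
  d <- state_distribution(c("00" = 2L, "01" = 1L, "10" = 1L), 2)
  expect_equal(variation_of_state(d), 1.5)
})

test_that("entropy is bounded, permutation invariant, and streaming equals batch", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(2:32, 1)
    counts <- stats::setNames(rpois(n, 3) + 1L, paste0("s", seq_len(n)))
    d <- state_distribution(counts, 5)
    h <- variation_of_state(d)
    expect_gte(h, 0)
    expect_lte(h, log2(n) + 1e-12)
    perm <- sample(n)
    d2 <- state_distribution(stats::setNames(counts[perm], names(counts)), 5)
    expect_equal(variation_of_state(d2), h)
  }

  m <- interpolate_vmax(fig1_fixture(), 0.25)
  trajs <- lapply(batch_simulate(m, enumerate_perturbations(m)),
                  discretize, model = m)
  batch <- pool_states(trajs, c(1, 4))
  acc <- empty_state_counter(4)
  for (tr in trajs) acc <- add_states(acc, tr, c(1, 4))
  stream <- state_distribution(acc$counts, 4)
  expect_equal(variation_of_state(stream), variation_of_state(batch),
               tolerance = 1e-12)
})

test_that("robustness matches its definition and a brute-force recount", {
  ref <- state_trajectory(rbind(c(0, 0, 1, 1), c(1, 1, 1, 1)))
  all_match <- list(state_trajectory(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))))
  expect_equal(robustness(all_match, ref), 1)
  none <- list(state_trajectory(rbind(c(0, 0, 1, 1), c(1, 1, 0, 0))))
  expect_equal(robustness(none, ref), 0)
  quarter <- list(state_trajectory(rbind(c(0, 0, 1, 1), c(0, 1, 0, 0))))
  expect_equal(robustness(quarter, ref), 0.25)

  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:6, 1); nr <- sample(1:8, 1); nt <- sample(2:5, 1)
    ref <- state_trajectory(matrix(rbinom(nt * k, 1, 0.5), nt, k))
    perturbed <- lapply(seq_len(nr), function(j)
      state_trajectory(matrix(rbinom(nt * k, 1, 0.5), nt, k)))
    expect_equal(robustness(perturbed, ref),
                 oracle_robustness(perturbed, ref))
  }
})

test_that("percent_of_max reproduces the four printed percentages", {
  expect_identical(percent_of_max(0.81, 0, 16), 20L)
  expect_identical(percent_of_max(3.80, 2.65, 256), 14L)
  expect_identical(percent_of_max(3.80, 2.05, 256), 22L)
  expect_identical(percent_of_max(3.80, 4.19, 256), -5L)
  expect_identical(percent_of_max(1.23, 1.23, 64), 0L)
  expect_error(percent_of_max(1, 0, 1), "n_states")
})

test_that("state distributions serialize to the tidy CSV layout", {
  d <- state_distribution(c("10" = 3L, "01" = 1L), 2)
  df <- write_state_distribution_csv(d)
  expect_named(df, c("state", "count", "probability"))
  expect_equal(sum(df$probability), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_state_distribution_csv(d, path)
  expect_equal(utils::read.csv(path, colClasses = c(state = "character"))$state,
               c("01", "10"))
})
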