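# Shared in-code fixtures and independent oracles.

# minimal closed two-species system A -> B
two_species_model <- function(vmax = 1, km = 0.5, a0 = 1, b0 = 0) {
  metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"),
               initial_amount = c(a0, b0),
               is_fitting_target = c(TRUE, TRUE),
               is_state_metabolite = c(TRUE, FALSE)),
    list(reaction_spec("R1",
                       data.frame(metabolite = "A", coef = 1, km = km),
                       data.frame(metabolite = "B", coef = 1),
                       c(control = vmax, stressed = vmax))),
    conditions = c("control", "stressed"))
}

# closed three-species cycle A -> B -> C -> A (total conserved)
cycle_model <- function() {
  rx <- function(id, s, p, v, km)
    reaction_spec(id, data.frame(metabolite = s, coef = 1, km = km),
                  data.frame(metabolite = p, coef = 1),
                  c(control = v, stressed = v))
  metabolic_model(
    data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
               initial_amount = c(2, 1, 0.5),
               is_fitting_target = TRUE,
               is_state_metabolite = c(TRUE, TRUE, FALSE)),
    list(rx("R1", "A", "B", 0.8, 0.6), rx("R2", "B", "C", 0.5, 0.4),
         rx("R3", "C", "A", 0.9, 0.7)))
}

# analytic single-reaction Michaelis-Menten decay:
# K ln(A0/A) + (A0 - A) = V t  (implicit; inverted by root finding)
analytic_mm_decay <- function(t, vmax, km, a0) {
  vapply(t, function(tt) {
    if (tt == 0) return(a0)
    stats::uniroot(function(a) km * log(a0 / a) + (a0 - a) - vmax * tt,
                   interval = c(1e-12, a0), tol = 1e-12)$root
  }, numeric(1))
}

# seeded random signed Boolean module network
random_boolean_network <- function(n_modules, n_edges, seed,
                                   clamps = NULL, inputs = list()) {
  set.seed(seed)
  mods <- paste0("M", seq_len(n_modules))
  edges <- data.frame(
    source = sample(mods, n_edges, replace = TRUE),
    target = sample(mods, n_edges, replace = TRUE),
    sign = sample(c(-1L, 1L), n_edges, replace = TRUE),
    multiplicity = sample(1:3, n_edges, replace = TRUE))
  boolean_module_network(mods, edges, inputs = inputs, clamps = clamps,
                         reference_state = rep(0L, n_modules))
}

# independent brute-force synchronous update (plain loops; no shared code
# with the package's matrix-based stepper)
oracle_boolean_step <- function(network, state, t) {
  mods <- network$modules
  nxt <- integer(length(mods))
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    s <- 0
    e <- network$edges
    for (k in seq_len(NROW(e)))
      if (e$target[k] == m)
        s <- s + e$sign[k] * e$multiplicity[k] * state[match(e$source[k], mods)]
    if (m %in% names(network$inputs)) {
      sch <- network$inputs[[m]]
      s <- s + if (t < sch$onset_time) sch$before_value else sch$after_value
    }
    nxt[mi] <- if (s > 0) 1L else if (s < 0) 0L else state[mi]
    if (m %in% names(network$clamps)) nxt[mi] <- network$clamps[[m]]
  }
  nxt
}

# independent robustness recount over (run, module) pairs
oracle_robustness <- function(perturbed, reference) {
  ref0 <- reference$states[1, ]
  hits <- 0; total <- 0
  for (tr in perturbed) {
    fin <- tr$states[nrow(tr$states), ]
    for (j in seq_along(ref0)) {
      total <- total + 1
      if (fin[j] == ref0[j]) hits <- hits + 1
    }
  }
  hits / total
}

# memoized heavy fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())
fig1_fixture <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- make_metabolic_fixture(generator_config(seed = 1))
  .fixture_env$model
}
ladder_fixture <- function() {
  if (is.null(.fixture_env$net))
    .fixture_env$net <- make_ladder_network(generator_config(seed = 1))
  .fixture_env$net
}
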