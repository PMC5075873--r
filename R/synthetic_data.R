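#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator so that a whole input set
#' is reproducible bit-for-bit from a single integer.
#'
#' @param seed integer seed fixing all generator randomness.
#' @param topology `"fig1"` for the packaged glycolysis / fermentation / TCA /
#'   GABA-shunt reconstruction, `"random"` for a seeded random
#'   Michaelis-Menten network.
#' @param n_metabolites,n_reactions size of a random network.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   observation noise (0 = noiseless).
#' @param n_replicates replicates averaged per observed sample.
#' @param vmax_fold_change_range `(low, high)` range of stressed/control Vmax
#'   fold changes drawn for random networks.
#' @param n_modules number of Boolean modules (even; two channels).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1, topology = c("fig1", "random"),
                             n_metabolites = 8, n_reactions = 10,
                             noise_cv = 0.05, n_replicates = 3,
                             vmax_fold_change_range = c(0.5, 4),
                             n_modules = 8) {
  topology <- match.arg(topology)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(seed = as.integer(seed), topology = topology,
                 n_metabolites = n_metabolites, n_reactions = n_reactions,
                 noise_cv = noise_cv, n_replicates = n_replicates,
                 vmax_fold_change_range = vmax_fold_change_range,
                 n_modules = n_modules),
            class = "generator_config")
}

# ---------------------------------------------------------------------------
# The fig1-style soybean reconstruction.
#
# SYNTHETIC: the published supplementary parameter files are not available,
# so this model is an authored stand-in with the same shape: glycolysis,
# fermentation, TCA cycle and GABA shunt; 33 irreversible reactions; 11
# fitting-target metabolites; the four GABA-shunt members (2OG, Glu, GABA,
# succinate) as state metabolites; reaction ids R16 (alanine
# aminotransferase) and R19 (glutamate decarboxylase) match the two ids the
# source network names.  Short-lived intermediates and cofactors (G6P, PEP,
# OAA, fumarate, SSA, acetyl-CoA, NAD, GTP) are lumped into their
# neighbouring steps so that nearly every rate is a function of observed
# (fitting-target) pools only; this keeps the Vmax parameterization
# identifiable from the 11 observed time courses, which the full
# intermediate-resolved variant is not (near-null sensitivity directions
# along invisible futile cycles).  Kinetic values are BRENDA-plausible
# orders of magnitude on the day scale, tuned so that under the stressed
# (flooded) Vmax set all four state metabolites at least double within the
# 4-day simulation, while the control set keeps them below double.
# ---------------------------------------------------------------------------
fig1_metabolites <- function() {
  m <- function(id, name, x0, target = FALSE, state = FALSE)
    data.frame(id = id, name = name, initial_amount = x0,
               is_fitting_target = target, is_state_metabolite = state,
               stringsAsFactors = FALSE)
  rbind(
    m("Glc", "glucose reserve", 20),
    m("Pyr", "pyruvate", 0.4, target = TRUE),
    m("Lac", "lactate", 0.25, target = TRUE),
    m("EtOH", "ethanol", 0.2),
    m("Cit", "citrate", 2.5, target = TRUE),
    m("2OG", "2-oxoglutarate", 0.8, target = TRUE, state = TRUE),
    m("Suc", "succinate", 1.5, target = TRUE, state = TRUE),
    m("Mal", "malate", 3.5, target = TRUE),
    m("Glu", "glutamate", 2.0, target = TRUE, state = TRUE),
    m("GABA", "gamma-aminobutyrate", 0.9, target = TRUE, state = TRUE),
    m("Ala", "alanine", 0.8, target = TRUE),
    m("Asp", "aspartate", 2.5, target = TRUE),
    m("Gln", "glutamine", 3.0, target = TRUE),
    m("LDHi", "lactate dehydrogenase inhibitor", 0.05))
}

# id | substrates (metabolite, coef, km) | products | control | stressed vmax
fig1_reaction_table <- function() {
  rx <- function(id, sub, prod, v_ctl, v_str, inhibitor = NULL)
    list(id = id, sub = sub, prod = prod, v_ctl = v_ctl, v_str = v_str,
         inhibitor = inhibitor)
  list(
    # glycolysis (lumped); alanine deamination to pyruvate
    rx("R1",  list(c("Glc", 1, 10)),   list(c("Pyr", 1)),               0.8, 2.2),
    rx("R2",  list(c("Ala", 1, 3)),    list(c("Pyr", 1)),               0.25, 0.1),
    # fermentative succinate production from malate
    rx("R3",  list(c("Mal", 1, 4)),    list(c("Suc", 1)),               0.3, 2.8),
    # cytosolic citrate to malate bypass
    rx("R4",  list(c("Cit", 1, 3)),    list(c("Mal", 1)),               0.25, 0.2),
    rx("R5",  list(c("Gln", 1, 3)),    list(),                          0.3, 0.2),
    # fermentation
    rx("R6",  list(c("Pyr", 1, 0.5)),  list(c("Lac", 1)),               0.6, 1.8,
       inhibitor = list(metabolite = "LDHi", ki = 0.2)),
    rx("R7",  list(c("Lac", 1, 0.6)),  list(c("Pyr", 1)),               0.5, 0.2),
    # TCA cycle (lumped over acetyl-CoA, isocitrate, succinyl-CoA, OAA)
    rx("R8",  list(c("Pyr", 1, 1), c("Mal", 1, 1.5)), list(c("Cit", 1)), 0.9, 0.45),
    rx("R9",  list(c("Ala", 1, 1.5)),  list(),                          0.25, 0.15),
    rx("R10", list(c("Cit", 1, 1.2)),  list(c("2OG", 1)),               0.55, 0.7),
    rx("R11", list(c("Glu", 1, 8)),    list(),                          0.3, 0.15),
    rx("R12", list(c("2OG", 1, 1)),    list(c("Suc", 1)),               0.4, 0.12),
    rx("R13", list(c("Suc", 1, 4)),    list(),                          0.3, 0.1),
    rx("R14", list(c("Suc", 1, 1.5)),  list(c("Mal", 1)),               0.6, 0.1),
    rx("R15", list(c("Lac", 1, 2)),    list(),                          0.2, 0.5),
    # alanine aminotransferase pair
    rx("R16", list(c("Pyr", 1, 0.8), c("Glu", 1, 3)),
       list(c("Ala", 1), c("2OG", 1)),                                  0.5, 3.5),
    rx("R17", list(c("Ala", 1, 1.2), c("2OG", 1, 0.6)),
       list(c("Pyr", 1), c("Glu", 1)),                                  0.4, 0.25),
    # GABA shunt
    rx("R18", list(c("2OG", 1, 0.6)),  list(c("Glu", 1)),               0.35, 0.15),
    rx("R19", list(c("Glu", 1, 4)),    list(c("GABA", 1)),              0.45, 4.0),
    rx("R20", list(c("GABA", 1, 0.5)), list(c("Suc", 1)),               0.4, 0.3),
    rx("R21", list(c("GABA", 1, 2.5), c("Pyr", 1, 1)),
       list(c("Suc", 1), c("Ala", 1)),                                  0.3, 1.8),
    # malate hub
    rx("R22", list(c("Mal", 1, 2)),    list(c("Pyr", 1)),               0.35, 0.6),
    # glutamate synthase (GOGAT)
    rx("R23", list(c("Gln", 1, 2), c("2OG", 1, 1)), list(c("Glu", 2)),  0.3, 0.5),
    rx("R24", list(c("Mal", 1, 0.8)),  list(),                          0.3, 0.2),
    # aspartate aminotransferase pair (over the malate/OAA pool)
    rx("R25", list(c("Mal", 1, 1.8), c("Glu", 1, 3.5)),
       list(c("Asp", 1), c("2OG", 1)),                                  0.5, 0.4),
    rx("R26", list(c("Asp", 1, 1.4), c("2OG", 1, 0.9)),
       list(c("Mal", 1), c("Glu", 1)),                                  0.4, 0.3),
    # glutamine cycle
    rx("R27", list(c("Glu", 1, 2.5)),  list(c("Gln", 1)),               0.5, 0.3),
    rx("R28", list(c("Gln", 1, 1.5)),  list(c("Glu", 1)),               0.35, 0.5),
    rx("R29", list(c("Cit", 1, 0.8)),  list(),                          0.15, 0.1),
    # alanine from glutamine transamination
    rx("R30", list(c("Pyr", 1, 1), c("Gln", 1, 2)),
       list(c("Ala", 1), c("Glu", 1)),                                  0.25, 0.4),
    # proteolytic glutamate release (zero-order source)
    rx("R31", list(),                  list(c("Glu", 1)),               0.15, 4.0),
    rx("R32", list(c("Pyr", 1, 6)),    list(c("EtOH", 1)),              0.3, 1.4),
    rx("R33", list(c("Asp", 1, 2)),    list(),                          0.25, 0.15))
}

fig1_model <- function() {
  mets <- fig1_metabolites()
  rxns <- lapply(fig1_reaction_table(), function(r) {
    subs <- if (length(r$sub) > 0)
      data.frame(metabolite = vapply(r$sub, `[`, character(1), 1),
                 coef = as.numeric(vapply(r$sub, `[`, character(1), 2)),
                 km = as.numeric(vapply(r$sub, `[`, character(1), 3)),
                 stringsAsFactors = FALSE)
    prods <- if (length(r$prod) > 0)
      data.frame(metabolite = vapply(r$prod, `[`, character(1), 1),
                 coef = as.numeric(vapply(r$prod, `[`, character(1), 2)),
                 stringsAsFactors = FALSE)
    reaction_spec(r$id, subs, prods,
                  c(control = r$v_ctl, stressed = r$v_str), r$inhibitor)
  })
  metabolic_model(mets, rxns)
}

#' Generate a metabolic model fixture
#'
#' `topology = "fig1"` returns the packaged synthetic reconstruction of a
#' flooding-stress metabolic network (33 reactions, 11 fitting targets, the
#' four GABA-shunt state metabolites, two Vmax sets); this model is fixed
#' and independent of the seed.  `topology = "random"` returns a seeded
#' random Michaelis-Menten network of the requested size, useful for
#' property tests.
#'
#' @param config a [generator_config()].
#' @return a validated [metabolic_model()]; attribute `generator_seed`
#'   records the generating seed.
#' @export
make_metabolic_fixture <- function(config = generator_config()) {
  model <- if (config$topology == "fig1") {
    fig1_model()
  } else {
    random_mm_model(config)
  }
  attr(model, "generator_seed") <- config$seed
  model
}

random_mm_model <- function(config) {
  set.seed(config$seed)
  n_m <- max(2, config$n_metabolites)
  n_r <- max(1, config$n_reactions)
  ids <- paste0("M", seq_len(n_m))
  mets <- data.frame(id = ids, name = ids,
                     initial_amount = round(stats::rlnorm(n_m, 0, 0.5), 4),
                     is_fitting_target = seq_len(n_m) %% 2 == 1,
                     is_state_metabolite = seq_len(n_m) <= min(4, n_m),
                     stringsAsFactors = FALSE)
  fold <- config$vmax_fold_change_range
  rxns <- lapply(seq_len(n_r), function(i) {
    sub <- sample(ids, 1)
    prod <- sample(setdiff(ids, sub), 1)
    v0 <- round(stats::runif(1, 0.2, 1.5), 4)
    reaction_spec(paste0("R", i),
                  data.frame(metabolite = sub, coef = 1,
                             km = round(stats::rlnorm(1, 0, 0.4), 4)),
                  data.frame(metabolite = prod, coef = 1),
                  c(control = v0,
                    stressed = round(v0 * stats::runif(1, fold[1], fold[2]), 4)))
  })
  metabolic_model(mets, rxns)
}

#' Generate observed metabolite time courses
#'
#' Simulates each condition of `model`, samples the fitting-target
#' metabolites daily over `duration` days, applies multiplicative lognormal
#' observation noise with coefficient of variation `config$noise_cv`
#' (mean-unbiased parameterization, so `noise_cv = 0` reproduces the
#' simulation exactly), averages `config$n_replicates` replicates and
#' reports the standard error of the mean.
#'
#' @param model a two-condition `metabolic_model`.
#' @param config a [generator_config()].
#' @param duration,sample_interval sampling design in days.
#' @return an [observed_timecourse()] covering both conditions.
#' @export
make_observed_timecourses <- function(model, config = generator_config(),
                                      duration = 4, sample_interval = 1) {
  set.seed(config$seed)
  targets <- fitting_targets(model)
  times <- seq(0, duration, by = sample_interval)
  cv <- config$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  out <- do.call(rbind, lapply(model$conditions, function(cond) {
    sim <- ode_sample(model, cond, times)
    do.call(rbind, lapply(targets, function(m) {
      mu <- sim$amounts[match(times, sim$times), m]
      reps <- vapply(seq_len(config$n_replicates), function(r) {
        if (cv == 0) mu
        else mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
      }, numeric(length(mu)))
      reps <- matrix(reps, nrow = length(mu))
      data.frame(condition = cond, metabolite_id = m, time_days = times,
                 amount = rowMeans(reps),
                 se = apply(reps, 1, stats::sd) / sqrt(ncol(reps)),
                 stringsAsFactors = FALSE)
    }))
  }))
  observed_timecourse(out)
}

#' Generate the ladder-like Boolean module network
#'
#' Two promoting channels (`A1 -> B1 -> C1 -> D1` and
#' `A2 -> B2 -> C2 -> D2`) bridged by inhibitory cross-channel edges; for
#' the default 8 modules the interaction multiplicities sum to 19 promoting
#' and 17 inhibitory, distributed by a fixed deterministic rule (the exact
#' placement in the source network is not published).  Step inputs modelling
#' PMA stimulation are attached to `B1` (0 to 1) and `B2` (1 to 0), both
#' switching at step 0.  The network's `reference_state` is the resting
#' pattern: channel 1 inactive, channel 2 active.
#'
#' @param config a [generator_config()]; `n_modules` must be even.  Sizes
#'   other than 8 yield a minimal two-channel toy with unit multiplicities.
#' @return a validated [boolean_module_network()].
#' @export
make_ladder_network <- function(config = generator_config()) {
  n <- config$n_modules
  if (n < 2 || n %% 2 != 0) stop("n_modules must be an even number >= 2")
  L <- n / 2
  ch1 <- paste0(LETTERS[seq_len(L)], 1)
  ch2 <- paste0(LETTERS[seq_len(L)], 2)
  modules <- c(ch1, ch2)
  e <- function(s, t, sign, mult)
    data.frame(source = s, target = t, sign = as.integer(sign),
               multiplicity = as.integer(mult), stringsAsFactors = FALSE)
  if (n == 8) {
    edges <- rbind(
      e("A1", "B1", 1, 4), e("B1", "C1", 1, 4), e("C1", "D1", 1, 5),
      e("A2", "B2", 1, 2), e("B2", "C2", 1, 2), e("C2", "D2", 1, 2),
      e("A1", "A2", -1, 2), e("A2", "A1", -1, 3),
      e("B1", "B2", -1, 4),
      e("C1", "C2", -1, 2), e("C2", "C1", -1, 1),
      e("D1", "D2", -1, 2), e("D2", "D1", -1, 3))
  } else {
    edges <- NULL
    if (L > 1) {
      edges <- rbind(
        do.call(rbind, lapply(seq_len(L - 1), function(i)
          e(ch1[i], ch1[i + 1], 1, 1))),
        do.call(rbind, lapply(seq_len(L - 1), function(i)
          e(ch2[i], ch2[i + 1], 1, 1))))
    }
    edges <- rbind(edges, e(ch1[1], ch2[1], -1, 1), e(ch2[1], ch1[1], -1, 1))
  }
  inputs <- list()
  drive1 <- if (L >= 2) ch1[2] else ch1[1]
  drive2 <- if (L >= 2) ch2[2] else ch2[1]
  inputs[[drive1]] <- input_schedule(0, 1, onset_time = 0)
  inputs[[drive2]] <- input_schedule(1, 0, onset_time = 0)
  ref <- stats::setNames(c(rep(0L, L), rep(1L, L)), modules)
  net <- boolean_module_network(modules, edges, inputs,
                                reference_state = ref)
  attr(net, "generator_seed") <- config$seed
  net
}
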