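#' Kinetic metabolic network models
#'
#' A `metabolic_model` bundles a set of metabolites (with initial amounts in
#' umol/g dry weight), a set of irreversible Michaelis-Menten reactions with
#' per-substrate Michaelis constants and condition-specific maximum
#' velocities (amount/day), and an ordered set of condition labels -- for
#' two-condition models always `c("control", "stressed")`.  Reversible steps
#' are declared as two reactions.  A subset of metabolites is flagged as
#' *state metabolites*: the Boolean accumulation tuple over these defines the
#' discrete system state used by [discretize()] and the entropy/robustness
#' metrics.  Another subset is flagged as *fitting targets* for Vmax
#' calibration against observed time courses.
#'
#' @param metabolites data.frame with columns `id`, `name`, `initial_amount`,
#'   `is_fitting_target`, `is_state_metabolite`.
#' @param reactions list of reactions built with [reaction_spec()].
#' @param conditions character vector of condition labels; every reaction
#'   must carry a `vmax` entry per condition.
#' @return An object of class `metabolic_model`.
#' @seealso [read_metabolic_model()], [interpolate_vmax()], [overexpress()]
#' @export
metabolic_model <- function(metabolites, reactions, conditions = c("control", "stressed")) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  need <- c("id", "name", "initial_amount", "is_fitting_target", "is_state_metabolite")
  missing_cols <- setdiff(need, names(metabolites))
  if (length(missing_cols) > 0)
    stop("metabolite table lacks column(s): ", paste(missing_cols, collapse = ", "))
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         conditions = as.character(conditions)),
    class = "metabolic_model")
  validate_metabolic_model(model)
  model
}

#' Declare one irreversible reaction
#'
#' @param id reaction label, conventionally `"R"` + number (e.g. `"R19"`).
#' @param substrates data.frame with columns `metabolite`, `coef`
#'   (stoichiometric coefficient > 0) and `km` (Michaelis constant > 0, same
#'   units as amounts).  Empty data.frame for a pure source.
#' @param products data.frame with columns `metabolite`, `coef`.  Empty for a
#'   pure sink.
#' @param vmax named numeric, one maximum velocity (amount/day) per condition.
#' @param inhibitor optional `list(metabolite =, ki =)`: a non-competitive
#'   inhibition factor `ki / (ki + I)` multiplying the rate (off when `NULL`).
#' @return A `reaction_spec` list.
#' @export
reaction_spec <- function(id, substrates, products, vmax, inhibitor = NULL) {
  empty_sub <- data.frame(metabolite = character(), coef = numeric(), km = numeric())
  empty_prod <- data.frame(metabolite = character(), coef = numeric())
  structure(
    list(id = as.character(id),
         substrates = if (NROW(substrates) > 0) as.data.frame(substrates) else empty_sub,
         products = if (NROW(products) > 0) as.data.frame(products) else empty_prod,
         vmax = vmax,
         inhibitor = inhibitor),
    class = "reaction_spec")
}

#' Validate a metabolic model's invariants
#'
#' Checks id uniqueness, non-negative initial amounts, positive Km and
#' stoichiometric coefficients, non-negative Vmax with complete condition
#' coverage, and that every referenced metabolite is declared.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; stops with an informative error otherwise.
#' @export
validate_metabolic_model <- function(model) {
  met <- model$metabolites
  if (anyDuplicated(met$id))
    stop("duplicated metabolite id(s): ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (any(met$initial_amount < 0))
    stop("negative initial_amount for metabolite(s): ",
         paste(met$id[met$initial_amount < 0], collapse = ", "))
  if (length(model$conditions) < 1) stop("model declares no conditions")
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicated reaction id(s): ", paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (rx in model$reactions) {
    refs <- c(rx$substrates$metabolite, rx$products$metabolite,
              if (!is.null(rx$inhibitor)) rx$inhibitor$metabolite)
    unknown <- setdiff(refs, met$id)
    if (length(unknown) > 0)
      stop("reaction ", rx$id, " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (NROW(rx$substrates) > 0) {
      if (any(rx$substrates$km <= 0))
        stop("reaction ", rx$id, " has km <= 0")
      if (any(rx$substrates$coef <= 0))
        stop("reaction ", rx$id, " has substrate coefficient <= 0")
    }
    if (NROW(rx$products) > 0 && any(rx$products$coef <= 0))
      stop("reaction ", rx$id, " has product coefficient <= 0")
    miss <- setdiff(model$conditions, names(rx$vmax))
    if (length(miss) > 0)
      stop("reaction ", rx$id, " lacks vmax for condition(s): ",
           paste(miss, collapse = ", "))
    if (any(rx$vmax[model$conditions] < 0))
      stop("reaction ", rx$id, " has negative vmax")
    if (!is.null(rx$inhibitor) && rx$inhibitor$ki <= 0)
      stop("reaction ", rx$id, " has inhibitor ki <= 0")
  }
  sm <- state_metabolites(model)
  if (length(sm) < 1) stop("model declares no state metabolites")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  cat("  state metabolites: ", paste(state_metabolites(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' State-metabolite and fitting-target ids of a model
#' @param model a `metabolic_model`.
#' @return character vector of metabolite ids, in declaration order.
#' @export
state_metabolites <- function(model)
  model$metabolites$id[as.logical(model$metabolites$is_state_metabolite)]

#' @rdname state_metabolites
#' @export
fitting_targets <- function(model)
  model$metabolites$id[as.logical(model$metabolites$is_fitting_target)]

#' Initial amounts as a named vector
#' @param model a `metabolic_model`.
#' @return named numeric of declared (unperturbed) initial amounts.
#' @export
initial_amounts <- function(model) {
  stats::setNames(model$metabolites$initial_amount, model$metabolites$id)
}

SCHEMA_VERSION <- 1L

#' Read / write metabolic model files
#'
#' Model files are YAML or JSON (chosen by extension: `.json` for JSON,
#' anything else parsed as YAML, which is a JSON superset) with top-level
#' keys `schema_version`, `conditions`, `metabolites` and `reactions`.
#' Each metabolite entry carries `id`, `name`, `initial_amount`,
#' `fitting_target`, `state_metabolite`; each reaction entry carries `id`,
#' `substrates` (list of `metabolite`/`coef`/`km`), `products` (list of
#' `metabolite`/`coef`), `vmax` (map condition -> velocity) and optional
#' `inhibitor` (`metabolite`/`ki`).
#'
#' @param path file location.
#' @return `read_metabolic_model()`: a validated [metabolic_model()];
#'   parse or invariant violations raise errors naming the offending field.
#' @export
read_metabolic_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- parse_structured_file(path)
  model_from_list(raw, context = path)
}

#' @rdname read_metabolic_model
#' @param model a `metabolic_model`.
#' @export
write_metabolic_model <- function(model, path) {
  obj <- model_to_list(model)
  write_structured_file(obj, path)
  invisible(path)
}

parse_structured_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

write_structured_file <- function(obj, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path, precision = 15)
  }
  invisible(path)
}

model_from_list <- function(raw, context = "model") {
  sv <- raw$schema_version
  if (is.null(sv))
    stop(context, ": missing schema_version")
  if (as.integer(sv) != SCHEMA_VERSION)
    stop(context, ": schema_version ", sv, " not supported; this build reads version ",
         SCHEMA_VERSION, " (regenerate or convert the file)")
  if (is.null(raw$metabolites) || is.null(raw$reactions) || is.null(raw$conditions))
    stop(context, ": model file needs keys metabolites, reactions, conditions")
  mets <- do.call(rbind, lapply(raw$metabolites, function(m) {
    if (is.null(m$id) || is.null(m$initial_amount))
      stop(context, ": metabolite entry lacks id or initial_amount")
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               initial_amount = as.numeric(m$initial_amount),
               is_fitting_target = isTRUE(m$fitting_target),
               is_state_metabolite = isTRUE(m$state_metabolite),
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(raw$reactions, function(r) {
    if (is.null(r$id)) stop(context, ": reaction entry lacks id")
    subs <- do.call(rbind, lapply(r$substrates, function(s)
      data.frame(metabolite = s$metabolite, coef = as.numeric(s$coef),
                 km = as.numeric(s$km), stringsAsFactors = FALSE)))
    prods <- do.call(rbind, lapply(r$products, function(p)
      data.frame(metabolite = p$metabolite, coef = as.numeric(p$coef),
                 stringsAsFactors = FALSE)))
    vmax <- unlist(r$vmax)
    inh <- if (!is.null(r$inhibitor))
      list(metabolite = r$inhibitor$metabolite, ki = as.numeric(r$inhibitor$ki))
    reaction_spec(r$id, subs, prods, vmax, inh)
  })
  metabolic_model(mets, rxns, conditions = unlist(raw$conditions))
}

model_to_list <- function(model) {
  list(
    schema_version = SCHEMA_VERSION,
    conditions = as.list(model$conditions),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name, initial_amount = m$initial_amount,
           fitting_target = m$is_fitting_target,
           state_metabolite = m$is_state_metabolite)
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      out <- list(
        id = r$id,
        substrates = lapply(seq_len(NROW(r$substrates)), function(i)
          list(metabolite = r$substrates$metabolite[i],
               coef = r$substrates$coef[i], km = r$substrates$km[i])),
        products = lapply(seq_len(NROW(r$products)), function(i)
          list(metabolite = r$products$metabolite[i], coef = r$products$coef[i])),
        vmax = as.list(r$vmax))
      if (!is.null(r$inhibitor)) out$inhibitor <- r$inhibitor
      out
    }))
}

#' Michaelis-Menten reaction rate
#'
#' Irreversible multiplicative Michaelis-Menten: the rate is
#' `vmax * prod_i S_i / (Km_i + S_i)` over the substrates, times an optional
#' non-competitive inhibition factor `Ki / (Ki + I)`.  The rate is bounded in
#' `[0, vmax]` and is zero whenever any substrate is absent.
#'
#' @param reaction a [reaction_spec()].
#' @param amounts named numeric map metabolite id -> amount (>= 0).
#' @param condition_vmax maximum velocity to use.
#' @return rate (amount/day).
#' @export
reaction_rate <- function(reaction, amounts, condition_vmax) {
  if (any(amounts < 0)) stop("negative amount(s) supplied to reaction_rate")
  rate <- condition_vmax
  if (NROW(reaction$substrates) > 0) {
    s <- amounts[reaction$substrates$metabolite]
    if (anyNA(s))
      stop("amounts lack substrate(s) of reaction ", reaction$id)
    rate <- rate * prod(s / (reaction$substrates$km + s))
  }
  if (!is.null(reaction$inhibitor)) {
    inh <- amounts[reaction$inhibitor$metabolite]
    if (is.na(inh)) stop("amounts lack inhibitor of reaction ", reaction$id)
    rate <- rate * reaction$inhibitor$ki / (reaction$inhibitor$ki + inh)
  }
  unname(rate)
}

#' Interpolate between the two condition parameter sets
#'
#' Builds the single-condition model at blending fraction `lambda`, whose
#' every maximum velocity is
#' `Vmax(lambda) = Vmax(lambda = 0) + lambda * (Vmax(lambda = 1) - Vmax(lambda = 0))`
#' with `lambda = 0` the first declared condition (control) and `lambda = 1`
#' the second (stressed).  All other fields are unchanged.
#'
#' @param model a two-condition `metabolic_model`.
#' @param lambda blending fraction in `[0, 1]`.
#' @return a `metabolic_model` with the single condition
#'   `"lambda=<value>"`.
#' @export
interpolate_vmax <- function(model, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  if (length(model$conditions) != 2)
    stop("interpolation needs a two-condition model; found conditions: ",
         paste(model$conditions, collapse = ", "))
  lab <- paste0("lambda=", format(lambda))
  ctl <- model$conditions[1]
  str <- model$conditions[2]
  model$reactions <- lapply(model$reactions, function(r) {
    v0 <- r$vmax[[ctl]]
    v1 <- r$vmax[[str]]
    r$vmax <- stats::setNames(v0 + lambda * (v1 - v0), lab)
    r
  })
  model$conditions <- lab
  model
}

#' Restrict a model to one named condition
#'
#' @param model a `metabolic_model`.
#' @param condition one of the model's condition labels.
#' @return single-condition model keeping only that condition's Vmax set.
#' @export
select_condition <- function(model, condition) {
  if (!condition %in% model$conditions)
    stop("unknown condition '", condition, "'; model has: ",
         paste(model$conditions, collapse = ", "))
  model$reactions <- lapply(model$reactions, function(r) {
    r$vmax <- r$vmax[condition]
    r
  })
  model$conditions <- condition
  model
}

#' Over-express one enzyme
#'
#' Multiplies the named reaction's maximum velocity by `factor` in the given
#' condition (default: the control condition, i.e. the first declared one),
#' leaving everything else untouched.  Models enzyme over-expression such as
#' a four-fold increase of a single reaction's Vmax.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction label to boost.
#' @param factor positive multiplier.
#' @param condition condition label whose Vmax is scaled.
#' @return modified copy of the model.
#' @export
overexpress <- function(model, reaction_id, factor, condition = model$conditions[1]) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a single positive number")
  if (!reaction_id %in% names(model$reactions))
    stop("unknown reaction id '", reaction_id, "'")
  if (!condition %in% model$conditions)
    stop("unknown condition '", condition, "'")
  model$reactions[[reaction_id]]$vmax[[condition]] <-
    model$reactions[[reaction_id]]$vmax[[condition]] * factor
  model
}
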