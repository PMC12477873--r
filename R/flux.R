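#' Assemble the FBA linear program for a model
#'
#' Rows are the metabolite steady-state balances `S v = b` (default
#' `b = 0`) followed by the coupling inequalities, converted to equalities
#' with nonnegative slack variables.
#'
#' @param model A `reconstruction`.
#' @param rhs Optional named numeric vector overriding the right-hand side
#'   of selected metabolite rows (a positive entry models a production
#'   surplus of that metabolite, i.e. extra availability downstream).
#' @return List with `A`, `b`, `lb`, `ub`, `n_rxns` and row/col names.
#' @keywords internal
build_fba_lp <- function(model, rhs = NULL) {
  n <- nrow(model$rxns)
  m <- nrow(model$mets)
  b <- stats::setNames(rep(0, m), model$mets$id)
  if (!is.null(rhs)) {
    bad <- setdiff(names(rhs), model$mets$id)
    if (length(bad)) stopf("rhs names not in model: %s", paste(bad, collapse = ", "))
    b[names(rhs)] <- rhs
  }
  A <- model$S
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  cp <- model$couplings
  if (!is.null(cp) && nrow(cp)) {
    ridx <- match(cp$rxn, model$rxns$id)
    bidx <- match(cp$biomass_rxn, model$rxns$id)
    if (anyNA(ridx) || anyNA(bidx)) stopf("coupling refers to unknown reaction")
    sgn <- ifelse(cp$sense == "le", -1, +1) # v_j -/+ f*v_bio
    nC <- nrow(cp)
    Crows <- Matrix::sparseMatrix(
      i = c(seq_len(nC), seq_len(nC)),
      j = c(ridx, bidx),
      x = c(rep(1, nC), sgn * cp$factor),
      dims = c(nC, n))
    slack_sgn <- ifelse(cp$sense == "le", 1, -1) # le: +s ; ge: -s
    Slk <- rbind(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                      dims = c(m, nC)),
                 Matrix::sparseMatrix(i = seq_len(nC), j = seq_len(nC), x = slack_sgn,
                                      dims = c(nC, nC)))
    A <- cbind(rbind(A, Crows), Slk)
    b <- c(b, stats::setNames(rep(0, nC), sprintf("coupling_%d", seq_len(nC))))
    lb <- c(lb, rep(0, nC))
    ub <- c(ub, rep(Inf, nC))
  }
  list(A = A, b = b, lb = lb, ub = ub, n_rxns = n,
       var_names = c(model$rxns$id, if (!is.null(cp) && nrow(cp)) sprintf("slack_%d", seq_len(nrow(cp)))))
}

#' Add a demand reaction for a metabolite
#'
#' Demand reactions are unbalanced sinks `1 met -> nothing` used as FBA
#' objectives to measure a compartment's maximal production capacity. The
#' reaction is named `DM_<met>[<compartment>]` with bounds `[0, 1e6]`.
#'
#' @param model A `reconstruction`.
#' @param metabolite_id Metabolite base name (without compartment tag).
#' @param compartment Compartment tag (default `"[bc]"`, blood).
#' @return List with `model` (modified) and `rxn_id`.
#' @export
add_demand_reaction <- function(model, metabolite_id, compartment = "[bc]") {
  met <- paste0(metabolite_id, compartment)
  if (!met %in% model$mets$id) {
    stopf("metabolite '%s' not present in model '%s'", met, model$id)
  }
  rxn_id <- sprintf("DM_%s%s", metabolite_id, compartment)
  model <- add_reaction(model, rxn_id, stats::setNames(-1, met), lb = 0, ub = BIG)
  list(model = model, rxn_id = rxn_id)
}

#' Solve the flux balance analysis problem
#'
#' Maximizes (or minimizes) the flux through `objective_rxn` subject to
#' steady state, bounds, and any coupling constraints. Fluxes and the
#' objective are rounded to six decimals to remove numerical artifacts;
#' unrounded values are retained alongside. Metabolite shadow prices are
#' reported in the convention `pi = -dZ/db`, where `db > 0` is a
#' production surplus (extra availability) of the metabolite: a negative
#' shadow price therefore marks a metabolite whose extra availability
#' would raise the objective. Internally the simplex returns the standard
#' dual `y = dZ/db` of the max problem, so `pi = -y`; the mapping is
#' verified by finite-difference perturbation tests.
#'
#' @param model A `reconstruction`.
#' @param objective_rxn Reaction ID to optimize.
#' @param sense `"max"` (default) or `"min"`.
#' @param rhs Optional steady-state right-hand side override (see
#'   [build_fba_lp()]).
#' @return An `fba_solution`: list with `status` ("optimal", "infeasible"
#'   or "unbounded"), `objective` (rounded), `objective_raw`, `fluxes`
#'   (named, rounded), `fluxes_raw`, `shadow_prices` (named by metabolite,
#'   negative-sensitivity convention) and `objective_rxn`.
#' @export
solve_fba <- function(model, objective_rxn, sense = "max", rhs = NULL) {
  j <- match(objective_rxn, model$rxns$id)
  if (is.na(j)) stopf("objective reaction '%s' not in model '%s'", objective_rxn, model$id)
  lp <- build_fba_lp(model, rhs = rhs)
  cc <- numeric(ncol(lp$A))
  cc[j] <- 1
  res <- solve_lp(lp$A, lp$b, cc, lp$lb, lp$ub, sense = sense)
  if (res$status == "maxit") {
    stopf("LP iteration limit reached for objective '%s' in model '%s'",
          objective_rxn, model$id)
  }
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective = NA_real_,
                          objective_raw = NA_real_, fluxes = NULL,
                          fluxes_raw = NULL, shadow_prices = NULL,
                          objective_rxn = objective_rxn, model_id = model$id),
                     class = "fba_solution"))
  }
  v_raw <- stats::setNames(res$x[seq_len(lp$n_rxns)], model$rxns$id)
  y_met <- res$y[seq_len(nrow(model$mets))]
  structure(list(status = "optimal",
                 objective = round(res$objective, 6),
                 objective_raw = res$objective,
                 fluxes = round(v_raw, 6),
                 fluxes_raw = v_raw,
                 shadow_prices = stats::setNames(-y_met, model$mets$id),
                 objective_rxn = objective_rxn,
                 model_id = model$id),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution '%s' on '%s'>: status %s, Z = %s\n",
              x$objective_rxn, x$model_id, x$status,
              format(x$objective)))
  invisible(x)
}

#' Shadow prices of the species biomass metabolites
#'
#' Extracts the steady-state shadow price of each `pan<species>_biomass[c]`
#' metabolite from an optimal FBA solution. Values below the numerical
#' tolerance (1e-6) in magnitude are reported as exactly zero.
#'
#' @param solution An optimal `fba_solution`.
#' @param model The model the solution was computed on.
#' @param tol Zero tolerance (default 1e-6).
#' @return Named numeric vector, one shadow price per species present.
#' @export
extract_biomass_shadow_prices <- function(solution, model, tol = 1e-6) {
  stopifnot(inherits(solution, "fba_solution"))
  if (solution$status != "optimal") stopf("solution is not optimal")
  mets <- grep("^pan.+_biomass\\[c\\]$", model$mets$id, value = TRUE)
  sp <- sub("^pan(.+)_biomass\\[c\\]$", "\\1", mets)
  pi_vals <- solution$shadow_prices[mets]
  pi_vals[abs(pi_vals) < tol] <- 0
  stats::setNames(as.numeric(pi_vals), sp)
}

#' Is a predicted flux influenced by the gut microbiome?
#'
#' TRUE iff at least one species biomass metabolite carries a nonzero
#' shadow price (after the 1e-6 tolerance), i.e. the microbiome is a
#' binding resource for the objective.
#'
#' @inheritParams extract_biomass_shadow_prices
#' @return Logical scalar.
#' @export
is_microbiome_influenced <- function(solution, model, tol = 1e-6) {
  any(extract_biomass_shadow_prices(solution, model, tol = tol) != 0)
}

#' Predict maximal blood fluxes across samples
#'
#' One FBA per (sample, metabolite): a demand reaction is added in the
#' blood compartment, its flux maximized, the objective and the
#' microbiome-influence flag recorded, and the demand discarded. Solver
#' failures are recorded as missing cells, never as zeros.
#'
#' @param models_by_sample Named list of host-microbiome models.
#' @param metabolite_list Metabolite base names to assay in blood.
#' @param compartment Compartment tag (default `"[bc]"`).
#' @param collect_contributions If TRUE, also return per-species
#'   contribution potentials for every solved cell (see
#'   [contribution_potentials()]).
#' @return List with `flux` (samples x metabolites matrix), `influenced`
#'   (logical matrix), `failures` (data frame) and optionally
#'   `contributions` (long data frame).
#' @export
predict_blood_fluxes <- function(models_by_sample, metabolite_list,
                                 compartment = "[bc]",
                                 collect_contributions = FALSE) {
  samples <- names(models_by_sample)
  stopifnot(length(samples) >= 1, length(metabolite_list) >= 1)
  flux <- matrix(NA_real_, length(samples), length(metabolite_list),
                 dimnames = list(samples, metabolite_list))
  infl <- matrix(NA, length(samples), length(metabolite_list),
                 dimnames = list(samples, metabolite_list))
  failures <- list()
  contribs <- list()
  for (s in samples) {
    base <- models_by_sample[[s]]
    lp <- build_fba_lp(base)
    Adense <- as.matrix(lp$A)
    n_var <- ncol(Adense)
    for (met in metabolite_list) {
      met_id <- paste0(met, compartment)
      i <- match(met_id, base$mets$id)
      if (is.na(i)) {
        failures[[length(failures) + 1L]] <- data.frame(
          sample = s, metabolite = met,
          reason = sprintf("metabolite '%s' not in model", met_id),
          stringsAsFactors = FALSE)
        next
      }
      # demand column appended in LP space (equivalent to adding the
      # DM_<met>[bc] reaction, solving, and removing it again)
      dcol <- numeric(nrow(Adense))
      dcol[i] <- -1
      res <- solve_lp(cbind(Adense, dcol), lp$b,
                      c(numeric(n_var), 1), c(lp$lb, 0), c(lp$ub, BIG))
      if (res$status != "optimal") {
        failures[[length(failures) + 1L]] <- data.frame(
          sample = s, metabolite = met, reason = res$status,
          stringsAsFactors = FALSE)
        next
      }
      v_raw <- stats::setNames(res$x[seq_len(lp$n_rxns)], base$rxns$id)
      y_met <- res$y[seq_len(nrow(base$mets))]
      sol <- structure(list(status = "optimal",
                            objective = round(res$objective, 6),
                            objective_raw = res$objective,
                            fluxes = round(v_raw, 6), fluxes_raw = v_raw,
                            shadow_prices = stats::setNames(-y_met, base$mets$id),
                            objective_rxn = sprintf("DM_%s%s", met, compartment),
                            model_id = base$id),
                       class = "fba_solution")
      flux[s, met] <- sol$objective
      infl[s, met] <- is_microbiome_influenced(sol, base)
      if (collect_contributions) {
        cr <- contribution_potentials(sol, base, attr(base, "abundances"))
        if (nrow(cr)) {
          cr$sample <- s
          cr$metabolite <- met
          contribs[[length(contribs) + 1L]] <- cr
        }
      }
    }
  }
  out <- list(flux = flux, influenced = infl,
              failures = if (length(failures)) do.call(rbind, failures) else
                data.frame(sample = character(0), metabolite = character(0),
                           reason = character(0)))
  if (collect_contributions) {
    out$contributions <- if (length(contribs)) do.call(rbind, contribs) else
      data.frame(sample = character(0), metabolite = character(0),
                 species = character(0), pi = numeric(0), v_bio = numeric(0),
                 delta_Z = numeric(0))
  }
  out
}
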