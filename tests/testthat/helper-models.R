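# Shared fixtures: tiny models built in code, plus independent oracles.

# Independent LP oracle: exhaustive basic-solution (vertex) enumeration for
# equality-constrained LPs with finite bounds. Only for n <= 9 variables.
lp_vertex_oracle <- function(A, b, c_obj, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(n <= 9, all(is.finite(lb)), all(is.finite(ub)))
  best <- -Inf
  bestx <- NULL
  basics <- utils::combn(n, m, simplify = FALSE)
  for (B in basics) {
    N <- setdiff(seq_len(n), B)
    Bm <- A[, B, drop = FALSE]
    if (abs(det(Bm)) < 1e-12) next
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    for (g in seq_len(nrow(grid))) {
      xN <- ifelse(unlist(grid[g, ]), ub[N], lb[N])
      rhs <- b - if (length(N)) A[, N, drop = FALSE] %*% xN else 0
      xB <- solve(Bm, rhs)
      if (any(xB < lb[B] - tol) || any(xB > ub[B] + tol)) next
      x <- numeric(n)
      x[B] <- xB
      x[N] <- xN
      val <- sum(c_obj * x)
      if (val > best) { best <- val; bestx <- x }
    }
  }
  list(objective = best, x = bestx)
}

# Reachability of `to` metabolites from `from` metabolites over the model's
# reaction hypergraph (a reaction with a consumed metabolite reachable makes
# all its produced metabolites reachable; reversible reactions work both
# ways).
metabolite_reachable <- function(model, from, to) {
  S <- as.matrix(model$S)
  reach <- rownames(S) %in% from
  repeat {
    changed <- FALSE
    for (j in seq_len(ncol(S))) {
      col <- S[, j]
      subs <- col < 0; prods <- col > 0
      if (any(reach[subs]) && any(!reach[prods])) {
        reach[prods] <- TRUE; changed <- TRUE
      }
      if (model$rxns$lb[j] < 0 && any(reach[prods]) && any(!reach[subs])) {
        reach[subs] <- TRUE; changed <- TRUE
      }
    }
    if (!changed) break
  }
  all(reach[rownames(S) %in% to])
}

# Minimal linear-chain host-style model:
#   diet --(uptake bound)--> lumen --> blood, with a demandable blood pool.
chain_model <- function(uptake = 5) {
  make_reconstruction("chain", list(
    list(id = "Diet_EX_m[d]", stoich = c(`m[d]` = -1), lb = -uptake, ub = 1e6),
    list(id = "T_D2LI_m", stoich = c(`m[d]` = -1, `m[luLI]` = 1), lb = 0, ub = 1e6),
    list(id = "T_LI2BC_m", stoich = c(`m[luLI]` = -1, `m[bc]` = 1), lb = 0, ub = 1e6)
  ))
}

# Fully-assembled joined toy: catalog -> pans -> community -> host -> diet.
build_toy_joined <- function(n_species = 3, strains = 1, seed = 1,
                             abundances = NULL, sex = "male",
                             coupling_factor = 400) {
  catalog <- generate_strain_catalog(n_species, strains, seed)
  by_sp <- split(catalog, vapply(catalog, attr, character(1), "species"))
  pans <- lapply(names(by_sp), function(sp) build_pan_species(by_sp[[sp]], sp))
  names(pans) <- names(by_sp)
  if (is.null(abundances)) {
    abundances <- with_seed_local(seed + 1000, {
      x <- stats::rlnorm(length(pans))
      stats::setNames(x / sum(x), names(pans))
    })
  }
  comm <- add_coupling_constraints(assemble_community(pans, abundances),
                                   coupling_factor)
  host <- generate_host_template(sex)
  diet <- generate_diet(20, 0.25, seed)
  suppressWarnings(apply_diet(join_host(host, comm), diet))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Shadow-price-vs-removal-oracle comparison over seeded toy communities.
# Returns one row per (community, species) pair with defined oracle plus
# counts of infeasible (flagged, undefined) removals.
run_oracle_suite <- function(n_communities, seed0 = 100) {
  rows <- list()
  n_infeasible <- 0L
  for (k in seq_len(n_communities)) {
    n_sp <- 3 + (k %% 4)
    mdl <- build_toy_joined(n_species = n_sp, strains = 1, seed = seed0 + k)
    met <- PRODUCT_METS[1 + (k %% length(PRODUCT_METS))]
    dm <- add_demand_reaction(mdl, met)
    sol <- solve_fba(dm$model, dm$rxn_id)
    if (sol$status != "optimal") next
    cp <- contribution_potentials(sol, dm$model)
    for (i in seq_len(nrow(cp))) {
      bf <- brute_force_contribution(mdl, cp$species[i], met)
      if (is.na(bf$delta_Z_oracle)) {
        n_infeasible <- n_infeasible + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        community = k, species = cp$species[i], metabolite = met,
        shadow = cp$delta_Z[i], oracle = bf$delta_Z_oracle,
        basis_change = bf$basis_change)
    }
  }
  list(pairs = do.call(rbind, rows), n_infeasible = n_infeasible)
}
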