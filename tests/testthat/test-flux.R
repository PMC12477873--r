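test_that("demand reactions are added, rejected as duplicates, and removable", {
  m <- chain_model()
  dm <- add_demand_reaction(m, "m", "[bc]")
  expect_equal(dm$rxn_id, "DM_m[bc]")
  expect_equal(unname(reaction_stoich(dm$model, "DM_m[bc]")["m[bc]"]), -1)
  expect_equal(unname(reaction_bounds(dm$model, "DM_m[bc]")), c(0, 1e6))
  expect_error(add_demand_reaction(dm$model, "m", "[bc]"), "already present")
  back <- remove_reaction(dm$model, "DM_m[bc]")
  expect_equal(back$rxns, m$rxns)
  expect_equal(as.matrix(back$S), as.matrix(m$S))
  expect_error(add_demand_reaction(m, "nonexistent"), "not present")
})

test_that("FBA finds the bottleneck on a linear chain and zero with no path", {
  m <- chain_model(uptake = 5)
  dm <- add_demand_reaction(m, "m", "[bc]")
  sol <- solve_fba(dm$model, dm$rxn_id)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 5)
  expect_true(max(abs(as.numeric(dm$model$S %*% sol$fluxes_raw))) < 1e-6)

  # no producing path: close the diet uptake
  m0 <- set_bounds(m, "Diet_EX_m[d]", 0, 1e6)
  dm0 <- add_demand_reaction(m0, "m", "[bc]")
  expect_equal(solve_fba(dm0$model, dm0$rxn_id)$objective, 0)
})

test_that("FBA optimum equals exhaustive vertex enumeration on a toy model", {
  m <- make_reconstruction("vtx", list(
    list(id = "in_a", stoich = c(`a[c]` = 1), lb = 0, ub = 4),
    list(id = "in_b", stoich = c(`b[c]` = 1), lb = 0, ub = 3),
    list(id = "r1", stoich = c(`a[c]` = -1, `p[c]` = 1), lb = 0, ub = 10),
    list(id = "r2", stoich = c(`a[c]` = -1, `b[c]` = -1, `p[c]` = 3), lb = 0, ub = 2),
    list(id = "out_p", stoich = c(`p[c]` = -1), lb = 0, ub = 100)
  ))
  sol <- solve_fba(m, "out_p")
  lp <- wbmflux:::build_fba_lp(m)
  cc <- numeric(ncol(lp$A)); cc[match("out_p", m$rxns$id)] <- 1
  oracle <- lp_vertex_oracle(as.matrix(lp$A), lp$b, cc, lp$lb,
                             pmin(lp$ub, 1e9))
  expect_equal(sol$objective_raw, oracle$objective, tolerance = 1e-7)
})

test_that("shadow prices follow the negative-sensitivity convention", {
  # finite-difference check: pi = -(Z(b_i = +eps) - Z(0)) / eps, where a
  # positive rhs entry is a production surplus (extra availability)
  mdl <- build_toy_joined(n_species = 3, strains = 1, seed = 71)
  dm <- add_demand_reaction(mdl, "but")
  base <- solve_fba(dm$model, dm$rxn_id)
  expect_equal(base$status, "optimal")
  pis <- extract_biomass_shadow_prices(base, dm$model)
  eps <- 1e-4
  for (sp in names(pis)) {
    met <- sprintf("pan%s_biomass[c]", sp)
    pert <- solve_fba(dm$model, dm$rxn_id, rhs = setNames(eps, met))
    if (pert$status != "optimal") next
    fd <- (pert$objective_raw - base$objective_raw) / eps
    expect_equal(-fd, unname(pis[sp]), tolerance = 1e-4, label = sp)
  }
  # the sole producer of 'but' gains the objective from extra biomass
  expect_lt(pis[["synthetic_sp01"]], 0)
})

test_that("shadow prices below 1e-6 report as exactly zero", {
  sol <- structure(list(status = "optimal",
                        shadow_prices = c(`panspA_biomass[c]` = 5e-7,
                                          `panspB_biomass[c]` = -0.2)),
                   class = "fba_solution")
  fake <- list(mets = data.frame(id = c("panspA_biomass[c]", "panspB_biomass[c]")))
  pis <- extract_biomass_shadow_prices(sol, fake)
  expect_identical(unname(pis["spA"]), 0)
  expect_identical(unname(pis["spB"]), -0.2)
  expect_true(is_microbiome_influenced(sol, fake))
  sol$shadow_prices[2] <- 1e-8
  expect_false(is_microbiome_influenced(sol, fake))
})

test_that("host-saturated metabolites are not microbiome influenced", {
  # a pure-producer community exerts no forced draw on the precursors it
  # does not use for growth; such metabolites reach blood through host
  # transports alone and the microbiome is not a binding resource
  mdl <- build_toy_joined(n_species = 1, strains = 1, seed = 73,
                          abundances = c(synthetic_sp01 = 1))
  dm <- add_demand_reaction(mdl, "ser_L")
  sol <- solve_fba(dm$model, dm$rxn_id)
  expect_equal(sol$status, "optimal")
  expect_false(is_microbiome_influenced(sol, dm$model))
  # whereas the staple is competed for by forced microbial growth
  dms <- add_demand_reaction(mdl, "glc_D")
  expect_true(is_microbiome_influenced(solve_fba(dms$model, dms$rxn_id),
                                       dms$model))
})

test_that("predict_blood_fluxes bookkeeping: shape, determinism, missingness", {
  mdl <- build_toy_joined(n_species = 3, strains = 1, seed = 75)
  res <- predict_blood_fluxes(list(s1 = mdl, s2 = mdl), c("but", "ppa", "nac"))
  expect_equal(dim(res$flux), c(2, 3))
  expect_equal(res$flux["s1", ], res$flux["s2", ]) # identical samples
  expect_equal(nrow(res$failures), 0)

  # a metabolite absent from the model is recorded as missing, not zero
  res2 <- predict_blood_fluxes(list(s1 = mdl), c("but", "not_a_met"))
  expect_true(is.na(res2$flux[1, "not_a_met"]))
  expect_equal(nrow(res2$failures), 1)
  expect_false(is.na(res2$flux[1, "but"]))
})

test_that("a sample lacking the only producer has strictly lower flux", {
  r_with <- c(synthetic_sp01 = 0.4, synthetic_sp02 = 0.3, synthetic_sp03 = 0.3)
  m_with <- build_toy_joined(3, 1, seed = 77, abundances = r_with)
  catalog <- generate_strain_catalog(3, 1, seed = 77)
  by_sp <- split(catalog, vapply(catalog, attr, character(1), "species"))
  pans <- lapply(names(by_sp), function(sp) build_pan_species(by_sp[[sp]], sp))
  names(pans) <- names(by_sp)
  # drop the sole producer of 'but' (species 1) entirely
  r_wo <- c(synthetic_sp02 = 0.5, synthetic_sp03 = 0.5)
  comm <- add_coupling_constraints(assemble_community(pans[names(r_wo)], r_wo))
  m_wo <- suppressWarnings(apply_diet(join_host(generate_host_template("male"), comm),
                                      generate_diet(20, 0.25, 77)))
  fx <- predict_blood_fluxes(list(with = m_with, without = m_wo), "but")
  expect_lt(fx$flux["without", "but"], fx$flux["with", "but"])
})

test_that("relaxing diet uptake bounds never decreases the objective", {
  for (seed in c(81, 82, 83)) {
    mdl <- build_toy_joined(n_species = 3, strains = 1, seed = seed)
    dm <- add_demand_reaction(mdl, PRODUCT_METS[1 + seed %% 3])
    z0 <- solve_fba(dm$model, dm$rxn_id)$objective_raw
    diet_rxns <- grep("^Diet_EX_", dm$model$rxns$id, value = TRUE)
    for (rid in sample(diet_rxns, 4)) {
      bb <- reaction_bounds(dm$model, rid)
      relaxed <- set_bounds(dm$model, rid, bb[1] - 10, bb[2])
      z1 <- solve_fba(relaxed, dm$rxn_id)$objective_raw
      expect_gte(z1, z0 - 1e-6)
    }
  }
})

test_that("six-decimal rounding does not change feasibility classification", {
  mdl <- build_toy_joined(n_species = 2, strains = 1, seed = 85)
  dm <- add_demand_reaction(mdl, "but")
  sol <- solve_fba(dm$model, dm$rxn_id)
  expect_equal(sol$status, "optimal")
  v <- sol$fluxes # rounded to 6 decimals
  expect_true(max(abs(as.numeric(dm$model$S %*% v))) < 1e-4)
  expect_true(all(v >= dm$model$rxns$lb - 1e-6 & v <= dm$model$rxns$ub + 1e-6))
})
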