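strain <- function(id, sp, rxns) {
  m <- make_reconstruction(id, rxns)
  m$rxns$species <- sp
  attr(m, "species") <- sp
  m
}

base_rxns <- function() list(
  list(id = "T_up", stoich = c(`a[luM]` = -1, `a[c]` = 1), lb = 0, ub = 10),
  list(id = "biomass", stoich = c(`a[c]` = -1, `biomass[c]` = 1),
       lb = 0, ub = 10, is_biomass = TRUE),
  list(id = "EX_a", stoich = c(`a[luM]` = -1), lb = -10, ub = 10)
)

test_that("pan models are reaction unions with widest bounds", {
  s1 <- strain("s1", "spX", base_rxns())
  pan1 <- build_pan_species(list(s1), "spX")
  expect_setequal(pan1$rxns$id, c("T_up", "panspX_biomass", "EX_a"))
  expect_true("panspX_biomass[c]" %in% pan1$mets$id)
  expect_length(biomass_reactions(pan1), 1)

  extra <- c(base_rxns(), list(
    list(id = "conv_p", stoich = c(`a[c]` = -1, `p[c]` = 1), lb = 0, ub = 5)))
  s2 <- strain("s2", "spX", extra)
  pan2 <- build_pan_species(list(s1, s2), "spX")
  expect_setequal(pan2$rxns$id, c("T_up", "panspX_biomass", "EX_a", "conv_p"))

  # widest-interval bound merging
  wide <- base_rxns()
  wide[[1]]$lb <- -5
  s3 <- strain("s3", "spX", wide)
  pan3 <- build_pan_species(list(s1, s3), "spX")
  expect_equal(unname(reaction_bounds(pan3, "T_up")), c(-5, 10))

  # disjoint reaction sets of sizes 8 and 5 union to 13
  mk <- function(k) list(id = sprintf("r%02d", k),
                         stoich = setNames(c(-1, 1), sprintf(c("m%02d[c]", "m%02d_b[c]"), k)),
                         lb = 0, ub = 1)
  a8 <- c(lapply(1:7, mk), list(
    list(id = "biomass", stoich = c(`m01[c]` = -1, `biomass[c]` = 1),
         lb = 0, ub = 1, is_biomass = TRUE)))
  b5 <- lapply(8:12, mk)
  pan_u <- build_pan_species(list(strain("sa", "spY", a8),
                                  strain("sb", "spY", b5)), "spY")
  expect_equal(nrow(pan_u$rxns), 13)

  # conflicting stoichiometry is an error
  conf <- base_rxns()
  conf[[1]]$stoich <- c(`a[luM]` = -2, `a[c]` = 1)
  expect_error(build_pan_species(list(s1, strain("s4", "spX", conf)), "spX"),
               "conflicting stoichiometry")
  expect_error(build_pan_species(list(), "spX"), "empty strain list")
})

test_that("community assembly encodes abundances in communityBiomass", {
  cat3 <- generate_strain_catalog(2, 1, seed = 11)
  pans <- lapply(split(cat3, vapply(cat3, attr, character(1), "species")),
                 function(s) build_pan_species(s, attr(s[[1]], "species")))
  r <- c(0.6, 0.4)
  names(r) <- names(pans)
  comm <- assemble_community(pans, r)
  st <- reaction_stoich(comm, "communityBiomass")
  expect_equal(unname(st[sprintf("pan%s_biomass[c]", names(r))]), c(-0.6, -0.4))
  expect_equal(unname(st["microbiota_LI_biomass[luM]"]), 1)

  # one species at r = 1
  comm1 <- assemble_community(pans[1], setNames(1, names(pans)[1]))
  expect_equal(unname(reaction_stoich(comm1, "communityBiomass")[1]), -1)

  # every lumen metabolite touches >= 1 species transport
  lum <- grep("\\[luM\\]$", comm$mets$id, value = TRUE)
  lum <- setdiff(lum, "microbiota_LI_biomass[luM]")
  for (ml in lum) {
    row <- comm$S[ml, ]
    touching <- comm$rxns$id[which(row != 0)]
    expect_true(any(!grepl("^EX_", touching)), info = ml)
  }

  expect_error(assemble_community(pans, c(0.6, 0.4)), "exactly the pan")
  zero_r <- setNames(c(0, 1), names(pans))
  expect_error(assemble_community(pans, zero_r), "zero or negative")
  expect_error(assemble_community(pans, r * 0.9), "sum to 1")
})

test_that("coupling rows count irreversible and reversible reactions correctly", {
  s <- strain("s", "spZ", list(
    list(id = "irrev", stoich = c(`a[luM]` = -1, `a[c]` = 1), lb = 0, ub = 10),
    list(id = "rev", stoich = c(`a[c]` = -1, `b[c]` = 1), lb = -10, ub = 10),
    list(id = "biomass", stoich = c(`a[c]` = -1, `biomass[c]` = 1),
         lb = 0, ub = 10, is_biomass = TRUE)))
  pan <- build_pan_species(list(s), "spZ")
  comm <- assemble_community(list(pan), setNames(1, "spZ"))
  comm <- add_coupling_constraints(comm)
  # 1 irreversible (1 row) + 1 reversible (2 rows); community transports are
  # untagged and receive no coupling
  expect_equal(nrow(comm$couplings), 3)
  expect_equal(sum(comm$couplings$sense == "le"), 2)
  expect_equal(sum(comm$couplings$sense == "ge"), 1)
  expect_true(all(comm$couplings$factor == 400))
})

test_that("coupling caps fluxes at factor times biomass flux", {
  mdl <- build_toy_joined(n_species = 2, strains = 1, seed = 21,
                          abundances = c(synthetic_sp01 = 0.25,
                                         synthetic_sp02 = 0.75))
  # biomass flux of sp01 is pinned to 0.25; any coupled reaction <= 100
  dm <- add_demand_reaction(mdl, "but")
  sol <- solve_fba(dm$model, dm$rxn_id)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$fluxes["pansynthetic_sp01_biomass"]), 0.25,
               tolerance = 1e-6)
  coupled <- mdl$couplings$rxn[mdl$couplings$biomass_rxn == "pansynthetic_sp01_biomass"]
  expect_true(all(abs(sol$fluxes[coupled]) <= 100 + 1e-6))

  # forcing biomass to zero forces all coupled fluxes to zero
  mdl0 <- set_bounds(mdl, "pansynthetic_sp01_biomass", 0, 0)
  dm0 <- add_demand_reaction(mdl0, "but")
  sol0 <- solve_fba(dm0$model, dm0$rxn_id,
                    rhs = setNames(-0.25, "pansynthetic_sp01_biomass[c]"))
  if (sol0$status == "optimal") {
    expect_true(all(abs(sol0$fluxes[coupled]) <= 1e-6))
  }
})

test_that("host join pins excretion and objective and conserves host bounds", {
  catalog <- generate_strain_catalog(3, 1, seed = 31)
  pans <- lapply(split(catalog, vapply(catalog, attr, character(1), "species")),
                 function(s) build_pan_species(s, attr(s[[1]], "species")))
  r <- setNames(c(0.5, 0.3, 0.2), names(pans))
  comm <- add_coupling_constraints(assemble_community(pans, r))
  host <- generate_host_template("female")
  joined <- join_host(host, comm)
  expect_equal(unname(reaction_bounds(joined, "Excretion_EX_microbiota_LI_biomass[fe]")),
               c(1, 1))
  expect_equal(unname(reaction_bounds(joined, "Whole_body_objective_rxn")),
               c(1, 1))
  # all other host reaction bounds unchanged
  for (rid in setdiff(host$rxns$id, "Whole_body_objective_rxn")) {
    expect_equal(reaction_bounds(joined, rid), reaction_bounds(host, rid),
                 info = rid)
  }
  expect_error(join_host(chain_model(), comm), "Whole_body_objective_rxn|luLI")
})

test_that("species biomass fluxes are pinned to relative abundances", {
  for (seed in c(41, 42)) {
    mdl <- build_toy_joined(n_species = 4, strains = 1, seed = seed)
    r <- attr(mdl, "abundances")
    dm <- add_demand_reaction(mdl, "ppa")
    sol <- solve_fba(dm$model, dm$rxn_id)
    expect_equal(sol$status, "optimal")
    v_bio <- sol$fluxes_raw[sprintf("pan%s_biomass", names(r))]
    expect_equal(unname(v_bio), unname(r), tolerance = 1e-6)
  }
})

test_that("splitting a species into two copies preserves the maximal flux", {
  catalog <- generate_strain_catalog(2, 1, seed = 51)
  by_sp <- split(catalog, vapply(catalog, attr, character(1), "species"))
  pans <- lapply(names(by_sp), function(sp) build_pan_species(by_sp[[sp]], sp))
  names(pans) <- names(by_sp)
  host <- generate_host_template("male")
  diet <- generate_diet(20, 0.25, seed = 51)
  solve_with <- function(pan_list, r) {
    comm <- add_coupling_constraints(assemble_community(pan_list, r))
    mdl <- suppressWarnings(apply_diet(join_host(host, comm), diet))
    dm <- add_demand_reaction(mdl, "but")
    solve_fba(dm$model, dm$rxn_id)$objective
  }
  z1 <- solve_with(pans, setNames(c(0.6, 0.4), names(pans)))
  # duplicate species 1 under a new ID with abundance split r/2 + r/2
  dup <- pans[[1]]
  dup_id <- "synthetic_sp99"
  rl <- wbmflux:::model_to_reaction_list(dup)
  rl <- lapply(rl, function(r) {
    names(r$stoich) <- sub(sprintf("^pan%s_", attr(dup, "species")),
                           sprintf("pan%s_", dup_id), names(r$stoich))
    r$id <- sub(sprintf("^pan%s_", attr(dup, "species")),
                sprintf("pan%s_", dup_id), r$id)
    r$species <- dup_id
    r
  })
  dup2 <- make_reconstruction(sprintf("pan_%s", dup_id), rl)
  attr(dup2, "species") <- dup_id
  z2 <- solve_with(c(pans, list(dup2)),
                   setNames(c(0.3, 0.4, 0.3), c(names(pans), dup_id)))
  expect_equal(z2, z1, tolerance = 1e-5)
})

test_that("apply_diet follows the uptake-negative convention", {
  host <- generate_host_template("male")
  diet <- data.frame(metabolite = c("glc_D", "ala_L", "unknown_met"),
                     intake = c(10, 0.05, 3))
  expect_warning(m <- apply_diet(host, diet), "skipped")
  expect_equal(unname(reaction_bounds(m, "Diet_EX_glc_D[d]")), c(-10, 1e6))
  expect_equal(unname(reaction_bounds(m, "Diet_EX_ala_L[d]")[1]), -0.05)
  # metabolite absent from the diet: uptake closed
  expect_equal(unname(reaction_bounds(m, "Diet_EX_but[d]")[1]), 0)
  expect_equal(attr(m, "skipped_diet_entries"), "unknown_met")
  # flexibility scales the uptake bound
  m2 <- suppressWarnings(apply_diet(host, diet, flexibility = 0.5))
  expect_equal(unname(reaction_bounds(m2, "Diet_EX_glc_D[d]")[1]), -5)
})

test_that("personalize_abundances equals reassembly from scratch", {
  catalog <- generate_strain_catalog(3, 1, seed = 61)
  by_sp <- split(catalog, vapply(catalog, attr, character(1), "species"))
  pans <- lapply(names(by_sp), function(sp) build_pan_species(by_sp[[sp]], sp))
  names(pans) <- names(by_sp)
  host <- generate_host_template("male")
  diet <- generate_diet(20, 0.25, seed = 61)
  build <- function(r) {
    comm <- add_coupling_constraints(assemble_community(pans, r))
    suppressWarnings(apply_diet(join_host(host, comm), diet))
  }
  r1 <- setNames(c(1, 1, 1) / 3, names(pans))
  r2 <- setNames(c(0.5, 0.2, 0.3), names(pans))
  direct <- build(r2)
  personalized <- personalize_abundances(build(r1), r2)
  expect_equal(as.matrix(personalized$S), as.matrix(direct$S))
  expect_equal(attr(personalized, "abundances"), attr(direct, "abundances"))
})
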