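test_that("contribution potential is -pi times biomass flux", {
  sol <- structure(list(
    status = "optimal",
    shadow_prices = c(`panspA_biomass[c]` = -2.0, `panspB_biomass[c]` = 0),
    fluxes_raw = c(panspA_biomass = 0.25, panspB_biomass = 0.75)),
    class = "fba_solution")
  fake <- list(mets = data.frame(id = c("panspA_biomass[c]", "panspB_biomass[c]")))
  cp <- contribution_potentials(sol, fake, abundances = c(spA = 0.25, spB = 0.75))
  expect_equal(cp$delta_Z[cp$species == "spA"], 0.5) # -(-2.0) * 0.25
  expect_equal(cp$delta_Z[cp$species == "spB"], 0)   # pi = 0 -> delta_Z = 0
  # a biomass flux inconsistent with the abundances is an error
  expect_error(contribution_potentials(sol, fake,
                                       abundances = c(spA = 0.5, spB = 0.5)),
               "deviates")
})

test_that("the sole producer's contribution equals the microbial objective share", {
  r <- c(synthetic_sp01 = 0.5, synthetic_sp02 = 0.5)
  mdl <- build_toy_joined(2, 1, seed = 91, abundances = r)
  dm <- add_demand_reaction(mdl, "but")
  sol <- solve_fba(dm$model, dm$rxn_id)
  cp <- contribution_potentials(sol, dm$model)
  bf <- brute_force_contribution(mdl, "synthetic_sp01", "but")
  # removal of the sole producer leaves only non-microbial sources
  expect_equal(cp$delta_Z[cp$species == "synthetic_sp01"],
               bf$Z_full - bf$Z_reduced, tolerance = 1e-5)
  expect_equal(bf$Z_reduced, 0, tolerance = 1e-6)
  expect_false(bf$basis_change)
  # the non-producing, non-consuming species contributes nothing
  sp2 <- cp$delta_Z[cp$species == "synthetic_sp02"]
  bf2 <- brute_force_contribution(mdl, "synthetic_sp02", "but")
  expect_equal(sp2, bf2$delta_Z_oracle, tolerance = 1e-5)
})

test_that("shadow-price contributions match brute-force removal across seeds", {
  suite <- run_oracle_suite(60, seed0 = 500)
  pairs <- suite$pairs
  expect_gt(nrow(pairs), 120)
  agree <- abs(pairs$shadow - pairs$oracle) <= 1e-5
  # exceptions must carry the basis-change flag
  expect_true(all(pairs$basis_change[!agree]))
  expect_gte(mean(agree), 0.95)
  # sign agreement everywhere (zero treated as sign-compatible at tolerance)
  sgn <- function(x, tol = 1e-6) ifelse(abs(x) < tol, 0, sign(x))
  expect_true(all(sgn(pairs$shadow) == sgn(pairs$oracle) |
                    sgn(pairs$shadow) == 0 | sgn(pairs$oracle) == 0))
})

test_that("bootstrap mean and CI behave on degenerate and normal input", {
  b <- bootstrap_mean_ci(rep(3.5, 20), n_boot = 500, seed = 1)
  expect_equal(unname(b), c(3.5, 3.5, 3.5))
  expect_identical(bootstrap_mean_ci(1:10, n_boot = 1000, seed = 9),
                   bootstrap_mean_ci(1:10, n_boot = 1000, seed = 9))
  x <- with_seed_local(4, rnorm(200))
  b2 <- bootstrap_mean_ci(x, n_boot = 50000, seed = 2)
  width <- b2[["hi"]] - b2[["lo"]]
  analytic <- 2 * qnorm(0.975) / sqrt(200)
  expect_lt(abs(width - analytic) / analytic, 0.15)
})

test_that("pruning returns the smallest prefix reaching the share", {
  v <- c(a = 0.5, b = 0.3, c = 0.15, d = 0.05)
  expect_equal(prune_to_cumulative(v, 0.95), c("a", "b", "c"))
  expect_equal(prune_to_cumulative(c(x = 2), 0.95), "x")
  eq <- setNames(rep(1, 20), sprintf("s%02d", 1:20))
  expect_length(prune_to_cumulative(eq, 0.95), 19)
  expect_equal(prune_to_cumulative(c(a = 0, b = 0)), character(0))
  # magnitudes rank consumers too; ties break lexicographically
  expect_equal(prune_to_cumulative(c(b = -0.5, a = 0.5), 0.6)[1], "a")
  # pruned-share property on random vectors
  set.seed(6)
  for (i in 1:10) {
    w <- setNames(runif(12), sprintf("t%02d", 1:12))
    sel <- prune_to_cumulative(w, 0.95)
    expect_gte(sum(w[sel]) / sum(w), 0.95)
    if (length(sel) > 1) {
      expect_lt(sum(w[sel[-length(sel)]]) / sum(w), 0.95)
    }
  }
})

test_that("species-flux correlation handles perfect, inverse and null signals", {
  a <- c(1, 3, 2, 5, 4, 6, 8, 7)
  expect_equal(correlate_species_flux(a, a)$rho, 1)
  expect_equal(correlate_species_flux(a, -a)$rho, -1)
  set.seed(8)
  r0 <- correlate_species_flux(runif(1000), runif(1000))
  expect_lt(abs(r0$rho), 0.1)
  flagged <- correlate_species_flux(rep(1, 10), rnorm(10))
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$rho))
  # pairwise deletion of missing flux cells
  f <- a; f[2] <- NA
  expect_equal(correlate_species_flux(a, f)$n, 7)
  expect_error(correlate_species_flux(1:2, 1:2), "3 complete pairs")
})

test_that("cluster search is exhaustive, order-invariant and rule-faithful", {
  set.seed(12)
  n <- 120
  ab <- matrix(runif(5 * n), 5, n,
               dimnames = list(c("spA", "spB", "spC", "spD", "spE"),
                               sprintf("s%03d", 1:n)))
  # flux equal to one species' abundance: k = 1, that species, rho = 1
  res1 <- search_microbe_clusters(rownames(ab), ab, ab["spC", ])
  expect_equal(res1$k, 1)
  expect_equal(res1$species, "spC")
  expect_equal(res1$rho, 1)

  # pair signal: flux = a_A + a_B with independent abundances
  fpair <- ab["spA", ] + ab["spB", ]
  res2 <- search_microbe_clusters(rownames(ab), ab, fpair)
  expect_equal(res2$k, 2)
  expect_setequal(res2$species, c("spA", "spB"))
  singles <- res2$trace$rho[res2$trace$k == 1]
  expect_gt(abs(res2$rho), abs(singles) + 0.05)

  # independent brute-force enumeration agrees with the returned subset
  combos <- combn(rownames(ab), 2, simplify = FALSE)
  rhos <- vapply(combos, function(cc) {
    abs(cor(rank(colSums(ab[cc, ])), rank(fpair)))
  }, numeric(1))
  expect_setequal(res2$species, combos[[which.max(rhos)]])

  # invariance to the order of the input species
  res2b <- search_microbe_clusters(rev(rownames(ab)), ab, fpair)
  expect_equal(res2b$species, res2$species)
  expect_equal(res2b$rho, res2$rho)

  # delta = Inf degenerates to k = 1
  res3 <- search_microbe_clusters(rownames(ab), ab, fpair, delta = Inf)
  expect_equal(res3$k, 1)

  # combinatorial cap
  big <- matrix(runif(30 * 20), 30, 20,
                dimnames = list(sprintf("q%02d", 1:30), sprintf("s%02d", 1:20)))
  expect_error(search_microbe_clusters(rownames(big), big, runif(20),
                                       max_subsets = 100),
               "prune")
})
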