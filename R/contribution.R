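#' Per-species contribution potentials from an FBA solution
#'
#' The contribution potential of species `i` to a predicted blood flux is
#' `delta_Z_i = -pi_i * v_bio,i`: the species biomass shadow price (in the
#' `pi = -dZ/db` convention) times its biomass reaction flux. Because the
#' community biomass excretion is pinned to 1, `v_bio,i` equals the
#' species' relative abundance; the flux is nevertheless read from the
#' solution and checked against the abundance rather than assumed.
#'
#' @param solution Optimal `fba_solution` on a host-microbiome model.
#' @param model The model the solution was computed on.
#' @param abundances Named relative abundances of the model's species
#'   (defaults to the `abundances` attribute of `model`).
#' @return Data frame with columns `species`, `pi`, `v_bio`, `delta_Z`.
#' @export
contribution_potentials <- function(solution, model,
                                    abundances = attr(model, "abundances")) {
  pi_vals <- extract_biomass_shadow_prices(solution, model)
  if (length(pi_vals) == 0L) {
    return(data.frame(species = character(0), pi = numeric(0),
                      v_bio = numeric(0), delta_Z = numeric(0)))
  }
  bio_rxn <- sprintf("pan%s_biomass", names(pi_vals))
  if (!all(bio_rxn %in% names(solution$fluxes_raw))) {
    stopf("missing biomass flux for species: %s",
          paste(names(pi_vals)[!bio_rxn %in% names(solution$fluxes_raw)],
                collapse = ", "))
  }
  v_bio <- as.numeric(solution$fluxes_raw[bio_rxn])
  if (!is.null(abundances)) {
    r <- as.numeric(abundances[names(pi_vals)])
    if (any(abs(v_bio - r) > 1e-5, na.rm = TRUE)) {
      stopf("biomass flux deviates from relative abundance beyond LP tolerance")
    }
  }
  data.frame(species = names(pi_vals), pi = as.numeric(pi_vals),
             v_bio = v_bio, delta_Z = -as.numeric(pi_vals) * v_bio,
             stringsAsFactors = FALSE)
}

#' Brute-force removal oracle for a species' contribution
#'
#' Recomputes the contribution potential the expensive way: solve the full
#' model, then a reduced model in which the species' biomass reaction is
#' closed (`[0, 0]`, so coupling shuts all its reactions) while its biomass
#' metabolite is supplied exogenously at the rate the community biomass
#' reaction consumes it (keeping the pinned community biomass feasible,
#' i.e. the remaining species' abundances unchanged). The oracle value is
#' `Z(full) - Z(reduced)`. A basis-change flag is raised when the species'
#' biomass shadow price differs between the two solutions (the linear
#' shadow-price extrapolation is then not valid over the whole removal
#' range) or the reduced model is infeasible.
#'
#' @param model Host-microbiome model (demand reaction not yet added).
#' @param species Species ID to remove.
#' @param metabolite Blood metabolite whose demand is the objective.
#' @param compartment Compartment tag (default `"[bc]"`).
#' @return List with `delta_Z_oracle` (NA if the reduced model is
#'   infeasible), `Z_full`, `Z_reduced`, `basis_change` and
#'   `reduced_status`.
#' @export
brute_force_contribution <- function(model, species, metabolite,
                                     compartment = "[bc]") {
  bio_rxn <- sprintf("pan%s_biomass", species)
  bio_met <- sprintf("pan%s_biomass[c]", species)
  if (!has_reaction(model, bio_rxn)) {
    stopf("species '%s' not in model '%s'", species, model$id)
  }
  dm <- add_demand_reaction(model, metabolite, compartment)
  full <- solve_fba(dm$model, dm$rxn_id)
  if (full$status != "optimal") {
    stopf("full model not solvable for %s", metabolite)
  }
  pi_full <- extract_biomass_shadow_prices(full, dm$model)[species]
  # consumption rate of the species biomass metabolite by communityBiomass
  coef <- dm$model$S[bio_met, "communityBiomass"]
  v_cb <- full$fluxes_raw[["communityBiomass"]]
  supply <- -coef * v_cb # = r_i when community biomass is pinned to 1
  red_model <- set_bounds(dm$model, bio_rxn, 0, 0)
  red <- solve_fba(red_model, dm$rxn_id,
                   rhs = stats::setNames(-supply, bio_met))
  if (red$status != "optimal") {
    return(list(delta_Z_oracle = NA_real_, Z_full = full$objective_raw,
                Z_reduced = NA_real_, basis_change = TRUE,
                reduced_status = red$status))
  }
  pi_red <- extract_biomass_shadow_prices(red, red_model)[species]
  list(delta_Z_oracle = full$objective_raw - red$objective_raw,
       Z_full = full$objective_raw, Z_reduced = red$objective_raw,
       basis_change = abs(pi_full - pi_red) > 1e-6,
       reduced_status = "optimal")
}

#' Bootstrap mean and percentile confidence interval
#'
#' Resamples `values` with replacement `n_boot` times; reports the mean of
#' the bootstrap means and the 2.5/97.5 percentile interval.
#' Deterministic given `seed`.
#'
#' @param values Non-empty numeric vector.
#' @param n_boot Number of bootstrap resamples (default 50000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(mean, lo, hi)`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 50000, seed = 1, conf = 0.95) {
  stopifnot(length(values) >= 1, n_boot >= 1)
  n <- length(values)
  with_seed(seed, {
    means <- numeric(n_boot)
    chunk <- max(1L, min(n_boot, floor(2e6 / n)))
    done <- 0L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      idx <- sample.int(n, n * k, replace = TRUE)
      means[done + seq_len(k)] <-
        colMeans(matrix(values[idx], nrow = n, ncol = k))
      done <- done + k
    }
    a <- (1 - conf) / 2
    qs <- stats::quantile(means, c(a, 1 - a), names = FALSE, type = 7)
    c(mean = mean(means), lo = qs[1], hi = qs[2])
  })
}

#' Prune species to a cumulative contribution share
#'
#' Species are ranked by the magnitude of their mean contribution (ties
#' broken lexicographically by species ID) and the smallest prefix whose
#' cumulative share of the total magnitude reaches `frac` is returned.
#'
#' @param species_mean_contributions Named numeric vector of mean
#'   contribution potentials (sign allowed; ranking uses magnitudes).
#' @param frac Cumulative share to cover (default 0.95).
#' @return Character vector of species IDs, in rank order (empty if all
#'   contributions are zero).
#' @export
prune_to_cumulative <- function(species_mean_contributions, frac = 0.95) {
  stopifnot(frac > 0, frac <= 1)
  mag <- abs(species_mean_contributions)
  if (sum(mag) == 0) return(character(0))
  ord <- order(-mag, names(mag))
  mag <- mag[ord]
  share <- cumsum(mag) / sum(mag)
  k <- which(share >= frac - 1e-12)[1]
  names(mag)[seq_len(k)]
}

#' Spearman correlation between species abundance and flux
#'
#' Mid-rank Spearman correlation with pairwise deletion of missing flux
#' cells; zero variance in either vector yields an undefined (flagged)
#' correlation.
#'
#' @param abundance_vector,flux_vector Equal-length numeric vectors
#'   (>= 3 complete pairs).
#' @return List with `rho`, `p`, `n` and `flagged`.
#' @export
correlate_species_flux <- function(abundance_vector, flux_vector) {
  stopifnot(length(abundance_vector) == length(flux_vector))
  ok <- stats::complete.cases(abundance_vector, flux_vector)
  x <- abundance_vector[ok]; y <- flux_vector[ok]
  if (length(x) < 3) stopf("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x), flagged = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       flagged = FALSE)
}

#' Exhaustive microbial cluster search
#'
#' For each subset size `k = 1..max_k`, evaluates the Spearman correlation
#' of the summed relative abundances of every k-subset of the pruned
#' species with the flux vector, and selects the largest `k` whose best
#' absolute correlation exceeds the best at every smaller size by more
#' than `delta`. Species are processed in sorted order and ties at equal
#' correlation are broken by lexicographic subset order, so the result is
#' invariant to input order.
#'
#' @param pruned_species Candidate species IDs (>= 1).
#' @param abundance_table Species x samples abundance matrix containing
#'   the candidates.
#' @param flux_vector Named flux vector over the table's samples.
#' @param max_k Largest subset size (default 5).
#' @param delta Required improvement in |rho| over every smaller size
#'   (default 0.05).
#' @param max_subsets Cap on the number of subsets per size; exceeding it
#'   is an error advising tighter pruning.
#' @return List with `k`, `species`, `rho`, and `trace` (data frame of the
#'   best subset per size).
#' @export
search_microbe_clusters <- function(pruned_species, abundance_table,
                                    flux_vector, max_k = 5, delta = 0.05,
                                    max_subsets = 5e5) {
  stopifnot(length(pruned_species) >= 1)
  sp <- sort(unique(pruned_species))
  missing_sp <- setdiff(sp, rownames(abundance_table))
  if (length(missing_sp)) {
    stopf("species not in abundance table: %s", paste(missing_sp, collapse = ", "))
  }
  samples <- colnames(abundance_table)
  if (!is.null(names(flux_vector))) flux_vector <- flux_vector[samples]
  ok <- !is.na(flux_vector)
  fr <- rank(flux_vector[ok]) # mid-ranks
  A <- abundance_table[sp, ok, drop = FALSE]
  spearman_abs <- function(svec) {
    if (stats::sd(svec) == 0) return(NA_real_)
    stats::cor(rank(svec), fr)
  }
  best <- data.frame(k = integer(0), rho = numeric(0), subset = character(0),
                     stringsAsFactors = FALSE)
  best_sets <- list()
  for (k in seq_len(min(max_k, length(sp)))) {
    n_sub <- choose(length(sp), k)
    if (n_sub > max_subsets) {
      stopf(paste("cluster search size %d has %g subsets (cap %g);",
                  "prune the species set more tightly"), k, n_sub, max_subsets)
    }
    combos <- utils::combn(sp, k, simplify = FALSE)
    best_rho <- -Inf; best_signed <- NA_real_; best_combo <- NULL
    for (cmb in combos) {
      s <- colSums(A[cmb, , drop = FALSE])
      r <- spearman_abs(s)
      if (!is.na(r) && abs(r) > best_rho + 1e-15) {
        best_rho <- abs(r); best_signed <- r; best_combo <- cmb
      }
    }
    best <- rbind(best, data.frame(k = k, rho = best_signed,
                                   subset = paste(best_combo, collapse = "+"),
                                   stringsAsFactors = FALSE))
    best_sets[[k]] <- list(species = best_combo, rho = best_signed)
  }
  abs_best <- abs(best$rho)
  sel <- 1L
  for (k in seq_along(abs_best)[-1]) {
    if (!is.na(abs_best[k]) &&
        all(abs_best[k] > abs_best[seq_len(k - 1)] + delta)) {
      sel <- k
    }
  }
  list(k = sel, species = best_sets[[sel]]$species,
       rho = best_sets[[sel]]$rho, trace = best)
}
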