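#' @keywords internal
model_to_reaction_list <- function(model) {
  lapply(seq_len(nrow(model$rxns)), function(j) {
    list(id = model$rxns$id[j],
         stoich = reaction_stoich(model, model$rxns$id[j]),
         lb = model$rxns$lb[j], ub = model$rxns$ub[j],
         species = model$rxns$species[j],
         is_biomass = model$rxns$is_biomass[j])
  })
}

#' Build a pan-species model from strain reconstructions
#'
#' The pan model is the union of all strains' reactions and metabolites by
#' ID. Reactions present in several strains must agree in stoichiometry;
#' their bounds are merged to the widest interval. The strains' biomass
#' reactions (which share one ID by construction) are merged into a single
#' pan biomass reaction named `pan<species>_biomass`, producing the
#' species biomass metabolite `pan<species>_biomass[c]`.
#'
#' @param strain_models List of strain `reconstruction`s, all tagged with
#'   `species_id`.
#' @param species_id The species these strains belong to.
#' @return A `reconstruction` with exactly one biomass reaction.
#' @export
build_pan_species <- function(strain_models, species_id) {
  if (length(strain_models) == 0L) stopf("empty strain list for '%s'", species_id)
  tags <- vapply(strain_models, function(m) attr(m, "species") %||% NA_character_,
                 character(1))
  if (!all(tags == species_id)) {
    stopf("strain(s) not tagged with species '%s'", species_id)
  }
  merged <- list()
  for (m in strain_models) {
    for (r in model_to_reaction_list(m)) {
      if (is.null(merged[[r$id]])) {
        merged[[r$id]] <- r
      } else {
        prev <- merged[[r$id]]
        a <- prev$stoich[order(names(prev$stoich))]
        b <- r$stoich[order(names(r$stoich))]
        if (!identical(names(a), names(b)) || max(abs(a - b)) > 1e-12) {
          stopf("conflicting stoichiometry for reaction '%s' across strains of '%s'",
                r$id, species_id)
        }
        prev$lb <- min(prev$lb, r$lb)
        prev$ub <- max(prev$ub, r$ub)
        merged[[r$id]] <- prev
      }
    }
  }
  bio <- names(merged)[vapply(merged, function(r) isTRUE(r$is_biomass), logical(1))]
  if (length(bio) != 1L) {
    stopf("pan model for '%s' must have exactly one biomass reaction, found %d",
          species_id, length(bio))
  }
  pan_bio_rxn <- sprintf("pan%s_biomass", species_id)
  pan_bio_met <- sprintf("pan%s_biomass[c]", species_id)
  merged <- lapply(merged, function(r) {
    nm <- names(r$stoich)
    nm[nm == "biomass[c]"] <- pan_bio_met
    names(r$stoich) <- nm
    r$species <- species_id
    r
  })
  names(merged)[names(merged) == bio] <- pan_bio_rxn
  merged[[pan_bio_rxn]]$id <- pan_bio_rxn
  mdl <- make_reconstruction(sprintf("pan_%s", species_id), unname(merged))
  attr(mdl, "species") <- species_id
  mdl
}

species_prefix <- function(sp) sprintf("pan%s_", sp)

#' Assemble an abundance-personalized community model
#'
#' Per-species reactions and cytosolic metabolites are prefixed with
#' `pan<species>_` and connected to the shared microbiota lumen `[luM]`
#' (lumen metabolites are shared unprefixed; each species' own transport
#' reactions link its cytosol to the lumen). Strain-level lumen exchange
#' reactions are replaced by community-level exchanges. A
#' `communityBiomass` reaction consumes each species' biomass metabolite
#' with its relative abundance as the (negative) stoichiometric coefficient
#' and produces one unit of `microbiota_LI_biomass[luM]`.
#'
#' @param pan_models Named list of pan-species `reconstruction`s.
#' @param abundances Named numeric vector of relative abundances covering
#'   exactly the pan models' species; must sum to 1 and be strictly
#'   positive (zero-abundance species are excluded upstream).
#' @return A `reconstruction` with class `community_model`.
#' @export
assemble_community <- function(pan_models, abundances) {
  sp_models <- vapply(pan_models, function(m) attr(m, "species"), character(1))
  names(pan_models) <- sp_models
  if (!setequal(names(abundances), sp_models) ||
      length(abundances) != length(sp_models)) {
    stopf("abundances must cover exactly the pan models' species")
  }
  if (any(abundances <= 0)) {
    stopf("zero or negative abundance retained in model for: %s",
          paste(names(abundances)[abundances <= 0], collapse = ", "))
  }
  if (abs(sum(abundances) - 1) > 1e-9) {
    stopf("abundances must sum to 1 (got %.12f)", sum(abundances))
  }
  rx <- list()
  for (sp in sp_models) {
    pre <- species_prefix(sp)
    for (r in model_to_reaction_list(pan_models[[sp]])) {
      if (grepl("^EX_", r$id)) next # strain-level boundary, replaced below
      nm <- names(r$stoich)
      cyt <- grepl("\\[c\\]$", nm) & !startsWith(nm, pre)
      nm[cyt] <- paste0(pre, nm[cyt])
      names(r$stoich) <- nm
      if (!startsWith(r$id, pre)) r$id <- paste0(pre, r$id)
      r$species <- sp
      rx[[length(rx) + 1L]] <- r
    }
  }
  lumen <- unique(unlist(lapply(rx, function(r) {
    nm <- names(r$stoich); nm[grepl("\\[luM\\]$", nm)]
  })))
  for (mlu in lumen) {
    rx[[length(rx) + 1L]] <- list(
      id = sprintf("EX_%s", mlu),
      stoich = stats::setNames(-1, mlu), lb = -BIG, ub = BIG)
  }
  bio_st <- stats::setNames(-as.numeric(abundances[sp_models]),
                            sprintf("pan%s_biomass[c]", sp_models))
  bio_st <- c(bio_st, `microbiota_LI_biomass[luM]` = 1)
  rx[[length(rx) + 1L]] <- list(id = "communityBiomass", stoich = bio_st,
                                lb = 0, ub = BIG)
  rx[[length(rx) + 1L]] <- list(id = "EX_microbiota_LI_biomass[luM]",
                                stoich = c(`microbiota_LI_biomass[luM]` = -1),
                                lb = 0, ub = BIG)
  mdl <- make_reconstruction("community", rx)
  class(mdl) <- c("community_model", class(mdl))
  attr(mdl, "abundances") <- abundances[sp_models]
  mdl
}

#' Add flux-coupling constraints to a community model
#'
#' Every non-biomass reaction `j` of species `m` is tied to the species'
#' biomass flux: `v_j - factor * v_bio,m <= 0`, and for reversible
#' reactions additionally `v_j + factor * v_bio,m >= 0`, so organisms that
#' do not grow cannot carry flux.
#'
#' @param model A `community_model`.
#' @param coupling_factor Coupling multiple (default 400).
#' @return The model with its `couplings` table populated (one row per
#'   inequality, column `sense` in `{"le","ge"}`).
#' @export
add_coupling_constraints <- function(model, coupling_factor = 400) {
  species <- unique(stats::na.omit(model$rxns$species))
  if (length(species) == 0L) stopf("model has no species-tagged reactions")
  rows <- list()
  for (sp in species) {
    mine <- model$rxns$species %in% sp
    bio <- model$rxns$id[mine & model$rxns$is_biomass]
    if (length(bio) != 1L) {
      stopf("species '%s' must have exactly one biomass reaction", sp)
    }
    for (j in which(mine & !model$rxns$is_biomass)) {
      rows[[length(rows) + 1L]] <- data.frame(
        rxn = model$rxns$id[j], biomass_rxn = bio, factor = coupling_factor,
        sense = "le", stringsAsFactors = FALSE)
      if (model$rxns$lb[j] < 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          rxn = model$rxns$id[j], biomass_rxn = bio, factor = coupling_factor,
          sense = "ge", stringsAsFactors = FALSE)
      }
    }
  }
  model$couplings <- do.call(rbind, rows)
  attr(model, "n_coupling_constraints") <- nrow(model$couplings)
  model
}

#' Join a community model to the host template
#'
#' The community's shared lumen `[luM]` is identified with the host's
#' large-intestine lumen `[luLI]` (community lumen metabolites are renamed
#' into the host compartment, so host transports take over all boundary
#' exchanges and the community-level exchange reactions are dropped). Two
#' pinning constraints are applied: the community-biomass excretion
#' reaction `Excretion_EX_microbiota_LI_biomass[fe]` is added with bounds
#' `[1, 1]`, and the host `Whole_body_objective_rxn` bounds are set to
#' `[1, 1]`. Together these fix every species' biomass flux to its
#' relative abundance in any feasible solution.
#'
#' @param host Host `reconstruction` with a `[luLI]` compartment.
#' @param community Assembled (and normally coupled) `community_model`.
#' @return A `reconstruction` with class `host_microbiome_model`.
#' @export
join_host <- function(host, community) {
  if (!"luLI" %in% host$compartments) {
    stopf("host model '%s' has no large-intestine lumen compartment [luLI]", host$id)
  }
  if (!has_reaction(host, "Whole_body_objective_rxn")) {
    stopf("host model '%s' lacks Whole_body_objective_rxn", host$id)
  }
  if (!has_reaction(community, "communityBiomass")) {
    stopf("community model is not assembled (no communityBiomass reaction)")
  }
  rx <- model_to_reaction_list(host)
  for (r in model_to_reaction_list(community)) {
    if (grepl("^EX_", r$id)) next # community boundary handled by the host
    names(r$stoich) <- sub("\\[luM\\]$", "[luLI]", names(r$stoich))
    rx[[length(rx) + 1L]] <- r
  }
  rx[[length(rx) + 1L]] <- list(
    id = "Excretion_EX_microbiota_LI_biomass[fe]",
    stoich = c(`microbiota_LI_biomass[luLI]` = -1), lb = 1, ub = 1)
  mdl <- make_reconstruction(sprintf("%s_mWBM", host$id), rx,
                             couplings = community$couplings)
  mdl <- set_bounds(mdl, "Whole_body_objective_rxn", 1, 1)
  class(mdl) <- c("host_microbiome_model", class(mdl))
  attr(mdl, "abundances") <- attr(community, "abundances")
  mdl
}

#' Re-personalize a joined model's relative abundances
#'
#' Replaces the `communityBiomass` coefficients of a joined (or assembled)
#' model with a new abundance vector over the same species set. Because
#' the abundances enter the model only through that one reaction column,
#' this is equivalent to reassembling the community from scratch.
#'
#' @param model A `community_model` or `host_microbiome_model`.
#' @param abundances Named positive abundances over exactly the model's
#'   species, summing to 1.
#' @return The personalized model.
#' @export
personalize_abundances <- function(model, abundances) {
  sp <- names(attr(model, "abundances"))
  if (!setequal(names(abundances), sp)) {
    stopf("abundances must cover exactly the model's species")
  }
  if (any(abundances <= 0)) stopf("abundances must be strictly positive")
  if (abs(sum(abundances) - 1) > 1e-9) {
    stopf("abundances must sum to 1 (got %.12f)", sum(abundances))
  }
  j <- match("communityBiomass", model$rxns$id)
  if (is.na(j)) stopf("model has no communityBiomass reaction")
  mets <- sprintf("pan%s_biomass[c]", names(abundances))
  model$S[mets, j] <- -as.numeric(abundances)
  attr(model, "abundances") <- abundances[sp]
  model
}

#' Apply a diet to a host(-microbiome) model
#'
#' Sets each matching diet exchange reaction's lower bound to
#' `-flexibility * intake` (the uptake-negative convention) and closes the
#' uptake of every other diet exchange (`lb = 0`); secretion stays
#' unrestricted. Diet entries without a matching `Diet_EX_<met>[d]`
#' reaction are skipped with a warning.
#'
#' @param model A `reconstruction` with `Diet_EX_*[d]` reactions.
#' @param diet Data frame from [generate_diet()] (columns `metabolite`,
#'   `intake`).
#' @param flexibility Uptake flexibility multiplier (default 1).
#' @return The parameterized model; skipped entries in attribute
#'   `skipped_diet_entries`.
#' @export
apply_diet <- function(model, diet, flexibility = 1.0) {
  stopifnot(is.data.frame(diet), all(c("metabolite", "intake") %in% names(diet)),
            all(diet$intake >= 0), flexibility >= 0)
  diet_rxn <- sprintf("Diet_EX_%s[d]", diet$metabolite)
  present <- diet_rxn %in% model$rxns$id
  all_diet_rxns <- model$rxns$id[grepl("^Diet_EX_", model$rxns$id)]
  closed <- setdiff(all_diet_rxns, diet_rxn[present])
  for (r in closed) {
    model$rxns$lb[model$rxns$id == r] <- 0
  }
  for (k in which(present)) {
    i <- match(diet_rxn[k], model$rxns$id)
    model$rxns$lb[i] <- -flexibility * diet$intake[k]
  }
  skipped <- diet$metabolite[!present]
  if (length(skipped)) {
    warning(sprintf("%d diet entr%s without a matching diet exchange skipped",
                    length(skipped), if (length(skipped) == 1) "y" else "ies"),
            call. = FALSE)
  }
  attr(model, "skipped_diet_entries") <- skipped
  model
}
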