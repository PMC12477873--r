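#' Stoichiometric reconstruction objects
#'
#' A `reconstruction` is the package's container for a constraint-based
#' metabolic model: a strain, a pan-species model, a microbial community, a
#' host template, or a joined host-microbiome model. It holds metabolite and
#' reaction tables, a sparse stoichiometric matrix S (metabolites x
#' reactions), flux bounds in mmol/day/person, per-reaction species tags for
#' community members, biomass flags, and any flux-coupling constraints.
#'
#' Metabolite IDs carry a compartment tag as a bracketed suffix, e.g.
#' `glc_D[luM]` (shared microbiota lumen), `leu_L[bc]` (blood), `x[c]`
#' (cytosol), `x[d]` (diet boundary), `x[u]`/`x[fe]` (urine/feces).
#'
#' @name reconstruction
NULL

met_compartment <- function(met_ids) {
  m <- regmatches(met_ids, regexpr("\\[[^]]+\\]$", met_ids))
  out <- rep(NA_character_, length(met_ids))
  has <- grepl("\\[[^]]+\\]$", met_ids)
  out[has] <- gsub("^\\[|\\]$", "", m)
  out
}

#' Build a reconstruction from a reaction list
#'
#' @param id Model identifier.
#' @param reactions List of reactions; each a list with elements `id`,
#'   `stoich` (named numeric, names are metabolite IDs with compartment
#'   tags; negative = substrate, positive = product), `lb`, `ub`, and
#'   optionally `species` and `is_biomass`.
#' @param couplings Optional data frame with columns `rxn`, `biomass_rxn`,
#'   `factor` describing flux-coupling constraints
#'   (|v_rxn| <= factor * v_biomass).
#' @return A `reconstruction` object.
#' @export
make_reconstruction <- function(id, reactions, couplings = NULL) {
  if (length(reactions) == 0L) stopf("model '%s' has no reactions", id)
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids)) {
    stopf("duplicate reaction IDs: %s",
          paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  met_ids <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (length(met_ids) == 0L) stopf("model '%s' has no metabolites", id)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    st <- st[st != 0]
    if (length(st) == 0L) stopf("reaction '%s' has all-zero stoichiometry", rxn_ids[j])
    ii <- c(ii, met_index[names(st)])
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(reactions)),
                            dimnames = list(met_ids, rxn_ids))
  rxns <- data.frame(
    id = rxn_ids,
    lb = vapply(reactions, function(r) as.numeric(r$lb), numeric(1)),
    ub = vapply(reactions, function(r) as.numeric(r$ub), numeric(1)),
    species = vapply(reactions, function(r) r$species %||% NA_character_, character(1)),
    is_biomass = vapply(reactions, function(r) isTRUE(r$is_biomass), logical(1)),
    stringsAsFactors = FALSE
  )
  if (any(rxns$lb > rxns$ub)) {
    stopf("lb > ub for reaction(s): %s",
          paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "))
  }
  mets <- data.frame(id = met_ids, compartment = met_compartment(met_ids),
                     stringsAsFactors = FALSE)
  if (is.null(couplings)) {
    couplings <- data.frame(rxn = character(0), biomass_rxn = character(0),
                            factor = numeric(0), stringsAsFactors = FALSE)
  }
  structure(
    list(id = id, compartments = sort(unique(stats::na.omit(mets$compartment))),
         mets = mets, rxns = rxns, S = S, couplings = couplings),
    class = "reconstruction"
  )
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction '%s'>\n", x$id))
  cat(sprintf("  %d metabolites x %d reactions; %d coupling constraint(s)\n",
              nrow(x$mets), nrow(x$rxns), nrow(x$couplings)))
  sp <- unique(stats::na.omit(x$rxns$species))
  if (length(sp)) cat(sprintf("  species: %s\n", paste(sp, collapse = ", ")))
  cat(sprintf("  compartments: %s\n", paste(x$compartments, collapse = ", ")))
  invisible(x)
}

#' Reaction accessors
#'
#' @param model A `reconstruction`.
#' @param rxn_id Reaction ID.
#' @return `has_reaction` returns a logical; `reaction_bounds` a numeric
#'   `c(lb, ub)`; `reaction_stoich` a named numeric vector.
#' @export
has_reaction <- function(model, rxn_id) rxn_id %in% model$rxns$id

#' @rdname has_reaction
#' @export
reaction_bounds <- function(model, rxn_id) {
  i <- match(rxn_id, model$rxns$id)
  if (is.na(i)) stopf("no reaction '%s' in model '%s'", rxn_id, model$id)
  c(lb = model$rxns$lb[i], ub = model$rxns$ub[i])
}

#' @rdname has_reaction
#' @export
reaction_stoich <- function(model, rxn_id) {
  j <- match(rxn_id, model$rxns$id)
  if (is.na(j)) stopf("no reaction '%s' in model '%s'", rxn_id, model$id)
  col <- model$S[, j]
  col[col != 0]
}

#' Set flux bounds on a reaction
#'
#' @inheritParams has_reaction
#' @param lb,ub New lower/upper bounds (mmol/day/person).
#' @return The modified model.
#' @export
set_bounds <- function(model, rxn_id, lb, ub) {
  i <- match(rxn_id, model$rxns$id)
  if (is.na(i)) stopf("no reaction '%s' in model '%s'", rxn_id, model$id)
  if (lb > ub) stopf("lb > ub for '%s'", rxn_id)
  model$rxns$lb[i] <- lb
  model$rxns$ub[i] <- ub
  model
}

#' Add or remove a single reaction
#'
#' `add_reaction` appends one reaction column; `remove_reaction` deletes it
#' (and any metabolite rows left without reactions). Adding a duplicate ID
#' is an error and leaves the model unchanged.
#'
#' @inheritParams has_reaction
#' @param stoich Named numeric vector (metabolite IDs to coefficients).
#' @param lb,ub Flux bounds.
#' @param species Optional species tag.
#' @param is_biomass Whether this is a biomass reaction.
#' @return The modified model.
#' @export
add_reaction <- function(model, rxn_id, stoich, lb, ub,
                         species = NA_character_, is_biomass = FALSE) {
  if (has_reaction(model, rxn_id)) {
    stopf("reaction '%s' already present in model '%s'", rxn_id, model$id)
  }
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L) stopf("reaction '%s' has all-zero stoichiometry", rxn_id)
  new_mets <- setdiff(names(stoich), model$mets$id)
  if (length(new_mets)) {
    model$S <- rbind(model$S,
                     Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                          dims = c(length(new_mets), ncol(model$S)),
                                          dimnames = list(new_mets, colnames(model$S))))
    model$mets <- rbind(model$mets,
                        data.frame(id = new_mets, compartment = met_compartment(new_mets),
                                   stringsAsFactors = FALSE))
  }
  col <- Matrix::sparseMatrix(i = match(names(stoich), rownames(model$S)),
                              j = rep(1L, length(stoich)), x = unname(stoich),
                              dims = c(nrow(model$S), 1L),
                              dimnames = list(rownames(model$S), rxn_id))
  model$S <- cbind(model$S, col)
  model$rxns <- rbind(model$rxns,
                      data.frame(id = rxn_id, lb = lb, ub = ub, species = species,
                                 is_biomass = is_biomass, stringsAsFactors = FALSE))
  model$compartments <- sort(unique(stats::na.omit(model$mets$compartment)))
  model
}

#' @rdname add_reaction
#' @export
remove_reaction <- function(model, rxn_id) {
  j <- match(rxn_id, model$rxns$id)
  if (is.na(j)) stopf("no reaction '%s' in model '%s'", rxn_id, model$id)
  model$S <- model$S[, -j, drop = FALSE]
  model$rxns <- model$rxns[-j, , drop = FALSE]
  rownames(model$rxns) <- NULL
  keep <- Matrix::rowSums(abs(model$S)) > 0
  model$S <- model$S[keep, , drop = FALSE]
  model$mets <- model$mets[keep, , drop = FALSE]
  rownames(model$mets) <- NULL
  model$couplings <- model$couplings[model$couplings$rxn != rxn_id, , drop = FALSE]
  model$compartments <- sort(unique(stats::na.omit(model$mets$compartment)))
  model
}

#' Read and write reconstructions as JSON
#'
#' The on-disk schema has top-level keys `id`, `compartments`, `metabolites`
#' (list of `{id, compartment}`), `reactions` (list of `{id, stoich, lb, ub,
#' species, is_biomass}`) and `couplings` (list of `{rxn, biomass_rxn,
#' factor}`).
#'
#' @param model A `reconstruction`.
#' @param path File path.
#' @return `write_reconstruction_json` returns `path` invisibly;
#'   `read_reconstruction_json` returns a `reconstruction`.
#' @export
write_reconstruction_json <- function(model, path) {
  rx <- lapply(seq_len(nrow(model$rxns)), function(j) {
    st <- reaction_stoich(model, model$rxns$id[j])
    out <- list(id = model$rxns$id[j], stoich = as.list(st),
                lb = model$rxns$lb[j], ub = model$rxns$ub[j],
                is_biomass = model$rxns$is_biomass[j])
    if (!is.na(model$rxns$species[j])) out$species <- model$rxns$species[j]
    out
  })
  cp <- lapply(seq_len(nrow(model$couplings)), function(i) {
    list(rxn = model$couplings$rxn[i], biomass_rxn = model$couplings$biomass_rxn[i],
         factor = model$couplings$factor[i])
  })
  obj <- list(id = model$id, compartments = as.list(model$compartments),
              metabolites = lapply(seq_len(nrow(model$mets)), function(i) {
                list(id = model$mets$id[i], compartment = model$mets$compartment[i])
              }),
              reactions = rx, couplings = cp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_reconstruction_json
#' @export
read_reconstruction_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- lapply(obj$reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoich),
         lb = r$lb, ub = r$ub,
         species = r$species %||% NA_character_,
         is_biomass = isTRUE(r$is_biomass))
  })
  couplings <- NULL
  if (length(obj$couplings)) {
    couplings <- data.frame(
      rxn = vapply(obj$couplings, `[[`, character(1), "rxn"),
      biomass_rxn = vapply(obj$couplings, `[[`, character(1), "biomass_rxn"),
      factor = vapply(obj$couplings, function(x) as.numeric(x$factor), numeric(1)),
      stringsAsFactors = FALSE)
  }
  make_reconstruction(obj$id, reactions, couplings = couplings)
}

#' IDs of biomass reactions in a model
#' @param model A `reconstruction`.
#' @return Character vector of reaction IDs flagged as biomass.
#' @export
biomass_reactions <- function(model) model$rxns$id[model$rxns$is_biomass]
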