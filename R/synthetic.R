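#' Synthetic host-microbiome study generator
#'
#' These functions generate every input the pipeline consumes: strain-level
#' metabolic reconstructions with species-level redundancy, a miniature
#' compartmentalized host template, compositional abundance cohorts with
#' planted case/control effects, sample metadata, and a diet with trace
#' entries. All generators are deterministic given their seed.
#'
#' The shared metabolite universe is small but structured like the real
#' system: a staple carbon source (`glc_D`) every organism can grow on, six
#' dietary precursors, and six microbially producible "product" metabolites
#' (butyrate, propionate, nicotinic acid, pantothenate, L-leucine, acetate)
#' that reach the host's blood compartment via the gut lumen. The first
#' product (`but`) is only ever assigned to the first species, so cohorts
#' always contain a guaranteed sole producer for planted-effect experiments.
#'
#' @name synthetic_data
NULL

BIG <- 1e6

#' Metabolite universe of the synthetic system
#'
#' `STAPLE_MET` is the always-present dietary carbon source every species
#' grows on; `PRECURSOR_METS` are the dietary precursors; `PRODUCT_METS`
#' the microbially producible metabolites that can accumulate in blood.
#' @export
STAPLE_MET <- "glc_D"

#' @rdname STAPLE_MET
#' @export
PRECURSOR_METS <- c("ala_L", "ser_L", "asp_L", "thr_L", "gly", "pro_L")

#' @rdname STAPLE_MET
#' @export
PRODUCT_METS <- c("but", "ppa", "nac", "pnto_R", "leu_L", "ac")

#' @rdname STAPLE_MET
#' @export
universe_metabolites <- function() {
  c(STAPLE_MET, PRECURSOR_METS, PRODUCT_METS)
}

#' Configuration for a synthetic cohort
#'
#' @param n_pd,n_ctrl Case and control sample counts.
#' @param n_species Number of microbial species in the catalog.
#' @param strains_per_species Strain redundancy per species.
#' @param effect_map Named numeric vector: multiplicative abundance effect
#'   applied to the named species in the case group before compositional
#'   closure (e.g. `c(synthetic_sp01 = 0.2)` for a 5-fold depletion).
#' @param n_diet_mets Number of diet entries (default 192, the size of the
#'   average Western diet formulation this emulates).
#' @param trace_fraction Fraction of diet entries below the 0.1
#'   mmol/day/person trace threshold (default 92/192).
#' @param seed Master seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pd = 100, n_ctrl = 100, n_species = 6,
                             strains_per_species = 2, effect_map = numeric(0),
                             n_diet_mets = 192, trace_fraction = 92 / 192,
                             seed = 1) {
  stopifnot(n_pd >= 1, n_ctrl >= 1, n_species >= 1, strains_per_species >= 1,
            n_diet_mets >= 1)
  if (trace_fraction < 0 || trace_fraction > 1) {
    stopf("trace_fraction must be in [0, 1]")
  }
  if (length(effect_map) && (is.null(names(effect_map)) || any(effect_map <= 0))) {
    stopf("effect_map must be a named vector of positive effects")
  }
  structure(list(n_pd = n_pd, n_ctrl = n_ctrl, n_species = n_species,
                 strains_per_species = strains_per_species,
                 effect_map = effect_map, n_diet_mets = n_diet_mets,
                 trace_fraction = trace_fraction, seed = seed),
            class = "synthetic_config")
}

species_id <- function(i) sprintf("synthetic_sp%02d", i)

# Species-level blueprint: products, yields, consumer role. Shared by all
# strains of the species so the pan model's pathway content is stable.
species_blueprint <- function(n_species, seed) {
  with_seed(split_seed(seed, "blueprint"), {
    lapply(seq_len(n_species), function(i) {
      p_main <- ((i - 1L) %% length(PRODUCT_METS)) + 1L
      extra_pool <- setdiff(2:length(PRODUCT_METS), p_main)
      n_extra <- sample(0:2, 1)
      extras <- if (n_extra > 0) sort(sample(extra_pool, n_extra)) else integer(0)
      products <- PRODUCT_METS[c(p_main, extras)]
      yields <- stats::setNames(sample(c(0.5, 1, 2), length(products), replace = TRUE),
                                products)
      # species 1 stays a pure producer (the anchor sole producer of 'but').
      # Consumers only consume products some other species' main pathway
      # makes, so assembled communities always admit biomass flux.
      other_mains <- PRODUCT_METS[((setdiff(seq_len(n_species), i) - 1L) %%
                                     length(PRODUCT_METS)) + 1L]
      consumable <- setdiff(other_mains, products)
      consumer_of <- NA_character_
      if (i > 1 && length(consumable) && stats::runif(1) < 0.4) {
        consumer_of <- sample(consumable, 1)
      }
      list(species = species_id(i), products = products, yields = yields,
           consumer_of = consumer_of,
           filler_pool = sprintf("fil%d_sp%02d", 1:4, i))
    })
  })
}

strain_reactions <- function(bp, strain_fillers) {
  prec_of <- stats::setNames(PRECURSOR_METS, PRODUCT_METS)
  rx <- list(
    list(id = "T_glc_D_up",
         stoich = c(`glc_D[luM]` = -1, `glc_D[c]` = 1), lb = 0, ub = BIG)
  )
  bio_st <- c(`glc_D[c]` = -1, `biomass[c]` = 1)
  if (!is.na(bp$consumer_of)) {
    cons <- bp$consumer_of
    bio_st <- c(bio_st, stats::setNames(-0.5, sprintf("%s[c]", cons)))
    rx[[length(rx) + 1L]] <- list(
      id = sprintf("T_%s_up", cons),
      stoich = stats::setNames(c(-1, 1), sprintf(c("%s[luM]", "%s[c]"), cons)),
      lb = 0, ub = BIG)
  }
  rx[[length(rx) + 1L]] <- list(id = "biomass", stoich = bio_st,
                                lb = 0, ub = BIG, is_biomass = TRUE)
  for (p in bp$products) {
    prec <- prec_of[[p]]
    rx[[length(rx) + 1L]] <- list(
      id = sprintf("T_%s_up", prec),
      stoich = stats::setNames(c(-1, 1), sprintf(c("%s[luM]", "%s[c]"), prec)),
      lb = 0, ub = BIG)
    rx[[length(rx) + 1L]] <- list(
      id = sprintf("CONV_%s", p),
      stoich = stats::setNames(c(-1, bp$yields[[p]]),
                               c(sprintf("%s[c]", prec), sprintf("%s[c]", p))),
      lb = 0, ub = BIG)
    rx[[length(rx) + 1L]] <- list(
      id = sprintf("T_%s_sec", p),
      stoich = stats::setNames(c(-1, 1), sprintf(c("%s[c]", "%s[luM]"), p)),
      lb = 0, ub = BIG)
  }
  for (f in strain_fillers) {
    rx[[length(rx) + 1L]] <- list(
      id = sprintf("FIL_%s", f),
      stoich = stats::setNames(c(-1, 1), c("glc_D[c]", sprintf("%s[c]", f))),
      lb = -BIG, ub = BIG)
  }
  # exchange reactions so the strain model is closed on its lumen boundary
  lum <- unique(unlist(lapply(rx, function(r) {
    nm <- names(r$stoich); nm[grepl("\\[luM\\]$", nm)]
  })))
  for (mlu in lum) {
    rx[[length(rx) + 1L]] <- list(
      id = sprintf("EX_%s", sub("\\[luM\\]$", "", mlu)),
      stoich = stats::setNames(-1, mlu), lb = -BIG, ub = BIG)
  }
  rx
}

#' Generate a strain-resolved reconstruction catalog
#'
#' Each species gets a fixed pathway blueprint (growth on the staple,
#' production of 1-3 product metabolites from dedicated dietary precursors,
#' optionally forced consumption of one product through its biomass
#' reaction); strains of a species share that core and differ in small
#' filler reactions, so within-species reaction overlap exceeds
#' between-species overlap.
#'
#' @param n_species Number of species (>= 1).
#' @param strains_per_species Strains per species.
#' @param seed Integer seed.
#' @return List of `reconstruction` objects, one per strain, each with a
#'   `species` attribute and exactly one biomass reaction.
#' @export
generate_strain_catalog <- function(n_species, strains_per_species, seed) {
  stopifnot(n_species >= 1, strains_per_species >= 1)
  bps <- species_blueprint(n_species, seed)
  out <- list()
  for (i in seq_len(n_species)) {
    bp <- bps[[i]]
    fills <- with_seed(split_seed(seed, paste0("fillers_", i)), {
      lapply(seq_len(strains_per_species), function(s) {
        bp$filler_pool[stats::runif(4) < 0.4]
      })
    })
    for (s in seq_len(strains_per_species)) {
      strain <- sprintf("%s_strain%02d", bp$species, s)
      mdl <- make_reconstruction(strain, strain_reactions(bp, fills[[s]]))
      mdl$rxns$species <- bp$species
      attr(mdl, "species") <- bp$species
      out[[strain]] <- mdl
    }
  }
  out
}

#' Generate the miniature host template
#'
#' A compartmentalized host model with diet boundary `[d]`, large-intestine
#' lumen `[luLI]`, blood `[bc]`, and urine/feces boundaries `[u]`/`[fe]`.
#' Every universe metabolite has a diet exchange (closed until a diet is
#' applied), diet-to-lumen and lumen-to-blood transports, and urinary and
#' fecal excretion. Two organ biomass reactions (muscle, liver) feed a
#' `Whole_body_objective_rxn` whose coefficients are the sex-specific
#' proportional organ weights; each sex additionally carries one
#' sex-specific hormone synthesis reaction.
#'
#' @param sex `"male"` or `"female"`.
#' @return A `reconstruction`.
#' @export
generate_host_template <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  rx <- list()
  for (m in universe_metabolites()) {
    rx[[length(rx) + 1L]] <- list(id = sprintf("Diet_EX_%s[d]", m),
                                  stoich = stats::setNames(-1, sprintf("%s[d]", m)),
                                  lb = 0, ub = BIG)
    rx[[length(rx) + 1L]] <- list(id = sprintf("T_D2LI_%s", m),
                                  stoich = stats::setNames(c(-1, 1), sprintf(c("%s[d]", "%s[luLI]"), m)),
                                  lb = 0, ub = BIG)
    rx[[length(rx) + 1L]] <- list(id = sprintf("T_LI2BC_%s", m),
                                  stoich = stats::setNames(c(-1, 1), sprintf(c("%s[luLI]", "%s[bc]"), m)),
                                  lb = 0, ub = BIG)
    rx[[length(rx) + 1L]] <- list(id = sprintf("Excretion_EX_%s[u]", m),
                                  stoich = stats::setNames(-1, sprintf("%s[bc]", m)),
                                  lb = 0, ub = BIG)
    rx[[length(rx) + 1L]] <- list(id = sprintf("Excretion_EX_%s[fe]", m),
                                  stoich = stats::setNames(-1, sprintf("%s[luLI]", m)),
                                  lb = 0, ub = BIG)
  }
  w <- if (sex == "male") c(muscle = 0.85, liver = 0.15) else c(muscle = 0.78, liver = 0.22)
  rx[[length(rx) + 1L]] <- list(id = "Muscle_biomass_rxn",
                                stoich = c(`glc_D[bc]` = -0.7, `biomass_muscle[c]` = 1),
                                lb = 0, ub = BIG)
  rx[[length(rx) + 1L]] <- list(id = "Liver_biomass_rxn",
                                stoich = c(`glc_D[bc]` = -0.3, `biomass_liver[c]` = 1),
                                lb = 0, ub = BIG)
  rx[[length(rx) + 1L]] <- list(
    id = "Whole_body_objective_rxn",
    stoich = c(`biomass_muscle[c]` = -w[["muscle"]], `biomass_liver[c]` = -w[["liver"]]),
    lb = 0, ub = BIG)
  horm <- if (sex == "male") "andr" else "estr"
  syn_id <- if (sex == "male") "Mtestis_andr_syn" else "Fovary_estr_syn"
  rx[[length(rx) + 1L]] <- list(id = syn_id,
                                stoich = stats::setNames(c(-1, 1), c("ser_L[bc]", sprintf("%s[bc]", horm))),
                                lb = 0, ub = BIG)
  rx[[length(rx) + 1L]] <- list(id = sprintf("Excretion_EX_%s[u]", horm),
                                stoich = stats::setNames(-1, sprintf("%s[bc]", horm)),
                                lb = 0, ub = BIG)
  make_reconstruction(sprintf("host_%s", sex), rx)
}

#' Generate an abundance cohort with planted case effects
#'
#' Abundances follow a log-normal-then-closure compositional model:
#' per-species log-mean drawn once, per-sample log-normal draws, case-group
#' means multiplied by `effect_map` entries before closure to 1. Metadata
#' contains diagnosis, sex, age, BMI, six binary lifestyle/medication
#' covariates and total read counts, with group-specific rates loosely
#' matching a PD case-control cohort.
#'
#' @param config A [synthetic_config()].
#' @param species_ids Species to include (non-empty character vector).
#' @return List with `abundance` (species x samples matrix, columns sum to
#'   1) and `metadata` (data frame keyed by `sample`).
#' @export
generate_abundance_cohort <- function(config, species_ids) {
  stopifnot(inherits(config, "synthetic_config"), length(species_ids) >= 1)
  em <- config$effect_map
  if (length(em) && !all(names(em) %in% species_ids)) {
    stopf("effect_map names not in species_ids: %s",
          paste(setdiff(names(em), species_ids), collapse = ", "))
  }
  n_sp <- length(species_ids)
  n <- config$n_pd + config$n_ctrl
  samples <- c(sprintf("PD_%03d", seq_len(config$n_pd)),
               sprintf("CTRL_%03d", seq_len(config$n_ctrl)))
  group <- rep(c("PD", "Control"), c(config$n_pd, config$n_ctrl))

  ab <- with_seed(split_seed(config$seed, "abundance"), {
    mu <- stats::rnorm(n_sp, mean = 0, sd = 1)
    mat <- matrix(0, n_sp, n, dimnames = list(species_ids, samples))
    eff_idx <- match(names(em), species_ids)
    for (j in seq_len(n)) {
      x <- stats::rlnorm(n_sp, meanlog = mu, sdlog = 0.8)
      if (group[j] == "PD" && length(em)) {
        x[eff_idx] <- x[eff_idx] * unname(em)
      }
      mat[, j] <- x / sum(x)
    }
    mat
  })

  md <- with_seed(split_seed(config$seed, "metadata"), {
    is_pd <- group == "PD"
    rate <- function(p_pd, p_ctrl) ifelse(is_pd, p_pd, p_ctrl)
    data.frame(
      sample = samples,
      diagnosis = group,
      sex = ifelse(stats::runif(n) < rate(0.63, 0.30), "male", "female"),
      age = round(stats::rnorm(n, mean = ifelse(is_pd, 68.5, 65.8),
                               sd = ifelse(is_pd, 8.6, 8.8)), 1),
      bmi = round(stats::rnorm(n, mean = ifelse(is_pd, 28.0, 28.5),
                               sd = ifelse(is_pd, 5.5, 6.5)), 1),
      alcohol = as.integer(stats::runif(n) < rate(0.368, 0.511)),
      laxatives = as.integer(stats::runif(n) < rate(0.301, 0.105)),
      pain_meds = as.integer(stats::runif(n) < rate(0.223, 0.164)),
      mood_meds = as.integer(stats::runif(n) < rate(0.379, 0.228)),
      antihistamines = as.integer(stats::runif(n) < rate(0.161, 0.320)),
      sleep_aid = as.integer(stats::runif(n) < rate(0.402, 0.265)),
      read_count = round(stats::rlnorm(n, meanlog = log(1.9e7), sdlog = 0.5)),
      stringsAsFactors = FALSE
    )
  })
  list(abundance = ab, metadata = md)
}

#' Generate a diet specification
#'
#' Produces `n_mets` positive daily intakes (mmol/day/person) over the
#' metabolite universe plus filler diet entries, with exactly
#' `floor(trace_fraction * n_mets)` entries below the 0.1 mmol/day trace
#' threshold. The staple carbon source is the last entry eligible for trace
#' assignment, so any community's biomass demand stays dietarily supported
#' whenever `trace_fraction < 1`.
#'
#' @param n_mets Number of diet entries (>= 1).
#' @param trace_fraction Fraction of entries below 0.1 mmol/day.
#' @param seed Integer seed.
#' @return Data frame with columns `metabolite`, `intake` and `trace`.
#' @export
generate_diet <- function(n_mets, trace_fraction, seed) {
  stopifnot(n_mets >= 1, trace_fraction >= 0, trace_fraction <= 1)
  # product metabolites are microbially sourced, not dietary
  core <- c(STAPLE_MET, PRECURSOR_METS)
  mets <- if (n_mets <= length(core)) core[seq_len(n_mets)] else {
    c(core, sprintf("diet_fill_%03d", seq_len(n_mets - length(core))))
  }
  n_trace <- floor(trace_fraction * n_mets)
  with_seed(split_seed(seed, "diet"), {
    intake <- numeric(n_mets)
    names(intake) <- mets
    if (STAPLE_MET %in% mets) intake[STAPLE_MET] <- 400
    prec <- intersect(PRECURSOR_METS, mets)
    intake[prec] <- round(stats::runif(length(prec), 150, 500), 2)
    fillers <- setdiff(mets, c(STAPLE_MET, prec))
    intake[fillers] <- round(stats::runif(length(fillers), 0.2, 50), 3)
    # trace assignment: fillers first, then precursors, staple last
    trace_order <- c(sample(fillers), sample(prec),
                     intersect(STAPLE_MET, mets))
    trace_ids <- trace_order[seq_len(min(n_trace, length(trace_order)))]
    intake[trace_ids] <- round(stats::runif(length(trace_ids), 0.001, 0.0995), 4)
    data.frame(metabolite = mets, intake = unname(intake[mets]),
               trace = unname(intake[mets]) < 0.1, stringsAsFactors = FALSE)
  })
}

#' Write/read the synthetic inputs as plain-text files
#'
#' Abundances go to TSV (rows = species), metadata to CSV, diets to TSV and
#' reconstructions to the JSON schema of [write_reconstruction_json()].
#'
#' @param abundance Species x samples matrix.
#' @param path File path.
#' @return Readers return the parsed object; writers return `path`.
#' @export
write_abundance_tsv <- function(abundance, path) {
  df <- data.frame(species = rownames(abundance), abundance, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_abundance_tsv
#' @param diet Diet data frame from [generate_diet()].
#' @export
write_diet_tsv <- function(diet, path) {
  utils::write.table(diet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_diet_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
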