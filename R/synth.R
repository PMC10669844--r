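# Seeded synthetic datasets with planted structure: a taxonomy forest with
# sparse activity labels, fingerprints generated from K planted prototypes
# by bit-flip noise, Bernoulli toxicity flags, compound-target maps with one
# planted enriched pathway, and a planted candidate plant.  Every pipeline
# stage can therefore be checked against ground truth.

#' Synthetic-dataset configuration
#'
#' Defaults emulate the study conditions at desk scale: 180 plant species
#' (20 families x 3 genera x 3 species) with per-class activity prevalences
#' matching the curated collection's rates (21.3% anti-oxidant, 19.1%
#' anti-inflammatory, 1.4% anti-aging, 0.6% anti-senescence, ~64% without
#' evidence), 150 phytochemicals from 3 fingerprint prototypes (density
#' 0.12, 5% bit flips), an 18-drug reference panel, ~13% prevalence per
#' toxicity flag (so ~42% of compounds carry some alert), 35% of compounds
#' with reported targets, 15 pathway gene sets with one planted enriched
#' set, and a 6x6 edema design.
#'
#' @param seed Master seed; artifact-specific substreams are derived from
#'   it.
#' @param ... Overrides for any default listed above (see the function
#'   definition for names and shapes).
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_families = 20L, genera_per_family = 3L, species_per_genus = 3L,
    activity_prevalence = c(AOX = 0.213, AINF = 0.191, AAG = 0.014,
                            ASEN = 0.006),
    n_compounds = 150L,
    compounds_per_plant = c(min = 2L, max = 8L),
    K_true = 3L, fp_length = 1024L, prototype_density = 0.12,
    bitflip_prob = 0.05,
    n_reference = 18L, reference_prototypes = 1L,
    descriptor_marginals = list(
      MW = c(meanlog = log(300), sdlog = 0.35),
      ALOGP = c(mean = 2.5, sd = 1.2),
      PSA = c(meanlog = log(70), sdlog = 0.4),
      HBA = c(lambda = 4), HBD = c(lambda = 1.5), ROTB = c(lambda = 4),
      AROM = c(lambda = 1.5), ALERTS = c(lambda = 0.25)
    ),
    tox_flag_prob = c(mutagenic = 0.13, tumorigenic = 0.13, irritant = 0.13,
                      reproductive = 0.13),
    target_universe_size = 200L,
    p_has_targets = 0.35, targets_per_compound_mean = 2,
    known_activity_prob = 0.30,
    n_pathways = 15L, pathway_size = c(min = 10L, max = 40L),
    planted_pathway = list(prototype = 1L, hit_prob = 0.6),
    planted_plant_compounds = 6L,
    edema = list(
      groups = c("carrageenan", "indomethacin_10", "extract_10",
                 "extract_31", "extract_100", "vehicle_oil"),
      n_per_group = 6L,
      times = 1:6,
      baseline_mean = 2.0, baseline_sd = 0.05,
      # mean edema % trajectories per group at the times above
      trajectories = rbind(
        carrageenan     = c(20, 40, 60, 60, 50, 40),
        indomethacin_10 = c(15, 20, 25, 25, 20, 18),
        extract_10      = c(18, 35, 55, 55, 48, 38),
        extract_31      = c(15, 22, 30, 30, 26, 22),
        extract_100     = c(12, 18, 25, 25, 22, 18),
        vehicle_oil     = c(20, 38, 58, 58, 48, 38)
      ),
      sd_mouse = 5, sd_resid = 6
    )
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown synth_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  probs <- c(cfg$activity_prevalence, cfg$bitflip_prob,
             cfg$prototype_density, cfg$tox_flag_prob, cfg$p_has_targets,
             cfg$known_activity_prob, cfg$planted_pathway$hit_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$K_true < 1) stop("K_true must be at least 1")
  sizes <- c(cfg$n_families, cfg$genera_per_family, cfg$species_per_genus,
             cfg$n_compounds, cfg$fp_length, cfg$target_universe_size,
             cfg$n_pathways)
  if (any(sizes <= 0)) stop("all sizes must be positive")
  if (any(cfg$reference_prototypes > cfg$K_true)) {
    stop("reference prototype index exceeds K_true")
  }
  if (cfg$edema$baseline_mean <= 0) {
    stop("edema baseline mean must be positive")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a complete synthetic dataset
#'
#' Produces the plant table, compound table (descriptors, fingerprints,
#' toxicity flags, targets), pathway gene sets, and a `truth` record
#' (prototype label per compound, planted candidate plant, planted enriched
#' pathway).  Each artifact draws from its own substream of the master
#' seed, and identical configurations yield byte-identical outputs.
#'
#' @param config `synth_config` object.
#' @return List with `plants`, `compounds`, `pathways` (`pathway_db`),
#'   `truth` and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  cfg <- validate_synth_config(config)
  streams <- split_seed(cfg$seed, 6L)

  # --- taxonomy forest with sparse activity labels --------------------
  n_plants <- cfg$n_families * cfg$genera_per_family * cfg$species_per_genus
  fam <- sprintf("Family%02d", rep(seq_len(cfg$n_families),
                                   each = cfg$genera_per_family *
                                     cfg$species_per_genus))
  gen <- sprintf("Genus%03d", rep(seq_len(cfg$n_families *
                                            cfg$genera_per_family),
                                  each = cfg$species_per_genus))
  spe <- sprintf("species%03d", seq_len(n_plants))
  plants <- tibble::tibble(
    plant_id = sprintf("P%04d", seq_len(n_plants)),
    family = fam, genus = gen, species = spe
  )
  plants$activities <- with_local_seed(streams[1], {
    lapply(seq_len(n_plants), function(i) {
      hit <- stats::runif(length(ACTIVITY_CLASSES)) <
        cfg$activity_prevalence[ACTIVITY_CLASSES]
      ACTIVITY_CLASSES[hit]
    })
  })
  plants$has_evidence <- lengths(plants$activities) > 0

  # --- compounds ------------------------------------------------------
  n_ref <- cfg$n_reference
  n_all <- cfg$n_compounds + n_ref
  comp <- with_local_seed(streams[2], {
    proto_bits <- matrix(
      as.integer(stats::runif(cfg$K_true * cfg$fp_length) <
                   cfg$prototype_density),
      nrow = cfg$K_true
    )
    proto <- c(sample.int(cfg$K_true, cfg$n_compounds, replace = TRUE),
               rep_len(cfg$reference_prototypes, n_ref))
    fps <- lapply(seq_len(n_all), function(i) {
      bits <- proto_bits[proto[i], ]
      flip <- stats::runif(cfg$fp_length) < cfg$bitflip_prob
      fingerprint(as.integer(xor(bits, flip)))
    })
    dm <- cfg$descriptor_marginals
    tab <- tibble::tibble(
      compound_id = c(sprintf("C%04d", seq_len(cfg$n_compounds)),
                      sprintf("REF%02d", seq_len(n_ref))),
      name = c(sprintf("phytochemical-%04d", seq_len(cfg$n_compounds)),
               sprintf("reference-drug-%02d", seq_len(n_ref))),
      MW = stats::rlnorm(n_all, dm$MW["meanlog"], dm$MW["sdlog"]),
      ALOGP = stats::rnorm(n_all, dm$ALOGP["mean"], dm$ALOGP["sd"]),
      HBA = stats::rpois(n_all, dm$HBA["lambda"]),
      HBD = stats::rpois(n_all, dm$HBD["lambda"]),
      PSA = stats::rlnorm(n_all, dm$PSA["meanlog"], dm$PSA["sdlog"]),
      ROTB = stats::rpois(n_all, dm$ROTB["lambda"]),
      AROM = stats::rpois(n_all, dm$AROM["lambda"]),
      ALERTS = stats::rpois(n_all, dm$ALERTS["lambda"]),
      fingerprint = fps
    )
    for (flag in names(cfg$tox_flag_prob)) {
      tab[[flag]] <- stats::runif(n_all) < cfg$tox_flag_prob[flag]
    }
    tab$is_reference <- c(rep(FALSE, cfg$n_compounds), rep(TRUE, n_ref))
    tab$known_activities <- lapply(seq_len(n_all), function(i) {
      if (tab$is_reference[i]) {
        sample(ACTIVITY_CLASSES, 1 + stats::rbinom(1, 1, 0.5))
      } else if (stats::runif(1) < cfg$known_activity_prob) {
        sample(ACTIVITY_CLASSES, 1 + stats::rbinom(1, 1, 0.3))
      } else character(0)
    })
    attr(tab, "prototype") <- proto
    tab
  })
  proto <- attr(comp, "prototype")
  attr(comp, "prototype") <- NULL

  # --- pathways and compound-target maps ------------------------------
  universe <- sprintf("G%04d", seq_len(cfg$target_universe_size))
  pw <- with_local_seed(streams[3], {
    sizes <- sample(cfg$pathway_size["min"]:cfg$pathway_size["max"],
                    cfg$n_pathways, replace = TRUE)
    sets <- lapply(sizes, function(s) sort(sample(universe, s)))
    names(sets) <- sprintf("PW%03d", seq_len(cfg$n_pathways))
    planted_id <- names(sets)[1]
    planted_genes <- sets[[planted_id]]
    targets <- lapply(seq_len(n_all), function(i) {
      if (!comp$is_reference[i] && stats::runif(1) >= cfg$p_has_targets) {
        return(character(0))
      }
      k <- 1 + stats::rpois(1, cfg$targets_per_compound_mean)
      if (proto[i] == cfg$planted_pathway$prototype) {
        from_planted <- stats::runif(k) < cfg$planted_pathway$hit_prob
        unique(c(sample(planted_genes, sum(from_planted), replace = TRUE),
                 sample(universe, sum(!from_planted), replace = TRUE)))
      } else {
        unique(sample(setdiff(universe, planted_genes), k, replace = TRUE))
      }
    })
    list(sets = sets, planted_id = planted_id, targets = targets)
  })
  comp$targets <- pw$targets
  pathways <- structure(
    pw$sets,
    pathway_names = stats::setNames(
      sprintf("synthetic pathway %d", seq_len(cfg$n_pathways)),
      names(pw$sets)),
    class = "pathway_db"
  )

  # --- plant-compound incidence with a planted candidate plant --------
  nonref_ids <- comp$compound_id[!comp$is_reference]
  inc <- with_local_seed(streams[4], {
    sizes <- sample(cfg$compounds_per_plant["min"]:
                      cfg$compounds_per_plant["max"],
                    n_plants, replace = TRUE)
    memb <- lapply(sizes, function(s) sample(nonref_ids, s))
    # eligible survivors: reference prototype, alert-free, with targets,
    # no known activity, drug-like
    scored <- score_qed(comp)
    eligible <- !comp$is_reference &
      proto == cfg$reference_prototypes[1] &
      rowSums(as.matrix(comp[, TOX_FLAGS])) == 0 &
      lengths(comp$targets) > 0 &
      lengths(comp$known_activities) == 0 &
      scored$qed > 0.5
    planted_idx <- which(!plants$has_evidence)[1]
    planted <- utils::head(comp$compound_id[eligible],
                           cfg$planted_plant_compounds)
    if (!is.na(planted_idx) && length(planted) > 0) {
      memb[[planted_idx]] <- unique(c(memb[[planted_idx]], planted))
    }
    list(memb = memb, planted_idx = planted_idx, planted = planted)
  })
  plants$compound_ids <- inc$memb
  plants$other_annotations <- rep(list(character(0)), n_plants)

  truth <- list(
    prototype = stats::setNames(proto, comp$compound_id),
    planted_plant = if (!is.na(inc$planted_idx)) {
      plants$plant_id[inc$planted_idx]
    } else NA_character_,
    planted_plant_compounds = inc$planted,
    planted_pathway = pw$planted_id
  )
  list(plants = plants, compounds = comp, pathways = pathways,
       truth = truth, config = cfg)
}

#' Generate per-mouse paw-edema records
#'
#' Baseline `M_i ~ N(baseline_mean, baseline_sd)` per mouse; observed edema
#' percentage at each time is the group trajectory mean plus a mouse random
#' effect (`sd_mouse`) plus residual noise (`sd_resid`); `M_f` is derived
#' so that `edema_percent(M_i, M_f)` reproduces the drawn percentage.
#'
#' @param config `synth_config` (only the `edema` block and `seed` are
#'   used).
#' @return Long tibble: `group`, `mouse`, `time`, `M_i`, `M_f`,
#'   `edema_pct`.
#' @export
generate_edema <- function(config = synth_config()) {
  cfg <- validate_synth_config(config)
  ed <- cfg$edema
  stopifnot(all(rownames(ed$trajectories) == ed$groups),
            ncol(ed$trajectories) == length(ed$times))
  seed <- split_seed(cfg$seed, 6L)[5]
  with_local_seed(seed, {
    rows <- list()
    for (g in ed$groups) {
      for (m in seq_len(ed$n_per_group)) {
        M_i <- stats::rnorm(1, ed$baseline_mean, ed$baseline_sd)
        if (M_i <= 0) M_i <- ed$baseline_mean
        mouse_eff <- stats::rnorm(1, 0, ed$sd_mouse)
        pct <- ed$trajectories[g, ] + mouse_eff +
          stats::rnorm(length(ed$times), 0, ed$sd_resid)
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = g, mouse = sprintf("%s_m%d", g, m), time = ed$times,
          M_i = M_i, M_f = M_i * (1 + pct / 100), edema_pct = pct
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
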