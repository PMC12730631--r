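# Seeded generator of survey-like community datasets. The stated world it
# emulates: a 5-estuary x 4-season x 3-station survey with 69 species over
# 5 taxon classes (19 rotifers, 19 copepods, 13 protozoans, 11 other taxa,
# 7 cladocerans), a June abundance peak, one bloom-dominated
# stratum-season where a single photosynthetic-protozoan species drives
# its group to ~95% of the community, and optional pairwise co-occurrence
# coupling with a prescribed phi.

#' Scenario configuration for the synthetic survey generator
#'
#' @param strata character vector of stratum (estuary) labels.
#' @param seasons ordered character vector of season labels.
#' @param stations_per_stratum stations sampled in each stratum per season.
#' @param species_plan named counts of species per taxon class; classes
#'   `rotifer`, `copepod`, `protozoan`, `other`, `cladoceran`.
#' @param abundance_model per-class lognormal parameters: named list of
#'   `list(meanlog =, sdlog =)` entries (log ind m^-3).
#' @param seasonal_multipliers per-season abundance factor (named by season
#'   or positional); the default peaks in the second season, emulating an
#'   early-summer biomass maximum.
#' @param occupancy baseline presence probability per (species, sample).
#' @param bloom `NULL`, or `list(stratum =, season =, species = NULL,
#'   share =)`: within that stratum-season the bloom species (default: the
#'   first photosynthetic protozoan) is rescaled so its functional group
#'   reaches `share` of the included community abundance.
#' @param association `NULL`, or a list of `list(pair = c(id_a, id_b),
#'   rho =)` presence-coupling directives with `|rho| <= 1`. Coupling is a
#'   shared-event construction: the second species copies (rho > 0) or
#'   negates (rho < 0) the first with probability `|rho|`, else draws
#'   independently, giving expected phi = rho at occupancy 0.5 (negative
#'   coupling is exact only there; it attenuates as occupancy leaves 0.5).
#' @param volume filtered volume per sample (m^3); at the default 1 the
#'   stored counts equal abundances.
#' @param seed integer seed making traits and community fully reproducible.
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(strata = c("DHK", "YHK", "SHK", "THK", "LHK"),
                            seasons = c("Mar", "Jun", "Sep", "Dec"),
                            stations_per_stratum = 3,
                            species_plan = c(rotifer = 19, copepod = 19,
                                             protozoan = 13, other = 11,
                                             cladoceran = 7),
                            abundance_model = NULL,
                            seasonal_multipliers = NULL,
                            occupancy = 0.5,
                            bloom = NULL,
                            association = NULL,
                            volume = 1,
                            seed = NULL) {
  stopifnot(length(strata) >= 1, length(seasons) >= 1,
            stations_per_stratum >= 1)
  plan_classes <- c("rotifer", "copepod", "protozoan", "other", "cladoceran")
  if (is.null(names(species_plan)) ||
      !all(names(species_plan) %in% plan_classes))
    stop("species_plan must be named with: ",
         paste(plan_classes, collapse = ", "))
  if (any(species_plan < 0) || sum(species_plan) == 0)
    stop("species_plan must be nonnegative with a positive total")
  if (!(occupancy > 0 && occupancy < 1))
    stop("occupancy must be in (0, 1)")
  if (!(volume > 0)) stop("volume must be > 0")

  if (is.null(abundance_model)) {
    # per-class lognormal locations: protozoans numerically dominant,
    # rotifers abundant, crustaceans sparser; sdlog 1 = typical skew
    abundance_model <- list(
      rotifer = list(meanlog = log(100), sdlog = 1),
      copepod = list(meanlog = log(50), sdlog = 1),
      protozoan = list(meanlog = log(200), sdlog = 1),
      other = list(meanlog = log(20), sdlog = 1),
      cladoceran = list(meanlog = log(30), sdlog = 1))
  }
  if (is.null(seasonal_multipliers)) {
    seasonal_multipliers <- rep(1, length(seasons))
    if (length(seasons) >= 2) seasonal_multipliers[2] <- 3
    if (length(seasons) >= 3) seasonal_multipliers[3] <- 1.5
    if (length(seasons) >= 4) seasonal_multipliers[4] <- 0.6
  }
  if (is.null(names(seasonal_multipliers)))
    names(seasonal_multipliers) <- seasons
  if (!all(seasons %in% names(seasonal_multipliers)))
    stop("seasonal_multipliers must cover every season")
  if (any(seasonal_multipliers <= 0))
    stop("seasonal multipliers must be > 0")

  if (!is.null(bloom)) {
    stopifnot(is.list(bloom),
              all(c("stratum", "season", "share") %in% names(bloom)))
    if (!bloom$stratum %in% strata) stop("bloom stratum not in strata")
    if (!bloom$season %in% seasons) stop("bloom season not in seasons")
    if (!(bloom$share > 0 && bloom$share < 1))
      stop("bloom share must be in (0, 1)")
  }
  if (!is.null(association)) {
    for (asc in association) {
      stopifnot(is.list(asc), all(c("pair", "rho") %in% names(asc)),
                length(asc$pair) == 2)
      if (abs(asc$rho) > 1) stop("association rho must be in [-1, 1]")
    }
  }
  structure(
    list(strata = as.character(strata), seasons = as.character(seasons),
         stations_per_stratum = as.integer(stations_per_stratum),
         species_plan = species_plan, abundance_model = abundance_model,
         seasonal_multipliers = seasonal_multipliers,
         occupancy = as.numeric(occupancy), bloom = bloom,
         association = association,
         volume = as.numeric(volume), seed = seed),
    class = "scenario_config")
}

#' Default survey scenario
#'
#' A ready-to-run [scenario_config()]: 5 estuaries x 4 seasons x 3 stations
#' (15 sampling sites, 60 sampling units), the default 69-species plan, a
#' June abundance peak, and a September bloom in the THK stratum where the
#' photosynthetic-protozoan group is driven to 95% of the community.
#'
#' @param seed integer seed (default 1).
#' @return a `scenario_config`.
#' @export
qinhuangdao_preset <- function(seed = 1) {
  scenario_config(
    bloom = list(stratum = "THK", season = "Sep", species = NULL,
                 share = 0.95),
    seed = seed)
}

size_ranges <- list(S = c(0.30, 0.65), M = c(0.70, 1.50), L = c(1.60, 3.00))

#' Generate a species trait table from a scenario
#'
#' Deterministic under the scenario seed. Feeding habits cycle through the
#' class vocabularies so every size class of copepods/cladocerans and at
#' least 11 functional groups are populated; body sizes are drawn uniformly
#' within the size-class ranges. Two larvae are flagged `nauplius` (these
#' join the small-filter-feeder group); the remaining larvae/other taxa
#' stay outside functional-group analysis.
#'
#' @param cfg a [scenario_config()].
#' @return a [trait_table()] with `sum(cfg$species_plan)` species.
#' @export
generate_traits <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  plan <- cfg$species_plan
  if (sum(plan) == 0) stop("species_plan has zero total")
  with_seed(cfg$seed, {
    rows <- list()
    mk_ids <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

    n <- plan[["rotifer"]] %||% 0
    if (n > 0) {
      habits <- rep(c("filter", "filter", "carnivore", "algivore"),
                    length.out = n)
      rows$rot <- data.frame(species_id = mk_ids("rot", n),
                             taxon_class = "rotifer", body_size_mm = NA_real_,
                             feeding_habit = habits, notes = "")
    }
    cope_sizes <- function(n, habit_cycle) {
      cls <- rep(c("S", "M", "L"), length.out = n)
      size <- vapply(cls, function(s)
        stats::runif(1, size_ranges[[s]][1], size_ranges[[s]][2]), 0)
      list(size = size, habit = rep(habit_cycle, length.out = n))
    }
    n <- plan[["copepod"]] %||% 0
    if (n > 0) {
      cs <- cope_sizes(n, c("filter", "filter", "carnivore"))
      rows$cop <- data.frame(species_id = mk_ids("cop", n),
                             taxon_class = "copepod_cladoceran",
                             body_size_mm = cs$size,
                             feeding_habit = cs$habit, notes = "")
    }
    n <- plan[["cladoceran"]] %||% 0
    if (n > 0) {
      cs <- cope_sizes(n, c("filter", "filter", "filter", "carnivore"))
      rows$cla <- data.frame(species_id = mk_ids("cla", n),
                             taxon_class = "copepod_cladoceran",
                             body_size_mm = cs$size,
                             feeding_habit = cs$habit, notes = "")
    }
    n <- plan[["protozoan"]] %||% 0
    if (n > 0) {
      habits <- rep(c("photosynthetic", "bacterivore", "algivore",
                      "fungivore", "raptor", "omnivore"), length.out = n)
      notes <- character(n)
      notes[habits == "photosynthetic"][1] <-
        "bloom-forming dinoflagellate (synthetic)"
      rows$pro <- data.frame(species_id = mk_ids("pro", n),
                             taxon_class = "protozoan",
                             body_size_mm = NA_real_,
                             feeding_habit = habits, notes = notes)
    }
    n <- plan[["other"]] %||% 0
    if (n > 0) {
      # about half larvae (first two are copepod nauplii), rest other taxa
      n_larva <- ceiling(n / 2)
      cls <- c(rep("larva", n_larva), rep("other", n - n_larva))
      notes <- character(n)
      notes[seq_len(min(2, n_larva))] <- "nauplius"
      rows$oth <- data.frame(species_id = mk_ids("oth", n),
                             taxon_class = cls, body_size_mm = NA_real_,
                             feeding_habit = "omnivore", notes = notes)
    }
    trait_table(do.call(rbind, rows))
  })
}

# per-class wet weight per individual (mg), for the optional biomass column
UNIT_MASS <- c(rotifer = 0.002, copepod_cladoceran = 0.05,
               protozoan = 0.005, larva = 0.01, other = 0.01)

#' Generate a synthetic community dataset
#'
#' Draws presence per (species, sample) from the baseline occupancy, applies
#' any configured presence coupling, then draws abundances from the
#' per-class lognormal scaled by the season multiplier. Counts are stored as
#' integers (`n = max(1, round(N * v))` for present cells); with the default
#' volume of 1 m^3 the counts equal the abundances up to rounding. If a
#' bloom is configured, the bloom species is rescaled within its
#' stratum-season so its functional group reaches the target share of the
#' included community abundance.
#'
#' @param cfg a [scenario_config()].
#' @param traits a trait table, default [generate_traits()] of the same
#'   config.
#' @return a [community_dataset()] with a biomass column.
#' @export
generate_community <- function(cfg, traits = generate_traits(cfg)) {
  stopifnot(inherits(cfg, "scenario_config"))
  seed2 <- if (is.null(cfg$seed)) NULL else cfg$seed + 1L
  species <- traits$species_id
  n_sp <- length(species)
  grid <- expand.grid(station = seq_len(cfg$stations_per_stratum),
                      season = cfg$seasons, stratum = cfg$strata,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_S%d", grid$stratum, grid$season,
                            grid$station)
  n_samp <- nrow(grid)

  # taxon class -> plan class used by the abundance model
  plan_class <- ifelse(traits$taxon_class == "copepod_cladoceran",
                       ifelse(grepl("^cla", species), "cladoceran", "copepod"),
                       ifelse(traits$taxon_class %in% c("larva"), "other",
                              traits$taxon_class))
  plan_class[!plan_class %in% names(cfg$abundance_model)] <- "other"

  with_seed(seed2, {
    pres <- matrix(stats::rbinom(n_sp * n_samp, 1, cfg$occupancy),
                   nrow = n_sp, dimnames = list(species, grid$sample_id))
    for (asc in cfg$association %||% list()) {
      ia <- match(asc$pair[1], species)
      ib <- match(asc$pair[2], species)
      if (is.na(ia) || is.na(ib))
        stop("association pair references unknown species")
      copy <- stats::runif(n_samp) < abs(asc$rho)
      base <- stats::rbinom(n_samp, 1, cfg$occupancy)
      target <- if (asc$rho >= 0) pres[ia, ] else 1 - pres[ia, ]
      pres[ib, ] <- ifelse(copy, target, base)
    }
    mult <- cfg$seasonal_multipliers[grid$season]
    meanlog <- vapply(plan_class,
                      function(cl) cfg$abundance_model[[cl]]$meanlog, 0)
    sdlog <- vapply(plan_class,
                    function(cl) cfg$abundance_model[[cl]]$sdlog, 0)
    draw <- matrix(stats::rlnorm(n_sp * n_samp,
                                 meanlog = rep(meanlog, times = n_samp),
                                 sdlog = rep(sdlog, times = n_samp)),
                   nrow = n_sp)
    abund <- pres * draw * matrix(mult, nrow = n_sp, ncol = n_samp,
                                  byrow = TRUE)

    if (!is.null(cfg$bloom)) {
      assignment <- assign_functional_group(traits)
      bloom_sp <- cfg$bloom$species
      if (is.null(bloom_sp)) {
        pp <- species[assignment[species] == "PP"]
        if (length(pp) == 0) stop("bloom: no photosynthetic protozoan to use")
        bloom_sp <- pp[1]
      }
      bi <- match(bloom_sp, species)
      if (is.na(bi)) stop("bloom species not in trait table")
      unit <- grid$stratum == cfg$bloom$stratum &
              grid$season == cfg$bloom$season
      grp <- assignment[bloom_sp]
      included <- species[assignment[species] != "EXCLUDED"]
      grp_members <- setdiff(species[assignment[species] == grp], bloom_sp)
      I0 <- sum(abund[included, unit]) - sum(abund[bi, unit])
      g0 <- sum(abund[grp_members, unit, drop = FALSE])
      target <- cfg$bloom$share
      x <- (target * I0 - g0) / (1 - target)
      if (x <= 0)
        stop("bloom share already exceeded by the rest of the group")
      # spread the bloom mass over the unit's stations in proportion to
      # their community size, forcing presence everywhere in the unit
      w <- colSums(abund[included, unit, drop = FALSE])
      w <- if (sum(w) == 0) rep(1 / sum(unit), sum(unit)) else w / sum(w)
      abund[bi, unit] <- x * w
    }

    counts <- round(abund * cfg$volume)
    counts[abund > 0 & counts == 0] <- 1

    keep <- which(counts > 0, arr.ind = TRUE)
    mass <- UNIT_MASS[traits$taxon_class[keep[, 1]]]
    records <- data.frame(
      sample_id = grid$sample_id[keep[, 2]],
      stratum = grid$stratum[keep[, 2]],
      season = grid$season[keep[, 2]],
      species_id = species[keep[, 1]],
      n = as.numeric(counts[keep]),
      v = cfg$volume,
      biomass = counts[keep] / cfg$volume * mass,
      stringsAsFactors = FALSE)
    community_dataset(records)
  })
}

#' Write / read a scenario configuration as JSON
#'
#' @param cfg a [scenario_config()].
#' @param path file path.
#' @return `read_scenario_config()` returns a validated `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  out <- unclass(cfg)
  # jsonlite drops names on atomic vectors; keep them as objects
  out$species_plan <- as.list(out$species_plan)
  out$seasonal_multipliers <- as.list(out$seasonal_multipliers)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$association) && is.data.frame(raw$association))
    raw$association <- lapply(seq_len(nrow(raw$association)), function(i)
      list(pair = unlist(raw$association$pair[i]),
           rho = raw$association$rho[i]))
  am <- raw$abundance_model
  if (!is.null(am)) am <- lapply(am, function(m) list(meanlog = m$meanlog,
                                                      sdlog = m$sdlog))
  scenario_config(
    strata = raw$strata, seasons = raw$seasons,
    stations_per_stratum = raw$stations_per_stratum,
    species_plan = unlist(raw$species_plan),
    abundance_model = am,
    seasonal_multipliers = unlist(raw$seasonal_multipliers),
    occupancy = raw$occupancy,
    bloom = raw$bloom, association = raw$association,
    volume = raw$volume, seed = raw$seed)
}
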