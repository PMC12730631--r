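# End-to-end orchestration: ingest or simulate, assign functional groups,
# diversity + dominance, Bray-Curtis, niche breadth/overlap, overall and
# pairwise association, composition percentages. Every stage writes its own
# table; the report layer only collects, it never recomputes.

#' Run configuration for the analysis pipeline
#'
#' Exactly one of (`community` + `traits`) or `scenario` must be given.
#'
#' @param community path to a community table (see [read_community_table()]).
#' @param traits path to a trait table (see [read_trait_table()]).
#' @param scenario a [scenario_config()] or path to one written by
#'   [write_scenario_config()].
#' @param out output directory (created if missing).
#' @param level entity level for niche/association stages: `"group"`
#'   (default) or `"species"`.
#' @param measure `"abundance"` (default) or `"biomass"` for group
#'   composition.
#' @param dominance_threshold dominance cutoff on Y (default 0.02).
#' @param overlap_threshold high-overlap cutoff (default 0.7).
#' @param strong_r strong Pearson-pair cutoff (default 0.7).
#' @param alpha significance level for association tests (default 0.05).
#' @param seed integer seed recorded in the log and passed to a scenario
#'   without an explicit seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(community = NULL, traits = NULL, scenario = NULL,
                       out = NULL, level = c("group", "species"),
                       measure = c("abundance", "biomass"),
                       dominance_threshold = 0.02, overlap_threshold = 0.7,
                       strong_r = 0.7, alpha = 0.05, seed = NULL) {
  level <- match.arg(level)
  measure <- match.arg(measure)
  has_files <- !is.null(community) || !is.null(traits)
  if (has_files && is.null(scenario) &&
      (is.null(community) || is.null(traits)))
    stop("file input needs both community and traits paths")
  if (has_files == !is.null(scenario))
    stop("exactly one of (community + traits) or scenario must be given")
  for (nm in c("dominance_threshold", "overlap_threshold", "strong_r")) {
    val <- get(nm)
    if (!(val >= 0 && val <= 1))
      stop(nm, " must lie in [0, 1], got ", val)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(
    list(community = community, traits = traits, scenario = scenario,
         out = out, level = level, measure = measure,
         dominance_threshold = dominance_threshold,
         overlap_threshold = overlap_threshold, strong_r = strong_r,
         alpha = alpha, seed = seed),
    class = "run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full community-analysis pipeline
#'
#' Ordered execution: ingest or simulate, functional-group assignment and
#' aggregation, diversity and dominance, group composition, Bray-Curtis
#' similarity between stratum-season units, niche breadth/overlap with
#' high-overlap pairs, overall variance-ratio association, pairwise phi
#' classification with stability verdict and network export, Pearson pair
#' summary, and species-composition percentages. If `cfg$out` is set, each
#' stage's table is written there along with a `summary.json` and the
#' resolved configuration snapshot.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a named list with every stage result.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))

  if (!is.null(cfg$scenario)) {
    scen <- if (inherits(cfg$scenario, "scenario_config")) cfg$scenario
            else read_scenario_config(cfg$scenario)
    if (is.null(scen$seed)) scen$seed <- cfg$seed
    traits <- pipeline_stage("simulate", generate_traits(scen))
    ds <- pipeline_stage("simulate", generate_community(scen, traits))
  } else {
    ds <- pipeline_stage("ingest", read_community_table(cfg$community))
    traits <- pipeline_stage("ingest", read_trait_table(cfg$traits))
  }

  mat <- pipeline_stage("abundance", abundance_matrix(ds))
  gm <- pipeline_stage("assign-groups", aggregate_by_group(mat, traits))
  composition <- pipeline_stage("assign-groups",
    relative_composition(gm, by = "stratum_season", samples = ds$samples))
  diversity <- pipeline_stage("diversity", diversity_table(ds))
  dom <- pipeline_stage("dominance",
    dominance(ds, threshold = cfg$dominance_threshold))

  # pooled stratum-season profiles feed similarity, niche and association
  idx <- match(colnames(gm$values), ds$samples$sample_id)
  unit <- paste(ds$samples$stratum[idx], ds$samples$season[idx], sep = ":")
  units <- unique(unit)
  pool <- function(m) {
    out <- vapply(units, function(u) rowSums(m[, unit == u, drop = FALSE]),
                  numeric(nrow(m)))
    matrix(out, nrow = nrow(m), dimnames = list(rownames(m), units))
  }
  gmat_pooled <- pool(gm$values)
  ent_pooled <- if (cfg$level == "group") gmat_pooled else pool(mat)

  bc <- pipeline_stage("bray-curtis", bray_curtis_matrix(gmat_pooled))
  niche <- pipeline_stage("niche",
    niche_analysis(ent_pooled, threshold = cfg$overlap_threshold))

  # association statistics run on per-sample presence; at species level the
  # entity set defaults to the dominant species (Y above the threshold)
  ent_samples <- if (cfg$level == "group") gm$values else {
    dom_sp <- dom$species_id[dom$is_dominant]
    if (length(dom_sp) < 2) mat else mat[dom_sp, , drop = FALSE]
  }
  pm <- pipeline_stage("association", presence_absence(ent_samples))
  overall <- pipeline_stage("association",
    overall_variance_ratio(pm, alpha = cfg$alpha))
  pairs <- pipeline_stage("association", classify_pairs(pm, alpha = cfg$alpha))
  stability <- pipeline_stage("association", stability_summary(pairs))
  pearson <- pipeline_stage("association",
    pearson_pair_summary(ent_samples, strong_r = cfg$strong_r))

  class_counts <- table(traits$taxon_class)
  comp_pct <- pipeline_stage("composition",
    composition_percentages(stats::setNames(as.numeric(class_counts),
                                            names(class_counts))))

  result <- list(
    dataset = ds, traits = traits,
    assignment = data.frame(species_id = names(gm$assignment),
                            group = unname(gm$assignment),
                            stringsAsFactors = FALSE),
    group_matrix = gm, composition = composition,
    diversity = diversity, dominance = dom, bray_curtis = bc,
    niche = niche, overall_association = overall,
    pair_associations = pairs, stability = stability,
    pearson = pearson, composition_percentages = comp_pct,
    config = cfg)

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, name) write_results(x, file.path(cfg$out, name))
    w(result$assignment, "assignment.tsv")
    w(composition, "composition.tsv")
    w(diversity, "diversity.tsv")
    w(dom, "dominance.tsv")
    w(bc, "bray_curtis.tsv")
    w(data.frame(entity = names(niche$breadth), breadth = niche$breadth,
                 row.names = NULL), "niche_breadth.tsv")
    w(niche$overlap, "niche_overlap.tsv")
    w(niche$high_pairs, "high_overlap_pairs.tsv")
    w(as.data.frame(pairs), "pair_associations.tsv")
    export_network(pairs, file.path(cfg$out, "network_edges.tsv"))
    w(pearson$pairs, "pearson_pairs.tsv")
    w(comp_pct, "composition_percentages.tsv")
    summary <- list(
      n_species = length(ds$species), n_samples = nrow(ds$samples),
      n_groups = nrow(gm$values),
      overall_association = overall[c("sigma_T2", "S_T2", "VR", "W", "N",
                                      "verdict", "significant", "alpha")],
      stability = stability[c("n_positive", "n_negative", "n_sig_positive",
                              "n_sig_negative", "verdict")],
      n_dominant = sum(dom$is_dominant),
      n_high_overlap_pairs = nrow(niche$high_pairs),
      n_strong_pearson_pairs = pearson$n_strong,
      thresholds = cfg[c("dominance_threshold", "overlap_threshold",
                         "strong_r", "alpha")],
      seed = cfg$seed %||% NA)
    jsonlite::write_json(summary, file.path(cfg$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    snap <- cfg
    snap$scenario <- if (is.null(cfg$scenario)) NULL
                     else if (is.character(cfg$scenario)) cfg$scenario
                     else unclass(cfg$scenario)
    jsonlite::write_json(unclass(snap), file.path(cfg$out, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(result)
}
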