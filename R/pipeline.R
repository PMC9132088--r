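# ---- config-driven pipeline orchestration ----

.default_config <- function() {
  list(
    peptide_table = NULL,      # path; NULL -> simulate
    string_links = NULL,       # path; NULL -> simulate (with the data) or none
    glyco_table = NULL,        # optional path
    region_table = NULL,       # optional path
    bait_id = NULL,            # required for external data; default for sims
    out_dir = "aapl_results",
    seed = 1,
    scoring_mode = "spc_epo",
    design = list(
      treatments = paste0("M", 1:6),
      controls = paste0("C", 1:3),
      selected = "M5",
      replicates = 3
    ),
    thresholds = list(
      l1 = 1, l2_fc = 1.5, string_high = 0.7, string_low = 0.4,
      score_floor = 0.4
    ),
    sim = list()               # overrides for sim_params()
  )
}

#' Validate (and normalize) a pipeline configuration
#'
#' Accepts a YAML file path or a named list, fills every default, and
#' collects all problems instead of failing on the first: unknown keys,
#' non-positive thresholds, a selected condition outside the treatments,
#' and referenced input files that do not exist.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return List with elements `config` (fully populated) and `errors`
#'   (character vector; empty when valid).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      return(list(config = NULL,
                  errors = sprintf("config file not found: %s", config)))
    }
    config <- yaml::read_yaml(config)
  }
  errors <- character(0)
  base <- .default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown config field(s): %s",
                                paste(unknown, collapse = ", ")))
    config <- config[setdiff(names(config), unknown)]
  }
  cfg <- modifyList(base, config)
  for (sub in c("design", "thresholds")) {
    cfg[[sub]] <- modifyList(base[[sub]], as.list(cfg[[sub]]))
  }
  th <- cfg$thresholds
  for (nm in names(th)) {
    if (!is.numeric(th[[nm]]) || length(th[[nm]]) != 1L || th[[nm]] <= 0) {
      errors <- c(errors, sprintf("threshold '%s' must be a positive number",
                                  nm))
    }
  }
  d <- cfg$design
  if (is.null(d$selected) || !d$selected %in% d$treatments) {
    errors <- c(errors, "design$selected must be one of design$treatments")
  }
  if (!is.numeric(d$replicates) || d$replicates < 2) {
    errors <- c(errors, "design$replicates must be >= 2")
  }
  for (f in c("peptide_table", "string_links", "glyco_table",
              "region_table")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      errors <- c(errors, sprintf("%s file not found: %s", f, cfg[[f]]))
    }
  }
  if (!is.null(cfg$peptide_table) && is.null(cfg$bait_id)) {
    errors <- c(errors, "bait_id is required when peptide_table is supplied")
  }
  if (!cfg$scoring_mode %in% c("spc_epo", "spc", "tops_epo")) {
    errors <- c(errors, "scoring_mode must be spc_epo, spc, or tops_epo")
  }
  list(config = cfg, errors = errors)
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] rows in: %s, rows out: %s", stage, n_in, n_out))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_aaplr(sprintf("pipeline stage '%s' failed: %s", stage,
                        conditionMessage(e)), "aaplr_pipeline_error")
  })
}

#' Run the full AAPL analysis pipeline
#'
#' Executes the stages in order - simulate (or load), quantify, score,
#' classify, network, glyco - writing each stage's tables to
#' `config$out_dir` and logging one row-count summary line per stage.
#' End-to-end deterministic given `config$seed`.
#'
#' @param config Path to a YAML file or a named list (see
#'   [validate_config()]); invalid configs abort with the aggregated
#'   error report.
#' @return Data frame manifest of written files (`name`, `path`,
#'   `n_rows`), invisibly; the classified interactor table is attached as
#'   attribute `"results"`.
#' @export
run_aapl_pipeline <- function(config = list()) {
  v <- validate_config(config)
  if (length(v$errors)) {
    abort_aaplr(paste(c("invalid configuration:", v$errors),
                      collapse = "\n  - "), "aaplr_config_error")
  }
  cfg <- v$config
  design <- experiment_design(treatments = cfg$design$treatments,
                              controls = cfg$design$controls,
                              selected = cfg$design$selected,
                              replicates = cfg$design$replicates)
  tables <- list()

  if (is.null(cfg$peptide_table)) {
    sim <- run_stage("simulate", {
      params <- do.call(sim_params, modifyList(list(seed = cfg$seed),
                                               cfg$sim))
      simulate_aapl_experiment(params, design, bait_id = cfg$bait_id)
    })
    measurements <- sim$measurements
    edges <- sim$edges
    bait_id <- sim$bait_id
    tables$measurements <- measurements
    tables$ground_truth <- as.data.frame(sim$truth)
    stage_log("simulate", nrow(sim$proteome), nrow(measurements))
  } else {
    measurements <- run_stage("load", read_peptide_table(cfg$peptide_table))
    bait_id <- cfg$bait_id
    edges <- NULL
    stage_log("load", NA, nrow(measurements))
  }
  if (!is.null(cfg$string_links)) {
    edges <- run_stage("load-edges",
                       read_string_links(cfg$string_links,
                                         score_floor = cfg$thresholds$score_floor))
  }
  if (is.null(edges)) {
    edges <- data.frame(protein_a = character(0), protein_b = character(0),
                        combined_score = numeric(0))
  }
  tables$string_links <- edges

  profiles <- run_stage("quantify", oxidation_profiles(measurements, design))
  tables$site_degrees <- site_degrees(measurements)
  tables$protein_profiles <- profiles
  cm <- condition_matrix(profiles)
  tables$epo_matrix <- data.frame(condition = rownames(cm$matrix),
                                  cm$matrix, check.names = FALSE)
  stage_log("quantify", nrow(measurements), nrow(profiles))

  scores <- run_stage("score",
                      aapl_scores(profiles, design, mode = cfg$scoring_mode))
  tables$aapl_scores <- scores
  stage_log("score", nrow(profiles), nrow(scores))

  results <- run_stage("classify", classify_interactors(
    profiles, scores, edges, bait_id, design,
    l1_threshold = cfg$thresholds$l1,
    l2_fc_threshold = cfg$thresholds$l2_fc,
    string_high = cfg$thresholds$string_high,
    string_low = cfg$thresholds$string_low))
  tables$interactors <- results
  tables$score_bins <- mean_sites_by_score_bin(results)
  stage_log("classify", nrow(scores), nrow(results))

  graph <- run_stage("network", build_network(results, edges, bait_id))
  stage_log("network", nrow(results), igraph::vcount(graph))

  if (!is.null(cfg$region_table)) {
    regions <- run_stage("regions", read_region_table(cfg$region_table))
    tables$region_map <- map_sites_to_regions(tables$site_degrees, regions)
  }
  if (!is.null(cfg$glyco_table)) {
    glyco <- run_stage("glyco", read_glyco_table(cfg$glyco_table))
    interactor_ids <- results$protein_id[results$level %in% c("L1", "L2")]
    glyco_ids <- intersect(interactor_ids, unique(glyco$protein_id))
    sums <- lapply(glyco_ids, function(p) {
      s <- glyco_summary(glyco, protein_id = p)
      s$protein_id <- p
      s
    })
    if (length(sums)) tables$glyco_summary <- do.call(rbind, sums)
    stage_log("glyco", nrow(glyco), length(glyco_ids))
  }

  manifest <- write_results(tables, cfg$out_dir)
  gml <- file.path(cfg$out_dir, "network.graphml")
  write_network_graphml(graph, gml)
  sif <- write_network_sif(graph, file.path(cfg$out_dir, "network"))
  manifest <- rbind(manifest, data.frame(
    name = c("network.graphml", "network.sif", "network.nodes",
             "network.edges"),
    path = c(gml, sif),
    n_rows = c(igraph::vcount(graph), igraph::ecount(graph),
               igraph::vcount(graph), igraph::ecount(graph)),
    stringsAsFactors = FALSE))
  attr(manifest, "results") <- results
  invisible(manifest)
}
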