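#' Pipeline run configuration
#'
#' Bundles either a simulation config or paths to real inputs with the
#' analysis thresholds and output location. Exactly one of `simulation` or
#' the real-input paths (`reference_fasta` + `annotation` + tree inputs)
#' must be active.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for every stochastic stage.
#' @param simulation optional [simulation_config()] (simulation mode).
#' @param reference_fasta,annotation paths to the reference FASTA and gene
#'   TSV (real-input mode).
#' @param tree path to a rooted Newick file.
#' @param alignment optional aligned FASTA of tip sequences (mutations are
#'   then mapped by parsimony); otherwise `events` must point to a
#'   pre-annotated branch-mutation TSV.
#' @param events optional branch-mutation TSV.
#' @param scores optional pathogenicity score TSV ([load_score_table()]).
#' @param score_policy `"strict"` or `"skip"` for unmatched scores.
#' @param score_threshold,rho_threshold,nu analysis thresholds (defaults
#'   0.7, 4, 2.5e-3).
#' @param clock a [clock_config()], or `NULL` in simulation mode to derive
#'   the synthetic clocks from the generator rates and fitted asymptote.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed, simulation = NULL,
                       reference_fasta = NULL, annotation = NULL,
                       tree = NULL, alignment = NULL, events = NULL,
                       scores = NULL, score_policy = "skip",
                       score_threshold = 0.7, rho_threshold = 4,
                       nu = 2.5e-3, clock = NULL) {
  sim_mode <- !is.null(simulation)
  real_mode <- !is.null(reference_fasta)
  if (sim_mode == real_mode)
    stop("exactly one of simulation config or real inputs must be given")
  if (real_mode && is.null(annotation))
    stop("real-input mode needs a gene annotation table")
  if (real_mode && is.null(tree))
    stop("real-input mode needs a rooted Newick tree")
  if (real_mode && is.null(alignment) && is.null(events))
    stop("real-input mode needs either an alignment or a branch-event TSV")
  stopifnot(score_threshold > 0, rho_threshold > 0, nu > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation,
                 reference_fasta = reference_fasta, annotation = annotation,
                 tree = tree, alignment = alignment, events = events,
                 scores = scores, score_policy = score_policy,
                 score_threshold = score_threshold,
                 rho_threshold = rho_threshold, nu = nu, clock = clock),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulation`
#' mapping is passed to [simulation_config()] and a `clock` mapping to
#' [clock_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation))
    y$simulation <- do.call(simulation_config, y$simulation)
  if (!is.null(y$clock)) y$clock <- do.call(clock_config, y$clock)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — enumerate (real mode), annotate/map,
#' rho, selection, Gompertz, clock validation — writing every intermediate
#' table as TSV (with a header line recording package version, config
#' checksum and seed), fitted models as JSON, and a manifest of produced
#' artifacts. Reruns with the same config and seed reproduce identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message("purisel: ", msg)
    log_lines <<- c(log_lines, msg)
  }
  artifacts <- character(0)
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config_as_list(config), cfg_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  # checksum over the scientific configuration only, so identical analyses
  # in different output directories stamp identical headers
  norm <- config_as_list(config)
  norm$out_dir <- NULL
  norm_json <- tempfile(fileext = ".json")
  jsonlite::write_json(norm, norm_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  config_hash <- unname(tools::md5sum(norm_json))
  unlink(norm_json)
  artifacts["config"] <- cfg_json
  stamp <- function(path) {
    cat("# purisel ", as.character(utils::packageVersion("purisel")),
        "; config_md5=", config_hash, "; seed=", config$seed, "\n",
        sep = "", file = path)
  }
  write_tsv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    stamp(path)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    artifacts[[sub("\\.tsv$", "", name)]] <<- path
    path
  }

  sim_mode <- !is.null(config$simulation)
  genome <- NULL
  all_possible_scores <- NULL
  if (sim_mode) {
    note("stage simulate: ", config$simulation$n_tips, "-tip ",
         config$simulation$tree_model, " tree, sigma = ",
         config$simulation$sigma)
    ds <- simulate_dataset(config$simulation)
    tree <- ds$tree
    ape::write.tree(tree$phy, file.path(config$out_dir, "tree.nwk"))
    artifacts["tree"] <- file.path(config$out_dir, "tree.nwk")
    all_possible_scores <- ds$truth$attempts$score
    note("stage simulate: ", nrow(tree$events), " events retained from ",
         ds$truth$n_attempts, " nonsynonymous attempts + ",
         ds$truth$n_synonymous, " synonymous events")
  } else {
    genome <- load_reference(config$reference_fasta, config$annotation)
    note("stage enumerate: reference '", genome$name, "', ",
         genome$length, " bp, ", nrow(genome$genes), " genes")
    variants <- enumerate_all_substitutions(genome)
    if (!is.null(config$scores))
      variants <- attach_scores(variants, load_score_table(config$scores),
                                policy = config$score_policy)
    write_tsv(variants, "variants.tsv")
    note("stage enumerate: ", length(unique(paste(variants$position,
                                                  variants$alt))),
         " substitutions classified")
    resolved <- resolve_variant_class(variants)
    all_possible_scores <- resolved$score[
      resolved$resolved_class == "nonsynonymous" & !is.na(resolved$score)]
    if (!is.null(config$alignment)) {
      phy <- ape::read.tree(config$tree)
      tree <- map_mutations_parsimony(phy, load_alignment(config$alignment),
                                      genome = genome)
    } else {
      tree <- load_annotated_tree(config$tree, config$events,
                                  genome = genome)
    }
    if (!is.null(config$scores)) {
      score_map <- setNames(resolved$score,
                            paste(resolved$position, resolved$alt,
                                  sep = ":"))
      need <- tree$events$class == "nonsynonymous" &
        is.na(tree$events$score)
      key <- paste(tree$events$position, tree$events$to, sep = ":")
      tree$events$score[need] <- unname(score_map[key[need]])
    }
    note("stage map: ", nrow(tree$events), " events on branches")
  }
  write_tsv(tree$events[, c("node", "position", "from", "to", "class",
                            "score", "occurrence_id")], "events.tsv")

  rho <- rho_table(tree)
  write_tsv(rho, "node_rhos.tsv")
  obs <- observations(tree, rho)
  write_tsv(obs, "observations.tsv")
  note("stage rho: ", nrow(rho), " nodes, ", nrow(obs), " observations")

  scored <- obs$score[obs$class == "nonsynonymous" & !is.na(obs$score)]
  selection <- list(
    rho_by_score = mean_rho_by_score_class(obs, config$score_threshold),
    score_by_rho = mean_score_by_rho_class(obs, config$rho_threshold))
  sel_fit <- NULL
  if (length(scored) && length(all_possible_scores)) {
    hists <- score_histograms(scored, all_possible_scores)
    dist_df <- data.frame(bin_low = seq(0, 0.9, 0.1),
                          bin_high = seq(0.1, 1, 0.1),
                          p_observed = hists$observed$probabilities,
                          p_possible = hists$possible$probabilities)
    dist_df$ratio <- ifelse(dist_df$p_possible > 0,
                            dist_df$p_observed / dist_df$p_possible, NA)
    write_tsv(dist_df, "score_distributions.tsv")
    sel_fit <- tryCatch(fit_selection_constant(hists$observed,
                                               hists$possible),
                        error = function(e) {
                          note("stage selection: exponential fit failed: ",
                               conditionMessage(e))
                          NULL
                        })
    if (!is.null(sel_fit))
      note("stage selection: R = ", signif(sel_fit$R, 4), " (se ",
           signif(sel_fit$stderr_R, 3), ")")
  }
  sel_json <- file.path(config$out_dir, "selection.json")
  jsonlite::write_json(list(
    rho_by_score = unclass(selection$rho_by_score),
    score_by_rho = unclass(selection$score_by_rho),
    selection_fit = if (!is.null(sel_fit))
      unclass(sel_fit)[c("A", "R", "stderr_A", "stderr_R", "n_bins_used")]),
    sel_json, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  artifacts["selection"] <- sel_json

  pts <- node_points(rho)
  agg <- agglomerate_nodes(pts, nu = config$nu)
  write_tsv(agg, "agglomerated_points.tsv")
  gfit <- fit_gompertz(agg)
  note("stage gompertz: ", nrow(agg), " agglomerated points, asymptote = ",
       signif(gfit$a, 4), ", intercept = ", signif(gfit$y_intercept, 4))
  gom_json <- file.path(config$out_dir, "gompertz.json")
  jsonlite::write_json(unclass(gfit), gom_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  artifacts["gompertz"] <- gom_json

  clock <- config$clock
  if (is.null(clock) && sim_mode) {
    # synthetic clocks: the synonymous clock is the generator rate; the
    # long-run protein-coding rate follows from it and the fitted
    # equilibrium synonymous fraction
    clock <- clock_config(
      protein_coding_rate = config$simulation$syn_rate_per_year / gfit$a,
      synonymous_rate = config$simulation$syn_rate_per_year,
      coding_sites = 1, coding_codons = 1, species = "synthetic")
  }
  val <- NULL
  if (!is.null(clock)) {
    val <- tryCatch(validate_correction(rho, gfit, clock),
                    error = function(e) {
                      note("stage validate: skipped: ",
                           conditionMessage(e))
                      NULL
                    })
    if (!is.null(val)) {
      note("stage validate: r = ", signif(val$pearson_r, 4),
           ", through-origin slope = ", signif(val$slope, 4), " over ",
           val$n_nodes, " nodes")
      val_json <- file.path(config$out_dir, "validation.json")
      jsonlite::write_json(val[c("pearson_r", "slope", "n_nodes")],
                           val_json, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      artifacts["validation"] <- val_json
      write_tsv(val$ages, "node_ages.tsv")
    }
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  artifacts["log"] <- file.path(config$out_dir, "run.log")
  manifest <- list(package_version =
                     as.character(utils::packageVersion("purisel")),
                   seed = config$seed, config_md5 = config_hash,
                   artifacts = as.list(artifacts))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  if (!is.null(out$clock)) out$clock <- unclass(out$clock)
  out
}
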