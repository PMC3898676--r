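#' Default pipeline configuration
#'
#' Every analysis constant has a named key defaulting to its standard value:
#' sigma = 3 um, the 150 ms / 500 ms response window, FDR alpha = 0.01, the
#' 45 ms subthreshold boxcar, the 400 Hz spike-extraction smoothing cutoff.
#'
#' @return nested list of defaults, suitable to edit and pass to
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "results/pipeline",
    morphology = list(
      n_per_group = 10L,
      jitter_sd = 2, segment_length = 2,
      branch_count = c(4L, 7L), branch_segments = 10L,
      groups = list(
        list(label = "A", dendrite_centroid = c(0, 0, 0),
             axon_target_centroid = c(0, 80, 0), responsive = TRUE),
        list(label = "B", dendrite_centroid = c(30, 0, 0),
             axon_target_centroid = c(0, 80, 0), responsive = FALSE))),
    similarity = list(sigma = 3, symmetrize = "mean", k_neighbors = 5L,
                      resample_step = 1, k_clusters = 2L,
                      linkage = "ward.D"),
    ephys = list(sampling_rate = 11100, n_trials = 4L,
                 odors = c("cVA", "PA"), responsive_odor = "cVA",
                 odor_rate_hz = 40, control_rate_hz = 2,
                 epsp_amplitude = 8, noise_sd = 0.5,
                 spike_amplitude = 40, onset = 1.0, post_s = 1.0,
                 control_label = "mineral_oil"),
    analysis = list(alpha = 0.01, response_start_offset = 0.150,
                    response_window_s = 0.500, smooth_cutoff_hz = 400,
                    subthreshold_boxcar_s = 0.045))
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
                      !is.null(names(new[[nm]])))
      modify_list(base[[nm]], new[[nm]]) else new[[nm]]
  }
  base
}

#' Run the joint morphology-physiology pipeline on simulated data
#'
#' End-to-end composition of the package: simulate a skeleton population
#' with group structure, cluster the morphologies (dot-property similarity,
#' Ward linkage), simulate each cell's odor trials (cells of responsive
#' groups respond to the designated odor), extract spikes, build the
#' response table (exact Poisson test + FDR), compute lifetime sparseness
#' and subthreshold peaks, and emit a study summary whose columns follow
#' dendrogram leaf order — the joint morphology x physiology table the
#' heatmap figures embody.
#'
#' Writes `matrix.csv`, `dendrogram.nwk`, `responses.csv`, `summary.csv`
#' and `run_log.txt` (all parameters) under `config$output_dir`.
#' Deterministic given the config (same config, byte-identical summary).
#'
#' @param config a config list (see [default_pipeline_config()]) or the
#'   path of a YAML file holding one; partial configs are filled in with
#'   the defaults.
#' @return invisibly, a list with `summary` (the study summary data.frame),
#'   `responses`, `tree`, `cluster_labels`, `true_labels`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modify_list(default_pipeline_config(), config)
  if (length(cfg$morphology$groups) < 1L ||
      cfg$morphology$n_per_group < 1L)
    stop("pipeline stage 'simulate_morphology': empty cell list")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. morphology
  pop <- stage("simulate_morphology", {
    mspec <- morpho_population_spec(
      n_per_group = cfg$morphology$n_per_group,
      groups = cfg$morphology$groups,
      branch_count = unlist(cfg$morphology$branch_count),
      branch_segments = cfg$morphology$branch_segments,
      segment_length = cfg$morphology$segment_length,
      jitter_sd = cfg$morphology$jitter_sd,
      seed = cfg$seed)
    simulate_skeleton_population(mspec)
  })
  dps <- stage("dotprops", {
    lapply(pop$skeletons, function(s)
      to_dotprops(resample_skeleton(s, cfg$similarity$resample_step),
                  k_neighbors = cfg$similarity$k_neighbors))
  })
  dm <- stage("distance_matrix", {
    distance_matrix(dps, similarity_params(
      sigma = cfg$similarity$sigma,
      symmetrize = cfg$similarity$symmetrize))
  })
  tree <- stage("clustering", cluster_neurons(dm, cfg$similarity$linkage))
  clusters <- stage("clustering", cut_clusters(tree,
                                               cfg$similarity$k_clusters))
  write_distance_matrix(dm, file.path(cfg$output_dir, "matrix.csv"))
  write_dendrogram_newick(tree, file.path(cfg$output_dir,
                                          "dendrogram.nwk"))

  ## 2. physiology per cell
  responsive_groups <- vapply(cfg$morphology$groups, function(g)
    isTRUE(g$responsive), logical(1L))
  names(responsive_groups) <- vapply(cfg$morphology$groups, `[[`,
                                     character(1L), "label")
  cells <- names(pop$skeletons)
  resp_rows <- list(); sub_rows <- list()
  for (i in seq_along(cells)) {
    cell <- cells[i]
    is_resp <- responsive_groups[[pop$labels[[cell]]]]
    espec <- stage("simulate_ephys", ephys_sim_spec(
      sampling_rate = cfg$ephys$sampling_rate,
      noise_sd = cfg$ephys$noise_sd,
      spike_amplitude = cfg$ephys$spike_amplitude,
      epsp_amplitude = cfg$ephys$epsp_amplitude,
      odor_rate_hz = cfg$ephys$odor_rate_hz,
      control_rate_hz = cfg$ephys$control_rate_hz,
      n_trials = cfg$ephys$n_trials, onset = cfg$ephys$onset,
      post_s = cfg$ephys$post_s, seed = cfg$seed + 1000L + i))
    sim <- stage("simulate_ephys", simulate_trialset(
      espec, odors = cfg$ephys$odors,
      responsive = if (is_resp) cfg$ephys$responsive_odor else character(0),
      control_label = cfg$ephys$control_label, cell_id = cell))
    spikes <- stage("spike_detection", lapply(sim$trialset$trials, function(v)
      detect_spikes(v, smooth_cutoff = cfg$analysis$smooth_cutoff_hz)))
    resp_rows[[cell]] <- stage("response_stats", response_table(
      spikes, control_label = cfg$ephys$control_label,
      alpha = cfg$analysis$alpha,
      start_offset = cfg$analysis$response_start_offset,
      window_length = cfg$analysis$response_window_s))
    sub_rows[[cell]] <- stage("subthreshold", {
      labs <- vapply(sim$trialset$trials, `[[`, character(1L),
                     "stimulus_label")
      vapply(cfg$ephys$odors, function(od) {
        mean(vapply(which(labs == od), function(j)
          subthreshold_response(sim$trialset$trials[[j]],
                                boxcar = cfg$analysis$subthreshold_boxcar_s),
          numeric(1L)))
      }, numeric(1L))
    })
  }
  responses <- do.call(rbind, resp_rows)
  rownames(responses) <- NULL

  ## 3. study summary in dendrogram leaf order
  leaf_order <- cells[tree$order]
  summary <- do.call(rbind, lapply(leaf_order, function(cell) {
    rr <- responses[responses$cell_id == cell, ]
    sp <- lifetime_sparseness(pmax(rr$rate_hz, 0))
    row <- data.frame(cell_id = cell,
                      true_group = unname(pop$labels[[cell]]),
                      cluster = unname(clusters[[cell]]),
                      sparseness = sp)
    for (od in cfg$ephys$odors) {
      row[[paste0("rate_hz_", od)]] <-
        rr$rate_hz[rr$stimulus_label == od]
      row[[paste0("significant_", od)]] <-
        rr$significant[rr$stimulus_label == od]
      row[[paste0("subthreshold_mv_", od)]] <- sub_rows[[cell]][[od]]
    }
    row
  }))
  utils::write.csv(responses, file.path(cfg$output_dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(cfg$output_dir, "summary.csv"),
                   row.names = FALSE)
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  writeLines(c("pherocircuit pipeline run", yaml::as.yaml(cfg)), log_path)
  invisible(list(summary = summary, responses = responses, tree = tree,
                 cluster_labels = clusters, true_labels = pop$labels))
}
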