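#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: windows and bin
#' widths, normalization, cluster counts (`NULL` = choose by silhouette
#' over `k_range`), shuffle counts, the network threshold, regressor
#' coding, stage toggles, and the master seed.
#'
#' @param cue_window,outcome_window analysis windows (s) relative to cue
#'   onset / shock offset.
#' @param bin_width_s bin width (s).
#' @param sd_floor_hz baseline-SD floor for normalization.
#' @param k_cue,k_outcome cluster counts; `NULL` selects by silhouette.
#' @param k_range candidate k when selecting automatically.
#' @param n_shuffles_contrib,n_shuffles_lesion shuffle repetitions.
#' @param network_threshold minimum mean within-network correlation.
#' @param pe_coding prediction-error coding, `"residual"` or
#'   `"indicator"`.
#' @param standardize_cue_design z-score cue regressors.
#' @param stages character vector of stage names to run, in pipeline
#'   order; any subset of the default.
#' @param seed master seed fanned out to every stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cue_window = c(-2, 12),
                            outcome_window = c(0, 10),
                            bin_width_s = 1,
                            sd_floor_hz = 0.1,
                            k_cue = NULL,
                            k_outcome = NULL,
                            k_range = 2:10,
                            n_shuffles_contrib = 200,
                            n_shuffles_lesion = 50,
                            network_threshold = 0.5,
                            pe_coding = c("residual", "indicator"),
                            standardize_cue_design = TRUE,
                            stages = c("behavior", "cue", "outcome",
                                       "networks", "encoding", "lesion",
                                       "membership"),
                            seed = 1L) {
  pe_coding <- match.arg(pe_coding)
  structure(list(cue_window = cue_window, outcome_window = outcome_window,
                 bin_width_s = bin_width_s, sd_floor_hz = sd_floor_hz,
                 k_cue = k_cue, k_outcome = k_outcome, k_range = k_range,
                 n_shuffles_contrib = n_shuffles_contrib,
                 n_shuffles_lesion = n_shuffles_lesion,
                 network_threshold = network_threshold,
                 pe_coding = pe_coding,
                 standardize_cue_design = standardize_cue_design,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_line <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  writeLines(line, con)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
}

#' Run the full analysis pipeline on one session
#'
#' Executes the stages in order — behavior metrics; cue-period binning,
#' normalization, condition averaging, clustering, population PCA,
#' shuffle contribution and danger latency; outcome-period counterpart;
#' correlation networks, hubs and regional composition; encoding
#' regressions and signaling PCA in both modes; network lesions; and the
#' cue/outcome membership chi-squared test — writing every artifact as CSV
#' or JSON under `out_dir`, together with the config echo, seed and a
#' line-oriented log. Later stages that need a disabled stage stop with a
#' clear error. Identical input + config + seed give identical outputs.
#'
#' @param session a `fear_session` or the list returned by
#'   [read_session()].
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results of every stage
#'   that ran.
#' @export
run_pipeline <- function(session, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(log_con))
  .write_json(unclass(config), file.path(out_dir, "config.json"))
  trials <- session$trials
  pokes <- if (!is.null(session$behavior)) session$behavior$pokes else session$pokes
  spikes <- session$spikes
  stages <- config$stages
  res <- list()
  need <- function(stage, dep) {
    if (!dep %in% stages) {
      fail("stage '", stage, "' requires stage '", dep,
           "', which is not enabled")
    }
  }

  if ("behavior" %in% stages) {
    .log_line(log_con, "stage behavior")
    res$behavior <- behavior_records(pokes, trials)
    utils::write.csv(res$behavior, file.path(out_dir, "behavior.csv"),
                     row.names = FALSE)
    res$discrimination <- session_discrimination_summary(res$behavior)
    .write_json(res$discrimination, file.path(out_dir, "discrimination.json"))
  }

  analyze_period <- function(mode) {
    .log_line(log_con, "stage ", mode)
    window <- if (mode == "cue") config$cue_window else config$outcome_window
    align <- if (mode == "cue") "cue_onset" else "shock_offset"
    tensor <- bin_firing(spikes, trials, alignment = align, window = window,
                         bin_width_s = config$bin_width_s)
    baseline_from <- NULL
    if (!any(attr(tensor, "time") < 0)) {
      baseline_from <- bin_firing(spikes, trials, alignment = "cue_onset",
                                  window = config$cue_window,
                                  bin_width_s = config$bin_width_s)
    }
    norm <- normalize_firing(tensor, sd_floor_hz = config$sd_floor_hz,
                             baseline_from = baseline_from)
    prof <- condition_average(norm, mode = mode)
    k <- if (mode == "cue") config$k_cue else config$k_outcome
    if (is.null(k)) {
      kr <- config$k_range[config$k_range < nrow(prof)]
      k <- select_k(prof, kr, seed = derive_seed(config$seed, mode, "k")
                    )$recommended_k
      .log_line(log_con, mode, " k selected by silhouette: ", k)
    }
    clusters <- cluster_profiles(prof, k,
                                 seed = derive_seed(config$seed, mode, "km"))
    pca <- population_pca(prof)
    contrib <- cluster_pc_contribution(
      prof, clusters, n_shuffles = config$n_shuffles_contrib,
      seed = derive_seed(config$seed, mode, "contrib"))
    pm <- as.data.frame(unclass(prof))
    pm <- cbind(neuron_id = rownames(prof), pm)
    utils::write.csv(pm, file.path(out_dir, paste0(mode, "_profiles.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(neuron_id = names(clusters$assignments),
                                cluster = unname(clusters$assignments)),
                     file.path(out_dir, paste0(mode, "_clusters.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(contrib),
                     file.path(out_dir, paste0(mode, "_contributions.csv")),
                     row.names = FALSE)
    list(tensor = tensor, norm = norm, prof = prof, clusters = clusters,
         pca = pca, contrib = contrib)
  }

  if ("cue" %in% stages) {
    res$cue <- analyze_period("cue")
    lat <- danger_onset_latency(spikes, trials)
    utils::write.csv(lat, file.path(out_dir, "latencies.csv"),
                     row.names = FALSE)
    res$latency <- lat
    cl_lat <- cluster_latencies(lat, res$cue$clusters)
    res$latency_regression <- tryCatch(
      latency_contribution_regression(cl_lat, res$cue$contrib),
      error = function(e) NULL)
    if (!is.null(res$latency_regression)) {
      .write_json(res$latency_regression,
                  file.path(out_dir, "latency_regression.json"))
    }
  }
  if ("outcome" %in% stages) res$outcome <- analyze_period("outcome")

  if ("networks" %in% stages) {
    need("networks", "cue")
    .log_line(log_con, "stage networks")
    res$networks <- lapply(intersect(c("cue", "outcome"), names(res)),
                           function(mode) {
      per <- res[[mode]]
      corr <- cluster_correlation_matrix(per$clusters, per$prof)
      part <- detect_networks(corr, threshold = config$network_threshold)
      hubs <- hub_scores(per$prof, per$clusters, part, network = "net1")
      asg <- per$clusters$assignments
      neuron_net <- unname(part[paste0("k", asg)])
      regions <- spikes$neurons$region[match(names(asg),
                                             spikes$neurons$neuron_id)]
      regional <- regional_composition(regions, neuron_net)
      list(mode = mode, corr = corr, partition = part, hubs = hubs,
           neuron_network = stats::setNames(neuron_net, names(asg)),
           regional = regional)
    })
    names(res$networks) <- vapply(res$networks, `[[`, "", "mode")
    for (nw in res$networks) {
      .write_json(list(partition = as.list(nw$partition),
                       threshold = config$network_threshold),
                  file.path(out_dir, paste0(nw$mode, "_networks.json")))
      if (!is.null(nw$hubs)) {
        utils::write.csv(nw$hubs$units,
                         file.path(out_dir, paste0(nw$mode, "_hubs.csv")),
                         row.names = FALSE)
      }
      utils::write.csv(nw$regional$composition,
                       file.path(out_dir, paste0(nw$mode, "_regional.csv")),
                       row.names = FALSE)
    }
  }

  if ("encoding" %in% stages) {
    need("encoding", "behavior")
    need("encoding", "cue")
    .log_line(log_con, "stage encoding")
    res$cue_design <- build_cue_design(
      trials, res$behavior, standardize = config$standardize_cue_design)
    res$cue_fit <- fit_unit_encoding(res$cue$norm, res$cue_design)
    res$cue_betas <- cluster_beta_profiles(res$cue_fit, res$cue$clusters)
    res$cue_signaling <- signaling_pca(res$cue_betas)
    .write_json(list(var_explained = res$cue_signaling$var_explained),
                file.path(out_dir, "cue_signaling_pcs.json"))
    if ("outcome" %in% names(res)) {
      res$outcome_design <- build_outcome_design(trials,
                                                 pe_coding = config$pe_coding)
      res$outcome_fit <- fit_unit_encoding(res$outcome$norm,
                                           res$outcome_design)
      res$outcome_betas <- cluster_beta_profiles(res$outcome_fit,
                                                 res$outcome$clusters)
      res$outcome_signaling <- signaling_pca(res$outcome_betas)
      .write_json(list(var_explained = res$outcome_signaling$var_explained),
                  file.path(out_dir, "outcome_signaling_pcs.json"))
    }
    for (mode in intersect(c("cue", "outcome"), names(res))) {
      fit <- res[[paste0(mode, "_fit")]]
      long <- expand.grid(neuron_id = dimnames(fit$beta)[[1]],
                          bin = dimnames(fit$beta)[[2]],
                          regressor = fit$regressors,
                          stringsAsFactors = FALSE)
      long$beta <- as.vector(fit$beta)
      long$se <- as.vector(fit$se)
      utils::write.csv(long, file.path(out_dir, paste0(mode, "_betas.csv")),
                       row.names = FALSE)
    }
  }

  if ("lesion" %in% stages) {
    need("lesion", "encoding")
    need("lesion", "networks")
    .log_line(log_con, "stage lesion")
    res$lesions <- list()
    for (mode in names(res$networks)) {
      part <- res$networks[[mode]]$partition
      design <- res[[paste0(mode, "_design")]]
      per <- res[[mode]]
      for (target in setdiff(unique(part), character(0))) {
        key <- paste0(mode, "_", target)
        res$lesions[[key]] <- lesion_network_signaling(
          per$norm, per$clusters, part, target, design,
          n_shuffles = config$n_shuffles_lesion,
          seed = derive_seed(config$seed, mode, "lesion", target))
      }
    }
    .write_json(lapply(res$lesions, function(lr) {
      list(target = lr$target,
           intact_ve = lr$intact$var_explained[seq_along(lr$delta_ve)],
           lesioned_ve = lr$lesioned_ve_mean,
           lesioned_ve_sd = lr$lesioned_ve_sd,
           delta_ve = lr$delta_ve, n_shuffles = lr$n_shuffles)
    }), file.path(out_dir, "lesion_results.json"))
  }

  if ("membership" %in% stages) {
    need("membership", "networks")
    .log_line(log_con, "stage membership")
    if (all(c("cue", "outcome") %in% names(res$networks))) {
      cue_net <- res$networks$cue$neuron_network
      out_net <- res$networks$outcome$neuron_network
      p0 <- mean(cue_net == "net1")
      if (p0 > 0 && p0 < 1) {
        res$membership <- lapply(setdiff(unique(out_net), "none"),
                                 function(g) {
          ids <- names(out_net)[out_net == g]
          membership_chi_square(sum(cue_net[ids] == "net1"), length(ids), p0)
        })
        .write_json(lapply(res$membership, unclass),
                    file.path(out_dir, "membership.json"))
      }
    }
  }
  .log_line(log_con, "pipeline complete; seed ", config$seed)
  invisible(res)
}
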