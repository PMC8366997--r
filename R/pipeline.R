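# Pipeline orchestration: simulate -> preprocess -> network -> cluster ->
# outcomes -> variable networks -> validation, with a manifest of hashed
# artifacts for reproducibility checks.

#' Pipeline run configuration
#'
#' Bundles every stage's parameters under a single seed. Unknown arguments are
#' rejected; the object round-trips exactly through JSON.
#'
#' @param cohort A [cohort_config()] (its own seed is overridden by the global
#'   seed fan-out).
#' @param window_days,z_limit Preprocessing options.
#' @param metric Similarity metric.
#' @param grid_step Density-cutoff grid increment.
#' @param k_range Candidate K values for [select_k()].
#' @param K Number of subgroups to use when not selecting automatically
#'   (`NULL` = use [select_k()]).
#' @param alpha Significance level for K selection.
#' @param varnet_fraction Top-correlation fraction for variable networks.
#' @param stability_runs Restarts for [stability_analysis()] (default 100).
#' @param split A [split_plan()].
#' @param seed Global seed fanned out per stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), window_days = 92, z_limit = 4,
                       metric = "cosine", grid_step = 0.05, k_range = 3:8,
                       K = 4, alpha = 0.05, varnet_fraction = 0.15,
                       stability_runs = 100, split = split_plan(), seed = 42L) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(split, "split_plan"))
  out <- list(cohort = cohort, window_days = window_days, z_limit = z_limit,
              metric = metric, grid_step = grid_step, k_range = k_range,
              K = K, alpha = alpha, varnet_fraction = varnet_fraction,
              stability_runs = stability_runs, split = split,
              seed = as.integer(seed))
  class(out) <- "run_config"
  out
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected so silently ignored options cannot creep in.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(x$cohort)) {
    x$cohort$event_hazards <- if (!is.null(x$cohort$event_hazards))
      as.matrix(x$cohort$event_hazards) else NULL
    x$cohort <- do.call(cohort_config, x$cohort[!vapply(x$cohort, is.null, TRUE)])
  }
  if (!is.null(x$split)) x$split <- do.call(split_plan, x$split)
  do.call(run_config, x)
}

#' Write a pipeline configuration to JSON
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$cohort <- jsonlite::fromJSON(config_to_json(config$cohort))
  x$split <- unclass(config$split)
  writeLines(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, pretty = TRUE),
             path)
  invisible(path)
}

#' Run the full stratification pipeline
#'
#' Simulates (or accepts) a cohort, preprocesses it, fits the similarity
#' network and its density profile, clusters the patients, runs the outcome
#' analyses, builds per-subgroup variable networks, assesses clustering
#' stability, and runs split validation. Every artifact is written under
#' `out_dir` and listed in `manifest.json` with its md5 hash; rerunning with
#' the same configuration reproduces the hashes of all deterministic stages.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @param cohort Optional pre-built `synthetic_cohort` (skips simulation).
#' @return Invisibly, a list with the manifest, the fitted `psn_fit`, the
#'   outcome table and the per-stage results.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifacts <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }

  ## simulate ------------------------------------------------------------------
  if (is.null(cohort)) {
    cc <- config$cohort
    cc$seed <- stage_seed(config$seed, "cohort")
    cohort <- generate_cohort(cc)
  }
  artifacts <- c(artifacts, write_cohort(cohort, file.path(out_dir, "cohort")))

  ## preprocess + fit ----------------------------------------------------------
  fit <- psn_fit(cohort, K = config$K %||% 4, metric = config$metric,
                 window_days = config$window_days, z_limit = config$z_limit,
                 seed = stage_seed(config$seed, "cluster"))
  artifacts <- c(artifacts,
                 write_features(fit$features, file.path(out_dir, "features.csv"),
                                file.path(out_dir, "features_meta.json")),
                 file.path(out_dir, "features_meta.json"))

  ## network + density profile -------------------------------------------------
  dens <- select_density_cutoff(fit$sim, grid_step = config$grid_step)
  put(dens$profile, "density_profile.csv")
  net <- build_network(fit$sim, dens$cutoff)
  artifacts <- c(artifacts, write_network(net, file.path(out_dir, "edges.tsv"),
                                          file.path(out_dir, "network.graphml")),
                 file.path(out_dir, "network.graphml"))

  ## outcomes ------------------------------------------------------------------
  outcomes <- classify_events(cohort$events)
  ot <- outcomes[match(names(fit$labels), outcomes$patient_id), ]
  g <- factor(fit$labels)
  ksel <- NULL
  if (is.null(config$K)) {
    ksel <- select_k(fit$sim, outcomes, k_range = config$k_range,
                     alpha = config$alpha, seed = stage_seed(config$seed, "cluster"))
    put(ksel$report, "k_selection.csv")
    if (!is.na(ksel$K) && ksel$K != fit$K) {
      fit <- psn_fit(cohort, K = ksel$K, metric = config$metric,
                     window_days = config$window_days, z_limit = config$z_limit,
                     seed = stage_seed(config$seed, "cluster"))
      g <- factor(fit$labels)
      ot <- outcomes[match(names(fit$labels), outcomes$patient_id), ]
    }
  }
  put(data.frame(patient_id = names(fit$labels), cluster = unname(fit$labels)),
      "clusters.csv")
  km_os <- km_by_group(ot$os_years, ot$death, g)
  ch_dn <- cumulative_hazard_by_group(ot$denovo_years, ot$de_novo_ctrcd, g)
  put(km_os$curves, "survival_curves.csv")
  put(ch_dn$curves, "cumhaz_denovo.csv")
  put(rbind(cbind(endpoint = "os", km_os$pairwise),
            cbind(endpoint = "denovo", ch_dn$pairwise)), "logrank_pairwise.csv")
  cl_f <- relevel_lowest_risk(g, ot$de_novo_ctrcd)
  cox_df <- data.frame(time = ot$denovo_years, status = ot$de_novo_ctrcd,
                       cluster = cl_f,
                       age = cohort$static$age[match(ot$patient_id,
                                                     cohort$static$patient_id)])
  hr <- cox_hr(cox_df, "time", "status", c("cluster", "age"))
  put(as.data.frame(hr), "hazard_ratios.csv")
  put(chi2_enrichment(g, ot$de_novo_ctrcd), "enrichment.csv")
  put(period_breakdown(ot$denovo_years, ot$de_novo_ctrcd, g), "period_breakdown.csv")

  ## variable networks ---------------------------------------------------------
  fams <- feature_families(fit$features)
  cats <- stats::setNames(cohort$variables$category, cohort$variables$variable)
  noncat <- fit$features$feature_info$feature[
    !fit$features$feature_info$feature %in% c("sex_male", "tumor_hematologic")]
  deg_mat <- NULL
  for (cl in levels(g)) {
    rows <- fit$labels == as.integer(cl)
    if (sum(rows) < 3) next
    pcc <- cluster_pcc(fit$features$x[rows, intersect(noncat, colnames(fit$features$x)),
                                      drop = FALSE])
    agg <- aggregate_derived_family(pcc, fams, within_families = "aggregate")
    vn <- topk_edges(agg, fraction = config$varnet_fraction, categories = cats)
    write_variable_network(vn, file.path(out_dir, paste0("varnet_", cl, "_edges.tsv")),
                           file.path(out_dir, paste0("varnet_", cl, ".graphml")))
    artifacts <- c(artifacts, file.path(out_dir, paste0("varnet_", cl, "_edges.tsv")),
                   file.path(out_dir, paste0("varnet_", cl, ".graphml")))
    deg_mat <- cbind(deg_mat, vn$nodes$degree)
    rownames(deg_mat) <- vn$nodes$variable
  }
  cent_rows <- NULL
  if (!is.null(deg_mat)) {
    colnames(deg_mat) <- paste0("cluster", levels(g)[seq_len(ncol(deg_mat))])
    put(data.frame(variable = rownames(deg_mat), deg_mat), "centrality.csv")
    vd <- cluster_variables(deg_mat)
    writeLines(jsonlite::toJSON(list(leaf_order = vd$leaf_order,
                                     merge = vd$hclust$merge,
                                     height = vd$hclust$height), digits = NA),
               file.path(out_dir, "variable_dendrogram.json"))
    artifacts <- c(artifacts, file.path(out_dir, "variable_dendrogram.json"))
  }
  coll <- collinearity_summary(fit$features$x)
  put(data.frame(threshold = coll$threshold, fraction_below = coll$fraction,
                 n_pairs = coll$n_pairs), "collinearity.csv")

  ## stability + validation ----------------------------------------------------
  stab <- stability_analysis(fit$sim, fit$K, n_runs = config$stability_runs,
                             base_seed = stage_seed(config$seed, "stability"))
  put(stab$runs, "stability.csv")
  plan <- config$split
  plan$seed <- stage_seed(config$seed, "validate")
  val <- run_split_validation(cohort, plan, K = fit$K, metric = config$metric,
                              window_days = config$window_days,
                              z_limit = config$z_limit)
  put(val$results, "validation_report.csv")

  ## truth benchmark (synthetic cohorts only) ----------------------------------
  ari_truth <- NA_real_
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth$subgroup[match(names(fit$labels), cohort$truth$patient_id)]
    ari_truth <- adjusted_rand_index(fit$labels, tr)
  }

  manifest <- list(
    created = "see hashes; timestamps omitted for determinism",
    seed = config$seed, K = fit$K, density_cutoff = dens$cutoff,
    density_at_cutoff = dens$profile$density[dens$profile$cutoff == dens$cutoff],
    ari_vs_truth = ari_truth, stability_n_stable = stab$n_stable,
    artifacts = lapply(sort(unique(artifacts)), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(list(manifest = manifest, fit = fit, outcomes = outcomes,
                 density = dens, network = net, stability = stab,
                 validation = val, hazard_ratios = hr, k_selection = ksel))
}
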