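## End-to-end study orchestration: simulate (or load) -> features -> MCA ->
## four clustering methods -> evaluation -> outcomes -> comparison, driven
## by a single declarative config and writing every stage's outputs to a
## run directory.

#' Default run configuration
#'
#' Returns the full configuration list consumed by [run_study()], with the
#' given seed filled in. Expensive stages (kernel k-means and affinity
#' propagation model selection / stability) run on configurable subsamples
#' so a demo-sized study completes on one CPU; all sizes are explicit here.
#'
#' @param seed integer seed (mandatory for any run).
#' @return Named list of configuration entries.
#' @export
default_run_config <- function(seed) {
  list(
    seed = seed,
    n_patients = 2000,
    n_practices = 20,
    followup_years = 5,
    test_fraction = 0.25,
    n_components = NULL,          # NULL = elbow rule
    kmeans_k_range = 2:10,
    kmeans_restarts = 100,
    kernel_k_range = 2:6,
    kernel_restarts = 10,
    kernel_subsample = 800,
    ap_grid_size = 8,
    ap_subsample = 800,
    ap_max_iter = 400,
    lca_k_range = 2:8,
    lca_starts = 5,
    n_bootstraps = 100,
    n_bootstraps_slow = 20,
    stability_subsample = 600,
    alpha = 0.05,
    signature = c("depression", "anxiety", "age_band:42-73",
                  "smoking:current smoker")
  )
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop("config must specify a seed", call. = FALSE)
  base <- default_run_config(config$seed)
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

## clustering procedure factory: re-embeds a raw binary feature matrix with
## MCA and applies k-means — the full method as applied to external data
make_pipeline_clusterer <- function(meta, k, n_components, n_restarts = 20) {
  force(meta); force(k); force(n_components); force(n_restarts)
  function(x, seed) {
    fm <- structure(list(x = as.matrix(x), meta = meta,
                         patients = rownames(x)),
                    class = "feature_matrix")
    m <- suppressWarnings(fit_mca(fm))
    nc <- min(n_components, m$n_components)
    run_kmeans(m$row_coordinates[, seq_len(nc), drop = FALSE], k,
               n_restarts = n_restarts, seed = seed)$labels
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full subtype-discovery study
#'
#' Executes every stage in order on a synthetic cohort (or tables loaded
#' from `config$input_dir` in the same schema): cohort simulation, feature
#' construction, the 25%-of-practices train/test split, MCA, the four
#' clustering methods with their model-selection procedures, the four
#' evaluation measures (structure, stability, replicability — against both
#' the held-out practices and a second simulated cohort — and clinical
#' utility), per-cluster outcomes, cluster characterisation and
#' cross-method comparison. All stage outputs and the effective config are
#' written to `out_dir`; a collated `summary.json` reports per-method k,
#' silhouette, stability, replicability, utility ranking and the
#' consistent-cluster count.
#'
#' @param config configuration list or path to a YAML file; see
#'   [default_run_config()]. `seed` is mandatory.
#' @param out_dir output directory. Default: `adsubtype-run-<seed>` under
#'   `tempdir()`.
#' @return The summary list, invisibly; side effect: files under `out_dir`.
#' @export
run_study <- function(config, out_dir = NULL) {
  cfg <- load_run_config(config)
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), paste0("adsubtype-run-", cfg$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  profiles <- default_profiles()

  ## ---- simulate / load --------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$input_dir)) {
    raw <- stage("load", read_cohort(cfg$input_dir))
    events <- raw$events; demographics <- raw$demographics
    truth <- raw$truth
  } else {
    ch <- stage("simulate", generate_cohort(
      profiles, cfg$n_patients, cfg$n_practices, seed = cfg$seed))
    write_cohort(ch, file.path(out_dir, "cohort"))
    events <- ch$events; demographics <- ch$demographics
    truth <- ch$truth
    outcomes_raw <- stage("simulate-outcomes", generate_outcomes(
      ch, profiles, followup_years = cfg$followup_years,
      seed = cfg$seed + 1L))
  }

  ## ---- features ---------------------------------------------------------
  fx <- stage("features", extract_features(events, demographics))
  cohort <- fx$cohort
  fm <- fx$features
  utils::write.csv(cbind(patient_id = fm$patients, as.data.frame(fm$x)),
                   file.path(out_dir, "feature_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(fm$meta, file.path(out_dir, "feature_meta.csv"),
                   row.names = FALSE)
  split <- stage("split", split_by_practice(cohort, cfg$test_fraction,
                                            seed = cfg$seed))
  tr <- fm$patients %in% split$train
  te <- !tr

  ## ---- MCA --------------------------------------------------------------
  mca <- stage("mca", fit_mca(fm))
  n_comp <- cfg$n_components
  if (is.null(n_comp)) n_comp <- select_components(mca)
  n_comp <- max(n_comp, 2L)
  coords <- mca$row_coordinates[, seq_len(n_comp), drop = FALSE]
  utils::write.csv(mca_scree(mca), file.path(out_dir, "mca_scree.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(patient_id = fm$patients, as.data.frame(coords)),
                   file.path(out_dir, "mca_coordinates.csv"),
                   row.names = FALSE)

  ## ---- clustering: four methods ----------------------------------------
  set.seed(cfg$seed)
  coords_tr <- coords[tr, , drop = FALSE]
  ksel <- stage("kmeans-select", select_k(
    coords_tr, cfg$kmeans_k_range, cfg$kmeans_restarts, seed = cfg$seed))
  km <- stage("kmeans", run_kmeans(coords_tr, ksel$chosen_k,
                                   cfg$kmeans_restarts, seed = cfg$seed))

  sub_idx <- function(n, size) {
    if (n <= size) seq_len(n) else sample.int(n, size)
  }
  tr_idx <- which(tr)
  kk_rows <- tr_idx[sub_idx(length(tr_idx), cfg$kernel_subsample)]
  fm_kk <- structure(list(x = fm$x[kk_rows, , drop = FALSE], meta = fm$meta,
                          patients = fm$patients[kk_rows]),
                     class = "feature_matrix")
  K <- stage("kernel", hamming_kernel(fm_kk))
  kk_sel <- stage("kernel-select", {
    sils <- vapply(cfg$kernel_k_range, function(k) {
      sol <- run_kernel_kmeans(K, k, cfg$kernel_restarts, seed = cfg$seed)
      silhouette_score(sqrt(pmax(outer(diag(K), diag(K), `+`) - 2 * K, 0)),
                       sol$labels)$mean
    }, numeric(1))
    cfg$kernel_k_range[which.max(sils)]
  })
  kk <- stage("kernel-kmeans", run_kernel_kmeans(
    K, kk_sel, cfg$kernel_restarts, seed = cfg$seed))

  ap_rows <- tr_idx[sub_idx(length(tr_idx), cfg$ap_subsample)]
  S <- negative_sqdist(coords[ap_rows, , drop = FALSE])
  ap_sweep <- stage("affinity", sweep_preference(
    S, n_grid = cfg$ap_grid_size, max_iter = cfg$ap_max_iter))
  ap <- ap_sweep$chosen

  lca <- stage("lca", run_latent_class(
    coords_tr, cfg$lca_k_range, cfg$lca_starts, seed = cfg$seed))

  solutions <- list(kmeans = km, kernel_kmeans = kk,
                    affinity_propagation = ap, lca = lca)
  sol_rows <- list(kmeans = tr_idx, kernel_kmeans = kk_rows,
                   affinity_propagation = ap_rows, lca = tr_idx)
  for (m in names(solutions)) {
    utils::write.csv(
      data.frame(patient_id = fm$patients[sol_rows[[m]]],
                 cluster = solutions[[m]]$labels),
      file.path(out_dir, paste0("labels_", m, ".csv")), row.names = FALSE)
  }

  ## ---- evaluation -------------------------------------------------------
  ev <- stage("evaluate", {
    d_tr <- as.matrix(stats::dist(coords_tr))
    sil <- lapply(names(solutions), function(m) {
      rows <- sol_rows[[m]]
      if (identical(rows, tr_idx)) {
        silhouette_score(d_tr, solutions[[m]]$labels)$mean
      } else {
        silhouette_score(as.matrix(stats::dist(coords[rows, , drop = FALSE])),
                         solutions[[m]]$labels)$mean
      }
    })
    names(sil) <- names(solutions)

    st_rows <- tr_idx[sub_idx(length(tr_idx), cfg$stability_subsample)]
    st_coords <- coords[st_rows, , drop = FALSE]
    stab <- list(
      kmeans = bootstrap_stability(
        coords_tr, function(x, s) run_kmeans(x, km$k, 20, seed = s)$labels,
        cfg$n_bootstraps, seed = cfg$seed),
      kernel_kmeans = bootstrap_stability(
        fm$x[kk_rows[sub_idx(length(kk_rows), cfg$stability_subsample)], ,
             drop = FALSE],
        function(x, s) {
          fmx <- structure(list(x = x, meta = fm$meta, patients = rownames(x)),
                           class = "feature_matrix")
          run_kernel_kmeans(hamming_kernel(fmx), kk$k, 5, seed = s)$labels
        }, cfg$n_bootstraps_slow, seed = cfg$seed),
      affinity_propagation = bootstrap_stability(
        st_coords, function(x, s) run_affinity_propagation(
          negative_sqdist(x), preference = ap$extras$preference,
          max_iter = cfg$ap_max_iter)$labels,
        cfg$n_bootstraps_slow, seed = cfg$seed),
      lca = bootstrap_stability(
        coords_tr, function(x, s) run_latent_class(
          x, k_range = lca$k, n_starts = 2, seed = s)$labels,
        cfg$n_bootstraps, seed = cfg$seed)
    )

    clusterer <- make_pipeline_clusterer(fm$meta, km$k, n_comp)
    rep_internal <- replicability(fm$x[tr, , drop = FALSE], km$labels,
                                  fm$x[te, , drop = FALSE], clusterer,
                                  seed = cfg$seed)
    ## second-cohort emulation: an independent draw from the same mixture
    ch2 <- generate_cohort(profiles, max(500, round(cfg$n_patients / 4)),
                           cfg$n_practices, seed = cfg$seed + 1000L)
    fx2 <- extract_features(ch2$events, ch2$demographics)
    rep_external <- replicability(fm$x[tr, , drop = FALSE], km$labels,
                                  fx2$features$x, clusterer,
                                  seed = cfg$seed + 1L)
    list(silhouette = sil, stability = stab,
         replicability = list(internal = rep_internal,
                              external = rep_external))
  })

  ## ---- outcomes & utility ----------------------------------------------
  ut <- NULL
  if (exists("outcomes_raw", inherits = FALSE)) {
    sl <- mmse_slopes(outcomes_raw$visits)
    ot <- merge(outcomes_raw$table, sl, by = "patient_id")
    ot$mmse_slope <- ot$slope
    rownames(ot) <- ot$patient_id
    ot_tr <- ot[fm$patients[tr], ]
    fm_tr <- structure(list(x = fm$x[tr, , drop = FALSE], meta = fm$meta,
                            patients = fm$patients[tr]),
                       class = "feature_matrix")
    ut <- stage("outcomes", {
      summ <- outcome_summary(ot_tr, km$labels)
      utils::write.csv(summ$means,
                       file.path(out_dir, "outcomes_by_cluster.csv"),
                       row.names = FALSE)
      for (ep in names(summ$km))
        utils::write.csv(summ$km[[ep]],
                         file.path(out_dir, paste0("km_", ep, ".csv")),
                         row.names = FALSE)
      utility_comparison(fm_tr, km$labels, ot_tr)
    })
    utils::write.csv(ut$ranking, file.path(out_dir, "utility_ranking.csv"),
                     row.names = FALSE)
  }

  ## ---- comparison -------------------------------------------------------
  cmp <- stage("compare", {
    fm_tr <- structure(list(x = fm$x[tr, , drop = FALSE], meta = fm$meta,
                            patients = fm$patients[tr]),
                       class = "feature_matrix")
    chars <- list()
    for (m in names(solutions)) {
      rows <- sol_rows[[m]]
      fmx <- structure(list(x = fm$x[rows, , drop = FALSE], meta = fm$meta,
                            patients = fm$patients[rows]),
                       class = "feature_matrix")
      chars[[m]] <- suppressWarnings(
        characterize(fmx, solutions[[m]]$labels, alpha = cfg$alpha))
    }
    flow <- cross_method_flow(list(kmeans = km, lca = lca))
    ## consistent cluster: intersect over patient ids since the methods run
    ## on (possibly) different subsamples
    sets <- list()
    for (m in names(solutions)) {
      hits <- integer(0)
      tab <- chars[[m]]$table
      for (j in unique(tab$cluster))
        if (all(cfg$signature %in%
                  tab$feature[tab$cluster == j & tab$significant &
                                tab$direction == "higher"]))
          hits <- c(hits, j)
      if (length(hits))
        sets[[m]] <- fm$patients[sol_rows[[m]]][solutions[[m]]$labels %in%
                                                  hits]
    }
    consistent <- if (length(sets)) Reduce(intersect, sets) else character(0)
    utils::write.csv(flow$flows, file.path(out_dir, "flow_table.csv"),
                     row.names = FALSE)
    char_tab <- do.call(rbind, lapply(names(chars), function(m)
      cbind(method = m, chars[[m]]$table)))
    utils::write.csv(char_tab, file.path(out_dir, "characterisation.csv"),
                     row.names = FALSE)
    list(characterisations = chars, flow = flow,
         consistent_patients = consistent,
         consistent_count = length(consistent))
  })

  ## ---- ARI vs planted truth --------------------------------------------
  ari <- NA_real_
  if (!is.null(truth)) {
    tt <- truth$class_id[match(fm$patients[tr], truth$patient_id)]
    if (!anyNA(tt)) ari <- adjusted_rand(tt, km$labels)
  }

  summary <- list(
    seed = cfg$seed,
    n_cohort = nrow(cohort),
    n_train = sum(tr), n_test = sum(te),
    n_parent_variables = n_parent_variables(fm),
    mca_components = n_comp,
    k = lapply(solutions, `[[`, "k"),
    silhouette = ev$silhouette,
    stability_mean_jaccard = lapply(ev$stability, `[[`,
                                    "overall_mean_jaccard"),
    replicability_concordance = list(
      internal = ev$replicability$internal$concordance,
      external = ev$replicability$external$concordance),
    kmeans_ari_vs_truth = ari,
    cluster_names = lapply(cmp$characterisations, `[[`, "names"),
    consistent_cluster_count = cmp$consistent_count,
    utility_cluster_best_r2 = if (is.null(ut)) NA else ut$cluster_best_r2,
    utility_cluster_best_cox = if (is.null(ut)) NA else ut$cluster_best_cox
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(summary)
}
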