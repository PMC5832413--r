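# Pipeline driver: runs the synthetic study end to end (behavior models ->
# patterns -> first/second-level RSA -> searchlight -> group inference ->
# overlap) and writes all tables plus a JSON run manifest.

#' Pipeline configuration
#'
#' @param out_dir output directory
#' @param seed master seed (mandatory; every stochastic stage derives from it)
#' @param synthetic a `synthetic_config`
#' @param min_count feature-norm reliability threshold (default 4)
#' @param exclude_tags feature tags removed from the conceptual model
#' @param n_iter randomization-test iterations (default 10000)
#' @param k searchlight neighborhood size (default 30 at the default grid;
#'   100 at study scale)
#' @param E,H TFCE exponents
#' @param alpha FWE threshold
#' @param m_bonferroni comparisons for ROI Bonferroni (default 16)
#' @param n_subject_null,n_group permutation-null sizes
#' @param searchlight run the searchlight/group/overlap stages (default TRUE)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            min_count = 4L,
                            exclude_tags = c("visual_form", "color"),
                            n_iter = 10000L, k = 30L, E = 0.5, H = 2,
                            alpha = 0.05, m_bonferroni = 16L,
                            n_subject_null = 100L, n_group = 1000L,
                            searchlight = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: behavior-model construction (ratings -> visual RDM,
#' norms -> conceptual RDM, embeddings -> embedding RDM, model-to-model
#' randomization tests), pattern simulation, first-level ROI RDMs,
#' second-level group RSA per region x context x model, within-object
#' cross-context similarity, and (optionally) searchlight mapping with group
#' TFCE permutation inference and voxel overlap. All outputs are written
#' under `config$out_dir` together with `manifest.json`.
#'
#' @param config a `pipeline_config`
#' @return invisibly, a list with the main in-memory results
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # -- stage 1: behavior models ------------------------------------------
  mods <- make_model_rdms(config$synthetic$n_objects, seed = config$seed)
  ratings <- simulate_ratings(mods$V, n_raters = config$synthetic$n_raters,
                              noise_sd = config$synthetic$rating_noise_sd,
                              fail_fraction = 0.1, seed = config$seed + 1L)
  kept <- filter_raters(ratings)
  note("excluded %d rater(s) on catch trials",
       length(attr(kept, "excluded_raters")))
  vis_rdm <- visual_rdm(kept)
  norms <- simulate_norms(mods$C, n_producers = config$synthetic$n_producers,
                          seed = config$seed + 2L)
  cfm <- filter_features(norms, config$min_count, config$exclude_tags)
  con_rdm <- conceptual_rdm(cfm)
  emb <- simulate_embeddings(mods$C, mods$V, leak = 0.3, seed = config$seed + 3L)
  emb_rdm <- embedding_rdm(emb)
  model_cmp <- randomization_test(vis_rdm, con_rdm, config$n_iter,
                                  seed = config$seed + 4L)
  write_rdm_csv(vis_rdm, file.path(config$out_dir, "visual_rdm.csv"))
  write_rdm_csv(con_rdm, file.path(config$out_dir, "conceptual_rdm.csv"))
  write_rdm_csv(emb_rdm, file.path(config$out_dir, "embedding_rdm.csv"))
  stages <- c(stages, "behavior_models")

  # -- stage 2: patterns --------------------------------------------------
  sim <- simulate_patterns(mods$V, mods$C, config$synthetic)
  stages <- c(stages, "patterns")

  # -- stage 3: first-level ROI RDMs -------------------------------------
  regions <- names(config$synthetic$regions)
  subjects <- names(sim$patterns)
  contexts <- c("visual", "conceptual")
  first <- list()
  for (rg in regions) for (ctx in contexts)
    first[[rg]][[ctx]] <- lapply(subjects, function(s)
      pattern_rdm(roi_patterns(sim, s, ctx, rg)))
  stages <- c(stages, "first_level")

  # -- stage 4: second-level ROI RSA -------------------------------------
  rows <- list()
  for (rg in regions) for (ctx in contexts)
    for (model in c(visual = "V", conceptual = "C")) {
      fit <- group_model_fit(first[[rg]][[ctx]], mods[[model]],
                             m = config$m_bonferroni, alpha = config$alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, context = ctx,
        model = if (model == "V") "visual" else "conceptual",
        mean_tau = fit$mean_tau, p = fit$p, p_adj = fit$p_adj,
        significant = fit$significant)
    }
  roi_table <- do.call(rbind, rows)
  write_tsv(roi_table, file.path(config$out_dir, "roi_second_level.tsv"))
  within_rows <- lapply(regions, function(rg) {
    wr <- vapply(subjects, function(s)
      within_object_similarity(roi_patterns(sim, s, "visual", rg),
                               roi_patterns(sim, s, "conceptual", rg))$mean_r,
      numeric(1))
    data.frame(region = rg, mean_r = mean(wr),
               p = as.numeric(wilcoxon_signed_rank_one_sided(wr)))
  })
  within_table <- do.call(rbind, within_rows)
  write_tsv(within_table, file.path(config$out_dir, "within_object.tsv"))
  stages <- c(stages, "second_level")

  searchlight_res <- NULL
  overlap_res <- NULL
  if (isTRUE(config$searchlight)) {
    # -- stage 5: searchlight + group inference --------------------------
    nb <- build_neighborhoods(sim$mask, k = config$k)
    subj_patterns <- lapply(subjects, function(s) sim$patterns[[s]]$visual)
    searchlight_res <- list(
      visual = permutation_null(subj_patterns, mods$V, nb,
                                n_subject_null = config$n_subject_null,
                                n_group = config$n_group,
                                seed = config$seed + 5L,
                                E = config$E, H = config$H,
                                alpha = config$alpha),
      conceptual = permutation_null(subj_patterns, mods$C, nb,
                                    n_subject_null = config$n_subject_null,
                                    n_group = config$n_group,
                                    seed = config$seed + 6L,
                                    E = config$E, H = config$H,
                                    alpha = config$alpha))
    sig_vols <- lapply(searchlight_res, function(res) {
      arr <- array(FALSE, dim(sim$mask))
      arr[sim$voxel_index[res$significant]] <- TRUE
      volume(arr, vol_affine(sim$mask))
    })
    for (nmv in names(sig_vols))
      write_volume_tsv(sig_vols[[nmv]],
                       file.path(config$out_dir,
                                 sprintf("sig_visualtask_%s.tsv", nmv)))
    cl <- cluster_report(sig_vols$visual, affine = vol_affine(sim$mask))
    write_tsv(cl, file.path(config$out_dir, "clusters_visualtask_visual.tsv"))
    stages <- c(stages, "searchlight")

    # -- stage 6: overlap ------------------------------------------------
    overlap_res <- overlap(sig_vols)
    write_tsv(overlap_res$clusters, file.path(config$out_dir, "overlap_clusters.tsv"))
    stages <- c(stages, "overlap")
  }

  manifest <- list(
    package = "rsacodes",
    version = as.character(utils::packageVersion("rsacodes")),
    seed = config$seed,
    stages = stages,
    parameters = list(min_count = config$min_count, n_iter = config$n_iter,
                      k = config$k, E = config$E, H = config$H,
                      alpha = config$alpha, m_bonferroni = config$m_bonferroni,
                      n_subject_null = config$n_subject_null,
                      n_group = config$n_group,
                      synthetic = unclass(config$synthetic)[
                        c("n_objects", "n_subjects", "n_runs", "noise_sd",
                          "rating_noise_sd", "n_raters", "n_producers")]),
    model_comparison = list(tau_a = model_cmp$tau_a, p = model_cmp$p),
    log = log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(models = mods, visual_rdm = vis_rdm, conceptual_rdm = con_rdm,
                 embedding_rdm = emb_rdm, model_comparison = model_cmp,
                 roi_table = roi_table, within_table = within_table,
                 searchlight = searchlight_res, overlap = overlap_res,
                 manifest = manifest))
}
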