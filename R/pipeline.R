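## End-to-end orchestration: simulate (optional) -> estimate -> spectrum ->
## ray/ring clustering -> chapter flows -> constellations -> stability, per
## sex stratum, with a reproducible manifest.

#' Pipeline configuration
#'
#' A single configuration object for [run_pipeline()]. Every randomized stage
#' receives an explicit seed derived from the master seed by a fixed offset
#' rule (`master * 1000 + stage index`), so the whole run is reproducible
#' from one integer. Can be written to / read from YAML.
#'
#' @param out_dir Output directory.
#' @param sex Stratum label(s); one sub-tree per stratum.
#' @param n,D Cohort size and disease count for the synthetic stage.
#' @param density,effect_range,negative_fraction Planted-graph settings.
#' @param min_effect Strong-effect threshold used by spectrum/flows/graph.
#' @param g_bounds Propensity truncation bounds.
#' @param prevalence_threshold Per-sex prevalence filter threshold.
#' @param design TMLE exposure design; the pipeline defaults to `"landmark"`,
#'   the design under which the point-treatment TMLE with baseline covariates
#'   is strictly valid (see the methods vignette); `run_all_pairs()` keeps
#'   `"ever-before"` as its own default for onset-interval-style analyses.
#' @param boot_B Multiscale-bootstrap replicates per scale.
#' @param perm_B Permutation draws for chapter flows.
#' @param stability_seeds k-means reinitializations for the stability report.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sex = "female", n = 5000, D = 12,
                            density = 0.1, effect_range = c(0.3, 0.9),
                            negative_fraction = 0.25, min_effect = 0.01,
                            g_bounds = c(0.01, 0.99), prevalence_threshold = 0.01,
                            design = "landmark", boot_B = 500, perm_B = 2000,
                            stability_seeds = 50, seed = 7) {
  structure(list(out_dir = out_dir, sex = sex, n = n, D = D, density = density,
                 effect_range = effect_range, negative_fraction = negative_fraction,
                 min_effect = min_effect, g_bounds = g_bounds,
                 prevalence_threshold = prevalence_threshold, design = design,
                 boot_B = boot_B, perm_B = perm_B,
                 stability_seeds = stability_seeds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(config, stage_index) {
  (config$seed * 1000L + stage_index) %% .Machine$integer.max
}

#' Run the full multimorbidity-progression pipeline
#'
#' Executes, per sex stratum: cohort simulation (skipped when stage outputs
#' already exist and `resume = TRUE`), all-pairs TMLE estimation, spectrum
#' summaries, ray and ring clustering with AU support, chapter-flow analysis
#' with permutation tests, constellation detection with hubs and layout, and
#' the ARI stability report. All stage outputs are CSV/JSON files under
#' `out_dir/<sex>/`; `manifest.json` records the configuration, stage seeds
#' and MD5 digests of every output.
#'
#' @param config A [pipeline_config()].
#' @param resume If TRUE, stages whose outputs already exist are loaded
#'   instead of recomputed (checkpoint restart).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  outputs <- character(0)
  for (sex in config$sex) {
    dir <- file.path(config$out_dir, sex)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(dir, f)

    ## stage 1: simulate
    sim_files <- c(pth("diagnoses.csv"), pth("covariates.csv"),
                   pth("planted_graph.csv"), pth("true_effects.csv"))
    scfg <- sim_config(n = config$n, D = config$D, sex = sex,
                       seed = stage_seed(config, 1L) + match(sex, config$sex))
    gamma <- make_planted_graph(config$D, density = config$density,
                                effect_range = config$effect_range,
                                negative_fraction = config$negative_fraction,
                                seed = stage_seed(config, 2L))
    if (!(resume && all(file.exists(sim_files)))) {
      cohort <- simulate_cohort(scfg, gamma)
      write_diagnosis_table(cohort$diag, sim_files[1])
      write_covariate_table(cohort$cov, sim_files[2])
      gdf <- data.frame(gamma, check.names = FALSE)
      colnames(gdf) <- cohort$diseases
      write.csv(cbind(code = cohort$diseases, gdf), sim_files[3], row.names = FALSE)
      te <- true_effect_matrix(gamma, scfg, n_mc = min(2L * config$n, 20000L),
                               seed = stage_seed(config, 3L))
      write.csv(te, sim_files[4], row.names = FALSE)
    } else {
      cohort <- list(diag = read_diagnosis_table(sim_files[1], sex = sex),
                     cov = read_covariate_table(sim_files[2]),
                     diseases = sim_disease_codes(config$D))
    }

    ## stage 2: prevalence filter + estimate
    eff_file <- pth("effects.csv")
    diseases <- prevalence_filter(cohort$diag, cohort$cov,
                                  threshold = config$prevalence_threshold)
    if (!(resume && file.exists(eff_file))) {
      em <- run_all_pairs(cohort$diag, cohort$cov, diseases,
                          design = config$design, g_bounds = config$g_bounds)
      write_effect_matrix(em, eff_file)
    } else {
      em <- read_effect_matrix(eff_file, sex = sex, design = config$design)
    }

    ## stage 3: spectrum
    cc <- classify_counts(em)
    writeLines(jsonlite::toJSON(cc, auto_unbox = TRUE, digits = NA),
               pth("class_counts.json"))
    write.csv(rank_influential(em, config$min_effect), pth("rank_influential.csv"),
              row.names = FALSE)
    write.csv(rank_influenced(em, config$min_effect), pth("rank_influenced.csv"),
              row.names = FALSE)
    write.csv(rank_preventive(em, config$min_effect), pth("rank_preventive.csv"),
              row.names = FALSE)
    write.csv(rank_prevented(em, config$min_effect), pth("rank_prevented.csv"),
              row.names = FALSE)
    ti <- onset_intervals(cohort$diag, em, config$min_effect)
    write.csv(ti$pairs, pth("onset_intervals.csv"), row.names = FALSE)
    if (nrow(as.data.frame(ti$bands))) {
      write.csv(ti$bands, pth("onset_bands.csv"), row.names = FALSE)
    }

    ## stage 4: ray / ring clustering with AU support
    for (type in c("rays", "rings")) {
      prof <- profile_matrix(em, type = type)
      bpt <- multiscale_bootstrap(prof, B = config$boot_B,
                                  seed = stage_seed(config, 4L))
      cut <- cut_support(bpt, mode = "au-threshold", parameter = 0.87)
      cl_au <- setNames(cut$clusters$au, cut$clusters$cluster)
      memb <- data.frame(disease = names(cut$membership),
                         cluster = as.integer(cut$membership),
                         au = as.numeric(cl_au[as.character(cut$membership)]))
      write.csv(memb, pth(sprintf("clusters_%s.csv", type)), row.names = FALSE)
      write.csv(au_support(bpt), pth(sprintf("au_support_%s.csv", type)),
                row.names = FALSE)
      write_newick(bpt$tree, pth(sprintf("dendrogram_%s.nwk", type)))
    }

    ## stage 5: chapter flows
    edges <- classify_directionality(em, config$min_effect)
    flows <- aggregate_flows(edges)
    write.csv(chord_export(flows), pth("chord.csv"), row.names = FALSE)
    for (dirn in c("uni", "bi")) {
      if (sum(edges$direction == dirn) > 0) {
        ft <- flow_permutation_test(edges, direction = dirn, B = config$perm_B,
                                    seed = stage_seed(config, 5L))
        write.csv(ft, pth(sprintf("flow_test_%s.csv", dirn)), row.names = FALSE)
      }
    }

    ## stage 6: constellations + stability
    pg <- build_progress_graph(em, config$min_effect)
    if (igraph::vcount(pg$graph) >= 2) {
      cs <- self_tuning_cluster(pg, seed = stage_seed(config, 6L))
      hubs <- identify_hubs(pg, cs)
      coords <- layout_components(pg)
      memb <- data.frame(node = names(cs$membership),
                         constellation = as.integer(cs$membership))
      memb$hub <- memb$node %in% hubs$hub
      memb$chapter <- map_chapter(memb$node)
      write.csv(memb, pth("constellations.csv"), row.names = FALSE)
      write.csv(hubs, pth("hubs.csv"), row.names = FALSE)
      write.csv(data.frame(node = rownames(coords), x = coords[, 1], y = coords[, 2]),
                pth("layout.csv"), row.names = FALSE)
      write.csv(pg$edges, pth("progress_edges.csv"), row.names = FALSE)
      sr <- stability_report(pg, cs, n_seeds = config$stability_seeds,
                             seed = stage_seed(config, 7L))
      writeLines(jsonlite::toJSON(list(mean_ari = sr$mean_ari,
                                       by_method = as.list(sr$mean_ari_by_method)),
                                  auto_unbox = TRUE, digits = NA),
                 pth("stability.json"))
    }
    outputs <- c(outputs, list.files(dir, full.names = TRUE))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("morbidmap")),
    config = unclass(config),
    stage_seeds = setNames(as.list(vapply(1:7, function(i) stage_seed(config, i),
                                          numeric(1))),
                           c("simulate", "graph", "oracle", "bootstrap",
                             "permutation", "constellations", "stability")),
    digests = as.list(tools::md5sum(sort(unique(outputs))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             manifest_path)
  invisible(manifest)
}
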