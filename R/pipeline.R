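#' Pipeline configuration
#'
#' Assembles all stage parameters with the study defaults pre-filled:
#' detection ring 4 (human-like) / 3 (macaque-like) with a median gyral
#' split, anisotropic smoothing, watershed clustering, the Dice > 0 OR
#' center distance < 7 mm shared criterion, top-10% connection thresholding,
#' and the 10-fold CV lasso over a 1e-4..1 lambda grid.
#'
#' @param design a [synthetic_design()].
#' @param stages stages to run, in pipeline order; later stages require
#'   earlier ones.
#' @param detect_k named per-species detection ring sizes.
#' @param gyral_quantile gyral restriction quantile (default 0.5).
#' @param smooth_iterations,smooth_ring,smooth_beta anisotropic smoothing
#'   parameters.
#' @param flood_floor_fraction watershed flooding starts only on vertices
#'   whose smoothed count exceeds this fraction of the subject count
#'   (default 0.025, i.e. 0.5 subjects at n = 20): isolated single-subject
#'   noise peaks never seed a basin.
#' @param saddle_ratio watershed basin-merge threshold.
#' @param min_mass_fraction surviving basins must collect at least this
#'   fraction of subjects' worth of raw counts (default 0.5: a group-wise
#'   cluster is a majority-consensus landmark, which cleanly separates
#'   planted loci, supported by nearly every subject, from chance
#'   co-occurrences of individual noise peaks).
#' @param d_max shared-criterion center distance (mm).
#' @param threshold_fraction top fraction of connections retained per row.
#' @param lambda_grid,cv_folds,holdout gene-stage parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = synthetic_design(),
                            stages = c("detect", "cluster", "match",
                                       "consistency", "features",
                                       "connectome", "diversity", "genes"),
                            detect_k = c(human = 4L, macaque = 3L),
                            gyral_quantile = 0.5,
                            smooth_iterations = 3L, smooth_ring = 1L,
                            smooth_beta = 2,
                            flood_floor_fraction = 0.025, saddle_ratio = 0.15,
                            min_mass_fraction = 0.5,
                            d_max = 7,
                            threshold_fraction = 0.10,
                            lambda_grid = lambda_grid_default(),
                            cv_folds = 10L, holdout = 0.25) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys match the arguments of
#' [pipeline_config()] and (under `design`) of [synthetic_design()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  design_args <- y$design %||% list()
  design <- do.call(synthetic_design, design_args)
  rest <- y[setdiff(names(y), "design")]
  do.call(pipeline_config, c(list(design = design), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the cross-species gyral peak pipeline
#'
#' Executes the enabled stages on the synthetic study design:
#' detect -> count -> smooth -> watershed (per species), correspondence ->
#' shared/unique match, consistency statistics, anatomical feature
#' comparison, connectome node metrics, atlas diversity and network tallies,
#' and gene selection. Any stage failure halts with the stage name.
#' Re-running with the same configuration reproduces identical results.
#'
#' @param config a [pipeline_config()].
#' @return list of class `gyralpeak_result`; see the returned element names.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg <- config
  design <- cfg$design
  res <- list(config = cfg)
  enabled <- function(s) s %in% cfg$stages

  res$species <- stage("simulate", lapply(
    c(human = "human", macaque = "macaque"),
    function(sp) make_species(design, sp)))

  if (!enabled("detect")) return(structure(res, class = "gyralpeak_result"))
  res$peaks <- stage("detect", lapply(res$species, function(spd) {
    k <- cfg$detect_k[[spd$species]]
    lapply(seq_along(spd$subjects), function(s) {
      detect_peaks(spd$mesh, spd$subjects[[s]]$sulc, k = k,
                   gyral_quantile = cfg$gyral_quantile,
                   subject_id = sprintf("%s_%02d", spd$species, s),
                   species = spd$species)
    })
  }))

  if (!enabled("cluster")) return(structure(res, class = "gyralpeak_result"))
  res$counts <- stage("count", lapply(c(human = "human", macaque = "macaque"),
    function(sp) {
      accumulate_count(res$peaks[[sp]], n_vertices(res$species[[sp]]$mesh))
    }))
  res$clusters <- stage("cluster", lapply(
    c(human = "human", macaque = "macaque"),
    function(sp) {
      mesh <- res$species[[sp]]$mesh
      sm <- anisotropic_smooth(mesh, res$counts[[sp]],
                               iterations = cfg$smooth_iterations,
                               ring = cfg$smooth_ring, beta = cfg$smooth_beta)
      watershed_clusters(mesh, sm, res$counts[[sp]],
                         flood_floor = cfg$flood_floor_fraction *
                           design$n_subjects,
                         min_mass = ceiling(cfg$min_mass_fraction *
                                              design$n_subjects),
                         saddle_ratio = cfg$saddle_ratio, species = sp)
    }))

  if (!enabled("match")) return(structure(res, class = "gyralpeak_result"))
  res$correspondence <- stage("correspondence", make_correspondence(
    design, "macaque_to_human", source = res$species$macaque,
    target = res$species$human))
  res$match <- stage("match", {
    mapped <- map_cluster_set(res$clusters$macaque, res$correspondence)
    match_shared(res$clusters$human, mapped, res$species$human$mesh,
                 d_max = cfg$d_max)
  })
  # classes pulled back to the original macaque clusters by cluster id
  res$classes <- stage("match", {
    pick <- function(cl, ids, negate = FALSE) {
      sel <- if (negate) !(cl$cluster_id %in% ids) else cl$cluster_id %in% ids
      peak_clusters(tibble::as_tibble(cl)[sel, , drop = FALSE],
                    species = attr(cl, "species"),
                    hemisphere = attr(cl, "hemisphere"),
                    n_subjects = attr(cl, "n_subjects"))
    }
    list(human = list(shared = res$match$shared_a,
                      unique = res$match$unique_a),
         macaque = list(
           shared = pick(res$clusters$macaque, res$match$matches$cluster_b_id),
           unique = pick(res$clusters$macaque, res$match$matches$cluster_b_id,
                         negate = TRUE)))
  })

  if (enabled("consistency")) {
    res$consistency <- stage("consistency", {
      per_species <- lapply(c(human = "human", macaque = "macaque"),
        function(sp) {
          cl <- res$clusters[[sp]]
          shared_ids <- res$classes[[sp]]$shared$cluster_id
          tibble::tibble(
            species = sp, cluster_id = cl$cluster_id,
            class = ifelse(cl$cluster_id %in% shared_ids, "shared", "unique"),
            consistency = cl$mass / design$n_subjects)
        })
      tbl <- dplyr::bind_rows(per_species)
      tests <- dplyr::bind_rows(lapply(
        c(human = "human", macaque = "macaque"), function(sp) {
          x <- tbl[tbl$species == sp, ]
          ht <- two_sample_t(x$consistency[x$class == "shared"],
                             x$consistency[x$class == "unique"])
          tibble::tibble(species = sp, t_value = ht$t, p_value = ht$p)
        }))
      mm <- res$match$matches
      hu <- res$clusters$human
      ma <- res$clusters$macaque
      pairs <- tibble::tibble(
        consistency_m = ma$mass[match(mm$cluster_b_id, ma$cluster_id)] /
          design$n_subjects,
        consistency_h = hu$mass[match(mm$cluster_a_id, hu$cluster_id)] /
          design$n_subjects)
      reg <- consistency_regression(pairs$consistency_m, pairs$consistency_h)
      list(table = tbl, tests = tests, pairs = pairs, regression = reg)
    })
  }

  res$classed_peaks <- stage("classing", lapply(
    c(human = "human", macaque = "macaque"), function(sp) {
      lapply(res$peaks[[sp]], individual_class_peaks,
             shared = res$classes[[sp]]$shared,
             unique = res$classes[[sp]]$unique)
    }))

  if (enabled("features")) {
    res$morpho <- stage("features", lapply(
      c(human = "human", macaque = "macaque"), function(sp) {
        feats <- c("sulc", "curv", "area")
        if (sp == "human") feats <- c(feats, "thickness", "myelin")
        per_subject_means(res, sp, feats)
      }))
  }

  if (enabled("connectome")) {
    res$connectome <- stage("connectome", lapply(
      c(human = "human", macaque = "macaque"), function(sp) {
        mesh <- res$species[[sp]]$mesh
        parc <- patch_parcellate(mesh, design$n_patches[[sp]],
                                 seed = design$seed * 10L +
                                   match(sp, c("human", "macaque")))
        loci <- res$species[[sp]]$loci
        hubs <- sort(unique(
          as.integer(parc)[loci$vertex[loci$class == "shared"]]))
        ts <- make_timeseries(design, parc, hub_patches = hubs,
                              seed_offset = match(sp, c("human", "macaque")))
        fc <- group_average(lapply(ts$series, fc_matrix))
        fc_thr <- threshold_top(fc, cfg$threshold_fraction)
        fc_metrics <- node_metrics(fc_thr)
        fc_cmp <- peak_node_props(res$classed_peaks[[sp]], parc, fc_metrics)
        out <- list(parc = parc, hubs = hubs, fc = fc_thr,
                    fc_metrics = fc_metrics, fc_comparison = fc_cmp)
        if (sp == "human") {
          ep <- make_endpoints(design, parc, ts$community, hubs)
          sc <- threshold_top(sc_matrix(ep, parc), cfg$threshold_fraction)
          out$sc_metrics <- node_metrics(sc)
          out$sc_comparison <- peak_node_props(res$classed_peaks[[sp]], parc,
                                               out$sc_metrics)
        }
        out
      }))
  }

  if (enabled("diversity")) {
    res$diversity <- stage("diversity", lapply(
      c(human = "human", macaque = "macaque"), function(sp) {
        mesh <- res$species[[sp]]$mesh
        atlases <- make_atlases(design, mesh, loci = res$species[[sp]]$loci)
        div <- diversity_stats(res$classed_peaks[[sp]], mesh,
                               atlases[setdiff(names(atlases), "networks")])
        tal <- network_tally(res$classes[[sp]]$shared$center,
                             res$classes[[sp]]$unique$center,
                             atlases$networks)
        list(diversity = div, tally = tal, atlases = atlases)
      }))
  }

  if (enabled("genes")) {
    res$genes <- stage("genes", {
      # spatial region classing on the gene atlas (recorded for reference);
      # at desk scale the handful of synthetic clusters can only class a
      # handful of regions, so the lasso itself runs on the design's
      # region-class counts, which emulate the hundreds of classed regions a
      # full-resolution atlas yields on real data
      mesh <- res$species$human$mesh
      gene_parc <- patch_parcellate(mesh, max(design$atlas_resolutions),
                                    seed = design$seed * 100L +
                                      length(design$atlas_resolutions))
      gene_atlas <- label_map(as.integer(gene_parc), atlas_name = "gene_atlas")
      rc_spatial <- label_regions(gene_atlas, res$classes$human$shared$center,
                                  res$classes$human$unique$center)
      gt <- make_gene_table(design)
      sel <- select_genes(gt$expression, gt$region_class,
                          holdout = cfg$holdout, grid = cfg$lambda_grid,
                          folds = cfg$cv_folds, seed = design$seed)
      list(region_class = gt$region_class, region_class_spatial = rc_spatial,
           truth = gt$informative_genes, selection = sel)
    })
  }

  structure(res, class = "gyralpeak_result")
}

# subject-level feature means per class and the pooled-t comparison table
per_subject_means <- function(res, sp, feats) {
  spd <- res$species[[sp]]
  classed <- res$classed_peaks[[sp]]
  rows <- lapply(feats, function(f) {
    ms <- vapply(seq_along(classed), function(s) {
      vals <- spd$subjects[[s]][[f]]
      if (f == "sulc") vals <- scalar_map(abs(map_values(vals)), name = "sulc")
      cp <- classed[[s]]
      subject_feature_mean(cp$vertex[cp$class == "shared"], vals)
    }, 0)
    mu <- vapply(seq_along(classed), function(s) {
      vals <- spd$subjects[[s]][[f]]
      if (f == "sulc") vals <- scalar_map(abs(map_values(vals)), name = "sulc")
      cp <- classed[[s]]
      subject_feature_mean(cp$vertex[cp$class == "unique"], vals)
    }, 0)
    compare_classes(ms, mu, feature_name = f)
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_bh(out$p_value)
  class(out) <- c("feature_comparison", class(tibble::tibble()))
  out
}

#' @export
print.gyralpeak_result <- function(x, ...) {
  cat("gyralpeak_result\n")
  if (!is.null(x$clusters)) {
    cat("  clusters: human", nrow(x$clusters$human), "| macaque",
        nrow(x$clusters$macaque), "\n")
  }
  if (!is.null(x$match)) {
    cat("  shared pairs:", nrow(x$match$matches), "| unique human",
        nrow(x$match$unique_a), "| unique macaque",
        nrow(x$match$unique_b), "\n")
  }
  if (!is.null(x$genes)) {
    cat("  genes: lambda", signif(x$genes$selection$lasso$chosen_lambda, 3),
        "|", length(x$genes$selection$selected_genes), "selected\n")
  }
  invisible(x)
}

#' Score a pipeline run against the planted ground truth
#'
#' Matches every planted locus to the nearest recovered cluster center (by
#' graph geodesic on the species template), scores the cluster's vertex set
#' against the planted disc ([planted_disc()]) with the Dice coefficient, and
#' checks the recovered shared/unique class against the planted class.
#'
#' @param result a [run_pipeline()] result (match stage required).
#' @return list with `per_locus` (tibble: species, locus_id, class,
#'   recovered_class, dice, center_distance_mm, correct) and `summary`
#'   (one row per species: n_loci, n_clusters, mean_dice, min_dice,
#'   class_accuracy).
#' @export
evaluate_recovery <- function(result) {
  design <- result$config$design
  rows <- lapply(c("human", "macaque"), function(sp) {
    spd <- result$species[[sp]]
    cl <- result$clusters[[sp]]
    shared_ids <- result$classes[[sp]]$shared$cluster_id
    if (nrow(cl) == 0L) {
      return(tibble::tibble(species = sp, locus_id = spd$loci$locus_id,
                            class = spd$loci$class,
                            recovered_class = NA_character_, dice = 0,
                            center_distance_mm = NA_real_, correct = FALSE))
    }
    d <- geodesic_distances(spd$mesh, spd$loci$vertex, cl$center)
    nearest <- apply(d, 1, which.min)
    tibble::tibble(
      species = sp,
      locus_id = spd$loci$locus_id,
      class = spd$loci$class,
      recovered_class = ifelse(cl$cluster_id[nearest] %in% shared_ids,
                               "shared", "unique"),
      dice = vapply(seq_along(nearest), function(i) {
        dice(planted_disc(spd$mesh, spd$loci$vertex[i], design$jitter_rings),
             cl$vertices[[nearest[i]]])
      }, 0),
      center_distance_mm = d[cbind(seq_along(nearest), nearest)],
      correct = class == recovered_class
    )
  })
  per_locus <- dplyr::bind_rows(rows)
  summary <- per_locus |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      mean_dice = mean(.data$dice),
      min_dice = min(.data$dice),
      class_accuracy = mean(.data$correct),
      .groups = "drop") |>
    dplyr::mutate(n_clusters = vapply(
      .data$species, function(sp) nrow(result$clusters[[sp]]), 0L,
      USE.NAMES = FALSE))
  list(per_locus = per_locus, summary = summary)
}

#' Write pipeline outputs to a directory
#'
#' Writes the result tables as CSV/JSON with a provenance log
#' (`provenance.json`: all parameters plus the MD5 digest of every written
#' file). Re-running the same configuration reproduces byte-identical
#' outputs.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  put_json <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
  }
  for (sp in c("human", "macaque")) {
    if (!is.null(result$clusters[[sp]])) {
      cl <- result$clusters[[sp]]
      put_json(lapply(seq_len(nrow(cl)), function(i) list(
        id = cl$cluster_id[i], center = cl$center[i] - 1L,
        mass = cl$mass[i], vertices = cl$vertices[[i]] - 1L)),
        paste0("clusters_", sp, ".json"))
    }
    if (!is.null(result$morpho[[sp]])) {
      put_csv(result$morpho[[sp]], paste0("table_morpho_", sp, ".csv"))
    }
    if (!is.null(result$connectome[[sp]])) {
      put_csv(result$connectome[[sp]]$fc_comparison,
              paste0("table_fc_", sp, ".csv"))
    }
    if (!is.null(result$diversity[[sp]])) {
      put_csv(result$diversity[[sp]]$diversity,
              paste0("table_diversity_", sp, ".csv"))
      put_csv(result$diversity[[sp]]$tally$by_network,
              paste0("table_networks_", sp, ".csv"))
    }
  }
  if (!is.null(result$connectome$human$sc_comparison)) {
    put_csv(result$connectome$human$sc_comparison, "table_sc_human.csv")
  }
  if (!is.null(result$match)) put_json(result$match$matches, "matches.json")
  if (!is.null(result$consistency)) {
    put_csv(result$consistency$table, "table_consistency.csv")
    put_csv(result$consistency$tests, "table_consistency_tests.csv")
  }
  if (!is.null(result$genes)) {
    las <- result$genes$selection$lasso
    put_json(list(lambda_grid = las$lambda_grid,
                  cv_accuracy = las$cv_accuracy, cv_mse = las$cv_mse,
                  chosen_lambda = las$chosen_lambda,
                  selected_genes = las$selected_genes), "lasso.json")
    put_csv(result$genes$selection$welch, "welch_genes.csv")
  }
  prov <- list(
    parameters = result$config[setdiff(names(result$config), "design")],
    design = unclass(result$config$design),
    files = as.list(tools::md5sum(paths))
  )
  p <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(paths, p))
}
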