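# End-to-end orchestration: one call runs filtering, partitioning,
# absolute abundance, stability, beta diversity, networks, MNC and PLS-PM
# for every depth layer and writes a results bundle plus a machine-readable
# manifest.

#' Analysis run configuration
#'
#' Collects every tunable threshold of the pipeline with its conventional
#' default: core occupancy 0.75, satellite occupancy 0.50, abundant 1%,
#' rare 0.01%, network |rho| 0.8 at FDR p < 0.01 with a 0.05% node filter,
#' 5-sample windows, 0.2 degC/m thermocline gradient.
#'
#' @param min_total low-count taxon filter (dataset-wide reads).
#' @param core_min,satellite_max occupancy thresholds.
#' @param abundant_thr,rare_thr abundance-category thresholds.
#' @param rho_min,fdr_max,node_min_rel network construction thresholds.
#' @param window moving-window length.
#' @param thermocline_gradient degC/m criterion.
#' @param env_collinearity_r2,net_collinearity_r2 squared-Spearman cutoffs
#'   for the collinearity pre-filters.
#' @param plspm_n_boot bootstrap resamples for path significance.
#' @param seed master seed; all stage seeds are derived from it.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(min_total = 10, core_min = 0.75, satellite_max = 0.50,
                       abundant_thr = 0.01, rare_thr = 0.0001,
                       rho_min = 0.8, fdr_max = 0.01, node_min_rel = 0.0005,
                       window = 5, thermocline_gradient = 0.2,
                       env_collinearity_r2 = 0.5, net_collinearity_r2 = 0.6,
                       plspm_n_boot = 299, seed = 1) {
  if (satellite_max > core_min) stop_input("satellite_max must not exceed core_min")
  if (!(rare_thr < abundant_thr)) stop_input("rare_thr must be below abundant_thr")
  stopifnot(
    core_min > 0, core_min <= 1, satellite_max > 0, satellite_max <= 1,
    rho_min > 0, rho_min <= 1, fdr_max > 0, fdr_max < 1,
    window >= 2, thermocline_gradient >= 0
  )
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' For each depth layer of the dataset: filter and rarefy counts, partition
#' taxa into core/satellite, compute qPCR-scaled absolute abundances,
#' moving-window 1/CV stability with disturbance groups and
#' subcommunity-vs-entire relations, Bray-Curtis beta diversity (NMDS,
#' ANOSIM, SIMPER class contributions, time-lag trend, period-pair bins)
#' for the core and satellite subcommunities, co-occurrence networks with
#' per-sample subnetwork topology and period comparisons, the MNC index,
#' and PLS path models linking environment, community ordination scores,
#' network topology and MNC. Writes CSV/TSV artefacts plus `manifest.json`
#' (thresholds, seed, config hash, file list) to `outdir`.
#'
#' @param dataset a `synthetic_dataset` from [generate_scenario()], or any
#'   list with the same `community`/`qpcr`/`environment` elements.
#' @param config a [run_config()].
#' @param outdir output directory (created if needed); `NULL` skips writing.
#' @return (invisibly) a list of per-depth results plus `manifest`.
#' @export
run_pipeline <- function(dataset, config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  depths <- names(dataset$community)
  qpcr <- setNames(dataset$qpcr$copies_per_ml, dataset$qpcr$sample_id)
  results <- list()
  for (depth in depths) {
    results[[depth]] <- tryCatch(
      run_depth(dataset, depth, qpcr, config),
      error = function(e) {
        stop_input("pipeline failed for depth '", depth, "': ", conditionMessage(e))
      }
    )
  }
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("coresat")),
    depths = depths
  )
  if (!is.null(outdir)) {
    manifest$files <- write_bundle(results, manifest, outdir)
    jsonlite::write_json(
      manifest, file.path(outdir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(c(results, list(manifest = manifest)))
}

run_depth <- function(dataset, depth, qpcr, config) {
  table <- dataset$community[[depth]]
  meta <- table$sample_meta
  periods <- as_period(meta$period)
  dates <- as.Date(meta$date)

  # --- community preparation -------------------------------------------
  table <- filter_low_count_taxa(table, config$min_total)
  table <- rarefy_table(table, seed = derive_seed(config$seed, paste0("rarefy_", depth)))
  part <- partition_taxa(
    table,
    core_min = config$core_min, satellite_max = config$satellite_max,
    abundant_thr = config$abundant_thr, rare_thr = config$rare_thr
  )
  abs_ab <- absolute_abundance(table, qpcr, part)

  # --- stability --------------------------------------------------------
  stab <- do.call(rbind, lapply(c("entire", "core", "satellite"), function(sub) {
    stability_series(abs_ab$group_sums[[sub]], periods, w = config$window, subcommunity = sub)
  }))
  stab$depth <- depth
  relations <- lapply(c("core", "satellite"), function(sub) {
    r <- stability_relation(
      stab[stab$subcommunity == sub, ],
      stab[stab$subcommunity == "entire", ]
    )
    data.frame(depth = depth, subcommunity = sub, slope = r$slope,
               intercept = r$intercept, r = r$r, p = r$p, n = r$n)
  })
  relations <- do.call(rbind, relations)

  # --- beta diversity ---------------------------------------------------
  subsets <- list(
    core = part$taxon_id[part$occupancy_class == "core"],
    satellite = part$taxon_id[part$occupancy_class == "satellite"]
  )
  beta <- lapply(names(subsets), function(sub) {
    tab <- subset_community(table, taxa = subsets[[sub]])
    ok <- rowSums(tab$counts) > 0
    if (!all(ok)) {
      warning(
        sum(!ok), " sample(s) without ", sub, " reads at ", depth,
        " dropped from the ", sub, " beta-diversity analyses",
        call. = FALSE
      )
      tab <- subset_community(tab, samples = which(ok))
    }
    dm <- bray_curtis(tab)
    ord <- nmds(dm, k = 2, seed = derive_seed(config$seed, paste0("nmds_", depth, sub)))
    list(
      subcommunity = sub,
      samples = tab$sample_meta$sample_id,
      dm = dm,
      nmds = ord,
      anosim = anosim_test(dm, periods[ok], seed = derive_seed(config$seed, paste0("anosim_", depth, sub))),
      timelag = time_lag(dm, dates[ok]),
      period_pairs = period_pair_dissimilarity(dm, periods[ok])
    )
  })
  names(beta) <- names(subsets)
  # SIMPER on the whole community, contributions aggregated by occupancy class
  simper <- simper_contributions(table, periods)
  class_contrib <- simper_class_contributions(simper, part)

  # --- networks ---------------------------------------------------------
  eligible <- network_node_filter(table, periods, config$node_min_rel)
  networks <- lapply(names(subsets), function(sub) {
    taxa <- intersect(eligible, subsets[[sub]])
    if (length(taxa) < 2) {
      warning("fewer than 2 eligible ", sub, " network nodes at ", depth, call. = FALSE)
      return(NULL)
    }
    net <- build_network(table, taxa = taxa, rho_min = config$rho_min, fdr_max = config$fdr_max)
    metrics <- subnetwork_metrics(net, subset_community(table, taxa = taxa))
    list(
      subcommunity = sub, network = net, metrics = metrics,
      kw = compare_metrics_by_period(metrics, periods)
    )
  })
  names(networks) <- names(subsets)

  # --- nutrient function ------------------------------------------------
  env <- dataset$environment[dataset$environment$sample_id %in% meta$sample_id, ]
  env <- env[match(meta$sample_id, env$sample_id), ]
  nutrient_cols <- c("tc", "toc", "tn", "nh4", "no3", "no2", "tp", "po4")
  mnc <- mnc_index(env[, nutrient_cols])

  plspm <- lapply(names(subsets), function(sub) {
    keep <- match(beta[[sub]]$samples, meta$sample_id)
    metr <- networks[[sub]]$metrics
    if (!is.null(metr)) metr <- metr[match(beta[[sub]]$samples, metr$sample_id), ]
    fit_depth_plspm(env[keep, ], beta[[sub]]$nmds$points, metr, mnc[keep],
                    config, paste0(depth, "_", sub))
  })
  names(plspm) <- names(subsets)

  list(
    depth = depth, table = table, partition = part, absolute = abs_ab,
    stability = stab, stability_relations = relations, beta = beta,
    simper_class_contributions = class_contrib, networks = networks,
    mnc = data.frame(sample_id = meta$sample_id, depth = depth,
                     mnc = as.numeric(mnc), stringsAsFactors = FALSE),
    plspm = plspm
  )
}

# Aggregate SIMPER percentage contributions by occupancy class, averaged
# over the period pairs.
simper_class_contributions <- function(simper, partition) {
  cls <- setNames(as.character(partition$occupancy_class), partition$taxon_id)
  per_pair <- lapply(names(simper), function(pair) {
    df <- simper[[pair]]
    agg <- tapply(df$contribution_pct, cls[df$taxon_id], sum)
    data.frame(pair = pair, class = names(agg), contribution_pct = as.numeric(agg),
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, per_pair)
  mean_by_class <- tapply(per_pair$contribution_pct, per_pair$class, mean)
  list(per_pair = per_pair, mean_by_class = mean_by_class)
}

# One PLS path model: WT / Phys / Nutr / Chl-a drive the two NMDS axes and
# the network topology; everything except Nutr may drive MNC (the Nutr ->
# MNC path is structurally absent because the nutrients define the index).
fit_depth_plspm <- function(env, nmds_points, net_metrics, mnc, config, tag) {
  dat <- data.frame(
    wt = env$wt, do = env$do, ph = env$ph,
    tn = env$tn, nh4 = env$nh4, no3 = env$no3, no2 = env$no2,
    tp = env$tp, po4 = env$po4, chla = env$chla,
    comm1 = nmds_points[, 1], comm2 = nmds_points[, 2],
    mnc = as.numeric(mnc)
  )
  phys_keep <- collinearity_filter(dat[, c("do", "ph")], config$env_collinearity_r2)
  nutr_keep <- collinearity_filter(
    dat[, c("tn", "nh4", "no3", "no2", "tp", "po4")], config$env_collinearity_r2
  )
  blocks <- list(WT = "wt", Phys = phys_keep, Nutr = nutr_keep, Chla = "chla",
                 Comm1 = "comm1", Comm2 = "comm2")
  if (!is.null(net_metrics)) {
    net_cols <- c("avg_path_length", "betweenness_centralization", "density", "modularity")
    net_cols <- net_cols[vapply(net_cols, function(cl) {
      x <- net_metrics[[cl]]
      all(is.finite(x)) && sd(x) > 0
    }, TRUE)]
    if (length(net_cols) >= 1) {
      net_keep <- if (length(net_cols) > 1) {
        collinearity_filter(net_metrics[, net_cols], config$net_collinearity_r2)
      } else {
        net_cols
      }
      dat[, paste0("net_", net_keep)] <- net_metrics[, net_keep]
      blocks$Net <- paste0("net_", net_keep)
    }
  }
  blocks$MNC <- "mnc"
  lv <- names(blocks)
  inner <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  drivers <- c("WT", "Phys", "Nutr", "Chla")
  for (resp in intersect(c("Comm1", "Comm2", "Net"), lv)) inner[resp, drivers] <- 1
  inner["MNC", setdiff(lv, c("Nutr", "MNC"))] <- 1
  fit <- tryCatch(
    fit_plspm(dat, blocks, inner),
    error = function(e) {
      warning("PLS-PM pruning failed for ", tag, " (", conditionMessage(e),
              "); refitting without pruning", call. = FALSE)
      fit_plspm(dat, blocks, inner, prune = FALSE)
    }
  )
  boot <- bootstrap_paths(
    fit, n_boot = config$plspm_n_boot,
    seed = derive_seed(config$seed, paste0("boot_", tag))
  )
  list(model = fit, paths = boot)
}

# Write the per-depth results as flat files; returns the file list.
write_bundle <- function(results, manifest, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(outdir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  depths <- setdiff(names(results), "manifest")
  collect <- function(f) do.call(rbind, lapply(depths, function(d) f(results[[d]], d)))

  emit_csv(collect(function(r, d) cbind(depth = d, r$partition)), "partition.csv")
  emit_csv(collect(function(r, d) cbind(depth = d, r$absolute$group_sums)), "absolute_abundance.csv")
  emit_csv(collect(function(r, d) r$stability), "stability.csv")
  emit_csv(collect(function(r, d) r$stability_relations), "stability_relations.csv")
  emit_csv(collect(function(r, d) {
    do.call(rbind, lapply(r$beta, function(b) data.frame(
      depth = d, subcommunity = b$subcommunity,
      sample_id = labels(b$dm), NMDS1 = b$nmds$points[, 1], NMDS2 = b$nmds$points[, 2],
      stress = b$nmds$stress, stringsAsFactors = FALSE
    )))
  }), "nmds.csv")
  emit_csv(collect(function(r, d) {
    do.call(rbind, lapply(r$beta, function(b) data.frame(
      depth = d, subcommunity = b$subcommunity, anosim_R = b$anosim$R,
      anosim_p = b$anosim$p, timelag_slope = b$timelag$slope,
      timelag_p = b$timelag$p, stringsAsFactors = FALSE
    )))
  }), "beta_tests.csv")
  emit_csv(collect(function(r, d) {
    do.call(rbind, lapply(r$beta, function(b) {
      kw <- b$period_pairs$kw
      data.frame(
        depth = d, subcommunity = b$subcommunity, bin = names(kw$letters),
        median_dissimilarity = as.numeric(b$period_pairs$kw$group_medians),
        letter = as.character(kw$letters), stringsAsFactors = FALSE
      )
    }))
  }), "period_pair_dissimilarity.csv")
  emit_csv(collect(function(r, d) cbind(depth = d, r$simper_class_contributions$per_pair)),
           "simper_class_contributions.csv")
  for (d in depths) {
    for (sub in names(results[[d]]$networks)) {
      nw <- results[[d]]$networks[[sub]]
      if (is.null(nw)) next
      name <- paste0("network_edges_", d, "_", sub, ".tsv")
      write.table(nw$network$edges, file.path(outdir, name),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, name)
    }
  }
  emit_csv(collect(function(r, d) {
    do.call(rbind, lapply(r$networks, function(nw) {
      if (is.null(nw)) return(NULL)
      cbind(depth = d, subcommunity = nw$subcommunity, nw$metrics)
    }))
  }), "network_metrics.csv")
  emit_csv(collect(function(r, d) r$mnc), "mnc.csv")
  emit_csv(collect(function(r, d) {
    do.call(rbind, lapply(names(r$plspm), function(sub) {
      p <- r$plspm[[sub]]$paths
      cbind(depth = d, subcommunity = sub, p,
            gof = r$plspm[[sub]]$model$gof)
    }))
  }), "plspm_paths.csv")
  files
}
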