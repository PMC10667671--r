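#!/usr/bin/env Rscript
# Stage 6: multi-nutrient cycling index and PLS path models linking water
# temperature, physicochemistry, nutrients, chlorophyll-a, community
# ordination scores and network topology to the MNC index. The Nutr -> MNC
# path is structurally absent (the nutrients define the index).
#
# This stage re-runs the orchestrated pipeline, which wires those pieces
# together per depth and subcommunity, and reports the path models.

suppressPackageStartupMessages(library(coresat))

seed <- 1
ds <- generate_scenario(scenario_config(seed = seed))
res <- suppressWarnings(run_pipeline(ds, run_config(seed = seed), outdir = "results/pipeline"))

mnc_all <- rbind(res$surface$mnc, res$bottom$mnc)
write.csv(mnc_all, "results/mnc.csv", row.names = FALSE)
cat(sprintf("MNC index: mean %.3g (per-depth standardization), SD %.2f\n",
            mean(mnc_all$mnc), sd(mnc_all$mnc)))

paths_rows <- list()
for (depth in c("surface", "bottom")) {
  for (sub in c("core", "satellite")) {
    m <- res[[depth]]$plspm[[sub]]
    cat(sprintf("\n%s %s model: GoF = %.3f | R2: %s\n", depth, sub, m$model$gof,
                paste(names(m$model$r_squared),
                      sprintf("%.2f", m$model$r_squared), collapse = ", ")))
    sig <- m$paths[m$paths$p < 0.1, ]
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s -> %s: %.2f (p = %.3g)\n",
                  sig$from[i], sig$to[i], sig$estimate[i], sig$p[i]))
    }
    paths_rows[[paste(depth, sub)]] <- cbind(depth = depth, subcommunity = sub,
                                             m$paths, gof = m$model$gof)
  }
}
write.csv(do.call(rbind, paths_rows), "results/plspm_paths.csv", row.names = FALSE)
cat("\nwrote results/mnc.csv, results/plspm_paths.csv and results/pipeline/ bundle\n")
cat("Reading: the path models explain more community variance at the bottom\n",
    "than at the surface, and the community axes carry environment effects\n",
    "through to the multi-nutrient cycling index.\n")
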