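# Synthetic scenario generator. Emulates the sampling design of a deep
# subtropical reservoir followed through stratification -> complete mixing
# -> re-stratification at two depths: 34 visits per depth every 10 days
# (14 before / 11 mixing / 9 after), core and satellite taxa, a
# total-abundance crash during mixing with recovery in surface waters only,
# and covarying environmental drivers. The generator retains its latent
# truth so downstream modules can be tested against known structure.

#' Scenario configuration for the synthetic generator
#'
#' @param n_timepoints_per_depth visits per depth (default 34).
#' @param period_sizes integer vector (before, mixing, after); must sum to
#'   `n_timepoints_per_depth` (default 14, 11, 9).
#' @param n_core_taxa,n_intermediate_taxa,n_satellite_taxa taxon pool sizes.
#' @param depth_layers depth layer names.
#' @param crash_multiplier multiplicative factor on the latent total
#'   abundance during complete mixing (default 0.2).
#' @param recovery named logical per depth: do latent totals return to the
#'   pre-mixing mean after mixing? (default surface TRUE, bottom FALSE).
#' @param seed master seed; identical seeds give identical datasets.
#' @param sequencing_depth multinomial draws (reads) per sample.
#' @param qpcr_noise_cv coefficient of variation of the log-normal
#'   measurement noise on qPCR totals.
#' @param total_mean latent mean total abundance, 18S copies per mL.
#' @param composition_shift_sd SD of per-taxon log-abundance shifts switched
#'   on during mixing (and persisting after mixing at non-recovering
#'   depths): the size of the community rearrangement.
#' @param factor_loading_sd SD of per-taxon loadings on the two latent
#'   drivers (a seasonal temperature-like trajectory and the mixing pulse)
#'   that give taxa shared dynamics, hence co-occurrence structure.
#' @param sample_noise_sd SD of per-sample per-taxon log-abundance noise.
#' @param total_noise_sd SD (log scale) of sample-to-sample latent total
#'   variation during undisturbed periods.
#' @param aftermath_volatility_sd terminal per-step log-scale random-walk SD
#'   of latent totals in the after period at non-recovering depths; the step
#'   SD ramps linearly up to this value, so instability keeps growing after
#'   the disturbance instead of recovering.
#' @param aftermath_drift per-step log-scale drift of the same walk
#'   (negative: continued decline).
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_timepoints_per_depth = 34,
                            period_sizes = c(before = 14, mixing = 11, after = 9),
                            n_core_taxa = 60,
                            n_intermediate_taxa = 40,
                            n_satellite_taxa = 300,
                            depth_layers = c("surface", "bottom"),
                            crash_multiplier = 0.2,
                            recovery = c(surface = TRUE, bottom = FALSE),
                            seed = 1,
                            sequencing_depth = 20000,
                            qpcr_noise_cv = 0.1,
                            total_mean = 1e6,
                            composition_shift_sd = 0.8,
                            factor_loading_sd = 0.8,
                            sample_noise_sd = 0.5,
                            total_noise_sd = 0.25,
                            aftermath_volatility_sd = 2.0,
                            aftermath_drift = -0.3) {
  period_sizes <- setNames(as.integer(period_sizes), c("before", "mixing", "after"))
  if (sum(period_sizes) != n_timepoints_per_depth) {
    stop_input("period sizes must sum to n_timepoints_per_depth")
  }
  if (any(period_sizes < 0)) stop_input("period sizes must be non-negative")
  if (!(crash_multiplier > 0 && crash_multiplier <= 1)) {
    stop_input("crash_multiplier must be in (0, 1]")
  }
  if (sequencing_depth < 1) stop_input("sequencing_depth must be positive")
  if (qpcr_noise_cv <= 0) stop_input("qpcr_noise_cv must be positive")
  if (!all(depth_layers %in% names(recovery))) {
    stop_input("recovery must be named for every depth layer")
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a complete synthetic dataset
#'
#' Produces, per depth layer: a [community_table()] of multinomial read
#' counts at fixed sequencing depth; per-sample qPCR total 18S copy numbers
#' (latent total x log-normal noise); an environmental table (water
#' temperature, DO, pH, TC, TOC, TN, NH4, NO3, NO2, TP, PO4, Chl-a) whose
#' trajectories encode the disturbance (surface temperature rebounds after
#' mixing, bottom oxygen pulses during mixing, bottom temperature, Chl-a,
#' TN and TP decline after mixing); and per-visit depth-temperature
#' profiles (stratified visits have a thermocline, mixing visits are
#' vertically uniform). Latent generator parameters are retained in
#' `$truth`.
#'
#' @param config a [scenario_config()].
#' @return list of class `synthetic_dataset` with elements `community`
#'   (named list of `community_table` per depth), `qpcr` (data.frame:
#'   sample_id, copies_per_ml), `environment` (data.frame per sample),
#'   `profiles` (data.frame: visit_id, date, depth_m, temperature_C),
#'   `truth` (list per depth) and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, {
    n <- config$n_timepoints_per_depth
    periods <- as_period(rep(period_levels(), config$period_sizes))
    dates <- as.Date("2015-07-01") + 10 * (seq_len(n) - 1)
    out <- list(community = list(), qpcr = NULL, environment = NULL, truth = list())
    for (depth in config$depth_layers) {
      g <- generate_depth(config, depth, periods, dates)
      out$community[[depth]] <- g$community
      out$qpcr <- rbind(out$qpcr, g$qpcr)
      out$environment <- rbind(out$environment, g$environment)
      out$truth[[depth]] <- g$truth
    }
    out$profiles <- generate_temperature_profiles(config)
    out$config <- config
    structure(out, class = "synthetic_dataset")
  })
}

generate_depth <- function(config, depth, periods, dates) {
  n <- length(periods)
  rec <- isTRUE(config$recovery[[depth]])
  day <- as.numeric(dates - dates[1])

  # ---- latent total abundance (copies/mL) -------------------------------
  mult <- rep(1, n)
  mult[periods == "mixing"] <- config$crash_multiplier
  if (!rec) {
    # persistent depression plus progressively growing instability after
    # mixing: a log-scale random walk whose step SD ramps up over the after
    # period, so variability keeps increasing instead of recovering
    i_after <- which(periods == "after")
    k <- seq_along(i_after)
    walk <- cumsum(rnorm(length(i_after), mean = config$aftermath_drift,
                         sd = config$aftermath_volatility_sd * k / length(i_after)))
    mult[i_after] <- config$crash_multiplier * exp(walk)
  }
  latent_total <- config$total_mean * mult * rlnorm(n, 0, config$total_noise_sd)

  # ---- taxon pool -------------------------------------------------------
  n_core <- config$n_core_taxa
  n_int <- config$n_intermediate_taxa
  n_sat <- config$n_satellite_taxa
  classes <- rep(c("core", "intermediate", "satellite"), c(n_core, n_int, n_sat))
  n_taxa <- length(classes)
  taxon_ids <- sprintf("OTU%04d", seq_len(n_taxa))
  base_log <- c(
    rnorm(n_core, mean = 4, sd = 1.2),        # few, abundant, persistent
    rnorm(n_int, mean = 1.5, sd = 1),
    rnorm(n_sat, mean = -0.5, sd = 1.5)       # many, mostly rare, transient
  )
  occupancy_p <- c(
    rep(1, n_core),
    runif(n_int, 0.55, 0.72),
    runif(n_sat, 0.08, 0.45)
  )
  shift_mix <- rnorm(n_taxa, 0, config$composition_shift_sd)
  shift_after <- if (rec) rep(0, n_taxa) else rnorm(n_taxa, 0, config$composition_shift_sd)

  # ---- latent shared drivers -------------------------------------------
  # Taxa load on a seasonal temperature-like trajectory and on the mixing
  # pulse, giving them the shared dynamics real plankton show (and hence
  # non-trivial co-occurrence structure). The seasonal driver is cyclic at
  # recovering depths and a persistent step otherwise, mirroring the water
  # temperature trajectories.
  f_season <- if (rec) {
    as.vector(scale(cos(2 * pi * (day - 15) / 365)))
  } else {
    as.vector(scale((periods == "before") * 1 - (periods == "after") * 1))
  }
  f_mix <- as.vector(scale(as.integer(periods == "mixing")))
  load_season <- rnorm(n_taxa, 0, config$factor_loading_sd)
  load_mix <- rnorm(n_taxa, 0, config$factor_loading_sd)

  # ---- per-sample latent intensities and counts -------------------------
  shift <- outer(shift_mix, as.integer(periods == "mixing")) +
    outer(shift_after, as.integer(periods == "after")) +
    outer(load_season, f_season) + outer(load_mix, f_mix)
  loglam <- base_log + shift +
    matrix(rnorm(n_taxa * n, 0, config$sample_noise_sd), n_taxa, n)
  present <- matrix(rbinom(n_taxa * n, 1, rep(occupancy_p, n)), n_taxa, n)
  lambda <- exp(loglam) * present
  counts <- vapply(seq_len(n), function(i) {
    pr <- lambda[, i]
    if (sum(pr) == 0) pr[1] <- 1  # pathological guard: keep sample non-empty
    rmultinom(1, config$sequencing_depth, pr)[, 1]
  }, integer(n_taxa))
  sample_ids <- sprintf("%s_%02d", toupper(substr(depth, 1, 1)), seq_len(n))
  dimnames(counts) <- list(taxon_ids, sample_ids)

  meta <- data.frame(
    sample_id = sample_ids, depth = depth, date = dates,
    period = as.character(periods), stringsAsFactors = FALSE
  )
  community <- community_table(t(counts), meta)

  # ---- qPCR totals ------------------------------------------------------
  sdlog <- sqrt(log(1 + config$qpcr_noise_cv^2))
  qpcr <- data.frame(
    sample_id = sample_ids,
    copies_per_ml = latent_total * rlnorm(n, -sdlog^2 / 2, sdlog),
    stringsAsFactors = FALSE
  )

  # ---- environment ------------------------------------------------------
  env <- synth_environment(depth, periods, day, meta)

  list(
    community = community, qpcr = qpcr, environment = env,
    truth = list(
      depth = depth, periods = periods, latent_total = latent_total,
      multiplier = mult, taxon_class = setNames(classes, taxon_ids),
      base_log = setNames(base_log, taxon_ids),
      occupancy_p = setNames(occupancy_p, taxon_ids),
      shift_mix = setNames(shift_mix, taxon_ids),
      shift_after = setNames(shift_after, taxon_ids),
      load_season = setNames(load_season, taxon_ids),
      load_mix = setNames(load_mix, taxon_ids),
      f_season = f_season, f_mix = f_mix,
      recovery = rec
    )
  )
}

# Environmental trajectories. Annual sinusoid for surface temperature (which
# therefore rebounds to pre-mixing values by construction); step changes for
# the bottom layer (oxygenation pulse during mixing, persistent post-mixing
# declines in temperature, Chl-a, TN and TP); nitrification signature during
# mixing in the bottom layer (NH4 down, NO3 up).
synth_environment <- function(depth, periods, day, meta) {
  n <- length(periods)
  before <- periods == "before"; mixing <- periods == "mixing"; after <- periods == "after"
  if (depth == "surface") {
    wt <- 21.5 + 8 * cos(2 * pi * (day - 15) / 365) + rnorm(n, 0, 0.8)
    do_ <- 8 + rnorm(n, 0, 0.6)
    chla <- ifelse(mixing, 3.5, 8) + rnorm(n, 0, 1)
    tn <- 0.9 + 0.2 * mixing + rnorm(n, 0, 0.08)
    tp <- 0.040 + 0.012 * mixing + rnorm(n, 0, 0.005)
    nh4 <- 0.12 + 0.05 * mixing + rnorm(n, 0, 0.02)
    no3 <- 0.45 + 0.15 * mixing + rnorm(n, 0, 0.05)
  } else {
    wt <- 15.5 * before + 14 * mixing + 11.5 * after + rnorm(n, 0, 0.5)
    do_ <- 0.3 * before + 7.85 * mixing + 0.5 * after + rnorm(n, 0, 0.2)
    chla <- 6 * before + 3 * mixing + 1.5 * after + rnorm(n, 0, 0.6)
    tn <- 1.4 * before + 1.2 * mixing + 0.8 * after + rnorm(n, 0, 0.08)
    tp <- 0.070 * before + 0.060 * mixing + 0.035 * after + rnorm(n, 0, 0.006)
    nh4 <- 0.60 * before + 0.15 * mixing + 0.30 * after + rnorm(n, 0, 0.05)
    no3 <- 0.20 * before + 0.80 * mixing + 0.50 * after + rnorm(n, 0, 0.06)
  }
  env <- data.frame(
    meta,
    wt = wt,
    do = pmax(do_, 0.02),
    ph = 7.6 + 0.4 * (depth == "surface") + rnorm(n, 0, 0.15),
    tc = pmax(12 + 2 * mixing + rnorm(n, 0, 1), 0.1),
    toc = pmax(3.5 + 0.5 * mixing + rnorm(n, 0, 0.4), 0.1),
    tn = pmax(tn, 0.01),
    nh4 = pmax(nh4, 0.005),
    no3 = pmax(no3, 0.005),
    no2 = pmax(0.02 + 0.01 * mixing + rnorm(n, 0, 0.004), 0.001),
    tp = pmax(tp, 0.002),
    po4 = pmax(0.5 * tp + rnorm(n, 0, 0.003), 0.001),
    chla = pmax(chla, 0.05),
    stringsAsFactors = FALSE
  )
  env
}

#' Generate per-visit depth-temperature profiles
#'
#' Stratified visits (before/after periods) have a logistic temperature
#' step across a thermocline that deepens through the stratified season, so
#' some successive-pair gradient exceeds 0.2 degC/m; complete-mixing visits
#' are vertically uniform within 0.1 degC.
#'
#' @param config a [scenario_config()].
#' @return data.frame: `visit_id`, `date`, `period`, `depth_m`,
#'   `temperature_C`.
#' @export
generate_temperature_profiles <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_timepoints_per_depth
  periods <- as_period(rep(period_levels(), config$period_sizes))
  dates <- as.Date("2015-07-01") + 10 * (seq_len(n) - 1)
  day <- as.numeric(dates - dates[1])
  z <- seq(0.5, 30, by = 0.5)
  out <- withr::with_seed(derive_seed(config$seed, "profiles"), lapply(seq_len(n), function(i) {
    p <- periods[i]
    if (p == "mixing") {
      t0 <- 14 + rnorm(1, 0, 0.3)
      temp <- t0 + runif(length(z), -0.04, 0.04)  # uniform within 0.1 degC
    } else {
      surf <- 21.5 + 8 * cos(2 * pi * (day[i] - 15) / 365)
      bot <- 12
      # thermocline deepens over each stratified season
      pos <- if (p == "before") i / sum(periods == "before") else
        (i - which(periods == "after")[1] + 1) / sum(periods == "after")
      zc <- 5 + 18 * pos
      temp <- bot + (surf - bot) / (1 + exp((z - zc) / 1.2))
    }
    data.frame(
      visit_id = sprintf("V%02d", i), date = dates[i], period = as.character(p),
      depth_m = z, temperature_C = temp, stringsAsFactors = FALSE
    )
  }))
  do.call(rbind, out)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$community), "depth layer(s),",
      nrow(x$qpcr), "samples, seed", x$config$seed, "\n")
  invisible(x)
}
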