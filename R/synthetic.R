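# Run a block of code with a locally seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generators
#'
#' Collects the ground-truth parameters used to emulate the experimental
#' designs: monoculture OD growth curves across a log-spaced inoculum
#' grid with and without the antibiotic, co-culture colony counts under
#' the dilution protocol, and antibiotic decay series.
#'
#' @param growth_rates Named per-hour growth rates (natural-log units) of
#'   the strains to simulate.
#' @param K Carrying capacity in CFU/ml (default 1e9).
#' @param inoculum_densities Initial densities in CFU/ml (default
#'   log-spaced 1e5-1e9).
#' @param smx_concentration Antibiotic concentration in ug/l (default 200).
#' @param smx_effects Named additive change to each strain's net rate
#'   while exposed (negative = inhibition, positive = hormetic boost, 0 =
#'   neutral); defaults mirror the community model (`cooperator` +0.6,
#'   `cheater` -0.8).
#' @param noise_sd Multiplicative lognormal sigma on OD readings.
#' @param od_per_density OD600 per CFU/ml conversion (default 1e-9, i.e.
#'   OD 1.0 at 1e9 CFU/ml).
#' @param sample_dt,horizon OD sampling interval and duration, hours.
#' @param plated_volume Plated volume for colony counts, ml.
#' @param seed Integer seed recorded in all outputs.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(growth_rates = c(cooperator = 0.5, cheater = 0.75),
                         K = 1e9,
                         inoculum_densities = 10^(5:9),
                         smx_concentration = 200,
                         smx_effects = c(cooperator = 0.6, cheater = -0.8),
                         noise_sd = 0.02,
                         od_per_density = 1e-9,
                         sample_dt = 0.5, horizon = 72,
                         plated_volume = 0.01,
                         seed = 1L) {
  stopifnot(noise_sd >= 0, K > 0, od_per_density > 0, sample_dt > 0,
            horizon > sample_dt, all(inoculum_densities > 0),
            !is.null(names(growth_rates)), all(growth_rates >= 0))
  structure(list(growth_rates = growth_rates, K = K,
                 inoculum_densities = inoculum_densities,
                 smx_concentration = smx_concentration,
                 smx_effects = smx_effects, noise_sd = noise_sd,
                 od_per_density = od_per_density, sample_dt = sample_dt,
                 horizon = horizon, plated_volume = plated_volume,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Logistic closed form on normalized abundance; valid for negative rates
# (decay toward zero) as long as x0 <= 1.
logistic_curve <- function(x0, r, t) {
  e <- exp(r * t)
  x0 * e / (1 + x0 * (e - 1))
}

#' Generate monoculture OD600 growth curves with ground truth
#'
#' Logistic trajectories from each inoculum density, for each strain, with
#' and without antibiotic exposure, converted to OD via a fixed
#' OD-per-density factor and perturbed by i.i.d. multiplicative lognormal
#' noise. Antibiotic wells apply the configured per-strain additive rate
#' effect for the whole incubation. The true net rate per well is emitted
#' alongside.
#'
#' @param cfg A [synth_config()].
#' @param replicates Wells per condition (default 6).
#' @param seed Overrides `cfg$seed` when given.
#' @return List with `od` (long format: `well`, `strain`,
#'   `initial_density`, `smx`, `time`, `od600`) and `truth` (one row per
#'   well: identifying columns plus `true_rate`, natural-log units per
#'   hour, and `seed`).
#' @export
generate_od_curves <- function(cfg, replicates = 6, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"), replicates >= 1)
  tt <- seq(0, cfg$horizon, by = cfg$sample_dt)
  design <- expand.grid(replicate = seq_len(replicates),
                        smx = c(FALSE, TRUE),
                        initial_density = cfg$inoculum_densities,
                        strain = names(cfg$growth_rates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$well <- sprintf("W%04d", seq_len(nrow(design)))
  design$true_rate <- cfg$growth_rates[design$strain] +
    ifelse(design$smx, cfg$smx_effects[design$strain], 0)
  with_seed(seed, {
    od <- do.call(rbind, lapply(seq_len(nrow(design)), function(k) {
      x0 <- design$initial_density[k] / cfg$K
      x <- logistic_curve(x0, design$true_rate[k], tt)
      clean <- x * cfg$K * cfg$od_per_density
      noisy <- clean * exp(stats::rnorm(length(tt), 0, cfg$noise_sd))
      data.frame(well = design$well[k], strain = design$strain[k],
                 initial_density = design$initial_density[k],
                 smx = design$smx[k], time = tt, od600 = noisy)
    }))
    truth <- design[, c("well", "strain", "initial_density", "smx",
                        "true_rate")]
    truth$seed <- seed
    list(od = od, truth = truth)
  })
}

# Smallest power-of-ten dilution putting the expected colony count at or
# below 300 (targets the 30-300 countable window).
auto_dilution <- function(density, plated_volume) {
  if (density <= 0) return(1)
  10^max(0, ceiling(log10(density * plated_volume / 300)))
}

#' Generate co-culture colony counts under the dilution protocol
#'
#' Runs [run_protocol()] on the given model, converts each cycle-end
#' (pre-dilution) snapshot to an expected plate count at an automatically
#' chosen power-of-ten dilution (targeting 30-300 colonies), and draws
#' observed counts from a Poisson distribution — the standard counting
#' noise model for plated colonies.
#'
#' @param model A [community_model()].
#' @param spec A [protocol_spec()].
#' @param cfg A [synth_config()] (supplies `K`, `plated_volume`, `seed`).
#' @param seed Overrides `cfg$seed` when given.
#' @param solver A [solver_opts()].
#' @return Data frame with one row per cycle and member: `cycle`,
#'   `strain`, `colonies`, `dilution_factor`, `plated_volume`,
#'   `true_density` (CFU/ml) and `seed`.
#' @export
generate_cocult_counts <- function(model, spec, cfg, seed = cfg$seed,
                                   solver = solver_opts(out_dt = 2)) {
  stopifnot(inherits(cfg, "synth_config"))
  traj <- run_protocol(model, spec, solver)
  nm <- colnames(traj$cycle_ends)
  nc <- nrow(traj$cycle_ends)
  rows <- expand.grid(cycle = seq_len(nc), strain = nm,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$true_density <- as.vector(traj$cycle_ends) * cfg$K
  rows$dilution_factor <- vapply(rows$true_density, auto_dilution,
                                 numeric(1), plated_volume = cfg$plated_volume)
  rows$plated_volume <- cfg$plated_volume
  expected <- rows$true_density * cfg$plated_volume / rows$dilution_factor
  with_seed(seed, {
    rows$colonies <- stats::rpois(nrow(rows), expected)
    rows$seed <- seed
    rows[order(rows$cycle, rows$strain), ]
  })
}

#' Generate an antibiotic decay series
#'
#' Emulates cooperator-mediated clearance: the concentration declines
#' linearly in time with slope proportional to the cooperator density,
#' floored at zero, plus additive Gaussian measurement noise.
#'
#' @param initial_conc Starting concentration, ug/l (default 200).
#' @param cooperator_density Cooperator density in CFU/ml.
#' @param clearance_coefficient Clearance per cell: ug/l per hour per
#'   CFU/ml (default 5e-8, an order-of-magnitude scale at which 1e8
#'   CFU/ml clears 200 ug/l within a daily cycle).
#' @param noise_sd Additive Gaussian sigma, ug/l.
#' @param times Sampling times in hours.
#' @param seed Integer seed.
#' @return Data frame with `time`, `concentration` (observed),
#'   `true_concentration` and `seed`.
#' @export
generate_smx_decay <- function(initial_conc = 200, cooperator_density,
                               clearance_coefficient = 5e-8,
                               noise_sd = 0, times = seq(0, 24, by = 2),
                               seed = 1L) {
  stopifnot(initial_conc >= 0, cooperator_density >= 0,
            clearance_coefficient >= 0, noise_sd >= 0)
  true <- pmax(0, initial_conc -
                 clearance_coefficient * cooperator_density * times)
  with_seed(seed, {
    obs <- true + stats::rnorm(length(times), 0, noise_sd)
    data.frame(time = times, concentration = obs, true_concentration = true,
               seed = as.integer(seed))
  })
}
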