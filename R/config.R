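#' Default run configuration
#'
#' The shipped defaults reproduce the reference simulation setup: the
#' two-member cooperator-cheater model (`alpha_AB = 1.9`, `alpha_BA =
#' 1.75`, zero Allee constants, `mu_A = -0.6`, density-protected cheater
#' mortality), daily dilution back to the initial total density, a 168-h
#' run with the antibiotic window at `[72, 96)` h, and the standard sweep
#' and synthetic-data settings.
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = ".",
    log_level = "info",
    model = list(
      members = 2L,
      cooperator = list(growth_rate = 0.5, allee = 0, mu = -0.6),
      cheater = list(growth_rate = 0.75, allee = 0,
                     mu_max = 1.2, d_protect = 0.2),
      regulator = list(growth_rate = 0.75, allee = 0,
                       phenotype = "sensitive"),
      interactions = list(alpha_AB = 1.9, alpha_BA = 1.75,
                          alpha_AC = 0.5, alpha_BC = 1.0)
    ),
    protocol = list(
      cycle_hours = 24, n_cycles = 7L,
      dilution_mode = "to_fixed_total", dilution_factor = 10,
      initial_total_density = 0.01, initial_proportions = NULL,
      antibiotic_window = c(72, 96)
    ),
    solver = list(method = "lsoda", rtol = 1e-8, atol = 1e-12,
                  out_dt = 0.1, extinction_floor = 1e-9, clamp = FALSE),
    sweep = list(
      cheater_rate_range = c(0.25, 0.75), d_range = c(1e-4, 1e-1),
      alpha_ac_range = c(-1, 2), alpha_bc_range = c(-1, 2),
      regulator_rate_range = c(0.25, 1.0),
      phenotypes = c("sensitive", "detoxifying", "intrinsic"),
      n_points = 25L
    ),
    synth = list(
      noise_sd = 0.02, replicates = 6L,
      inoculum_densities = 10^(5:9),
      smx_concentration = 200,
      clearance_coefficient = 5e-8
    )
  ), class = "run_config")
}

# Recursive merge of user values over defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = character(0)) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(paste(c(path, ""), collapse = "/"), unknown,
               sep = "", collapse = ", "))
  }
  for (k in names(user)) {
    val <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      user[[k]]
    }
    # single-bracket assignment keeps keys whose value is NULL
    defaults[k] <- list(val)
  }
  defaults
}

validate_config <- function(cfg) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  m <- cfg$model
  for (s in c("cooperator", "cheater", "regulator")) {
    if (m[[s]]$growth_rate < 0) add(sprintf("model/%s/growth_rate must be >= 0", s))
    if (m[[s]]$allee < 0) add(sprintf("model/%s/allee must be >= 0", s))
  }
  if (m$cheater$mu_max < 0) add("model/cheater/mu_max must be >= 0")
  if (m$cheater$d_protect <= 0) add("model/cheater/d_protect must be > 0")
  if (!m$members %in% c(2L, 3L)) add("model/members must be 2 or 3")
  if (!m$regulator$phenotype %in% c("sensitive", "detoxifying", "intrinsic")) {
    add("model/regulator/phenotype must be sensitive, detoxifying or intrinsic")
  }
  p <- cfg$protocol
  if (p$cycle_hours <= 0) add("protocol/cycle_hours must be > 0")
  if (p$n_cycles < 1) add("protocol/n_cycles must be >= 1")
  if (!p$dilution_mode %in% c("to_fixed_total", "by_factor")) {
    add("protocol/dilution_mode must be to_fixed_total or by_factor")
  }
  if (p$dilution_factor < 1) add("protocol/dilution_factor must be >= 1")
  if (p$initial_total_density <= 0 || p$initial_total_density > 1) {
    add("protocol/initial_total_density must be in (0, 1]")
  }
  if (!is.null(p$initial_proportions)) {
    if (abs(sum(p$initial_proportions) - 1) > 1e-12) {
      add("protocol/initial_proportions must sum to 1")
    }
    if (any(p$initial_proportions < 0)) {
      add("protocol/initial_proportions must be non-negative")
    }
  }
  if (!is.null(p$antibiotic_window)) {
    w <- p$antibiotic_window
    if (length(w) != 2L || w[1] >= w[2]) {
      add("protocol/antibiotic_window must be [start, end) with start < end")
    }
  }
  if (cfg$synth$noise_sd < 0) add("synth/noise_sd must be >= 0")
  if (cfg$sweep$n_points < 1) add("sweep/n_points must be >= 1")
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  invisible(cfg)
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected (all offenders listed); omitted keys fall
#' back to [default_config()]. An empty or sectionless file is an error
#' naming the required sections.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list with all defaults filled in.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user) || length(user) == 0) {
    stop("empty configuration; expected sections: ",
         paste(names(default_config()), collapse = ", "))
  }
  cfg <- merge_config(default_config(), user)
  # YAML scalars arrive untyped; coerce the integer-ish fields
  cfg$seed <- as.integer(cfg$seed)
  cfg$protocol$n_cycles <- as.integer(cfg$protocol$n_cycles)
  cfg$sweep$n_points <- as.integer(cfg$sweep$n_points)
  if (is.list(cfg$protocol$antibiotic_window)) {
    cfg$protocol$antibiotic_window <- unlist(cfg$protocol$antibiotic_window)
  }
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  cfg
}

#' Write the fully resolved configuration back to YAML
#'
#' Round-trip contract: `parse_config(echo_config(cfg, f))` reproduces the
#' identical resolved configuration.
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @export
echo_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build the community model described by a configuration
#'
#' @param cfg A `run_config`.
#' @return A [community_model()] with 2 or 3 members as configured.
#' @export
build_model <- function(cfg) {
  m <- cfg$model
  w <- cfg$protocol$antibiotic_window %||% c(72, 96)
  if (m$members == 2L) {
    kin_pair_model(cooperator_rate = m$cooperator$growth_rate,
                   cheater_rate = m$cheater$growth_rate,
                   alpha_AB = m$interactions$alpha_AB,
                   alpha_BA = m$interactions$alpha_BA,
                   allee_A = m$cooperator$allee, allee_B = m$cheater$allee,
                   mu_A = m$cooperator$mu,
                   mu_B_max = m$cheater$mu_max,
                   D_protect = m$cheater$d_protect, window = w)
  } else {
    kin_trio_model(alpha_AC = m$interactions$alpha_AC,
                   alpha_BC = m$interactions$alpha_BC,
                   regulator_phenotype = m$regulator$phenotype,
                   regulator_rate = m$regulator$growth_rate,
                   cooperator_rate = m$cooperator$growth_rate,
                   cheater_rate = m$cheater$growth_rate,
                   alpha_AB = m$interactions$alpha_AB,
                   alpha_BA = m$interactions$alpha_BA,
                   allee_A = m$cooperator$allee, allee_B = m$cheater$allee,
                   allee_C = m$regulator$allee,
                   mu_A = m$cooperator$mu,
                   mu_B_max = m$cheater$mu_max,
                   D_protect = m$cheater$d_protect, window = w)
  }
}

#' Build the protocol described by a configuration
#'
#' @param cfg A `run_config`.
#' @return A [protocol_spec()].
#' @export
build_protocol <- function(cfg) {
  p <- cfg$protocol
  protocol_spec(cycle_hours = p$cycle_hours, n_cycles = p$n_cycles,
                dilution_mode = p$dilution_mode,
                dilution_factor = p$dilution_factor,
                initial_total_density = p$initial_total_density,
                initial_proportions = p$initial_proportions,
                antibiotic_window = p$antibiotic_window)
}

build_solver <- function(cfg) {
  s <- cfg$solver
  solver_opts(method = s$method, rtol = s$rtol, atol = s$atol,
              out_dt = s$out_dt, extinction_floor = s$extinction_floor,
              clamp = isTRUE(s$clamp))
}

#' Run a named analysis stage and write its outputs
#'
#' Thin driver over the package functions: builds the model and protocol
#' from the configuration, runs the requested stage, and writes the
#' documented tables plus a resolved-config echo and a small run log into
#' `out_dir`.
#'
#' Commands: `"simulate"` (trajectory + snapshot tables), `"sweep2"`
#' (two-member phase diagram), `"sweep3"` (three-member diagrams, one per
#' phenotype), `"classify"` (outcome of the configured run), `"growthfit"`
#' (synthetic OD curves, per-well growth rates and rate-vs-density fit),
#' `"synth"` (all three synthetic datasets).
#'
#' @param command Stage name.
#' @param cfg A `run_config` (see [parse_config()], [default_config()]).
#' @param out_dir Output directory (default from the configuration).
#' @return Invisibly, a character vector of the files written.
#' @export
run_command <- function(command = c("simulate", "sweep2", "sweep3",
                                    "classify", "growthfit", "synth"),
                        cfg = default_config(), out_dir = cfg$output_dir) {
  command <- match.arg(command)
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- character(0)
  emit <- function(name) {
    f <- file.path(out_dir, name)
    files <<- c(files, f)
    f
  }
  solver <- build_solver(cfg)
  sweep_solver <- build_solver(cfg)
  sweep_solver$out_dt <- max(sweep_solver$out_dt, 2)

  if (command == "simulate") {
    traj <- run_protocol(build_model(cfg), build_protocol(cfg), solver)
    write_trajectory(traj, emit("trajectory.csv"))
    utils::write.csv(cycle_snapshots(traj), emit("snapshots.csv"),
                     row.names = FALSE)
  } else if (command == "sweep2") {
    cfg2 <- cfg
    cfg2$model$members <- 2L
    pd <- sweep_two_member(build_model(cfg2), build_protocol(cfg),
                           cheater_rate_range = cfg$sweep$cheater_rate_range,
                           D_range = cfg$sweep$d_range,
                           n_points = cfg$sweep$n_points,
                           solver = sweep_solver)
    write_phase_diagram(pd, emit("phase_two_member.csv"))
  } else if (command == "sweep3") {
    cfg3 <- cfg
    cfg3$model$members <- 3L
    pds <- sweep_three_member(build_model(cfg3), build_protocol(cfg),
                              alpha_AC_range = cfg$sweep$alpha_ac_range,
                              alpha_BC_range = cfg$sweep$alpha_bc_range,
                              phenotypes = cfg$sweep$phenotypes,
                              n_points = cfg$sweep$n_points,
                              solver = sweep_solver)
    for (ph in names(pds)) {
      write_phase_diagram(pds[[ph]],
                          emit(sprintf("phase_three_member_%s.csv", ph)))
    }
  } else if (command == "classify") {
    traj <- run_protocol(build_model(cfg), build_protocol(cfg), solver)
    out <- classify_coexistence(traj)
    utils::write.csv(
      data.frame(category = out$category, dominant = out$dominant,
                 member = names(out$per_member_decline) %||%
                   seq_along(out$per_member_decline),
                 final_cycle_decline = out$per_member_decline),
      emit("outcome.csv"), row.names = FALSE)
  } else if (command == "growthfit") {
    cfg_s <- synth_config(noise_sd = cfg$synth$noise_sd,
                          inoculum_densities = cfg$synth$inoculum_densities,
                          smx_concentration = cfg$synth$smx_concentration,
                          seed = cfg$seed)
    gen <- generate_od_curves(cfg_s, replicates = cfg$synth$replicates)
    est <- growth_rate_table(gen$od)
    utils::write.csv(est, emit("growth_rates.csv"), row.names = FALSE)
    ok <- !est$censored & !est$smx
    fit <- fit_linear(log10(est$initial_density[ok]), est$rate[ok])
    utils::write.csv(
      data.frame(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, n = fit$n),
      emit("rate_vs_density_fit.csv"), row.names = FALSE)
  } else if (command == "synth") {
    cfg_s <- synth_config(noise_sd = cfg$synth$noise_sd,
                          inoculum_densities = cfg$synth$inoculum_densities,
                          smx_concentration = cfg$synth$smx_concentration,
                          seed = cfg$seed)
    gen <- generate_od_curves(cfg_s, replicates = cfg$synth$replicates)
    utils::write.csv(gen$od, emit("synth_od.csv"), row.names = FALSE)
    utils::write.csv(gen$truth, emit("synth_od_truth.csv"), row.names = FALSE)
    counts <- generate_cocult_counts(build_model(cfg), build_protocol(cfg),
                                     cfg_s)
    utils::write.csv(counts, emit("synth_cfu.csv"), row.names = FALSE)
    decay <- generate_smx_decay(
      initial_conc = cfg$synth$smx_concentration,
      cooperator_density = cfg$protocol$initial_total_density * cfg_s$K,
      clearance_coefficient = cfg$synth$clearance_coefficient,
      noise_sd = 5, seed = cfg$seed)
    utils::write.csv(decay, emit("synth_smx_decay.csv"), row.names = FALSE)
  }

  echo_config(cfg, emit("config_echo.yaml"))
  writeLines(c(
    sprintf("command: %s", command),
    sprintf("seed: %d", cfg$seed),
    sprintf("runtime_s: %.2f", as.numeric(Sys.time() - t0, units = "secs")),
    sprintf("files: %s", paste(basename(files), collapse = ", "))
  ), emit("run_log.txt"))
  invisible(files)
}

#' Classify coexistence from a colony-count table
#'
#' Reconstructs per-cycle member densities from plate counts via
#' [cfu_per_ml()] and applies the final-cycle decline rule. The
#' post-dilution start of the final cycle is inferred from the previous
#' cycle's end and the protocol's dilution rule.
#'
#' @param cfu_table Data frame with columns `cycle`, `strain`, `colonies`,
#'   `dilution_factor`, `plated_volume`.
#' @param spec The [protocol_spec()] the counts were collected under.
#' @param decline_threshold Fractional decline cut-off (default 0.20).
#' @param K Carrying capacity used to normalize densities (default 1e9).
#' @return An `outcome_label`.
#' @export
classify_cfu_table <- function(cfu_table, spec, decline_threshold = 0.20,
                               K = 1e9) {
  need <- c("cycle", "strain", "colonies", "dilution_factor", "plated_volume")
  missing <- setdiff(need, names(cfu_table))
  if (length(missing)) {
    stop("CFU table lacks columns: ", paste(missing, collapse = ", "))
  }
  cfu_table$density <- as.numeric(
    cfu_per_ml(cfu_table$colonies, cfu_table$dilution_factor,
               cfu_table$plated_volume))
  wide <- stats::xtabs(density ~ cycle + strain, data = cfu_table)
  nc <- nrow(wide)
  if (nc < 2L) stop("need at least two cycles of counts")
  prev <- wide[nc - 1L, ] / K
  ends <- wide[nc, ] / K
  starts <- if (spec$dilution_mode == "by_factor") {
    prev / spec$dilution_factor
  } else {
    if (sum(prev) <= 0) prev * 0 else
      prev * (spec$initial_total_density / sum(prev))
  }
  extinct <- ends <= 0
  decline <- ifelse(starts > 0, (starts - ends) / starts, NA_real_)
  over <- decline > decline_threshold + 1e-12
  category <- if (all(extinct)) "collapse"
  else if (any(extinct) || any(over, na.rm = TRUE))
    "exclusion"
  else "coexistence"
  dominant <- if (category == "exclusion") {
    dominant_member(stats::setNames(as.numeric(ends), colnames(wide)))
  } else NA_character_
  structure(list(category = category, dominant = dominant,
                 per_member_decline = stats::setNames(as.numeric(decline),
                                                      colnames(wide)),
                 decline_threshold = decline_threshold,
                 baseline = "final_cycle_start"),
            class = "outcome_label")
}
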