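#' Serial-dilution protocol specification
#'
#' Describes the batch-culture regime: daily growth cycles each ended by a
#' dilution event, with an optional pulsed antibiotic window expressed in
#' absolute hours. Two dilution modes are supported: `"to_fixed_total"`
#' rescales the community back to the initial total density while keeping
#' composition (the simulation convention), `"by_factor"` divides every
#' member by a fixed factor (the plate-transfer convention, default
#' 10-fold).
#'
#' @param cycle_hours Cycle duration in hours (default 24).
#' @param n_cycles Number of cycles (7 for the 168-h reference runs, 5 for
#'   coexistence classification runs).
#' @param dilution_mode `"to_fixed_total"` or `"by_factor"`.
#' @param dilution_factor Factor for `"by_factor"` mode (default 10).
#' @param initial_total_density Normalized initial total density `D`
#'   (fraction of `K = 1e9` CFU/ml).
#' @param initial_proportions Per-member fractions summing to 1; `NULL`
#'   (default) means equal proportions.
#' @param antibiotic_window `c(start, end)` in absolute hours, or `NULL`
#'   for no antibiotic pulse at all. The window overrides the windows
#'   stored in the model's death models when the protocol is run.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(cycle_hours = 24, n_cycles = 7,
                          dilution_mode = c("to_fixed_total", "by_factor"),
                          dilution_factor = 10,
                          initial_total_density = 1e-2,
                          initial_proportions = NULL,
                          antibiotic_window = c(72, 96)) {
  dilution_mode <- match.arg(dilution_mode)
  stopifnot(cycle_hours > 0, n_cycles >= 1, n_cycles == as.integer(n_cycles),
            dilution_factor >= 1,
            initial_total_density > 0, initial_total_density <= 1)
  if (!is.null(initial_proportions)) {
    stopifnot(is.numeric(initial_proportions), all(initial_proportions >= 0))
    if (abs(sum(initial_proportions) - 1) > 1e-12) {
      stop("'initial_proportions' must sum to 1 (within 1e-12)")
    }
  }
  if (!is.null(antibiotic_window)) {
    stopifnot(is.numeric(antibiotic_window), length(antibiotic_window) == 2L)
    if (antibiotic_window[1] >= antibiotic_window[2]) {
      stop("antibiotic window start must precede its end")
    }
  }
  structure(list(cycle_hours = cycle_hours, n_cycles = as.integer(n_cycles),
                 dilution_mode = dilution_mode,
                 dilution_factor = dilution_factor,
                 initial_total_density = initial_total_density,
                 initial_proportions = initial_proportions,
                 antibiotic_window = antibiotic_window),
            class = "protocol_spec")
}

#' Numerical solver settings
#'
#' @param method deSolve integration method (default `"lsoda"`,
#'   stiff-capable with automatic switching).
#' @param rtol,atol Relative and absolute tolerances.
#' @param out_dt Output resolution in hours (dense output grid).
#' @param extinction_floor Normalized abundance below which a member is
#'   considered extinct (default 1e-9, about one cell per ml at `K = 1e9`).
#'   Used by the outcome classifier and, when `clamp = TRUE`, as a hard
#'   clamp-to-zero during integration.
#' @param clamp If `TRUE`, members crossing the floor during integration
#'   are set to exactly zero for the rest of the run (root-triggered
#'   event). The default `FALSE` keeps abundances continuous, matching the
#'   plain-ODE treatment in which arbitrarily rare members can rebound
#'   after a perturbation; see the methods vignette for the trade-off.
#' @return A list of class `solver_opts`.
#' @export
solver_opts <- function(method = "lsoda", rtol = 1e-8, atol = 1e-12,
                        out_dt = 0.1, extinction_floor = 1e-9,
                        clamp = FALSE) {
  stopifnot(rtol > 0, atol > 0, out_dt > 0, extinction_floor >= 0)
  structure(list(method = method, rtol = rtol, atol = atol, out_dt = out_dt,
                 extinction_floor = extinction_floor, clamp = isTRUE(clamp)),
            class = "solver_opts")
}

# Integrate one sub-segment with piecewise-constant death rates, clamping
# members to zero when they cross the extinction floor (deSolve root event).
integrate_segment <- function(model, state0, times, mu, floor, clamp) {
  parms <- list(rates = model$rates, a = model$allee, alpha = model$alpha,
                mu = mu, floor = floor)
  func <- function(t, y, p) {
    y[y < 0] <- 0
    list(rhs_core(y, p$rates, p$a, p$alpha, p$mu))
  }
  args <- list(y = state0, times = times, func = func, parms = parms,
               method = attr(model, "method") %||% "lsoda",
               rtol = attr(model, "rtol") %||% 1e-8,
               atol = attr(model, "atol") %||% 1e-12)
  if (clamp) {
    args$rootfunc <- function(t, y, p) y - p$floor
    args$events <- list(func = function(t, y, p) {
      y[y <= p$floor] <- 0
      y
    }, root = TRUE)
  }
  out <- do.call(deSolve::ode, args)
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("ODE solver failed at t = %.3f h (state: %s)",
                 out[nrow(out), 1],
                 paste(signif(out[nrow(out), -1], 4), collapse = ", ")))
  }
  m <- unname(as.matrix(out[, -1, drop = FALSE]))
  if (!is.matrix(m)) m <- matrix(m, ncol = length(state0))
  m[m < 0] <- 0
  if (clamp) m[m < floor] <- 0
  list(times = out[, 1], states = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate the community through one growth cycle
#'
#' Solves the modified Lotka-Volterra system on `[t0, t1]` with deSolve,
#' splitting the interval at antibiotic-window boundaries so the death term
#' is piecewise constant within each solver call. Members that fall below
#' the extinction floor are clamped to exactly zero for the remainder of
#' the cycle (root-triggered event).
#'
#' @param model A [community_model()] (death-model windows already set).
#' @param state0 Non-negative state at `t0` (entries below the floor are
#'   treated as zero).
#' @param t0,t1 Absolute start and end times, hours, `t0 < t1`.
#' @param D Normalized initial total density of the run (for the
#'   linear-in-density death kind).
#' @param solver A [solver_opts()] list.
#' @return List with `times` and a `states` matrix (rows = times).
#' @export
integrate_cycle <- function(model, state0, t0, t1, D = sum(state0),
                            solver = solver_opts()) {
  stopifnot(inherits(model, "community_model"), t0 < t1,
            length(state0) == model$n_members, all(state0 >= 0),
            all(is.finite(state0)))
  if (solver$clamp) state0[state0 < solver$extinction_floor] <- 0
  names(state0) <- model$member_names
  edges <- unlist(lapply(model$deaths,
                         function(d) c(d$window_start, d$window_end)))
  cuts <- sort(unique(edges[edges > t0 & edges < t1]))
  bounds <- c(t0, cuts, t1)
  attr(model, "method") <- solver$method
  attr(model, "rtol") <- solver$rtol
  attr(model, "atol") <- solver$atol

  all_t <- numeric(0)
  all_s <- NULL
  state <- state0
  for (k in seq_len(length(bounds) - 1L)) {
    s0 <- bounds[k]; s1 <- bounds[k + 1L]
    tt <- unique(c(seq(s0, s1, by = solver$out_dt), s1))
    if (length(tt) < 2L) tt <- c(s0, s1)
    tm <- (s0 + s1) / 2
    mu <- vapply(model$deaths, effective_death_rate, numeric(1), t = tm, D = D)
    seg <- integrate_segment(model, state, tt, mu, solver$extinction_floor,
                             solver$clamp)
    keep <- if (k == 1L) seq_along(seg$times) else -1L
    all_t <- c(all_t, seg$times[keep])
    all_s <- rbind(all_s, seg$states[keep, , drop = FALSE])
    state <- seg$states[nrow(seg$states), ]
  }
  colnames(all_s) <- model$member_names
  list(times = all_t, states = all_s)
}

#' Apply a dilution event
#'
#' Rescales the state at a cycle boundary, preserving composition exactly.
#' `"to_fixed_total"` returns the community to the protocol's initial total
#' density; `"by_factor"` divides every member by the dilution factor.
#' Members at zero stay at zero; members landing below the extinction floor
#' are clamped to zero.
#'
#' @param state Non-negative numeric state vector (pre-dilution).
#' @param spec A [protocol_spec()].
#' @param extinction_floor Clamp threshold; the default 0 leaves arbitrarily
#'   small positive abundances intact (set to the solver floor when running
#'   with hard extinction clamping).
#' @return Post-dilution state vector.
#' @export
apply_dilution <- function(state, spec, extinction_floor = 0) {
  stopifnot(inherits(spec, "protocol_spec"), all(state >= 0))
  if (spec$dilution_mode == "by_factor") {
    out <- state / spec$dilution_factor
  } else {
    total <- sum(state)
    if (total <= 0) {
      warning("community collapsed: zero total density at dilution")
      return(state * 0)
    }
    out <- state * (spec$initial_total_density / total)
  }
  out[out < extinction_floor] <- 0
  out
}

#' Run the full serial-dilution protocol
#'
#' Alternates [integrate_cycle()] and [apply_dilution()] for
#' `spec$n_cycles` cycles, with the antibiotic death term active only where
#' absolute time falls inside `spec$antibiotic_window`. Deterministic given
#' inputs and solver options.
#'
#' @param model A [community_model()].
#' @param spec A [protocol_spec()].
#' @param solver A [solver_opts()] list.
#' @return An object of class `community_trajectory`: fields `times`,
#'   `abundances` (matrix, one column per member), `cycle`, `phase`
#'   (`cycle_start` / `within_cycle` / `cycle_end`), snapshot matrices
#'   `cycle_starts` (post-dilution) and `cycle_ends` (pre-dilution), and
#'   provenance (`model`, `protocol`, `solver`, `D`).
#' @export
run_protocol <- function(model, spec, solver = solver_opts()) {
  stopifnot(inherits(model, "community_model"), inherits(spec, "protocol_spec"))
  n <- model$n_members
  model <- set_antibiotic_window(model, spec$antibiotic_window)
  props <- spec$initial_proportions %||% rep(1 / n, n)
  if (length(props) != n) stop("initial_proportions length must match members")
  D <- spec$initial_total_density
  state <- D * props
  dil_floor <- if (solver$clamp) solver$extinction_floor else 0
  state[state < dil_floor] <- 0

  times <- numeric(0)
  ab <- NULL
  cyc <- integer(0)
  phase <- character(0)
  starts <- matrix(NA_real_, spec$n_cycles, n,
                   dimnames = list(NULL, model$member_names))
  ends <- starts
  for (k in seq_len(spec$n_cycles)) {
    t0 <- (k - 1) * spec$cycle_hours
    t1 <- k * spec$cycle_hours
    starts[k, ] <- state
    seg <- integrate_cycle(model, state, t0, t1, D = D, solver = solver)
    np <- length(seg$times)
    times <- c(times, seg$times)
    ab <- rbind(ab, seg$states)
    cyc <- c(cyc, rep.int(k, np))
    phase <- c(phase, c("cycle_start", rep("within_cycle", max(0, np - 2L)),
                        "cycle_end"))
    ends[k, ] <- seg$states[np, ]
    state <- apply_dilution(ends[k, ], spec, dil_floor)
  }
  structure(list(times = times, abundances = ab, cycle = cyc, phase = phase,
                 cycle_starts = starts, cycle_ends = ends,
                 model = model, protocol = spec, solver = solver, D = D),
            class = "community_trajectory")
}

#' @export
print.community_trajectory <- function(x, ...) {
  cat(sprintf("Serial-dilution trajectory: %d members, %d cycles of %g h (%g h total)\n",
              ncol(x$abundances), x$protocol$n_cycles, x$protocol$cycle_hours,
              x$protocol$n_cycles * x$protocol$cycle_hours))
  w <- x$protocol$antibiotic_window
  cat(if (is.null(w)) "No antibiotic pulse\n" else
    sprintf("Antibiotic window: [%g, %g) h\n", w[1], w[2]))
  cat("Final pre-dilution state:\n")
  print(signif(x$cycle_ends[x$protocol$n_cycles, ], 4))
  invisible(x)
}

#' @export
as.data.frame.community_trajectory <- function(x, ...) {
  nm <- colnames(x$abundances)
  do.call(rbind, lapply(seq_along(nm), function(j) {
    data.frame(time_h = x$times, member = nm[j],
               abundance = x$abundances[, j],
               cycle = x$cycle, phase = x$phase)
  }))
}

#' Per-cycle snapshot summary
#'
#' @param traj A `community_trajectory`.
#' @return Data frame with one row per cycle and member: post-dilution
#'   start, pre-dilution end and within-cycle fold change.
#' @export
cycle_snapshots <- function(traj) {
  stopifnot(inherits(traj, "community_trajectory"))
  nm <- colnames(traj$abundances)
  nc <- nrow(traj$cycle_starts)
  out <- expand.grid(cycle = seq_len(nc), member = nm,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$start <- as.vector(traj$cycle_starts)
  out$end <- as.vector(traj$cycle_ends)
  out$fold_change <- ifelse(out$start > 0, out$end / out$start, NA_real_)
  out[order(out$cycle, out$member), ]
}

#' Plot a trajectory
#'
#' @param x A `community_trajectory`.
#' @param log Use a log abundance axis (default TRUE).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.community_trajectory <- function(x, log = TRUE, ...) {
  ab <- x$abundances
  if (log) {
    ab[ab <= 0] <- NA
    graphics::matplot(x$times, ab, type = "l", lty = 1, log = "y",
                      xlab = "time (h)", ylab = "normalized abundance", ...)
  } else {
    graphics::matplot(x$times, ab, type = "l", lty = 1,
                      xlab = "time (h)", ylab = "normalized abundance", ...)
  }
  w <- x$protocol$antibiotic_window
  if (!is.null(w)) graphics::abline(v = w, lty = 3)
  graphics::legend("bottomright", legend = colnames(x$abundances),
                   col = seq_len(ncol(x$abundances)), lty = 1, bty = "n")
  invisible(x)
}

#' Write a trajectory as long-format CSV
#'
#' Columns: `time_h`, `member`, `abundance`, `cycle`, `phase`.
#'
#' @param traj A `community_trajectory`.
#' @param file Output path.
#' @export
write_trajectory <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}

#' First cycle in which a member crosses the extinction floor
#'
#' @param traj A `community_trajectory`.
#' @param member Member name or index.
#' @param floor Extinction threshold; defaults to the trajectory's solver
#'   floor (1e-9 normalized, about one cell per ml).
#' @return Index of the first cycle whose trajectory drops below the
#'   threshold, or `NA` if the member never goes extinct.
#' @export
extinction_cycle <- function(traj, member, floor = traj$solver$extinction_floor) {
  j <- if (is.character(member)) match(member, colnames(traj$abundances)) else member
  stopifnot(!is.na(j))
  gone <- traj$cycle[traj$abundances[, j] < floor]
  if (length(gone) == 0) NA_integer_ else min(gone)
}
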