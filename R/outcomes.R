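#' Classify a trajectory as coexistence, exclusion or collapse
#'
#' Operational coexistence rule: the community coexists iff no member's
#' population declined by strictly more than `decline_threshold` (default
#' 20%) over the final growth cycle and no member is extinct. A member's
#' decline is measured from its post-dilution abundance at the start of the
#' final cycle to its pre-dilution abundance at the end of that cycle
#' (`baseline = "final_cycle_start"`, the default); the alternative
#' `"global_initial"` baseline compares against the member's share of the
#' run's initial inoculum instead. Communities failing the rule are
#' labelled `"exclusion"` (with the dominant surviving member), or
#' `"collapse"` when every member is extinct.
#'
#' @param traj A `community_trajectory` from [run_protocol()], with at
#'   least one complete cycle.
#' @param decline_threshold Fractional decline above which a member is
#'   considered on a pathway to extinction (strict inequality).
#' @param baseline `"final_cycle_start"` or `"global_initial"`.
#' @param extinction_floor Abundance below which a member counts as
#'   extinct; defaults to the trajectory's solver floor.
#' @return An object of class `outcome_label`: list with `category`
#'   (`"coexistence"`, `"exclusion"`, `"collapse"`), `dominant` (member
#'   label, or `NA` when coexisting/collapsed) and `per_member_decline`
#'   (fractional decline over the final cycle; negative values are growth).
#' @export
classify_coexistence <- function(traj, decline_threshold = 0.20,
                                 baseline = c("final_cycle_start",
                                              "global_initial"),
                                 extinction_floor = traj$solver$extinction_floor) {
  stopifnot(inherits(traj, "community_trajectory"))
  baseline <- match.arg(baseline)
  nc <- nrow(traj$cycle_ends)
  if (is.null(nc) || nc < 1) stop("trajectory has no complete cycle")
  ends <- traj$cycle_ends[nc, ]
  starts <- if (baseline == "final_cycle_start") {
    traj$cycle_starts[nc, ]
  } else {
    traj$cycle_starts[1, ]
  }
  extinct <- ends < extinction_floor
  decline <- ifelse(starts > 0, (starts - ends) / starts, NA_real_)
  # strict inequality with a float guard: a decline of exactly the
  # threshold still counts as coexisting
  over <- decline > decline_threshold + 1e-12
  category <- if (all(extinct)) {
    "collapse"
  } else if (any(extinct) || any(over, na.rm = TRUE)) {
    "exclusion"
  } else {
    "coexistence"
  }
  dominant <- if (category == "exclusion") dominant_member(ends) else NA_character_
  structure(list(category = category, dominant = dominant,
                 per_member_decline = decline,
                 decline_threshold = decline_threshold, baseline = baseline),
            class = "outcome_label")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat("Outcome:", x$category)
  if (!is.na(x$dominant)) cat(" (dominant:", x$dominant, ")")
  cat("\nFinal-cycle decline per member (negative = growth):\n")
  print(signif(x$per_member_decline, 3))
  invisible(x)
}

#' Member with the largest abundance
#'
#' Ties are broken in favour of the lowest member index, with a message.
#'
#' @param state Named (or unnamed) non-negative abundance vector with at
#'   least one positive entry.
#' @return The dominant member's label (name if available, else index as
#'   character).
#' @export
dominant_member <- function(state) {
  stopifnot(is.numeric(state), all(state >= 0))
  if (all(state <= 0)) stop("all members extinct: community collapsed")
  i <- which(state == max(state))
  if (length(i) > 1L) {
    message("dominance tie between members ", paste(i, collapse = ", "),
            "; breaking toward the lowest index")
    i <- i[1L]
  }
  if (!is.null(names(state))) names(state)[i] else as.character(i)
}

# Interaction regime of a mutual coefficient pair, under the equations'
# minus-sign convention (positive alpha = inhibition).
interaction_regime <- function(a1, a2) {
  if (a1 > 0 && a2 > 0) "competition"
  else if (a1 < 0 && a2 < 0) "mutualism"
  else if (a1 * a2 < 0) "exploitation"
  else "neutral"
}

#' Two-member phase diagram: cheater growth rate vs initial density
#'
#' Runs the full serial-dilution protocol at every grid point of a
#' (cheater growth rate, initial total density) grid and records both the
#' dominant member at the final pre-dilution snapshot and the coexistence
#' category. The density axis is log-spaced; the initial density sets both
#' the integration initial condition and the cheater's density-dependent
#' pulse mortality.
#'
#' @param template A two-member [community_model()] with a `"cheater"`
#'   member.
#' @param spec A [protocol_spec()]; its `initial_total_density` is
#'   overridden by the density axis.
#' @param cheater_rate_range Length-2 range of cheater growth rates
#'   (per hour), linear axis.
#' @param D_range Length-2 range of normalized initial densities, log axis.
#' @param n_points Grid resolution per axis (length 1 or 2: rate axis,
#'   density axis). The reference resolution is 500; reduced grids use the
#'   identical code path.
#' @param solver A [solver_opts()]; sweeps default to a coarser output
#'   grid since only cycle snapshots feed the labels.
#' @return An object of class `phase_diagram` with fields `axes`, `grid`
#'   (one row per cell: axis values, `category`, `dominant`) and
#'   provenance.
#' @export
sweep_two_member <- function(template, spec,
                             cheater_rate_range = c(0.25, 0.75),
                             D_range = c(1e-4, 1e-1),
                             n_points = 25,
                             solver = solver_opts(out_dt = 2)) {
  stopifnot(inherits(template, "community_model"), template$n_members == 2L)
  ich <- which(template$roles == "cheater")
  if (length(ich) != 1L) stop("template must contain exactly one cheater")
  n_points <- rep_len(as.integer(n_points), 2L)
  stopifnot(all(n_points >= 1L))
  rates <- seq(cheater_rate_range[1], cheater_rate_range[2],
               length.out = n_points[1])
  Ds <- 10^seq(log10(D_range[1]), log10(D_range[2]),
               length.out = n_points[2])
  cells <- expand.grid(cheater_rate = rates, initial_density = Ds,
                       KEEP.OUT.ATTRS = FALSE)
  lab <- lapply(seq_len(nrow(cells)), function(k) {
    m <- set_growth_rate(template, ich, cells$cheater_rate[k])
    sp <- spec
    sp$initial_total_density <- cells$initial_density[k]
    tryCatch(suppressMessages({
      tr <- run_protocol(m, sp, solver)
      out <- classify_coexistence(tr)
      fin <- tr$cycle_ends[nrow(tr$cycle_ends), ]
      dom <- if (all(fin <= 0)) NA_character_ else dominant_member(fin)
      list(category = out$category, dominant = dom)
    }), error = function(e) list(category = "error", dominant = NA_character_))
  })
  cells$category <- vapply(lab, `[[`, character(1), "category")
  cells$dominant <- vapply(lab, `[[`, character(1), "dominant")
  structure(list(
    axes = list(
      x = list(name = "cheater_growth_rate", scale = "linear", values = rates),
      y = list(name = "initial_density", scale = "log", values = Ds)
    ),
    grid = cells,
    template = template, protocol = spec, solver = solver
  ), class = "phase_diagram")
}

#' Three-member phase diagrams: regulator interactions and growth rate
#'
#' For each regulator phenotype, runs the coexistence protocol over a grid
#' of mutual interaction coefficients (`axes = "interactions"`: alpha_AC
#' vs alpha_BC, both mirror-symmetric) or over regulator growth rate vs
#' alpha_BC (`axes = "growth_rate"`, with alpha_AC fixed at the template's
#' value). Every cell is labelled by [classify_coexistence()] and annotated
#' with its interaction regime (competition / mutualism / exploitation).
#'
#' @param template A three-member [community_model()] (see
#'   [kin_trio_model()]); the regulator death rate is replaced per
#'   phenotype (sensitive 0.8, detoxifying -0.3, intrinsic 0).
#' @param spec A [protocol_spec()] for the coexistence runs.
#' @param alpha_AC_range,alpha_BC_range Ranges for the interaction axes
#'   (spanning both signs to cover all regimes).
#' @param regulator_rate_range Range for the growth-rate axis (only used
#'   for `axes = "growth_rate"`).
#' @param phenotypes Character vector of regulator phenotypes to sweep.
#' @param n_points Grid resolution per axis (length 1 or 2).
#' @param axes `"interactions"` or `"growth_rate"`.
#' @param solver A [solver_opts()].
#' @return Named list of `phase_diagram` objects, one per phenotype.
#' @export
sweep_three_member <- function(template, spec,
                               alpha_AC_range = c(-1, 2),
                               alpha_BC_range = c(-1, 2),
                               regulator_rate_range = c(0.25, 1.0),
                               phenotypes = c("sensitive", "detoxifying",
                                              "intrinsic"),
                               n_points = 25,
                               axes = c("interactions", "growth_rate"),
                               solver = solver_opts(out_dt = 2)) {
  axes <- match.arg(axes)
  stopifnot(inherits(template, "community_model"), template$n_members == 3L)
  ireg <- which(template$roles == "regulator")
  iA <- which(template$roles == "cooperator")
  iB <- which(template$roles == "cheater")
  if (length(ireg) != 1L || length(iA) != 1L || length(iB) != 1L) {
    stop("template must contain one cooperator, one cheater and one regulator")
  }
  phenotypes <- match.arg(phenotypes, several.ok = TRUE)
  n_points <- rep_len(as.integer(n_points), 2L)
  mu_by_ph <- c(sensitive = 0.8, detoxifying = -0.3, intrinsic = 0)

  run_cell <- function(m, sp) {
    tryCatch(suppressMessages({
      out <- classify_coexistence(run_protocol(m, sp, solver))
      list(category = out$category, dominant = out$dominant)
    }), error = function(e) list(category = "error", dominant = NA_character_))
  }

  out <- lapply(phenotypes, function(ph) {
    tmpl <- template
    w <- c(tmpl$deaths[[ireg]]$window_start, tmpl$deaths[[ireg]]$window_end)
    tmpl$deaths[[ireg]] <- death_constant(mu_by_ph[[ph]], w)
    if (axes == "interactions") {
      xs <- seq(alpha_AC_range[1], alpha_AC_range[2], length.out = n_points[1])
      ys <- seq(alpha_BC_range[1], alpha_BC_range[2], length.out = n_points[2])
      cells <- expand.grid(alpha_AC = xs, alpha_BC = ys,
                           KEEP.OUT.ATTRS = FALSE)
      lab <- lapply(seq_len(nrow(cells)), function(k) {
        m <- set_interaction_pair(tmpl, iA, ireg, cells$alpha_AC[k])
        m <- set_interaction_pair(m, iB, ireg, cells$alpha_BC[k])
        run_cell(m, spec)
      })
      cells$regime <- mapply(interaction_regime, cells$alpha_AC,
                             cells$alpha_BC)
      ax <- list(
        x = list(name = "alpha_AC", scale = "linear", values = xs),
        y = list(name = "alpha_BC", scale = "linear", values = ys)
      )
    } else {
      xs <- seq(regulator_rate_range[1], regulator_rate_range[2],
                length.out = n_points[1])
      ys <- seq(alpha_BC_range[1], alpha_BC_range[2], length.out = n_points[2])
      cells <- expand.grid(regulator_rate = xs, alpha_BC = ys,
                           KEEP.OUT.ATTRS = FALSE)
      aAC <- tmpl$alpha[iA, ireg]
      lab <- lapply(seq_len(nrow(cells)), function(k) {
        m <- set_growth_rate(tmpl, ireg, cells$regulator_rate[k])
        m <- set_interaction_pair(m, iB, ireg, cells$alpha_BC[k])
        run_cell(m, spec)
      })
      cells$regime <- vapply(cells$alpha_BC, interaction_regime,
                             character(1), a2 = aAC)
      ax <- list(
        x = list(name = "regulator_rate", scale = "linear", values = xs),
        y = list(name = "alpha_BC", scale = "linear", values = ys)
      )
    }
    cells$category <- vapply(lab, `[[`, character(1), "category")
    cells$dominant <- vapply(lab, `[[`, character(1), "dominant")
    structure(list(axes = ax, grid = cells, phenotype = ph,
                   template = tmpl, protocol = spec, solver = solver),
              class = "phase_diagram")
  })
  names(out) <- phenotypes
  out
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram: %s (%d points) x %s (%d points)\n",
              x$axes$x$name, length(x$axes$x$values),
              x$axes$y$name, length(x$axes$y$values)))
  if (!is.null(x$phenotype)) cat("Regulator phenotype:", x$phenotype, "\n")
  print(table(x$grid$category))
  invisible(x)
}

#' Plot a phase diagram as a raster of outcome categories
#'
#' @param x A `phase_diagram`.
#' @param what Grid column to display (`"category"` or `"dominant"`).
#' @param ... Passed to [graphics::image()].
#' @export
plot.phase_diagram <- function(x, what = c("category", "dominant"), ...) {
  what <- match.arg(what)
  v <- factor(x$grid[[what]])
  z <- matrix(as.integer(v), nrow = length(x$axes$x$values))
  cols <- grDevices::hcl.colors(max(nlevels(v), 2L), "viridis")
  ylab <- x$axes$y$name
  yv <- x$axes$y$values
  if (identical(x$axes$y$scale, "log")) {
    yv <- log10(yv)
    ylab <- paste0("log10 ", ylab)
  }
  graphics::image(x$axes$x$values, yv, z, col = cols[seq_len(nlevels(v))],
                  xlab = x$axes$x$name, ylab = ylab, ...)
  graphics::legend("topright", legend = levels(v),
                   fill = cols[seq_len(nlevels(v))], bg = "white", cex = 0.8)
  invisible(x)
}

#' Write a phase diagram as delimited text
#'
#' One row per grid cell plus a sidecar YAML echo of the sweep settings.
#'
#' @param pd A `phase_diagram`.
#' @param file Output CSV path; the sidecar is written next to it with a
#'   `.yaml` extension.
#' @export
write_phase_diagram <- function(pd, file) {
  utils::write.csv(pd$grid, file, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".yaml", file)
  if (identical(sidecar, file)) sidecar <- paste0(file, ".yaml")
  yaml::write_yaml(list(
    axes = lapply(pd$axes, function(a) list(name = a$name, scale = a$scale,
                                            n = length(a$values),
                                            range = range(a$values))),
    phenotype = pd$phenotype,
    protocol = unclass(pd$protocol)
  ), sidecar)
  invisible(file)
}

#' Re-run a classified parameter set for extra unperturbed cycles
#'
#' Persistence check: extends the protocol by `extra_cycles` cycles (the
#' antibiotic window stays at its original absolute position, so the added
#' cycles are perturbation-free) and re-classifies the final cycle.
#'
#' @param model A [community_model()].
#' @param spec The original [protocol_spec()].
#' @param extra_cycles Number of additional cycles (default 5).
#' @param solver A [solver_opts()].
#' @return The `outcome_label` of the extended run.
#' @export
persistence_check <- function(model, spec, extra_cycles = 5,
                              solver = solver_opts(out_dt = 2)) {
  sp <- spec
  sp$n_cycles <- spec$n_cycles + as.integer(extra_cycles)
  classify_coexistence(run_protocol(model, sp, solver))
}
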