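#' Per-strain growth parameters
#'
#' Defines one community member by its ecological role, maximum per-capita
#' growth rate and Allee constant. Abundances throughout the package are
#' normalized to the carrying capacity `K = 1e9` CFU/ml, so growth rates are
#' per hour and the Allee constant is dimensionless on the same scale.
#'
#' @param name Member label (e.g. `"A"`, `"cooperator"`).
#' @param role One of `"cooperator"` (antibiotic-detoxifying strain whose
#'   activity protects neighbours), `"cheater"` (sensitive kin strain that
#'   exploits that protection) or `"regulator"` (third, non-kin competitor).
#' @param max_growth_rate Maximum per-capita growth rate, per hour, >= 0.
#' @param allee_constant Allee constant `a` in the density-dependence factor
#'   `X/(a + X)`; `0` disables the Allee effect.
#' @return An object of class `strain_params`.
#' @export
strain_params <- function(name, role = c("cooperator", "cheater", "regulator"),
                          max_growth_rate, allee_constant = 0) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(max_growth_rate) || length(max_growth_rate) != 1L ||
      !is.finite(max_growth_rate) || max_growth_rate < 0) {
    stop("'max_growth_rate' must be a single finite non-negative number")
  }
  if (!is.numeric(allee_constant) || length(allee_constant) != 1L ||
      !is.finite(allee_constant) || allee_constant < 0) {
    stop("'allee_constant' must be a single finite non-negative number")
  }
  structure(list(name = name, role = role,
                 max_growth_rate = max_growth_rate,
                 allee_constant = allee_constant),
            class = "strain_params")
}

#' Antibiotic death model for one member
#'
#' Describes the additional per-capita mortality a member experiences while
#' the antibiotic pulse is active. The rate applies only inside the
#' half-open time window `[window_start, window_end)` and is exactly zero
#' outside it. Two kinds are supported:
#'
#' * `"constant"`: a fixed rate. Negative values are allowed and act as a
#'   growth boost (hormesis), as for a detoxifying strain whose activity is
#'   stimulated by the drug.
#' * `"linear_in_density"`: the rate is a linear function
#'   `slope * D + intercept` of the run's initial total density `D`
#'   (normalized), clamped below at zero. This encodes density-dependent
#'   cross-protection: the more cooperator biomass present at inoculation,
#'   the faster the drug is cleared and the less the sensitive member dies.
#'
#' @param kind `"constant"` or `"linear_in_density"`.
#' @param constant_rate Per-hour rate for the constant kind (may be negative).
#' @param slope,intercept Coefficients of the linear-in-density kind
#'   (per hour per unit normalized density, and per hour).
#' @param window Numeric length-2, `c(start, end)` in absolute hours.
#' @return An object of class `death_model`.
#' @seealso [death_density_protected()] for the standard cross-protection
#'   parameterization.
#' @export
death_model <- function(kind = c("constant", "linear_in_density"),
                        constant_rate = 0, slope = 0, intercept = 0,
                        window = c(72, 96)) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(window), length(window) == 2L, all(is.finite(window)))
  if (window[1] >= window[2]) stop("death window start must precede its end")
  stopifnot(is.numeric(constant_rate), length(constant_rate) == 1L,
            is.finite(constant_rate),
            is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  structure(list(kind = kind, constant_rate = constant_rate,
                 slope = slope, intercept = intercept,
                 window_start = window[1], window_end = window[2]),
            class = "death_model")
}

#' @rdname death_model
#' @param rate Per-hour constant rate.
#' @export
death_constant <- function(rate, window = c(72, 96)) {
  death_model("constant", constant_rate = rate, window = window)
}

#' Density-protected death model for the sensitive (cheater) member
#'
#' The standard parameterization of the linear density dependence:
#' `mu(D) = mu_max * max(0, 1 - D / D_protect)`. At vanishing inoculum the
#' cheater dies at `mu_max`; once the initial total density reaches
#' `D_protect` the cooperators clear the drug fast enough that the cheater
#' is fully protected.
#'
#' @param mu_max Maximal death rate, per hour (default 1.2; large enough
#'   that an unprotected cheater declines during the pulse despite its
#'   growth, the regime in which the density-dependent dominance switch
#'   exists).
#' @param D_protect Normalized initial density at which protection is
#'   complete (default 0.2, i.e. 2e8 CFU/ml at `K = 1e9`; mortality stays
#'   partially active across the experimentally probed inoculum range).
#' @param window Antibiotic window in absolute hours.
#' @return A `death_model` of kind `"linear_in_density"`.
#' @export
death_density_protected <- function(mu_max = 1.2, D_protect = 0.2,
                                    window = c(72, 96)) {
  stopifnot(mu_max >= 0, D_protect > 0)
  death_model("linear_in_density", slope = -mu_max / D_protect,
              intercept = mu_max, window = window)
}

#' Effective antibiotic death rate at a given time
#'
#' Returns 0 outside the model's time window. Inside it, the constant kind
#' passes its rate through unchanged (including negative, hormetic rates);
#' the linear-in-density kind evaluates `slope * D + intercept` and clamps
#' the result below at zero, so density-dependent mortality never turns
#' into growth.
#'
#' @param death A [death_model()].
#' @param t Absolute time in hours.
#' @param D Normalized initial total density of the run.
#' @return Per-hour rate (scalar).
#' @export
effective_death_rate <- function(death, t, D = 0) {
  stopifnot(inherits(death, "death_model"))
  if (t < death$window_start || t >= death$window_end) return(0)
  if (death$kind == "constant") return(death$constant_rate)
  max(0, death$slope * D + death$intercept)
}

#' Interaction matrix between community members
#'
#' Square matrix of dimensionless competition coefficients `alpha[i, j]`,
#' the per-unit inhibitory effect of member `j` on member `i` (positive =
#' inhibition under the equations' minus-sign convention; negative =
#' facilitation). Diagonal entries are unused — self-limitation lives in the
#' logistic `(1 - X)` term — and must be zero.
#'
#' @param coefficients Square numeric matrix with zero diagonal.
#' @param symmetric_regulator If `TRUE`, rows/columns that involve a
#'   regulator member are required to be mirror-equal (`alpha[i, j] ==
#'   alpha[j, i]`), the complete-correlation assumption used for the
#'   three-member sweeps.
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(coefficients, symmetric_regulator = FALSE) {
  stopifnot(is.matrix(coefficients), nrow(coefficients) == ncol(coefficients),
            is.numeric(coefficients), all(is.finite(coefficients)))
  if (any(diag(coefficients) != 0)) {
    stop("diagonal interaction entries must be zero (self-limitation is logistic)")
  }
  structure(list(coefficients = coefficients,
                 symmetric_regulator = isTRUE(symmetric_regulator)),
            class = "interaction_matrix")
}

#' Assemble a community model
#'
#' Bundles 2 or 3 members, their interaction matrix and one death model per
#' member into the object consumed by [evaluate_rhs()] and [run_protocol()].
#'
#' @param members List of [strain_params()] objects (length 2 or 3).
#' @param interactions An [interaction_matrix()] of matching dimension.
#' @param deaths List of [death_model()] objects, one per member.
#' @return An object of class `community_model`.
#' @export
community_model <- function(members, interactions, deaths) {
  stopifnot(is.list(members), length(members) %in% c(2L, 3L),
            all(vapply(members, inherits, logical(1), "strain_params")),
            inherits(interactions, "interaction_matrix"),
            is.list(deaths),
            all(vapply(deaths, inherits, logical(1), "death_model")))
  n <- length(members)
  if (nrow(interactions$coefficients) != n) {
    stop("interaction matrix dimension does not match member count")
  }
  if (length(deaths) != n) stop("need one death model per member")
  nm <- vapply(members, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("member names must be unique")
  roles <- vapply(members, `[[`, character(1), "role")
  M <- interactions$coefficients
  dimnames(M) <- list(nm, nm)
  if (interactions$symmetric_regulator) {
    reg <- which(roles == "regulator")
    for (i in reg) {
      if (!isTRUE(all.equal(M[i, ], M[, i], tolerance = 1e-12))) {
        stop("symmetric_regulator requires alpha[i, regulator] == alpha[regulator, i]")
      }
    }
  }
  structure(list(members = members,
                 interactions = interactions,
                 deaths = deaths,
                 n_members = n,
                 member_names = nm,
                 roles = roles,
                 rates = vapply(members, `[[`, numeric(1), "max_growth_rate"),
                 allee = vapply(members, `[[`, numeric(1), "allee_constant"),
                 alpha = M),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("Community model:", x$n_members, "members\n")
  for (i in seq_len(x$n_members)) {
    m <- x$members[[i]]
    d <- x$deaths[[i]]
    dd <- if (d$kind == "constant") {
      sprintf("mu = %g", d$constant_rate)
    } else {
      sprintf("mu(D) = max(0, %g D + %g)", d$slope, d$intercept)
    }
    cat(sprintf("  %s (%s): r = %g /h, a = %g, %s on [%g, %g) h\n",
                m$name, m$role, m$max_growth_rate, m$allee_constant,
                dd, d$window_start, d$window_end))
  }
  cat("Interaction matrix (alpha[i, j], effect of j on i):\n")
  print(x$alpha)
  invisible(x)
}

# Allee factor X/(a + X) with the limit convention: 1 when a = 0 and X > 0,
# 0 when X = 0 (so the derivative of an extinct member is exactly 0).
allee_factor <- function(x, a) {
  out <- ifelse(x > 0, x / (a + x), 0)
  out[a == 0 & x > 0] <- 1
  out
}

#' Right-hand side of the modified Lotka-Volterra system
#'
#' Evaluates the per-member derivatives of the competition model with Allee
#' density dependence and time-windowed antibiotic mortality:
#' `dX_i/dt = r_i X_i [ X_i/(a_i + X_i) (1 - X_i) - sum_j alpha_ij X_j ]
#'  - mu_i(t, D) X_i`, where `mu_i` comes from [effective_death_rate()].
#'
#' @param model A [community_model()].
#' @param state Numeric vector of non-negative normalized abundances.
#' @param t Absolute time in hours.
#' @param D Normalized initial total density of the run (drives the
#'   linear-in-density death kind).
#' @return Numeric vector of derivatives, per hour.
#' @export
evaluate_rhs <- function(model, state, t = 0, D = 0) {
  stopifnot(inherits(model, "community_model"))
  if (length(state) != model$n_members) {
    stop("state length does not match the number of members")
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state must be finite and non-negative")
  }
  mu <- vapply(model$deaths, effective_death_rate, numeric(1), t = t, D = D)
  rhs_core(state, model$rates, model$allee, model$alpha, mu)
}

# Bare algebraic kernel shared by evaluate_rhs and the ODE integrator.
rhs_core <- function(x, rates, a, alpha, mu) {
  fac <- allee_factor(x, a)
  rates * x * (fac * (1 - x) - drop(alpha %*% x)) - mu * x
}

#' Interior coexistence fixed point of the two-member system
#'
#' Analytic equilibrium of the death-free, Allee-free two-member model:
#' `A* = (1 - alpha_AB) / (1 - alpha_AB * alpha_BA)` and symmetrically for
#' `B*`. Used as an analytic anchor for the dynamics; with both cross
#' coefficients above 1 (the default parameter regime) this point exists but
#' is unstable, which is what makes the serial-dilution competition
#' bistable and exclusionary.
#'
#' @param model A two-member [community_model()] with zero Allee constants
#'   and zero death rates.
#' @return Named numeric vector `c(A, B)` of interior abundances, or `NULL`
#'   when no strictly interior equilibrium exists.
#' @export
interior_fixed_point_two_member <- function(model) {
  stopifnot(inherits(model, "community_model"))
  if (model$n_members != 2L) stop("requires a two-member model")
  if (any(model$allee != 0)) stop("requires zero Allee constants")
  dead <- vapply(model$deaths, function(d) {
    if (d$kind == "constant") d$constant_rate == 0 else
      d$slope == 0 && d$intercept <= 0
  }, logical(1))
  if (!all(dead)) stop("requires zero (constant) death rates")
  a12 <- model$alpha[1, 2]
  a21 <- model$alpha[2, 1]
  den <- 1 - a12 * a21
  if (den == 0) return(NULL)
  xs <- c((1 - a12) / den, (1 - a21) / den)
  if (any(xs <= 0)) return(NULL)
  names(xs) <- model$member_names
  xs
}

#' Two-member cooperator-cheater model with the standard parameters
#'
#' Convenience constructor for the kin pair: a slow-growing detoxifying
#' cooperator A that is hormetically boosted during the antibiotic pulse,
#' and a fast-growing sensitive cheater B whose pulse mortality falls
#' linearly with the initial total density (cross-protection). Defaults are
#' the simulation constants: `alpha_AB = 1.9`, `alpha_BA = 1.75`,
#' `a_A = a_B = 0`, `mu_A = -0.6`, pulse window `[72, 96)` h.
#'
#' @param cooperator_rate,cheater_rate Maximum growth rates, per hour.
#' @param alpha_AB Effect of cheater on cooperator (dimensionless).
#' @param alpha_BA Effect of cooperator on cheater.
#' @param allee_A,allee_B Allee constants.
#' @param mu_A Cooperator rate during the pulse (negative = hormetic boost).
#' @param mu_B_max,D_protect Cross-protection parameters, see
#'   [death_density_protected()].
#' @param window Antibiotic window in absolute hours.
#' @return A `community_model` with members `A` (cooperator), `B` (cheater).
#' @export
kin_pair_model <- function(cooperator_rate = 0.5, cheater_rate = 0.75,
                           alpha_AB = 1.9, alpha_BA = 1.75,
                           allee_A = 0, allee_B = 0,
                           mu_A = -0.6, mu_B_max = 1.2, D_protect = 0.2,
                           window = c(72, 96)) {
  community_model(
    members = list(
      strain_params("A", "cooperator", cooperator_rate, allee_A),
      strain_params("B", "cheater", cheater_rate, allee_B)
    ),
    interactions = interaction_matrix(
      matrix(c(0, alpha_AB, alpha_BA, 0), 2, 2, byrow = TRUE)
    ),
    deaths = list(
      death_constant(mu_A, window),
      death_density_protected(mu_B_max, D_protect, window)
    )
  )
}

#' Three-member model: kin pair plus a regulator
#'
#' Extends [kin_pair_model()] with a third, non-kin regulator C whose
#' pairwise interactions with the kin strains obey the complete-correlation
#' assumption (`alpha_AC = alpha_CA`, `alpha_BC = alpha_CB`). The
#' regulator's response to the pulse is set by its phenotype: sensitive
#' (`mu_C = 0.8`), detoxifying (`mu_C = -0.3`) or intrinsically resistant
#' (`mu_C = 0`).
#'
#' @inheritParams kin_pair_model
#' @param regulator_rate Regulator maximum growth rate, per hour (default
#'   0.75, matched to the cheater).
#' @param alpha_AC Mutual interaction coefficient between cooperator and
#'   regulator.
#' @param alpha_BC Mutual interaction coefficient between cheater and
#'   regulator.
#' @param regulator_phenotype One of `"sensitive"`, `"detoxifying"`,
#'   `"intrinsic"`.
#' @param allee_C Regulator Allee constant.
#' @return A `community_model` with members `A`, `B`, `C`.
#' @export
kin_trio_model <- function(alpha_AC = 0.5, alpha_BC = 1.0,
                           regulator_phenotype = c("sensitive", "detoxifying",
                                                   "intrinsic"),
                           regulator_rate = 0.75,
                           cooperator_rate = 0.5, cheater_rate = 0.75,
                           alpha_AB = 1.9, alpha_BA = 1.75,
                           allee_A = 0, allee_B = 0, allee_C = 0,
                           mu_A = -0.6, mu_B_max = 1.2, D_protect = 0.2,
                           window = c(72, 96)) {
  regulator_phenotype <- match.arg(regulator_phenotype)
  mu_C <- switch(regulator_phenotype,
                 sensitive = 0.8, detoxifying = -0.3, intrinsic = 0)
  M <- matrix(0, 3, 3)
  M[1, 2] <- alpha_AB; M[2, 1] <- alpha_BA
  M[1, 3] <- alpha_AC; M[3, 1] <- alpha_AC
  M[2, 3] <- alpha_BC; M[3, 2] <- alpha_BC
  community_model(
    members = list(
      strain_params("A", "cooperator", cooperator_rate, allee_A),
      strain_params("B", "cheater", cheater_rate, allee_B),
      strain_params("C", "regulator", regulator_rate, allee_C)
    ),
    interactions = interaction_matrix(M, symmetric_regulator = TRUE),
    deaths = list(
      death_constant(mu_A, window),
      death_density_protected(mu_B_max, D_protect, window),
      death_constant(mu_C, window)
    )
  )
}

# Replace every death model's window (used when a protocol overrides the
# pulse timing) or disable the pulse entirely (window = NULL).
set_antibiotic_window <- function(model, window) {
  stopifnot(inherits(model, "community_model"))
  model$deaths <- lapply(model$deaths, function(d) {
    if (is.null(window)) {
      death_constant(0, c(d$window_start, d$window_end))
    } else {
      d$window_start <- window[1]
      d$window_end <- window[2]
      d
    }
  })
  model
}

# Replace one member's maximum growth rate by position or name.
set_growth_rate <- function(model, member, rate) {
  i <- if (is.character(member)) match(member, model$member_names) else member
  stopifnot(!is.na(i), i >= 1, i <= model$n_members)
  model$members[[i]]$max_growth_rate <- rate
  model$rates[i] <- rate
  model
}

# Set a mirror-equal pair of interaction coefficients.
set_interaction_pair <- function(model, i, j, value) {
  model$alpha[i, j] <- value
  model$alpha[j, i] <- value
  model$interactions$coefficients[i, j] <- value
  model$interactions$coefficients[j, i] <- value
  model
}
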