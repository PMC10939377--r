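#' Effective growth rate from an OD600 time series
#'
#' Assumes exponential growth up to a fixed optical-density threshold and
#' reports the decadal-log rate `log10(od_threshold / od_initial) /
#' T_threshold`, where `T_threshold` is the first crossing time of the
#' threshold, linearly interpolated between the bracketing samples. Wells
#' that never reach the threshold are censored (rate `NA`).
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param od600 Optical densities (per cm), non-negative, same length.
#' @param od_threshold Threshold OD (default 0.5 per cm).
#' @return An object of class `growth_rate_estimate`: list with `rate`
#'   (log10 units per hour, `NA` if censored), `t_threshold`,
#'   `od_threshold`, `od_initial` and `censored`.
#' @export
effective_growth_rate <- function(times, od600, od_threshold = 0.5) {
  stopifnot(is.numeric(times), is.numeric(od600),
            length(times) == length(od600), length(times) >= 2L,
            all(is.finite(times)), all(is.finite(od600)),
            all(diff(times) > 0), all(od600 >= 0))
  od0 <- od600[1L]
  if (od0 <= 0) stop("initial OD must be positive")
  if (od0 >= od_threshold) {
    stop("initial OD is already at or past the threshold; rate undefined")
  }
  hit <- which(od600 >= od_threshold)
  if (length(hit) == 0L) {
    return(structure(list(rate = NA_real_, t_threshold = NA_real_,
                          od_threshold = od_threshold, od_initial = od0,
                          censored = TRUE),
                     class = "growth_rate_estimate"))
  }
  i <- hit[1L]
  t_thr <- if (od600[i] == od_threshold) {
    times[i]
  } else {
    times[i - 1L] + (od_threshold - od600[i - 1L]) *
      (times[i] - times[i - 1L]) / (od600[i] - od600[i - 1L])
  }
  structure(list(rate = log10(od_threshold / od0) / t_thr,
                 t_threshold = t_thr, od_threshold = od_threshold,
                 od_initial = od0, censored = FALSE),
            class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Censored: OD never reached %g\n", x$od_threshold))
  } else {
    cat(sprintf("Effective growth rate: %.4g log10/h (threshold %g reached at %.2f h)\n",
                x$rate, x$od_threshold, x$t_threshold))
  }
  invisible(x)
}

#' Per-well growth rates from a long-format OD table
#'
#' @param od_table Data frame with columns `well`, `strain`,
#'   `initial_density`, `smx`, `time`, `od600` (the plate-reader export
#'   schema; one row per well and time point).
#' @param od_threshold Threshold OD (default 0.5).
#' @return Data frame with one row per well: identifying columns plus
#'   `rate`, `t_threshold`, `censored`.
#' @export
growth_rate_table <- function(od_table, od_threshold = 0.5) {
  need <- c("well", "strain", "initial_density", "smx", "time", "od600")
  missing <- setdiff(need, names(od_table))
  if (length(missing)) {
    stop("OD table lacks columns: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(split(od_table, od_table$well), function(d) {
    d <- d[order(d$time), ]
    est <- effective_growth_rate(d$time, d$od600, od_threshold)
    data.frame(well = d$well[1], strain = d$strain[1],
               initial_density = d$initial_density[1], smx = d$smx[1],
               rate = est$rate, t_threshold = est$t_threshold,
               censored = est$censored)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Viable density from a colony count
#'
#' Standard serial-dilution plate-count arithmetic:
#' `colonies * dilution_factor / plated_volume`, in CFU/ml. Zero-colony
#' plates return 0 with a below-detection flag; counts outside the 3-300
#' plausibility window are flagged (attribute `implausible`) but not
#' rejected.
#'
#' @param colonies Non-negative integer colony counts (vectorized).
#' @param dilution_factor Dilution factors, >= 1.
#' @param plated_volume Plated volume in ml (default 0.01, i.e. 10 ul).
#' @return Numeric CFU/ml vector with logical attributes
#'   `below_detection` and `implausible`.
#' @export
cfu_per_ml <- function(colonies, dilution_factor, plated_volume = 0.01) {
  stopifnot(is.numeric(colonies), all(colonies >= 0),
            all(colonies == round(colonies)),
            is.numeric(dilution_factor), all(dilution_factor >= 1),
            is.numeric(plated_volume))
  if (any(plated_volume <= 0)) stop("plated volume must be positive")
  out <- colonies * dilution_factor / plated_volume
  attr(out, "below_detection") <- colonies == 0
  attr(out, "implausible") <- colonies > 0 & (colonies < 3 | colonies > 300)
  out
}

#' Ordinary least-squares line
#'
#' Simple linear regression via [stats::lm()], reported as slope,
#' intercept, coefficient of determination and slope standard error. A
#' constant response is returned as slope 0 with `r_squared` 0.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, no missing values.
#' @return An object of class `linear_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `slope_se`, `n`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::var(x) == 0) stop("x has zero variance: slope undefined")
  if (stats::var(y) == 0) {
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          slope_se = 0, n = length(x)),
                     class = "linear_fit"))
  }
  fit <- stats::lm(y ~ x)
  # exact fits trip summary.lm's "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 slope_se = sm$coefficients[2L, 2L],
                 n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g   (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Group comparison as used for the growth-rate assays: exact null
#' distribution for small samples (both groups <= 12 and no ties), normal
#' approximation with continuity and tie correction otherwise. Degenerate
#' input (every value identical in both groups) returns p = 1 with a
#' warning.
#'
#' @param x,y Numeric vectors, each with at least 3 observations.
#' @return List with `statistic` (rank-sum W of the first group),
#'   `p_value` and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 3L, length(y) >= 3L)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical in both groups; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 12L && length(y) <= 12L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}
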