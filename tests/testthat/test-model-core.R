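test_that("constructors validate their domain", {
  expect_error(strain_params("A", "cooperator", -0.1), "non-negative")
  expect_error(strain_params("A", "cooperator", 0.5, allee_constant = -1),
               "non-negative")
  expect_error(death_model("constant", window = c(96, 72)), "precede")
  expect_error(interaction_matrix(matrix(1, 2, 2)), "diagonal")
  m <- kin_pair_model()
  expect_s3_class(m, "community_model")
  expect_identical(m$roles, c("cooperator", "cheater"))
  expect_equal(m$alpha["A", "B"], 1.9)
  expect_equal(m$alpha["B", "A"], 1.75)
  expect_error(community_model(m$members, m$interactions,
                               deaths = m$deaths[1]), "one death model")
  expect_error(
    kin_trio_model(alpha_AC = 0.5, alpha_BC = 1) |>
      (\(x) {
        x$interactions$coefficients[1, 3] <- 99
        community_model(x$members, x$interactions, x$deaths)
      })(),
    "mirror-equal|symmetric"
  )
})

test_that("effective death rate is windowed, clamped and hormesis-capable", {
  d <- death_constant(-0.6, window = c(72, 96))
  expect_equal(effective_death_rate(d, 80), -0.6)
  expect_equal(effective_death_rate(d, 71.999), 0)
  expect_equal(effective_death_rate(d, 96), 0)  # half-open window
  dc <- death_constant(0.8, window = c(72, 96))
  expect_equal(effective_death_rate(dc, 100), 0)
  # linear kind: zero at its root, clamped (never negative) beyond it
  dl <- death_model("linear_in_density", slope = -2, intercept = 1,
                    window = c(72, 96))
  expect_equal(effective_death_rate(dl, 80, D = 0.5), 0)
  expect_equal(effective_death_rate(dl, 80, D = 0.9), 0)
  expect_equal(effective_death_rate(dl, 80, D = 0.25), 0.5)
  # density-protected parameterization hits mu_max at D = 0
  dp <- death_density_protected(mu_max = 1.2, D_protect = 0.2)
  expect_equal(effective_death_rate(dp, 80, D = 0), 1.2)
  expect_equal(effective_death_rate(dp, 80, D = 0.1), 0.6)
  expect_equal(effective_death_rate(dp, 80, D = 0.3), 0)
})

test_that("right-hand side matches the displayed equations", {
  m <- pair_nodeath()
  # absorbing state
  expect_identical(evaluate_rhs(m, c(0, 0)), c(A = 0, B = 0))
  # logistic reduction: one member alone, a = 0, mu = 0
  m1 <- pair_nodeath(r_A = 0.75)
  expect_equal(evaluate_rhs(m1, c(0.5, 0))[["A"]], 0.75 * 0.5 * (1 - 0.5))
  # hand arithmetic on the displayed equation with the reference values
  m2 <- pair_nodeath(r_A = 0.75, r_B = 0.5)
  d <- evaluate_rhs(m2, c(0.1, 0.1))
  expect_equal(d[["A"]], 0.75 * 0.1 * (0.9 - 0.19))  # 0.05325
  expect_equal(d[["B"]], 0.5 * 0.1 * (0.9 - 0.175))  # 0.03625
  # contract violations
  expect_error(evaluate_rhs(m, c(0.1, -0.1)), "non-negative")
  expect_error(evaluate_rhs(m, c(0.1, 0.1, 0.1)), "length")
})

test_that("rhs agrees with a literal brute-force transcription", {
  set.seed(101)
  for (k in 1:1000) {
    n <- sample(2:3, 1)
    rates <- runif(n, 0, 1.5)
    allee <- ifelse(runif(n) < 0.5, 0, runif(n, 0, 0.5))
    alpha <- matrix(runif(n * n, -1, 2), n, n)
    diag(alpha) <- 0
    mu <- runif(n, -0.8, 1.2)
    x <- ifelse(runif(n) < 0.2, 0, runif(n, 0, 1.2))
    members <- lapply(seq_len(n), function(i) {
      strain_params(LETTERS[i],
                    c("cooperator", "cheater", "regulator")[i],
                    rates[i], allee[i])
    })
    deaths <- lapply(mu, function(r) death_constant(r, c(0, 1e6)))
    m <- community_model(members, interaction_matrix(alpha), deaths)
    expect_equal(unname(evaluate_rhs(m, x, t = 10)),
                 brute_rhs(rates, allee, alpha, mu, x),
                 tolerance = 1e-12)
  }
})

test_that("label swap exchanges the derivative components exactly", {
  set.seed(7)
  for (k in 1:50) {
    rA <- runif(1, 0.1, 1); rB <- runif(1, 0.1, 1)
    aAB <- runif(1, -1, 2); aBA <- runif(1, -1, 2)
    x <- runif(2, 0, 1)
    m <- pair_nodeath(alpha_AB = aAB, alpha_BA = aBA, r_A = rA, r_B = rB)
    swapped <- kin_pair_model(cooperator_rate = rB, cheater_rate = rA,
                              alpha_AB = aBA, alpha_BA = aAB,
                              mu_A = 0, mu_B_max = 0)
    expect_identical(unname(evaluate_rhs(m, x)),
                     rev(unname(evaluate_rhs(swapped, rev(x)))))
  }
})

test_that("interior fixed point has the closed form and zero residual", {
  # decoupled logistics
  m0 <- pair_nodeath(alpha_AB = 0, alpha_BA = 0)
  expect_equal(unname(interior_fixed_point_two_member(m0)), c(1, 1))
  # reference coefficients
  m <- pair_nodeath()
  fp <- interior_fixed_point_two_member(m)
  expect_equal(unname(fp), c(0.9 / 2.325, 0.75 / 2.325), tolerance = 1e-12)
  expect_equal(unname(fp), c(0.3870968, 0.3225806), tolerance = 1e-6)
  expect_lt(max(abs(evaluate_rhs(m, fp, t = 0))), 1e-12)
  # boundary case: A* = 0 is not interior
  expect_null(interior_fixed_point_two_member(pair_nodeath(alpha_AB = 1)))
  # contract: needs zero Allee and death
  expect_error(interior_fixed_point_two_member(kin_pair_model()),
               "death")
  mall <- kin_pair_model(allee_A = 0.1, mu_A = 0, mu_B_max = 0)
  expect_error(interior_fixed_point_two_member(mall), "Allee")
})

test_that("strong mutual inhibition makes the interior point unstable", {
  # from equal start one member excludes the other; a sufficiently
  # asymmetric start flips the winner (bistability probe)
  m <- pair_nodeath()
  sp <- protocol_spec(n_cycles = 4, dilution_mode = "to_fixed_total",
                      initial_total_density = 0.02,
                      antibiotic_window = NULL)
  so <- solver_opts(out_dt = 2)
  eq <- run_protocol(m, sp, so)$cycle_ends[4, ]
  expect_gt(eq[["B"]], 100 * eq[["A"]])  # faster member wins from 1:1
  sp$initial_proportions <- c(0.999, 0.001)
  fl <- run_protocol(m, sp, so)$cycle_ends[4, ]
  expect_gt(fl[["A"]], 100 * fl[["B"]])  # asymmetry flips the outcome
})
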