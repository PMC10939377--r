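test_that("single-member trajectory matches the logistic closed form", {
  m <- pair_nodeath(r_A = 0.5)
  seg <- integrate_cycle(m, c(0.01, 0), 0, 24)
  expect_lt(max(abs(seg$states[, 1] -
                      logistic_closed_form(0.01, 0.5, seg$times))), 1e-6)
  expect_true(all(seg$states[, 2] == 0))
})

test_that("all-zero state is absorbing", {
  seg <- integrate_cycle(kin_pair_model(), c(0, 0), 0, 24)
  expect_true(all(seg$states == 0))
})

test_that("one cycle agrees with a fine-step Euler oracle", {
  m <- pair_nodeath()
  x0 <- c(0.015, 0.015)
  seg <- integrate_cycle(m, x0, 0, 24, solver = solver_opts(out_dt = 6))
  fin <- seg$states[nrow(seg$states), ]
  oracle <- euler_two_member(m, x0, 24, dt = 5e-4)
  expect_equal(unname(fin), oracle, tolerance = 2e-3)
  expect_gt(fin[["B"]], fin[["A"]])  # faster member strictly ahead
})

test_that("dilution preserves composition and handles edge cases", {
  sp <- protocol_spec(dilution_mode = "to_fixed_total",
                      initial_total_density = 0.01)
  expect_equal(apply_dilution(c(0.6, 0.4), sp), c(0.006, 0.004))
  spf <- protocol_spec(dilution_mode = "by_factor", dilution_factor = 10)
  expect_equal(apply_dilution(c(0.5, 0.3, 0.2), spf), c(0.05, 0.03, 0.02))
  expect_equal(apply_dilution(c(0, 0.4), spf), c(0, 0.04))
  expect_warning(out <- apply_dilution(c(0, 0), sp), "collapse")
  expect_equal(out, c(0, 0))
  # composition conserved to 1e-12 relative error across random states
  set.seed(3)
  for (k in 1:50) {
    x <- runif(3)
    y <- apply_dilution(x, sp)
    expect_equal(y / sum(y), x / sum(x), tolerance = 1e-12)
    expect_equal(sum(y), 0.01, tolerance = 1e-9)
  }
})

test_that("a 7-cycle daily protocol spans exactly 168 h with snapshots", {
  tr <- run_protocol(kin_pair_model(), protocol_spec(),
                     solver_opts(out_dt = 2))
  expect_equal(range(tr$times), c(0, 168))
  expect_equal(dim(tr$cycle_starts), c(7L, 2L))
  expect_equal(dim(tr$cycle_ends), c(7L, 2L))
  expect_true(all(tr$abundances >= 0))
  expect_equal(sum(tr$phase == "cycle_start"), 7L)
  expect_equal(sum(tr$phase == "cycle_end"), 7L)
  # post-dilution totals equal the target
  expect_equal(unname(rowSums(tr$cycle_starts))[-1], rep(0.01, 6),
               tolerance = 1e-9)
  df <- as.data.frame(tr)
  expect_named(df, c("time_h", "member", "abundance", "cycle", "phase"))
})

test_that("symmetric three-member community keeps equal proportions", {
  members <- lapply(1:3, function(i) {
    strain_params(LETTERS[i],
                  c("cooperator", "cheater", "regulator")[i], 0.6)
  })
  m <- community_model(members, interaction_matrix(matrix(0, 3, 3)),
                       lapply(1:3, function(i) death_constant(0)))
  tr <- run_protocol(m, protocol_spec(n_cycles = 4, antibiotic_window = NULL),
                     solver_opts(out_dt = 6))
  for (k in 1:4) {
    expect_equal(unname(tr$cycle_starts[k, ]),
                 rep(unname(tr$cycle_starts[k, 1]), 3))
    expect_equal(unname(tr$cycle_ends[k, ]),
                 rep(unname(tr$cycle_ends[k, 1]), 3), tolerance = 1e-10)
  }
})

test_that("runs are deterministic and tolerance-converged", {
  m <- kin_pair_model()
  sp <- protocol_spec()
  a <- run_protocol(m, sp, solver_opts(out_dt = 2))
  b <- run_protocol(m, sp, solver_opts(out_dt = 2))
  expect_identical(a$cycle_ends, b$cycle_ends)
  expect_identical(a$abundances, b$abundances)
  tight <- run_protocol(m, sp, solver_opts(out_dt = 2, rtol = 5e-9,
                                           atol = 5e-13))
  expect_lt(max(abs(a$cycle_ends[7, ] - tight$cycle_ends[7, ])), 1e-6)
})

test_that("stronger cheater mortality never helps the cheater", {
  sp <- protocol_spec()
  finals <- vapply(c(0.6, 0.9, 1.2, 1.5), function(mm) {
    tr <- run_protocol(kin_pair_model(mu_B_max = mm), sp,
                       solver_opts(out_dt = 4))
    tr$cycle_ends[7, "B"]
  }, numeric(1))
  expect_true(all(diff(finals) <= 1e-6))
})

test_that("an antibiotic window after the run end changes nothing", {
  m <- kin_pair_model()
  late <- run_protocol(m, protocol_spec(antibiotic_window = c(200, 224)),
                       solver_opts(out_dt = 2))
  none <- run_protocol(m, protocol_spec(antibiotic_window = NULL),
                       solver_opts(out_dt = 2))
  expect_identical(late$abundances, none$abundances)
})

test_that("opt-in clamping pins members to zero at the floor", {
  sp <- protocol_spec(n_cycles = 4, dilution_mode = "by_factor",
                      initial_total_density = 0.03,
                      antibiotic_window = NULL)
  tr <- run_protocol(kin_pair_model(), sp, solver_opts(out_dt = 2,
                                                       clamp = TRUE))
  expect_identical(unname(tr$cycle_ends[3, "A"]), 0)
  expect_identical(unname(tr$cycle_ends[4, "A"]), 0)
  # unclamped run keeps a continuous (tiny but positive) abundance
  tru <- run_protocol(kin_pair_model(), sp, solver_opts(out_dt = 2))
  expect_gt(tru$cycle_ends[4, "A"], 0)
  expect_equal(extinction_cycle(tru, "A"), 3L)
})
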