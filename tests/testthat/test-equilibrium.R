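# Ternary equilibrium model: free-energy conversion, exact solver, dilute
# closed form, optimal dose, titration curves, grid scans.

test_that("free-energy / dissociation-constant conversion obeys the Boltzmann relation", {
  expect_equal(dg_to_kd(0), 1)
  # independent evaluation of exp(-5 / (0.0019872 * 298.15))
  expect_equal(dg_to_kd(-5, 298.15), 2.162553e-4, tolerance = 1e-6)
  # a slightly repulsive interaction maps above 1 M
  expect_gt(dg_to_kd(0.11, 298.15), 1)
  # strictly increasing in ddg, and kd_to_dg round-trips
  dd <- seq(-40, 40, by = 5)
  expect_true(all(diff(dg_to_kd(dd)) > 0))
  expect_equal(kd_to_dg(dg_to_kd(dd)), dd, tolerance = 1e-12)
  expect_error(dg_to_kd(NaN), "finite")
  expect_error(dg_to_kd(Inf), "finite")
  expect_error(kd_to_dg(-1), "positive")
})

test_that("binding_parameters validates its invariants", {
  expect_s3_class(binding_parameters(1e-6, 1e-6), "binding_parameters")
  expect_error(binding_parameters(0, 1e-6), "k_rs")
  expect_error(binding_parameters(1e-6, -1), "k_ls")
  expect_error(binding_parameters(1e-6, 1e-6, phi = 0), "phi")
  expect_error(binding_parameters(1e-6, 1e-6, temperature = -3),
               "temperature")
})

test_that("solver handles the no-stabilizer case and the symmetric case", {
  p <- binding_parameters(1e-6, 1e-6)
  st <- solve_equilibrium(p, r0 = 2e-6, l0 = 3e-6, s0 = 0)
  expect_equal(st$rls, 0)
  expect_equal(st$rs, 0)
  expect_equal(st$r_free, 2e-6)
  expect_equal(st$l_free, 3e-6)

  st <- solve_equilibrium(p, r0 = 1e-6, l0 = 1e-6, s0 = 5e-7)
  expect_equal(st$rs, st$ls, tolerance = 1e-10)
  expect_equal(st$r_free, st$l_free, tolerance = 1e-10)
})

test_that("solver matches the brute-force oracle and conserves mass on random systems", {
  set.seed(41)
  for (i in 1:40) {
    k_rs <- 10^runif(1, -9, -1)
    k_ls <- 10^runif(1, -9, -1)
    phi <- sample(c(0.1, 1, 10), 1)
    r0 <- 10^runif(1, -8, -3)
    l0 <- 10^runif(1, -8, -3)
    s0 <- 10^runif(1, -8, -3)
    p <- binding_parameters(k_rs, k_ls, phi = phi)
    st <- solve_equilibrium(p, r0, l0, s0)
    # mass conservation to 1e-8 relative on all three totals
    expect_lt(abs(st$r_free + st$rs + st$rls - r0) / r0, 1e-8)
    expect_lt(abs(st$l_free + st$ls + st$rls - l0) / l0, 1e-8)
    expect_lt(abs(st$s_free + st$rs + st$ls + st$rls - s0) / s0, 1e-8)
    # mass-action residuals
    expect_lt(abs(st$r_free * st$s_free - k_rs * st$rs) /
                (k_rs * st$rs), 1e-6)
    expect_lt(abs(st$l_free * st$s_free - k_ls * st$ls) /
                (k_ls * st$ls), 1e-6)
    expect_lt(abs(phi * st$rs * st$l_free - k_ls * st$rls) /
                (k_ls * st$rls), 1e-6)
    # independent oracle
    orc <- oracle_equilibrium(k_rs, k_ls, phi, r0, l0, s0)
    expect_lt(abs(st$rls - orc$rls) / orc$rls, 1e-6)
  }
})

test_that("rls is invariant under swapping the receptor and ligand roles", {
  set.seed(7)
  for (i in 1:10) {
    k_rs <- 10^runif(1, -8, -2); k_ls <- 10^runif(1, -8, -2)
    r0 <- 10^runif(1, -7, -4); l0 <- 10^runif(1, -7, -4)
    s0 <- 10^runif(1, -7, -3)
    a <- solve_equilibrium(binding_parameters(k_rs, k_ls), r0, l0, s0)
    b <- solve_equilibrium(binding_parameters(k_ls, k_rs), l0, r0, s0)
    expect_equal(a$rls, b$rls, tolerance = 1e-9)
  }
})

test_that("dilute closed form agrees with the exact solver and peaks at sqrt(K_RS K_LS)", {
  p <- binding_parameters(2e-4, 8e-4)
  expect_equal(rls_dilute(p, 1e-6, 1e-6, 0), 0)
  # hook-effect tail
  expect_lt(rls_dilute(p, 1e-6, 1e-6, 1e3),
            rls_dilute(p, 1e-6, 1e-6, sqrt(2e-4 * 8e-4)))
  # symmetric K: numeric maximisation of the closed form lands on s_free = K
  ps <- binding_parameters(1e-4, 1e-4)
  opt <- optimize(function(s) rls_dilute(ps, 1e-9, 1e-9, s),
                  c(1e-8, 1e2), maximum = TRUE, tol = 1e-12)
  expect_equal(opt$maximum, 1e-4, tolerance = 1e-4)
  # dilute agreement r0, l0 <= min(K)/1e3: evaluate the closed form at the
  # exact solver's own free-stabilizer concentration
  set.seed(13)
  r0 <- 2e-4 / 1e3 / 2; l0 <- r0
  for (s0 in 10^runif(20, -7, -1)) {
    exact <- solve_equilibrium(p, r0, l0, s0)
    expect_equal(exact$rls, rls_dilute(p, r0, l0, exact$s_free),
                 tolerance = 1e-3)
  }
})

test_that("optimal dose reproduces the dilute-limit laws", {
  K <- dg_to_kd(-5, 298.15)
  p <- binding_parameters(K, K)
  d <- optimal_dose(p, 1e-6, 1e-6)
  # K_RL,eff = (sqrt(K_RS) + sqrt(K_LS))^2 / phi = 4K in the symmetric case
  expect_equal(d$k_rl_eff, 4 * K, tolerance = 1e-2)
  expect_equal(d$k_rl_eff, 8.65e-4, tolerance = 2e-2)
  # free stabilizer at the optimum ~ sqrt(k_rs k_ls)
  expect_equal(d$species$s_free, K, tolerance = 1e-2)
  # doubling phi halves k_rl_eff (dilute limit)
  d2 <- optimal_dose(binding_parameters(K, K, phi = 2), 1e-6, 1e-6)
  expect_equal(d$k_rl_eff / d2$k_rl_eff, 2, tolerance = 1e-2)
  # k_rl_eff * phi invariant over phi in {0.1, 1, 10} (dilute limit)
  ks <- vapply(c(0.1, 1, 10), function(phi) {
    optimal_dose(binding_parameters(K, K, phi = phi), 1e-9, 1e-9)$k_rl_eff * phi
  }, numeric(1))
  expect_lt(diff(range(ks)) / mean(ks), 2e-2)
  # asymmetric K pair against the closed form
  pa <- binding_parameters(1e-5, 4e-4)
  da <- optimal_dose(pa, 1e-8, 1e-8)
  expect_equal(da$k_rl_eff, (sqrt(1e-5) + sqrt(4e-4))^2, tolerance = 1e-3)
  expect_s3_class(tidy(d), "tbl_df")
  expect_equal(glance(d)$k_rl_eff, d$k_rl_eff)
})

test_that("titration curves are unimodal and peak at the optimal dose", {
  p <- binding_parameters_dg(-5, -5)
  expect_error(titration_curve(p, 1e-6, 1e-6, numeric(0)), "non-empty")
  one <- titration_curve(p, 1e-6, 1e-6, 0)
  expect_equal(one$rls, 0)

  grid <- 10^seq(-8, 0, length.out = 60)
  tc <- titration_curve(p, 1e-6, 1e-6, grid)
  expect_equal(tc$s0, grid)
  d <- optimal_dose(p, 1e-6, 1e-6)
  i <- which.max(tc$rls)
  expect_lt(abs(log10(tc$s0[i]) - log10(d$s0_opt)),
            diff(log10(grid[1:2])) + 1e-9)

  # unimodality on random parameter draws: rises then falls
  set.seed(99)
  for (k in 1:15) {
    pk <- binding_parameters(10^runif(1, -8, -2), 10^runif(1, -8, -2),
                             phi = sample(c(0.1, 1, 10), 1))
    tck <- titration_curve(pk, 1e-6, 1e-6, 10^seq(-9, 1, length.out = 40))
    sgn <- sign(diff(tck$rls))
    sgn <- sgn[sgn != 0]
    expect_lte(sum(diff(sgn) != 0), 1)  # at most one direction change
  }
})

test_that("energy grid scans are symmetric, monotone and consistent with optimal_dose", {
  one <- energy_grid_scan(-5, -5)
  K <- dg_to_kd(-5)
  expect_equal(one$k_rl_eff,
               optimal_dose(binding_parameters(K, K), 1e-6, 1e-6)$k_rl_eff)

  ax <- seq(-3, -7, by = -1)
  g <- energy_grid_scan(ax, ax)
  # swap symmetry at r0 = l0
  sym <- merge(g, g, by.x = c("ddg_rs", "ddg_ls"),
               by.y = c("ddg_ls", "ddg_rs"))
  expect_equal(sym$k_rl_eff.x, sym$k_rl_eff.y, tolerance = 1e-6)
  # strictly decreasing toward more negative energies along either axis
  by_rs <- tapply(g$k_rl_eff, g$ddg_ls, function(v) all(diff(v) < 0))
  expect_true(all(by_rs))
  # dilute diagonal: K_RL,eff = 4 exp(ddg/RT), so a step of delta on both
  # axes multiplies it by exp(delta/RT)
  gd <- energy_grid_scan(ax, ax, r0 = 1e-12, l0 = 1e-12)
  diag_k <- vapply(ax, function(a) {
    gd$k_rl_eff[gd$ddg_rs == a & gd$ddg_ls == a]
  }, numeric(1))
  ratios <- diag_k[-1] / diag_k[-length(diag_k)]
  expect_equal(ratios, rep(exp(-1 / (1.9872e-3 * 298.15)), length(ratios)),
               tolerance = 1e-3)
  expect_error(energy_grid_scan(c(-1, -3, -2), -5), "monotone")
})

test_that("threshold scan returns the least-negative sufficient energy", {
  ts <- threshold_scan(seq(-1, -10, by = -0.5))
  expect_true(ts$reached)
  expect_equal(ts$threshold, -5)
  # boundary +Inf: first (least negative) grid point
  expect_equal(threshold_scan(c(-1, -2, -3), boundary = Inf)$threshold, -1)
  # not reached: explicit flag, no error
  nr <- threshold_scan(c(-1, -2), boundary = 1e-12)
  expect_false(nr$reached)
  expect_true(is.na(nr$threshold))
  # monotone non-increasing magnitude as the boundary loosens
  t_tight <- threshold_scan(seq(-1, -10, by = -0.5), boundary = 1e-4)
  expect_lte(t_tight$threshold, ts$threshold)
})

test_that("concentration strings parse with unit suffixes", {
  expect_equal(parse_concentration("1uM"), 1e-6)
  expect_equal(parse_concentration(c("2mM", "3nM", "0.5M")),
               c(2e-3, 3e-9, 0.5))
  expect_equal(parse_concentration(1e-6), 1e-6)
  expect_error(parse_concentration("five uM"), "parse")
})
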