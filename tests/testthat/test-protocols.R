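test_that("pulse construction respects amplitude, extent and species", {
  g <- std_grid()
  s0 <- make_pulse(g, amplitude = 0)
  expect_true(all(s0$rho == 0) && all(s0$m == 0))
  rec <- simulate_cortex(s0, std_kp(), mech_params(pe = 5), g, t_end = 3)
  expect_equal(max(state_at(rec)$rho), 0)

  s <- make_pulse(g, amplitude = 0.8, half_width = 2.5)
  expect_equal(max(s$rho), 0.8)
  expect_equal(sum(s$rho > 0) * g$dx, 5, tolerance = g$dx * 2)
  expect_equal(max(s$m), 0)
  sb <- make_pulse(g, amplitude = 0.8, species = "both")
  expect_equal(sb$m, sb$rho)
  expect_error(make_pulse(g, 1, half_width = 30), "half the domain")
})

test_that("identity protocol reproduces the plain simulation exactly", {
  kp <- std_kp()
  g <- std_grid(20, 200)
  mp <- mech_params(pe = 8)
  init <- make_pulse(grid_1d(20, 200), amplitude = 1)
  pr <- perturbation_protocol(t_switch = 10, pe_after = 8)
  rec_p <- run_protocol(init, kp, mp, g, pr, t_end = 20)
  rec_s <- simulate_cortex(init, kp, mp, g, t_end = 20)
  expect_identical(rec_p$times, rec_s$times)
  expect_identical(rec_p$rho_xt, rec_s$rho_xt)
  expect_identical(rec_p$m_xt, rec_s$m_xt)
})

test_that("decay factors multiply only the dissociation terms", {
  kp <- std_kp()
  r <- reaction_rates(0.5, 0.5, kp, decay = c(1, 3))
  r1 <- reaction_rates(0.5, 0.5, kp)
  expect_equal(r$d_rho, r1$d_rho) # rho equation untouched
  expect_equal(r$d_m, r1$d_m - kp$alpha * 2 * 0.5) # extra -2*alpha*m
  # recruitment term unchanged: at m = 0 the rho rate has no decay part
  expect_equal(
    reaction_rates(0, 0.2, kp, decay = c(7, 7))$d_rho,
    0.5
  )
})

test_that("the 2-fold NMIIA destabilization alone does not exit the bistable regime", {
  # effective system with the NMIIA dissociation doubled keeps a stable
  # contractile state near (0.97, 0.50) - the basis for applying the
  # inhibition to both species (see the methods vignette)
  kp <- std_kp()
  expect_true(bistability_check(kp, decay = c(1, 2)))
  fp <- find_fixed_points(kp, decay = c(1, 2))
  hi <- fp[which.max(fp$rho), ]
  expect_equal(hi$rho, 0.975, tolerance = 1e-2)
  expect_equal(hi$m, 0.499, tolerance = 1e-2)
  # the both-species reading is also still formally bistable ...
  expect_true(bistability_check(kp, decay = c(2, 2)))
  # ... its fixed points are those of the kappa = 0.4 system, rescaled
  fp2 <- find_fixed_points(kp, decay = c(2, 2))
  expect_equal(
    sort(fp2$rho) * 2, c(0, diagonal_roots(0.4)),
    tolerance = 1e-6
  )
})

test_that("inhibition protocol: transient broadening then complete inactivation", {
  kp <- kinetic_params(alpha = 0.02, kappa1 = 0.2)
  g <- std_grid()
  mp <- mech_params(pe = 8)
  init <- make_pulse(g, amplitude = 1, species = "both")
  rec <- run_protocol(init, kp, mp, g, inhibition_protocol(t_switch = 40),
    t_end = 400
  )
  tr <- zone_width_series(rec)
  i_switch <- which(tr$time == 40)
  # total RhoA eventually monotone decreasing to below 1% of pre-switch
  w_post <- tr$width[tr$time > 40]
  expect_lt(tail(w_post, 1), 0.01 * tr$width[i_switch])
  late <- tail(w_post, 100)
  expect_true(all(diff(late) <= 1e-9))
  # threshold-based width is biphasic: broadens, then collapses to zero
  qs <- quantify_kymograph(record_to_kymograph(rec), background = 0.05)
  post <- qs[qs$time > 40, ]
  expect_gt(max(post$width), qs$width[i_switch])
  expect_equal(tail(post$width, 1), 0)
})

test_that("washout: restoring contractility narrows a broadened zone to the stationary width", {
  kp <- std_kp()
  g <- std_grid()
  # build a broad zone by letting the front run without advection
  rec0 <- simulate_cortex(
    make_pulse(g, amplitude = high_state(kp)), kp,
    mech_params(pe = 0), g,
    t_end = 12
  )
  broad <- state_at(rec0)
  pr <- perturbation_protocol(t_switch = 0, pe_after = 15)
  rec <- run_protocol(broad, kp, mech_params(pe = 0), g, pr, t_end = 250)
  tr <- zone_width_series(rec)
  v <- detect_stationary(tr)
  expect_true(v$is_stationary)
  # narrow-init run pins at the same width: the stationary zone does not
  # remember whether it started small or big
  rec2 <- simulate_cortex(
    make_pulse(g, amplitude = high_state(kp)), kp,
    mech_params(pe = 15), g,
    t_end = 140
  )
  v2 <- detect_stationary(zone_width_series(rec2))
  expect_equal(v$stationary_width, v2$stationary_width, tolerance = 1e-3)
  # kymo-style series: width collapses while the mean zone intensity is
  # roughly preserved (the saturated plateau cannot brighten further)
  qs <- quantify_kymograph(record_to_kymograph(rec), background = 0.05)
  expect_lt(tail(qs$width_norm, 1), 0.2)
  expect_gt(tail(qs$intensity_norm, 1), 0.7)
  expect_lt(tail(qs$intensity_norm, 1), 1.2)
})

test_that("protocol guards: switch inside the horizon and on the record grid", {
  g <- std_grid(20, 200)
  init <- make_pulse(grid_1d(20, 200), 1)
  pr <- perturbation_protocol(30, 0)
  expect_error(
    run_protocol(init, std_kp(), mech_params(pe = 5), g, pr, t_end = 20),
    "less than"
  )
  pr2 <- perturbation_protocol(10.5, 0)
  expect_error(
    run_protocol(init, std_kp(), mech_params(pe = 5), g, pr2,
      t_end = 20, record_every = 1
    ),
    "multiple"
  )
})
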