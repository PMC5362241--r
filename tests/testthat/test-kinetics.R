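test_that("reaction rates match the Hill kinetics pointwise", {
  kp <- std_kp()
  # the origin is a fixed point
  expect_equal(unlist(reaction_rates(0, 0, kp)), c(d_rho = 0, d_m = 0))
  # Hill term at half-saturation is 1/2
  expect_equal(reaction_rates(0, 0.2, kp)$d_rho, 0.5)
  # direct evaluation at rho = m = 1 (hand-checked arithmetic)
  r <- reaction_rates(1, 1, kp)
  expect_equal(r$d_rho, -0.00159744408945687, tolerance = 1e-12)
  expect_equal(r$d_m, r$d_rho)
  # alpha scales the rates linearly
  expect_equal(
    reaction_rates(0.3, 0.7, std_kp(alpha = 5))$d_rho,
    5 * reaction_rates(0.3, 0.7, kp)$d_rho
  )
  expect_error(reaction_rates(-0.1, 0, kp), "non-negative")
})

test_that("fixed points agree with the polynomial-root oracle for symmetric kappa", {
  for (kappa in c(0.2, 0.3, 0.4)) {
    kp <- kinetic_params(kappa1 = kappa)
    fp <- find_fixed_points(kp)
    oracle <- diagonal_roots(kappa)
    expect_equal(nrow(fp), 3)
    expect_equal(sort(fp$rho), c(0, oracle), tolerance = 1e-8)
    # symmetric system: all fixed points on the diagonal
    expect_equal(fp$rho, fp$m, tolerance = 1e-8)
    # exactly one saddle, flanked by the two stable states
    expect_equal(sum(fp$stability == "saddle"), 1)
    expect_equal(sum(fp$stability == "stable"), 2)
    # rates vanish at every fixed point
    r <- reaction_rates(fp$rho, fp$m, kp)
    expect_true(all(abs(unlist(r)) < 1e-8))
  }
  # frozen oracle roots of c^4 - c^3 + kappa^4 at kappa = 0.4 and 0.2
  fp4 <- find_fixed_points(kinetic_params(kappa1 = 0.4))
  expect_equal(fp4$rho[2], 0.338198, tolerance = 1e-4)
  expect_equal(fp4$rho[3], 0.972135, tolerance = 1e-4)
  fp2 <- find_fixed_points(std_kp())
  expect_equal(fp2$rho[2], 0.122152, tolerance = 1e-4)
  expect_equal(fp2$rho[3], 0.998392, tolerance = 1e-4)
  # saddle closer to the origin than to the high state at kappa = 0.4
  expect_lt(
    sqrt(2) * fp4$rho[2],
    sqrt(2) * (fp4$rho[3] - fp4$rho[2])
  )
})

test_that("bistability verdict follows the nullcline intersection count", {
  expect_true(bistability_check(kinetic_params(kappa1 = 0.4)))
  expect_true(bistability_check(std_kp()))
  # kappa = 1: c^4 - c^3 + 1 has no positive real roots (oracle), monostable
  expect_length(diagonal_roots(1.0), 0)
  expect_false(bistability_check(kinetic_params(kappa1 = 1.0)))
  # steep-nullcline limit stays bistable
  expect_true(bistability_check(kinetic_params(kappa1 = 0.05)))
})

test_that("trajectories respect the exchange symmetry and the saddle threshold", {
  kp <- std_kp()
  fp <- find_fixed_points(kp)
  saddle <- fp$rho[fp$stability == "saddle"]
  high <- max(fp$rho)
  # on-diagonal initial conditions stay on the diagonal
  tr <- integrate_kinetics(0.6, 0.6, kp, t_end = 30)
  expect_equal(tr$rho, tr$m, tolerance = 1e-10)
  # below the saddle: decay to the origin; above: converge to the high state
  lo <- integrate_kinetics(saddle * 0.9, saddle * 0.9, kp, t_end = 200)
  expect_lt(max(tail(lo$rho, 1)), 1e-4)
  hi <- integrate_kinetics(saddle * 1.1, saddle * 1.1, kp, t_end = 200)
  expect_equal(tail(hi$rho, 1), high, tolerance = 1e-5)
})

test_that("stability labels agree with forward integration from perturbed fixed points", {
  kp <- kinetic_params(kappa1 = 0.4)
  fp <- find_fixed_points(kp)
  for (i in seq_len(nrow(fp))) {
    for (eps in c(-0.01, 0.01)) {
      y <- pmax(c(fp$rho[i] + eps, fp$m[i] + eps), 0)
      end <- integrate_kinetics(y[1], y[2], kp, t_end = 300)
      dist <- sqrt((tail(end$rho, 1) - fp$rho[i])^2 + (tail(end$m, 1) - fp$m[i])^2)
      if (fp$stability[i] == "stable") {
        expect_lt(dist, 1e-4)
      } else {
        expect_gt(dist, 0.05) # saddle: symmetric perturbations leave
      }
    }
  }
})

test_that("separatrix is the basin boundary", {
  kp <- kinetic_params(kappa1 = 0.4)
  sep <- separatrix(kp)
  sad <- attr(sep, "saddle")
  # exchange symmetry of the curve
  flipped <- tibble::tibble(rho = sep$m, m = sep$rho)
  for (k in sample(nrow(sep), 10)) {
    d <- min(sqrt((flipped$rho - sep$rho[k])^2 + (flipped$m - sep$m[k])^2))
    expect_lt(d, 0.02)
  }
  # points on the curve flow back toward the saddle before diverging
  for (k in c(20, 60, 120)) {
    tr <- integrate_kinetics(sep$rho[k], sep$m[k], kp, t_end = 30, n_out = 601)
    dmin <- min(sqrt((tr$rho - sad["rho"])^2 + (tr$m - sad["m"])^2))
    expect_lt(dmin, 5e-3)
  }
  # side-of-separatrix classification agrees with brute-force integration
  # on a 10 x 10 grid of initial conditions over [0, 1.2]^2
  ord <- order(sep$rho)
  m_sep <- approxfun(sep$rho[ord], sep$m[ord], rule = 2)
  high <- max(find_fixed_points(kp)$rho)
  pts <- expand.grid(
    rho = seq(0, 1.2, length.out = 10),
    m = seq(0, 1.2, length.out = 10)
  )
  for (j in seq_len(nrow(pts))) {
    predicted_high <- pts$m[j] > m_sep(pts$rho[j])
    end <- integrate_kinetics(pts$rho[j], pts$m[j], kp, t_end = 250)
    actual_high <- abs(tail(end$rho, 1) - high) < 0.05
    expect_identical(predicted_high, actual_high)
  }
})

test_that("separatrix demands bistability and tidiers summarize fixed points", {
  expect_error(separatrix(kinetic_params(kappa1 = 1.0)), "bistable")
  fp <- find_fixed_points(std_kp())
  expect_named(tidy(fp), c("rho", "m", "stability"))
  gl <- glance(fp)
  expect_true(gl$is_bistable)
  expect_equal(gl$rho_high, 0.998, tolerance = 1e-3)
})

test_that("phase-portrait export writes plain CSV tables", {
  dir <- withr::local_tempdir()
  paths <- export_phase_portrait(kinetic_params(kappa1 = 0.4), dir)
  expect_true(all(file.exists(file.path(
    dir, c("nullclines.csv", "fixed_points.csv", "separatrix.csv")
  ))))
  nc <- read.csv(file.path(dir, "nullclines.csv"))
  expect_setequal(unique(nc$curve), c("rho", "m"))
})
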