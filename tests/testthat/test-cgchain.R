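kc_seq <- ki67_consensus_repeat()

test_that("trajectories are bitwise reproducible under a fixed seed", {
  a <- simulate_chain(kc_seq, 300, n_steps = 1e4, seed = 4, save_every = 500)
  b <- simulate_chain(kc_seq, 300, n_steps = 1e4, seed = 4, save_every = 500)
  expect_identical(a$coords, b$coords)
  c_ <- simulate_chain(kc_seq, 300, n_steps = 1e4, seed = 5, save_every = 500)
  expect_false(identical(a$coords, c_$coords))
})

test_that("bonded-only chain reproduces the harmonic bond statistics", {
  tr <- simulate_chain(kc_seq, 300, n_steps = 2e5, seed = 8, use_lj = FALSE,
                       use_coulomb = FALSE, save_every = 200)
  co <- tr$coords
  nf <- dim(co)[1]
  bl <- vapply(seq(nf %/% 5, nf), function(f) {
    d <- co[f, -1, ] - co[f, -dim(co)[2], ]
    mean(sqrt(rowSums(d^2)))
  }, 0)
  # oracle: exact thermal mean of a harmonic bond including the r^2 Jacobian
  expect_equal(mean(bl), harmonic_bond_mean(0.38, 1000, 300), tolerance = 0.02)
  expect_equal(mean(bl), 0.38, tolerance = 0.05)
})

test_that("energies are invariant under rigid translations and rotations", {
  set.seed(12)
  x <- phosphosep:::init_chain(122, 0.38, 3)
  e0 <- cg_energy(x, kc_seq)
  e_t <- cg_energy(sweep(x, 2, c(5, -3, 11), `+`), kc_seq)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  e_r <- cg_energy(x %*% R, kc_seq)
  for (term in c("bond", "coulomb", "pair", "total")) {
    expect_equal(e_t[[term]], e0[[term]], tolerance = 1e-9)
    expect_equal(e_r[[term]], e0[[term]], tolerance = 1e-9)
  }
  # forces rotate with the frame
  expect_equal(e_r$force, e0$force %*% R, tolerance = 1e-6)
})

test_that("Arg-Arg pairs keep a small repulsive lambda after combination", {
  tb <- phosphosep:::ff_tables(cg_forcefield(), aa_sequence("rr", "ARAR"))
  expect_equal(tb$lam_pair[2, 4], 0.01)
  expect_equal(tb$lam_pair[1, 3], cg_forcefield()$table["A", "lambda"],
               ignore_attr = TRUE)
  # phosphorylation swaps in the phospho-residue parameters and -2e
  pat <- phospho_pattern(2L, 2L)
  tbp <- phosphosep:::ff_tables(cg_forcefield(), aa_sequence("ps", "ASA"), pat)
  expect_equal(tbp$residues[2], "pS")
  expect_equal(tbp$charges[2], -2)
})

test_that("radius of gyration matches the discrete rod closed form", {
  N <- 50; b <- 0.38
  rod <- cbind((seq_len(N) - 1) * b, 0, 0)
  frames <- array(0, dim = c(3, N, 3))
  for (f in 1:3) frames[f, , ] <- rod
  traj <- structure(list(coords = frames), class = "chain_trajectory")
  rg <- radius_of_gyration(traj, n_blocks = 3)
  rg_rod <- b * sqrt((N^2 - 1) / 12)   # discrete uniform rod
  expect_equal(rg$mean, rg_rod, tolerance = 1e-12)
  expect_equal(rg$sem, 0)
  # the mean is independent of the blocking used for the error bar
  rgv <- rnorm(100, 2, 0.1)
  expect_equal(radius_of_gyration(rgv, n_blocks = 10)$mean,
               radius_of_gyration(rgv, n_blocks = 20)$mean)
})

test_that("scaling-exponent fits are exact on power-law inputs", {
  sep <- 5:100
  expect_equal(fit_scaling_exponent(sep, 0.55 * sep^0.5), 0.5,
               tolerance = 1e-10)
  expect_equal(fit_scaling_exponent(sep, 0.55 * sep^1.0), 1.0,
               tolerance = 1e-10)
  # 1% multiplicative noise: nu recovered within 0.01 across seeded draws
  set.seed(77)
  errs <- replicate(100, {
    R <- 0.55 * sep^0.5 * exp(rnorm(length(sep), 0, 0.01))
    fit_scaling_exponent(sep, R) - 0.5
  })
  expect_lt(max(abs(errs)), 0.01)
  expect_error(fit_scaling_exponent(1:4, rep(1, 4)), "at least 5")
  expect_error(fit_scaling_exponent(5:20, rep(-1, 16)), "positive")
})

test_that("theta temperature interpolates the nu = 0.5 crossing", {
  expect_equal(theta_temperature(c(300, 320), c(0.45, 0.55)), 310)
  expect_equal(theta_temperature(c(280, 300, 320), c(0.4, 0.5, 0.6)), 300)
  nd <- theta_temperature(c(300, 320), c(0.4, 0.45))
  expect_true(is.na(nd))
  expect_match(attr(nd, "reason"), "not determined")
  expect_warning(theta_temperature(c(1, 2, 3, 4), c(0.4, 0.6, 0.4, 0.6)),
                 "multiple")
})

test_that("slab windows recover dense and dilute densities", {
  z <- seq(0.5, 199.5, 1)
  flat <- data.frame(z = z, density = rep(7, 200))
  expect_equal(dense_dilute_densities(flat), list(rho_H = 7, rho_L = 7))
  step <- data.frame(z = z, density = ifelse(z > 80 & z < 120, 42, 0))
  dd <- dense_dilute_densities(step)
  expect_equal(dd$rho_H, 42)
  expect_equal(dd$rho_L, 0)
  # off-centre slab: centring first gives the same answer
  off <- synth_physics_curves(slab_center = 60, rho_H = 42, rho_L = 0)$profile
  dd_off <- dense_dilute_densities(center_density_profile(off))
  expect_equal(dd_off$rho_H, 42)
  expect_equal(dd_off$rho_L, 0)
  # shrunken axis: proportional windows with a warning
  half <- data.frame(z = seq(0.25, 99.75, 0.5),
                     density = ifelse(abs(seq(0.25, 99.75, 0.5) - 50) < 12, 9, 1))
  expect_warning(dd2 <- dense_dilute_densities(half), "rescaled")
  expect_equal(dd2$rho_H, 9)
})

test_that("binodal fits invert the order-parameter law", {
  pts <- synth_physics_curves(A = 1, Tc = 2,
                              temps = seq(0.5, 1.9, 0.2))$binodal_points
  fit <- fit_binodal(pts$T, pts$drho)
  expect_equal(fit$A, 1, tolerance = 1e-8)
  expect_equal(fit$Tc, 2, tolerance = 1e-8)
  expect_true(fit$monotone)
  # single-point scaling: at Tc - T = 1 the gap equals A
  expect_equal(1 * (2 - 1)^0.325, 1)
  # 2% noise, 8 temperatures: Tc within 2% across seeded draws
  errs <- vapply(1:100, function(s) {
    p <- synth_physics_curves(A = 1, Tc = 2, temps = seq(0.4, 1.8, 0.2),
                              noise_sd = 0.02, seed = 5000 + s)$binodal_points
    fit_binodal(p$T, abs(p$drho))$Tc
  }, 0)
  expect_gte(mean(abs(errs - 2) / 2 < 0.02), 0.9)
  expect_error(fit_binodal(c(1, 2), c(1, 0.5)), ">= 3")
})

test_that("XYZ export writes one block per frame", {
  tr <- simulate_chain(kc_seq, 300, n_steps = 2000, seed = 2, save_every = 1000)
  path <- tempfile(fileext = ".xyz")
  write_xyz(tr, path)
  lines <- readLines(path)
  expect_equal(lines[1], "122")
  expect_length(lines, 2 * (122 + 2))
})
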