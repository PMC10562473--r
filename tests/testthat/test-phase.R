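fh_model <- function(N, eps = 2) {
  free_energy_model(rep(0, N), eps_fh = eps, electrostatics = "off")
}

test_that("an ideal athermal solution never phase separates", {
  m <- free_energy_model(rep(0, 50), eps_fh = 0, electrostatics = "off")
  phi <- 10^seq(-8, -0.1, length.out = 60)
  expect_true(all(free_energy(m, phi, 1)$d2f > 0))
  expect_false(critical_point(m)$found)
})

test_that("electrostatics off matches the Flory-Huggins closed form", {
  for (N in c(10, 100, 122, 500)) {
    cp <- critical_point(fh_model(N))
    expect_true(cp$found)
    expect_equal(cp$phic, 1 / (1 + sqrt(N)), tolerance = 1e-6)
    chi_c <- (1 + 1 / sqrt(N))^2 / 2
    expect_equal(cp$Tc, 2 / chi_c, tolerance = 1e-6)
  }
})

test_that("a neutral sequence with electrostatics on equals electrostatics off", {
  q <- rep(0, 40)
  on <- free_energy_model(q, eps_fh = 2, electrostatics = "rpa")
  off <- free_energy_model(q, eps_fh = 2, electrostatics = "off")
  phi <- c(1e-6, 1e-3, 0.05, 0.3, 0.7)
  for (Ts in c(0.5, 2)) {
    a <- free_energy(on, phi, Ts); b <- free_energy(off, phi, Ts)
    expect_equal(a$f, b$f, tolerance = 1e-10)
    expect_equal(a$mu, b$mu, tolerance = 1e-10)
  }
})

test_that("free energy evaluation enforces the physical density range", {
  m <- fh_model(20)
  expect_error(free_energy(m, 1.2, 1), "phi outside")
  expect_error(free_energy(m, 0, 1), "phi outside")
})

test_that("spinodal roots satisfy the FH closed form and widen on cooling", {
  m <- fh_model(100)
  cp <- critical_point(m)
  Tg <- cp$Tc * c(0.95, 0.9, 0.85, 0.8)
  sp <- spinodal(m, Tg, crit = cp)
  for (i in seq_along(Tg)) {
    chi <- 2 / Tg[i]
    for (phi in c(sp$phi_lo[i], sp$phi_hi[i])) {
      expect_equal(1 / (100 * phi) + 1 / (1 - phi), 2 * chi, tolerance = 1e-6)
    }
  }
  expect_true(all(diff(sp$phi_lo) < 0))   # dilute root shrinks on cooling
  expect_true(all(diff(sp$phi_hi) > 0))   # dense root grows
  # approaching Tc the two roots collapse onto phi_c (split ~ sqrt(Tc - T))
  sp_c <- spinodal(m, cp$Tc * (1 - 1e-7), crit = cp)
  expect_equal(sp_c$phi_lo, cp$phic, tolerance = 5e-3)
  expect_equal(sp_c$phi_hi, cp$phic, tolerance = 5e-3)
})

test_that("the symmetric mixture has a symmetric binodal", {
  m <- fh_model(1, eps = 1)
  cp <- critical_point(m)
  expect_equal(cp$phic, 0.5, tolerance = 1e-6)
  bi <- binodal(m, cp$Tc * c(0.9, 0.8), crit = cp)
  expect_equal(bi$phi_L, 1 - bi$phi_H, tolerance = 1e-7)
})

test_that("coexistence agrees with brute-force two-phase minimisation", {
  # FH-only: minimise the lever-rule free energy of a two-phase split over
  # a dense (phi_L, phi_H) grid at fixed overall composition
  m <- fh_model(50)
  cp <- critical_point(m)
  Ts <- 0.85 * cp$Tc
  bi <- binodal(m, Ts, crit = cp)
  phi0 <- cp$phic
  f_of <- function(phi) free_energy(m, phi, Ts)$f
  grid_L <- seq(bi$phi_L * 0.2, min(phi0, bi$phi_L * 5), length.out = 400)
  grid_H <- seq(phi0, 0.95, length.out = 400)
  best <- Inf; arg <- c(NA, NA)
  for (pl in grid_L) {
    w <- (grid_H - phi0) / (grid_H - pl)
    ok <- w > 0 & w < 1
    tot <- w * f_of(pl) + (1 - w) * vapply(grid_H, f_of, 0)
    i <- which.min(ifelse(ok, tot, Inf))
    if (tot[i] < best) { best <- tot[i]; arg <- c(pl, grid_H[i]) }
  }
  expect_equal(bi$phi_L, arg[1], tolerance = 5e-2)
  expect_equal(bi$phi_H, arg[2], tolerance = 5e-2)
  # the equal-potential construction is far tighter than the grid oracle
  expect_lt(bi$mu_gap, 1e-8)
  expect_lt(bi$Pi_gap, 1e-8)
})

test_that("critical temperature scales exactly with eps_fh when only FH acts", {
  cp1 <- critical_point(fh_model(80, eps = 1.3))
  cp2 <- critical_point(fh_model(80, eps = 2.6))
  expect_equal(cp2$Tc, 2 * cp1$Tc, tolerance = 1e-7)
  expect_equal(cp2$phic, cp1$phic, tolerance = 1e-6)
})

test_that("Tc is monotone in eps_fh and rises with attractive charge patterning", {
  q_blocky <- assign_charges(synth_polyampholyte(10, 60), "scdm")$charges
  cache <- phase_kernel_cache(60)
  Tc <- vapply(c(1.5, 2, 2.5), function(e) {
    critical_point(free_energy_model(q_blocky, eps_fh = e, cache = cache))$Tc
  }, 0)
  expect_true(all(diff(Tc) > 0))
  cp_neutral <- critical_point(free_energy_model(rep(0, 60), eps_fh = 2,
                                                 electrostatics = "off"))
  cp_charged <- critical_point(free_energy_model(q_blocky, eps_fh = 2,
                                                 cache = cache))
  expect_gt(cp_charged$Tc, cp_neutral$Tc)
})

test_that("binodal encloses spinodal around the critical density", {
  kc <- ki67_consensus_repeat()
  m <- free_energy_model(assign_charges(kc, "scdm")$charges, eps_fh = 2.5)
  pd <- phase_diagram(m, nT = 6, frac_lo = 0.82)
  cv <- pd$curves
  expect_true(all(cv$phi_L <= cv$phi_spin_lo))
  expect_true(all(cv$phi_spin_lo <= pd$critical$phic))
  expect_true(all(pd$critical$phic <= cv$phi_spin_hi))
  expect_true(all(cv$phi_spin_hi <= cv$phi_H))
  expect_true(all(cv$mu_gap <= 1e-8))
  expect_true(all(cv$Pi_gap <= 1e-8))
})

test_that("renormalised mode runs and keeps the FH limit intact", {
  q <- assign_charges(synth_polyampholyte(5, 40), "scdm")$charges
  cp_rg <- critical_point(free_energy_model(q, eps_fh = 2,
                                            electrostatics = "rg_rpa"))
  expect_true(cp_rg$found)
  # neutral chain: renormalisation is inert, FH closed form still holds
  cp0 <- critical_point(free_energy_model(rep(0, 100), eps_fh = 2,
                                          electrostatics = "rg_rpa"))
  expect_equal(cp0$Tc, 2 / ((1 + 1 / sqrt(100))^2 / 2), tolerance = 1e-6)
})

test_that("small scans are complete, deterministic and order-invariant", {
  s <- aa_sequence("mini", "KKSPAKKASPAKKSPAK")
  sites <- candidate_proline_directed_sites(s)
  expect_length(sites, 3)
  sc1 <- phospho_scan(s, sites, eps_fh = 2)
  sc2 <- phospho_scan(s, rev(sites), eps_fh = 2)
  expect_equal(nrow(sc1), 8L)
  expect_equal(sc1$Tc, sc2$Tc, tolerance = 1e-9)
  expect_true(all(sc1$found))
  # empty candidate list: single entry equal to the unmodified sequence
  sc0 <- phospho_scan(s, integer(), eps_fh = 2)
  expect_equal(nrow(sc0), 1L)
  cp <- critical_point(free_energy_model(assign_charges(s, "scdm")$charges,
                                         eps_fh = 2))
  expect_equal(sc0$Tc, cp$Tc, tolerance = 1e-6)
  # per-stoichiometry extremes flagged exactly once per occupied level
  for (k in unique(sc1$n_phospho)) {
    expect_equal(sum(sc1$is_max[sc1$n_phospho == k]), 1L)
    expect_equal(sum(sc1$is_min[sc1$n_phospho == k]), 1L)
  }
})
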