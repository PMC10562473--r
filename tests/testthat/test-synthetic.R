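test_that("generators are pure functions of spec and seed", {
  a <- synth_proteome(n_proteins = 5, seed = 2)
  b <- synth_proteome(n_proteins = 5, seed = 2)
  expect_identical(a$sites, b$sites)
  expect_identical(a$intensity, b$intensity)
  expect_identical(vapply(a$sequences, function(s) s$residues, ""),
                   vapply(b$sequences, function(s) s$residues, ""))
  expect_false(identical(a$sites,
                         synth_proteome(n_proteins = 5, seed = 3)$sites))
  expect_identical(synth_frap(seed = 4, noise_sd = 0.05)$bleached,
                   synth_frap(seed = 4, noise_sd = 0.05)$bleached)
})

test_that("polyampholyte families span alternating to diblock", {
  alt <- synth_polyampholyte(1, 50)
  expect_equal(substr(alt$residues, 1, 4), "EKEK")
  expect_equal(net_charge(assign_charges(alt, "scdm")), 0)
  di <- synth_polyampholyte(25, 50)
  expect_equal(di$residues, paste0(strrep("E", 25), strrep("K", 25)))
  expect_error(synth_polyampholyte(7, 50), "multiple")
  # SCD becomes monotonically more attractive with block size
  scds <- vapply(c(1, 5, 25), function(p) {
    sequence_scd(assign_charges(synth_polyampholyte(p, 50), "scdm"))
  }, 0)
  expect_true(all(diff(scds) < 0))
})

test_that("proteome compositions carry the planted S/T/P disorder bias", {
  pr <- synth_proteome(n_proteins = 40, seed = 6, intensity = FALSE)
  frac_stp <- function(seqs, mask_fun) {
    counts <- c(inside = 0, total_in = 0, outside = 0, total_out = 0)
    for (id in names(seqs)) {
      r <- strsplit(seqs[[id]]$residues, "")[[1]]
      m <- mask_fun(id)
      counts["inside"] <- counts["inside"] + sum(r[m] %in% c("S", "T", "P"))
      counts["total_in"] <- counts["total_in"] + sum(m)
      counts["outside"] <- counts["outside"] + sum(r[!m] %in% c("S", "T", "P"))
      counts["total_out"] <- counts["total_out"] + sum(!m)
    }
    c(counts[["inside"]] / counts[["total_in"]],
      counts[["outside"]] / counts[["total_out"]])
  }
  f <- frac_stp(pr$sequences, function(id) pr$tracks[[id]]$mask)
  expect_gt(f[1], f[2] + 0.05)   # S/T/P enriched inside disordered blocks
})

test_that("a null proteome yields no planted dynamics or enrichment", {
  pr <- synth_proteome(n_proteins = 10, or_planted = 1, dynamic_fraction = 0,
                       missingness = 0, seed = 8)
  expect_equal(sum(pr$sites$dynamic), 0L)
  res <- classify_dynamic_sites(pr$intensity, pr$groups)
  expect_lte(sum(res$dynamic, na.rm = TRUE), ceiling(0.05 * nrow(res)))
  expect_error(synth_proteome(p_phospho_structured = 1.2), "p_phospho")
})

test_that("planted dynamic sites are detectable after imputation", {
  pr <- synth_proteome(n_proteins = 15, dynamic_fraction = 0.3, seed = 10)
  mat <- impute_missing(median_normalize(pr$intensity), seed = 1)
  res <- classify_dynamic_sites(mat, pr$groups)
  truth <- pr$truth$dynamic_flags
  sens <- mean(res$dynamic[truth])
  fpr <- mean(res$dynamic[!truth])
  expect_gt(sens, 0.8)
  expect_lt(fpr, 0.1)
})

test_that("physics-curve generator plants the ground truth it reports", {
  pc <- synth_physics_curves(nu = 0.5)
  expect_equal(fit_scaling_exponent(pc$distances$sep, pc$distances$R), 0.5,
               tolerance = 1e-10)
  fit <- fit_binodal(pc$binodal_points$T, pc$binodal_points$drho)
  expect_equal(fit$Tc, pc$truth$Tc, tolerance = 1e-8)
  # planted off-centre slab is restored by centring
  off <- synth_physics_curves(slab_center = 60)
  prof <- center_density_profile(off$profile)
  dense_bins <- prof$z[prof$density > mean(c(off$truth$rho_H, off$truth$rho_L))]
  expect_equal(mean(range(dense_bins)), 100, tolerance = 2)
  dd <- dense_dilute_densities(prof)
  expect_equal(dd$rho_H, off$truth$rho_H)
})

test_that("noise-free FRAP generation inverts through the fitter", {
  tr <- synth_frap(a = 0.45, k = 0.25, c = 0.92)
  fit <- fit_recovery(tr)
  tru <- attr(tr, "truth")
  expect_equal(fit$a, tru$a, tolerance = 1e-6)
  expect_equal(fit$k, tru$k, tolerance = 1e-6)
  expect_equal(fit$c, tru$c, tolerance = 1e-6)
})

test_that("the synthetic consensus repeat has the advertised architecture", {
  kc <- ki67_consensus_repeat()
  expect_equal(length(kc), 122L)
  sites <- candidate_proline_directed_sites(kc)
  expect_length(sites, 11)
  expect_equal(net_charge(assign_charges(kc, "scdm")), 7)
  # full phosphorylation overshoots neutrality: net -15
  full <- assign_charges(kc, "scdm", phospho_pattern(sites, sites))
  expect_equal(net_charge(full), -15)
})
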