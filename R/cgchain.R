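#' Coarse-grained force field for one-bead-per-residue simulations
#'
#' Harmonic bonds (1000 kJ/mol/nm^2, 0.38 nm), screened Coulomb with a 1 nm
#' Debye length on the `cg` charge scheme (His +0.5e, phospho-S/T -2e), and
#' a hydrophobicity-scaled Lennard-Jones pair potential
#' `V_ij(r) = 4 lambda_ij eps ((sigma_ij/r)^12 - (sigma_ij/r)^6)`.
#' Per-residue lambda and sigma come from an editable parameter table
#' (arithmetic-mean combination; the shipped defaults follow the standard
#' hydrophobicity-scale convention, with provisional phospho-S/T entries),
#' and lambda for Arg-Arg pairs is overridden to 0.01 after combination so
#' excluded volume is retained. Pair potentials are truncated at
#' `3 sigma_ij` (Coulomb at 3.5 nm) and shifted to zero at the cutoff.
#'
#' @param param_path TSV with columns `residue`, `mass`, `lambda`, `sigma`
#'   (rows `pS`, `pT` for phosphoresidues); default the shipped table.
#' @param eps_lj LJ well depth in kJ/mol (default 0.8368).
#' @param pair_potential `"lj"` (plain, the default) or `"ashbaugh"`
#'   (Ashbaugh-Hatch split of the same parameters).
#' @param dielectric Relative permittivity for the Coulomb prefactor.
#' @return A `cg_forcefield` object.
#' @export
cg_forcefield <- function(param_path = system.file("extdata", "cg_params.tsv",
                                                   package = "phosphosep"),
                          eps_lj = 0.8368,
                          pair_potential = c("lj", "ashbaugh"),
                          dielectric = 80) {
  pair_potential <- match.arg(pair_potential)
  tab <- utils::read.delim(param_path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "mass", "lambda", "sigma") %in% names(tab)))
  rownames(tab) <- tab$residue
  structure(list(table = tab, eps_lj = eps_lj,
                 pair_potential = pair_potential,
                 kbond = 1000, r0 = 0.38, debye = 1.0,
                 rc_coul = 3.5, lj_cut_sigmas = 3.0,
                 coul_k = 138.935458 / dielectric,
                 scheme = charge_scheme("cg")),
            class = "cg_forcefield")
}

# per-bead parameter vectors + combined pair matrices for a sequence
ff_tables <- function(ff, seq, pattern = NULL) {
  r <- seq_chars(seq)
  if (!is.null(pattern) && length(pattern$active)) {
    r[pattern$active] <- ifelse(r[pattern$active] == "S", "pS", "pT")
  }
  missing <- setdiff(unique(r), rownames(ff$table))
  if (length(missing)) stop("no parameters for: ", paste(missing, collapse = ","))
  lam <- ff$table[r, "lambda"]
  sig <- ff$table[r, "sigma"]
  mass <- ff$table[r, "mass"]
  cs <- assign_charges(seq, ff$scheme, pattern)
  lam_pair <- outer(lam, lam, `+`) / 2
  arg <- r == "R"
  lam_pair[arg, arg] <- 0.01   # Arg-Arg override, applied after combination
  sig_pair <- outer(sig, sig, `+`) / 2
  list(charges = cs$charges, lam_pair = lam_pair, sig_pair = sig_pair,
       mass = mass, residues = r)
}

ff_opts <- function(ff, use_lj = TRUE, use_coulomb = TRUE) {
  list(kbond = ff$kbond, r0 = ff$r0, coul_k = ff$coul_k, debye = ff$debye,
       rc_coul = ff$rc_coul, eps_lj = ff$eps_lj,
       lj_cut_sigmas = ff$lj_cut_sigmas,
       use_lj = use_lj, use_coul = use_coulomb,
       ashbaugh = identical(ff$pair_potential, "ashbaugh"))
}

# extended zigzag start: no nonbonded overlaps, deterministic
init_extended <- function(N, b = 0.38) {
  i <- seq_len(N) - 1
  cbind(i * b * 0.95, 0.12 * b * (i %% 2), 0.05 * b * sin(i / 3))
}

# seeded random-walk initial configuration with fixed bond length
init_chain <- function(N, b = 0.38, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  set.seed(seed)
  steps <- matrix(stats::rnorm(3 * (N - 1)), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * b
  x <- rbind(0, apply(steps, 2, cumsum))
  x
}

#' Run a single-chain Langevin simulation
#'
#' NVT Langevin dynamics (BAOAB discretisation) of one chain under the
#' coarse-grained force field, at a 10 fs time step and 25 ps^-1 friction.
#' Runs are bitwise reproducible for a given seed.
#'
#' @param seq An [aa_sequence()] (N <= 500 recommended at desk scale).
#' @param temperature Kelvin.
#' @param n_steps Number of steps (default 2e6, a deliberate scale-down of
#'   cluster-scale sampling).
#' @param seed Integer seed (initial velocities, noise, start conformation).
#' @param forcefield A [cg_forcefield()].
#' @param pattern Optional [phospho_pattern()]; active sites become pS/pT.
#' @param save_every Save a frame every this many steps (default 1000).
#' @param dt Time step in ps (default 0.01 = 10 fs).
#' @param friction Langevin friction in ps^-1 (default 25).
#' @param use_lj,use_coulomb Toggle nonbonded terms (both off = ideal
#'   bonded-only chain).
#' @param restraints Optional elastic-network matrix with columns
#'   (i, j, r0, k) in 1-based residue indices, nm, kJ/mol/nm^2.
#' @param coords Optional starting coordinates (N x 3 matrix, nm).
#' @param init Start conformation when `coords` is absent: `"walk"` (seeded
#'   ideal random walk, an equilibrium draw of the bonded-only chain),
#'   `"extended"` (overlap-free zigzag), or `"auto"` (extended when
#'   nonbonded terms are on). Random-walk starts with nonbonded terms on
#'   need a capped push-off (`cap_steps > 0`) to relax overlaps.
#' @param cap_steps Clamp per-component forces to `fmax` for this many
#'   initial steps (soft push-off; 0 disables).
#' @param fmax Force cap during the push-off (kJ/mol/nm).
#' @return A `chain_trajectory`: list with `coords` (frames x N x 3 array,
#'   nm), `kinetic`, `potential` (kJ/mol per frame), and run metadata.
#' @export
simulate_chain <- function(seq, temperature = 300, n_steps = 2e6, seed = 1,
                           forcefield = cg_forcefield(), pattern = NULL,
                           save_every = 1000, dt = 0.01, friction = 25,
                           use_lj = TRUE, use_coulomb = TRUE,
                           restraints = NULL, coords = NULL,
                           init = c("auto", "extended", "walk"),
                           cap_steps = 0, fmax = 1e4) {
  stopifnot(inherits(seq, "aa_sequence"))
  init <- match.arg(init)
  N <- length(seq)
  tb <- ff_tables(forcefield, seq, pattern)
  if (is.null(coords)) {
    # random-walk starts are equilibrium draws for the ideal (bonded-only)
    # chain; interacting chains start extended to avoid overlaps
    extended <- switch(init, auto = use_lj || use_coulomb,
                       extended = TRUE, walk = FALSE)
    coords <- if (extended) init_extended(N, forcefield$r0)
              else init_chain(N, forcefield$r0, seed)
  }
  if (is.null(restraints)) restraints <- matrix(numeric(), 0, 4)
  res <- .cg_run(coords, tb$charges, tb$lam_pair, tb$sig_pair, restraints,
                 ff_opts(forcefield, use_lj, use_coulomb),
                 temperature, dt, friction, n_steps,
                 as.integer(save_every), as.integer(seed), tb$mass,
                 cap_steps, fmax)
  frames <- aperm(res$frames, c(3, 2, 1))  # frames x N x 3
  structure(list(coords = frames, kinetic = res$kinetic,
                 potential = res$potential, temperature = temperature,
                 dt = dt, friction = friction, save_every = save_every,
                 seed = seed, n_steps = n_steps, sequence = seq,
                 residues = tb$residues, mass = tb$mass),
            class = "chain_trajectory")
}

#' Potential-energy components of a configuration
#'
#' Exposes the force-field energy terms (bond, Coulomb, pair) for a single
#' configuration; used e.g. to verify translation/rotation invariance.
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param seq An [aa_sequence()].
#' @param forcefield A [cg_forcefield()].
#' @param pattern Optional phosphorylation pattern.
#' @param restraints Optional restraint matrix as in [simulate_chain()].
#' @return list with `bond`, `coulomb`, `pair`, `total`, `force`.
#' @export
cg_energy <- function(coords, seq, forcefield = cg_forcefield(),
                      pattern = NULL, restraints = NULL) {
  tb <- ff_tables(forcefield, seq, pattern)
  if (is.null(restraints)) restraints <- matrix(numeric(), 0, 4)
  .cg_energy(coords, tb$charges, tb$lam_pair, tb$sig_pair, restraints,
             ff_opts(forcefield))
}

frame_rg <- function(coords) {
  # coords: frames x N x 3; mass-uniform Rg per frame
  mu <- apply(coords, c(1, 3), mean)
  nf <- dim(coords)[1]
  vapply(seq_len(nf), function(f) {
    d <- sweep(coords[f, , , drop = TRUE], 2, mu[f, ])
    sqrt(mean(rowSums(d^2)))
  }, 0)
}

#' Radius of gyration with block-averaged errors
#'
#' Mass-uniform per-frame Rg; the trajectory is split into `n_blocks`
#' non-overlapping equal blocks and the SEM is the standard deviation of the
#' block means over sqrt(n_blocks).
#'
#' @param traj A `chain_trajectory`, or a numeric vector of per-frame Rg.
#' @param n_blocks Number of blocks (default 10).
#' @param burn_in Fraction of initial frames discarded (default 0).
#' @return list with `mean`, `sem`, `block_means`, `rg` (per frame).
#' @export
radius_of_gyration <- function(traj, n_blocks = 10, burn_in = 0) {
  rg <- if (inherits(traj, "chain_trajectory")) frame_rg(traj$coords)
        else as.numeric(traj)
  if (burn_in > 0) rg <- rg[-seq_len(floor(burn_in * length(rg)))]
  if (length(rg) < n_blocks) stop("fewer frames than blocks")
  per <- length(rg) %/% n_blocks
  rg_used <- rg[seq_len(per * n_blocks)]
  blocks <- matrix(rg_used, nrow = per)
  bm <- colMeans(blocks)
  list(mean = mean(rg_used), sem = stats::sd(bm) / sqrt(n_blocks),
       block_means = bm, rg = rg)
}

#' Mean intramolecular distances by sequence separation
#'
#' Average distance between residues i and j as a function of `|i - j|`,
#' over all frames (after burn-in) and all pairs at each separation.
#'
#' @param traj A `chain_trajectory`.
#' @param burn_in Fraction of initial frames discarded (default 0.2).
#' @return data.frame with `sep`, `R` (nm).
#' @export
intramolecular_distances <- function(traj, burn_in = 0.2) {
  co <- traj$coords
  nf <- dim(co)[1]; N <- dim(co)[2]
  keep <- seq.int(floor(burn_in * nf) + 1L, nf)
  acc <- numeric(N - 1L); cnt <- numeric(N - 1L)
  for (f in keep) {
    xf <- co[f, , , drop = TRUE]
    for (s in seq_len(N - 1L)) {
      d <- xf[(1 + s):N, , drop = FALSE] - xf[1:(N - s), , drop = FALSE]
      acc[s] <- acc[s] + sum(sqrt(rowSums(d^2)))
      cnt[s] <- cnt[s] + (N - s)
    }
  }
  data.frame(sep = seq_len(N - 1L), R = acc / cnt)
}

#' Fit the intramolecular distance scaling exponent
#'
#' Least-squares fit of `R_ij = prefactor * |i - j|^nu` with the prefactor
#' fixed (0.55 nm by convention) and `nu` the only free parameter, solved as
#' a no-intercept linear regression in log space. Short separations
#' (`|i - j| < min_sep`) are excluded by default since the power law holds
#' asymptotically.
#'
#' @param sep Sequence separations.
#' @param R Mean distances (nm), positive.
#' @param prefactor Fixed prefactor in nm (default 0.55).
#' @param min_sep Minimum separation included (default 5).
#' @return Fitted exponent `nu`.
#' @export
fit_scaling_exponent <- function(sep, R, prefactor = 0.55, min_sep = 5) {
  keep <- sep >= min_sep
  sep <- sep[keep]; R <- R[keep]
  if (length(sep) < 5L) stop("need at least 5 separations")
  if (any(R <= 0)) stop("distances must be positive")
  lx <- log(sep); ly <- log(R / prefactor)
  sum(lx * ly) / sum(lx * lx)
}

#' Theta temperature from a scaling-exponent series
#'
#' The temperature at which the chain is ideal (`nu = 0.5`), located by
#' linear interpolation between the two bracketing temperatures. Exact grid
#' hits are returned as such; with several crossings the lowest-temperature
#' one is returned with a warning.
#'
#' @param temps Temperatures.
#' @param nus Fitted exponents at those temperatures.
#' @return Interpolated theta temperature, or `NA` (with message attribute)
#'   when `nu = 0.5` is not bracketed.
#' @export
theta_temperature <- function(temps, nus) {
  o <- order(temps)
  temps <- temps[o]; nus <- nus[o]
  d <- nus - 0.5
  hits <- which(d == 0)
  cross <- which(d[-length(d)] * d[-1] < 0)
  cands <- sort(c(temps[hits], vapply(cross, function(i) {
    temps[i] + (temps[i + 1] - temps[i]) * (0 - d[i]) / (d[i + 1] - d[i])
  }, 0)))
  if (!length(cands)) {
    out <- NA_real_
    attr(out, "reason") <- "not determined: nu = 0.5 not bracketed"
    return(out)
  }
  if (length(cands) > 1) warning("multiple nu = 0.5 crossings; returning the lowest-T one")
  cands[1]
}

#' Dense- and dilute-phase densities from a slab profile
#'
#' For a density profile along a 200 nm z-axis with the dense slab centred
#' at z = 100 nm: the dilute density is the mean over the flank windows
#' (0-60 nm and 140-200 nm) and the dense density the mean over the central
#' window (90-110 nm). Profiles on a different axis length are handled by
#' rescaling the windows proportionally, with a warning.
#'
#' @param profile data.frame with `z` (bin centres, nm) and `density`.
#' @return list with `rho_H`, `rho_L`.
#' @export
dense_dilute_densities <- function(profile) {
  stopifnot(all(c("z", "density") %in% names(profile)))
  z <- profile$z; rho <- profile$density
  scale <- (max(z) - min(z) + diff(z)[1]) / 200
  if (abs(scale - 1) > 0.02) {
    warning("axis length differs from 200 nm; windows rescaled proportionally")
  } else scale <- 1
  lo <- function(a) a * scale; # window edges
  dilute <- (z < lo(60)) | (z > lo(140))
  dense <- (z > lo(90)) & (z < lo(110))
  list(rho_H = mean(rho[dense]), rho_L = mean(rho[dilute]))
}

#' Centre the dense slab of a density profile
#'
#' Circularly shifts a periodic z-profile so the density-weighted circular
#' mean sits at the axis midpoint (100 nm on the standard axis), the usual
#' preprocessing before window averaging.
#'
#' @param profile data.frame with `z`, `density`.
#' @return The shifted profile (same bins).
#' @export
center_density_profile <- function(profile) {
  z <- profile$z; rho <- profile$density
  L <- max(z) - min(z) + diff(z)[1]
  theta <- 2 * pi * (z - min(z)) / L
  ang <- atan2(sum(rho * sin(theta)), sum(rho * cos(theta))) %% (2 * pi)
  com_bin <- which.min(abs(theta - ang))
  target <- which.min(abs(z - (min(z) + L / 2)))
  shift <- (target - com_bin) %% length(z)
  profile$density <- rho[((seq_along(rho) - 1 - shift) %% length(rho)) + 1]
  profile
}

#' Fit the critical temperature from coexistence densities
#'
#' Nonlinear least squares of the coexistence order parameter
#' `rho_H - rho_L = A (Tc - T)^0.325` (3D Ising surface-tension exponent
#' fixed), initialised from the highest sampled temperature and the
#' lowest-temperature point.
#'
#' @param temps Temperatures with computed density gaps.
#' @param drho `rho_H - rho_L` at those temperatures (positive).
#' @param beta_exp Fixed critical exponent (default 0.325).
#' @return list with `A`, `Tc`, `residuals`, `monotone` (whether the input
#'   gaps decrease with temperature, flagged not enforced).
#' @export
fit_binodal <- function(temps, drho, beta_exp = 0.325) {
  stopifnot(length(temps) == length(drho), length(temps) >= 3)
  if (any(drho <= 0)) stop("density differences must be positive")
  o <- order(temps)
  temps <- temps[o]; drho <- drho[o]
  monotone <- all(diff(drho) <= 0)
  span <- max(temps) - min(temps)
  Tc0 <- max(temps) + max(span, abs(max(temps)) * 0.05) / 10
  A0 <- drho[1] / (Tc0 - temps[1])^beta_exp
  fit <- minpack.lm::nlsLM(
    drho ~ A * (Tc - temps)^beta_exp,
    start = list(A = A0, Tc = Tc0),
    lower = c(1e-12, max(temps) + 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- stats::coef(fit)
  list(A = unname(cf["A"]), Tc = unname(cf["Tc"]),
       residuals = stats::resid(fit), monotone = monotone)
}

#' Export a trajectory to XYZ text format
#'
#' @param traj A `chain_trajectory`.
#' @param path Output file.
#' @param stride Write every `stride`-th frame.
#' @export
write_xyz <- function(traj, path, stride = 1) {
  co <- traj$coords
  nf <- dim(co)[1]; N <- dim(co)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq(1, nf, by = stride)) {
    writeLines(c(as.character(N), sprintf("frame %d", f)), con)
    xf <- co[f, , , drop = TRUE]
    writeLines(sprintf("%s %.5f %.5f %.5f", traj$residues,
                       xf[, 1], xf[, 2], xf[, 3]), con)
  }
  invisible(path)
}
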