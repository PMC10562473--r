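#' Sequence-dependent free-energy model for a charged-polymer solution
#'
#' Mean-field free energy (per lattice site, in kT) of a solution of chains
#' with a fixed per-residue charge sequence:
#'
#' * ideal mixing entropy of chains `(phi/N) log phi`, solvent
#'   `phi_s log phi_s`, and - for chains with net charge Q - the
#'   translational entropy of their neutralising counterions
#'   `(|Q|/N) phi log((|Q|/N) phi)`;
#' * a Flory-Huggins mean-field term `-chi phi^2` with `chi = eps_fh / T*`,
#'   collecting hydrophobic, cation-pi and other non-electrostatic
#'   attractions;
#' * an electrostatic correlation (one-loop / RPA) term built from the
#'   Gaussian-chain sequence charge structure factor
#'   `S(k) = (1/N) sum_{m,n} q_m q_n exp(-k^2 |m-n| / 6)` (lengths in bond
#'   units), with counterions and optional added salt screening at the
#'   Debye-Hueckel level.
#'
#' The reduced temperature `T*` is the ratio of bond length to Bjerrum
#' length, so electrostatic strength is `1/T*`; only orderings and ratios of
#' `T*` are physically meaningful. Electrostatics modes: `"rpa"` (Gaussian
#' chain, the reference implementation), `"rg_rpa"` (chain statistics
#' renormalised by a Flory-type single-chain variational condition, see
#' vignette), `"off"`.
#'
#' @param charges Per-residue charge vector (units of e, `scdm` scheme).
#' @param eps_fh Flory-Huggins strength in kT (`chi = eps_fh / T*`);
#'   default 2, with 2.5 used for the Ki-67 consensus-repeat runs.
#' @param electrostatics `"rpa"`, `"rg_rpa"` or `"off"`.
#' @param salt Dimensionless added-salt number density (default 0).
#' @param kmax Upper quadrature cutoff in k (analytic tail beyond).
#' @param nk Number of log-spaced Gauss-Legendre quadrature nodes.
#' @param cache Optional kernel cache from [phase_kernel_cache()] shared
#'   across models of equal length (results are independent of caching).
#' @return A `free_energy_model` object.
#' @export
free_energy_model <- function(charges, eps_fh = 2,
                              electrostatics = c("rpa", "rg_rpa", "off"),
                              salt = 0, kmax = 60, nk = 192, cache = NULL) {
  electrostatics <- match.arg(electrostatics)
  charges <- as.numeric(charges)
  N <- length(charges)
  stopifnot(N >= 1, eps_fh >= 0, salt >= 0)
  if (is.null(cache)) cache <- phase_kernel_cache(N, kmax = kmax, nk = nk)
  stopifnot(cache$N == N)
  Q <- sum(charges)
  r <- abs(Q) / N
  # charge autocorrelation by separation d = 0..N-1:
  # c_d = sum_{|m-n|=d} q_m q_n  (both orders for d > 0)
  cd <- sapply(0:(N - 1L), function(d) {
    if (d == 0L) sum(charges^2) else
      2 * sum(charges[1:(N - d)] * charges[(1 + d):N])
  })
  Sk <- as.numeric(cache$E %*% cd) / N
  # single-chain charge-interaction sum for the variational renormalisation
  q2sum <- sum(cd[-1] / sqrt(seq_len(N - 1L))) / 2
  structure(list(charges = charges, N = N, Q = Q, r = r,
                 eps_fh = eps_fh, electrostatics = electrostatics,
                 salt = salt, cd = cd, Sk = Sk, Sinf = sum(charges^2) / N,
                 q2sum = q2sum, cache = cache),
            class = "free_energy_model")
}

#' Quadrature kernel cache for the RPA correlation integral
#'
#' Precomputes log-spaced Gauss-Legendre nodes/weights in k and the
#' separation kernel `exp(-k^2 d / 6)` shared by all charge sequences of one
#' length. Sharing the cache across a combinatorial scan is an optimisation
#' only; results are identical with or without it.
#'
#' @param N Chain length.
#' @param kmax Upper cutoff.
#' @param nk Number of nodes.
#' @param kmin Lower cutoff (default 1e-9; the integrand vanishes as k^3
#'   log k below the screening scale).
#' @return List with nodes `k`, combined weights `w` (including the
#'   log-substitution Jacobian), kernel matrix `E` (nk x N) and `P`
#'   (`k^2 d / 6`, for renormalised modes).
#' @export
phase_kernel_cache <- function(N, kmax = 60, nk = 192, kmin = 1e-9) {
  gl <- gauss_legendre(nk, log(kmin), log(kmax))
  k <- exp(gl$x)
  d <- 0:(N - 1L)
  P <- outer(k^2, d) / 6
  list(N = N, k = k, w = gl$w * k, kmax = kmax, E = exp(-P), P = P)
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# Flory-type variational swelling factor for rg_rpa mode: balances the
# Gaussian-chain elastic free energy (3/2)(x - log x) against the
# single-chain screened... unscreened 1/r charge energy ~ lB * q2sum / sqrt(x).
renorm_factor <- function(model, lB) {
  cpre <- sqrt(6 / pi) * lB * model$q2sum / model$N
  g <- function(x) 1.5 * (1 - 1 / x) - 0.5 * cpre * x^(-1.5)
  if (abs(cpre) < 1e-14) return(1)
  lo <- 0.05; hi <- 50
  if (g(lo) > 0 && g(hi) > 0) return(lo)
  if (g(lo) < 0 && g(hi) < 0) return(hi)
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

# curvature d2f/dphi2 only: the hot path of critical-point bisection
fe_curv <- function(model, phi, Tstar) {
  N <- model$N; r <- model$r
  chi <- model$eps_fh / Tstar
  lB <- 1 / Tstar
  phis <- 1 - (1 + r) * phi
  f2 <- 1 / (N * phi) + (1 + r)^2 / phis - 2 * chi
  if (r > 0) f2 <- f2 + r / phi
  if (model$electrostatics != "off") {
    k <- model$cache$k
    Sk <- model_Sk(model, lB)
    A <- 4 * pi * lB * (r + Sk) / k^2
    B <- 8 * pi * lB * model$salt / k^2
    one <- 1 + outer(phi, A) + rep(B, each = length(phi))
    wk2A2 <- model$cache$w * k^2 * A^2
    f2 <- f2 - as.numeric((1 / one^2) %*% wk2A2) / (4 * pi^2) -
      (4 * pi * lB * (r + model$Sinf))^2 / (4 * pi^2 * model$cache$kmax)
  }
  f2
}

model_Sk <- function(model, lB) {
  if (model$electrostatics == "rg_rpa") {
    x <- renorm_factor(model, lB)
    as.numeric(exp(-x * model$cache$P) %*% model$cd) / model$N
  } else {
    model$Sk
  }
}

# Core evaluator: f and its first three phi-derivatives at scalar Tstar,
# vectorised over phi. All terms analytic, including the correlation
# integral and its large-k tail.
fe_terms <- function(model, phi, Tstar) {
  N <- model$N; r <- model$r
  chi <- model$eps_fh / Tstar
  lB <- 1 / Tstar
  phimax <- 1 / (1 + r)
  if (any(phi <= 0 | phi >= phimax)) {
    stop("phi outside (0, ", signif(phimax, 6), ")")
  }
  phis <- 1 - (1 + r) * phi
  f <- phi / N * log(phi) + phis * log(phis) - chi * phi^2
  f1 <- (log(phi) + 1) / N - (1 + r) * (log(phis) + 1) - 2 * chi * phi
  f2 <- 1 / (N * phi) + (1 + r)^2 / phis - 2 * chi
  f3 <- -1 / (N * phi^2) + (1 + r)^3 / phis^2
  if (r > 0) {
    f <- f + r * phi * log(r * phi)
    f1 <- f1 + r * (log(r * phi) + 1)
    f2 <- f2 + r / phi
    f3 <- f3 - r / phi^2
  }
  if (model$electrostatics != "off") {
    k <- model$cache$k; w <- model$cache$w
    Sk <- model$Sk
    Sinf <- model$Sinf
    Sk <- model_Sk(model, lB)
    A <- 4 * pi * lB * (r + Sk) / k^2          # phi coefficient
    B <- 8 * pi * lB * model$salt / k^2        # salt (phi-independent)
    X <- outer(phi, A)
    Xb <- sweep(X, 2, B, `+`)
    pref <- 1 / (4 * pi^2)
    wk2 <- w * k^2
    f_el <- pref * as.numeric((log1p(Xb) - Xb) %*% wk2)
    one <- 1 + Xb
    f1_el <- -pref * as.numeric((sweep(Xb / one, 2, A, `*`)) %*% wk2)
    f2_el <- -pref * as.numeric((1 / one^2) %*% (wk2 * A^2))
    f3_el <- 2 * pref * as.numeric((1 / one^3) %*% (wk2 * A^3))
    # analytic 1/k tail beyond kmax (S -> Sinf there)
    at <- 4 * pi * lB * (r + Sinf)
    bt <- 8 * pi * lB * model$salt
    u <- at * phi + bt
    K <- model$cache$kmax
    f <- f + f_el - u^2 / (8 * pi^2 * K)
    f1 <- f1 + f1_el - u * at / (4 * pi^2 * K)
    f2 <- f2 + f2_el - at^2 / (4 * pi^2 * K)
    f3 <- f3 + f3_el
  }
  list(f = f, f1 = f1, f2 = f2, f3 = f3)
}

#' Evaluate the free energy, chemical potential and osmotic pressure
#'
#' All three from one analytic evaluation: `mu = df/dphi` and
#' `Pi = phi mu - f` (kT per site / per unit volume, bond-length units).
#'
#' @param model A [free_energy_model()].
#' @param phi Monomer volume fraction(s) in (0, 1/(1+r)) where r is the
#'   counterion-to-monomer ratio.
#' @param Tstar Reduced temperature (> 0).
#' @return list with vectors `f`, `mu`, `Pi` (and curvature `d2f`, `d3f`).
#' @export
free_energy <- function(model, phi, Tstar) {
  stopifnot(inherits(model, "free_energy_model"), Tstar > 0)
  ft <- fe_terms(model, phi, Tstar)
  list(f = ft$f, mu = ft$f1, Pi = phi * ft$f1 - ft$f,
       d2f = ft$f2, d3f = ft$f3)
}

phi_upper <- function(model) (1 - 1e-9) / (1 + model$r)

# minimum of d2f/dphi2 over phi at fixed Tstar: grid scan + local refine
min_curvature <- function(model, Tstar, ngrid = 160) {
  hi <- phi_upper(model) * 0.999
  grid <- exp(seq(log(1e-9), log(hi), length.out = ngrid))
  f2 <- fe_curv(model, grid, Tstar)
  i <- which.min(f2)
  lo <- grid[max(1L, i - 1L)]; up <- grid[min(ngrid, i + 1L)]
  op <- stats::optimize(function(lp) fe_curv(model, exp(lp), Tstar),
                        c(log(lo), log(up)), tol = 1e-12)
  list(phi = exp(op$minimum), value = op$objective)
}

#' Critical point of the phase diagram
#'
#' The highest reduced temperature at which the free energy loses convexity:
#' the simultaneous zero of the second and third phi-derivatives, located by
#' bisection in `T*` on the minimum of the curvature (the minimiser at the
#' bisection limit is the critical density, where the third derivative
#' vanishes by construction).
#'
#' @param model A [free_energy_model()].
#' @param bracket Initial `T*` search bracket (expanded automatically).
#' @param tol Relative bisection tolerance (default 1e-10).
#' @return list with `Tc`, `phic`, `found`. `found = FALSE` means no
#'   criticality in the bracket (no phase separation).
#' @export
critical_point <- function(model, bracket = c(1e-4, 20), tol = 1e-10) {
  h <- function(Ts) min_curvature(model, Ts)$value
  lo <- bracket[1]; hi <- bracket[2]
  it <- 0
  while (h(hi) < 0 && it < 40) { hi <- hi * 2; it <- it + 1 }
  if (h(hi) < 0) return(list(Tc = NA_real_, phic = NA_real_, found = FALSE))
  it <- 0
  while (h(lo) > 0 && it < 40) { lo <- lo / 2; it <- it + 1 }
  if (h(lo) > 0) return(list(Tc = NA_real_, phic = NA_real_, found = FALSE))
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (h(mid) < 0) lo <- mid else hi <- mid
  }
  Tc <- (lo + hi) / 2
  list(Tc = Tc, phic = min_curvature(model, Tc)$phi, found = TRUE)
}

# root of f2 = 0 in log-phi on [lo, hi] (phi scale)
curvature_root <- function(model, Tstar, lo, hi) {
  g <- function(lp) fe_curv(model, exp(lp), Tstar)
  glo <- g(log(lo)); ghi <- g(log(hi))
  if (sign(glo) == sign(ghi)) return(NA_real_)
  exp(stats::uniroot(g, c(log(lo), log(hi)), f.lower = glo, f.upper = ghi,
                     tol = 1e-13)$root)
}

#' Spinodal curve
#'
#' For each temperature below the critical point, the two densities where
#' the curvature changes sign (limits of local stability), bracketing the
#' critical density.
#'
#' @param model A [free_energy_model()].
#' @param Tgrid Reduced temperatures (values at or above `Tc` yield NA rows).
#' @param crit Optional precomputed [critical_point()].
#' @return data.frame with `Tstar`, `phi_lo`, `phi_hi`.
#' @export
spinodal <- function(model, Tgrid, crit = NULL) {
  if (is.null(crit)) crit <- critical_point(model)
  if (!crit$found) stop("model has no critical point; no spinodal")
  out <- lapply(Tgrid, function(Ts) {
    if (Ts >= crit$Tc) return(c(NA_real_, NA_real_))
    mc <- min_curvature(model, Ts)
    c(curvature_root(model, Ts, 1e-12, mc$phi),
      curvature_root(model, Ts, mc$phi, phi_upper(model) * 0.9999))
  })
  out <- do.call(rbind, out)
  data.frame(Tstar = Tgrid, phi_lo = out[, 1], phi_hi = out[, 2])
}

# coexistence at one temperature: equal chemical potential and pressure,
# solved by monotone bisection in mu between the spinodal bounds
coexist_at <- function(model, Tstar, sp_lo, sp_hi, tol = 1e-10) {
  phimin <- 1e-14
  phimax <- phi_upper(model)
  f1 <- function(phi) fe_terms(model, phi, Tstar)$f1
  omega <- function(phi, mu) fe_terms(model, phi, Tstar)$f - mu * phi
  root_f1 <- function(mu, lo, hi) {
    g <- function(lp) f1(exp(lp)) - mu
    glo <- g(log(lo)); ghi <- g(log(hi))
    if (sign(glo) == sign(ghi)) return(NA_real_)
    exp(stats::uniroot(g, c(log(lo), log(hi)), tol = 1e-15)$root)
  }
  mu_lo <- f1(sp_hi * (1 + 1e-10))
  mu_hi <- f1(sp_lo * (1 - 1e-10))
  gap <- function(mu) {
    pl <- root_f1(mu, phimin, sp_lo)
    ph <- root_f1(mu, sp_hi, phimax)
    if (is.na(pl) || is.na(ph)) return(NA_real_)
    omega(ph, mu) - omega(pl, mu)   # decreasing in mu
  }
  # root-find on mu slightly inside the admissible interval
  a <- mu_lo + abs(mu_hi - mu_lo) * 1e-12
  b <- mu_hi - abs(mu_hi - mu_lo) * 1e-12
  ga <- gap(a); gb <- gap(b)
  if (is.na(ga) || is.na(gb) || sign(ga) == sign(gb)) {
    return(NULL)
  }
  mu <- stats::uniroot(gap, c(a, b), f.lower = ga, f.upper = gb,
                       tol = .Machine$double.eps * max(1, abs(a), abs(b)))$root
  pl <- root_f1(mu, phimin, sp_lo)
  ph <- root_f1(mu, sp_hi, phimax)
  el <- free_energy(model, pl, Tstar)
  eh <- free_energy(model, ph, Tstar)
  list(phi_L = pl, phi_H = ph,
       mu_gap = abs(el$mu - eh$mu), Pi_gap = abs(el$Pi - eh$Pi))
}

#' Binodal (coexistence) curve
#'
#' For each temperature below the critical point, the dilute/dense density
#' pair with equal chemical potential and osmotic pressure, solved by
#' monotone bisection on the chemical potential (equal-grand-potential
#' construction). Failures near `Tc` are retried on a refined bracket and
#' reported as NA rows if persistent.
#'
#' @param model A [free_energy_model()].
#' @param Tgrid Reduced temperatures below `Tc`.
#' @param crit Optional precomputed [critical_point()].
#' @return data.frame with `Tstar`, `phi_L`, `phi_H`, `mu_gap`, `Pi_gap`.
#' @export
binodal <- function(model, Tgrid, crit = NULL) {
  if (is.null(crit)) crit <- critical_point(model)
  if (!crit$found) stop("model has no critical point; no binodal")
  sp <- spinodal(model, Tgrid, crit = crit)
  out <- lapply(seq_along(Tgrid), function(i) {
    Ts <- Tgrid[i]
    if (Ts >= crit$Tc || is.na(sp$phi_lo[i]) || is.na(sp$phi_hi[i])) {
      return(rep(NA_real_, 4))
    }
    cx <- coexist_at(model, Ts, sp$phi_lo[i], sp$phi_hi[i])
    if (is.null(cx)) return(rep(NA_real_, 4))
    c(cx$phi_L, cx$phi_H, cx$mu_gap, cx$Pi_gap)
  })
  out <- do.call(rbind, out)
  data.frame(Tstar = Tgrid, phi_L = out[, 1], phi_H = out[, 2],
             mu_gap = out[, 3], Pi_gap = out[, 4])
}

#' Full phase diagram
#'
#' Critical point plus binodal and spinodal branches on a temperature grid
#' spanning `[frac_lo, frac_hi] * Tc`.
#'
#' @param model A [free_energy_model()].
#' @param nT Number of temperatures.
#' @param frac_lo,frac_hi Grid span as fractions of `Tc`.
#' @return A `phase_diagram` object: list with `critical` and data.frame
#'   `curves` (`Tstar`, `phi_L`, `phi_spin_lo`, `phi_spin_hi`, `phi_H`, ...).
#' @export
phase_diagram <- function(model, nT = 25, frac_lo = 0.75, frac_hi = 0.995) {
  crit <- critical_point(model)
  if (!crit$found) stop("no phase separation: no critical point found")
  Tgrid <- seq(frac_lo, frac_hi, length.out = nT) * crit$Tc
  sp <- spinodal(model, Tgrid, crit = crit)
  bi <- binodal(model, Tgrid, crit = crit)
  curves <- data.frame(Tstar = Tgrid,
                       phi_L = bi$phi_L, phi_spin_lo = sp$phi_lo,
                       phi_spin_hi = sp$phi_hi, phi_H = bi$phi_H,
                       mu_gap = bi$mu_gap, Pi_gap = bi$Pi_gap)
  structure(list(critical = crit, curves = curves, eps_fh = model$eps_fh,
                 electrostatics = model$electrostatics),
            class = "phase_diagram")
}

#' Write a phase diagram to CSV (plus its critical point as JSON)
#'
#' Columns: `Tstar`, `phi_L`, `phi_spin_lo`, `phi_c`, `phi_spin_hi`,
#' `phi_H`. When the jsonlite package is available, the critical point is
#' written alongside as `<path>.critical.json`.
#'
#' @param pd A [phase_diagram()].
#' @param path Output CSV path.
#' @export
write_phase_diagram_csv <- function(pd, path) {
  stopifnot(inherits(pd, "phase_diagram"))
  df <- data.frame(Tstar = pd$curves$Tstar, phi_L = pd$curves$phi_L,
                   phi_spin_lo = pd$curves$phi_spin_lo,
                   phi_c = pd$critical$phic,
                   phi_spin_hi = pd$curves$phi_spin_hi,
                   phi_H = pd$curves$phi_H)
  utils::write.csv(df, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(pd$critical, paste0(path, ".critical.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a phosphosite scan to CSV, keyed by bitmask
#'
#' @param scan A `scan_result` from [phospho_scan()].
#' @param path Output CSV path.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> Tc* = %.6g, phi_c = %.6g (%s, eps_fh = %g)\n",
              x$critical$Tc, x$critical$phic, x$electrostatics, x$eps_fh))
  invisible(x)
}

#' Combinatorial phosphosite scan of critical points
#'
#' Enumerates phosphorylation patterns over the candidate sites (all 2^n by
#' default, or one stoichiometry), computes the critical point of each
#' pattern's charge sequence, and flags the per-stoichiometry extremes
#' (highest and lowest critical temperature). The quadrature kernel is
#' cached across patterns; results are independent of the cache and of the
#' order of the candidate-site list. Solver failures propagate as
#' `found = FALSE` rows, never silent drops.
#'
#' @param seq An [aa_sequence()].
#' @param candidate_sites Phosphosite positions; default the
#'   proline-directed (S/T-P) sites of the sequence.
#' @param eps_fh Flory-Huggins strength (default 2.5, the consensus-repeat
#'   value; 2 is the generic default elsewhere).
#' @param electrostatics Electrostatics mode (default `"rpa"`).
#' @param stoichiometry Optional fixed number of phosphosites.
#' @param salt Added salt (default 0).
#' @param progress Print progress every 256 patterns.
#' @return A `scan_result` data.frame with `bitmask`, `n_phospho`, `Tc`,
#'   `phic`, `found`, `is_max`, `is_min` (extremes within stoichiometry).
#' @export
phospho_scan <- function(seq, candidate_sites = NULL, eps_fh = 2.5,
                         electrostatics = "rpa", stoichiometry = NULL,
                         salt = 0, progress = FALSE) {
  stopifnot(inherits(seq, "aa_sequence"))
  if (is.null(candidate_sites)) {
    candidate_sites <- candidate_proline_directed_sites(seq)
  }
  patterns <- enumerate_phospho_patterns(candidate_sites, stoichiometry)
  scheme <- charge_scheme("scdm")
  cache <- phase_kernel_cache(length(seq))
  bracket <- c(1e-4, 20); bracket0 <- NULL
  rows <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    cs <- assign_charges(seq, scheme, p)
    model <- free_energy_model(cs$charges, eps_fh = eps_fh,
                               electrostatics = electrostatics,
                               salt = salt, cache = cache)
    cp <- critical_point(model, bracket = bracket, tol = 1e-7)
    if (cp$found && is.null(bracket0)) {
      # reuse a generous bracket around the first solution for the rest
      bracket0 <- c(cp$Tc / 8, cp$Tc * 8)
      bracket <- bracket0
    }
    mask <- attr(p, "bitmask")
    rows[[i]] <- data.frame(
      bitmask = if (is.null(mask)) NA_integer_ else mask,
      n_phospho = length(p$active),
      Tc = cp$Tc, phic = cp$phic, found = cp$found)
    if (progress && i %% 256L == 0L) {
      message("scan: ", i, "/", length(patterns))
    }
  }
  out <- do.call(rbind, rows)
  out$is_max <- FALSE; out$is_min <- FALSE
  for (k in unique(out$n_phospho)) {
    idx <- which(out$n_phospho == k & out$found)
    if (!length(idx)) next
    out$is_max[idx[which.max(out$Tc[idx])]] <- TRUE
    out$is_min[idx[which.min(out$Tc[idx])]] <- TRUE
  }
  class(out) <- c("scan_result", "data.frame")
  attr(out, "candidate_sites") <- sort(as.integer(candidate_sites))
  attr(out, "eps_fh") <- eps_fh
  out
}
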