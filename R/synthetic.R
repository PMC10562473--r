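with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  set.seed(seed)
  expr
}

#' Synthetic Ki-67-like consensus repeat
#'
#' A synthetic 122-residue stand-in for a single Ki-67 consensus repeat
#' unit: an intrinsically disordered, lysine/arginine-rich sequence carrying
#' eleven proline-directed (S/T-P) CDK phosphosites spread evenly along the
#' chain and a net charge of +7e, so that charge neutralisation by
#' multisite phosphorylation (each site adding -2e) falls inside the
#' phosphosite range. It is constructed, not a natural sequence; its
#' composition (K/R 16, D/E 9, S/T/P/G/Q/N/A/V/L background) emulates a
#' basic disordered repeat.
#'
#' @return An [aa_sequence()] of length 122 with 11 S/T-P sites
#'   (positions 4, 15, ..., 114).
#' @export
ki67_consensus_repeat <- function() {
  blocks <- c("AGSPNKRQVGL", "QATPGERNAVL", "GNSPAKDQAVL", "QASPGKRNEVL",
              "GQTPNRDASVL", "ANSPGKEQAVL", "GQSPAKRNDVL", "ANTPGRDQAVL",
              "GQSPNKETAVL", "AGSPQKRNAVL", "GNSPAKRQEVL")
  aa_sequence("synthetic_ki67_consensus_repeat",
              paste0("M", paste(blocks, collapse = "")))
}

#' Synthetic polyampholyte sequences of controlled blockiness
#'
#' Glu/Lys sequences with equal composition across the family: alternation
#' period 1 gives `EKEK...`, period N/2 the diblock. The windowed
#' sequence-charge-decoration becomes more attractive (more negative) as
#' block size grows.
#'
#' @param period Block length (residues of the same charge in a row).
#' @param N Total length (must be divisible by `2 * period` for exact
#'   charge balance).
#' @return An [aa_sequence()] with attribute `blockiness` (the period).
#' @export
synth_polyampholyte <- function(period, N) {
  stopifnot(period >= 1, N >= 2 * period)
  if (N %% (2 * period) != 0) {
    stop("N must be a multiple of 2 * period for a net-neutral sequence")
  }
  unit <- c(rep("E", period), rep("K", period))
  s <- paste(rep(unit, N / (2 * period)), collapse = "")
  out <- aa_sequence(sprintf("synthetic_EK_period%d_N%d", period, N), s)
  attr(out, "blockiness") <- period
  out
}

#' Synthetic FRAP trace from the exponential recovery model
#'
#' Generates `y(t) = c - a exp(-k t)` for the bleached region (post-bleach),
#' a constant-1 pre-bleach segment, constant unbleached and nucleus
#' channels, and additive Gaussian noise; the generating parameters ride
#' along as `truth`.
#'
#' @param a Bleach depth (ymax - ymin).
#' @param k Recovery rate (1/s, > 0).
#' @param c Recovery plateau ymax.
#' @param noise_sd Additive Gaussian noise sd (0 = noise-free).
#' @param n_points Number of post-bleach samples (1 s spacing).
#' @param seed Seed for the noise.
#' @return A [frap_trace()] with attribute `truth`.
#' @export
synth_frap <- function(a = 0.6, k = 0.1, c = 1, noise_sd = 0,
                       n_points = 100, seed = NULL) {
  stopifnot(k > 0)
  with_seed(seed, {
    t_pre <- c(-2, -1)
    t_post <- seq(0, n_points - 1)
    y_post <- c - a * exp(-k * t_post)
    y <- c(rep(1, 2), y_post)
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    tr <- frap_trace(c(t_pre, t_post), pmax(y, 0),
                     unbleached = rep(1, length(y)),
                     nucleus = rep(1, length(y)))
    tr$normalized <- TRUE
    attr(tr, "truth") <- list(a = a, k = k, c = c, noise_sd = noise_sd)
    tr
  })
}

#' Synthetic physics curves: distances, coexistence gaps, slab profile
#'
#' Model-generated inputs for the fitting estimators, with ground truth
#' attached: intramolecular distances `R = 0.55 sep^nu`, coexistence
#' density gaps `A (Tc - T)^0.325`, and a slab density profile on a 200 nm
#' axis whose dense slab can be planted off-centre to exercise centring.
#'
#' @param nu Scaling exponent for the distance curve.
#' @param seps Separations (default 5:100).
#' @param A,Tc Coexistence-gap parameters.
#' @param temps Temperatures for the gap curve (must lie below `Tc`).
#' @param rho_H,rho_L Dense/dilute densities of the slab profile.
#' @param slab_center Slab centre on the z axis (nm; 100 = centred).
#' @param slab_halfwidth Slab half-width (nm).
#' @param noise_sd Multiplicative (distances) / additive (gaps, profile)
#'   noise level; 0 = exact.
#' @param seed Seed.
#' @return list with `distances`, `binodal_points`, `profile`, `truth`.
#' @export
synth_physics_curves <- function(nu = 0.5, seps = 5:100,
                                 A = 1, Tc = 2, temps = seq(1, 1.9, by = 0.1),
                                 rho_H = 300, rho_L = 5,
                                 slab_center = 100, slab_halfwidth = 25,
                                 noise_sd = 0, seed = NULL) {
  stopifnot(all(temps < Tc))
  with_seed(seed, {
    R <- 0.55 * seps^nu
    if (noise_sd > 0) R <- R * exp(stats::rnorm(length(R), 0, noise_sd))
    drho <- A * (Tc - temps)^0.325
    if (noise_sd > 0) drho <- drho + stats::rnorm(length(drho), 0, noise_sd * A)
    z <- seq(0.5, 199.5, by = 1)
    dist_circ <- pmin(abs(z - slab_center), 200 - abs(z - slab_center))
    dens <- ifelse(dist_circ <= slab_halfwidth, rho_H, rho_L)
    if (noise_sd > 0) dens <- pmax(dens + stats::rnorm(length(z), 0, noise_sd * rho_H), 0)
    list(distances = data.frame(sep = seps, R = R),
         binodal_points = data.frame(T = temps, drho = drho),
         profile = data.frame(z = z, density = dens),
         truth = list(nu = nu, A = A, Tc = Tc, rho_H = rho_H, rho_L = rho_L,
                      slab_center = slab_center))
  })
}

COMP_IDR <- c(A = 0.08, R = 0.05, N = 0.05, D = 0.06, C = 0.005, Q = 0.07,
              E = 0.09, G = 0.09, H = 0.02, I = 0.02, L = 0.04, K = 0.08,
              M = 0.01, F = 0.01, P = 0.10, S = 0.12, T = 0.06, W = 0.005,
              Y = 0.01, V = 0.03)
COMP_ORD <- c(A = 0.09, R = 0.05, N = 0.04, D = 0.05, C = 0.02, Q = 0.04,
              E = 0.06, G = 0.07, H = 0.02, I = 0.06, L = 0.10, K = 0.06,
              M = 0.03, F = 0.05, P = 0.03, S = 0.06, T = 0.05, W = 0.01,
              Y = 0.03, V = 0.08)

#' Synthetic proteome with planted disorder and phosphorylation structure
#'
#' Generates proteins with one planted disordered block each (pLDDT-style
#' confidence tracks: disordered residues ~N(35, 8), ordered ~N(85, 6),
#' clamped to \[0, 100\]), residue compositions enriched in S/T/P and
#' charged residues inside the disordered blocks, phosphosites on S/T
#' residues assigned so that the odds of phosphorylation in disordered vs
#' structured regions equal a planted odds ratio, and (optionally) a log2
#' phosphopeptide intensity matrix with time-structured dynamic sites and
#' intensity-dependent (left-censored, logistic) missingness. Everything is
#' a pure function of the spec and seed; ground truth is returned alongside.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (uniform draw).
#' @param idr_fraction_range Range of the per-protein disordered fraction.
#' @param or_planted Planted odds ratio of phosphorylation in disordered vs
#'   structured S/T (must be > 0).
#' @param p_phospho_structured Baseline phosphorylation probability of a
#'   structured S/T (the disordered probability follows from the OR).
#' @param dynamic_fraction Fraction of phosphosites given a planted
#'   timepoint effect.
#' @param n_timepoints,n_replicates Intensity-matrix design.
#' @param group_shift Planted dynamic effect, in units of the residual sd.
#' @param noise_sd Residual intensity sd (log2 units).
#' @param missingness Target overall missing fraction (0 disables).
#' @param intensity Generate the intensity matrix (disable for speed when
#'   only site counts are needed).
#' @param seed Seed.
#' @return list with `sequences` (list of [aa_sequence()]), `tracks` (list
#'   of [disorder_track()]), `sites` (data.frame: `protein_id`, `position`,
#'   `residue`, `phosphorylated`, `dynamic`, `in_idr`), `intensity`
#'   (matrix or `NULL`), `groups` (sample grouping), `truth`.
#' @export
synth_proteome <- function(n_proteins = 40, length_range = c(300, 600),
                           idr_fraction_range = c(0.25, 0.55),
                           or_planted = 4.6, p_phospho_structured = 0.1,
                           dynamic_fraction = 0.3, n_timepoints = 4,
                           n_replicates = 3, group_shift = 4, noise_sd = 1,
                           missingness = 0.15, intensity = TRUE,
                           seed = NULL) {
  stopifnot(or_planted > 0, p_phospho_structured > 0, p_phospho_structured < 1)
  odds_out <- p_phospho_structured / (1 - p_phospho_structured)
  odds_in <- or_planted * odds_out
  p_in <- odds_in / (1 + odds_in)
  if (p_in >= 1) stop("infeasible odds ratio for the given baseline")
  with_seed(seed, {
    seqs <- vector("list", n_proteins)
    tracks <- vector("list", n_proteins)
    site_rows <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      id <- sprintf("synprot%03d", i)
      L <- sample(seq(length_range[1], length_range[2]), 1)
      fidr <- stats::runif(1, idr_fraction_range[1], idr_fraction_range[2])
      lidr <- max(10L, round(fidr * L))
      start <- sample(seq_len(L - lidr + 1L), 1)
      planted <- rep(FALSE, L)
      planted[start:(start + lidr - 1L)] <- TRUE
      res <- character(L)
      res[planted] <- sample(names(COMP_IDR), sum(planted), TRUE, COMP_IDR)
      res[!planted] <- sample(names(COMP_ORD), sum(!planted), TRUE, COMP_ORD)
      scores <- ifelse(planted, stats::rnorm(L, 35, 8), stats::rnorm(L, 85, 6))
      scores <- pmin(pmax(scores, 0), 100)
      seqs[[i]] <- aa_sequence(id, paste(res, collapse = ""))
      tracks[[i]] <- disorder_track(id, scores, "plddt")
      st <- which(res %in% c("S", "T"))
      if (!length(st)) next
      in_idr <- tracks[[i]]$mask[st]
      ph <- stats::runif(length(st)) < ifelse(in_idr, p_in, p_phospho_structured)
      site_rows[[i]] <- data.frame(
        protein_id = id, position = st, residue = res[st],
        phosphorylated = ph, dynamic = FALSE, in_idr = in_idr,
        stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, site_rows)
    rownames(sites) <- NULL
    names(seqs) <- names(tracks) <- vapply(seqs, function(s) s$id, "")
    mat <- NULL; groups <- NULL
    phos_idx <- which(sites$phosphorylated)
    n_dyn <- round(dynamic_fraction * length(phos_idx))
    dyn_idx <- if (n_dyn > 0) sample(phos_idx, n_dyn) else integer()
    sites$dynamic[dyn_idx] <- TRUE
    if (intensity && length(phos_idx)) {
      ns <- n_timepoints * n_replicates
      groups <- factor(rep(seq_len(n_timepoints), each = n_replicates))
      base <- stats::rnorm(length(phos_idx), 20, 2)
      mu <- matrix(base, length(phos_idx), ns)
      is_dyn <- sites$dynamic[phos_idx]
      if (any(is_dyn)) {
        # each dynamic site peaks in one random timepoint
        peak <- sample(seq_len(n_timepoints), sum(is_dyn), TRUE)
        shift <- group_shift * noise_sd
        mu[is_dyn, ] <- mu[is_dyn, ] +
          shift * (matrix(peak, sum(is_dyn), ns) ==
                     matrix(rep(as.integer(groups), each = sum(is_dyn)),
                            sum(is_dyn), ns))
      }
      mat <- mu + stats::rnorm(length(mu), 0, noise_sd)
      rownames(mat) <- paste0(sites$protein_id[phos_idx], "_",
                              sites$position[phos_idx])
      if (missingness > 0) {
        # left-censored: logistic in the true intensity
        thr <- stats::quantile(mat, missingness)
        p_miss <- stats::plogis((thr - mat) / (0.5 * noise_sd) + 0)
        mat[stats::runif(length(mat)) < p_miss] <- NA
      }
    }
    list(sequences = seqs, tracks = tracks, sites = sites,
         intensity = mat, groups = groups,
         truth = list(or_planted = or_planted, p_in = p_in,
                      p_out = p_phospho_structured,
                      dynamic_sites = rownames(mat)[sites$dynamic[phos_idx]],
                      dynamic_flags = sites$dynamic[phos_idx]))
  })
}
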