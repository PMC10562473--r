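#' Construct a FRAP trace
#'
#' Time series of region intensities around a photobleaching event at
#' t = 0: the bleached region, a contiguous unbleached region of the same
#' compartment, and the whole nucleus (used for acquisition-photobleaching
#' correction). At least two pre-bleach samples (t < 0) are required.
#'
#' @param time Seconds, strictly increasing, bleach at t = 0.
#' @param bleached,unbleached,nucleus Non-negative intensity vectors.
#' @return A `frap_trace` object.
#' @export
frap_trace <- function(time, bleached, unbleached = NULL, nucleus = NULL) {
  stopifnot(length(time) == length(bleached))
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (sum(time < 0) < 2L) stop("need >= 2 pre-bleach samples (t < 0)")
  if (any(bleached < 0)) stop("intensities must be >= 0")
  if (is.null(unbleached)) unbleached <- rep(NA_real_, length(time))
  if (is.null(nucleus)) nucleus <- rep(1, length(time))
  structure(list(time = time, bleached = bleached, unbleached = unbleached,
                 nucleus = nucleus),
            class = "frap_trace")
}

#' Read a FRAP trace from CSV
#'
#' Columns: `t`, `bleached`, `unbleached`, `nucleus`.
#' @param path CSV file.
#' @return A [frap_trace()].
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "bleached", "unbleached", "nucleus") %in% names(df)))
  frap_trace(df$t, df$bleached, df$unbleached, df$nucleus)
}

#' Normalise a FRAP trace
#'
#' Each region intensity is divided by the whole-nucleus mean at the same
#' time point (removing multiplicative acquisition photobleaching), then
#' scaled so the mean pre-bleach value equals 1. The result is invariant
#' under a global multiplicative gain.
#'
#' @param trace A [frap_trace()].
#' @return The trace with `bleached`/`unbleached` normalised and
#'   `normalized = TRUE`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (any(trace$nucleus <= 0)) stop("nucleus intensity must be > 0 at all times")
  pre <- trace$time < 0
  b <- trace$bleached / trace$nucleus
  u <- trace$unbleached / trace$nucleus
  b <- b / mean(b[pre])
  if (!all(is.na(u))) u <- u / mean(u[pre])
  out <- trace
  out$bleached <- b
  out$unbleached <- u
  out$normalized <- TRUE
  out
}

#' Fit the exponential FRAP recovery model
#'
#' Nonlinear least squares of `y = c - a * exp(b * t)` (with `b = -k`) to
#' the post-bleach points of a normalised trace. `c` is the recovery
#' plateau ymax and `c - a` the post-bleach minimum ymin. Initialisation:
#' `c` from the mean of the last 10\% of points, `a = c - y(0+)`, and `k`
#' from the first time the signal passes halfway to the plateau. A trace
#' with no upward trend is still fitted but flagged.
#'
#' @param trace A normalised [frap_trace()] (or any list with `time` and
#'   `bleached`).
#' @param channel `"bleached"` (default) or `"unbleached"` (the mixing
#'   comparison uses the same model on the unbleached region).
#' @return A `frap_fit` list: `a`, `b`, `c`, `k` (= -b), `ymin`, `ymax`,
#'   `t_half` in both conventions, `total_recovery`, `residual_norm`,
#'   `warning_flat`.
#' @export
fit_recovery <- function(trace, channel = c("bleached", "unbleached")) {
  channel <- match.arg(channel)
  y <- trace[[channel]]
  t <- trace$time
  post <- t >= 0
  if (sum(post) < 10L) stop("need >= 10 post-bleach points")
  tp <- t[post]; yp <- y[post]
  c0 <- mean(yp[tp >= stats::quantile(tp, 0.9)])
  y0 <- yp[1]
  a0 <- max(c0 - y0, 1e-6)
  half <- (c0 + y0) / 2
  idx <- which(yp >= half)
  t_rough <- if (length(idx)) max(tp[idx[1]], tp[2]) else max(tp) / 2
  k0 <- log(2) / t_rough
  flat <- stats::coef(stats::lm(yp ~ tp))[2] <= 0 ||
    (max(yp) - min(yp)) < 1e-3 * max(abs(yp), 1e-12)
  # self-starting asymptotic regression (same model, y = c - a exp(-k t)),
  # polished by Levenberg-Marquardt; plain LM from the rough start as
  # fallback for traces SSasymp rejects
  cf <- NULL
  ss <- try(suppressWarnings(
    stats::nls(yp ~ SSasymp(tp, Asym, R0, lrc))), silent = TRUE)
  if (!inherits(ss, "try-error")) {
    sc <- stats::coef(ss)
    cf <- c(cc = unname(sc["Asym"]), aa = unname(sc["Asym"] - sc["R0"]),
            kk = exp(unname(sc["lrc"])))
  }
  start <- if (is.null(cf)) list(cc = c0, aa = a0, kk = k0) else as.list(cf)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    yp ~ cc - aa * exp(-kk * tp),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))), silent = TRUE)
  if (inherits(fit, "try-error")) {
    if (is.null(cf)) {
      cf <- c(cc = c0, aa = 0, kk = k0)
      flat <- TRUE
    }
    rn <- sqrt(sum((cf["cc"] - cf["aa"] * exp(-cf["kk"] * tp) - yp)^2))
  } else {
    cf <- stats::coef(fit)
    rn <- sqrt(sum(stats::resid(fit)^2))
  }
  a <- unname(cf["aa"]); k <- unname(cf["kk"]); cmax <- unname(cf["cc"])
  ymin <- cmax - a
  structure(list(a = a, b = -k, c = cmax, k = k,
                 ymin = ymin, ymax = cmax,
                 t_half_paper = if (k > 0) t_half(k, "paper") else NA_real_,
                 t_half_ln2_over_k = if (k > 0) t_half(k, "ln2_over_k") else NA_real_,
                 total_recovery = if (ymin < 1) total_recovery(cmax, ymin) else NA_real_,
                 residual_norm = rn, warning_flat = flat),
            class = "frap_fit")
}

#' Recovery half-time
#'
#' Two conventions are exposed and every result is tagged: `"paper"`
#' returns `1 / (k * ln 2)` (the printed formula of the source model) and
#' `"ln2_over_k"` the conventional exponential half-life `ln 2 / k`. The
#' two differ by a factor `(ln 2)^2`.
#'
#' @param k Recovery rate constant (> 0), 1/s.
#' @param convention `"paper"` or `"ln2_over_k"`.
#' @return Half-time in seconds, with attribute `convention`.
#' @export
t_half <- function(k, convention = c("paper", "ln2_over_k")) {
  convention <- match.arg(convention)
  if (any(k <= 0)) stop("k must be > 0")
  out <- if (convention == "paper") 1 / (k * log(2)) else log(2) / k
  attr(out, "convention") <- convention
  out
}

#' Total (mobile) fraction recovered
#'
#' `TR = (ymax - ymin) / (1 - ymin)` on a normalised trace.
#'
#' @param ymax Recovery plateau.
#' @param ymin Post-bleach minimum (< 1).
#' @return Total recovery.
#' @export
total_recovery <- function(ymax, ymin) {
  if (any(ymin >= 1)) stop("ymin must be < 1")
  (ymax - ymin) / (1 - ymin)
}
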