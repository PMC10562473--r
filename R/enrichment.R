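#' Impute missing intensities by low-end normal draws
#'
#' Missing entries of a log2 intensity matrix are replaced by draws from a
#' normal distribution downshifted relative to the observed data:
#' mean = mean(observed) - downshift * sd(observed), sd = width * sd(observed).
#' This emulates left-censored missingness, where values are absent because
#' they fall below the detection limit.
#'
#' @param mat Numeric matrix (sites x samples), `NA` marks missing.
#' @param downshift Downshift in units of the dataset sd (default 1.8).
#' @param width Width of the imputation distribution in sd units (default 0.3).
#' @param seed Optional integer seed for reproducible imputation.
#' @return The matrix with missing entries filled in.
#' @export
impute_missing <- function(mat, downshift = 1.8, width = 0.3, seed = NULL) {
  stopifnot(is.matrix(mat))
  obs <- mat[is.finite(mat)]
  if (length(obs) < 2L) stop("need at least two finite values to impute")
  miss <- which(!is.finite(mat))
  if (!length(miss)) return(mat)
  m <- mean(obs); s <- stats::sd(obs)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  mat[miss] <- stats::rnorm(length(miss), mean = m - downshift * s,
                            sd = width * s)
  mat
}

#' Median-normalise a log2 intensity matrix
#'
#' Subtracts the per-sample median, the usual normalisation applied before
#' group testing.
#'
#' @param mat Numeric matrix (sites x samples).
#' @return Normalised matrix.
#' @export
median_normalize <- function(mat) {
  sweep(mat, 2, apply(mat, 2, stats::median, na.rm = TRUE))
}

#' Classify dynamic phosphosites by one-way ANOVA
#'
#' Per-site one-way ANOVA across timepoint groups on (imputed,
#' median-normalised) log2 intensities, with Benjamini-Hochberg adjustment
#' across sites; a site is dynamic when q < alpha. Sites with zero variance
#' in every group are skipped with a warning (flag `NA`).
#'
#' @param mat Numeric matrix (sites x samples), no missing values.
#' @param groups Factor or vector of length `ncol(mat)` giving the timepoint
#'   group of each sample; every group needs >= 2 members.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with columns `site`, `F`, `p`, `q`, `dynamic`.
#' @export
classify_dynamic_sites <- function(mat, groups, alpha = 0.05) {
  stopifnot(is.matrix(mat), ncol(mat) == length(groups))
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  groups <- as.factor(groups)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 replicates each")
  }
  n <- ncol(mat); g <- length(tab)
  gm <- t(apply(mat, 1, function(x) tapply(x, groups, mean)))
  grand <- rowMeans(mat)
  ns <- as.numeric(tab[colnames(gm)])
  ss_between <- as.numeric((gm - grand)^2 %*% ns)
  fitted <- gm[, as.character(groups), drop = FALSE]
  ss_within <- rowSums((mat - fitted)^2)
  df1 <- g - 1L; df2 <- n - g
  Fstat <- (ss_between / df1) / (ss_within / df2)
  degenerate <- ss_within < .Machine$double.eps * n & ss_between < .Machine$double.eps * n
  if (any(degenerate)) {
    warning(sum(degenerate), " site(s) with zero variance skipped")
    Fstat[degenerate] <- NA_real_
  }
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(site = if (is.null(rownames(mat))) seq_len(nrow(mat)) else rownames(mat),
             F = Fstat, p = p, q = q,
             dynamic = !is.na(q) & q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected vs observed phosphorylation in IDRs, per protein
#'
#' For each protein, the expected number of phospho-S/T falling in its IDRs
#' under compositional indifference is `n_phospho * (S/T in IDR)/(S/T total)`;
#' the observed count is tested against this proportion with a one-sided
#' (greater) binomial test, and p-values are BH-adjusted across proteins.
#' Tyr sites are excluded throughout.
#'
#' @param sites data.frame with columns `protein_id`, `residue` (S/T/Y),
#'   `phosphorylated` (logical), `in_idr` (logical).
#' @return data.frame with `protein_id`, `n_st`, `n_st_idr`, `n_phospho`,
#'   `expected`, `observed`, `p_value`, `q_value`.
#' @export
expected_observed_idr <- function(sites) {
  need <- c("protein_id", "residue", "phosphorylated", "in_idr")
  stopifnot(all(need %in% names(sites)))
  st <- sites[sites$residue %in% c("S", "T"), ]
  out <- lapply(split(st, st$protein_id), function(d) {
    n_st <- nrow(d)
    if (n_st == 0L) stop("protein with zero S/T: ", d$protein_id[1])
    n_idr <- sum(d$in_idr)
    n_ph <- sum(d$phosphorylated)
    obs <- sum(d$phosphorylated & d$in_idr)
    p0 <- n_idr / n_st
    pv <- if (n_ph == 0L) 1 else
      stats::binom.test(obs, n_ph, p = p0, alternative = "greater")$p.value
    data.frame(protein_id = d$protein_id[1], n_st = n_st, n_st_idr = n_idr,
               n_phospho = n_ph, expected = n_ph * p0, observed = obs,
               p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Pooled odds ratio of phosphorylation in disordered regions
#'
#' Builds the pooled two-by-two table of phosphorylatable (S/T) residues,
#' phosphorylated or not, in IDRs or structured regions, and reports the
#' sample odds ratio (a*d)/(b*c) with Fisher exact inference. The 95\% CI is
#' the conditional maximum-likelihood interval from the Fisher test. With
#' `method = "mh"` a Mantel-Haenszel estimate stratified by protein is
#' returned instead. Zero cells trigger the Haldane-Anscombe 0.5 correction
#' for the sample OR (flagged in the output).
#'
#' @param sites data.frame as in [expected_observed_idr()].
#' @param method `"fisher"` (pooled) or `"mh"` (stratified by protein).
#' @return list with `or`, `ci` (length 2), `p`, `table`, `method`,
#'   `ci_method`, `corrected`.
#' @export
pooled_odds_ratio <- function(sites, method = c("fisher", "mh")) {
  method <- match.arg(method)
  st <- sites[sites$residue %in% c("S", "T"), ]
  a <- sum(st$phosphorylated & st$in_idr)
  b <- sum(st$phosphorylated & !st$in_idr)
  c_ <- sum(!st$phosphorylated & st$in_idr)
  d <- sum(!st$phosphorylated & !st$in_idr)
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("phospho", "non_phospho"),
                                c("idr", "structured")))
  if (method == "mh") {
    strata <- split(st, st$protein_id)
    arr <- vapply(strata, function(dd) {
      c(sum(dd$phosphorylated & dd$in_idr), sum(dd$phosphorylated & !dd$in_idr),
        sum(!dd$phosphorylated & dd$in_idr), sum(!dd$phosphorylated & !dd$in_idr))
    }, numeric(4))
    arr3 <- array(arr, dim = c(2, 2, ncol(arr)))
    mh <- stats::mantelhaen.test(arr3)
    return(list(or = unname(mh$estimate), ci = unname(mh$conf.int),
                p = mh$p.value, table = tab, method = "mh",
                ci_method = "mantel-haenszel", corrected = FALSE))
  }
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  ft <- stats::fisher.test(round(t2))
  list(or = or, ci = unname(ft$conf.int), p = ft$p.value, table = tab,
       method = "fisher", ci_method = "conditional-mle", corrected = corrected)
}

aa_composition <- function(seqs) {
  chars <- unlist(lapply(seqs, function(s) {
    if (inherits(s, "aa_sequence")) seq_chars(s) else strsplit(s, "")[[1]]
  }))
  counts <- table(factor(chars, levels = AA_ALPHABET))
  as.numeric(counts) / length(chars)
}

#' Differential disorder composition
#'
#' Per-amino-acid relative compositional difference between the disordered
#' subsequences and the whole phosphoproteome:
#' `(comp_disorder - comp_phosphoproteome) / comp_phosphoproteome`.
#' Positive values mark residues enriched in disordered regions. An amino
#' acid absent from the phosphoproteome has an undefined delta (`NA`,
#' flagged).
#'
#' @param disorder_seqs List of sequences (strings or [aa_sequence()]) of
#'   the disordered regions.
#' @param phospho_seqs List of full phosphoproteome sequences.
#' @return data.frame with `amino_acid`, `comp_disorder`,
#'   `comp_phosphoproteome`, `delta`, `defined`.
#' @export
differential_composition <- function(disorder_seqs, phospho_seqs) {
  if (!length(disorder_seqs) || !length(phospho_seqs)) {
    stop("both sequence sets must be non-empty")
  }
  cd <- aa_composition(disorder_seqs)
  cp <- aa_composition(phospho_seqs)
  delta <- ifelse(cp > 0, (cd - cp) / cp, NA_real_)
  data.frame(amino_acid = AA_ALPHABET, comp_disorder = cd,
             comp_phosphoproteome = cp, delta = delta,
             defined = cp > 0, stringsAsFactors = FALSE)
}

HYDROPHOBIC <- c("A", "V", "I", "L", "M", "F", "W", "Y")

#' Kinase consensus motif rules
#'
#' The rule set used by [classify_motifs()], expressed relative to the
#' phosphosite (offset 0 = the phosphorylated S/T). Each rule is a list of
#' `offset` -> allowed residue set; all offsets must exist in the sequence
#' and match. `PLK` and `PKA` use the hydrophobic set
#' A,V,I,L,M,F,W,Y at +1.
#'
#' @return Named list of rule lists (a label may carry several alternative
#'   rules; any match suffices).
#' @export
motif_rules <- function() {
  H <- HYDROPHOBIC
  list(
    PLK = list(list(`-2` = c("D", "N", "E", "Y"), `1` = H)),
    Aurora = list(list(`-2` = c("K", "R"), `1` = setdiff(AA_ALPHABET, "P"))),
    NEK = list(list(`-2` = c("L", "M", "F", "W"),
                    `1` = c("A", "V", "I", "L", "F", "W", "Y", "M"),
                    `2` = c("K", "R"))),
    CK1 = list(list(`-5` = c("D", "E"), `-4` = c("D", "E"), `-3` = c("D", "E")),
               list(`-3` = c("S", "T"))),
    CK2 = list(list(`-1` = c("S", "T"), `2` = c("E", "D", "S"))),
    DDK = list(list(`1` = c("E", "D"), `3` = c("E", "D")),
               list(`1` = c("S", "T"), `2` = "P")),
    PKA = list(list(`-3` = "R", `-2` = c("R", "K"), `1` = H)),
    CDK_full = list(list(`1` = "P", `3` = c("K", "R"))),
    CDK_minimal = list(list(`1` = "P")),
    MAPK_GPLSP = list(list(`-3` = "G", `-2` = "P", `-1` = "L", `1` = "P"))
  )
}

#' Classify a phosphosite by kinase consensus motifs
#'
#' Tests the sequence context of an S/T phosphosite against the kinase
#' consensus rules ([motif_rules()]). A site may carry several labels;
#' a full CDK consensus (S/T-P-x-K/R) always implies the minimal one
#' (S/T-P). Rules whose required context runs off the sequence edge simply
#' do not match.
#'
#' @param seq An [aa_sequence()].
#' @param position 1-based S/T position.
#' @return Character vector of matching labels (possibly empty).
#' @export
classify_motifs <- function(seq, position) {
  stopifnot(inherits(seq, "aa_sequence"))
  r <- seq_chars(seq)
  n <- length(r)
  position <- as.integer(position)
  if (position < 1L || position > n) stop("position out of range")
  if (!r[position] %in% c("S", "T")) stop("position does not hold S/T")
  rules <- motif_rules()
  hit <- vapply(rules, function(alts) {
    any(vapply(alts, function(rule) {
      offs <- as.integer(names(rule))
      pos <- position + offs
      if (any(pos < 1L | pos > n)) return(FALSE)
      all(mapply(function(p, allowed) r[p] %in% allowed, pos, rule))
    }, TRUE))
  }, TRUE)
  names(hit)[hit]
}

#' Dunn's post hoc test for pairwise group comparisons
#'
#' Two-sided Dunn z-tests on mean ranks after a Kruskal-Wallis test, with
#' the standard ties correction, BH-adjusted across pairs.
#'
#' @param values Numeric vector.
#' @param groups Factor of the same length.
#' @return data.frame with `group1`, `group2`, `z`, `p`, `q`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  labs <- levels(groups)
  pairs <- utils::combn(labs, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    (mr[pr[1]] - mr[pr[2]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p = as.numeric(p), q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Compare disorder fractions between groups
#'
#' Two groups: two-sided Wilcoxon-Mann-Whitney test. More than two:
#' Kruskal-Wallis followed by Dunn's two-sided pairwise post hoc tests with
#' BH adjustment.
#'
#' @param groups Named list of numeric vectors (disorder fractions per
#'   group); each group needs n >= 3.
#' @return list with `test` (`"wilcoxon"` or `"kruskal_dunn"`), `p`
#'   (global p-value), and for >2 groups `pairwise` (the Dunn table).
#' @export
disorder_fraction_compare <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 3L)) stop("each group needs n >= 3")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), ns), levels = names(groups))
  if (length(groups) == 2L) {
    w <- stats::wilcox.test(groups[[1]], groups[[2]], alternative = "two.sided",
                            exact = FALSE, correct = TRUE)
    return(list(test = "wilcoxon", p = w$p.value))
  }
  kw <- stats::kruskal.test(values, fac)
  list(test = "kruskal_dunn", p = kw$p.value,
       pairwise = dunn_test(values, fac))
}
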