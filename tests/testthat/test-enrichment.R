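test_that("imputation draws from the downshifted normal law", {
  m <- matrix(rnorm(50, 20, 2), 10, 5)
  expect_identical(impute_missing(m), m)   # nothing missing: unchanged
  set.seed(3)
  big <- matrix(rnorm(40000, 20, 2), 200, 200)
  miss <- sample(length(big), 8000)
  holes <- big; holes[miss] <- NA
  obs_mean <- mean(holes, na.rm = TRUE); obs_sd <- sd(holes[!is.na(holes)])
  imp <- impute_missing(holes, seed = 9)
  vals <- imp[miss]
  expect_equal(mean(vals), obs_mean - 1.8 * obs_sd, tolerance = 0.02)
  expect_equal(sd(vals), 0.3 * obs_sd, tolerance = 0.02)
  expect_identical(impute_missing(holes, seed = 9), imp)  # seeded determinism
  expect_error(impute_missing(matrix(NA_real_, 3, 3)), "finite")
})

test_that("dynamic-site ANOVA flags planted shifts and controls the null", {
  set.seed(5)
  groups <- rep(1:4, each = 4)
  m <- matrix(rnorm(200 * 16), 200, 16)
  m[101:200, groups == 2] <- m[101:200, groups == 2] + 4  # 4-sd group shift
  res <- classify_dynamic_sites(m, groups)
  expect_gte(sum(res$dynamic[101:200]), 95)
  expect_lte(sum(res$dynamic[1:100]), 10)
  # permuting samples within groups leaves flags unchanged
  perm <- c(2, 1, 3, 4, 6, 5, 7, 8, 9, 11, 10, 12, 16, 13, 15, 14)
  res_p <- classify_dynamic_sites(m[, perm], groups[perm])
  expect_equal(res_p$dynamic, res$dynamic)
  # all sites identical across groups: zero variance handled with a warning
  flat <- matrix(7, 5, 16)
  expect_warning(res0 <- classify_dynamic_sites(flat, groups), "zero variance")
  expect_equal(sum(res0$dynamic, na.rm = TRUE), 0)
})

test_that("expected/observed counts follow the compositional proportion", {
  sites <- data.frame(
    protein_id = "p1",
    residue = rep(c("S", "T"), 5),
    phosphorylated = c(rep(TRUE, 5), rep(FALSE, 5)),
    in_idr = rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 2))
  eo <- expected_observed_idr(sites)
  expect_equal(eo$expected, 5 * 4 / 10)   # n_phospho * (S/T in IDR)/(S/T)
  expect_equal(eo$n_st, 10L)
  # all S/T in IDR: observed = expected = n_phospho, p degenerate at 1
  all_in <- transform(sites, in_idr = TRUE)
  eo2 <- expected_observed_idr(all_in)
  expect_equal(eo2$observed, eo2$n_phospho)
  expect_equal(eo2$expected, eo2$n_phospho)
  expect_equal(eo2$p_value, 1)
  # observed equal to expected: one-sided binomial p >= 0.5, checked against
  # a tail summation oracle
  s3 <- data.frame(protein_id = "p", residue = "S",
                   phosphorylated = rep(c(TRUE, FALSE), c(10, 10)),
                   in_idr = rep(c(TRUE, FALSE), 10))
  eo3 <- expected_observed_idr(s3)
  expect_equal(eo3$observed, eo3$expected)
  p_oracle <- sum(dbinom(eo3$observed:eo3$n_phospho, eo3$n_phospho, 0.5))
  expect_equal(eo3$p_value, p_oracle)
  expect_gte(eo3$p_value, 0.5)
  # Y sites never enter the denominators
  with_y <- rbind(sites, data.frame(protein_id = "p1", residue = "Y",
                                    phosphorylated = TRUE, in_idr = TRUE))
  expect_equal(expected_observed_idr(with_y)$n_st, 10L)
})

test_that("pooled odds ratio matches the cross-product and its symmetries", {
  mk <- function(a, b, c_, d) data.frame(
    protein_id = "p", residue = "S",
    phosphorylated = rep(c(TRUE, FALSE), c(a + b, c_ + d)),
    in_idr = c(rep(c(TRUE, FALSE), c(a, b)), rep(c(TRUE, FALSE), c(c_, d))))
  expect_equal(pooled_odds_ratio(mk(10, 10, 10, 10))$or, 1.0)
  res <- pooled_odds_ratio(mk(20, 5, 10, 40))
  expect_equal(res$or, 16.0)
  expect_equal(res$ci_method, "conditional-mle")
  # swapping the roles of the two factors inverts the OR
  swapped <- mk(20, 5, 10, 40)
  tmp <- swapped$phosphorylated
  swapped$phosphorylated <- swapped$in_idr
  swapped$in_idr <- tmp
  expect_equal(pooled_odds_ratio(swapped)$or, res$or)  # symmetric in roles
  flipped <- mk(20, 5, 10, 40)
  flipped$in_idr <- !flipped$in_idr
  expect_equal(pooled_odds_ratio(flipped)$or, 1 / res$or)
  # zero cell: Haldane-Anscombe correction, flagged
  zc <- pooled_odds_ratio(mk(5, 0, 3, 7))
  expect_true(zc$corrected)
  expect_true(is.finite(zc$or))
  # stratified Mantel-Haenszel route runs on multi-protein data
  two <- rbind(mk(8, 4, 5, 9), transform(mk(6, 3, 4, 8), protein_id = "q"))
  mh <- pooled_odds_ratio(two, method = "mh")
  expect_equal(mh$method, "mh")
  expect_true(is.finite(mh$or))
})

test_that("differential composition implements the relative delta", {
  same <- differential_composition(list("ACDEFG"), list("ACDEFG"))
  expect_equal(same$delta[same$defined], rep(0, sum(same$defined)))
  # comp_disorder(P) = 0.10 vs comp_phospho(P) = 0.08 -> 0.25
  dis <- paste(c(rep("P", 10), rep("A", 90)), collapse = "")
  pho <- paste(c(rep("P", 8), rep("A", 92)), collapse = "")
  dc <- differential_composition(list(dis), list(pho))
  expect_equal(dc$delta[dc$amino_acid == "P"], 0.25)
  # disorder lacking W while the phosphoproteome has it: delta = -1
  dc2 <- differential_composition(list("AAAA"), list("AAWW"))
  expect_equal(dc2$delta[dc2$amino_acid == "W"], -1.0)
  # absent from the phosphoproteome: undefined, reported as such
  expect_true(is.na(dc2$delta[dc2$amino_acid == "C"]))
  expect_false(dc2$defined[dc2$amino_acid == "C"])
  # each composition vector sums to one
  expect_equal(sum(dc$comp_disorder), 1)
  expect_equal(sum(dc$comp_phosphoproteome), 1)
})

test_that("motif classification matches the printed consensus rules", {
  expect_setequal(classify_motifs(aa_sequence("m", "AASPAKAA"), 3),
                  c("CDK_minimal", "CDK_full"))
  expect_length(classify_motifs(aa_sequence("m", "AASAAAAA"), 3), 0)
  expect_true("MAPK_GPLSP" %in% classify_motifs(aa_sequence("m", "GPLSPAA"), 4))
  expect_true("PKA" %in% classify_motifs(aa_sequence("m", "ARRASLA"), 5))
  # edge positions: rules needing out-of-range context do not match
  expect_length(classify_motifs(aa_sequence("m", "SA"), 1), 0)
  expect_error(classify_motifs(aa_sequence("m", "APA"), 1), "S/T")
})

test_that("motif classifier equals the regex oracle on random sites", {
  set.seed(23)
  s <- random_aa_seq(1000)
  r <- strsplit(s$residues, "")[[1]]
  st <- which(r %in% c("S", "T"))
  for (pos in st) {
    expect_setequal(classify_motifs(s, pos), motif_regex_oracle(r, pos))
  }
})

test_that("group comparison picks the right test and detects shifts", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_equal(disorder_fraction_compare(g)$test, "wilcoxon")
  expect_gt(disorder_fraction_compare(g)$p, 0.9)
  set.seed(19)
  shifted <- list(a = rnorm(200), b = rnorm(200, 2))   # 2-sd shift
  expect_lt(disorder_fraction_compare(shifted)$p, 1e-3)
  # three equal groups: Kruskal-Wallis + Dunn, nothing significant
  eq3 <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  res <- disorder_fraction_compare(eq3)
  expect_equal(res$test, "kruskal_dunn")
  expect_true(all(res$pairwise$q > 0.05))
  expect_error(disorder_fraction_compare(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("median normalisation zeroes each sample median", {
  m <- matrix(rnorm(60, 10, 3), 12, 5)
  mn <- median_normalize(m)
  expect_equal(apply(mn, 2, median), rep(0, 5))
})
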