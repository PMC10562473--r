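# Independent oracles used across test files.

# brute-force windowed charge-decoration sum: direct double loop over all
# pairs inside every [i, j] window, independent of the package's recurrence
scdm_bruteforce <- function(q) {
  N <- length(q)
  M <- matrix(0, N, N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      idx <- i:j
      tot <- 0
      for (m in idx) {
        for (n in idx) {
          if (m > n) tot <- tot + q[m] * q[n] * sqrt(m - n)
        }
      }
      M[i, j] <- tot / (j - i)
      M[j, i] <- M[i, j]
    }
  }
  M
}

# regex oracle for the kinase motif rules: builds one regular expression per
# rule from the printed rule strings and matches it against the sequence
# window centred on the site (offset 0 = the phosphosite).
motif_regex_oracle <- function(residues, pos) {
  n <- length(residues)
  window <- function(lo, hi) {
    if (pos + lo < 1 || pos + hi > n) return(NA_character_)
    paste(residues[(pos + lo):(pos + hi)], collapse = "")
  }
  hyd <- "[AVILMFWY]"
  rules <- list(
    PLK = list(c(-2, 1, paste0("[DNEY].[ST]", hyd))),
    Aurora = list(c(-2, 1, "[KR].[ST][^P]")),
    NEK = list(c(-2, 2, "[LMFW].[ST][AVILFWYM][KR]")),
    CK1 = list(c(-5, 0, "[DE][DE][DE]..[ST]"), c(-3, 0, "[ST]..[ST]")),
    CK2 = list(c(-1, 2, "[ST][ST].[EDS]")),
    DDK = list(c(0, 3, "[ST][ED].[ED]"), c(0, 2, "[ST][ST]P")),
    PKA = list(c(-3, 1, paste0("R[RK].[ST]", hyd))),
    CDK_full = list(c(1, 3, "P.[KR]")),
    CDK_minimal = list(c(1, 1, "P")),
    MAPK_GPLSP = list(c(-3, 1, "GPL[ST]P"))
  )
  hits <- vapply(rules, function(alts) {
    any(vapply(alts, function(r) {
      w <- window(as.integer(r[1]), as.integer(r[2]))
      !is.na(w) && grepl(paste0("^", r[3], "$"), w)
    }, TRUE))
  }, TRUE)
  names(hits)[hits]
}

random_aa_seq <- function(n, seed = NULL, id = "rnd") {
  if (!is.null(seed)) set.seed(seed)
  aa_sequence(id, paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                               n, replace = TRUE), collapse = ""))
}

# exact equilibrium mean bond length of a harmonic bond with the radial
# Jacobian, by 1D quadrature: <r> = int r^3 exp(-k(r-r0)^2/2kT) /
#                                   int r^2 exp(-k(r-r0)^2/2kT)
harmonic_bond_mean <- function(r0 = 0.38, k = 1000, temperature = 300) {
  kT <- 0.00831446261815324 * temperature
  num <- stats::integrate(function(r) r^3 * exp(-k * (r - r0)^2 / (2 * kT)),
                          0, r0 + 1)$value
  den <- stats::integrate(function(r) r^2 * exp(-k * (r - r0)^2 / (2 * kT)),
                          0, r0 + 1)$value
  num / den
}

# minimal AlphaFold-style mmCIF with the given per-residue pLDDT values
write_minimal_cif <- function(plddt, path) {
  n <- length(plddt)
  hdr <- c("data_synthetic", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- unlist(lapply(seq_len(n), function(i) {
    sprintf("ATOM %d %s %s . ALA A 1 %d ? %.1f 0.0 0.0 1.0 %.2f ? %d ALA A %s 1",
            c(2 * i - 1, 2 * i), c("N", "C"), c("N", "CA"), c(i, i),
            c(i, i + 0.5), c(plddt[i], plddt[i]), c(i, i), c("N", "CA"))
  }))
  writeLines(c(hdr, rows), path)
  path
}
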