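#' @useDynLib phosphosep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct an amino-acid sequence
#'
#' A minimal container for a protein (or IDR) sequence over the canonical
#' 20-letter alphabet. Residues are addressed by 1-based position throughout
#' the package.
#'
#' @param id Character identifier.
#' @param residues Single string of one-letter amino-acid codes.
#' @return An object of class `aa_sequence` with fields `id` and `residues`.
#' @export
aa_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("sequence must be non-empty")
  r <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(r), AA_ALPHABET)
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  structure(list(id = id, residues = residues), class = "aa_sequence")
}

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' @export
length.aa_sequence <- function(x) nchar(x$residues)

#' @export
print.aa_sequence <- function(x, ...) {
  cat(sprintf("<aa_sequence> %s (%d aa)\n", x$id, length(x)))
  invisible(x)
}

#' Named residue charge schemes
#'
#' Two fixed-charge coarse-grained schemes are supported. In both, Asp and
#' Glu carry -1e, Arg and Lys +1e, phosphorylated Ser/Thr -2e and
#' phosphomimetic substitutions -1e. They differ only in histidine:
#' the `scdm` scheme (used for SCDM maps and phase diagrams) treats His as
#' neutral; the `cg` scheme (used by the bead-per-residue simulator) assigns
#' His +0.5e. Terminal charges and pH dependence are deliberately ignored:
#' charges are plain sequence-table lookups.
#'
#' @param name One of `"scdm"` or `"cg"`.
#' @return A `charge_scheme` object with fields `name`, `table` (named
#'   numeric vector over the 20 residues, units of elementary charge),
#'   `phospho_charge` (-2) and `mimic_charge` (-1).
#' @export
charge_scheme <- function(name = c("scdm", "cg")) {
  name <- match.arg(name)
  tab <- stats::setNames(numeric(20), AA_ALPHABET)
  tab[c("D", "E")] <- -1
  tab[c("R", "K")] <- +1
  if (name == "cg") tab["H"] <- 0.5
  structure(list(name = name, table = tab,
                 phospho_charge = -2, mimic_charge = -1),
            class = "charge_scheme")
}

#' Construct a phosphorylation pattern
#'
#' @param candidate_sites Sorted integer vector of 1-based candidate
#'   phosphosite positions (must hold S or T in the parent sequence; this is
#'   checked when charges are assigned).
#' @param active Subset of `candidate_sites` currently phosphorylated.
#' @return A `phospho_pattern` object.
#' @export
phospho_pattern <- function(candidate_sites = integer(), active = integer()) {
  candidate_sites <- as.integer(candidate_sites)
  active <- as.integer(active)
  if (anyDuplicated(candidate_sites)) stop("candidate sites must be distinct")
  if (is.unsorted(candidate_sites)) candidate_sites <- sort(candidate_sites)
  if (!all(active %in% candidate_sites)) {
    stop("active positions must be a subset of candidate_sites")
  }
  structure(list(candidate_sites = candidate_sites, active = sort(active)),
            class = "phospho_pattern")
}

check_st_positions <- function(seq, positions, what = "phosphosite") {
  n <- length(seq)
  if (any(positions < 1L | positions > n)) {
    stop(what, " position out of range 1..", n)
  }
  r <- seq_chars(seq)[positions]
  bad <- positions[!r %in% c("S", "T")]
  if (length(bad)) {
    stop(what, " position(s) not S/T: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Assign per-residue charges under a named scheme
#'
#' Builds the charge sequence used by SCDM and phase-diagram computations.
#' Phosphorylation is modelled by overriding the neutral S/T charge with
#' -2e at each active pattern position.
#'
#' @param seq An [aa_sequence()].
#' @param scheme A [charge_scheme()] or scheme name.
#' @param pattern A [phospho_pattern()]; `NULL` means unmodified.
#' @return A `charge_sequence` object with fields `sequence`, `scheme`,
#'   `pattern` and `charges` (numeric, units of e).
#' @export
assign_charges <- function(seq, scheme = charge_scheme("scdm"), pattern = NULL) {
  if (is.character(scheme)) scheme <- charge_scheme(scheme)
  stopifnot(inherits(seq, "aa_sequence"), inherits(scheme, "charge_scheme"))
  if (is.null(pattern)) pattern <- phospho_pattern()
  stopifnot(inherits(pattern, "phospho_pattern"))
  if (length(pattern$candidate_sites)) {
    check_st_positions(seq, pattern$candidate_sites, "pattern")
  }
  charges <- unname(scheme$table[seq_chars(seq)])
  if (length(pattern$active)) charges[pattern$active] <- scheme$phospho_charge
  structure(list(sequence = seq, scheme = scheme, pattern = pattern,
                 charges = charges),
            class = "charge_sequence")
}

#' Net charge of a charge sequence
#' @param cs A `charge_sequence`.
#' @return Numeric net charge in units of e.
#' @export
net_charge <- function(cs) {
  stopifnot(inherits(cs, "charge_sequence"))
  sum(cs$charges)
}

#' Apply phosphomimetic substitutions
#'
#' Phosphomimetic (S/T to D/E-like) substitutions add a single negative
#' charge per site, in contrast to phosphorylation which adds two. Only the
#' charge is changed; short-range interaction parameters are untouched.
#'
#' @param seq An [aa_sequence()].
#' @param positions S/T positions to substitute.
#' @param scheme Charge scheme (default `scdm`).
#' @return A `charge_sequence` with -1e at the substituted positions.
#' @export
apply_phosphomimetic <- function(seq, positions, scheme = charge_scheme("scdm")) {
  if (is.character(scheme)) scheme <- charge_scheme(scheme)
  positions <- as.integer(positions)
  if (length(positions)) check_st_positions(seq, positions, "mimic")
  cs <- assign_charges(seq, scheme)
  cs$charges[positions] <- scheme$mimic_charge
  cs$mimic_positions <- positions
  cs
}

#' Enumerate phosphosite combinations
#'
#' All subsets of a candidate site list, in deterministic
#' lexicographic-by-bitmask order (bit 1 = first candidate site), or all
#' subsets of a fixed size when `stoichiometry` is given. Eleven candidate
#' sites give the 2048 patterns of a full combinatorial scan.
#'
#' @param candidate_sites Distinct sorted 1-based positions.
#' @param stoichiometry Optional subset size k; `NULL` returns all 2^n.
#' @param limit Refuse enumeration for more than this many sites
#'   (default 20; 2^n memory).
#' @return List of [phospho_pattern()] objects. Full enumerations carry the
#'   bitmask as attribute `bitmask` on each element.
#' @export
enumerate_phospho_patterns <- function(candidate_sites, stoichiometry = NULL,
                                       limit = 20L) {
  candidate_sites <- sort(as.integer(candidate_sites))
  if (anyDuplicated(candidate_sites)) stop("candidate sites must be distinct")
  n <- length(candidate_sites)
  if (n > limit) {
    stop("refusing to enumerate 2^", n, " patterns (limit ", limit,
         "); raise `limit` explicitly if this is intended")
  }
  if (!is.null(stoichiometry)) {
    k <- as.integer(stoichiometry)
    stopifnot(k >= 0L, k <= n)
    if (k == 0L) return(list(phospho_pattern(candidate_sites)))
    sets <- utils::combn(candidate_sites, k, simplify = FALSE)
    return(lapply(sets, function(a) phospho_pattern(candidate_sites, a)))
  }
  lapply(0:(2^n - 1), function(mask) {
    active <- candidate_sites[bitwAnd(mask, bitwShiftL(1L, 0:(max(n, 1) - 1))) != 0L]
    p <- phospho_pattern(candidate_sites, if (n) active else integer())
    attr(p, "bitmask") <- mask
    p
  })
}

#' Proline-directed (S/T-P) candidate sites
#'
#' Positions matching the CDK minimal consensus: S or T immediately followed
#' by proline.
#'
#' @param seq An [aa_sequence()].
#' @return Integer vector of 1-based positions (possibly empty).
#' @export
candidate_proline_directed_sites <- function(seq) {
  stopifnot(inherits(seq, "aa_sequence"))
  r <- seq_chars(seq)
  n <- length(r)
  if (n < 2L) return(integer())
  which(r[-n] %in% c("S", "T") & r[-1] == "P")
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (multi-record supported).
#' @return Named list of [aa_sequence()] objects; description lines are kept
#'   as the `id`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    aa_sequence(names(set)[i], as.character(set[[i]]))
  })
  names(out) <- vapply(out, function(s) s$id, "")
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs List of [aa_sequence()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "aa_sequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, function(s) s$residues, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a phosphosite pattern table
#'
#' CSV with columns `protein_id`, `position`, `state` (one of `phospho`,
#' `mimic`).
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "state")
  if (!all(need %in% names(df))) {
    stop("site table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$state %in% c("phospho", "mimic"))) {
    stop("state must be 'phospho' or 'mimic'")
  }
  df$position <- as.integer(df$position)
  df
}
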