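#' Construct a per-residue disorder track
#'
#' Holds per-residue disorder scores and the derived binary disorder mask.
#' AlphaFold pLDDT scores live on 0..100 and mark disorder below 50;
#' IUPred scores live on 0..1 and mark disorder above 0.5.
#'
#' @param protein_id Identifier.
#' @param scores Numeric vector, one score per residue in sequence order.
#' @param source `"plddt"` or `"iupred"`.
#' @return A `disorder_track` with fields `protein_id`, `scores`, `source`,
#'   `mask`.
#' @export
disorder_track <- function(protein_id, scores, source = c("plddt", "iupred")) {
  source <- match.arg(source)
  scores <- as.numeric(scores)
  if (!length(scores)) stop("empty score track")
  if (anyNA(scores)) stop("NA scores in track")
  if (source == "plddt" && (any(scores < 0) || any(scores > 100))) {
    stop("pLDDT scores must lie in [0, 100]")
  }
  if (source == "iupred" && (any(scores < 0) || any(scores > 1))) {
    stop("IUPred scores must lie in [0, 1]")
  }
  mask <- if (source == "plddt") scores < 50 else scores > 0.5
  structure(list(protein_id = protein_id, scores = scores,
                 source = source, mask = mask),
            class = "disorder_track")
}

#' @export
length.disorder_track <- function(x) length(x$scores)

#' Read a disorder score track from TSV
#'
#' Expected columns (header required): `position`, `aa`, `score`. Positions
#' must cover 1..N without gaps.
#'
#' @param path TSV file.
#' @param source Score source, `"plddt"` or `"iupred"`.
#' @param protein_id Identifier; defaults to the file name.
#' @return A [disorder_track()].
#' @export
read_disorder_tsv <- function(path, source = c("plddt", "iupred"),
                              protein_id = NULL) {
  source <- match.arg(source)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "aa", "score")
  if (!all(need %in% names(df))) {
    stop("track TSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[order(df$position), ]
  gaps <- setdiff(seq_len(max(df$position)), df$position)
  if (length(gaps)) {
    stop("missing residues in track: ", paste(utils::head(gaps, 10), collapse = ", "))
  }
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  disorder_track(protein_id, df$score, source)
}

#' Read per-residue pLDDT from an AlphaFold mmCIF file
#'
#' Extracts the per-residue model confidence stored in the B-factor field of
#' the atom records (the convention used by AlphaFold depositions); one value
#' per residue, taken from its first atom. Multi-model files are refused.
#'
#' @param path mmCIF file.
#' @param protein_id Identifier; defaults to the file name.
#' @return A [disorder_track()] with `source = "plddt"`.
#' @export
read_plddt_cif <- function(path, protein_id = NULL) {
  cif <- suppressWarnings(bio3d::read.cif(path))
  at <- cif$atom
  if ("model" %in% names(at) && length(unique(at$model)) > 1) {
    stop("multi-model mmCIF files are not supported")
  }
  ch <- unique(at$chain)
  if (length(ch) > 1) at <- at[at$chain == ch[1], ]
  first <- !duplicated(at$resno)
  at <- at[first, ]
  at <- at[order(at$resno), ]
  gaps <- setdiff(seq(min(at$resno), max(at$resno)), at$resno)
  if (length(gaps)) {
    stop("missing residues in mmCIF: ", paste(utils::head(gaps, 10), collapse = ", "))
  }
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  disorder_track(protein_id, at$b, source = "plddt")
}

idr_interval <- function(start, end, disordered_fraction, truncated_by_lor,
                         found = TRUE) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 disordered_fraction = disordered_fraction,
                 truncated_by_lor = truncated_by_lor, found = found),
            class = "idr_interval")
}

no_idr <- function() idr_interval(NA_integer_, NA_integer_, NA_real_, FALSE,
                                  found = FALSE)

#' @export
print.idr_interval <- function(x, ...) {
  if (!x$found) {
    cat("<idr_interval> no IDR\n")
  } else {
    cat(sprintf("<idr_interval> [%d, %d] disordered fraction %.3f%s\n",
                x$start, x$end, x$disordered_fraction,
                if (x$truncated_by_lor) " (LOR-truncated)" else ""))
  }
  invisible(x)
}

# longest run of TRUE in a logical vector; returns c(start, length) or NULL
longest_run <- function(flag) {
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  best <- idx[which.max(r$lengths[idx])]  # ties: first
  c(starts[best], r$lengths[best])
}

#' Select the analysis IDR from a pLDDT track
#'
#' Finds the longest contiguous window in which the fraction of residues
#' with pLDDT below `cutoff` strictly exceeds `majority` (exact search over
#' all windows; equal-length ties broken by the smallest start). The longest
#' ordered run (LOR: consecutive residues with score >= cutoff) inside the
#' window is then examined; if it exceeds `lor_frac` of the window length,
#' the window is truncated to end just before the LOR, and the check is
#' repeated on the remaining prefix until no LOR violates the threshold.
#'
#' @param track A [disorder_track()] with `source = "plddt"`.
#' @param cutoff pLDDT disorder cutoff (default 50).
#' @param majority Required disordered fraction (default 0.6, strict).
#' @param lor_frac Maximum tolerated LOR fraction (default 0.15; this
#'   threshold is a convention and may be adjusted).
#' @param all_windows If `TRUE`, also return every maximal qualifying
#'   window as attribute `windows` (matrix of start, end).
#' @return An `idr_interval`; `found = FALSE` when no window qualifies.
#' @export
select_idr_plddt <- function(track, cutoff = 50, majority = 0.6,
                             lor_frac = 0.15, all_windows = FALSE) {
  stopifnot(inherits(track, "disorder_track"))
  if (track$source != "plddt") stop("track source must be plddt")
  dis <- track$scores < cutoff
  n <- length(dis)
  # prefix sums: window [s, e] qualifies iff sum(dis[s:e]) > majority*(e-s+1)
  cs <- c(0, cumsum(dis))
  best <- NULL
  cands <- NULL
  for (s in seq_len(n)) {
    e <- seq(s, n)
    frac_ok <- (cs[e + 1L] - cs[s]) > majority * (e - s + 1L)
    if (!any(frac_ok)) next
    e_best <- max(e[frac_ok])
    len <- e_best - s + 1L
    cands <- rbind(cands, c(s, e_best))
    if (is.null(best) || len > best[2L] - best[1L] + 1L) best <- c(s, e_best)
  }
  if (is.null(best)) return(no_idr())
  s <- best[1L]; e <- best[2L]
  truncated <- FALSE
  repeat {
    run <- longest_run(!dis[s:e])
    if (is.null(run) || run[2L] <= lor_frac * (e - s + 1L)) break
    if (run[1L] == 1L) {
      # LOR sits at the window start: nothing precedes it, so trim the
      # ordered run itself and keep the disordered remainder
      s <- s + run[2L]
    } else {
      e <- s + run[1L] - 2L  # end just before the LOR start
    }
    if (e < s) return(no_idr())
    truncated <- TRUE
  }
  out <- idr_interval(s, e, mean(dis[s:e]), truncated)
  if (all_windows) attr(out, "windows") <- cands
  out
}

#' Select the analysis IDR from an IUPred track
#'
#' The longest maximal run of consecutive residues with score above
#' `cutoff`; ties broken by the smallest start.
#'
#' @param track A [disorder_track()] with `source = "iupred"`.
#' @param cutoff Disorder cutoff (default 0.5, strict).
#' @return An `idr_interval`; `found = FALSE` when no residue qualifies.
#' @export
select_idr_iupred <- function(track, cutoff = 0.5) {
  stopifnot(inherits(track, "disorder_track"))
  if (track$source != "iupred") stop("track source must be iupred")
  dis <- track$scores > cutoff
  run <- longest_run(dis)
  if (is.null(run)) return(no_idr())
  s <- run[1L]; e <- run[1L] + run[2L] - 1L
  idr_interval(s, e, 1.0, FALSE)
}

#' Fraction of disordered residues in a track
#'
#' @param track A [disorder_track()].
#' @return `count(mask) / N`, in `[0, 1]`.
#' @export
disorder_fraction <- function(track) {
  stopifnot(inherits(track, "disorder_track"))
  mean(track$mask)
}

#' Export IDR intervals as BED
#'
#' BED uses 0-based half-open coordinates; the package's 1-based closed
#' intervals are converted here (start-1, end).
#'
#' @param intervals List of `idr_interval` objects (or one).
#' @param ids Character names for the BED name column.
#' @param path Output path.
#' @export
write_idr_bed <- function(intervals, ids, path) {
  if (inherits(intervals, "idr_interval")) intervals <- list(intervals)
  keep <- vapply(intervals, function(x) isTRUE(x$found), TRUE)
  df <- data.frame(
    chrom = ids[keep],
    start = vapply(intervals[keep], function(x) x$start, 1L) - 1L,
    end = vapply(intervals[keep], function(x) x$end, 1L),
    name = paste0(ids[keep], "_IDR")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
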