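# Read-mapping coverage, completeness against the nearest homologue, and
# the completeness-bin x median-coverage summary.

#' Map reads onto isotigs and compute per-base depth
#'
#' Exact-seed gapless mapping: each read (either orientation) is anchored
#' by `seed_length`-mer lookups at its two ends and scored by full-length
#' mismatch count; placements with identity below `min_identity` are
#' discarded.  Every read gets at most one placement -- the highest
#' identity, ties broken deterministically by (isotig id, position, forward
#' strand first) -- and contributes +1 to every base it covers.
#'
#' @param isotigs data.frame with `isotig_id`, `sequence`, or named
#'   character vector.
#' @param reads character vector of read sequences.
#' @param min_identity mapping identity floor (default 0.95).
#' @param seed_length anchor seed length (default 21).
#' @return object of class `coverage_profiles`: `profiles` (data.frame
#'   `isotig_id`, `length`, `mean_depth`, `n_reads`), `depth` (named list
#'   of per-base integer vectors), `n_unmapped`, `total_mapped_bases`.
#' @export
map_reads <- function(isotigs, reads, min_identity = 0.95,
                      seed_length = 21L) {
  if (is.character(isotigs))
    isotigs <- data.frame(isotig_id = names(isotigs),
                          sequence = unname(isotigs),
                          stringsAsFactors = FALSE)
  stopifnot(nrow(isotigs) > 0L)
  s <- as.integer(seed_length)
  iso_seq <- isotigs$sequence
  iso_len <- nchar(iso_seq)
  profiles <- data.frame(isotig_id = isotigs$isotig_id, length = iso_len,
                         mean_depth = 0, n_reads = 0L,
                         stringsAsFactors = FALSE)
  depth <- lapply(iso_len, function(L) integer(L))
  names(depth) <- isotigs$isotig_id
  res <- structure(list(profiles = profiles, depth = depth,
                        n_unmapped = length(reads),
                        total_mapped_bases = 0),
                   class = "coverage_profiles")
  if (length(reads) == 0L) return(res)
  # positional seed index over all isotigs
  idx <- data.table::rbindlist(lapply(seq_along(iso_seq), function(i) {
    L <- iso_len[i]
    if (L < s) return(NULL)
    st <- seq_len(L - s + 1L)
    data.table::data.table(seed = substring(iso_seq[i], st, st + s - 1L),
                           iso = i, pos = st)
  }))
  data.table::setkey(idx, seed)
  rl <- nchar(reads)
  ori <- data.table::rbindlist(list(
    data.table::data.table(rid = seq_along(reads), seq = reads, fwd = TRUE),
    data.table::data.table(rid = seq_along(reads), seq = revcomp(reads),
                           fwd = FALSE)))
  ori <- ori[nchar(seq) >= s]
  # candidate placements from seeds at both read ends
  q <- data.table::rbindlist(list(
    ori[, list(rid, fwd, seq, seed = substr(seq, 1L, s), off = 0L)],
    ori[, list(rid, fwd, seq, seed = substring(seq, nchar(seq) - s + 1L),
               off = nchar(seq) - s)]))
  cand <- idx[q, on = "seed", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0L) return(res)
  cand[, start := pos - off]
  cand <- cand[start >= 1L & start + nchar(seq) - 1L <= iso_len[iso]]
  cand <- unique(cand[, list(rid, fwd, seq, iso, start)])
  if (nrow(cand) == 0L) return(res)
  mm <- vapply(seq_len(nrow(cand)), function(i) {
    .str_mismatch(cand$seq[i],
                  substr(iso_seq[cand$iso[i]], cand$start[i],
                         cand$start[i] + nchar(cand$seq[i]) - 1L))
  }, 0L)
  cand[, identity := 1 - mm / nchar(seq)]
  cand <- cand[identity >= min_identity]
  if (nrow(cand) == 0L) return(res)
  # best single placement per read
  cand[, iso_id := isotigs$isotig_id[iso]]
  cand[, fwdi := as.integer(fwd)]
  data.table::setorder(cand, rid, -identity, iso_id, start, -fwdi)
  best <- cand[!duplicated(rid)]
  # accumulate depth with difference arrays
  for (i in seq_len(nrow(isotigs))) {
    b <- best[best$iso == i]
    if (nrow(b) == 0L) next
    L <- iso_len[i]
    d <- numeric(L + 1L)
    starts <- b$start
    ends <- b$start + nchar(b$seq) - 1L
    for (j in seq_along(starts)) {
      d[starts[j]] <- d[starts[j]] + 1
      d[ends[j] + 1L] <- d[ends[j] + 1L] - 1
    }
    depth[[i]] <- as.integer(cumsum(d[seq_len(L)]))
    profiles$n_reads[i] <- nrow(b)
    profiles$mean_depth[i] <- mean(depth[[i]])
  }
  structure(list(profiles = profiles, depth = depth,
                 n_unmapped = length(reads) - nrow(best),
                 total_mapped_bases = sum(nchar(best$seq))),
            class = "coverage_profiles")
}

#' @export
print.coverage_profiles <- function(x, ...) {
  cat("<coverage_profiles>", nrow(x$profiles), "isotigs |",
      sum(x$profiles$n_reads), "reads mapped |", x$n_unmapped,
      "unmapped\n")
  invisible(x)
}

#' Completeness of assembled sequences against their homologues
#'
#' The full length of an assembled gene is unknown, so the length of its
#' nearest protein homologue stands in for it.  The default estimator is
#' the aligned fraction of the homologue (aligned subject span over subject
#' length, unit-consistent and bounded); `"isotig_nt"` instead divides the
#' isotig length in codons by the subject length.  Both are capped at 1.
#'
#' @param assignments assignment table from [assign_homologues()] (needs
#'   `isotig_id`, `subject_id`, `s_start`, `s_end`).
#' @param protein_db named character vector of database proteins (for
#'   subject lengths).
#' @param coverage_profiles optional [map_reads()] result; when supplied,
#'   each record carries the isotig's mean depth as its coverage.
#' @param isotig_lengths named integer vector (needed for mode
#'   `"isotig_nt"`).
#' @param mode completeness denominator convention.
#' @return data.frame with `isotig_id`, `homologue_id`, `completeness`,
#'   `coverage`.
#' @export
completeness_table <- function(assignments, protein_db,
                               coverage_profiles = NULL,
                               isotig_lengths = NULL,
                               mode = c("aligned_aa", "isotig_nt")) {
  mode <- match.arg(mode)
  if (nrow(assignments) == 0L)
    return(data.frame(isotig_id = character(0), homologue_id = character(0),
                      completeness = numeric(0), coverage = numeric(0)))
  slen <- nchar(protein_db)[assignments$subject_id]
  comp <- if (mode == "aligned_aa") {
    (assignments$s_end - assignments$s_start + 1L) / slen
  } else {
    stopifnot(!is.null(isotig_lengths))
    (isotig_lengths[assignments$isotig_id] / 3) / slen
  }
  comp <- pmin(1, comp)
  covr <- rep(NA_real_, nrow(assignments))
  if (!is.null(coverage_profiles)) {
    p <- coverage_profiles$profiles
    covr <- p$mean_depth[match(assignments$isotig_id, p$isotig_id)]
  }
  data.frame(isotig_id = assignments$isotig_id,
             homologue_id = assignments$subject_id,
             completeness = as.numeric(comp), coverage = covr,
             stringsAsFactors = FALSE)
}

#' Completeness-binned median coverage
#'
#' Records are binned by completeness into ten 10-percentage-point bins
#' (left-closed, right-open; completeness 1.0 falls in the top bin) and
#' each bin reports its count and median coverage.  In transcriptome data
#' the median coverage rises with completeness: highly expressed
#' transcripts yield more reads and assemble into more complete sequences.
#'
#' @param records data.frame from [completeness_table()] (needs
#'   `completeness` and `coverage`).
#' @return data.frame with `bin` (1..10), `bin_label`, `n`,
#'   `median_coverage`; attribute `"spearman"` holds the Spearman rank
#'   correlation between bin index and median coverage over occupied bins.
#' @export
completeness_coverage_bins <- function(records) {
  stopifnot(nrow(records) >= 1L)
  bin <- pmin(floor(records$completeness * 10) + 1L, 10L)
  out <- data.frame(bin = 1:10,
                    bin_label = paste0(seq(0, 90, 10), "-",
                                       seq(10, 100, 10), "%"),
                    n = 0L, median_coverage = NA_real_)
  agg <- split(records$coverage, bin)
  for (b in names(agg)) {
    i <- as.integer(b)
    out$n[i] <- length(agg[[b]])
    out$median_coverage[i] <- stats::median(agg[[b]], na.rm = TRUE)
  }
  occ <- out[out$n > 0L & !is.na(out$median_coverage), ]
  attr(out, "spearman") <- if (nrow(occ) >= 3L)
    stats::cor(occ$bin, occ$median_coverage, method = "spearman")
  else NA_real_
  out
}
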