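# Read filtering: the 5'-window Phred rule, content screening (uncalled
# bases, adapters), and paired/orphan accounting.

#' 5'-window quality rule
#'
#' A read passes when at least `min_good` of its first `window` bases have
#' quality scores strictly greater than `min_q` (defaults: at least 25 of
#' the first 35 bases above Q30).  Reads shorter than the window are
#' rejected: the rule is undefined for them.
#'
#' @param quals qualities: a character vector of Phred strings, a list of
#'   integer vectors, or a single integer vector (one read).
#' @param window,min_good,min_q rule parameters.
#' @param offset Phred ASCII offset for character input (default 33).
#' @return logical vector, one element per read.
#' @export
passes_quality_window <- function(quals, window = 35L, min_good = 25L,
                                  min_q = 30L, offset = 33L) {
  if (is.numeric(quals)) quals <- list(as.integer(quals))
  if (is.character(quals)) {
    lens <- nchar(quals)
    if (length(quals) && length(unique(lens)) == 1L && lens[1] >= window) {
      m <- .phred_matrix(quals, offset)
      return(rowSums(m[, seq_len(window), drop = FALSE] > min_q) >= min_good)
    }
    quals <- phred_decode(quals, offset)
  }
  vapply(quals, function(q) {
    if (length(q) < window) return(FALSE)
    sum(q[seq_len(window)] > min_q) >= min_good
  }, NA)
}

#' Content rule: uncalled bases and adapters
#'
#' A read fails when it contains one or more `N`, or any of the configured
#' adapter sequences as an exact forward-orientation substring.
#'
#' @param bases character vector of read sequences.
#' @param adapters character vector of adapter sequences (may be empty).
#' @return logical vector, one element per read.
#' @export
passes_content <- function(bases, adapters = character(0)) {
  ok <- !grepl("N", bases, fixed = TRUE)
  for (ad in adapters[nzchar(adapters)])
    ok <- ok & !grepl(ad, bases, fixed = TRUE)
  ok
}

# classify each failing read by its first failing rule
.fail_reason <- function(pass_q, bases, adapters) {
  reason <- rep(NA_character_, length(pass_q))
  reason[!pass_q] <- "low_quality"
  todo <- is.na(reason)
  hasN <- grepl("N", bases, fixed = TRUE)
  reason[todo & hasN] <- "contains_N"
  todo <- is.na(reason)
  if (length(adapters)) {
    hasA <- rep(FALSE, length(bases))
    for (ad in adapters[nzchar(adapters)])
      hasA <- hasA | grepl(ad, bases, fixed = TRUE)
    reason[todo & hasA] <- "adapter"
  }
  reason
}

#' Filter paired reads, keeping single survivors
#'
#' Applies the quality-window and content rules to both mates of every
#' pair.  Pairs where both mates pass are retained as pairs; pairs where
#' exactly one mate passes contribute that mate as a single (orphan) read;
#' pairs where neither passes are dropped.
#'
#' @param pairs a `read_pairs` data.frame (columns `pair_id`, `bases1`,
#'   `quals1`, `bases2`, `quals2`), or a list of two read tables
#'   (`read_id`, `bases`, `quals`) with mates synchronized by id.
#' @param adapters adapter list for the content rule.
#' @param window,min_good,min_q quality-window parameters.
#' @param offset Phred ASCII offset.
#' @return list with `pairs` (retained pairs), `singles` (data.frame
#'   `read_id`, `mate`, `bases`, `quals`), and `report` (a `qc_report`).
#' @export
filter_read_pairs <- function(pairs, adapters = character(0),
                              window = 35L, min_good = 25L, min_q = 30L,
                              offset = 33L) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    r1 <- pairs[[1]]; r2 <- pairs[[2]]
    id1 <- sub("/[12]$", "", r1$read_id)
    id2 <- sub("/[12]$", "", r2$read_id)
    if (length(id1) != length(id2) || any(id1 != id2)) {
      bad <- if (length(id1) != length(id2)) min(length(id1), length(id2)) + 1L
             else which(id1 != id2)[1]
      stop("mate files desynchronized at record ", bad, ": '",
           if (bad <= length(id1)) id1[bad] else "<missing>", "' vs '",
           if (bad <= length(id2)) id2[bad] else "<missing>", "'")
    }
    pairs <- data.frame(pair_id = id1,
                        bases1 = r1$bases, quals1 = r1$quals,
                        bases2 = r2$bases, quals2 = r2$quals,
                        stringsAsFactors = FALSE)
  }
  n_pairs <- nrow(pairs)
  if (n_pairs == 0L) {
    report <- .qc_report(0L, 0L, 0L, 0L,
                         c(low_quality = 0L, contains_N = 0L, adapter = 0L),
                         0L)
    return(list(pairs = pairs, singles = data.frame(
      read_id = character(0), mate = integer(0), bases = character(0),
      quals = character(0)), report = report))
  }
  q1 <- passes_quality_window(pairs$quals1, window, min_good, min_q, offset)
  q2 <- passes_quality_window(pairs$quals2, window, min_good, min_q, offset)
  c1 <- passes_content(pairs$bases1, adapters)
  c2 <- passes_content(pairs$bases2, adapters)
  p1 <- q1 & c1
  p2 <- q2 & c2
  both <- p1 & p2
  one <- xor(p1, p2)
  retained_pairs <- pairs[both, , drop = FALSE]
  s1 <- one & p1
  s2 <- one & p2
  singles <- rbind(
    data.frame(read_id = paste0(pairs$pair_id, "/1")[s1],
               mate = rep(1L, sum(s1)),
               bases = pairs$bases1[s1], quals = pairs$quals1[s1],
               stringsAsFactors = FALSE),
    data.frame(read_id = paste0(pairs$pair_id, "/2")[s2],
               mate = rep(2L, sum(s2)),
               bases = pairs$bases2[s2], quals = pairs$quals2[s2],
               stringsAsFactors = FALSE))
  reasons <- c(.fail_reason(q1, pairs$bases1, adapters)[!p1],
               .fail_reason(q2, pairs$bases2, adapters)[!p2])
  tally <- c(low_quality = sum(reasons == "low_quality"),
             contains_N = sum(reasons == "contains_N"),
             adapter = sum(reasons == "adapter"))
  total_len <- sum(nchar(retained_pairs$bases1)) +
    sum(nchar(retained_pairs$bases2)) + sum(nchar(singles$bases))
  report <- .qc_report(
    n_input = 2L * n_pairs,
    n_retained = 2L * nrow(retained_pairs) + nrow(singles),
    n_paired_retained = 2L * nrow(retained_pairs),
    n_single_retained = nrow(singles),
    rejection_tally = tally,
    total_retained_length = total_len)
  rownames(retained_pairs) <- NULL
  rownames(singles) <- NULL
  list(pairs = retained_pairs, singles = singles, report = report)
}

.qc_report <- function(n_input, n_retained, n_paired_retained,
                       n_single_retained, rejection_tally,
                       total_retained_length) {
  stopifnot(n_retained == n_paired_retained + n_single_retained,
            n_retained <= n_input,
            sum(rejection_tally) == n_input - n_retained)
  structure(list(n_input = n_input, n_retained = n_retained,
                 n_paired_retained = n_paired_retained,
                 n_single_retained = n_single_retained,
                 rejection_tally = rejection_tally,
                 total_retained_length = total_retained_length),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read filtering report\n")
  cat("  input reads:        ", format(x$n_input, big.mark = ","), "\n")
  cat("  retained reads:     ", format(x$n_retained, big.mark = ","), "\n")
  cat("    paired:           ", format(x$n_paired_retained,
                                       big.mark = ","), "\n")
  cat("    single:           ", format(x$n_single_retained,
                                       big.mark = ","), "\n")
  cat("  retained length:    ", format(x$total_retained_length,
                                       big.mark = ","), "bp\n")
  cat("  rejected by reason: ",
      paste(names(x$rejection_tally), x$rejection_tally, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Published read-accounting table
#'
#' The read-filtering accounting reported for the original *Bactrocera
#' dorsalis* transcriptome sequencing run (26.1 million 90-base reads), as
#' a named numeric vector: raw read count and total length, retained read
#' count split into paired and single survivors, and retained total length.
#' Bundled so its arithmetic identities (retained = paired + single;
#' lengths = 90 x counts) can be re-verified cheaply.
#'
#' @return named numeric vector.
#' @export
published_read_accounting <- function() {
  path <- system.file("extdata", "read_accounting_published.tsv",
                      package = "isotigr")
  tab <- utils::read.delim(path, comment.char = "#")
  stats::setNames(as.numeric(tab$value), tab$metric)
}
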