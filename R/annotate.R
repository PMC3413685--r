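# Enzyme annotation: EC-group prediction from enzymatic homologues,
# flexible-gap catalytic-site motif parsing and matching, coverage-based
# deduplication of redundant isotigs, and collapsing into putative genes.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a flexible-gap protein motif pattern
#'
#' Grammar: an uppercase letter is a fixed residue; `x` matches any single
#' residue; `x(m,n)` matches between `m` and `n` arbitrary residues; `-` is a
#' cosmetic separator.  Wildcards and gaps never match a stop (`*`), so a
#' match can never span a stop codon.
#'
#' @param raw pattern string, e.g. `"PxLxD-x(7,10)-SxAIxxYLxxK"`.
#' @return an object of class `motif_pattern` with the element list.
#' @examples
#' parse_motif("GxSxG")
#' @export
parse_motif <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  chars <- strsplit(raw, "")[[1]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "-") {
      i <- i + 1L
    } else if (ch == "x") {
      if (i < n && chars[i + 1L] == "(") {
        close <- which(chars == ")" & seq_len(n) > i)
        if (length(close) == 0L)
          stop("unterminated gap at position ", i, " in '", raw, "'")
        close <- close[1L]
        body <- paste(chars[(i + 2L):(close - 1L)], collapse = "")
        parts <- strsplit(body, ",", fixed = TRUE)[[1]]
        mn <- suppressWarnings(as.integer(parts))
        if (length(mn) != 2L || anyNA(mn))
          stop("malformed gap 'x(", body, ")' at position ", i, " in '", raw, "'")
        if (mn[1] > mn[2] || mn[1] < 0L)
          stop("invalid gap bounds x(", mn[1], ",", mn[2], ") at position ", i,
               " in '", raw, "': require 0 <= m <= n")
        elements[[length(elements) + 1L]] <-
          list(type = "gap", min = mn[1], max = mn[2])
        i <- close + 1L
      } else {
        elements[[length(elements) + 1L]] <- list(type = "any")
        i <- i + 1L
      }
    } else if (ch %in% LETTERS) {
      elements[[length(elements) + 1L]] <- list(type = "fixed", residue = ch)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' at position ", i, " in '", raw, "'")
    }
  }
  if (!any(vapply(elements, `[[`, "", "type") == "fixed"))
    stop("pattern '", raw, "' contains no fixed residue")
  structure(list(raw = raw, elements = elements), class = "motif_pattern")
}

#' Render a motif pattern back to its string form
#'
#' Produces the canonical (separator-free) rendering; `parse_motif()` of the
#' result reproduces the same element list.
#'
#' @param pattern a `motif_pattern`.
#' @return pattern string.
#' @export
render_motif <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  paste(vapply(pattern$elements, function(e) {
    switch(e$type,
           fixed = e$residue,
           any = "x",
           gap = sprintf("x(%d,%d)", e$min, e$max))
  }, ""), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  nf <- sum(vapply(x$elements, `[[`, "", "type") == "fixed")
  cat("<motif_pattern> ", x$raw, "  (", length(x$elements), " elements, ",
      nf, " fixed)\n", sep = "")
  invisible(x)
}

#' Minimum and maximum peptide length matched by a motif
#'
#' @param pattern a `motif_pattern`.
#' @return integer vector `c(min, max)`.
#' @export
motif_length_range <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  lo <- hi <- 0L
  for (e in pattern$elements) {
    if (e$type == "gap") { lo <- lo + e$min; hi <- hi + e$max }
    else { lo <- lo + 1L; hi <- hi + 1L }
  }
  c(lo, hi)
}

#' Sample one peptide from a motif's language
#'
#' Fixed residues are kept, wildcards and gap positions are drawn uniformly
#' from the 20 amino acids, and each gap width is drawn uniformly from its
#' bounds.  Uses the current RNG state.
#'
#' @param pattern a `motif_pattern`.
#' @return peptide string matching `pattern` at position 1.
#' @export
sample_motif_instance <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  parts <- vapply(pattern$elements, function(e) {
    switch(e$type,
           fixed = e$residue,
           any = sample(.AA20, 1L),
           gap = {
             w <- if (e$min == e$max) e$min else
               sample(seq.int(e$min, e$max), 1L)
             if (w == 0L) "" else paste(sample(.AA20, w, replace = TRUE),
                                        collapse = "")
           })
  }, "")
  paste(parts, collapse = "")
}

# recursive matcher: does pattern$elements[ei..] match chars starting at pos?
# returns the end position (last consumed index) of the shortest match, or -1
.match_from <- function(chars, pos, elements, ei) {
  if (ei > length(elements)) return(pos - 1L)
  if (pos > length(chars)) return(-1L)
  e <- elements[[ei]]
  ch <- chars[pos]
  if (e$type == "fixed") {
    if (ch != e$residue) return(-1L)
    return(.match_from(chars, pos + 1L, elements, ei + 1L))
  }
  if (e$type == "any") {
    if (ch == "*") return(-1L)
    return(.match_from(chars, pos + 1L, elements, ei + 1L))
  }
  # gap: try widths ascending so the first success is the shortest match
  for (w in seq.int(e$min, e$max)) {
    if (w > 0L) {
      seg <- chars[pos + seq_len(w) - 1L]
      if (pos + w - 1L > length(chars) || any(seg == "*")) break
    }
    res <- .match_from(chars, pos + w, elements, ei + 1L)
    if (res >= 0L) return(res)
  }
  -1L
}

#' Find all matches of a motif in a peptide
#'
#' Reports every distinct start position admitting a match (overlapping
#' matches included).  Wildcards and gaps never match `*`, so matches cannot
#' cross stop codons.
#'
#' @param pattern a `motif_pattern` (or pattern string, parsed on the fly).
#' @param peptide peptide string over the 20-letter alphabet plus `*`.
#' @return data.frame with 1-based closed spans: columns `start`, `end`
#'   (`end` is the shortest match from that start).  Zero rows if no match.
#' @examples
#' match_motif("GxSxG", "AGASAGA")   # match at start 2
#' @export
match_motif <- function(pattern, peptide) {
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  stopifnot(inherits(pattern, "motif_pattern"),
            is.character(peptide), length(peptide) == 1L)
  chars <- strsplit(peptide, "")[[1]]
  n <- length(chars)
  rng <- motif_length_range(pattern)
  if (n < rng[1]) return(data.frame(start = integer(0), end = integer(0)))
  # candidate starts: if the first element is fixed, only its positions
  e1 <- pattern$elements[[1L]]
  cand <- if (e1$type == "fixed") which(chars == e1$residue)
          else which(chars != "*")
  cand <- cand[cand <= n - rng[1] + 1L]
  hits <- lapply(cand, function(s) {
    e <- .match_from(chars, s, pattern$elements, 1L)
    if (e >= 0L) c(s, e) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = hits[, 1], end = hits[, 2])
}

#' Load a motif library
#'
#' The library is a plain-text TSV with columns `ec` and `pattern`
#' (`#`-comment lines skipped).  The default is the bundled catalytic-site
#' motif set: the short literature motifs for EC 1.14.14.1 (cytochrome P450),
#' EC 2.5.1.18 (glutathione S-transferase), EC 3.1.1.1 (carboxylesterase) and
#' EC 3.1.1.7 (acetylcholinesterase), plus the flexible-gap GST signature
#' `PxLxD-x(7,10)-SxAIxxYLxxK`.
#'
#' @param path file path; `NULL` for the bundled library.
#' @return data.frame with columns `ec`, `raw`, and list-column `pattern` of
#'   parsed `motif_pattern` objects.
#' @export
read_motif_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "e1ds_motifs.tsv", package = "isotigr")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("ec", "pattern") %in% names(tab)))
  out <- data.frame(ec = tab$ec, raw = tab$pattern, stringsAsFactors = FALSE)
  out$pattern <- lapply(tab$pattern, parse_motif)
  out
}

#' Construct an enzyme database
#'
#' @param proteins named character vector (or `AAStringSet`) of enzyme
#'   protein sequences.
#' @param ec character vector of EC numbers, one per protein (dotted 4-field
#'   codes; wildcard fields allowed).
#' @return object of class `enzyme_db`.
#' @export
enzyme_db <- function(proteins, ec) {
  if (methods::is(proteins, "AAStringSet"))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  stopifnot(length(proteins) == length(ec), !is.null(names(proteins)))
  structure(list(proteins = proteins,
                 ec = stats::setNames(ec, names(proteins))),
            class = "enzyme_db")
}

#' Read an enzyme database from FASTA with `EC=` header tags
#'
#' Headers look like `>P_g0001 EC=2.5.1.18`; entries without a tag are
#' dropped with a message.
#'
#' @param path FASTA file of protein sequences.
#' @return an `enzyme_db`.
#' @export
read_enzyme_db <- function(path) {
  seqs <- read_fasta(path, type = "AA")
  ids <- sub("\\s.*$", "", names(seqs))
  ec <- ifelse(grepl("EC=", names(seqs)),
               sub(".*EC=([0-9x.×]+).*", "\\1", names(seqs)), NA)
  keep <- !is.na(ec)
  if (any(!keep))
    message(sum(!keep), " entries without EC= tag dropped")
  enzyme_db(stats::setNames(seqs[keep], ids[keep]), ec[keep])
}

#' Write an enzyme database to FASTA with `EC=` header tags
#'
#' @param db an `enzyme_db`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_enzyme_db <- function(db, path) {
  stopifnot(inherits(db, "enzyme_db"))
  x <- Biostrings::AAStringSet(db$proteins)
  names(x) <- paste0(names(db$proteins), " EC=", unname(db$ec))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# does any motif of the given EC group match any of the six frame
# translations of nt?
.motif_in_frames <- function(nt, ec_code, motif_library) {
  pats <- motif_library$pattern[motif_library$ec == ec_code]
  if (length(pats) == 0L) return(FALSE)
  frames <- translate_six_frames(nt)
  for (p in pats) for (f in frames) {
    if (nzchar(f) && nrow(match_motif(p, f)) > 0L) return(TRUE)
  }
  FALSE
}

#' Predict the EC group of an assembled sequence
#'
#' The sequence is aligned (translated, six frames) against an enzyme
#' database; it is assigned to the EC group of the closest enzyme, i.e. the
#' hit with the smallest E-value among alignments longer than `min_aa` amino
#' acids with E-value below `max_e`.  When the top hits disagree on EC and
#' their E-values are within `ambiguity_factor` of each other (no clear
#' ranking), catalytic-site motifs arbitrate: if exactly one competing EC has
#' a motif matching some frame translation, that EC is chosen and flagged
#' `motif_confirmed`; otherwise the minimum-E choice is kept and flagged
#' unresolved with the competitors listed.
#'
#' @param query_nt nucleotide sequence of the isotig.
#' @param db an `enzyme_db`.
#' @param motif_library motif table from [read_motif_library()].
#' @param ambiguity_factor E-value ratio under which two hits count as
#'   indistinguishable (default 10).
#' @param min_aa,max_e homology thresholds (defaults: alignment length
#'   strictly greater than 60 aa, E-value below 1e-5).
#' @param query_id identifier carried into the result.
#' @return an `ec_prediction` (list with `isotig_id`, `ec`, `subject_id`,
#'   `evalue`, `motif_confirmed`, `unresolved`, `competing_ecs`, `hit`), or
#'   `NULL` when no hit passes the thresholds.
#' @export
predict_ec <- function(query_nt, db, motif_library = read_motif_library(),
                       ambiguity_factor = 10, min_aa = 60L, max_e = 1e-5,
                       query_id = "query") {
  stopifnot(inherits(db, "enzyme_db"))
  hits <- all_translated_hits(query_nt, db$proteins,
                              min_aa = min_aa, max_e = max_e)
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[order(hits$evalue, -hits$score, hits$subject_id), ]
  top <- hits[1L, ]
  cand <- hits[hits$evalue <= top$evalue * ambiguity_factor, ]
  cand_ecs <- unique(unname(db$ec[cand$subject_id]))
  ec <- unname(db$ec[top$subject_id])
  motif_confirmed <- FALSE
  unresolved <- FALSE
  competing <- character(0)
  if (length(cand_ecs) > 1L) {
    matched <- cand_ecs[vapply(cand_ecs, function(e)
      .motif_in_frames(query_nt, e, motif_library), NA)]
    if (length(matched) == 1L) {
      ec <- matched
      best_of_ec <- cand[unname(db$ec[cand$subject_id]) == ec, ][1L, ]
      top <- best_of_ec
      motif_confirmed <- TRUE
    } else {
      unresolved <- TRUE
      competing <- setdiff(cand_ecs, ec)
    }
  }
  if (!motif_confirmed)
    motif_confirmed <- .motif_in_frames(query_nt, ec, motif_library)
  structure(list(isotig_id = query_id, ec = ec,
                 subject_id = top$subject_id, evalue = top$evalue,
                 motif_confirmed = motif_confirmed, unresolved = unresolved,
                 competing_ecs = competing, hit = top),
            class = "ec_prediction")
}

#' Predict EC groups for a set of isotigs
#'
#' @param isotigs data.frame with `isotig_id` and `sequence` (as produced by
#'   the assembler), or a named character vector.
#' @param db,motif_library,ambiguity_factor,min_aa,max_e see [predict_ec()].
#' @return data.frame with one row per isotig that received a prediction:
#'   `isotig_id`, `ec`, `subject_id`, `evalue`, `identity`, `aligned_len`,
#'   `s_start`, `s_end`, `length`, `motif_confirmed`, `unresolved`.
#' @export
predict_ec_batch <- function(isotigs, db,
                             motif_library = read_motif_library(),
                             ambiguity_factor = 10, min_aa = 60L,
                             max_e = 1e-5) {
  if (is.character(isotigs))
    isotigs <- data.frame(isotig_id = names(isotigs), sequence = unname(isotigs),
                          stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(isotigs)), function(i) {
    p <- predict_ec(isotigs$sequence[i], db, motif_library,
                    ambiguity_factor, min_aa, max_e,
                    query_id = isotigs$isotig_id[i])
    if (is.null(p)) return(NULL)
    data.frame(isotig_id = p$isotig_id, ec = p$ec, subject_id = p$subject_id,
               evalue = p$evalue, identity = p$hit$identity,
               aligned_len = p$hit$aligned_len,
               s_start = p$hit$s_start, s_end = p$hit$s_end,
               length = nchar(isotigs$sequence[i]),
               motif_confirmed = p$motif_confirmed,
               unresolved = p$unresolved, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(isotig_id = character(0), ec = character(0),
                      subject_id = character(0), evalue = numeric(0),
                      identity = numeric(0), aligned_len = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0), motif_confirmed = logical(0),
                      unresolved = logical(0))
  out
}

#' Keep the highest-coverage isotig among redundant predictions
#'
#' Within each group of predictions sharing both the EC group and the same
#' nearest reference protein, only the isotig with the highest coverage
#' (mean mapped-read depth) is retained; ties broken by longer isotig, then
#' lexicographic id.
#'
#' @param predictions data.frame from [predict_ec_batch()] (needs
#'   `isotig_id`, `ec`, `subject_id`, `length`).
#' @param coverages named numeric vector of mean depths, one per isotig.
#'   Isotigs missing from it get coverage 0.
#' @return filtered predictions data.frame.
#' @export
dedupe_by_coverage <- function(predictions, coverages) {
  if (nrow(predictions) == 0L) return(predictions)
  cov <- coverages[predictions$isotig_id]
  cov[is.na(cov)] <- 0
  ord <- order(predictions$ec, predictions$subject_id,
               -cov, -predictions$length, predictions$isotig_id)
  p <- predictions[ord, ]
  keep <- !duplicated(paste(p$ec, p$subject_id, sep = "\r"))
  out <- p[keep, ]
  rownames(out) <- NULL
  out
}

# single-linkage partition of intervals where reciprocal overlap >= thr
# joins two intervals; returns integer group labels
.overlap_units <- function(s, e, thr) {
  n <- length(s)
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ov <- min(e[i], e[j]) - max(s[i], s[j]) + 1L
    if (ov <= 0L) next
    li <- e[i] - s[i] + 1L; lj <- e[j] - s[j] + 1L
    if (ov / li >= thr && ov / lj >= thr) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) grp[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Collapse isotig predictions into putative genes
#'
#' Isotigs sharing the same nearest reference protein (`gene_key`) are one
#' putative gene.  Within a gene, isotigs whose alignments on the reference
#' overlap reciprocally by at least `overlap_threshold` are isoform
#' candidates of the same transcript unit; mutually non-overlapping
#' alignments are fragments of the same gene and count as separate
#' transcript units.
#'
#' @param predictions data.frame with `isotig_id`, `ec`, `subject_id`,
#'   `s_start`, `s_end` (subject-coordinate spans, 1-based closed).
#' @param coverages named numeric vector of per-isotig mean depths (used to
#'   pick each cluster's representative); missing values treated as 0.
#' @param overlap_threshold reciprocal-overlap fraction marking two
#'   alignments as overlapping (default 0.2).
#' @param families optional named character vector mapping `subject_id` (or
#'   EC number, checked second) to a family label for the tally table.
#' @return list with `clusters` (one row per gene: `gene_key`, `ec`,
#'   `family`, `n_isotigs`, `n_transcript_units`, `representative`,
#'   `member_isotigs` list-column) and `tally` (per family: `n_isotigs`,
#'   `n_genes`).
#' @export
collapse_genes <- function(predictions, coverages = NULL,
                           overlap_threshold = 0.2, families = NULL) {
  need <- c("isotig_id", "ec", "subject_id", "s_start", "s_end")
  miss_col <- setdiff(need, names(predictions))
  if (length(miss_col))
    stop("predictions lack column(s): ", paste(miss_col, collapse = ", "))
  bad <- is.na(predictions$s_start) | is.na(predictions$s_end)
  if (any(bad)) {
    message(sum(bad), " predictions without subject spans excluded")
    predictions <- predictions[!bad, ]
  }
  if (nrow(predictions) == 0L)
    return(list(clusters = data.frame(), tally = data.frame()))
  cov <- if (is.null(coverages)) rep(0, nrow(predictions))
         else { x <- coverages[predictions$isotig_id]; x[is.na(x)] <- 0; x }
  predictions$.cov <- as.numeric(cov)
  split_idx <- split(seq_len(nrow(predictions)), predictions$subject_id)
  clusters <- lapply(names(split_idx), function(key) {
    p <- predictions[split_idx[[key]], ]
    units <- .overlap_units(p$s_start, p$s_end, overlap_threshold)
    fam <- NA_character_
    if (!is.null(families)) {
      if (key %in% names(families)) fam <- unname(families[[key]])
      else if (p$ec[1] %in% names(families)) fam <- unname(families[[p$ec[1]]])
    }
    data.frame(gene_key = key, ec = p$ec[1], family = fam,
               n_isotigs = nrow(p),
               n_transcript_units = length(unique(units)),
               representative = p$isotig_id[which.max(p$.cov)],
               member_isotigs = I(list(p$isotig_id)),
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, clusters)
  tal <- stats::aggregate(cbind(n_isotigs = clusters$n_isotigs,
                                n_genes = 1) ~ family,
                          data = transform(clusters,
                            family = ifelse(is.na(family), "unclassified",
                                            family)),
                          FUN = sum)
  list(clusters = clusters, tally = tal)
}
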