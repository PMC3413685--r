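# Translated local alignment against protein databases, best-homologue
# assignment, homologue-keyed merging of multi-k assemblies, validation
# against known mRNAs, poly-N gap consistency, and translated target-site
# scans.
#
# Alignment is exact local dynamic programming (Smith-Waterman with affine
# gaps, BLOSUM62 by default); E-values use the ungapped Karlin-Altschul
# formula E = K * m * n * exp(-lambda * S) applied to the gapped score, with
# the database residue count as the size factor, so the familiar E-value
# thresholds behave comparably to heuristic search tools.

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 read the forward strand with offsets 0..2; frames -1..-3
#' read the reverse complement likewise.  The standard codon table is used,
#' stop codons render as `*`, and codons containing `N` render as `X`.
#'
#' @param nt nucleotide string.
#' @return named character vector of six peptides
#'   (`"+1"`,`"+2"`,`"+3"`,`"-1"`,`"-2"`,`"-3"`); empty strings when fewer
#'   than three bases remain in a frame.
#' @examples
#' translate_six_frames("ATGGCC")[["+1"]]   # "MA"
#' @export
translate_six_frames <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  n <- nchar(nt)
  out <- stats::setNames(character(6),
                         c("+1", "+2", "+3", "-1", "-2", "-3"))
  if (n < 3L) {
    message("sequence shorter than one codon; all frames empty")
    return(out)
  }
  rev <- revcomp(nt)
  for (i in 0:2) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") nt else rev
      len <- n - i
      len <- len - (len %% 3L)
      if (len < 3L) next
      out[paste0(strand, i + 1L)] <- .translate_fast(substr(s, i + 1L,
                                                            i + len))
    }
  }
  out
}

# cached standard codon table; codons with uncalled bases render as 'X'
.translate_fast <- function(nt) {
  tab <- .isotigr_cache$codon_table
  if (is.null(tab)) {
    gc_tab <- Biostrings::GENETIC_CODE
    tab <- stats::setNames(unname(gc_tab), names(gc_tab))
    .isotigr_cache$codon_table <- tab
  }
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' E-value of a local alignment score
#'
#' Ungapped Karlin-Altschul statistic `E = K * m * n * exp(-lambda * S)`.
#'
#' @param score raw alignment score.
#' @param m query length (residues).
#' @param n subject length times database-size factor (residues).
#' @param lambda,K Karlin-Altschul parameters (BLOSUM62 ungapped defaults).
#' @return E-value (positive numeric, strictly decreasing in `score`).
#' @export
evalue_from_score <- function(score, m, n, lambda = 0.318, K = 0.13) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

#' Optimal local protein alignment
#'
#' Exact Smith-Waterman local alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`).
#'
#' @param query,subject peptide strings (may contain `*`/`X`; scored by the
#'   matrix's corresponding rows).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (defaults 11, 1).
#' @param db_residues database-size factor for the E-value; defaults to the
#'   subject length.
#' @param lambda,K Karlin-Altschul parameters.
#' @return an `alignment_hit` list (`score`, `evalue`, `identity`,
#'   `aligned_len`, `n_match`, `q_start`, `q_end`, `s_start`, `s_end`; spans
#'   1-based closed), or `NULL` when no alignment scores above zero.
#' @export
local_align_protein <- function(query, subject, matrix = NULL,
                                gap_open = 11, gap_extend = 1,
                                db_residues = NULL,
                                lambda = 0.318, K = 0.13) {
  stopifnot(nzchar(query), nzchar(subject))
  if (is.null(matrix)) matrix <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0) return(NULL)
  alen <- Biostrings::nchar(pa)
  nm <- Biostrings::nmatch(pa)
  n_eff <- db_residues %||% nchar(subject)
  structure(list(
    score = s,
    evalue = evalue_from_score(s, nchar(query), n_eff, lambda, K),
    identity = nm / alen,
    aligned_len = alen,
    n_match = nm,
    q_start = Biostrings::start(Biostrings::pattern(pa)),
    q_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa))),
    class = "alignment_hit")
}

# ---- word prefilter -------------------------------------------------------

# index of all length-w peptide words per database entry
.build_word_index <- function(db, w = 4L) {
  ids <- names(db)
  dt <- data.table::rbindlist(lapply(seq_along(db), function(i) {
    words <- unique(.kmers(db[[i]], w))
    if (length(words) == 0L) return(NULL)
    data.table::data.table(word = words, subject = ids[i])
  }))
  if (nrow(dt) == 0L) return(NULL)
  data.table::setkey(dt, word)
  dt
}

# subjects sharing at least min_shared distinct w-words with peptide
.word_candidates <- function(pep, index, w = 4L, min_shared = 1L) {
  if (is.null(index) || nchar(pep) < w) return(character(0))
  words <- unique(.kmers(pep, w))
  hits <- index[data.table::data.table(word = words), on = "word",
                nomatch = NULL]
  if (nrow(hits) == 0L) return(character(0))
  if (min_shared <= 1L) return(unique(hits$subject))
  tab <- hits[, list(n = .N), by = "subject"]
  tab$subject[tab$n >= min_shared]
}

# all (frame x subject) hits of a nucleotide query against a protein db that
# pass the length/E-value thresholds; db may be a named character vector
#' All passing translated hits of a query against a protein database
#'
#' Six-frame translations of the query are locally aligned against every
#' candidate database protein (candidates share at least one `word_size`-mer
#' with some frame); hits with alignment length strictly greater than
#' `min_aa` and E-value below `max_e` are returned.
#'
#' @param query_nt nucleotide query sequence.
#' @param db named character vector (or `AAStringSet`) of proteins.
#' @param min_aa,max_e thresholds (defaults 60 aa, 1e-5).
#' @param word_size prefilter word length (default 5).
#' @param db_index optional precomputed index from an earlier call (internal
#'   reuse).
#' @return data.frame with one row per passing hit: `subject_id`, `frame`,
#'   `score`, `evalue`, `identity`, `aligned_len`, `q_start`, `q_end`,
#'   `s_start`, `s_end`.
#' @export
all_translated_hits <- function(query_nt, db, min_aa = 60L, max_e = 1e-5,
                                word_size = 5L, db_index = NULL) {
  if (methods::is(db, "AAStringSet"))
    db <- stats::setNames(as.character(db), names(db))
  stopifnot(!is.null(names(db)))
  if (is.null(db_index)) db_index <- .build_word_index(db, word_size)
  n_db <- sum(nchar(db))
  frames <- translate_six_frames(query_nt)
  rows <- list()
  for (fr in names(frames)) {
    pep <- frames[[fr]]
    if (!nzchar(pep)) next
    # two-hit style prefilter: peptides long enough to pass the >60 aa rule
    # at workable identities always share two or more words with a real
    # homologue, while chance single-word candidates are dropped
    min_shared <- if (nchar(pep) >= 40L) 2L else 1L
    for (sid in .word_candidates(pep, db_index, word_size, min_shared)) {
      hit <- local_align_protein(pep, db[[sid]], db_residues = n_db)
      if (is.null(hit)) next
      if (hit$aligned_len > min_aa && hit$evalue < max_e) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, frame = fr, score = hit$score,
          evalue = hit$evalue, identity = hit$identity,
          aligned_len = hit$aligned_len,
          q_start = hit$q_start, q_end = hit$q_end,
          s_start = hit$s_start, s_end = hit$s_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(0), frame = character(0),
                      score = numeric(0), evalue = numeric(0),
                      identity = numeric(0), aligned_len = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0))
  out
}

#' Assign the best protein homologue to an assembled sequence
#'
#' The homologue is the database protein with the smallest E-value among
#' six-frame local alignments of length strictly greater than `min_aa` amino
#' acids and E-value below `max_e`; ties broken by higher score, then
#' lexicographic subject id.
#'
#' @inheritParams all_translated_hits
#' @param query_id identifier carried into the result.
#' @return list of class `homologue_assignment` (`isotig_id`, `subject_id`,
#'   `frame`, plus the hit columns), or `NULL` when nothing passes.
#' @export
assign_best_homologue <- function(query_nt, db, min_aa = 60L, max_e = 1e-5,
                                  word_size = 5L, db_index = NULL,
                                  query_id = "query") {
  hits <- all_translated_hits(query_nt, db, min_aa, max_e, word_size,
                              db_index)
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[order(hits$evalue, -hits$score, hits$subject_id), ]
  top <- hits[1L, ]
  structure(c(list(isotig_id = query_id), as.list(top)),
            class = "homologue_assignment")
}

#' Assign best homologues for a whole isotig table
#'
#' @param isotigs data.frame with `isotig_id` and `sequence`, or a named
#'   character vector.
#' @inheritParams all_translated_hits
#' @return data.frame with one row per isotig that received an assignment:
#'   `isotig_id`, `subject_id`, `frame`, `score`, `evalue`, `identity`,
#'   `aligned_len`, `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
assign_homologues <- function(isotigs, db, min_aa = 60L, max_e = 1e-5,
                              word_size = 5L) {
  if (is.character(isotigs))
    isotigs <- data.frame(isotig_id = names(isotigs),
                          sequence = unname(isotigs),
                          stringsAsFactors = FALSE)
  if (methods::is(db, "AAStringSet"))
    db <- stats::setNames(as.character(db), names(db))
  idx <- .build_word_index(db, word_size)
  rows <- lapply(seq_len(nrow(isotigs)), function(i) {
    a <- assign_best_homologue(isotigs$sequence[i], db, min_aa, max_e,
                               word_size, db_index = idx,
                               query_id = isotigs$isotig_id[i])
    if (is.null(a)) return(NULL)
    data.frame(isotig_id = a$isotig_id, subject_id = a$subject_id,
               frame = a$frame, score = a$score, evalue = a$evalue,
               identity = a$identity, aligned_len = a$aligned_len,
               q_start = a$q_start, q_end = a$q_end,
               s_start = a$s_start, s_end = a$s_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(isotig_id = character(0), subject_id = character(0),
                      frame = character(0), score = numeric(0),
                      evalue = numeric(0), identity = numeric(0),
                      aligned_len = integer(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0))
  out
}

#' Merge isotig sets assembled at different k by homologue novelty
#'
#' The k = `base_k` assembly is kept in full.  Isotigs from every other k
#' are added only when their assigned homologue is absent both from the base
#' set's homologues and from homologues already contributed by previously
#' processed k values.  Non-base k values are processed in ascending
#' distance from `base_k`, ties toward the smaller k (configurable via
#' `k_order`).
#'
#' @param per_k_isotigs named list (names = k values) of isotig data.frames
#'   (columns `isotig_id`, `sequence`, ...).
#' @param assignments data.frame mapping `isotig_id` to `subject_id`
#'   (isotigs without an assignment simply never add novelty).
#' @param base_k the reference k (default 31); must be present.
#' @param k_order optional explicit processing order for the non-base k.
#' @return list with `isotigs` (merged data.frame), `tally` (per k: number
#'   of isotigs, distinct subjects, and subjects newly contributed), and
#'   `subjects` (the union of assigned subject ids).
#' @export
merge_multi_k <- function(per_k_isotigs, assignments, base_k = 31L,
                          k_order = NULL) {
  ks <- as.integer(names(per_k_isotigs))
  if (anyNA(ks)) stop("per_k_isotigs must be named by integer k values")
  if (!base_k %in% ks) stop("base k = ", base_k, " missing from input sets")
  sub_of <- stats::setNames(assignments$subject_id, assignments$isotig_id)
  others <- setdiff(ks, base_k)
  if (is.null(k_order)) {
    others <- others[order(abs(others - base_k), others)]
  } else {
    stopifnot(setequal(k_order, others))
    others <- as.integer(k_order)
  }
  base_set <- per_k_isotigs[[as.character(base_k)]]
  seen <- unique(stats::na.omit(unname(sub_of[base_set$isotig_id])))
  tally <- data.frame(
    k = base_k, n_isotigs = nrow(base_set),
    n_subjects = length(seen), n_additional = 0L)
  merged <- base_set
  for (k in others) {
    set_k <- per_k_isotigs[[as.character(k)]]
    subs_k <- sub_of[set_k$isotig_id]
    novel <- !is.na(subs_k) & !(subs_k %in% seen)
    # one isotig per novel subject: best (first) representative
    if (any(novel)) {
      nov <- set_k[novel, , drop = FALSE]
      nov_subs <- subs_k[novel]
      keep <- !duplicated(nov_subs)
      merged <- rbind(merged, nov[keep, , drop = FALSE])
      added <- unique(nov_subs)
      seen <- c(seen, added)
    } else added <- character(0)
    tally <- rbind(tally, data.frame(
      k = k, n_isotigs = nrow(set_k),
      n_subjects = length(unique(stats::na.omit(unname(subs_k)))),
      n_additional = length(added)))
  }
  rownames(merged) <- NULL
  list(isotigs = merged, tally = tally[order(tally$k), ], subjects = seen)
}

#' Validate assembled sequences against known mRNAs
#'
#' A pair (isotig, known mRNA) passes when their best local nucleotide
#' alignment (either strand) has identity strictly greater than
#' `min_identity` and the ratio of alignment length to isotig length
#' strictly greater than `min_cov`.
#'
#' @param isotigs data.frame with `isotig_id`, `sequence`, or named
#'   character vector.
#' @param known_mrnas named character vector (or `DNAStringSet`) of known
#'   mRNA sequences.
#' @param min_identity identity threshold (default 0.95).
#' @param min_cov alignment-length / isotig-length threshold (default 0.80).
#' @param word_size nucleotide seed length of the candidate prefilter: only
#'   (isotig, mRNA) pairs sharing an exact word of this length (either
#'   strand) are aligned.  At the 95% identity this validation demands, a
#'   passing pair always contains such a word; lower it for very divergent
#'   inputs.
#' @return data.frame of passing pairs (`mrna_id`, `isotig_id`, `identity`,
#'   `coverage`, `aligned_len`), with a per-mRNA summary in attribute
#'   `"per_mrna"`.
#' @export
validate_against_known <- function(isotigs, known_mrnas,
                                   min_identity = 0.95, min_cov = 0.80,
                                   word_size = 21L) {
  if (is.character(isotigs))
    isotigs <- data.frame(isotig_id = names(isotigs),
                          sequence = unname(isotigs),
                          stringsAsFactors = FALSE)
  if (methods::is(known_mrnas, "DNAStringSet"))
    known_mrnas <- stats::setNames(as.character(known_mrnas),
                                   names(known_mrnas))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  widx <- .build_word_index(known_mrnas, word_size)
  rows <- list()
  for (i in seq_len(nrow(isotigs))) {
    cand_m <- union(
      .word_candidates(isotigs$sequence[i], widx, word_size),
      .word_candidates(revcomp(isotigs$sequence[i]), widx, word_size))
    for (mid in cand_m) {
      best <- NULL
      for (qseq in c(isotigs$sequence[i], revcomp(isotigs$sequence[i]))) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(qseq),
          Biostrings::DNAString(known_mrnas[[mid]]),
          type = "local", substitutionMatrix = mat,
          gapOpening = 5, gapExtension = 2)
        if (is.null(best) || Biostrings::score(pa) > Biostrings::score(best))
          best <- pa
      }
      alen <- Biostrings::nchar(best)
      ident <- Biostrings::nmatch(best) / alen
      covr <- alen / nchar(isotigs$sequence[i])
      if (ident > min_identity && covr > min_cov) {
        rows[[length(rows) + 1L]] <- data.frame(
          mrna_id = mid, isotig_id = isotigs$isotig_id[i],
          identity = ident, coverage = covr, aligned_len = alen,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mrna_id = character(0), isotig_id = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      aligned_len = integer(0))
  per <- if (nrow(out)) do.call(rbind, lapply(split(out, out$mrna_id),
    function(d) data.frame(mrna_id = d$mrna_id[1], n_isotigs = nrow(d),
                           mean_identity = mean(d$identity),
                           stringsAsFactors = FALSE)))
  else data.frame(mrna_id = character(0))
  rownames(per) <- NULL
  attr(out, "per_mrna") <- per
  out
}

#' Check homologue consistency across poly-N gaps
#'
#' Sequences containing internal runs of `N` (scaffolding gaps) are split at
#' those runs; the sequence is consistent when every segment's best
#' homologue is the same protein and the segments' subject coordinates run
#' in the same order as the segments do along the sequence (reversed order
#' for minus-strand frames).
#'
#' @param sequence nucleotide string, expected to contain at least one `N`
#'   run.
#' @param db named character vector of proteins.
#' @param min_segment segments shorter than this many bases are ignored
#'   (default 60).
#' @param ... passed to [assign_best_homologue()].
#' @return list with `has_gap`, `consistent` (NA when no gap or fewer than
#'   two alignable segments), `subject_id`, and the per-segment table.
#' @export
check_gap_consistency <- function(sequence, db, min_segment = 60L, ...) {
  segs <- strsplit(sequence, "N+")[[1]]
  segs <- segs[nzchar(segs)]
  if (length(segs) < 2L) {
    message("no internal N run; nothing to check")
    return(list(has_gap = FALSE, consistent = NA, subject_id = NA_character_,
                segments = NULL))
  }
  segs <- segs[nchar(segs) >= min_segment]
  rows <- list()
  for (i in seq_along(segs)) {
    a <- assign_best_homologue(segs[i], db, ...)
    if (is.null(a)) next
    rows[[length(rows) + 1L]] <- data.frame(
      segment = i, subject_id = a$subject_id, frame = a$frame,
      s_start = a$s_start, s_end = a$s_end, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2L)
    return(list(has_gap = TRUE, consistent = NA, subject_id = NA_character_,
                segments = tab))
  one_subject <- length(unique(tab$subject_id)) == 1L
  plus <- grepl("^\\+", tab$frame)
  ordered <- if (all(plus)) !is.unsorted(tab$s_start, strictly = TRUE)
             else if (all(!plus)) !is.unsorted(rev(tab$s_start),
                                               strictly = TRUE)
             else FALSE
  list(has_gap = TRUE, consistent = one_subject && ordered,
       subject_id = if (one_subject) tab$subject_id[1] else NA_character_,
       segments = tab)
}

#' Translated scan of assembled sequences against reference genes
#'
#' Both query and reference are translated in all six frames and locally
#' aligned frame-against-frame (the approach used to find insecticide
#' target-site genes from the closest related species).  The best alignment
#' per (isotig, reference) pair is reported; pairs with identity strictly
#' greater than `min_identity` are flagged as passing, and the best
#' sub-threshold identity is still reported so near-misses remain visible.
#'
#' @param isotigs data.frame with `isotig_id`, `sequence`, or named
#'   character vector.
#' @param references named character vector (or `DNAStringSet`) of
#'   nucleotide reference genes.
#' @param min_identity identity threshold (default 0.90).
#' @param min_aa minimum alignment length in residues to consider (default
#'   20).
#' @param word_size peptide word length for candidate prefiltering.
#' @return data.frame with one row per (reference, isotig) pair that aligned
#'   at all: `reference_id`, `isotig_id`, `identity`, `evalue`,
#'   `aligned_len`, `isotig_length`, `q_frame`, `r_frame`, `passes`.
#' @export
translated_scan <- function(isotigs, references, min_identity = 0.90,
                            min_aa = 20L, word_size = 5L) {
  if (is.character(isotigs))
    isotigs <- data.frame(isotig_id = names(isotigs),
                          sequence = unname(isotigs),
                          stringsAsFactors = FALSE)
  if (methods::is(references, "DNAStringSet"))
    references <- stats::setNames(as.character(references),
                                  names(references))
  ref_frames <- lapply(references, translate_six_frames)
  # flatten reference frames into one pseudo-database for word filtering
  flat <- list()
  for (rid in names(ref_frames)) for (fr in names(ref_frames[[rid]])) {
    pep <- ref_frames[[rid]][[fr]]
    if (nzchar(pep)) flat[[paste(rid, fr, sep = "\r")]] <- pep
  }
  flat <- unlist(flat)
  idx <- .build_word_index(flat, word_size)
  n_db <- sum(nchar(flat))
  rows <- list()
  for (i in seq_len(nrow(isotigs))) {
    qf <- translate_six_frames(isotigs$sequence[i])
    best <- list()
    for (fr in names(qf)) {
      pep <- qf[[fr]]
      if (!nzchar(pep)) next
      for (key in .word_candidates(pep, idx, word_size)) {
        hit <- local_align_protein(pep, flat[[key]], db_residues = n_db)
        if (is.null(hit) || hit$aligned_len < min_aa) next
        parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
        rid <- parts[1]
        if (is.null(best[[rid]]) || hit$score > best[[rid]]$hit$score)
          best[[rid]] <- list(hit = hit, q_frame = fr, r_frame = parts[2])
      }
    }
    for (rid in names(best)) {
      b <- best[[rid]]
      rows[[length(rows) + 1L]] <- data.frame(
        reference_id = rid, isotig_id = isotigs$isotig_id[i],
        identity = b$hit$identity, evalue = b$hit$evalue,
        aligned_len = b$hit$aligned_len,
        isotig_length = nchar(isotigs$sequence[i]),
        q_frame = b$q_frame, r_frame = b$r_frame,
        passes = b$hit$identity > min_identity,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(reference_id = character(0), isotig_id = character(0),
                      identity = numeric(0), evalue = numeric(0),
                      aligned_len = integer(0), isotig_length = integer(0),
                      q_frame = character(0), r_frame = character(0),
                      passes = logical(0))
  out[order(out$reference_id, -out$identity), ]
}
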