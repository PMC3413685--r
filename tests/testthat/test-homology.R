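# Six-frame translation, local alignment, homologue assignment, multi-k
# merging, validation, gap consistency, and translated scans.

test_that("six-frame translation matches an independent codon table", {
  fr <- translate_six_frames("ATGGCC")
  expect_equal(fr[["+1"]], "MA")
  expect_equal(translate_six_frames("ATG")[["+2"]], "")
  expect_equal(translate_six_frames("ATG")[["+3"]], "")
  set.seed(11)
  for (i in 1:20) {
    nt <- random_dna(300)
    expect_equal(translate_six_frames(nt), oracle_six_frames(nt))
  }
  # N-containing codons render as X
  expect_equal(translate_six_frames("ATGNNNGCC")[["+1"]], "MXA")
})

test_that("local protein alignment equals a quadratic DP oracle", {
  h <- local_align_protein("MKTAYIAKQRQISFVKSHFS", "MKTAYIAKQRQISFVKSHFS")
  expect_equal(h$identity, 1.0)
  expect_equal(c(h$q_start, h$q_end), c(1L, 20L))
  expect_equal(c(h$s_start, h$s_end), c(1L, 20L))

  # disjoint residue alphabets with negative substitution scores: no hit
  expect_null(local_align_protein(strrep("A", 20), strrep("W", 20)))

  b62 <- local_align_protein("AC", "AC")  # warm the matrix cache
  mat <- get("BLOSUM62",
             envir = asNamespace("isotigr")$.isotigr_cache)
  set.seed(12)
  for (i in 1:50) {
    a <- random_pep(sample(10:50, 1))
    b <- random_pep(sample(10:50, 1))
    got <- local_align_protein(a, b)
    want <- oracle_sw_score(a, b, mat)
    expect_equal(if (is.null(got)) 0 else got$score, want)
  }
})

test_that("E-values decrease strictly with score", {
  s <- seq(20, 200, by = 5)
  e <- evalue_from_score(s, m = 100, n = 1e5)
  expect_true(all(diff(e) < 0))
  expect_true(all(e > 0))
})

test_that("best-homologue assignment obeys thresholds and ties", {
  set.seed(13)
  pep <- random_pep(100)
  db <- c(P_target = pep, P_decoy = random_pep(100))
  nt <- oracle_backtranslate(pep)
  a <- assign_best_homologue(nt, db, query_id = "q1")
  expect_equal(a$subject_id, "P_target")
  expect_equal(a$identity, 1.0)
  expect_equal(a$frame, "+1")

  # an alignment of exactly 60 residues fails the strict > 60 rule
  pep60 <- random_pep(60)
  a60 <- assign_best_homologue(oracle_backtranslate(pep60),
                               c(P = pep60))
  expect_null(a60)
  pep61 <- random_pep(61)
  a61 <- assign_best_homologue(oracle_backtranslate(pep61),
                               c(P = pep61))
  expect_false(is.null(a61))
  expect_equal(a61$aligned_len, 61L)
})

test_that("assignments point to the true source gene on simulated data", {
  cfg <- sim_config(n_genes = 30, isoform_probability = 0, seed = 14)
  tx <- generate_transcriptome(cfg)
  pdb <- build_protein_db(tx, target_identity = 0.7, seed = 15)
  asg <- assign_homologues(
    data.frame(isotig_id = tx$isoform_id, sequence = tx$sequence), pdb)
  expect_gte(nrow(asg), 0.95 * nrow(tx))
  correct <- sub("^P_", "", asg$subject_id) ==
    sub("\\.\\d+$", "", asg$isotig_id)
  expect_gte(mean(correct), 0.95)
})

test_that("multi-k merging adds only novel homologues", {
  sets <- list(
    "31" = data.frame(isotig_id = c("a", "b"), sequence = c("s", "s")),
    "21" = data.frame(isotig_id = c("c", "d"), sequence = c("s", "s")),
    "41" = data.frame(isotig_id = c("e", "f"), sequence = c("s", "s")))
  asg <- data.frame(isotig_id = c("a", "b", "c", "d", "e", "f"),
                    subject_id = c("A", "B", "B", "C", "C", "D"))
  m <- merge_multi_k(sets, asg, base_k = 31)
  expect_equal(nrow(m$isotigs), 4L)          # base a,b + one C + one D
  expect_setequal(m$subjects, c("A", "B", "C", "D"))
  # k=21 (closer to 31) is processed first and claims C
  expect_true("d" %in% m$isotigs$isotig_id)
  expect_true("f" %in% m$isotigs$isotig_id)
  expect_false("e" %in% m$isotigs$isotig_id)
  expect_equal(m$tally$n_additional[m$tally$k == 21], 1L)
  expect_equal(m$tally$n_additional[m$tally$k == 41], 1L)

  # all-duplicate case: merged equals the base set
  asg2 <- transform(asg, subject_id = c("A", "B", "A", "B", "A", "B"))
  m2 <- merge_multi_k(sets, asg2, base_k = 31)
  expect_equal(m2$isotigs$isotig_id, c("a", "b"))
  expect_true(all(m2$tally$n_additional == 0L))

  # missing base k is a hard error
  expect_error(merge_multi_k(sets[c("21", "41")], asg, base_k = 31),
               "base k")

  # empty non-base sets: base set, zero tallies
  m3 <- merge_multi_k(list("31" = sets[["31"]]), asg, base_k = 31)
  expect_equal(nrow(m3$isotigs), 2L)
})

test_that("merged subject set equals the per-k union (property)", {
  set.seed(16)
  for (rep in 1:20) {
    ks <- c(21, 31, 41)
    sets <- list(); asg <- list()
    for (k in ks) {
      n <- sample(1:8, 1)
      ids <- sprintf("k%d_i%d", k, seq_len(n))
      sets[[as.character(k)]] <- data.frame(isotig_id = ids,
                                            sequence = ids)
      asg[[as.character(k)]] <- data.frame(
        isotig_id = ids,
        subject_id = sample(LETTERS[1:6], n, replace = TRUE))
    }
    asg <- do.call(rbind, asg)
    m <- merge_multi_k(sets, asg, base_k = 31)
    expect_setequal(m$subjects, unique(asg$subject_id))
  }
})

test_that("known-mRNA validation applies both criteria", {
  set.seed(17)
  mrna <- random_dna(600)
  # exact substring covering 90% of its own length: passes with identity 1
  iso_pass <- substr(mrna, 31, 570)
  # 94% identity copy: excluded by the identity rule
  iso_94 <- iso_pass
  at <- seq(5, 540, length.out = round(0.06 * 540))
  for (p in at) {
    cur <- substr(iso_94, p, p)
    substr(iso_94, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  # unrelated sequence: no alignment worth reporting
  iso_junk <- random_dna(500)
  res <- validate_against_known(
    c(ok = iso_pass, near = iso_94, junk = iso_junk), c(M1 = mrna))
  expect_equal(res$isotig_id, "ok")
  expect_equal(res$identity, 1.0)
  expect_equal(res$coverage, 1.0)

  # planted pass/fail fixture: passing set equals the plant list
  planted <- lapply(1:10, function(i) {
    if (i <= 6) substr(mrna, 1, 400)          # pass
    else random_dna(400)                       # fail
  })
  names(planted) <- sprintf("i%02d", 1:10)
  res2 <- validate_against_known(unlist(planted), c(M1 = mrna))
  expect_setequal(res2$isotig_id, sprintf("i%02d", 1:6))
  # reverse-complement isotigs also validate
  res3 <- validate_against_known(c(rc = oracle_revcomp(iso_pass)),
                                 c(M1 = mrna))
  expect_equal(res3$isotig_id, "rc")
})

test_that("poly-N gap consistency checks subject and order", {
  set.seed(18)
  pep <- random_pep(200)
  db <- c(P1 = pep, P2 = random_pep(200))
  seg_a <- oracle_backtranslate(substr(pep, 1, 70))     # subject 1..70
  seg_b <- oracle_backtranslate(substr(pep, 101, 180))  # subject 101..180
  gap <- strrep("N", 20)

  ok <- check_gap_consistency(paste0(seg_a, gap, seg_b), db)
  expect_true(ok$has_gap)
  expect_true(ok$consistent)
  expect_equal(ok$subject_id, "P1")

  rev_order <- check_gap_consistency(paste0(seg_b, gap, seg_a), db)
  expect_false(rev_order$consistent)

  seg_c <- oracle_backtranslate(substr(db[["P2"]], 1, 70))
  two_prot <- check_gap_consistency(paste0(seg_a, gap, seg_c), db)
  expect_false(two_prot$consistent)

  expect_message(nog <- check_gap_consistency(seg_a, db), "no internal N")
  expect_false(nog$has_gap)
})

test_that("translated scans find target-site genes across frames", {
  set.seed(19)
  cfg <- sim_config(n_genes = 2, isoform_probability = 0,
                    cds_length_range = c(600, 900), seed = 20)
  tx <- generate_transcriptome(cfg)
  ref <- setNames(tx$sequence[1], "refgene")

  # an exact subsequence of >= 150 bp scores identity 1 and passes
  frag <- substr(tx$sequence[1], tx$cds_start[1], tx$cds_start[1] + 299)
  res <- translated_scan(c(hit = frag), ref)
  expect_equal(unique(res$reference_id), "refgene")
  expect_equal(max(res$identity), 1.0)
  expect_true(any(res$passes))

  # an unrelated gene shares no long peptide word: no hit
  res2 <- translated_scan(c(other = tx$sequence[2]), ref, word_size = 10)
  expect_equal(nrow(res2), 0L)

  # fragments tiling one reference are all grouped under it
  starts <- seq(tx$cds_start[1], tx$cds_start[1] + 449, by = 50)
  frags <- setNames(substring(tx$sequence[1], starts, starts + 179),
                    sprintf("f%02d", seq_along(starts)))
  res3 <- translated_scan(frags, ref)
  expect_setequal(res3$isotig_id, names(frags))
  expect_true(all(res3$reference_id == "refgene"))
  expect_true(all(res3$passes))
})
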