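# Motif grammar, matching, EC prediction, deduplication, gene collapsing.

test_that("motif parsing follows the flexible-gap grammar", {
  p <- parse_motif("GxSxG")
  expect_length(p$elements, 5)
  expect_equal(vapply(p$elements, `[[`, "", "type"),
               c("fixed", "any", "fixed", "any", "fixed"))

  p2 <- parse_motif("FxxGxRxCxG")
  expect_length(p2$elements, 10)
  expect_equal(sum(vapply(p2$elements, `[[`, "", "type") == "fixed"), 5)

  p3 <- parse_motif("PxLxD-x(7,10)-SxAIxxYLxxK")
  types <- vapply(p3$elements, `[[`, "", "type")
  expect_equal(sum(types == "gap"), 1)
  g <- p3$elements[[which(types == "gap")]]
  expect_equal(c(g$min, g$max), c(7, 10))
  expect_equal(motif_length_range(p3), c(23L, 26L))

  # round trip: parse -> render -> parse preserves the elements
  expect_equal(parse_motif(render_motif(p3))$elements, p3$elements)

  expect_error(parse_motif("x(3,1)A"), "0 <= m <= n")
  expect_error(parse_motif("x(a,b)A"), "malformed")
  expect_error(parse_motif("xxx"), "no fixed residue")
  expect_error(parse_motif("G?S"), "unexpected character")
})

test_that("motif matching reports every admissible start", {
  expect_equal(match_motif("GxSxG", "AGASAGA")$start, 2L)
  inst <- paste0("PALAD", "AAAAAAA", "SAAIAAYLAAK")
  m <- match_motif("PxLxD-x(7,10)-SxAIxxYLxxK", inst)
  expect_equal(m$start, 1L)
  expect_equal(m$end, 23L)
  # matches never cross a stop codon
  expect_equal(nrow(match_motif("GxSxG", "AG*SAG")), 0L)
  expect_equal(nrow(match_motif("GxSxG", "G*SAG")), 0L)
  # overlapping matches are all reported
  m2 <- match_motif("GxG", "GAGAGAG")
  expect_equal(m2$start, c(1L, 3L, 5L))
})

test_that("motif matcher agrees with a regex transcription oracle", {
  lib <- read_motif_library()
  set.seed(21)
  alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
  for (i in seq_len(nrow(lib))) {
    for (rep in 1:30) {
      pep <- random_pep(200, alphabet = alpha)
      got <- match_motif(lib$pattern[[i]], pep)$start
      want <- oracle_motif_starts(lib$raw[i], pep)
      expect_equal(got, want,
                   info = paste("pattern", lib$raw[i], "rep", rep))
    }
    # seeded positives: a sampled instance is always found at its plant
    for (rep in 1:10) {
      inst <- sample_motif_instance(lib$pattern[[i]])
      host <- paste0(random_pep(40), inst, random_pep(40))
      expect_true(41L %in% match_motif(lib$pattern[[i]], host)$start)
    }
  }
})

test_that("EC prediction follows the closest enzyme and motif tie-break", {
  set.seed(22)
  # single candidate: its EC is taken
  cfg <- sim_config(n_genes = 1, enzyme_fraction = 1, seed = 23)
  tx <- generate_transcriptome(cfg)
  pdb <- build_protein_db(tx, target_identity = 0.9, seed = 24)
  truth <- attr(pdb, "truth")
  db1 <- enzyme_db(pdb, truth$ec)
  pr <- predict_ec(tx$sequence[1], db1, query_id = tx$isoform_id[1])
  expect_equal(pr$ec, tx$ec[1])
  expect_false(pr$unresolved)

  # ambiguity resolved by a motif: two equally close enzymes with
  # different ECs; the query carries the GST motif SxAI
  core <- random_pep(120)
  query_pep <- paste0(random_pep(10), "SAAI", core)
  db2 <- enzyme_db(c(E_gst = paste0("DDDD", core),
                     E_coe = paste0("EEEE", core)),
                   c("2.5.1.18", "3.1.1.1"))
  pr2 <- predict_ec(oracle_backtranslate(query_pep), db2)
  expect_equal(pr2$ec, "2.5.1.18")
  expect_true(pr2$motif_confirmed)
  expect_false(pr2$unresolved)

  # clear ranking: a vastly closer enzyme wins regardless of motifs
  far <- diverge_pep(core, 0.55)
  db3 <- enzyme_db(c(E_near = paste0("DDDD", core),
                     E_far = paste0("EEEE", far)),
                   c("4.2.1.1", "5.3.1.1"))
  pr3 <- predict_ec(oracle_backtranslate(paste0(random_pep(10), core)),
                    db3)
  expect_equal(pr3$ec, "4.2.1.1")
  expect_false(pr3$unresolved)

  # nothing passing: NULL
  expect_null(predict_ec(oracle_backtranslate(random_pep(80)), db1))
})

test_that("coverage deduplication keeps the best isotig per homologue", {
  preds <- data.frame(
    isotig_id = c("i1", "i2", "i3", "i4"),
    ec = c("1.1.1.1", "1.1.1.1", "1.1.1.1", "1.1.1.1"),
    subject_id = c("P1", "P1", "P1", "P2"),
    length = c(500L, 400L, 300L, 200L))
  covs <- c(i1 = 5, i2 = 9, i3 = 2, i4 = 1)
  out <- dedupe_by_coverage(preds, covs)
  expect_setequal(out$isotig_id, c("i2", "i4"))

  # distinct homologues are all retained
  preds2 <- transform(preds, subject_id = c("P1", "P2", "P3", "P4"))
  expect_equal(nrow(dedupe_by_coverage(preds2, covs)), 4L)

  # ties break by longer isotig then id
  preds3 <- preds[1:2, ]
  out3 <- dedupe_by_coverage(preds3, c(i1 = 5, i2 = 5))
  expect_equal(out3$isotig_id, "i1")

  # property: equals a brute-force group-by max on random inputs
  set.seed(25)
  for (rep in 1:20) {
    n <- 50
    p <- data.frame(
      isotig_id = sprintf("i%02d", 1:n),
      ec = sample(c("1.1.1.1", "2.2.2.2"), n, replace = TRUE),
      subject_id = sample(c("P1", "P2", "P3"), n, replace = TRUE),
      length = sample(100:1000, n, replace = TRUE))
    cv <- setNames(runif(n, 1, 50), p$isotig_id)
    out <- dedupe_by_coverage(p, cv)
    brute <- do.call(rbind, lapply(
      split(p, paste(p$ec, p$subject_id)), function(d) {
        cvd <- cv[d$isotig_id]
        d[order(-cvd, -d$length, d$isotig_id)[1], ]
      }))
    expect_setequal(out$isotig_id, brute$isotig_id)
  }
})

test_that("gene collapsing separates isoforms from fragments", {
  base <- data.frame(ec = "1.14.14.1", stringsAsFactors = FALSE)
  # disjoint alignments on one reference: one gene, two transcript units
  p <- data.frame(isotig_id = c("a", "b"), ec = "1.14.14.1",
                  subject_id = "P1", s_start = c(1L, 151L),
                  s_end = c(100L, 300L))
  cg <- collapse_genes(p)
  expect_equal(nrow(cg$clusters), 1L)
  expect_equal(cg$clusters$n_transcript_units, 2L)

  # near-identical spans: isoform candidates, one unit
  p2 <- transform(p, s_start = c(1L, 1L), s_end = c(300L, 300L))
  cg2 <- collapse_genes(p2, coverages = c(a = 2, b = 7))
  expect_equal(cg2$clusters$n_transcript_units, 1L)
  expect_equal(cg2$clusters$representative, "b")

  # gene count <= isotig count, equality iff all gene keys distinct
  p3 <- data.frame(isotig_id = c("a", "b", "c"), ec = "2.5.1.18",
                   subject_id = c("P1", "P2", "P3"),
                   s_start = 1L, s_end = 100L)
  cg3 <- collapse_genes(p3, families = c("2.5.1.18" = "GST"))
  expect_equal(nrow(cg3$clusters), 3L)
  expect_equal(cg3$tally$n_genes[cg3$tally$family == "GST"], 3)
  expect_equal(cg3$tally$n_isotigs[cg3$tally$family == "GST"], 3)
})

test_that("collapsing recovers the simulated gene count exactly", {
  set.seed(26)
  n_genes <- 12
  cfg <- sim_config(n_genes = n_genes, isoform_probability = 0,
                    enzyme_fraction = 1, cds_length_range = c(450, 720),
                    seed = 27)
  tx <- generate_transcriptome(cfg)
  pdb <- build_protein_db(tx, target_identity = 0.9, seed = 28)
  truth <- attr(pdb, "truth")
  edb <- enzyme_db(pdb, truth$ec)
  # catalogue with redundant fragments and full-length isoforms
  frags <- list()
  for (i in seq_len(nrow(tx))) {
    s <- tx$sequence[i]; cs <- tx$cds_start[i]; ce <- tx$cds_end[i]
    mid <- cs + ((ce - cs) %/% 2)
    frags[[paste0(tx$isoform_id[i], "_full")]] <- s
    frags[[paste0(tx$isoform_id[i], "_5p")]] <- substr(s, cs, mid + 60)
    frags[[paste0(tx$isoform_id[i], "_3p")]] <- substr(s, mid - 60, ce)
  }
  cat_iso <- data.frame(isotig_id = names(frags),
                        sequence = unlist(frags),
                        stringsAsFactors = FALSE)
  preds <- predict_ec_batch(cat_iso, edb)
  cg <- collapse_genes(preds)
  expect_equal(nrow(cg$clusters), n_genes)
  expect_true(all(cg$clusters$n_isotigs >= 2))

  # dedupe then collapse is stable under repetition
  covs <- setNames(rep(1, nrow(preds)), preds$isotig_id)
  d1 <- dedupe_by_coverage(preds, covs)
  d2 <- dedupe_by_coverage(d1, covs)
  expect_identical(d1, d2)
})

test_that("enzyme database round-trips through tagged FASTA", {
  db <- enzyme_db(c(E1 = "MKTAYIAK", E2 = "MSHHWGYG"),
                  c("1.14.14.1", "2.5.1.18"))
  f <- tempfile(fileext = ".fa")
  write_enzyme_db(db, f)
  back <- read_enzyme_db(f)
  expect_equal(back$proteins, db$proteins)
  expect_equal(back$ec, db$ec)
})
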