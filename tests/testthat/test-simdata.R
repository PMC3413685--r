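# Synthetic transcriptome / read / protein-database generators.

test_that("transcriptome generation respects counts, invariants and seeds", {
  expect_equal(nrow(generate_transcriptome(sim_config(n_genes = 0))), 0L)

  cfg <- sim_config(n_genes = 10, isoform_probability = 0, seed = 1)
  tx <- generate_transcriptome(cfg)
  expect_equal(nrow(tx), 10L)
  expect_equal(length(unique(tx$gene_id)), 10L)
  expect_true(all(tx$expression > 0))
  expect_true(all(nchar(tx$sequence) >= 3 * cfg$min_orf_aa))
  # CDS coordinates frame a real ORF
  cds <- substr(tx$sequence, tx$cds_start, tx$cds_end)
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  expect_true(all(nchar(cds) %% 3 == 0))

  tx2 <- generate_transcriptome(cfg)
  expect_identical(tx, tx2)
  expect_error(sim_config(n_genes = 5, error_rate = 1.5), "probabilities")
})

test_that("isoforms of one gene share a long exon block", {
  cfg <- sim_config(n_genes = 15, isoform_probability = 1, seed = 3)
  tx <- generate_transcriptome(cfg)
  for (g in unique(tx$gene_id)) {
    iso <- tx[tx$gene_id == g, ]
    if (nrow(iso) < 2) next
    # the first exon block (>= 60 bp) is never skipped
    probe <- substr(iso$sequence[2], iso$cds_start[2],
                    iso$cds_start[2] + 59)
    expect_true(grepl(probe, iso$sequence[1], fixed = TRUE))
  }
})

test_that("noise-free reads are exact substrings and rates force content", {
  cfg <- sim_config(n_genes = 5, error_rate = 0, adapter_rate = 0,
                    n_rate = 0, seed = 2)
  tx <- generate_transcriptome(cfg)
  rp <- simulate_reads(tx, cfg, n_pairs = 300)
  seqs <- setNames(tx$sequence, tx$isoform_id)
  for (i in seq_len(nrow(rp))) {
    s <- seqs[[rp$origin[i]]]
    expect_true(grepl(rp$bases1[i], s, fixed = TRUE) ||
                grepl(revcomp(rp$bases1[i]), s, fixed = TRUE))
    expect_true(grepl(rp$bases2[i], s, fixed = TRUE) ||
                grepl(revcomp(rp$bases2[i]), s, fixed = TRUE))
    # recorded origin coordinates are valid and carry the fragment
    expect_gte(rp$frag_start[i], 1L)
    expect_lte(rp$frag_end[i], nchar(s))
  }
  cfgN <- sim_config(n_genes = 3, n_rate = 1, seed = 4)
  txN <- generate_transcriptome(cfgN)
  rpN <- simulate_reads(txN, cfgN, n_pairs = 50)
  expect_true(all(grepl("N", rpN$bases1)) && all(grepl("N", rpN$bases2)))
  expect_error(sim_config(insert_size_mean = 50, read_length = 90),
               "insert size")
})

test_that("fragment origins follow expression with multinomial error", {
  cfg <- sim_config(n_genes = 2, isoform_probability = 0,
                    cds_length_range = c(600, 600),
                    utr_length_range = c(50, 50), seed = 7)
  tx <- generate_transcriptome(cfg)
  # sampling weights are expression x length; normalize lengths away so the
  # origin odds are exactly 9:1
  tx$expression <- c(9, 1) / nchar(tx$sequence)
  rp <- simulate_reads(tx, cfg, n_pairs = 10000)
  n1 <- sum(rp$origin == tx$isoform_id[1])
  # lengths equal by construction, so weights are 9:1
  p <- 0.9
  expect_lt(abs(n1 - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))
})

test_that("per-base error and N rates are calibrated", {
  cfg <- sim_config(n_genes = 5, error_rate = 0.01, n_rate = 0.005,
                    seed = 9)
  tx <- generate_transcriptome(cfg)
  rp <- simulate_reads(tx, cfg, n_pairs = 6000)
  seqs <- setNames(tx$sequence, tx$isoform_id)
  rl <- cfg$read_length
  nN <- 0; nerr <- 0; ntot <- 0
  for (i in seq_len(nrow(rp))) {
    frag <- substr(seqs[[rp$origin[i]]], rp$frag_start[i], rp$frag_end[i])
    ins <- nchar(frag)
    exp_fwd <- substr(frag, 1, rl)
    exp_rev <- revcomp(substr(frag, ins - rl + 1, ins))
    for (obs in c(rp$bases1[i], rp$bases2[i])) {
      mm <- min(sum(charToRaw(obs) != charToRaw(exp_fwd)),
                sum(charToRaw(obs) != charToRaw(exp_rev)))
      isN <- sum(charToRaw(obs) == charToRaw("N"))
      nN <- nN + isN
      nerr <- nerr + mm - isN
      ntot <- ntot + rl
    }
  }
  se <- function(p) sqrt(p * (1 - p) / ntot)
  expect_lt(abs(nN / ntot - cfg$n_rate), 3 * se(cfg$n_rate))
  expect_lt(abs(nerr / ntot - cfg$error_rate), 3 * se(cfg$error_rate))
})

test_that("protein database identity is controlled", {
  cfg <- sim_config(n_genes = 100, isoform_probability = 0, seed = 5)
  tx <- generate_transcriptome(cfg)

  exact <- build_protein_db(tx, target_identity = 1.0, seed = 1)
  cds <- substr(tx$sequence, tx$cds_start, tx$cds_end)
  truth_pep <- vapply(cds, function(s) {
    p <- oracle_translate(s)
    sub("\\*$", "", p)
  }, "", USE.NAMES = FALSE)
  expect_identical(unname(exact[paste0("P_", tx$gene_id)]), truth_pep)

  div <- build_protein_db(tx, target_identity = 0.7, seed = 2)
  idents <- mapply(function(p, t) {
    sum(charToRaw(p) == charToRaw(t)) / nchar(t)
  }, div[paste0("P_", tx$gene_id)], truth_pep)
  expect_gte(mean(idents), 0.68)
  expect_lte(mean(idents), 0.72)

  empty <- build_protein_db(generate_transcriptome(sim_config(n_genes = 0)))
  expect_length(empty, 0L)
})

test_that("motif planting places retrievable in-frame instances", {
  cfg <- sim_config(n_genes = 1, isoform_probability = 0, seed = 6)
  tx <- generate_transcriptome(cfg)

  p1 <- plant_motif(tx[1, ], "GxSxG", seed = 11, motif_id = "m1")
  info <- attr(p1, "planted")
  pep <- oracle_translate(substr(p1$sequence, p1$cds_start, p1$cds_end))
  hit <- substr(pep, info$aa_offset, info$aa_offset + 4)
  expect_equal(substr(hit, 1, 1), "G")
  expect_equal(substr(hit, 3, 3), "S")
  expect_equal(substr(hit, 5, 5), "G")
  expect_true(info$aa_offset %in% match_motif("GxSxG", pep)$start)

  # flexible-gap instance length bounds: 5 + (7..10) + 11 residues
  big <- "PxLxD-x(7,10)-SxAIxxYLxxK"
  for (s in 1:10) {
    inst <- sample_motif_instance(parse_motif(big))
    expect_gte(nchar(inst), 23)
    expect_lte(nchar(inst), 26)
  }
  p2 <- plant_motif(tx[1, ], big, seed = 12)
  info2 <- attr(p2, "planted")
  pep2 <- oracle_translate(substr(p2$sequence, p2$cds_start, p2$cds_end))
  expect_true(info2$aa_offset %in% match_motif(big, pep2)$start)
})

test_that("read simulation is byte-deterministic through FASTQ", {
  cfg <- sim_config(n_genes = 4, seed = 13)
  tx <- generate_transcriptome(cfg)
  rp <- simulate_reads(tx, cfg, n_pairs = 100)
  d1 <- tempfile(); d2 <- tempfile()
  write_read_pairs(rp, d1)
  rp2 <- simulate_reads(generate_transcriptome(cfg), cfg, n_pairs = 100)
  write_read_pairs(rp2, d2)
  expect_identical(readLines(paste0(d1, "_1.fq")),
                   readLines(paste0(d2, "_1.fq")))
  expect_identical(readLines(paste0(d1, "_2.fq")),
                   readLines(paste0(d2, "_2.fq")))
  # round trip through the FASTQ reader
  back <- read_fastq(paste0(d1, "_1.fq"))
  expect_equal(back$bases, rp$bases1)
  expect_equal(back$quals, rp$quals1)
})
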