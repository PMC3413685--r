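# Independent oracles used to cross-check the package's implementations.
# Deliberately written with different algorithms/data than the package code.

# hand-written standard codon table (independent of any library)
ORACLE_CODON <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(s, function(x)
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(nt, 3L * i - 2L, 3L * i)
    out[i] <- if (cod %in% names(ORACLE_CODON)) ORACLE_CODON[[cod]] else "X"
  }
  paste(out, collapse = "")
}

oracle_six_frames <- function(nt) {
  rc <- oracle_revcomp(nt)
  out <- character(6)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (i in 1:3) {
    out[paste0("+", i)] <- oracle_translate(substr(nt, i, nchar(nt)))
    out[paste0("-", i)] <- oracle_translate(substr(rc, i, nchar(rc)))
  }
  out
}

# Smith-Waterman with affine gaps (Gotoh), plain quadratic DP.
# A gap of length L costs open + L * ext.
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(M[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(M[i - 1, j] - open - ext, F[i - 1, j] - ext)
      sub <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# independent re-implementation of the read filter predicates
oracle_read_pass <- function(bases, quals_int, adapters = character(0),
                             window = 35, min_good = 25, min_q = 30) {
  if (length(quals_int) < window) return(FALSE)
  good <- 0L
  for (i in seq_len(window)) if (quals_int[i] > min_q) good <- good + 1L
  if (good < min_good) return(FALSE)
  if (any(strsplit(bases, "")[[1]] == "N")) return(FALSE)
  for (ad in adapters) {
    if (nzchar(ad) && length(gregexpr(ad, bases, fixed = TRUE)[[1]]) > 0 &&
        gregexpr(ad, bases, fixed = TRUE)[[1]][1] != -1) return(FALSE)
  }
  TRUE
}

# brute-force N50: try candidate lengths from largest down
oracle_n50 <- function(lens) {
  tot <- sum(as.numeric(lens))
  for (L in sort(unique(lens), decreasing = TRUE)) {
    if (sum(as.numeric(lens[lens >= L])) >= tot / 2) return(L)
  }
  min(lens)
}

# transcribe a flexible-gap motif into an equivalent regular expression;
# overlapping matches found with a capture-in-lookahead scan
motif_to_regex <- function(raw) {
  s <- gsub("-", "", raw, fixed = TRUE)
  rx <- ""
  i <- 1L
  while (i <= nchar(s)) {
    ch <- substr(s, i, i)
    if (ch == "x") {
      rest <- substr(s, i + 1L, nchar(s))
      if (startsWith(rest, "(")) {
        close <- regexpr(")", rest, fixed = TRUE)
        body <- substr(rest, 2L, close - 1L)
        mn <- as.integer(strsplit(body, ",")[[1]])
        rx <- paste0(rx, "[^*]{", mn[1], ",", mn[2], "}")
        i <- i + 1L + close
      } else {
        rx <- paste0(rx, "[^*]")
        i <- i + 1L
      }
    } else {
      rx <- paste0(rx, ch)
      i <- i + 1L
    }
  }
  rx
}

oracle_motif_starts <- function(raw, peptide) {
  rx <- paste0("(?=(", motif_to_regex(raw), "))")
  m <- gregexpr(rx, peptide, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# substitute a fraction of residues (always to a different letter)
diverge_pep <- function(pep, identity) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- nchar(pep)
  at <- sample(n, round((1 - identity) * n))
  for (p in at) {
    cur <- substr(pep, p, p)
    substr(pep, p, p) <- sample(setdiff(aa, cur), 1)
  }
  pep
}

# back-translate a peptide with the first codon of each residue
oracle_backtranslate <- function(pep) {
  rev_tab <- tapply(names(ORACLE_CODON), ORACLE_CODON, `[`, 1)
  paste(rev_tab[strsplit(pep, "")[[1]]], collapse = "")
}
random_pep <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                              "")[[1]])
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# reads tiling a sequence end to end at a fixed stride
tile_reads <- function(s, rl = 90L, step = 3L) {
  st <- unique(c(seq(1L, nchar(s) - rl + 1L, by = step),
                 nchar(s) - rl + 1L))
  substring(s, st, st + rl - 1L)
}

# shared expensive simulation for the completeness/coverage properties,
# computed once per test run
.fig2_env <- new.env()
fig2_simulation <- function(seed = 421L) {
  key <- paste0("s", seed)
  if (!is.null(.fig2_env[[key]])) return(.fig2_env[[key]])
  cfg <- sim_config(n_genes = 500L, isoform_probability = 0,
                    cds_length_range = c(300L, 600L),
                    utr_length_range = c(30L, 60L),
                    expression_sdlog = 1.2, error_rate = 0, seed = seed)
  tx <- generate_transcriptome(cfg)
  pairs <- simulate_reads(tx, cfg, coverage = 20)
  reads <- c(pairs$bases1, pairs$bases2)
  g <- build_graph(reads, 31L)
  iso <- build_isotigs(g, extract_contigs(g))$isotigs
  iso <- iso[iso$length >= 100L, ]
  pdb <- build_protein_db(tx, target_identity = 0.9, seed = seed + 1L)
  asg <- assign_homologues(iso, pdb)
  cov <- map_reads(iso, reads)
  ct <- completeness_table(asg, pdb, coverage_profiles = cov)
  res <- list(cfg = cfg, tx = tx, iso = iso, pdb = pdb, asg = asg,
              cov = cov, ct = ct)
  .fig2_env[[key]] <- res
  res
}
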