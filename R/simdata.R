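# Synthetic data with known ground truth: transcriptomes with optional
# splice isoforms, lognormal expression, ~90-bp paired-end reads with
# position-dependent Phred qualities, adapter/N contamination, planted
# catalytic-site motifs, and protein databases diverged to a controlled
# identity.  Every generator is deterministic for a fixed seed.

.DNA4 <- c("A", "C", "G", "T")

# the 61 sense codons of the standard table, and one codon per amino acid
.sense_codons <- function() {
  if (is.null(.isotigr_cache$sense)) {
    all64 <- apply(expand.grid(.DNA4, .DNA4, .DNA4), 1, paste, collapse = "")
    aa <- vapply(all64, function(c3)
      as.character(Biostrings::translate(Biostrings::DNAString(c3))), "")
    sense <- all64[aa != "*"]
    .isotigr_cache$sense <- sense
    .isotigr_cache$sense_aa <- aa[aa != "*"]
    .isotigr_cache$codons_by_aa <- split(sense, aa[aa != "*"])
  }
  .isotigr_cache$sense
}

.codons_for <- function(aa) {
  .sense_codons()
  .isotigr_cache$codons_by_aa[[aa]]
}

.random_dna <- function(n) paste(sample(.DNA4, n, replace = TRUE),
                                 collapse = "")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic transcriptome and read generator.
#' Defaults emulate the study conditions the downstream analysis was
#' designed for: 90-base paired-end reads, lognormal expression, Phred
#' scores high at the 5' end and decaying toward the 3' end.
#'
#' @param n_genes number of genes (>= 0).
#' @param isoform_probability probability that a gene carries one extra
#'   splice isoform built by skipping one internal exon block.
#' @param read_length read length in bases (default 90).
#' @param insert_size_mean,insert_size_sd fragment (insert) size model in
#'   bases; the mean must be at least `read_length`.
#' @param expression_meanlog,expression_sdlog lognormal law for relative
#'   transcript abundance.
#' @param error_rate per-base substitution error probability.
#' @param adapter_rate probability that a fragment is shorter than the read
#'   length so the read runs into the adapter.
#' @param n_rate per-base probability of an uncalled base (`N`).
#' @param adapter adapter sequence appended in adapter events.
#' @param quality_high,quality_low,quality_sd Phred score model: per-base
#'   means decay linearly from `quality_high` (5' end) to `quality_low`
#'   (3' end) with gaussian jitter `quality_sd`, clamped to [2, 41].
#' @param cds_length_range,utr_length_range,block_size_range transcript
#'   architecture in bases (CDS lengths rounded to codons; blocks are the
#'   exon-sized units isoforms may skip).
#' @param min_orf_aa minimum ORF length (residues) for protein-database
#'   entries.
#' @param enzyme_fraction fraction of genes designated enzymes: they get an
#'   EC number and a planted catalytic-site motif instance in their CDS.
#' @param seed integer seed; all generators derive their randomness from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L, isoform_probability = 0.15,
                       read_length = 90L,
                       insert_size_mean = 200, insert_size_sd = 15,
                       expression_meanlog = 0, expression_sdlog = 1.2,
                       error_rate = 0.001, adapter_rate = 0, n_rate = 0,
                       adapter = "AGATCGGAAGAGCACACGTCT",
                       quality_high = 39, quality_low = 25, quality_sd = 3,
                       cds_length_range = c(300L, 900L),
                       utr_length_range = c(30L, 120L),
                       block_size_range = c(60L, 150L),
                       min_orf_aa = 50L, enzyme_fraction = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              isoform_probability = isoform_probability,
              read_length = as.integer(read_length),
              insert_size_mean = insert_size_mean,
              insert_size_sd = insert_size_sd,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              error_rate = error_rate, adapter_rate = adapter_rate,
              n_rate = n_rate, adapter = adapter,
              quality_high = quality_high, quality_low = quality_low,
              quality_sd = quality_sd,
              cds_length_range = as.integer(cds_length_range),
              utr_length_range = as.integer(utr_length_range),
              block_size_range = as.integer(block_size_range),
              min_orf_aa = as.integer(min_orf_aa),
              enzyme_fraction = enzyme_fraction,
              seed = as.integer(seed))
  probs <- c(isoform_probability = cfg$isoform_probability,
             error_rate = cfg$error_rate, adapter_rate = cfg$adapter_rate,
             n_rate = cfg$n_rate, enzyme_fraction = cfg$enzyme_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0,1]: ", paste(names(probs)[bad],
                                                collapse = ", "))
  if (cfg$n_genes < 0L) stop("n_genes must be >= 0")
  if (cfg$read_length < 1L) stop("read_length must be positive")
  if (cfg$insert_size_mean < cfg$read_length)
    stop("insert size mean (", cfg$insert_size_mean,
         ") below read length (", cfg$read_length,
         "): overlapping mates must be enabled explicitly via adapter_rate")
  structure(cfg, class = "sim_config")
}

# EC groups available to the enzyme planting step, with one representative
# motif each (drawn from the bundled library at generation time)
.ENZYME_ECS <- c("1.14.14.1", "2.5.1.18", "3.1.1.1", "3.1.1.7")

#' Generate a synthetic transcriptome
#'
#' Each gene is a transcript of 5' UTR + CDS + 3' UTR.  The CDS is a start
#' codon, a run of exon-sized blocks of sense codons (no internal stops),
#' and a stop codon.  With probability `isoform_probability` a gene emits a
#' second isoform that skips one internal block (frame-preserving), creating
#' the bubble structures an isotig builder must resolve.  A configurable
#' fraction of genes are "enzymes": they receive an EC number and a
#' catalytic-site motif instance planted in-frame inside the CDS.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `transcriptome` with columns `gene_id`,
#'   `isoform_id`, `sequence`, `expression`, `cds_start`, `cds_end`, `ec`;
#'   attributes `config` and `planted_motifs` (data.frame `isoform_id`,
#'   `motif_id`, `ec`, `pattern`, `aa_offset`, `aa_len`).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  empty <- data.frame(gene_id = character(0), isoform_id = character(0),
                      sequence = character(0), expression = numeric(0),
                      cds_start = integer(0), cds_end = integer(0),
                      ec = character(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "config") <- config
    attr(empty, "planted_motifs") <- data.frame()
    class(empty) <- c("transcriptome", "data.frame")
    return(empty)
  }
  sense <- .sense_codons()
  n_enz <- round(config$enzyme_fraction * n)
  enz_genes <- if (n_enz > 0L) sample(n, n_enz) else integer(0)
  enz_ecs <- if (n_enz > 0L)
    sample(.ENZYME_ECS, n_enz, replace = TRUE) else character(0)
  motlib <- if (n_enz > 0L) read_motif_library() else NULL
  rows <- list()
  motifs <- list()
  for (g in seq_len(n)) {
    gid <- sprintf("g%04d", g)
    # block architecture, in codons
    blk_rng <- pmax(1L, config$block_size_range %/% 3L)
    cds_rng <- pmax(3L, config$cds_length_range %/% 3L)
    target <- sample(seq.int(cds_rng[1], cds_rng[2]), 1L)
    blocks <- integer(0)
    while (sum(blocks) < target)
      blocks <- c(blocks, sample(seq.int(blk_rng[1], blk_rng[2]), 1L))
    block_seqs <- vapply(blocks, function(b)
      paste(sample(sense, b, replace = TRUE), collapse = ""), "")
    utr5 <- .random_dna(sample(seq.int(config$utr_length_range[1],
                                       config$utr_length_range[2]), 1L))
    # in-frame stop immediately upstream of the start codon, so the CDS is
    # exactly the longest ORF (no silent in-frame extension through the UTR)
    if (nchar(utr5) >= 3L)
      substr(utr5, nchar(utr5) - 2L, nchar(utr5)) <- "TAA"
    utr3 <- .random_dna(sample(seq.int(config$utr_length_range[1],
                                       config$utr_length_range[2]), 1L))
    ec <- NA_character_
    # plant an enzyme motif inside the first block (never skipped by
    # isoform construction, so every isoform carries it)
    planted <- NULL
    if (g %in% enz_genes) {
      ec <- enz_ecs[match(g, enz_genes)]
      pats <- motlib[motlib$ec == ec, ]
      pick <- sample(nrow(pats), 1L)
      inst <- sample_motif_instance(pats$pattern[[pick]])
      bt <- paste(vapply(strsplit(inst, "")[[1]], function(a)
        sample(.codons_for(a), 1L), ""), collapse = "")
      b1_codons <- nchar(block_seqs[1]) %/% 3L
      need <- nchar(inst)
      if (b1_codons < need + 2L)  # grow block 1 if the instance won't fit
        block_seqs[1] <- paste0(block_seqs[1],
          paste(sample(sense, need + 2L - b1_codons, replace = TRUE),
                collapse = ""))
      b1_codons <- nchar(block_seqs[1]) %/% 3L
      at <- sample(seq.int(2L, b1_codons - need), 1L)  # codon index in block
      substr(block_seqs[1], (at - 1L) * 3L + 1L, (at + need - 1L) * 3L) <- bt
      planted <- data.frame(motif_id = paste0("m_", gid), ec = ec,
                            pattern = pats$raw[pick],
                            aa_offset = at + 1L,  # +1 for the start codon M
                            aa_len = need, stringsAsFactors = FALSE)
    }
    make_tx <- function(iso_idx, keep) {
      cds <- paste0("ATG", paste(block_seqs[keep], collapse = ""), "TAA")
      seqs <- paste0(utr5, cds, utr3)
      data.frame(gene_id = gid,
                 isoform_id = sprintf("%s.%d", gid, iso_idx),
                 sequence = seqs,
                 expression = stats::rlnorm(1, config$expression_meanlog,
                                            config$expression_sdlog),
                 cds_start = nchar(utr5) + 1L,
                 cds_end = nchar(utr5) + nchar(cds),
                 ec = ec, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- make_tx(1L, seq_along(block_seqs))
    if (!is.null(planted)) {
      planted$isoform_id <- sprintf("%s.1", gid)
      motifs[[length(motifs) + 1L]] <- planted
    }
    if (length(block_seqs) >= 3L &&
        stats::runif(1) < config$isoform_probability) {
      skip <- sample(seq.int(2L, length(block_seqs) - 1L), 1L)
      rows[[length(rows) + 1L]] <-
        make_tx(2L, setdiff(seq_along(block_seqs), skip))
      if (!is.null(planted)) {
        p2 <- planted; p2$isoform_id <- sprintf("%s.2", gid)
        motifs[[length(motifs) + 1L]] <- p2
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "planted_motifs") <-
    if (length(motifs)) do.call(rbind, motifs) else data.frame()
  class(out) <- c("transcriptome", "data.frame")
  out
}

#' Plant a motif instance into a transcript's coding sequence
#'
#' A peptide is sampled uniformly from the pattern's language,
#' back-translated with random synonymous codons, and spliced in-frame into
#' the CDS interior; the planted protein-coordinate offset is recorded.
#'
#' @param transcript one-row data.frame (or list) with `sequence`,
#'   `cds_start`, `cds_end`.
#' @param pattern a `motif_pattern` or pattern string.
#' @param seed integer seed.
#' @param motif_id identifier recorded for the plant.
#' @return the transcript with modified `sequence` and attribute
#'   `"planted"` = list(`motif_id`, `aa_offset`, `aa_len`, `instance`);
#'   `aa_offset` is the 1-based residue position within the CDS
#'   translation.
#' @export
plant_motif <- function(transcript, pattern, seed = 1L,
                        motif_id = "motif") {
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  set.seed(seed)
  seqs <- transcript$sequence
  cs <- transcript$cds_start; ce <- transcript$cds_end
  stopifnot(length(seqs) == 1L, !is.null(cs), !is.null(ce))
  inst <- sample_motif_instance(pattern)
  need <- nchar(inst)
  n_codons <- (ce - cs + 1L) %/% 3L
  if (n_codons < need + 3L)
    stop("transcript CDS too short (", n_codons, " codons) to host a ",
         need, "-residue motif instance")
  bt <- paste(vapply(strsplit(inst, "")[[1]], function(a)
    sample(.codons_for(a), 1L), ""), collapse = "")
  at <- sample(seq.int(2L, n_codons - need), 1L)  # codon index within CDS
  pos <- cs + (at - 1L) * 3L
  substr(seqs, pos, pos + need * 3L - 1L) <- bt
  transcript$sequence <- seqs
  attr(transcript, "planted") <- list(motif_id = motif_id, aa_offset = at,
                                      aa_len = need, instance = inst)
  transcript
}

#' Simulate paired-end reads from a transcriptome
#'
#' Fragments are drawn per transcript with probability proportional to
#' expression times length ("sampled" mode), or laid down at a regular
#' stride covering every base including the ends ("tiled" mode, for exact
#' reconstruction experiments).  Each pair records its true origin.
#' Per-base substitution errors and uncalled bases are injected at the
#' configured rates; adapter events shorten the fragment below the read
#' length so the read runs into the adapter sequence.
#'
#' @param transcripts a `transcriptome` (or data.frame with `isoform_id`,
#'   `sequence`, `expression`).
#' @param config a [sim_config()].
#' @param n_pairs total number of fragments ("sampled" mode).
#' @param coverage alternative to `n_pairs`: target mean fold-coverage.
#' @param mode "sampled" (multinomial by expression x length) or "tiled".
#' @return data.frame of class `read_pairs` with columns `pair_id`,
#'   `bases1`, `quals1`, `bases2`, `quals2`, `origin` (isoform id),
#'   `frag_start`, `frag_end`, `r1_forward`, `has_adapter`.
#' @export
simulate_reads <- function(transcripts, config, n_pairs = NULL,
                           coverage = NULL, mode = c("sampled", "tiled")) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (nrow(transcripts) == 0L) stop("transcripts must be non-empty")
  set.seed(config$seed + 1L)
  rl <- config$read_length
  tlen <- nchar(transcripts$sequence)
  if (any(tlen < rl))
    stop("all transcripts must be at least one read length long")
  ins_mean <- config$insert_size_mean
  if (mode == "sampled") {
    if (is.null(n_pairs)) {
      coverage <- coverage %||% 30
      n_pairs <- ceiling(sum(tlen) * coverage / (2 * rl))
    }
    w <- transcripts$expression * tlen
    origin <- sample(nrow(transcripts), n_pairs, replace = TRUE,
                     prob = w / sum(w))
    ins <- pmin(pmax(round(stats::rnorm(n_pairs, ins_mean,
                                        config$insert_size_sd)), rl),
                tlen[origin])
    fstart <- 1L + floor(stats::runif(n_pairs) * (tlen[origin] - ins + 1L))
  } else {
    coverage <- coverage %||% 30
    step <- max(1L, as.integer(ceiling(2 * rl / coverage)))
    per_tx <- lapply(seq_len(nrow(transcripts)), function(i) {
      ins_i <- min(ins_mean, tlen[i])
      st <- unique(c(seq.int(1L, tlen[i] - ins_i + 1L, by = step),
                     tlen[i] - ins_i + 1L))
      cbind(i, st, ins_i)
    })
    grid <- do.call(rbind, per_tx)
    origin <- grid[, 1]; fstart <- grid[, 2]; ins <- grid[, 3]
    n_pairs <- length(origin)
  }
  fend <- fstart + ins - 1L
  # adapter events: fragment shorter than the read, adapter fills the rest
  has_ad <- stats::runif(n_pairs) < config$adapter_rate
  if (any(has_ad)) {
    short <- pmax(2L * rl %/% 3L, 30L)
    ins[has_ad] <- pmin(short, tlen[origin[has_ad]])
    fend <- fstart + ins - 1L
  }
  frag <- substr(transcripts$sequence[origin], fstart, fend)
  r1 <- substr(frag, 1L, pmin(rl, ins))
  r2 <- revcomp(substr(frag, pmax(1L, ins - rl + 1L), ins))
  if (any(has_ad)) {
    pad <- function(r) {
      short_by <- rl - nchar(r)
      paste0(r, substr(strrep(config$adapter,
                              ceiling(rl / nchar(config$adapter))),
                       1L, short_by))
    }
    r1[has_ad] <- pad(r1[has_ad])
    r2[has_ad] <- pad(r2[has_ad])
  }
  inject <- function(reads, rate, alphabet_fun) {
    if (rate <= 0) return(reads)
    n_mut <- stats::rbinom(length(reads), nchar(reads), rate)
    idx <- which(n_mut > 0L)
    for (i in idx) {
      at <- sample(nchar(reads[i]), n_mut[i])
      for (p in at) {
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- alphabet_fun(cur)
      }
    }
    reads
  }
  sub_base <- function(cur) sample(setdiff(.DNA4, cur), 1L)
  r1 <- inject(r1, config$error_rate, sub_base)
  r2 <- inject(r2, config$error_rate, sub_base)
  r1 <- inject(r1, config$n_rate, function(cur) "N")
  r2 <- inject(r2, config$n_rate, function(cur) "N")
  # orientation: half the pairs have mate 1 on the reverse strand
  r1fwd <- stats::runif(n_pairs) < 0.5
  swap <- !r1fwd
  tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
  qual_strings <- function(n) {
    mu <- seq(config$quality_high, config$quality_low, length.out = rl)
    q <- matrix(round(stats::rnorm(n * rl, rep(mu, n), config$quality_sd)),
                nrow = n, byrow = TRUE)
    q <- pmin(pmax(q, 2L), 41L)
    allq <- intToUtf8(t(q) + 33L)
    substring(allq, seq.int(1L, by = rl, length.out = n),
              seq.int(rl, by = rl, length.out = n))
  }
  out <- data.frame(
    pair_id = sprintf("rp%06d", seq_len(n_pairs)),
    bases1 = r1, quals1 = qual_strings(n_pairs),
    bases2 = r2, quals2 = qual_strings(n_pairs),
    origin = transcripts$isoform_id[origin],
    frag_start = as.integer(fstart), frag_end = as.integer(fend),
    r1_forward = r1fwd, has_adapter = has_ad,
    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

# substitute a controlled fraction of positions in a sequence (alphabet
# depends on type); substitutions always change the character
.diverge <- function(seqs, identity, alphabet) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    nsub <- round((1 - identity) * n)
    if (nsub == 0L) return(s)
    at <- sample(n, nsub)
    for (p in at) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(alphabet, cur), 1L)
    }
    s
  }, "", USE.NAMES = FALSE)
}

#' Find the longest open reading frame
#'
#' Scans all six frames for the longest `ATG`-initiated run of sense codons
#' (ending at a stop codon or the frame end).
#'
#' @param nt nucleotide string.
#' @return list with `peptide` (no stop), `strand`, `frame`, `nt_start`,
#'   `nt_end` (1-based, on the given strand's coordinates), or `NULL` when
#'   no ORF exists.
#' @export
find_longest_orf <- function(nt) {
  best <- NULL
  frames <- translate_six_frames(nt)
  for (fr in names(frames)) {
    pep <- frames[[fr]]
    if (!nzchar(pep)) next
    m <- gregexpr("M[^*]*", pep)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    i <- which.max(len)
    if (is.null(best) || len[i] > nchar(best$peptide)) {
      off <- as.integer(substr(fr, 2, 2)) - 1L
      aa_start <- as.integer(m[i])
      best <- list(peptide = substr(pep, aa_start, aa_start + len[i] - 1L),
                   strand = substr(fr, 1, 1), frame = fr,
                   nt_start = off + (aa_start - 1L) * 3L + 1L,
                   nt_end = off + (aa_start - 1L + len[i]) * 3L)
    }
  }
  best
}

#' Build a protein database diverged from the true translations
#'
#' One protein per gene, taken from the longest-ORF translation of the
#' gene's longest isoform, with random substitutions bringing the identity
#' to `target_identity` (within rounding).  A stand-in for the reference
#' proteome of a related model species.
#'
#' @param transcripts a `transcriptome`.
#' @param target_identity fraction in [0.3, 1].
#' @param seed integer seed.
#' @param min_orf_aa genes whose longest ORF is shorter are skipped with a
#'   message.
#' @return named character vector of proteins (ids `P_<gene_id>`), with
#'   attribute `truth` (data.frame `protein_id`, `gene_id`, `identity`,
#'   `ec`) mapping entries back to source genes.
#' @export
build_protein_db <- function(transcripts, target_identity = 1.0, seed = 1L,
                             min_orf_aa = NULL) {
  stopifnot(target_identity >= 0.3, target_identity <= 1.0)
  cfg <- attr(transcripts, "config")
  min_orf_aa <- min_orf_aa %||% (if (!is.null(cfg)) cfg$min_orf_aa else 50L)
  set.seed(seed)
  if (nrow(transcripts) == 0L) {
    out <- character(0)
    attr(out, "truth") <- data.frame()
    return(out)
  }
  prot <- character(0)
  truth <- list()
  for (gid in unique(transcripts$gene_id)) {
    iso <- transcripts[transcripts$gene_id == gid, ]
    longest <- iso[which.max(nchar(iso$sequence)), ]
    orf <- find_longest_orf(longest$sequence)
    if (is.null(orf) || nchar(orf$peptide) < min_orf_aa) {
      message("gene ", gid, " skipped: no ORF of at least ",
              min_orf_aa, " residues")
      next
    }
    pep <- .diverge(orf$peptide, target_identity, .AA20)
    pid <- paste0("P_", gid)
    prot[pid] <- pep
    truth[[length(truth) + 1L]] <- data.frame(
      protein_id = pid, gene_id = gid,
      identity = 1 - round((1 - target_identity) * nchar(orf$peptide)) /
        nchar(orf$peptide),
      ec = longest$ec, stringsAsFactors = FALSE)
  }
  attr(prot, "truth") <-
    if (length(truth)) do.call(rbind, truth) else data.frame()
  prot
}

#' Build diverged nucleotide reference genes
#'
#' Nucleotide copies of selected transcripts mutated to a controlled
#' identity: a stand-in for orthologous genes of the closest related
#' species, as used in translated target-site scans.
#'
#' @param transcripts a `transcriptome`.
#' @param gene_ids genes to copy (default: all).
#' @param target_identity nucleotide identity of the copies.
#' @param seed integer seed.
#' @return named character vector (ids `ref_<gene_id>`).
#' @export
build_reference_genes <- function(transcripts, gene_ids = NULL,
                                  target_identity = 0.95, seed = 1L) {
  set.seed(seed)
  gene_ids <- gene_ids %||% unique(transcripts$gene_id)
  out <- character(0)
  for (gid in gene_ids) {
    iso <- transcripts[transcripts$gene_id == gid, ]
    longest <- iso[which.max(nchar(iso$sequence)), ]
    out[paste0("ref_", gid)] <-
      .diverge(longest$sequence, target_identity, .DNA4)
  }
  out
}

#' Write a simulated read set as a FASTQ pair
#'
#' @param pairs a `read_pairs` data.frame.
#' @param prefix output path prefix; writes `<prefix>_1.fq` and
#'   `<prefix>_2.fq` (Phred+33).
#' @return invisibly, the two paths.
#' @export
write_read_pairs <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_1.fq"); p2 <- paste0(prefix, "_2.fq")
  write_fastq(data.frame(read_id = paste0(pairs$pair_id, "/1"),
                         bases = pairs$bases1, quals = pairs$quals1), p1)
  write_fastq(data.frame(read_id = paste0(pairs$pair_id, "/2"),
                         bases = pairs$bases2, quals = pairs$quals2), p2)
  invisible(c(p1, p2))
}
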