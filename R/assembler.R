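# De Bruijn graph assembly: strand-agnostic k-mer graphs at odd k, unitig
# (contig) extraction, and isotig/isogroup generation by bounded path
# enumeration through the contig graph.
#
# Representation: the graph stores *oriented* k-mers -- every k-mer of the
# reads and of their reverse complements -- so each contig is discovered
# once per strand and deduplicated by its canonical form afterwards.  Odd k
# guarantees no k-mer equals its own reverse complement.  Edges are the
# observed (k+1)-mers, i.e. adjacencies actually supported by a read.

#' Build a de Bruijn graph from reads
#'
#' @param reads character vector of read sequences (A/C/G/T only; reads
#'   containing other letters are dropped with a warning), or a
#'   `read_pairs` data.frame (both mates used).
#' @param k odd k-mer length.
#' @param k_range allowed k interval (default 21..41, the usual sweep for
#'   short-read transcriptome assembly); override for toy graphs.
#' @return object of class `debruijn_graph`: `k`, `nodes` (data.table of
#'   oriented `kmer` and `count`; counts are canonical, i.e. identical for
#'   a k-mer and its reverse complement), `edges` (data.table `from`,
#'   `to`), `n_canonical`.
#' @export
build_graph <- function(reads, k, k_range = c(21L, 41L)) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("bases1", "bases2") %in% names(reads)) ||
              "bases" %in% names(reads))
    reads <- if ("bases" %in% names(reads)) reads$bases
             else c(reads$bases1, reads$bases2)
  }
  k <- as.integer(k)
  if (k %% 2L == 0L)
    stop("k must be odd (strand-agnostic canonical k-mers require it); got ",
         k)
  if (k < k_range[1] || k > k_range[2])
    stop("k = ", k, " outside the allowed range [", k_range[1], ", ",
         k_range[2], "]")
  clean <- grepl("^[ACGT]*$", reads)
  if (!all(clean)) {
    warning(sum(!clean), " reads with non-ACGT characters dropped")
    reads <- reads[clean]
  }
  reads <- reads[nchar(reads) >= k]
  if (length(reads) == 0L) {
    g <- list(k = k,
              nodes = data.table::data.table(kmer = character(0),
                                             count = integer(0)),
              edges = data.table::data.table(from = character(0),
                                             to = character(0)),
              n_canonical = 0L)
    class(g) <- "debruijn_graph"
    return(g)
  }
  doubled <- c(reads, revcomp(reads))
  nodes <- data.table::data.table(kmer = .kmers(doubled, k))
  nodes <- nodes[, list(count = .N), by = "kmer"]
  data.table::setkey(nodes, kmer)
  ek <- unique(.kmers(doubled, k + 1L))
  edges <- data.table::data.table(from = substr(ek, 1L, k),
                                  to = substr(ek, 2L, k + 1L))
  data.table::setkey(edges, from, to)
  g <- list(k = k, nodes = nodes, edges = edges,
            n_canonical = nrow(nodes) %/% 2L)
  class(g) <- "debruijn_graph"
  g
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat("<debruijn_graph> k =", x$k, "|", x$n_canonical, "canonical k-mers |",
      nrow(x$edges) %/% 2L, "canonical edges\n")
  invisible(x)
}

# internal: oriented unitigs of a (pruned) graph.
# Returns list(seq, cov, first, last) over oriented chains (each contig
# appears once per strand).
.oriented_unitigs <- function(nodes, edges, k) {
  N <- nrow(nodes)
  if (N == 0L)
    return(data.frame(seq = character(0), cov = numeric(0),
                      first = character(0), last = character(0)))
  fi <- match(edges$from, nodes$kmer)
  ti <- match(edges$to, nodes$kmer)
  keep <- !is.na(fi) & !is.na(ti)
  fi <- fi[keep]; ti <- ti[keep]
  od <- tabulate(fi, N)
  id <- tabulate(ti, N)
  uni <- od[fi] == 1L & id[ti] == 1L
  nxt <- rep(NA_integer_, N)
  nxt[fi[uni]] <- ti[uni]
  is_target <- logical(N)
  is_target[ti[uni]] <- TRUE
  ord <- integer(N); cid <- integer(N)
  pos <- 0L; ci <- 0L
  visited <- logical(N)
  for (s in which(!is_target)) {
    ci <- ci + 1L
    cur <- s
    while (!is.na(cur) && !visited[cur]) {
      pos <- pos + 1L; ord[pos] <- cur; cid[pos] <- ci
      visited[cur] <- TRUE
      cur <- nxt[cur]
    }
  }
  # leftover nodes belong to simple cycles; break each arbitrarily
  while (any(!visited)) {
    ci <- ci + 1L
    cur <- which(!visited)[1]
    while (!is.na(cur) && !visited[cur]) {
      pos <- pos + 1L; ord[pos] <- cur; cid[pos] <- ci
      visited[cur] <- TRUE
      cur <- nxt[cur]
    }
  }
  ord <- ord[seq_len(pos)]; cid <- cid[seq_len(pos)]
  kmv <- nodes$kmer[ord]
  cnt <- nodes$count[ord]
  dt <- data.table::data.table(cid = cid, km = kmv,
                               lc = substr(kmv, k, k), cnt = cnt)
  ut <- dt[, list(seq = paste0(km[1L], paste(lc[-1L], collapse = "")),
                  cov = mean(cnt), first = km[1L], last = km[.N]),
           by = "cid"]
  as.data.frame(ut[, c("seq", "cov", "first", "last")])
}

#' Extract contigs (unitigs) from a de Bruijn graph
#'
#' K-mers observed fewer than `min_count` times are pruned, then maximal
#' unbranched paths are rendered as contigs.  Each contig is reported once
#' (not together with its reverse complement), deterministically ordered.
#'
#' @param graph a `debruijn_graph`.
#' @param min_count minimum canonical k-mer count (default 1 = keep all).
#' @return data.frame with `contig_id`, `sequence`, `length`,
#'   `mean_kmer_coverage`, `origin_k`.
#' @export
extract_contigs <- function(graph, min_count = 1L) {
  stopifnot(inherits(graph, "debruijn_graph"))
  nodes <- graph$nodes[graph$nodes$count >= min_count, ]
  ut <- .oriented_unitigs(nodes, graph$edges, graph$k)
  if (nrow(ut) == 0L)
    return(data.frame(contig_id = character(0), sequence = character(0),
                      length = integer(0), mean_kmer_coverage = numeric(0),
                      origin_k = integer(0)))
  canon <- .canonical(ut$seq)
  ord <- order(canon)
  ut <- ut[ord, ]
  keep <- !duplicated(canon[ord])
  ut <- ut[keep, , drop = FALSE]
  data.frame(contig_id = sprintf("k%d_C%05d", graph$k, seq_len(nrow(ut))),
             sequence = ut$seq, length = nchar(ut$seq),
             mean_kmer_coverage = ut$cov, origin_k = graph$k,
             stringsAsFactors = FALSE)
}

# enumerate all source-to-sink paths in a small directed graph given as an
# adjacency list of integer vectors; stops after `cap` paths
.enumerate_paths <- function(adj, sources, cap) {
  paths <- list()
  truncated <- FALSE
  dfs <- function(path) {
    if (truncated) return()
    v <- path[length(path)]
    nxt <- setdiff(adj[[v]], path)  # no node revisits: acyclic walks only
    if (length(adj[[v]]) == 0L || length(nxt) == 0L) {
      if (length(paths) >= cap) { truncated <<- TRUE; return() }
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (w in nxt) dfs(c(path, w))
  }
  for (s in sources) dfs(s)
  list(paths = paths, truncated = truncated)
}

#' Generate isotigs and isogroups from contigs
#'
#' Contigs are linked by the graph's junction edges; each connected
#' component of the resulting contig graph is an isogroup (the putative
#' gene), and its distinct source-to-sink paths -- bounded by `max_paths`,
#' ranked by mean k-mer coverage -- are the isotigs (the putative splice
#' forms).  A two-branch bubble therefore yields two isotigs in one
#' isogroup.  Components that exceed the path cap emit the top-ranked
#' paths with a warning.
#'
#' @param graph a `debruijn_graph`.
#' @param contigs contig table from [extract_contigs()].
#' @param max_paths isotig cap per isogroup (default 16).
#' @return list with `isotigs` (data.frame `isotig_id`, `isogroup_id`,
#'   `sequence`, `length`, `mean_coverage`, `origin_k`) and `n_isogroups`.
#'   Isotig ids follow the `k{K}_Locus_{i}.{j}` style.
#' @export
build_isotigs <- function(graph, contigs, max_paths = 16L) {
  stopifnot(inherits(graph, "debruijn_graph"))
  k <- graph$k
  empty <- list(isotigs = data.frame(
    isotig_id = character(0), isogroup_id = character(0),
    sequence = character(0), length = integer(0),
    mean_coverage = numeric(0), origin_k = integer(0)), n_isogroups = 0L)
  if (nrow(contigs) == 0L) return(empty)
  nc <- nrow(contigs)
  # oriented contigs: forward = as reported, reverse = complement strand
  oseq <- c(contigs$sequence, revcomp(contigs$sequence))
  ocov <- rep(contigs$mean_kmer_coverage, 2L)
  obase <- rep(seq_len(nc), 2L)  # canonical contig index
  first <- substr(oseq, 1L, k)
  last <- substr(oseq, nchar(oseq) - k + 1L, nchar(oseq))
  # junction edges: graph edges that are not internal to a unitig
  nodes <- graph$nodes
  N <- nrow(nodes)
  fi <- match(graph$edges$from, nodes$kmer)
  ti <- match(graph$edges$to, nodes$kmer)
  od <- tabulate(fi, N); id <- tabulate(ti, N)
  junction <- !(od[fi] == 1L & id[ti] == 1L)
  jfrom <- graph$edges$from[junction]
  jto <- graph$edges$to[junction]
  # oriented contig adjacency via terminal k-mers
  by_first <- split(seq_along(oseq), first)
  by_last <- split(seq_along(oseq), last)
  adj <- vector("list", length(oseq))
  for (i in seq_along(adj)) adj[[i]] <- integer(0)
  if (length(jfrom)) {
    fidx <- by_last[jfrom]
    tidx <- by_first[jto]
    for (e in seq_along(jfrom)) {
      fs <- fidx[[e]]; ts <- tidx[[e]]
      if (is.null(fs) || is.null(ts)) next
      for (a in fs) adj[[a]] <- union(adj[[a]], ts)
    }
  }
  # isogroups: connected components over canonical contigs
  el <- do.call(rbind, lapply(seq_along(adj), function(a)
    if (length(adj[[a]])) cbind(obase[a], obase[adj[[a]]]) else NULL))
  gr <- igraph::graph_from_data_frame(
    d = if (is.null(el)) data.frame(from = integer(0), to = integer(0))
        else data.frame(from = el[, 1], to = el[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nc)))
  comp <- igraph::components(gr)$membership
  comp <- comp[as.character(seq_len(nc))]
  indeg <- integer(length(oseq))
  for (a in seq_along(adj)) indeg[adj[[a]]] <- indeg[adj[[a]]] + 1L
  out <- list()
  truncated_any <- FALSE
  comp_ids <- sort(unique(comp))
  for (ci in seq_along(comp_ids)) {
    members <- which(comp == comp_ids[ci])            # canonical indices
    omembers <- which(obase %in% members)             # oriented indices
    sources <- omembers[indeg[omembers] == 0L]
    res <- if (length(sources))
      .enumerate_paths(adj, sources, cap = 4L * max_paths)
    else list(paths = as.list(omembers), truncated = FALSE)  # cyclic
    truncated_any <- truncated_any || res$truncated
    seqs <- vapply(res$paths, function(p) {
      parts <- c(oseq[p[1]],
                 if (length(p) > 1L) substring(oseq[p[-1]], k))
      paste(parts, collapse = "")
    }, "")
    covs <- vapply(res$paths, function(p) {
      w <- nchar(oseq[p]) - k + 1L
      sum(ocov[p] * w) / sum(w)
    }, 0)
    keep <- !duplicated(.canonical(seqs))
    seqs <- seqs[keep]; covs <- covs[keep]
    ord <- order(-covs, seqs)
    seqs <- seqs[ord]; covs <- covs[ord]
    if (length(seqs) > max_paths) {
      truncated_any <- TRUE
      seqs <- seqs[seq_len(max_paths)]
      covs <- covs[seq_len(max_paths)]
    }
    out[[ci]] <- data.frame(
      isotig_id = sprintf("k%d_Locus_%d.%d", k, ci, seq_along(seqs)),
      isogroup_id = sprintf("k%d_Locus_%d", k, ci),
      sequence = seqs, length = nchar(seqs), mean_coverage = covs,
      origin_k = k, stringsAsFactors = FALSE)
  }
  if (truncated_any)
    warning("some isogroups exceeded the path cap (", max_paths,
            "); top-ranked paths reported")
  iso <- do.call(rbind, out)
  rownames(iso) <- NULL
  list(isotigs = iso, n_isogroups = length(comp_ids))
}

#' Assembly summary statistics
#'
#' The usual length accounting for an assembled sequence set: extremes,
#' totals, mean (integer floor), N50, and counts above standard length
#' cuts.  N50 is the largest length L such that sequences of length >= L
#' together contain at least half of all assembled bases.
#'
#' @param x character vector of sequences, or integer vector of lengths.
#' @return data.frame with columns `statistic`, `value`.
#' @export
assembly_stats <- function(x) {
  lens <- if (is.character(x)) nchar(x) else as.integer(x)
  if (length(lens) == 0L) {
    vals <- rep(0L, 12L)
  } else {
    s <- sort(lens, decreasing = TRUE)
    cum <- cumsum(as.numeric(s))
    n50 <- s[which(cum >= sum(as.numeric(s)) / 2)[1]]
    vals <- c(length(s), min(s), max(s),
              if (length(s) >= 2L) s[2] else s[1],
              if (length(s) >= 3L) s[3] else s[length(s)],
              sum(as.numeric(s)), floor(mean(s)), n50,
              sum(s > 0L), sum(s > 100L), sum(s > 500L), sum(s > 1000L))
  }
  data.frame(statistic = c("n_sequences", "min_length", "max_length",
                           "second_longest", "third_longest",
                           "total_length", "mean_length", "N50",
                           "n_gt_0", "n_gt_100", "n_gt_500", "n_gt_1000"),
             value = vals, stringsAsFactors = FALSE)
}
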