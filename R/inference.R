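#' Pairwise global sequence identity and coverage
#'
#' Aligns two sequences globally with match-maximising scoring (match +1,
#' mismatch 0, gaps free) and a deterministic diagonal-first traceback.
#' Identity is the fraction of identical positions among aligned columns
#' after trimming terminal overhangs; coverage is the fraction of the
#' shorter sequence's residues falling inside that trimmed span.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences.
#' @return Named numeric vector with `identity` and `coverage`, both in
#'   \[0, 1\].
#' @examples
#' pairwise_identity("PEPTIDE", "PEPTIDE")
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  st <- .nw_stats(seq_a, seq_b)
  identity <- if (st[2] > 0L) st[1] / st[2] else 0
  coverage <- st[3] / min(nchar(seq_a), nchar(seq_b))
  c(identity = identity, coverage = coverage)
}

# BLAST-like k-mer seeding: only sequence pairs sharing at least one exact
# k-mer can reach high identity over high coverage, so alignment is
# restricted to seeded pairs.
.candidate_pairs <- function(seqs, k = 8L, max_hits = 50L) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  kmer_lists <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  prot <- rep.int(seq_len(n), lengths(kmer_lists))
  by_kmer <- split(prot, unlist(kmer_lists, use.names = FALSE))
  pairs <- lapply(by_kmer, function(p) {
    if (length(p) < 2L || length(p) > max_hits) return(NULL)
    t(combn(sort(p), 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2L))
  unique(pairs)
}

#' Single-linkage clustering of a protein database by sequence identity
#'
#' Places an edge between two proteins when their pairwise identity is at
#' least `identity_min` over a coverage of at least `coverage_min`
#' (coverage relative to the shorter sequence), then takes connected
#' components as clusters — the single-linkage rule, so A and C fall in one
#' cluster whenever both resemble B even if they do not resemble each
#' other. Each cluster is labelled by its representative: the longest
#' member, ties broken by lexicographically smallest accession. The result
#' is invariant to the input order.
#'
#' @param proteins Target protein table (`id`, `sequence`, ...).
#' @param identity_min Minimum pairwise identity (default 0.95).
#' @param coverage_min Minimum coverage of the shorter sequence (default
#'   0.90).
#' @return data.frame with columns `id`, `cluster` (the representative's
#'   accession) and `representative` (logical).
#' @export
cluster_proteins <- function(proteins, identity_min = 0.95,
                             coverage_min = 0.90) {
  n <- nrow(proteins)
  if (n == 0L) stop("no proteins to cluster")
  ord <- order(proteins$id)
  prot <- proteins[ord, , drop = FALSE]

  cand <- .candidate_pairs(prot$sequence)
  edges <- matrix(integer(0), ncol = 2L)
  if (nrow(cand) > 0L) {
    pass <- vapply(seq_len(nrow(cand)), function(r) {
      pi <- pairwise_identity(prot$sequence[cand[r, 1L]],
                              prot$sequence[cand[r, 2L]])
      pi["identity"] >= identity_min && pi["coverage"] >= coverage_min
    }, logical(1))
    edges <- cand[pass, , drop = FALSE]
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership

  len <- nchar(prot$sequence)
  rep_of <- vapply(split(seq_len(n), memb), function(members) {
    m <- members[order(-len[members], prot$id[members])]
    prot$id[m[1L]]
  }, character(1))

  out <- data.frame(
    id = prot$id,
    cluster = unname(rep_of[as.character(memb)]),
    stringsAsFactors = FALSE
  )
  out$representative <- out$id == out$cluster
  out <- out[match(proteins$id, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.evidence_to_list <- function(evidence) {
  if (is.data.frame(evidence)) {
    ev <- .split_protein_ids(evidence$proteins)
    names(ev) <- evidence$peptide
  } else {
    ev <- evidence
  }
  ev <- ev[!duplicated(names(ev))]
  if (any(lengths(ev) == 0L))
    stop("peptide with empty protein set: data error")
  ev
}

#' Smallest minimally-redundant protein set explaining all peptides
#'
#' Solves the parsimony protein-inference problem: find the smallest set of
#' proteins such that every identified peptide maps to at least one
#' retained protein, admitting isoforms only when unique peptides require
#' them. Small instances (at most `exact_max` candidate proteins) are
#' solved exactly by subset enumeration in increasing cardinality; larger
#' instances use greedy set cover (most uncovered peptides first, ties
#' broken by cluster-representative status, then sequence length, then
#' accession) followed by an irredundancy sweep that removes any protein
#' whose peptides are all covered by the rest. Both routes return a cover
#' that is complete and irredundant.
#'
#' @param evidence Either a data.frame with columns `peptide` and
#'   `proteins` (semicolon-separated accessions) or a named list mapping
#'   peptide to a character vector of accessions.
#' @param clusters Optional cluster assignment from [cluster_proteins()];
#'   used to prefer cluster representatives among ties.
#' @param seq_lengths Optional named vector of sequence lengths used in
#'   tie-breaking.
#' @param method `"auto"` (exact when small, greedy otherwise), `"exact"`,
#'   or `"greedy"`.
#' @param exact_max Largest candidate-set size solved exactly under
#'   `method = "auto"`.
#' @return Sorted character vector of retained accessions, with the route
#'   taken in attribute `method`.
#' @export
minimal_protein_set <- function(evidence, clusters = NULL,
                                seq_lengths = NULL,
                                method = c("auto", "exact", "greedy"),
                                exact_max = 15L) {
  method <- match.arg(method)
  ev <- .evidence_to_list(evidence)
  if (length(ev) == 0L)
    return(structure(character(0), method = method))

  prots <- sort(unique(unlist(ev, use.names = FALSE)))
  n <- length(prots)
  P <- length(ev)
  M <- matrix(FALSE, nrow = P, ncol = n, dimnames = list(NULL, prots))
  for (i in seq_len(P)) M[i, ev[[i]]] <- TRUE

  is_rep <- rep(TRUE, n)
  if (!is.null(clusters)) {
    hit <- match(prots, clusters$id)
    is_rep <- ifelse(is.na(hit), TRUE, clusters$representative[hit])
  }
  lens <- rep(0, n)
  if (!is.null(seq_lengths)) {
    hit <- match(prots, names(seq_lengths))
    lens <- ifelse(is.na(hit), 0, seq_lengths[hit])
  }
  # preference order: representatives, longer sequences, accession
  pref <- order(!is_rep, -lens, prots)

  do_exact <- method == "exact" || (method == "auto" && n <= exact_max)
  if (do_exact) {
    Mp <- M[, pref, drop = FALSE]
    for (k in seq_len(n)) {
      combos <- combn(n, k)
      for (ci in seq_len(ncol(combos))) {
        S <- combos[, ci]
        if (all(.row_any(Mp, S))) {
          res <- sort(colnames(Mp)[S])
          return(structure(res, method = "exact"))
        }
      }
    }
  }

  # greedy cover
  uncovered <- rep(TRUE, P)
  chosen <- integer(0)
  while (any(uncovered)) {
    gain <- colSums(M[uncovered, , drop = FALSE])
    if (max(gain) == 0L) stop("peptide cannot be covered: data error")
    best <- which(gain == max(gain))
    best <- best[order(match(best, pref))][1L]
    chosen <- c(chosen, best)
    uncovered <- uncovered & !M[, best]
  }
  # irredundancy sweep, last chosen first
  for (p in rev(seq_along(chosen))) {
    rest <- chosen[-p]
    if (length(rest) > 0L &&
        all(.row_any(M, rest)))
      chosen <- rest
  }
  structure(sort(colnames(M)[chosen]), method = "greedy")
}

# any-covered indicator over a column subset
.row_any <- function(M, cols) {
  rowSums(M[, cols, drop = FALSE]) > 0L
}
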