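# Independent reference implementations used as oracles. These are written
# against the definitions, not against the package internals.

# Reference global-alignment identity/coverage via a plain R dynamic
# program: maximise matches (match +1, mismatch 0, free gaps), traceback
# preferring diagonal, then up, then left; trim terminal overhangs.
ref_pairwise_identity <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n))
    for (j in seq_len(m))
      S[i + 1L, j + 1L] <- max(S[i, j] + (A[i] == B[j]),
                               S[i, j + 1L], S[i + 1L, j])
  i <- n; j <- m
  colA <- logical(0); colB <- logical(0); colM <- logical(0)
  while (i > 0L || j > 0L) {
    cur <- S[i + 1L, j + 1L]
    if (i > 0L && j > 0L && S[i, j] + (A[i] == B[j]) == cur) {
      colA <- c(TRUE, colA); colB <- c(TRUE, colB)
      colM <- c(A[i] == B[j], colM)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i, j + 1L] == cur) {
      colA <- c(TRUE, colA); colB <- c(FALSE, colB); colM <- c(FALSE, colM)
      i <- i - 1L
    } else {
      colA <- c(FALSE, colA); colB <- c(TRUE, colB); colM <- c(FALSE, colM)
      j <- j - 1L
    }
  }
  ra <- range(which(colA)); rb <- range(which(colB))
  start <- max(ra[1L], rb[1L]); end <- min(ra[2L], rb[2L])
  if (end < start) return(c(identity = 0, coverage = 0))
  span <- start:end
  shorter <- if (n <= m) colA else colB
  c(identity = sum(colM[span]) / length(span),
    coverage = sum(shorter[span]) / min(n, m))
}

# Exhaustive minimum set-cover cardinality by enumerating all subsets in
# increasing size.
ref_min_cover_size <- function(ev) {
  prots <- sort(unique(unlist(ev, use.names = FALSE)))
  n <- length(prots)
  covers <- lapply(ev, function(p) match(p, prots))
  for (k in seq_len(n)) {
    combos <- combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      S <- combos[, ci]
      if (all(vapply(covers, function(cv) any(cv %in% S), logical(1))))
        return(k)
    }
  }
  n
}

# Straightforward filter-and-count FDR reference.
ref_fdr <- function(target, decoy, score_min = c(`1` = 13, `2` = 13, `3` = 16),
                    spi_min = 70) {
  pass <- function(df) {
    cut <- score_min[as.character(df$charge)]
    df[!is.na(cut) & df$score >= cut & df$spi >= spi_min, , drop = FALSE]
  }
  tp <- pass(target); dp <- pass(decoy)
  one <- function(ch) {
    t_n <- sum(tp$charge == ch); d_n <- sum(dp$charge == ch)
    if (t_n == 0L) NaN else d_n / t_n
  }
  list(fdr2 = one(2L), fdr3 = one(3L),
       total = if (nrow(tp) == 0L) NaN else nrow(dp) / nrow(tp),
       n_target = nrow(tp), n_decoy = nrow(dp))
}

# Quick PSM row constructor with sensible defaults.
make_psm <- function(peptide = "PEPTIDEK", proteins = "P1", charge = 2L,
                     score = 20, spi = 90, fraction = "soluble",
                     replicate = 1L, slice = 1L, is_decoy = FALSE,
                     is_noise = FALSE) {
  data.frame(peptide = peptide, proteins = proteins, charge = charge,
             score = score, spi = spi, fraction = fraction,
             replicate = replicate, slice = slice, is_decoy = is_decoy,
             is_noise = is_noise, stringsAsFactors = FALSE)
}

# Random PSM table independent of the package generator.
random_psm_table <- function(n, seed) {
  set.seed(seed)
  make_psm(
    peptide = paste0("PEP", sample.int(200, n, replace = TRUE), "K"),
    proteins = paste0("P", sample.int(40, n, replace = TRUE)),
    charge = sample(1:3, n, replace = TRUE),
    score = round(runif(n, 0, 30), 2),
    spi = round(runif(n, 0, 100), 1),
    fraction = sample(c("soluble", "membrane"), n, replace = TRUE),
    replicate = sample.int(4, n, replace = TRUE),
    slice = sample.int(8, n, replace = TRUE)
  )
}

# Random parsimony instance: n proteins, p peptides, each peptide mapped
# to 1-3 random proteins (every protein id may appear in several peptides).
random_evidence <- function(n_prot, n_pep, seed) {
  set.seed(seed)
  ids <- paste0("P", seq_len(n_prot))
  ev <- lapply(seq_len(n_pep), function(i)
    sample(ids, sample(1:3, 1L)))
  names(ev) <- paste0("pep", seq_len(n_pep))
  ev
}

random_aa_seq <- function(len) {
  paste(sample(c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}
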