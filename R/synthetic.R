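.AA20 <- names(.RESIDUE_MASS)

#' Configuration for the synthetic GeLC-MS/MS generator
#'
#' Bundles every tunable of the simulated experiment: a two-fraction
#' (soluble/membrane) design with replicate gel lanes cut into molecular
#' weight slices, a proteome containing isoform clusters, and
#' peptide-spectrum matches (PSMs) whose counts follow a multinomial
#' sampling model with abundance- and length-proportional expectations.
#'
#' @param n_proteins Number of target proteins in the database.
#' @param n_isoform_clusters Number of isoform clusters the proteome is
#'   partitioned into; clusters with more than one member share >95%
#'   sequence identity so that similarity clustering is exercised. Must not
#'   exceed `n_proteins`.
#' @param mean_seq_len Mean protein length in residues.
#' @param fractions Labels of the two subcellular fractions.
#' @param n_replicates Number of replicate gel lanes per fraction.
#' @param n_slices Number of gel slices (molecular-weight bands) per lane.
#' @param depth Expected number of signal PSMs per replicate-fraction run.
#' @param decoy_ratio Expected fraction of random matches injected, applied
#'   both to decoy-database hits and to spurious target-database hits so
#'   that the decoy count estimates the false-match count.
#' @param charge_probs Probabilities of precursor charge states +1, +2, +3.
#' @param dynamic_range Ratio between the largest and smallest molar
#'   abundance; abundances are drawn log-uniformly over this span.
#' @param score_target_mean,score_target_sd Mean and SD of the identification
#'   score for correct matches (charge +3 shifted by `charge3_shift`).
#' @param score_null_mean,score_null_sd Mean and SD of the score for random
#'   matches (decoy and spurious target hits).
#' @param charge3_shift Additive score shift for +3 precursors.
#' @param spi_target_min Lower bound of the uniform %SPI distribution for
#'   correct matches (random matches draw %SPI uniformly on \[0, 100\]).
#' @param seed Integer RNG seed; the seed fully determines all outputs.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200L,
                             n_isoform_clusters = 170L,
                             mean_seq_len = 400L,
                             fractions = c("soluble", "membrane"),
                             n_replicates = 4L,
                             n_slices = 8L,
                             depth = 10000,
                             decoy_ratio = 0.1,
                             charge_probs = c(`1` = 0.1, `2` = 0.6, `3` = 0.3),
                             dynamic_range = 1e5,
                             score_target_mean = 20, score_target_sd = 4,
                             score_null_mean = 8, score_null_sd = 2,
                             charge3_shift = 2,
                             spi_target_min = 55,
                             seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_isoform_clusters = as.integer(n_isoform_clusters),
    mean_seq_len = as.numeric(mean_seq_len),
    fractions = as.character(fractions),
    n_replicates = as.integer(n_replicates),
    n_slices = as.integer(n_slices),
    depth = as.numeric(depth),
    decoy_ratio = as.numeric(decoy_ratio),
    charge_probs = charge_probs,
    dynamic_range = as.numeric(dynamic_range),
    score_target_mean = score_target_mean, score_target_sd = score_target_sd,
    score_null_mean = score_null_mean, score_null_sd = score_null_sd,
    charge3_shift = charge3_shift,
    spi_target_min = spi_target_min,
    seed = as.integer(seed)
  )
  if (cfg$n_proteins < 1L) stop("n_proteins must be >= 1")
  if (cfg$n_isoform_clusters < 1L || cfg$n_isoform_clusters > cfg$n_proteins)
    stop("n_isoform_clusters must be between 1 and n_proteins")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (cfg$n_slices < 1L) stop("n_slices must be >= 1")
  if (cfg$depth < 0) stop("depth must be non-negative")
  if (cfg$decoy_ratio < 0 || cfg$decoy_ratio >= 1)
    stop("decoy_ratio must be in [0, 1)")
  if (length(cfg$charge_probs) != 3L ||
      abs(sum(cfg$charge_probs) - 1) > 1e-8 || any(cfg$charge_probs < 0))
    stop("charge_probs must be 3 non-negative values summing to 1")
  if (length(cfg$fractions) != 2L) stop("exactly two fraction labels required")
  class(cfg) <- "synthetic_config"
  cfg
}

#' In-silico tryptic digest
#'
#' Cleaves a protein sequence after every lysine (K) or arginine (R) that is
#' not followed by proline (P), the conventional trypsin specificity. The
#' concatenation of the returned peptides always reproduces the input.
#'
#' @param sequence A single amino-acid sequence.
#' @return Character vector of peptides in N- to C-terminal order.
#' @examples
#' tryptic_digest("AAKBBRCC")
#' @export
tryptic_digest <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  substring(sequence, starts, ends)
}

# Peptides in the standard observability window for LC-MS/MS.
.detectable_peptides <- function(sequence, min_len = 7L, max_len = 30L) {
  p <- tryptic_digest(sequence)
  p[nchar(p) >= min_len & nchar(p) <= max_len]
}

#' Build a decoy database by twice shuffling each target sequence
#'
#' Each decoy is produced by two successive uniform permutations of the
#' residues of one target sequence, so length and residue composition (and
#' therefore molecular weight) are preserved exactly. Decoy accessions are
#' prefixed `DECOY_`.
#'
#' @param proteins Protein table as returned by [generate_proteome()] (or
#'   [read_fasta()]): columns `id`, `symbol`, `sequence`, `mw`, `category`,
#'   `is_decoy`.
#' @param seed Integer RNG seed.
#' @return A protein table of the same shape with `is_decoy = TRUE`.
#' @export
shuffle_decoy <- function(proteins, seed = 1L) {
  if (nrow(proteins) == 0L) stop("target protein table is empty")
  set.seed(seed)
  shuffled <- vapply(proteins$sequence, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    aa <- aa[sample.int(length(aa))]
    aa <- aa[sample.int(length(aa))]
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out <- proteins
  out$id <- paste0("DECOY_", proteins$id)
  out$symbol <- paste0("DECOY_", proteins$symbol)
  out$sequence <- shuffled
  out$is_decoy <- TRUE
  rownames(out) <- NULL
  out
}

#' Generate a synthetic proteome with ground truth
#'
#' Draws a protein database partitioned into isoform clusters (members of a
#' multi-member cluster differ by 0.5-2% point substitutions, keeping
#' pairwise identity above 95% over the full length) together with the
#' ground truth the peptide-spectrum match generator consumes: log-uniform
#' molar abundances spanning `dynamic_range`, a soluble-fraction propensity
#' `theta_soluble` per protein, and organelle marker labels. The most
#' abundant protein is tagged as the granule matrix marker (the chromogranin
#' A analogue used by the purity module) and three low-abundance proteins as
#' mitochondrial, lysosomal, and endoplasmic-reticulum contaminant markers.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `proteins` (data.frame: `id`, `symbol`,
#'   `sequence`, `mw`, `category`, `is_decoy`) and `truth` (data.frame:
#'   `id`, `molar_abundance`, `theta_soluble`, `cluster`, `marker`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  k <- config$n_isoform_clusters

  sizes <- rep(1L, k)
  extra <- n - k
  if (extra > 0L)
    sizes <- sizes + tabulate(sample.int(k, extra, replace = TRUE), nbins = k)

  seqs <- character(n)
  cluster <- integer(n)
  idx <- 1L
  for (cl in seq_len(k)) {
    len <- max(50L, round(rnorm(1, config$mean_seq_len, config$mean_seq_len / 5)))
    base <- sample(.AA20, len, replace = TRUE)
    for (m in seq_len(sizes[cl])) {
      s <- base
      if (m > 1L) {
        rate <- runif(1, 0.005, 0.02)
        npos <- max(1L, rbinom(1, len, rate))
        pos <- sample.int(len, npos)
        for (p in pos) s[p] <- sample(.AA20[.AA20 != s[p]], 1L)
      }
      seqs[idx] <- paste(s, collapse = "")
      cluster[idx] <- cl
      idx <- idx + 1L
    }
  }

  categories <- c(
    "Neurotransmitters and Neurohumoural Factors",
    "Biochemical Processes",
    "Internal Conditions of Secretory Vesicles",
    "Regulated Secretion Mechanisms",
    "Morphological Functions",
    "Miscellaneous"
  )
  # cluster members share a functional category
  cat_by_cluster <- sample(categories, k, replace = TRUE,
                           prob = c(0.2, 0.17, 0.23, 0.2, 0.1, 0.1))

  proteins <- data.frame(
    id = sprintf("SYN%04d", seq_len(n)),
    symbol = sprintf("G%04d", seq_len(n)),
    sequence = seqs,
    mw = protein_mw(seqs),
    category = cat_by_cluster[cluster],
    is_decoy = FALSE,
    stringsAsFactors = FALSE
  )

  abundance <- 10^runif(n, 0, log10(config$dynamic_range))
  theta <- rbeta(n, 0.6, 0.6)
  # markers are drawn from singleton clusters: organelle markers are
  # unrelated sequences and must not share peptides with isoform clusters
  marker <- rep(NA_character_, n)
  singleton <- which(cluster %in% which(sizes == 1L))
  if (length(singleton) >= 1L) {
    anchor <- singleton[which.max(abundance[singleton])]
    marker[anchor] <- "secretory_granule"
    low <- setdiff(
      singleton[abundance[singleton] <= quantile(abundance, 0.25)], anchor)
    if (length(low) >= 1L) {
      contam <- sample(low, min(3L, length(low)))
      marker[contam] <- c("mitochondrion", "lysosome",
                          "endoplasmic_reticulum")[seq_along(contam)]
    }
  }

  truth <- data.frame(
    id = proteins$id,
    molar_abundance = abundance,
    theta_soluble = theta,
    cluster = cluster,
    marker = marker,
    stringsAsFactors = FALSE
  )
  list(proteins = proteins, truth = truth)
}

# Map each unique peptide to the ";"-joined ids of all proteins containing it.
.peptide_protein_map <- function(peptide_lists, ids) {
  pep <- unlist(peptide_lists, use.names = FALSE)
  prot <- rep(ids, lengths(peptide_lists))
  keep <- !duplicated(paste(pep, prot, sep = "\r"))
  pep <- pep[keep]; prot <- prot[keep]
  tapply(prot, pep, function(x) paste(sort(x), collapse = ";"))
}

.draw_scores <- function(n, charge, mean0, sd0, shift3) {
  mu <- mean0 + ifelse(charge == 3L, shift3, 0)
  pmax(0, rnorm(n, mu, sd0))
}

#' Simulate a peptide-spectrum match table
#'
#' For every replicate-fraction run, per-protein PSM counts are drawn as
#' independent Poissons with expectation proportional to molar abundance
#' times the number of detectable tryptic peptides (7-30 residues), split
#' between the soluble and membrane fractions by `theta_soluble`; this is a
#' multinomial count model conditional on the run total. A per-protein,
#' per-run dropout with probability `exp(-expected count)` emulates
#' stochastic missingness across replicate lanes. PSMs are assigned to gel
#' slices by the molecular-weight band of their protein with 10% spill-over
#' to adjacent bands. Random matches are injected at rate `decoy_ratio`
#' both against the decoy database (`is_decoy`) and against the target
#' database (`is_noise`, the ground-truth label used to validate FDR
#' estimates); both draw scores from the null distribution. Each PSM
#' carries its generating peptide and all database proteins containing it.
#'
#' @param proteins Combined target (+ optionally decoy) protein table.
#' @param truth Ground-truth table from [generate_proteome()].
#' @param config A [synthetic_config()].
#' @param seed RNG seed for the PSM draws; defaults to `config$seed + 1` so
#'   proteome and PSM randomness are separate but both determined by the
#'   configuration seed.
#' @return A PSM data.frame: `peptide`, `proteins` (semicolon-separated
#'   ids), `charge`, `score`, `spi`, `fraction`, `replicate`, `slice`,
#'   `is_decoy`, `is_noise`.
#' @export
generate_psms <- function(proteins, truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)

  targets <- proteins[!proteins$is_decoy, , drop = FALSE]
  decoys <- proteins[proteins$is_decoy, , drop = FALSE]
  stopifnot(all(truth$id == targets$id))

  empty <- data.frame(
    peptide = character(), proteins = character(), charge = integer(),
    score = numeric(), spi = numeric(), fraction = character(),
    replicate = integer(), slice = integer(), is_decoy = logical(),
    is_noise = logical(), stringsAsFactors = FALSE
  )
  if (config$depth == 0) return(empty)

  t_peps <- lapply(targets$sequence, .detectable_peptides)
  t_map <- .peptide_protein_map(t_peps, targets$id)
  npep <- lengths(t_peps)
  t_pool <- names(t_map)

  d_pool <- character(0)
  d_map <- NULL
  if (nrow(decoys) > 0L) {
    d_peps <- lapply(decoys$sequence, .detectable_peptides)
    d_map <- .peptide_protein_map(d_peps, decoys$id)
    d_pool <- names(d_map)
  }

  # flat peptide store for O(1) per-PSM peptide lookup
  all_pep <- unlist(t_peps, use.names = FALSE)
  offset <- c(0L, cumsum(npep))

  w <- truth$molar_abundance * npep
  share <- if (sum(w) > 0) w / sum(w) else rep(0, length(w))

  bands <- .mw_bands(targets$mw, config$n_slices)

  charges <- c(1L, 2L, 3L)
  out <- vector("list", 2L * config$n_replicates * 3L)
  oi <- 1L
  for (f in seq_along(config$fractions)) {
    frac <- config$fractions[f]
    th <- if (f == 1L) truth$theta_soluble else 1 - truth$theta_soluble
    for (r in seq_len(config$n_replicates)) {
      lambda <- 2 * config$depth * share * th
      dropout <- rbinom(length(lambda), 1L, exp(-lambda)) == 1L
      cnt <- rpois(length(lambda), lambda)
      cnt[dropout] <- 0L

      pidx <- rep.int(seq_along(cnt), cnt)
      n_true <- length(pidx)
      if (n_true > 0L) {
        u <- ceiling(runif(n_true) * npep[pidx])
        pep <- all_pep[offset[pidx] + u]
        chg <- sample(charges, n_true, replace = TRUE, prob = config$charge_probs)
        slice <- bands[pidx] + sample(c(-1L, 0L, 1L), n_true, replace = TRUE,
                                      prob = c(0.05, 0.9, 0.05))
        slice <- pmin(pmax(slice, 1L), config$n_slices)
        out[[oi]] <- data.frame(
          peptide = pep,
          proteins = unname(t_map[pep]),
          charge = chg,
          score = .draw_scores(n_true, chg, config$score_target_mean,
                               config$score_target_sd, config$charge3_shift),
          spi = runif(n_true, config$spi_target_min, 100),
          fraction = frac, replicate = r, slice = slice,
          is_decoy = FALSE, is_noise = FALSE,
          stringsAsFactors = FALSE
        )
        oi <- oi + 1L
      }

      n_noise <- rpois(1L, config$depth * config$decoy_ratio)
      if (n_noise > 0L && length(t_pool) > 0L) {
        pep <- t_pool[ceiling(runif(n_noise) * length(t_pool))]
        chg <- sample(charges, n_noise, replace = TRUE, prob = config$charge_probs)
        out[[oi]] <- data.frame(
          peptide = pep, proteins = unname(t_map[pep]), charge = chg,
          score = .draw_scores(n_noise, chg, config$score_null_mean,
                               config$score_null_sd, config$charge3_shift),
          spi = runif(n_noise, 0, 100),
          fraction = frac, replicate = r,
          slice = sample.int(config$n_slices, n_noise, replace = TRUE),
          is_decoy = FALSE, is_noise = TRUE,
          stringsAsFactors = FALSE
        )
        oi <- oi + 1L
      }

      n_dec <- rpois(1L, config$depth * config$decoy_ratio)
      if (n_dec > 0L && length(d_pool) > 0L) {
        pep <- d_pool[ceiling(runif(n_dec) * length(d_pool))]
        chg <- sample(charges, n_dec, replace = TRUE, prob = config$charge_probs)
        out[[oi]] <- data.frame(
          peptide = pep, proteins = unname(d_map[pep]), charge = chg,
          score = .draw_scores(n_dec, chg, config$score_null_mean,
                               config$score_null_sd, config$charge3_shift),
          spi = runif(n_dec, 0, 100),
          fraction = frac, replicate = r,
          slice = sample.int(config$n_slices, n_dec, replace = TRUE),
          is_decoy = TRUE, is_noise = TRUE,
          stringsAsFactors = FALSE
        )
        oi <- oi + 1L
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster-level ground truth for recovery comparisons
#'
#' After parsimony inference an isoform cluster is usually represented by a
#' single retained protein whose spectral counts pool the whole cluster,
#' so the quantity that protein estimates is the cluster aggregate, not
#' the member-level truth. This helper returns, for every protein, the
#' summed molar abundance of its planted cluster and the
#' abundance-weighted mean soluble propensity, the correct ground truth to
#' compare a retained representative against.
#'
#' @param truth Truth table from [generate_proteome()].
#' @return data.frame: `id`, `cluster`, `cluster_abundance`,
#'   `cluster_theta_soluble`.
#' @export
cluster_truth <- function(truth) {
  ab <- tapply(truth$molar_abundance, truth$cluster, sum)
  wth <- tapply(truth$molar_abundance * truth$theta_soluble,
                truth$cluster, sum) / ab
  cl <- as.character(truth$cluster)
  data.frame(
    id = truth$id,
    cluster = truth$cluster,
    cluster_abundance = unname(ab[cl]),
    cluster_theta_soluble = unname(wth[cl]),
    stringsAsFactors = FALSE
  )
}

# Equal-probability molecular-weight bands; band 1 = highest MW (top of gel).
.mw_bands <- function(mw, n_slices) {
  if (length(mw) == 1L) return(rep(1L, 1L))
  edges <- quantile(mw, probs = seq(0, 1, length.out = n_slices + 1L),
                    names = FALSE, type = 7)
  band <- findInterval(mw, edges, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(n_slices + 1L - band)
}
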