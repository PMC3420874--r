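#' Spectral-count matrix from filtered PSMs
#'
#' Tallies accepted (and rescued) PSMs into a protein-by-sample matrix of
#' spectral counts (SpC), where a sample is one fraction-replicate run and
#' counts are summed over gel slices. A PSM whose peptide maps to several
#' retained proteins contributes one count to each (shared counts are not
#' distributed); after parsimony inference such peptides are rare. PSMs
#' whose peptide maps to no retained protein are dropped with a message.
#'
#' @param psms Accepted target PSM table. The pipeline passes only PSMs
#'   meeting the strict per-charge thresholds (`accepted` from
#'   [apply_thresholds()]); rescued PSMs support identification but are
#'   not counted toward abundance.
#' @param retained Character vector of retained protein accessions.
#' @param fractions Fraction labels defining the design (columns are laid
#'   out fraction by fraction even when a run has no PSMs).
#' @param n_replicates Number of replicate runs per fraction.
#' @return Integer matrix, rows = retained proteins, columns named
#'   `"<fraction>:<replicate>"`.
#' @export
count_matrix <- function(psms, retained,
                         fractions = c("soluble", "membrane"),
                         n_replicates = 4L) {
  samples <- as.vector(outer(fractions, seq_len(n_replicates),
                             function(f, r) paste(f, r, sep = ":")))
  M <- matrix(0L, nrow = length(retained), ncol = length(samples),
              dimnames = list(retained, samples))
  if (nrow(psms) == 0L) return(M)

  ids <- .split_protein_ids(psms$proteins)
  kept <- lapply(ids, function(p) p[p %in% retained])
  n_dropped <- sum(lengths(kept) == 0L)
  if (n_dropped > 0L)
    message(n_dropped, " PSM(s) matched no retained protein and were dropped")
  n_shared <- sum(lengths(kept) > 1L)
  if (n_shared > 0L)
    message(n_shared, " PSM(s) map to multiple retained proteins; ",
            "counted once per protein")

  prot <- unlist(kept, use.names = FALSE)
  samp <- rep(paste(psms$fraction, psms$replicate, sep = ":"), lengths(kept))
  ok <- samp %in% samples
  if (any(!ok)) {
    prot <- prot[ok]; samp <- samp[ok]
  }
  if (length(prot) > 0L) {
    tab <- table(factor(prot, levels = retained),
                 factor(samp, levels = samples))
    M[] <- as.integer(tab)
  }
  M
}

#' Normalized spectral abundance factors
#'
#' For each sample (column) independently, NSAF of protein K is
#' `(SpC/MW)_K` divided by the sum of `SpC/MW` over all proteins observed
#' in that sample, so the column sums to one: the spectral count is
#' corrected for protein size and normalized for run depth. Samples with
#' no counts at all yield a column of `NA` with a warning.
#'
#' @param counts Spectral-count matrix from [count_matrix()] (any
#'   protein-by-sample non-negative matrix works).
#' @param mw Named numeric vector of molecular weights (Daltons) covering
#'   all proteins with non-zero counts.
#' @return Numeric matrix of NSAF values, same shape as `counts`;
#'   unobserved proteins get 0 in observed samples.
#' @export
nsaf <- function(counts, mw) {
  mwv <- mw[rownames(counts)]
  if (anyNA(mwv)) stop("molecular weight missing for some proteins")
  if (any(mwv <= 0)) stop("molecular weights must be positive")
  saf <- counts / mwv
  tot <- colSums(saf)
  empty <- tot == 0
  if (any(empty)) {
    warning("sample(s) with no spectral counts: ",
            paste(colnames(counts)[empty], collapse = ", "))
    tot[empty] <- NA_real_
  }
  sweep(saf, 2L, tot, `/`)
}

#' Replicate summary with the minimum-observation rule
#'
#' A protein is quantitated in a fraction when it is observed (NSAF > 0)
#' in at least `min_obs` of the `n_replicates` replicate runs. The mean is
#' taken over the observed values; the standard deviation is taken over
#' all `n_replicates` values with a zero filled in for every missed
#' observation, so a missed run widens the SD instead of being ignored.
#'
#' @param values Protein-by-replicate NSAF matrix for one fraction (or for
#'   pooled totals); `NA` entries count as missed observations.
#' @param min_obs Minimum number of observations required (default 3).
#' @param n_replicates Number of replicates in the design.
#' @return data.frame: `id`, `n_obs`, `mean_nsaf`, `sd_nsaf`,
#'   `quantitated`.
#' @export
summarize_replicates <- function(values, min_obs = 3L, n_replicates = 4L) {
  stopifnot(ncol(values) == n_replicates)
  v <- values
  v[is.na(v)] <- 0
  n_obs <- rowSums(v > 0)
  mean_nsaf <- ifelse(n_obs > 0, rowSums(v) / n_obs, 0)
  sd_nsaf <- apply(v, 1L, sd)
  data.frame(
    id = rownames(values),
    n_obs = as.integer(n_obs),
    mean_nsaf = mean_nsaf,
    sd_nsaf = sd_nsaf,
    quantitated = n_obs >= min_obs,
    stringsAsFactors = FALSE
  )
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z-statistic and the Anscombe-Glynn
#' kurtosis z-statistic into the omnibus K-squared statistic, referred to
#' a chi-squared distribution with 2 degrees of freedom. Requires at least
#' 8 observations; constant input is reported as degenerate (`NA`
#' statistic) rather than an error.
#'
#' @param x Numeric vector.
#' @return List of class `htest` with `statistic` (K-squared), `p.value`,
#'   and the component z-scores in `estimate`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  out <- list(method = "D'Agostino-Pearson omnibus normality test",
              data.name = deparse(substitute(x)))
  class(out) <- "htest"
  if (n < 8L) {
    out$statistic <- c(K2 = NA_real_)
    out$p.value <- NA_real_
    out$estimate <- c(z_skew = NA_real_, z_kurt = NA_real_)
    return(out)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {  # constant data: degenerate, no crash
    out$statistic <- c(K2 = NA_real_)
    out$p.value <- NA_real_
    out$estimate <- c(z_skew = NA_real_, z_kurt = NA_real_)
    return(out)
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis transform (Anscombe-Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- z1^2 + z2^2
  out$statistic <- c(K2 = K2)
  out$p.value <- pchisq(K2, df = 2, lower.tail = FALSE)
  out$estimate <- c(z_skew = z1, z_kurt = z2)
  out$parameter <- c(df = 2)
  out
}

#' Natural-log scale distribution statistics
#'
#' Transforms the soluble, membrane, and total NSAF value sets to the
#' natural log scale (non-measurements, i.e. zeros and `NA`s, are excluded
#' before testing), checks Gaussian normality of each set with both the
#' D'Agostino-Pearson omnibus and Shapiro-Wilk tests, and compares
#' ln-soluble against ln-membrane with a two-sample two-tailed Student's
#' t-test (classical equal-variance test by default; Welch via
#' `welch = TRUE`).
#'
#' @param soluble,membrane,total Numeric vectors of NSAF values.
#' @param welch Use the Welch unequal-variance t-test instead.
#' @return List with `ln_values` (the three transformed vectors),
#'   `normality` (data.frame: set, n, K2, K2 p, Shapiro W, Shapiro p,
#'   degenerate flag), and `t_test` (an `htest`, or `NULL` when a set has
#'   fewer than 2 values).
#' @export
ln_stats <- function(soluble, membrane, total, welch = FALSE) {
  tr <- function(x) log(x[!is.na(x) & x > 0])
  ln <- list(soluble = tr(soluble), membrane = tr(membrane),
             total = tr(total))
  norm_row <- function(set, x) {
    degen <- length(x) >= 2 && sd(x) == 0
    k2 <- if (length(x) >= 3 && !degen) dagostino_pearson(x) else NULL
    sw <- if (length(x) >= 3 && length(x) <= 5000 && !degen)
      shapiro.test(x) else NULL
    data.frame(
      set = set, n = length(x),
      k2 = if (!is.null(k2)) unname(k2$statistic) else NA_real_,
      k2_p = if (!is.null(k2)) k2$p.value else NA_real_,
      shapiro_w = if (!is.null(sw)) unname(sw$statistic) else NA_real_,
      shapiro_p = if (!is.null(sw)) sw$p.value else NA_real_,
      degenerate = degen,
      stringsAsFactors = FALSE
    )
  }
  normality <- rbind(norm_row("soluble", ln$soluble),
                     norm_row("membrane", ln$membrane),
                     norm_row("total", ln$total))
  tt <- NULL
  if (length(ln$soluble) >= 2 && length(ln$membrane) >= 2 &&
      (sd(ln$soluble) > 0 || sd(ln$membrane) > 0))
    tt <- t.test(ln$soluble, ln$membrane, var.equal = !welch,
                 alternative = "two.sided")
  list(ln_values = ln, normality = normality, t_test = tt)
}

#' Soluble/membrane differential NSAF and distribution class
#'
#' Computes `Diff-NSAF = (soluble - membrane) * 1000` from the per-fraction
#' mean NSAFs and assigns the distribution class used for network
#' colouring: green (predominantly soluble, positive Diff-NSAF), red
#' (predominantly membrane, negative), yellow (equally distributed, i.e.
#' relative difference `|S - M| / (S + M)` below `epsilon`), or grey for
#' proteins quantitated in neither fraction. A fraction in which the
#' protein is not quantitated contributes 0.
#'
#' @param mean_soluble,mean_membrane Mean NSAF per fraction.
#' @param quant_soluble,quant_membrane Logical quantitation flags per
#'   fraction.
#' @param epsilon Relative-difference band treated as "equal" (default
#'   0.2).
#' @return data.frame: `diff_nsaf_scaled`, `dist_class` (factor with
#'   levels green, red, yellow, grey).
#' @export
diff_nsaf <- function(mean_soluble, mean_membrane,
                      quant_soluble, quant_membrane, epsilon = 0.2) {
  s <- ifelse(quant_soluble, mean_soluble, 0)
  m <- ifelse(quant_membrane, mean_membrane, 0)
  d <- (s - m) * 1e3
  cls <- rep("grey", length(d))
  quantitated <- quant_soluble | quant_membrane
  tot <- s + m
  rel <- ifelse(tot > 0, abs(s - m) / tot, 0)
  cls[quantitated & rel < epsilon] <- "yellow"
  cls[quantitated & rel >= epsilon & d > 0] <- "green"
  cls[quantitated & rel >= epsilon & d < 0] <- "red"
  # both fractions zero but formally quantitated: equally distributed
  data.frame(
    diff_nsaf_scaled = ifelse(quantitated, d, NA_real_),
    dist_class = factor(cls, levels = c("green", "red", "yellow", "grey")),
    stringsAsFactors = FALSE
  )
}

#' Full per-protein quantitation table
#'
#' Convenience wrapper chaining [nsaf()], [summarize_replicates()] per
#' fraction, total NSAF on pooled soluble+membrane counts per replicate
#' index, and [diff_nsaf()] into one record per protein.
#'
#' @param counts Spectral-count matrix from [count_matrix()].
#' @param mw Named molecular-weight vector.
#' @param fractions The two fraction labels, soluble first.
#' @param n_replicates Replicates per fraction.
#' @param min_obs Minimum observations for quantitation.
#' @param epsilon Yellow-band width for [diff_nsaf()].
#' @return List of class `quant_table`: `quant` (one row per protein),
#'   `nsaf` (per-sample NSAF matrix), `nsaf_total` (per-replicate pooled
#'   NSAF matrix).
#' @export
quantify_proteins <- function(counts, mw,
                              fractions = c("soluble", "membrane"),
                              n_replicates = 4L, min_obs = 3L,
                              epsilon = 0.2) {
  nz <- nsaf(counts, mw)
  frac_of <- sub(":.*$", "", colnames(counts))
  sol <- nz[, frac_of == fractions[1L], drop = FALSE]
  mem <- nz[, frac_of == fractions[2L], drop = FALSE]

  pooled <- counts[, frac_of == fractions[1L], drop = FALSE] +
    counts[, frac_of == fractions[2L], drop = FALSE]
  colnames(pooled) <- paste0("total:", seq_len(n_replicates))
  nz_tot <- nsaf(pooled, mw)

  s_sum <- summarize_replicates(sol, min_obs, n_replicates)
  m_sum <- summarize_replicates(mem, min_obs, n_replicates)
  t_sum <- summarize_replicates(nz_tot, min_obs, n_replicates)
  dn <- diff_nsaf(s_sum$mean_nsaf, m_sum$mean_nsaf,
                  s_sum$quantitated, m_sum$quantitated, epsilon)

  quant <- data.frame(
    id = rownames(counts),
    n_obs_soluble = s_sum$n_obs, mean_soluble = s_sum$mean_nsaf,
    sd_soluble = s_sum$sd_nsaf, quant_soluble = s_sum$quantitated,
    n_obs_membrane = m_sum$n_obs, mean_membrane = m_sum$mean_nsaf,
    sd_membrane = m_sum$sd_nsaf, quant_membrane = m_sum$quantitated,
    n_obs_total = t_sum$n_obs, mean_total = t_sum$mean_nsaf,
    sd_total = t_sum$sd_nsaf, quant_total = t_sum$quantitated,
    diff_nsaf_scaled = dn$diff_nsaf_scaled,
    dist_class = dn$dist_class,
    stringsAsFactors = FALSE
  )
  structure(list(quant = quant, nsaf = nz, nsaf_total = nz_tot),
            class = "quant_table")
}

#' Per-category NSAF sums across replicates
#'
#' For each functional category and fraction, sums the NSAF values of the
#' quantitated member proteins within every replicate run, then reports
#' the mean and standard error of the mean of those per-replicate sums.
#' Proteins without a category are assigned "Miscellaneous" with a
#' warning.
#'
#' @param qt A `quant_table` from [quantify_proteins()].
#' @param categories data.frame with columns `id` and `category`.
#' @return data.frame: `fraction`, `category`, `mean_sum`, `sem`.
#' @export
category_summary <- function(qt, categories) {
  stopifnot(inherits(qt, "quant_table"))
  ids <- rownames(qt$nsaf)
  cat_of <- categories$category[match(ids, categories$id)]
  if (anyNA(cat_of)) {
    warning(sum(is.na(cat_of)), " protein(s) without category assigned ",
            "to 'Miscellaneous'")
    cat_of[is.na(cat_of)] <- "Miscellaneous"
  }
  frac_of <- sub(":.*$", "", colnames(qt$nsaf))
  rows <- list()
  for (frac in unique(frac_of)) {
    qflag <- if (frac == "soluble") qt$quant$quant_soluble
             else qt$quant$quant_membrane
    V <- qt$nsaf[, frac_of == frac, drop = FALSE]
    V[is.na(V)] <- 0
    V[!qflag, ] <- 0
    for (cat in sort(unique(cat_of))) {
      sums <- colSums(V[cat_of == cat, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = frac, category = cat,
        mean_sum = mean(sums),
        sem = if (length(sums) > 1L) sd(sums) / sqrt(length(sums)) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative abundance ratio of two quantitated proteins
#'
#' Ratio of the mean total NSAFs of two proteins, the statistic behind
#' statements such as "PC1/3 : PC2 : CPE approximately 1 : 3 : 6".
#'
#' @param quant Quantitation data.frame (the `quant` element of a
#'   `quant_table`, or any table with `id` and `mean_total`).
#' @param numerator_id,denominator_id Protein accessions.
#' @return The ratio, or `NA` with a warning when the denominator is zero
#'   or missing.
#' @export
abundance_ratio <- function(quant, numerator_id, denominator_id) {
  num <- quant$mean_total[match(numerator_id, quant$id)]
  den <- quant$mean_total[match(denominator_id, quant$id)]
  if (is.na(num) || is.na(den)) {
    warning("protein not found in quantitation table")
    return(NA_real_)
  }
  if (den == 0) {
    warning("denominator protein has zero NSAF; ratio undefined")
    return(NA_real_)
  }
  num / den
}

#' Marker-based organelle purity estimate
#'
#' Anchors contamination estimates to the granule matrix protein
#' chromogranin A (CgA), which is taken to compose `cga_fraction` percent
#' of the vesicle protein content: each contaminant organelle marker
#' contributes `NSAF_marker / NSAF_CgA * cga_fraction` percent, and the
#' overall purity is 100 minus the summed contamination, floored at zero.
#' Markers that were not quantitated contribute zero (below detection).
#'
#' @param quant Quantitation data.frame with `id` and `mean_total`.
#' @param markers data.frame with columns `id` and `organelle` for the
#'   contaminant markers.
#' @param cga_id Accession of the CgA-like anchor protein.
#' @param cga_fraction Percent of vesicle protein attributed to the anchor
#'   (default 46).
#' @return List of class `purity_report`: `markers` (data.frame `id`,
#'   `organelle`, `contamination_pct`), `purity_pct`.
#' @export
purity_estimate <- function(quant, markers, cga_id, cga_fraction = 46.0) {
  cga <- quant$mean_total[match(cga_id, quant$id)]
  if (is.na(cga) || cga <= 0)
    stop("anchor protein ", cga_id, " not quantitated; purity undefined")
  mk <- quant$mean_total[match(markers$id, quant$id)]
  mk[is.na(mk)] <- 0
  contam <- mk / cga * cga_fraction
  res <- data.frame(id = markers$id, organelle = markers$organelle,
                    contamination_pct = contam, stringsAsFactors = FALSE)
  structure(list(markers = res,
                 purity_pct = max(0, 100 - sum(contam))),
            class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  cat("Estimated organelle purity:", sprintf("%.1f%%", x$purity_pct), "\n")
  if (nrow(x$markers) > 0L) print(x$markers, row.names = FALSE)
  invisible(x)
}
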