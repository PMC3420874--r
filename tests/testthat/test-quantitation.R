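test_that("spectral counts match a direct group-by recount and credit shared peptides", {
  psms <- rbind(
    make_psm(peptide = "AAAAK", proteins = "A", fraction = "soluble", replicate = 1L),
    make_psm(peptide = "AAAAK", proteins = "A", fraction = "soluble", replicate = 1L, slice = 3L),
    make_psm(peptide = "CCCCK", proteins = "A", fraction = "soluble", replicate = 1L),
    make_psm(peptide = "SHAREDK", proteins = "A;B", fraction = "membrane", replicate = 2L),
    make_psm(peptide = "DDDDK", proteins = "Z", fraction = "soluble", replicate = 1L)
  )
  expect_message(
    M <- count_matrix(psms, retained = c("A", "B")),
    "matched no retained protein")
  expect_equal(M["A", "soluble:1"], 3L)   # summed over slices
  expect_equal(M["A", "membrane:2"], 1L)  # shared peptide credited to both
  expect_equal(M["B", "membrane:2"], 1L)
  expect_equal(sum(M), 5L)

  # recount oracle on a random table
  psms <- random_psm_table(2000, seed = 81)
  retained <- paste0("P", 1:40)
  M <- count_matrix(psms, retained)
  for (i in 1:20) {
    p <- sample(retained, 1); f <- sample(c("soluble", "membrane"), 1)
    r <- sample(1:4, 1)
    expect_equal(M[p, paste(f, r, sep = ":")],
                 sum(psms$proteins == p & psms$fraction == f &
                       psms$replicate == r))
  }
})

test_that("NSAF follows the size-corrected normalization formula", {
  M <- matrix(5L, nrow = 1, ncol = 1, dimnames = list("A", "soluble:1"))
  expect_equal(nsaf(M, c(A = 10000))[1, 1], 1)  # single protein

  M2 <- matrix(c(4L, 4L), nrow = 2,
               dimnames = list(c("A", "B"), "soluble:1"))
  v <- nsaf(M2, c(A = 10000, B = 20000))
  expect_equal(unname(v[, 1]), c(2 / 3, 1 / 3))

  # random matrices: spreadsheet-style recomputation, column sums exactly 1
  set.seed(82)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    M <- matrix(rpois(n * 8, 5), nrow = n,
                dimnames = list(paste0("P", 1:n),
                                paste0(rep(c("soluble", "membrane"), each = 4),
                                       ":", 1:4)))
    mw <- setNames(runif(n, 5000, 2e5), rownames(M))
    got <- suppressWarnings(nsaf(M, mw))
    for (j in seq_len(ncol(M))) {
      saf <- M[, j] / mw
      if (sum(saf) == 0) next
      expect_equal(unname(got[, j]), unname(saf / sum(saf)))
      expect_lt(abs(sum(got[, j]) - 1), 1e-9)
    }
    # scale invariance: doubling all counts in a sample changes nothing
    M3 <- M; M3[, 1] <- M3[, 1] * 2L
    got3 <- suppressWarnings(nsaf(M3, mw))
    expect_equal(got3[, 1], got[, 1])
  }

  expect_warning(nsaf(matrix(0L, 1, 1, dimnames = list("A", "s:1")),
                      c(A = 1e4)), "no spectral counts")
})

test_that("replicate rule quantitates at 3 of 4 and zero-fills the SD", {
  V <- rbind(
    two = c(0.1, 0.2, 0, 0),
    three = c(0.1, 0.2, 0.3, 0),
    four = c(0.5, 0.5, 0.5, 0.5)
  )
  s <- summarize_replicates(V)
  expect_false(s$quantitated[s$id == "two"])
  expect_true(s$quantitated[s$id == "three"])
  expect_equal(s$mean_nsaf[s$id == "three"], mean(c(0.1, 0.2, 0.3)))
  expect_equal(s$sd_nsaf[s$id == "three"], sd(c(0.1, 0.2, 0.3, 0)))
  expect_equal(s$mean_nsaf[s$id == "four"], 0.5)
  expect_equal(s$sd_nsaf[s$id == "four"], 0)
})

test_that("omnibus normality statistic matches reference values", {
  # frozen oracle values from an independent implementation of the same
  # K-squared statistic
  x <- c(2.1, 3.5, 1.7, 4.2, 2.8, 3.1, 5.9, 2.2, 3.3, 4.8,
         1.1, 2.5, 3.9, 4.4, 2.0, 3.6, 2.9, 5.1, 3.2, 1.9)
  r <- dagostino_pearson(x)
  expect_equal(unname(r$statistic), 0.7263036055, tolerance = 1e-8)
  expect_equal(r$p.value, 0.6954808496, tolerance = 1e-8)

  y <- c(1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 10, 20, 40)
  r2 <- dagostino_pearson(y)
  expect_equal(unname(r2$statistic), 19.8924034202, tolerance = 1e-8)
  expect_equal(r2$p.value, 4.790926e-05, tolerance = 1e-5)

  expect_true(is.na(dagostino_pearson(rep(1, 20))$p.value))  # degenerate
  expect_true(is.na(dagostino_pearson(c(1, 2, 3))$p.value))  # too few
})

test_that("log-scale statistics behave on log-normal, identical, and constant inputs", {
  set.seed(91)
  sol <- exp(rnorm(200, -6, 1)); mem <- exp(rnorm(200, -6, 1))
  st <- ln_stats(sol, mem, c(sol, mem))
  expect_true(all(st$normality$k2_p > 0.01))
  expect_true(all(st$normality$shapiro_p > 0.01))

  # identical distributions: t-test non-significant in >= 95/100 runs
  n_ns <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    a <- exp(rnorm(200, -6, 1)); b <- exp(rnorm(200, -6, 1))
    if (ln_stats(a, b, c(a, b))$t_test$p.value > 0.05) n_ns <- n_ns + 1L
  }
  expect_gte(n_ns, 95L)

  # constant data: degenerate flag, no crash
  stc <- ln_stats(rep(2, 10), rep(3, 10), rep(2.5, 20))
  expect_true(all(stc$normality$degenerate))
  expect_true(is.na(stc$normality$k2_p[1]))

  # non-measurements excluded
  st0 <- ln_stats(c(0, 0, sol), c(NA, mem), c(sol, mem))
  expect_equal(st0$normality$n[1], 200)
})

test_that("Diff-NSAF classes follow the red/green/yellow/grey rule", {
  d <- diff_nsaf(mean_soluble = c(0.002, 0.001, 0, 0),
                 mean_membrane = c(0.001, 0.001, 0.004, 0),
                 quant_soluble = c(TRUE, TRUE, FALSE, FALSE),
                 quant_membrane = c(TRUE, TRUE, TRUE, FALSE),
                 epsilon = 0.2)
  expect_equal(d$diff_nsaf_scaled[1], 1.0)
  expect_equal(as.character(d$dist_class), c("green", "yellow", "red", "grey"))
  expect_true(is.na(d$diff_nsaf_scaled[4]))
})

test_that("category sums honour NSAF normalization and recount directly", {
  M <- matrix(c(3L, 6L), nrow = 2, ncol = 8,
              dimnames = list(c("A", "B"),
                              paste0(rep(c("soluble", "membrane"), each = 4),
                                     ":", 1:4)))
  qt <- quantify_proteins(M, c(A = 1e4, B = 1e4))
  # single category holding every protein: per-replicate sums are exactly 1
  cs <- category_summary(qt, data.frame(id = c("A", "B"), category = "All"))
  expect_equal(cs$mean_sum, c(1, 1))
  expect_equal(cs$sem, c(0, 0))

  expect_warning(
    cs2 <- category_summary(qt, data.frame(id = "A", category = "OnlyA")),
    "Miscellaneous")
  got <- cs2$mean_sum[cs2$category == "OnlyA" & cs2$fraction == "soluble"]
  expect_equal(got, mean(qt$nsaf["A", 1:4]))
})

test_that("abundance ratios reproduce the prohormone-pathway stoichiometry", {
  tab <- read.delim(system.file("extdata", "prohormone_nsaf.tsv",
                                package = "dcsvquant"))
  expect_equal(abundance_ratio(tab, "PCSK2", "PCSK1"), 13.8 / 4.42)
  expect_equal(round(abundance_ratio(tab, "CPE", "PCSK1")), 6)
  expect_equal(abundance_ratio(tab, "CGA", "CGA"), 1)
  expect_warning(r <- abundance_ratio(tab, "CGA", "MISSING"), "not found")
  expect_true(is.na(r))
})

test_that("purity estimate anchors contamination to the granule marker", {
  quant <- data.frame(id = c("CGA", "M1", "M2"),
                      mean_total = c(0.1, 0.1, 0.1 * 0.3 / 46),
                      stringsAsFactors = FALSE)
  markers <- data.frame(id = c("M1"), organelle = "lysosome")
  pr <- purity_estimate(quant, markers, cga_id = "CGA")
  expect_equal(pr$markers$contamination_pct, 46)  # marker NSAF equals CgA

  pr2 <- purity_estimate(quant, data.frame(id = "M2", organelle = "lysosome"),
                         cga_id = "CGA")
  expect_equal(pr2$markers$contamination_pct, 0.3)
  expect_equal(pr2$purity_pct, 99.7)

  none <- purity_estimate(quant, markers[0, , drop = FALSE], cga_id = "CGA")
  expect_equal(none$purity_pct, 100)
  expect_error(purity_estimate(quant, markers, cga_id = "ABSENT"),
               "purity undefined")
})
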