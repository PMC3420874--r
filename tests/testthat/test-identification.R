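test_that("per-charge thresholds accept at the boundary and grade +3 more strictly", {
  psms <- rbind(
    make_psm(peptide = "AAAAK", proteins = "P1", charge = 2L, score = 13.0, spi = 70.0),
    make_psm(peptide = "CCCCK", proteins = "P1", charge = 3L, score = 14, spi = 90),
    make_psm(peptide = "DDDDK", proteins = "P2", charge = 3L, score = 16, spi = 70),
    make_psm(peptide = "EEEEK", proteins = "P3", charge = 1L, score = 12.9, spi = 99)
  )
  res <- apply_thresholds(psms)
  expect_setequal(res$accepted$peptide, c("AAAAK", "DDDDK"))
  expect_false("CCCCK" %in% res$accepted$peptide)  # score < 16 at +3
  expect_false("EEEEK" %in% res$accepted$peptide)  # +1 graded like +2

  empty <- psms[0, ]
  res0 <- apply_thresholds(empty)
  expect_equal(nrow(res0$accepted), 0L)
  expect_equal(nrow(res0$rescued), 0L)
})

test_that("two distinct moderate peptides rescue a protein, single ones do not", {
  psms <- rbind(
    make_psm(peptide = "AAAAK", proteins = "P1", charge = 2L, score = 11, spi = 75),
    make_psm(peptide = "CCCCK", proteins = "P1", charge = 2L, score = 11, spi = 75),
    make_psm(peptide = "DDDDK", proteins = "P2", charge = 2L, score = 11, spi = 75),
    make_psm(peptide = "DDDDK", proteins = "P2", charge = 2L, score = 11.5, spi = 80)
  )
  res <- apply_thresholds(psms)
  expect_equal(nrow(res$accepted), 0L)
  # P1 has two distinct peptides -> both rescued; P2 has two PSMs of one
  # peptide -> peptide-level evidence insufficient
  expect_setequal(res$rescued$peptide, c("AAAAK", "CCCCK"))
})

test_that("decoys are filtered by the same rules but kept separate", {
  psms <- rbind(
    make_psm(peptide = "AAAAK", proteins = "P1", charge = 2L, score = 20, spi = 90),
    make_psm(peptide = "CCCCK", proteins = "DECOY_P1", charge = 2L, score = 20,
             spi = 90, is_decoy = TRUE)
  )
  res <- apply_thresholds(psms)
  expect_equal(res$accepted$peptide, "AAAAK")
  expect_equal(res$decoy_accepted$peptide, "CCCCK")
  expect_false(any(res$accepted$is_decoy))
})

test_that("unknown charge states are dropped with a warning", {
  psms <- rbind(make_psm(score = 20), make_psm(charge = 5L, score = 20))
  expect_warning(res <- apply_thresholds(psms), "unknown charge")
  expect_equal(nrow(res$accepted), 1L)
})

test_that("filtering is idempotent and monotone in the score cuts", {
  psms <- random_psm_table(3000, seed = 31)
  res <- apply_thresholds(psms)
  again <- apply_thresholds(res$accepted)
  expect_equal(again$accepted, res$accepted, ignore_attr = TRUE)
  expect_equal(nrow(again$rescued), 0L)

  # raising any cut never increases passing counts
  prev_t <- Inf; prev_d <- Inf
  decoys <- random_psm_table(3000, seed = 32)
  decoys$is_decoy <- TRUE
  for (cut in seq(5, 25, by = 2)) {
    th <- threshold_set(score_min = c(`1` = cut, `2` = cut, `3` = cut + 3),
                        rescue_score = min(cut, 10))
    rep <- suppressWarnings(compute_fdr(psms, decoys, th))
    tot <- rep$per_charge[rep$per_charge$charge == "total", ]
    expect_lte(tot$n_target_pass, prev_t)
    expect_lte(tot$n_decoy_pass, prev_d)
    prev_t <- tot$n_target_pass; prev_d <- tot$n_decoy_pass
  }
})

test_that("FDR equals decoy/target at the thresholds, with guarded edge cases", {
  tgt <- make_psm(peptide = paste0("P", 1:200, "K"), proteins = "P1",
                  charge = 2L, score = 20, spi = 90)
  dec <- make_psm(peptide = c("XK", "YK"), proteins = "DECOY_P1",
                  charge = 2L, score = 20, spi = 90, is_decoy = TRUE)
  # the empty charge-3 stratum warns; the totals are the point here
  rep <- suppressWarnings(compute_fdr(tgt, dec))
  expect_equal(rep$per_charge$fdr[rep$per_charge$charge == "total"], 0.01)

  rep0 <- suppressWarnings(compute_fdr(tgt, dec[0, ]))
  expect_equal(rep0$per_charge$fdr[rep0$per_charge$charge == "total"], 0)

  w <- capture_warnings(repn <- compute_fdr(tgt[0, ], dec))
  expect_true(any(grepl("FDR undefined", w)))
  expect_true(is.nan(repn$per_charge$fdr[repn$per_charge$charge == "total"]))
})

test_that("FDR report matches an independent recount and histogram marginals are complete", {
  for (seed in 1:10) {
    tgt <- random_psm_table(800, seed = seed)
    dec <- random_psm_table(400, seed = seed + 100)
    dec$is_decoy <- TRUE
    rep <- suppressWarnings(compute_fdr(tgt, dec))
    oracle <- ref_fdr(tgt, dec)
    pc <- rep$per_charge
    expect_equal(pc$fdr[pc$charge == "2"], oracle$fdr2)
    expect_equal(pc$fdr[pc$charge == "3"], oracle$fdr3)
    expect_equal(pc$fdr[pc$charge == "total"], oracle$total)
    expect_equal(sum(rep$histogram$n_target), nrow(tgt))
    expect_equal(sum(rep$histogram$n_decoy), nrow(dec))
  }
})

test_that("decoy FDR tracks the realized false-match fraction in labelled data", {
  cfg <- synthetic_config(n_proteins = 50, n_isoform_clusters = 45,
                          mean_seq_len = 250, depth = 2e4,
                          decoy_ratio = 0.15, seed = 41)
  sim <- generate_proteome(cfg)
  prot <- rbind(sim$proteins, shuffle_decoy(sim$proteins, seed = 43))
  psms <- generate_psms(prot, sim$truth, cfg)
  tgt <- psms[!psms$is_decoy, ]; dec <- psms[psms$is_decoy, ]
  rep <- compute_fdr(tgt, dec)
  est <- rep$per_charge$fdr[rep$per_charge$charge == "total"]

  th <- threshold_set()
  cut <- th$score_min[as.character(tgt$charge)]
  pass <- tgt$score >= cut & tgt$spi >= th$spi_min
  realized <- mean(tgt$is_noise[pass])
  se <- sqrt(realized * (1 - realized) / sum(pass))
  expect_lt(abs(est - realized), 3 * se + 1e-12)
})

test_that("threshold search returns the smallest cut meeting the goal", {
  # decoys all scoring low: cut lands at the minimum bin
  tgt <- make_psm(peptide = paste0("P", 1:50, "K"), proteins = "P1",
                  charge = 2L, score = runif(50, 10, 30), spi = 90)
  dec <- make_psm(peptide = paste0("D", 1:10, "K"), proteins = "DECOY_P1",
                  charge = 2L, score = runif(10, 0, 4), spi = 90,
                  is_decoy = TRUE)
  ts <- threshold_search(tgt, dec, fdr_goal = 0.5)
  expect_equal(unname(ts$score_min[["2"]]), 0)

  # goal ~ 1 gives the minimum possible cut everywhere
  ts1 <- threshold_search(tgt, dec, fdr_goal = 0.999)
  expect_true(all(ts1$score_min == 0))

  # synthetic score distributions: agree with an exhaustive scan oracle
  set.seed(51)
  tgt <- make_psm(peptide = paste0("T", 1:4000, "K"), proteins = "P1",
                  charge = sample(2:3, 4000, replace = TRUE),
                  score = pmax(0, rnorm(4000, 20, 4)), spi = runif(4000, 55, 100))
  dec <- make_psm(peptide = paste0("D", 1:1500, "K"), proteins = "DECOY_P1",
                  charge = sample(2:3, 1500, replace = TRUE),
                  score = pmax(0, rnorm(1500, 8, 2)), spi = runif(1500, 0, 100),
                  is_decoy = TRUE)
  ts <- threshold_search(tgt, dec, fdr_goal = 0.01)
  for (ch in 2:3) {
    t_s <- tgt$score[tgt$charge == ch & tgt$spi >= 70]
    d_s <- dec$score[dec$charge == ch & dec$spi >= 70]
    scan <- vapply(0:40, function(cut) {
      t_n <- sum(t_s >= cut)
      if (t_n == 0) 0 else sum(d_s >= cut) / t_n
    }, numeric(1))
    oracle_cut <- (0:40)[which(scan <= 0.01)[1L]]
    expect_lte(abs(ts$score_min[[as.character(ch)]] - oracle_cut), 1)
  }
})
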