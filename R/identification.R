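#' Per-charge score/%SPI acceptance thresholds
#'
#' The default thresholds are the ones used for ion-trap data graded by
#' charge state: score >= 13 with %SPI >= 70 for +1 and +2 precursors,
#' score >= 16 with %SPI >= 70 for +3, plus a rescue rule admitting PSMs
#' with score >= 10 and %SPI >= 70 when a protein is supported by at least
#' two distinct peptides at that level.
#'
#' @param score_min Named numeric vector of per-charge score minima.
#' @param spi_min Minimum %SPI for primary acceptance.
#' @param rescue_score,rescue_spi Score/%SPI floor for the two-peptide
#'   rescue rule.
#' @param rescue_min_peptides Distinct peptides per protein required to
#'   trigger the rescue rule.
#' @return A list of class `threshold_set`.
#' @export
threshold_set <- function(score_min = c(`1` = 13, `2` = 13, `3` = 16),
                          spi_min = 70,
                          rescue_score = 10, rescue_spi = 70,
                          rescue_min_peptides = 2L) {
  if (is.null(names(score_min)) || !all(c("1", "2", "3") %in% names(score_min)))
    stop("score_min must be named with charges '1', '2', '3'")
  if (any(rescue_score > score_min))
    stop("rescue_score must not exceed any per-charge score minimum")
  structure(list(score_min = score_min, spi_min = spi_min,
                 rescue_score = rescue_score, rescue_spi = rescue_spi,
                 rescue_min_peptides = as.integer(rescue_min_peptides)),
            class = "threshold_set")
}

.split_protein_ids <- function(x) strsplit(x, ";", fixed = TRUE)

# distinct peptide count per protein over a set of PSM rows
.peptides_per_protein <- function(psms) {
  if (nrow(psms) == 0L) return(integer(0))
  ids <- .split_protein_ids(psms$proteins)
  prot <- unlist(ids, use.names = FALSE)
  pep <- rep(psms$peptide, lengths(ids))
  keep <- !duplicated(paste(prot, pep, sep = "\r"))
  table(prot[keep])
}

.filter_one <- function(psms, thresholds) {
  if (nrow(psms) == 0L)
    return(list(accepted = psms, rescued = psms))
  cut <- thresholds$score_min[as.character(psms$charge)]
  primary <- !is.na(cut) & psms$score >= cut & psms$spi >= thresholds$spi_min
  candidate <- !primary &
    psms$score >= thresholds$rescue_score &
    psms$spi >= thresholds$rescue_spi
  pool <- psms[primary | candidate, , drop = FALSE]
  npp <- .peptides_per_protein(pool)
  ok_prot <- names(npp)[npp >= thresholds$rescue_min_peptides]
  cand_rows <- which(candidate)
  rescued_flag <- vapply(.split_protein_ids(psms$proteins[cand_rows]),
                         function(p) any(p %in% ok_prot), logical(1))
  list(accepted = psms[primary, , drop = FALSE],
       rescued = psms[cand_rows[rescued_flag], , drop = FALSE])
}

#' Filter PSMs by per-charge thresholds with the two-peptide rescue rule
#'
#' Primary acceptance requires a PSM to meet its charge state's score
#' minimum and the %SPI minimum. Rescue candidates (score >= 10, %SPI >= 70
#' by default) are additionally admitted when they map to a protein carrying
#' at least `rescue_min_peptides` distinct peptide sequences among primary
#' acceptances and rescue candidates combined. Decoy PSMs are filtered by
#' identical rules but reported separately and never mixed into the target
#' output. Rows with a charge state outside the threshold table are dropped
#' with a warning.
#'
#' @param psms PSM table (see [generate_psms()] for the column contract).
#' @param thresholds A [threshold_set()].
#' @return List with target `accepted` and `rescued` tables and the
#'   analogous `decoy_accepted` / `decoy_rescued` tables.
#' @export
apply_thresholds <- function(psms, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (nrow(psms) > 0L) {
    known <- as.character(psms$charge) %in% names(thresholds$score_min)
    if (any(!known)) {
      warning(sum(!known), " PSM(s) with unknown charge state dropped")
      psms <- psms[known, , drop = FALSE]
    }
  }
  tgt <- .filter_one(psms[!psms$is_decoy, , drop = FALSE], thresholds)
  dec <- .filter_one(psms[psms$is_decoy, , drop = FALSE], thresholds)
  list(accepted = tgt$accepted, rescued = tgt$rescued,
       decoy_accepted = dec$accepted, decoy_rescued = dec$rescued)
}

.pass_primary <- function(psms, thresholds) {
  if (nrow(psms) == 0L) return(logical(0))
  cut <- thresholds$score_min[as.character(psms$charge)]
  !is.na(cut) & psms$score >= cut & psms$spi >= thresholds$spi_min
}

#' Score-binned decoy FDR estimation
#'
#' Segregates target and decoy PSMs by charge state, bins scores into
#' left-closed intervals of `bin_width` score units starting at zero, and
#' computes the false discovery rate at the supplied thresholds as
#' decoy identifications / target identifications, reported for +2 and +3
#' precursors separately and for all identifications combined.
#'
#' @param target_psms,decoy_psms PSM tables (targets and decoys).
#' @param thresholds A [threshold_set()].
#' @param bin_width Histogram bin width in score units.
#' @return An object of class `fdr_report`: `per_charge` (data.frame with
#'   `charge`, `n_target_pass`, `n_decoy_pass`, `fdr`; charge `"total"` in
#'   the last row) and `histogram` (data.frame `charge`, `bin_low`,
#'   `n_target`, `n_decoy`). With zero passing targets the FDR is `NaN`
#'   and a warning is raised.
#' @export
compute_fdr <- function(target_psms, decoy_psms,
                        thresholds = threshold_set(), bin_width = 1) {
  stopifnot(inherits(thresholds, "threshold_set"), bin_width > 0)

  hist_one <- function(psms, charge) {
    s <- psms$score[psms$charge == charge]
    if (length(s) == 0L) return(integer(0))
    tabulate(floor(s / bin_width) + 1L)
  }
  charges <- sort(unique(c(target_psms$charge, decoy_psms$charge)))
  hist <- do.call(rbind, lapply(charges, function(ch) {
    ht <- hist_one(target_psms, ch)
    hd <- hist_one(decoy_psms, ch)
    nb <- max(length(ht), length(hd), 1L)
    data.frame(charge = ch,
               bin_low = (seq_len(nb) - 1L) * bin_width,
               n_target = c(ht, rep(0L, nb - length(ht))),
               n_decoy = c(hd, rep(0L, nb - length(hd))))
  }))

  fdr_at <- function(tp, dp) {
    t_n <- sum(tp); d_n <- sum(dp)
    if (t_n == 0L) {
      warning("no passing target identifications; FDR undefined")
      return(c(t_n, d_n, NaN))
    }
    c(t_n, d_n, d_n / t_n)
  }
  tp <- .pass_primary(target_psms, thresholds)
  dp <- .pass_primary(decoy_psms, thresholds)
  rows <- lapply(c(2L, 3L), function(ch)
    fdr_at(tp & target_psms$charge == ch, dp & decoy_psms$charge == ch))
  rows <- c(rows, list(fdr_at(tp, dp)))
  per_charge <- data.frame(
    charge = c("2", "3", "total"),
    n_target_pass = vapply(rows, `[`, numeric(1), 1L),
    n_decoy_pass = vapply(rows, `[`, numeric(1), 2L),
    fdr = vapply(rows, `[`, numeric(1), 3L),
    stringsAsFactors = FALSE
  )
  structure(list(per_charge = per_charge, histogram = hist,
                 thresholds = thresholds),
            class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat("Decoy-estimated FDR at thresholds (score >= ",
      paste(sprintf("%s:%g", names(x$thresholds$score_min),
                    x$thresholds$score_min), collapse = ", "),
      "; %SPI >= ", x$thresholds$spi_min, ")\n", sep = "")
  print(x$per_charge, row.names = FALSE)
  invisible(x)
}

#' Search the smallest per-charge score cut achieving an FDR goal
#'
#' For each charge state independently, scans integer score cuts (with
#' %SPI fixed at the primary minimum) from low to high and returns the
#' smallest cut whose decoy/target FDR is at or below `fdr_goal`. If the
#' goal is unattainable the maximum scanned cut is returned with a warning
#' and the attained FDR recorded in the `attained_fdr` attribute.
#'
#' @param target_psms,decoy_psms PSM tables.
#' @param fdr_goal Target FDR in (0, 1).
#' @param spi_min %SPI floor applied while scanning.
#' @return A [threshold_set()] with the selected per-charge score minima;
#'   attribute `attained_fdr` holds the per-charge FDR at the selected cuts.
#' @export
threshold_search <- function(target_psms, decoy_psms, fdr_goal = 0.01,
                             spi_min = 70) {
  stopifnot(fdr_goal > 0, fdr_goal < 1)
  cuts <- c(`1` = 0, `2` = 0, `3` = 0)
  attained <- c(`1` = 0, `2` = 0, `3` = 0)
  all_scores <- c(target_psms$score, decoy_psms$score)
  lo <- if (length(all_scores)) floor(min(all_scores)) else 0
  hi <- if (length(all_scores)) ceiling(max(all_scores)) + 1 else 1
  for (ch in c(1L, 2L, 3L)) {
    ts <- target_psms$score[target_psms$charge == ch &
                              target_psms$spi >= spi_min]
    ds <- decoy_psms$score[decoy_psms$charge == ch &
                             decoy_psms$spi >= spi_min]
    found <- FALSE
    for (cut in seq(lo, hi)) {
      t_n <- sum(ts >= cut); d_n <- sum(ds >= cut)
      fdr <- if (t_n == 0L) { if (d_n == 0L) 0 else Inf } else d_n / t_n
      if (fdr <= fdr_goal) {
        cuts[as.character(ch)] <- cut
        attained[as.character(ch)] <- fdr
        found <- TRUE
        break
      }
    }
    if (!found) {
      warning("FDR goal ", fdr_goal, " unattainable for charge ", ch)
      t_n <- sum(ts >= hi); d_n <- sum(ds >= hi)
      cuts[as.character(ch)] <- hi
      attained[as.character(ch)] <- if (t_n == 0L) NaN else d_n / t_n
    }
  }
  out <- threshold_set(score_min = cuts, spi_min = spi_min,
                       rescue_score = min(cuts), rescue_spi = spi_min)
  attr(out, "attained_fdr") <- attained
  out
}
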