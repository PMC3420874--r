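#' Pipeline configuration
#'
#' Validated bundle of every knob of the end-to-end analysis. Unknown
#' arguments are rejected.
#'
#' @param synthetic A [synthetic_config()] describing the simulated
#'   experiment (used when no PSM table is supplied).
#' @param thresholds A [threshold_set()].
#' @param min_obs Minimum replicate observations for quantitation.
#' @param epsilon Yellow-band width for [diff_nsaf()].
#' @param cga_fraction Percent of vesicle protein attributed to the purity
#'   anchor.
#' @param identity_min,coverage_min Clustering cutoffs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            thresholds = threshold_set(),
                            min_obs = 3L, epsilon = 0.2,
                            cga_fraction = 46.0,
                            identity_min = 0.95, coverage_min = 0.90) {
  stopifnot(inherits(synthetic, "synthetic_config"),
            inherits(thresholds, "threshold_set"))
  if (min_obs < 1L || min_obs > synthetic$n_replicates)
    stop("min_obs must be between 1 and n_replicates")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (cga_fraction <= 0 || cga_fraction > 100)
    stop("cga_fraction must be a percentage in (0, 100]")
  if (identity_min < 0 || identity_min > 1 ||
      coverage_min < 0 || coverage_min > 1)
    stop("identity_min and coverage_min must be in [0, 1]")
  structure(list(synthetic = synthetic, thresholds = thresholds,
                 min_obs = as.integer(min_obs), epsilon = epsilon,
                 cga_fraction = cga_fraction,
                 identity_min = identity_min, coverage_min = coverage_min),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains every stage in order: simulate (unless a PSM table and protein
#' database are supplied) -> filter PSMs and estimate FDR -> cluster the
#' database and infer the minimal protein set -> NSAF quantitation with
#' Diff-NSAF classes -> category summary -> marker purity -> node
#' attributes. All randomness flows from the seed inside the
#' configuration, so a rerun with the same configuration is byte-identical
#' on disk.
#'
#' @param config A [pipeline_config()].
#' @param psms Optional externally supplied PSM table (targets and decoys
#'   mixed; decoys flagged).
#' @param proteins Optional protein database matching `psms`.
#' @param truth Optional ground-truth table (enables marker purity and
#'   recovery diagnostics for simulated data).
#' @param edges Optional interaction edge table for node-attribute export.
#' @param out_dir Optional directory; when given, every stage's table plus
#'   a JSON summary are written (atomically) into it.
#' @return List of class `pipeline_result` with elements `filtered`,
#'   `fdr`, `clusters`, `retained`, `counts`, `quant_table`, `categories`,
#'   `purity`, `nodes`, and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), psms = NULL,
                         proteins = NULL, truth = NULL, edges = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  scfg <- config$synthetic

  if (is.null(psms)) {
    sim <- generate_proteome(scfg)
    proteins <- rbind(sim$proteins, shuffle_decoy(sim$proteins,
                                                  seed = scfg$seed + 2L))
    truth <- sim$truth
    psms <- generate_psms(proteins, truth, scfg)
  }
  if (is.null(proteins)) stop("a protein database is required with external PSMs")
  targets <- proteins[!proteins$is_decoy, , drop = FALSE]

  filt <- apply_thresholds(psms, config$thresholds)
  fdr <- suppressWarnings(
    compute_fdr(psms[!psms$is_decoy, , drop = FALSE],
                psms[psms$is_decoy, , drop = FALSE], config$thresholds))

  # rescued PSMs support identification; quantitation counts only PSMs
  # meeting the strict per-charge thresholds
  identified_psms <- rbind(filt$accepted, filt$rescued)

  clusters <- cluster_proteins(targets, config$identity_min,
                               config$coverage_min)
  retained <- character(0)
  if (nrow(identified_psms) > 0L) {
    evidence <- unique(identified_psms[, c("peptide", "proteins")])
    retained <- minimal_protein_set(
      evidence, clusters = clusters,
      seq_lengths = setNames(nchar(targets$sequence), targets$id))
  }

  counts <- count_matrix(filt$accepted, retained,
                         fractions = scfg$fractions,
                         n_replicates = scfg$n_replicates)
  mw <- setNames(targets$mw, targets$id)
  qt <- quantify_proteins(counts, mw, fractions = scfg$fractions,
                          n_replicates = scfg$n_replicates,
                          min_obs = config$min_obs,
                          epsilon = config$epsilon)

  cats <- NULL
  if (!all(is.na(targets$category)))
    cats <- category_summary(qt, targets[, c("id", "category")])

  purity <- NULL
  if (!is.null(truth) && "marker" %in% names(truth)) {
    cga_id <- truth$id[!is.na(truth$marker) &
                         truth$marker == "secretory_granule"]
    mk <- truth[!is.na(truth$marker) &
                  truth$marker != "secretory_granule",
                c("id", "marker")]
    names(mk) <- c("id", "organelle")
    if (length(cga_id) == 1L && cga_id %in% qt$quant$id &&
        qt$quant$mean_total[qt$quant$id == cga_id] > 0)
      purity <- purity_estimate(qt$quant, mk, cga_id, config$cga_fraction)
  }

  nodes <- node_attributes(qt$quant, targets[, c("id", "symbol")],
                           targets[, c("id", "category")])

  frac_of <- sub(":.*$", "", colnames(counts))
  identified_in <- function(frac)
    sum(rowSums(counts[, frac_of == frac, drop = FALSE]) > 0)
  summary <- list(
    n_psms = nrow(psms),
    n_accepted = nrow(filt$accepted),
    n_rescued = nrow(filt$rescued),
    n_identified = length(retained),
    n_identified_soluble = identified_in(scfg$fractions[1L]),
    n_identified_membrane = identified_in(scfg$fractions[2L]),
    n_quantitated = sum(qt$quant$quant_soluble | qt$quant$quant_membrane),
    n_quantitated_soluble = sum(qt$quant$quant_soluble),
    n_quantitated_membrane = sum(qt$quant$quant_membrane),
    fdr = setNames(as.list(fdr$per_charge$fdr), fdr$per_charge$charge),
    purity_pct = if (!is.null(purity)) purity$purity_pct else NA
  )

  res <- structure(
    list(filtered = filt, fdr = fdr, clusters = clusters,
         retained = retained, counts = counts, quant_table = qt,
         categories = cats, purity = purity, nodes = nodes, edges = edges,
         summary = summary, truth = truth, proteins = proteins),
    class = "pipeline_result")

  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_psms(res$filtered$accepted, file.path(out_dir, "psms_accepted.tsv"))
  write_psms(res$filtered$rescued, file.path(out_dir, "psms_rescued.tsv"))
  .write_tsv(res$fdr$per_charge, file.path(out_dir, "fdr_per_charge.tsv"))
  .write_tsv(res$fdr$histogram, file.path(out_dir, "fdr_histogram.tsv"))
  .write_tsv(res$clusters, file.path(out_dir, "clusters.tsv"))
  .write_tsv(data.frame(id = res$retained),
             file.path(out_dir, "retained_proteins.tsv"))
  cm <- data.frame(id = rownames(res$counts), res$counts,
                   check.names = FALSE)
  .write_tsv(cm, file.path(out_dir, "spectral_counts.tsv"))
  .write_tsv(res$quant_table$quant, file.path(out_dir, "quant.tsv"))
  if (!is.null(res$categories))
    .write_tsv(res$categories, file.path(out_dir, "category_summary.tsv"))
  if (!is.null(res$purity))
    .write_tsv(res$purity$markers, file.path(out_dir, "purity_markers.tsv"))
  .write_tsv(res$nodes, file.path(out_dir, "node_attributes.tsv"))
  tmp <- file.path(out_dir, "summary.json.tmp")
  jsonlite::write_json(res$summary, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Pipeline result:", s$n_psms, "PSMs ->", s$n_accepted, "accepted +",
      s$n_rescued, "rescued ->", s$n_identified, "proteins identified,",
      s$n_quantitated, "quantitated\n")
  cat("FDR (total):", format(s$fdr$total, digits = 3), "\n")
  if (!is.na(s$purity_pct))
    cat("Estimated purity:", sprintf("%.1f%%", s$purity_pct), "\n")
  invisible(x)
}
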