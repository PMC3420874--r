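#' Read an undirected protein-interaction edge list
#'
#' Accepts either a two-column tab-separated file (source, target; a
#' header line is auto-detected when its first field is "source") or the
#' simple interaction format (SIF: source, interaction type, one or more
#' targets per line). Symbols are upper-cased, self-loops removed, and
#' duplicate unordered pairs collapsed.
#'
#' @param path File path.
#' @param format `"auto"`, `"tsv"`, or `"sif"`.
#' @return data.frame with columns `a` and `b` (sorted within a row).
#' @export
read_edges <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "[\t ]+")
  if (format == "auto")
    format <- if (any(lengths(fields) >= 3L)) "sif" else "tsv"
  if (format == "tsv") {
    if (tolower(fields[[1L]][1L]) == "source") fields <- fields[-1L]
    a <- vapply(fields, `[`, character(1), 1L)
    b <- vapply(fields, `[`, character(1), 2L)
  } else {
    a <- character(0); b <- character(0)
    for (f in fields) {
      if (length(f) < 3L) next  # SIF line with no target
      a <- c(a, rep(f[1L], length(f) - 2L))
      b <- c(b, f[-(1:2)])
    }
  }
  edge_table(a, b)
}

#' Normalize a pair of symbol vectors into an edge table
#'
#' @param a,b Character vectors of interacting node symbols.
#' @return data.frame with sorted, upper-cased, de-duplicated, loop-free
#'   pairs `a`, `b`.
#' @export
edge_table <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- toupper(a); b <- toupper(b)
  keep <- !is.na(a) & !is.na(b) & a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
}

#' Node-attribute table for network tools
#'
#' Emits one row per quantified or identified protein with the Diff-NSAF
#' colour class, ready for import as a node attribute file: quantitated
#' proteins carry green/red/yellow per their soluble-membrane
#' distribution, identified-but-unquantitated proteins are grey. Proteins
#' whose accession cannot be resolved to a symbol are kept under their
#' accession with a grey class and a warning; duplicate symbols are
#' suffixed `_2`, `_3`, ... with a message.
#'
#' @param quant Quantitation data.frame (the `quant` element of a
#'   `quant_table`).
#' @param symbol_map data.frame with columns `id` and `symbol`.
#' @param categories Optional data.frame with `id` and `category`.
#' @return data.frame: `symbol`, `diff_nsaf`, `class`, `category`,
#'   `quantitated`.
#' @export
node_attributes <- function(quant, symbol_map, categories = NULL) {
  if (nrow(quant) == 0L)
    return(data.frame(symbol = character(), diff_nsaf = numeric(),
                      class = character(), category = character(),
                      quantitated = logical(), stringsAsFactors = FALSE))
  sym <- symbol_map$symbol[match(quant$id, symbol_map$id)]
  unresolved <- is.na(sym) | !nzchar(sym)
  cls <- as.character(quant$dist_class)
  if (any(unresolved)) {
    warning(sum(unresolved), " protein(s) could not be mapped to a symbol; ",
            "kept under accession with grey class")
    sym[unresolved] <- quant$id[unresolved]
    cls[unresolved] <- "grey"
  }
  sym <- toupper(sym)
  if (anyDuplicated(sym)) {
    message("duplicate symbols suffixed to keep node names unique")
    dup_idx <- stats::ave(seq_along(sym), sym, FUN = seq_along)
    sym[dup_idx > 1L] <- paste0(sym[dup_idx > 1L], "_", dup_idx[dup_idx > 1L])
  }
  cat_of <- rep(NA_character_, nrow(quant))
  if (!is.null(categories))
    cat_of <- categories$category[match(quant$id, categories$id)]
  data.frame(
    symbol = sym,
    diff_nsaf = quant$diff_nsaf_scaled,
    class = cls,
    category = cat_of,
    quantitated = quant$quant_soluble | quant$quant_membrane,
    stringsAsFactors = FALSE
  )
}

#' Partition interaction neighbourhoods of two kinase seed sets
#'
#' Given an edge list and two seed symbol sets (for example the PKA and
#' PKC subunits present in the data), splits the union of their direct
#' interaction neighbourhoods into proteins interacting only with the
#' first set, only with the second, and with both. Seeds themselves are
#' excluded from all three sets; absent seeds simply yield empty
#' neighbourhoods.
#'
#' @param edges Edge data.frame from [read_edges()] / [edge_table()].
#' @param seeds_a,seeds_b Character vectors of seed symbols.
#' @return List with sorted character vectors `a_only`, `b_only`, `both`.
#' @export
kinase_partition <- function(edges, seeds_a, seeds_b) {
  seeds_a <- toupper(seeds_a); seeds_b <- toupper(seeds_b)
  nbrs <- function(seeds) {
    hit_a <- edges$a %in% seeds
    hit_b <- edges$b %in% seeds
    unique(c(edges$b[hit_a], edges$a[hit_b]))
  }
  na <- setdiff(nbrs(seeds_a), c(seeds_a, seeds_b))
  nb <- setdiff(nbrs(seeds_b), c(seeds_a, seeds_b))
  list(a_only = sort(setdiff(na, nb)),
       b_only = sort(setdiff(nb, na)),
       both = sort(intersect(na, nb)))
}
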