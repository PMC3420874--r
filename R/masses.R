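# Average (isotope-abundance weighted) residue masses in Daltons.
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.MASS_WATER <- 18.01528

#' Protein molecular weight from sequence
#'
#' Computes the average molecular weight of an unmodified polypeptide as the
#' sum of average residue masses plus one water. NSAF only requires a
#' consistent size proxy, so average (not monoisotopic) masses are used.
#'
#' @param sequence Character vector of amino-acid sequences (standard
#'   20-letter alphabet, upper case).
#' @return Numeric vector of molecular weights in Daltons.
#' @examples
#' protein_mw("ACDEFGHIKLMNPQRSTVWY")
#' @export
protein_mw <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty sequence has no molecular weight")
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    m <- .RESIDUE_MASS[aa]
    if (anyNA(m)) {
      bad <- unique(aa[is.na(m)])
      stop("unknown residue(s): ", paste(bad, collapse = ", "))
    }
    sum(m) + .MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}
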