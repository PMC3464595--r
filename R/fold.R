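#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' Computes the minimum-free-energy nested secondary structure of a sequence
#' under the package's reduced nearest-neighbor model: Turner-style stacking
#' energies over the six canonical pair types (Watson-Crick plus G:U wobble),
#' a minimum hairpin loop of 3 nt, linear hairpin/interior/bulge loop
#' penalties, and an affine multiloop cost.  The recursion is a Zuker-style
#' dynamic program with a deterministic traceback, so identical input always
#' yields an identical structure string.
#'
#' The model is intentionally self-contained and is the one used by the
#' hairpin evaluation gate (\code{\link{evaluate_candidate}}); its absolute
#' energies are comparable between sequences folded by this package but are
#' not interchangeable with energies from other folding programs.
#'
#' @param seq character scalar, 15-400 nt over A/C/G/T/U (case-insensitive)
#' @param allow_gu logical; permit G:U wobble pairs (default \code{TRUE})
#' @return a list of class \code{fold_result} with elements
#'   \item{structure}{dot-bracket string, same length as \code{seq}}
#'   \item{mfe}{minimum free energy in kcal/mol (\eqn{\le 0})}
#'   \item{pairs}{integer vector of 1-based pairing partners, \code{NA} where
#'     unpaired}
#' @examples
#' fold("GGGGAAAACCCCGGGGAAAACCCC")
#' @export
fold <- function(seq, allow_gu = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n < 15 || n > 400) {
    stop("fold: sequence length must be between 15 and 400 nt, got ", n)
  }
  res <- fold_cpp(seq, isTRUE(allow_gu))
  pairs <- res$pairs + 1L
  pairs[pairs == 0L] <- NA_integer_
  structure(
    list(structure = res$structure, mfe = res$mfe, pairs = pairs),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n")
  cat(sprintf("MFE: %.2f kcal/mol\n", x$mfe))
  invisible(x)
}

#' Exhaustive-enumeration folding oracle
#'
#' Enumerates every nested secondary structure of a short sequence (hairpin
#' loops of at least 3 nt) and scores each one by full loop decomposition
#' under the same energy parameters as \code{\link{fold}}.  Used as an
#' independent check on the dynamic program; practical only for sequences of
#' about 22 nt or fewer.
#'
#' @inheritParams fold
#' @return list with \code{structure} (dot-bracket) and \code{mfe} (kcal/mol)
#' @export
brute_force_fold <- function(seq, allow_gu = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- normalize_seq(seq)
  brute_fold_cpp(seq, isTRUE(allow_gu))
}
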