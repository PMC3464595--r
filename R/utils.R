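## Shared small utilities: sequence handling, rounding, collapsed-FASTA I/O.

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

#' Round half away from zero
#'
#' Fixed-precision rounding used for all reported table values, so that a
#' value like 2.885 prints as 2.89 regardless of binary representation
#' quirks.  Internal arithmetic is always full precision; rounding is a
#' reporting step only.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## normalize sequences to uppercase DNA alphabet (U -> T)
normalize_seq <- function(x) {
  chartr("Uu", "Tt", toupper(x))
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Write a collapsed tag FASTA
#'
#' Tags are written with headers of the form \code{>tag_<i>_x<count>}, the
#' conventional collapsed representation of a small RNA library.
#'
#' @param tags data.frame with columns \code{seq} and \code{count}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_collapsed_fasta <- function(tags, path) {
  stopifnot(all(c("seq", "count") %in% names(tags)))
  ids <- sprintf("tag_%d_x%d", seq_len(nrow(tags)), as.integer(tags$count))
  x <- Biostrings::DNAStringSet(tags$seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a collapsed tag FASTA
#'
#' @param path FASTA file with \code{>id_x<count>} headers; a header without
#'   a \code{_x<count>} suffix gets count 1.
#' @return data.frame with columns \code{seq}, \code{count}
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  counts <- suppressWarnings(
    as.integer(sub(".*_x(\\d+)$", "\\1", names(x)))
  )
  counts[is.na(counts)] <- 1L
  data.frame(seq = as.character(x), count = counts, stringsAsFactors = FALSE)
}

## write a simple TSV (all report tables use this)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
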