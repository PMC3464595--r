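## miRNA target prediction by ungapped complementarity scanning under
## Allen-style penalty rules.

#' Score a miRNA/target-site duplex under Allen-style rules
#'
#' Position 1 is the miRNA 5' end; the site is given 5' to 3' on the
#' transcript, so miRNA position i faces site position \code{len - i + 1}.
#' Per position: Watson-Crick pair 0, G:U wobble 0.5, mismatch 1.0; the
#' penalty (not the counts) is doubled in the 5' core, positions 2-13.
#'
#' @param mirna miRNA sequence (DNA or RNA alphabet)
#' @param site equal-length target site, transcript sense, 5' to 3'
#' @param core positions with doubled penalties (default 2:13)
#' @return list with \code{penalty}, \code{mismatches}, \code{gu_pairs}
#' @examples
#' score_duplex("TGACCTGAAA", revcomp("TGACCTGAAA"))  # penalty 0
#' @export
score_duplex <- function(mirna, site, core = 2:13) {
  mirna <- normalize_seq(mirna)
  site <- normalize_seq(site)
  m <- nchar(mirna)
  if (m != nchar(site)) stop("score_duplex: miRNA and site must have equal length")
  mb <- strsplit(mirna, "")[[1]]
  sb <- rev(strsplit(site, "")[[1]])          # sb[i] faces miRNA position i
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wc <- sb == comp[mb]
  gu <- (mb == "G" & sb == "T") | (mb == "T" & sb == "G")
  mm <- !wc & !gu
  per_pos <- ifelse(wc, 0, ifelse(gu, 0.5, 1.0))
  dbl <- seq_len(m) %in% core
  list(penalty = sum(per_pos * ifelse(dbl, 2, 1)),
       mismatches = sum(mm), gu_pairs = sum(gu))
}

#' Scan transcripts for miRNA target sites
#'
#' Slides the miRNA along every transcript (ungapped) and keeps windows with
#' at most \code{max_mismatch} mismatches and Allen penalty at most
#' \code{max_penalty}.  G:U wobble pairs are counted separately from
#' mismatches by default; set \code{gu_as_mismatch} to fold them into the
#' mismatch count.
#'
#' @param mirna miRNA sequence, 18-26 nt
#' @param transcripts named character vector or data.frame (\code{id},
#'   \code{seq}) of transcript sequences
#' @param max_mismatch maximum mismatches per site (default 3, i.e. "fewer
#'   than four")
#' @param max_penalty maximum Allen penalty (default 4.0)
#' @param gu_as_mismatch count G:U pairs as mismatches (default FALSE)
#' @param mirna_id label used in the output (default \code{"mirna"})
#' @return data.frame of hits sorted by (penalty, transcript, position):
#'   \code{mirna_id}, \code{transcript_id}, \code{start} (1-based),
#'   \code{mismatches}, \code{gu_pairs}, \code{penalty}, \code{site},
#'   \code{mirna_aligned}, \code{site_aligned}
#' @export
scan_targets <- function(mirna, transcripts, max_mismatch = 3,
                         max_penalty = 4.0, gu_as_mismatch = FALSE,
                         mirna_id = "mirna") {
  mirna <- normalize_seq(mirna)
  m <- nchar(mirna)
  if (m < 18 || m > 26) stop("scan_targets: miRNA must be 18-26 nt")
  if (is.data.frame(transcripts)) {
    tx <- setNames(transcripts$seq, transcripts$id)
  } else {
    tx <- transcripts
    if (is.null(names(tx))) names(tx) <- sprintf("tx_%d", seq_along(tx))
  }
  if (length(tx) == 0) stop("scan_targets: no transcripts")
  tx <- normalize_seq(tx)

  mb <- strsplit(mirna, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  core <- 2:13
  hits <- list()
  for (tid in names(tx)) {
    s <- tx[[tid]]
    L <- nchar(s)
    if (L < m) next
    starts <- seq_len(L - m + 1)
    ## site base faced by miRNA position i is at window offset m - i
    chars <- matrix(strsplit(s, "")[[1]][outer(starts - 1, m:1, "+")],
                    nrow = length(starts))
    wc <- sweep(chars, 2, comp[mb], "==")
    gu <- sweep(chars, 2, mb == "G", function(cc, g) g & cc == "T") |
          sweep(chars, 2, mb == "T", function(cc, g) g & cc == "G")
    mm <- !wc & !gu
    per_pos <- matrix(0, nrow(mm), m)
    per_pos[gu] <- 0.5
    per_pos[mm] <- 1.0
    w <- ifelse(seq_len(m) %in% core, 2, 1)
    penalty <- as.numeric(per_pos %*% w)
    mismatches <- rowSums(mm) + if (gu_as_mismatch) rowSums(gu) else 0
    keep <- mismatches <= max_mismatch & penalty <= max_penalty
    if (!any(keep)) next
    idx <- which(keep)
    site <- substr(rep(s, length(idx)), starts[idx], starts[idx] + m - 1)
    hits[[tid]] <- data.frame(
      mirna_id = mirna_id, transcript_id = tid, start = starts[idx],
      mismatches = as.integer(mismatches[idx]), gu_pairs = as.integer(rowSums(gu)[idx]),
      penalty = penalty[idx], site = site,
      stringsAsFactors = FALSE
    )
  }
  if (length(hits) == 0) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), mismatches = integer(0),
                      gu_pairs = integer(0), penalty = numeric(0),
                      site = character(0), mirna_aligned = character(0),
                      site_aligned = character(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$penalty, out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  ## aligned strings: miRNA 5'->3' over the reversed site
  out$mirna_aligned <- mirna
  out$site_aligned <- stringi::stri_reverse(out$site)
  out
}
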