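## Read cleaning and tag collapsing.
##
## A raw read is assigned to exactly one category, checked in a fixed
## precedence order (mirroring the cleaning-ledger row order):
##   low quality -> 3' adapter null -> 5' adapter contaminant ->
##   insert null -> shorter than min_len -> poly(A) -> clean.

CLEAN_CATEGORIES <- c("low_quality", "adapter3_null", "adapter5_contaminant",
                      "insert_null", "shorter_than_18", "polyA", "clean")

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Sanger Phred+33)
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with \code{id}, \code{seq} and optionally
#'   \code{qual}; missing qualities are written as constant \code{"I"}
#'   (Phred 40)
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(qual)
  )
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, filepath = path)
  invisible(path)
}

## fraction of bases below a Phred threshold, per read (Phred+33)
low_qual_fraction <- function(qual, phred_min = 20) {
  if (length(qual) == 0) return(numeric(0))
  scores <- lapply(stringi::stri_enc_toutf32(qual), function(v) v - 33L)
  vapply(scores, function(v) mean(v < phred_min), numeric(1))
}

#' Clean raw small RNA reads
#'
#' Trims the 3' sequencing adapter and assigns every read to exactly one
#' cleaning category.  The 3' adapter is located by an exact match of its
#' first \code{adapter_seed} nt, taking the rightmost occurrence; a read
#' without such a match is "3' adapter null".  A read containing the first
#' \code{adapter_seed} nt of the 5' adapter is a 5' adapter contaminant
#' (adapter dimer or mispriming).  An empty trimmed insert is "insert null";
#' inserts shorter than \code{min_len} are tallied separately; inserts whose
#' base composition is at least 80\% A are poly(A) artifacts.  A read is low
#' quality if it contains an N or if at least \code{max_low_qual_frac} of its
#' bases fall below Phred \code{phred_min} (only when qualities are present).
#'
#' @param reads data.frame with \code{seq} and optionally \code{qual}
#'   (as from \code{\link{read_fastq}})
#' @param adapter3 3' adapter sequence (required, >= \code{adapter_seed} nt)
#' @param adapter5 5' adapter sequence (optional; \code{NULL} disables the
#'   contaminant check)
#' @param min_len,max_len insert length bounds for clean reads (18-30 nt)
#' @param adapter_seed number of adapter prefix bases that must match (8)
#' @param phred_min,max_low_qual_frac quality-filter parameters
#' @param polyA_frac minimum A fraction for the poly(A) category (0.8)
#' @return list with
#'   \item{clean}{data.frame of clean inserts (\code{seq} column)}
#'   \item{summary}{one-row cleaning ledger (\code{total_reads},
#'     \code{high_quality}, one column per removal category,
#'     \code{clean_total})}
#'   \item{category}{per-read category vector, in input order}
#' @export
clean_reads <- function(reads, adapter3, adapter5 = NULL,
                        min_len = 18, max_len = 30, adapter_seed = 8,
                        phred_min = 20, max_low_qual_frac = 0.1,
                        polyA_frac = 0.8) {
  if (is.null(adapter3) || !nzchar(adapter3)) stop("clean_reads: adapter3 is required")
  adapter3 <- normalize_seq(adapter3)
  if (nchar(adapter3) < adapter_seed) stop("clean_reads: adapter3 shorter than adapter_seed")
  seed3 <- substr(adapter3, 1, adapter_seed)
  seed5 <- if (!is.null(adapter5) && nzchar(adapter5)) {
    substr(normalize_seq(adapter5), 1, adapter_seed)
  } else NULL

  n <- nrow(reads)
  if (n == 0) {
    summary <- as.data.frame(as.list(setNames(rep(0L, 9),
      c("total_reads", "high_quality", "adapter3_null", "adapter5_contaminant",
        "insert_null", "shorter_than_18", "polyA", "clean_total", "removed_total"))))
    return(list(clean = data.frame(seq = character(0)), summary = summary,
                category = character(0)))
  }

  seqs <- normalize_seq(reads$seq)
  category <- rep(NA_character_, n)

  ## 1. quality
  bad <- stringi::stri_detect_fixed(seqs, "N")
  nonacgt <- stringi::stri_detect_regex(seqs, "[^ACGTN]")
  if (any(nonacgt)) {
    warning("clean_reads: reads with non-ACGTN characters rejected as low quality")
    bad <- bad | nonacgt
  }
  if ("qual" %in% names(reads) && !all(is.na(reads$qual))) {
    bad <- bad | low_qual_fraction(reads$qual, phred_min) >= max_low_qual_frac
  }
  category[bad] <- "low_quality"
  todo <- which(is.na(category))

  ## 2. 3' adapter: rightmost exact occurrence of the adapter seed
  pos3 <- stringi::stri_locate_last_fixed(seqs[todo], seed3)[, 1]
  category[todo[is.na(pos3)]] <- "adapter3_null"
  insert <- rep(NA_character_, n)
  hit <- !is.na(pos3)
  insert[todo[hit]] <- substr(seqs[todo[hit]], 1L, pos3[hit] - 1L)
  todo <- which(is.na(category))

  ## 3. 5' adapter contaminant: 5' adapter seed detected anywhere in the read
  if (!is.null(seed5)) {
    has5 <- stringi::stri_detect_fixed(seqs[todo], seed5)
    category[todo[has5]] <- "adapter5_contaminant"
    todo <- which(is.na(category))
  }

  ## 4. insert null / 5. too short / oversized
  len <- nchar(insert[todo])
  category[todo[len == 0]] <- "insert_null"
  category[todo[len > 0 & len < min_len]] <- "shorter_than_18"
  category[todo[len > max_len]] <- "adapter3_null" # no usable small RNA insert
  todo <- which(is.na(category))

  ## 6. poly(A)
  a_frac <- stringi::stri_count_fixed(insert[todo], "A") / nchar(insert[todo])
  category[todo[a_frac >= polyA_frac]] <- "polyA"

  ## 7. clean
  category[is.na(category)] <- "clean"

  tab <- table(factor(category, levels = CLEAN_CATEGORIES))
  high_quality <- n - as.integer(tab[["low_quality"]])
  removed <- sum(tab[c("adapter3_null", "adapter5_contaminant", "insert_null",
                       "shorter_than_18", "polyA")])
  summary <- data.frame(
    total_reads = n,
    high_quality = high_quality,
    adapter3_null = as.integer(tab[["adapter3_null"]]),
    adapter5_contaminant = as.integer(tab[["adapter5_contaminant"]]),
    insert_null = as.integer(tab[["insert_null"]]),
    shorter_than_18 = as.integer(tab[["shorter_than_18"]]),
    polyA = as.integer(tab[["polyA"]]),
    clean_total = as.integer(tab[["clean"]]),
    removed_total = as.integer(removed)
  )
  stopifnot(summary$clean_total == summary$high_quality - summary$removed_total)
  list(clean = data.frame(seq = insert[category == "clean"],
                          stringsAsFactors = FALSE),
       summary = summary, category = category)
}

#' Collapse clean reads into unique tags
#'
#' @param clean data.frame of clean reads (\code{seq} column) or a character
#'   vector of sequences
#' @return data.frame with \code{seq} and \code{count}, ordered by
#'   decreasing count then sequence; \code{sum(count)} equals the number of
#'   input reads (redundant total) and \code{nrow} is the unique total
#' @export
collapse_tags <- function(clean) {
  seqs <- if (is.data.frame(clean)) clean$seq else clean
  if (length(seqs) == 0) {
    return(data.frame(seq = character(0), count = integer(0)))
  }
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length distribution of a tag set
#'
#' @param tags data.frame with \code{seq} and \code{count}
#' @param weighted if \code{TRUE}, fractions are weighted by redundant read
#'   counts; otherwise each unique tag counts once
#' @param lengths lengths to report (default 18:30)
#' @return data.frame with \code{length}, \code{count}, \code{fraction};
#'   fractions sum to 1 over tags whose length falls in \code{lengths}
#' @export
length_histogram <- function(tags, weighted = TRUE, lengths = 18:30) {
  if (nrow(tags) == 0) stop("length_histogram: empty tag set")
  len <- nchar(tags$seq)
  w <- if (weighted) tags$count else rep(1L, nrow(tags))
  counts <- vapply(lengths, function(L) sum(w[len == L]), numeric(1))
  total <- sum(counts)
  if (total == 0) stop("length_histogram: no tags within the length range")
  data.frame(length = lengths, count = counts, fraction = counts / total)
}

#' Common and library-specific tag statistics
#'
#' For two tag sets cleaned with the same parameters, tallies unique and
#' redundant counts for the classes all / common / A-specific / B-specific
#' and their mean frequencies (redundant total divided by unique total).
#' Common-class redundant counts include reads from both libraries.
#'
#' @param tags_a,tags_b tag data.frames (\code{seq}, \code{count})
#' @param labels class label prefixes for the two libraries
#' @return data.frame with \code{class}, \code{unique}, \code{redundant},
#'   \code{mean_frequency} (2 decimals reported by the pipeline; full
#'   precision here)
#' @export
overlap_stats <- function(tags_a, tags_b, labels = c("A", "B")) {
  common <- intersect(tags_a$seq, tags_b$seq)
  a_only <- setdiff(tags_a$seq, common)
  b_only <- setdiff(tags_b$seq, common)
  ca <- setNames(tags_a$count, tags_a$seq)
  cb <- setNames(tags_b$count, tags_b$seq)
  red_common <- sum(ca[common]) + sum(cb[common])
  red_a <- sum(ca[a_only])
  red_b <- sum(cb[b_only])
  uniq <- c(length(common) + length(a_only) + length(b_only),
            length(common), length(a_only), length(b_only))
  red <- c(red_common + red_a + red_b, red_common, red_a, red_b)
  data.frame(
    class = c("total", "common", paste0(labels[1], "_specific"),
              paste0(labels[2], "_specific")),
    unique = uniq, redundant = red,
    mean_frequency = ifelse(uniq > 0, red / uniq, 0),
    stringsAsFactors = FALSE
  )
}
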