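## Classification of unique tags into ncRNA classes and known miRNAs.

NC_CLASSES <- c("rRNA", "snRNA", "snoRNA", "tRNA")
DEFAULT_PRECEDENCE <- c(NC_CLASSES, "mature_miRNA")

#' Read an annotation reference FASTA
#'
#' Headers follow \code{>id|family|class}; \code{family} may be empty for
#' ncRNA classes.  Sequences are normalized to uppercase DNA (U to T).
#'
#' @param path FASTA file
#' @return data.frame with \code{id}, \code{family}, \code{class}, \code{seq}
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- stringi::stri_split_fixed(names(x), "|", simplify = TRUE)
  if (ncol(parts) < 3) stop("read_reference_fasta: headers must be id|family|class")
  if (anyDuplicated(parts[, 1])) stop("read_reference_fasta: duplicate reference ids")
  data.frame(id = unname(parts[, 1]), family = unname(parts[, 2]),
             class = unname(parts[, 3]),
             seq = unname(normalize_seq(as.character(x))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an annotation reference FASTA
#'
#' @param refs data.frame as from \code{\link{read_reference_fasta}}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_reference_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(refs$seq)
  names(x) <- sprintf("%s|%s|%s", refs$id, refs$family, refs$class)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

## does each tag occur as a substring of any reference sequence (either
## strand)?  References are concatenated with a separator so one fixed-text
## search per tag suffices.
tags_in_refs <- function(tags, ref_seqs) {
  if (length(ref_seqs) == 0) return(rep(FALSE, length(tags)))
  hay <- paste(c(ref_seqs, revcomp(ref_seqs)), collapse = "#")
  stringi::stri_detect_fixed(rep(hay, length(tags)), tags)
}

#' Classify unique tags against ncRNA and miRNA references
#'
#' Each tag receives exactly one class: the first class in
#' \code{precedence} it matches, or \code{"unannotated"}.  ncRNA classes
#' match by substring containment in any reference of the class (either
#' strand) since reads are degradation fragments of long ncRNAs;
#' \code{mature_miRNA} matches by exact full-length identity.
#'
#' @param tags data.frame with \code{seq} and count columns (any columns
#'   whose name starts with \code{count} are tallied as redundant reads)
#' @param references data.frame from \code{\link{read_reference_fasta}}
#' @param precedence class order; default rRNA, snRNA, snoRNA, tRNA,
#'   mature_miRNA
#' @return list with
#'   \item{assignments}{\code{tags} plus a \code{class} column}
#'   \item{tally}{per-class unique/redundant counts and percentages}
#' @export
classify_tags <- function(tags, references,
                          precedence = DEFAULT_PRECEDENCE) {
  cls <- rep("unannotated", nrow(tags))
  if (nrow(references) == 0) {
    warning("classify_tags: empty reference set; all tags unannotated")
  } else {
    todo <- rep(TRUE, nrow(tags))
    for (p in precedence) {
      refs <- references$seq[references$class == p]
      if (length(refs) == 0 || !any(todo)) next
      hit <- if (p == "mature_miRNA") {
        tags$seq[todo] %in% refs
      } else {
        tags_in_refs(tags$seq[todo], refs)
      }
      idx <- which(todo)[hit]
      cls[idx] <- p
      todo[idx] <- FALSE
    }
  }
  count_cols <- grep("^count", names(tags), value = TRUE)
  red <- if (length(count_cols)) rowSums(tags[, count_cols, drop = FALSE]) else
    rep(1, nrow(tags))
  lev <- c(precedence, "unannotated")
  f <- factor(cls, levels = lev)
  tally <- data.frame(
    class = lev,
    unique = as.integer(table(f)),
    redundant = as.numeric(tapply(red, f, sum, default = 0))
  )
  tally$unique_pct <- if (nrow(tags)) 100 * tally$unique / nrow(tags) else 0
  tally$redundant_pct <- if (sum(red) > 0) 100 * tally$redundant / sum(red) else 0
  assignments <- tags
  assignments$class <- cls
  list(assignments = assignments, tally = tally)
}

#' Match tags against mature miRNA references
#'
#' A known-miRNA hit is an exact, full-length identity between a tag and a
#' mature reference sequence.  Multiple reference ids sharing one sequence
#' all report a hit (with a warning).
#'
#' @param tags data.frame with \code{seq} and per-library count columns
#' @param mature data.frame of mature references (\code{id}, \code{family},
#'   \code{seq})
#' @return data.frame of hits: \code{mirna_id}, \code{family_id}, \code{seq}
#'   and the tag count columns
#' @export
match_known_mirnas <- function(tags, mature) {
  if (nrow(mature) == 0) stop("match_known_mirnas: empty mature reference set")
  mature$seq <- normalize_seq(mature$seq)
  if (anyDuplicated(mature$seq)) {
    warning("match_known_mirnas: duplicate mature sequences with different ids; all reported")
  }
  idx <- match(mature$seq, tags$seq)
  hit <- !is.na(idx)
  out <- data.frame(mirna_id = mature$id[hit],
                    family_id = mature$family[hit],
                    seq = mature$seq[hit],
                    stringsAsFactors = FALSE)
  count_cols <- grep("^count", names(tags), value = TRUE)
  for (cc in count_cols) out[[cc]] <- tags[[cc]][idx[hit]]
  out
}

## strip -3p/-5p arm suffixes: family members are counted per locus name,
## and the two arms of one precursor are a single member
strip_arm <- function(id) sub("-[35]p$", "", id)

#' Per-family member counts and read totals
#'
#' Member count is the number of distinct miRNA names per family after
#' removing \code{-3p}/\code{-5p} arm suffixes (the two arms of one hairpin
#' are one member); read totals sum the per-library counts over all hits of
#' the family.
#'
#' @param hits data.frame from \code{\link{match_known_mirnas}}
#' @return data.frame with \code{family_id}, \code{members} and one
#'   \code{total_*} column per count column
#' @export
family_summary <- function(hits) {
  count_cols <- grep("^count", names(hits), value = TRUE)
  fams <- sort(unique(hits$family_id))
  out <- data.frame(family_id = fams, stringsAsFactors = FALSE)
  out$members <- vapply(fams, function(f) {
    length(unique(strip_arm(hits$mirna_id[hits$family_id == f])))
  }, integer(1))
  for (cc in count_cols) {
    out[[sub("^count", "total", cc)]] <- vapply(fams, function(f) {
      sum(hits[[cc]][hits$family_id == f])
    }, numeric(1))
  }
  out
}
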