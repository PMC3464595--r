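## Novel miRNA discovery: map unannotated tags to the genome, fold the
## flanking windows, and apply duplex / star / MFE acceptance criteria.

#' Map tags to a genome by exact full-length matching
#'
#' Tags are matched on both strands.  Minus-strand coordinates refer to the
#' plus strand (0-based, half-open); the genomic substring at a minus-strand
#' locus reverse-complements to the tag.  Tags hitting more than
#' \code{max_loci} positions are dropped as repeats.
#'
#' @param tags character vector of tag sequences (or data.frame with
#'   \code{seq})
#' @param genome named character vector of scaffold sequences, or a
#'   \code{DNAStringSet}
#' @param max_loci repeat filter (default 20)
#' @return data.frame with \code{tag}, \code{scaffold}, \code{start},
#'   \code{end}, \code{strand}
#' @export
map_to_genome <- function(tags, genome, max_loci = 20) {
  seqs <- unique(if (is.data.frame(tags)) tags$seq else tags)
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  gset <- Biostrings::DNAStringSet(genome)
  empty <- data.frame(tag = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  if (length(seqs) == 0) return(empty)

  res <- list()
  for (w in sort(unique(nchar(seqs)))) {
    sub <- seqs[nchar(seqs) == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    for (sc in seq_along(gset)) {
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") gset[[sc]] else
          Biostrings::reverseComplement(gset[[sc]])
        m <- Biostrings::matchPDict(pd, subject)
        counts <- S4Vectors::elementNROWS(m)
        hit <- which(counts > 0)
        if (length(hit) == 0) next
        for (h in hit) {
          st <- BiocGenerics::start(m[[h]])
          if (strand == "-") {
            L <- length(subject)
            st <- L - (st + w - 1) + 1   # 1-based start on the plus strand
          }
          res[[length(res) + 1]] <- data.frame(
            tag = sub[h], scaffold = names(genome)[sc],
            start = st - 1L, end = st - 1L + w, strand = strand
          )
        }
      }
    }
  }
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  n_loci <- table(out$tag)
  out <- out[out$tag %in% names(n_loci)[n_loci <= max_loci], , drop = FALSE]
  out <- out[order(out$tag, out$scaffold, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the two candidate precursor windows around a mapped tag
#'
#' Window A extends \code{flank} nt downstream of the tag (plus 20 nt
#' upstream), window B the reverse, so a hairpin is captured whichever arm
#' the tag sits on.  Windows are clipped at scaffold edges.  Coordinates are
#' 0-based half-open on the plus strand; for minus-strand loci the returned
#' sequences are reverse-complemented so the tag always appears in sense.
#'
#' @param locus one row of \code{\link{map_to_genome}} output
#' @param genome named character vector of scaffolds
#' @param flank flank length in nt (default 250)
#' @return list of two window records (\code{seq}, \code{start}, \code{end},
#'   \code{tag_start} 1-based position of the tag within \code{seq})
#' @export
extract_windows <- function(locus, genome, flank = 250) {
  s <- genome[[locus$scaffold]]
  L <- nchar(s)
  mk <- function(up, down) {
    if (locus$strand == "-") { tmp <- up; up <- down; down <- tmp }
    a <- max(0L, locus$start - up)
    b <- min(L, locus$end + down)
    seq <- substr(s, a + 1L, b)
    if (locus$strand == "-") {
      seq <- revcomp(seq)
      tag_start <- b - locus$end + 1L
    } else {
      tag_start <- locus$start - a + 1L
    }
    list(seq = seq, start = a, end = b, tag_start = tag_start)
  }
  list(A = mk(20L, flank), B = mk(flank, 20L))
}

hairpin_thresholds <- function(mfe_max = -18, max_mismatch = 4,
                               max_bulge = 2, min_hairpin_len = 50,
                               min_mature_count = 5, flank = 250,
                               max_loci = 20) {
  list(mfe_max = mfe_max, max_mismatch = max_mismatch, max_bulge = max_bulge,
       min_hairpin_len = min_hairpin_len, min_mature_count = min_mature_count,
       flank = flank, max_loci = max_loci)
}

## nearest paired position to i within [lo, hi]; NA if none
nearest_paired <- function(pairs, i, lo, hi) {
  cand <- lo:hi
  cand <- cand[!is.na(pairs[cand])]
  if (length(cand) == 0) return(NA_integer_)
  cand[which.min(abs(cand - i))]
}

#' Evaluate a candidate precursor window
#'
#' Applies the stem-loop acceptance criteria to a folded window containing a
#' mapped tag (the putative mature): (a) the mature lies wholly on one arm
#' of the stem, outside the terminal loop; (b) the star sequence implied by
#' a duplex with 2-nt 3' overhangs on both strands exists in the tag set
#' with at least one read; (c) the mature/star duplex has at most
#' \code{max_mismatch} unpaired mature positions and no asymmetric bulge
#' larger than \code{max_bulge} nt; (d) the window MFE is at most
#' \code{mfe_max} kcal/mol under the package's folding model; (e) the
#' precursor trimmed to the minimal hairpin containing the duplex is at
#' least \code{min_hairpin_len} nt.  Rejection reasons are machine-readable
#' strings; rejection is a result, not an error.
#'
#' @param window a window record from \code{\link{extract_windows}}
#' @param tag the mature tag sequence
#' @param tag_counts named numeric vector: read count per tag sequence
#'   (both libraries combined)
#' @param fold_result optional precomputed \code{\link{fold}} of
#'   \code{window$seq}
#' @param thresholds list from \code{hairpin_thresholds()}
#' @return list of class \code{hairpin_candidate}: \code{accepted},
#'   \code{reasons}, \code{arm}, \code{mature}, \code{mature_count},
#'   \code{star}, \code{star_count}, \code{mfe}, \code{structure},
#'   \code{precursor}, \code{precursor_start}, \code{precursor_end}
#'   (1-based within the window), \code{mismatches}
#' @export
evaluate_candidate <- function(window, tag, tag_counts,
                               fold_result = NULL,
                               thresholds = hairpin_thresholds()) {
  th <- thresholds
  m <- nchar(tag)
  ms <- window$tag_start
  me <- ms + m - 1L
  if (is.null(fold_result)) fold_result <- fold(window$seq)
  pairs <- fold_result$pairs
  reasons <- character(0)
  arm <- NA_character_
  star <- NA_character_; star_count <- 0
  mismatches <- NA_integer_
  hp_lo <- hp_hi <- NA_integer_

  partners <- pairs[ms:me]
  paired <- which(!is.na(partners))
  if (length(paired) == 0) {
    reasons <- c(reasons, "mature not on a stem")
  } else {
    pp <- partners[paired]
    if (all(pp > me)) arm <- "5p"
    else if (all(pp < ms)) arm <- "3p"
    else reasons <- c(reasons, "mature spans the terminal loop")
  }

  if (!is.na(arm)) {
    ## extrapolate star span from nearest paired positions (2-nt 3'
    ## overhangs on both strands)
    j1 <- nearest_paired(pairs, me - 2L, ms, me)
    j2 <- nearest_paired(pairs, ms, ms, me)
    p_me2 <- pairs[j1] - ((me - 2L) - j1)
    p_ms <- pairs[j2] + (j2 - ms)
    star_beg <- min(p_me2, p_ms + 2L)
    star_end <- max(p_me2, p_ms + 2L)
    if (star_beg < 1 || star_end > nchar(window$seq)) {
      reasons <- c(reasons, "star outside window")
    } else if (star_beg <= me && star_end >= ms) {
      reasons <- c(reasons, "star overlaps mature")
    } else {
      star <- substr(window$seq, star_beg, star_end)
      star_count <- if (star %in% names(tag_counts)) tag_counts[[star]] else 0
      if (star_count < 1) reasons <- c(reasons, "no miRNA* read support")

      ## duplex geometry: mismatches and bulges over the paired core
      duplex_pos <- ms:(me - 2L)
      in_star <- function(p) !is.na(p) & p >= star_beg & p <= star_end
      ok_pair <- in_star(pairs[duplex_pos])
      mismatches <- sum(!ok_pair)
      if (mismatches > th$max_mismatch) {
        reasons <- c(reasons, sprintf("duplex has %d mismatches (max %d)",
                                      mismatches, th$max_mismatch))
      }
      anchored <- duplex_pos[ok_pair]
      if (length(anchored) >= 2) {
        gaps_m <- diff(anchored) - 1L
        gaps_s <- abs(diff(pairs[anchored])) - 1L
        if (any(abs(gaps_m - gaps_s) > th$max_bulge)) {
          reasons <- c(reasons, sprintf("asymmetric bulge > %d nt", th$max_bulge))
        }
      }
      hp_lo <- min(ms, star_beg)
      hp_hi <- max(me, star_end)
      if (hp_hi - hp_lo + 1L < th$min_hairpin_len) {
        reasons <- c(reasons, sprintf("hairpin shorter than %d nt",
                                      th$min_hairpin_len))
      }
    }
  }

  if (fold_result$mfe > th$mfe_max) {
    reasons <- c(reasons, sprintf("MFE above threshold %g kcal/mol", th$mfe_max))
  }

  out <- list(
    accepted = length(reasons) == 0,
    reasons = reasons,
    arm = arm,
    mature = tag,
    mature_count = if (tag %in% names(tag_counts)) tag_counts[[tag]] else 0,
    star = star, star_count = star_count,
    mfe = fold_result$mfe, structure = fold_result$structure,
    precursor = if (!is.na(hp_lo)) substr(window$seq, hp_lo, hp_hi) else NA_character_,
    precursor_start = hp_lo, precursor_end = hp_hi,
    mismatches = mismatches
  )
  class(out) <- "hairpin_candidate"
  out
}

#' Discover novel miRNA hairpins from unannotated tags
#'
#' Maps tags with at least \code{min_mature_count} reads to the genome,
#' folds both flanking windows of each locus, evaluates the acceptance
#' criteria, and reports one row per locus (taking the accepted window, or
#' window A if both fail).  Overlapping accepted loci on the same strand are
#' clustered and the highest-count mature kept as the representative, so one
#' hairpin supported by both its mature and star tags is reported once.
#'
#' @param tags data.frame of unannotated tags with \code{seq} and count
#'   columns (summed for abundance)
#' @param genome named character vector of scaffolds
#' @param thresholds list from \code{hairpin_thresholds()}
#' @return data.frame with one row per candidate locus: location, arm,
#'   mature/star sequences and counts, precursor length, MFE, verdict and
#'   reasons; plus attribute \code{"clusters"} giving the representative
#'   accepted loci after clustering
#' @export
predict_hairpins <- function(tags, genome, thresholds = hairpin_thresholds()) {
  count_cols <- grep("^count", names(tags), value = TRUE)
  total <- if (length(count_cols)) rowSums(tags[, count_cols, drop = FALSE]) else
    rep(1, nrow(tags))
  tag_counts <- setNames(total, tags$seq)
  cand_tags <- tags$seq[total >= thresholds$min_mature_count]
  loci <- map_to_genome(cand_tags, genome, max_loci = thresholds$max_loci)
  ## candidate precursors are excised at several extents: a hairpin embedded
  ## in a long window can be masked by flanking co-folding, so shorter
  ## excisions are tried first and the first clean duplex wins
  flank_steps <- sort(unique(pmin(thresholds$flank, c(30, 80, 150, thresholds$flank))))
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    ev <- w <- NULL
    for (fl in flank_steps) {
      wins <- extract_windows(locus, genome, flank = fl)
      for (side in c("A", "B")) {
        cand <- evaluate_candidate(wins[[side]], locus$tag, tag_counts,
                                   thresholds = thresholds)
        if (is.null(ev)) { ev <- cand; w <- wins[[side]] }
        if (cand$accepted) { ev <- cand; w <- wins[[side]]; break }
      }
      if (ev$accepted) break
    }
    ## precursor genomic coordinates (0-based half-open, plus strand)
    if (!is.na(ev$precursor_start)) {
      if (locus$strand == "+") {
        p_start <- w$start + ev$precursor_start - 1L
        p_end <- w$start + ev$precursor_end
      } else {
        p_start <- w$end - ev$precursor_end
        p_end <- w$end - ev$precursor_start + 1L
      }
    } else {
      p_start <- p_end <- NA_integer_
    }
    rows[[i]] <- data.frame(
      tag = locus$tag, scaffold = locus$scaffold,
      tag_start = locus$start, tag_end = locus$end, strand = locus$strand,
      location = sprintf("%s:%d:%d:%s", locus$scaffold,
                         ifelse(is.na(p_start), locus$start + 1L, p_start + 1L),
                         ifelse(is.na(p_end), locus$end, p_end),
                         locus$strand),
      arm = ev$arm,
      mature_count = ev$mature_count,
      star = ev$star, star_count = ev$star_count,
      precursor_length = ifelse(is.na(ev$precursor), NA_integer_,
                                nchar(ev$precursor)),
      precursor_start = p_start, precursor_end = p_end,
      mfe = ev$mfe,
      accepted = ev$accepted,
      reasons = paste(ev$reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag = character(0), scaffold = character(0),
               tag_start = integer(0), tag_end = integer(0),
               strand = character(0), location = character(0),
               arm = character(0), mature_count = numeric(0),
               star = character(0), star_count = numeric(0),
               precursor_length = integer(0), precursor_start = integer(0),
               precursor_end = integer(0), mfe = numeric(0),
               accepted = logical(0), reasons = character(0))
  rownames(out) <- NULL
  attr(out, "clusters") <- cluster_accepted(out)
  out
}

## cluster accepted candidates whose precursor intervals overlap on the same
## scaffold/strand; keep the highest-count mature as representative
cluster_accepted <- function(cands) {
  acc <- cands[cands$accepted, , drop = FALSE]
  if (nrow(acc) == 0) return(acc)
  gr <- GenomicRanges::GRanges(acc$scaffold,
                               IRanges::IRanges(acc$precursor_start + 1,
                                                acc$precursor_end),
                               strand = acc$strand)
  cl <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr))
  acc$cluster <- S4Vectors::subjectHits(cl)
  keep <- unlist(lapply(split(seq_len(nrow(acc)), acc$cluster), function(ii) {
    ii[which.max(acc$mature_count[ii])]
  }))
  out <- acc[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' First-nucleotide bias of candidate matures by length
#'
#' @param matures character vector of mature sequences (DNA or RNA)
#' @return data.frame with \code{length}, \code{base} (A/C/G/U),
#'   \code{count}, \code{fraction}; fractions sum to 1 within each length
#' @export
first_nt_bias <- function(matures) {
  if (length(matures) == 0) {
    return(data.frame(length = integer(0), base = character(0),
                      count = integer(0), fraction = numeric(0)))
  }
  matures <- normalize_seq(matures)
  len <- nchar(matures)
  first <- chartr("T", "U", substr(matures, 1, 1))
  bases <- c("A", "C", "G", "U")
  out <- do.call(rbind, lapply(sort(unique(len)), function(L) {
    f <- first[len == L]
    counts <- vapply(bases, function(b) sum(f == b), integer(1))
    data.frame(length = L, base = bases, count = counts,
               fraction = counts / sum(counts))
  }))
  rownames(out) <- NULL
  out
}
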