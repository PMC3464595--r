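## Synthetic small RNA study generator: a genome with planted miRNA
## hairpins, ncRNA/mature-miRNA reference sets, and two condition libraries
## (here called "perfect" and "imperfect" after the flower-bud phenotypes
## they emulate) with complete ground truth.

## draw random sequences that avoid the adapter seed k-mers, so that every
## cleaning category stays unambiguous and truth round-trips exactly
random_dna_avoid <- function(n, len, forbidden) {
  if (n == 0) return(character(0))
  out <- character(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    cand <- vapply(todo, function(i) {
      paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    }, character(1))
    bad <- Reduce(`|`, lapply(forbidden, function(f) {
      stringi::stri_detect_fixed(cand, f)
    }), rep(FALSE, length(cand)))
    out[todo[!bad]] <- cand[!bad]
    todo <- todo[bad]
  }
  out
}

## default per-condition insert length distributions over 18-28 nt, peaked
## at 21 and 24 nt as in typical plant flower-bud libraries (the 24-nt
## heterochromatic siRNA class dominates the perfect-bud library, the 21-nt
## miRNA class the imperfect one)
default_length_probs <- function() {
  lens <- 18:28
  perfect <- c(0.01, 0.03, 0.07, 0.28, 0.08, 0.06, 0.40, 0.04, 0.02, 0.005, 0.005)
  imperfect <- c(0.01, 0.04, 0.08, 0.32, 0.10, 0.07, 0.31, 0.04, 0.02, 0.005, 0.005)
  list(perfect = setNames(perfect, lens), imperfect = setNames(imperfect, lens))
}

## 61 mature miRNAs in 24 families with member counts 8/6/5 for the first
## three families; abundances follow a geometric rank profile floored at 5
default_known_plan <- function() {
  members <- c(8, 6, 5, rep(3, 7), rep(2, 7), rep(1, 7))
  stopifnot(sum(members) == 61, length(members) == 24)
  fam <- rep(sprintf("MIR%03d", seq_along(members)), members)
  idx <- unlist(lapply(members, seq_len))
  id <- sprintf("%s-%s", tolower(sub("MIR", "mir", fam)), letters[idx])
  ab <- pmax(5, round(1500 * 0.85^(seq_along(fam) - 1)))
  plan <- data.frame(id = id, family = fam,
                     abundance_perfect = ab, abundance_imperfect = ab,
                     planted_fold = 1, stringsAsFactors = FALSE)
  ## three ~3-fold differential miRNAs (two up, one down in "imperfect")
  plan$abundance_imperfect[5] <- plan$abundance_perfect[5] * 3
  plan$planted_fold[5] <- 3
  plan$abundance_imperfect[12] <- plan$abundance_perfect[12] * 3
  plan$planted_fold[12] <- 3
  plan$abundance_imperfect[3] <- round(plan$abundance_perfect[3] / 3)
  plan$planted_fold[3] <- 1 / 3
  ## two condition-specific miRNAs
  plan$abundance_imperfect[20] <- 0
  plan$planted_fold[20] <- 0
  plan$abundance_perfect[24] <- 0
  plan$planted_fold[24] <- Inf
  plan
}

#' Build a simulation specification
#'
#' The defaults define the study conditions every test runs under: two
#' libraries of 1e5 reads, fixed 36-nt reads with 3' adapter read-through,
#' 61 planted known miRNAs in 24 families (three of them at a planted
#' 3-fold differential, two condition-specific), five planted novel miRNA
#' hairpins with star reads at 2 percent of the mature abundance, an ncRNA
#' fragment background, and contaminant classes at the per-mille rates
#' typical of a well-behaved sequencing run.
#'
#' @param seed integer seed; identical seeds give byte-identical outputs
#' @param n_scaffolds,scaffold_len genome shape (default 2 x 60 kb)
#' @param n_hairpins number of auto-designed novel hairpins (default 5);
#'   ignored when \code{hairpins} is supplied
#' @param hairpins optional data.frame(\code{name}, \code{mature},
#'   \code{arm} in \code{c("5p","3p")}, \code{abundance_perfect},
#'   \code{abundance_imperfect}) overriding the auto design.  All planted
#'   abundances are expected reads per 100,000 library reads and scale
#'   linearly with \code{library_depth}
#' @param known optional data.frame like \code{default_known_plan()}
#' @param star_fraction star reads as a fraction of mature abundance (0.02)
#' @param star_mismatches controlled mutations planted into the star side of
#'   each duplex (0-4, default 2): real hairpins are imperfect, and the
#'   mismatches keep mature and star mapping to unique genomic loci instead
#'   of forming an exact inverted repeat
#' @param u5_bias probability that an auto-designed mature starts with U
#' @param ncRNA_fraction expected fraction of clean reads that are ncRNA
#'   fragments (default 0.126, split over rRNA/tRNA/snRNA/snoRNA)
#' @param adapter3,adapter5 adapter sequences
#' @param contamination named rates for \code{adapter3_null},
#'   \code{insert_null}, \code{adapter5_contaminant}, \code{shorter_than_18},
#'   \code{polyA}, \code{low_quality}
#' @param library_depth reads per library (default 1e5)
#' @param read_len fixed read length (default 36)
#' @param length_probs per-condition insert length distributions
#' @return a \code{simulation_spec} list
#' @export
simulation_spec <- function(seed = 1,
                            n_scaffolds = 2, scaffold_len = 60000,
                            n_hairpins = 5, hairpins = NULL, known = NULL,
                            star_fraction = 0.02, star_mismatches = 2,
                            u5_bias = 0.7,
                            ncRNA_fraction = 0.126,
                            adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            contamination = c(adapter3_null = 0.0024,
                                              insert_null = 0.0003,
                                              adapter5_contaminant = 0.0016,
                                              shorter_than_18 = 0.0022,
                                              polyA = 0.0003,
                                              low_quality = 0),
                            library_depth = 1e5,
                            read_len = 36,
                            length_probs = default_length_probs()) {
  stopifnot(seed == round(seed), library_depth >= 0, read_len >= 30)
  if (star_mismatches < 0 || star_mismatches > 4) {
    stop("simulation_spec: star_mismatches must be in 0..4")
  }
  spec <- list(seed = as.integer(seed), n_scaffolds = n_scaffolds,
               scaffold_len = scaffold_len, n_hairpins = n_hairpins,
               hairpins = hairpins, known = known,
               star_fraction = star_fraction,
               star_mismatches = star_mismatches, u5_bias = u5_bias,
               ncRNA_fraction = ncRNA_fraction,
               adapter3 = normalize_seq(adapter3),
               adapter5 = normalize_seq(adapter5),
               contamination = contamination,
               library_depth = library_depth, read_len = read_len,
               length_probs = length_probs)
  class(spec) <- "simulation_spec"
  spec
}

seed_kmers <- function(spec) {
  c(substr(spec$adapter3, 1, 8), substr(spec$adapter5, 1, 8))
}

## design one hairpin precursor with a perfect (or controlled-mismatch)
## mature/star duplex leaving 2-nt 3' overhangs on both strands
design_hairpin <- function(mature, arm, loop_len = 12, star_mismatches = 0,
                           forbidden = character(0)) {
  mature <- normalize_seq(mature)
  m <- nchar(mature)
  if (m < 18 || m > 24) {
    stop("design_hairpin: mature length ", m,
         " nt cannot sit on the stem with 2-nt overhangs (need 18-24 nt)")
  }
  repeat {
    loop <- random_dna_avoid(1, loop_len, forbidden)
    if (arm == "5p") {
      f <- random_dna_avoid(1, 5, forbidden)
      stem5 <- paste0(f, mature)
      pre <- paste0(stem5, loop, revcomp(stem5))
      ms <- 6L
    } else {
      x2 <- random_dna_avoid(1, 2, forbidden)
      x3 <- random_dna_avoid(1, 3, forbidden)
      stem3 <- paste0(x2, mature, x3)
      pre <- paste0(revcomp(stem3), loop, stem3)
      ms <- nchar(pre) - nchar(stem3) + 3L
    }
    me <- ms + m - 1L
    L <- nchar(pre)
    ## perfect-stem pairing: position i pairs L - i + 1; the star span
    ## follows from the 2-nt 3'-overhang rule on both strands
    star_beg <- L - me + 3L
    star_end <- L - ms + 3L
    star <- substr(pre, star_beg, star_end)
    if (star_mismatches > 0) {
      pos <- sort(sample(seq(star_beg + 2, star_end - 2), star_mismatches))
      pb <- strsplit(pre, "")[[1]]
      for (p in pos) pb[p] <- sample(setdiff(DNA_BASES, pb[p]), 1)
      pre <- paste(pb, collapse = "")
      star <- substr(pre, star_beg, star_end)
    }
    ok <- !any(vapply(forbidden, function(f) {
      stringi::stri_detect_fixed(pre, f) ||
        stringi::stri_detect_fixed(revcomp(pre), f)
    }, logical(1)))
    ## a planted hairpin must be recoverable: the precursor has to fold back
    ## to the designed duplex (mutations can otherwise slip the helix into a
    ## shifted register); redraw flanks/loop/mutations until it does
    if (ok) {
      win <- list(seq = pre, start = 0L, end = nchar(pre), tag_start = ms)
      ev <- evaluate_candidate(win, mature,
                               setNames(c(10, 1), c(mature, star)))
      ok <- isTRUE(ev$accepted) && identical(ev$star, star)
    }
    if (ok) break
  }
  list(precursor = pre, mature = mature, star = star, arm = arm,
       mature_start = ms, mature_end = me,
       star_start = star_beg, star_end = star_end)
}

## auto-design n hairpin matures (21-22 nt, 5'-U biased)
auto_hairpin_plan <- function(n, u5_bias, forbidden) {
  if (n == 0) {
    return(data.frame(name = character(0), mature = character(0),
                      arm = character(0), abundance_perfect = numeric(0),
                      abundance_imperfect = numeric(0)))
  }
  lens <- rep(c(21L, 22L), length.out = n)
  mature <- vapply(seq_len(n), function(i) {
    s <- random_dna_avoid(1, lens[i], forbidden)
    if (runif(1) < u5_bias) s <- paste0("T", substr(s, 2, nchar(s)))
    s
  }, character(1))
  ab <- round(seq(300, 60, length.out = n))
  data.frame(name = sprintf("novel_%02d", seq_len(n)), mature = mature,
             arm = rep(c("5p", "3p"), length.out = n),
             abundance_perfect = ab, abundance_imperfect = ab,
             stringsAsFactors = FALSE)
}

#' Generate the synthetic genome with planted hairpin loci
#'
#' Scaffolds are i.i.d. uniform nucleotides; each planted hairpin precursor
#' is written into the genome exactly once at a recorded locus (alternating
#' strands).  The returned truth carries precursor, mature and star
#' coordinates (0-based, half-open).
#'
#' @param spec a \code{\link{simulation_spec}}
#' @return list with
#'   \item{genome}{named character vector of scaffold sequences}
#'   \item{hairpins}{data.frame of planted hairpin designs and coordinates}
#'   \item{loci}{BED-style data.frame (scaffold, start, end, name, strand)
#'     for precursor and mature intervals}
#'   \item{known}{mature miRNA reference plan (id, family, seq, abundances)}
#'   \item{ncrna}{ncRNA reference set (id, class, seq)}
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  forbidden <- seed_kmers(spec)

  genome <- setNames(random_dna_avoid(spec$n_scaffolds, spec$scaffold_len,
                                      forbidden),
                     sprintf("scaffold_%d", seq_len(spec$n_scaffolds)))

  ## ncRNA references (independent of the genome; the classifier sees only
  ## fragments of these)
  ncrna <- rbind(
    data.frame(id = sprintf("rRNA_%d", 1:2), class = "rRNA",
               seq = random_dna_avoid(2, 1200, forbidden)),
    data.frame(id = sprintf("tRNA_%d", 1:4), class = "tRNA",
               seq = random_dna_avoid(4, 75, forbidden)),
    data.frame(id = sprintf("snRNA_%d", 1:3), class = "snRNA",
               seq = random_dna_avoid(3, 150, forbidden)),
    data.frame(id = sprintf("snoRNA_%d", 1:3), class = "snoRNA",
               seq = random_dna_avoid(3, 120, forbidden))
  )

  ## known mature miRNA references
  known <- spec$known
  if (is.null(known)) known <- default_known_plan()
  if (is.null(known$seq)) {
    lens <- rep(c(21L, 21L, 22L, 20L), length.out = nrow(known))
    known$seq <- vapply(seq_len(nrow(known)), function(i) {
      s <- random_dna_avoid(1, lens[i], forbidden)
      if (runif(1) < spec$u5_bias) s <- paste0("T", substr(s, 2, nchar(s)))
      s
    }, character(1))
  }

  ## hairpin designs
  plan <- spec$hairpins
  if (is.null(plan)) plan <- auto_hairpin_plan(spec$n_hairpins, spec$u5_bias,
                                               forbidden)
  n_hp <- nrow(plan)
  designs <- vector("list", n_hp)
  if (n_hp > 0) {
    for (i in seq_len(n_hp)) {
      designs[[i]] <- design_hairpin(plan$mature[i], plan$arm[i],
                                     star_mismatches = spec$star_mismatches,
                                     forbidden = forbidden)
    }
  }

  ## place precursors at non-overlapping, well-spaced positions
  hp <- plan
  hp$precursor <- vapply(designs, function(d) d$precursor, character(1),
                         USE.NAMES = FALSE)
  hp$scaffold <- character(n_hp); hp$start <- integer(n_hp)
  hp$end <- integer(n_hp); hp$strand <- character(n_hp)
  hp$mature_genome_start <- integer(n_hp); hp$mature_genome_end <- integer(n_hp)
  hp$star <- character(n_hp); hp$mature_start <- integer(n_hp)
  hp$mature_end <- integer(n_hp)
  if (n_hp > 0) {
    slots_per <- ceiling(n_hp / spec$n_scaffolds)
    for (i in seq_len(n_hp)) {
      d <- designs[[i]]
      sc <- ((i - 1) %% spec$n_scaffolds) + 1
      slot <- ((i - 1) %/% spec$n_scaffolds)
      span <- floor(spec$scaffold_len / slots_per)
      lo <- slot * span + 500
      hi <- (slot + 1) * span - nchar(d$precursor) - 500
      if (hi <= lo) stop("make_genome: scaffolds too short for the hairpin plan")
      pos <- sample(lo:hi, 1)                      # 0-based start
      strand <- if (i %% 2 == 1) "+" else "-"
      ins <- if (strand == "+") d$precursor else revcomp(d$precursor)
      s <- genome[[sc]]
      genome[[sc]] <- paste0(substr(s, 1, pos),
                             ins,
                             substr(s, pos + nchar(ins) + 1, nchar(s)))
      hp$scaffold[i] <- names(genome)[sc]
      hp$start[i] <- pos
      hp$end[i] <- pos + nchar(ins)
      hp$strand[i] <- strand
      hp$star[i] <- d$star
      hp$mature_start[i] <- d$mature_start
      hp$mature_end[i] <- d$mature_end
      ## genomic coordinates of the mature (0-based, half-open)
      if (strand == "+") {
        hp$mature_genome_start[i] <- pos + d$mature_start - 1L
        hp$mature_genome_end[i] <- pos + d$mature_end
      } else {
        hp$mature_genome_start[i] <- pos + nchar(ins) - d$mature_end
        hp$mature_genome_end[i] <- pos + nchar(ins) - d$mature_start + 1L
      }
    }
    ## each mature must occur exactly once genome-wide (both strands)
    for (i in seq_len(n_hp)) {
      hits <- sum(stringi::stri_count_fixed(genome, plan$mature[i])) +
        sum(stringi::stri_count_fixed(revcomp(genome), plan$mature[i]))
      if (hits != 1) {
        stop("make_genome: planted mature '", plan$name[i],
             "' occurs ", hits, " times in the genome; reseed or enlarge scaffolds")
      }
    }
  }

  loci <- if (n_hp > 0) {
    rbind(
      data.frame(scaffold = hp$scaffold, start = hp$start, end = hp$end,
                 name = paste0(hp$name, "_precursor"), strand = hp$strand),
      data.frame(scaffold = hp$scaffold, start = hp$mature_genome_start,
                 end = hp$mature_genome_end,
                 name = paste0(hp$name, "_mature"), strand = hp$strand)
    )
  } else {
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               name = character(0), strand = character(0))
  }

  list(genome = genome, hairpins = hp, loci = loci, known = known,
       ncrna = ncrna)
}

## assemble a fixed-length read from an insert: insert + 3' adapter,
## truncated/padded to read_len (padding avoids the adapter seeds)
assemble_reads <- function(inserts, adapter3, read_len, forbidden) {
  if (length(inserts) == 0) return(character(0))
  full <- paste0(inserts, adapter3)
  short <- nchar(full) < read_len
  if (any(short)) {
    pads <- random_dna_avoid(sum(short), read_len, forbidden)
    full[short] <- paste0(full[short],
                          substr(pads, 1, read_len - nchar(full[short])))
  }
  substr(full, 1, read_len)
}

#' Simulate the two condition libraries
#'
#' Reads are drawn by a single multinomial per library over all planted
#' sources: each known miRNA, each hairpin mature and its star, the ncRNA
#' fragment pool, the contaminant classes, and a random unannotated
#' background absorbing the remaining probability mass.  Every read id
#' encodes its truth record (\code{<category>|<name>}), and the returned
#' truth tables give per-tag planted counts per condition plus the
#' per-category cleaning-ledger truth.
#'
#' @param gen output of \code{\link{make_genome}}
#' @param spec the same \code{\link{simulation_spec}}
#' @return list with
#'   \item{reads}{list of two data.frames (\code{perfect}, \code{imperfect})
#'     with \code{id}, \code{seq}, \code{qual}}
#'   \item{truth}{list: \code{categories} (per-condition cleaning-ledger
#'     truth), \code{tags} (per planted tag: seq, class, counts per
#'     condition, planted_fold), \code{length_probs}}
#' @export
simulate_libraries <- function(gen, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  forbidden <- seed_kmers(spec)
  depth <- spec$library_depth
  conds <- c("perfect", "imperfect")
  if (depth == 0) warning("simulate_libraries: depth 0; libraries are empty")

  known <- gen$known
  hp <- gen$hairpins
  star_ab <- function(ab) ifelse(ab > 0, pmax(1, round(ab * spec$star_fraction)), 0)

  ## planted abundances are expected reads per 100,000 library reads and
  ## scale linearly with the configured depth
  depth_scale <- depth / 1e5
  sources <- list()
  for (cond in conds) {
    ab_known <- known[[paste0("abundance_", cond)]] * depth_scale
    ab_mat <- if (nrow(hp)) hp[[paste0("abundance_", cond)]] * depth_scale else numeric(0)
    ab_star <- star_ab(ab_mat)
    cont <- spec$contamination * depth
    src <- data.frame(
      name = c(known$id,
               if (nrow(hp)) paste0(hp$name, "_mature"),
               if (nrow(hp)) paste0(hp$name, "_star"),
               "ncRNA", names(spec$contamination), "background"),
      class = c(rep("known_miRNA", nrow(known)),
                rep("novel_mature", nrow(hp)), rep("novel_star", nrow(hp)),
                "ncRNA", names(spec$contamination), "background"),
      expected = c(ab_known, ab_mat, ab_star, spec$ncRNA_fraction * depth,
                   cont, 0),
      stringsAsFactors = FALSE
    )
    leftover <- depth - sum(src$expected)
    if (leftover < 0) stop("simulate_libraries: planted abundances exceed depth")
    src$expected[src$name == "background"] <- leftover
    sources[[cond]] <- src
  }

  reads <- list(); tag_counts <- list(); cat_truth <- list()
  for (cond in conds) {
    src <- sources[[cond]]
    n_draw <- if (depth > 0) as.vector(rmultinom(1, depth, src$expected / depth)) else
      rep(0L, nrow(src))
    src$count <- n_draw
    ## any expressed planted hairpin is accompanied by at least one star
    ## read, so hairpin truth stays recoverable at shallow depths
    if (nrow(hp)) {
      i_mat <- match(paste0(hp$name, "_mature"), src$name)
      i_star <- match(paste0(hp$name, "_star"), src$name)
      bump <- src$count[i_mat] > 0 & src$count[i_star] == 0
      src$count[i_star[bump]] <- 1L
    }

    lens_prob <- spec$length_probs[[cond]]
    lens <- as.integer(names(lens_prob))

    ids <- character(0); seqs <- character(0)
    add <- function(cat, name, s) {
      k <- length(s)
      if (k == 0) return()
      ids <<- c(ids, sprintf("%s|%s|r%d", cat, name, seq_along(s) + length(ids)))
      seqs <<- c(seqs, s)
    }

    for (i in seq_len(nrow(src))) {
      k <- src$count[i]
      if (k == 0) next
      cls <- src$class[i]; nm <- src$name[i]
      if (cls == "known_miRNA") {
        add("known_miRNA", nm, rep(known$seq[match(nm, known$id)], k))
      } else if (cls == "novel_mature") {
        j <- match(sub("_mature$", "", nm), hp$name)
        add("novel_mature", nm, rep(hp$mature[j], k))
      } else if (cls == "novel_star") {
        j <- match(sub("_star$", "", nm), hp$name)
        add("novel_star", nm, rep(hp$star[j], k))
      } else if (cls == "ncRNA") {
        cw <- c(rRNA = 0.80, tRNA = 0.18, snRNA = 0.013, snoRNA = 0.007)
        classes <- sample(names(cw), k, replace = TRUE, prob = cw)
        frag_len <- sample(lens, k, replace = TRUE, prob = lens_prob)
        frag <- vapply(seq_len(k), function(q) {
          refs <- gen$ncrna[gen$ncrna$class == classes[q], ]
          r <- refs[sample(nrow(refs), 1), ]
          L <- nchar(r$seq)
          st <- sample(L - frag_len[q] + 1, 1)
          substr(r$seq, st, st + frag_len[q] - 1)
        }, character(1))
        add("ncRNA", classes, frag)
      } else if (cls == "background") {
        bl <- sample(lens, k, replace = TRUE, prob = lens_prob)
        for (L in unique(bl)) {
          add("background", paste0("len", L),
              random_dna_avoid(sum(bl == L), L, forbidden))
        }
      }
    }
    n_insert <- length(seqs)
    read_seq <- assemble_reads(seqs, spec$adapter3, spec$read_len, forbidden)

    ## contaminant classes
    cont_reads <- character(0); cont_ids <- character(0)
    cadd <- function(cat, s) {
      if (length(s) == 0) return()
      cont_ids <<- c(cont_ids, sprintf("%s|%s|c%d", cat, cat,
                                       seq_along(s) + length(cont_ids)))
      cont_reads <<- c(cont_reads, s)
    }
    cnt <- setNames(src$count[match(names(spec$contamination), src$name)],
                    names(spec$contamination))
    cnt[is.na(cnt)] <- 0
    if (cnt[["adapter3_null"]] > 0) {
      cadd("adapter3_null",
           random_dna_avoid(cnt[["adapter3_null"]], spec$read_len, forbidden))
    }
    if (cnt[["insert_null"]] > 0) {
      cadd("insert_null",
           assemble_reads(rep("", cnt[["insert_null"]]), spec$adapter3,
                          spec$read_len, forbidden))
    }
    if (cnt[["adapter5_contaminant"]] > 0) {
      k <- cnt[["adapter5_contaminant"]]
      mid <- random_dna_avoid(k, 2, forbidden)
      cadd("adapter5_contaminant",
           substr(paste0(spec$adapter5, mid, spec$adapter3,
                         strrep("A", spec$read_len)), 1, spec$read_len))
    }
    if (cnt[["shorter_than_18"]] > 0) {
      k <- cnt[["shorter_than_18"]]
      sl <- sample(10:17, k, replace = TRUE)
      shorts <- vapply(seq_len(k), function(q) {
        repeat {
          s <- random_dna_avoid(1, sl[q], forbidden)
          a_frac <- stringi::stri_count_fixed(s, "A") / nchar(s)
          if (a_frac < 0.8) return(s)
        }
      }, character(1))
      cadd("shorter_than_18",
           assemble_reads(shorts, spec$adapter3, spec$read_len, forbidden))
    }
    if (cnt[["polyA"]] > 0) {
      k <- cnt[["polyA"]]
      pl <- sample(lens, k, replace = TRUE, prob = lens_prob)
      cadd("polyA", assemble_reads(strrep("A", pl), spec$adapter3,
                                   spec$read_len, forbidden))
    }
    qual <- rep(strrep("I", spec$read_len), n_insert + length(cont_reads))
    if (cnt[["low_quality"]] > 0) {
      k <- cnt[["low_quality"]]
      lows <- random_dna_avoid(k, spec$read_len, forbidden)
      substr(lows, 5, 5) <- "N"
      cadd("low_quality", lows)
      qual <- c(qual, rep(strrep("I", spec$read_len), k))
    }

    all_ids <- c(ids, cont_ids)
    all_seq <- c(read_seq, cont_reads)
    ord <- sample(length(all_seq))
    reads[[cond]] <- data.frame(id = all_ids[ord], seq = all_seq[ord],
                                qual = qual[ord], stringsAsFactors = FALSE)

    ## per-tag truth (planted tags only; background tags are anonymous)
    tg <- src[src$class %in% c("known_miRNA", "novel_mature", "novel_star"), ]
    tg$seq <- c(known$seq[match(tg$name[tg$class == "known_miRNA"], known$id)],
                hp$mature[match(sub("_mature$", "",
                                    tg$name[tg$class == "novel_mature"]), hp$name)],
                hp$star[match(sub("_star$", "",
                                  tg$name[tg$class == "novel_star"]), hp$name)])
    tag_counts[[cond]] <- tg[, c("name", "class", "seq", "count")]

    cat_counts <- c(
      clean = sum(src$count[!src$name %in% names(spec$contamination)]),
      setNames(as.integer(cnt), names(cnt))
    )
    cat_truth[[cond]] <- data.frame(condition = cond,
                                    category = names(cat_counts),
                                    count = as.integer(cat_counts))
  }

  tags <- merge(tag_counts$perfect, tag_counts$imperfect,
                by = c("name", "class", "seq"), suffixes = c("_perfect", "_imperfect"))
  pk <- known$planted_fold[match(tags$name, known$id)]
  tags$planted_fold <- ifelse(is.na(pk), NA_real_, pk)
  tags <- tags[order(tags$class, tags$name), ]
  rownames(tags) <- NULL

  list(reads = reads,
       truth = list(categories = do.call(rbind, cat_truth),
                    tags = tags,
                    length_probs = spec$length_probs))
}

#' Run the generator and write all artifacts to disk
#'
#' Writes the genome FASTA, per-library FASTQ (Phred+33), the combined
#' reference FASTA (\code{id|family|class} headers), planted-locus BED
#' (0-based, half-open) and truth TSVs.  Identical seeds give byte-identical
#' files.
#'
#' @param spec a \code{\link{simulation_spec}}
#' @param dir output directory (created if needed)
#' @return invisible list of written paths plus the in-memory \code{gen} and
#'   \code{sim} objects
#' @export
write_simulation <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_genome(spec)
  sim <- simulate_libraries(gen, spec)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    perfect = file.path(dir, "perfect.fastq"),
    imperfect = file.path(dir, "imperfect.fastq"),
    references = file.path(dir, "references.fa"),
    loci = file.path(dir, "planted_loci.bed"),
    truth_tags = file.path(dir, "truth_tags.tsv"),
    truth_categories = file.path(dir, "truth_categories.tsv")
  )
  g <- Biostrings::DNAStringSet(gen$genome)
  Biostrings::writeXStringSet(g, paths$genome)
  write_fastq(sim$reads$perfect, paths$perfect)
  write_fastq(sim$reads$imperfect, paths$imperfect)
  refs <- rbind(
    data.frame(id = gen$ncrna$id, family = "", class = gen$ncrna$class,
               seq = gen$ncrna$seq),
    data.frame(id = gen$known$id, family = gen$known$family,
               class = "mature_miRNA", seq = gen$known$seq)
  )
  write_reference_fasta(refs, paths$references)
  if (nrow(gen$loci) > 0) {
    gr <- GenomicRanges::GRanges(
      gen$loci$scaffold,
      IRanges::IRanges(gen$loci$start + 1, gen$loci$end),
      strand = gen$loci$strand
    )
    names(gr) <- gen$loci$name
    rtracklayer::export(gr, paths$loci, format = "BED")
  } else {
    file.create(paths$loci)
  }
  write_tsv(sim$truth$tags, paths$truth_tags)
  write_tsv(sim$truth$categories, paths$truth_categories)
  invisible(c(paths, list(gen = gen, sim = sim)))
}
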