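# Independent oracles and shared fixtures.  Oracles deliberately avoid the
# code paths they check: plain loops and direct summation only.

# direct tail summation for the count test (both orientations averaged,
# matching the reported definition)
oracle_ac_pvalue <- function(x, y, N1, N2, gmax = 1e4) {
  one <- function(x, y, r) {
    g <- 0:max(gmax, x + y + 200)
    lp <- g * log(r) + lgamma(x + g + 1) - lgamma(x + 1) - lgamma(g + 1) -
      (x + g + 1) * log1p(r)
    p <- exp(lp)
    min(1, 2 * min(sum(p[g <= y]), sum(p[g >= y])))
  }
  (one(x, y, N2 / N1) + one(y, x, N1 / N2)) / 2
}

# character-by-character window scanner for target sites
oracle_scan_targets <- function(mirna, transcripts, max_mismatch = 3,
                                max_penalty = 4.0) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- nchar(mirna)
  mb <- strsplit(mirna, "")[[1]]
  hits <- list()
  for (tid in names(transcripts)) {
    s <- strsplit(transcripts[[tid]], "")[[1]]
    if (length(s) < m) next
    for (st in 1:(length(s) - m + 1)) {
      pen <- 0; mm <- 0; gu <- 0
      for (i in 1:m) {
        b <- s[st + m - i]            # site base facing miRNA position i
        w <- if (i >= 2 && i <= 13) 2 else 1
        if (b == comp[[mb[i]]]) {
        } else if ((mb[i] == "G" && b == "T") || (mb[i] == "T" && b == "G")) {
          gu <- gu + 1; pen <- pen + 0.5 * w
        } else {
          mm <- mm + 1; pen <- pen + 1 * w
        }
      }
      if (mm <= max_mismatch && pen <= max_penalty) {
        hits[[length(hits) + 1]] <- data.frame(
          transcript_id = tid, start = st, mismatches = mm,
          gu_pairs = gu, penalty = pen)
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  out <- do.call(rbind, hits)
  out[order(out$penalty, out$transcript_id, out$start), ]
}

# hash-based recount of clean reads, independent of collapse_tags()
oracle_recount <- function(seqs) {
  env <- new.env(hash = TRUE)
  for (s in seqs) {
    assign(s, (if (exists(s, envir = env, inherits = FALSE))
      get(s, envir = env) else 0L) + 1L, envir = env)
  }
  vals <- mget(ls(env), envir = env)
  data.frame(seq = names(vals), count = as.integer(unlist(vals)),
             stringsAsFactors = FALSE)
}

# naive both-strand exact scan of a genome for a tag
oracle_genome_scan <- function(tag, genome) {
  n <- 0
  for (sc in genome) {
    n <- n + length(gregexpr(tag, sc, fixed = TRUE)[[1]][
      gregexpr(tag, sc, fixed = TRUE)[[1]] > 0])
    rc <- sRNAbud:::revcomp(sc)
    hits <- gregexpr(tag, rc, fixed = TRUE)[[1]]
    n <- n + length(hits[hits > 0])
  }
  n
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# shared small simulated study (module tests); built once per session
.sim_cache <- new.env()
small_sim <- function() {
  if (!exists("sim", envir = .sim_cache)) {
    spec <- simulation_spec(seed = 11, library_depth = 2e4)
    gen <- make_genome(spec)
    sim <- simulate_libraries(gen, spec)
    assign("spec", spec, envir = .sim_cache)
    assign("gen", gen, envir = .sim_cache)
    assign("sim", sim, envir = .sim_cache)
  }
  list(spec = get("spec", envir = .sim_cache),
       gen = get("gen", envir = .sim_cache),
       sim = get("sim", envir = .sim_cache))
}

# merged tag table (both libraries) for the small study
small_tags <- function() {
  if (!exists("tags", envir = .sim_cache)) {
    s <- small_sim()
    cl <- lapply(s$sim$reads, function(r) {
      clean_reads(r, s$spec$adapter3, s$spec$adapter5)
    })
    tg <- lapply(cl, function(x) collapse_tags(x$clean))
    tags <- merge(tg$perfect, tg$imperfect, by = "seq", all = TRUE)
    names(tags) <- c("seq", "count_perfect", "count_imperfect")
    tags$count_perfect[is.na(tags$count_perfect)] <- 0L
    tags$count_imperfect[is.na(tags$count_imperfect)] <- 0L
    assign("cleaned", cl, envir = .sim_cache)
    assign("tags", tags, envir = .sim_cache)
  }
  list(cleaned = get("cleaned", envir = .sim_cache),
       tags = get("tags", envir = .sim_cache))
}

sim_references <- function(gen) {
  rbind(
    data.frame(id = gen$ncrna$id, family = "", class = gen$ncrna$class,
               seq = gen$ncrna$seq, stringsAsFactors = FALSE),
    data.frame(id = gen$known$id, family = gen$known$family,
               class = "mature_miRNA", seq = gen$known$seq,
               stringsAsFactors = FALSE)
  )
}
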