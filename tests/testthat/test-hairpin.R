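test_that("genome mapping finds planted loci on both strands", {
  s <- small_sim()
  hp <- s$gen$hairpins
  loci <- map_to_genome(hp$mature, s$gen$genome)
  expect_equal(nrow(loci), nrow(hp))
  m <- merge(loci, hp, by.x = "tag", by.y = "mature")
  expect_equal(m$scaffold.x, m$scaffold.y)
  expect_equal(m$strand.x, m$strand.y)
  expect_equal(m$start.x, m$mature_genome_start)
  expect_equal(m$end.x, m$mature_genome_end)
  # absent tag maps nowhere
  expect_equal(nrow(map_to_genome("TTTTTTTTTTTTTTTTTTTTT", s$gen$genome)), 0)
})

test_that("palindromic tags report distinct loci on both strands", {
  core <- paste0("ACGTTACTGA", sRNAbud:::revcomp("ACGTTACTGA"))  # palindrome
  expect_equal(core, sRNAbud:::revcomp(core))
  genome <- c(chr = paste0(strrep("G", 30), core, strrep("T", 30)))
  loci <- map_to_genome(core, genome)
  expect_equal(nrow(loci), 2)
  expect_setequal(loci$strand, c("+", "-"))
  expect_equal(unique(loci$start), 30)
})

test_that("repeat tags beyond max_loci are dropped", {
  unit <- "TACGATCGATCGTTACGATAC"
  genome <- c(chr = paste(rep(c(unit, strrep("C", 40)), 4), collapse = ""))
  expect_equal(nrow(map_to_genome(unit, genome, max_loci = 20)), 4)
  expect_equal(nrow(map_to_genome(unit, genome, max_loci = 3)), 0)
})

test_that("window extraction clips at edges and has the documented lengths", {
  genome <- c(chr = strrep("ACGT", 200))   # 800 nt
  locus <- data.frame(tag = substr(genome[["chr"]], 301, 321),
                      scaffold = "chr", start = 300L, end = 321L,
                      strand = "+")
  w <- extract_windows(locus, genome, flank = 250)
  expect_equal(nchar(w$A$seq), 20 + 21 + 250)
  expect_equal(nchar(w$B$seq), 250 + 21 + 20)
  expect_equal(substr(w$A$seq, w$A$tag_start, w$A$tag_start + 20), locus$tag)
  expect_equal(substr(w$B$seq, w$B$tag_start, w$B$tag_start + 20), locus$tag)
  # locus at position 0 clips window A's upstream side
  locus0 <- data.frame(tag = substr(genome[["chr"]], 1, 21), scaffold = "chr",
                       start = 0L, end = 21L, strand = "+")
  w0 <- extract_windows(locus0, genome)
  expect_equal(w0$A$start, 0)
  expect_equal(w0$A$tag_start, 1)
})

test_that("planted hairpin windows contain the full precursor", {
  s <- small_sim()
  hp <- s$gen$hairpins
  for (i in seq_len(nrow(hp))) {
    locus <- data.frame(tag = hp$mature[i], scaffold = hp$scaffold[i],
                        start = hp$mature_genome_start[i],
                        end = hp$mature_genome_end[i], strand = hp$strand[i])
    w <- extract_windows(locus, s$gen$genome, flank = 250)
    hits <- stringi::stri_detect_fixed(c(w$A$seq, w$B$seq), hp$precursor[i])
    expect_true(any(hits), info = hp$name[i])
  }
})

test_that("candidate evaluation accepts planted hairpins with matching arm", {
  s <- small_sim()
  tg <- small_tags()
  counts <- setNames(tg$tags$count_perfect + tg$tags$count_imperfect,
                     tg$tags$seq)
  hp <- s$gen$hairpins
  for (i in seq_len(nrow(hp))) {
    locus <- data.frame(tag = hp$mature[i], scaffold = hp$scaffold[i],
                        start = hp$mature_genome_start[i],
                        end = hp$mature_genome_end[i], strand = hp$strand[i])
    w <- extract_windows(locus, s$gen$genome)
    evs <- lapply(w, evaluate_candidate, tag = hp$mature[i], tag_counts = counts)
    acc <- evs[vapply(evs, `[[`, logical(1), "accepted")]
    expect_equal(length(acc), 1, info = hp$name[i])
    expect_equal(acc[[1]]$arm, sub("p", "p", hp$arm[i]))
    expect_equal(acc[[1]]$star, hp$star[i])
    # self-audit: accepted candidates re-verify their own criteria
    expect_lte(acc[[1]]$mfe, -18)
    expect_lte(acc[[1]]$mismatches, 4)
    expect_gte(acc[[1]]$star_count, 1)
    expect_gte(nchar(acc[[1]]$precursor), 50)
    expect_true(grepl(acc[[1]]$mature, acc[[1]]$precursor, fixed = TRUE) ||
                  grepl(acc[[1]]$star, acc[[1]]$precursor, fixed = TRUE))
  }
})

test_that("rejection reasons are specific: no star support, weak fold", {
  s <- small_sim()
  tg <- small_tags()
  hp <- s$gen$hairpins[1, ]
  counts <- setNames(tg$tags$count_perfect + tg$tags$count_imperfect,
                     tg$tags$seq)
  locus <- data.frame(tag = hp$mature, scaffold = hp$scaffold,
                      start = hp$mature_genome_start,
                      end = hp$mature_genome_end, strand = hp$strand)
  w <- extract_windows(locus, s$gen$genome)
  pick <- if (hp$arm == "5p") "A" else "B"
  # remove the star reads from the tag set
  counts_nostar <- counts[names(counts) != hp$star]
  ev <- evaluate_candidate(w[[pick]], hp$mature, counts_nostar)
  expect_false(ev$accepted)
  expect_true("no miRNA* read support" %in% ev$reasons)
  # force a weak fold energy through the fold_result argument
  f <- fold(w[[pick]]$seq)
  f$mfe <- -10
  ev2 <- evaluate_candidate(w[[pick]], hp$mature, counts, fold_result = f)
  expect_false(ev2$accepted)
  expect_true(any(grepl("MFE above threshold", ev2$reasons)))
})

test_that("first-nucleotide bias tables are per-length distributions", {
  b <- first_nt_bias(c("TAGC", "TGGC", "ATGCA"))
  expect_equal(b$fraction[b$length == 4 & b$base == "U"], 1)
  expect_equal(b$fraction[b$length == 5 & b$base == "A"], 1)
  for (L in unique(b$length)) expect_equal(sum(b$fraction[b$length == L]), 1)
  expect_equal(nrow(first_nt_bias(character(0))), 0)
  # planted 70% 5'-U bias is recovered within 3 sd
  set.seed(55)
  n <- 400
  firsts <- ifelse(runif(n) < 0.7, "T", "G")
  mats <- paste0(firsts, vapply(1:n, function(i)
    random_rna(20, c("A", "C", "G", "T")), character(1)))
  b2 <- first_nt_bias(mats)
  u_frac <- sum(b2$count[b2$base == "U"]) / n
  expect_lt(abs(u_frac - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("full discovery accepts all planted hairpins and nothing else", {
  s <- small_sim()
  tg <- small_tags()
  refs <- sim_references(s$gen)
  ann <- classify_tags(tg$tags, refs)
  unann <- ann$assignments[ann$assignments$class == "unannotated", ]
  res <- predict_hairpins(unann, s$gen$genome)
  novel <- attr(res, "clusters")
  hp <- s$gen$hairpins
  expect_setequal(novel$tag, hp$mature)
  expect_equal(nrow(novel), nrow(hp))
  # no accepted locus outside the planted precursor intervals
  for (i in seq_len(nrow(novel))) {
    j <- match(novel$tag[i], hp$mature)
    expect_equal(novel$scaffold[i], hp$scaffold[j])
    expect_true(novel$precursor_start[i] >= hp$start[j] - 5 &&
                  novel$precursor_end[i] <= hp$end[j] + 5)
  }
})
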