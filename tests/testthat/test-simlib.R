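test_that("a spec without hairpins yields pure background and empty loci", {
  spec <- simulation_spec(seed = 5, n_hairpins = 0, library_depth = 0)
  gen <- make_genome(spec)
  expect_equal(nrow(gen$hairpins), 0)
  expect_equal(nrow(gen$loci), 0)
  expect_equal(length(gen$genome), spec$n_scaffolds)
  expect_true(all(nchar(gen$genome) == spec$scaffold_len))
})

test_that("generation is deterministic: same seed, byte-identical files", {
  spec <- simulation_spec(seed = 7, n_hairpins = 1, library_depth = 500,
                          scaffold_len = 20000)
  d1 <- file.path(tempdir(), "simdet1"); d2 <- file.path(tempdir(), "simdet2")
  write_simulation(spec, d1)
  write_simulation(spec, d2)
  for (f in c("genome.fa", "perfect.fastq", "imperfect.fastq",
              "references.fa", "planted_loci.bed", "truth_tags.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("every planted mature occurs exactly once by naive genome scan", {
  s <- small_sim()
  for (i in seq_len(nrow(s$gen$hairpins))) {
    expect_equal(oracle_genome_scan(s$gen$hairpins$mature[i], s$gen$genome), 1,
                 info = s$gen$hairpins$name[i])
  }
  # and the recorded locus substring round-trips to the mature
  for (i in seq_len(nrow(s$gen$hairpins))) {
    hp <- s$gen$hairpins[i, ]
    sub <- substr(s$gen$genome[[hp$scaffold]],
                  hp$mature_genome_start + 1, hp$mature_genome_end)
    if (hp$strand == "-") sub <- sRNAbud:::revcomp(sub)
    expect_equal(sub, hp$mature)
  }
})

test_that("hairpin designs reject matures that cannot sit on the stem", {
  expect_error(
    make_genome(simulation_spec(seed = 1, hairpins = data.frame(
      name = "bad", mature = strrep("ACGT", 8), arm = "5p",
      abundance_perfect = 10, abundance_imperfect = 10))),
    "stem")
})

test_that("default abundance plan is non-negative with >= 1.5-fold planted differences", {
  plan <- sRNAbud:::default_known_plan()
  expect_equal(nrow(plan), 61)
  expect_equal(length(unique(plan$family)), 24)
  expect_true(all(plan$abundance_perfect >= 0))
  expect_true(all(plan$abundance_imperfect >= 0))
  diffs <- plan[plan$planted_fold != 1 & is.finite(plan$planted_fold) &
                  plan$planted_fold > 0, ]
  expect_true(all(pmax(diffs$planted_fold, 1 / diffs$planted_fold) >= 1.5))
})

test_that("with contamination off, every read trims to a truth insert", {
  spec <- simulation_spec(seed = 13, library_depth = 3000,
                          scaffold_len = 20000,
                          contamination = c(adapter3_null = 0, insert_null = 0,
                                            adapter5_contaminant = 0,
                                            shorter_than_18 = 0, polyA = 0,
                                            low_quality = 0))
  gen <- make_genome(spec)
  sim <- simulate_libraries(gen, spec)
  cl <- clean_reads(sim$reads$perfect, spec$adapter3, spec$adapter5)
  expect_equal(cl$summary$clean_total, cl$summary$total_reads)
  expect_equal(cl$summary$removed_total, 0)
})

test_that("reads are traceable: ids carry the truth category", {
  s <- small_sim()
  cats <- vapply(strsplit(s$sim$reads$perfect$id, "|", fixed = TRUE),
                 `[`, character(1), 1)
  expect_true(all(cats %in% c("known_miRNA", "novel_mature", "novel_star",
                              "ncRNA", "background", "adapter3_null",
                              "insert_null", "adapter5_contaminant",
                              "shorter_than_18", "polyA", "low_quality")))
})

test_that("planted insert length fractions are recovered within 3 binomial sd", {
  # background-only library so the planted length distribution is the only
  # source of length structure
  probs <- setNames(c(0.5, 0.2, 0.3), c(21, 22, 24))
  empty_known <- data.frame(id = character(0), family = character(0),
                            abundance_perfect = numeric(0),
                            abundance_imperfect = numeric(0),
                            planted_fold = numeric(0), seq = character(0))
  spec <- simulation_spec(seed = 21, n_hairpins = 0, known = empty_known,
                          ncRNA_fraction = 0, library_depth = 2e4,
                          scaffold_len = 5000,
                          contamination = c(adapter3_null = 0, insert_null = 0,
                                            adapter5_contaminant = 0,
                                            shorter_than_18 = 0, polyA = 0,
                                            low_quality = 0),
                          length_probs = list(perfect = probs,
                                              imperfect = probs))
  gen <- make_genome(spec)
  sim <- simulate_libraries(gen, spec)
  cl <- clean_reads(sim$reads$perfect, spec$adapter3, spec$adapter5)
  tags <- collapse_tags(cl$clean)
  h <- length_histogram(tags, weighted = TRUE, lengths = 18:28)
  n <- sum(h$count)
  for (L in c(21, 22, 24)) {
    p <- probs[[as.character(L)]]
    expect_lt(abs(h$fraction[h$length == L] - p),
              3 * sqrt(p * (1 - p) / n))
  }
})

test_that("zero depth gives empty libraries with a warning", {
  spec <- simulation_spec(seed = 3, n_hairpins = 0, library_depth = 0,
                          scaffold_len = 5000)
  gen <- make_genome(spec)
  expect_warning(sim <- simulate_libraries(gen, spec), "depth 0")
  expect_equal(nrow(sim$reads$perfect), 0)
})
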