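adapter3 <- "TCGTATGCCGTCTTCTGCTTG"
adapter5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
pad36 <- function(x) substr(paste0(x, strrep("C", 36)), 1, 36)

test_that("each cleaning category is assigned by the documented precedence", {
  reads <- data.frame(seq = c(
    pad36(adapter3),                                    # insert null
    pad36(paste0(strrep("GT", 8), adapter3)),           # 16-nt insert: short
    pad36(paste0(strrep("GATC", 6), adapter3)),         # clean 24-nt insert
    pad36(paste0(strrep("A", 20), adapter3)),           # poly(A)
    pad36(paste0(adapter5, "GT", adapter3)),            # 5' contaminant
    strrep("G", 36),                                    # no 3' adapter
    pad36(paste0("GATCNGATCGATCGATCGAT", adapter3))     # N: low quality
  ))
  res <- clean_reads(reads, adapter3, adapter5)
  expect_equal(res$category,
               c("insert_null", "shorter_than_18", "clean", "polyA",
                 "adapter5_contaminant", "adapter3_null", "low_quality"))
  s <- res$summary
  expect_equal(s$clean_total, s$high_quality - s$removed_total)
  expect_equal(s$total_reads, s$high_quality + 1)  # one low-quality read
  expect_equal(res$clean$seq, strrep("GATC", 6))
})

test_that("quality filtering uses the low-quality base fraction", {
  seqs <- rep(pad36(paste0(strrep("GATC", 6), adapter3)), 2)
  # read 2: first 10 of 36 bases below Phred 20 (28% >= 10% threshold)
  quals <- c(strrep("I", 36), paste0(strrep("#", 10), strrep("I", 26)))
  res <- clean_reads(data.frame(seq = seqs, qual = quals), adapter3)
  expect_equal(res$category, c("clean", "low_quality"))
})

test_that("empty input produces an all-zero ledger", {
  res <- clean_reads(data.frame(seq = character(0)), adapter3)
  expect_equal(res$summary$total_reads, 0)
  expect_equal(nrow(res$clean), 0)
})

test_that("cleaning ledger equals the simulated truth exactly", {
  s <- small_sim()
  for (cond in c("perfect", "imperfect")) {
    res <- clean_reads(s$sim$reads[[cond]], s$spec$adapter3, s$spec$adapter5)
    truth <- s$sim$truth$categories
    truth <- truth[truth$condition == cond, ]
    tget <- function(cat) truth$count[truth$category == cat]
    expect_equal(res$summary$clean_total, tget("clean"))
    expect_equal(res$summary$adapter3_null, tget("adapter3_null"))
    expect_equal(res$summary$insert_null, tget("insert_null"))
    expect_equal(res$summary$adapter5_contaminant, tget("adapter5_contaminant"))
    expect_equal(res$summary$shorter_than_18, tget("shorter_than_18"))
    expect_equal(res$summary$polyA, tget("polyA"))
  }
})

test_that("collapse preserves totals and matches an independent recount", {
  expect_equal(collapse_tags(rep("ACGTACGTACGTACGTAC", 3)),
               data.frame(seq = "ACGTACGTACGTACGTAC", count = 3L))
  set.seed(31)
  pool <- vapply(1:300, function(i) random_rna(21, c("A", "C", "G", "T")),
                 character(1))
  reads <- sample(pool, 1e4, replace = TRUE, prob = runif(300))
  tags <- collapse_tags(reads)
  expect_equal(sum(tags$count), length(reads))        # redundant total
  oracle <- oracle_recount(reads)
  m <- merge(tags, oracle, by = "seq")
  expect_equal(nrow(m), nrow(tags))
  expect_equal(m$count.x, m$count.y)
  # idempotent / order-independent
  expect_equal(collapse_tags(sample(reads)), tags)
})

test_that("length histograms are proper distributions", {
  tags <- data.frame(seq = rep(strrep("A", 21), 3), count = c(5L, 2L, 1L))
  h <- length_histogram(tags)
  expect_equal(h$fraction[h$length == 21], 1)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  # weighted and unweighted differ when one tag dominates
  tags2 <- data.frame(seq = c(strrep("A", 21), strrep("C", 24)),
                      count = c(99L, 1L))
  hw <- length_histogram(tags2, weighted = TRUE)
  hu <- length_histogram(tags2, weighted = FALSE)
  expect_equal(hw$fraction[hw$length == 21], 0.99)
  expect_equal(hu$fraction[hu$length == 21], 0.5)
  expect_error(length_histogram(tags[0, ]), "empty")
})

test_that("overlap statistics partition the union and compute mean frequencies", {
  a <- data.frame(seq = c("AAAA", "CCCC", "GGGG"), count = c(10L, 5L, 1L))
  b <- data.frame(seq = c("CCCC", "TTTT"), count = c(7L, 3L))
  st <- overlap_stats(a, b)
  expect_equal(st$unique[st$class == "total"], 4)
  expect_equal(st$unique[st$class == "common"], 1)
  expect_equal(st$redundant[st$class == "common"], 12)   # both libraries
  expect_equal(st$mean_frequency[st$class == "total"], 26 / 4)
  expect_equal(st$unique[st$class == "A_specific"] +
                 st$unique[st$class == "B_specific"] +
                 st$unique[st$class == "common"],
               st$unique[st$class == "total"])
  # disjoint sets
  st2 <- overlap_stats(a, data.frame(seq = "TTTT", count = 2L))
  expect_equal(st2$unique[st2$class == "common"], 0)
  expect_equal(st2$mean_frequency[st2$class == "A_specific"], 16 / 3)
})

test_that("collapsed FASTA round-trips tags with counts", {
  tags <- data.frame(seq = c("ACGTACGTACGTACGTACGT", "TTTTGGGGCCCCAAAATTTT"),
                     count = c(12L, 3L))
  p <- tempfile(fileext = ".fa")
  write_collapsed_fasta(tags, p)
  back <- read_collapsed_fasta(p)
  expect_equal(back$seq, tags$seq)
  expect_equal(back$count, tags$count)
})
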