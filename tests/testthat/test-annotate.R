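mk_tags <- function(seqs, counts = rep(1L, length(seqs))) {
  data.frame(seq = seqs, count_perfect = counts, count_imperfect = 0L,
             stringsAsFactors = FALSE)
}

test_that("classification follows precedence and containment rules", {
  frag <- strrep("AGCT", 6)
  refs <- data.frame(
    id = c("r1", "t1", "m1"),
    family = c("", "", "MIRX"),
    class = c("rRNA", "tRNA", "mature_miRNA"),
    seq = c(paste0("GGGG", frag, "GGGG"),  # rRNA containing the fragment
            paste0("TTTT", frag, "TTTT"),  # tRNA containing the same fragment
            "TACGTACGTACGTACGTACGT"),
    stringsAsFactors = FALSE
  )
  tags <- mk_tags(c(frag,                          # matches rRNA AND tRNA
                    "TACGTACGTACGTACGTACGT",       # exact mature
                    "TACGTACGTACGTACGTACGA",      # 1 nt off: no miRNA hit
                    strrep("CAGT", 6)))            # unannotated
  res <- classify_tags(tags, refs)
  expect_equal(res$assignments$class,
               c("rRNA", "mature_miRNA", "unannotated", "unannotated"))
  expect_equal(sum(res$tally$unique), nrow(tags))
  expect_equal(sum(res$tally$unique_pct), 100, tolerance = 1e-9)
  # reverse-strand fragments of ncRNA still match
  res2 <- classify_tags(mk_tags(sRNAbud:::revcomp(frag)), refs)
  expect_equal(res2$assignments$class, "rRNA")
  # mature matching is full-length only: no substring hits
  res3 <- classify_tags(mk_tags(substr("TACGTACGTACGTACGTACGT", 1, 20)), refs)
  expect_equal(res3$assignments$class, "unannotated")
})

test_that("empty references warn and leave all tags unannotated", {
  expect_warning(res <- classify_tags(mk_tags(strrep("ACGT", 5)), data.frame(
    id = character(0), family = character(0), class = character(0),
    seq = character(0))), "empty")
  expect_equal(res$assignments$class, "unannotated")
})

test_that("classification tally equals simulated truth per class", {
  s <- small_sim()
  tg <- small_tags()
  refs <- sim_references(s$gen)
  res <- classify_tags(tg$tags, refs)
  tally <- res$tally
  truth <- s$sim$truth$tags
  known <- truth[truth$class == "known_miRNA", ]
  present <- known[known$count_perfect + known$count_imperfect > 0, ]
  # every planted known mature with at least one read is classified as miRNA
  expect_equal(tally$unique[tally$class == "mature_miRNA"], nrow(present))
  expect_equal(tally$redundant[tally$class == "mature_miRNA"],
               sum(present$count_perfect + present$count_imperfect))
  # permuting tag order leaves the tally unchanged
  set.seed(1)
  res2 <- classify_tags(tg$tags[sample(nrow(tg$tags)), ], refs)
  expect_equal(res2$tally, tally)
})

test_that("known-miRNA matching is exact and complete on simulated data", {
  s <- small_sim()
  tg <- small_tags()
  mature <- data.frame(id = s$gen$known$id, family = s$gen$known$family,
                       seq = s$gen$known$seq)
  hits <- match_known_mirnas(tg$tags, mature)
  truth <- s$sim$truth$tags
  known <- truth[truth$class == "known_miRNA", ]
  present <- known[known$count_perfect + known$count_imperfect > 0, ]
  expect_equal(nrow(hits), nrow(present))
  m <- merge(hits, known, by.x = "mirna_id", by.y = "name")
  expect_equal(nrow(m), nrow(hits))
  expect_equal(m$count_perfect.x, m$count_perfect.y)
  expect_equal(m$count_imperfect.x, m$count_imperfect.y)
})

test_that("duplicate mature sequences are both reported with a warning", {
  tags <- mk_tags("TACGTACGTACGTACGTACGT", 9L)
  mature <- data.frame(id = c("miRA", "miRB"), family = c("F1", "F2"),
                       seq = rep("TACGTACGTACGTACGTACGT", 2))
  expect_warning(hits <- match_known_mirnas(tags, mature), "duplicate")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$count_perfect, c(9L, 9L))
})

test_that("family summary counts arm-collapsed members and sums reads", {
  hits <- data.frame(
    mirna_id = c("miR171", "miR171b", "miR171b-3p", "miR171d", "miR171f",
                 "miR171l", "miR9a"),
    family_id = c(rep("MIR171", 6), "MIR9"),
    count_perfect = c(483, 1578, 2195, 1, 13, 4, 7),
    count_imperfect = c(630, 1994, 2831, 0, 15, 9, 2)
  )
  fam <- family_summary(hits)
  expect_equal(fam$members[fam$family_id == "MIR171"], 5)  # b and b-3p merge
  expect_equal(fam$members[fam$family_id == "MIR9"], 1)
  expect_equal(fam$total_perfect[fam$family_id == "MIR171"],
               sum(hits$count_perfect[1:6]))
  # conservation: family totals sum to total hit counts
  expect_equal(sum(fam$total_perfect), sum(hits$count_perfect))
  expect_equal(sum(fam$total_imperfect), sum(hits$count_imperfect))
})

test_that("reference FASTA round-trips ids, families and classes", {
  refs <- data.frame(id = c("r1", "m7"), family = c("", "MIR7"),
                     class = c("rRNA", "mature_miRNA"),
                     seq = c(strrep("ACGT", 30), "TAGCTAGCTAGCTAGCTAGCT"))
  p <- tempfile(fileext = ".fa")
  write_reference_fasta(refs, p)
  back <- read_reference_fasta(p)
  expect_equal(back, refs)
})
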