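test_that("IUPAC matching accepts and rejects per position-wise sets", {
  m <- iupac_motif("SYTTWWAA")
  hit <- match_motif(core_with("GCTTATAA", -31), m)
  expect_equal(hit$match_label, -31)
  expect_equal(hit$match_seq, "GCTTATAA")
  expect_null(match_motif(core_with("TTTTTTTT", -31), m))  # S excludes T
  v <- iupac_motif("VYTTWWAA")
  expect_equal(match_motif(core_with("ACTTAAAA", -31), v)$match_label, -31)
  # sequence N never satisfies a pattern position
  expect_null(match_motif(core_with("GCTTATNA", -31), m))
})

test_that("matching is confined to the search window", {
  m <- iupac_motif("SYTTWWAA", window = c(-40, -20))
  expect_null(match_motif(core_with("GCTTATAA", -50), m))
  expect_equal(match_motif(core_with("GCTTATAA", -20), m)$match_label, -20)
  wide <- iupac_motif("SYTTWWAA", window = c(-60, -20))
  expect_equal(match_motif(core_with("GCTTATAA", -50), wide)$match_label, -50)
})

test_that("among multiple matches the one closest to -28 wins, upstream first", {
  m <- iupac_motif("SYTTWWAA")
  rec <- core_with("GCTTATAA", -36)
  s <- rec$sequence
  substr(s, label_to_offset(-22, 80) + 1, label_to_offset(-22, 80) + 8) <-
    "GCTTATAA"
  rec2 <- tss_sequence("two", s, 80)
  # -36 and -22 hit; |-36 + 28| = 8 > |-22 + 28| = 6
  expect_equal(match_motif(rec2, m)$match_label, -22)
  # equidistant pair: -35 vs -21, tie broken upstream
  rec3 <- core_with("GCTTATAA", -35)
  s3 <- rec3$sequence
  substr(s3, label_to_offset(-21, 80) + 1, label_to_offset(-21, 80) + 8) <-
    "GCTTATAA"
  expect_equal(match_motif(tss_sequence("tie", s3, 80), m)$match_label, -35)
})

test_that("every concrete expansion of SYTTWWAA matches itself", {
  sets <- expand_iupac("SYTTWWAA")
  combos <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  expect_equal(nrow(combos), 16L)
  m <- iupac_motif("SYTTWWAA")
  for (i in seq_len(nrow(combos))) {
    word <- paste(unlist(combos[i, ]), collapse = "")
    expect_equal(match_motif(core_with(word, -31), m)$match_seq, word)
  }
})

test_that("motif construction validates length, window and gap", {
  expect_error(iupac_motif("TATA"), "length")
  expect_error(iupac_motif(strrep("W", 16)), "length")
  expect_silent(iupac_motif("KVRWAAAVYTTWWWW"))  # 15-mer BRE+TATA
  g <- iupac_motif("KVRWAAAVYTTWWWW"); expect_equal(nchar(g$pattern), 15)
  gapped <- iupac_motif("AAATTT", gap = 2, gap_after = 3)
  expect_equal(gapped$pattern, "AAANNTTT")
  expect_error(iupac_motif("AAATTT", gap = 2), "gap_after")
})

test_that("classification partitions the set deterministically", {
  set.seed(31)
  g <- gen_promoters(generator_spec(n = 60, preset = "tko", seed = 31))
  cores <- lapply(g$records, extract_core)
  cl <- classify_promoters(cores, TATA_MOTIFS[["tko"]])
  ids <- vapply(cores, `[[`, "", "id")
  expect_setequal(c(cl$conserved$id, cl$degenerated), ids)
  expect_length(intersect(cl$conserved$id, cl$degenerated), 0)
  # at most one recorded match per sequence
  expect_false(anyDuplicated(cl$conserved$id) > 0)
  # order independence
  cl_rev <- classify_promoters(rev(cores), TATA_MOTIFS[["tko"]])
  expect_setequal(cl_rev$conserved$id, cl$conserved$id)
  expect_error(classify_promoters(list(), "SYTTWWAA"), "empty")
})

test_that("degenerate extremes classify as expected", {
  # every sequence embeds the motif: degenerated group empty
  planted <- lapply(1:10, function(i) {
    r <- core_with("GCTTATAA", -31)
    tss_sequence(paste0("p", i), r$sequence, 80)
  })
  cl <- classify_promoters(planted, "SYTTWWAA")
  expect_length(cl$degenerated, 0)
  # pure-AT sequences can never satisfy S: conserved group empty
  set.seed(32)
  atonly <- lapply(1:10, function(i) {
    tss_sequence(paste0("a", i), random_dna(100, at = 1), 80)
  })
  cl2 <- classify_promoters(atonly, "SYTTWWAA")
  expect_equal(nrow(cl2$conserved), 0L)
  expect_length(cl2$degenerated, 10)
})

test_that("classified sets carry per-sequence GC and a summary", {
  set.seed(33)
  g <- gen_promoters(generator_spec(n = 40, preset = "sso_core", seed = 33))
  cl <- classify_promoters(g$records, TATA_MOTIFS[["sso"]])
  expect_equal(nrow(cl$gc), 40L)
  expect_true(all(cl$gc$gc_percent >= 0 & cl$gc$gc_percent <= 100))
  s <- summary(cl)
  expect_equal(sum(s$n), 40L)
  expect_equal(sum(s$percent), 100)
})
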