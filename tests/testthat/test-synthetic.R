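test_that("generation is deterministic per seed and spec", {
  s <- generator_spec(n = 5, length = 200L, at_fraction = 0.6,
                      motif = "VYTTWWAA", seed = 71)
  g1 <- gen_promoters(s)
  g2 <- gen_promoters(s)
  expect_identical(vapply(g1$records, `[[`, "", "sequence"),
                   vapply(g2$records, `[[`, "", "sequence"))
  expect_identical(g1$truth, g2$truth)
  s2 <- s; s2$seed <- 72L
  g3 <- gen_promoters(s2)
  expect_false(identical(g1$records[[1]]$sequence,
                         g3$records[[1]]$sequence))
})

test_that("motif probability endpoints control the truth labels", {
  s0 <- generator_spec(n = 20, length = 200L, motif = "VYTTWWAA",
                       motif_probability = 0, seed = 73)
  expect_false(any(gen_promoters(s0)$truth$has_motif))
  s1 <- generator_spec(n = 20, length = 200L, motif = "VYTTWWAA",
                       motif_probability = 1, seed = 73)
  expect_true(all(gen_promoters(s1)$truth$has_motif))
})

test_that("background composition matches the requested AT fraction", {
  s <- generator_spec(n = 200, length = 1000L, at_fraction = 0.655,
                      seed = 74)
  g <- gen_promoters(s)
  at <- mean(vapply(g$records, at_content, numeric(1)))
  se <- 100 * sqrt(0.655 * 0.345 / (200 * 1000))
  expect_lt(abs(at - 65.5), 3 * se)
})

test_that("planted motifs sit where the truth table says, within jitter", {
  s <- generator_spec(n = 50, length = 1000L, at_fraction = 0.5,
                      motif = "SYTTWWAA", motif_probability = 1,
                      motif_center = -28L, jitter = 2L, seed = 75)
  g <- gen_promoters(s)
  sets <- expand_iupac("SYTTWWAA")
  for (i in seq_len(50)) {
    tr <- g$truth[i, ]
    expect_true(tr$motif_start_label %in% c(-33:-29))  # -31 +/- 2
    word <- substr(g$records[[i]]$sequence, tr$motif_start_offset + 1,
                   tr$motif_start_offset + 8)
    expect_identical(word, tr$motif_seq)
    expect_true(all(mapply(function(ch, st) ch %in% st,
                           strsplit(word, "")[[1]], sets)))
  }
})

test_that("architecture elements are planted at their canonical sites", {
  s <- generator_spec(n = 30, length = 100L, tss_index = 80L,
                      at_fraction = 0, elements = promoter_elements(),
                      seed = 76)
  g <- gen_promoters(s)
  for (rec in g$records) {
    chars <- strsplit(rec$sequence, "")[[1]]
    # initiator: pyrimidine at -1, purine at +1 (offsets 79, 80), no jitter
    expect_true(chars[80] %in% c("C", "T"))
    expect_true(chars[81] %in% c("A", "G"))
  }
  # GC-only background elsewhere means every A/T comes from an element
  at_pos <- which(strsplit(g$records[[1]]$sequence, "")[[1]] %in% c("A", "T"))
  labs <- sequence_labels(g$records[[1]])
  expect_true(all(labs[at_pos] >= -36 & labs[at_pos] <= 1))
})

test_that("generator validation rejects impossible geometries", {
  expect_error(generator_spec(n = 1, length = 30L, motif = "SYTTWWAA",
                              motif_center = -28L),
               "does not fit|tss_index")
  expect_error(generator_spec(n = 1, length = 101L), "even length")
  expect_error(generator_spec(n = 1, preset = "nope"), "unknown preset")
  expect_error(generator_spec(n = 1, length = 100L, at_fraction = 1.2))
})

test_that("organism presets carry the published compositions", {
  expect_equal(ORGANISM_PRESETS$at_fraction[ORGANISM_PRESETS$preset == "sso"],
               0.655)
  expect_equal(
    ORGANISM_PRESETS$at_fraction[ORGANISM_PRESETS$preset == "hvo_core"],
    0.400)
  core <- generator_spec(n = 1, preset = "tko_core", seed = 1)
  expect_equal(core$tss_index, 80L)
  expect_equal(core$length, 100L)
  full <- generator_spec(n = 1, preset = "tko", seed = 1)
  expect_equal(full$tss_index, 500L)
})

test_that("upstream regions place the insert flush with the 3' end", {
  s <- generator_spec(n = 4, length = 400L, at_fraction = 0.4, seed = 77)
  ins <- generator_spec(n = 1, preset = "hvo_core", motif_probability = 1)
  u <- gen_upstream(s, insert_spec = ins)
  expect_equal(u$truth$insert_start_offset, rep(300L, 4))
  expect_true(all(nchar(u$sequences) == 400L))
  expect_true(all(u$truth$has_motif))
  u0 <- gen_upstream(s, insert_at_end = FALSE)
  expect_true(all(is.na(u0$truth$insert_start_offset)))
  empty <- gen_upstream(generator_spec(n = 0, length = 400L, seed = 1))
  expect_length(empty$sequences, 0)
  expect_error(gen_upstream(generator_spec(n = 1, length = 100L, seed = 1)),
               "at least")
})

test_that("planted promoters are recovered end to end by classification", {
  g <- gen_promoters(generator_spec(n = 120, length = 1000L,
                                    at_fraction = 0.655,
                                    motif = "VYTTWWWW",
                                    motif_probability = 0.5, seed = 78))
  cores <- lapply(g$records, extract_core)
  cl <- classify_promoters(cores, "VYTTWWWW")
  planted <- g$truth$id[g$truth$has_motif]
  expect_true(all(planted %in% cl$conserved$id))  # recall 1 by construction
  # recorded matches on planted records are genuine occurrences
  m <- merge(cl$conserved, g$truth[g$truth$has_motif, ], by = "id")
  sets <- expand_iupac("VYTTWWWW")
  expect_true(all(vapply(m$match_seq, function(w) {
    all(mapply(function(ch, st) ch %in% st, strsplit(w, "")[[1]], sets))
  }, logical(1))))
})
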