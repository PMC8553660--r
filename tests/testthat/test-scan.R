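pent0 <- build_pentamer_table(zero_wedges())

make_cores <- function(n, seed, preset = "hvo_core", p = 1) {
  gen_promoters(generator_spec(n = n, preset = preset, seed = seed,
                               motif_probability = p,
                               elements = promoter_elements()))$records
}

test_that("the reference is the per-position mean of the pooled sequences", {
  cores <- make_cores(8, seed = 61)
  ref1 <- build_reference(cores, features = "stability")
  direct <- encode_set(cores, load_step_table("stability"))
  expect_equal(ref1$features$stability$mean_values, direct$mean_values)
  # two disjoint equal-size sets pool to the same mean
  ref2 <- build_reference(list(a = cores[1:4], b = cores[5:8]),
                          features = "stability")
  expect_equal(ref2$features$stability$mean_values, direct$mean_values)
  # equal-size sets: per-set weighting changes nothing
  ref3 <- build_reference(list(a = cores[1:4], b = cores[5:8]),
                          features = "stability", per_set_weighting = TRUE)
  expect_equal(ref3$features$stability$mean_values, direct$mean_values,
               tolerance = 1e-12)
  expect_error(build_reference(cores, features = character(0)), "empty")
  long <- tss_sequence("bad", random_dna(150), 75)
  expect_error(build_reference(list(list(long))), "core")
})

test_that("sliding correlation equals the direct cor() oracle", {
  set.seed(62)
  v <- rnorm(150)
  r <- rnorm(40)
  fast <- promstruct:::sliding_correlation(v, r)
  direct <- vapply(seq_len(length(v) - 39), function(s) {
    stats::cor(v[s:(s + 39)], r)
  }, numeric(1))
  expect_equal(fast, direct, tolerance = 1e-9)
  # missing values fall back to pairwise-complete correlation
  v_na <- v; v_na[c(10, 75)] <- NA
  slow <- promstruct:::sliding_correlation(v_na, r, min_n = 10)
  d2 <- vapply(seq_len(length(v) - 39), function(s) {
    w <- v_na[s:(s + 39)]
    ok <- !is.na(w)
    stats::cor(w[ok], r[ok])
  }, numeric(1))
  expect_equal(slow, d2, tolerance = 1e-9)
})

test_that("a window identical to the reference scores exactly 1", {
  core <- make_cores(1, seed = 63)[[1]]
  ref <- build_reference(list(list(core)), pentamers = pent0)
  seq <- paste0(random_dna(250), core$sequence, random_dna(50))
  set.seed(999)  # scan must not depend on ambient RNG
  hit <- scan_region(seq, ref, null_draws = 0, id = "self")
  expect_equal(hit$offset, 250)
  expect_equal(hit$score, 1, tolerance = 1e-9)
  expect_equal(unname(hit$feature_scores[c("stability", "enthalpy",
                                           "bendability")]),
               rep(1, 3), tolerance = 1e-9)
})

test_that("scores are invariant to affine rescaling of a feature's units", {
  cores <- make_cores(5, seed = 64)
  st <- load_step_table("stability")
  ref <- build_reference(cores, features = "stability")
  seq <- random_dna(300, at = 0.4)
  base <- promstruct:::sliding_correlation(
    promstruct:::encode_values(seq, st), ref$features$stability$mean_values)
  # rescale: x -> 3x - 2 on both reference and encoder side
  scaled_tab <- structure(3 * as.numeric(st) - 2, names = names(st),
                          feature = "stability", units = "arbitrary",
                          class = c("step_table", "numeric"))
  ref_scaled <- ref
  ref_scaled$features$stability$mean_values <-
    3 * ref$features$stability$mean_values - 2
  scaled <- promstruct:::sliding_correlation(
    promstruct:::encode_values(seq, scaled_tab),
    ref_scaled$features$stability$mean_values)
  expect_equal(base, scaled, tolerance = 1e-9)
})

test_that("scan input validation and missing-data handling", {
  cores <- make_cores(3, seed = 65)
  ref <- build_reference(cores, features = "stability")
  expect_error(scan_region(random_dna(90), ref, null_draws = 0), "shorter")
  # windows with too few usable positions are skipped
  seq <- paste0(random_dna(150), strrep("N", 60), random_dna(150))
  hit <- scan_region(seq, ref, null_draws = 0, seed = 1)
  expect_true(hit$offset <= 110 || hit$offset >= 140)
})

test_that("best offsets concentrate on a promoter-like 3' insert", {
  ref <- build_reference(make_cores(300, seed = 66))
  ins <- generator_spec(n = 1, preset = "hvo_core", motif_probability = 1,
                        elements = promoter_elements())
  ups <- gen_upstream(generator_spec(n = 30, length = 400L,
                                     at_fraction = 0.338, seed = 67),
                      insert_spec = ins)
  offs <- vapply(seq_along(ups$sequences), function(i) {
    scan_region(ups$sequences[[i]], ref, null_draws = 0, seed = 1)$offset
  }, numeric(1))
  expect_lte(stats::median(abs(offs - 300)), 5)
})

test_that("shuffled regions give calibrated z-scores", {
  ref <- build_reference(make_cores(200, seed = 68))
  nulls <- gen_upstream(generator_spec(n = 25, length = 400L,
                                       at_fraction = 0.338, seed = 69),
                        insert_at_end = FALSE)
  z <- vapply(seq_along(nulls$sequences), function(i) {
    scan_region(nulls$sequences[[i]], ref, null_draws = 40,
                seed = 700 + i)$z
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.5)
  expect_true(all(abs(z) < 5))
})

test_that("group profile comparison contracts hold", {
  cores <- make_cores(20, seed = 70)
  ref <- build_reference(cores, features = "bendability")
  same <- ref$features$bendability
  res <- compare_group_profiles(ref, same)
  expect_equal(res[[1]]$statistic, 0)
  expect_equal(res[[1]]$p_value, 1)
  shifted <- same
  shifted$mean_values <- shifted$mean_values + 5
  res2 <- compare_group_profiles(ref, list(same, shifted))
  expect_length(res2, 2)
  expect_equal(res2[[1]]$p_value, 1)
  expect_lt(res2[[2]]$p_value, 0.05)
  trimmed <- same
  trimmed$positions <- trimmed$positions[-1]
  trimmed$mean_values <- trimmed$mean_values[-1]
  expect_error(compare_group_profiles(ref, trimmed), "mismatch")
})
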