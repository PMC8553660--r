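# Shared fixtures: frozen printed parameter values, wedge-table builders and
# a brute-force curvature oracle kept independent of the package internals.

# The dinucleotide property table as printed in the source (enthalpy and
# stability in kcal/mol-bp, bendability in degrees), frozen here as the
# oracle for the packaged file.
PRINTED_TABLE <- data.frame(
  step        = c("AA", "AT", "AC", "AG", "TT", "TA", "TC", "TG",
                  "CC", "CA", "CT", "CG", "GG", "GA", "GT", "GC"),
  enthalpy    = c(-7.6, -7.2, -8.5, -8.2, -7.6, -7.2, -7.8, -8.4,
                  -8, -8.5, -7.8, -10.6, -8, -8.2, -8.4, -10.6),
  stability   = c(-1.00, -0.88, -1.45, -1.3, -1, -0.58, -1.28, -1.44,
                  -1.28, -1.45, -1.28, -2.24, -1.84, -1.3, -1.44, -2.24),
  bendability = c(3.07, 2.6, 2.97, 2.31, 3.07, 6.74, 2.51, 3.58,
                  2.16, 3.58, 2.31, 2.81, 2.16, 2.51, 2.97, 3.06),
  stringsAsFactors = FALSE
)

# Wedge table with every roll/tilt zero (twist kept positive).
zero_wedges <- function(twist = 34) {
  wedge_table(rep(0, 16), rep(0, 16), rep(twist, 16))
}

# Wedge table with named per-step roll/tilt overrides, zero elsewhere.
wedges_with <- function(roll = c(), tilt = c(), twist = 34) {
  r <- stats::setNames(rep(0, 16), promstruct:::ALL_STEPS)
  t <- r
  r[names(roll)] <- roll
  t[names(tilt)] <- tilt
  wedge_table(r, t, rep(twist, 16), steps = names(r))
}

# Brute-force curvature oracle: builds every step's deflection vector
# explicitly (rotation matrix, running twist) and sums; independent of
# window_curvature()'s complex-arithmetic path.
oracle_curvature <- function(kmer, wedges) {
  chars <- strsplit(kmer, "")[[1]]
  acc <- c(0, 0)
  twist_sum <- 0
  for (i in seq_len(length(chars) - 1)) {
    step <- paste0(chars[i], chars[i + 1])
    th <- twist_sum * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    acc <- acc + rot %*% c(wedges[step, "roll"], wedges[step, "tilt"])
    twist_sum <- twist_sum + wedges[step, "twist"]
  }
  sqrt(sum(acc^2)) / (length(chars) - 1)
}

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# A -80..+20 core with `insert` occupying the run of labels starting at
# `at_label`, embedded in a non-matching C/G checkerboard background.
core_with <- function(insert, at_label, background = "CG") {
  bg <- strrep(background, 50)
  rec <- tss_sequence("core", substr(bg, 1, 100), 80L)
  start <- label_to_offset(at_label, 80L)
  s <- rec$sequence
  substr(s, start + 1, start + nchar(insert)) <- insert
  tss_sequence("core", s, 80L)
}

# Exact two-sided rank-sum p by enumeration of all group labelings;
# independent oracle for rank_sum_test's exact path.
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mu <- n * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}
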