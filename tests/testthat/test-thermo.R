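# Energy model: triplet encoding, weighted energies, mismatch adjustment,
# and the FH log-intensity form.

test_that("triplet_index follows the base-4 encoding", {
  expect_equal(triplet_index("A", "A", "A"), 0L)
  expect_equal(triplet_index("T", "T", "T"), 63L)
  expect_equal(triplet_index("A", "C", "G"), 6L)
  expect_error(triplet_index("A", "N", "G"), "A, C, G, T")
})

test_that("the model serializes to exactly 343 parameters and round-trips", {
  m <- random_model(11)
  expect_equal(n_parameters(m), 343L)
  p <- pack_model(m)
  expect_length(p, 343L)
  m2 <- unpack_model(p)
  expect_equal(pack_model(m2), p)
  expect_error(energy_model(rep(1, 63), rep(0, 64), rep(0, 192), rep(1, 19),
                            1, 1, 1, 1), "64")
  expect_error(energy_model(rep(1, 64), rep(0, 64), rep(-1, 192), rep(1, 19),
                            1, 1, 1, 1), ">= 0")
})

test_that("weighted energies match closed forms and the brute-force oracle", {
  seqs <- vapply(1:25, function(i) random_genome(1000, 0.5, 100 + i),
                 character(1)) |> substr(1, 21)
  uni <- make_uniform_model(eps_s = 1, eps_ns = 0, w = 1)
  expect_equal(specific_energy(uni, seqs), rep(19, 25))
  expect_equal(nonspecific_energy(uni, seqs), rep(0, 25))
  zero_w <- make_uniform_model(w = 0)
  expect_equal(specific_energy(zero_w, seqs), rep(0, 25))
  cc <- make_uniform_model(eps_ns = 0.3, w = 0.5)
  expect_equal(nonspecific_energy(cc, seqs), rep(19 * 0.3 * 0.5, 25))
  m <- random_model(21)
  expect_equal(specific_energy(m, seqs),
               vapply(seqs, function(s)
                 o_weighted_energy(m$eps_specific, m$weights, s), numeric(1),
                 USE.NAMES = FALSE),
               tolerance = 1e-12)
  expect_equal(nonspecific_energy(m, seqs),
               vapply(seqs, function(s)
                 o_weighted_energy(m$eps_nonspecific, m$weights, s),
                 numeric(1), USE.NAMES = FALSE),
               tolerance = 1e-12)
})

test_that("mismatch counting covers the five configurations", {
  g <- random_genome(1000, 0.5, 31)
  d <- build_tiling_design(g)
  m <- random_model(32)
  tab <- probe_table(d, sequences = FALSE)

  # choose a forward PM probe away from the origin and a substitution
  pm_row <- which(tab$kind == "PM" & tab$position == 500L)
  mm_rows <- which(tab$kind == "MM" & tab$position == 500L)
  ref <- substr(g, 500, 500)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  hyp <- hypothesis(500L, alt)

  Gs_pm <- specific_energy(m, probe_sequences(d, pm_row))

  # PM / reference: zero mismatches
  expect_equal(mismatch_adjusted_energy(m, d, NULL, pm_row), Gs_pm)
  # MM / reference: exactly one penalty
  for (r in mm_rows) {
    got <- mismatch_adjusted_energy(m, d, NULL, r)
    expect_equal(got, o_adjusted_Gs(m, g, 500L, tab$strand[r], "MM",
                                    tab$central_alt[r]), tolerance = 1e-12)
    expect_lt(got, Gs_pm)
  }
  # PM spanning the substitution: one penalty
  got_pm_hyp <- mismatch_adjusted_energy(m, d, hyp, pm_row)
  expect_equal(got_pm_hyp, o_adjusted_Gs(m, g, 500L, tab$strand[pm_row], "PM",
                                         NA, 500L, alt), tolerance = 1e-12)
  expect_lt(got_pm_hyp, Gs_pm)
  # MM whose central alt equals the mutant base: zero penalties (becomes PM)
  strand <- tab$strand[pm_row]
  alt_probe_space <- if (strand == "+") alt else o_revcomp(alt)
  conv <- mm_rows[tab$central_alt[mm_rows] == alt_probe_space]
  expect_equal(mismatch_adjusted_energy(m, d, hyp, conv), Gs_pm)
  # MM spanning the substitution off-center: two penalties
  mm_off <- which(tab$kind == "MM" & tab$position == 505L)[1]
  ref505 <- mismatch_adjusted_energy(m, d, NULL, mm_off)
  two <- mismatch_adjusted_energy(m, d, hyp, mm_off)
  expect_lt(two, ref505)
  expect_equal(two, o_adjusted_Gs(m, g, 505L, tab$strand[mm_off], "MM",
                                  tab$central_alt[mm_off], 500L, alt),
               tolerance = 1e-12)
})

test_that("oracle equivalence holds on many random probes and models", {
  g <- random_genome(2000, 0.45, 41)
  d <- build_tiling_design(g)
  tab <- probe_table(d, sequences = FALSE)
  set.seed(42)
  rows <- sample.int(nrow(tab), 250L)
  for (ms in 1:4) {
    m <- random_model(50 + ms)
    got <- mismatch_adjusted_energy(m, d, NULL, rows)
    want <- vapply(rows, function(r)
      o_adjusted_Gs(m, g, tab$position[r], tab$strand[r], tab$kind[r],
                    tab$central_alt[r]), numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("FH log intensity matches direct arithmetic and obeys its limits", {
  m <- random_model(61)
  Gs <- seq(-2, 25, length.out = 40)
  Gns <- rep(1.2, 40); Gf <- rep(0.8, 40)
  expect_equal(fh_log_intensity(m, Gs, Gns, Gf),
               o_log_intensity(m, Gs, Gns, Gf), tolerance = 1e-12)
  # hand-evaluated closed form on a small instance
  hand <- make_uniform_model(alpha = 0.5, A = 100, B = 10, Cns = 0.2)
  K <- exp(0.5 * 2); Kn <- exp(0.5 * 1) * 0.2; Kf <- exp(0.5 * 3)
  expect_equal(fh_log_intensity(hand, 2, 1, 3),
               log(100 * (K + Kn) / (1 + Kf + K + Kn) + 10),
               tolerance = 1e-12)
  # limits: no specific signal, fully folded probe
  zeroA <- make_uniform_model(A = 1e-300)
  expect_equal(fh_log_intensity(zeroA, 5, 1, 0), log(zeroA$background),
               tolerance = 1e-6)
  expect_equal(fh_log_intensity(m, 5, 1, 1e6), log(m$background))
  # deletion encoding: specific term absent
  del <- fh_log_intensity(m, -Inf, 1, 0)
  expect_gt(del, log(m$background))
  expect_lt(del, fh_log_intensity(m, 5, 1, 0))
  # saturation: strictly inside (log B, log(A + B))
  big <- fh_log_intensity(m, 20, 1, 0)
  expect_lt(big, log(m$intensity_scale + m$background))
  expect_gt(fh_log_intensity(m, -20, -20, 0), log(m$background))
  # monotone: increasing in Gs, decreasing in Gf
  v <- fh_log_intensity(m, Gs, 1, 0)
  expect_true(all(diff(v) > 0))
  vf <- fh_log_intensity(m, 5, 1, seq(0, 10, 0.5))
  expect_true(all(diff(vf) < 0))
})

test_that("adding a positive penalty never increases predicted intensity", {
  g <- random_genome(1000, 0.5, 71)
  d <- build_tiling_design(g)
  m <- random_model(72)
  rows <- 1:200
  base <- predict_log_intensity(m, d, NULL, rows = rows)
  m2 <- m
  m2$penalty <- m$penalty + 0.5
  expect_true(all(predict_log_intensity(m2, d, NULL, rows = rows) <= base))
})

test_that("predicted log ratios are zero off-span and signed as expected", {
  g <- random_genome(1000, 0.5, 81)
  d <- build_tiling_design(g)
  m <- random_model(82)
  ref <- substr(g, 300, 300)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  hyp <- hypothesis(300L, alt)
  rows <- seq_len(nrow(d$probes))
  ratio <- predict_log_ratio(m, d, hyp, rows = rows)
  off <- abs(d$probes$position - 300L) > 10L &
    abs(d$probes$position - 300L) < 990L
  expect_true(all(ratio[off] == 0))
  expect_equal(predict_log_ratio(m, d, NULL, rows = 1:10), rep(0, 10))
  # PM probes spanning the substitution lose intensity
  pm_span <- which(d$probes$kind == "PM" &
                     abs(d$probes$position - 300L) <= 10L)
  expect_true(all(ratio[pm_span] < 0))
  # the MM probe converted into a PM gains intensity
  tabc <- probe_table(d, sequences = FALSE)
  strand300 <- tabc$strand[tabc$position == 300L][1]
  alt_ps <- if (strand300 == "+") alt else o_revcomp(alt)
  conv <- which(tabc$kind == "MM" & tabc$position == 300L &
                  tabc$central_alt == alt_ps)
  expect_gt(ratio[conv], 0)
})

test_that("hypothesis objects are validated", {
  expect_null(hypothesis())
  expect_error(hypothesis(5), "both")
  expect_error(hypothesis(5, "N"), "A, C, G, T")
  g <- random_genome(1000, 0.5, 91)
  d <- build_tiling_design(g)
  m <- random_model(92)
  ref <- substr(g, 100, 100)
  expect_error(predict_log_intensity(m, d, hypothesis(100L, ref), rows = 1:4),
               "differ")
})
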