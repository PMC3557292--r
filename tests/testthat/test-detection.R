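# Residual statistics, candidate-region screening, and LLR calling.

det_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 4000, n_substitutions = 3,
                        min_spacing = 300, noise_sd = 0, seed = 401)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

test_that("identical samples give zero residuals and no calls", {
  fx <- det_fixture()
  prof <- residual_profile(fx$model, fx$design, fx$wt, fx$wt,
                           folding = fx$folding)
  expect_true(all(abs(prof$D) < 1e-18))
  expect_equal(nrow(screen_candidate_regions(prof)), 0L)
  # null data: LLR never positive beyond rounding
  for (i in c(50L, 1234L)) {
    ref <- substr(fx$genome, i, i)
    for (b in setdiff(c("A", "C", "G", "T"), ref)) {
      expect_lte(likelihood_ratio(fx$model, fx$design, fx$wt, fx$wt, i, b,
                                  fx$folding), 1e-12)
    }
  }
})

test_that("residuals and LLRs equal brute-force recomputation from definitions", {
  fx <- det_fixture()
  ptab <- probe_table(fx$design, sequences = FALSE)
  pts <- c(fx$truth$position[1], fx$truth$position[1] + 4L, 777L)
  for (i in pts) {
    ref <- substr(fx$genome, i, i)
    D_pkg <- position_residual(fx$model, fx$design, fx$wt, fx$mut, i,
                               folding = fx$folding)
    D_orc <- o_position_residual(fx$model, fx$genome, ptab, fx$folding,
                                 fx$wt, fx$mut, i, NULL)
    expect_equal(D_pkg, D_orc, tolerance = 1e-10)
    for (b in setdiff(c("A", "C", "G", "T"), ref)) {
      E_pkg <- position_residual(fx$model, fx$design, fx$wt, fx$mut, i, b,
                                 fx$folding)
      E_orc <- o_position_residual(fx$model, fx$genome, ptab, fx$folding,
                                   fx$wt, fx$mut, i, b)
      expect_equal(E_pkg, E_orc, tolerance = 1e-10)
      expect_equal(likelihood_ratio(fx$model, fx$design, fx$wt, fx$mut, i, b,
                                    fx$folding), D_pkg - E_pkg,
                   tolerance = 1e-12)
    }
  }
})

test_that("noise-free forward-model self-consistency: E(i*,b*) = 0, argmax at truth", {
  fx <- det_fixture()
  prof <- residual_profile(fx$model, fx$design, fx$wt, fx$mut,
                           folding = fx$folding)
  regs <- screen_candidate_regions(prof)
  expect_equal(nrow(regs), nrow(fx$truth))
  best <- region_max_llr(fx$model, fx$design, fx$wt, fx$mut, regs, fx$folding)
  setkey(best, position)
  expect_equal(best$position, fx$truth$position)
  expect_equal(best$alt, fx$truth$alt)
  for (j in seq_len(nrow(fx$truth))) {
    E <- position_residual(fx$model, fx$design, fx$wt, fx$mut,
                           fx$truth$position[j], fx$truth$alt[j], fx$folding)
    expect_lt(E, 1e-18)
    D <- position_residual(fx$model, fx$design, fx$wt, fx$mut,
                           fx$truth$position[j], folding = fx$folding)
    expect_gt(D, 0)
  }
})

test_that("the running average and threshold behave as defined", {
  fx <- det_fixture()
  prof <- residual_profile(fx$model, fx$design, fx$wt, fx$mut, window = 11,
                           k_sd = 2, folding = fx$folding)
  # two-pass recomputation of the profile statistics
  expect_equal(prof$theta_R, mean(prof$D) + 2 * sd(prof$D), tolerance = 1e-12)
  L <- length(prof$D)
  for (i in c(1L, 57L, 2000L, L)) {
    idx <- ((i + (-5:5)) - 1L) %% L + 1L
    expect_equal(prof$running_avg[i], mean(prof$D[idx]), tolerance = 1e-12)
  }
  expect_error(residual_profile(fx$model, fx$design, fx$wt, fx$mut,
                                window = 10, folding = fx$folding), "odd")
  # uniformly scaled mutant sample: constant D, running average equals it
  scaled <- intensity_table(fx$wt$probe_id, fx$wt$intensity * exp(0.3), "sc")
  pc <- residual_profile(fx$model, fx$design, fx$wt, scaled,
                         folding = fx$folding)
  expect_equal(pc$D, rep(84 * 0.3^2, L), tolerance = 1e-12)
  expect_equal(pc$running_avg, pc$D, tolerance = 1e-12)
  # huge k_sd: nothing exceeds the threshold
  prof_hi <- residual_profile(fx$model, fx$design, fx$wt, fx$mut, window = 11,
                              k_sd = 1e6, folding = fx$folding)
  expect_equal(nrow(screen_candidate_regions(prof_hi)), 0L)
})

test_that("region screening enforces length rules and wraps the origin", {
  prof <- structure(list(D = numeric(200), running_avg = numeric(200),
                         theta_R = 0.5, window = 11L, k_sd = 2,
                         genome_length = 200L, circular = TRUE,
                         genome_id = "toy"),
                    class = "residual_profile")
  # a 9-bp run: dropped
  prof$running_avg[51:59] <- 1
  expect_equal(nrow(screen_candidate_regions(prof)), 0L)
  # a 10-bp run: kept
  prof$running_avg[51:60] <- 1
  regs <- screen_candidate_regions(prof)
  expect_equal(regs$start, 51L)
  expect_equal(regs$end, 60L)
  expect_false(regs$structural)
  # an 80-bp run: structural
  prof$running_avg[] <- 0
  prof$running_avg[100:179] <- 1
  regs <- screen_candidate_regions(prof)
  expect_true(regs$structural)
  # run crossing the origin is merged
  prof$running_avg[] <- 0
  prof$running_avg[c(195:200, 1:6)] <- 1
  regs <- screen_candidate_regions(prof)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$start, 195L)
  expect_equal(regs$end, 6L)
  expect_equal(regs$length, 12L)
})

test_that("calling respects the strict theta_L threshold and tie rules", {
  fx <- det_fixture()
  prof <- residual_profile(fx$model, fx$design, fx$wt, fx$mut,
                           folding = fx$folding)
  regs <- screen_candidate_regions(prof)
  best <- region_max_llr(fx$model, fx$design, fx$wt, fx$mut, regs, fx$folding)
  expect_equal(nrow(call_substitutions(fx$model, fx$design, fx$wt, fx$mut,
                                       regs, Inf, fx$folding)), 0L)
  # a region whose max equals theta_L exactly is not called (strict >)
  th <- min(best$llr)
  called <- call_substitutions(fx$model, fx$design, fx$wt, fx$mut, regs, th,
                               fx$folding)
  expect_equal(nrow(called), nrow(best) - 1L)
  expect_equal(nrow(call_substitutions(fx$model, fx$design, fx$wt, fx$mut,
                                       regs, max(best$llr), fx$folding)), 0L)
  all_called <- call_substitutions(fx$model, fx$design, fx$wt, fx$mut, regs,
                                   -Inf, fx$folding)
  expect_equal(nrow(all_called), nrow(best))
})

test_that("a simulated deletion yields a structural region with no call inside", {
  cfg <- sim_config(genome_length = 4000, n_substitutions = 2,
                    min_spacing = 300, deletions = list(c(2000L, 500L)),
                    noise_sd = 0, seed = 402)
  sim <- simulate_dataset(cfg)
  prof <- residual_profile(sim$model, sim$design, sim$wt, sim$mut,
                           folding = sim$folding)
  regs <- screen_candidate_regions(prof)
  struct <- regs[regs$structural]
  expect_equal(nrow(struct), 1L)
  expect_gte(struct$length, 80L)
  expect_lte(abs(struct$start - 2000L), 30L)
  calls <- call_substitutions(sim$model, sim$design, sim$wt, sim$mut, regs,
                              -Inf, sim$folding)
  inside <- calls$position >= 2000L & calls$position < 2500L
  expect_false(any(inside))
  expect_equal(sort(calls$position), sim$truth$position)
})
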