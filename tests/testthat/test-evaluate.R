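# Truth-set filtering, call matching, curves, threshold selection.

test_that("neighboring substitutions are both removed", {
  g <- random_genome(2000, 0.5, 71)
  truth <- data.table::data.table(
    position = c(300L, 310L, 1000L),
    ref = substring(g, c(300, 310, 1000), c(300, 310, 1000)),
    alt = "A")
  truth$alt <- ifelse(truth$ref == "A", "C", "A")
  out <- filter_truth_substitutions(truth, g, gc_low = 0, gc_high = 1)
  expect_equal(out$position, 1000L)
  expect_equal(attr(out, "removed")[["neighbor"]], 2L)
})

test_that("substitutions inside repeated 21-mers are removed", {
  unit <- random_genome(1000, 0.5, 72)
  core <- substr(unit, 1, 100)
  g <- paste0(core, random_genome(1000, 0.5, 73), core,
              random_genome(1000, 0.5, 74))
  pos_rep <- 50L                      # inside the duplicated block
  pos_uniq <- 600L
  truth <- data.table::data.table(
    position = c(pos_rep, pos_uniq),
    ref = substring(g, c(pos_rep, pos_uniq), c(pos_rep, pos_uniq)))
  truth$alt <- ifelse(truth$ref == "A", "C", "A")
  out <- filter_truth_substitutions(truth, g, gc_low = 0, gc_high = 1,
                                    circular = FALSE)
  expect_equal(out$position, pos_uniq)
  expect_equal(attr(out, "removed")[["repeated"]], 1L)
})

test_that("the GC filter uses the centered window and permissive bounds keep all", {
  set.seed(75)
  gc_block <- paste(sample(c("G", "C"), 41, replace = TRUE), collapse = "")
  at_block <- paste(sample(c("A", "T"), 41, replace = TRUE), collapse = "")
  g <- paste0(random_genome(1000, 0.5, 75), gc_block,
              random_genome(1000, 0.5, 76), at_block,
              random_genome(1000, 0.5, 77))
  pos <- c(1021L, 1500L, 2062L)   # centers of the GC block, random, AT block
  truth <- data.table::data.table(position = pos,
                                  ref = substring(g, pos, pos))
  truth$alt <- ifelse(truth$ref == "A", "C", "A")
  out <- filter_truth_substitutions(truth, g, gc_low = 0.2, gc_high = 0.8,
                                    circular = FALSE)
  expect_equal(out$position, 1500L)
  expect_equal(attr(out, "removed")[["gc"]], 2L)
  all_kept <- filter_truth_substitutions(truth, g, gc_low = 0, gc_high = 1,
                                         circular = FALSE)
  expect_equal(nrow(all_kept), 3L)
})

test_that("matching handles identity, tolerance boundaries, and bases", {
  truth <- data.table::data.table(position = c(100L, 200L, 300L),
                                  ref = c("A", "C", "G"),
                                  alt = c("C", "G", "T"))
  perfect <- data.table::data.table(position = truth$position,
                                    alt = truth$alt)
  ev <- match_calls(perfect, truth, tol_bp = 2)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$fp, 0L)
  expect_equal(ev$exact_position, 3L)
  expect_equal(ev$exact_position_base, 3L)
  # a call 3 bp away with tol 2: both FP and FN
  off <- data.table::data.table(position = 103L, alt = "C")
  ev2 <- match_calls(off, truth, tol_bp = 2)
  expect_equal(ev2$tp, 0L)
  expect_equal(ev2$fp, 1L)
  expect_equal(ev2$fn, 3L)
  # 2 bp away matches, but is not an exact-position match
  near <- data.table::data.table(position = 102L, alt = "G")
  ev3 <- match_calls(near, truth, tol_bp = 2)
  expect_equal(ev3$tp, 1L)
  expect_equal(ev3$exact_position, 0L)
  expect_equal(ev3$exact_position_base, 0L)
})

test_that("greedy matching agrees with exhaustive bipartite search on small cases", {
  # exhaustive maximum matching restricted to pairs within tolerance
  exhaustive_tp <- function(calls, truth, tol) {
    ok <- outer(calls$position, truth$position,
                function(a, b) abs(a - b) <= tol)
    n <- nrow(calls)
    best <- 0L
    assign_next <- function(ci, used) {
      if (ci > n) return(0L)
      res <- assign_next(ci + 1L, used)    # leave call unmatched
      for (ti in which(ok[ci, ] & !used)) {
        used[ti] <- TRUE
        res <- max(res, 1L + assign_next(ci + 1L, used))
        used[ti] <- FALSE
      }
      res
    }
    assign_next(1L, logical(nrow(truth)))
  }
  set.seed(77)
  for (rep in 1:20) {
    calls <- data.table::data.table(position = sample(1:60, 5), alt = "A")
    truth <- data.table::data.table(position = sample(1:60, 5),
                                    ref = "C", alt = "G")
    ev <- match_calls(calls, truth, tol_bp = 2)
    expect_equal(ev$tp, exhaustive_tp(calls, truth, 2L))
  }
})

test_that("threshold selection maximizes TP - FP with ties toward larger theta", {
  curve <- data.table::data.table(theta_L = c(1, 2, 3, 4),
                                  tp = c(10L, 9L, 9L, 5L),
                                  fp = c(3L, 2L, 2L, 0L))
  # scores: 7, 7, 7, 5 -> tie among 1,2,3 -> pick 3
  expect_equal(best_threshold(curve), 3)
  expect_equal(best_threshold(curve[1]), 1)
  expect_error(best_threshold(curve[0]), "nonempty")
})

test_that("the sensitivity/FP curve is a monotone step function of theta_L", {
  cfg <- sim_config(genome_length = 4000, n_substitutions = 3,
                    min_spacing = 300, noise_sd = 0.05, seed = 81)
  sim <- simulate_dataset(cfg)
  prof <- residual_profile(sim$model, sim$design, sim$wt, sim$mut,
                           folding = sim$folding)
  regs <- screen_candidate_regions(prof)
  best <- region_max_llr(sim$model, sim$design, sim$wt, sim$mut, regs,
                         sim$folding)
  curve <- threshold_curve(best, sim$truth, tol_bp = 2)
  o <- order(curve$theta_L)
  expect_true(all(diff(curve$tp[o]) <= 0))
  expect_true(all(diff(curve$fp[o]) <= 0))
  # exhaustive-scan agreement for the selected threshold
  score <- curve$tp - curve$fp
  cand <- curve$theta_L[score == max(score)]
  expect_equal(best_threshold(curve), max(cand))
})
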