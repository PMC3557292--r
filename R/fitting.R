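# Estimation of the 343 energy-model parameters from reference-sample
# intensities: residual-sum-of-squares objective, a seeded
# differential-evolution population search initialized by an
# alternating-least-squares heuristic, and a Levenberg-Marquardt polish of
# the best candidate.  Global scalars are searched on the log scale.

#' Default fitting bounds
#'
#' Per-group `(lower, upper)` search bounds: triplet energies and penalties
#' in \[0, 10\], weights in \[0, 1\], global scalars bounded on the log
#' scale.
#'
#' @return Named list of numeric `c(lower, upper)` pairs (scalars on the
#'   natural scale; they are log-transformed internally).
#' @export
default_fit_bounds <- function() {
  list(eps_specific = c(0, 10), eps_nonspecific = c(0, 10),
       penalty = c(0, 10), weights = c(0, 1),
       alpha = c(0.05, 5), intensity_scale = c(10, 1e6),
       background = c(1, 1e4), conc_nonspecific = c(1e-5, 10))
}

#' Fitting configuration
#'
#' @param seed Integer RNG seed (mandatory; the fit is bit-reproducible
#'   given inputs and configuration).
#' @param population_size Population size of the search (>= 8).
#' @param generations Number of generations.
#' @param bounds Per-group bounds, as [default_fit_bounds()].
#' @param tolerance Stop early when the best objective improves by less than
#'   this over `patience` generations.
#' @param patience Generations without sufficient improvement tolerated
#'   before early stopping.
#' @param subset_fraction Fraction of probes (uniformly sampled, seeded) the
#'   objective is evaluated on during the search; 1 fits on all probes.
#' @param F,CR Differential-evolution mutation weight and crossover rate.
#' @param polish Run a bounded Levenberg-Marquardt refinement
#'   (`minpack.lm::nls.lm`) of the best member after the population search.
#' @param polish_maxit Maximum LM iterations.
#' @return A `fit_config` object.
#' @export
fit_config <- function(seed, population_size = 40L, generations = 150L,
                       bounds = default_fit_bounds(), tolerance = 1e-8,
                       patience = 30L, subset_fraction = 1,
                       F = 0.7, CR = 0.9, polish = TRUE,
                       polish_maxit = 100L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  population_size <- as.integer(population_size)
  if (population_size < 8L) stop("population_size must be >= 8", call. = FALSE)
  if (!all(is.finite(unlist(bounds)))) stop("bounds must be finite", call. = FALSE)
  structure(
    list(seed = as.integer(seed), population_size = population_size,
         generations = as.integer(generations), bounds = bounds,
         tolerance = tolerance, patience = as.integer(patience),
         subset_fraction = subset_fraction, F = F, CR = CR,
         polish = isTRUE(polish), polish_maxit = as.integer(polish_maxit)),
    class = "fit_config"
  )
}

# search-space vector (scalars on log scale) <-> model
.pack_search <- function(model) {
  p <- pack_model(model)
  p[340:343] <- log(p[340:343])
  p
}

.unpack_search <- function(par) {
  par[340:343] <- exp(par[340:343])
  unpack_model(par)
}

.search_bounds <- function(bounds) {
  lower <- c(rep(bounds$eps_specific[1], 64), rep(bounds$eps_nonspecific[1], 64),
             rep(bounds$penalty[1], 192), rep(bounds$weights[1], 19),
             log(bounds$alpha[1]), log(bounds$intensity_scale[1]),
             log(bounds$background[1]), log(bounds$conc_nonspecific[1]))
  upper <- c(rep(bounds$eps_specific[2], 64), rep(bounds$eps_nonspecific[2], 64),
             rep(bounds$penalty[2], 192), rep(bounds$weights[2], 19),
             log(bounds$alpha[2]), log(bounds$intensity_scale[2]),
             log(bounds$background[2]), log(bounds$conc_nonspecific[2]))
  list(lower = lower, upper = upper)
}

# Precomputed per-probe structures for fast objective evaluation.
.fit_data <- function(design, observed, folding = NULL, rows = NULL) {
  dt <- if (is.null(rows)) design$probes else design$probes[rows]
  ids <- probe_ids(design, rows)
  obs <- observed$intensity[match(ids, observed$probe_id)]
  nmiss <- sum(is.na(obs))
  if (nmiss > 0) {
    stop(sprintf("observed table is missing %d probe value(s)", nmiss),
         call. = FALSE)
  }
  m <- .probe_code_matrix(design, rows)
  trip_ns <- .triplet_matrix(m)
  ref_center <- .pm_center_codes(design, rows)
  mm <- which(dt$kind == "MM")
  pm_m <- m
  if (length(mm)) pm_m[cbind(mm, 11L)] <- ref_center[mm]
  trip_pm <- .triplet_matrix(pm_m)
  pen_idx <- rep(NA_integer_, nrow(dt))
  if (length(mm)) {
    alt <- match(dt$central_alt[mm], BASES) - 1L
    pen_idx[mm] <- .penalty_index(trip_pm[mm, 10L], ref_center[mm], alt)
  }
  list(n = nrow(dt), y = log(obs), trip_pm = trip_pm, trip_ns = trip_ns,
       pen_idx = pen_idx, has_pen = !is.na(pen_idx),
       Gf = .folding_for_rows(design, folding, rows))
}

# predicted log intensities for a search-space parameter vector
.fit_predict <- function(par, fd) {
  eps_s <- par[1:64]; eps_ns <- par[65:128]
  penv <- par[129:320]; w <- par[321:339]
  alpha <- exp(par[340]); A <- exp(par[341])
  B <- exp(par[342]); Cns <- exp(par[343])
  Gs <- as.vector(matrix(eps_s[fd$trip_pm + 1L], nrow = fd$n) %*% w)
  Gs[fd$has_pen] <- Gs[fd$has_pen] - penv[fd$pen_idx[fd$has_pen]]
  Gns <- as.vector(matrix(eps_ns[fd$trip_ns + 1L], nrow = fd$n) %*% w)
  logS <- .logaddexp(alpha * Gs, alpha * Gns + log(Cns))
  logden <- .logaddexp(.logaddexp(0, alpha * fd$Gf), logS)
  log(B) + log1p(A / B * exp(logS - logden))
}

#' Residual-sum-of-squares fitting objective
#'
#' Sum over probes of the squared difference between observed and predicted
#' (reference-hypothesis) log intensities.  PM probes contribute with zero
#' mismatches, MM probes with their single central mismatch, so the penalty
#' parameters are exercised by the reference sample alone.
#'
#' @param model An [energy_model()].
#' @param design A `tiling_design`.
#' @param observed_wt An [intensity_table()] covering every probe in
#'   `design` (missing probes are an error reporting the count).
#' @param folding Per-probe folding energies.
#' @param rows Optional row subset of `design$probes`.
#' @return Non-negative numeric scalar.
#' @export
objective <- function(model, design, observed_wt, folding = NULL,
                      rows = NULL) {
  fd <- .fit_data(design, observed_wt, folding, rows)
  sum((fd$y - .fit_predict(.pack_search(model), fd))^2)
}

# Alternating-least-squares initializer: inverts the saturation to an
# approximate adjusted specific energy per probe, then alternates ridge
# solves for (eps_specific, weights) on PM probes and averages PM-MM energy
# gaps into the penalty table.
.heuristic_init <- function(fd, sb) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  I <- exp(fd$y)
  B0 <- clip(0.8 * min(I), exp(sb$lower[342]), exp(sb$upper[342]))
  A0 <- clip(1.1 * (max(I) - B0), exp(sb$lower[341]), exp(sb$upper[341]))
  alpha0 <- clip(1, exp(sb$lower[340]), exp(sb$upper[340]))
  C0 <- clip(0.05, exp(sb$lower[343]), exp(sb$upper[343]))
  frac <- clip((I - B0) / A0, 1e-4, 1 - 1e-3)
  S <- frac * (1 + exp(alpha0 * fd$Gf)) / (1 - frac)
  target <- log(S) / alpha0                    # approximate adjusted G_s
  pm <- which(!fd$has_pen)
  w <- 1 - abs(seq(2, 20) - 11) / 18           # triangular start
  eps_lo <- sb$lower[1]; eps_hi <- sb$upper[1]
  eps_s <- rep(mean(c(eps_lo, eps_hi)) / 4, 64)
  tpm <- fd$trip_pm[pm, , drop = FALSE]
  tgt <- target[pm]
  for (it in 1:4) {
    X <- matrix(0, length(pm), 64)
    for (k in 1:19) {
      idx <- cbind(seq_along(pm), tpm[, k] + 1L)
      X[idx] <- X[idx] + w[k]
    }
    eps_s <- tryCatch(
      clip(as.vector(solve(crossprod(X) + 1e-6 * diag(64), crossprod(X, tgt))),
           eps_lo, eps_hi),
      error = function(e) eps_s)
    Y <- matrix(eps_s[tpm + 1L], nrow = length(pm))
    w <- tryCatch(
      clip(as.vector(solve(crossprod(Y) + 1e-6 * diag(19), crossprod(Y, tgt))),
           max(sb$lower[321], 0.01), sb$upper[321]),
      error = function(e) w)
  }
  # penalties from PM-MM gaps in the recovered energy scale
  pen <- rep(mean(c(sb$lower[129], min(sb$upper[129], 3))), 192)
  mmr <- which(fd$has_pen)
  if (length(mmr)) {
    Gs_mm <- as.vector(matrix(eps_s[fd$trip_pm[mmr, , drop = FALSE] + 1L],
                              nrow = length(mmr)) %*% w)
    gap <- Gs_mm - target[mmr]
    ag <- rowsum(gap, fd$pen_idx[mmr])
    cn <- rowsum(rep(1, length(mmr)), fd$pen_idx[mmr])
    est <- clip(ag[, 1L] / cn[, 1L], sb$lower[129], sb$upper[129])
    pen[as.integer(rownames(ag))] <- est
  }
  eps_ns <- rep(clip(0.1, sb$lower[65], sb$upper[65]), 64)
  par <- c(eps_s, eps_ns, pen, w, log(alpha0), log(A0), log(B0), log(C0))
  clip(par, sb$lower, sb$upper)
}

#' Fit the energy model to reference-sample intensities
#'
#' Minimizes [objective()] by a seeded differential-evolution population
#' search whose population is initialized around an alternating-least-squares
#' heuristic (plus `init`, if given), followed by a bounded
#' Levenberg-Marquardt refinement of the best member.  Candidates with a
#' non-finite objective are discarded (and counted), never propagated.
#'
#' @inheritParams objective
#' @param config A [fit_config()].
#' @param init Optional starting [energy_model()]; included in the initial
#'   population.
#' @return An `fh_fit` list: `model` (fitted [energy_model()]), `objective`
#'   (on the probes used for fitting), `trajectory` (best objective per
#'   generation), `seed`, `rows` (fitted probe subset), `n_discarded`.
#' @export
fit_parameters <- function(design, observed_wt, config, init = NULL,
                           folding = NULL) {
  stopifnot(inherits(config, "fit_config"))
  sb <- .search_bounds(config$bounds)
  npar <- 343L
  n_discarded <- 0L

  .with_seed(config$seed, {
    rows <- if (config$subset_fraction < 1) {
      sort(sample.int(nrow(design$probes),
                      max(100L, round(config$subset_fraction *
                                        nrow(design$probes)))))
    } else {
      NULL
    }
    fd <- .fit_data(design, observed_wt, folding, rows)
    evalf <- function(par) {
      v <- sum((fd$y - .fit_predict(par, fd))^2)
      if (!is.finite(v)) {
        n_discarded <<- n_discarded + 1L
        v <- Inf
      }
      v
    }
    h0 <- .heuristic_init(fd, sb)
    NP <- config$population_size
    pop <- matrix(0, NP, npar)
    pop[1L, ] <- h0
    k <- 2L
    if (!is.null(init)) {
      pop[2L, ] <- pmin(pmax(.pack_search(init), sb$lower), sb$upper)
      k <- 3L
    }
    span <- sb$upper - sb$lower
    for (j in k:NP) {
      pop[j, ] <- if (j %% 2L == 0L) {
        pmin(pmax(h0 + stats::rnorm(npar, 0, 0.05 * span), sb$lower), sb$upper)
      } else {
        sb$lower + stats::runif(npar) * span
      }
    }
    fit <- apply(pop, 1L, evalf)
    best_traj <- numeric(config$generations)
    best_val <- min(fit)
    stall <- 0L
    for (gen in seq_len(config$generations)) {
      for (j in seq_len(NP)) {
        r <- sample(setdiff(seq_len(NP), j), 3L)
        v <- pop[r[1L], ] + config$F * (pop[r[2L], ] - pop[r[3L], ])
        jrand <- sample.int(npar, 1L)
        cross <- stats::runif(npar) < config$CR
        cross[jrand] <- TRUE
        u <- ifelse(cross, v, pop[j, ])
        # reflect into bounds
        u <- ifelse(u < sb$lower, pmin(2 * sb$lower - u, sb$upper), u)
        u <- ifelse(u > sb$upper, pmax(2 * sb$upper - u, sb$lower), u)
        fu <- evalf(u)
        if (fu <= fit[j]) {
          pop[j, ] <- u
          fit[j] <- fu
        }
      }
      new_best <- min(fit)
      if (best_val - new_best < config$tolerance) {
        stall <- stall + 1L
      } else {
        stall <- 0L
      }
      best_val <- min(best_val, new_best)
      best_traj[gen] <- best_val
      if (stall >= config$patience) {
        best_traj <- best_traj[seq_len(gen)]
        break
      }
    }
    best_par <- pop[which.min(fit), ]
    if (config$polish) {
      res <- tryCatch(
        minpack.lm::nls.lm(
          par = best_par,
          fn = function(p) fd$y - .fit_predict(p, fd),
          lower = sb$lower, upper = sb$upper,
          control = minpack.lm::nls.lm.control(
            maxiter = config$polish_maxit, nprint = 0)),
        error = function(e) NULL)
      if (!is.null(res)) {
        pol_val <- evalf(res$par)
        if (is.finite(pol_val) && pol_val <= min(fit)) {
          best_par <- res$par
          best_val <- pol_val
        }
      }
    }
    structure(
      list(model = .unpack_search(best_par),
           objective = min(best_val, min(fit)),
           trajectory = best_traj,
           seed = config$seed,
           rows = rows,
           n_discarded = n_discarded,
           config = config),
      class = "fh_fit"
    )
  })
}

#' @export
print.fh_fit <- function(x, ...) {
  cat(sprintf(
    "fh_fit: objective %.6g after %d generation(s)%s (seed %d)\n",
    x$objective, length(x$trajectory),
    if (x$config$polish) " + LM polish" else "", x$seed))
  invisible(x)
}
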