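# Seeded synthetic-data generator: random genomes, implanted substitutions
# and deletions, ground-truth energy models, and forward-model intensity
# tables with multiplicative log-normal noise.  Every artifact is a pure
# function of the configuration (including its seed).

#' Random genome sequence
#'
#' I.i.d. bases with `P(G) + P(C) = gc_content`, split evenly within the
#' GC and AT pairs.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_content GC fraction, strictly inside (0, 1).
#' @param seed Integer RNG seed.
#' @return Character scalar genome sequence.
#' @export
random_genome <- function(length, gc_content = 0.5, seed = 1L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1000L) {
    stop("genome length must be at least 1000 bp", call. = FALSE)
  }
  if (!is.numeric(gc_content) || gc_content <= 0 || gc_content >= 1) {
    stop("gc_content must lie strictly inside (0, 1)", call. = FALSE)
  }
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  .with_seed(seed, paste(sample(BASES, length, replace = TRUE, prob = p),
                         collapse = ""))
}

#' Implant single-base substitutions into a genome
#'
#' Draws `n` positions uniformly subject to a minimum pairwise spacing
#' (enforced with circular wrap-around), substitutes each with a base drawn
#' uniformly from the three non-reference bases, and returns the mutant
#' sequence with the truth records.
#'
#' @param genome Character scalar genome sequence.
#' @param n Number of substitutions.
#' @param min_spacing Minimum distance in bp between substitutions (>= 22 so
#'   no probe spans two of them).
#' @param seed Integer RNG seed.
#' @param exclude Optional list of `c(start, length)` intervals (e.g. planned
#'   deletions) that substitutions must avoid, with a `min_spacing` margin.
#' @return `list(mutant = <sequence>, truth = data.table(position, ref, alt))`
#'   with truth ordered by position.
#' @export
implant_substitutions <- function(genome, n, min_spacing = 100L, seed = 1L,
                                  exclude = NULL) {
  stopifnot(is.character(genome), length(genome) == 1L)
  L <- nchar(genome)
  n <- as.integer(n)
  min_spacing <- as.integer(min_spacing)
  if (min_spacing < 22L) stop("min_spacing must be >= 22 bp", call. = FALSE)
  if (n * min_spacing >= L) {
    stop("n * min_spacing must be smaller than the genome length", call. = FALSE)
  }
  codes <- .base_lookup[utf8ToInt(toupper(genome))]
  blocked <- is.na(codes)
  block_around <- function(p) {
    span <- .wrap(p + seq.int(-min_spacing, min_spacing), L)
    blocked[span] <<- TRUE
  }
  if (!is.null(exclude)) {
    for (iv in exclude) {
      span <- .wrap(iv[1L] + seq.int(-min_spacing, iv[2L] - 1L + min_spacing), L)
      blocked[span] <- TRUE
    }
  }
  res <- .with_seed(seed, {
    order <- sample.int(L)
    chosen <- integer(0)
    for (p in order) {
      if (length(chosen) == n) break
      if (!blocked[p]) {
        chosen <- c(chosen, p)
        block_around(p)
      }
    }
    if (length(chosen) < n) {
      stop(sprintf(
        "could not place %d substitutions at spacing %d (maximum feasible: %d)",
        n, min_spacing, length(chosen)), call. = FALSE)
    }
    alt <- vapply(chosen, function(p) {
      sample(BASES[-(codes[p] + 1L)], 1L)
    }, character(1L))
    list(position = chosen, alt = alt)
  })
  truth <- data.table(position = res$position,
                      ref = BASES[codes[res$position] + 1L],
                      alt = res$alt)
  setorderv(truth, "position")
  mutant <- genome
  for (j in seq_len(nrow(truth))) {
    substr(mutant, truth$position[j], truth$position[j]) <- truth$alt[j]
  }
  list(mutant = mutant, truth = truth[])
}

#' Default sampling ranges for ground-truth energy models
#'
#' Uniform sampling intervals per parameter group, chosen so simulated
#' intensities resemble real array data: roughly two decades of dynamic
#' range, moderate probe-site saturation, mismatch-driven intensity drops
#' well above the default measurement noise, and a non-specific floor a few
#' percent of full scale.
#'
#' @return Named list of `c(lower, upper)` ranges.
#' @export
default_model_ranges <- function() {
  list(eps_specific = c(0.05, 0.30),
       eps_nonspecific = c(0.02, 0.15),
       penalty = c(0.5, 2.5),
       weights = c(0.3, 1.0),
       alpha = c(0.8, 1.2),
       intensity_scale = c(1500, 3000),
       background = c(30, 80),
       conc_nonspecific = c(0.02, 0.2))
}

#' Sample a ground-truth energy model
#'
#' Uniform draws per parameter group; position weights are rearranged to be
#' unimodal with the maximum at the probe center (weights decrease toward
#' the probe ends).
#'
#' @param model_ranges Ranges as from [default_model_ranges()].
#' @param seed Integer RNG seed.
#' @return An [energy_model()].
#' @export
sample_true_model <- function(model_ranges = default_model_ranges(),
                              seed = 1L) {
  r <- model_ranges
  .with_seed(seed, {
    u <- sort(runif(19, r$weights[1], r$weights[2]))
    # unimodal arrangement peaking at probe position 11
    w <- c(u[seq(1, 19, by = 2)], rev(u[seq(2, 18, by = 2)]))
    energy_model(
      eps_specific = runif(64, r$eps_specific[1], r$eps_specific[2]),
      eps_nonspecific = runif(64, r$eps_nonspecific[1], r$eps_nonspecific[2]),
      penalty = runif(192, r$penalty[1], r$penalty[2]),
      weights = w,
      alpha = runif(1, r$alpha[1], r$alpha[2]),
      intensity_scale = runif(1, r$intensity_scale[1], r$intensity_scale[2]),
      background = runif(1, r$background[1], r$background[2]),
      conc_nonspecific = runif(1, r$conc_nonspecific[1], r$conc_nonspecific[2])
    )
  })
}

#' Simulate probe intensities with the FH forward model
#'
#' Per probe, `intensity = exp(predicted log intensity + eps)` with
#' `eps ~ Normal(0, noise_sd^2)` (multiplicative log-normal noise);
#' `noise_sd = 0` gives exact forward-model values.  The target is the
#' (possibly mutated) genome; probes overlapping a deleted interval lose
#' their specific binding and hybridize non-specifically only.
#'
#' @param model An [energy_model()].
#' @param design A `tiling_design`.
#' @param genome_variant Target genome sequence (character, same length as
#'   the design genome) or `NULL` for the reference itself.  At most one
#'   substitution may fall within any probe span.
#' @param folding Per-probe folding energies (see [predict_log_intensity()]).
#' @param noise_sd Log-scale noise standard deviation (>= 0).
#' @param seed Integer RNG seed for the noise draws.
#' @param deletions Optional list of `c(start, length)` deleted intervals.
#' @param sample_id Sample label stored on the returned table.
#' @return An [intensity_table()].
#' @export
simulate_intensities <- function(model, design, genome_variant = NULL,
                                 folding = NULL, noise_sd = 0, seed = 1L,
                                 deletions = NULL, sample_id = "sample") {
  stopifnot(noise_sd >= 0)
  en <- .design_energies(model, design)
  pen <- en$pen_ref
  if (!is.null(genome_variant)) {
    vcodes <- .base_lookup[utf8ToInt(toupper(genome_variant))]
    if (length(vcodes) != design$genome_length) {
      stop("genome_variant must match the design genome length", call. = FALSE)
    }
    subs <- which(vcodes != design$genome$codes)
    for (g in subs) {
      rows <- probes_covering(design, g, rows_only = TRUE)
      en_sub <- list(probes = design$probes[rows], pen_ref = en$pen_ref[rows])
      pen[rows] <- .hyp_penalties(model, design, en_sub,
                                  hypothesis(g, BASES[vcodes[g] + 1L]))
    }
  }
  Gs <- en$Gs_pm - pen
  if (!is.null(deletions)) {
    L <- design$genome_length
    for (iv in deletions) {
      span <- .wrap(iv[1L] + seq.int(-10L, iv[2L] - 1L + 10L), L)
      Gs[design$probes$position %in% span] <- -Inf
    }
  }
  Gf <- .folding_for_rows(design, folding)
  pred <- fh_log_intensity(model, Gs, en$Gns, Gf)
  eps <- if (noise_sd > 0) {
    .with_seed(seed, rnorm(length(pred), 0, noise_sd))
  } else {
    0
  }
  intensity_table(probe_ids(design), exp(pred + eps), sample_id = sample_id)
}

#' Simulation configuration
#'
#' Bundles the study conditions of a synthetic two-sample (reference vs
#' mutant) tiling-array experiment.  Defaults define the desk-scale
#' benchmark: a 50 kbp circular genome, 20 substitutions at >= 100 bp
#' spacing, log-normal noise with sd 0.05, seed 17.
#'
#' @param genome_length Genome length in bp.
#' @param gc_content GC fraction in (0, 1).
#' @param n_substitutions Number of implanted substitutions.
#' @param min_spacing Minimum spacing between substitutions (>= 22 bp).
#' @param deletions List of `c(start, length)` deleted intervals.
#' @param noise_sd Log-scale noise sd (>= 0).
#' @param seed Master seed; sub-seeds for genome, model, substitutions and
#'   the two noise draws are derived from it.
#' @param model_ranges Ground-truth model sampling ranges.
#' @return A `sim_config` object.
#' @export
sim_config <- function(genome_length = 50000L, gc_content = 0.5,
                       n_substitutions = 20L, min_spacing = 100L,
                       deletions = list(), noise_sd = 0.05, seed = 17L,
                       model_ranges = default_model_ranges()) {
  cfg <- structure(
    list(genome_length = as.integer(genome_length),
         gc_content = gc_content,
         n_substitutions = as.integer(n_substitutions),
         min_spacing = as.integer(min_spacing),
         deletions = deletions,
         noise_sd = noise_sd,
         seed = as.integer(seed),
         model_ranges = model_ranges),
    class = "sim_config"
  )
  if (cfg$min_spacing < 22L) stop("min_spacing must be >= 22 bp", call. = FALSE)
  if (cfg$n_substitutions * cfg$min_spacing >= cfg$genome_length) {
    stop("n_substitutions * min_spacing must be below genome_length",
         call. = FALSE)
  }
  if (length(cfg$deletions) > 1L) {
    iv <- do.call(rbind, cfg$deletions)
    o <- order(iv[, 1L])
    if (any(iv[o, 1L][-1L] <= iv[o, 1L][-nrow(iv)] + iv[o, 2L][-nrow(iv)] - 1L)) {
      stop("deletions must be non-overlapping", call. = FALSE)
    }
  }
  cfg
}

#' Run a complete forward simulation
#'
#' Generates the genome, ground-truth model, mutant genome with truth set,
#' full-resolution design, folding energies, and noisy wild-type and mutant
#' intensity tables, all deterministically from the configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `tc_simulation` with components `config`,
#'   `genome` (sequence), `mutant` (sequence), `design`, `model`, `folding`,
#'   `wt`, `mut` (intensity tables), `truth`, `deletions`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$seed
  genome <- random_genome(config$genome_length, config$gc_content, s + 1L)
  model <- sample_true_model(config$model_ranges, s + 2L)
  imp <- implant_substitutions(genome, config$n_substitutions,
                               config$min_spacing, s + 3L,
                               exclude = config$deletions)
  design <- build_tiling_design(genome, resolution = 1L, circular = TRUE,
                                mm_mode = "all_three", genome_id = "sim")
  folding <- design_folding_energies(design)
  wt <- simulate_intensities(model, design, NULL, folding,
                             config$noise_sd, s + 4L, sample_id = "wt")
  mut <- simulate_intensities(model, design, imp$mutant, folding,
                              config$noise_sd, s + 5L,
                              deletions = config$deletions, sample_id = "mut")
  structure(
    list(config = config, genome = genome, mutant = imp$mutant,
         design = design, model = model, folding = folding,
         wt = wt, mut = mut, truth = imp$truth,
         deletions = config$deletions),
    class = "tc_simulation"
  )
}
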