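# Substitution detection: per-position residual sums of squared
# mutant/reference log-intensity ratios, running-average screening of
# candidate regions, and maximum-likelihood-ratio calling.

# per-design-row log ratio mut/wt, aligned by probe ID
.aligned_log_ratio <- function(design, wt, mut) {
  ids <- probe_ids(design)
  w <- wt$intensity[match(ids, wt$probe_id)]
  m <- mut$intensity[match(ids, mut$probe_id)]
  miss <- sum(is.na(w)) + sum(is.na(m))
  if (miss > 0) {
    stop(sprintf("intensity tables are missing %d probe value(s)", miss),
         call. = FALSE)
  }
  log(m) - log(w)
}

# centered circular/linear rolling sum of width 2*half+1 (positions outside a
# linear genome contribute 0)
.rolling_sum <- function(x, half, circular) {
  n <- length(x)
  xp <- if (circular) {
    c(x[(n - half + 1L):n], x, x[1L:half])
  } else {
    c(rep(0, half), x, rep(0, half))
  }
  cs <- c(0, cumsum(xp))
  cs[seq_len(n) + 2L * half + 1L] - cs[seq_len(n)]
}

#' Residual sum of squares at a genome position under a hypothesis
#'
#' \eqn{E_i(b)}: the sum over all probes covering position `i` of the squared
#' difference between the observed mutant/reference log-intensity ratio and
#' the ratio predicted under the hypothesis that base `i` is substituted to
#' `b`.  With `b = NULL` (or the reference base) the predicted ratios are 0
#' and the statistic is the null residual \eqn{D_i}.
#'
#' @param model A fitted [energy_model()].
#' @param design A `tiling_design`.
#' @param wt,mut [intensity_table()]s for the reference and mutant samples.
#' @param i Genome position.
#' @param b Alternative base, or `NULL`/reference base for \eqn{D_i}.
#' @param folding Per-probe folding energies (see [predict_log_intensity()]).
#' @return Non-negative numeric scalar.
#' @export
position_residual <- function(model, design, wt, mut, i, b = NULL,
                              folding = NULL) {
  rows <- probes_covering(design, i, rows_only = TRUE)
  r <- .aligned_log_ratio(design, wt, mut)[rows]
  ref <- BASES[design$genome$codes[i] + 1L]
  if (is.null(b) || identical(b, ref)) return(sum(r^2))
  rho <- predict_log_ratio(model, design, hypothesis(i, b),
                           folding = .folding_for_rows(design, folding, rows),
                           rows = rows)
  sum((r - rho)^2)
}

#' Genome-wide residual profile and screening threshold
#'
#' Computes the null residual \eqn{D_i} at every genome position, its
#' centered running average over `window` positions, and the screening
#' threshold `theta_R = mean(D) + k_sd * sd(D)`.
#'
#' @inheritParams position_residual
#' @param window Odd running-average window width in bp.
#' @param k_sd Multiplier of `sd(D)` in the screening threshold.
#' @return A `residual_profile` object with components `D`, `running_avg`,
#'   `theta_R`, `window`, `k_sd`, `genome_length`, `circular`.
#' @export
residual_profile <- function(model, design, wt, mut, window = 11L,
                             k_sd = 2.0, folding = NULL) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  r <- .aligned_log_ratio(design, wt, mut)
  L <- design$genome_length
  # residual mass per probe center, then 21-wide centered sum = D_i
  s2 <- numeric(L)
  agg <- rowsum(r^2, design$probes$position)
  s2[as.integer(rownames(agg))] <- agg[, 1L]
  D <- .rolling_sum(s2, 10L, design$circular)
  half <- (window - 1L) %/% 2L
  if (design$circular) {
    run <- .rolling_sum(D, half, TRUE) / window
  } else {
    cnt <- .rolling_sum(rep(1, L), half, FALSE)
    run <- .rolling_sum(D, half, FALSE) / cnt
  }
  structure(
    list(D = D, running_avg = run,
         theta_R = mean(D) + k_sd * stats::sd(D),
         window = window, k_sd = k_sd,
         genome_length = L, circular = design$circular,
         genome_id = design$genome_id),
    class = "residual_profile"
  )
}

#' @export
print.residual_profile <- function(x, ...) {
  cat(sprintf(
    "residual_profile: %d positions, window %d, theta_R = %.4g (mean D = %.4g)\n",
    x$genome_length, x$window, x$theta_R, mean(x$D)))
  invisible(x)
}

# genome positions of a (possibly origin-wrapping) region
.region_positions <- function(start, end, L) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, L), seq.int(1L, end))
}

# maximal runs of TRUE (with circular origin merge); data.table(start, end,
# length)
.runs_above <- function(above, L, circular) {
  if (!any(above)) {
    return(data.table(start = integer(), end = integer(), length = integer()))
  }
  if (all(above)) return(data.table(start = 1L, end = L, length = L))
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- data.table(start = starts[rl$values], end = ends[rl$values],
                     length = rl$lengths[rl$values])
  if (circular && above[1L] && above[L] && nrow(runs) > 1L) {
    last <- nrow(runs)
    runs$start[1L] <- runs$start[last]
    runs$length[1L] <- runs$length[1L] + runs$length[last]
    runs <- runs[-last]
  }
  runs
}

#' Screen candidate regions from a residual profile
#'
#' Maximal runs of consecutive positions whose running-average residual
#' exceeds the screening threshold.  Runs shorter than `min_len` are
#' dropped; runs of `max_len` or longer are flagged structural
#' (deletion-like) and are excluded from substitution calling.  On circular
#' genomes a run crossing the origin is merged.
#'
#' High-residual regions (deletions above all) dominate the genome-wide
#' moments of \eqn{D}, which would push the threshold above genuine
#' substitution signal; following the procedure of removing detected
#' regions from the analysis before thresholding, screening iterates:
#' compute `theta = mean(D) + k_sd * sd(D)` over unmasked positions, find
#' the above-threshold runs of at least `min_len`, mask their spans (plus a
#' margin covering probe reach and running-average smoothing), and repeat
#' until the mask stabilizes.  The emitted regions are the maximal runs at
#' the final threshold, so the threshold always reflects the null
#' background only.
#'
#' @param profile A [residual_profile()].
#' @param min_len Minimum region length in bp.
#' @param max_len Length at and beyond which a region is structural.
#' @param max_iter Cap on threshold-refinement iterations.
#' @return `data.table(start, end, length, mean_residual, structural)`;
#'   `end < start` denotes an origin-wrapping region.  Attribute
#'   `theta_screen` records the final screening threshold.
#' @export
screen_candidate_regions <- function(profile, min_len = 10L, max_len = 80L,
                                     max_iter = 10L) {
  L <- profile$genome_length
  margin <- 20L + (profile$window - 1L) %/% 2L
  mask <- logical(L)
  theta <- profile$theta_R
  for (it in seq_len(max_iter)) {
    theta <- mean(profile$D[!mask]) +
      profile$k_sd * stats::sd(profile$D[!mask])
    runs <- .runs_above(profile$running_avg > theta, L, profile$circular)
    runs <- runs[runs$length >= min_len]
    newmask <- mask
    for (j in seq_len(nrow(runs))) {
      core <- .region_positions(runs$start[j], runs$end[j], L)
      ext <- c(core[1L] - seq_len(margin), core,
               core[length(core)] + seq_len(margin))
      ext <- if (profile$circular) .wrap(ext, L) else
        ext[ext >= 1L & ext <= L]
      newmask[ext] <- TRUE
    }
    if (identical(newmask, mask)) break
    mask <- newmask
  }
  out <- if (nrow(runs) == 0L) {
    data.table(start = integer(), end = integer(), length = integer(),
               mean_residual = numeric(), structural = logical())
  } else {
    runs$mean_residual <- vapply(seq_len(nrow(runs)), function(j) {
      mean(profile$running_avg[
        .region_positions(runs$start[j], runs$end[j], L)])
    }, numeric(1L))
    runs$structural <- runs$length >= max_len
    setorderv(runs, "start")
    setcolorder(runs,
                c("start", "end", "length", "mean_residual", "structural"))
    runs[]
  }
  setattr(out, "theta_screen", theta)
  out
}

#' Log-likelihood ratio for a substitution hypothesis
#'
#' \eqn{L_i(b) = E_i(\mathrm{ref}) - E_i(b)} (the normal-error log-likelihood
#' ratio up to a neglected positive constant); positive values favor the
#' substitution of base `i` to `b`.
#'
#' @inheritParams position_residual
#' @param b Alternative base (must differ from the reference base at `i`).
#' @return Numeric scalar.
#' @export
likelihood_ratio <- function(model, design, wt, mut, i, b, folding = NULL) {
  ref <- BASES[design$genome$codes[i] + 1L]
  if (identical(b, ref)) stop("b must differ from the reference base", call. = FALSE)
  position_residual(model, design, wt, mut, i, NULL, folding) -
    position_residual(model, design, wt, mut, i, b, folding)
}

#' Maximum-likelihood substitution per candidate region
#'
#' For each non-structural region, evaluates the log-likelihood ratio for
#' every position and every alternative base and reports the maximizing
#' `(position, base)` pair, with ties broken toward the smaller position and
#' then base order A < C < G < T.
#'
#' @inheritParams position_residual
#' @param regions Candidate regions from [screen_candidate_regions()].
#' @return `data.table(position, ref, alt, llr, region_start, region_end)`,
#'   one row per non-structural region.
#' @export
region_max_llr <- function(model, design, wt, mut, regions, folding = NULL) {
  r_all <- .aligned_log_ratio(design, wt, mut)
  en <- .design_energies(model, design)
  Gf <- .folding_for_rows(design, folding)
  pred_ref <- fh_log_intensity(model, en$Gs_pm - en$pen_ref, en$Gns, Gf)
  L <- design$genome_length
  regions <- regions[!regions$structural]
  out <- vector("list", nrow(regions))
  for (j in seq_len(nrow(regions))) {
    pos <- .region_positions(regions$start[j], regions$end[j], L)
    best <- list(llr = -Inf, position = NA_integer_, ref = NA_character_,
                 alt = NA_character_)
    for (i in pos) {
      rows <- probes_covering(design, i, rows_only = TRUE)
      en_sub <- list(probes = design$probes[rows], pen_ref = en$pen_ref[rows])
      ri <- r_all[rows]
      D_i <- sum(ri^2)
      ref_code <- design$genome$codes[i]
      for (b in BASES[-(ref_code + 1L)]) {
        pen <- .hyp_penalties(model, design, en_sub, hypothesis(i, b))
        pred_alt <- fh_log_intensity(model, en$Gs_pm[rows] - pen,
                                     en$Gns[rows], Gf[rows])
        rho <- pred_alt - pred_ref[rows]
        llr <- D_i - sum((ri - rho)^2)
        if (llr > best$llr) {
          best <- list(llr = llr, position = i,
                       ref = BASES[ref_code + 1L], alt = b)
        }
      }
    }
    out[[j]] <- data.table(position = best$position, ref = best$ref,
                           alt = best$alt, llr = best$llr,
                           region_start = regions$start[j],
                           region_end = regions$end[j])
  }
  if (length(out) == 0L) {
    return(data.table(position = integer(), ref = character(),
                      alt = character(), llr = numeric(),
                      region_start = integer(), region_end = integer()))
  }
  rbindlist(out)
}

#' Call substitutions from candidate regions
#'
#' Emits, per non-structural candidate region, the single maximizing
#' `(position, base)` substitution if its log-likelihood ratio strictly
#' exceeds `theta_L`.
#'
#' @inheritParams region_max_llr
#' @param theta_L Calling threshold on the maximum log-likelihood ratio
#'   (strict inequality).
#' @return `data.table(position, ref, alt, llr, region_start, region_end)`.
#' @export
call_substitutions <- function(model, design, wt, mut, regions, theta_L,
                               folding = NULL) {
  best <- region_max_llr(model, design, wt, mut, regions, folding)
  best[best$llr > theta_L]
}
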