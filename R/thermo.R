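# Finite-hybridization (FH) forward model: position-weighted triplet free
# energies for specific and non-specific binding, mismatch penalties, probe
# self-folding as a competing state, and the saturating log-intensity form.

#' Triplet index of three bases
#'
#' Encodes a base triplet as `16*code(prev) + 4*code(center) + code(next)`
#' with A,C,G,T -> 0,1,2,3.
#'
#' @param prev,center,nxt Bases in `A,C,G,T` (vectorized).
#' @return Integer in 0..63.
#' @export
triplet_index <- function(prev, center, nxt) {
  .assert_base(prev); .assert_base(center); .assert_base(nxt)
  p <- match(prev, BASES) - 1L
  c0 <- match(center, BASES) - 1L
  n <- match(nxt, BASES) - 1L
  16L * p + 4L * c0 + n
}

# n x 19 triplet-index matrix from an n x 21 base-code matrix
.triplet_matrix <- function(m) {
  16L * m[, 1:19, drop = FALSE] + 4L * m[, 2:20, drop = FALSE] +
    m[, 3:21, drop = FALSE]
}

# position-weighted sum of triplet energies; tripmat is n x 19 (0-based codes)
.weighted_energy <- function(eps, weights, tripmat) {
  as.vector(matrix(eps[tripmat + 1L], nrow = nrow(tripmat)) %*% weights)
}

.seqs_to_code_matrix <- function(probe_seq) {
  stopifnot(is.character(probe_seq))
  if (any(nchar(probe_seq) != 21L)) {
    stop("probe sequences must be 21-mers", call. = FALSE)
  }
  codes <- .base_lookup[utf8ToInt(paste(toupper(probe_seq), collapse = ""))]
  if (anyNA(codes)) stop("probe sequences must contain only A,C,G,T", call. = FALSE)
  matrix(codes, ncol = 21L, byrow = TRUE)
}

#' Specific and non-specific hybridization free energy of probe sequences
#'
#' The position-dependent nearest-neighbor (triplet) model: the energy of a
#' 21-mer is the sum over triplet centers k = 2..20 of
#' `weights[k-1] * eps[triplet at k]`, with `eps` the specific
#' (`specific_energy`) or non-specific (`nonspecific_energy`) local energy
#' table.  Both share the position weights.
#'
#' @param model An [energy_model()].
#' @param probe_seq Character vector of 21-mers.
#' @return Numeric vector of energies (fitted units; larger = stronger
#'   binding).
#' @export
specific_energy <- function(model, probe_seq) {
  .weighted_energy(model$eps_specific, model$weights,
                   .triplet_matrix(.seqs_to_code_matrix(probe_seq)))
}

#' @rdname specific_energy
#' @export
nonspecific_energy <- function(model, probe_seq) {
  .weighted_energy(model$eps_nonspecific, model$weights,
                   .triplet_matrix(.seqs_to_code_matrix(probe_seq)))
}

#' Substitution hypothesis
#'
#' The reference hypothesis is `NULL` (or both fields `NULL`); a substitution
#' hypothesis fixes a genome position and an alternative base.
#'
#' @param position Genome coordinate (1-based) or `NULL`.
#' @param alt_base Base in `A,C,G,T` or `NULL`.
#' @return A `tc_hypothesis` object or `NULL`.
#' @export
hypothesis <- function(position = NULL, alt_base = NULL) {
  if (is.null(position) && is.null(alt_base)) return(NULL)
  if (is.null(position) || is.null(alt_base)) {
    stop("position and alt_base must both be set or both NULL", call. = FALSE)
  }
  .assert_base(alt_base, "alt_base")
  structure(list(position = as.integer(position), alt_base = alt_base),
            class = "tc_hypothesis")
}

# strand-adjusted reference triplet context at genome position g (vectorized
# over g/strand).  Linear genomes clamp out-of-range neighbors to the end
# base; circular genomes wrap.
.context_triplet <- function(design, g, strand) {
  L <- design$genome_length
  codes <- design$genome$codes
  gm <- g - 1L; gp <- g + 1L
  if (design$circular) {
    gm <- .wrap(gm, L); gp <- .wrap(gp, L)
  } else {
    gm <- pmax(gm, 1L); gp <- pmin(gp, L)
  }
  a <- codes[gm]; b <- codes[g]; d <- codes[gp]
  fwd <- 16L * a + 4L * b + d
  rev <- 16L * (3L - d) + 4L * (3L - b) + (3L - a)
  ifelse(strand == "+", fwd, rev)
}

# signed center-to-position offset, minimal under circular wrap
.signed_offset <- function(g, center, L, circular) {
  d <- g - center
  if (circular) {
    d <- ((d + L %/% 2L) %% L) - L %/% 2L
  }
  d
}

# Baseline per-probe energies for a model on design rows: PM-locus specific
# energy, reference-state mismatch penalty (MM center), and non-specific
# energy of the actual probe sequence.
.design_energies <- function(model, design, rows = NULL) {
  dt <- if (is.null(rows)) design$probes else design$probes[rows]
  m <- .probe_code_matrix(design, rows)          # actual probe sequence
  Gns <- .weighted_energy(model$eps_nonspecific, model$weights,
                          .triplet_matrix(m))
  # PM-locus sequence: reset MM centers to the reference base
  ref_center <- .pm_center_codes(design, rows)
  mm <- which(dt$kind == "MM")
  pm_m <- m
  if (length(mm)) pm_m[cbind(mm, 11L)] <- ref_center[mm]
  trip_pm <- .triplet_matrix(pm_m)
  Gs_pm <- .weighted_energy(model$eps_specific, model$weights, trip_pm)
  pen_ref <- numeric(nrow(dt))
  if (length(mm)) {
    alt <- match(dt$central_alt[mm], BASES) - 1L
    pen_ref[mm] <- model$penalty[
      .penalty_index(trip_pm[mm, 10L], ref_center[mm], alt)]
  }
  list(probes = dt, Gs_pm = Gs_pm, pen_ref = pen_ref, Gns = Gns,
       ref_center = ref_center)
}

# Total mismatch penalty per probe row under a hypothesis (NULL = reference).
# `en` is the output of .design_energies for the same rows.
.hyp_penalties <- function(model, design, en, hyp) {
  pen <- en$pen_ref
  if (is.null(hyp)) return(pen)
  dt <- en$probes
  L <- design$genome_length
  g <- hyp$position
  b <- match(hyp$alt_base, BASES) - 1L
  rb_g <- design$genome$codes[g]                 # reference base at g
  if (is.na(rb_g)) stop("hypothesis position has a non-ACGT reference base")
  if (b == rb_g) {
    stop("alt_base must differ from the reference base at the position",
         call. = FALSE)
  }
  d <- .signed_offset(g, dt$position, L, design$circular)
  span <- abs(d) <= 10L
  if (!any(span)) return(pen)
  idx <- which(span)
  strand <- dt$strand[idx]
  is_mm <- dt$kind[idx] == "MM"
  k <- ifelse(strand == "+", 11L + d[idx], 11L - d[idx])
  tb <- ifelse(strand == "+", b, 3L - b)         # probe-space target base
  rb <- ifelse(strand == "+", rb_g, 3L - rb_g)   # probe-space reference base
  trip_g <- .context_triplet(design, rep(g, length(idx)), strand)
  pg <- model$penalty[.penalty_index(trip_g, rb, tb)]
  at_center <- k == 11L
  alt_code <- ifelse(is_mm, match(dt$central_alt[idx], BASES) - 1L, NA_integer_)
  pen[idx] <- ifelse(
    at_center,
    # center of probe: MM matching the mutant base -> no mismatch; otherwise
    # a single mismatch whose substituted base is the mutant (target) base
    ifelse(is_mm & alt_code == tb, 0, pg),
    # off-center substitution: penalty for it, plus the MM center mismatch
    en$pen_ref[idx] + pg
  )
  pen
}

#' Mismatch-adjusted specific energy of probes under a hypothesis
#'
#' Returns the PM-locus specific energy minus one penalty per probe-target
#' mismatch.  Mismatch counts: PM probe/no substitution 0; MM probe/no
#' substitution 1 (its designed central mismatch); PM spanning the
#' substitution 1; MM spanning it off-center 2; an MM probe whose central
#' alternative equals the mutant base at its center 0 (the substitution turns
#' it into a PM probe).  Each penalty is looked up by the strand-appropriate
#' reference triplet context at the mismatch position and the substituted
#' (non-reference) base.
#'
#' @param model An [energy_model()].
#' @param design A `tiling_design`.
#' @param hyp A [hypothesis()] or `NULL` for the reference.
#' @param rows Row indices into `design$probes` (default: all).
#' @return Numeric vector of adjusted specific energies.
#' @export
mismatch_adjusted_energy <- function(model, design, hyp = NULL, rows = NULL) {
  en <- .design_energies(model, design, rows)
  en$Gs_pm - .hyp_penalties(model, design, en, hyp)
}

#' FH log-intensity from energies
#'
#' The finite-hybridization intensity of a probe with specific, non-specific
#' and folding energies \eqn{G_s, G_{ns}, G_f} is
#' \deqn{I = A \frac{K_s + K_{ns} C_{ns}}{1 + K_f + K_s + K_{ns} C_{ns}} + B}
#' with \eqn{K_x = e^{\alpha G_x}}; this returns \eqn{\log I}, evaluated in
#' log space so large energies cannot overflow.  `G_specific = -Inf` encodes
#' an absent specific target (deleted locus).
#'
#' @param model An [energy_model()] (only the 4 global scalars are used).
#' @param G_specific,G_nonspecific,G_folding Numeric vectors (recycled).
#' @return Numeric vector of log intensities, in `(log B, log(A + B))`.
#' @export
fh_log_intensity <- function(model, G_specific, G_nonspecific, G_folding = 0) {
  a <- model$alpha
  logS <- .logaddexp(a * G_specific,
                     a * G_nonspecific + log(model$conc_nonspecific))
  logden <- .logaddexp(.logaddexp(0, a * G_folding), logS)
  frac <- exp(logS - logden)
  log(model$background) + log1p(model$intensity_scale / model$background * frac)
}

# resolve a folding argument to a numeric vector aligned with `rows`
.folding_for_rows <- function(design, folding, rows = NULL) {
  n <- if (is.null(rows)) nrow(design$probes) else length(rows)
  if (is.null(folding)) return(numeric(n))
  if (is.data.frame(folding)) {
    ids <- probe_ids(design, rows)
    e <- folding$energy[match(ids, folding$probe_id)]
    if (anyNA(e)) stop("folding table is missing probes", call. = FALSE)
    return(as.numeric(e))
  }
  folding <- as.numeric(folding)
  if (length(folding) == n) return(folding)
  if (!is.null(rows) && length(folding) == nrow(design$probes)) {
    return(folding[rows])
  }
  stop("folding must be NULL, a per-probe numeric vector, or a (probe_id, energy) table",
       call. = FALSE)
}

#' Predicted log intensity of design probes under a hypothesis
#'
#' Applies the FH model ([fh_log_intensity()]) with the mismatch-adjusted
#' specific energy under `hyp`, the probe's non-specific energy, and its
#' folding energy.
#'
#' @inheritParams mismatch_adjusted_energy
#' @param folding Per-probe folding energies: `NULL` (no folding), a numeric
#'   vector aligned with `rows` (or the whole design), or a
#'   `(probe_id, energy)` table as from [design_folding_energies()].
#' @return Numeric vector of predicted log intensities.
#' @export
predict_log_intensity <- function(model, design, hyp = NULL, folding = NULL,
                                  rows = NULL) {
  en <- .design_energies(model, design, rows)
  Gs <- en$Gs_pm - .hyp_penalties(model, design, en, hyp)
  Gf <- .folding_for_rows(design, folding, rows)
  fh_log_intensity(model, Gs, en$Gns, Gf)
}

#' Predicted log-intensity ratio (hypothesis vs reference)
#'
#' `predict_log_intensity(hyp) - predict_log_intensity(reference)`; exactly 0
#' for the reference hypothesis and for probes not spanning the hypothesis
#' position.
#'
#' @inheritParams predict_log_intensity
#' @return Numeric vector of predicted log ratios.
#' @export
predict_log_ratio <- function(model, design, hyp, folding = NULL,
                              rows = NULL) {
  if (is.null(hyp)) {
    n <- if (is.null(rows)) nrow(design$probes) else length(rows)
    return(numeric(n))
  }
  en <- .design_energies(model, design, rows)
  Gf <- .folding_for_rows(design, folding, rows)
  ref <- fh_log_intensity(model, en$Gs_pm - en$pen_ref, en$Gns, Gf)
  alt <- fh_log_intensity(model,
                          en$Gs_pm - .hyp_penalties(model, design, en, hyp),
                          en$Gns, Gf)
  alt - ref
}
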