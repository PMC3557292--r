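# The 343-parameter energy model behind the finite-hybridization (FH)
# intensity model: 64 specific + 64 non-specific triplet energies, 192
# mismatch penalties (triplet context x 3 alternative central bases), 19
# position weights (probe positions 2..20), and 4 global scalars.

#' Construct an energy model
#'
#' @param eps_specific Numeric\[64\]; specific-target local hybridization
#'   energy per base triplet, indexed by [triplet_index()] + 1.
#' @param eps_nonspecific Numeric\[64\]; non-specific counterpart, same
#'   indexing.
#' @param penalty Numeric\[192\], all >= 0; free-energy decrement per
#'   probe-target mismatch, indexed by (reference triplet context,
#'   substituted base): entry `3 * t + r + 1` where `t` is the triplet index
#'   and `r` is the 0-based rank of the substituted base among the three
#'   bases different from the triplet's central base, in A<C<G<T order.
#' @param weights Numeric\[19\] in \[0, 1\]; position-dependent weight for
#'   triplet centers at probe positions 2..20 (decreasing toward probe ends).
#' @param alpha Positive scaling constant converting energies to log reaction
#'   coefficients (the fitted inverse RT scale).
#' @param intensity_scale Positive optical scale A (counts per hybridized
#'   unit; specific target concentration and probe amount absorbed).
#' @param background Positive optical background B (counts).
#' @param conc_nonspecific Positive effective non-specific target
#'   concentration.
#' @return An `energy_model` object (343 free parameters).
#' @export
energy_model <- function(eps_specific, eps_nonspecific, penalty, weights,
                         alpha, intensity_scale, background,
                         conc_nonspecific) {
  m <- structure(
    list(eps_specific = as.numeric(eps_specific),
         eps_nonspecific = as.numeric(eps_nonspecific),
         penalty = as.numeric(penalty),
         weights = as.numeric(weights),
         alpha = as.numeric(alpha),
         intensity_scale = as.numeric(intensity_scale),
         background = as.numeric(background),
         conc_nonspecific = as.numeric(conc_nonspecific)),
    class = "energy_model"
  )
  validate_energy_model(m)
  m
}

#' @rdname energy_model
#' @param model An `energy_model`.
#' @export
validate_energy_model <- function(model) {
  stopifnot(inherits(model, "energy_model"))
  if (length(model$eps_specific) != 64L) stop("eps_specific must have 64 values")
  if (length(model$eps_nonspecific) != 64L) stop("eps_nonspecific must have 64 values")
  if (length(model$penalty) != 192L) stop("penalty must have 192 values")
  if (any(model$penalty < 0)) stop("penalties must be >= 0")
  if (length(model$weights) != 19L) stop("weights must have 19 values")
  if (any(model$weights < 0 | model$weights > 1)) stop("weights must lie in [0, 1]")
  for (s in c("alpha", "intensity_scale", "background", "conc_nonspecific")) {
    v <- model[[s]]
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("%s must be a single positive finite value", s))
    }
  }
  invisible(model)
}

#' Number of free parameters of an energy model
#'
#' @param model An `energy_model`.
#' @return Integer (343 for the full model).
#' @export
n_parameters <- function(model) {
  length(pack_model(model))
}

#' Flatten an energy model to its 343-vector / rebuild it
#'
#' `pack_model` serializes in the fixed order (eps_specific, eps_nonspecific,
#' penalty, weights, alpha, intensity_scale, background, conc_nonspecific);
#' `unpack_model` inverts it.
#'
#' @param model An `energy_model`.
#' @return `pack_model`: numeric\[343\]; `unpack_model`: an `energy_model`.
#' @export
pack_model <- function(model) {
  c(model$eps_specific, model$eps_nonspecific, model$penalty, model$weights,
    model$alpha, model$intensity_scale, model$background,
    model$conc_nonspecific)
}

#' @rdname pack_model
#' @param par Numeric vector of length 343 as produced by `pack_model`.
#' @export
unpack_model <- function(par) {
  stopifnot(length(par) == 343L)
  energy_model(
    eps_specific = par[1:64],
    eps_nonspecific = par[65:128],
    penalty = par[129:320],
    weights = par[321:339],
    alpha = par[340],
    intensity_scale = par[341],
    background = par[342],
    conc_nonspecific = par[343]
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    paste0("energy_model: %d parameters ",
           "(alpha=%.4g, A=%.4g, B=%.4g, C_ns=%.4g)\n"),
    n_parameters(x), x$alpha, x$intensity_scale, x$background,
    x$conc_nonspecific))
  invisible(x)
}

# penalty vector index for mismatch with reference-context triplet `trip`
# (center base code `center`) substituted by base code `alt` (!= center)
.penalty_index <- function(trip, center, alt) {
  3L * trip + ifelse(alt > center, alt - 1L, alt) + 1L
}
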