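# Probe self-folding: a deterministic simplified stem-loop estimator standing
# in for full secondary-structure prediction, with a hook to supply
# precomputed per-probe energies instead.

#' Default DNA/DNA nearest-neighbor stack table
#'
#' Unified DNA/DNA nearest-neighbor stacking free-energy magnitudes at 37C
#' (kcal/mol, SantaLucia 1998), indexed by the 5'->3' dinucleotide of the
#' stem's upstream strand in A<C<G<T order (AA, AC, ..., TT).  Larger values
#' mean more stable stacks.
#'
#' @return Named numeric vector of length 16.
#' @export
default_stack_table <- function() {
  c(AA = 1.00, AC = 1.44, AG = 1.28, AT = 0.88,
    CA = 1.45, CC = 1.84, CG = 2.17, CT = 1.28,
    GA = 1.30, GC = 2.24, GG = 1.84, GT = 1.44,
    TA = 0.58, TC = 1.30, TG = 1.45, TT = 1.00)
}

#' Self-folding free energy of probe sequences
#'
#' Deterministic stem-loop estimator: enumerates all stem candidates where
#' `seq[i..i+l-1]` pairs with the reverse complement of `seq[j..j+l-1]`
#' (`j >= i + l + min_loop`, stem length `l >= 2`), scores each candidate as
#' the sum of nearest-neighbor stack terms minus `loop_penalty`, and returns
#' `max(0, best score)`.  A sequence with no self-complementary stem folds
#' with energy 0.
#'
#' @param probe_seq Character vector of sequences over A,C,G,T.
#' @param stack_table Numeric\[16\] stack scores (see
#'   [default_stack_table()]).
#' @param loop_penalty Free-energy cost of closing the hairpin loop.
#' @param min_loop Minimum number of unpaired loop bases between the stem
#'   halves.
#' @return Numeric vector of folding energies (>= 0; larger = more folded).
#' @export
folding_energy <- function(probe_seq, stack_table = default_stack_table(),
                           loop_penalty = 3.5, min_loop = 3L) {
  stopifnot(is.character(probe_seq), length(stack_table) == 16L)
  probe_seq <- toupper(probe_seq)
  if (any(is.na(.base_lookup[utf8ToInt(paste(probe_seq, collapse = ""))]))) {
    stop("sequences must contain only A,C,G,T", call. = FALSE)
  }
  fold_energy_cpp(probe_seq, as.numeric(stack_table),
                  as.numeric(loop_penalty), as.integer(min_loop))
}

#' Folding energies for every probe of a design
#'
#' @param design A `tiling_design`.
#' @param rows Row indices into `design$probes` (default: all).
#' @inheritParams folding_energy
#' @return A `data.table` with columns `probe_id`, `energy`, usable as the
#'   `folding` argument of the prediction and detection functions.
#' @export
design_folding_energies <- function(design, rows = NULL,
                                    stack_table = default_stack_table(),
                                    loop_penalty = 3.5, min_loop = 3L) {
  data.table(probe_id = probe_ids(design, rows),
             energy = folding_energy(probe_sequences(design, rows),
                                     stack_table, loop_penalty, min_loop))
}
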