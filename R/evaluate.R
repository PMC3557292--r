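# Evaluation against a truth set: filtering of detectable substitutions,
# greedy call-truth matching, sensitivity/false-positive curves, and
# threshold selection.

#' Filter a truth set down to array-detectable substitutions
#'
#' Removes truth records that the tiling-array method cannot be expected to
#' detect: (1) records with another record within `neighbor_bp`;
#' (2) records whose centered `kmer`-mer occurs more than once in the genome
#' or its reverse complement (repeated sequence); (3) records whose centered
#' 21-bp window has GC fraction below `gc_low` or above `gc_high`.
#'
#' @param truth `data.table(position, ref, alt)`.
#' @param genome Genome sequence (character scalar).
#' @param neighbor_bp Neighbor-exclusion distance in bp.
#' @param kmer Length of the centered uniqueness k-mer.
#' @param gc_low,gc_high GC-content bounds (strict) on the centered window.
#' @param circular Treat the genome as circular when extracting windows and
#'   counting k-mer occurrences.
#' @return The filtered truth `data.table`; attribute `"removed"` holds the
#'   per-criterion removal counts.
#' @export
filter_truth_substitutions <- function(truth, genome, neighbor_bp = 21L,
                                       kmer = 21L, gc_low = 0.2,
                                       gc_high = 0.8, circular = TRUE) {
  stopifnot(is.character(genome), length(genome) == 1L)
  genome <- toupper(genome)
  L <- nchar(genome)
  half <- (kmer - 1L) %/% 2L
  n <- nrow(truth)
  pos <- truth$position

  window_at <- function(p) {
    idx <- p + seq.int(-half, half)
    if (circular) idx <- .wrap(idx, L) else idx <- idx[idx >= 1L & idx <= L]
    paste(strsplit(genome, "")[[1L]][idx], collapse = "")
  }
  wins <- vapply(pos, window_at, character(1L))

  # (1) neighboring substitution
  near <- vapply(seq_len(n), function(j) {
    d <- abs(pos[-j] - pos[j])
    if (circular) d <- pmin(d, L - d)
    any(d <= neighbor_bp)
  }, logical(1L))

  # (2) k-mer multiplicity over both strands (wrap-extended when circular)
  subject <- Biostrings::DNAString(
    if (circular) paste0(genome, substr(genome, 1L, kmer - 1L)) else genome)
  subject_rc <- Biostrings::reverseComplement(subject)
  repeated <- vapply(wins, function(wn) {
    if (nchar(wn) < kmer) return(FALSE)
    p <- Biostrings::DNAString(wn)
    (Biostrings::countPattern(p, subject) +
       Biostrings::countPattern(p, subject_rc)) > 1L
  }, logical(1L))

  # (3) GC content of the centered window
  gc <- vapply(wins, function(wn) {
    b <- strsplit(wn, "")[[1L]]
    mean(b %in% c("G", "C"))
  }, numeric(1L))
  gc_bad <- gc < gc_low | gc > gc_high

  keep <- !(near | repeated | gc_bad)
  out <- truth[keep]
  attr(out, "removed") <- c(neighbor = sum(near), repeated = sum(repeated),
                            gc = sum(gc_bad))
  out
}

#' Match calls against a truth set
#'
#' Greedy nearest matching within `tol_bp`: candidate call-truth pairs are
#' processed in order of increasing distance and each call and truth record
#' is used at most once.  Exact-position and exact position-plus-base match
#' counts are reported separately.
#'
#' @param calls `data.table` with columns `position`, `alt` (others ignored).
#' @param truth `data.table(position, ref, alt)`.
#' @param tol_bp Maximum distance in bp for a match.
#' @return An `evaluation_result` list: `tp`, `fp`, `fn`, `sensitivity`,
#'   `exact_position`, `exact_position_base`, `matches` (a `data.table` of
#'   matched pairs with distances), `n_truth`.
#' @export
match_calls <- function(calls, truth, tol_bp = 2L) {
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)
  matches <- data.table(call_position = integer(), truth_position = integer(),
                        distance = integer(), base_match = logical())
  if (n_calls > 0L && n_truth > 0L) {
    pairs <- CJ(ci = seq_len(n_calls), ti = seq_len(n_truth))
    pairs[, `:=`(distance = abs(calls$position[pairs$ci] -
                                  truth$position[pairs$ti]))]
    pairs <- pairs[pairs$distance <= tol_bp]
    setorderv(pairs, c("distance", "ti", "ci"))
    used_c <- logical(n_calls); used_t <- logical(n_truth)
    keep <- logical(nrow(pairs))
    for (j in seq_len(nrow(pairs))) {
      ci <- pairs$ci[j]; ti <- pairs$ti[j]
      if (!used_c[ci] && !used_t[ti]) {
        used_c[ci] <- TRUE; used_t[ti] <- TRUE; keep[j] <- TRUE
      }
    }
    pairs <- pairs[keep]
    if (nrow(pairs)) {
      matches <- data.table(
        call_position = calls$position[pairs$ci],
        truth_position = truth$position[pairs$ti],
        distance = pairs$distance,
        base_match = calls$alt[pairs$ci] == truth$alt[pairs$ti])
    }
  }
  tp <- nrow(matches)
  structure(
    list(tp = tp, fp = n_calls - tp, fn = n_truth - tp,
         sensitivity = if (n_truth > 0L) tp / n_truth else NA_real_,
         exact_position = sum(matches$distance == 0L),
         exact_position_base = sum(matches$distance == 0L & matches$base_match),
         matches = matches, n_truth = n_truth),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "evaluation_result: TP %d / %d (sensitivity %.3f), FP %d, FN %d; exact position %d, exact position+base %d\n",
    x$tp, x$n_truth, x$sensitivity, x$fp, x$fn,
    x$exact_position, x$exact_position_base))
  invisible(x)
}

#' Sensitivity / false-positive curve over the calling threshold
#'
#' Sweeps `theta_L` over the per-region maximum log-likelihood ratios (calls
#' are regions with `llr > theta_L`) and evaluates each call set against the
#' truth.
#'
#' @param region_best Per-region maxima from [region_max_llr()].
#' @param truth `data.table(position, ref, alt)`.
#' @param tol_bp Matching tolerance in bp.
#' @param thetas Thresholds to evaluate; defaults to one just below the
#'   smallest observed maximum (everything called), each observed maximum,
#'   and the midpoints between consecutive maxima.  The midpoints let
#'   [best_threshold()]'s larger-theta tie rule settle halfway between the
#'   lowest accepted and the highest rejected region rather than exactly on
#'   an observed value, which transfers better to new data.
#' @return `data.table(theta_L, tp, fp, sensitivity)`.
#' @export
threshold_curve <- function(region_best, truth, tol_bp = 2L, thetas = NULL) {
  if (is.null(thetas)) {
    u <- sort(unique(region_best$llr))
    mids <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else numeric()
    thetas <- sort(unique(c(u[1L] - 1, u, mids)))
  }
  out <- lapply(thetas, function(th) {
    ev <- match_calls(region_best[region_best$llr > th], truth, tol_bp)
    data.table(theta_L = th, tp = ev$tp, fp = ev$fp,
               sensitivity = ev$sensitivity)
  })
  rbindlist(out)
}

#' Select the calling threshold maximizing TP - FP
#'
#' @param curve Output of [threshold_curve()] (columns `theta_L`, `tp`,
#'   `fp`).
#' @return The `theta_L` maximizing `tp - fp`; ties are broken toward the
#'   larger threshold (fewer calls).
#' @export
best_threshold <- function(curve) {
  if (nrow(curve) == 0L) stop("curve must be nonempty", call. = FALSE)
  score <- curve$tp - curve$fp
  cand <- which(score == max(score))
  curve$theta_L[cand[which.max(curve$theta_L[cand])]]
}
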