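# Independent brute-force oracles, written from the model definitions with
# plain string/loop code.  They deliberately share no internals with the
# package implementation beyond the documented parameter layout.

o_code <- function(b) match(b, c("A", "C", "G", "T")) - 1L

o_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

o_wrap <- function(i, L) ((i - 1L) %% L) + 1L

o_window <- function(genome, i, circular = TRUE) {
  L <- nchar(genome)
  idx <- i + (-10:10)
  if (circular) idx <- o_wrap(idx, L)
  paste(strsplit(genome, "")[[1]][idx], collapse = "")
}

# probe sequence (probe 5'->3') from a probe-table row and a genome
o_probe_seq <- function(genome, pos, strand, kind, alt, circular = TRUE) {
  w <- o_window(genome, pos, circular)
  if (strand == "-") w <- o_revcomp(w)
  if (kind == "MM") substr(w, 11, 11) <- alt
  w
}

o_trip <- function(a, b, c) 16L * o_code(a) + 4L * o_code(b) + o_code(c)

o_weighted_energy <- function(eps, weights, seq) {
  s <- strsplit(seq, "")[[1]]
  tot <- 0
  for (k in 2:20) {
    tot <- tot + weights[k - 1] * eps[o_trip(s[k - 1], s[k], s[k + 1]) + 1]
  }
  tot
}

# strand-appropriate reference triplet context at genome position g
o_context_trip <- function(genome, g, strand, circular = TRUE) {
  L <- nchar(genome)
  gm <- g - 1L; gp <- g + 1L
  if (circular) { gm <- o_wrap(gm, L); gp <- o_wrap(gp, L) }
  else { gm <- max(gm, 1L); gp <- min(gp, L) }
  s <- strsplit(genome, "")[[1]]
  t3 <- paste0(s[gm], s[g], s[gp])
  if (strand == "-") t3 <- o_revcomp(t3)
  b <- strsplit(t3, "")[[1]]
  o_trip(b[1], b[2], b[3])
}

o_penalty <- function(model, trip, center_code, alt_code) {
  rank <- if (alt_code > center_code) alt_code - 1L else alt_code
  model$penalty[3L * trip + rank + 1L]
}

# mismatch-adjusted specific energy from definitions: PM-locus energy minus
# one context/base-indexed penalty per probe-target mismatch
o_adjusted_Gs <- function(model, genome, pos, strand, kind, alt,
                          hyp_pos = NULL, hyp_alt = NULL, circular = TRUE) {
  target_genome <- genome
  if (!is.null(hyp_pos)) substr(target_genome, hyp_pos, hyp_pos) <- hyp_alt
  pm_seq <- o_probe_seq(genome, pos, strand, "PM", NA, circular)
  probe_seq <- o_probe_seq(genome, pos, strand, kind, alt, circular)
  target_seq <- o_probe_seq(target_genome, pos, strand, "PM", NA, circular)
  Gs <- o_weighted_energy(model$eps_specific, model$weights, pm_seq)
  for (k in 1:21) {
    pb <- substr(probe_seq, k, k)
    tb <- substr(target_seq, k, k)
    if (pb == tb) next
    rb <- substr(pm_seq, k, k)
    g <- if (strand == "+") pos + (k - 11L) else pos + (11L - k)
    if (circular) g <- o_wrap(g, nchar(genome))
    trip <- o_context_trip(genome, g, strand, circular)
    sub_base <- if (tb != rb) tb else pb
    Gs <- Gs - o_penalty(model, trip, o_code(rb), o_code(sub_base))
  }
  Gs
}

# direct (non-log-space) FH intensity
o_log_intensity <- function(model, Gs, Gns, Gf) {
  Ks <- exp(model$alpha * Gs)
  Kns <- exp(model$alpha * Gns)
  Kf <- exp(model$alpha * Gf)
  num <- Ks + Kns * model$conc_nonspecific
  log(model$intensity_scale * num / (1 + Kf + num) + model$background)
}

# E_i(b) from definitions, looping over the probe table
o_position_residual <- function(model, genome, ptab, folding, wt, mut, i, b,
                                circular = TRUE) {
  L <- nchar(genome)
  ref <- substr(genome, i, i)
  total <- 0
  for (j in seq_len(nrow(ptab))) {
    d <- abs(ptab$position[j] - i)
    if (circular) d <- min(d, L - d)
    if (d > 10) next
    w <- wt$intensity[match(ptab$probe_id[j], wt$probe_id)]
    m <- mut$intensity[match(ptab$probe_id[j], mut$probe_id)]
    robs <- log(m) - log(w)
    rho <- 0
    if (!is.null(b) && b != ref) {
      Gf <- folding$energy[match(ptab$probe_id[j], folding$probe_id)]
      Gns <- o_weighted_energy(
        model$eps_nonspecific, model$weights,
        o_probe_seq(genome, ptab$position[j], ptab$strand[j], ptab$kind[j],
                    ptab$central_alt[j], circular))
      Gs_ref <- o_adjusted_Gs(model, genome, ptab$position[j], ptab$strand[j],
                              ptab$kind[j], ptab$central_alt[j],
                              circular = circular)
      Gs_hyp <- o_adjusted_Gs(model, genome, ptab$position[j], ptab$strand[j],
                              ptab$kind[j], ptab$central_alt[j],
                              hyp_pos = i, hyp_alt = b, circular = circular)
      rho <- o_log_intensity(model, Gs_hyp, Gns, Gf) -
        o_log_intensity(model, Gs_ref, Gns, Gf)
    }
    total <- total + (robs - rho)^2
  }
  total
}

# exhaustive stem-loop folding enumeration
o_fold <- function(seq, stack, loop_penalty, min_loop) {
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  code <- o_code(s)
  best <- 0
  for (i in 1:(n - 1)) {
    for (l in 2:(n - i + 1)) {
      if (i + l - 1 > n) next
      j0 <- i + l + min_loop
      if (j0 + l - 1 > n) next
      for (j in j0:(n - l + 1)) {
        ok <- TRUE
        for (t in 0:(l - 1)) {
          if (code[i + t] + code[j + l - 1 - t] != 3) { ok <- FALSE; break }
        }
        if (!ok) next
        sc <- -loop_penalty
        for (t in 0:(l - 2)) sc <- sc + stack[code[i + t] * 4 + code[i + t + 1] + 1]
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# small helper models / genomes used across files
make_uniform_model <- function(eps_s = 1, eps_ns = 0, pen = 0, w = 1,
                               alpha = 1, A = 1000, B = 50, Cns = 0.05) {
  energy_model(rep(eps_s, 64), rep(eps_ns, 64), rep(pen, 192), rep(w, 19),
               alpha, A, B, Cns)
}

random_model <- function(seed) sample_true_model(seed = seed)
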