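# Internal helpers shared across modules: base encodings, circular index
# arithmetic, and seeded-RNG scoping.

BASES <- c("A", "C", "G", "T")

# utf8 code -> base code 0..3 (A,C,G,T), NA otherwise
.base_lookup <- local({
  lk <- rep(NA_integer_, 128L)
  lk[utf8ToInt("A")] <- 0L
  lk[utf8ToInt("C")] <- 1L
  lk[utf8ToInt("G")] <- 2L
  lk[utf8ToInt("T")] <- 3L
  lk
})

#' @noRd
seq_to_codes <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  .base_lookup[utf8ToInt(toupper(s))]
}

#' @noRd
codes_to_seq <- function(codes) {
  intToUtf8(utf8ToInt("ACGT")[codes + 1L])
}

# complement in code space: A<->T (0<->3), C<->G (1<->2)
.comp_code <- function(codes) 3L - codes

.comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# 1-based circular wrap onto 1..L
.wrap <- function(i, L) ((i - 1L) %% L) + 1L

# Run expr with a private RNG stream; restores the caller's .Random.seed.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.assert_base <- function(b, what = "base") {
  if (!is.character(b) || any(!b %in% BASES)) {
    stop(sprintf("%s must be one of A, C, G, T", what), call. = FALSE)
  }
  invisible(b)
}

# log(exp(a) + exp(b)) elementwise, overflow-safe; accepts -Inf
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  # both -Inf
  out[is.infinite(m) & m < 0] <- -Inf
  out
}
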