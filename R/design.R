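# Tiling-array design: 21-mer perfect-match (PM) probes at fixed genomic
# resolution plus central-base mismatch (MM) companions.  A design stores the
# genome and a compact probe metadata table; probe IDs and sequences are
# derived on demand so genome-scale designs (millions of probes) stay cheap.

#' @import data.table
NULL

# Normalize genome input (character, DNAString(Set), or tc_genome) to an
# internal record with integer base codes.
.as_genome <- function(genome, genome_id = NULL, circular = TRUE) {
  if (inherits(genome, "tc_genome")) {
    if (!is.null(genome_id)) genome$genome_id <- genome_id
    genome$circular <- isTRUE(circular)
    return(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    if (length(genome) != 1L) {
      stop("multi-record genomes are not supported; supply a single sequence",
           call. = FALSE)
    }
    if (is.null(genome_id)) genome_id <- names(genome)[1L]
    genome <- as.character(genome[[1L]])
  } else if (inherits(genome, "DNAString")) {
    genome <- as.character(genome)
  }
  stopifnot(is.character(genome), length(genome) == 1L)
  s <- toupper(genome)
  structure(
    list(genome_id = if (is.null(genome_id)) "genome" else genome_id,
         seq = s,
         codes = .base_lookup[utf8ToInt(s)],
         length = nchar(s),
         circular = isTRUE(circular)),
    class = "tc_genome"
  )
}

# alt base codes (columns) for each central base code (rows), ascending
.ALT_CODES <- rbind(c(1L, 2L, 3L), c(0L, 2L, 3L), c(0L, 1L, 3L), c(0L, 1L, 2L))

#' Build a 1-bp (or coarser) tiling design
#'
#' Tiles a genome with 21-mer PM probes whose "position" is the genomic
#' coordinate of the central (11th) probe base, alternating the probe strand
#' between consecutive tiled positions (even tiled index = forward).  For each
#' PM probe, MM companions substitute the central probe-sequence character.
#'
#' @param genome A single genome sequence: character scalar,
#'   `Biostrings::DNAString`/`DNAStringSet` with one record, or the record
#'   returned by [read_genome_fasta()].
#' @param resolution Spacing in bp between consecutive PM probe centers.
#' @param circular Treat the genome as circular (bacterial chromosome); a
#'   linear genome loses the first and last 10 positions from the design.
#' @param mm_mode `"all_three"` (3 MM probes per PM), `"complementary_only"`
#'   (the single MM whose central base is the Watson-Crick complement of the
#'   PM central base), or `"none"`.
#' @param genome_id Identifier used in outputs; defaults to the FASTA record
#'   name or `"genome"`.
#' @return A `tiling_design` object.  Its `$probes` component is a
#'   `data.table` with columns `position`, `strand` (`"+"`/`"-"`), `kind`
#'   (`"PM"`/`"MM"`) and `central_alt` (probe-space substituted base, `NA` for
#'   PM), ordered by position, PM before MM, MM alternatives in base order.
#' @details Tiled positions whose 21-mer window contains non-ACGT characters
#'   are skipped with a warning reporting the count.
#' @export
build_tiling_design <- function(genome, resolution = 1L, circular = TRUE,
                                mm_mode = c("all_three", "complementary_only",
                                            "none"),
                                genome_id = NULL) {
  mm_mode <- match.arg(mm_mode)
  g <- .as_genome(genome, genome_id, circular)
  L <- g$length
  if (L < 21L) stop("genome length must be at least 21 bp", call. = FALSE)
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 1L) {
    stop("resolution must be a positive integer", call. = FALSE)
  }

  pos <- seq.int(1L, L, by = resolution)
  if (!g$circular) pos <- pos[pos >= 11L & pos <= L - 10L]

  # drop tiled positions whose window touches a non-ACGT base
  bad <- is.na(g$codes)
  if (any(bad)) {
    padded <- if (g$circular) {
      c(bad[(L - 9L):L], bad, bad[1L:10L])
    } else {
      c(rep(FALSE, 10L), bad, rep(FALSE, 10L))
    }
    cs <- c(0, cumsum(padded))
    nbad <- cs[pos + 21L] - cs[pos]   # window of genome pos i = padded[i..i+20]
    skip <- nbad > 0
    if (any(skip)) {
      warning(sprintf(
        "skipped %d tiled position(s) whose 21-mer window contains non-ACGT characters",
        sum(skip)), call. = FALSE)
      pos <- pos[!skip]
    }
  }
  if (length(pos) == 0L) stop("no valid tiled positions", call. = FALSE)

  tiled_index <- (pos - 1L) %/% resolution
  strand <- ifelse(tiled_index %% 2L == 0L, "+", "-")
  gcode <- g$codes[pos]
  center <- ifelse(strand == "+", gcode, 3L - gcode)  # probe-space central base

  pm <- data.table(position = pos, strand = strand, kind = "PM",
                   central_alt = NA_character_)
  probes <- pm
  if (mm_mode == "all_three") {
    alt <- .ALT_CODES[center + 1L, , drop = FALSE]   # n x 3, ascending
    mm <- data.table(position = rep(pos, each = 3L),
                     strand = rep(strand, each = 3L),
                     kind = "MM",
                     central_alt = BASES[as.vector(t(alt)) + 1L])
    probes <- rbind(pm, mm)
  } else if (mm_mode == "complementary_only") {
    mm <- data.table(position = pos, strand = strand, kind = "MM",
                     central_alt = BASES[(3L - center) + 1L])
    probes <- rbind(pm, mm)
  }
  setorderv(probes, c("position", "kind", "central_alt"),
            order = c(1L, -1L, 1L), na.last = FALSE)

  structure(
    list(genome = g, genome_id = g$genome_id, genome_length = L,
         circular = g$circular, resolution = resolution, mm_mode = mm_mode,
         probes = probes),
    class = "tiling_design"
  )
}

#' @export
print.tiling_design <- function(x, ...) {
  cat(sprintf(
    "tiling_design: %s (%d bp, %s), resolution %d bp, mm_mode=%s, %d probes\n",
    x$genome_id, x$genome_length,
    if (x$circular) "circular" else "linear",
    x$resolution, x$mm_mode, nrow(x$probes)))
  invisible(x)
}

#' Reduce a full design to a coarser tiling resolution
#'
#' Retains PM probes whose tiled index is divisible by `r` and, optionally,
#' only the MM companion whose central base is the Watson-Crick complement of
#' the PM central base (the subset usable by ratio-regression methods).
#'
#' @param design A resolution-1 `tiling_design`.
#' @param r Target resolution; one of 1, 3, 5, 7, 9, 11, 13.
#' @param mm_mode `"all_three"` or `"complementary_only"`.
#' @return A new `tiling_design` at resolution `r`.
#' @export
reduce_resolution <- function(design, r,
                              mm_mode = c("all_three", "complementary_only")) {
  stopifnot(inherits(design, "tiling_design"))
  mm_mode <- match.arg(mm_mode)
  if (design$resolution != 1L) {
    stop("reduce_resolution requires a resolution-1 design", call. = FALSE)
  }
  r <- as.integer(r)
  if (!r %in% c(1L, 3L, 5L, 7L, 9L, 11L, 13L)) {
    stop("r must be one of 1, 3, 5, 7, 9, 11, 13", call. = FALSE)
  }
  position <- kind <- central_alt <- strand <- NULL  # NSE notes
  probes <- design$probes[(position - 1L) %% r == 0L]
  if (mm_mode == "complementary_only") {
    gcode <- design$genome$codes[probes$position]
    center <- ifelse(probes$strand == "+", gcode, 3L - gcode)
    comp <- BASES[(3L - center) + 1L]
    probes <- probes[kind == "PM" | central_alt == comp]
  }
  out <- design
  out$resolution <- r
  out$mm_mode <- mm_mode
  out$probes <- probes
  out
}

#' Probe IDs for rows of a design's probe table
#'
#' IDs encode kind, position, strand, and (for MM) the substituted base, e.g.
#' `P1024F`, `M1024R_C`.
#'
#' @param design A `tiling_design`.
#' @param rows Integer row indices into `design$probes` (default: all).
#' @return Character vector of probe IDs.
#' @export
probe_ids <- function(design, rows = NULL) {
  dt <- if (is.null(rows)) design$probes else design$probes[rows]
  paste0(ifelse(dt$kind == "PM", "P", "M"),
         dt$position,
         ifelse(dt$strand == "+", "F", "R"),
         ifelse(is.na(dt$central_alt), "", paste0("_", dt$central_alt)))
}

# n x 21 matrix of probe-sequence base codes (probe 5'->3' orientation)
.probe_code_matrix <- function(design, rows = NULL) {
  dt <- if (is.null(rows)) design$probes else design$probes[rows]
  L <- design$genome_length
  idx <- outer(dt$position, -10L:10L, "+")
  if (design$circular) idx <- .wrap(idx, L)
  m <- matrix(design$genome$codes[idx], nrow = nrow(dt), ncol = 21L)
  rev_rows <- dt$strand == "-"
  if (any(rev_rows)) {
    m[rev_rows, ] <- 3L - m[rev_rows, 21L:1L, drop = FALSE]
  }
  mm <- which(dt$kind == "MM")
  if (length(mm)) {
    m[cbind(mm, 11L)] <- match(dt$central_alt[mm], BASES) - 1L
  }
  m
}

#' Probe sequences of a design
#'
#' Materializes 21-mer probe sequences (probe 5'->3'; reverse-strand probes
#' are the reverse complement of the genomic window, MM probes substitute the
#' 11th character).
#'
#' @inheritParams probe_ids
#' @return Character vector of 21-mers.
#' @export
probe_sequences <- function(design, rows = NULL) {
  m <- .probe_code_matrix(design, rows)
  vapply(seq_len(nrow(m)), function(i) codes_to_seq(m[i, ]), character(1L))
}

#' Full probe table with IDs and sequences
#'
#' @inheritParams probe_ids
#' @param sequences Include the `sequence` column (materialized on demand).
#' @return A `data.table` with columns `probe_id`, `position`, `strand`,
#'   `kind`, `central_alt` and optionally `sequence`.
#' @export
probe_table <- function(design, rows = NULL, sequences = TRUE) {
  dt <- copy(if (is.null(rows)) design$probes else design$probes[rows])
  dt[, `:=`(probe_id = probe_ids(design, rows))]
  if (sequences) dt[, `:=`(sequence = probe_sequences(design, rows))]
  setcolorder(dt, c("probe_id", "position", "strand", "kind", "central_alt"))
  dt[]
}

#' Probes whose 21-base span covers a genome position
#'
#' Returns the probes whose genomic window (center +/- 10, wrapping on
#' circular genomes) includes position `i`, in deterministic order (position,
#' PM before MM, MM base order).
#'
#' @param design A `tiling_design`.
#' @param i Genome position (1-based).
#' @param rows_only If `TRUE`, return integer row indices into
#'   `design$probes` instead of a probe table.
#' @return A probe table as in [probe_table()], or row indices.
#' @export
probes_covering <- function(design, i, rows_only = FALSE) {
  i <- as.integer(i)
  L <- design$genome_length
  if (is.na(i) || i < 1L || i > L) {
    stop("position out of range", call. = FALSE)
  }
  centers <- i + (-10L:10L)
  centers <- if (design$circular) unique(.wrap(centers, L)) else
    centers[centers >= 1L & centers <= L]
  rows <- which(design$probes$position %in% centers)
  if (rows_only) return(rows)
  probe_table(design, rows)
}

# reference (strand-appropriate PM) central base, probe space, for rows
.pm_center_codes <- function(design, rows = NULL) {
  dt <- if (is.null(rows)) design$probes else design$probes[rows]
  gcode <- design$genome$codes[dt$position]
  ifelse(dt$strand == "+", gcode, 3L - gcode)
}
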