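# File formats: FASTA (Biostrings), TSV tables (data.table), energy-model
# JSON (jsonlite), calls as VCF, structural regions as BED.  VCF output is a
# minimal VCFv4.2 text emitter; reading goes through vcfR when available.

#' Per-sample intensity table
#'
#' @param probe_id Character vector of probe IDs.
#' @param intensity Strictly positive linear optical intensities.
#' @param sample_id Sample label.
#' @return A `data.table(probe_id, intensity)` of class `intensity_table`
#'   with attribute `sample_id`.
#' @export
intensity_table <- function(probe_id, intensity, sample_id = "sample") {
  intensity <- as.numeric(intensity)
  if (any(!is.finite(intensity) | intensity <= 0)) {
    stop("intensities must be strictly positive and finite", call. = FALSE)
  }
  out <- data.table(probe_id = as.character(probe_id), intensity = intensity)
  setattr(out, "sample_id", sample_id)
  setattr(out, "class", c("intensity_table", class(out)))
  out
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table '%s': %d probes, median intensity %.4g\n",
              attr(x, "sample_id"), nrow(x), stats::median(x$intensity)))
  invisible(x)
}

#' Read / write a genome FASTA
#'
#' @param path File path.
#' @param circular Treat the genome as circular.
#' @return `read_genome_fasta`: an internal genome record usable wherever a
#'   genome sequence is accepted; multi-record files are rejected.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) {
    stop(sprintf("expected a single FASTA record, found %d", length(ss)),
         call. = FALSE)
  }
  .as_genome(ss, circular = circular)
}

#' @rdname read_genome_fasta
#' @param genome Genome sequence (character scalar).
#' @param genome_id FASTA record name.
#' @export
write_genome_fasta <- function(genome, path, genome_id = "genome") {
  ss <- Biostrings::DNAStringSet(stats::setNames(genome, genome_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write / read a probe design TSV
#'
#' Columns: `probe_id`, `position`, `strand`, `kind`, `central_alt`,
#' `sequence`.
#'
#' @param design A `tiling_design`.
#' @param path File path.
#' @export
write_probe_design <- function(design, path) {
  fwrite(probe_table(design), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_probe_design
#' @return `read_probe_design`: a `data.table` with the same columns and
#'   types as [probe_table()].
#' @export
read_probe_design <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("probe_id", "strand", "kind",
                                              "central_alt", "sequence"),
                                integer = "position"),
              na.strings = "NA")
  dt[]
}

#' Write / read a per-sample intensity TSV
#'
#' Columns: `probe_id`, `intensity`.  Non-positive intensities are rejected
#' at load.
#'
#' @param tab An [intensity_table()].
#' @param path File path.
#' @export
write_intensity_table <- function(tab, path) {
  fwrite(tab[, c("probe_id", "intensity")], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_intensity_table
#' @param sample_id Sample label for the loaded table.
#' @export
read_intensity_table <- function(path, sample_id = NULL) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  intensity_table(dt$probe_id, dt$intensity, sample_id)
}

#' Write / read an energy model as JSON
#'
#' Flat JSON document with named parameter groups and a schema version.
#'
#' @param model An [energy_model()].
#' @param path File path.
#' @export
write_energy_model <- function(model, path) {
  validate_energy_model(model)
  doc <- list(schema_version = "1.0",
              eps_specific = model$eps_specific,
              eps_nonspecific = model$eps_nonspecific,
              penalty = model$penalty,
              weights = model$weights,
              alpha = model$alpha,
              intensity_scale = model$intensity_scale,
              background = model$background,
              conc_nonspecific = model$conc_nonspecific)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_energy_model
#' @export
read_energy_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version)) {
    stop("not an energy-model JSON document (missing schema_version)",
         call. = FALSE)
  }
  energy_model(doc$eps_specific, doc$eps_nonspecific, doc$penalty,
               doc$weights, doc$alpha, doc$intensity_scale, doc$background,
               doc$conc_nonspecific)
}

#' Write / read per-probe folding energies as TSV
#'
#' Columns: `probe_id`, `energy`.
#'
#' @param folding A `data.table(probe_id, energy)`.
#' @param path File path.
#' @export
write_folding_table <- function(folding, path) {
  fwrite(folding[, c("probe_id", "energy")], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_folding_table
#' @export
read_folding_table <- function(path) {
  fread(path, sep = "\t", header = TRUE)[]
}

# minimal VCFv4.2 emitter shared by calls and truth writers
.write_vcf <- function(pos, ref, alt, qual, info, genome_id, genome_length,
                       path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome_id, genome_length),
    "##INFO=<ID=REGION_START,Number=1,Type=Integer,Description=\"Candidate region start\">",
    "##INFO=<ID=REGION_END,Number=1,Type=Integer,Description=\"Candidate region end\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (length(pos)) {
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s", genome_id, pos, ref, alt, qual,
            info)
  } else {
    character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write substitution calls as VCF
#'
#' QUAL carries the log-likelihood ratio; INFO records the candidate region.
#'
#' @param calls Output of [call_substitutions()].
#' @param genome_id,genome_length Contig name and length for the VCF header.
#' @param path File path.
#' @export
write_calls_vcf <- function(calls, genome_id, genome_length, path) {
  .write_vcf(calls$position, calls$ref, calls$alt,
             sprintf("%.6g", calls$llr),
             sprintf("REGION_START=%d;REGION_END=%d",
                     calls$region_start, calls$region_end),
             genome_id, genome_length, path)
}

#' Write a truth set as VCF
#'
#' @param truth `data.table(position, ref, alt)`.
#' @inheritParams write_calls_vcf
#' @export
write_truth_vcf <- function(truth, genome_id, genome_length, path) {
  .write_vcf(truth$position, truth$ref, truth$alt,
             rep(".", nrow(truth)), rep(".", nrow(truth)),
             genome_id, genome_length, path)
}

#' Read substitution records from a VCF
#'
#' Uses `vcfR::read.vcfR` when available, otherwise a plain-text fallback.
#'
#' @param path File path.
#' @return `data.table(position, ref, alt, qual)`.
#' @export
read_vcf_variants <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) {          # single record drops to a vector
      fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    }
    return(data.table(position = as.integer(fix[, "POS"]),
                      ref = as.character(fix[, "REF"]),
                      alt = as.character(fix[, "ALT"]),
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"]))))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.table(position = integer(), ref = character(),
                      alt = character(), qual = numeric()))
  }
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  data.table(position = as.integer(f[[2L]]), ref = f[[4L]], alt = f[[5L]],
             qual = suppressWarnings(as.numeric(f[[6L]])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write structural regions as BED
#'
#' 0-based half-open intervals; origin-wrapping regions on circular genomes
#' are split at the origin.
#'
#' @param regions Regions from [screen_candidate_regions()] (typically the
#'   structural subset).
#' @param genome_id Contig name.
#' @param genome_length Genome length (used to split wrapped regions).
#' @param path File path.
#' @export
write_regions_bed <- function(regions, genome_id, genome_length, path) {
  rows <- list()
  for (j in seq_len(nrow(regions))) {
    s <- regions$start[j]; e <- regions$end[j]
    name <- if (isTRUE(regions$structural[j])) "structural" else "candidate"
    if (s <= e) {
      rows[[length(rows) + 1L]] <- sprintf("%s\t%d\t%d\t%s", genome_id,
                                           s - 1L, e, name)
    } else {
      rows[[length(rows) + 1L]] <- sprintf("%s\t%d\t%d\t%s", genome_id,
                                           s - 1L, genome_length, name)
      rows[[length(rows) + 1L]] <- sprintf("%s\t%d\t%d\t%s", genome_id,
                                           0L, e, name)
    }
  }
  writeLines(as.character(unlist(rows)), path)
  invisible(path)
}
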