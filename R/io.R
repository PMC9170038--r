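# Readers and writers for the package's exchange formats: FASTA sequences,
# JSON motif sidecars, and the bound/limit curve export.

#' Write / read switch designs as FASTA plus a JSON motif sidecar
#'
#' Sequences travel as FASTA (via \pkg{Biostrings}); motif locations,
#' polarity, round and author class travel in a JSON sidecar keyed by design
#' id. Coordinates are 0-based half-open, matching [aptamer_motif()].
#'
#' @param designs list of [switch_design()] objects.
#' @param fasta,sidecar file paths.
#' @return `read_design_fasta`: a list of [switch_design()] objects.
#' @export
write_design_fasta <- function(designs, fasta, sidecar) {
  seqs <- Biostrings::RNAStringSet(vapply(designs, `[[`, "", "sequence"))
  names(seqs) <- vapply(designs, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta)
  side <- lapply(designs, function(d) {
    motif_json <- function(m) list(
      segments = m$segments,
      closing_pairs = m$closing_pairs,
      kd_intrinsic = m$kd_intrinsic)
    list(polarity = d$polarity, round = d$round,
         author_class = d$author_class,
         input_motif = motif_json(d$input_motif),
         output_motif = motif_json(d$output_motif))
  })
  names(side) <- names(seqs)
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(fasta)
}

#' @rdname write_design_fasta
#' @export
read_design_fasta <- function(fasta, sidecar) {
  seqs <- Biostrings::readRNAStringSet(fasta)
  side <- jsonlite::read_json(sidecar)
  lapply(names(seqs), function(id) {
    s <- side[[id]]
    if (is.null(s)) stop("design ", id, " missing from sidecar")
    motif <- function(m) aptamer_motif(
      segments = lapply(m$segments, unlist),
      closing_pairs = lapply(m$closing_pairs, unlist),
      kd_intrinsic = m$kd_intrinsic)
    switch_design(id, as.character(seqs[[id]]),
                  motif(s$input_motif), motif(s$output_motif),
                  polarity = s$polarity, round = s$round,
                  author_class = s$author_class)
  })
}

#' Tabulate activation-ratio ceilings and off-state Kd limits
#'
#' For each (trigger concentration, intrinsic Kd) row, computes the ceiling
#' [ar_max()]; when an on-state Kd column is present, also the off-state
#' limit [kd_off_limit()].
#'
#' @param table data.frame with columns `trigger_uM`, `kd_input_uM`, and
#'   optionally `kd_on_nM`.
#' @param file optional TSV output path.
#' @return the input with `ar_max` (and `kd_off_limit_nM`) appended.
#' @export
bound_table <- function(table, file = NULL) {
  stopifnot(all(c("trigger_uM", "kd_input_uM") %in% names(table)))
  table$ar_max <- ar_max(table$trigger_uM, table$kd_input_uM)
  if ("kd_on_nM" %in% names(table))
    table$kd_off_limit_nM <- kd_off_limit(table$kd_on_nM, table$trigger_uM,
                                          table$kd_input_uM)
  if (!is.null(file)) {
    write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(table))
  }
  table
}
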