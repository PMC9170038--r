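# Scoring and annotation built on the partition-function engine.

# mean pairing probability of the outermost closing pair(s) of a motif.
# "outermost" defaults to the single closing pair with the smallest i and
# largest j; outermost = FALSE averages over all closing pairs.
closing_pair_prob <- function(pp, motif, outermost = TRUE) {
  cp <- do.call(rbind, motif$closing_pairs) + 1L
  if (is.null(cp) || nrow(cp) == 0) stop("motif has no closing pairs")
  if (outermost) {
    span <- cp[, 2] - cp[, 1]
    cp <- cp[span == max(span), , drop = FALSE]
  }
  mean(pp$p[cp])
}

#' Split-aptamer "x ratio" switch score
#'
#' The x ratio is the ratio of predicted pairing probabilities of the
#' outermost base pair(s) of the split aptamer between the ligand-absent and
#' ligand-present ensembles. Because the ligand bonus can only promote
#' formation of the input motif, the raw absent/present ratio is `<= 1`; the
#' reported `score` is oriented so that a functional switch scores `> 1`
#' ("higher is better"), with the raw ratio preserved alongside.
#'
#' @param design a [switch_design()].
#' @param model an [energy_model()].
#' @param ligand_conc input-ligand concentration, µM.
#' @param which_motif which motif is the designated split aptamer; the input
#'   motif (which carries the ligand Kd) by default.
#' @param outermost use only the widest-span closing pair(s) (default) or all.
#' @return list with `score` (polarity-oriented, `> 1` = switching), `raw`
#'   (absent / present as defined), `p_absent`, `p_present` and `scoreable`
#'   (`FALSE` when the denominator probability is zero).
#' @export
x_ratio <- function(design, model = energy_model(), ligand_conc,
                    which_motif = c("input", "output"), outermost = TRUE) {
  stopifnot(inherits(design, "switch_design"), ligand_conc >= 0)
  which_motif <- match.arg(which_motif)
  motif <- if (which_motif == "input") design$input_motif else design$output_motif
  lig <- list(motif = design$input_motif, conc = ligand_conc)
  pp0 <- partition_function(design$sequence, model, ligand = list(
    motif = design$input_motif, conc = 0))
  ppL <- partition_function(design$sequence, model, ligand = lig)
  p0 <- closing_pair_prob(pp0, motif, outermost)
  pL <- closing_pair_prob(ppL, motif, outermost)
  if (p0 == pL) {
    # identical ensembles (includes L = 0 and motifs that cannot form:
    # the bonus never applies), so no predicted switching
    return(list(score = 1, raw = 1, p_absent = p0, p_present = pL,
                scoreable = TRUE))
  }
  if (pL == 0 || p0 == 0) {
    return(list(score = NA_real_, raw = NA_real_, p_absent = p0,
                p_present = pL, scoreable = FALSE))
  }
  raw <- p0 / pL
  score <- max(raw, 1 / raw)
  list(score = score, raw = raw, p_absent = p0, p_present = pL,
       scoreable = TRUE)
}

#' Annotate functional elements along a design
#'
#' Labels each position of a design from the pair-probability matrices in
#' both ligand states. Motif positions keep their motif label; a position
#' outside both motifs is called a *complement* of a motif when its predicted
#' probability of pairing with any position of that motif exceeds `threshold`
#' in either ligand state, *static* when it pairs anywhere else above
#' `threshold` in both states, and *unpaired* otherwise.
#'
#' @inheritParams x_ratio
#' @param threshold pairing-probability threshold for complement/static calls.
#' @return data.frame with columns `pos` (0-based), `base` and `label` in
#'   `{input, output, input_comp, output_comp, static, unpaired}`.
#' @export
annotate_elements <- function(design, model = energy_model(), ligand_conc,
                              threshold = 0.5) {
  stopifnot(inherits(design, "switch_design"), threshold > 0, threshold <= 1)
  n <- nchar(design$sequence)
  pp0 <- partition_function(design$sequence, model,
                            ligand = list(motif = design$input_motif, conc = 0))
  ppL <- partition_function(design$sequence, model,
                            ligand = list(motif = design$input_motif,
                                          conc = ligand_conc))
  # symmetric full matrices, elementwise max over ligand states
  sym <- function(p) p + t(p)
  pmax2 <- pmax(sym(pp0$p), sym(ppL$p))
  in_segs <- function(motif) {
    pos <- unlist(lapply(motif$segments, function(s) seq(s[1] + 1L, s[2])))
    sort(unique(pos))
  }
  ipos <- in_segs(design$input_motif)
  opos <- in_segs(design$output_motif)
  label <- rep("unpaired", n)
  for (k in seq_len(n)) {
    if (k %in% ipos) { label[k] <- "input"; next }
    if (k %in% opos) { label[k] <- "output"; next }
    p_in <- if (length(ipos)) max(pmax2[k, ipos]) else 0
    p_out <- if (length(opos)) max(pmax2[k, opos]) else 0
    p_any <- max(pmax2[k, ])
    if (max(p_in, p_out) > threshold) {
      label[k] <- if (p_out >= p_in) "output_comp" else "input_comp"
    } else if (p_any > threshold) {
      label[k] <- "static"
    }
  }
  data.frame(pos = seq_len(n) - 1L,
             base = strsplit(design$sequence, "")[[1]],
             label = label, stringsAsFactors = FALSE)
}

#' Export paired-state arc data for a design
#'
#' The "arcplot" view overlays base-pairing probabilities of the ligand-absent
#' and ligand-present ensembles in one chart. This export emits one row per
#' base pair whose probability exceeds `threshold` in either state, ordered by
#' `(i, j)`.
#'
#' @inheritParams x_ratio
#' @param threshold minimum of `max(p_absent, p_present)` for a pair to be
#'   reported.
#' @param file optional path; when given the table is written as TSV.
#' @return data.frame with columns `i`, `j` (0-based), `p_absent`,
#'   `p_present`, invisibly when written to `file`.
#' @export
arcplot_export <- function(design, model = energy_model(), ligand_conc,
                           threshold = 0.01, file = NULL) {
  stopifnot(inherits(design, "switch_design"))
  pp0 <- partition_function(design$sequence, model,
                            ligand = list(motif = design$input_motif, conc = 0))
  ppL <- partition_function(design$sequence, model,
                            ligand = list(motif = design$input_motif,
                                          conc = ligand_conc))
  keep <- which(pmax(pp0$p, ppL$p) > threshold, arr.ind = TRUE)
  out <- data.frame(i = integer(0), j = integer(0),
                    p_absent = numeric(0), p_present = numeric(0))
  if (nrow(keep) > 0) {
    keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
    out <- data.frame(i = keep[, 1] - 1L, j = keep[, 2] - 1L,
                      p_absent = pp0$p[keep], p_present = ppL$p[keep])
  }
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
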