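#' A ligand-toggling time series
#'
#' Cycle-averaged fluorescence of one design as the input ligand is repeatedly
#' exchanged between 0 and the trigger concentration.
#'
#' @param design_id identifier.
#' @param ligand_level per-cycle ligand level (µM); must alternate between
#'   exactly two levels, one of them 0.
#' @param intensity mean intensity per cycle, finite.
#' @param n_clusters number of clusters averaged per cycle (scalar or vector).
#' @return an object of class `toggle_series`.
#' @export
toggle_series <- function(design_id, ligand_level, intensity, n_clusters = 1L) {
  stopifnot(length(ligand_level) == length(intensity),
            all(is.finite(intensity)), all(ligand_level >= 0))
  lev <- sort(unique(ligand_level))
  if (length(lev) != 2 || lev[1] != 0)
    stop("ligand levels must alternate between 0 and one trigger level")
  if (any(diff(ligand_level) == 0))
    stop("ligand levels must alternate every cycle")
  structure(list(design_id = as.character(design_id),
                 cycle_index = seq_along(intensity),
                 ligand_level = as.numeric(ligand_level),
                 intensity = as.numeric(intensity),
                 n_clusters = n_clusters),
            class = "toggle_series")
}

#' Analyse reversible toggling of a switch
#'
#' For each interior cycle the signed response is the intensity minus the mean
#' of its two neighbouring (opposite-state) cycles; the per-cycle amplitude is
#' its magnitude. The direction is the sign of the mean signed response at
#' ligand-present cycles (`+1`: signal rises with ligand). Functional
#' degradation is estimated from a log-linear fit of amplitude versus cycle
#' index restricted to interior ligand-present cycles, giving a per-cycle
#' fractional decay `rate = 1 - exp(slope)`. Classification:
#' `flat` when the median amplitude falls below `3 *` the noise SD (estimated
#' from lag-2 differences, which compare same-state cycles); otherwise
#' `inverted` when `polarity` is supplied and the direction opposes it;
#' otherwise `degraded` when the decay exceeds `degraded_tol`
#' (default 0.5 %/cycle); otherwise `consistent`.
#'
#' @param series a [toggle_series()] with at least 4 cycles.
#' @param polarity optional expected polarity (`"on"`: intensity higher with
#'   ligand) used for the `inverted` call.
#' @param degraded_tol per-cycle decay above which the switch is `degraded`.
#' @return list with `amplitude` (per interior cycle), `cycle` (their
#'   indices), `direction`, `degradation_rate`, `noise_sd`, `class`.
#' @export
toggle_analysis <- function(series, polarity = NULL, degraded_tol = 0.005) {
  stopifnot(inherits(series, "toggle_series"))
  y <- series$intensity
  n <- length(y)
  if (n < 4) stop("need at least 4 cycles")
  idx <- 2:(n - 1)
  signed <- y[idx] - (y[idx - 1] + y[idx + 1]) / 2
  amp <- abs(signed)
  present <- series$ligand_level[idx] > 0
  # direction: response at ligand-present cycles relative to neighbours
  direction <- sign(mean(signed[present]))
  # same-state lag-2 differences estimate noise (amplitude trend is slow)
  noise_sd <- mad(diff(y, lag = 2)) / sqrt(2)
  amp_med <- median(amp)
  # degradation from ligand-present interior cycles with positive amplitude
  cyc <- series$cycle_index[idx]
  use <- present & amp > 0
  rate <- NA_real_
  if (sum(use) >= 3) {
    sl <- coef(lm(log(amp[use]) ~ cyc[use]))[[2]]
    rate <- 1 - exp(sl)
  }
  floor_amp <- max(3 * noise_sd, 1e-9 * max(1, max(abs(y))))
  cls <- if (amp_med < floor_amp) {
    "flat"
  } else if (!is.null(polarity) &&
             direction != (if (match.arg(polarity, c("on", "off")) == "on") 1 else -1)) {
    "inverted"
  } else if (is.finite(rate) && rate > degraded_tol) {
    "degraded"
  } else {
    "consistent"
  }
  list(amplitude = amp, cycle = cyc, direction = direction,
       degradation_rate = rate, noise_sd = noise_sd, class = cls)
}

#' Read / write toggling time series tables
#'
#' TSV with columns `design_id`, `cycle`, `ligand_uM`, `intensity`,
#' `n_clusters`.
#'
#' @param file path to a TSV file.
#' @return `read_toggle_tsv`: a named list of [toggle_series()].
#' @export
read_toggle_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("design_id", "cycle", "ligand_uM", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("toggle table lacks columns: ", paste(miss, collapse = ", "))
  lapply(split(x, x$design_id), function(d) {
    d <- d[order(d$cycle), , drop = FALSE]
    toggle_series(d$design_id[1], d$ligand_uM, d$intensity,
                  if ("n_clusters" %in% names(d)) d$n_clusters else 1L)
  })
}

#' @rdname read_toggle_tsv
#' @param series_list named list of [toggle_series()].
#' @export
write_toggle_tsv <- function(series_list, file) {
  rows <- lapply(series_list, function(s) {
    data.frame(design_id = s$design_id, cycle = s$cycle_index,
               ligand_uM = s$ligand_level, intensity = s$intensity,
               n_clusters = s$n_clusters)
  })
  write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
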