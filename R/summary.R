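#' Summarise one design from its ± ligand cluster fits
#'
#' The headline observed Kd of each condition comes from fitting the
#' median-aggregated titration; the per-cluster fits feed a seeded bootstrap
#' (resampling clusters with replacement) of the activation ratio, where each
#' draw's Kd is the median of the resampled per-cluster Kds. A condition with
#' no converged cluster fit flags the summary and leaves the AR absent.
#'
#' @param clusters_absent,clusters_present lists of [cluster_series()] for the
#'   two ligand conditions of one design.
#' @param polarity switch polarity, `"on"` or `"off"`.
#' @param n_boot bootstrap draws.
#' @param conf confidence level of the percentile interval.
#' @param seed integer seed for the bootstrap.
#' @return an object of class `design_summary`: list with `design_id`,
#'   `kd_obs_absent`, `kd_obs_present`, `ar`, `ar_ci` (percentile interval),
#'   `n_clusters_absent`, `n_clusters_present`, `flags`.
#' @export
design_summary <- function(clusters_absent, clusters_present,
                           polarity = c("on", "off"),
                           n_boot = 1000L, conf = 0.95, seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(length(clusters_absent) >= 1, length(clusters_present) >= 1)
  design_id <- clusters_absent[[1]]$design_id
  flags <- character(0)

  one_condition <- function(clusters) {
    agg <- median_aggregate(clusters)
    headline <- fit_binding_curve(agg)
    per <- vapply(clusters, function(cl) {
      f <- fit_binding_curve(cl)
      if (f$converged) f$kd else NA_real_
    }, numeric(1))
    list(headline = headline, cluster_kds = per[!is.na(per)])
  }
  ca <- one_condition(clusters_absent)
  cp <- one_condition(clusters_present)

  kd_a <- if (ca$headline$converged) ca$headline$kd else NA_real_
  kd_p <- if (cp$headline$converged) cp$headline$kd else NA_real_
  if (!ca$headline$converged) flags <- c(flags, "absent condition not converged")
  if (!cp$headline$converged) flags <- c(flags, "present condition not converged")

  ar <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (is.finite(kd_a) && is.finite(kd_p)) {
    ar <- activation_ratio(kd_a, kd_p, polarity)
    na <- length(ca$cluster_kds); np <- length(cp$cluster_kds)
    if (na >= 2 && np >= 2) {
      set.seed(seed)
      ia <- matrix(sample.int(na, n_boot * na, replace = TRUE), n_boot, na)
      ip <- matrix(sample.int(np, n_boot * np, replace = TRUE), n_boot, np)
      med_a <- apply(matrix(ca$cluster_kds[ia], n_boot, na), 1, median)
      med_p <- apply(matrix(cp$cluster_kds[ip], n_boot, np), 1, median)
      ar_b <- if (polarity == "on") med_a / med_p else med_p / med_a
      alpha <- (1 - conf) / 2
      ci <- unname(quantile(ar_b, c(alpha, 1 - alpha)))
    } else {
      flags <- c(flags, "too few converged cluster fits for bootstrap")
    }
  }
  structure(list(design_id = design_id, polarity = polarity,
                 kd_obs_absent = kd_a, kd_obs_present = kd_p,
                 ar = ar, ar_ci = ci,
                 n_clusters_absent = length(clusters_absent),
                 n_clusters_present = length(clusters_present),
                 flags = flags),
            class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("Design %s (%s): Kd -ligand %.4g nM, +ligand %.4g nM, AR = %.3g [%.3g, %.3g]\n",
              x$design_id, x$polarity, x$kd_obs_absent, x$kd_obs_present,
              x$ar, x$ar_ci[1], x$ar_ci[2]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Summarise every design in a cluster titration table
#'
#' Convenience wrapper applying [design_summary()] to each design of a long
#' titration table (see [read_titration_tsv()] for the layout).
#'
#' @param table titration data.frame.
#' @param polarities named character vector mapping design_id to polarity
#'   (defaults to `"on"` when missing).
#' @inheritParams design_summary
#' @return data.frame with one row per design: `design_id`, `polarity`,
#'   `kd_obs_absent`, `kd_obs_present`, `ar`, `ar_lo`, `ar_hi`,
#'   `n_clusters_absent`, `n_clusters_present`, `flagged`.
#' @export
summarize_designs <- function(table, polarities = NULL,
                              n_boot = 1000L, conf = 0.95, seed = 1L) {
  series <- titration_to_series(table)
  by_design <- split(series, vapply(series, `[[`, "", "design_id"))
  rows <- lapply(names(by_design), function(id) {
    ss <- by_design[[id]]
    cond <- vapply(ss, `[[`, "", "condition")
    if (!any(cond == "absent") || !any(cond == "present")) return(NULL)
    pol <- if (!is.null(polarities) && id %in% names(polarities))
      polarities[[id]] else "on"
    s <- design_summary(ss[cond == "absent"], ss[cond == "present"],
                        polarity = pol, n_boot = n_boot, conf = conf,
                        seed = seed)
    data.frame(design_id = s$design_id, polarity = s$polarity,
               kd_obs_absent = s$kd_obs_absent,
               kd_obs_present = s$kd_obs_present,
               ar = s$ar, ar_lo = s$ar_ci[1], ar_hi = s$ar_ci[2],
               n_clusters_absent = s$n_clusters_absent,
               n_clusters_present = s$n_clusters_present,
               flagged = length(s$flags) > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Boxplot statistics by group
#'
#' Tukey box statistics as drawn in round-by-round performance plots:
#' median and quartiles (linear-interpolation quantiles, R type 7), IQR,
#' whiskers at the most extreme observations within `± 1.5 * IQR` of the
#' quartiles, and the outliers beyond them.
#'
#' @param values numeric vector (e.g. activation ratios).
#' @param groups grouping factor of the same length (e.g. design round).
#' @return data.frame with one row per non-empty group: `group`, `n`,
#'   `median`, `q1`, `q3`, `iqr`, `whisker_lo`, `whisker_hi`, `n_outliers`,
#'   and an `outliers` list-column.
#' @export
round_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  sp <- split(values, groups, drop = TRUE)
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    if (length(v) == 0) return(NULL)
    qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    lo_fence <- qs[1] - 1.5 * iqr
    hi_fence <- qs[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    out <- v[v < lo_fence | v > hi_fence]
    data.frame(group = g, n = length(v), median = qs[2], q1 = qs[1],
               q3 = qs[3], iqr = iqr,
               whisker_lo = min(inside), whisker_hi = max(inside),
               n_outliers = length(out),
               outliers = I(list(sort(out))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replicate concordance of observed Kds
#'
#' Squared Pearson correlation of `log10(Kd_obs)` over designs measured in
#' both replicates (log space, because observed Kds span decades).
#'
#' @param rep1,rep2 data.frames as returned by [summarize_designs()] (need
#'   `design_id` and a Kd column).
#' @param column which Kd column to correlate.
#' @return squared correlation in `[0, 1]`.
#' @export
replicate_r2 <- function(rep1, rep2, column = "kd_obs_absent") {
  shared <- merge(rep1[, c("design_id", column)],
                  rep2[, c("design_id", column)],
                  by = "design_id", suffixes = c(".1", ".2"))
  x <- shared[[paste0(column, ".1")]]
  y <- shared[[paste0(column, ".2")]]
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3) stop("need at least 3 shared designs with converged Kds")
  cor(log10(x[ok]), log10(y[ok]))^2
}
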