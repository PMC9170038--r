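#' One cluster's fluorescence titration
#'
#' @param cluster_id,design_id identifiers.
#' @param condition ligand condition, `"absent"` or `"present"`.
#' @param concentrations reporter concentrations in nM, strictly increasing,
#'   `>= 0`, at least 4 points.
#' @param intensities fluorescence intensities (arbitrary units), same length,
#'   finite.
#' @return an object of class `cluster_series`.
#' @export
cluster_series <- function(cluster_id, design_id,
                           condition = c("absent", "present"),
                           concentrations, intensities) {
  condition <- match.arg(condition)
  stopifnot(length(concentrations) == length(intensities),
            length(concentrations) >= 4,
            all(is.finite(concentrations)), all(is.finite(intensities)),
            all(concentrations >= 0), all(diff(concentrations) > 0))
  structure(list(cluster_id = as.character(cluster_id),
                 design_id = as.character(design_id),
                 condition = condition,
                 concentrations = as.numeric(concentrations),
                 intensities = as.numeric(intensities)),
            class = "cluster_series")
}

#' Langmuir binding isotherm
#'
#' `f(c) = fmin + (fmax - fmin) * c / (kd + c)` — the single-site equilibrium
#' binding curve underlying every titration in the package.
#'
#' @param conc concentration(s), nM.
#' @param kd dissociation constant, nM.
#' @param fmax,fmin saturated and baseline intensities.
#' @return intensity value(s).
#' @export
langmuir <- function(conc, kd, fmax, fmin = 0) {
  fmin + (fmax - fmin) * conc / (kd + conc)
}

#' Fit a Langmuir binding curve to one titration
#'
#' Least-squares fit of `f(c) = fmin + (fmax - fmin) * c / (kd + c)` with a
#' deterministic start rule (fmin = min intensity, fmax = max intensity,
#' kd = geometric mean of the positive concentrations) and box bounds
#' `kd in [0.1 * c_min_pos, 10 * c_max]` (Levenberg–Marquardt via
#' \pkg{minpack.lm}). A fit whose Kd lands on a bound, or whose intensities
#' carry no information (zero variance), is returned with `converged = FALSE`
#' rather than trusted.
#'
#' @param series a [cluster_series()] (or any list with `concentrations` and
#'   `intensities`).
#' @param kd_bounds optional length-2 Kd bounds (nM), overriding the rule.
#' @return an object of class `binding_fit`: list with `kd`, `fmax`, `fmin`,
#'   `rmse`, `n_points`, `converged` and `flag`.
#' @examples
#' s <- cluster_series("c1", "d1", "absent", c(1, 3, 10, 30, 100),
#'                     langmuir(c(1, 3, 10, 30, 100), kd = 10, fmax = 1))
#' fit_binding_curve(s)$kd
#' @export
fit_binding_curve <- function(series, kd_bounds = NULL) {
  conc <- series$concentrations
  y <- series$intensities
  if (length(conc) < 4) stop("need at least 4 titration points")
  pos <- conc[conc > 0]
  if (length(pos) < 2) stop("need at least 2 positive concentrations")
  if (is.null(kd_bounds)) kd_bounds <- c(0.1 * min(pos), 10 * max(pos))
  nofit <- function(flag) {
    structure(list(kd = NA_real_, fmax = NA_real_, fmin = NA_real_,
                   rmse = NA_real_, n_points = length(conc),
                   converged = FALSE, flag = flag),
              class = "binding_fit")
  }
  if (sd(y) == 0) return(nofit("zero-variance intensities"))
  start <- c(kd = exp(mean(log(pos))), fmax = max(y), fmin = min(y))
  resid_fn <- function(p) y - (p[3] + (p[2] - p[3]) * conc / (p[1] + conc))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = c(kd_bounds[1], -Inf, -Inf),
                       upper = c(kd_bounds[2], Inf, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(nofit("optimizer failure"))
  kd <- fit$par[[1]]; fmax <- fit$par[[2]]; fmin <- fit$par[[3]]
  at_bound <- kd <= kd_bounds[1] * (1 + 1e-8) || kd >= kd_bounds[2] * (1 - 1e-8)
  if (fmax < fmin) {  # canonicalize: report fmax >= fmin, flag the inversion
    tmp <- fmax; fmax <- fmin; fmin <- tmp
    flag <- "descending curve"
    conv <- FALSE
  } else {
    flag <- if (at_bound) "kd at bound" else NA_character_
    conv <- !at_bound
  }
  rmse <- sqrt(mean((y - langmuir(conc, kd, fmax, fmin))^2))
  structure(list(kd = kd, fmax = fmax, fmin = fmin, rmse = rmse,
                 n_points = length(conc), converged = conv, flag = flag),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Langmuir fit: Kd = %.4g nM, fmax = %.4g, fmin = %.4g, rmse = %.3g (n = %d)\n",
                x$kd, x$fmax, x$fmin, x$rmse, x$n_points))
  else
    cat(sprintf("Langmuir fit: not converged (%s)\n", x$flag))
  invisible(x)
}

#' Median-aggregate titrations across clusters
#'
#' The headline binding curve of a design is the per-concentration median
#' intensity over its clusters ("median fit"), which is robust to occasional
#' aberrant clusters. All series must share design, condition and
#' concentration grid.
#'
#' @param clusters list of [cluster_series()] objects.
#' @return a [cluster_series()] with the median intensities and an
#'   `n_clusters` attribute.
#' @export
median_aggregate <- function(clusters) {
  stopifnot(length(clusters) >= 1)
  ref <- clusters[[1]]
  for (cl in clusters) {
    if (!identical(cl$design_id, ref$design_id) ||
        !identical(cl$condition, ref$condition) ||
        !isTRUE(all.equal(cl$concentrations, ref$concentrations)))
      stop("clusters must share design, condition and concentration grid")
  }
  med <- apply(do.call(rbind, lapply(clusters, `[[`, "intensities")), 2, median)
  out <- cluster_series(paste0(ref$design_id, ":median"), ref$design_id,
                        ref$condition, ref$concentrations, med)
  attr(out, "n_clusters") <- length(clusters)
  out
}

#' Read / write cluster titration tables
#'
#' Tab-separated with columns `cluster_id`, `design_id`, `condition`
#' (`absent`/`present`), `conc_nM`, `intensity`; one row per measured point.
#'
#' @param file path to a TSV file.
#' @return `read_titration_tsv`: a data.frame in the column layout above.
#' @export
read_titration_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("cluster_id", "design_id", "condition", "conc_nM", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("titration table lacks columns: ", paste(miss, collapse = ", "))
  stopifnot(all(x$condition %in% c("absent", "present")))
  x
}

#' @rdname read_titration_tsv
#' @param table data.frame in the titration layout.
#' @export
write_titration_tsv <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# split a long titration table into cluster_series objects
titration_to_series <- function(table) {
  key <- interaction(table$cluster_id, table$design_id, table$condition,
                     drop = TRUE)
  lapply(split(table, key), function(d) {
    d <- d[order(d$conc_nM), , drop = FALSE]
    cluster_series(d$cluster_id[1], d$design_id[1], d$condition[1],
                   d$conc_nM, d$intensity)
  })
}
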