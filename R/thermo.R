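#' Three-state equilibrium parameters of a stand-alone RNA switch
#'
#' The switch ensemble is coarse-grained into three states: the
#' reporter-competent fold (output element formed, statistical weight
#' `w_reporter`), the input-aptamer fold (input aptamer formed, weight
#' `w_aptamer`) and everything else (`w_other`). Input-ligand binding at
#' concentration `L` multiplies the weight of the state that carries the
#' formed aptamer by `(1 + L / kd_input)`.
#'
#' @param w_reporter,w_aptamer,w_other non-negative dimensionless Boltzmann
#'   weights; at least one must be positive.
#' @param kd_input intrinsic input-ligand aptamer dissociation constant, in µM.
#' @param kd_reporter intrinsic reporter dissociation constant of the properly
#'   folded output element, in nM.
#' @return an object of class `three_state_params`.
#' @examples
#' p <- three_state_params(1, 5, 0.2, kd_input = 1.53, kd_reporter = 5)
#' reporter_fraction(p, ligand_conc = 200)
#' @export
three_state_params <- function(w_reporter, w_aptamer, w_other,
                               kd_input, kd_reporter) {
  w <- c(w_reporter, w_aptamer, w_other)
  stopifnot(length(w) == 3, is.finite(w), is.finite(kd_input), is.finite(kd_reporter))
  if (any(w < 0)) stop("statistical weights must be non-negative")
  if (all(w == 0)) stop("degenerate model: all statistical weights are zero")
  if (kd_input <= 0) stop("kd_input must be positive")
  if (kd_reporter <= 0) stop("kd_reporter must be positive")
  structure(list(w_reporter = w_reporter, w_aptamer = w_aptamer,
                 w_other = w_other, kd_input = kd_input,
                 kd_reporter = kd_reporter),
            class = "three_state_params")
}

#' @export
print.three_state_params <- function(x, ...) {
  cat("Three-state switch parameters\n")
  cat(sprintf("  weights (reporter / aptamer / other): %.4g / %.4g / %.4g\n",
              x$w_reporter, x$w_aptamer, x$w_other))
  cat(sprintf("  kd_input: %.4g uM   kd_reporter: %.4g nM\n",
              x$kd_input, x$kd_reporter))
  invisible(x)
}

#' Equilibrium fraction of molecules in the reporter-competent fold
#'
#' With the ligand bonus on the competing input-aptamer fold (the default,
#' `bound_state = "aptamer"`, an OFF-type response) the fraction is
#' \deqn{f_R(L) = \frac{w_R}{w_R + w_A (1 + L/K_d^{in}) + w_O},}
#' monotone non-increasing in `L`. With `bound_state = "reporter"` the aptamer
#' is nested inside the reporter-competent fold so the bonus multiplies
#' `w_reporter` instead (an ON-type response).
#'
#' @param params a [three_state_params()] object.
#' @param ligand_conc input-ligand concentration, µM, `>= 0`.
#' @param bound_state which coarse state carries the formed input aptamer.
#' @return fraction in `[0, 1]`.
#' @export
reporter_fraction <- function(params, ligand_conc,
                              bound_state = c("aptamer", "reporter")) {
  stopifnot(inherits(params, "three_state_params"),
            is.numeric(ligand_conc), all(ligand_conc >= 0))
  bound_state <- match.arg(bound_state)
  bonus <- 1 + ligand_conc / params$kd_input
  if (bound_state == "aptamer") {
    num <- params$w_reporter
    den <- params$w_reporter + params$w_aptamer * bonus + params$w_other
  } else {
    num <- params$w_reporter * bonus
    den <- params$w_reporter * bonus + params$w_aptamer + params$w_other
  }
  num / den
}

#' Observed reporter dissociation constant of a switch
#'
#' In the titration (weak-reporter) regime the observed Kd is the intrinsic
#' reporter Kd divided by the fraction of molecules folded into the
#' reporter-competent state: `kd_obs = kd_reporter / f_R(L)`. When no
#' reporter-competent state is populated the affinity is absent and `Inf` is
#' returned (not an error), mirroring a non-binding cluster.
#'
#' @inheritParams reporter_fraction
#' @return observed Kd in nM; `Inf` for an unbindable state.
#' @export
kd_obs <- function(params, ligand_conc,
                   bound_state = c("aptamer", "reporter")) {
  f <- reporter_fraction(params, ligand_conc, match.arg(bound_state))
  ifelse(f > 0, params$kd_reporter / f, Inf)
}

#' Activation ratio of a measured switch
#'
#' The activation ratio (AR) is the fold change in observed reporter Kd
#' between the off state (weak reporter binding) and the on state (strong
#' reporter binding). For an `"on"` switch the ligand improves binding, so
#' `AR = kd_obs(no ligand) / kd_obs(with ligand)`; for an `"off"` switch the
#' orientation is reversed. `AR > 1` means functional switching in the
#' designed direction; `AR < 1` an inverted response.
#'
#' @param kd_obs_no_ligand,kd_obs_with_ligand observed Kds (nM), both `> 0`
#'   and finite.
#' @param polarity `"on"` or `"off"`.
#' @return dimensionless activation ratio.
#' @examples
#' activation_ratio(800, 10, "on")  # 80-fold switch
#' @export
activation_ratio <- function(kd_obs_no_ligand, kd_obs_with_ligand,
                             polarity = c("on", "off")) {
  polarity <- match.arg(polarity)
  ok <- is.finite(kd_obs_no_ligand) & is.finite(kd_obs_with_ligand) &
    kd_obs_no_ligand > 0 & kd_obs_with_ligand > 0
  if (!all(ok)) stop("observed Kds must be finite and positive")
  if (polarity == "on") kd_obs_no_ligand / kd_obs_with_ligand
  else kd_obs_with_ligand / kd_obs_no_ligand
}

#' Thermodynamic ceiling on the activation ratio
#'
#' For a switch with a single input aptamer the activation ratio can never
#' exceed \deqn{AR_{max} = 1 + \frac{[L]}{K_d^{in}},} the free-energy budget
#' of one ligand-binding event at trigger concentration `[L]`. This is the
#' supremum of [activation_ratio()] over all three-state parameter sets with
#' the given intrinsic aptamer Kd.
#'
#' @param trigger_conc input-ligand concentration at readout, µM, `>= 0`.
#' @param kd_input intrinsic input aptamer Kd, µM, `> 0`.
#' @return dimensionless ceiling, `>= 1`.
#' @examples
#' ar_max(200, fmn_constants()$kd_input)  # ceiling for the FMN aptamer
#' @seealso [kd_off_limit()], [ar_max_delta()]
#' @export
ar_max <- function(trigger_conc, kd_input) {
  stopifnot(is.numeric(trigger_conc), is.numeric(kd_input))
  if (any(trigger_conc < 0)) stop("trigger_conc must be non-negative")
  if (any(kd_input <= 0)) stop("kd_input must be positive")
  1 + trigger_conc / kd_input
}

#' Delta-method uncertainty on the activation-ratio ceiling
#'
#' Propagates a standard error on the intrinsic aptamer Kd through
#' [ar_max()]: `sd(AR_max) = trigger_conc * kd_se / kd_input^2`. This is a
#' first-order approximation; it makes no claim about how any published
#' uncertainty was derived.
#'
#' @inheritParams ar_max
#' @param kd_se standard error of `kd_input`, µM.
#' @return list with `value` and `sd`.
#' @export
ar_max_delta <- function(trigger_conc, kd_input, kd_se) {
  stopifnot(kd_se >= 0)
  list(value = ar_max(trigger_conc, kd_input),
       sd = trigger_conc * kd_se / kd_input^2)
}

#' Constants used for the FMN input aptamer
#'
#' Intrinsic affinity of the 11-nt FMN aptamer and the trigger concentration
#' at which FMN-responsive switches are read out. `kd_se` feeds the
#' delta-method uncertainty on the ceiling.
#'
#' @return list with `kd_input` (µM), `kd_se` (µM) and `trigger_conc` (µM).
#' @export
fmn_constants <- function() {
  list(kd_input = 1.53, kd_se = 0.39, trigger_conc = 200)
}

#' Thermodynamic limit on the off-state Kd given the on-state Kd
#'
#' The weakest off-state reporter affinity attainable by a single-aptamer
#' switch whose on-state Kd is `kd_on`:
#' `kd_off_limit = kd_on * ar_max(trigger_conc, kd_input)`. Measured designs
#' fall on or below this line in a (Kd_on, Kd_off) scatter.
#'
#' @param kd_on on-state observed Kd, nM, `> 0`.
#' @inheritParams ar_max
#' @return limiting off-state Kd, nM.
#' @export
kd_off_limit <- function(kd_on, trigger_conc, kd_input) {
  if (any(kd_on <= 0)) stop("kd_on must be positive")
  kd_on * ar_max(trigger_conc, kd_input)
}

#' Intensity fold change at finite reporter concentration
#'
#' The fluorescence intensity of a cluster is proportional to the fraction of
#' molecules that are both reporter-competent and reporter-bound. Treating
#' reporter binding explicitly (weight `w_R * (1 + P/kd_reporter)` on the
#' reporter state) the ± ligand intensity ratio is
#' computed at reporter concentration `P` and oriented like
#' [activation_ratio()]. It converges to the activation ratio as `P -> 0` and
#' to 1 as `P -> Inf`: quoting switch performance as an intensity fold change
#' at a single reporter concentration understates AR unless `P` is well below
#' the on-state Kd.
#'
#' @inheritParams reporter_fraction
#' @param reporter_conc reporter (output-ligand) concentration, nM, `>= 0`.
#' @param trigger_conc input-ligand concentration of the ligand-present
#'   condition, µM.
#' @param polarity switch polarity; `"on"` uses `bound_state = "reporter"`,
#'   `"off"` uses `"aptamer"`.
#' @return dimensionless intensity ratio (bright state over dark state).
#' @export
intensity_ratio <- function(params, reporter_conc, trigger_conc,
                            polarity = c("on", "off")) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(reporter_conc), all(reporter_conc >= 0),
            trigger_conc >= 0)
  bound_state <- if (polarity == "on") "reporter" else "aptamer"
  bound_frac <- function(L, P) {
    bonus <- 1 + L / params$kd_input
    p <- P / params$kd_reporter
    if (bound_state == "aptamer") {
      num <- params$w_reporter * p
      den <- params$w_reporter * (1 + p) + params$w_aptamer * bonus + params$w_other
    } else {
      # ligand and reporter both bind the reporter-competent fold (independent sites)
      num <- params$w_reporter * bonus * p
      den <- params$w_reporter * bonus * (1 + p) + params$w_aptamer + params$w_other
    }
    num / den
  }
  f0 <- bound_frac(0, reporter_conc)
  fL <- bound_frac(trigger_conc, reporter_conc)
  if (polarity == "on") fL / f0 else f0 / fL
}
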