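# Seeded generators for every input the pipeline consumes, with ground truth
# retained for parameter-recovery tests.

# canonical motif sequences implanted into generated designs
MS2_HAIRPIN <- "ACAUGAGGAUUACCCAUGU"          # 19-nt MS2 coat-protein hairpin
FMN_SEG_5P <- "AGGAUAU"                       # split FMN aptamer halves
FMN_SEG_3P <- "AGAAGG"

#' Default desk-scale generator settings
#'
#' The settings behind every generator: log-uniform parameter ranges of the
#' three-state model, the titration concentration grid, cluster counts and the
#' noise model. Scaling up is config-only.
#'
#' @return named list of defaults (documented inline).
#' @export
sim_defaults <- function() {
  list(
    n_designs = 200L,           # designs per library
    n_clusters = 30L,           # clusters per design and condition
    # reporter titration grid, nM (half-log ladder)
    conc_grid = round(0.5 * 10^(seq(0, 4.5, by = 0.5)), 2),
    trigger_conc = 200,         # µM input ligand at readout
    kd_input_range = c(1, 10),  # µM, log-uniform
    kd_reporter_range = c(1, 5),   # nM, log-uniform
    w_aptamer_range = c(0.2, 5),   # log-uniform (w_reporter fixed at 1)
    w_other_range = c(0.05, 0.5),  # log-uniform
    fmax_sdlog = 0.3,           # lognormal spread of cluster fmax
    background_sd = 0.03,       # additive background, units of mean fmax
    shot_cv = 0.05,             # multiplicative shot noise CV
    cluster_nb_size = 20,       # truncated negative binomial cluster counts
    design_length = 60L         # nt per generated design
  )
}

runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

# implant the split FMN input aptamer and the MS2 output hairpin into a random
# background, returning a switch_design; closing pair = the complementary
# flanks added around the split aptamer halves
implant_design <- function(id, polarity, round, author_class, length_nt) {
  f5 <- FMN_SEG_5P; f3 <- FMN_SEG_3P; ms2 <- MS2_HAIRPIN
  core <- paste0("G", f5, "A", ms2, "A", f3, "C")  # G...C closing pair flanks
  pad_total <- length_nt - nchar(core)
  if (pad_total < 2) stop("design_length too short for the motifs")
  left <- pad_total %/% 2
  right <- pad_total - left
  pads <- function(k) paste(sample(RNA_BASES, k, replace = TRUE), collapse = "")
  seqc <- paste0(pads(left), core, pads(right))
  off <- left  # 0-based offset of core
  i_g <- off                                   # the flanking G
  i_f5 <- off + 1L
  i_ms2 <- i_f5 + nchar(f5) + 1L
  i_f3 <- i_ms2 + nchar(ms2) + 1L
  i_c <- i_f3 + nchar(f3)                      # the flanking C
  input <- aptamer_motif(
    segments = list(c(i_f5, i_f5 + nchar(f5)), c(i_f3, i_f3 + nchar(f3))),
    closing_pairs = list(c(i_g, i_c)),
    kd_intrinsic = 1.53)
  output <- aptamer_motif(
    segments = list(c(i_ms2, i_ms2 + nchar(ms2))),
    closing_pairs = list(c(i_ms2, i_ms2 + nchar(ms2) - 1L)))
  switch_design(id, seqc, input, output, polarity, round, author_class)
}

#' Generate a synthetic switch library with retained ground truth
#'
#' Draws `n_designs` designs: random-background sequences with the split FMN
#' input aptamer and the MS2 output hairpin implanted, three-state parameters
#' from log-uniform ranges, polarity and submission round assigned, and the
#' implied true observed Kds and activation ratio computed from the
#' three-state model. Deterministic under `seed`.
#'
#' @param n_designs number of designs.
#' @param config settings list, see [sim_defaults()].
#' @param seed integer seed.
#' @return list with `designs` (list of [switch_design()]) and `truth`
#'   (data.frame: per-design parameters, `kd_obs_absent`, `kd_obs_present`,
#'   `ar_true`, `polarity`, `round`), plus the `config` and `seed` used.
#' @export
generate_library <- function(n_designs = sim_defaults()$n_designs,
                             config = sim_defaults(), seed = 1L) {
  stopifnot(n_designs >= 1)
  set.seed(seed)
  ids <- sprintf("D%04d", seq_len(n_designs))
  polarity <- sample(c("on", "off"), n_designs, replace = TRUE)
  round <- sample(1:7, n_designs, replace = TRUE,
                  prob = c(1, 1, 1.5, 1.5, 2, 2, 2))
  author <- sample(c("player", "automated", "modification"), n_designs,
                   replace = TRUE, prob = c(0.5, 0.2, 0.3))
  kd_input <- runif_log(n_designs, config$kd_input_range)
  kd_rep <- runif_log(n_designs, config$kd_reporter_range)
  w_a <- runif_log(n_designs, config$w_aptamer_range)
  w_o <- runif_log(n_designs, config$w_other_range)
  L <- config$trigger_conc

  designs <- vector("list", n_designs)
  kd0 <- kdL <- ar <- numeric(n_designs)
  for (k in seq_len(n_designs)) {
    designs[[k]] <- implant_design(ids[k], polarity[k], round[k], author[k],
                                   config$design_length)
    p <- three_state_params(1, w_a[k], w_o[k], kd_input[k], kd_rep[k])
    bs <- if (polarity[k] == "on") "reporter" else "aptamer"
    kd0[k] <- kd_obs(p, 0, bound_state = bs)
    kdL[k] <- kd_obs(p, L, bound_state = bs)
    ar[k] <- activation_ratio(kd0[k], kdL[k], polarity[k])
  }
  truth <- data.frame(design_id = ids, polarity = polarity, round = round,
                      author_class = author,
                      w_reporter = 1, w_aptamer = w_a, w_other = w_o,
                      kd_input = kd_input, kd_reporter = kd_rep,
                      kd_obs_absent = kd0, kd_obs_present = kdL,
                      ar_true = ar, stringsAsFactors = FALSE)
  list(designs = designs, truth = truth, config = config, seed = seed)
}

#' Simulate cluster-level fluorescence titrations
#'
#' For each design and ligand condition, clusters get a lognormal
#' cluster-specific saturation intensity (display density varies per
#' cluster), and each measured point is the Langmuir value at the true
#' observed Kd with multiplicative shot noise and additive background.
#' Deterministic under `seed`.
#'
#' @param truth truth data.frame from [generate_library()].
#' @param config settings list, see [sim_defaults()]; noise parameters must be
#'   non-negative.
#' @param n_clusters clusters per design and condition; when `NA`, drawn per
#'   design from a truncated negative binomial (mean `n_clusters_mean`).
#' @param seed integer seed.
#' @return list with `table` (long titration data.frame, see
#'   [read_titration_tsv()]) and `cluster_truth` (per-cluster fmax draws).
#' @export
simulate_cluster_intensities <- function(truth, config = sim_defaults(),
                                         n_clusters = config$n_clusters,
                                         seed = 2L) {
  stopifnot(config$fmax_sdlog >= 0, config$background_sd >= 0,
            config$shot_cv >= 0, all(diff(config$conc_grid) > 0))
  set.seed(seed)
  grid <- config$conc_grid
  ng <- length(grid)
  rows <- vector("list", 2 * nrow(truth))
  ctruth <- vector("list", 2 * nrow(truth))
  r <- 0L
  for (k in seq_len(nrow(truth))) {
    for (cond in c("absent", "present")) {
      kd <- if (cond == "absent") truth$kd_obs_absent[k] else truth$kd_obs_present[k]
      nc <- if (is.na(n_clusters))
        max(1L, min(112L, rnbinom(1, size = config$cluster_nb_size, mu = 30)))
      else as.integer(n_clusters)
      fmax <- rlnorm(nc, meanlog = 0, sdlog = config$fmax_sdlog)
      clean <- outer(fmax, langmuir(grid, kd, 1))          # nc x ng
      shot <- matrix(rnorm(nc * ng, 1, config$shot_cv), nc, ng)
      bg <- matrix(rnorm(nc * ng, 0, config$background_sd), nc, ng)
      y <- clean * shot + bg
      r <- r + 1L
      rows[[r]] <- data.frame(
        cluster_id = rep(sprintf("%s.%s.c%03d", truth$design_id[k],
                                 substr(cond, 1, 1), seq_len(nc)), each = ng),
        design_id = truth$design_id[k], condition = cond,
        conc_nM = rep(grid, nc), intensity = as.vector(t(y)),
        stringsAsFactors = FALSE)
      ctruth[[r]] <- data.frame(design_id = truth$design_id[k],
                                condition = cond,
                                cluster = seq_len(nc), fmax = fmax)
    }
  }
  list(table = do.call(rbind, rows[seq_len(r)]),
       cluster_truth = do.call(rbind, ctruth[seq_len(r)]))
}

#' Simulate a ligand-toggling time series
#'
#' Per-cycle mean intensity from the equilibrium reporter-bound fraction at
#' the cycle's ligand level, with the toggle amplitude damped by
#' `(1 - degradation_rate)^cycle` and Gaussian noise added. Ligand levels
#' alternate 0, trigger, 0, trigger, ...
#'
#' @param kd_obs_absent,kd_obs_present true observed Kds (nM).
#' @param polarity switch polarity (sets the toggle direction).
#' @param n_cycles number of cycles (`>= 2`).
#' @param trigger_conc trigger ligand level, µM.
#' @param reporter_conc reporter concentration during imaging, nM.
#' @param degradation_rate per-cycle fractional amplitude loss in `[0, 1)`.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param design_id identifier.
#' @param seed integer seed.
#' @return a [toggle_series()].
#' @export
simulate_toggle_series <- function(kd_obs_absent, kd_obs_present,
                                   polarity = c("on", "off"),
                                   n_cycles = 52L, trigger_conc = 200,
                                   reporter_conc = 50,
                                   degradation_rate = 0, noise_sd = 0,
                                   design_id = "D0001", seed = 3L) {
  polarity <- match.arg(polarity)
  stopifnot(n_cycles >= 2, noise_sd >= 0)
  if (degradation_rate < 0 || degradation_rate >= 1)
    stop("degradation_rate must be in [0, 1)")
  set.seed(seed)
  cyc <- seq_len(n_cycles)
  level <- ifelse(cyc %% 2 == 0, trigger_conc, 0)  # start ligand-free
  bound <- function(kd) reporter_conc / (reporter_conc + kd)
  i0 <- bound(kd_obs_absent)
  iL <- bound(kd_obs_present)
  base <- min(i0, iL)
  amp0 <- abs(iL - i0)
  hi_state <- if (iL > i0) level > 0 else level == 0
  y <- base + ifelse(hi_state, amp0 * (1 - degradation_rate)^cyc, 0)
  y <- y + rnorm(n_cycles, 0, noise_sd)
  toggle_series(design_id, level, y)
}

#' Simulate two-conformation chemical reactivity profiles
#'
#' Per-base reactivities for a schedule of time points alternating between two
#' secondary structures of the same sequence: gamma-distributed with a high
#' mean for bases unpaired in the scheduled structure and a low mean for
#' paired bases.
#'
#' @param structure_a,structure_b dot-bracket strings of equal length.
#' @param schedule character vector of `"a"` / `"b"` states per time point.
#' @param shape gamma shape parameter.
#' @param mean_unpaired,mean_paired expected reactivity of unpaired / paired
#'   bases (arbitrary units).
#' @param seed integer seed.
#' @return list with `reactivity` (bases x time points matrix), `schedule`,
#'   and the per-structure paired masks.
#' @export
simulate_reactivity <- function(structure_a, structure_b, schedule,
                                shape = 5, mean_unpaired = 1,
                                mean_paired = 0.15, seed = 4L) {
  if (nchar(structure_a) != nchar(structure_b))
    stop("structures must have equal length")
  stopifnot(all(schedule %in% c("a", "b")), mean_unpaired > mean_paired,
            mean_paired > 0)
  set.seed(seed)
  paired_mask <- function(db) {
    pr <- dotbracket_to_pairs(db)
    m <- rep(FALSE, nchar(db))
    if (nrow(pr) > 0) m[c(pr[, 1], pr[, 2])] <- TRUE
    m
  }
  ma <- paired_mask(structure_a)
  mb <- paired_mask(structure_b)
  n <- length(ma)
  react <- matrix(NA_real_, n, length(schedule))
  for (t in seq_along(schedule)) {
    m <- if (schedule[t] == "a") ma else mb
    mu <- ifelse(m, mean_paired, mean_unpaired)
    react[, t] <- rgamma(n, shape = shape, scale = mu / shape)
  }
  list(reactivity = react, schedule = schedule,
       paired_a = ma, paired_b = mb)
}

#' Classify reactivity time points back to their conformation
#'
#' Assigns each time point of a reactivity matrix to one of two structures
#' using the positions where their pairing differs: the per-column statistic
#' is the mean reactivity at positions paired only in structure `a` minus the
#' mean at positions paired only in `b`, and columns below the midpoint of
#' the statistic's range over the time course are called `"a"` (low
#' reactivity where `a` predicts pairing). Assumes the schedule visits both
#' states, as in a toggling experiment.
#'
#' @param reactivity bases x time points matrix.
#' @param paired_a,paired_b logical paired masks of the two structures.
#' @return character vector of `"a"` / `"b"` per time point.
#' @export
classify_reactivity_states <- function(reactivity, paired_a, paired_b) {
  if (all(paired_a == paired_b)) stop("structures are indistinguishable")
  only_a <- which(paired_a & !paired_b)
  only_b <- which(paired_b & !paired_a)
  stat <- apply(reactivity, 2, function(col) {
    sa <- if (length(only_a)) mean(col[only_a]) else 0
    sb <- if (length(only_b)) mean(col[only_b]) else 0
    sa - sb
  })
  mid <- (max(stat) + min(stat)) / 2
  ifelse(stat < mid, "a", "b")
}
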