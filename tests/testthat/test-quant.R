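# Langmuir fitting, aggregation, design summaries, boxplot statistics,
# replicate concordance and toggling analysis.

conc5 <- c(1, 3, 10, 30, 100)

test_that("noiseless titrations are recovered exactly", {
  s <- cluster_series("c1", "d1", "absent", conc5,
                      langmuir(conc5, kd = 10, fmax = 1, fmin = 0))
  f <- fit_binding_curve(s)
  expect_true(f$converged)
  expect_lt(abs(f$kd - 10) / 10, 1e-6)
  expect_lt(abs(f$fmax - 1), 1e-6)
  expect_lt(abs(f$fmin - 0), 1e-6)
})

test_that("uninformative titrations are flagged, not fitted", {
  s <- cluster_series("c1", "d1", "absent", conc5, rep(2, 5))
  f <- fit_binding_curve(s)
  expect_false(f$converged)
  expect_true(is.na(f$kd))
  expect_error(cluster_series("c1", "d1", "absent", c(1, 3, 10), c(1, 2, 3)),
               "length")
})

test_that("a Kd outside the probed range lands on the bound and is flagged", {
  y <- langmuir(conc5, kd = 1e5, fmax = 1)  # essentially linear, tiny signal
  s <- cluster_series("c1", "d1", "absent", conc5, y)
  f <- fit_binding_curve(s)
  expect_false(f$converged)
})

test_that("noisy fits agree with a dense grid-search oracle", {
  set.seed(21)
  conc <- c(0.5, 1.6, 5, 16, 50, 158, 500)
  for (rep in 1:5) {
    kd <- 10^runif(1, 0.3, 1.7)
    y <- langmuir(conc, kd, fmax = 1) * rnorm(7, 1, 0.05) + rnorm(7, 0, 0.02)
    f <- fit_binding_curve(cluster_series("c", "d", "absent", conc, y))
    o <- langmuir_grid_oracle(conc, y)
    expect_true(f$converged)
    # the optimizer should do at least as well as the grid, and land close
    expect_lte(f$rmse, sqrt(o$rss / length(conc)) * (1 + 1e-6))
    expect_lt(abs(log(f$kd / o$kd)), log(1.5))
  }
})

test_that("median aggregation is per-point and robust to an outlier cluster", {
  mk <- function(id, y) cluster_series(id, "d1", "absent", conc5, y)
  one <- mk("c1", langmuir(conc5, 10, 1))
  expect_equal(median_aggregate(list(one))$intensities, one$intensities)
  trio <- list(mk("c1", rep(1, 5)), mk("c2", rep(2, 5)), mk("c3", rep(9, 5)))
  expect_equal(median_aggregate(trio)$intensities, rep(2, 5))
  # one wild cluster: median tracks truth, mean does not
  truth <- langmuir(conc5, 10, 1)
  cl <- list(mk("c1", truth), mk("c2", truth * 1.02), mk("c3", truth * 0.98),
             mk("c4", truth + 10))
  med <- median_aggregate(cl)$intensities
  avg <- colMeans(do.call(rbind, lapply(cl, `[[`, "intensities")))
  expect_lt(max(abs(med - truth)), 0.05)
  expect_gt(max(abs(avg - truth)), 1)
  # mismatched grids refuse
  bad <- cluster_series("c9", "d1", "absent", conc5 * 2, truth)
  expect_error(median_aggregate(list(one, bad)), "grid")
})

test_that("design summaries orient AR by polarity and flag dead conditions", {
  mk <- function(id, cond, kd) cluster_series(id, "d1", cond, conc5,
                                              langmuir(conc5, kd, 1))
  same <- design_summary(list(mk("a1", "absent", 10), mk("a2", "absent", 10)),
                         list(mk("p1", "present", 10), mk("p2", "present", 10)))
  expect_equal(same$ar, 1, tolerance = 1e-6)
  # off switch: binding weakens with ligand, AR still > 1
  off <- design_summary(list(mk("a1", "absent", 5), mk("a2", "absent", 5)),
                        list(mk("p1", "present", 50), mk("p2", "present", 50)),
                        polarity = "off")
  expect_equal(off$ar, 10, tolerance = 1e-6)
  # a condition with no information flags the summary, AR absent
  dead <- design_summary(list(mk("a1", "absent", 10), mk("a2", "absent", 10)),
                         list(cluster_series("p1", "d1", "present", conc5,
                                             rep(1, 5)),
                              cluster_series("p2", "d1", "present", conc5,
                                             rep(1, 5))))
  expect_true(is.na(dead$ar))
  expect_gt(length(dead$flags), 0)
})

test_that("bootstrap interval covers truth in a small recovery simulation", {
  set.seed(22)
  conc <- c(0.5, 1.6, 5, 16, 50, 158, 500, 1580)
  kd_a <- 8; kd_p <- 400  # true AR = 50 for an on switch read as absent/present
  mk <- function(id, cond, kd) {
    y <- langmuir(conc, kd, 1) * rnorm(8, 1, 0.05) + rnorm(8, 0, 0.03)
    cluster_series(id, "d1", cond, conc, y)
  }
  ca <- lapply(1:30, function(i) mk(paste0("a", i), "absent", kd_a))
  cp <- lapply(1:30, function(i) mk(paste0("p", i), "present", kd_p))
  s <- design_summary(ca, cp, polarity = "off", seed = 5)
  truth <- kd_p / kd_a
  expect_lt(abs(log(s$ar / truth)), log(1.3))
  expect_true(s$ar_ci[1] <= truth && truth <= s$ar_ci[2])
  # determinism of the seeded bootstrap
  s2 <- design_summary(ca, cp, polarity = "off", seed = 5)
  expect_identical(s$ar_ci, s2$ar_ci)
})

test_that("boxplot statistics implement the stated definitions", {
  one <- round_summary(5, "r1")
  expect_equal(one$median, 5)
  expect_equal(one$whisker_lo, 5)
  expect_equal(one$whisker_hi, 5)
  nine <- round_summary(1:9, rep("r1", 9))
  expect_equal(nine$median, 5)
  expect_equal(nine$q1, 3)
  expect_equal(nine$q3, 7)
  # an injected far outlier is listed; the whisker stops inside the fence
  v <- c(1:9, 100)
  rs <- round_summary(v, rep("r1", 10))
  expect_equal(rs$n_outliers, 1)
  expect_equal(rs$outliers[[1]], 100)
  expect_lt(rs$whisker_hi, rs$q3 + 1.5 * rs$iqr + 1e-9)
  # agreement with a direct independent computation on random vectors
  set.seed(23)
  for (rep in 1:20) {
    v <- rlnorm(sample(5:40, 1), 1, 1)
    rs <- round_summary(v, rep("g", length(v)))
    qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    inside <- v[v >= qs[1] - 1.5 * iqr & v <= qs[3] + 1.5 * iqr]
    expect_equal(rs$median, qs[2])
    expect_equal(rs$q1, qs[1])
    expect_equal(rs$q3, qs[3])
    expect_equal(rs$whisker_lo, min(inside))
    expect_equal(rs$whisker_hi, max(inside))
    expect_equal(rs$n_outliers, length(v) - length(inside))
  }
})

test_that("replicate concordance is the squared correlation of log10 Kds", {
  df <- function(kds) data.frame(design_id = sprintf("d%02d", seq_along(kds)),
                                 kd_obs_absent = kds)
  kds <- 10^seq(0, 3, length.out = 12)
  expect_equal(replicate_r2(df(kds), df(kds)), 1)
  set.seed(24)
  r2 <- replicate_r2(df(10^runif(50, 0, 3)), df(10^runif(50, 0, 3)))
  expect_lt(r2, 0.2)
  expect_error(replicate_r2(df(kds[1:2]), df(kds[1:2])), "at least 3")
})

test_that("toggling analysis recovers direction, decay and classes", {
  # perfectly periodic, no decay
  ts <- simulate_toggle_series(10, 1000, "off", n_cycles = 52,
                               degradation_rate = 0, noise_sd = 0)
  a <- toggle_analysis(ts, polarity = "off")
  expect_equal(a$degradation_rate, 0, tolerance = 1e-9)
  expect_equal(a$class, "consistent")
  expect_equal(a$direction, -1)  # off switch: signal drops with ligand
  # 1 %/cycle decay recovered within 20 % over 52 cycles
  ts2 <- simulate_toggle_series(10, 1000, "off", n_cycles = 52,
                                degradation_rate = 0.01, noise_sd = 0)
  a2 <- toggle_analysis(ts2, polarity = "off")
  expect_lt(abs(a2$degradation_rate - 0.01) / 0.01, 0.2)
  # constant series is flat
  flat <- toggle_series("d", rep(c(0, 200), 10), rep(3, 20))
  expect_equal(toggle_analysis(flat)$class, "flat")
  # wrong direction is called inverted
  inv <- toggle_analysis(ts, polarity = "on")
  expect_equal(inv$class, "inverted")
  # non-alternating schedules refuse
  expect_error(toggle_series("d", c(0, 0, 200, 200), 1:4), "alternate")
})

test_that("toggle direction matches polarity whenever amplitude clears the
           noise floor", {
  set.seed(25)
  for (rep in 1:20) {
    pol <- sample(c("on", "off"), 1)
    kd0 <- 10^runif(1, 0.5, 1.5)
    kdL <- kd0 * 10^runif(1, 0.8, 1.5)
    if (pol == "on") { tmp <- kd0; kd0 <- kdL; kdL <- tmp }
    ts <- simulate_toggle_series(kd0, kdL, pol, n_cycles = 30,
                                 degradation_rate = 0.005, noise_sd = 0.01,
                                 seed = rep)
    a <- toggle_analysis(ts, polarity = pol)
    if (median(a$amplitude) >= 3 * a$noise_sd)
      expect_equal(a$direction, if (pol == "on") 1 else -1)
  }
})

test_that("titration tables round-trip through TSV", {
  lib <- generate_library(n_designs = 2, seed = 31)
  sim <- simulate_cluster_intensities(lib$truth, n_clusters = 3, seed = 32)
  tf <- tempfile(fileext = ".tsv")
  write_titration_tsv(sim$table, tf)
  back <- read_titration_tsv(tf)
  expect_equal(nrow(back), nrow(sim$table))
  expect_equal(back$intensity, sim$table$intensity, tolerance = 1e-9)
  series <- switchmap:::titration_to_series(back)
  expect_equal(length(series),
               length(unique(paste(sim$table$cluster_id, sim$table$condition))))
})
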