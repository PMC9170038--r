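# Independent oracles used across the suite. These deliberately share no code
# with the package implementation.

# Boltzmann averages by exhaustive enumeration: partition function and pair
# probabilities of a short sequence, from the enumerated structure list.
brute_pair_probs <- function(sequence, model = energy_model(),
                             bonus_pair = NULL, bonus = 0) {
  en <- enumerate_structures(sequence, model)
  w <- exp(-en$energy / model$RT)
  if (!is.null(bonus_pair)) {
    has <- vapply(en$structure, function(db) {
      pr <- dotbracket_to_pairs(db)
      nrow(pr) > 0 && any(pr[, 1] == bonus_pair[1] & pr[, 2] == bonus_pair[2])
    }, logical(1))
    w <- w * ifelse(has, 1 + bonus, 1)
  }
  Z <- sum(w)
  n <- nchar(sequence)
  p <- matrix(0, n, n)
  for (k in seq_len(nrow(en))) {
    pr <- dotbracket_to_pairs(en$structure[k])
    if (nrow(pr) > 0) p[pr] <- p[pr] + w[k]
  }
  list(Z = Z, p = p / Z)
}

# Independent count of non-crossing structures: recursion on the first
# position (paired-with-whom or unpaired), memoised on the interval.
count_structures_oracle <- function(sequence, model = energy_model()) {
  x <- strsplit(toupper(sequence), "")[[1]]
  n <- length(x)
  pairable <- function(a, b) {
    paste0(min(x[a], x[b]), max(x[a], x[b])) %in% c("CG", "AU", "GU")
  }
  memo <- new.env()
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)  # i unpaired
    for (k in seq(i + 1, j)) {
      if (k - i - 1 >= model$min_hairpin && pairable(i, k))
        total <- total + cnt(i + 1, k - 1) * cnt(k + 1, j)
    }
    memo[[key]] <- total
    total
  }
  cnt(1, n)
}

# recursive-definition Levenshtein distance (memoised on suffix indices;
# independent of utils::adist)
lev_recursive <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  memo <- matrix(NA_integer_, n + 1L, m + 1L)
  rec <- function(i, j) {  # distance between x[i..n] and y[j..m]
    if (i > n) return(m - j + 1L)
    if (j > m) return(n - i + 1L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    d <- min(rec(i + 1L, j + 1L) + (x[i] != y[j]),
             rec(i + 1L, j) + 1L,
             rec(i, j + 1L) + 1L)
    memo[i, j] <<- d
    d
  }
  rec(1L, 1L)
}

# dense grid search for the Langmuir fit: for each trial kd the model is
# linear in (fmin, fmax), solved by ordinary least squares
langmuir_grid_oracle <- function(conc, y, n_grid = 400) {
  kds <- exp(seq(log(0.1 * min(conc[conc > 0])), log(10 * max(conc)),
                 length.out = n_grid))
  best <- list(rss = Inf)
  for (kd in kds) {
    f <- conc / (kd + conc)
    fit <- lm(y ~ f)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss)
      best <- list(kd = kd, fmin = unname(coef(fit)[1]),
                   fmax = unname(coef(fit)[1] + coef(fit)[2]), rss = rss)
  }
  best
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# a small fixed design: split input aptamer (closing pair G1:C10, 0-based 1/10)
# around an A spacer; used where a deterministic switch_design is needed
tiny_design <- function(polarity = "on") {
  # 0:  G G C A A A A G C C U  A A A A ...
  seqc <- "GGCAAAAGCCAAAAA"
  input <- aptamer_motif(list(c(0, 3), c(7, 10)),
                         closing_pairs = list(c(1, 8)), kd_intrinsic = 2)
  output <- aptamer_motif(list(c(10, 14)),
                          closing_pairs = list(c(10, 13)))
  switch_design("T1", seqc, input, output, polarity = polarity)
}
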