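#' Aptamer motif annotation
#'
#' Describes where an aptamer lives in a design: the sequence segments that
#' compose it (a split aptamer has two or more) and the closing base pairs
#' that must form for the motif to count as folded. For input aptamers the
#' intrinsic ligand Kd gives the magnitude of the ligand bonus; output
#' hairpins carry no Kd.
#'
#' @param segments list of integer vectors `c(start, end)`, 0-based half-open,
#'   non-overlapping.
#' @param closing_pairs list of integer pairs `c(i, j)` (0-based, `i < j`)
#'   that must pair for the motif to be formed; include the outermost pair(s)
#'   of a split aptamer.
#' @param kd_intrinsic intrinsic ligand Kd in µM, or `NULL` for output motifs.
#' @return an object of class `aptamer_motif`.
#' @export
aptamer_motif <- function(segments, closing_pairs = list(), kd_intrinsic = NULL) {
  segments <- lapply(segments, as.integer)
  stopifnot(all(vapply(segments, length, 1L) == 2L),
            all(vapply(segments, function(s) s[2] > s[1] && s[1] >= 0, TRUE)))
  if (length(segments) > 1) {
    ivs <- do.call(rbind, segments)
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    if (any(ivs[-1, 1] < ivs[-nrow(ivs), 2]))
      stop("motif segments overlap")
  }
  closing_pairs <- lapply(closing_pairs, as.integer)
  stopifnot(all(vapply(closing_pairs, length, 1L) == 2L),
            all(vapply(closing_pairs, function(p) p[1] < p[2] && p[1] >= 0, TRUE)))
  if (!is.null(kd_intrinsic)) stopifnot(kd_intrinsic > 0)
  structure(list(segments = segments, closing_pairs = closing_pairs,
                 kd_intrinsic = kd_intrinsic),
            class = "aptamer_motif")
}

#' A switch design record
#'
#' @param id design identifier.
#' @param sequence RNA string.
#' @param input_motif,output_motif [aptamer_motif()] objects located within
#'   the sequence (input must carry `kd_intrinsic`).
#' @param polarity `"on"` (ligand raises reporter signal) or `"off"`.
#' @param round integer submission round.
#' @param author_class one of `"player"`, `"automated"`, `"modification"`.
#' @return an object of class `switch_design`.
#' @export
switch_design <- function(id, sequence, input_motif, output_motif,
                          polarity = c("on", "off"), round = 1L,
                          author_class = c("player", "automated", "modification")) {
  chars <- rna_chars(sequence)
  n <- length(chars)
  check_motif <- function(m, needs_kd) {
    stopifnot(inherits(m, "aptamer_motif"))
    if (any(vapply(m$segments, function(s) s[2] > n, TRUE)))
      stop("motif segment outside sequence bounds")
    if (any(vapply(m$closing_pairs, function(p) p[2] >= n, TRUE)))
      stop("closing pair outside sequence bounds")
    if (needs_kd && is.null(m$kd_intrinsic))
      stop("input motif needs kd_intrinsic")
    m
  }
  structure(list(id = as.character(id), sequence = paste(chars, collapse = ""),
                 input_motif = check_motif(input_motif, TRUE),
                 output_motif = check_motif(output_motif, FALSE),
                 polarity = match.arg(polarity), round = as.integer(round),
                 author_class = match.arg(author_class)),
            class = "switch_design")
}

# ---- McCaskill inside / outside --------------------------------------------

# Inside/outside over non-crossing structures with the per-pair model.
#   q:       n x n Boltzmann pair-weight matrix (0 = pair disallowed)
#   forced:  named integer vector partner[i] = j for positions constrained to
#            pair with a specific partner (both ends present); such positions
#            may neither stay unpaired nor pair elsewhere.
# Returns Z (scalar), the interval partition matrix, and the pair-probability
# matrix. All probabilities are exact for this grammar (validated against
# exhaustive enumeration in the tests).
mccaskill <- function(q, forced = integer(0)) {
  n <- nrow(q)
  partner <- rep(NA_integer_, n)
  if (length(forced) > 0) {
    fp <- forced
    partner[fp[, 1]] <- fp[, 2]
    partner[fp[, 2]] <- fp[, 1]
    # constrain the weight matrix: a forced end may only pair with its partner
    for (i in which(!is.na(partner))) {
      keep <- partner[i]
      row <- q[i, ]; col <- q[, i]
      q[i, ] <- 0; q[, i] <- 0
      if (keep > i) q[i, keep] <- row[keep]
      if (keep < i) q[keep, i] <- col[keep]
    }
  }
  can_unpair <- is.na(partner)

  # Zmat[i, j]: partition function of interval [i, j]; empty interval = 1
  Zmat <- matrix(1, n + 1L, n + 1L)  # index shift: Zget(i, j) = Zmat[i, j + 1]
  Zb <- matrix(0, n, n)
  Zget <- function(i, j) if (i > j) 1 else Zmat[i, j + 1L]
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (i == j) { Zmat[i, j + 1L] <- if (can_unpair[j]) 1 else 0; next }
      # j paired with k
      for (k in seq(i, j - 1L)) {
        if (q[k, j] > 0)
          Zb[k, j] <- q[k, j] * Zget(k + 1L, j - 1L)
      }
      z <- if (can_unpair[j]) Zget(i, j - 1L) else 0
      ks <- seq(i, j - 1L)
      zb <- Zb[ks, j]
      nz <- which(zb > 0)
      if (length(nz) > 0) {
        left <- vapply(ks[nz], function(k) Zget(i, k - 1L), numeric(1))
        z <- z + sum(left * zb[nz])
      }
      Zmat[i, j + 1L] <- z
    }
  }
  Ztot <- Zget(1L, n)
  p <- matrix(0, n, n)
  if (Ztot > 0 && n >= 2) {
    # U[i, k] = Z(k+1, i-1); V[l, j] = Z(j+1, l-1); precompute once
    U <- matrix(0, n, n)
    V <- matrix(0, n, n)
    for (i in seq_len(n)) for (k in seq_len(n))
      if (k < i) U[i, k] <- Zget(k + 1L, i - 1L)
    for (l in seq_len(n)) for (j in seq_len(n))
      if (l > j) V[l, j] <- Zget(j + 1L, l - 1L)
    extL <- vapply(seq_len(n), function(i) Zget(1L, i - 1L), numeric(1))
    extR <- vapply(seq_len(n), function(j) Zget(j + 1L, n), numeric(1))
    A <- matrix(0, n, n)  # A[k, l] = p[k, l] / Z(k+1, l-1), filled outside-in
    for (len in seq(n, 2L)) {
      nested <- NULL
      idx_i <- seq_len(n - len + 1L)
      for (i in idx_i) {
        j <- i + len - 1L
        if (Zb[i, j] <= 0) next
        w <- extL[i] * extR[j] / Ztot
        if (is.null(nested)) nested <- U %*% A %*% V  # spans > len already in A
        w <- w + nested[i, j]
        p[i, j] <- Zb[i, j] * w
      }
      for (i in idx_i) {  # make this span available to smaller spans
        j <- i + len - 1L
        if (p[i, j] > 0) {
          zin <- Zget(i + 1L, j - 1L)
          A[i, j] <- p[i, j] / zin
        }
      }
    }
  }
  list(Z = Ztot, Zmat = Zmat, Zb = Zb, p = p, n = n)
}

#' Partition function and base-pair probabilities, optionally ligand-aware
#'
#' Computes the equilibrium ensemble of non-crossing secondary structures
#' under the per-pair [energy_model()] by an inside/outside dynamic program
#' (the unfolded chain has weight 1). When a `ligand` is supplied, every
#' structure in which *all* closing pairs of the motif are formed has its
#' Boltzmann weight multiplied by the binding factor `1 + L / kd_intrinsic`:
#' the total partition function becomes `Z_free + (L/Kd) * Z_motif`, where
#' `Z_motif` is a constrained run forcing the closing pairs, and the pair
#' probabilities are the corresponding weighted mixture.
#'
#' @param sequence RNA string.
#' @param model an [energy_model()].
#' @param ligand `NULL`, or `list(motif = <aptamer_motif>, conc = <µM>)`.
#' @return an object of class `pair_prob`: list with `n`, `Z`, matrix `p`
#'   (`p[i, j]`, upper triangle, 1-based), `ligand_conc` and
#'   `p_motif_formed` (probability that all closing pairs form; `NA` when no
#'   motif was supplied).
#' @examples
#' pp <- partition_function("GGGGAAAACCCC")
#' round(pp$p[1, 12], 3)
#' @export
partition_function <- function(sequence, model = energy_model(), ligand = NULL) {
  chars <- rna_chars(sequence)
  n <- length(chars)
  q <- pair_weight_matrix(chars, model)
  free <- mccaskill(q)
  p_motif <- NA_real_
  if (is.null(ligand)) {
    Z <- free$Z
    p <- free$p
    L <- 0
  } else {
    stopifnot(inherits(ligand$motif, "aptamer_motif"), ligand$conc >= 0)
    if (is.null(ligand$motif$kd_intrinsic))
      stop("ligand-aware folding needs a motif with kd_intrinsic")
    cp <- ligand$motif$closing_pairs
    if (length(cp) == 0) stop("motif has no closing pairs")
    forced <- do.call(rbind, cp) + 1L  # to 1-based
    bad <- q[forced] == 0  # closing pair not pairable under the grammar
    L <- ligand$conc
    if (any(bad)) {
      # motif cannot form at all: the bonus never applies
      con <- list(Z = 0, p = matrix(0, n, n))
    } else {
      con <- mccaskill(q, forced = forced)
    }
    b <- L / ligand$motif$kd_intrinsic
    if (b == 0) {  # no bonus: the ligand-free ensemble, bit for bit
      Z <- free$Z
      p <- free$p
    } else {
      Z <- free$Z + b * con$Z
      p <- (free$p * free$Z + b * con$p * con$Z) / Z
    }
    p_motif <- (1 + b) * con$Z / Z
  }
  structure(list(n = n, sequence = paste(chars, collapse = ""), Z = Z, p = p,
                 ligand_conc = L, p_motif_formed = p_motif, model = model),
            class = "pair_prob")
}

#' @export
print.pair_prob <- function(x, ...) {
  cat(sprintf("Pair-probability matrix: %d nt, Z = %.6g, ligand %.4g uM\n",
              x$n, x$Z, x$ligand_conc))
  if (!is.na(x$p_motif_formed))
    cat(sprintf("  P(motif closing pairs all formed) = %.4f\n", x$p_motif_formed))
  invisible(x)
}
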