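#' Exhaustively enumerate secondary structures of a short RNA
#'
#' Lists every non-crossing set of allowed base pairs (GC/AU/GU, hairpin gap
#' `>= min_hairpin`), including the empty structure, with the energy of each.
#' This is the package's exact oracle: partition-function quantities on short
#' sequences are validated against Boltzmann averages over this list. It is
#' intentionally capped — the count grows exponentially.
#'
#' @param sequence RNA string over A/C/G/U.
#' @param model an [energy_model()].
#' @param max_length refuse sequences longer than this (oracle guard).
#' @return data.frame with columns `structure` (dot-bracket), `energy`
#'   (kcal/mol) and `n_pairs`.
#' @examples
#' enumerate_structures("GGGAAACCC")
#' @export
enumerate_structures <- function(sequence, model = energy_model(),
                                 max_length = 18L) {
  chars <- rna_chars(sequence)
  n <- length(chars)
  if (n > max_length)
    stop("sequence longer than the enumeration cap (", max_length,
         " nt); raise max_length only for testing")
  q <- pair_weight_matrix(chars, model)
  structs <- enumerate_pair_sets(q, 1L, n)
  db <- vapply(structs, function(pr) pairs_to_dotbracket(pr, n), character(1))
  en <- vapply(structs, function(pr) {
    if (is.null(pr) || nrow(pr) == 0) return(0)
    sum(vapply(seq_len(nrow(pr)), function(k)
      pair_energy(chars[pr[k, 1]], chars[pr[k, 2]], model), numeric(1)))
  }, numeric(1))
  np <- vapply(structs, function(pr) if (is.null(pr)) 0L else nrow(pr), integer(1))
  out <- data.frame(structure = db, energy = en, n_pairs = np,
                    stringsAsFactors = FALSE)
  out[order(out$energy, out$structure), , drop = FALSE]
}

# recursive enumeration of all non-crossing pair sets on [i, j];
# returns a list of 2-column matrices (possibly 0-row)
enumerate_pair_sets <- function(q, i, j) {
  if (i >= j) return(list(matrix(integer(0), 0, 2)))
  # case: j unpaired
  out <- enumerate_pair_sets(q, i, j - 1L)
  # case: j paired with k in [i, j-1]
  for (k in seq(i, j - 1L)) {
    if (q[k, j] <= 0) next
    left <- enumerate_pair_sets(q, i, k - 1L)
    inner <- enumerate_pair_sets(q, k + 1L, j - 1L)
    for (a in left) for (b in inner)
      out[[length(out) + 1L]] <- rbind(a, b, c(k, j))
  }
  out
}

#' Convert a pair list to dot-bracket notation
#'
#' @param pairs 2-column matrix of 1-based pair indices (i < j), non-crossing.
#' @param n sequence length.
#' @return dot-bracket string using `(`, `)` and `.` only.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  s <- rep(".", n)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    s[pairs[, 1]] <- "("
    s[pairs[, 2]] <- ")"
  }
  paste(s, collapse = "")
}

#' Parse dot-bracket notation into a pair list
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return 2-column integer matrix of pairs (i < j).
#' @export
dotbracket_to_pairs <- function(db) {
  x <- strsplit(db, "")[[1]]
  stopifnot(all(x %in% c("(", ")", ".")))
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_along(x)) {
    if (x[i] == "(") stack <- c(stack, i)
    else if (x[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  pairs
}

#' Minimum-energy representative structure
#'
#' Dynamic program for the lowest-energy structure under the per-pair model
#' (ties broken toward fewer pairs, then the lexicographically first
#' decomposition); used for dot-bracket exports of a representative fold.
#'
#' @inheritParams enumerate_structures
#' @return list with `structure` (dot-bracket) and `energy` (kcal/mol).
#' @export
mfe_structure <- function(sequence, model = energy_model()) {
  chars <- rna_chars(sequence)
  n <- length(chars)
  q <- pair_weight_matrix(chars, model)
  E <- matrix(NA_real_, n, n)
  emat <- -model$RT * log(ifelse(q > 0, q, NA))  # per-pair energies back from weights
  best <- function(i, j) if (i > j || i < 1) 0 else E[i, j]
  choice <- matrix(0L, n, n)  # 0 = j unpaired, k > 0 = pair (k, j)
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (i >= j) { E[i, j] <- 0; next }
      e0 <- best(i, j - 1L)
      ch <- 0L
      for (k in seq(i, j - 1L)) {
        if (q[k, j] <= 0) next
        ek <- best(i, k - 1L) + best(k + 1L, j - 1L) + emat[k, j]
        if (ek < e0 - 1e-12) { e0 <- ek; ch <- k }
      }
      E[i, j] <- e0
      choice[i, j] <- ch
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  trace <- function(i, j) {
    while (i < j) {
      k <- choice[i, j]
      if (k == 0L) { j <- j - 1L; next }
      pairs <<- rbind(pairs, c(k, j))
      if (k + 1L <= j - 1L) trace(k + 1L, j - 1L)
      j <- k - 1L
    }
  }
  if (n > 1) trace(1L, n)
  list(structure = pairs_to_dotbracket(pairs, n), energy = E[1, n])
}
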