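#' Simplified RNA pairing energy model
#'
#' A transparent per-pair energy model: each base pair contributes a fixed
#' stability (GC, AU, GU wobble), loops are free, and any pair must enclose at
#' least `min_hairpin` unpaired-or-paired bases (the sterically required
#' hairpin gap). The Boltzmann weight of a structure is the product of
#' `exp(-E_pair / RT)` over its pairs. The model is deliberately minimal so an
#' exhaustive enumeration oracle stays exact; it is pluggable, so
#' nearest-neighbour terms can replace the defaults.
#'
#' @param gc,au,gu pair energies in kcal/mol (negative = stabilising).
#' @param min_hairpin minimum number of bases strictly enclosed by a pair
#'   (`>= 3`).
#' @param temperature temperature in kelvin.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(gc = -3, au = -2, gu = -1,
                         min_hairpin = 3L, temperature = 310) {
  stopifnot(is.finite(gc), is.finite(au), is.finite(gu),
            min_hairpin >= 3, temperature > 0)
  R <- 0.0019872  # kcal / (mol K)
  structure(list(gc = gc, au = au, gu = gu,
                 min_hairpin = as.integer(min_hairpin),
                 temperature = temperature,
                 RT = R * temperature),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    "Pair energy model: GC %.2f / AU %.2f / GU %.2f kcal/mol, min hairpin %d, T = %.0f K\n",
    x$gc, x$au, x$gu, x$min_hairpin, x$temperature))
  invisible(x)
}

RNA_BASES <- c("A", "C", "G", "U")

# split an RNA string into an uppercase character vector, validating alphabet
rna_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  x <- strsplit(toupper(gsub("T", "U", sequence)), "")[[1]]
  bad <- setdiff(unique(x), RNA_BASES)
  if (length(bad) > 0)
    stop("invalid RNA characters: ", paste(bad, collapse = ", "))
  x
}

# energy of the (unordered) base pair b1:b2, NA if not pairable
pair_energy <- function(b1, b2, model) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  unname(c(CG = model$gc, AU = model$au, GU = model$gu)[key])
}

# n x n matrix of Boltzmann weights exp(-E/RT); 0 where bases cannot pair or
# the hairpin constraint is violated
pair_weight_matrix <- function(chars, model) {
  n <- length(chars)
  q <- matrix(0, n, n)
  if (n < 2) return(q)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (j - i - 1 < model$min_hairpin) next
      e <- pair_energy(chars[i], chars[j], model)
      if (!is.na(e)) q[i, j] <- exp(-e / model$RT)
    }
  }
  q
}
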