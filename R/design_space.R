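# Sequence-space analysis of design collections: edit distances, "mod"
# linkage, design families, distance trees and round trajectories.

#' Levenshtein edit distance between RNA sequences
#'
#' Minimal number of single-base insertions, deletions and substitutions
#' (unit costs, no affine gaps). Vectorised over pairs of inputs; the full
#' dynamic program is delegated to [utils::adist()].
#'
#' @param a,b character vectors of RNA sequences over A/C/G/U.
#' @return integer distance(s).
#' @examples
#' seq_edit_distance("GAUUACA", "GACUACA")  # 1
#' @export
seq_edit_distance <- function(a, b) {
  check <- function(x) {
    bad <- grepl("[^ACGUacgu]", x)
    if (any(bad)) stop("sequences must be over A/C/G/U")
  }
  check(a); check(b)
  as.integer(adist(toupper(a), toupper(b)))
}

# full pairwise Levenshtein matrix for a vector of sequences
edit_distance_matrix <- function(sequences, ids = names(sequences)) {
  m <- adist(toupper(sequences))
  storage.mode(m) <- "integer"
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  m
}

#' "Mod" edges of a design collection
#'
#' A *mod* is a design derived by small modification of another; two designs
#' are linked when their Levenshtein distance is strictly below `threshold`
#' (default 5, i.e. distance `<= 4` links, distance 5 does not).
#'
#' @param sequences named character vector of design sequences (names =
#'   design ids).
#' @param threshold strict upper bound on the linking distance.
#' @return an object of class `design_graph`: list with `ids`, `edges`
#'   (data.frame `from`, `to`, `distance`, `from < to` by id order) and
#'   `threshold`.
#' @export
mod_edges <- function(sequences, threshold = 5L) {
  stopifnot(length(sequences) >= 2, threshold >= 1)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("D%04d", seq_along(sequences))
  dm <- edit_distance_matrix(sequences, ids)
  idx <- which(upper.tri(dm) & dm < threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      distance = dm[idx], stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$from, ids), match(edges$to, ids)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(ids = ids, edges = edges, threshold = as.integer(threshold)),
            class = "design_graph")
}

#' @export
print.design_graph <- function(x, ...) {
  cat(sprintf("Design graph: %d designs, %d mod edges (distance < %d)\n",
              length(x$ids), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Design families: connected components of the mod graph
#'
#' Iterative modification of successful designs produces families of closely
#' related sequences; a family is a connected component of the mod graph
#' (membership is transitive even when distant members differ by more than
#' the linking threshold). Families are labelled by their smallest member id.
#'
#' @param graph a [mod_edges()] result.
#' @return data.frame with `design_id` and `family` (label of the smallest
#'   member), one row per design, in input order.
#' @export
design_families <- function(graph) {
  stopifnot(inherits(graph, "design_graph"))
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = graph$ids))
  comp <- igraph::components(g)
  member <- comp$membership[graph$ids]
  fam <- vapply(seq_len(comp$no), function(k) {
    min(graph$ids[member == k])
  }, character(1))
  data.frame(design_id = graph$ids, family = fam[member],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Distance tree of a design collection
#'
#' Neighbor-joining tree on the pairwise Levenshtein distance matrix — a
#' presentational clustering of sequence space, not phylogenetic inference.
#' Duplicate sequences collapse to zero-length branches.
#'
#' @param sequences named character vector of at least 3 design sequences.
#' @param file optional path; when given the tree is written in newick format.
#' @return an [ape::nj()] `phylo` tree (invisibly when written to `file`).
#' @export
distance_tree <- function(sequences, file = NULL) {
  stopifnot(length(sequences) >= 3)
  dm <- edit_distance_matrix(sequences,
                             ids = names(sequences) %||%
                               sprintf("D%04d", seq_along(sequences)))
  tree <- ape::nj(as.dist(dm))
  if (!is.null(file)) {
    ape::write.tree(tree, file)
    return(invisible(tree))
  }
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-round improvement trajectory
#'
#' Best, median and IQR of the activation ratio by submission round — the
#' community-learning view of a design campaign. No monotone improvement is
#' asserted; the table reports what the data show.
#'
#' @param ar numeric activation ratios.
#' @param round round labels (integer or factor).
#' @return data.frame with `round`, `n`, `ar_max`, `ar_median`, `ar_q1`,
#'   `ar_q3`, ordered by round.
#' @export
improvement_trajectory <- function(ar, round) {
  stopifnot(length(ar) == length(round))
  keep <- is.finite(ar)
  ar <- ar[keep]; round <- round[keep]
  sp <- split(ar, round, drop = TRUE)
  out <- do.call(rbind, lapply(names(sp), function(r) {
    v <- sp[[r]]
    qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(round = r, n = length(v), ar_max = max(v),
               ar_median = qs[2], ar_q1 = qs[1], ar_q3 = qs[3],
               stringsAsFactors = FALSE)
  }))
  out[order(suppressWarnings(as.numeric(out$round)), out$round), ,
      drop = FALSE]
}
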