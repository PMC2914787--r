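#' Detect species as reproductively isolated clusters
#'
#' Clusters -- the model's analogue of species -- are determined by who
#' mates with whom. Starting from any organism, the iterative search over
#' everything it, its mate, and its second-nearest neighbour have mated
#' with, repeated for every organism so found, closes on a unique set. That
#' closure is realized here as the connected components of the undirected
#' graph whose edges join every organism to its mate (nearest other
#' organism) and to its second-nearest other organism; mate edges are
#' symmetric in the mated-with relation, so the component reproduces the
#' iterative closure exactly while guaranteeing that each organism belongs
#' to one, and only one, cluster.
#'
#' @param organisms Organism data.frame (columns `id, x, y`).
#' @param mates Optional mate assignment from [assign_mates()]; recomputed
#'   when missing.
#' @param neighbors Optional precomputed n x 2 matrix of nearest and
#'   second-nearest row indices (as returned by the internal neighbour
#'   search); when supplied, `mates` is ignored.
#' @param generation Generation stamp stored on the partition.
#' @param extent Morphospace side length (spatial hash sizing).
#' @return An object of class `cluster_partition`: list with `generation`,
#'   `assignment` (integer cluster labels named by organism id) and
#'   `n_clusters`.
#' @export
find_clusters <- function(organisms, mates = NULL, neighbors = NULL,
                          generation = NA_integer_, extent = 45) {
  n <- nrow(organisms)
  if (n < 1L) stop("no organisms to cluster")
  ord <- order(organisms$id)
  o <- organisms[ord, , drop = FALSE]

  if (n == 1L) {
    memb <- 1L
  } else {
    if (is.null(neighbors)) {
      neighbors <- nearest_two(o, extent)
      if (!is.null(mates)) {
        # honour a caller-supplied mate map (first column only)
        neighbors[, 1] <- match(unname(mates[as.character(o$id)]), o$id)
      }
    }
    from <- rep.int(seq_len(n), 2L)
    to <- c(neighbors[, 1], neighbors[, 2])
    keep <- to > 0L
    g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    memb <- igraph::components(g)$membership
  }
  memb <- as.integer(match(memb, unique(memb)))  # labels 1..k, stable order
  names(memb) <- o$id
  structure(list(generation = as.integer(generation),
                 assignment = memb,
                 n_clusters = length(unique(memb))),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition: %d organisms in %d clusters%s>\n",
              length(x$assignment), x$n_clusters,
              if (is.na(x$generation)) "" else
                sprintf(" (generation %d)", x$generation)))
  invisible(x)
}

#' Within-cluster diversity
#'
#' For each cluster with at least two members, the mean Euclidean distance
#' over all unordered member pairs; these per-cluster means are then
#' averaged, unweighted, over clusters. Singleton clusters are excluded (a
#' one-member mean distance is undefined); `NA` is returned when no cluster
#' has two members.
#'
#' For clusters larger than `exact_limit` members the all-pairs sum becomes
#' the dominant cost of a run, so the per-cluster mean is estimated from an
#' evenly strided subsample of `exact_limit` members (deterministic, no
#' random draws; relative error well below one percent at the default
#' limit).
#'
#' @param partition A [find_clusters()] result.
#' @param organisms The matching organism data.frame.
#' @param exact_limit Cluster size above which the strided-subsample
#'   estimator replaces the exact all-pairs mean. Default 2000.
#' @return Mean within-cluster pairwise distance, in trait units, or `NA`.
#' @export
within_cluster_diversity <- function(partition, organisms,
                                     exact_limit = 2000L) {
  memb <- partition$assignment[as.character(organisms$id)]
  if (anyNA(memb)) stop("partition does not match organisms")
  groups <- split(seq_along(memb), memb)
  means <- vapply(groups, function(ix) {
    if (length(ix) < 2L) return(NA_real_)
    if (length(ix) > exact_limit) {
      ix <- ix[unique(round(seq(1L, length(ix), length.out = exact_limit)))]
    }
    mean_pairdist_cpp(organisms$x[ix], organisms$y[ix])
  }, numeric(1))
  if (all(is.na(means))) NA_real_ else mean(means, na.rm = TRUE)
}
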