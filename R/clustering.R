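#' Euclidean distances between feature vectors
#' @param F feature matrix, conditions in rows
#' @return symmetric distance matrix with zero diagonal
#' @export
pairwise_distances <- function(F) {
  stopifnot(is.matrix(F) || is.data.frame(F))
  D <- as.matrix(stats::dist(F, method = "euclidean"))
  dimnames(D) <- list(rownames(F), rownames(F))
  D
}

#' Partition of stimulus conditions
#'
#' @param clusters list of integer/character vectors, one per cluster; every
#'   element in exactly one cluster, clusters non-empty
#' @param elements vector of all element labels (defaults to the sorted
#'   union of the clusters)
#' @param nonresponder_cluster index into `clusters` designating the
#'   non-responder cluster, or NULL
#' @return object of class `partition`
#' @export
partition <- function(clusters, elements = NULL,
                      nonresponder_cluster = NULL) {
  if (!length(clusters) || any(!lengths(clusters)))
    stop("clusters must be non-empty", call. = FALSE)
  all_el <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_el))
    stop("an element appears in more than one cluster", call. = FALSE)
  if (is.null(elements)) elements <- sort(all_el)
  if (!setequal(all_el, elements))
    stop("clusters must cover exactly the element set", call. = FALSE)
  if (!is.null(nonresponder_cluster)) {
    nonresponder_cluster <- as.integer(nonresponder_cluster)
    if (nonresponder_cluster < 1L ||
        nonresponder_cluster > length(clusters))
      stop("`nonresponder_cluster` out of range", call. = FALSE)
  }
  structure(list(clusters = lapply(clusters, function(cl) unname(cl)),
                 elements = elements,
                 nonresponder_cluster = nonresponder_cluster),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d elements in %d cluster(s)%s\n",
              length(x$elements), length(x$clusters),
              if (is.null(x$nonresponder_cluster)) "" else
                sprintf(" (non-responders: cluster %d, n = %d)",
                        x$nonresponder_cluster,
                        length(x$clusters[[x$nonresponder_cluster]]))))
  invisible(x)
}

#' Cluster membership as a named integer vector
#' @param p `partition`
#' @return integer cluster id per element, named by element
#' @export
partition_membership <- function(p) {
  stopifnot(inherits(p, "partition"))
  m <- integer(length(p$elements))
  names(m) <- as.character(p$elements)
  for (k in seq_along(p$clusters))
    m[as.character(p$clusters[[k]])] <- k
  m
}

#' Responder clusters of a partition
#' @param p `partition`
#' @return list of clusters excluding the designated non-responder cluster
#' @export
responder_clusters <- function(p) {
  stopifnot(inherits(p, "partition"))
  if (is.null(p$nonresponder_cluster)) return(p$clusters)
  p$clusters[-p$nonresponder_cluster]
}

#' Epsilon-network clustering
#'
#' Non-responder elements are removed first and form the designated
#' non-responder cluster. The remaining elements are vertices of a graph
#' with an edge wherever the pairwise distance is `<= eps` (ties connect);
#' clusters are the connected components, so two responses farther apart
#' than eps still cluster together when linked through intermediates.
#'
#' @param D symmetric distance matrix
#' @param eps linking radius, > 0
#' @param nonresponders indices (or rownames) of non-responder elements
#' @return [partition()] over the row labels of `D` (indices when unnamed),
#'   with the non-responder cluster designated when non-empty
#' @export
epsilon_cluster <- function(D, eps, nonresponders = integer(0)) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (!is.finite(eps) || eps <= 0)
    stop("`eps` must be > 0", call. = FALSE)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- seq_len(n)
  if (is.character(nonresponders))
    nonresponders <- match(nonresponders, labels)
  nonresponders <- sort(unique(as.integer(nonresponders)))
  resp <- setdiff(seq_len(n), nonresponders)
  clusters <- list()
  if (length(resp)) {
    adj <- D[resp, resp, drop = FALSE] <= eps
    comp <- .components(adj)
    for (k in sort(unique(comp)))
      clusters[[length(clusters) + 1L]] <- labels[resp[comp == k]]
  }
  nr_id <- NULL
  if (length(nonresponders)) {
    clusters[[length(clusters) + 1L]] <- labels[nonresponders]
    nr_id <- length(clusters)
  }
  partition(clusters, elements = labels, nonresponder_cluster = nr_id)
}

# connected components of a boolean adjacency matrix (BFS)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v]) next
    k <- k + 1L
    queue <- v
    comp[v] <- k
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}
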