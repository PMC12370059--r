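#' Specificity, confusion and inhibition scores of one regime
#'
#' From the partition of the 15 stimulus conditions under one regime:
#' * SRS (stimulus-response specificity) = number of responder clusters,
#' * SRC (stimulus-response confusion) = size of the largest responder
#'   cluster (0 when every condition is inhibited),
#' * INH (inhibition) = size of the non-responder cluster.
#'
#' @param p [partition()] of the regime's stimulus conditions
#' @param regime_id label carried into the result
#' @return object of class `regime_scorecard`: `regime_id`, `SRS`, `SRC`,
#'   `INH`, `partition`, `confusion` (see [confusion_matrix()]),
#'   `nonresponders` (element labels)
#' @export
compute_scores <- function(p, regime_id = NA_character_) {
  stopifnot(inherits(p, "partition"))
  resp <- responder_clusters(p)
  nr <- if (is.null(p$nonresponder_cluster)) character(0) else
    as.character(p$clusters[[p$nonresponder_cluster]])
  structure(
    list(regime_id = regime_id,
         SRS = length(resp),
         SRC = if (length(resp)) max(lengths(resp)) else 0L,
         INH = length(nr),
         partition = p,
         confusion = confusion_matrix(p),
         nonresponders = nr),
    class = "regime_scorecard"
  )
}

#' @export
print.regime_scorecard <- function(x, ...) {
  cat(sprintf("<regime_scorecard> %s: SRS = %d, SRC = %d, INH = %d\n",
              x$regime_id, x$SRS, x$SRC, x$INH))
  invisible(x)
}

#' Binary stimulus confusion matrix of a partition
#'
#' Symmetric matrix over the element set: off-diagonal entry 1 when the two
#' stimuli share a responder cluster, 0 otherwise; the diagonal carries the
#' non-responder flags.
#'
#' @param p [partition()]
#' @return square 0/1 matrix with element labels as dimnames
#' @export
confusion_matrix <- function(p) {
  stopifnot(inherits(p, "partition"))
  el <- as.character(p$elements)
  n <- length(el)
  M <- matrix(0L, n, n, dimnames = list(el, el))
  for (k in seq_along(p$clusters)) {
    if (!is.null(p$nonresponder_cluster) && k == p$nonresponder_cluster) {
      idx <- match(as.character(p$clusters[[k]]), el)
      M[cbind(idx, idx)] <- 1L
    } else {
      idx <- match(as.character(p$clusters[[k]]), el)
      if (length(idx) > 1L) {
        for (a in idx) M[a, idx] <- 1L
        diag(M)[idx] <- 0L
      }
    }
  }
  M
}

#' Tally pairwise confusion across a regime collection
#'
#' Counts, per stimulus pair, the regimes in which the pair is confused
#' (off-diagonal 1 in the regime's confusion matrix). Regimes in which both
#' members of a pair are non-responders are excluded from that pair's
#' eligible set.
#'
#' @param scorecards list of `regime_scorecard`
#' @return object of class `confusion_tally`: `counts` (pair confusion
#'   counts), `eligible` (regimes eligible per pair), `n_regimes`
#' @export
tally_pairwise <- function(scorecards) {
  if (!length(scorecards)) {
    el <- stimulus_order()
    z <- matrix(0L, length(el), length(el), dimnames = list(el, el))
    return(structure(list(counts = z, eligible = z, n_regimes = 0L),
                     class = "confusion_tally"))
  }
  el <- rownames(scorecards[[1L]]$confusion)
  n <- length(el)
  counts <- matrix(0L, n, n, dimnames = list(el, el))
  eligible <- matrix(0L, n, n, dimnames = list(el, el))
  for (sc in scorecards) {
    stopifnot(inherits(sc, "regime_scorecard"),
              identical(rownames(sc$confusion), el))
    M <- sc$confusion
    nr <- el %in% sc$nonresponders
    both_nr <- outer(nr, nr, `&`)
    elig <- !both_nr
    diag(elig) <- FALSE
    eligible <- eligible + elig
    off <- M
    diag(off) <- 0L
    counts <- counts + off * elig
  }
  structure(list(counts = counts, eligible = eligible,
                 n_regimes = length(scorecards)),
            class = "confusion_tally")
}

#' @export
print.confusion_tally <- function(x, ...) {
  cat(sprintf("<confusion_tally> %d regime(s), %d confused pair-events\n",
              x$n_regimes, sum(x$counts[upper.tri(x$counts)])))
  invisible(x)
}

#' Treated-versus-untreated confusion
#'
#' For each regime, compares the treated 15 feature vectors with the
#' untreated 15: a treated responder and an untreated responder are confused
#' when their Euclidean distance is strictly below `eps` (strict, unlike the
#' within-regime linking rule which ties at eps). Treated non-responders are
#' not scored against responders; they are flagged against the untreated
#' non-responder condition(s) separately.
#'
#' @param untreated feature matrix of the untreated regime (15 rows,
#'   canonical order)
#' @param treated list of feature matrices, one per regime, same space and
#'   normalization bounds as `untreated`
#' @param eps optimized linking radius of the feature space
#' @param treated_nonresponders list of non-responder label vectors per
#'   regime (default: none)
#' @param untreated_nonresponders labels of untreated non-responder
#'   conditions (default: none)
#' @return object of class `confusion_tally` with `counts` (treated rows x
#'   untreated columns, aggregated over regimes) and `inhibited` (per
#'   treated stimulus, number of regimes in which it was a non-responder)
#' @export
treated_vs_untreated <- function(untreated, treated, eps,
                                 treated_nonresponders = NULL,
                                 untreated_nonresponders = character(0)) {
  stopifnot(is.matrix(untreated), length(treated) >= 1L)
  el <- rownames(untreated)
  n <- nrow(untreated)
  if (is.null(treated_nonresponders))
    treated_nonresponders <- rep(list(character(0)), length(treated))
  counts <- matrix(0L, n, n, dimnames = list(treated = el, untreated = el))
  inhibited <- setNames(integer(n), el)
  for (g in seq_along(treated)) {
    Ft <- treated[[g]]
    if (!identical(rownames(Ft), el) || ncol(Ft) != ncol(untreated))
      stop("treated feature matrix ", g,
           " does not match the untreated space", call. = FALSE)
    nr <- el %in% treated_nonresponders[[g]]
    d2 <- outer(rowSums(Ft ^ 2), rowSums(untreated ^ 2), `+`) -
      2 * Ft %*% t(untreated)
    D <- sqrt(pmax(d2, 0))
    conf <- (D < eps)
    conf[nr, ] <- FALSE
    conf[, el %in% untreated_nonresponders] <- FALSE
    counts <- counts + conf
    inhibited[nr] <- inhibited[nr] + 1L
  }
  structure(list(counts = counts, inhibited = inhibited,
                 n_regimes = length(treated)),
            class = "confusion_tally")
}

#' Scores table across regimes
#' @param scorecards list of `regime_scorecard`
#' @return data.frame with columns `regime_id`, `SRS`, `SRC`, `INH`
#' @export
scores_table <- function(scorecards) {
  data.frame(
    regime_id = vapply(scorecards, `[[`, "", "regime_id"),
    SRS = vapply(scorecards, `[[`, 0L, "SRS"),
    SRC = vapply(scorecards, `[[`, 0L, "SRC"),
    INH = vapply(scorecards, `[[`, 0L, "INH"),
    stringsAsFactors = FALSE
  )
}
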