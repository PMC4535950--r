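#' Clustering parameters for consensus-cluster identification
#'
#' @param cluster_width maximum number of consecutive scale points a cluster
#'   may span (default 3, i.e. clusters of up to three points on a 1-10
#'   scale).
#' @param secondary_threshold fraction `p` in (0,1): an interval only counts
#'   as a secondary cluster if it holds at least `p * r_mode` ratings, where
#'   `r_mode` is the count inside the most populous interval.  Values below
#'   0.5 let small outlying clusters capture too many neighbours; 0.5 is the
#'   recommended lower bound and the default.
#' @return a list of class `"clustering_params"`.
#' @export
clustering_params <- function(cluster_width = 3L, secondary_threshold = 0.5) {
  cluster_width <- as.integer(cluster_width)
  if (is.na(cluster_width) || cluster_width < 1L)
    stop("`cluster_width` must be a positive integer", call. = FALSE)
  if (!is.numeric(secondary_threshold) || length(secondary_threshold) != 1L ||
      secondary_threshold <= 0 || secondary_threshold >= 1)
    stop("`secondary_threshold` must lie strictly between 0 and 1", call. = FALSE)
  structure(list(cluster_width = cluster_width,
                 secondary_threshold = secondary_threshold),
            class = "clustering_params")
}

#' @export
print.clustering_params <- function(x, ...) {
  cat(sprintf("<clustering_params> width v = %d, secondary threshold p = %g\n",
              x$cluster_width, x$secondary_threshold))
  invisible(x)
}

#' Identify consensus clusters in one item's ratings
#'
#' Finds the opinion clusters for a single survey item.  Every interval of
#' `1..cluster_width` consecutive scale points is a candidate; candidates
#' are ranked by member count (ties broken toward wider intervals, then
#' lower scale position) and selected greedily subject to disjointness.  The
#' first selection is the modal interval, whose count defines `r_mode`;
#' further intervals are kept only while they hold at least
#' `secondary_threshold * r_mode` ratings.  Each cluster records its member
#' count and the arithmetic mean of its member ratings — the value experts
#' converge toward in the next round.
#'
#' @param ratings integer vector of scores, all in `[1, scale_max]`.
#' @param params a [clustering_params()].
#' @param scale_max rating-scale upper end.
#' @return an object of class `"cluster_set"`: a list with elements
#'   `clusters` (list of `low`, `high`, `member_count`, `mean_rating`,
#'   ordered by `low`), `r_mode`, and `scale_max`.
#' @examples
#' cs <- identify_clusters(c(1, 1, 2, 5, 9, 9, 10, 10, 10))
#' as.data.frame(cs)   # [8,10] holds 5 raters (mean 9.6), [1,3] holds 3
#' @export
identify_clusters <- function(ratings, params = clustering_params(),
                              scale_max = 10L) {
  scale_max <- as.integer(scale_max)
  ratings <- as.integer(ratings)
  if (length(ratings) < 1L) stop("need at least one rating", call. = FALSE)
  if (anyNA(ratings) || any(ratings < 1L | ratings > scale_max))
    stop(sprintf("ratings must be integers in [1, %d]", scale_max), call. = FALSE)
  v <- min(params$cluster_width, scale_max)
  p <- params$secondary_threshold

  cnt <- tabulate(ratings, nbins = scale_max)
  csum <- cumsum(c(0L, cnt))                       # csum[b+1]-csum[a] = count in [a,b]
  vsum <- cumsum(c(0, seq_len(scale_max) * cnt))   # sum of member ratings

  lows <- integer(0); highs <- integer(0)
  for (w in seq_len(v)) {
    a <- seq_len(scale_max - w + 1L)
    lows <- c(lows, a); highs <- c(highs, a + w - 1L)
  }
  counts <- csum[highs + 1L] - csum[lows]
  ord <- order(-counts, -(highs - lows), lows)

  sel_low <- integer(0); sel_high <- integer(0)
  covered <- logical(scale_max)
  r_mode <- counts[ord[1L]]
  thr <- p * r_mode - 1e-9
  for (idx in ord) {
    if (counts[idx] < thr || counts[idx] == 0L) break
    span <- lows[idx]:highs[idx]
    if (any(covered[span])) next
    covered[span] <- TRUE
    sel_low <- c(sel_low, lows[idx]); sel_high <- c(sel_high, highs[idx])
  }

  keep <- order(sel_low)
  clusters <- lapply(keep, function(i) {
    a <- sel_low[i]; b <- sel_high[i]
    mc <- csum[b + 1L] - csum[a]
    list(low = a, high = b, member_count = mc,
         mean_rating = (vsum[b + 1L] - vsum[a]) / mc)
  })
  structure(list(clusters = clusters, r_mode = r_mode, scale_max = scale_max),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), r_mode = %d\n",
              length(x$clusters), x$r_mode))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.cluster_set <- function(x, ...) {
  data.frame(
    low = vapply(x$clusters, `[[`, integer(1), "low"),
    high = vapply(x$clusters, `[[`, integer(1), "high"),
    member_count = vapply(x$clusters, `[[`, integer(1), "member_count"),
    mean_rating = vapply(x$clusters, `[[`, numeric(1), "mean_rating")
  )
}

# Internal: vectorised nearest-cluster assignment for one item.
# Returns the cluster index for each rating.  Distance is measured to the
# cluster's score interval (0 for a rating inside it); an exact midway tie
# goes to the larger cluster, and a remaining tie to the cluster at the
# lower end of the scale.
assign_cluster_index <- function(ratings, cluster_set) {
  cl <- cluster_set$clusters
  k <- length(cl)
  if (k == 0L) return(rep(NA_integer_, length(ratings)))
  lws <- vapply(cl, `[[`, integer(1), "low")
  highs <- vapply(cl, `[[`, integer(1), "high")
  cnts <- vapply(cl, `[[`, integer(1), "member_count")
  vapply(as.numeric(ratings), function(x) {
    d <- pmax(lws - x, x - highs, 0)
    order(d, -cnts, lws)[1L]
  }, integer(1))
}

#' Assign an expert's rating to its target cluster
#'
#' Picks the cluster an expert converges toward between rounds: the one
#' nearest to the expert's current score, with distance measured to the
#' cluster's score interval (zero when the score lies inside it).  A score
#' exactly midway between two clusters goes to the larger (more populous)
#' one; if the counts also tie, to the cluster lower on the scale.
#' Interval distances between integer scores are integers, so exact midway
#' ties are a routine occurrence, not a degenerate edge case.
#'
#' @param rating a single integer score.
#' @param cluster_set a [identify_clusters()] result.
#' @return the selected cluster (a list with `low`, `high`, `member_count`,
#'   `mean_rating`), with attribute `index` giving its position in the set.
#' @export
assign_target_cluster <- function(rating, cluster_set) {
  if (length(cluster_set$clusters) == 0L)
    stop("empty cluster set: no target to converge toward", call. = FALSE)
  i <- assign_cluster_index(rating, cluster_set)
  structure(cluster_set$clusters[[i]], index = i)
}

#' Update a rating under the Group Conformity Index
#'
#' One between-round opinion shift: the new score is
#' `round(gci * target_mean + (1 - gci) * prev_rating)`, rounded half away
#' from zero and clamped to the scale.  `gci = 0` is a fully stubborn expert
#' (no change); `gci = 1` a fully conforming one (jumps to the rounded
#' cluster mean).
#'
#' @param prev_rating integer score(s) from the previous round (vectorised).
#' @param target_mean mean rating of the target cluster (recycled).
#' @param gci Group Conformity Index in `[0, 1]`.
#' @param scale_max rating-scale upper end.
#' @return integer score(s) in `[1, scale_max]`.
#' @examples
#' update_rating(2, 9.4, gci = 0.5)   # round(5.7) = 6
#' @export
update_rating <- function(prev_rating, target_mean, gci, scale_max = 10L) {
  if (!is.numeric(gci) || length(gci) != 1L || is.na(gci) || gci < 0 || gci > 1)
    stop("`gci` must be a single number in [0, 1]", call. = FALSE)
  # half-away-from-zero rounding; all quantities are positive here
  x <- floor(gci * target_mean + (1 - gci) * as.numeric(prev_rating) + 0.5)
  as.integer(pmin(pmax(x, 1), scale_max))
}
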