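# ---------------------------------------------------------------------------
# Compositional clustering of spots and probabilistic cell-type
# co-occurrence within the selected clusters.
# ---------------------------------------------------------------------------

#' Cluster spots by cell-type composition with elbow selection of k
#'
#' k-means on the row-proportion abundance matrix over a range of k; the
#' total within-cluster sum of squares (WSS) is recorded per k and the
#' number of clusters selected by an algorithmic elbow rule: the k whose
#' point on the (k, WSS) curve — rescaled to the unit square — lies
#' farthest from the chord joining the first and last k. Each k is fitted
#' from `n_restarts` random starts plus a warm start that augments the
#' previous k's centers with the point farthest from its center, which
#' guarantees WSS is non-increasing in k.
#'
#' @param abundance an `abundance_matrix` (see [deconvolve()]).
#' @param k_range candidate numbers of clusters (default 1:15).
#' @param seed integer seed for the k-means restarts.
#' @param n_restarts random restarts per k.
#' @return A list of class `composition_clustering`: `k` (ks actually
#'   fitted), `wss`, `selected_k`, `labels` (for the selected k),
#'   `labels_by_k`, `centers_by_k`, `condition_counts` (cluster x condition
#'   spot counts for the selected k).
#' @export
cluster_compositions <- function(abundance, k_range = 1:15, seed = 1L,
                                 n_restarts = 10L) {
  P <- abundance_proportions(abundance)
  n <- nrow(P)
  ks <- sort(unique(as.integer(k_range)))
  drop_ks <- ks[ks > n]
  if (length(drop_ks)) {
    warning("skipping k > number of spots: ",
            paste(drop_ks, collapse = ", "), call. = FALSE)
    ks <- ks[ks <= n]
  }
  set.seed(seed)
  wss <- numeric(length(ks))
  labels_by_k <- vector("list", length(ks))
  centers_by_k <- vector("list", length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k == 1) {
      ctr <- matrix(colMeans(P), nrow = 1, dimnames = list(NULL, colnames(P)))
      lab <- rep(1L, n)
      w <- sum(sweep(P, 2, ctr[1, ])^2)
      fit <- list(cluster = lab, centers = ctr, tot.withinss = w)
    } else {
      fits <- list()
      fits[[1]] <- tryCatch(
        stats::kmeans(P, centers = k, nstart = n_restarts, iter.max = 100),
        error = function(e) NULL)
      if (!is.null(prev)) {
        # warm start: previous centers plus the worst-fit point
        d2 <- rowSums((P - prev$centers[prev$cluster, , drop = FALSE])^2)
        init <- rbind(prev$centers, P[which.max(d2), ])
        init <- init[!duplicated(init), , drop = FALSE]
        if (nrow(init) == k)
          fits[[2]] <- tryCatch(
            stats::kmeans(P, centers = init, iter.max = 100),
            error = function(e) NULL)
      }
      fits <- Filter(Negate(is.null), fits)
      if (!length(fits)) {
        uP <- unique(P)
        if (k == nrow(uP)) {
          # every distinct composition its own cluster: WSS is exactly zero
          lab <- match(apply(P, 1, paste, collapse = "\r"),
                       apply(uP, 1, paste, collapse = "\r"))
          fit <- list(cluster = lab, centers = uP, tot.withinss = 0)
          wss[i] <- 0
          labels_by_k[[i]] <- lab
          centers_by_k[[i]] <- uP
          prev <- fit
          next
        }
        warning("k-means failed for k = ", k, "; skipped", call. = FALSE)
        next
      }
      fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "tot.withinss"))]]
    }
    wss[i] <- fit$tot.withinss
    labels_by_k[[i]] <- fit$cluster
    centers_by_k[[i]] <- fit$centers
    prev <- fit
  }
  fitted <- !vapply(labels_by_k, is.null, logical(1))
  ks <- ks[fitted]; wss <- wss[fitted]
  labels_by_k <- labels_by_k[fitted]; centers_by_k <- centers_by_k[fitted]
  selected_k <- ks[elbow_index(ks, wss)]
  labels <- labels_by_k[[match(selected_k, ks)]]
  cc <- table(cluster = labels, condition = abundance$condition)
  structure(list(k = ks, wss = wss, selected_k = selected_k,
                 labels = labels, labels_by_k = labels_by_k,
                 centers_by_k = centers_by_k,
                 condition_counts = cc, sample_id = abundance$sample_id,
                 condition = abundance$condition, seed = seed),
            class = "composition_clustering")
}

# elbow rule: farthest point (in the unit square) from the chord between the
# first and last (k, wss) points
elbow_index <- function(ks, wss) {
  if (length(ks) == 1) return(1L)
  x <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
  span <- max(wss) - min(wss)
  y <- if (span > 0) (wss - min(wss)) / span else rep(0, length(wss))
  # distance from (x, y) to the line through (x1,y1) and (xn,yn)
  dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
  d <- abs(dy * x - dx * y + dx * y[1] - dy * x[1]) / sqrt(dx^2 + dy^2)
  which.max(d)
}

#' Re-select the number of compositional clusters manually
#'
#' Preserves the visual-selection workflow: the elbow choice can be
#' overridden by any fitted k.
#'
#' @param clustering a `composition_clustering`.
#' @param k the desired number of clusters (must be among the fitted ks).
#' @return The clustering with `selected_k`, `labels` and
#'   `condition_counts` updated.
#' @export
set_selected_k <- function(clustering, k) {
  i <- match(k, clustering$k)
  if (is.na(i)) stop("k = ", k, " was not fitted", call. = FALSE)
  clustering$selected_k <- k
  clustering$labels <- clustering$labels_by_k[[i]]
  clustering$condition_counts <- table(cluster = clustering$labels,
                                       condition = clustering$condition)
  clustering
}

#' Select compositional clusters of interest
#'
#' Default rule: rank clusters by the fraction of their spots coming from
#' diseased conditions times the mean summed proportion of the configured
#' cell types of interest, and return the top `m`; ties break toward the
#' lower cluster id. A manual override returns the given ids verbatim.
#'
#' @param clustering a `composition_clustering`.
#' @param abundance the `abundance_matrix` that was clustered.
#' @param diseased_conditions condition labels counted as diseased.
#' @param types_of_interest cell types whose abundance drives the ranking.
#' @param m number of clusters to select (default 2).
#' @param manual optional integer vector of cluster ids, returned verbatim.
#' @return Integer vector of selected cluster ids.
#' @export
select_clusters <- function(clustering, abundance,
                            diseased_conditions = NULL,
                            types_of_interest = NULL, m = 2,
                            manual = NULL) {
  if (!is.null(manual)) return(as.integer(manual))
  if (is.null(types_of_interest) || !length(types_of_interest))
    stop("automatic cluster selection needs a non-empty types_of_interest",
         call. = FALSE)
  P <- abundance_proportions(abundance)
  types_of_interest <- intersect(types_of_interest, colnames(P))
  ids <- sort(unique(clustering$labels))
  score <- vapply(ids, function(cl) {
    in_cl <- clustering$labels == cl
    frac_dis <- mean(abundance$condition[in_cl] %in% diseased_conditions)
    interest <- mean(rowSums(P[in_cl, types_of_interest, drop = FALSE]))
    frac_dis * interest
  }, numeric(1))
  ids[order(-score, ids)][seq_len(min(m, length(ids)))]
}

#' Classify cell-type pair co-occurrence within a compositional cluster
#'
#' Presence of a type in a spot means its proportion exceeds
#' `presence_threshold`. For each unordered pair, with `N` spots in the
#' cluster, marginal presence counts `N1`, `N2` and observed co-presence
#' `j`, the exact hypergeometric tails
#' `P[X >= j]` and `P[X <= j]` (with `P[X = j] =
#' C(N1, j) C(N - N1, N2 - j) / C(N, N2)`) classify the pair as `positive`
#' (`p_gt < alpha`), `negative` (`p_lt < alpha`) or `random`. Self-pairs
#' are always classified positive: autocrine signaling is permitted and
#' must not be blocked by the spatial filter.
#'
#' @param abundance an `abundance_matrix`.
#' @param clustering a `composition_clustering` on that abundance.
#' @param cluster_id which cluster to analyse.
#' @param presence_threshold proportion above which a type counts as
#'   present in a spot (default 0.05).
#' @param alpha significance level for the tail tests (default 0.05).
#' @return A data.frame of class `cooccurrence_result` with columns
#'   `cluster_id, type_a, type_b, N, N1, N2, j, p_gt, p_lt, classification`.
#' @export
cooccurrence <- function(abundance, clustering, cluster_id,
                         presence_threshold = 0.05, alpha = 0.05) {
  in_cl <- clustering$labels == cluster_id
  if (!any(in_cl)) stop("cluster ", cluster_id, " is empty", call. = FALSE)
  P <- abundance_proportions(abundance)[in_cl, , drop = FALSE]
  pres <- P > presence_threshold
  types <- colnames(P)
  N <- nrow(pres)
  rows <- list()
  for (i in seq_along(types)) for (k in i:length(types)) {
    N1 <- sum(pres[, i]); N2 <- sum(pres[, k])
    j <- sum(pres[, i] & pres[, k])
    if (N1 == 0 || N2 == 0) {
      p_gt <- 1; p_lt <- 1
      cls <- if (i == k) "positive" else "random"
    } else {
      p_gt <- stats::phyper(j - 1, N1, N - N1, N2, lower.tail = FALSE)
      p_lt <- stats::phyper(j, N1, N - N1, N2)
      cls <- if (i == k) "positive"
      else if (p_gt < alpha) "positive"
      else if (p_lt < alpha) "negative"
      else "random"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cluster_id, type_a = types[i], type_b = types[k],
      N = N, N1 = N1, N2 = N2, j = j, p_gt = p_gt, p_lt = p_lt,
      classification = cls, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cooccurrence_result", "data.frame")
  out
}
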