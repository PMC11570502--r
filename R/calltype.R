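# Call-type clustering: z-scored (duration, max frequency) features,
# deterministic BUILD+SWAP k-medoids, silhouette widths, and the mapping of
# the two-cluster solution onto the A/B call-type labels.

#' Standardize acoustic features for clustering
#'
#' Z-scores the `duration` and `max_frequency` columns of a call table so the
#' two incommensurate scales (seconds, kHz) contribute comparably to the
#' Euclidean dissimilarity used by [pam_cluster()].
#'
#' @param calls data.frame with numeric columns `duration` and
#'   `max_frequency` (at least two rows, all finite).
#' @return list with `x` (n x 2 matrix, columns `duration`,`max_frequency`),
#'   and the `center` and `scale` used, for reuse on new data.
#' @export
standardize_features <- function(calls) {
  need <- c("duration", "max_frequency")
  if (!all(need %in% names(calls)))
    stop("calls must have columns duration and max_frequency", call. = FALSE)
  x <- as.matrix(calls[, need])
  if (nrow(x) < 2) stop("need at least two calls", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl <= 0
  if (any(zero))
    stop("zero-variance feature column: ", paste(need[zero], collapse = ", "),
         call. = FALSE)
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Partitioning Around Medoids (classic BUILD + SWAP)
#'
#' Deterministic k-medoids on Euclidean dissimilarities. BUILD greedily seeds
#' the medoids to minimize total cost; SWAP repeatedly applies the best
#' cost-decreasing (medoid, non-medoid) exchange, first-best in scan order on
#' ties, until no exchange improves the cost or `max_iter` swaps have been
#' made. The total cost (sum of distances of every point to its nearest
#' medoid) is non-increasing across SWAP iterations.
#'
#' @param x numeric feature matrix (rows = calls), typically the standardized
#'   features from [standardize_features()].
#' @param k number of clusters, `2 <= k <= nrow(x) - 1`.
#' @param max_iter maximum number of SWAP exchanges.
#' @return list of class `"callgram_pam"`: `k`, `medoids` (row indices),
#'   `labels` (cluster id per row, 1..k), `total_cost`, `iterations`,
#'   `per_point_silhouette`, `mean_silhouette`.
#' @export
pam_cluster <- function(x, k, max_iter = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (k < 2 || k > n - 1) stop("k must be in [2, n-1]", call. = FALSE)
  D <- as.matrix(stats::dist(x))

  # BUILD: first medoid minimizes total distance; each next maximizes the
  # decrease in cost
  med <- which.min(colSums(D))
  dnear <- D[, med]
  while (length(med) < k) {
    gain <- colSums(pmax(dnear - D, 0))
    gain[med] <- -Inf
    new <- which.max(gain)
    med <- c(med, new)
    dnear <- pmin(dnear, D[, new])
  }

  nearest_two <- function(med) {
    Dm <- D[, med, drop = FALSE]
    ord1 <- max.col(-Dm, ties.method = "first")
    d1 <- Dm[cbind(seq_len(n), ord1)]
    Dm[cbind(seq_len(n), ord1)] <- Inf
    d2 <- Dm[cbind(seq_len(n), max.col(-Dm, ties.method = "first"))]
    list(which = med[ord1], d1 = d1, d2 = d2)
  }

  it <- 0L
  cost <- sum(nearest_two(med)$d1)
  repeat {
    nt <- nearest_two(med)
    best_delta <- -1e-12; best_m <- NA; best_c <- NA
    for (mi in seq_along(med)) {
      m <- med[mi]
      base <- ifelse(nt$which == m, nt$d2, nt$d1)
      pm <- pmin(base, D)                  # base recycles down columns
      dim(pm) <- dim(D)
      newcost <- colSums(pm)
      newcost[med] <- Inf
      ci <- which.min(newcost)
      delta <- newcost[ci] - cost
      if (delta < best_delta) { best_delta <- delta; best_m <- mi; best_c <- ci }
    }
    if (is.na(best_m) || it >= max_iter) break
    med[best_m] <- best_c
    cost <- cost + best_delta
    it <- it + 1L
  }

  labels <- max.col(-D[, med, drop = FALSE], ties.method = "first")
  sil <- silhouette_score(x, labels, D = D)
  structure(list(k = k, medoids = med, labels = labels,
                 total_cost = sum(D[cbind(seq_len(n), med[labels])]),
                 iterations = it,
                 per_point_silhouette = sil$widths,
                 mean_silhouette = sil$mean),
            class = "callgram_pam")
}

#' @export
print.callgram_pam <- function(x, ...) {
  cat("PAM clustering: k =", x$k, " total cost =", format(x$total_cost),
      " mean silhouette =", format(x$mean_silhouette), "\n")
  cat("cluster sizes:", tabulate(x$labels, x$k), "\n")
  invisible(x)
}

#' Silhouette widths of a clustering
#'
#' For each point, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is
#' the mean dissimilarity to the other members of its own cluster and `b(i)`
#' the smallest mean dissimilarity to another cluster. Points in singleton
#' clusters get `s(i) = 0` by convention.
#'
#' @param x feature matrix (ignored when `D` is supplied).
#' @param labels integer cluster assignment, at least two nonempty clusters.
#' @param D optional precomputed distance matrix.
#' @return list with `widths` (per point, in \[-1, 1\]) and `mean`.
#' @export
silhouette_score <- function(x, labels, D = NULL) {
  if (is.null(D)) D <- as.matrix(stats::dist(as.matrix(x)))
  n <- nrow(D)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette undefined for a single cluster", call. = FALSE)
  sizes <- tabulate(labels, k)
  G <- matrix(0, n, k)
  G[cbind(seq_len(n), labels)] <- 1
  S <- D %*% G                               # total distance to each cluster
  own <- S[cbind(seq_len(n), labels)]
  a <- own / pmax(sizes[labels] - 1, 1)      # exclude self
  Sm <- sweep(S, 2, sizes, "/")
  Sm[cbind(seq_len(n), labels)] <- Inf
  b <- apply(Sm, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1] <- 0
  list(widths = as.numeric(s), mean = mean(s))
}

#' Choose the number of clusters by mean silhouette
#'
#' Runs [pam_cluster()] for each candidate `k` and returns the `k` with the
#' highest mean silhouette width; ties break toward the smaller `k`. The
#' silhouette is undefined for a single cluster, so candidate values start
#' at 2.
#'
#' @param x feature matrix.
#' @param k_range integer vector of candidate cluster counts (within
#'   `[2, n - 1]`).
#' @return list with `best_k`, `curve` (data.frame `k`, `mean_silhouette`)
#'   and `fits` (the per-k `"callgram_pam"` objects).
#' @export
select_k <- function(x, k_range = 2:10) {
  if (length(k_range) == 0) stop("empty k_range", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("k_range must be >= 2", call. = FALSE)
  fits <- lapply(k_range, function(k) pam_cluster(x, k))
  ms <- vapply(fits, `[[`, 0, "mean_silhouette")
  best <- k_range[which.max(ms)]             # which.max takes the first tie
  list(best_k = best,
       curve = data.frame(k = k_range, mean_silhouette = ms),
       fits = stats::setNames(fits, paste0("k", k_range)))
}

#' Map a two-cluster solution onto the A/B call types
#'
#' Labels the cluster with the lower mean maximum frequency "A" (the short,
#' low-frequency call) and the other "B" (the long, high-frequency call).
#'
#' @param result a `"callgram_pam"` fit with `k = 2`.
#' @param calls the call table the fit was computed from (uses
#'   `max_frequency`).
#' @return `calls` with an added `assigned_type` column of `"A"`/`"B"`.
#' @export
label_clusters <- function(result, calls) {
  if (!inherits(result, "callgram_pam") || result$k != 2)
    stop("label_clusters requires a k = 2 PAM result", call. = FALSE)
  mf <- tapply(calls$max_frequency, result$labels, mean)
  if (abs(diff(mf)) < 1e-12)
    stop("equal cluster mean frequencies: A/B mapping ambiguous", call. = FALSE)
  map <- c("A", "B")[order(order(mf))]       # low frequency -> A
  calls$assigned_type <- map[result$labels]
  calls
}
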