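#' Pairwise epigenetic distances between samples
#'
#' Concatenates each sample's M and H call vectors and computes pairwise
#' dissimilarities. The default `squared_euclidean` metric is the count of
#' differing calls (the Hamming count, which on binary data equals the
#' squared Euclidean distance) — the standard input convention for binary
#' data feeding AMOVA and PCoA. Bands missing in either member of a pair are
#' dropped (pairwise deletion) and the count is rescaled to the full band
#' count by `n_bands / n_shared`.
#'
#' @param x a `band_matrix`.
#' @param metric one of `"squared_euclidean"`, `"euclidean"`, `"jaccard"`,
#'   `"simple_matching"`.
#' @return A symmetric matrix of class `band_dist` with zero diagonal,
#'   sample ids as dimnames and the metric in `attr(, "metric")`. For
#'   `squared_euclidean` the entries are already squared distances; every
#'   consumer in this package honours that convention.
#' @export
band_distance <- function(x, metric = c("squared_euclidean", "euclidean",
                                        "jaccard", "simple_matching")) {
  metric <- match.arg(metric)
  B <- cbind(x$calls_M, x$calls_H)
  n <- nrow(B)
  if (n < 2) stop("need at least 2 samples")
  nb <- ncol(B)
  if (!anyNA(B) && metric %in% c("squared_euclidean", "euclidean")) {
    k <- rowSums(B)
    d <- outer(k, k, "+") - 2 * tcrossprod(B)  # Hamming count on binary
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sh <- !is.na(B[i, ]) & !is.na(B[j, ])
      ns <- sum(sh)
      if (ns == 0)
        stop("samples '", rownames(B)[i], "' and '", rownames(B)[j],
             "' share no non-missing bands")
      a <- B[i, sh]; b <- B[j, sh]
      d[i, j] <- d[j, i] <- switch(
        metric,
        squared_euclidean = , euclidean = sum(a != b) * nb / ns,
        simple_matching = sum(a != b) / ns,
        jaccard = {
          un <- sum(a == 1 | b == 1)
          if (un == 0) 0 else 1 - sum(a == 1 & b == 1) / un
        })
    }
  }
  if (metric == "euclidean") d <- sqrt(d)
  diag(d) <- 0
  dimnames(d) <- list(rownames(B), rownames(B))
  structure(d, metric = metric, class = c("band_dist", "matrix"))
}

# Entries of d as *squared* distances, honouring the metric convention.
squared_dissim <- function(d) {
  if (identical(attr(d, "metric"), "squared_euclidean")) unclass(d)
  else unclass(d)^2
}

#' @export
print.band_dist <- function(x, ...) {
  cat(sprintf("band_dist [%s]: %d samples\n", attr(x, "metric"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  invisible(x)
}

#' Principal coordinate analysis
#'
#' Metric multidimensional scaling: the squared-dissimilarity matrix is
#' Gower double-centered (B = -1/2 J D2 J) and eigendecomposed; coordinates
#' are eigenvectors scaled by the square roots of the positive eigenvalues.
#' For the `squared_euclidean` metric the matrix entries are used as D2
#' directly; other metrics are squared first. Negative eigenvalues are
#' dropped and their magnitudes reported.
#'
#' @param d a `band_dist` (or plain symmetric matrix of distances).
#' @param n_axes number of axes to retain; truncated to the number of
#'   positive eigenvalues with a message if it exceeds the rank.
#' @return A `pcoa_result`: list with `coordinates` (samples x axes),
#'   `eigenvalues`, `pct_explained` (percent of the positive-eigenvalue
#'   total), `negative_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2) {
  D2 <- squared_dissim(d)
  if (!isSymmetric(unname(D2))) stop("distance matrix is not symmetric")
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  neg <- e$values[e$values < -tol]
  if (n_axes > length(pos)) {
    message("only ", length(pos), " positive axes available; returning those")
    n_axes <- length(pos)
  }
  ax <- pos[seq_len(n_axes)]
  coords <- e$vectors[, ax, drop = FALSE] %*%
    diag(sqrt(e$values[ax]), n_axes, n_axes)
  dimnames(coords) <- list(rownames(D2), paste0("Axis", seq_len(n_axes)))
  structure(
    list(coordinates = coords,
         eigenvalues = e$values[ax],
         pct_explained = 100 * e$values[ax] / sum(e$values[pos]),
         negative_eigenvalues = neg),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes\n")
  cat("pct explained:",
      paste(sprintf("%.1f", x$pct_explained), collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat("dropped", length(x$negative_eigenvalues),
        "negative eigenvalues (|sum| =",
        format(sum(abs(x$negative_eigenvalues))), ")\n")
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with one-tailed
#' (greater) permutation significance: rows and columns of the second matrix
#' are permuted jointly and p = (1 + #\{permuted r >= observed r\}) /
#' (n_permutations + 1). The permutation machinery is vegan's.
#'
#' @param d1,d2 `band_dist` matrices over identical sample sets.
#' @param n_permutations number of permutations (>= 99).
#' @param seed RNG seed; with the same seed the p-value is reproducible.
#' @return A `mantel_result`: list with `r`, `r_squared`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = NULL) {
  stopifnot(n_permutations >= 99)
  if (!setequal(rownames(d1), rownames(d2)))
    stop("sample sets differ between the two matrices")
  m2 <- unclass(d2)[rownames(d1), rownames(d1)]
  v1 <- unclass(d1)[lower.tri(d1)]
  v2 <- m2[lower.tri(m2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance distance matrix: r undefined")
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(unclass(d1)), stats::as.dist(m2),
                      permutations = n_permutations)
  structure(
    list(r = unname(mt$statistic), r_squared = unname(mt$statistic)^2,
         p_value = mt$signif, n_permutations = n_permutations, seed = seed),
    class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f (r^2 = %.4f), p = %.4g (%d permutations)\n",
              x$r, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}
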