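#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair (i, j) minimising
#' Q(i, j) = (n - 2) d(i, j) - R_i - R_j (R = row sums) is joined, with ties
#' broken by the lowest (row, column) index pair; branch lengths use the
#' standard split b_i = d(i, j)/2 + (R_i - R_j) / (2(n - 2)). Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch (their sum d(i, j) is preserved) and flagged. Two taxa yield a
#' single edge split at its midpoint.
#'
#' The tree is built on the matrix entries as distances; pass a
#' `"euclidean"`-metric matrix (or any additive distance), not squared
#' distances.
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @return An [ape][ape::read.tree] `phylo` object (unrooted for >= 3
#'   leaves); attribute `negative_clamped` gives the number of clamped
#'   branches.
#' @export
neighbor_joining <- function(d) {
  D <- unclass(d)
  if (!isSymmetric(unname(D))) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 2) stop("need at least 2 samples")
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  clamped <- 0L
  fmt <- function(x) sprintf("%.12g", x)
  clamp_pair <- function(li, lj) {
    # preserve li + lj, move any deficit onto the sister branch
    if (li < 0) { lj <- lj + li; li <- 0; clamped <<- clamped + 1L }
    if (lj < 0) { li <- li + lj; lj <- 0; clamped <<- clamped + 1L }
    if (li < 0) { li <- 0; clamped <<- clamped + 1L }  # both negative
    if (lj < 0) { lj <- 0; clamped <<- clamped + 1L }
    c(li, lj)
  }
  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", labs[1], fmt(D[1, 2] / 2),
                   labs[2], fmt(D[1, 2] / 2))
  } else {
    while (n > 3) {
      R <- rowSums(D)
      Q <- (n - 2) * D - outer(R, R, "+")
      diag(Q) <- Inf
      # ties: lowest row, then lowest column, over i < j
      Q[lower.tri(Q)] <- Inf
      ij <- which(Q == min(Q), arr.ind = TRUE)
      ij <- ij[order(ij[, 1], ij[, 2])[1], ]
      i <- ij[1]; j <- ij[2]
      li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
      lj <- D[i, j] - li
      l <- clamp_pair(li, lj)
      new_lab <- sprintf("(%s:%s,%s:%s)", labs[i], fmt(l[1]),
                         labs[j], fmt(l[2]))
      du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
      keep <- setdiff(seq_len(n), c(i, j))
      D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
      labs <- c(labs[keep], new_lab)
      n <- n - 1
    }
    # unrooted star join of the last three nodes (three-point formulas)
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    for (v in c(la, lb, lc)) if (v < 0) clamped <- clamped + 1L
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   labs[1], fmt(max(la, 0)), labs[2], fmt(max(lb, 0)),
                   labs[3], fmt(max(lc, 0)))
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_clamped") <- clamped
  if (clamped > 0)
    message(clamped, " negative branch length(s) clamped to 0")
  tree
}

#' Evanno delta-K from clustering log-probabilities
#'
#' Post-processes a table of replicate log Pr(X | K) values from an external
#' Bayesian clustering run: per interior K, delta K = mean over replicates of
#' |L_r(K+1) - 2 L_r(K) + L_r(K-1)| divided by the across-replicate standard
#' deviation of L(K). The optimum K is the interior K maximising delta K.
#'
#' @param lnp `data.frame` with columns `K`, `replicate`, `lnP`; at least 3
#'   consecutive K values with at least 2 replicates each, forming a
#'   complete K x replicate grid.
#' @return A `delta_k` data.frame with columns `K`, `n_replicates`,
#'   `mean_lnP`, `sd_lnP`, `delta_K` (`NA` at boundary K and flagged
#'   undefined where sd = 0); attribute `optimum_K`.
#' @export
delta_k <- function(lnp) {
  stopifnot(all(c("K", "replicate", "lnP") %in% names(lnp)))
  Ks <- sort(unique(lnp$K))
  if (length(Ks) < 3) stop("need at least 3 K values")
  if (!all(diff(Ks) == 1)) stop("K values must be consecutive")
  reps <- sort(unique(lnp$replicate))
  if (length(reps) < 2) stop("need at least 2 replicates per K")
  L <- matrix(NA_real_, length(Ks), length(reps),
              dimnames = list(Ks, reps))
  L[cbind(match(lnp$K, Ks), match(lnp$replicate, reps))] <- lnp$lnP
  if (anyNA(L)) stop("K x replicate grid is incomplete")
  mean_lnP <- rowMeans(L)
  sd_lnP <- apply(L, 1, stats::sd)
  dk <- rep(NA_real_, length(Ks))
  for (i in seq(2, length(Ks) - 1)) {
    second <- L[i + 1, ] - 2 * L[i, ] + L[i - 1, ]
    dk[i] <- if (sd_lnP[i] == 0) NA_real_ else mean(abs(second)) / sd_lnP[i]
  }
  undefined <- vapply(seq_along(Ks), function(i)
    i > 1 && i < length(Ks) && sd_lnP[i] == 0, TRUE)
  if (any(undefined))
    warning("delta K undefined (sd = 0) at K = ",
            paste(Ks[undefined], collapse = ", "))
  out <- data.frame(K = Ks, n_replicates = length(reps),
                    mean_lnP = mean_lnP, sd_lnP = sd_lnP, delta_K = dk)
  rownames(out) <- NULL
  opt <- if (all(is.na(dk))) NA_integer_ else Ks[which.max(dk)]
  structure(out, optimum_K = opt, class = c("delta_k", "data.frame"))
}

#' @export
print.delta_k <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("optimum K:", attr(x, "optimum_K"), "\n")
  invisible(x)
}
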