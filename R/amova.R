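#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions the total squared pairwise distance among samples into
#' among-group and within-group components, in the dominant-marker (PhiPT)
#' convention: SS_total = sum over all pairs of d2 / N, SS_within = sum over
#' within-group pairs of d2 / n_g per group, SS_among by difference;
#' est. var. within = MS_within and est. var. among =
#' (MS_among - MS_within) / n0 with n0 = (N - sum n_g^2 / N) / (k - 1).
#' Significance comes from permuting whole samples among groups (group sizes
#' fixed) and counting permuted among-group variance components >= observed.
#'
#' For the `squared_euclidean` metric the matrix entries are used as squared
#' distances d2 directly; other metrics are squared first (the convention is
#' recorded in the result).
#'
#' @param d a `band_dist` matrix.
#' @param groups named character vector of group labels (names = sample ids),
#'   or a `band_matrix` plus `level` to derive them.
#' @param n_permutations permutations for the p-value (999 default).
#' @param seed RNG seed; fixed seed gives a bit-reproducible p-value.
#' @return An `amova_result`: list with `table` (rows Among groups / Within
#'   groups / Total: df, SS, MS, est_var, pct), `phi_pt`, `p_value`,
#'   `n_permutations`, `seed`, `est_var_among_raw` (before truncation at 0),
#'   `d2_convention`.
#' @export
amova <- function(d, groups, n_permutations = 999, seed = NULL) {
  d2 <- squared_dissim(d)
  ids <- rownames(d2)
  if (inherits(groups, "band_matrix")) groups <- group_labels(groups)
  g <- as.character(groups[ids])
  if (anyNA(g)) stop("groups missing for sample(s): ",
                     paste(ids[is.na(g)], collapse = ", "))
  if (length(unique(g)) < 2) stop("need at least 2 groups")

  comp <- amova_components(d2, g)
  if (comp$est_var_among_raw < 0)
    message("negative among-group variance component (",
            format(comp$est_var_among_raw), ") truncated to 0")

  p_value <- NA_real_
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs <- comp$est_var_among_raw
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (amova_components(d2, sample(g))$est_var_among_raw >= obs)
        hits <- hits + 1L
    }
    p_value <- (1 + hits) / (n_permutations + 1)
  }

  tab <- comp$table
  stopifnot(abs(tab["Total", "SS"] -
                  (tab["Among groups", "SS"] + tab["Within groups", "SS"]))
            < 1e-9 * max(1, tab["Total", "SS"]))
  structure(
    list(table = tab, phi_pt = comp$phi_pt, p_value = p_value,
         n_permutations = n_permutations, seed = seed,
         est_var_among_raw = comp$est_var_among_raw,
         d2_convention = if (identical(attr(d, "metric"),
                                       "squared_euclidean"))
           "matrix entries used as squared distances"
         else "matrix entries squared before use"),
    class = "amova_result")
}

# Core sums-of-squares decomposition on a squared-distance matrix.
amova_components <- function(d2, g) {
  N <- nrow(d2)
  grp <- unique(g)
  k <- length(grp)
  ss_total <- sum(d2) / 2 / N
  ng <- numeric(k)
  ss_within <- 0
  for (i in seq_len(k)) {
    idx <- which(g == grp[i])
    ng[i] <- length(idx)
    ss_within <- ss_within + sum(d2[idx, idx]) / 2 / ng[i]
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1
  df_within <- N - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(ng^2) / N) / (k - 1)
  va_raw <- (ms_among - ms_within) / n0
  va <- max(va_raw, 0)
  vw <- ms_within
  tot <- va + vw
  tab <- rbind(
    "Among groups" = c(df_among, ss_among, ms_among, va, 100 * va / tot),
    "Within groups" = c(df_within, ss_within, ms_within, vw, 100 * vw / tot),
    "Total" = c(N - 1, ss_total, NA, tot, 100))
  colnames(tab) <- c("df", "SS", "MS", "est_var", "pct")
  list(table = tab, phi_pt = va / tot, est_var_among_raw = va_raw)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$d2_convention, ")\n", sep = "")
  tab <- round(as.data.frame(x$table), 3)
  tab$P <- c(format(x$p_value, digits = 3), "", "")
  print(tab)
  cat(sprintf("PhiPT = %.3f, p = %.4g (%d permutations)\n",
              x$phi_pt, x$p_value, x$n_permutations))
  invisible(x)
}
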