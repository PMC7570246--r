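#' Classify paired digest calls into band types I-IV
#'
#' The four canonical MSAP band types encode the methylation state of the
#' CCGG site from the two isoschizomer digests: type I (M=1, H=1)
#' non-methylated, type II (M=1, H=0) fully (internally) methylated, type III
#' (M=0, H=1) hemi-methylated, type IV (M=0, H=0) counted as methylated by
#' the rate formulas (though it can also reflect restriction-site mutation;
#' its share is reported separately by [methylation_rates()]).
#'
#' @param m_call,h_call binary call vectors from the MseI/MspI and MseI/HpaII
#'   digests; `NA` for indistinct bands.
#' @return Factor with levels `I`, `II`, `III`, `IV`; `NA` (unclassifiable)
#'   where either call is missing.
#' @export
classify_band_type <- function(m_call, h_call) {
  stopifnot(length(m_call) == length(h_call))
  ok <- is.na(m_call) | m_call %in% c(0, 1)
  if (!all(ok & (is.na(h_call) | h_call %in% c(0, 1))))
    stop("calls must be 0, 1 or NA")
  code <- 2L * (1L - m_call) + (1L - h_call) + 1L  # (1,1)->1 ... (0,0)->4
  factor(c("I", "II", "III", "IV")[code], levels = c("I", "II", "III", "IV"))
}

#' Band-type counts per group
#'
#' Pools band-type classifications over all (sample, locus) pairs with
#' complete calls within each group. Counts may also be supplied directly
#' from a published table via [band_type_counts_table()], so printed counts
#' are first-class inputs.
#'
#' @param x a `band_matrix`.
#' @param level grouping level, `"treatment_group"` or `"treatment_class"`.
#' @return A `band_type_counts` data.frame with columns `group`, `n_I`,
#'   `n_II`, `n_III`, `n_IV`, `total`.
#' @export
count_band_types <- function(x, level = c("treatment_group",
                                          "treatment_class")) {
  g <- group_labels(x, match.arg(level))
  groups <- unique(g)
  rows <- lapply(groups, function(gr) {
    i <- which(g == gr)
    if (length(i) == 0) stop("empty group: ", gr)
    bt <- classify_band_type(as.vector(x$calls_M[i, , drop = FALSE]),
                             as.vector(x$calls_H[i, , drop = FALSE]))
    as.integer(table(bt))
  })
  cnt <- do.call(rbind, rows)
  band_type_counts_table(groups, cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
}

#' @param group group labels.
#' @param n_I,n_II,n_III,n_IV non-negative band-type counts.
#' @rdname count_band_types
#' @export
band_type_counts_table <- function(group, n_I, n_II, n_III, n_IV) {
  stopifnot(all(c(n_I, n_II, n_III, n_IV) >= 0))
  structure(
    data.frame(group = as.character(group),
               n_I = as.integer(n_I), n_II = as.integer(n_II),
               n_III = as.integer(n_III), n_IV = as.integer(n_IV),
               total = as.integer(n_I + n_II + n_III + n_IV),
               stringsAsFactors = FALSE),
    class = c("band_type_counts", "data.frame")
  )
}

#' Methylation rates from band-type counts
#'
#' Converts band-type counts to the four percentage rates:
#' total methylated = (II + III + IV) / total x 100, fully methylated =
#' II / total x 100, hemi-methylated = III / total x 100, non-methylated =
#' I / total x 100. The type-IV share (IV / total x 100), which the total
#' folds in, is reported separately. Values are kept at full precision;
#' printing rounds half-up to 2 decimals.
#'
#' @param counts a `band_type_counts` table (from [count_band_types()] or
#'   [band_type_counts_table()]).
#' @return A `methylation_rates` data.frame with columns `group`,
#'   `total_pct`, `full_pct`, `hemi_pct`, `non_pct`, `typeIV_pct`, `total`.
#' @export
methylation_rates <- function(counts) {
  if (any(counts$total == 0))
    stop("zero total band count for group(s): ",
         paste(counts$group[counts$total == 0], collapse = ", "))
  tot <- counts$total
  structure(
    data.frame(
      group = counts$group,
      total_pct = 100 * (counts$n_II + counts$n_III + counts$n_IV) / tot,
      full_pct = 100 * counts$n_II / tot,
      hemi_pct = 100 * counts$n_III / tot,
      non_pct = 100 * counts$n_I / tot,
      typeIV_pct = 100 * counts$n_IV / tot,
      total = tot,
      stringsAsFactors = FALSE),
    class = c("methylation_rates", "data.frame")
  )
}

#' @export
print.methylation_rates <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE) & names(y) != "total"
  y[num] <- lapply(y[num], round_half_up, 2)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' Treatment-class contrasts of methylation rates
#'
#' Averages each rate over the treatment groups of a class (unweighted) and
#' contrasts it against a reference. Group rates are first rounded half-up to
#' 2 decimals — the precision at which such tables are reported — so that
#' contrasts of published tables reproduce their published averages.
#'
#' @param rates a `methylation_rates` table, one row per treatment group.
#' @param classes named character vector mapping each group to its class
#'   (e.g. `c(G100 = "GR", ...)`); defaults to each group being its own
#'   class.
#' @param reference group label(s) forming the reference; the reference value
#'   is the mean of their (rounded) rates.
#' @return A `data.frame` with one row per class x rate: columns `class`,
#'   `rate`, `mean`, `reference_mean`, `delta` (class mean minus reference).
#' @export
rate_contrasts <- function(rates, classes = NULL, reference = "Control") {
  if (is.null(classes)) {
    classes <- rates$group
    names(classes) <- rates$group
  }
  if (!all(reference %in% rates$group))
    stop("unknown reference group(s): ",
         paste(setdiff(reference, rates$group), collapse = ", "))
  if (!all(rates$group %in% names(classes)))
    stop("groups missing from class map: ",
         paste(setdiff(rates$group, names(classes)), collapse = ", "))
  rate_cols <- c("total_pct", "full_pct", "hemi_pct", "non_pct")
  r2 <- lapply(rates[rate_cols], round_half_up, 2)
  cls <- unname(classes[rates$group])
  ref_idx <- rates$group %in% reference
  out <- do.call(rbind, lapply(unique(cls), function(cl) {
    i <- cls == cl
    data.frame(
      class = cl, rate = rate_cols,
      mean = vapply(r2, function(v) mean(v[i]), 0),
      reference_mean = vapply(r2, function(v) mean(v[ref_idx]), 0),
      stringsAsFactors = FALSE)
  }))
  out$delta <- out$mean - out$reference_mean
  rownames(out) <- NULL
  out
}
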