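#' Per-band presence frequencies
#'
#' Each scored band (one locus x digest column) is treated as a two-state
#' dominant phenotype. The frequency is the presence count over the
#' non-missing count; all-missing bands are returned as `NA` with a warning.
#'
#' @param x a `band_matrix`.
#' @param group optional group label (at `level`) restricting the samples.
#' @param level grouping level used when `group` is given.
#' @return Named numeric vector of frequencies over the `2 * n_loci` band
#'   columns (`<locus>__M`, then `<locus>__H`).
#' @export
band_frequencies <- function(x, group = NULL,
                             level = c("treatment_group", "treatment_class")) {
  idx <- seq_len(nrow(x$calls_M))
  if (!is.null(group)) {
    g <- group_labels(x, match.arg(level))
    idx <- which(g == group)
    if (length(idx) == 0) stop("empty group: ", group)
  }
  bands <- cbind(x$calls_M[idx, , drop = FALSE],
                 x$calls_H[idx, , drop = FALSE])
  colnames(bands) <- c(paste0(x$locus_ids, "__M"),
                       paste0(x$locus_ids, "__H"))
  p <- colMeans(bands, na.rm = TRUE)
  p[colSums(!is.na(bands)) == 0] <- NA
  if (anyNA(p))
    warning(sum(is.na(p)), " all-missing band(s) excluded")
  p
}

#' Per-band diversity indices under the two-state model
#'
#' For a band-presence frequency p (q = 1 - p): Nei's gene diversity
#' H = 1 - p^2 - q^2, Shannon's information index
#' I = -p ln p - q ln q (with 0 ln 0 := 0), effective number of alleles
#' ne = 1 / (p^2 + q^2), and the biallelic polymorphic information content
#' PIC = 1 - p^2 - q^2 - 2 p^2 q^2. Phenotype frequencies are used directly,
#' with no Hardy-Weinberg back-transformation of the dominant calls.
#'
#' @param p numeric vector of band frequencies in \[0, 1\].
#' @return A `data.frame` with columns `p`, `H`, `I`, `ne`, `PIC`,
#'   `polymorphic` (`TRUE` iff 0 < p < 1).
#' @export
locus_diversity <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- 1 - p
  plogp <- function(z) ifelse(z > 0, z * log(z), 0)
  data.frame(
    p = p,
    H = 1 - p^2 - q^2,
    I = -(plogp(p) + plogp(q)),
    ne = 1 / (p^2 + q^2),
    PIC = 1 - p^2 - q^2 - 2 * p^2 * q^2,
    polymorphic = p > 0 & p < 1
  )
}

#' Group-wise dominant-marker diversity summary
#'
#' Per group (and pooled `Total`): number and percentage of polymorphic
#' bands, and means of Nei's H, Shannon's I, effective allele number and
#' biallelic PIC over the chosen scope. The index definitions are those of
#' [locus_diversity()] and are recorded in the `"index_definitions"`
#' attribute of the result.
#'
#' @param x a `band_matrix`.
#' @param level grouping level.
#' @param scope `"all_loci"` (default) or `"polymorphic_only"`, the set of
#'   bands over which means are taken.
#' @return A `diversity_summary` data.frame with columns `group`,
#'   `n_samples`, `n_bands`, `n_polymorphic`, `pct_polymorphic`, `mean_H`,
#'   `mean_I`, `mean_ne`, `PIC`.
#' @export
diversity_summary <- function(x, level = c("treatment_group",
                                           "treatment_class"),
                              scope = c("all_loci", "polymorphic_only")) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  g <- group_labels(x, level)
  groups <- c(unique(g), "Total")
  rows <- lapply(groups, function(gr) {
    if (gr == "Total") {
      n <- length(g)
      p <- band_frequencies(x)
    } else {
      n <- sum(g == gr)
      if (n == 1)
        warning("group '", gr, "' has a single sample; polymorphism is ",
                "undefined and frequencies are taken as-is")
      p <- band_frequencies(x, gr, level)
    }
    ld <- locus_diversity(p[!is.na(p)])
    keep <- if (scope == "polymorphic_only") ld$polymorphic else
      rep(TRUE, nrow(ld))
    data.frame(
      group = gr, n_samples = n, n_bands = nrow(ld),
      n_polymorphic = sum(ld$polymorphic),
      pct_polymorphic = pct_polymorphic(sum(ld$polymorphic), nrow(ld)),
      mean_H = mean(ld$H[keep]), mean_I = mean(ld$I[keep]),
      mean_ne = mean(ld$ne[keep]), PIC = mean(ld$PIC[keep]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            scope = scope,
            index_definitions = paste(
              "two-state phenotype frequencies; H = 1-p^2-q^2;",
              "I = -p ln p - q ln q; ne = 1/(p^2+q^2);",
              "PIC = 1-p^2-q^2-2p^2q^2 (biallelic)"),
            class = c("diversity_summary", "data.frame"))
}

#' Percentage of polymorphic loci from counts
#'
#' @param n_polymorphic number of polymorphic loci (or bands).
#' @param n_total total number scored.
#' @return `100 * n_polymorphic / n_total`.
#' @export
pct_polymorphic <- function(n_polymorphic, n_total) {
  stopifnot(all(n_polymorphic <= n_total), all(n_total > 0))
  100 * n_polymorphic / n_total
}
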