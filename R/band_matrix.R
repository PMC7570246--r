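#' Sample metadata for a band matrix
#'
#' Builds the per-sample metadata table used by every grouped analysis. The
#' treatment class is derived deterministically from the doses: samples with
#' neither mutagen are `Control`, gamma irradiation alone is `GR`, a
#' methyltransferase inhibitor alone is `DNMTi`, and both together are
#' `DNMTi+GR`.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param treatment_group character vector of group labels (e.g. `"Control"`,
#'   `"G100"`, `"A80+G150"`).
#' @param gamma_dose absorbed gamma-ray dose in Gy (0 if unirradiated).
#' @param dnmti_agent methyltransferase-inhibitor agent, one of `"none"`,
#'   `"AZA"` (5-azacytidine) or `"ZEB"` (zebularine).
#' @param dnmti_conc inhibitor concentration in micromolar (0 if untreated).
#' @return A `data.frame` with columns `sample_id`, `treatment_group`,
#'   `treatment_class`, `gamma_dose`, `dnmti_agent`, `dnmti_conc`.
#' @export
sample_meta <- function(sample_id, treatment_group, gamma_dose = 0,
                        dnmti_agent = "none", dnmti_conc = 0) {
  n <- length(sample_id)
  stopifnot(!anyDuplicated(sample_id))
  dnmti_agent <- match.arg(rep_len(as.character(dnmti_agent), n),
                           c("none", "AZA", "ZEB"), several.ok = TRUE)
  out <- data.frame(
    sample_id = as.character(sample_id),
    treatment_group = rep_len(as.character(treatment_group), n),
    gamma_dose = rep_len(as.numeric(gamma_dose), n),
    dnmti_agent = rep_len(dnmti_agent, n),
    dnmti_conc = rep_len(as.numeric(dnmti_conc), n),
    stringsAsFactors = FALSE
  )
  out$treatment_class <- treatment_class(out$gamma_dose, out$dnmti_agent)
  out[c("sample_id", "treatment_group", "treatment_class",
        "gamma_dose", "dnmti_agent", "dnmti_conc")]
}

#' @rdname sample_meta
#' @export
treatment_class <- function(gamma_dose, dnmti_agent) {
  gr <- gamma_dose > 0
  dn <- dnmti_agent != "none"
  ifelse(gr & dn, "DNMTi+GR", ifelse(gr, "GR", ifelse(dn, "DNMTi", "Control")))
}

#' Paired-digest band matrix
#'
#' Container for scored MSAP/TMD profiles: per sample and per locus, one
#' presence call from the MseI/MspI digest (M) and one from the MseI/HpaII
#' digest (H). Calls are 1 (band present), 0 (band absent) or `NA`
#' (indistinct band, excluded from counting and distances).
#'
#' @param calls_M,calls_H integer matrices (samples x loci) of 0/1/`NA` calls,
#'   identical dimensions; column names are the locus ids.
#' @param samples metadata `data.frame` as returned by [sample_meta()], one
#'   row per matrix row, in matrix row order.
#' @param marker_system `"MSAP"`, `"TMD"` or `"MERGED"`.
#' @param locus_ids optional character vector of locus ids overriding the
#'   column names of `calls_M`.
#' @return An object of class `band_matrix`: a list with elements
#'   `marker_system`, `locus_ids`, `samples`, `calls_M`, `calls_H`.
#' @export
band_matrix <- function(calls_M, calls_H, samples,
                        marker_system = c("MSAP", "TMD", "MERGED"),
                        locus_ids = NULL) {
  marker_system <- match.arg(marker_system)
  calls_M <- as.matrix(calls_M)
  calls_H <- as.matrix(calls_H)
  locus_ids <- locus_ids %||% colnames(calls_M) %||%
    paste0("L", seq_len(ncol(calls_M)))
  if (identical(dim(calls_M), dim(calls_H)) &&
      nrow(samples) == nrow(calls_M) &&
      length(locus_ids) == ncol(calls_M))
    dimnames(calls_M) <- dimnames(calls_H) <-
      list(samples$sample_id, locus_ids)
  x <- structure(
    list(marker_system = marker_system, locus_ids = locus_ids,
         samples = samples, calls_M = calls_M, calls_H = calls_H),
    class = "band_matrix"
  )
  x <- validate_band_matrix(x)
  storage.mode(x$calls_M) <- "integer"
  storage.mode(x$calls_H) <- "integer"
  x
}

validate_band_matrix <- function(x) {
  if (!identical(dim(x$calls_M), dim(x$calls_H)))
    stop("calls_M and calls_H differ in shape: ",
         paste(dim(x$calls_M), collapse = "x"), " vs ",
         paste(dim(x$calls_H), collapse = "x"))
  for (side in c("calls_M", "calls_H")) {
    v <- x[[side]]
    bad <- which(!(is.na(v) | v == 0 | v == 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-binary call %s in %s at locus '%s', sample '%s'",
                   format(v[bad[1, , drop = FALSE]]), side,
                   x$locus_ids[bad[1, 2]], x$samples$sample_id[bad[1, 1]]))
  }
  if (anyDuplicated(x$locus_ids))
    stop("duplicated locus ids: ",
         paste(unique(x$locus_ids[duplicated(x$locus_ids)]), collapse = ", "))
  if (anyDuplicated(x$samples$sample_id))
    stop("duplicated sample ids")
  if (nrow(x$samples) != nrow(x$calls_M))
    stop("metadata has ", nrow(x$samples), " rows but matrix has ",
         nrow(x$calls_M), " samples")
  x
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix [%s]: %d samples x %d loci", x$marker_system,
              nrow(x$calls_M), ncol(x$calls_M)))
  nmiss <- sum(is.na(x$calls_M)) + sum(is.na(x$calls_H))
  if (nmiss > 0) cat(sprintf(" (%d missing calls)", nmiss))
  cat("\n")
  tab <- table(factor(x$samples$treatment_class,
                      c("Control", "GR", "DNMTi", "DNMTi+GR")))
  cat("classes:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$calls_M)

#' Per-sample group labels at a grouping level
#'
#' @param x a `band_matrix`.
#' @param level `"treatment_group"` (the ten treatment groups) or
#'   `"treatment_class"` (Control/GR/DNMTi/DNMTi+GR).
#' @return Named character vector (names = sample ids).
#' @export
group_labels <- function(x, level = c("treatment_group", "treatment_class")) {
  level <- match.arg(level)
  g <- x$samples[[level]]
  names(g) <- x$samples$sample_id
  g
}

#' Merge two marker systems into one band matrix
#'
#' Concatenates the loci of two band matrices scored on the same samples
#' (e.g. MSAP and TMD), namespacing locus ids by their source system. Sample
#' order of the result follows the first argument.
#'
#' @param a,b `band_matrix` objects over identical sample sets.
#' @return A `band_matrix` with `marker_system = "MERGED"` and
#'   `ncol(a) + ncol(b)` loci.
#' @export
merge_marker_systems <- function(a, b) {
  if (!setequal(a$samples$sample_id, b$samples$sample_id))
    stop("sample sets differ between the two matrices")
  idx <- match(a$samples$sample_id, b$samples$sample_id)
  ns <- function(x) {
    pre <- paste0(x$marker_system, ":")
    ifelse(startsWith(x$locus_ids, pre), x$locus_ids,
           paste0(pre, x$locus_ids))
  }
  band_matrix(
    cbind(a$calls_M, b$calls_M[idx, , drop = FALSE]),
    cbind(a$calls_H, b$calls_H[idx, , drop = FALSE]),
    samples = a$samples, marker_system = "MERGED",
    locus_ids = c(ns(a), ns(b))
  )
}
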