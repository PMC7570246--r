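#' Read a scored band matrix from delimited text
#'
#' The file dialect is one row per sample with a `sample_id` column followed
#' by two columns per locus, `<locus>__M` (MseI/MspI digest) and `<locus>__H`
#' (MseI/HpaII digest). Cells are 0, 1 or the missing token `NA`. Comma
#' delimiter is the default; tab is auto-detected. Metadata is a second file
#' keyed by `sample_id` with columns `treatment_group`, `gamma_dose`,
#' `dnmti_agent`, `dnmti_conc`.
#'
#' @param path path to the band-call file.
#' @param meta_path path to the sample-metadata file.
#' @param marker_system `"MSAP"`, `"TMD"` or `"MERGED"`.
#' @return A validated [band_matrix()]. Missing entries are kept as `NA`,
#'   never silently zeroed.
#' @export
read_band_matrix <- function(path, meta_path,
                             marker_system = c("MSAP", "TMD", "MERGED")) {
  marker_system <- match.arg(marker_system)
  tab <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  if (!"sample_id" %in% names(tab)) stop("band file lacks a sample_id column")
  ids <- tab$sample_id
  cols <- setdiff(names(tab), "sample_id")
  m_cols <- grep("__M$", cols, value = TRUE)
  h_cols <- grep("__H$", cols, value = TRUE)
  loci_m <- sub("__M$", "", m_cols)
  loci_h <- sub("__H$", "", h_cols)
  if (!setequal(loci_m, loci_h) ||
      length(c(m_cols, h_cols)) != length(cols))
    stop("M and H column blocks do not pair up: ",
         paste(c(setdiff(loci_m, loci_h), setdiff(loci_h, loci_m)),
               collapse = ", "))
  parse_block <- function(colnames_, loci) {
    v <- as.matrix(tab[colnames_])
    bad <- which(matrix(!(v %in% c("0", "1", "NA", "")), nrow(v)),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-binary cell value '%s' at locus '%s', sample '%s'",
                   v[bad[1, , drop = FALSE]], loci[bad[1, 2]],
                   ids[bad[1, 1]]))
    suppressWarnings(storage <- matrix(as.integer(v), nrow(v), ncol(v)))
    storage
  }
  calls_M <- parse_block(m_cols, loci_m)
  calls_H <- parse_block(paste0(loci_m, "__H"), loci_m)

  meta <- utils::read.table(meta_path, sep = sniff_sep(meta_path),
                            header = TRUE, stringsAsFactors = FALSE)
  if (!all(ids %in% meta$sample_id))
    stop("samples missing from metadata: ",
         paste(setdiff(ids, meta$sample_id), collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  samples <- sample_meta(meta$sample_id, meta$treatment_group,
                         meta$gamma_dose %||% 0,
                         meta$dnmti_agent %||% "none",
                         meta$dnmti_conc %||% 0)
  band_matrix(calls_M, calls_H, samples, marker_system, locus_ids = loci_m)
}

#' Write a band matrix (and optionally its metadata) to delimited text
#'
#' Inverse of [read_band_matrix()]: the written file re-reads to an equal
#' matrix, including missing calls (token `NA`).
#'
#' @param x a `band_matrix`.
#' @param path output path for the band-call file.
#' @param meta_path optional output path for the metadata file.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(x, path, meta_path = NULL, sep = ",") {
  L <- length(x$locus_ids)
  out <- data.frame(sample_id = x$samples$sample_id,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(L)) {
    out[[paste0(x$locus_ids[j], "__M")]] <- x$calls_M[, j]
    out[[paste0(x$locus_ids[j], "__H")]] <- x$calls_H[, j]
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  if (!is.null(meta_path))
    utils::write.table(
      x$samples[c("sample_id", "treatment_group", "gamma_dose",
                  "dnmti_agent", "dnmti_conc")],
      meta_path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a band matrix in a GenAlEx-style binary layout
#'
#' Writes the concatenated M/H calls as one binary column per digest band
#' with the conventional two header rows (number of bands, samples, groups
#' and per-group sizes), for interoperability with spreadsheet-based
#' dominant-marker tools.
#'
#' @param x a `band_matrix`.
#' @param path output path.
#' @param level grouping level defining the populations.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(x, path,
                          level = c("treatment_group", "treatment_class")) {
  level <- match.arg(level)
  g <- group_labels(x, level)
  sizes <- table(factor(g, unique(g)))
  bands <- cbind(x$calls_M, x$calls_H)
  colnames(bands) <- c(paste0(x$locus_ids, "__M"), paste0(x$locus_ids, "__H"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(ncol(bands), nrow(bands), length(sizes), sizes),
                   collapse = ","), con)
  writeLines(paste(c("", "", names(sizes)), collapse = ","), con)
  body <- cbind(sample_id = rownames(bands), pop = as.character(g),
                apply(bands, 2, as.character))
  writeLines(paste(colnames(body), collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}
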