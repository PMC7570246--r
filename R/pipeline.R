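#' Run the full epigenetic-diversity analysis pipeline
#'
#' Orchestrates the whole chain — band-type scoring, diversity summaries,
#' pairwise distances, AMOVA, PCoA, Mantel correlation between marker
#' systems, and neighbor-joining trees — from one configuration, writing
#' delimited/JSON/Newick outputs and a run manifest. Every stage calls the
#' exported module functions on the same objects, so reported values equal
#' direct calls.
#'
#' The configuration is a list (or path to a YAML file) with either input
#' paths (`msap`, `tmd` — at least one — and `meta`) or a `simulate` block
#' (arguments for [sim_config()], applied per marker system), plus `level`
#' (grouping level, default `"treatment_class"`), `permutations` (default
#' 999), `seed` (mandatory; fanned out to per-stage seeds by a fixed
#' derivation so adding a stage never perturbs earlier stages), and
#' `out_dir`.
#'
#' @param config list or YAML path as described.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the in-memory results per marker system
#'   (`rates`, `diversity`, `amova`, `pcoa`, `tree`), `mantel`, and
#'   `manifest`. Files written: `rates_<SYS>.csv`, `diversity_<SYS>.csv`,
#'   `amova_<SYS>.csv`, `pcoa_<SYS>.csv`, `nj_<SYS>.nwk` for each available
#'   system (MSAP/TMD/MERGED), `mantel.json` when both systems are present,
#'   and `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required")
  if (is.null(config$seed)) stop("seed is mandatory")
  seed <- as.integer(config$seed)
  level <- config$level %||% "treatment_class"
  perms <- config$permutations %||% 999
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  has_inputs <- !is.null(config$msap) || !is.null(config$tmd)
  has_sim <- !is.null(config$simulate)
  if (has_inputs == has_sim)
    stop("exactly one of input paths (msap/tmd + meta) or a simulate ",
         "block must be given")

  log_con <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    writeLines(line, log_con)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  num_csv <- function(df, path) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  }

  mats <- list()
  if (has_sim) {
    sims <- list()
    for (sys in c("MSAP", "TMD")) {
      args <- config$simulate
      args$marker_system <- sys
      args$seed <- derive_seed(seed, paste0("simulate_", sys))
      cfg <- do.call(sim_config, args)
      sims[[sys]] <- stage(paste0("simulate_", sys),
                           simulate_band_matrix(cfg))
      mats[[sys]] <- sims[[sys]]$matrix
      logmsg("simulated ", sys, " (seed ", cfg$seed, ")")
    }
  } else {
    if (is.null(config$meta)) stop("meta path is required with input paths")
    for (sys in c("MSAP", "TMD")) {
      p <- config[[tolower(sys)]]
      if (is.null(p)) {
        logmsg(sys, " input absent; skipping its outputs")
        next
      }
      mats[[sys]] <- stage(paste0("read_", sys),
                           read_band_matrix(p, config$meta, sys))
      logmsg("read ", sys, ": ", nrow(mats[[sys]]$calls_M), " samples x ",
             ncol(mats[[sys]]$calls_M), " loci")
    }
  }
  if (length(mats) == 2)
    mats$MERGED <- stage("merge", merge_marker_systems(mats$MSAP, mats$TMD))

  results <- list()
  dists <- list()
  for (sys in names(mats)) {
    m <- mats[[sys]]
    res <- list()
    res$rates <- stage(paste0("score_", sys),
                       methylation_rates(count_band_types(m, level)))
    num_csv(res$rates, file.path(out_dir, paste0("rates_", sys, ".csv")))
    res$diversity <- stage(paste0("diversity_", sys),
                           diversity_summary(m, level))
    num_csv(res$diversity,
            file.path(out_dir, paste0("diversity_", sys, ".csv")))
    d <- stage(paste0("distance_", sys), band_distance(m))
    dists[[sys]] <- d
    res$amova <- stage(paste0("amova_", sys),
                       amova(d, group_labels(m, level), perms,
                             derive_seed(seed, paste0("amova_", sys))))
    at <- as.data.frame(res$amova$table)
    at <- cbind(source = rownames(at), at,
                p_value = c(res$amova$p_value, NA, NA),
                phi_pt = c(res$amova$phi_pt, NA, NA))
    num_csv(at, file.path(out_dir, paste0("amova_", sys, ".csv")))
    res$pcoa <- stage(paste0("pcoa_", sys), pcoa(d, n_axes = 2))
    pc <- data.frame(sample_id = rownames(res$pcoa$coordinates),
                     res$pcoa$coordinates)
    num_csv(pc, file.path(out_dir, paste0("pcoa_", sys, ".csv")))
    res$tree <- stage(paste0("nj_", sys),
                      neighbor_joining(sqrt(unclass(d))))
    ape::write.tree(res$tree, file.path(out_dir, paste0("nj_", sys, ".nwk")))
    logmsg("completed ", sys)
    results[[sys]] <- res
  }

  if (all(c("MSAP", "TMD") %in% names(dists))) {
    results$mantel <- stage(
      "mantel", mantel_test(dists$MSAP, dists$TMD, perms,
                            derive_seed(seed, "mantel")))
    jsonlite::write_json(
      results$mantel[c("r", "r_squared", "p_value", "n_permutations",
                       "seed")],
      file.path(out_dir, "mantel.json"), auto_unbox = TRUE, digits = NA)
  } else {
    logmsg("mantel skipped: both marker systems required")
  }

  manifest <- list(
    seed = seed, level = level, permutations = perms,
    systems = names(mats),
    stage_seeds = c(
      stats::setNames(
        lapply(names(mats), function(s) derive_seed(seed, paste0("amova_", s))),
        paste0("amova_", names(mats))),
      list(mantel = derive_seed(seed, "mantel"))),
    decisions = c(
      "distances: squared_euclidean (entries are squared distances)",
      "NJ built on sqrt of squared-euclidean distances",
      "AMOVA: PhiPT convention, negative components truncated at 0"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  logmsg("pipeline complete")
  invisible(results)
}
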