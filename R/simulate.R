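#' Default treatment design
#'
#' The study design the simulator emulates: an untreated control (n = 5),
#' three gamma-ray doses (100/150/250 Gy, n = 8 each), two demethylating
#' agents at 80 uM (AZA, ZEB; n = 8 each) and four combined treatments
#' (AZA/ZEB x 100/150 Gy, n = 12 each) — 93 samples, classes
#' Control/GR/DNMTi/DNMTi+GR of sizes 5/24/16/48.
#'
#' @return A `data.frame` with columns `treatment_group`, `n_samples`,
#'   `gamma_dose`, `dnmti_agent`, `dnmti_conc`.
#' @export
default_design <- function() {
  data.frame(
    treatment_group = c("Control", "G100", "G150", "G250", "A80", "Z80",
                        "A80+G100", "A80+G150", "Z80+G100", "Z80+G150"),
    n_samples = c(5, 8, 8, 8, 8, 8, 12, 12, 12, 12),
    gamma_dose = c(0, 100, 150, 250, 0, 0, 100, 150, 100, 150),
    dnmti_agent = c("none", "none", "none", "none", "AZA", "ZEB",
                    "AZA", "AZA", "ZEB", "ZEB"),
    dnmti_conc = c(0, 0, 0, 0, 80, 80, 80, 80, 80, 80),
    stringsAsFactors = FALSE
  )
}

#' Simulator configuration
#'
#' Parameters of the dose-dependent demethylation model. Baseline state
#' probabilities default to the control-column proportions of the two marker
#' systems (MSAP: 102 loci, states I-IV at 0.413/0.131/0.191/0.265; TMD: 60
#' loci at 0.427/0.233/0.070/0.269). Treatment demethylates with probability
#' `pdem = 1 - exp(-(beta_gr * Gy + beta_dnmti * uM) * synergy^[both])`;
#' a fully methylated site (II) moves to hemi (III) with probability
#' `pdem * alpha` and to unmethylated (I) otherwise, hemi (III) moves to I,
#' and an absent-band site (IV) is partially demethylated to III with
#' probability `pdem * alpha`. `alpha` close to 1 gives the
#' repetitive-region (TMD-like) regime where full methylation converts to
#' hemi; close to 0 the euchromatic (MSAP-like) regime where both decline.
#' Each locus has a baseline state shared across samples; each sample
#' redraws it independently with probability `epsilon` (epimutation noise,
#' the source of within-group variance).
#'
#' @param marker_system `"MSAP"` or `"TMD"`; sets defaults for `n_loci`,
#'   `baseline` and `alpha`.
#' @param n_loci number of loci.
#' @param design treatment design as [default_design()].
#' @param baseline length-4 probability vector over states I-IV.
#' @param beta_gr demethylation rate per Gy.
#' @param beta_dnmti demethylation rate per uM.
#' @param synergy multiplicative rate factor (>= 1) applied when both
#'   mutagens are present.
#' @param alpha fraction of demethylating transitions that stop at the
#'   hemi-methylated state.
#' @param epsilon per-sample baseline redraw probability in \[0, 1\].
#' @param seed RNG seed used by [simulate_band_matrix()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(marker_system = c("MSAP", "TMD"),
                       n_loci = NULL, design = default_design(),
                       baseline = NULL, beta_gr = 1e-3, beta_dnmti = 1e-2,
                       synergy = 1.5, alpha = NULL, epsilon = 0.02,
                       seed = 1L) {
  marker_system <- match.arg(marker_system)
  defaults <- list(
    MSAP = list(n_loci = 102, baseline = c(0.413, 0.131, 0.191, 0.265),
                alpha = 0.2),
    TMD = list(n_loci = 60, baseline = c(0.427, 0.233, 0.070, 0.269),
               alpha = 0.8))[[marker_system]]
  cfg <- list(
    marker_system = marker_system,
    n_loci = n_loci %||% defaults$n_loci,
    design = design,
    baseline = baseline %||% defaults$baseline,
    beta_gr = beta_gr, beta_dnmti = beta_dnmti, synergy = synergy,
    alpha = alpha %||% defaults$alpha, epsilon = epsilon, seed = seed)
  cfg$baseline <- cfg$baseline / sum(cfg$baseline)
  stopifnot(all(cfg$baseline >= 0), cfg$beta_gr >= 0, cfg$beta_dnmti >= 0,
            cfg$synergy >= 1, cfg$alpha >= 0, cfg$alpha <= 1,
            cfg$epsilon >= 0, cfg$epsilon <= 1, cfg$n_loci >= 1,
            sum(cfg$design$n_samples) >= 1)
  structure(cfg, class = "sim_config")
}

# Per-group demethylation probability implied by a config.
demethylation_prob <- function(config, gamma_dose, dnmti_conc) {
  rate <- config$beta_gr * gamma_dose + config$beta_dnmti * dnmti_conc
  both <- gamma_dose > 0 & dnmti_conc > 0
  1 - exp(-rate * ifelse(both, config$synergy, 1))
}

#' Analytic post-treatment state probabilities
#'
#' Expected distribution over states I-IV for each design group, from the
#' baseline probabilities and the group's demethylation probability. The
#' epimutation redraw does not change these marginals (it redraws from the
#' same baseline).
#'
#' @param config a `sim_config`.
#' @return Matrix (groups x states I-IV) of probabilities.
#' @export
expected_state_probs <- function(config) {
  p <- config$baseline
  a <- config$alpha
  pd <- demethylation_prob(config, config$design$gamma_dose,
                           config$design$dnmti_conc)
  out <- cbind(
    I = p[1] + p[2] * pd * (1 - a) + p[3] * pd,
    II = p[2] * (1 - pd),
    III = p[3] * (1 - pd) + p[2] * pd * a + p[4] * pd * a,
    IV = p[4] * (1 - pd * a))
  rownames(out) <- config$design$treatment_group
  out
}

#' Analytic expected methylation rates per group
#'
#' @param config a `sim_config`.
#' @return `data.frame` with `group`, `total_pct`, `full_pct`, `hemi_pct`,
#'   `non_pct` (percent scale), from [expected_state_probs()].
#' @export
expected_rates <- function(config) {
  pr <- expected_state_probs(config)
  data.frame(group = rownames(pr),
             total_pct = 100 * (1 - pr[, "I"]),
             full_pct = 100 * pr[, "II"],
             hemi_pct = 100 * pr[, "III"],
             non_pct = 100 * pr[, "I"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a scored band matrix with dose-dependent demethylation
#'
#' Draws a shared baseline state per locus, adds per-sample epimutation
#' noise, applies the treatment transition model of [sim_config()], and maps
#' states to paired digest calls (I -> M1/H1, II -> M1/H0, III -> M0/H1,
#' IV -> M0/H0). The truth record retains latent states before and after
#' treatment for parameter-recovery checks.
#'
#' @param config a `sim_config`.
#' @return List with elements `matrix` (a [band_matrix()]) and `truth`
#'   (list: `state_before`, `state_after` (samples x loci, integer codes
#'   1-4), `group_tallies` (groups x states counts), `config`).
#' @export
simulate_band_matrix <- function(config) {
  set.seed(config$seed)
  des <- config$design
  N <- sum(des$n_samples)
  L <- config$n_loci
  grp_of <- rep(seq_len(nrow(des)), des$n_samples)
  samples <- sample_meta(
    sprintf("S%03d", seq_len(N)),
    des$treatment_group[grp_of], des$gamma_dose[grp_of],
    des$dnmti_agent[grp_of], des$dnmti_conc[grp_of])

  base_locus <- sample.int(4, L, replace = TRUE, prob = config$baseline)
  state0 <- matrix(base_locus, N, L, byrow = TRUE)
  redraw <- matrix(stats::runif(N * L) < config$epsilon, N, L)
  if (any(redraw))
    state0[redraw] <- sample.int(4, sum(redraw), replace = TRUE,
                                 prob = config$baseline)

  pd <- demethylation_prob(config, samples$gamma_dose,
                           samples$dnmti_conc)[row(state0)]
  u <- matrix(stats::runif(N * L), N, L)
  v <- matrix(stats::runif(N * L), N, L)
  state <- state0
  hit <- u < pd
  sel <- state0 == 2L & hit  # full -> hemi (alpha) or unmethylated
  state[sel] <- ifelse(v[sel] < config$alpha, 3L, 1L)
  state[state0 == 3L & hit] <- 1L
  state[state0 == 4L & u < pd * config$alpha] <- 3L

  calls_M <- matrix(as.integer(state %in% c(1L, 2L)), N, L)
  calls_H <- matrix(as.integer(state %in% c(1L, 3L)), N, L)
  mat <- band_matrix(calls_M, calls_H, samples, config$marker_system,
                     locus_ids = sprintf("%s_L%03d", config$marker_system,
                                         seq_len(L)))
  tallies <- t(vapply(seq_len(nrow(des)), function(i)
    tabulate(state[grp_of == i, ], 4L), integer(4)))
  dimnames(tallies) <- list(des$treatment_group, c("I", "II", "III", "IV"))
  list(matrix = mat,
       truth = list(state_before = state0, state_after = state,
                    group_tallies = tallies, config = config))
}

#' Parameter-recovery report for a simulated matrix
#'
#' Compares the scored methylation rates of each simulated group with the
#' analytic expectations of its configuration. The standard error treats
#' loci as the effective units (`SE = 100 * sqrt(p (1 - p) / n_loci)`):
#' because the baseline state is shared across samples within a locus,
#' samples are positively correlated and the locus count bounds the
#' effective sample size, making the 3 SE band conservative.
#'
#' @param matrix the simulated `band_matrix`.
#' @param truth the matching truth record.
#' @param config the `sim_config` used.
#' @return A `recovery_report` data.frame: one row per group x rate with
#'   `observed`, `expected`, `se`, `z`, `within_3se`.
#' @export
recover_parameters <- function(matrix, truth, config) {
  if (!identical(dim(matrix$calls_M), dim(truth$state_after)))
    stop("truth record does not match the matrix")
  if (!identical(truth$config$seed, config$seed) ||
      !identical(truth$config$n_loci, config$n_loci))
    stop("config does not match the truth record")
  obs <- methylation_rates(count_band_types(matrix, "treatment_group"))
  exp_ <- expected_rates(config)
  rate_cols <- c("total_pct", "full_pct", "hemi_pct", "non_pct")
  rows <- lapply(seq_len(nrow(exp_)), function(i) {
    j <- match(exp_$group[i], obs$group)
    e <- unlist(exp_[i, rate_cols]) / 100
    o <- unlist(obs[j, rate_cols]) / 100
    se <- sqrt(pmax(e * (1 - e), 1e-12) / config$n_loci)
    data.frame(group = exp_$group[i], rate = rate_cols,
               observed = 100 * o, expected = 100 * e, se = 100 * se,
               z = (o - e) / se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$within_3se <- abs(out$z) <= 3
  rownames(out) <- NULL
  structure(out, class = c("recovery_report", "data.frame"))
}
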