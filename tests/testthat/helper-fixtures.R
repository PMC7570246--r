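# Small in-code fixtures shared across test files.

# A 4-sample x 3-locus matrix covering all four band types and one missing
# call, over two treatment groups.
toy_matrix <- function() {
  samples <- sample_meta(
    c("a1", "a2", "b1", "b2"),
    c("Control", "Control", "A80", "A80"),
    gamma_dose = 0,
    dnmti_agent = c("none", "none", "AZA", "AZA"),
    dnmti_conc = c(0, 0, 80, 80))
  calls_M <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(1, NA, 0))
  calls_H <- rbind(c(1, 0, 1), c(1, 1, 0), c(1, 0, 1), c(0, NA, 1))
  band_matrix(calls_M, calls_H, samples, "MSAP",
              locus_ids = c("L1", "L2", "L3"))
}

# Random binary band matrix with a single group, for property tests.
random_matrix <- function(n_samples, n_loci, seed, p = 0.5,
                          marker_system = "MSAP") {
  set.seed(seed)
  samples <- sample_meta(sprintf("s%02d", seq_len(n_samples)), "Control")
  band_matrix(
    matrix(rbinom(n_samples * n_loci, 1, p), n_samples),
    matrix(rbinom(n_samples * n_loci, 1, p), n_samples),
    samples, marker_system,
    locus_ids = sprintf("%s_%d", marker_system, seq_len(n_loci)))
}

# Published band-type counts shipped with the package.
published_counts <- function(system = c("msap", "tmd")) {
  path <- system.file("extdata",
                      paste0(match.arg(system), "_band_type_counts.csv"),
                      package = "epidiv")
  tab <- read.csv(path, check.names = FALSE)
  band_type_counts_table(tab$group, tab$n_I, tab$n_II, tab$n_III, tab$n_IV)
}

# Group -> treatment-class map for the standard ten-group design.
design_classes <- function() {
  des <- default_design()
  stats::setNames(treatment_class(des$gamma_dose, des$dnmti_agent),
                  des$treatment_group)
}

# Brute-force AMOVA sums of squares by explicit double loops, independent of
# the package implementation.
amova_bruteforce <- function(d2, g) {
  N <- nrow(d2)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / N
  ss_within <- 0
  for (gr in unique(g)) {
    idx <- which(g == gr)
    acc <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + d2[idx[a], idx[b]]
    ss_within <- ss_within + acc / length(idx)
  }
  list(ss_total = ss_total, ss_within = ss_within,
       ss_among = ss_total - ss_within)
}
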