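test_that("band matrix validation rejects malformed input with coordinates", {
  s <- sample_meta(c("x", "y"), "Control")
  expect_error(
    band_matrix(rbind(c(1, 2), c(0, 1)), rbind(c(1, 1), c(0, 0)), s),
    "non-binary.*locus 'L2', sample 'x'")
  expect_error(
    band_matrix(matrix(1, 2, 2), matrix(1, 2, 3), s), "shape")
  expect_error(
    band_matrix(matrix(1, 2, 2), matrix(1, 2, 2), s,
                locus_ids = c("A", "A")), "duplicated locus")
  expect_error(band_matrix(matrix(1, 3, 2), matrix(1, 3, 2), s), "metadata")
})

test_that("treatment class is a deterministic function of the doses", {
  expect_equal(treatment_class(c(0, 100, 0, 150),
                               c("none", "none", "AZA", "ZEB")),
               c("Control", "GR", "DNMTi", "DNMTi+GR"))
  m <- toy_matrix()
  expect_equal(unname(group_labels(m, "treatment_class")),
               c("Control", "Control", "DNMTi", "DNMTi"))
})

test_that("read/write round trip is lossless including missing calls", {
  m <- toy_matrix()
  f <- tempfile(fileext = ".csv")
  fm <- tempfile(fileext = ".csv")
  write_band_matrix(m, f, fm)
  back <- read_band_matrix(f, fm, "MSAP")
  expect_identical(back$calls_M, m$calls_M)
  expect_identical(back$calls_H, m$calls_H)
  expect_equal(back$samples, m$samples)
  expect_true(is.na(back$calls_M["b2", "L2"]))

  # larger simulated matrix, tab-delimited
  sim <- simulate_band_matrix(sim_config("TMD", seed = 7))
  f2 <- tempfile(fileext = ".tsv")
  fm2 <- tempfile(fileext = ".tsv")
  write_band_matrix(sim$matrix, f2, fm2, sep = "\t")
  back2 <- read_band_matrix(f2, fm2, "TMD")
  expect_identical(back2$calls_M, sim$matrix$calls_M)
  expect_identical(back2$calls_H, sim$matrix$calls_H)
})

test_that("reading rejects non-binary cells naming locus and sample", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,L1__M,L1__H", "s1,1,0", "s2,2,1"), f)
  fm <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,treatment_group", "s1,Control", "s2,Control"), fm)
  expect_error(read_band_matrix(f, fm), "'2'.*locus 'L1', sample 's2'")
  writeLines(c("sample_id,L1__M,L1__H", "s1,1,0", "s3,1,1"), f)
  expect_error(read_band_matrix(f, fm), "missing from metadata: s3")
})

test_that("merging namespaces loci, sums locus counts, keeps sample order", {
  msap <- simulate_band_matrix(sim_config("MSAP", seed = 3))$matrix
  tmd <- simulate_band_matrix(sim_config("TMD", seed = 4))$matrix
  merged <- merge_marker_systems(msap, tmd)
  expect_equal(merged$marker_system, "MERGED")
  expect_equal(ncol(merged$calls_M), 102 + 60)
  expect_equal(nrow(merged$calls_M), 93)
  expect_equal(merged$samples$sample_id, msap$samples$sample_id)
  expect_true(all(startsWith(merged$locus_ids,
                             c(rep("MSAP:", 102), rep("TMD:", 60)))))

  # merge is tolerant of sample order differences in the second argument
  perm <- sample(seq_len(93))
  tmd_shuffled <- band_matrix(tmd$calls_M[perm, ], tmd$calls_H[perm, ],
                              tmd$samples[perm, ], "TMD", tmd$locus_ids)
  merged2 <- merge_marker_systems(msap, tmd_shuffled)
  expect_identical(merged2$calls_M, merged$calls_M)

  s <- sample_meta(msap$samples$sample_id, "Control")
  other <- band_matrix(msap$calls_M[, 1, drop = FALSE] * 0,
                       msap$calls_H[, 1, drop = FALSE] * 0,
                       msap$samples, "TMD", "solo")
  expect_error(merge_marker_systems(msap, other), NA)
  expect_error(
    merge_marker_systems(msap, band_matrix(matrix(1, 2, 1), matrix(1, 2, 1),
                                           sample_meta(c("q1", "q2"), "X"))),
    "sample sets differ")
})

test_that("squared-euclidean distances add over merged marker systems", {
  for (seed in 1:5) {
    a <- random_matrix(6, 8, seed)
    b <- random_matrix(6, 5, seed + 100, marker_system = "TMD")
    da <- band_distance(a)
    db <- band_distance(b)
    dm <- band_distance(merge_marker_systems(a, b))
    expect_equal(unclass(dm), unclass(da) + unclass(db), tolerance = 1e-12)
  }
})

test_that("genalex export writes the conventional header block", {
  m <- toy_matrix()
  f <- tempfile(fileext = ".csv")
  write_genalex(m, f, "treatment_group")
  lines <- readLines(f)
  expect_equal(lines[1], "6,4,2,2,2")  # bands, samples, groups, sizes
  expect_match(lines[2], "Control,A80")
  expect_equal(length(lines), 3 + 4)
})
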