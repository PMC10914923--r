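noiseless <- function() trace_model(noise_sd = 0, crosstalk = 0, amplitude_cv = 0)

test_that("identical seeds give bit-identical traces; different seeds differ", {
  a <- simulate_chromatogram("ACGTACGT", seed = 11)
  b <- simulate_chromatogram("ACGTACGT", seed = 11)
  expect_identical(a$traces, b$traces)
  expect_identical(a$basecalls, b$basecalls)
  c <- simulate_chromatogram("ACGTACGT", seed = 12)
  expect_false(identical(a$traces, c$traces))

  e1 <- simulate_experiment("CATCAT", data.frame(position = 2, fraction = 0.5),
                            n_sample = 2, n_control = 2, seed = 4)
  e2 <- simulate_experiment("CATCAT", data.frame(position = 2, fraction = 0.5),
                            n_sample = 2, n_control = 2, seed = 4)
  expect_identical(e1$sample[[1]]$traces, e2$sample[[1]]$traces)
  # replicates within an experiment differ
  expect_false(identical(e1$sample[[1]]$traces, e1$sample[[2]]$traces))
})

test_that("noiseless unedited and fully edited sites give exact pipeline ratios", {
  ref <- "CATCATCAT"
  cand <- enumerate_candidates(ref, "A_to_G")

  ratio_at <- function(ch) {
    q <- quantify_traces(ch, ref)
    tab <- build_editing_table(q$peaks, q$maps, cand, "sample")
    tab$values[, 1]
  }
  ch0 <- simulate_chromatogram(ref, NULL, model = noiseless(), seed = 1)
  expect_equal(unname(ratio_at(ch0)), c(0, 0, 0), tolerance = 1e-9)

  ch1 <- simulate_chromatogram(ref, data.frame(position = 5, fraction = 1),
                               model = noiseless(), seed = 1)
  r <- ratio_at(ch1)
  expect_equal(unname(r["5"]), 1, tolerance = 1e-9)
  expect_equal(unname(r[c("2", "8")]), c(0, 0), tolerance = 1e-9)
})

test_that("basecalls flag mixed peaks with two-base IUPAC codes above 25% minor fraction", {
  ref <- "CATCATCAT"
  half <- simulate_chromatogram(ref, data.frame(position = 5, fraction = 0.5),
                                model = noiseless(), seed = 1)
  expect_equal(substr(half$basecalls, 5, 5), "R")
  low <- simulate_chromatogram(ref, data.frame(position = 5, fraction = 0.1),
                               model = noiseless(), seed = 1)
  expect_equal(substr(low$basecalls, 5, 5), "A")
  full <- simulate_chromatogram(ref, data.frame(position = 5, fraction = 1),
                                model = noiseless(), seed = 1)
  expect_equal(substr(full$basecalls, 5, 5), "G")
  # C-to-T mode writes the product into the T channel
  ct <- simulate_chromatogram("ACGGA", data.frame(position = 2, fraction = 1),
                              edit_mode = "C_to_T", model = noiseless(), seed = 1)
  expect_equal(substr(ct$basecalls, 2, 2), "T")
})

test_that("edit specifications are validated against the reference", {
  expect_error(simulate_chromatogram("CATCAT",
                                     data.frame(position = 3, fraction = 0.5)),
               class = "sangeredit_value_error")
  expect_error(simulate_chromatogram("CATCAT",
                                     data.frame(position = 2, fraction = 1.5)),
               class = "sangeredit_value_error")
  expect_error(trace_model(crosstalk = 0.5), class = "sangeredit_value_error")
  expect_warning(trace_model(peak_spacing = 5, peak_sd = 3), "overlap")
})

test_that("experiment layout tags samples and controls and controls carry no editing", {
  ex <- simulate_experiment("CATCAT", data.frame(position = 2, fraction = 0.8),
                            n_sample = 3, n_control = 3, seed = 9,
                            model = noiseless())
  expect_length(ex$sample, 3)
  expect_length(ex$control, 3)
  run <- sangeredit:::call_experiment(ex)
  ctl_vals <- run$control_table$values
  expect_true(all(ctl_vals[, ] < 1e-9))
  smp_vals <- run$sample_table$values["2", ]
  expect_true(all(abs(smp_vals - 0.8) < 1e-9))
})

test_that("mean recovered ratio across replicates tracks a 0.5 truth under defaults", {
  ref <- synthetic_reference(6)$reference
  pos <- synthetic_reference(6)$positions
  seeds <- sangeredit:::derive_seeds(2024, 20)
  vals <- vapply(seeds, function(s) {
    ch <- simulate_chromatogram(ref, data.frame(position = pos, fraction = 0.5),
                                seed = s)
    q <- quantify_traces(ch, ref)
    tab <- build_editing_table(q$peaks, q$maps,
                               enumerate_candidates(ref, "A_to_G"), "sample")
    mean(tab$values[as.character(pos), 1])
  }, 0)
  expect_lt(abs(mean(vals) - 0.5), 0.03)
})

test_that("operating characteristics are monotone in the true fraction", {
  oc <- estimate_operating_characteristics(fractions = c(0, 0.1, 0.5, 1),
                                           n_sites = 12, n_runs = 1, seed = 5)
  expect_true(all(diff(oc$call_rate) >= -0.05))   # non-decreasing within MC error
  expect_equal(oc$call_rate[oc$fraction == 1], 1)
  expect_lte(oc$call_rate[oc$fraction == 0], 0.01)
})
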