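test_that("editing ratio follows G/(A+G) and T/(C+T) with a missing rule", {
  expect_equal(editing_ratio(c(A = 100, C = 0, G = 0, T = 0), "A_to_G"), 0)
  expect_equal(editing_ratio(c(A = 0, C = 0, G = 250, T = 0), "A_to_G"), 1)
  expect_equal(editing_ratio(c(A = 300, C = 5, G = 100, T = 7), "A_to_G"), 0.25)
  expect_equal(editing_ratio(c(A = 9, C = 60, G = 3, T = 20), "C_to_T"), 0.25)
  # zero substrate+product sum is missing, not an error
  expect_true(is.na(editing_ratio(c(A = 0, C = 50, G = 0, T = 50), "A_to_G")))
  # configurable signal floor
  expect_true(is.na(editing_ratio(c(A = 30, C = 0, G = 10, T = 0), "A_to_G",
                                  min_total_area = 50)))
  expect_error(editing_ratio(c(A = -1, C = 0, G = 1, T = 0), "A_to_G"),
               class = "sangeredit_value_error")
})

test_that("the two significance criteria reproduce hand-computed worked examples", {
  sample <- make_editing_table(matrix(c(0.30, 0.34, 0.32), 1), "sample")
  control <- make_editing_table(matrix(c(0.02, 0.02, 0.02), 1), "control")
  res <- call_significant_sites(sample, control)
  expect_equal(res$control_mean, 0.02)
  expect_equal(res$raw_mean, 0.32)
  expect_equal(res$corrected_mean, 0.30)
  expect_equal(res$corrected_sd, 0.02)
  expect_equal(res$corrected_mean, res$raw_mean - res$control_mean,
               tolerance = 1e-12)
  expect_true(res$criterion1)   # 0.30 > 3 * 0.02
  expect_true(res$criterion2)   # 0.32 >= 2 * 0.02
  expect_true(res$significant)

  # identical sample and control: corrected mean 0, criterion 1 fails
  same <- make_editing_table(matrix(c(0.1, 0.1, 0.1), 1), "sample")
  res2 <- call_significant_sites(same, make_editing_table(matrix(c(0.1, 0.1, 0.1), 1), "control"))
  expect_false(res2$criterion1)
  expect_false(res2$significant)

  # zero control: criterion 2 needs only raw_mean > 0, but 3xSD still guards
  noisy <- make_editing_table(matrix(c(0.05, 0.08, 0.02), 1), "sample")
  zero <- make_editing_table(matrix(c(0, 0, 0), 1), "control")
  res3 <- call_significant_sites(noisy, zero)
  expect_equal(res3$corrected_sd, 0.03)
  expect_true(res3$criterion2)
  expect_false(res3$criterion1)  # 0.05 < 0.09
  expect_false(res3$significant)
})

test_that("calls match a brute-force reimplementation on randomized tables", {
  set.seed(101)
  for (i in 1:200) {
    n_sites <- sample(1:10, 1)
    ns <- sample(3:5, 1); nc <- sample(1:5, 1)
    tabs <- list(sample = matrix(runif(n_sites * ns), n_sites, ns),
                 control = matrix(runif(n_sites * nc) * 0.2, n_sites, nc))
    tabs$sample[runif(length(tabs$sample)) < 0.1] <- NA
    tabs$control[runif(length(tabs$control)) < 0.1] <- NA
    res <- call_significant_sites(make_editing_table(tabs$sample, "sample"),
                                  make_editing_table(tabs$control, "control"))
    orc <- oracle_call_sites(tabs$sample, tabs$control)
    expect_identical(res$evaluable, orc$evaluable)
    expect_equal(res$corrected_mean, orc$corrected_mean, tolerance = 1e-12)
    expect_equal(res$corrected_sd, orc$corrected_sd, tolerance = 1e-12)
    expect_identical(res$significant, orc$significant)
  }
})

test_that("raising all sample replicates by a constant never loses significance", {
  set.seed(7)
  for (i in 1:50) {
    s <- matrix(runif(12, 0, 0.6), 3, 4)
    ctl <- matrix(runif(12, 0, 0.1), 3, 4)
    res0 <- call_significant_sites(make_editing_table(s, "sample"),
                                   make_editing_table(ctl, "control"))
    delta <- runif(1, 0.01, 0.3)
    res1 <- call_significant_sites(make_editing_table(pmin(s + delta, 1), "sample"),
                                   make_editing_table(ctl, "control"))
    sig0 <- which(res0$significant %in% TRUE)
    # shifting up preserves criterion 1 (same SD, larger mean) and criterion 2
    expect_true(all(res1$significant[sig0]),
                info = sprintf("iter %d delta %.3f", i, delta))
  }
})

test_that("site coverage gaps become missing cells and respect min_replicates", {
  ref <- "CATCATCAT"
  cand <- enumerate_candidates(ref, "A_to_G")
  chroms <- lapply(1:3, function(i)
    simulate_chromatogram(ref, data.frame(position = 5, fraction = 0.3),
                          model = trace_model(noise_sd = 0, amplitude_cv = 0),
                          seed = i))
  q <- quantify_traces(chroms, ref)
  # drop coverage of site 8 in replicate 2 by truncating its map
  q$maps[[2]] <- q$maps[[2]][q$maps[[2]]$ref_position < 8, ]
  tab <- build_editing_table(q$peaks, q$maps, cand, "sample")
  expect_true(is.na(tab$values["8", 2]))
  expect_false(anyNA(tab$values["8", c(1, 3)]))
  expect_false(anyNA(tab$values["5", ]))

  ctl_tab <- build_editing_table(q$peaks, q$maps, cand, "control")
  res <- call_significant_sites(tab, ctl_tab, min_replicates = 3)
  expect_false(res$evaluable[res$ref_position == 8])
  expect_true(res$evaluable[res$ref_position == 5])
})

test_that("run summaries count evaluable and significant sites with tie-break by position", {
  empty <- call_significant_sites(make_editing_table(matrix(numeric(), 0, 3), "sample"),
                                  make_editing_table(matrix(numeric(), 0, 3), "control"))
  s0 <- summarize_run(empty)
  expect_equal(s0$n_sites, 0)
  expect_equal(s0$n_significant, 0)

  vals <- matrix(c(0.5, 0.5, 0.5,   # site 1
                   0.02, 0.02, 0.02,
                   0.5, 0.5, 0.5), 3, 3, byrow = TRUE)
  ctl <- matrix(0.01, 3, 3)
  res <- call_significant_sites(make_editing_table(vals, "sample"),
                                make_editing_table(ctl, "control"))
  s <- summarize_run(res)
  expect_equal(s$n_evaluable, 3)
  expect_equal(s$max_corrected_mean, 0.49)
  expect_equal(s$max_position, 1)   # tie with site 3 broken by position
})

test_that("mismatched site lists or edit modes are errors", {
  a <- make_editing_table(matrix(0.1, 2, 3), "sample")
  b <- make_editing_table(matrix(0.1, 3, 3), "control")
  expect_error(call_significant_sites(a, b), class = "sangeredit_content_error")
  d <- make_editing_table(matrix(0.1, 2, 3), "control", edit_mode = "C_to_T")
  expect_error(call_significant_sites(a, d), class = "sangeredit_content_error")
})
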