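test_that("AB1 write/read round-trips a synthetic chromatogram", {
  ch <- simulate_chromatogram("ACGTACGTAC", seed = 5)
  f <- withr::local_tempfile(fileext = ".ab1")
  write_ab1(ch, f)
  back <- read_ab1(f)
  expect_identical(back$basecalls, ch$basecalls)
  expect_identical(back$peak_locations, ch$peak_locations)
  # traces are stored as rounded int16
  expect_equal(back$traces, round(ch$traces), ignore_attr = TRUE)
})

test_that("AB1 reader rejects non-ABIF input and names missing records", {
  f <- withr::local_tempfile(fileext = ".ab1")
  file.create(f)
  expect_error(read_ab1(f), class = "sangeredit_format_error")
  writeBin(charToRaw("not an abif file at all, just text padding......................................................................."), f)
  expect_error(read_ab1(f), class = "sangeredit_format_error")
})

test_that("stored channel order is inverted on read: A channel holds A signal", {
  # single strong A peak; write with a non-standard dye order
  ch <- simulate_chromatogram("CAT", model = trace_model(noise_sd = 0, crosstalk = 0,
                                                         amplitude_cv = 0),
                              seed = 1)
  for (ord in list(c("G", "A", "T", "C"), c("T", "C", "G", "A"))) {
    f <- withr::local_tempfile(fileext = ".ab1")
    write_ab1(ch, f, channel_order = ord)
    back <- read_ab1(f)
    a_peak <- back$peak_locations[2] + 1
    expect_equal(which.max(back$traces[a_peak, ]),
                 which(colnames(back$traces) == "A"), ignore_attr = TRUE)
    expect_equal(back$traces, round(ch$traces), ignore_attr = TRUE)
  }
})

test_that("peak tables parse with delimiter sniffing and schema checks", {
  df <- data.frame(position = c(2, 5, 8), base = c("A", "A", "A"),
                   area_A = c(900, 500, 100), area_C = 0,
                   area_G = c(100, 500, 900), area_T = 0)
  for (sep in c(",", "\t", ";")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write.table(df, f, sep = sep, row.names = FALSE, quote = FALSE)
    tab <- read_peak_table(f)
    expect_s3_class(tab, "peak_quant_table")
    expect_equal(nrow(tab), 3)
    expect_equal(tab$area_G, df$area_G)
  }

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "area_G")], f, row.names = FALSE)
  expect_error(read_peak_table(f), class = "sangeredit_schema_error")

  df_bad <- df; df_bad$area_A[2] <- -1
  write.csv(df_bad, f, row.names = FALSE)
  expect_error(read_peak_table(f), "row 2", class = "sangeredit_value_error")
})

test_that("workbook-style worksheets import via column remapping and ratio layout", {
  # differently headed worksheet re-saved as CSV
  df <- data.frame(Pos = c(1, 4), Base = c("A", "A"),
                   A = c(800, 400), C = c(1, 2), G = c(200, 600), T = c(0, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  tab <- read_peak_table(f, columns = c(position = "Pos", base = "Base",
                                        area_A = "A", area_C = "C",
                                        area_G = "G", area_T = "T"))
  expect_equal(tab$area_A, df$A)
  expect_equal(tab$area_G, df$G)

  # precomputed-ratio worksheet
  rf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(position = c(1, 4), base = "A", editing = c(0.2, 0.6)),
            rf, row.names = FALSE)
  rtab <- read_peak_table(rf)
  expect_s3_class(rtab, "editing_ratio_table")
  expect_equal(rtab$editing, c(0.2, 0.6))
})

test_that("FASTA references are uppercased and selectable by id", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">amp1 first", "acgt", ">amp2", "GGAATT"), f)
  expect_equal(as.character(read_reference(f)), "ACGT")
  r2 <- read_reference(f, id = "amp2")
  expect_equal(as.character(r2), "GGAATT")
  expect_equal(attr(r2, "id"), "amp2")
  expect_error(read_reference(f, id = "nope"), class = "sangeredit_content_error")
  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_reference(empty), class = "sangeredit_format_error")
})

test_that("results TSV round-trips numeric fields at 6 significant digits", {
  tabs <- random_editing_tables(5, 3)
  res <- call_significant_sites(make_editing_table(tabs$sample, "sample"),
                                make_editing_table(tabs$control, "control"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, f)
  back <- read_results(f)
  expect_equal(back$ref_position, res$ref_position)
  for (cc in c("raw_mean", "control_mean", "corrected_mean", "corrected_sd"))
    expect_equal(back[[cc]], signif(res[[cc]], 6))
  expect_identical(back$significant, res$significant)

  # empty collection -> header-only file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(res[0, ], f2)
  expect_equal(nrow(read_results(f2)), 0)
})

test_that("band tables validate treatments and convert mass to molar scale", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(lane_id = "L1", treatment = c("digested", "digested"),
                       length_nt = c(400, 300), quantity = c(40, 30),
                       unit = c("molar", "mass")), f, row.names = FALSE)
  bt <- read_band_table(f)
  expect_equal(bt$quantity, c(40, 30 / 300))

  write.csv(data.frame(lane_id = "L1", treatment = "boiled",
                       length_nt = 400, quantity = 1), f, row.names = FALSE)
  expect_error(read_band_table(f), class = "sangeredit_value_error")
})
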