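test_that("GPR parsing extracts spots, median background, and honors flags", {
  f <- withr::local_tempfile(fileext = ".gpr")
  write_minimal_gpr(f, '"P1"\t"ACDEF"\t100\t10\t0')
  s <- read_gpr(f)
  expect_equal(nrow(s), 1L)
  expect_equal(s$spot_id, "P1")
  expect_equal(s$sequence, "ACDEF")
  expect_equal(s$foreground, 100)
  expect_equal(attr(s, "median_background"), 10)

  # 12 rows (4 peptides x 3 replicates), backgrounds 1..12
  rows <- sprintf('"P%d_r%d"\t"SEQ%d"\t%d\t%d\t0',
                  rep(1:4, each = 3), rep(1:3, 4), rep(1:4, each = 3),
                  100 + 1:12, 1:12)
  write_minimal_gpr(f, rows)
  s <- read_gpr(f)
  expect_equal(nrow(s), 12L)
  expect_equal(attr(s, "median_background"), mean(sort(1:12)[6:7]))  # 6.5

  # flagged spot dropped when exclude_flagged = TRUE, kept otherwise
  rows <- c('"P1"\t"AAA"\t100\t10\t0', '"P2"\t"CCC"\t100\t10\t-100')
  write_minimal_gpr(f, rows)
  expect_message(s <- read_gpr(f, exclude_flagged = TRUE), "1 flagged")
  expect_false("P2" %in% s$spot_id)
  s2 <- read_gpr(f, exclude_flagged = FALSE)
  expect_true("P2" %in% s2$spot_id)
})

test_that("GPR format and parse errors name the offending column and line", {
  f <- withr::local_tempfile(fileext = ".gpr")
  write_minimal_gpr(f, '"P1"\t"AAA"\t100\t10\t0',
                    cols = c("ID", "Name", "F635 Median", "BadName", "Flags"))
  expect_error(read_gpr(f), "B635 Median", class = "immunosig_format_error")

  write_minimal_gpr(f, c('"P1"\t"AAA"\t100\t10\t0',
                         '"P2"\t"CCC"\txyz\t10\t0'))
  err <- expect_error(read_gpr(f), class = "immunosig_parse_error")
  expect_match(conditionMessage(err), "F635 Median")
  expect_match(conditionMessage(err), "line 7")  # 5 header lines + header row + 2nd data row

  writeLines(c("not ATF", "1\t2"), f)
  expect_error(read_gpr(f), "ATF", class = "immunosig_format_error")
})

test_that("spot CSV parsing handles headers, order, and duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("P1,ACDEF,100,10", f)
  s <- read_spot_csv(f)
  expect_equal(s$foreground, 100)
  expect_equal(s$spot_id, "P1")

  writeLines(c("P1,AAA,100,5", "P2,CCC,200,15", "P3,GGG,300,10"), f)
  expect_equal(attr(read_spot_csv(f), "median_background"), 10)

  # header auto-detection: same result with and without a header row
  writeLines(c("ID,Sequence,FG,BG", "P1,AAA,100,5", "P2,CCC,200,15"), f)
  with_header <- read_spot_csv(f)
  writeLines(c("P1,AAA,100,5", "P2,CCC,200,15"), f)
  without_header <- read_spot_csv(f)
  expect_equal(tibble::as_tibble(with_header), tibble::as_tibble(without_header))

  writeLines(c("P1,AAA,100"), f)
  expect_error(read_spot_csv(f), "at least 4", class = "immunosig_format_error")

  writeLines(c("P1,AAA,100,5", "P1,CCC,200,15"), f)
  expect_error(read_spot_csv(f), "P1", class = "immunosig_validation_error")
})

test_that("parsing preserves file row order and median background is permutation-invariant", {
  f <- withr::local_tempfile(fileext = ".csv")
  ids <- sprintf("P%02d", 1:9)
  bg <- c(9, 1, 7, 3, 5, 8, 2, 6, 4)
  set.seed(42)
  perm <- sample(9)
  writeLines(sprintf("%s,AAA,%d,%d", ids, 100 + 1:9, bg), f)
  s1 <- read_spot_csv(f)
  writeLines(sprintf("%s,AAA,%d,%d", ids[perm], (100 + 1:9)[perm], bg[perm]), f)
  s2 <- read_spot_csv(f)
  expect_equal(s1$spot_id, ids)             # order preserved
  expect_equal(s2$spot_id, ids[perm])
  expect_equal(attr(s1, "median_background"), attr(s2, "median_background"))
})

test_that("empty sequence cells fall back to the spot ID", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("P1,,100,5", "P2,CCC,200,15"), f)
  s <- read_spot_csv(f)
  expect_equal(s$sequence, c("P1", "CCC"))
})

test_that("targeting files enforce contiguity and single-protein rules", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pathogen,protein,start,end,spot_id",
               "v,spike,1,15,P1", "v,spike,5,19,P2", "v,spike,9,23,P3"), f)
  tt <- read_targeting(f, require_contiguous = TRUE)
  expect_equal(nrow(tt), 3L)
  expect_s3_class(tt, "targeting_table")

  writeLines(c("pathogen,protein,start,end,spot_id",
               "v,spike,1,15,P1", "v,spike,30,44,P2"), f)
  err <- expect_error(read_targeting(f, require_contiguous = TRUE),
                      class = "immunosig_validation_error")
  expect_match(conditionMessage(err), "16\\.\\.29")
  # arbitrary peptide collections are fine for strip plots
  expect_equal(nrow(read_targeting(f, require_contiguous = FALSE)), 2L)

  writeLines(c("pathogen,protein,start,end,spot_id",
               "v,spike,1,15,P1", "v,nucleoprotein,5,19,P2"), f)
  expect_error(read_targeting(f, require_contiguous = TRUE),
               "single protein", class = "immunosig_validation_error")

  writeLines(c("pathogen,protein,start,end,spot_id", "v,spike,10,5,P1"), f)
  expect_error(read_targeting(f), "start <= end",
               class = "immunosig_validation_error")

  writeLines(c("pathogen,protein,first,end,spot_id", "v,spike,1,15,P1"), f)
  expect_error(read_targeting(f), "start", class = "immunosig_format_error")
})

test_that("synoptic CSV layout and round trip are exact", {
  vals <- matrix(c(1.5, 2.25, 3.125, 10.1, 20.2, 30.3,
                   1.1, 2.2, 3.3, 9.9, 19.8, 29.7), nrow = 3)
  mat <- toy_matrix(vals, c("control", "control", "treatment", "treatment"))
  tab <- build_synoptic_table(mat)
  f <- withr::local_tempfile(fileext = ".csv")
  write_synoptic_csv(tab, f)

  raw <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(raw), 3L)
  expect_equal(names(raw)[1:2], c("Spot_ID", "Sequence"))
  # exactly 4 per-sample columns between Sequence and Control_Mean
  expect_equal(which(names(raw) == "Control_Mean") -
                 which(names(raw) == "Sequence") - 1L, 4L)
  expect_equal(names(raw)[(ncol(raw) - 6):ncol(raw)],
               c("Control_Mean", "Control_Variance", "Treatment_Mean",
                 "Treatment_Variance", "Delta_RFU", "P_Raw", "P_Adjusted"))

  back <- read_synoptic_csv(f)
  num <- vapply(tibble::as_tibble(tab), is.numeric, TRUE)
  for (cn in names(tab)[num]) {
    expect_equal(back[[cn]], tab[[cn]], tolerance = 1e-9)
  }
  expect_equal(attr(back, "samples"), attr(tab, "samples"))

  # single-peptide table: one header + one data row (single-sample cohorts
  # have undefined variance, written as NA)
  one <- suppressWarnings(
    build_synoptic_table(toy_matrix(matrix(c(1, 2), nrow = 1),
                                    c("control", "treatment"))))
  write_synoptic_csv(one, f)
  expect_length(readLines(f), 2L)
})
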