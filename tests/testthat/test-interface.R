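test_that("the packaged qPCR layout reproduces the published rank sums", {
  rs <- qpcr_rank_sums()
  expect_equal(unname(rs),
               c(7, 10, 10, 17, 18, 22, 32, 34, 36, 38, 40),
               ignore_attr = TRUE)
  # the synthetic 4 x 11 rank layout was constructed to share those rank sums
  path <- system.file("extdata", "qpcr_ranks_synthetic.csv", package = "frsd")
  m <- read_rank_table(path)
  expect_equal(dim(m), c(4, 11))
  expect_equal(unname(colSums(m)), unname(rs), ignore_attr = TRUE)
})

test_that("orientation transpose is an involution", {
  path <- system.file("extdata", "qpcr_ranks_synthetic.csv", package = "frsd")
  m <- read_rank_table(path)
  tmp <- withr::local_tempfile(fileext = ".csv")
  tdf <- data.frame(method = colnames(m), t(m), check.names = FALSE)
  readr::write_csv(tdf, tmp)
  m2 <- read_rank_table(tmp, orientation = "groups-rows")
  expect_equal(unname(m2), unname(m))
  expect_equal(colnames(m2), colnames(m))
})

test_that("a missing cell in complete mode is an error naming the cell", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("block,A,B,C", "b1,1,2,3", "b2,2,,3"), tmp)
  expect_error(read_rank_table(tmp), "b2.*B|B.*b2")
  m <- read_rank_table(tmp, allow_missing = TRUE)
  expect_equal(sum(is.na(m)), 1)
})

test_that("non-numeric cells and duplicate labels are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("block,A,B", "b1,1,x", "b2,2,1"), tmp)
  expect_error(read_rank_table(tmp), "non-numeric")
  writeLines(c("block,A,B", "b1,1,2", "b1,2,1"), tmp)
  expect_error(read_rank_table(tmp), "duplicate")
})

test_that("the incomplete-design fixture is a valid midrank layout", {
  z <- zagar_ranks()
  expect_equal(dim(z), c(10, 12))
  expect_equal(sum(is.na(z)), 2)
  complete <- rowSums(is.na(z)) == 0
  expect_equal(sum(complete), 9)
  expect_true(all(rowSums(z[complete, ]) == 12 * 13 / 2))
  expect_equal(sum(z[!complete, ], na.rm = TRUE), 10 * 11 / 2)
})

test_that("cli pvalue and cd subcommands emit the documented records", {
  out <- capture.output(status <- frsd_cli(c("pvalue", "--k", "5", "--n", "5",
                                             "--d", "11")))
  expect_identical(status, 0L)
  expect_match(paste(out, collapse = "\n"), "0.0326")
  out <- capture.output(status <- frsd_cli(c("cd", "--k", "5", "--n", "5",
                                             "--alpha", "0.05",
                                             "--mode", "all-pairs",
                                             "--method", "exact")))
  expect_identical(status, 0L)
  expect_match(out[2], "\t14$")
  # deterministic subcommands are byte-identical across runs
  out2 <- capture.output(frsd_cli(c("cd", "--k", "5", "--n", "5",
                                    "--alpha", "0.05", "--mode", "all-pairs",
                                    "--method", "exact")))
  expect_identical(out, out2)
})

test_that("cli parts subcommand reproduces the incomplete-design p-value", {
  out <- capture.output(status <- frsd_cli(c("parts", "--d", "46",
                                             "--part", "12:9",
                                             "--part", "10:1", "--json")))
  expect_identical(status, 0L)
  rec <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(round(rec$p, 3), 0.003)
  # exact rational carried alongside
  expect_equal(frsd:::big_ratio(rec$p_num, rec$den), rec$p)
})

test_that("cli compare runs end to end on a file", {
  path <- system.file("extdata", "qpcr_ranks_synthetic.csv", package = "frsd")
  out <- capture.output(status <- frsd_cli(c("compare", path)))
  expect_identical(status, 0L)
  expect_equal(length(out), 1 + choose(11, 2))  # header + 55 pairs
})

test_that("cli reports usage and domain errors with distinct exit codes", {
  expect_message(status <- frsd_cli(c("pvalue", "--bogus", "1")), "unknown")
  expect_identical(status, 2L)
  expect_message(status <- frsd_cli(c("nope")), "unknown subcommand")
  expect_identical(status, 2L)
  expect_message(status <- frsd_cli(c("pvalue", "--k", "1", "--n", "5",
                                      "--d", "0")))
  expect_identical(status, 3L)
})
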