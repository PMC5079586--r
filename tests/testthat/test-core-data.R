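test_that("reader keeps valid rows, rejects invalid ones with reasons", {
  f <- write_records_csv(data.frame(year = 2012, source = "obs",
                                    tl_cm = c(46.8, 65.3, 79.0)))
  rd <- read_length_records(f)
  expect_equal(rd$report$n_read, 3L)
  expect_equal(rd$report$n_rejected, 0L)
  expect_equal(rd$data$tl_cm, c(46.8, 65.3, 79.0))

  f2 <- write_records_csv(data.frame(year = 2012, source = "obs",
                                     tl_cm = c(50, -5, 60)))
  rd2 <- read_length_records(f2)
  expect_equal(rd2$report$n_kept, 2L)
  expect_named(rd2$report$reasons, "nonpositive length")
  expect_equal(rd2$data$tl_cm, c(50, 60))

  # 10-row file with 2 malformed numeric cells
  tl <- as.character(c(40, 45, "bad", 55, 60, "x1.2", 70, 75, 80, 85))
  f3 <- write_records_csv(data.frame(year = 2001:2010, source = "s", tl_cm = tl))
  rd3 <- read_length_records(f3)
  expect_equal(rd3$report$n_kept, 8L)
  expect_equal(rd3$report$n_rejected, 2L)
  expect_equal(rd3$report$n_read, rd3$report$n_kept + rd3$report$n_rejected)
})

test_that("reader enforces the length cap and the year window", {
  f <- write_records_csv(data.frame(year = c(2012, 2012, 1850),
                                    source = "s", tl_cm = c(50, 250, 60)))
  rd <- read_length_records(f)
  expect_equal(rd$report$n_kept, 1L)
  expect_setequal(names(rd$report$reasons),
                  c("length above cap (200 cm)", "year outside [1900, 2100]"))
  # cap is configurable
  rd2 <- read_length_records(f, max_tl = 300)
  expect_equal(rd2$report$n_kept, 2L)
})

test_that("missing file and missing mapped column are fatal", {
  expect_error(read_length_records(tempfile()), "not found")
  f <- write_records_csv(data.frame(year = 2012, source = "s", length = 50))
  expect_error(read_length_records(f), "tl_cm")
  rd <- read_length_records(f, column_map = c(year = "year", source = "source",
                                              tl_cm = "length"))
  expect_equal(rd$data$tl_cm, 50)
})

test_that("write/read round-trip preserves records to full precision", {
  ds <- length_dataset(c(2001, 2001, 2003), c("a", "b", "a"),
                       c(46.8123456789, 65.3, 110.000001))
  f <- tempfile(fileext = ".csv")
  write_length_records(ds, f)
  back <- read_length_records(f)$data
  expect_equal(back$year, ds$year)
  expect_equal(back$source, ds$source)
  expect_equal(back$tl_cm, ds$tl_cm)
})

test_that("per-year summary uses n-1 sd and marks single-fish years undefined", {
  ds <- length_dataset(c(2000, 2000, 2001), "s", c(40, 60, 50))
  sm <- summarize_by_year(ds)
  expect_equal(sm$n, c(2L, 1L))
  expect_equal(sm$mean_tl, c(50, 50))
  expect_equal(sm$sd_tl[1], sqrt(200))     # 14.1421: n-1 denominator
  expect_true(is.na(sm$sd_tl[2]))
  expect_equal(sum(sm$n), nrow(ds))
  expect_warning(summarize_by_year(length_dataset(integer(), character(),
                                                  numeric())), "empty")
})

test_that("historical photo fixture reproduces its published mean and sd", {
  rd <- read_length_records(photo_lengths_path())
  expect_equal(rd$report$n_kept, 25L)
  expect_equal(round(mean(rd$data$tl_cm), 1), 76.6)
  expect_equal(round(sd(rd$data$tl_cm), 1), 15.5)
})

test_that("life history derives the missing mortality/growth parameter", {
  lh <- life_history(l_inf = 110, lm50 = 65.3, m_nat = 0.29, m_over_k = 2.7)
  expect_equal(lh$k_growth, 0.29 / 2.7)
  lh2 <- life_history(l_inf = 110, lm50 = 65.3, m_nat = 0.29,
                      k_growth = 0.29 / 2.7)
  expect_equal(lh2$m_over_k, 2.7)
  expect_error(life_history(l_inf = 110, lm50 = 65.3, m_nat = 0.29,
                            k_growth = 0.1, m_over_k = 2.7), "inconsistent")
  expect_error(life_history(l_inf = 110, lm50 = 70, lm95 = 65, m_nat = 0.29,
                            m_over_k = 2.7), "lm50")
  expect_error(life_history(l_inf = 110, lm50 = 65.3, m_nat = 0.29),
               "at least two")
})

test_that("config reader resolves life history and defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("l_inf: 110", "lm50: 65.3", "m_nat: 0.29", "m_over_k: 2.7",
               "am: 6.5", "tmax: 21", "bin_width: 1", "seed: 7"), f)
  cfg <- read_assessment_config(f)
  expect_s3_class(cfg$life_history, "life_history")
  expect_equal(cfg$life_history$k_growth, 0.29 / 2.7)
  expect_equal(cfg$options$bin_width, 1)
  expect_equal(cfg$options$seed, 7)
  expect_equal(cfg$options$n_gtg, 13)  # default filled in
})
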