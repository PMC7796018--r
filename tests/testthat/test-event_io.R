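test_that("CASAS dialect lines parse field-by-field", {
  p <- withr::local_tempfile(lines = c(
    "2010-11-04 05:40:51 M004 ON Bed_to_Toilet begin",
    "2010-11-04 05:40:57 M005 ON",
    "2010-11-04 05:43:24 M004 ON Bed_to_Toilet end"))
  log <- read_casas_log(p)
  expect_s3_class(log, "event_log")
  expect_equal(nrow(log), 3)
  expect_equal(log$sensor, c("M004", "M005", "M004"))
  expect_equal(log$value, rep("ON", 3))
  expect_equal(log$activity, c("Bed_to_Toilet", NA, "Bed_to_Toilet"))
  expect_equal(log$marker, c("begin", NA, "end"))
  expect_equal(format(log$time[1], "%H:%M:%S", tz = "UTC"), "05:40:51")
})

test_that("malformed lines and files are rejected with positions", {
  p <- withr::local_tempfile(lines = c(
    "2010-11-04 05:40:51 M004 ON",
    "2010-11-04 garbage"))
  expect_error(read_casas_log(p), "line 2")
  expect_error(read_casas_log(file.path(tempdir(), "nope.txt")), "no such file")
  p2 <- withr::local_tempfile(lines = "2010-11-04 05:40:51 M004 ON Eating soon")
  expect_error(read_casas_log(p2), "marker")
})

test_that("empty file reads to an empty log and writes back empty", {
  p <- withr::local_tempfile(lines = character())
  log <- read_casas_log(p)
  expect_equal(nrow(log), 0)
  p2 <- withr::local_tempfile()
  write_casas_log(log, p2)
  expect_equal(nrow(read_casas_log(p2)), 0)
})

test_that("write/read round-trip preserves every field on a synthetic log", {
  log <- generate_days(tiny_model(), 3, seed = 11)
  p <- withr::local_tempfile()
  write_casas_log(log, p)
  back <- read_casas_log(p)
  expect_equal(as.data.frame(back), as.data.frame(log))
})

test_that("out-of-order timestamps warn and stable-sort, or error in strict mode", {
  p <- withr::local_tempfile(lines = c(
    "2010-11-04 06:00:00 M001 ON",
    "2010-11-04 05:00:00 M002 ON",
    "2010-11-04 05:00:00 M003 ON"))
  expect_warning(log <- read_casas_log(p), "stable sort")
  expect_equal(log$sensor, c("M002", "M003", "M001"))  # stable within ties
  expect_error(read_casas_log(p, strict = TRUE), "out-of-order")
})

test_that("annotate_activities pairs markers, including interleaved names", {
  mk <- function(s, sensor, act = NA, m = NA) {
    sprintf("2021-01-01 00:00:%02d %s ON%s", s, sensor,
            ifelse(is.na(act), "", paste0(" ", act, " ", m)))
  }
  p <- withr::local_tempfile(lines = c(
    mk(1, "M001", "Sleeping", "begin"),
    mk(5, "M004", "Bed_to_Toilet", "begin"),
    mk(8, "M004", "Bed_to_Toilet", "end"),
    mk(20, "M002", "Sleeping", "end")))
  inst <- annotate_activities(read_casas_log(p))
  expect_equal(nrow(inst), 2)
  expect_equal(inst$activity, c("Sleeping", "Bed_to_Toilet"))
  expect_equal(inst$start_idx, c(1L, 2L))
  expect_equal(inst$end_idx, c(4L, 3L))

  # instance count equals the number of matched begin markers
  log <- generate_days(tiny_model(), 2, seed = 3)
  inst2 <- annotate_activities(log)
  expect_equal(nrow(inst2), sum(log$marker == "begin", na.rm = TRUE))

  expect_equal(nrow(annotate_activities(event_log())), 0)
})

test_that("orphan markers are reported", {
  p <- withr::local_tempfile(lines = c(
    "2021-01-01 00:00:01 M001 ON Sleeping begin",
    "2021-01-01 00:00:02 M001 ON"))
  expect_error(annotate_activities(read_casas_log(p)), "begin.*Sleeping")
})

test_that("registry validates, normalises and indexes sensors", {
  expect_equal(length(default_registry()), 34)
  expect_equal(canonical_sensor(c("M3", "m026", "D1")), c("M003", "M026", "D001"))
  expect_equal(sensor_index(REG, c("M7", "D1")), c(7L, 32L))
  expect_error(sensor_registry(c("M1", "M001")), "duplicate")
  expect_error(sensor_index(REG, "M99"), "not in registry")
})
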