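log20 <- generate_days(default_aruba_model(), 4, seed = 21)

test_that("n = 0 leaves the log untouched for both generators", {
  for (f in list(inject_activity_anomalies, inject_subactivity_anomalies)) {
    r <- f(log20, n = 0)
    expect_identical(as.data.frame(r$log), as.data.frame(log20))
    expect_length(r$records, 0)
  }
})

test_that("activity injection conserves events and keeps originals a subsequence", {
  inj <- inject_activity_anomalies(log20, n = 7, seed = 4)
  expect_length(inj$records, 7)
  expect_true(all(vapply(inj$records, function(r) r$kind, "") == "activity"))
  expect_equal(nrow(inj$log), nrow(log20) + n_inserted(inj$records))
  expect_false(is.unsorted(inj$log$time))
  expect_true(is_subsequence_log(log20, inj$log))
  # determinism per seed
  inj2 <- inject_activity_anomalies(log20, n = 7, seed = 4)
  expect_identical(as.data.frame(inj$log), as.data.frame(inj2$log))
})

test_that("sleep-context insertions land strictly inside a sleeping span", {
  inj <- inject_activity_anomalies(
    log20, insert_activities = "Eating_Night", n = 3, seed = 8)
  sleeps <- annotate_activities(log20)
  sleeps <- sleeps[sleeps$activity == "Sleeping", ]
  for (r in inj$records) {
    expect_equal(r$activity, "Eating")
    inside <- any(r$span_start >= sleeps$start & r$span_end <= sleeps$end)
    expect_true(inside)
    # the inserted block is annotated as the donor activity in the output
    expect_true(any(inj$log$activity[r$event_idx] == "Eating", na.rm = TRUE))
  }
})

test_that("activity injection validates names and capacity", {
  expect_error(inject_activity_anomalies(log20, insert_activities = "Flying",
                                         contexts = c(Flying = "day"), n = 1),
               "Flying")
  one <- log20[event_activities(log20) %in% "Work", ]
  one <- raetrace:::as_event_log(one)
  expect_error(inject_activity_anomalies(
    one, insert_activities = "Work",
    contexts = c(Work = "day"), n = 1), "slot")
})

test_that("sub-activity injection repeats the mapped sensor in place", {
  inj <- inject_subactivity_anomalies(log20, n = 10, min_rep = 3,
                                      max_rep = 3, seed = 5)
  expect_length(inj$records, 10)
  expect_equal(nrow(inj$log), nrow(log20) + 30)  # 10 instances x 3 insertions
  expect_true(is_subsequence_log(log20, inj$log))
  map <- default_subactivity_map()
  for (r in inj$records) {
    expect_equal(r$kind, "subactivity")
    expect_true(r$sensor %in% map)
    expect_equal(unique(inj$log$sensor[r$event_idx]), r$sensor)
  }
  # removing the inserted indices recovers the original log exactly
  rm_idx <- unlist(lapply(inj$records, `[[`, "event_idx"))
  rest <- as.data.frame(inj$log)[-rm_idx, ]
  rownames(rest) <- NULL
  expect_equal(rest, as.data.frame(log20))
})

test_that("sub-activity injection errors on absent targets and over-capacity", {
  expect_error(inject_subactivity_anomalies(log20, sensor_map = c(Flying = "M001"),
                                            n = 1), "Flying")
  expect_error(inject_subactivity_anomalies(log20, n = 10000), "exceeds")
})

test_that("window ground truth flags exactly the windows holding injections", {
  inj <- inject_subactivity_anomalies(log20, n = 5, seed = 2)
  ch <- segment_windows(inj$log)
  truth <- windows_truth(ch, inj$records)
  times <- do.call(c, lapply(inj$records, `[[`, "times"))
  manual <- vapply(seq_len(nrow(ch)), function(i) {
    any(times >= ch$start[i] & times < ch$end[i])
  }, TRUE)
  expect_equal(truth, manual)
  expect_gt(sum(truth), 0)
})

test_that("truth files are valid JSON with one entry per record", {
  inj <- inject_subactivity_anomalies(log20, n = 3, seed = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_truth(inj$records, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(nrow(back), 3)
  expect_true(all(back$kind == "subactivity"))
})
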