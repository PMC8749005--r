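test_that("long sessions are exactly balanced at 78 trials per condition", {
  sched <- generate_schedule(task_config("long", seed = 7))
  tab <- table(sched$condition)
  expect_equal(unname(tab[["1back"]]), 78)
  expect_equal(unname(tab[["2back"]]), 78)
  # balance holds per run-pair by the alternating assignment
  expect_equal(unname(diff(table(sched$condition))), 0)
})

test_that("run durations follow from the configured components", {
  expect_equal(run_duration(task_config("short")), 3 + 60 + 25 + 60 + 7)
  expect_equal(run_duration(task_config("short")), 155)
  # long components sum to 253 s; the duration is derived, never forced
  expect_equal(run_duration(task_config("long")), 3 + 3 * 60 + 2 * 30 + 10)
})

test_that("zero runs give an empty schedule", {
  sched <- generate_schedule(task_config("long", n_runs = 0))
  expect_equal(nrow(sched), 0)
  expect_length(attr(sched, "run_duration_s"), 0)
})

test_that("ITIs stay inside the configured range and onsets increase", {
  itis <- numeric(0)
  for (s in 1:70) {
    sched <- generate_schedule(task_config("long", seed = s))
    for (r in unique(sched$run)) {
      run <- sched[sched$run == r, ]
      expect_true(all(diff(run$onset) > 0))
      blk <- split(run, run$block)
      itis <- c(itis, unlist(lapply(blk, function(b) {
        diff(b$onset) - b$duration[1]
      })))
    }
  }
  expect_gt(length(itis), 10000)
  expect_gte(min(itis), 1.5 - 1e-9)
  expect_lte(max(itis), 10 + 1e-9)
})

test_that("target placement respects n-back legality", {
  sched <- generate_schedule(task_config("long", seed = 11))
  for (key in unique(paste(sched$run, sched$block))) {
    blk <- sched[paste(sched$run, sched$block) == key, ]
    nback <- as.integer(substr(blk$condition[1], 1, 1))
    pos <- which(blk$is_target)
    expect_true(length(pos) >= 2 && length(pos) <= 4)
    expect_true(all(pos > nback))
    if (length(pos) > 1) expect_true(all(diff(pos) > 1))
    # a target repeats the stimulus shown n trials back
    expect_equal(blk$stimulus_id[pos], blk$stimulus_id[pos - nback])
  }
})

test_that("seeded generation is reproducible and event files byte-identical", {
  a <- generate_schedule(task_config("long", seed = 5))
  b <- generate_schedule(task_config("long", seed = 5))
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_events(a, f1); write_events(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("accuracy labelling hits exact boundaries and is seeded", {
  sched <- generate_schedule(task_config("long", seed = 2))
  expect_true(all(label_accuracy(sched, 1)$accuracy == "correct"))
  expect_true(all(label_accuracy(sched, 0)$accuracy == "incorrect"))
  l1 <- label_accuracy(sched, 0.8, seed = 9)
  l2 <- label_accuracy(sched, 0.8, seed = 9)
  expect_identical(l1$accuracy, l2$accuracy)
  # matches an independently seeded draw of the same generator
  set.seed(9)
  expect_identical(l1$accuracy,
                   ifelse(runif(nrow(sched)) < 0.8, "correct", "incorrect"))
  expect_error(label_accuracy(sched, 1.2), "accuracy_rate")
})

test_that("events round-trip field-for-field and malformed files error", {
  sched <- label_accuracy(generate_schedule(task_config("long", seed = 3)),
                          0.8, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_events(sched, path)
  back <- read_events(path)
  for (col in names(sched)) expect_equal(back[[col]], sched[[col]])
  expect_equal(attr(back, "run_duration_s"), attr(sched, "run_duration_s"))
  expect_equal(attr(back, "session_label"), attr(sched, "session_label"))

  # negative onset -> parse error with row number
  lines <- readLines(path)
  lines[3] <- sub("^[0-9.]+", "-1", lines[3])
  bad <- tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(read_events(bad), "negative onset at data row 1")

  # extra ignorable columns are preserved in a metadata map
  lines <- readLines(path)
  lines[2] <- paste0(lines[2], "\tresponse_time")
  lines[3:length(lines)] <- paste0(lines[3:length(lines)], "\t0.5")
  extra <- tempfile(fileext = ".tsv")
  writeLines(lines, extra)
  parsed <- read_events(extra)
  expect_equal(nrow(parsed), nrow(sched))
  expect_true("response_time" %in% names(attr(parsed, "extra_columns")))

  # missing required column
  lines <- sub("\tblock$", "", sub("\t[0-9]+$", "", readLines(path)))
  f <- tempfile()
  writeLines(lines, f)
  expect_error(read_events(f), "missing required column")
})

test_that("invalid configurations name the offending field", {
  expect_error(task_config("long", trials_per_block = 0), "trials_per_block")
  expect_error(task_config("long", iti_range_s = c(10, 1.5)), "iti_range_s")
  expect_error(task_config("long", block_duration_s = -1), "block_duration_s")
})
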