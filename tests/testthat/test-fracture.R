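test_that("distance categories partition [0, Inf) at the printed boundaries", {
  d <- seq(0, 6, by = 0.01)
  dc <- classify_frame(d, "dc")
  expect_false(anyNA(dc))
  expect_true(all(diff(as.integer(dc)) >= 0))  # monotone in distance
  expect_equal(as.character(classify_frame(c(0, 1.0, 1.49), "dc")),
               rep("close", 3))
  expect_equal(as.character(classify_frame(1.5, "dc")), "near")
  expect_equal(as.character(classify_frame(3.5, "dc")),
               "short-distance separated")
  expect_equal(as.character(classify_frame(c(5.0, 6.0), "dc")),
               rep("long-distance separated", 2))
  expect_equal(as.character(classify_frame(c(0, 1.5, 2.99, 3.0), "fibroblast")),
               c("close", "near", "near", "far"))
  expect_error(classify_frame(-0.1), ">= 0")
})

test_that("frame fracture call agrees with the close/near boundary", {
  expect_false(is_fractured_frame(1.49))
  expect_true(is_fractured_frame(1.5))
  expect_false(is_fractured_frame(0))
  # equivalence with classification, both schemes, across a sweep
  d <- seq(0, 6, by = 0.01)
  expect_equal(is_fractured_frame(d),
               classify_frame(d, "dc") != "close")
  expect_equal(is_fractured_frame(d),
               classify_frame(d, "fibroblast") != "close")
})

test_that("cell-level call needs two (not necessarily adjacent) time points", {
  one_spike <- c(rep(0.8, 10), 2.0, rep(0.8, 10))
  expect_false(cell_fractured(one_spike))
  expect_true(cell_fractured(c(0.8, 2.0, 0.8, 2.0, 0.8)))
  expect_false(cell_fractured(numeric(0)))
  expect_true(cell_fractured(c(2, 0.1, 0.1, 2), min_timepoints = 2))
})

test_that("breakage frequency is an order-invariant fraction", {
  flags <- c(rep(TRUE, 2), rep(FALSE, 8))
  expect_equal(breakage_frequency(as.list(flags)), 0.2)
  expect_equal(breakage_frequency(as.list(sample(flags))), 0.2)
  expect_equal(breakage_frequency(as.list(rep(FALSE, 5))), 0)
  expect_error(breakage_frequency(list()), "empty")
})

test_that("max separation is the series maximum", {
  expect_equal(max_separation(c(0.8, 2.3, 5.1, 1.0)), 5.1)
  expect_equal(max_separation(rep(0.8, 5)), 0.8)
  expect_error(max_separation(numeric(0)), "empty")
})

test_that("separation velocity is the post-onset window maximum", {
  # linear rise 1.0 -> 4.0 um over 2 min: slope 1.5 um/min in every window
  ser <- data.frame(time = seq(0, 120, by = 12),
                    distance = seq(1, 4, length.out = 11))
  sv <- separation_velocity(ser, threshold = 1.5, window = 3)
  expect_equal(sv$velocity, 1.5, tolerance = 1e-9)
  flat <- data.frame(time = 0:10, distance = rep(0.8, 11))
  expect_error(separation_velocity(flat), "never reaches")
})

test_that("repair outcome distinguishes repaired, non-repaired, censored", {
  t10 <- seq(0, 190, by = 10)
  rise_fall <- c(0.8, 1.0, 2.0, 3.0, 2.0, rep(0.8, 15))
  expect_equal(repair_outcome(data.frame(time = t10, distance = rise_fall)),
               "repaired")
  monotone <- seq(0.8, 4.0, length.out = 20)
  expect_equal(repair_outcome(data.frame(time = t10, distance = monotone)),
               "non-repaired")
  last_frame_only <- c(rep(0.8, 3), seq(2, 4, length.out = 16), 0.9)
  expect_equal(repair_outcome(data.frame(time = t10,
                                         distance = last_frame_only)),
               "censored")
  expect_error(repair_outcome(data.frame(time = t10,
                                         distance = rep(0.5, 20))),
               "never reaches")
})

test_that("fracture_report assembles the per-cell phenotype", {
  ser <- data.frame(time = seq(0, 570, by = 30),
                    distance = c(rep(0.8, 5), seq(1.3, 4.3, by = 0.5),
                                 rep(4.3, 8)))
  rp <- fracture_report(ser, cell_id = "cell-1")
  expect_s3_class(rp, "fracture_report")
  expect_true(rp$fractured)
  expect_equal(rp$max_separation, 4.3)
  expect_equal(rp$repair, "non-repaired")
  expect_equal(rp$separation_velocity, 1.0, tolerance = 1e-9)
  expect_equal(length(rp$categories), nrow(ser))
  intact <- fracture_report(data.frame(time = ser$time,
                                       distance = rep(0.7, 20)))
  expect_false(intact$fractured)
  expect_true(is.na(intact$separation_velocity))
})

test_that("decision time runs from first entry to permanent exit", {
  poly <- cbind(c(10, 25, 25, 10), c(0, 0, 20, 20))
  tr <- data.frame(time = seq(0, 3000, by = 60),
                   x = seq(0, 50, length.out = 51), y = 10)
  dt <- decision_time(tr, poly)
  expect_equal(dt$decision_time, 15)
  expect_equal(as.character(dt$phase[10]), "before")
  expect_equal(as.character(dt$phase[12]), "during")
  expect_equal(as.character(dt$phase[30]), "after")
  outside <- data.frame(time = 0:10, x = 0:10 * 0 + 50, y = 50)
  expect_error(decision_time(outside, poly), "never enters")
})

test_that("re-entrant tracks keep the during phase open to the final exit", {
  poly <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  inside_seq <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  x <- ifelse(inside_seq, 5, 20)
  tr <- data.frame(time = (seq_along(x) - 1) * 60, x = x, y = 5)
  dt <- decision_time(tr, poly)
  # brute-force over the entry/exit event sequence: first entry index 3,
  # last inside index 7, first permanently-outside index 8
  expect_equal(dt$decision_time, (tr$time[8] - tr$time[3]) / 60)
  expect_equal(as.character(dt$phase),
               c("before", "before", rep("during", 5), "after", "after"))
})
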