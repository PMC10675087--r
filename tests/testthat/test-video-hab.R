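test_that("preprocessing obeys the identity, shape and range laws", {
  fr <- make_camera_frames(1, size = c(64, 64), fractions = 0.2, seed = 5)[[1]]$frame
  out <- preprocess_frame(fr, c(64, 64), normalize = FALSE)
  expect_identical(out$pixels, fr$pixels)

  # 100(h) x 200(w) frame to 64 x 64: centre 100 x 100 crop then resize
  px <- array(runif(100 * 200 * 3, 0, 255), c(100, 200, 3))
  wide <- camera_frame(px, "d", "2021-07-01T10:00:00Z")
  out2 <- preprocess_frame(wide, c(64, 64))
  expect_identical(dim(out2$pixels), c(64L, 64L, 3L))
  # crop takes the middle columns: resizing the hand-cropped region agrees
  hand <- px[, 51:150, , drop = FALSE]
  expect_equal(out2$pixels, twinlake:::resize_bilinear(hand, 64, 64))

  out3 <- preprocess_frame(wide, c(64, 64), normalize = TRUE)
  expect_true(all(out3$pixels >= 0 & out3$pixels <= 1))

  expect_error(preprocess_frame(fr, c(8, 8)), "at least 16")
})

test_that("coverage ratio is an exact pixel fraction with bounds", {
  m <- matrix(FALSE, 10, 10); m[1:5, 1:5] <- TRUE
  rec <- coverage_ratio(m, "cam01", "2021-07-01T10:00:00Z")
  expect_equal(rec$ratio, 0.25)
  expect_equal(rec$hab_pixels, 25L)
  expect_equal(rec$total_pixels, 100L)
  expect_equal(coverage_ratio(matrix(TRUE, 4, 4))$ratio, 1)
  expect_equal(coverage_ratio(matrix(FALSE, 4, 4))$ratio, 0)
  expect_error(coverage_ratio(matrix(logical(0), 0, 0)), "zero-size")
})

test_that("confusion counts match hand tallies and conserve pixels", {
  t4 <- matrix(FALSE, 4, 4); t4[1, 1:3] <- TRUE; t4[2, 1:3] <- TRUE  # 6 true
  p4 <- t4; p4[2, 3] <- FALSE          # miss one
  p4[4, 1] <- TRUE; p4[4, 2] <- TRUE   # two spurious
  cc <- confusion_counts(p4, t4)
  expect_equal(cc[c("TP", "FP", "FN")], list(TP = 5L, FP = 2L, FN = 1L))
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 16L)

  same <- confusion_counts(t4, t4)
  expect_equal(same[c("TP", "FP", "FN")], list(TP = 6L, FP = 0L, FN = 0L))
  allp <- confusion_counts(matrix(TRUE, 4, 4), matrix(FALSE, 4, 4))
  expect_equal(allp[c("TP", "FP", "FN")], list(TP = 0L, FP = 16L, FN = 0L))
  expect_error(confusion_counts(matrix(TRUE, 2, 2), t4), "shape")
})

test_that("F-score follows its defining identities", {
  expect_equal(round(unname(f_score(list(TP = 50, FP = 10, FN = 10))["F"]), 4),
               0.8333)
  expect_equal(unname(f_score(list(TP = 30, FP = 10, FN = 20))),
               c(0.75, 0.6, 2 * 0.45 / 1.35))
  expect_equal(unname(f_score(list(TP = 7, FP = 0, FN = 0))["F"]), 1)
  expect_warning(fz <- f_score(list(TP = 0, FP = 0, FN = 0)), "defined as 0")
  expect_equal(unname(fz["F"]), 0)

  # min(P,R) <= F <= max(P,R); F = P when P = R; F = 1 iff FP = FN = 0
  set.seed(99)
  for (i in 1:300) {
    cc <- list(TP = sample(0:50, 1), FP = sample(0:50, 1), FN = sample(0:50, 1))
    if (cc$TP + cc$FP == 0 && cc$TP + cc$FN == 0) next
    s <- f_score(cc)
    expect_gte(s["F"], min(s["P"], s["R"]) - 1e-12)
    expect_lte(s["F"], max(s["P"], s["R"]) + 1e-12)
    if (s["P"] == s["R"]) expect_equal(unname(s["F"]), unname(s["P"]))
    expect_equal(unname(s["F"]) == 1, cc$FP == 0 && cc$FN == 0 && cc$TP > 0)
  }
})

test_that("baseline segmenter recovers scheduled coverage on synthetic frames", {
  seg <- baseline_segmenter()
  fr <- make_camera_frames(10, fractions = c(0, 0.1, 0.37, 0.8, 1), seed = 21)
  for (f in fr) {
    expect_lt(abs(mean(f$truth) - f$fraction), 0.005)  # rasterisation law
    m <- predict(seg, f$frame)
    expect_lt(abs(mean(m) - f$fraction), 0.02)
    if (f$fraction > 0 && f$fraction < 1) {
      expect_gte(unname(f_score(confusion_counts(m, f$truth))["F"]), 0.95)
    }
  }
  # noisy frames stay within the looser recovery band
  frn <- make_camera_frames(6, fractions = 0.37, noise_sd = 10, seed = 22)
  for (f in frn) {
    expect_lt(abs(mean(predict(seg, f$frame)) - 0.37), 0.05)
  }
  # segmenter is deterministic
  expect_identical(predict(seg, fr[[3]]$frame), predict(seg, fr[[3]]$frame))
})

test_that("trainable segmenter is seeded-deterministic with monotone loss", {
  pairs <- lapply(make_camera_frames(16, fractions = c(0.15, 0.35, 0.55),
                                     seed = 31),
                  function(f) list(frame = f$frame, truth = f$truth))
  s1 <- train_segmenter(pairs, list(epochs = 12), seed = 7)
  s2 <- train_segmenter(pairs, list(epochs = 12), seed = 7)
  expect_identical(s1$params$w, s2$params$w)
  expect_identical(attr(s1, "validation_f"), attr(s2, "validation_f"))
  expect_true(all(diff(attr(s1, "losses")) <= 1e-12))
  expect_gte(attr(s1, "validation_f"), 0.95)   # noiseless blobs are separable

  # degenerate all-background training set
  bg <- lapply(make_camera_frames(4, fractions = 0, seed = 32),
               function(f) list(frame = f$frame, truth = f$truth))
  expect_warning(s3 <- train_segmenter(bg, list(epochs = 3), seed = 1),
                 "all-false")
  expect_false(any(predict(s3, bg[[1]]$frame)))

  expect_error(train_segmenter(list()), "empty")
})

test_that("stream monitoring samples by period inside the daily window", {
  seg <- baseline_segmenter()
  mk <- function(start, n, period = 1) {
    lapply(make_camera_frames(n, fractions = 0.3, seed = 41,
                              start_time = start, period_s = period),
           `[[`, "frame")
  }
  # 10 frames at 1 Hz, period 1 -> 10 records
  recs <- monitor_stream(mk("2021-07-01T10:00:00Z", 10), seg)
  expect_equal(nrow(recs), 10L)
  expect_true(all(recs$ratio >= 0 & recs$ratio <= 1))

  # 23:00 frames fall outside the 08-18 window -> 0 records
  expect_equal(nrow(monitor_stream(mk("2021-07-01T23:00:00Z", 5), seg)), 0L)

  # period 2 s on a 1 Hz stream samples every other frame
  recs2 <- monitor_stream(mk("2021-07-01T10:00:00Z", 10), seg, period_s = 2)
  expect_equal(nrow(recs2), 5L)

  # unordered timestamps rejected
  fr <- mk("2021-07-01T10:00:00Z", 3)
  expect_error(monitor_stream(fr[c(2, 1, 3)], seg), "not time-ordered")
})

test_that("frames round-trip through PNG with device and time in the name", {
  f <- make_camera_frames(1, fractions = 0.4, seed = 51,
                          device_id = "cam07",
                          start_time = "2021-07-01T09:30:00Z")[[1]]$frame
  dir <- withr::local_tempdir()
  p <- file.path(dir, sprintf("%s_%s.png", f$device_id,
                              format(f$timestamp, "%Y-%m-%dT%H-%M-%SZ")))
  write_frame_png(f, p)
  back <- read_frame_png(p)
  expect_equal(back$pixels, f$pixels, tolerance = 0.5)  # 8-bit quantisation
  expect_identical(back$device_id, "cam07")
  expect_equal(back$timestamp, f$timestamp)
})
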