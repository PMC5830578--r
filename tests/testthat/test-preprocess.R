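test_that("recursive outlier removal keeps identical values and drops gross outliers", {
  all5 <- recursive_outlier_trim(rep(5, 5))
  expect_equal(as.numeric(all5), rep(5, 5))

  zeros <- recursive_outlier_trim(c(rep(0, 8), 100))
  expect_equal(sort(as.numeric(zeros)), rep(0, 8))
  expect_equal(attr(zeros, "n_removed"), 1L)

  set.seed(31)
  x <- c(rnorm(50), 10)
  out <- recursive_outlier_trim(x)
  expect_false(10 %in% out)
  expect_equal(sort(as.numeric(out)), oracle_trim(x))
})

test_that("recursive outlier removal matches the brute-force recursion oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- round(rnorm(n, sd = sample(c(1, 5, 50), 1)), 2)
    if (i %% 4 == 0) x[sample(n, 1)] <- x[sample(n, 1)] + sample(c(-1, 1), 1) * 100
    if (i %% 5 == 0) x <- c(x, rep(x[1], 3))  # ties / duplicates
    expect_equal(sort(as.numeric(recursive_outlier_trim(x))), oracle_trim(x),
                 info = paste("case", i))
  }
})

test_that("trim is idempotent and returns a sub-multiset, degenerate inputs flagged", {
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(sample(3:30, 1)) * sample(c(1, 10), 1)
    once <- recursive_outlier_trim(x)
    twice <- recursive_outlier_trim(as.numeric(once))
    expect_equal(sort(as.numeric(twice)), sort(as.numeric(once)))
    # sub-multiset check
    tab_in <- table(x)
    tab_out <- table(as.numeric(once))
    expect_true(all(tab_out <= tab_in[names(tab_out)]))
  }
  deg <- recursive_outlier_trim(c(1, 2))
  expect_true(attr(deg, "degenerate"))
  expect_equal(as.numeric(deg), c(1, 2))
})

make_trial <- function(x, y, valid = TRUE, t0 = -300, dt = 4) {
  n <- length(x)
  data.frame(t_ms = seq(t0, by = dt, length.out = n),
             x_px = x, y_px = y, valid = rep(valid, length.out = n))
}

test_that("baseline is the trimmed mean of the pre-stimulus window", {
  tr <- make_trial(rep(640, 75), rep(360, 75))
  b <- compute_baseline(tr)
  expect_equal(c(b$bx_px, b$by_px), c(640, 360))
  expect_true(b$valid)

  # one blink invalidates the trial's baseline
  tr2 <- tr; tr2$valid[10] <- FALSE
  expect_false(compute_baseline(tr2)$valid)

  # a y outlier is trimmed out of the mean but marks the baseline invalid
  tr3 <- make_trial(rep(100, 75), c(rep(100, 74), 900))
  b3 <- compute_baseline(tr3)
  expect_equal(c(b3$bx_px, b3$by_px), c(100, 100))
  expect_false(b3$valid)

  expect_false(compute_baseline(make_trial(numeric(0), numeric(0)))$valid)
})

test_that("drift correction shifts by baseline minus centre and imputes invalid baselines", {
  mk <- function(video, bx, by, blink = FALSE) {
    pre <- make_trial(rep(bx, 75), rep(by, 75), valid = !blink)
    post <- data.frame(t_ms = seq(0, 999, by = 3), x_px = 500, y_px = 300,
                       valid = TRUE)
    cbind(participant = 1, video = video, rbind(pre, post))
  }
  trials <- rbind(mk(1, 640, 360), mk(2, 660, 360), mk(3, 650, 365, blink = TRUE))
  out <- correct_trials(trials, 1280, 720)
  bl <- attr(out, "baselines")
  # invalid baseline replaced by the mean of the two valid ones
  expect_equal(bl$bx_px[bl$video == 3], 650)
  expect_equal(bl$by_px[bl$video == 3], 360)
  expect_true(bl$imputed[bl$video == 3])
  # centred baseline leaves gaze unchanged; offset baseline shifts it
  expect_equal(unique(out$x_px[out$video == 1]), 500)
  expect_equal(unique(out$x_px[out$video == 2]), 500 - 20)
  # onset exclusion: t < 150 ms dropped, boundary kept
  expect_true(all(out$t_ms >= 150))
  expect_true(150 %in% out$t_ms)
  # sample count preserved apart from onset exclusion
  expect_equal(nrow(out), 3 * sum(seq(0, 999, 3) >= 150))
})

test_that("frame alignment averages 8-9 samples per frame and flags empty frames", {
  tr <- data.frame(t_ms = seq(150, 999, by = 4), x_px = 100, y_px = 50,
                   valid = TRUE)
  fg <- align_gaze_to_frames(tr, n_frames = 30, fps = 30,
                             width_px = 1280, height_px = 720)
  expect_equal(nrow(fg), 30)
  # full frames (the onset-boundary frame 4 is only partially covered)
  counts <- table(floor(tr$t_ms / 1000 * 30))
  counts <- counts[as.integer(names(counts)) >= 5]
  expect_true(all(counts %in% 8:9))
  done <- fg[!fg$missing, ]
  expect_true(all(done$x_px == 100 & done$y_px == 50))
  # frames before the onset exclusion have no samples -> missing
  expect_true(all(fg$missing[fg$frame < 4]))
  # all-invalid samples give a missing frame
  tr$valid[floor(tr$t_ms / 1000 * 30) == 10] <- FALSE
  fg2 <- align_gaze_to_frames(tr, 30, 30, 1280, 720)
  expect_true(fg2$missing[fg2$frame == 10])
})
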