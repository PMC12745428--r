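rmsMid <- function(x) {
  n <- length(x)
  idx <- seq(round(n * 0.25), round(n * 0.75))
  sqrt(mean(x[idx]^2))
}

test_that("bandpass preserves in-band tones and rejects out-of-band power", {
  rec <- sineRecording(10, fs = 500, dur = 8)
  out <- bandpassFilter(rec, 0.5, 45, transition_hz = 1)
  expect_equal(rmsMid(out@data[1, ]), rmsMid(rec@data[1, ]),
               tolerance = 0.01)
  ## 50 Hz mains through the notch: residual amplitude <= 10%
  mains <- sineRecording(50, fs = 500, dur = 8)
  notched <- notchFilter(mains, 49, 51, transition_hz = 1)
  expect_lte(rmsMid(notched@data[1, ]), 0.1 * rmsMid(mains@data[1, ]))
  ## the notch leaves a 10 Hz tone essentially untouched
  thru <- notchFilter(rec, 49, 51, transition_hz = 1)
  expect_equal(rmsMid(thru@data[1, ]), rmsMid(rec@data[1, ]),
               tolerance = 0.01)
  ## DC is outside the passband
  dc <- EEGRecording(matrix(1, 1, 4000) |>
                       (\(m) rbind(m, matrix(0, 2, 4000)))(),
                     fs = 500, labels = c("x", "A1", "A2"))
  hp <- bandpassFilter(dc, 2, 45, transition_hz = 2)
  expect_lte(rmsMid(hp@data[1, ]), 0.1)
  ## edges at or above Nyquist are rejected
  expect_error(bandpassFilter(rec, 0.5, 300), "Nyquist|inside")
})

test_that("resampling decimates cleanly and rescales events", {
  t <- seq(0, 4 - 1 / 1000, by = 1 / 1000)
  dat <- rbind(sin(2 * pi * 10 * t), matrix(0, 2, length(t)))
  rec <- EEGRecording(dat, fs = 1000, labels = c("x", "A1", "A2"),
                      events = data.frame(sample = 1001L, task = "fist"))
  out <- resampleRecording(rec, 500)
  expect_equal(ncol(out@data), 2000L)
  expect_equal(samplingRate(out), 500)
  expect_equal(out@events$sample, 501L)
  ## spectral peak still at 10 Hz
  sp <- Mod(fft(out@data[1, ]))[1:1000]
  expect_equal(which.max(sp[-1]), 10 * 4)  # 0.25 Hz resolution over 4 s
  expect_error(resampleRecording(rec, -5), "positive")
  expect_error(resampleRecording(rec, 2000), "upsampling")
})

test_that("linked-ear re-referencing subtracts the ear mean and drops refs", {
  set.seed(1)
  dat <- matrix(rnorm(5 * 100), 5)
  rec <- EEGRecording(dat, fs = 100, labels = c("C3", "C4", "Fz", "A1", "A2"))
  out <- rereferenceLinkedEars(rec)
  expect_setequal(out@labels, c("C3", "C4", "Fz"))
  ref <- (dat[4, ] + dat[5, ]) / 2
  expect_equal(out@data["C3", ], dat[1, ] - ref)
  ## zero ears: identity except the dropped rows
  dat0 <- dat; dat0[4:5, ] <- 0
  rec0 <- EEGRecording(dat0, fs = 100, labels = rec@labels)
  expect_equal(rereferenceLinkedEars(rec0)@data, dat0[1:3, ],
               ignore_attr = TRUE)
  ## all channels equal to the ears: output identically zero
  datc <- matrix(rep(dat[4, ], 5), 5, byrow = TRUE)
  recc <- EEGRecording(datc, fs = 100, labels = rec@labels)
  expect_true(all(abs(rereferenceLinkedEars(recc)@data) < 1e-12))
  ## idempotence under re-attached zero ears
  once <- rereferenceLinkedEars(rec)
  re <- EEGRecording(rbind(once@data, matrix(0, 2, 100)), fs = 100,
                     labels = c(once@labels, "A1", "A2"))
  expect_equal(rereferenceLinkedEars(re)@data, once@data)
  expect_error(rereferenceLinkedEars(once), "A1")
})

test_that("epoching cuts exact cue-locked windows and drops boundary events", {
  fs <- 500
  dat <- matrix(rnorm(2 * fs * 120), 2)
  ev <- data.frame(sample = c(250L, seq(5000L, 52000L, by = 2500L)),
                   task = "fist")
  rec <- EEGRecording(dat, fs = fs, labels = c("a", "b"), events = ev)
  expect_message(ep <- epochRecording(rec, "fist"), "dropped")
  expect_identical(nTrials(ep), nrow(ev) - 1L)   # first event too early
  expect_identical(dim(ep@data)[3L], 2500L)      # 5 s at 500 Hz
  expect_identical(ep@t0, -1)
  ## epoch content matches the raw slice
  expect_equal(ep@data[1, 1, ], dat[1, 5000 - 500 + 0:2499])
  expect_warning(empty <- epochRecording(rec, "wrist"), "no events")
  expect_identical(nTrials(empty), 0L)
})

test_that("baseline correction zeroes the pre-cue mean and spares steps", {
  fs <- 100
  ep <- EpochSet(array(5, c(2, 3, 3 * fs)), fs = fs, t0 = -1,
                 task = "fist", labels = c("a", "b", "c"))
  bc <- baselineCorrect(ep)
  expect_true(all(abs(bc@data) < 1e-12))
  ## arbitrary input: pre-cue mean becomes 0 within 1e-12
  set.seed(2)
  ep2 <- EpochSet(array(rnorm(2 * 3 * 300), c(2, 3, 300)), fs = fs,
                  t0 = -1, task = "fist", labels = c("a", "b", "c"))
  bc2 <- baselineCorrect(ep2)
  expect_lt(max(abs(apply(bc2@data[, , 1:fs], c(1, 2), mean))), 1e-12)
  ## step at the cue is untouched (pre-mean already zero)
  step <- array(rep(c(rep(0, fs), rep(5, 2 * fs)), each = 1), c(1, 1, 300))
  eps <- EpochSet(step, fs = fs, t0 = -1, task = "fist", labels = "a")
  expect_equal(baselineCorrect(eps)@data, step)
})

test_that("lateral mirroring swaps homologs, spares the midline, inverts", {
  m <- standardMontage()
  labs <- m$labels
  set.seed(3)
  ep <- EpochSet(array(rnorm(2 * 19 * 50), c(2, 19, 50)), fs = 50,
                 t0 = -0.2, task = "fist", labels = labs)
  ## put a marker signal on C3 only
  ep@data[, , ] <- 0
  ep@data[1, match("C3", labs), ] <- 1
  mir <- mirrorLateral(ep, m)
  expect_equal(mir@data[1, match("C4", labs), ], rep(1, 50))
  expect_true(all(mir@data[1, match("C3", labs), ] == 0))
  ## involution and midline invariance on random data
  ep2 <- EpochSet(array(rnorm(2 * 19 * 50), c(2, 19, 50)), fs = 50,
                  t0 = -0.2, task = "fist", labels = labs)
  expect_equal(mirrorLateral(mirrorLateral(ep2, m), m)@data, ep2@data)
  mir2 <- mirrorLateral(ep2, m)
  for (mid in m$midline)
    expect_equal(mir2@data[, match(mid, labs), ],
                 ep2@data[, match(mid, labs), ])
})

test_that("mirroring commutes with re-referencing and epoching", {
  cpl <- singlePairCoupling(noise_sd = 0.5)
  rec <- generateRecording(coupling = cpl, n_trials = 2, fs = 200,
                           post_s = 2, gap_s = 0.5, tasks = "fist",
                           seed = 9)
  m <- standardMontage()
  ep <- baselineCorrect(epochRecording(rereferenceLinkedEars(rec), "fist",
                                       post_s = 2))
  a <- mirrorLateral(ep, m)
  ## mirror the raw recording rows first, then preprocess
  perm <- vapply(rec@labels, function(l) {
    if (l %in% c(m$midline, m$refs)) l else m$homolog_pairs[[l]]
  }, "")
  dat <- rec@data[match(rec@labels, perm), , drop = FALSE]
  rec2 <- EEGRecording(dat, fs = rec@fs, labels = rec@labels,
                       events = rec@events)
  b <- baselineCorrect(epochRecording(rereferenceLinkedEars(rec2), "fist",
                                      post_s = 2))
  expect_equal(a@data, b@data, tolerance = 1e-12)
})
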