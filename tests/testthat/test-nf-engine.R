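test_that("the standard protocols have the published block structure", {
  efp <- build_schedule("efp_nf")
  expect_equal(sum(efp$duration), 180 + 5 * (60 + 180))  # 1380 s
  expect_equal(efp$label[1], "Rest")
  expect_equal(efp$label[-1], rep(c("Watch", "Regulate"), 5))
  fmri <- build_schedule("fmri_nf")
  expect_equal(sum(fmri$duration), 54 + 2 * (60 + 60 + 9 + 15))  # 342 s
  expect_equal(fmri$label[-1],
               rep(c("Watch", "Regulate", "Washout", "Fixation"), 2))
  expect_error(build_schedule("bogus"), "unknown protocol")
  expect_error(nf_schedule(data.frame(label = "a", onset = 0,
                                      duration = -1)), "positive")
})

test_that("z-normalization uses the preceding Watch sample statistics", {
  expect_equal(z_normalize(2, c(1, 2, 3))$value, 0)
  expect_equal(z_normalize(3, c(1, 2, 3))$value, 1)  # sample SD of 1,2,3 is 1
  z <- z_normalize(4, c(5, 5, 5))
  expect_true(z$degenerate)
  expect_true(is.na(z$value))
  expect_error(z_normalize(1, c(2)), "2 Watch samples")
})

test_that("feedback mapping is the documented clamped affine rule", {
  expect_equal(map_feedback(z_normalize(2, c(1, 2, 3))), 6L)  # Z = 0
  expect_equal(map_feedback(1), 8L)    # 5.5 + 2 -> 7.5 -> round half up
  expect_equal(map_feedback(-3), 1L)   # clamp floor
  expect_equal(map_feedback(3), 10L)   # clamp ceiling
  expect_equal(map_feedback(z_normalize(4, c(5, 5, 5))), 6L)  # degenerate
  # monotone non-decreasing
  zs <- seq(-4, 4, by = 0.05)
  lv <- vapply(zs, map_feedback, integer(1))
  expect_true(all(diff(lv) >= 0))
  expect_true(all(lv >= 1 & lv <= 10))
})

test_that("the success index matches its defining arithmetic", {
  expect_equal(as.numeric(success_index(c(3, 3), c(2, 3, 4))), 0)
  # Watch {2,4,6} has sample SD 2; Regulate mean 1 => (1 - 4)/2 = -1.5
  expect_equal(as.numeric(success_index(c(1, 1, 1), c(2, 4, 6))), -1.5)
  # invariant under common positive rescaling
  si1 <- as.numeric(success_index(c(1, 2, 3), c(4, 5, 9)))
  si2 <- as.numeric(success_index(7 * c(1, 2, 3), 7 * c(4, 5, 9)))
  expect_equal(si1, si2)
  expect_true(attr(success_index(c(1, 2), c(3, 3)), "degenerate"))
  expect_error(success_index(c(1), c(2, 3)), "at least 2")
})

test_that("session success is the mean of the block indices", {
  expect_equal(session_success(rep(-0.5, 5)), -0.5)
  expect_equal(session_success(c(-1, 0, -1, 0, -0.5)), -0.5)
  expect_error(session_success(c(-1, NA)), "missing")
})

test_that("a no-modulation agent produces zero success indices", {
  bd <- band_definition(seq(0.5, 40, length.out = 11), rep(1, 10))
  m0 <- efp_model(bd, matrix(0, 10, 48), intercept = 1)
  ag0 <- agent_params(regulate_gain = 0, learning_rate = 0, noise_sd = 0)
  s <- run_closed_loop_session(ag0, m0, small_schedule(), seed = 1,
                               eeg_params = list(pink_amp = 0, line_amp = 0,
                                                 white_sd = 0,
                                                 couplings = list()))
  expect_equal(s$block_success, rep(0, 2), tolerance = 1e-6)
})

test_that("a skilled noise-free agent down-regulates in every cycle", {
  cal <- shared_cal()
  ag <- agent_params(regulate_gain = 0.02, learning_rate = 0.3,
                     noise_sd = 0)
  s <- run_closed_loop_session(ag, cal$model, small_schedule(), seed = 2)
  expect_true(all(s$block_success < 0))
  # recomputation oracle: block indices match success_index on raw samples
  d <- s$samples
  blocks <- efpnf:::schedule_block_at(s$schedule, d$time - 1.5)
  si2 <- as.numeric(success_index(
    d$efp[blocks == 5 & d$ok], d$efp[blocks == 4 & d$ok]))
  expect_equal(s$block_success[2], si2)
  expect_equal(session_success(s), mean(s$block_success))
})

test_that("closed-loop sessions are bit-identical under a fixed seed", {
  cal <- shared_cal()
  a <- run_closed_loop_session(skilled_agent(), cal$model, small_schedule(),
                               seed = 3)
  b <- run_closed_loop_session(skilled_agent(), cal$model, small_schedule(),
                               seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(a$block_success, b$block_success)
})

test_that("feedback is emitted during Regulate only and levels are valid", {
  cal <- shared_cal()
  s <- run_closed_loop_session(skilled_agent(), cal$model, small_schedule(),
                               seed = 4)
  d <- s$samples
  expect_true(all(is.na(d$feedback[d$label != "Regulate"])))
  fb <- d$feedback[d$label == "Regulate"]
  expect_true(all(fb[!is.na(fb)] %in% 1:10))
  expect_true(any(!is.na(fb)))
  # z-scores of the first Regulate block use the preceding Watch samples
  blocks <- efpnf:::schedule_block_at(s$schedule, d$time - 1.5)
  w <- d$efp[blocks == 2 & d$ok]
  r1 <- which(blocks == 3 & d$ok)[1]
  expect_equal(d$z[r1], (d$efp[r1] - mean(w)) / stats::sd(w))
})
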