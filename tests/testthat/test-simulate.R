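test_that("orthostatic HR response matches its closed form", {
  flat <- simulate_hr_response(70, delta = 0, tau = 20, noise_sd = 0,
                               duration = 60, rate = 1)
  expect_equal(flat$values, rep(70, 61), tolerance = 1e-12)

  s <- simulate_hr_response(70, delta = 20, tau = 20, noise_sd = 0,
                            duration = 60, rate = 1)
  expect_equal(s$values[s$time == 20], 70 + 20 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(s$values[s$time == 0], 70, tolerance = 1e-12)

  expect_error(simulate_hr_response(70, 20, tau = 0, duration = 10), "positive")
  expect_error(simulate_hr_response(70, 20, tau = 20, duration = 10, rate = -1),
               "positive")
})

test_that("HR noise has the stated distribution at the asymptote", {
  set.seed(42)
  # long series at t >> tau: mean should sit within 3 SE of baseline + delta
  s <- simulate_hr_response(70, delta = 20, tau = 1, noise_sd = 5,
                            duration = 9999, rate = 1)
  tail_v <- s$values[s$time >= 20]
  n <- length(tail_v)
  expect_gt(n, 9000)
  expect_lt(abs(mean(tail_v) - 90), 3 * 5 / sqrt(n))
})

test_that("pitch traces follow the posture conventions", {
  sched <- tiny_schedule() # 3 x (30 s toe-touch + 30 s standing + 60 s rest)
  tr <- simulate_pitch_trace(sched, transition_duration = 2,
                             pitch_noise_sd = 0, rate = 100)
  expect_equal(length(tr), 360 * 100) # half-open span x rate

  # noiseless standing segment is constant 0, away from the transitions
  stand <- window_ref(tr, sched$transition_time[1] + 5, sched$phase2_end[1] - 5)
  expect_equal(stand, rep(0, length(stand)), tolerance = 1e-9)
  # toe-touch hold at 85 deg, seated rest at 10 deg
  hold <- window_ref(tr, sched$phase1_start[2] + 5, sched$transition_time[2] - 5)
  expect_equal(hold, rep(85, length(hold)), tolerance = 1e-9)
  rest <- window_ref(tr, sched$phase2_end[1] + 5, sched$rest_end[1] - 5)
  expect_equal(rest, rep(10, length(rest)), tolerance = 1e-9)
})

test_that("a 300-s schedule at 100 Hz yields 30000 samples", {
  specs <- data.frame(movement_type = "SUPINE_STAND_2MIN", phase1_duration = 120,
                      phase2_duration = 60, repetitions = 1L, inter_rep_rest = 120)
  tr <- simulate_pitch_trace(battery_schedule(specs = specs), pitch_noise_sd = 0)
  expect_equal(length(tr), 30000L)
})

test_that("the sigmoid midpoint and velocity peak sit at the scripted transition", {
  specs <- data.frame(movement_type = "SUPINE_STAND_2MIN", phase1_duration = 120,
                      phase2_duration = 60, repetitions = 1L, inter_rep_rest = 60)
  sched <- battery_schedule(specs = specs)
  tr <- simulate_pitch_trace(sched, transition_duration = 2, pitch_noise_sd = 0)
  t0 <- sched$transition_time[1]
  expect_equal(tr$values[tr$time == t0], (90 + 0) / 2, tolerance = 1e-9)
  vel <- diff(tr$values) / diff(tr$time)
  t_peak <- tr$time[which.max(abs(vel))]
  expect_lt(abs(t_peak - t0), 0.05)
})

test_that("overlapping schedule phases are rejected", {
  sched <- tiny_schedule()
  sched$rest_end[1] <- sched$phase1_start[2] + 10
  expect_error(simulate_pitch_trace(sched), "overlapping")
  sched2 <- tiny_schedule()
  sched2$transition_time[1] <- sched2$phase1_start[1] - 1
  expect_error(simulate_pitch_trace(sched2), "overlapping|inverted")
})

test_that("cohort simulation is deterministic and sub-seeded per participant", {
  a <- simulate_cohort(2, seed = 9)
  b <- simulate_cohort(2, seed = 9)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$sessions[[1]]$hr$values, b$sessions[[1]]$hr$values)
  expect_identical(a$sessions[[8]]$pitch$values, b$sessions[[8]]$pitch$values)
  expect_equal(length(a$sessions), 8L) # 4 battery recordings per participant

  # adding a participant never changes earlier participants' draws
  two <- simulate_cohort(2, seed = 13, signals = FALSE)
  three <- simulate_cohort(3, seed = 13, signals = FALSE)
  expect_identical(two$ground_truth,
                   three$ground_truth[three$ground_truth$participant_id <= 2, ])
  expect_identical(two$participants, three$participants[1:2, ])
})

test_that("cohort design counts match the scripted battery", {
  study <- simulate_cohort(20, seed = 3, signals = FALSE)
  gt <- study$ground_truth
  expect_equal(nrow(gt), 960L)
  expect_equal(sum(gt$label == "DEHYDRATED"), 240L)
  expect_equal(gt$label, hydration_label_ref(gt$session_type, gt$timing))
})

test_that("dehydrated delta draws center on the configured mean", {
  study <- simulate_cohort(200, seed = 21, signals = FALSE)
  gt <- study$ground_truth
  deh <- gt$true_delta[gt$label == "DEHYDRATED"]
  p <- physio_params()
  se <- sqrt(p$ortho_delta_deh_sd^2 + p$participant_delta_sd^2) / sqrt(length(deh))
  expect_lt(abs(mean(deh) - p$ortho_delta_deh_mean), 3 * se)
  hyd <- gt$true_delta[gt$label == "EUHYDRATED"]
  se_h <- sqrt(p$ortho_delta_hyd_sd^2 + p$participant_delta_sd^2) / sqrt(length(hyd))
  expect_lt(abs(mean(hyd) - p$ortho_delta_hyd_mean), 3 * se_h)
})

test_that("noiseless battery HR reproduces first-order kinetics exactly", {
  quiet <- physio_params(hr_noise_sd = 0, pitch_noise_sd = 0,
                         resting_hr_sd = 0, participant_delta_sd = 0)
  study <- simulate_cohort(2, params = quiet, seed = 17)
  # pre-exercise battery: baseline is flat, so within the first repetition's
  # standing phase HR(t) = resting + delta * (1 - exp(-(t - t0)/tau))
  sess <- Find(function(s) s$participant_id == 1L && s$session_type == "NO_FLUID" &&
                 s$timing == "PRE_EXERCISE", study$sessions)
  gt <- study$ground_truth
  delta <- gt$true_delta[gt$participant_id == 1 & gt$session_type == "NO_FLUID" &
                           gt$timing == "PRE_EXERCISE" &
                           gt$movement_type == "SUPINE_STAND_2MIN" &
                           gt$repetition == 1]
  resting <- study$participants$resting_hr[1]
  sched <- sess$schedule[1, ]
  sel <- sess$hr$time >= sched$transition_time & sess$hr$time < sched$phase2_end
  t_rel <- sess$hr$time[sel] - sched$transition_time
  expected <- resting + delta * (1 - exp(-t_rel / quiet$ortho_tau))
  expect_equal(sess$hr$values[sel], expected, tolerance = 1e-9)
})

test_that("invalid generator parameters are rejected", {
  expect_error(physio_params(hr_noise_sd = -1), "SD")
  expect_error(physio_params(ortho_tau = 0), "> 0")
  expect_error(simulate_cohort(1), "at least 2")
})
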