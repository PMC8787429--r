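fs <- 24400

test_that("trial extraction counts, alignment and edge skipping", {
  nz <- gen_noise(noise_preset(1, c(300, 6000)), 12, fs, 2, seed = 2)
  ev <- data.frame(time_s = seq(1, 10, by = 1), current_uA = 50)
  tr <- extract_trials(nz, ev)
  expect_length(tr, 10)
  expect_length(unique(vapply(tr, function(t) nrow(t$snippet), numeric(1))), 1)

  # known 0.3 ms command-vs-artifact offset is recovered within 1 sample
  x <- nz$samples
  art_at <- round((5 + 0.3e-3) * fs) + 1
  x[art_at, ] <- x[art_at, ] + 500
  rec <- nerve_recording(x, fs)
  tr2 <- extract_trials(rec, data.frame(time_s = 5, current_uA = 50))
  # the detected onset sample should sit at the snippet's onset index
  expect_equal(tr2[[1]]$snippet[tr2[[1]]$onset_index, 1], x[art_at, 1])

  # event hard against the trace edge is dropped with a skip count
  ev3 <- data.frame(time_s = c(0.001, 5), current_uA = c(50, 50))
  expect_warning(tr3 <- extract_trials(nz, ev3), "skipped")
  expect_length(tr3, 1)
  expect_equal(attr(tr3, "n_skipped"), 1L)
})

test_that("artifact blanking interpolates linearly and leaves the response", {
  n <- round(30e-3 * fs) + 1
  t_ms <- (seq_len(n) - round(5e-3 * fs) - 1) / fs * 1000
  snip <- matrix(0, n, 1)
  snip[t_ms >= -0.1 & t_ms <= 0.6, 1] <- 300          # artifact
  peak <- which.min(abs(t_ms - 2)); trough <- which.min(abs(t_ms - 2.5))
  snip[peak, 1] <- 40; snip[trough, 1] <- -40          # late response
  tr <- make_trial(snip)
  bl <- blank_artifact(tr)
  idx <- which(t_ms >= -0.1 & t_ms <= 0.75)
  seg <- bl$snippet[idx, 1]
  expect_lt(max(abs(diff(diff(seg)))), 1e-9)           # straight segment
  resp_idx <- which(t_ms >= 0.75)
  expect_identical(bl$snippet[resp_idx, 1], tr$snippet[resp_idx, 1])
  expect_equal(response_vpp(bl), response_vpp(tr))
  expect_error(blank_artifact(tr, blank = c(-0.1, 2)), "overlaps")
})

test_that("response Vpp is max minus min in the window", {
  n <- round(30e-3 * fs) + 1
  t_ms <- (seq_len(n) - round(5e-3 * fs) - 1) / fs * 1000
  snip <- matrix(0, n, 2)
  snip[which.min(abs(t_ms - 2)), ] <- 25
  snip[which.min(abs(t_ms - 2.6)), ] <- -25
  tr <- make_trial(snip)
  expect_equal(response_vpp(tr), 50)
  expect_equal(response_vpp(make_trial(matrix(0, n, 1))), 0)
  # invariant under a common offset on all channels
  tr_off <- make_trial(snip + 12.3)
  expect_equal(response_vpp(tr_off), response_vpp(tr))
  expect_equal(unname(response_vpp(tr, channel = "per_channel")), c(50, 50))
  expect_error(response_vpp(tr, w = response_window(20, 25)), NA)
})

test_that("simulated trials recover twice the true amplitude on average", {
  sc <- acute_scenario(currents = 100, trials_per_current = 100,
                       n_channels = 1, noise = noise_preset(3, c(300, 6000)))
  ses <- gen_acute_session(sc, seed = 5)
  tr <- extract_trials(ses$recording, ses$events)
  mv <- mean(vapply(tr, response_vpp, numeric(1),
                    w = response_window(0.75, 7)))
  expect_equal(mv, 2 * ses$truth$trials$amplitude_uV[1], tolerance = 0.1)
})

test_that("bootstrap detector is deterministic, calibrated-by-construction
           and flags strong responses", {
  scn <- acute_scenario(currents = 50, trials_per_current = 6, n_channels = 1,
                        block_factor = 0, noise = noise_preset(3, c(300, 6000)))
  ses <- gen_acute_session(scn, seed = 21)
  tr <- extract_trials(ses$recording, ses$events)
  d1 <- detect_response(tr, n_boot = 1000, seed = 9)
  d2 <- detect_response(tr, n_boot = 1000, seed = 9)
  expect_identical(d1$ci, d2$ci)
  expect_true(d1$ci[1] <= d1$ci[2])

  # strong responses (amplitude ~10x the noise RMS) are always detected
  hits <- vapply(1:5, function(s) {
    sch <- acute_scenario(currents = 50, trials_per_current = 6,
                          n_channels = 1,
                          recruit = sigmoid_params(Vmax = 30),
                          noise = noise_preset(3, c(300, 6000)))
    sh <- gen_acute_session(sch, seed = s)
    detect_response(extract_trials(sh$recording, sh$events),
                    n_boot = 500, seed = s)$detected
  }, logical(1))
  expect_true(all(hits))

  expect_error(
    detect_response(list(make_trial(matrix(0, round(30e-3 * fs) + 1, 1))),
                    n_boot = 500),
    "zero noise RMS"
  )
  expect_error(detect_response(tr, n_boot = 50), ">= 100")
})

test_that("detection power is monotone in evoked amplitude", {
  amps <- c(0, 3, 6, 12, 24)
  power <- vapply(amps, function(Vm) {
    mean(vapply(1:10, function(s) {
      sch <- acute_scenario(currents = 50, trials_per_current = 6,
                            n_channels = 1,
                            recruit = sigmoid_params(Vmax = Vm),
                            noise = noise_preset(3, c(300, 6000)))
      sh <- gen_acute_session(sch, seed = 100 + s)
      detect_response(extract_trials(sh$recording, sh$events),
                      n_boot = 400, seed = s)$detected
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[length(amps)], power[1])
})

test_that("recruitment binning follows the 5 uA half-open convention", {
  n <- round(30e-3 * fs) + 1
  mk <- function(I) make_trial(matrix(stats::rnorm(n, sd = 2), ncol = 1),
                               current = I)
  set.seed(3)
  trials <- lapply(seq(10, 110, by = 5), mk)
  rc <- recruitment_curve(trials)
  expect_equal(nrow(rc), 21)
  expect_true(all(rc$n_trials == 1))
  expect_true(all(diff(rc$bin_center) > 0))

  same <- lapply(rep(42, 7), mk)
  rc1 <- recruitment_curve(same)
  expect_equal(nrow(rc1), 1)
  expect_equal(rc1$mean_vpp,
               mean(vapply(same, response_vpp, numeric(1))))

  # permutation invariance over trial order
  perm <- sample(length(trials))
  rc2 <- recruitment_curve(trials[perm])
  expect_equal(as.data.frame(rc2), as.data.frame(rc))
})

test_that("4PL fit recovers exact parameters and fails on flat data", {
  I <- seq(10, 110, 5)
  truth <- c(Vmin = 10, Vmax = 200, I50 = 35, slope = 6)
  V <- truth["Vmin"] + (truth["Vmax"] - truth["Vmin"]) /
    (1 + exp(-(I - truth["I50"]) / truth["slope"]))
  fit <- fit_recruitment(make_curve(I, V))
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-6)
  expect_equal(fit$plateau_current, 35 + 6 * log(19), tolerance = 1e-6)
  expect_equal(predict(fit, 35), 105, tolerance = 1e-6)

  expect_error(fit_recruitment(make_curve(I, rep(5, length(I)))), "flat")
  expect_error(fit_recruitment(make_curve(I[1:4], V[1:4])), "5 distinct")
})

test_that("repeated-measures comparison matches paired-t arithmetic and
           handles identical conditions", {
  # 2 conditions: omnibus F equals the squared paired t statistic
  m <- cbind(control = c(10, 12, 14, 16), treat = c(7, 8, 10, 12))
  cc <- compare_conditions(m)
  tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(cc$anova$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(cc$anova$p, tt$p.value, tolerance = 1e-8)

  ident <- cbind(a = c(3, 5, 9), b = c(3, 5, 9), c = c(3, 5, 9))
  ci <- compare_conditions(ident)
  expect_equal(ci$anova$p, 1)
  expect_false(any(ci$posthoc$reject))

  expect_error(compare_conditions(m[1, , drop = FALSE]), ">= 2 subjects")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(compare_conditions(m_na), "complete|unbalanced|incomplete")
})

test_that("conduction block is flagged against control but washout is not", {
  w7 <- response_window(0.75, 7)
  run <- function(seed) {
    conds <- c(control = 1, lidocaine = 0.02, washout = 1)
    m <- vapply(seq_along(conds), function(ci) {
      vapply(1:4, function(subj) {
        sc <- acute_scenario(currents = 60, trials_per_current = 12,
                             n_channels = 1, block_factor = conds[ci],
                             noise = noise_preset(3, c(300, 6000)))
        ses <- gen_acute_session(sc, seed = seed * 1000 + ci * 10 + subj)
        tr <- extract_trials(ses$recording, ses$events)
        mean(vapply(tr, response_vpp, numeric(1), w = w7))
      }, numeric(1))
    }, numeric(4))
    colnames(m) <- names(conds)
    cc <- compare_conditions(m)
    c(cc$posthoc$reject[1], cc$posthoc$reject[2])
  }
  res <- vapply(1:10, run, logical(2))
  expect_gte(mean(res[1, ]), 0.9)   # lidocaine flagged
  expect_lte(mean(res[2, ]), 0.1)   # washout not flagged
})
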