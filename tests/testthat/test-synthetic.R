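test_that("episode-free simulations carry no suppression", {
  spec <- eeg_sim_spec("propofol", duration = 30, fs = 100, seed = 1)
  sim <- simulate_eeg(spec)
  expect_equal(nrow(sim$truth), 0L)
  s <- detect_bs(sim$recording)
  expect_false(s$any_bs)
})

test_that("simulation is bit-identical for identical seeds", {
  spec <- eeg_sim_spec("sevoflurane", duration = 20, fs = 100,
                       episodes = data.frame(onset = 5, supp_dur = 2,
                                             burst_dur = 1, n_alt = 2),
                       seed = 99)
  a <- simulate_eeg(spec)
  b <- simulate_eeg(spec)
  expect_identical(as.numeric(a$recording), as.numeric(b$recording))
  expect_identical(a$truth$onset, b$truth$onset)
  spec2 <- eeg_sim_spec("sevoflurane", duration = 20, fs = 100,
                        episodes = spec$episodes, seed = 100)
  c <- simulate_eeg(spec2)
  expect_false(identical(as.numeric(a$recording), as.numeric(c$recording)))
})

test_that("agent-specific background spectra peak in the right band", {
  for (case in list(list(agent = "propofol", lo = 8, hi = 12),
                    list(agent = "sevoflurane", lo = 4, hi = 8))) {
    spec <- eeg_sim_spec(case$agent, duration = 120, fs = 100, seed = 12)
    sim <- simulate_eeg(spec)
    x <- sim$recording[, 1]
    pg <- stats::spec.pgram(stats::ts(x, frequency = 100), plot = FALSE,
                            taper = 0)
    peak <- pg$freq[which.max(pg$spec)]
    expect_gte(peak, case$lo)
    expect_lte(peak, case$hi)
  }
})

test_that("episode validation rejects overlap and out-of-range plans", {
  ep2 <- data.frame(onset = c(5, 6), supp_dur = 2, burst_dur = 1, n_alt = 2)
  expect_error(eeg_sim_spec("propofol", duration = 30, fs = 100,
                            episodes = ep2), "overlap")
  ep3 <- data.frame(onset = 28, supp_dur = 2, burst_dur = 1, n_alt = 2)
  expect_error(eeg_sim_spec("propofol", duration = 30, fs = 100,
                            episodes = ep3), "outside")
})

test_that("generated bursts satisfy the detector's ACNS criteria", {
  spec <- eeg_sim_spec("propofol", duration = 60, fs = 178,
                       episodes = data.frame(onset = 10, supp_dur = 3,
                                             burst_dur = c(0.5, 1.5, 3),
                                             n_alt = 3)[1, , drop = FALSE],
                       seed = 8)
  for (bd in c(0.5, 1.5, 3)) {
    spec$episodes$burst_dur <- bd
    sim <- simulate_eeg(spec)
    sup <- sim$truth[sim$truth$label == "suppression", ]
    fs <- rec_fs(sim$recording)
    gaps_on <- (sup$onset + sup$duration)[-nrow(sup)]
    gaps_end <- sup$onset[-1]
    for (g in seq_along(gaps_on)) {
      expect_gte(gaps_end[g] - gaps_on[g], 0.5)
      seg <- sim$recording[(round(gaps_on[g] * fs) + 1):
                             round(gaps_end[g] * fs), 1]
      expect_gte(count_phases(seg), 4)
    }
    # and the detector finds them as bursts
    ch <- sim$recording[, 1]
    p <- detection_params()
    sups <- detect_suppressions(ch, fs, p)
    bursts <- detect_bursts(ch, fs, sups, p)
    expect_equal(nrow(bursts), nrow(sup) - 1L)
  }
})

test_that("one-sample-window summarisation recovers the injected truth", {
  spec <- eeg_sim_spec("sevoflurane", duration = 60, fs = 100,
                       episodes = data.frame(onset = 10, supp_dur = 4,
                                             burst_dur = 1, n_alt = 4),
                       seed = 31)
  sim <- simulate_eeg(spec)
  fs <- rec_fs(sim$recording)
  s <- detect_bs(sim$recording, detection_params(w_env = 1 / fs))
  true_total <- sum(sim$truth$duration[sim$truth$label == "suppression"])
  n_seg <- sum(sim$truth$label == "suppression")
  expect_lt(abs(s$bs_duration - true_total), 2 * n_seg / fs + 0.05)
  # episodes are delimited as one epoch matching the plan
  expect_equal(nrow(s$episodes), 1L)
  expect_equal(s$episodes$onset, 10, tolerance = 0.1)
})

test_that("corpus truth totals order propofol above sevoflurane", {
  corp <- simulate_corpus(n_per_group = 40, "low", duration = 60, fs = 50,
                          seed = 19)
  expect_length(corp, 80L)
  truths <- vapply(unclass(corp), function(l) interval_total(l$truth),
                   numeric(1))
  groups <- vapply(unclass(corp), `[[`, character(1), "group")
  # zero-inflation: a substantial share of recordings has no BS at all
  expect_gt(mean(truths == 0), 0.3)
  expect_gt(mean(truths[groups == "propofol"]),
            mean(truths[groups == "sevoflurane"]))
  # reproducible manifests
  corp2 <- simulate_corpus(n_per_group = 40, "low", duration = 60, fs = 50,
                           seed = 19)
  truths2 <- vapply(unclass(corp2), function(l) interval_total(l$truth),
                    numeric(1))
  expect_identical(truths, truths2)
  # "none" intensity: every truth empty
  corp0 <- simulate_corpus(n_per_group = 5, "none", duration = 30, fs = 50,
                           seed = 4)
  expect_true(all(vapply(unclass(corp0), function(l) nrow(l$truth) == 0L,
                         logical(1))))
})

test_that("cohort simulation honours its probability structure", {
  # null odds ratios: POD prevalence = baseline in all four cells
  spec <- cohort_sim_spec(n = 50000, or_bs = 1, or_sevo = 1,
                          or_interaction = 1, baseline_pod = 0.25, seed = 5)
  coh <- simulate_cohort(spec)
  for (ag in c("propofol", "sevoflurane")) for (bs in c(FALSE, TRUE)) {
    cell <- coh[coh$agent == ag & coh$any_bs == bs, ]
    se <- sqrt(0.25 * 0.75 / nrow(cell))
    expect_lt(abs(mean(cell$pod) - 0.25), 3 * se)
  }
  # cell frequencies converge to the spec probabilities (3-sigma bounds)
  spec <- cohort_sim_spec(n = 100000, seed = 6)
  coh <- simulate_cohort(spec)
  p_sevo_hat <- mean(coh$agent == "sevoflurane")
  expect_lt(abs(p_sevo_hat - spec$p_sevo),
            3 * sqrt(spec$p_sevo * (1 - spec$p_sevo) / spec$n))
  for (ag in c("propofol", "sevoflurane")) {
    p <- if (ag == "propofol") spec$p_bs_given_propofol else
      spec$p_bs_given_sevo
    sub <- coh[coh$agent == ag, ]
    expect_lt(abs(mean(sub$any_bs) - p), 3 * sqrt(p * (1 - p) / nrow(sub)))
  }
  # determinism and invariants
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  expect_true(all(coh$any_bs == (coh$bs_duration > 0)))
  expect_true(all(coh$bsr >= 0 & coh$bsr <= 100))
  expect_error(cohort_sim_spec(p_sevo = 1.2), "probabilities")
  expect_error(cohort_sim_spec(or_bs = -1), "odds")
})

test_that("empirical cell odds ratios match the generative structure", {
  coh <- simulate_cohort(cohort_sim_spec(n = 200000, seed = 23))
  cell_odds <- function(ag, bs) {
    p <- mean(coh$pod[coh$agent == ag & coh$any_bs == bs])
    p / (1 - p)
  }
  ref <- cell_odds("propofol", FALSE)
  expect_lt(abs(cell_odds("propofol", TRUE) / ref - 1.50) / 1.50, 0.05)
  expect_lt(abs(cell_odds("sevoflurane", FALSE) / ref - 1.63) / 1.63, 0.05)
  expect_lt(abs(cell_odds("sevoflurane", TRUE) / ref - 9.30) / 9.30, 0.05)
})
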