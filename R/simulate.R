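# Synthetic anesthesia EEG with ground-truth burst-suppression episodes, and
# synthetic patient cohorts with a conditional POD-risk structure. Every
# stochastic function takes an explicit seed and restores the caller's RNG
# state (withr::with_seed), so identical seeds give bit-identical output.

#' Specification for a simulated anesthesia EEG recording
#'
#' The background is broadband noise plus an agent-specific oscillation:
#' propofol recordings carry coherent alpha (10 Hz) and slow-delta (1.5 Hz)
#' power, sevoflurane recordings coherent theta (6 Hz). Burst-suppression
#' episodes are injected as alternating suppression segments (low-amplitude
#' noise) and polyphasic bursts, identically timed on all channels.
#'
#' @param agent `"propofol"` or `"sevoflurane"`.
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz (default 178, the frontal-monitor rate).
#' @param n_channels number of channels (default 4: Fp1, Fp2, F7, F8).
#' @param background_rms RMS amplitude of the background in uV (default 15).
#' @param episodes data frame with columns `onset` (s), `supp_dur` (s,
#'   duration of each suppression segment), `burst_dur` (s, duration of each
#'   intervening burst) and `n_alt` (number of suppression segments; an
#'   episode is supp, burst, supp, ..., supp). May have zero rows.
#' @param suppression_rms RMS of suppressed-segment noise in uV (default 1.5,
#'   well below any plausible suppression threshold).
#' @param burst_amp peak amplitude of burst waveforms in uV (default 40).
#' @param seed integer seed.
#' @return A list of class `"eeg_sim_spec"`.
#' @export
eeg_sim_spec <- function(agent = c("propofol", "sevoflurane"),
                         duration = 60, fs = 178, n_channels = 4,
                         background_rms = 15,
                         episodes = data.frame(onset = numeric(),
                                               supp_dur = numeric(),
                                               burst_dur = numeric(),
                                               n_alt = integer()),
                         suppression_rms = 1.5, burst_amp = 40,
                         seed = 1L) {
  agent <- match.arg(agent)
  stopifnot(duration > 0, fs > 0, n_channels >= 1,
            background_rms > 0, suppression_rms > 0, burst_amp > 0,
            all(c("onset", "supp_dur", "burst_dur", "n_alt") %in%
                  names(episodes)))
  if (nrow(episodes)) {
    len <- episode_length(episodes)
    ends <- episodes$onset + len
    if (any(episodes$onset < 0) || any(ends > duration))
      stop("episode extends outside [0, duration)")
    o <- order(episodes$onset)
    episodes <- episodes[o, , drop = FALSE]
    if (any(episodes$onset[-1L] < (episodes$onset + len[o])[-nrow(episodes)]))
      stop("overlapping burst-suppression episodes")
  }
  structure(list(agent = agent, duration = duration, fs = fs,
                 n_channels = n_channels, background_rms = background_rms,
                 episodes = episodes, suppression_rms = suppression_rms,
                 burst_amp = burst_amp, seed = as.integer(seed)),
            class = "eeg_sim_spec")
}

episode_length <- function(ep)
  ep$n_alt * ep$supp_dur + pmax(ep$n_alt - 1L, 0L) * ep$burst_dur

# Agent-specific background: oscillations carry most of the variance so the
# periodogram peak falls in the agent's band; the remainder is smoothed
# white noise.
sim_background <- function(n, fs, agent, rms) {
  t <- (seq_len(n) - 1L) / fs
  comps <- if (agent == "propofol") {
    list(c(f = 10, share = 0.55), c(f = 1.5, share = 0.15))
  } else {
    list(c(f = 6, share = 0.70))
  }
  noise_share <- 1 - sum(vapply(comps, `[[`, numeric(1L), "share"))
  x <- numeric(n)
  for (cm in comps)
    x <- x + sqrt(2 * cm[["share"]]) * rms *
      sin(2 * pi * cm[["f"]] * t + runif(1L, 0, 2 * pi))
  w <- rnorm(n)
  w <- as.numeric(stats::filter(w, rep(1 / 3, 3), sides = 2L))
  w[is.na(w)] <- 0
  w <- w / max(sd(w), 1e-12)
  x + sqrt(noise_share) * rms * w
}

# Polyphasic burst waveform: 9 Hz sine at burst_amp with a 50 ms raised-
# cosine taper at each end, plus a little noise. Any segment >= 0.5 s has
# >= 9 half-waves, satisfying the ACNS polyphasic criterion by construction.
sim_burst <- function(n, fs, amp) {
  t <- (seq_len(n) - 1L) / fs
  taper <- rep(1, n)
  m <- min(n, max(2L, round(0.05 * fs)))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = m)))
  taper[seq_len(m)] <- ramp
  taper[(n - m + 1L):n] <- rev(ramp)
  amp * taper * sin(2 * pi * 9 * t + runif(1L, 0, 2 * pi)) +
    rnorm(n, sd = amp * 0.02)
}

#' Simulate an anesthesia EEG recording with ground-truth annotations
#'
#' Deterministic given `spec$seed`: the same spec yields bit-identical
#' signals. Episode timing is identical across channels (the noise
#' realisations differ), so the ground truth holds for every channel and is
#' recorded on channel `"all"`. All ground-truth boundaries are snapped to
#' the sample grid.
#'
#' @param spec an [eeg_sim_spec].
#' @return A list with elements `recording` ([eeg_recording]) and `truth`
#'   ([bs_annotations]: every suppression segment, plus each episode as a
#'   `bs_epoch`).
#' @examples
#' spec <- eeg_sim_spec("propofol", duration = 20, fs = 100,
#'                      episodes = data.frame(onset = 5, supp_dur = 2,
#'                                            burst_dur = 1, n_alt = 2),
#'                      seed = 42)
#' sim <- simulate_eeg(spec)
#' sim$truth
#' @export
simulate_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  withr::with_seed(spec$seed, {
    fs <- spec$fs
    n <- round(spec$duration * fs)
    labels <- if (spec$n_channels == 4L) c("Fp1", "Fp2", "F7", "F8")
              else paste0("ch", seq_len(spec$n_channels))
    sig <- vapply(seq_len(spec$n_channels), function(j)
      sim_background(n, fs, spec$agent, spec$background_rms), numeric(n))
    sup_on <- numeric(); sup_dur <- numeric()
    ep_on <- numeric(); ep_dur <- numeric()
    if (nrow(spec$episodes)) {
      for (i in seq_len(nrow(spec$episodes))) {
        ep <- spec$episodes[i, ]
        # sample-aligned segment boundaries
        s0 <- round(ep$onset * fs)
        ns_sup <- round(ep$supp_dur * fs)
        ns_bur <- round(ep$burst_dur * fs)
        pos <- s0
        first_on <- pos / fs
        for (k in seq_len(ep$n_alt)) {
          idx <- (pos + 1L):(pos + ns_sup)
          for (j in seq_len(spec$n_channels))
            sig[idx, j] <- rnorm(ns_sup, sd = spec$suppression_rms)
          sup_on <- c(sup_on, pos / fs)
          sup_dur <- c(sup_dur, ns_sup / fs)
          pos <- pos + ns_sup
          if (k < ep$n_alt) {
            idx <- (pos + 1L):(pos + ns_bur)
            for (j in seq_len(spec$n_channels))
              sig[idx, j] <- sim_burst(ns_bur, fs, spec$burst_amp)
            pos <- pos + ns_bur
          }
        }
        ep_on <- c(ep_on, first_on)
        ep_dur <- c(ep_dur, pos / fs - first_on)
      }
    }
    truth <- bs_annotations(
      onset = c(sup_on, ep_on), duration = c(sup_dur, ep_dur),
      label = c(rep("suppression", length(sup_on)),
                rep("bs_epoch", length(ep_on))),
      channel = "all")
    list(recording = eeg_recording(sig, fs = fs, channel_labels = labels),
         truth = truth)
  })
}

#' Bundle a recording with its ground truth and anesthetic group
#'
#' @param recording an [eeg_recording].
#' @param truth a [bs_annotations] track of ground-truth/expert intervals;
#'   must lie within the recording span.
#' @param group `"propofol"` or `"sevoflurane"`.
#' @param recording_id identifier string.
#' @return A list of class `"labeled_recording"`.
#' @export
labeled_recording <- function(recording, truth,
                              group = c("propofol", "sevoflurane"),
                              recording_id = "") {
  group <- match.arg(group)
  stopifnot(inherits(recording, "eeg_recording"))
  truth <- validate_annotations(truth)
  if (nrow(truth) &&
      any(truth$onset + truth$duration > rec_duration(recording) + 1e-6))
    stop("ground-truth interval extends beyond the recording span")
  structure(list(recording = recording, truth = truth, group = group,
                 recording_id = as.character(recording_id)),
            class = "labeled_recording")
}

#' Simulate a corpus of labelled recordings for detector calibration
#'
#' Generates `n_per_group` recordings per anesthetic agent. Under the `"low"`
#' episode intensity, the total true suppression per recording follows a
#' zero-inflated log-normal: propofol recordings are suppression-free with
#' probability 0.45 (non-zero totals log-normal, median 20 s), sevoflurane
#' with probability 0.65 (median 5 s) — propofol recordings thus carry
#' stochastically longer BS, mirroring the clinical ordering. Totals are
#' capped at 40% of the recording and laid out as one episode of alternating
#' suppressions and bursts. `"high"` halves the zero-inflation and doubles
#' the scale; `"none"` injects no episodes.
#'
#' @param n_per_group recordings per agent.
#' @param intensity `"none"`, `"low"` or `"high"`.
#' @param duration recording length in seconds (default 600).
#' @param fs sampling rate (default 178).
#' @param seed integer seed; recording i uses sub-seed `seed + i`.
#' @return A list of class `"bs_corpus"` of [labeled_recording] objects.
#' @export
simulate_corpus <- function(n_per_group = 30,
                            intensity = c("low", "none", "high"),
                            duration = 600, fs = 178, seed = 1L) {
  intensity <- match.arg(intensity)
  zero_p <- c(propofol = 0.45, sevoflurane = 0.65)
  meanlog <- c(propofol = log(20), sevoflurane = log(5))
  sdlog <- c(propofol = 1.0, sevoflurane = 1.0)
  if (intensity == "high") {
    zero_p <- zero_p / 2
    meanlog <- meanlog + log(2)
  }
  out <- vector("list", 2L * n_per_group)
  i <- 0L
  for (agent in c("propofol", "sevoflurane")) {
    for (r in seq_len(n_per_group)) {
      i <- i + 1L
      sub <- as.integer(seed) + i
      plan <- withr::with_seed(sub, {
        if (intensity == "none" || runif(1L) < zero_p[[agent]]) {
          data.frame(onset = numeric(), supp_dur = numeric(),
                     burst_dur = numeric(), n_alt = integer())
        } else {
          total <- min(rlnorm(1L, meanlog[[agent]], sdlog[[agent]]),
                       0.4 * duration)
          seg <- runif(1L, 1.5, 8)
          burst <- runif(1L, 1, 3)
          n_alt <- max(1L, min(20L, round(total / seg)))
          # keep the whole episode (with its bursts) inside the recording
          n_fit <- max(1L, floor((duration - 20 - total) / burst) + 1L)
          n_alt <- min(n_alt, n_fit)
          seg <- total / n_alt
          len <- n_alt * seg + (n_alt - 1L) * burst
          onset <- runif(1L, 10, duration - len - 10)
          data.frame(onset = onset, supp_dur = seg, burst_dur = burst,
                     n_alt = n_alt)
        }
      })
      sim <- simulate_eeg(eeg_sim_spec(
        agent = agent, duration = duration, fs = fs, episodes = plan,
        seed = sub + 1000000L))
      out[[i]] <- labeled_recording(sim$recording, sim$truth, group = agent,
                                    recording_id = sprintf("%s_%02d",
                                                           agent, r))
    }
  }
  structure(out, class = "bs_corpus")
}

#' @export
print.bs_corpus <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1L), "group")
  truths <- vapply(x, function(l) interval_total(l$truth), numeric(1L))
  cat("<bs_corpus> ", length(x), " labelled recording(s): ",
      paste(names(table(groups)), table(groups), sep = "=", collapse = ", "),
      "\n  true suppression per recording: median ",
      format(median(truths), digits = 4), " s, max ",
      format(max(truths), digits = 4), " s, ",
      sum(truths == 0), " zero(s)\n", sep = "")
  invisible(x)
}

#' Specification for a simulated patient cohort
#'
#' Encodes the conditional POD-risk structure: relative to the propofol /
#' no-BS reference cell, BS under propofol multiplies the POD odds by
#' `or_bs`, sevoflurane without BS by `or_sevo`, and sevoflurane with BS by
#' `or_sevo * or_bs * or_interaction` (defaults 1.63 x 1.50 x 3.80 = 9.30).
#'
#' @param n number of patients.
#' @param p_sevo probability of sevoflurane maintenance (default 126/265).
#' @param p_bs_given_propofol,p_bs_given_sevo probability of any
#'   intraoperative BS by agent (propofol patients suppress more often).
#' @param baseline_pod POD probability in the propofol / no-BS cell.
#' @param or_bs,or_sevo,or_interaction odds ratios of the risk structure.
#' @param age_mean,age_sd age distribution (years), truncated at 70.
#' @param asa_probs probabilities of ASA classes 1–4.
#' @param surgery_meanlog,surgery_sdlog log-normal surgery duration (hours).
#' @param p_recovery probability of postoperative recovery-room (vs
#'   PACU/ICU) care.
#' @param duration_or_per_h if not `NULL`, adds a per-hour surgery-duration
#'   effect on the POD odds (centred at the mean duration), e.g. 1.27.
#' @param seed integer seed.
#' @return A list of class `"cohort_sim_spec"`.
#' @export
cohort_sim_spec <- function(n = 265, p_sevo = 126 / 265,
                            p_bs_given_propofol = 0.55,
                            p_bs_given_sevo = 0.35,
                            baseline_pod = 0.25,
                            or_bs = 1.50, or_sevo = 1.63,
                            or_interaction = 3.80,
                            age_mean = 77, age_sd = 4,
                            asa_probs = c(0.03, 0.44, 0.51, 0.02),
                            surgery_meanlog = log(2.5), surgery_sdlog = 0.45,
                            p_recovery = 0.49,
                            duration_or_per_h = NULL, seed = 1L) {
  probs <- c(p_sevo, p_bs_given_propofol, p_bs_given_sevo, baseline_pod,
             p_recovery)
  if (any(probs <= 0) || any(probs >= 1))
    stop("all probabilities must lie strictly in (0, 1)")
  ors <- c(or_bs, or_sevo, or_interaction)
  if (any(ors <= 0)) stop("odds ratios must be positive")
  if (abs(sum(asa_probs) - 1) > 1e-6 || length(asa_probs) != 4L)
    stop("asa_probs must be 4 probabilities summing to 1")
  structure(list(n = as.integer(n), p_sevo = p_sevo,
                 p_bs_given_propofol = p_bs_given_propofol,
                 p_bs_given_sevo = p_bs_given_sevo,
                 baseline_pod = baseline_pod, or_bs = or_bs,
                 or_sevo = or_sevo, or_interaction = or_interaction,
                 age_mean = age_mean, age_sd = age_sd,
                 asa_probs = asa_probs,
                 surgery_meanlog = surgery_meanlog,
                 surgery_sdlog = surgery_sdlog, p_recovery = p_recovery,
                 duration_or_per_h = duration_or_per_h,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a patient cohort with the anesthetic-by-BS POD risk structure
#'
#' Per patient: agent ~ Bernoulli(`p_sevo`); `any_bs` ~ Bernoulli of the
#' agent-specific BS probability; POD ~ Bernoulli with
#' `logit(p) = logit(baseline_pod) + log(or_sevo)*sevo + log(or_bs)*bs +
#' log(or_interaction)*sevo*bs` (plus an optional centred surgery-duration
#' term). Covariates are drawn independently of POD unless
#' `duration_or_per_h` is set. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_sim_spec].
#' @return A data frame of class `"pod_cohort"` with columns `id`, `agent`,
#'   `pod`, `age`, `asa`, `surgery_duration` (hours), `bs_duration` (s),
#'   `bsr` (%), `any_bs`, `care_location`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n
    sevo <- rbinom(n, 1L, spec$p_sevo)
    p_bs <- ifelse(sevo == 1L, spec$p_bs_given_sevo,
                   spec$p_bs_given_propofol)
    bs <- rbinom(n, 1L, p_bs)
    surgery <- rlnorm(n, spec$surgery_meanlog, spec$surgery_sdlog)
    lin <- qlogis(spec$baseline_pod) + log(spec$or_sevo) * sevo +
      log(spec$or_bs) * bs + log(spec$or_interaction) * sevo * bs
    if (!is.null(spec$duration_or_per_h))
      lin <- lin + log(spec$duration_or_per_h) * (surgery - mean(surgery))
    pod <- rbinom(n, 1L, plogis(lin))
    age <- pmax(70, rnorm(n, spec$age_mean, spec$age_sd))
    asa <- sample.int(4L, n, replace = TRUE, prob = spec$asa_probs)
    # BS duration given presence: log-normal, longer under propofol
    dur <- ifelse(bs == 1L,
                  rlnorm(n, meanlog = ifelse(sevo == 1L, log(5), log(30)),
                         sdlog = 1.1),
                  0)
    bsr <- pmin(100, 100 * dur / (surgery * 3600))
    care <- ifelse(runif(n) < spec$p_recovery, "recovery", "pacu_icu")
    out <- data.frame(
      id = sprintf("pt%05d", seq_len(n)),
      agent = factor(ifelse(sevo == 1L, "sevoflurane", "propofol"),
                     levels = c("propofol", "sevoflurane")),
      pod = pod == 1L,
      age = age,
      asa = asa,
      surgery_duration = surgery,
      bs_duration = dur,
      bsr = bsr,
      any_bs = bs == 1L,
      care_location = factor(care, levels = c("recovery", "pacu_icu")),
      stringsAsFactors = FALSE
    )
    class(out) <- c("pod_cohort", "data.frame")
    validate_cohort(out)
  })
}
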