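#' Pulsatile magnetic-tweezers force protocol
#'
#' The standard mechanosensing regime: a 3 s, 6 nN force pulse followed by a
#' 4 s rest, repeated for 12 pulses (~100 s including margins). Bead
#' displacement amplitude per pulse, normalised to the first pulse, reports
#' cytoskeletal reinforcement.
#'
#' @param pulse_force pulse force in nN.
#' @param pulse_on pulse duration in s.
#' @param pulse_off rest duration in s.
#' @param n_pulses number of pulses (>= 2).
#' @param force_axis unit vector of the pulling direction in the image plane.
#' @return object of class `force_protocol`.
#' @export
force_protocol <- function(pulse_force = 6, pulse_on = 3, pulse_off = 4,
                           n_pulses = 12, force_axis = c(1, 0)) {
  stopifnot(pulse_on > 0, pulse_off > 0, n_pulses >= 2,
            length(force_axis) == 2, sum(force_axis^2) > 0)
  force_axis <- force_axis / sqrt(sum(force_axis^2))
  structure(list(pulse_force = pulse_force, pulse_on = pulse_on,
                 pulse_off = pulse_off, n_pulses = as.integer(n_pulses),
                 force_axis = force_axis),
            class = "force_protocol")
}

#' Bead trajectory container
#'
#' @param time time stamps in s (strictly increasing, uniform within 1%).
#' @param position n x 2 matrix of bead positions in um.
#' @return object of class `bead_trajectory`.
#' @export
bead_trajectory <- function(time, position) {
  position <- as.matrix(position)
  stopifnot(length(time) == nrow(position), ncol(position) == 2,
            all(diff(time) > 0))
  dt <- diff(time)
  if ((max(dt) - min(dt)) > 0.01 * mean(dt))
    stop("time stamps are not uniformly spaced (within 1%)")
  structure(list(time = as.numeric(time), position = position,
                 frame_rate = 1 / mean(dt)),
            class = "bead_trajectory")
}

#' Generate a synthetic bead trajectory under the pulsatile regime
#'
#' Simulates square-wave-driven creep along the force axis: during pulse i
#' the displacement rises as a power-law creep to amplitude A_i above the
#' pre-pulse baseline; during rest it relaxes exponentially to a residual
#' (incomplete recovery, so the baseline accumulates as in real bead traces).
#' Per-pulse amplitudes interpolate linearly from `amp1` (pulse 1) to
#' `amp1 * relamp12` (pulse 12). Gaussian tracking noise and linear drift are
#' added on top. The 12 true amplitudes are stored in the ground truth.
#'
#' @param protocol a [force_protocol()].
#' @param amp1 amplitude of the first pulse in um (> 0).
#' @param relamp12 ratio of 12th- to 1st-pulse amplitude (> 0).
#' @param noise_sd Gaussian tracking noise SD in um (5 nm default).
#' @param drift linear drift along the force axis in um/s.
#' @param frame_rate acquisition rate in Hz (>= 2 to resolve the pulse).
#' @param seed integer seed.
#' @param t0 onset of the first pulse in s.
#' @param creep_exponent power-law exponent of the within-pulse creep.
#' @param recovery_fraction fraction of each pulse amplitude left un-recovered
#'   at the end of the rest phase.
#' @return list with `trajectory` (a [bead_trajectory()]) and `truth`
#'   (a [ground_truth()] storing the amplitude schedule, t0 and the axis).
#' @export
generate_bead_trajectory <- function(protocol = force_protocol(),
                                     amp1 = 1, relamp12 = 0.63,
                                     noise_sd = 0.005, drift = 0,
                                     frame_rate = 10, seed = 1, t0 = 2,
                                     creep_exponent = 0.3,
                                     recovery_fraction = 0.3) {
  stopifnot(inherits(protocol, "force_protocol"))
  if (!(amp1 > 0)) stop("amp1 must be positive")
  if (!(relamp12 > 0)) stop("relamp12 must be positive")
  if (frame_rate < 2) stop("frame_rate must resolve the pulse (>= 2 Hz)")
  np <- protocol$n_pulses
  period <- protocol$pulse_on + protocol$pulse_off
  amps <- amp1 * (1 + (seq_len(np) - 1) / (np - 1) * (relamp12 - 1))
  t_end <- t0 + np * period + 2
  time <- seq(0, t_end, by = 1 / frame_rate)
  u <- numeric(length(time))       # displacement along the force axis
  base <- 0
  tau <- 0.5                        # rest-phase recovery time constant, s
  for (i in seq_len(np)) {
    on0 <- t0 + (i - 1) * period
    on1 <- on0 + protocol$pulse_on
    in_on <- time >= on0 & time <= on1
    u[in_on] <- base + amps[i] * ((time[in_on] - on0) / protocol$pulse_on)^creep_exponent
    in_off <- time > on1 & time < on0 + period + 1e-9
    resid <- base + recovery_fraction * amps[i]
    u[in_off] <- resid + (1 - recovery_fraction) * amps[i] *
      exp(-(time[in_off] - on1) / tau)
    base <- resid + (1 - recovery_fraction) * amps[i] *
      exp(-protocol$pulse_off / tau)
  }
  ax <- protocol$force_axis
  perp <- c(-ax[2], ax[1])
  withr::with_seed(seed, {
    n <- length(time)
    upar <- u + drift * time + rnorm(n, sd = noise_sd)
    uperp <- rnorm(n, sd = noise_sd)
  })
  pos <- outer(upar, ax) + outer(uperp, perp)
  truth <- ground_truth("tweezers", list(
    amplitudes_um = amps, relamp12 = relamp12, amp1_um = amp1, t0_s = t0,
    force_axis = ax, drift_um_per_s = drift, noise_sd_um = noise_sd
  ), seed)
  list(trajectory = bead_trajectory(time, pos), truth = truth)
}

#' Segment a trajectory into pulse and baseline windows
#'
#' Window i covers the 3 s force-on phase starting at `t0 + (i-1) * 7` s
#' (for the default protocol); its baseline window is the final 1 s of the
#' preceding rest (the 1 s before `t0` for pulse 1).
#'
#' @param traj a [bead_trajectory()].
#' @param protocol a [force_protocol()].
#' @param t0 onset of the first pulse in s.
#' @param baseline_s length of the pre-pulse baseline window in s.
#' @return list of `n_pulses` elements, each with integer index vectors `on`
#'   and `baseline`.
#' @export
segment_pulses <- function(traj, protocol, t0, baseline_s = 1) {
  stopifnot(inherits(traj, "bead_trajectory"),
            inherits(protocol, "force_protocol"))
  period <- protocol$pulse_on + protocol$pulse_off
  t_need <- t0 + protocol$n_pulses * period
  t_max <- max(traj$time)
  if (t_max < t_need - protocol$pulse_off) {
    complete <- max(0, floor((t_max - t0 - protocol$pulse_on) / period) + 1)
    complete <- min(complete, protocol$n_pulses)
    stop("trajectory too short for ", protocol$n_pulses, " pulses: only ",
         complete, " complete pulses found")
  }
  lapply(seq_len(protocol$n_pulses), function(i) {
    on0 <- t0 + (i - 1) * period
    on1 <- on0 + protocol$pulse_on
    on <- which(traj$time >= on0 - 1e-9 & traj$time <= on1 + 1e-9)
    bl <- which(traj$time >= on0 - baseline_s - 1e-9 & traj$time < on0 - 1e-9)
    if (length(on) == 0 || length(bl) == 0)
      stop("empty pulse or baseline window for pulse ", i)
    list(on = on, baseline = bl)
  })
}

#' Extract the displacement amplitude of one pulse
#'
#' Amplitude = (maximum displacement projected on the force axis during the
#' on-window) minus (median projected displacement in the pre-pulse baseline
#' window), clipped at zero (movement against the force is noise).
#'
#' @param traj a [bead_trajectory()].
#' @param window one element of [segment_pulses()] output.
#' @param protocol a [force_protocol()].
#' @return amplitude in um (scalar, >= 0).
#' @export
pulse_amplitude <- function(traj, window, protocol) {
  stopifnot(length(window$on) > 0, length(window$baseline) > 0)
  proj <- as.numeric(traj$position %*% protocol$force_axis)
  max(0, max(proj[window$on]) - median(proj[window$baseline]))
}

#' Normalise per-pulse amplitudes to the first pulse
#'
#' @param absolute numeric vector of absolute amplitudes in um (A1 > 0).
#' @return object of class `pulse_amplitudes` with `absolute` and `relative`
#'   (`relative[1]` is exactly 1).
#' @export
normalize_amplitudes <- function(absolute) {
  stopifnot(is.numeric(absolute), length(absolute) >= 2, all(absolute >= 0))
  if (absolute[1] <= 0)
    stop("first-pulse amplitude is zero: cell cannot be analysed")
  structure(list(absolute = absolute, relative = absolute / absolute[1]),
            class = "pulse_amplitudes")
}

#' Extract and normalise all pulse amplitudes from one trajectory
#'
#' @inheritParams segment_pulses
#' @return a `pulse_amplitudes` object.
#' @export
extract_pulse_amplitudes <- function(traj, protocol, t0, baseline_s = 1) {
  wins <- segment_pulses(traj, protocol, t0, baseline_s)
  abs_amp <- vapply(wins, function(w) pulse_amplitude(traj, w, protocol),
                    numeric(1))
  normalize_amplitudes(abs_amp)
}

#' Cohort-level mechanosensing (reinforcement) test
#'
#' Pairs each cell's 1st- and 12th-pulse absolute amplitudes and applies the
#' two-sided Wilcoxon signed-rank test; a significant decrease indicates
#' cytoskeletal reinforcement. Also reports the cohort mean and SEM of the
#' relative 12th-pulse amplitude.
#'
#' @param cohort list of `pulse_amplitudes` objects (>= 6 cells).
#' @return a `stat_result` (see [paired_test()]) with extra fields
#'   `mean_relamp12` and `sem_relamp12`.
#' @export
reinforcement_test <- function(cohort) {
  stopifnot(length(cohort) >= 6,
            all(vapply(cohort, inherits, logical(1), "pulse_amplitudes")))
  a1 <- vapply(cohort, function(p) p$absolute[1], numeric(1))
  a12 <- vapply(cohort, function(p) tail(p$absolute, 1), numeric(1))
  rel12 <- vapply(cohort, function(p) tail(p$relative, 1), numeric(1))
  res <- paired_test(a1, a12)
  res$mean_relamp12 <- mean(rel12)
  res$sem_relamp12 <- sd(rel12) / sqrt(length(rel12))
  res
}
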