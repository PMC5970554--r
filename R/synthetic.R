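#' Session profile for the synthetic anaesthesia generator
#'
#' Bundles the parameters describing one simulated anaesthesia session: its
#' duration, sampling rate, the ground-truth consciousness trajectory on the
#' 0-100 index scale, the amplitude of mains interference, and the rate of
#' amplitude-saturation artefacts.
#'
#' @param duration_s Session length in seconds (> 60).
#' @param fs Sampling rate in Hz (default 128, the acquisition rate of
#'   clinical BIS-sensor front ends).
#' @param trajectory Function mapping time (seconds) to the ground-truth
#'   index in \[0, 100\]. Defaults to [default_trajectory()] scaled to
#'   `duration_s`.
#' @param line_noise_amp Amplitude of the 60-Hz mains sinusoid, in µV.
#' @param artefact_rate Expected number of saturation artefacts per hour.
#' @param seed Integer seed; the same profile always generates a bit-identical
#'   session.
#' @return An object of class `session_profile`.
#' @seealso [generate_session()]
#' @export
session_profile <- function(duration_s = 600, fs = 128,
                            trajectory = NULL,
                            line_noise_amp = 2, artefact_rate = 6,
                            seed = 1L) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 60)
    stop("duration_s must be a single number > 60")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(trajectory)) trajectory <- default_trajectory(duration_s)
  if (!is.function(trajectory)) stop("trajectory must be a function of time")
  probe <- trajectory(seq(0, duration_s, length.out = 101))
  if (any(!is.finite(probe)) || any(probe < 0) || any(probe > 100))
    stop("trajectory must return finite values within [0, 100]")
  if (line_noise_amp < 0) stop("line_noise_amp must be >= 0")
  if (artefact_rate < 0) stop("artefact_rate must be >= 0")
  structure(list(duration_s = duration_s, fs = fs, trajectory = trajectory,
                 line_noise_amp = line_noise_amp,
                 artefact_rate = artefact_rate, seed = as.integer(seed)),
            class = "session_profile")
}

#' Default consciousness trajectory
#'
#' A piecewise-smooth awake / induction / maintenance / emergence / recovery
#' profile on the 0-100 index scale: fully awake (index 96) for the first
#' tenth of the session, a smooth induction drop to deep maintenance
#' (index around 30, with a slow wobble), then emergence back to 92.
#' Transitions use smoothstep ramps so the trajectory is continuous and
#' differentiable.
#'
#' @param duration_s Session length the profile is scaled to.
#' @return A vectorised function of time (seconds).
#' @export
default_trajectory <- function(duration_s) {
  smoothstep <- function(z) {
    z <- pmin(pmax(z, 0), 1)
    z * z * (3 - 2 * z)
  }
  force(duration_s)
  function(t) {
    f <- t / duration_s
    awake <- 96
    deep <- 30
    reco <- 92
    # awake 0-10%, induction 10-25%, maintenance 25-75%, emergence 75-92%
    u <- awake -
      (awake - deep) * smoothstep((f - 0.10) / 0.15) +
      (reco - deep) * smoothstep((f - 0.75) / 0.17)
    # slow physiological wobble during maintenance, +/- 3 index units
    wob <- 3 * sin(2 * pi * t / 180) *
      smoothstep((f - 0.20) / 0.1) * (1 - smoothstep((f - 0.70) / 0.1))
    pmin(pmax(u + wob, 0), 100)
  }
}

# Regime interpolation tables: component amplitudes (µV) as a function of the
# trajectory value. High index = broadband low-amplitude noise; low index =
# large slow-delta oscillations with burst suppression gating.
.regime_knots <- c(0, 20, 40, 65, 85, 100)
.regime_broadband <- c(1.5, 2.0, 3.0, 5.0, 9.0, 10.0)
.regime_delta <- c(18, 16, 12, 6, 2, 1)
.regime_alpha <- c(4, 9, 12, 7, 3, 2)

regime_amplitudes <- function(u) {
  list(
    broadband = approx(.regime_knots, .regime_broadband, u, rule = 2)$y,
    delta = approx(.regime_knots, .regime_delta, u, rule = 2)$y,
    alpha = approx(.regime_knots, .regime_alpha, u, rule = 2)$y
  )
}

# Two-state semi-Markov burst-suppression gate over the full timeline:
# suppression dwell U(0.5, 3) s, burst dwell U(0.5, 2) s. Returns a per-sample
# multiplicative gate (suppression ~ 0.08, burst ~ 1.3), later blended in by
# depth so it only acts where the index is below 40.
bs_gate <- function(n, fs) {
  gate <- numeric(0)
  state <- 1L # start in a burst
  while (length(gate) < n) {
    dur <- if (state == 1L) runif(1, 0.5, 2) else runif(1, 0.5, 3)
    lev <- if (state == 1L) 1.3 else 0.08
    gate <- c(gate, rep(lev, max(1L, round(dur * fs))))
    state <- 1L - state
  }
  gate[seq_len(n)]
}

#' Generate a synthetic anaesthesia session
#'
#' Synthesises an EEG-like signal whose composition is a deterministic
#' function of the consciousness trajectory, together with a co-sampled
#' BIS-like reference index (one value every 5 s) and a list of injected
#' saturation artefacts. The signal mixes: broadband Gaussian noise
#' (dominant while awake), slow-delta (0.5-4 Hz) and alpha (8-12 Hz)
#' oscillations whose amplitudes grow with depth, a burst-suppression gate
#' active below index 40, a fixed-amplitude EMG-like high-frequency noise
#' floor, and a 60-Hz mains sinusoid. Artefact events are rail-clipped
#' plateaus. The same profile (including seed) gives bit-identical output.
#'
#' @param profile A [session_profile()].
#' @return An object of class `doa_session`: a list with elements `eeg`
#'   (an [eeg_record()]), `truth_index` (data.frame `time_s`, `index`),
#'   `events` (data.frame `start_s`, `end_s` of injected artefacts) and
#'   `profile`.
#' @examples
#' s <- generate_session(session_profile(duration_s = 120, seed = 7))
#' length(s$eeg$samples) # 120 * 128
#' @export
generate_session <- function(profile) {
  if (!inherits(profile, "session_profile"))
    stop("profile must be a session_profile object")
  with_seed(profile$seed, {
    fs <- profile$fs
    n <- round(profile$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    u <- pmin(pmax(profile$trajectory(t), 0), 100)
    amp <- regime_amplitudes(u)

    # broadband component: white Gaussian noise
    broadband <- amp$broadband * rnorm(n)

    # slow-delta and alpha oscillations with slowly drifting frequency and
    # randomised phase, integrated so frequency changes stay continuous
    f_delta <- 1.6 + 0.9 * sin(2 * pi * t / 41 + runif(1, 0, 2 * pi))
    f_alpha <- 10 + 0.8 * sin(2 * pi * t / 23 + runif(1, 0, 2 * pi))
    ph_d <- 2 * pi * cumsum(f_delta) / fs + runif(1, 0, 2 * pi)
    ph_a <- 2 * pi * cumsum(f_alpha) / fs + runif(1, 0, 2 * pi)
    delta <- amp$delta * sin(ph_d)
    alpha <- amp$alpha * sin(ph_a)

    # burst-suppression gating, blended in below index 40
    w_bs <- pmin(pmax((40 - u) / 40, 0), 1)
    gate <- bs_gate(n, fs)
    mult <- (1 - w_bs) + w_bs * gate
    x <- (broadband + delta + alpha) * mult

    # state-independent contaminations, as on an unshielded frontal channel:
    # (a) EMG-like high-frequency noise with a slowly varying lognormal
    #     burst envelope (facial muscle activity), base RMS 3.5 µV
    emg <- diff(c(0, rnorm(n)))
    emg <- emg / pop_sd(emg)
    env_knots <- seq(0, profile$duration_s, by = 5)
    env <- exp(0.5 * stats::spline(env_knots, rnorm(length(env_knots)),
                                   xout = t)$y)
    x <- x + 3.5 * env / mean(env) * emg
    # (b) slow baseline wander (electrode drift / sweat), < 0.1 Hz, with a
    #     randomly varying amplitude around 30 µV RMS
    dr_knots <- seq(0, profile$duration_s, by = 15)
    drift <- stats::spline(dr_knots, rnorm(length(dr_knots)), xout = t)$y
    x <- x + 30 * drift

    # 60-Hz mains interference
    x <- x + profile$line_noise_amp * sin(2 * pi * 60 * t + runif(1, 0, 2 * pi))

    # saturation artefacts: rail-clipped plateaus at just above signal max
    n_events <- rpois(1, profile$artefact_rate * profile$duration_s / 3600)
    events <- data.frame(start_s = numeric(0), end_s = numeric(0))
    if (n_events > 0) {
      rail <- 1.05 * max(abs(x))
      starts <- sort(runif(n_events, 0, profile$duration_s - 2.5))
      durs <- runif(n_events, 0.5, 2)
      signs <- sign(rnorm(n_events))
      signs[signs == 0] <- 1
      for (k in seq_len(n_events)) {
        i0 <- floor(starts[k] * fs) + 1
        i1 <- min(n, i0 + round(durs[k] * fs) - 1)
        x[i0:i1] <- signs[k] * rail
      }
      events <- data.frame(start_s = (floor(starts * fs)) / fs,
                           end_s = pmin(profile$duration_s,
                                        (floor(starts * fs) + round(durs * fs)) / fs))
    }

    # BIS-like reference: trajectory sampled every 5 s + bounded noise
    t_ref <- seq(5, profile$duration_s, by = 5)
    ref <- profile$trajectory(t_ref) + rnorm(length(t_ref), sd = 2)
    ref <- pmin(pmax(ref, 0), 100)

    structure(list(
      eeg = eeg_record(x, fs = fs),
      truth_index = data.frame(time_s = t_ref, index = ref),
      events = events,
      profile = profile
    ), class = "doa_session")
  })
}

#' @export
print.doa_session <- function(x, ...) {
  cat(sprintf("<doa_session> %g s at %g Hz (%d samples), %d reference points, %d artefact events\n",
              x$profile$duration_s, x$profile$fs, length(x$eeg$samples),
              nrow(x$truth_index), nrow(x$events)))
  invisible(x)
}
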