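#' @useDynLib striacell, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Configuration for the current-clamp trace simulator
#'
#' Phenomenological single-cell simulator: a leaky-integrator membrane
#' with a slow H-current-like gate (sag + rebound), a spike-triggered
#' adaptation current, and stereotyped spike-waveform playback, so that
#' every ground-truth feature is exactly controllable. Archetypes mirror
#' the intrinsic phenotypes of striatal interneurons:
#' \itemize{
#' \item `fast_spiking`: brief APs (0.35 ms), high maximal rate, deep AHP,
#'   minimal adaptation, high rheobase.
#' \item `fast_spiking_like`: as fast-spiking with broader APs and lower
#'   maximal rate.
#' \item `late_spiking`: delayed first spike at rheobase (slow depolarizing
#'   ramp), moderate APs.
#' \item `bursting_low_threshold`: low rheobase, pronounced sag and
#'   rebound, moderate adaptation.
#' \item `regular`: broad APs (1 ms), low maximal rate, strong adaptation.
#' \item `passive`: spiking disabled (pure RC benchmark).
#' }
#'
#' @param archetype one of the names above.
#' @param ... overrides for any default field (e.g. `r_in`, `tau`,
#'   `rheobase`, `noise_sd`, `fs`, `half_width`).
#' @return a `TraceSimConfig` list. Fields include membrane `e_rest` (mV),
#'   `r_in` (MOhm), `tau` (s); spike `amp` (mV), `t_rise` (s),
#'   `half_width` (ms, sets the fall time), `ahp_depth` (mV), `t_ref` (s);
#'   `adapt_inc` (pA), `tau_adapt` (s); `sag_frac`, `tau_sag` (s),
#'   `reb_gain` (pA); `rheobase` (pA), `block_offset` (pA above rheobase
#'   where depolarization block silences the cell); `latency_target` (s,
#'   late-spiking only); protocol `fs`, `onset`, `offset`, `post`,
#'   `hyper_currents`; `noise_sd` (mV recording noise).
#' @export
traceSimConfig <- function(archetype = c("fast_spiking",
                                         "fast_spiking_like",
                                         "late_spiking",
                                         "bursting_low_threshold",
                                         "regular", "passive"), ...) {
  archetype <- match.arg(archetype)
  base <- list(archetype = archetype, e_rest = -70, fs = 20000,
               onset = 0.1, offset = 0.6, post = 0.2, noise_sd = 0.1,
               hyper_currents = c(-100, -60, -20), tau_sag = 0.4,
               ramp_frac = 0, ramp_tau = 0.05, latency_target = NA,
               block_offset = 320)
  arch <- switch(archetype,
    fast_spiking = list(r_in = 120, tau = 0.010, amp = 75, t_rise = 2.5e-4,
                        half_width = 0.35, ahp_depth = 20, t_ref = 0.0035,
                        adapt_inc = 2, tau_adapt = 0.05, sag_frac = 0.03,
                        reb_gain = 5, rheobase = 220),
    fast_spiking_like = list(r_in = 150, tau = 0.013, amp = 75,
                             t_rise = 3e-4, half_width = 0.45,
                             ahp_depth = 18, t_ref = 0.0045,
                             adapt_inc = 4, tau_adapt = 0.08,
                             sag_frac = 0.05, reb_gain = 8,
                             rheobase = 150),
    late_spiking = list(r_in = 250, tau = 0.020, amp = 80, t_rise = 4e-4,
                        half_width = 0.8, ahp_depth = 14, t_ref = 0.007,
                        adapt_inc = 3, tau_adapt = 0.1, sag_frac = 0.02,
                        reb_gain = 5, rheobase = 60, ramp_frac = 0.6,
                        latency_target = 0.15, block_offset = 240),
    bursting_low_threshold = list(r_in = 300, tau = 0.030, amp = 75,
                                  t_rise = 4e-4, half_width = 0.7,
                                  ahp_depth = 10, t_ref = 0.006,
                                  adapt_inc = 8, tau_adapt = 0.2,
                                  sag_frac = 0.18, reb_gain = 30,
                                  rheobase = 40, block_offset = 180),
    regular = list(r_in = 180, tau = 0.025, amp = 85, t_rise = 7e-4,
                   half_width = 1.0, ahp_depth = 12, t_ref = 0.010,
                   adapt_inc = 15, tau_adapt = 0.3, sag_frac = 0.05,
                   reb_gain = 8, rheobase = 80, block_offset = 220),
    passive = list(r_in = 100, tau = 0.020, amp = 80, t_rise = 3e-4,
                   half_width = 0.5, ahp_depth = 15, t_ref = 0.005,
                   adapt_inc = 0, tau_adapt = 0.1, sag_frac = 0,
                   reb_gain = 0, rheobase = 1e6))
  cfg <- utils::modifyList(utils::modifyList(base, arch), list(...))
  if (cfg$fs < 10000) stop("fs must be >= 10 kHz")
  if (!length(cfg$hyper_currents) || any(cfg$hyper_currents >= 0))
    stop("protocol must include hyperpolarizing steps")
  structure(cfg, class = "TraceSimConfig")
}

.spikeFallTime <- function(cfg) {
  # half-width (ms) = t_rise/2 + t_fall * amp / (2 (amp + ahp_depth))
  hw <- cfg$half_width / 1000
  (hw - cfg$t_rise / 2) * 2 * (cfg$amp + cfg$ahp_depth) / cfg$amp
}

.protocolCurrents <- function(cfg) {
  I0 <- cfg$rheobase
  if (cfg$archetype == "passive") return(cfg$hyper_currents)
  dep <- c(I0 + (-3:2),
           round(seq(I0 + 25, I0 + cfg$block_offset + 40, length.out = 8)))
  c(cfg$hyper_currents, unique(dep))
}

.solveRampTau <- function(cfg) {
  # choose the ramp time constant so the noiseless crossing at rheobase
  # lands on the configured latency
  if (!(cfg$ramp_frac > 0) || is.na(cfg$latency_target))
    return(cfg$ramp_tau)
  f <- function(rt) {
    cfg$ramp_tau <- rt
    out <- .runSweep(cfg, cfg$rheobase)
    l <- if (length(out$spikes)) out$spikes[1] - cfg$onset else Inf
    if (!is.finite(l)) 10 else l - cfg$latency_target
  }
  tryCatch(stats::uniroot(f, c(1e-3, 0.3), tol = 1e-5)$root,
           error = function(e) cfg$ramp_tau)
}

.runSweep <- function(cfg, I, spiking = TRUE) {
  fs <- cfg$fs
  nt <- round((cfg$offset + cfg$post) * fs)
  t_fall <- .spikeFallTime(cfg)
  # threshold placed so that currents >= rheobase (1 pA grid) cross and
  # rheobase - 1 does not
  vth <- cfg$e_rest + cfg$r_in * (cfg$rheobase - 0.5) / 1000
  block <- if (cfg$archetype == "passive") -Inf
    else cfg$rheobase + cfg$block_offset
  .simSweepCpp(I, nt, 1 / fs, round(cfg$onset * fs),
               round(cfg$offset * fs), cfg$e_rest, cfg$r_in,
               cfg$tau, vth, cfg$amp, cfg$t_rise, t_fall,
               cfg$ahp_depth, cfg$t_ref, cfg$adapt_inc,
               cfg$tau_adapt, cfg$sag_frac, cfg$tau_sag,
               cfg$reb_gain, cfg$ramp_frac, cfg$ramp_tau, block,
               spiking)
}

#' Simulate a current-clamp sweep set with known ground truth
#'
#' Runs the deterministic membrane model over the configured step protocol,
#' records the exact spike insertion times, adds Gaussian recording noise
#' to the traces, and returns both the noisy [SweepSet-class] and the
#' ground-truth feature vector. Truth spike-shape features come from the
#' waveform geometry (threshold voltage, amplitude, half-width, AHP
#' latency/amplitude are construction constants), rheobase from the
#' threshold placement, firing-rate features from the simulator's own
#' event log, and passive features (Rin, tau_m, sag, rebound) from the
#' noiseless trace evaluated with the same window conventions the
#' extractor uses — the noise-free exact output of the generative model.
#'
#' @param cfg a [traceSimConfig()].
#' @param seed integer seed (recording noise only; the membrane model is
#'   deterministic).
#' @param cell_id identifier.
#' @return list with `sweeps` (a [SweepSet-class]) and `truth` (named
#'   numeric over [ephysParameterSet()]("19")).
#' @export
simulateSweeps <- function(cfg, seed = 1, cell_id = "sim") {
  stopifnot(inherits(cfg, "TraceSimConfig"))
  fs <- cfg$fs
  dur <- cfg$offset - cfg$onset
  if (dur < 5 * cfg$tau)
    warning("stimulus shorter than 5 tau: time-constant fit will degrade")
  currents <- .protocolCurrents(cfg)
  cfg$ramp_tau <- .solveRampTau(cfg)
  clean <- lapply(currents, function(I) .runSweep(cfg, I))
  vs <- lapply(clean, `[[`, "v")
  spk <- lapply(clean, `[[`, "spikes")
  t_fall <- .spikeFallTime(cfg)

  truth <- setNames(rep(NA_real_, length(ephysParameterSet("19"))),
                    ephysParameterSet("19"))
  truth["rmp"] <- cfg$e_rest
  i_on <- round(cfg$onset * fs) + 1L
  i_off <- round(cfg$offset * fs)
  ss_idx <- (i_off - round(0.2 * dur * fs)):i_off
  hyp <- which(currents < 0)
  i_small <- hyp[which.min(abs(currents[hyp]))]
  i_big <- hyp[which.max(abs(currents[hyp]))]
  v <- vs[[i_small]]
  truth["rin"] <- (mean(v[ss_idx]) - cfg$e_rest) / currents[i_small] * 1000
  nw <- min(i_off - i_on, round(0.1 * fs))
  truth["tau_m"] <- .fitExpDecay((seq_len(nw) - 1) / fs,
                                 v[i_on:(i_on + nw - 1L)]) * 1000
  v <- vs[[i_big]]
  pd <- min(v[i_on:i_off]) - cfg$e_rest
  sdf <- mean(v[ss_idx]) - cfg$e_rest
  truth["sag"] <- (pd - sdf) / pd
  truth["rebound"] <- max(v[(i_off + 1L):length(v)]) - cfg$e_rest

  dep <- which(currents > 0)
  dep <- dep[order(currents[dep])]
  nsp <- lengths(spk)
  firing <- dep[nsp[dep] > 0]
  if (length(firing)) {
    irheo <- firing[1]
    truth["rheobase"] <- currents[irheo]
    vth <- cfg$e_rest + cfg$r_in * (cfg$rheobase - 0.5) / 1000
    truth["ap_thresh_v"] <- vth
    truth["ap_amplitude"] <- cfg$amp
    truth["ap_halfwidth"] <- cfg$half_width
    truth["ahp_latency"] <- t_fall * 1000
    truth["ahp_amplitude"] <- cfg$ahp_depth
    truth["latency_first_spike"] <- (spk[[irheo]][1] - cfg$onset) * 1000
    consider <- integer(0)
    for (i in dep[dep >= irheo]) {
      if (nsp[i] == 0) break
      consider <- c(consider, i)
    }
    rates <- nsp[consider] / dur
    imax <- consider[which.max(rates)]
    truth["max_freq"] <- max(rates)
    pk <- spk[[imax]] + cfg$t_rise
    truth["steady_freq"] <- sum(pk >= cfg$onset + dur / 2 &
                                  pk <= cfg$offset) / (dur / 2)
    if (length(pk) >= 3) {
      isi <- diff(pk)
      truth["adaptation"] <- (isi[length(isi)] - isi[1]) /
        (isi[length(isi)] + isi[1])
      truth["mean_iei"] <- mean(isi) * 1000
    }
  }

  set.seed(seed)
  noisy <- lapply(vs, function(v) v + rnorm(length(v), 0, cfg$noise_sd))
  list(sweeps = SweepSet(noisy, currents, fs, cfg$onset, cfg$offset,
                         cell_id),
       truth = truth)
}
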