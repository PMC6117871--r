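#' Detect action potentials in a voltage trace
#'
#' Threshold detection by the dV/dt criterion: an AP event starts at the
#' first sample where dV/dt rises through `dvdt_thresh`, must reach a peak
#' at least `min_amp` mV above the threshold voltage, and events do not
#' overlap. Amplitude is peak minus threshold voltage; half-width is the
#' trace width (ms) at threshold + amplitude/2, with linear interpolation
#' between samples; the AHP trough is the minimum between the spike and
#' the next event (or within `ahp_window` ms), reported as latency from
#' the peak and amplitude below the threshold voltage. When the AHP is
#' biphasic (a second, separated trough), the second phase is reported too.
#'
#' @param v numeric voltage trace (mV).
#' @param fs sampling rate (Hz), >= 5000.
#' @param dvdt_thresh threshold slope (mV/ms, default 10).
#' @param min_amp minimal peak elevation above threshold voltage (mV,
#'   default 10).
#' @param ahp_window AHP search window after the peak (ms, default 40).
#' @return data.frame, one row per AP: `threshold_t`, `threshold_v`,
#'   `peak_t`, `peak_v`, `amplitude`, `half_width`, `ahp_latency`,
#'   `ahp_amplitude`, `ahp2_latency`, `ahp2_amplitude` (times s, widths and
#'   latencies ms; second-phase columns NA when monophasic). Zero rows when
#'   no APs.
#' @export
detectAPs <- function(v, fs, dvdt_thresh = 10, min_amp = 10,
                      ahp_window = 40) {
  if (fs < 5000) stop("sampling rate must be >= 5 kHz")
  n <- length(v)
  dt <- 1 / fs
  empty <- data.frame(threshold_t = numeric(0), threshold_v = numeric(0),
                      peak_t = numeric(0), peak_v = numeric(0),
                      amplitude = numeric(0), half_width = numeric(0),
                      ahp_latency = numeric(0), ahp_amplitude = numeric(0),
                      ahp2_latency = numeric(0), ahp2_amplitude = numeric(0))
  if (n < 3) return(empty)
  # detection derivative on a ~0.25 ms boxcar-smoothed copy so recording
  # noise cannot push the slope of subthreshold transients over threshold;
  # all voltage measurements stay on the raw trace
  k <- max(1L, round(0.00025 * fs))
  vd <- if (k > 1) {
    sm <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
    sm[is.na(sm)] <- v[is.na(sm)]
    sm
  } else v
  dvdt <- c(0, diff(vd)) * fs / 1000  # mV/ms, aligned to the later sample
  up <- which(dvdt >= dvdt_thresh & c(0, dvdt[-n]) < dvdt_thresh)
  if (!length(up)) return(empty)
  win <- max(3L, round(0.005 * fs))  # 5 ms peak search
  rows <- list()
  last_end <- 0L
  for (c0 in up) {
    if (c0 <= last_end) next
    i0 <- c0 - 1L  # sample just before the slope crossing
    if (i0 < 1L) i0 <- 1L
    hi <- min(n, i0 + win)
    pk <- i0 + which.max(v[i0:hi]) - 1L
    if (v[pk] < v[i0] + min_amp) next
    amp <- v[pk] - v[i0]
    half <- v[i0] + amp / 2
    # rising half-crossing (interpolated)
    r <- pk
    for (j in seq(pk, i0)) if (v[j] < half) { r <- j; break }
    t_up <- if (v[r] < half && r < n)
      (r - 1 + (half - v[r]) / (v[r + 1] - v[r])) * dt
    else (pk - 1) * dt
    # falling half-crossing
    f <- which(v[pk:min(n, pk + 4 * win)] < half)
    t_dn <- if (length(f)) {
      j <- pk + f[1] - 1L
      (j - 2 + (v[j - 1] - half) / (v[j - 1] - v[j])) * dt
    } else NA_real_
    hw <- if (is.na(t_dn)) NA_real_ else (t_dn - t_up) * 1000
    # AHP search window: until next detected upstroke or ahp_window ms
    nxt <- up[up > pk]
    end <- min(n, pk + round(ahp_window / 1000 * fs),
               if (length(nxt)) nxt[1] - 1L else n)
    seg <- v[pk:end]
    tr <- pk + which.min(seg) - 1L
    ahp_lat <- (tr - pk) * dt * 1000
    ahp_amp <- v[i0] - v[tr]
    # second AHP phase: a later local minimum after >=0.5 mV recovery
    ahp2_lat <- ahp2_amp <- NA_real_
    if (tr < end - 2) {
      seg2 <- v[tr:end]
      m <- length(seg2)
      locmin <- which(seg2[2:(m - 1)] <= seg2[1:(m - 2)] &
                        seg2[2:(m - 1)] <= seg2[3:m]) + 1L
      locmin <- locmin[seg2[locmin] < v[i0]]
      for (lm in locmin) {
        # a genuine second phase needs >= 0.5 mV recovery in between
        if (max(seg2[1:lm]) >= v[tr] + 0.5) {
          tr2 <- tr + lm - 1L
          ahp2_lat <- (tr2 - pk) * dt * 1000
          ahp2_amp <- v[i0] - v[tr2]
          break
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      threshold_t = (i0 - 1) * dt, threshold_v = v[i0],
      peak_t = (pk - 1) * dt, peak_v = v[pk], amplitude = amp,
      half_width = hw, ahp_latency = ahp_lat, ahp_amplitude = ahp_amp,
      ahp2_latency = ahp2_lat, ahp2_amplitude = ahp2_amp)
    last_end <- tr
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

.fitExpDecay <- function(t, v, tau_range = c(5e-4, 0.3)) {
  # profiled least squares for v = C + A exp(-t/tau); returns tau (s)
  rss <- function(tau) {
    b <- exp(-t / tau)
    fit <- stats::lm.fit(cbind(1, b), v)
    sum(fit$residuals^2)
  }
  opt <- optimize(function(lt) rss(exp(lt)), log(tau_range))
  exp(opt$minimum)
}

#' Names of the intrinsic electrophysiological parameters
#'
#' The full 19-column feature vector extracted by [extractFeatures()]
#' (18 numeric parameters + the parameter-set tag added by the table
#' builder). `ephysParameterSet("15")` returns the reduced subset used
#' when biphasic-AHP and latency parameters are unavailable.
#'
#' @param set "19" (default) or "15".
#' @return character vector of parameter names.
#' @export
ephysParameterSet <- function(set = c("19", "15")) {
  set <- match.arg(set)
  full <- c("rmp", "rin", "tau_m", "sag", "rebound", "ap_thresh_v",
            "rheobase", "ap_amplitude", "ap_halfwidth", "ahp_latency",
            "ahp_amplitude", "ahp2_amp_diff", "ahp2_lat_diff",
            "latency_first_spike", "max_freq", "steady_freq",
            "adaptation", "mean_iei")
  if (set == "19") full
  else setdiff(full, c("ahp2_amp_diff", "ahp2_lat_diff",
                       "latency_first_spike"))
}

#' Extract intrinsic electrophysiological parameters from a sweep set
#'
#' Computes, from depolarizing and hyperpolarizing current steps:
#' \itemize{
#' \item RMP: mean pre-stimulus baseline of the first sweep (mV).
#' \item Rin: steady-state voltage deflection over current on the smallest
#'   hyperpolarizing step (MOhm).
#' \item tau_m: single-exponential least-squares fit (with free offset) to
#'   the onset decay of the smallest hyperpolarizing step (ms).
#' \item sag: (peak deflection - steady-state deflection) / peak
#'   deflection on the largest hyperpolarizing step, deflections relative
#'   to baseline.
#' \item rebound: post-stimulus peak minus baseline after the largest
#'   hyperpolarizing step (mV).
#' \item rheobase: smallest current eliciting >= 1 AP (pA); AP threshold
#'   voltage, amplitude, half-width, AHP latency/amplitude and, when the
#'   AHP is biphasic, the amplitude and latency differences between the
#'   two phases, all from the first AP of the rheobase sweep; latency to
#'   the first spike at rheobase (ms).
#' \item firing: sweeps above rheobase are scanned in increasing current
#'   until firing failure (a sweep with no APs); max firing frequency is
#'   the largest AP count / stimulus duration before failure (Hz), steady
#'   frequency counts APs in the last 50% of that sweep, adaptation is
#'   (last ISI - first ISI)/(last ISI + first ISI) on it, and mean IEI the
#'   mean inter-event interval (ms).
#' }
#' Features that cannot be measured are NA and listed in the `missing`
#' attribute.
#'
#' @param s a [SweepSet-class].
#' @param dvdt_thresh,min_amp passed to [detectAPs()].
#' @param tau_window onset-decay fit window (s, default 0.1).
#' @return named numeric vector over [ephysParameterSet()]("19"), with
#'   attribute `missing`.
#' @export
extractFeatures <- function(s, dvdt_thresh = 10, min_amp = 10,
                            tau_window = 0.1) {
  stopifnot(is(s, "SweepSet"))
  fs <- s@fs; dt <- 1 / fs
  i_on <- round(s@onset * fs) + 1L
  i_off <- round(s@offset * fs)
  dur <- s@offset - s@onset
  nvec <- setNames(rep(NA_real_, length(ephysParameterSet("19"))),
                   ephysParameterSet("19"))
  missing <- character(0)
  base_of <- function(v) mean(v[seq_len(max(1L, i_on - 1L))])
  nvec["rmp"] <- base_of(s@voltages[[1]])

  hyp <- which(s@currents < 0)
  if (!length(hyp)) {
    missing <- c(missing, "rin", "tau_m", "sag", "rebound")
  } else {
    ss_win <- function(v) mean(v[(i_off - round(0.2 * dur * fs)):i_off])
    # input resistance + membrane time constant: smallest hyperpolarizing
    i_small <- hyp[which.min(abs(s@currents[hyp]))]
    v <- s@voltages[[i_small]]
    b <- base_of(v)
    dv <- ss_win(v) - b
    nvec["rin"] <- dv / s@currents[i_small] * 1000
    nw <- min(i_off - i_on, round(tau_window * fs))
    tt <- (seq_len(nw) - 1) * dt
    nvec["tau_m"] <- .fitExpDecay(tt, v[i_on:(i_on + nw - 1L)]) * 1000
    # sag + rebound: largest hyperpolarizing; slow extrema are read off a
    # 1-ms boxcar-smoothed trace so recording noise does not bias them
    i_big <- hyp[which.max(abs(s@currents[hyp]))]
    v <- s@voltages[[i_big]]
    b <- base_of(v)
    k <- max(1L, round(fs / 1000))
    vsm <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
    vsm[is.na(vsm)] <- v[is.na(vsm)]
    peak_defl <- min(vsm[i_on:i_off]) - b
    ss_defl <- ss_win(v) - b
    nvec["sag"] <- if (peak_defl < 0) (peak_defl - ss_defl) / peak_defl
      else NA_real_
    post <- vsm[(i_off + 1L):length(v)]
    nvec["rebound"] <- if (length(post)) max(post) - b else NA_real_
  }

  dep <- which(s@currents > 0)
  dep <- dep[order(s@currents[dep])]
  aps <- lapply(seq_along(s@currents), function(i)
    detectAPs(s@voltages[[i]], fs, dvdt_thresh, min_amp))
  nsp <- vapply(aps, nrow, integer(1))
  firing <- dep[nsp[dep] > 0]
  if (!length(firing)) {
    missing <- c(missing, "rheobase", "ap_thresh_v", "ap_amplitude",
                 "ap_halfwidth", "ahp_latency", "ahp_amplitude",
                 "ahp2_amp_diff", "ahp2_lat_diff", "latency_first_spike",
                 "max_freq", "steady_freq", "adaptation", "mean_iei")
  } else {
    irheo <- firing[1]
    nvec["rheobase"] <- s@currents[irheo]
    ap1 <- aps[[irheo]][1, ]
    nvec["ap_thresh_v"] <- ap1$threshold_v
    nvec["ap_amplitude"] <- ap1$amplitude
    nvec["ap_halfwidth"] <- ap1$half_width
    nvec["ahp_latency"] <- ap1$ahp_latency
    nvec["ahp_amplitude"] <- ap1$ahp_amplitude
    if (!is.na(ap1$ahp2_latency)) {
      nvec["ahp2_amp_diff"] <- ap1$ahp_amplitude - ap1$ahp2_amplitude
      nvec["ahp2_lat_diff"] <- ap1$ahp2_latency - ap1$ahp_latency
    } else missing <- c(missing, "ahp2_amp_diff", "ahp2_lat_diff")
    nvec["latency_first_spike"] <- (ap1$threshold_t - s@onset) * 1000
    # scan upward from rheobase until firing failure
    above <- dep[dep >= irheo]
    consider <- integer(0)
    for (i in above) {
      if (nsp[i] == 0) break
      consider <- c(consider, i)
    }
    rates <- nsp[consider] / dur
    imax <- consider[which.max(rates)]
    nvec["max_freq"] <- max(rates)
    pk <- aps[[imax]]$peak_t
    half_start <- s@onset + dur / 2
    nvec["steady_freq"] <- sum(pk >= half_start & pk <= s@offset) /
      (dur / 2)
    if (length(pk) >= 3) {
      isi <- diff(pk)
      nvec["adaptation"] <- (isi[length(isi)] - isi[1]) /
        (isi[length(isi)] + isi[1])
      nvec["mean_iei"] <- mean(isi) * 1000
    } else {
      missing <- c(missing, "adaptation",
                   if (length(pk) < 2) "mean_iei")
      if (length(pk) >= 2) nvec["mean_iei"] <- mean(diff(pk)) * 1000
    }
  }
  attr(nvec, "missing") <- unique(c(missing,
                                    names(nvec)[is.na(nvec)]))
  nvec
}

#' Feature table over a list of sweep sets
#'
#' @param sweep_sets list of [SweepSet-class] objects.
#' @param set parameter set tag, "19" or "15" (see [ephysParameterSet()]).
#' @param ... passed to [extractFeatures()].
#' @return data.frame, one row per cell (`cell_id` + parameters +
#'   `parameter_set`).
#' @export
extractFeatureTable <- function(sweep_sets, set = "19", ...) {
  pars <- ephysParameterSet(set)
  rows <- lapply(sweep_sets, function(s) {
    f <- extractFeatures(s, ...)
    data.frame(cell_id = s@cellId, t(f[pars]), parameter_set = set,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exclude low-quality recordings
#'
#' A cell is excluded when its AP half-width is strictly larger than
#' `hw_max` ms or its AP amplitude strictly lower than `amp_min` mV. Cells
#' whose half-width and amplitude are both NA cannot be evaluated and are
#' kept with a warning.
#'
#' @param features data.frame from [extractFeatureTable()].
#' @param hw_max half-width ceiling (ms, default 2).
#' @param amp_min amplitude floor (mV, default 40).
#' @return list with `kept` (data.frame) and `excluded` (data.frame with a
#'   `reason` column).
#' @export
excludeLowQuality <- function(features, hw_max = 2, amp_min = 40) {
  hw <- features$ap_halfwidth
  amp <- features$ap_amplitude
  unknown <- is.na(hw) & is.na(amp)
  if (any(unknown))
    warning(sum(unknown), " cell(s) with unmeasurable AP features kept")
  bad_hw <- !is.na(hw) & hw > hw_max
  bad_amp <- !is.na(amp) & amp < amp_min
  out <- bad_hw | bad_amp
  excluded <- features[out, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- paste0(ifelse(bad_hw[out], "half_width", ""),
                              ifelse(bad_hw[out] & bad_amp[out], ",", ""),
                              ifelse(bad_amp[out], "amplitude", ""))
  list(kept = features[!out, , drop = FALSE], excluded = excluded)
}

.ephysTransform <- function(x) sign(x) * log(1 + abs(x))

.featureMatrix <- function(features, set, impute = TRUE) {
  pars <- intersect(ephysParameterSet(set), colnames(features))
  x <- as.matrix(features[, pars, drop = FALSE])
  x <- .ephysTransform(x)
  keep <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 1 && sd(v) > 0
  })
  if (any(!keep))
    warning("constant/empty parameter(s) dropped: ",
            paste(pars[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  if (impute)
    for (j in seq_len(ncol(x)))
      x[is.na(x[, j]), j] <- median(x[, j], na.rm = TRUE)
  scale(x)
}

#' PCA of the electrophysiological feature table
#'
#' Each parameter is signed-log transformed (`sign(v) * log(1 + |v|)`, so
#' negative-valued parameters such as RMP are handled) and z-scored;
#' missing values are imputed by the parameter median (the affected cells
#' are listed in the `imputed` element); constant parameters are dropped
#' with a warning. PCA is computed by singular value decomposition.
#'
#' @param features data.frame from [extractFeatureTable()].
#' @param set parameter subset tag ("19" or "15").
#' @return list with `scores` (cells x PCs), `loadings` (parameters x
#'   PCs), `var_explained`, `imputed` (cell ids with >= 1 imputed value).
#' @export
ephysPCA <- function(features, set = "19") {
  x <- .featureMatrix(features, set, impute = FALSE)
  imputed <- features$cell_id[apply(x, 1, anyNA)]
  for (j in seq_len(ncol(x)))
    x[is.na(x[, j]), j] <- median(x[, j], na.rm = TRUE)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  rownames(pc$x) <- features$cell_id
  list(scores = pc$x, loadings = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2), imputed = imputed)
}

#' Per-parameter group comparison
#'
#' Welch two-sided t-test per parameter on the signed-log transformed
#' scale, with BH adjustment across parameters. Missing values are dropped
#' per test, never imputed. Parameters with zero variance in both groups
#' yield NA and are flagged.
#'
#' @param features data.frame from [extractFeatureTable()].
#' @param groupA,groupB cell id vectors (>= 3 each).
#' @param set parameter subset tag.
#' @return data.frame: `parameter`, `t`, `p`, `q`, `flag`.
#' @export
pairwiseCompare <- function(features, groupA, groupB, set = "19") {
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("both groups need >= 3 cells")
  pars <- intersect(ephysParameterSet(set), colnames(features))
  ia <- features$cell_id %in% groupA
  ib <- features$cell_id %in% groupB
  res <- lapply(pars, function(pp) {
    a <- .ephysTransform(features[[pp]][ia])
    b <- .ephysTransform(features[[pp]][ib])
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (sd(a) == 0 && sd(b) == 0))
      return(data.frame(parameter = pp, t = NA_real_, p = NA_real_,
                        flag = "zero_variance_or_missing"))
    tt <- t.test(a, b)
    data.frame(parameter = pp, t = unname(tt$statistic), p = tt$p.value,
               flag = "")
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out[, c("parameter", "t", "p", "q", "flag")]
}

#' Hierarchical clustering of cells on ephys features
#'
#' Euclidean distance on the signed-log transformed, z-scored feature
#' matrix (median-imputed as for the PCA), average linkage by default.
#'
#' @param features data.frame from [extractFeatureTable()].
#' @param set parameter subset tag.
#' @param linkage hclust method (default "average").
#' @return an `hclust` tree over cells.
#' @export
hclusterEphys <- function(features, set = "19", linkage = "average") {
  x <- .featureMatrix(features, set, impute = TRUE)
  rownames(x) <- features$cell_id
  hclust(dist(x), method = linkage)
}

#' Read / write current-clamp sweep sets
#'
#' On disk a cell is a directory of per-sweep CSV traces (columns
#' `time_s`, `voltage_mV`) plus a `manifest.tsv` with columns `file`,
#' `current_pA`, `onset_s`, `offset_s`.
#'
#' @param path cell directory.
#' @return [readSweepSet()] returns a [SweepSet-class].
#' @export
readSweepSet <- function(path) {
  man <- read.delim(file.path(path, "manifest.tsv"))
  need <- c("file", "current_pA", "onset_s", "offset_s")
  if (!all(need %in% colnames(man)))
    stop("format error: manifest needs columns ",
         paste(need, collapse = ", "))
  traces <- lapply(man$file, function(f) {
    tab <- utils::read.csv(file.path(path, f))
    if (!all(c("time_s", "voltage_mV") %in% colnames(tab)))
      stop("format error: sweep CSV needs time_s, voltage_mV")
    tab
  })
  fs <- 1 / median(diff(traces[[1]]$time_s))
  SweepSet(lapply(traces, `[[`, "voltage_mV"), man$current_pA,
           fs = round(fs), onset = man$onset_s[1], offset = man$offset_s[1],
           cell_id = basename(path))
}

#' @rdname readSweepSet
#' @param s a [SweepSet-class]
#' @export
writeSweepSet <- function(s, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sweep_%03d.csv", seq_along(s@voltages))
  for (i in seq_along(files)) {
    v <- s@voltages[[i]]
    utils::write.csv(data.frame(time_s = (seq_along(v) - 1) / s@fs,
                                voltage_mV = v),
                     file.path(path, files[i]), row.names = FALSE)
  }
  write.table(data.frame(file = files, current_pA = s@currents,
                         onset_s = s@onset, offset_s = s@offset),
              file.path(path, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
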