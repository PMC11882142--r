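#' GCaMP6f-like transient kernel
#'
#' Double-exponential impulse response (difference of exponentials) with fast
#' rise and slow decay, normalized to unit peak. Only relative amplitudes
#' matter downstream because the analysis z-normalizes per lap type.
#'
#' @param rise,decay Rise and decay time constants in seconds.
#' @param rate Sampling rate in Hz.
#' @param duration Kernel support in seconds.
#' @return Numeric vector of kernel samples starting at lag 0.
#' @export
gcamp_kernel <- function(rise = 0.05, decay = 0.5, rate = 20, duration = 3) {
  stopifnot(rise > 0, decay > rise)
  t <- seq(0, duration, by = 1 / rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

#' Specify a synthetic cell population
#'
#' Builds the per-cell ground-truth table for [simulate_calcium()]. Cell
#' types: outcome cells respond with a fixed-amplitude transient to threat
#' delivery on their path; `signed_pe` cells scale the transient with the
#' prediction error (negative PE gives a dip); `unsigned_pe` cells with its
#' absolute value; `expectation` cells ramp up before threat-site entry in
#' proportion to the path value; `none` cells are baseline noise only.
#' Direction (+1/-1) alternates within the PE classes, planting Up-Down and
#' Down-Up signed coders and Up-Up / Down-Down unsigned coders.
#'
#' @param n Number of cells.
#' @param props Named proportions over
#'   `c("outcome_ht", "outcome_lt", "signed_pe", "unsigned_pe",
#'   "expectation", "none")`; normalized internally.
#' @param amplitude Transient amplitude in units of the baseline noise SD
#'   (per-sample SNR).
#' @param noise_sd Baseline noise SD (trace units).
#' @param led_gain Multiplier applied to outcome-cell transients on LED laps
#'   (1 = no effect; "ChrimsonR-like" cohorts use > 1).
#' @return Data frame `cell`, `type`, `direction`, `amplitude`, `noise_sd`,
#'   `led_gain`, `expected_label` (the classification label the plant should
#'   produce, `NA` where none is implied).
#' @export
cell_population <- function(n = 100,
                            props = c(outcome_ht = 0.1, outcome_lt = 0.1,
                                      signed_pe = 0.2, unsigned_pe = 0.1,
                                      expectation = 0.1, none = 0.4),
                            amplitude = 4, noise_sd = 1, led_gain = 1) {
  types <- c("outcome_ht", "outcome_lt", "signed_pe", "unsigned_pe",
             "expectation", "none")
  stopifnot(all(names(props) %in% types))
  p <- props[types]; p[is.na(p)] <- 0; p <- p / sum(p)
  counts <- floor(p * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(p * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  type <- rep(types, counts)
  dir <- rep(1, n)
  for (ty in c("signed_pe", "unsigned_pe")) {
    idx <- which(type == ty)
    if (length(idx) > 1) dir[idx[seq(2, length(idx), by = 2)]] <- -1
  }
  expected <- rep(NA_character_, n)
  expected[type == "signed_pe" & dir == 1] <- "Up-Down"
  expected[type == "signed_pe" & dir == -1] <- "Down-Up"
  expected[type == "unsigned_pe" & dir == 1] <- "Up-Up"
  expected[type == "unsigned_pe" & dir == -1] <- "Down-Down"
  data.frame(
    cell = sprintf("cell_%03d", seq_len(n)),
    type = type, direction = dir,
    amplitude = amplitude * noise_sd, noise_sd = noise_sd,
    led_gain = led_gain, expected_label = expected,
    stringsAsFactors = FALSE
  )
}

#' Simulate calcium traces locked to threat-site entries
#'
#' Generates one fluorescence trace per cell: Gaussian baseline noise plus
#' event-locked transients at every threat-site entry, with amplitudes
#' following each cell's coding rule (see [cell_population()]).
#'
#' @param laps Lap table with scheduled times (`t_enter_threat`), `path`,
#'   `threat_delivered`, `led`, `pe` and `v_path` columns (from
#'   [simulate_agent()] + [schedule_lap_times()]).
#' @param cells Cell table from [cell_population()].
#' @param rate Sampling rate in Hz (20).
#' @param kernel Transient kernel (defaults to [gcamp_kernel()] at `rate`).
#' @param t_end Recording end time; defaults to covering every lap window.
#' @return List with `traces` (data frame, first column `time_s`, one column
#'   per cell) and `truth` (= `cells`).
#' @export
simulate_calcium <- function(laps, cells, rate = 20,
                             kernel = gcamp_kernel(rate = rate),
                             t_end = NULL) {
  stopifnot(all(c("t_enter_threat", "path", "threat_delivered", "led",
                  "pe", "v_path") %in% names(laps)))
  if (is.null(t_end)) t_end <- max(laps$t_enter_threat) + 3
  ts <- seq(0, t_end, by = 1 / rate)
  nt <- length(ts)
  nk <- length(kernel)
  # pre-entry expectation ramp: 1-s linear rise to the entry, fast decay after
  ramp_pre <- seq(0, 1, length.out = rate + 1)[-(rate + 1)]
  ramp_post <- exp(-seq(0, 1, by = 1 / rate) / 0.2)
  ramp <- c(ramp_pre, ramp_post)

  entry_idx <- round(laps$t_enter_threat * rate) + 1
  traces <- matrix(stats::rnorm(nt * nrow(cells)), nt, nrow(cells))
  traces <- sweep(traces, 2, cells$noise_sd, "*")

  for (ci in seq_len(nrow(cells))) {
    spec <- cells[ci, ]
    amp <- switch(spec$type,
      outcome_ht = ifelse(laps$path == "path_1" & laps$threat_delivered,
                          spec$amplitude, 0) *
        ifelse(laps$led, spec$led_gain, 1),
      outcome_lt = ifelse(laps$path == "path_2" & laps$threat_delivered,
                          spec$amplitude, 0) *
        ifelse(laps$led, spec$led_gain, 1),
      signed_pe = spec$direction * spec$amplitude * laps$pe,
      unsigned_pe = spec$direction * spec$amplitude * abs(laps$pe),
      expectation = rep(0, nrow(laps)),
      none = rep(0, nrow(laps)),
      stop("unknown cell type: ", spec$type)
    )
    for (li in seq_len(nrow(laps))) {
      if (amp[li] != 0) {
        i0 <- entry_idx[li]
        i1 <- min(nt, i0 + nk - 1)
        if (i0 >= 1 && i0 <= nt) {
          traces[i0:i1, ci] <- traces[i0:i1, ci] +
            amp[li] * kernel[seq_len(i1 - i0 + 1)]
        }
      }
      if (spec$type == "expectation") {
        a <- spec$amplitude * laps$v_path[li]
        i0 <- entry_idx[li] - rate
        i1 <- min(nt, i0 + length(ramp) - 1)
        if (a != 0 && i0 >= 1) {
          traces[i0:i1, ci] <- traces[i0:i1, ci] +
            a * ramp[seq_len(i1 - i0 + 1)]
        }
      }
    }
  }
  colnames(traces) <- cells$cell
  list(
    traces = data.frame(time_s = ts, traces, check.names = FALSE),
    truth = cells
  )
}
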