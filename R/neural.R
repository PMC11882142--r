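#' Align calcium traces to threat-site entries
#'
#' Collects each cell's activity in a window around every event, averaging
#' trace samples into fixed-width half-open time bins `[t, t + bin)`. With the
#' default window (-1 s to +2 s) and 100-ms bins this yields 30 bins per lap;
#' bins 1-10 precede the event and bin 11 is the first post-entry bin
#' (covering entry up to puff onset at +100 ms).
#'
#' Events whose window is not fully covered by the recording, or for which
#' any bin would be empty, are dropped with a message; dropped event indices
#' are stored in `attr(, "dropped")`.
#'
#' @param traces Data frame: first column `time_s`, remaining columns one per
#'   cell (20 Hz nominal).
#' @param event_times Numeric vector of alignment times (threat-site
#'   entries), one per lap.
#' @param window Two-element numeric window around the event in seconds.
#' @param bin Bin width in seconds.
#' @return 3-d array `cells x laps x bins` with cell names on dimension 1;
#'   `attr(, "bin_left")` holds the bin left edges relative to the event.
#' @export
align_to_event <- function(traces, event_times, window = c(-1, 2), bin = 0.1) {
  stopifnot(names(traces)[1] == "time_s", length(event_times) >= 1)
  nb <- round((window[2] - window[1]) / bin)
  stopifnot(abs(nb * bin - (window[2] - window[1])) < 1e-8)
  tt <- traces$time_s
  mat <- as.matrix(traces[, -1, drop = FALSE])
  cells <- colnames(mat)

  keep <- logical(length(event_times))
  slabs <- vector("list", length(event_times))
  for (e in seq_along(event_times)) {
    rel <- tt - event_times[e]
    inside <- rel >= window[1] & rel < window[2]
    if (event_times[e] + window[1] < tt[1] ||
        event_times[e] + window[2] > tt[length(tt)] + bin) next
    b <- floor((rel[inside] - window[1]) / bin) + 1
    if (length(unique(b)) < nb) next
    g <- factor(b, levels = seq_len(nb))
    sums <- rowsum(mat[inside, , drop = FALSE], g)        # nb x cells
    cnt <- as.integer(table(g))
    slabs[[e]] <- t(sums / cnt)                           # cells x nb
    keep[e] <- TRUE
  }
  if (!any(keep)) stop("no event window fully covered by the recording")
  if (any(!keep)) {
    message("dropped ", sum(!keep), " event(s) not fully covered by the recording")
  }
  out <- array(NA_real_, dim = c(length(cells), sum(keep), nb),
               dimnames = list(cell = cells, lap = NULL, bin = NULL))
  j <- 0
  for (e in which(keep)) {
    j <- j + 1
    out[, j, ] <- slabs[[e]]
  }
  attr(out, "dropped") <- which(!keep)
  attr(out, "bin_left") <- window[1] + (seq_len(nb) - 1) * bin
  out
}

#' Lap-type averaged, baseline z-normalized responses
#'
#' For each cell and lap type: average the binned activity across the laps of
#' that type, then convert the averaged 30-bin trace to z-scores using the
#' mean and SD of its first `n_baseline` (pre-entry) bins. Normalization is
#' applied to each lap type separately; a cell whose baseline SD is zero for
#' a lap type is marked undefined (`NA`) for that type.
#'
#' @param aligned Array from [align_to_event()].
#' @param lap_type Character/factor vector, one lap-type label per lap
#'   (dimension 2 of `aligned`).
#' @param n_baseline Number of leading baseline bins.
#' @param per_lap Sensitivity-analysis variant: z-score each lap by its own
#'   baseline moments before averaging (default `FALSE`: average first, then
#'   z-score the lap-averaged trace).
#' @return 3-d array `cells x lap_type x bins` of z-scores;
#'   `attr(, "n_laps")` gives laps per type.
#' @export
lap_type_average_z <- function(aligned, lap_type, n_baseline = 10,
                               per_lap = FALSE) {
  stopifnot(length(lap_type) == dim(aligned)[2])
  types <- if (is.factor(lap_type)) levels(droplevels(lap_type)) else
    sort(unique(lap_type))
  nb <- dim(aligned)[3]
  out <- array(NA_real_, dim = c(dim(aligned)[1], length(types), nb),
               dimnames = list(cell = dimnames(aligned)[[1]],
                               lap_type = types, bin = NULL))
  n_laps <- stats::setNames(integer(length(types)), types)
  for (ty in types) {
    idx <- which(lap_type == ty)
    n_laps[ty] <- length(idx)
    if (length(idx) == 0) next
    slab <- aligned[, idx, , drop = FALSE]
    if (per_lap) {
      # z-score every lap by its own baseline, then average across laps
      for (l in seq_along(idx)) {
        base_l <- slab[, l, seq_len(n_baseline), drop = FALSE]
        mu_l <- apply(base_l, 1, mean)
        sd_l <- apply(base_l, 1, stats::sd)
        sd_l[sd_l == 0] <- NA_real_
        slab[, l, ] <- (slab[, l, ] - mu_l) / sd_l
      }
      out[, ty, ] <- apply(slab, c(1, 3), mean)
    } else {
      avg <- apply(slab, c(1, 3), mean)                # cells x bins
      base <- avg[, seq_len(n_baseline), drop = FALSE]
      mu <- rowMeans(base)
      sdev <- apply(base, 1, stats::sd)
      z <- (avg - mu) / sdev
      z[sdev == 0, ] <- NA_real_
      out[, ty, ] <- z
    }
  }
  attr(out, "n_laps") <- n_laps
  out
}

#' Response magnitude: mean z over the first 500 ms after entry
#'
#' @param zavg Array from [lap_type_average_z()].
#' @param response_bins Bin indices of the post-entry response window
#'   (1-based; bins 11-15 with the default alignment).
#' @return Matrix `cells x lap_type` of mean z.
#' @export
response_magnitude <- function(zavg, response_bins = 11:15) {
  apply(zavg[, , response_bins, drop = FALSE], c(1, 2), mean)
}

#' Classify outcome-responsive cells
#'
#' A cell responds to a lap type (threat delivery or omission on a given
#' path) when its response magnitude exceeds `threshold` (strict inequality);
#' symmetric decreases below `-threshold` are reported separately.
#'
#' @param magnitudes Matrix `cells x lap_type` from [response_magnitude()].
#' @param threshold Response threshold in z units.
#' @return List of logical matrices `increased` and `decreased`
#'   (`cells x lap_type`; `NA` propagates).
#' @export
classify_outcome_responders <- function(magnitudes, threshold = 2) {
  list(increased = magnitudes > threshold,
       decreased = magnitudes < -threshold)
}

#' Per-cell activity change evoked by puffs with and without LED
#'
#' Subtracts each cell's average omission-lap activity from its puff-lap and
#' puff+LED-lap activity (all in z units over the post-entry response
#' window). The two resulting per-cell distributions support the
#' two-sample Kolmogorov-Smirnov contrast between cohorts.
#'
#' @param magnitudes Matrix `cells x lap_type` with columns `omission`,
#'   `puff`, `puff_led`.
#' @return Data frame `cell`, `puff_minus_omission`,
#'   `puff_led_minus_omission`; cells with any missing lap type are excluded.
#' @export
led_effect_distribution <- function(magnitudes) {
  need <- c("omission", "puff", "puff_led")
  if (!all(need %in% colnames(magnitudes))) {
    stop("magnitudes must have lap types: ", paste(need, collapse = ", "))
  }
  ok <- stats::complete.cases(magnitudes[, need, drop = FALSE])
  m <- magnitudes[ok, need, drop = FALSE]
  data.frame(
    cell = rownames(magnitudes)[ok],
    puff_minus_omission = m[, "puff"] - m[, "omission"],
    puff_led_minus_omission = m[, "puff_led"] - m[, "omission"],
    stringsAsFactors = FALSE
  )
}

#' Expectation-dependent differential activity
#'
#' For each cell, subtracts the response magnitude in laps with expected
#' outcomes from that in laps with surprising outcomes, separately for threat
#' delivery and omission.
#'
#' @param magnitudes Matrix `cells x lap_type` with columns
#'   `threat_surprising`, `threat_expected`, `omission_surprising`,
#'   `omission_expected`.
#' @return Data frame `cell`, `d_threat`, `d_omission` (`NA` when any
#'   constituent is undefined).
#' @export
differential_activity <- function(magnitudes) {
  need <- c("threat_surprising", "threat_expected",
            "omission_surprising", "omission_expected")
  if (!all(need %in% colnames(magnitudes))) {
    stop("magnitudes must have lap types: ", paste(need, collapse = ", "))
  }
  data.frame(
    cell = rownames(magnitudes),
    d_threat = magnitudes[, "threat_surprising"] - magnitudes[, "threat_expected"],
    d_omission = magnitudes[, "omission_surprising"] - magnitudes[, "omission_expected"],
    stringsAsFactors = FALSE
  )
}

#' Classify prediction-error coding from differential activity
#'
#' Thresholds each cell's differential activity for threats and omissions at
#' `> threshold` (Up) / `< -threshold` (Down). Cells crossing both thresholds
#' get one of the four combined labels; exactly one gives `Threat-only` or
#' `Omission-only`; neither gives `none`. Cells that reverse response
#' direction between surprising threats and surprising omissions (`Up-Down`,
#' `Down-Up`) are signed prediction-error coders; same-direction cells
#' (`Up-Up`, `Down-Down`) are unsigned.
#'
#' @param diff Data frame from [differential_activity()].
#' @param threshold Differential-activity threshold in z units.
#' @return `diff` with `label`, `signed_pe`, `unsigned_pe` appended; labels
#'   are `NA` when either differential is undefined.
#' @export
classify_pe_type <- function(diff, threshold = 2) {
  up_t <- diff$d_threat > threshold
  dn_t <- diff$d_threat < -threshold
  up_o <- diff$d_omission > threshold
  dn_o <- diff$d_omission < -threshold
  lab <- rep(NA_character_, nrow(diff))
  both <- !is.na(up_t) & !is.na(up_o)
  lab[both & up_t & up_o] <- "Up-Up"
  lab[both & up_t & dn_o] <- "Up-Down"
  lab[both & dn_t & up_o] <- "Down-Up"
  lab[both & dn_t & dn_o] <- "Down-Down"
  lab[both & (up_t | dn_t) & !(up_o | dn_o)] <- "Threat-only"
  lab[both & !(up_t | dn_t) & (up_o | dn_o)] <- "Omission-only"
  lab[both & !(up_t | dn_t) & !(up_o | dn_o)] <- "none"
  diff$label <- lab
  diff$signed_pe <- lab %in% c("Up-Down", "Down-Up") & !is.na(lab)
  diff$unsigned_pe <- lab %in% c("Up-Up", "Down-Down") & !is.na(lab)
  diff$signed_pe[is.na(lab)] <- NA
  diff$unsigned_pe[is.na(lab)] <- NA
  diff
}

#' Category proportions with exact binomial confidence limits
#'
#' Proportion of cells per classification label with two-sided
#' Clopper-Pearson confidence limits.
#'
#' @param labels Character vector of per-cell labels (`NA` dropped).
#' @param n_cells Denominator; defaults to the number of labelled cells.
#' @param conf_level Confidence level.
#' @param categories Categories to report (default: all observed).
#' @return Data frame `label`, `count`, `n`, `prop`, `lower`, `upper`.
#' @export
pe_proportions <- function(labels, n_cells = sum(!is.na(labels)),
                           conf_level = 0.95,
                           categories = sort(unique(stats::na.omit(labels)))) {
  if (n_cells < 1) stop("pe_proportions needs at least one cell")
  rows <- lapply(categories, function(cat) {
    x <- sum(labels == cat, na.rm = TRUE)
    ci <- stats::binom.test(x, n_cells, conf.level = conf_level)$conf.int
    data.frame(label = cat, count = x, n = n_cells, prop = x / n_cells,
               lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-group binomial test on a category proportion
#'
#' Tests one group's category count against the other group's observed
#' proportion taken as the null rate (exact two-sided binomial test).
#'
#' @param x1,n1 Count and total in the tested group.
#' @param x2,n2 Count and total in the reference group.
#' @return List `statistic` (observed count), `null_p`, `p`.
#' @export
pe_group_binomial_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  p0 <- x2 / n2
  p0 <- min(max(p0, 1e-12), 1 - 1e-12)
  ht <- stats::binom.test(x1, n1, p = p0)
  list(statistic = x1, null_p = p0, p = ht$p.value)
}
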