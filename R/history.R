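#' Build a choice series across the probabilistic sessions
#'
#' Concatenates laps across sessions, preserving session order and
#' within-session lap order, and codes path choice as 1 for the high-threat
#' path and 0 for the low-threat path. The trailing outcome windows used by
#' [rolling_threat_probability()] are not reset at session boundaries.
#'
#' @param laps Lap table spanning one or more sessions, already in
#'   chronological order (session by session).
#' @param ht_path Path id of the high-threat path.
#' @return Data frame `lap`, `session`, `path`, `choice_code`,
#'   `threat_delivered`.
#' @export
choice_series <- function(laps, ht_path = "path_1") {
  data.frame(
    lap = seq_len(nrow(laps)),
    session = laps$session,
    path = laps$path,
    choice_code = as.integer(laps$path == ht_path),
    threat_delivered = laps$threat_delivered,
    stringsAsFactors = FALSE
  )
}

#' Trailing-window estimate of a path's threat probability
#'
#' At lap *i*, the estimate for `path` is the mean of `threat_delivered` over
#' the most recent `k` visits to that path strictly before lap *i*; it is
#' `NA` until `k` visits have accumulated.
#'
#' @param series Choice series from [choice_series()].
#' @param path Path id whose threat probability is estimated.
#' @param k Window length in laps (visits to `path`), `k >= 1`.
#' @return Numeric vector, one estimate per lap of `series`.
#' @export
rolling_threat_probability <- function(series, path, k) {
  stopifnot(k >= 1, k == round(k))
  n <- nrow(series)
  visits <- which(series$path == path)
  if (k > length(visits)) {
    warning("k = ", k, " exceeds the ", length(visits), " visits to ", path,
            "; all estimates undefined")
    return(rep(NA_real_, n))
  }
  outs <- as.numeric(series$threat_delivered[visits])
  cum <- c(0, cumsum(outs))
  # number of visits to `path` strictly before each lap
  nprior <- findInterval(seq_len(n) - 0.5, visits)
  est <- rep(NA_real_, n)
  ok <- nprior >= k
  est[ok] <- (cum[nprior[ok] + 1] - cum[nprior[ok] + 1 - k]) / k
  est
}

#' Pearson correlation between path choice and trailing threat-probability
#' estimates
#'
#' For each path and each window length `k`, correlates the binary choice
#' code with that path's trailing threat-probability estimate over the laps
#' where the estimate is defined. Significance is the standard two-sided t
#' transformation of r. A mouse is flagged significant for a path when any
#' `k` yields `p < alpha` (no multiple-comparison correction across `k`,
#' matching the any-window criterion).
#'
#' @param series Choice series from [choice_series()].
#' @param k_range Integer vector of window lengths.
#' @param alpha Significance level for the per-mouse flag.
#' @param paths Paths to analyse (default: both paths present).
#' @return List with `by_k` (data frame `path`, `k`, `n`, `r`, `p`) and
#'   `significant_any_k` (named logical per path). `r` is `NA` where fewer
#'   than 3 defined laps remain or either series has zero variance.
#' @export
history_choice_correlation <- function(series, k_range = 1:50, alpha = 0.05,
                                       paths = sort(unique(series$path))) {
  rows <- list()
  for (p in paths) {
    for (k in k_range) {
      est <- suppressWarnings(rolling_threat_probability(series, p, k))
      ok <- !is.na(est)
      n <- sum(ok)
      r <- p_val <- NA_real_
      if (n >= 3) {
        x <- series$choice_code[ok]; y <- est[ok]
        if (stats::var(x) > 0 && stats::var(y) > 0) {
          r <- stats::cor(x, y)
          p_val <- pearson_p(r, n)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(path = p, k = k, n = n,
                                             r = r, p = p_val,
                                             stringsAsFactors = FALSE)
    }
  }
  by_k <- do.call(rbind, rows)
  sig <- vapply(paths, function(p) {
    pk <- by_k$p[by_k$path == p]
    any(pk < alpha, na.rm = TRUE)
  }, logical(1))
  names(sig) <- paths
  list(by_k = by_k, significant_any_k = sig)
}

# two-sided p for a Pearson r at sample size n via the t transformation
pearson_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Proportion of post-threat laps that switch to the low-threat path
#'
#' For each session, selects the laps in which a threat was delivered on
#' `conditioning_path` and a subsequent lap exists in the same session, and
#' reports the proportion of those subsequent laps taken on the low-threat
#' path. Sessions with fewer than two qualifying laps are discarded
#' (`NA`).
#'
#' @param laps Lap table spanning sessions, chronologically ordered.
#' @param conditioning_path Path on which the threat conditioned the choice.
#' @param lt_path Low-threat path id.
#' @return Data frame `session`, `n_qualifying`, `prop_lt_next` (`NA` for
#'   discarded sessions).
#' @export
post_outcome_switch <- function(laps, conditioning_path,
                                lt_path = "path_2") {
  out <- lapply(split(laps, factor(laps$session, levels = unique(laps$session))),
                function(ls) {
    n <- nrow(ls)
    qual <- which(ls$path == conditioning_path & ls$threat_delivered &
                    seq_len(n) < n)
    data.frame(
      session = ls$session[1],
      n_qualifying = length(qual),
      prop_lt_next = if (length(qual) < 2) NA_real_ else
        mean(ls$path[qual + 1] == lt_path),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cohort table of post-threat switching, keeping complete mice only
#'
#' Applies [post_outcome_switch()] per mouse and keeps mice with usable data
#' (at least two qualifying laps) in all sessions.
#'
#' @param laps_by_mouse Named list of lap tables, one per mouse.
#' @param conditioning_path,lt_path As in [post_outcome_switch()].
#' @return Data frame `mouse`, `session`, `prop_lt_next` restricted to
#'   complete mice; excluded mice are reported in a message.
#' @export
post_outcome_switch_cohort <- function(laps_by_mouse, conditioning_path,
                                       lt_path = "path_2") {
  per_mouse <- lapply(laps_by_mouse, post_outcome_switch,
                      conditioning_path = conditioning_path, lt_path = lt_path)
  usable <- vapply(per_mouse, function(d) !any(is.na(d$prop_lt_next)), logical(1))
  if (!all(usable)) {
    message("excluding ", sum(!usable), " mouse/mice without usable data in ",
            "every session: ", paste(names(per_mouse)[!usable], collapse = ", "))
  }
  if (!any(usable)) stop("no mouse has usable data in every session")
  kept <- per_mouse[usable]
  out <- do.call(rbind, Map(function(m, d) cbind(mouse = m, d), names(kept), kept))
  rownames(out) <- NULL
  out
}

#' Compare counts of significantly correlated mice between groups
#'
#' 2x2 chi-square test (1 df, no continuity correction) on significant vs
#' not-significant mice across two groups.
#'
#' @param flags_group1,flags_group2 Logical vectors of per-mouse significance
#'   flags.
#' @return List with the 2x2 `table`, `statistic`, `df`, `p`.
#' @export
count_significant_mice <- function(flags_group1, flags_group2) {
  tab <- rbind(
    group1 = c(sig = sum(flags_group1), ns = sum(!flags_group1)),
    group2 = c(sig = sum(flags_group2), ns = sum(!flags_group2))
  )
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    stop("chi-square test undefined: a margin of the 2x2 table is zero")
  }
  ts <- chisq_2x2(tab)
  list(table = tab, statistic = ts$statistic, df = ts$df, p = ts$p)
}
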