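#' Maze geometry for the square threat-learning maze
#'
#' Builds the region-of-interest (ROI) layout of the square maze: two reward
#' sites (20 x 20 cm) at opposite corners and two threat sites (8 x 20 cm) at
#' the remaining corners. Each of the two paths connecting the reward sites
#' runs through exactly one threat site, so a path is identified with its
#' threat ROI.
#'
#' Rectangles are half-open: a point belongs to an ROI when
#' `xmin <= x < xmax` and `ymin <= y < ymax`, which guarantees single
#' membership for points on shared edges.
#'
#' @param side Side length of the square maze in cm.
#' @param reward_size Side of the square reward ROIs in cm.
#' @param threat_depth Depth of the threat ROIs (their short side) in cm.
#' @param threat_width Width of the threat ROIs (their long side, along the
#'   track) in cm.
#'
#' @return An object of class `maze_geometry`: a list with `side`, a `rois`
#'   data frame (`roi`, `kind`, `xmin`, `xmax`, `ymin`, `ymax`) and `paths`,
#'   a named character vector mapping threat ROI -> path id.
#' @export
#' @examples
#' geom <- maze_geometry()
#' geom$rois
maze_geometry <- function(side = 75, reward_size = 20, threat_depth = 8,
                          threat_width = 20) {
  stopifnot(side > 0, reward_size > 0, threat_depth > 0, threat_width > 0,
            reward_size + threat_depth <= side, reward_size + threat_width <= side)
  rois <- data.frame(
    roi  = c("reward_1", "reward_2", "threat_1", "threat_2"),
    kind = c("reward", "reward", "threat", "threat"),
    xmin = c(0, side - reward_size, 0, side - threat_depth),
    xmax = c(reward_size, side, threat_width, side),
    ymin = c(0, side - reward_size, side - threat_depth, 0),
    ymax = c(reward_size, side, side, threat_width),
    stringsAsFactors = FALSE
  )
  geom <- list(
    side = side,
    rois = rois,
    paths = c(threat_1 = "path_1", threat_2 = "path_2")
  )
  class(geom) <- "maze_geometry"
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  rois <- geom$rois
  stopifnot(all(c("roi", "kind", "xmin", "xmax", "ymin", "ymax") %in% names(rois)))
  stopifnot(sum(rois$kind == "reward") == 2, sum(rois$kind == "threat") == 2)
  # pairwise disjoint under half-open membership
  n <- nrow(rois)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      overlap_x <- rois$xmin[i] < rois$xmax[j] && rois$xmin[j] < rois$xmax[i]
      overlap_y <- rois$ymin[i] < rois$ymax[j] && rois$ymin[j] < rois$ymax[i]
      if (overlap_x && overlap_y) {
        stop("maze ROIs '", rois$roi[i], "' and '", rois$roi[j], "' overlap")
      }
    }
  }
  invisible(geom)
}

#' ROI membership of tracked points
#'
#' @param x,y Coordinates in cm.
#' @param geom A [maze_geometry()].
#' @return Character vector: ROI id per point, `NA` outside every ROI.
#' @export
roi_membership <- function(x, y, geom) {
  stopifnot(length(x) == length(y))
  out <- rep(NA_character_, length(x))
  rois <- geom$rois
  for (i in seq_len(nrow(rois))) {
    inside <- x >= rois$xmin[i] & x < rois$xmax[i] &
      y >= rois$ymin[i] & y < rois$ymax[i]
    out[inside] <- rois$roi[i]
  }
  out
}

#' Session schedule for the three-stage paradigm
#'
#' Builds the ordered session table of a training paradigm: five pre-training
#' sessions with no air puffs, then five sessions of the chosen contingency
#' stage, then (for the probabilistic paradigm) five random sessions at 50/50.
#' Threat probabilities are properties of the two paths: in the probabilistic
#' paradigm `path_1` is the high-threat path (75%) and `path_2` the low-threat
#' path (25%); the deterministic paradigm uses 100/0.
#'
#' @param paradigm One of `"probabilistic"`, `"deterministic"`.
#' @param n_laps Laps per session for simulation (sessions in the optogenetic
#'   cohorts stopped at 60 laps).
#' @param led_policy LED policy during puff sessions: `"none"`,
#'   `"half_of_puffs"` (imaging cohort) or `"all_puffs"` (optogenetic cohort).
#' @return Data frame with columns `session`, `stage`, `p_threat_ht`,
#'   `p_threat_lt`, `led_policy`, `n_laps`.
#' @export
#' @examples
#' stage_schedule("probabilistic")[6:10, ]
stage_schedule <- function(paradigm = c("probabilistic", "deterministic"),
                           n_laps = 60,
                           led_policy = c("all_puffs", "half_of_puffs", "none")) {
  paradigm <- match.arg(paradigm)
  led_policy <- match.arg(led_policy)
  pre <- data.frame(session = paste0("T", 1:5), stage = "pre",
                    p_threat_ht = 0, p_threat_lt = 0,
                    led_policy = "none", stringsAsFactors = FALSE)
  if (paradigm == "probabilistic") {
    main <- data.frame(session = paste0("P", 1:5), stage = "probabilistic",
                       p_threat_ht = 0.75, p_threat_lt = 0.25,
                       led_policy = led_policy, stringsAsFactors = FALSE)
    rnd <- data.frame(session = paste0("R", 1:5), stage = "random",
                      p_threat_ht = 0.5, p_threat_lt = 0.5,
                      led_policy = led_policy, stringsAsFactors = FALSE)
    out <- rbind(pre, main, rnd)
  } else {
    main <- data.frame(session = paste0("D", 1:5), stage = "deterministic",
                       p_threat_ht = 1, p_threat_lt = 0,
                       led_policy = led_policy, stringsAsFactors = FALSE)
    out <- rbind(pre, main)
  }
  out$n_laps <- n_laps
  validate_schedule(out)
  out
}

validate_schedule <- function(schedule) {
  stopifnot(all(c("session", "p_threat_ht", "p_threat_lt") %in% names(schedule)))
  p <- c(schedule$p_threat_ht, schedule$p_threat_lt)
  if (any(p < 0 | p > 1)) stop("threat probabilities must lie in [0, 1]")
  if ("stage" %in% names(schedule)) {
    pre <- schedule$stage == "pre"
    if (any(schedule$p_threat_ht[pre] != 0 | schedule$p_threat_lt[pre] != 0)) {
      stop("pre-training sessions must have zero threat probability")
    }
  }
  invisible(schedule)
}
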