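flat_traces <- function(value, t_end = 60, rate = 20, cells = c("c1")) {
  ts <- seq(0, t_end, by = 1 / rate)
  d <- data.frame(time_s = ts)
  for (cc in cells) d[[cc]] <- value
  d
}

test_that("alignment bins a constant trace to constants and an impulse to bin 11", {
  al <- align_to_event(flat_traces(3.5), event_times = c(10, 20, 30))
  expect_equal(dim(al), c(1, 3, 30))
  expect_true(all(al == 3.5))

  tr <- flat_traces(0)
  tr$c1[which.min(abs(tr$time_s - 10.05))] <- 7   # +0.05 s after the event
  al2 <- align_to_event(tr, event_times = 10)
  nonzero <- which(al2[1, 1, ] != 0)
  expect_equal(nonzero, 11)
})

test_that("binned values equal a brute-force per-sample mean", {
  set.seed(20)
  ts <- seq(0, 100, by = 0.05)
  tr <- data.frame(time_s = ts, c1 = rnorm(length(ts)), c2 = rnorm(length(ts)))
  events <- c(5.3, 40.01, 77.77)
  al <- align_to_event(tr, events)
  for (e in seq_along(events)) {
    for (b in 1:30) {
      lo <- events[e] - 1 + (b - 1) * 0.1
      hi <- lo + 0.1
      idx <- ts >= lo & ts < hi
      expect_equal(al["c1", e, b], mean(tr$c1[idx]), ignore_attr = TRUE)
      expect_equal(al["c2", e, b], mean(tr$c2[idx]), ignore_attr = TRUE)
    }
  }
})

test_that("events too close to the recording edge are dropped", {
  expect_message(al <- align_to_event(flat_traces(1), c(0.5, 30)), "dropped")
  expect_equal(dim(al)[2], 1)
  expect_equal(attr(al, "dropped"), 1L)
  expect_error(align_to_event(flat_traces(1, t_end = 3), c(0.2)), "no event")
})

test_that("z-normalization fixes baseline moments and is affine invariant", {
  set.seed(21)
  nlap <- 12
  al <- array(rnorm(2 * nlap * 30, mean = 5, sd = 2), c(2, nlap, 30),
              dimnames = list(cell = c("c1", "c2"), NULL, NULL))
  types <- rep(c("threat", "omission"), length.out = nlap)
  z <- lap_type_average_z(al, types)
  for (cc in 1:2) for (ty in c("omission", "threat")) {
    expect_equal(mean(z[cc, ty, 1:10]), 0, tolerance = 1e-12)
    expect_equal(sd(z[cc, ty, 1:10]), 1, tolerance = 1e-12)
  }
  # shift and scale invariance of the raw trace
  z_shift <- lap_type_average_z(al + 100, types)
  z_scale <- lap_type_average_z(al * 3, types)
  expect_equal(z, z_shift, tolerance = 1e-9)
  expect_equal(z, z_scale, tolerance = 1e-9)

  # two-step oracle: average across laps, then z with first-10-bin moments
  for (ty in c("omission", "threat")) {
    avg <- apply(al[, types == ty, , drop = FALSE], c(1, 3), mean)
    mu <- rowMeans(avg[, 1:10]); sdev <- apply(avg[, 1:10], 1, sd)
    expect_equal(z[, ty, ], (avg - mu) / sdev, ignore_attr = TRUE)
  }

  # zero-variance baseline is undefined, not imputed
  al[1, types == "threat", 1:10] <- 4
  z2 <- lap_type_average_z(al, types)
  expect_true(all(is.na(z2[1, "threat", ])))
  expect_false(anyNA(z2[2, "threat", ]))
})

test_that("the per-lap z variant averages lap-wise z-scores", {
  set.seed(25)
  nlap <- 6
  al <- array(rnorm(2 * nlap * 30, 3, 1.5), c(2, nlap, 30),
              dimnames = list(cell = c("c1", "c2"), NULL, NULL))
  types <- rep("t", nlap)
  z <- lap_type_average_z(al, types, per_lap = TRUE)
  # oracle: z-score each lap's 30-bin trace by its own baseline, then average
  for (cc in 1:2) {
    zl <- sapply(seq_len(nlap), function(l) {
      b <- al[cc, l, 1:10]
      (al[cc, l, ] - mean(b)) / sd(b)
    })
    expect_equal(z[cc, "t", ], rowMeans(zl), ignore_attr = TRUE)
  }
})

test_that("response magnitude is the mean of bins 11-15", {
  z <- array(0, c(1, 1, 30), dimnames = list("c1", "t", NULL))
  z[1, 1, 11:15] <- c(2, 2, 2, 2, 2)
  expect_equal(response_magnitude(z)[1, 1], 2)
  z[1, 1, 11:15] <- 1:5
  expect_equal(response_magnitude(z)[1, 1], 3)
  set.seed(22)
  z[1, 1, ] <- rnorm(30)
  expect_equal(response_magnitude(z)[1, 1], mean(z[1, 1, 11:15]))
})

test_that("outcome responders use a strict threshold", {
  mag <- matrix(c(2.1, 2.0, -2.1, 0), 4, 1,
                dimnames = list(paste0("c", 1:4), "threat_ht"))
  cls <- classify_outcome_responders(mag)
  expect_equal(unname(cls$increased[, 1]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(cls$decreased[, 1]), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("LED effect distributions subtract the omission baseline", {
  mag <- cbind(omission = c(1, 0), puff = c(1, 3), puff_led = c(1, 5))
  rownames(mag) <- c("c1", "c2")
  out <- led_effect_distribution(mag)
  expect_equal(out$puff_minus_omission, c(0, 3))
  expect_equal(out$puff_led_minus_omission, c(0, 5))
  expect_error(led_effect_distribution(mag[, 1:2]), "lap types")
  # planted LED gain separates the distributions by a KS test
  set.seed(23)
  base <- rnorm(150, 3, 0.5)
  no_gain <- data.frame(puff_led_minus_omission = base + rnorm(150, 0, 0.2))
  gain <- data.frame(puff_led_minus_omission = base * 1.6 + rnorm(150, 0, 0.2))
  ks <- ks_test_2s(no_gain$puff_led_minus_omission,
                   gain$puff_led_minus_omission)
  expect_lt(ks$p, 0.001)
})

test_that("differential activity subtracts expected from surprising and is
           antisymmetric in the labels", {
  mag <- cbind(threat_surprising = c(4, 1), threat_expected = c(1, 1),
               omission_surprising = c(0, 2), omission_expected = c(3, 2))
  rownames(mag) <- c("c1", "c2")
  d <- differential_activity(mag)
  expect_equal(d$d_threat, c(3, 0))
  expect_equal(d$d_omission, c(-3, 0))
  swapped <- mag[, c(2, 1, 4, 3)]
  colnames(swapped) <- colnames(mag)
  d2 <- differential_activity(swapped)
  expect_equal(d2$d_threat, -d$d_threat)
  expect_equal(d2$d_omission, -d$d_omission)
})

test_that("PE classification reproduces the canonical examples and boundary", {
  d <- data.frame(cell = paste0("c", 1:6),
                  d_threat = c(3, 3, 3, 2, -3, 0),
                  d_omission = c(-3, 3, 1, 3, 3, 0))
  cls <- classify_pe_type(d)
  expect_equal(cls$label,
               c("Up-Down", "Up-Up", "Threat-only", "Omission-only",
                 "Down-Up", "none"))
  expect_equal(cls$signed_pe, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(cls$unsigned_pe, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("PE classification is an exhaustive partition with sign symmetry", {
  set.seed(24)
  d <- data.frame(cell = sprintf("c%03d", 1:300),
                  d_threat = rnorm(300, 0, 3),
                  d_omission = rnorm(300, 0, 3))
  cls <- classify_pe_type(d)
  expect_false(anyNA(cls$label))
  expect_true(all(cls$label %in% c("Up-Up", "Up-Down", "Down-Up", "Down-Down",
                                   "Threat-only", "Omission-only", "none")))
  # negating every trace maps Up-Up <-> Down-Down, Up-Down <-> Down-Up and
  # preserves signed/unsigned membership
  neg <- d; neg$d_threat <- -d$d_threat; neg$d_omission <- -d$d_omission
  cls_neg <- classify_pe_type(neg)
  map <- c("Up-Up" = "Down-Down", "Down-Down" = "Up-Up",
           "Up-Down" = "Down-Up", "Down-Up" = "Up-Down",
           "Threat-only" = "Threat-only", "Omission-only" = "Omission-only",
           "none" = "none")
  expect_equal(cls_neg$label, unname(map[cls$label]))
  expect_equal(cls_neg$signed_pe, cls$signed_pe)
  expect_equal(cls_neg$unsigned_pe, cls$unsigned_pe)
})

test_that("category proportions carry exact Clopper-Pearson limits", {
  labs <- rep(c("Up-Down", "none"), c(0, 20))
  out <- pe_proportions(labs, categories = c("Up-Down", "none"))
  expect_equal(out$lower[out$label == "Up-Down"], 0)

  labs2 <- rep(c("Up-Down", "none"), c(5, 45))
  out2 <- pe_proportions(labs2, categories = "Up-Down")
  # direct Beta-quantile oracle
  expect_equal(out2$lower, qbeta(0.025, 5, 46), tolerance = 1e-12)
  expect_equal(out2$upper, qbeta(0.975, 6, 45), tolerance = 1e-12)

  same <- pe_group_binomial_test(5, 50, 5, 50)
  expect_gt(same$p, 0.9)
  expect_error(pe_proportions(character(0)), "at least one")
})
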