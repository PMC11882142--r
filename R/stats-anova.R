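#' Mixed / repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate split-plot ANOVA for designs with up to one between-subject
#' factor crossed with one or two within-subject factors (one observation per
#' subject per within-cell; between-group sizes may differ, within levels
#' must be complete). Sums of squares are computed by projecting the
#' subject x cell response matrix onto orthonormal within-subject contrasts
#' and testing Type-III hypotheses (sum-to-zero coding) in each stratum, so
#' unbalanced group sizes are handled the way standard mixed-ANOVA software
#' handles them.
#'
#' For every within-subject stratum with more than one degree of freedom,
#' Mauchly's sphericity test is run on the stratum's error covariance; when
#' its p-value falls below `sphericity_alpha` the Greenhouse-Geisser epsilon
#' multiplies both degrees of freedom and the reported p-value is the
#' corrected one.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject-id column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param between Optional name of a between-subject factor column.
#' @param sphericity_alpha Mauchly p-value below which the correction is
#'   applied.
#' @return Data frame of class `anova_table`: one row per effect with
#'   `effect`, `df_num`, `df_den`, `ss`, `ss_error`, `F`, `p_uncorrected`,
#'   `gg_epsilon`, `mauchly_p`, `correction_applied`, `df_num_corr`,
#'   `df_den_corr`, `p` (corrected when the correction applies).
#' @export
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6), session = paste0("P", 1:3))
#' set.seed(1)
#' d$y <- rnorm(nrow(d)) + as.integer(d$session)
#' mixed_anova(d, dv = "y", subject = "subject", within = "session")
mixed_anova <- function(data, dv, subject, within, between = NULL,
                        sphericity_alpha = 0.05) {
  stopifnot(length(within) %in% c(1, 2), is.null(between) || length(between) == 1)
  wide <- reshape_rm(data, dv, subject, within, between)
  Y <- wide$Y                 # subjects x cells
  group <- wide$group         # factor or NULL
  lv <- wide$within_levels    # list of level vectors, order matches columns
  n <- nrow(Y)

  # design matrix of the between-subject model (Type III, sum-to-zero)
  if (is.null(group)) {
    X <- matrix(1, n, 1)
    term_rows <- list()        # no between term
  } else {
    X <- stats::model.matrix(~ g, data.frame(g = group),
                             contrasts.arg = list(g = "contr.sum"))
    term_rows <- list(between = 2:ncol(X))
  }
  p_cols <- ncol(X)
  if (n <= p_cols) stop("not enough subjects for the between-subject model")

  contr <- lapply(lv, function(l) orthonormal_contrasts(length(l)))
  unit <- lapply(lv, function(l) matrix(rep(1 / sqrt(length(l)), length(l))))
  jvec <- Reduce(kronecker, unit)

  # within strata
  w_names <- within
  effs_w <- list()
  effs_w[[w_names[1]]] <- kron_list(contr[[1]], if (length(lv) == 2) unit[[2]] else NULL)
  if (length(lv) == 2) {
    effs_w[[w_names[2]]] <- kron_list(unit[[1]], contr[[2]])
    effs_w[[paste(w_names[1], w_names[2], sep = ":")]] <-
      kron_list(contr[[1]], contr[[2]])
  }

  rows <- list()
  # between-subject stratum: subject means
  if (!is.null(group)) {
    fit <- stratum_fit(Y %*% jvec, X)
    hs <- hypothesis_ss(fit, term_rows$between)
    rows[[length(rows) + 1]] <- anova_row(
      effect = between, d = 1, q = length(term_rows$between),
      ss_h = hs, E = fit$E, df_e = n - p_cols,
      eps = NA_real_, mauchly_p = NA_real_, sphericity_alpha = sphericity_alpha
    )
  }
  # within strata: each M gives effect (intercept hypothesis) and, with a
  # between factor, its group interaction (group hypothesis)
  for (nm in names(effs_w)) {
    M <- effs_w[[nm]]
    d <- ncol(M)
    Z <- Y %*% M
    fit <- stratum_fit(Z, X)
    df_e <- n - p_cols
    S <- fit$E / df_e
    eps <- gg_epsilon(S)
    mp <- mauchly_p_value(S, df_e)
    rows[[length(rows) + 1]] <- anova_row(
      effect = nm, d = d, q = 1,
      ss_h = hypothesis_ss(fit, 1L), E = fit$E, df_e = df_e,
      eps = eps, mauchly_p = mp, sphericity_alpha = sphericity_alpha
    )
    if (!is.null(group)) {
      rows[[length(rows) + 1]] <- anova_row(
        effect = paste(between, nm, sep = ":"), d = d,
        q = length(term_rows$between),
        ss_h = hypothesis_ss(fit, term_rows$between), E = fit$E, df_e = df_e,
        eps = eps, mauchly_p = mp, sphericity_alpha = sphericity_alpha
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_table", class(out))
  out
}

#' One-way repeated-measures ANOVA
#'
#' Special case of [mixed_anova()] with a single within-subject factor and no
#' between-subject factor.
#'
#' @inheritParams mixed_anova
#' @param within Name of the single within-subject factor column.
#' @return See [mixed_anova()].
#' @export
one_way_rm_anova <- function(data, dv, subject, within,
                             sphericity_alpha = 0.05) {
  stopifnot(length(within) == 1)
  mixed_anova(data, dv, subject, within, between = NULL,
              sphericity_alpha = sphericity_alpha)
}

#' Tukey multiple comparisons after one-way repeated-measures ANOVA
#'
#' Pairwise comparisons of the within-factor level means using the
#' studentized range distribution with the repeated-measures error term
#' (subject x factor interaction mean square).
#'
#' @inheritParams one_way_rm_anova
#' @return Data frame `level_1`, `level_2`, `diff`, `q`, `p_adj`.
#' @export
tukey_rm <- function(data, dv, subject, within) {
  wide <- reshape_rm(data, dv, subject, within, between = NULL)
  Y <- wide$Y
  n <- nrow(Y); k <- ncol(Y)
  means <- colMeans(Y)
  # error SS: subject x factor interaction
  resid <- Y - outer(rowMeans(Y), rep(1, k)) -
    outer(rep(1, n), means) + mean(Y)
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  df_e <- (n - 1) * (k - 1)
  levels_ <- wide$within_levels[[1]]
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    level_1 = levels_[pairs[1, ]],
    level_2 = levels_[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    stringsAsFactors = FALSE
  )
  out$q <- abs(out$diff) / sqrt(ms_e / n)
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = df_e, lower.tail = FALSE)
  out
}

# ---- internals --------------------------------------------------------------

# long -> subjects x cells matrix; errors on missing or duplicated cells
reshape_rm <- function(data, dv, subject, within, between) {
  need <- c(dv, subject, within, between)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  subj <- factor(data[[subject]])
  w <- lapply(within, function(v) factor(data[[v]]))
  cell <- do.call(interaction, c(w, list(lex.order = TRUE)))  # first factor slowest
  tab <- table(subj, cell)
  if (any(tab != 1)) {
    stop("design must be complete with one observation per subject per ",
         "within-subject cell (no imputation)")
  }
  ord <- order(subj, cell)
  Y <- matrix(data[[dv]][ord], nrow = nlevels(subj), byrow = TRUE)
  rownames(Y) <- levels(subj)
  group <- NULL
  if (!is.null(between)) {
    g <- tapply(as.character(data[[between]]), subj, function(v) {
      u <- unique(v)
      if (length(u) > 1) stop("a subject appears in more than one group")
      u
    })
    group <- factor(g[levels(subj)])
  }
  list(Y = Y, group = group,
       within_levels = lapply(w, levels),
       subject_ids = levels(subj))
}

# orthonormal contrasts orthogonal to the unit vector
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

kron_list <- function(A, B) if (is.null(B)) A else kronecker(A, B)

# least squares fit of Z ~ X, returning what the hypothesis tests need
stratum_fit <- function(Z, X) {
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  B <- XtXinv %*% crossprod(X, Z)
  E <- crossprod(Z - X %*% B)
  list(B = B, XtXinv = XtXinv, E = E)
}

# trace of the SSP for the hypothesis that the selected coefficient rows = 0
hypothesis_ss <- function(fit, rows) {
  L <- diag(nrow(fit$B))[rows, , drop = FALSE]
  LB <- L %*% fit$B
  H <- crossprod(LB, solve(L %*% fit$XtXinv %*% t(L), LB))
  sum(diag(as.matrix(H)))
}

# Greenhouse-Geisser epsilon of a stratum error covariance (already projected
# onto orthonormal contrasts)
gg_epsilon <- function(S) {
  d <- nrow(S)
  if (d == 1) return(1)
  eps <- sum(diag(S))^2 / (d * sum(S * S))
  min(max(eps, 1 / d), 1)
}

# Mauchly's sphericity test, Box's chi-square approximation with the
# second-order correction term
mauchly_p_value <- function(S, df_e) {
  d <- nrow(S)
  if (d == 1) return(NA_real_)
  detS <- det(S)
  if (detS <= 0) return(0)
  W <- detS / (sum(diag(S)) / d)^d
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * df_e)
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
    (288 * d^2 * df_e^2 * rho^2)
  z <- -df_e * rho * log(W)
  df <- d * (d + 1) / 2 - 1
  p <- stats::pchisq(z, df, lower.tail = FALSE) +
    w2 * (stats::pchisq(z, df + 4, lower.tail = FALSE) -
            stats::pchisq(z, df, lower.tail = FALSE))
  min(max(p, 0), 1)
}

anova_row <- function(effect, d, q, ss_h, E, df_e, eps, mauchly_p,
                      sphericity_alpha) {
  ss_e <- sum(diag(as.matrix(E)))
  df1 <- q * d
  df2 <- d * df_e
  Fval <- if (ss_h < 1e-12 * (ss_h + ss_e + 1)) 0
  else (ss_h / df1) / (ss_e / df2)
  p_unc <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  apply_corr <- !is.na(mauchly_p) && mauchly_p < sphericity_alpha && eps < 1
  df1c <- if (apply_corr) eps * df1 else df1
  df2c <- if (apply_corr) eps * df2 else df2
  p_rep <- if (apply_corr) stats::pf(Fval, df1c, df2c, lower.tail = FALSE) else p_unc
  data.frame(
    effect = effect, df_num = df1, df_den = df2,
    ss = ss_h, ss_error = ss_e, F = Fval, p_uncorrected = p_unc,
    gg_epsilon = eps, mauchly_p = mauchly_p,
    correction_applied = apply_corr,
    df_num_corr = df1c, df_den_corr = df2c, p = p_rep,
    stringsAsFactors = FALSE
  )
}
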