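#' Build a treatment-coded design matrix
#'
#' Factors are dummy coded against declared reference levels with an
#' intercept; interaction columns are elementwise products of the main
#' effect dummies.  A rank-deficient design is reported as an error.
#'
#' @param data data frame holding the response and predictors.
#' @param formula model formula, e.g. `y ~ shape * angle + bird`.
#' @param ref_levels named list mapping factor columns to their reference
#'   level.
#' @return List with `X` (design matrix), `y` (response) and `terms`
#'   (column names).
#' @export
build_design <- function(data, formula, ref_levels = NULL) {
  stopifnot(is.data.frame(data))
  for (nm in names(ref_levels)) {
    if (!nm %in% names(data)) stop("unknown factor: ", nm)
    f <- factor(data[[nm]])
    if (!ref_levels[[nm]] %in% levels(f)) {
      stop(sprintf("level '%s' not present in factor '%s'",
                   ref_levels[[nm]], nm))
    }
    data[[nm]] <- stats::relevel(f, ref = ref_levels[[nm]])
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (anyNA(y)) stop("missing responses are not allowed")
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (aliased terms)")
  }
  list(X = X, y = as.numeric(y), terms = colnames(X))
}

#' Ordinary least squares from the closed form
#'
#' QR-based least squares with classical standard errors
#' `sigma^2 (X'X)^-1`, `sigma^2 = RSS / (n - p)`, plus R-squared and the
#' overall F statistic against the intercept-only model.
#'
#' @param X design matrix (full column rank, `n > p`).
#' @param y numeric response.
#' @return A `model_fit`: list with a coefficient table (`term`,
#'   `estimate`, `se`, `t_value`), `sigma`, `df_residual`, `r_squared`,
#'   `f_statistic`, `f_df`, `residuals`, `fitted`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  has_intercept <- any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))
  tss <- if (has_intercept) sum((y - mean(y))^2) else sum(y^2)
  df1 <- p - has_intercept
  fstat <- if (df1 > 0) ((tss - rss) / df1) / sigma2 else NA_real_
  structure(
    list(
      coefficients = data.frame(term = colnames(X), estimate = beta, se = se,
                                t_value = beta / se, row.names = NULL),
      sigma = sqrt(sigma2),
      df_residual = n - p,
      r_squared = 1 - rss / tss,
      f_statistic = fstat,
      f_df = c(df1, n - p),
      residuals = res,
      fitted = fitted,
      method = "ols"
    ),
    class = "model_fit"
  )
}

# REML criterion (-2 restricted log-likelihood up to an additive constant)
# for the random-intercept model at variance ratio lambda = sigma_b^2 /
# sigma_e^2, with the fixed effects and sigma_e^2 profiled out.  Uses the
# closed-form inverse V_i^{-1} = I - lambda/(1 + lambda n_i) J per group.
reml_pieces <- function(X, y, group, lambda) {
  gi <- split(seq_along(y), group)
  ni <- lengths(gi)
  w <- lambda / (1 + lambda * ni)
  S <- t(vapply(gi, function(i) colSums(X[i, , drop = FALSE]), numeric(ncol(X))))
  if (ncol(X) == 1L) S <- matrix(S, ncol = 1L)
  u <- vapply(gi, function(i) sum(y[i]), numeric(1))
  xtvx <- crossprod(X) - crossprod(S * sqrt(w))
  xtvy <- crossprod(X, y) - crossprod(S, w * u)
  ytvy <- sum(y^2) - sum(w * u^2)
  beta <- solve(xtvx, xtvy)
  q <- drop(ytvy - crossprod(beta, xtvy))
  n <- length(y)
  p <- ncol(X)
  crit <- sum(log1p(lambda * ni)) + determinant(xtvx)$modulus[1] +
    (n - p) * log(q)
  list(beta = drop(beta), q = q, xtvx = xtvx, crit = crit)
}

#' Random-intercept linear mixed model fitted by REML
#'
#' Fits `y = X beta + b[group] + e`, `b ~ N(0, sigma_b^2)`,
#' `e ~ N(0, sigma_e^2)`, by profiling the REML criterion over the single
#' variance ratio `lambda = sigma_b^2 / sigma_e^2`: at each candidate
#' ratio the fixed effects are the GLS solution and the residual variance
#' has a closed form, leaving a 1-D optimization (golden-section via
#' [stats::optimize()] on `log10(lambda)`, with the boundary `lambda = 0`
#' checked explicitly so the fit degenerates exactly to OLS when the
#' between-group variance vanishes).
#'
#' t-values are reported against residual degrees of freedom
#' (`n - p`); no small-sample degrees-of-freedom correction (e.g.
#' Satterthwaite) is applied.
#'
#' @param X design matrix for the fixed effects.
#' @param y numeric response.
#' @param group grouping factor (>= 2 levels) for the random intercept.
#' @return A `model_fit` with the fixed-effect coefficient table,
#'   `varcomp` (group and residual variances and SDs), `lambda`,
#'   `reml_criterion`, `df_residual` and `criterion_fn` (the profiled
#'   criterion as a function of lambda, for diagnostics).
#' @export
fit_lmm_ranint <- function(X, y, group) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (nrow(X) <= ncol(X)) stop("need more observations than parameters")
  if (length(y) != nrow(X) || length(group) != nrow(X)) {
    stop("X, y and group must have matching lengths")
  }
  crit_fn <- function(lambda) reml_pieces(X, y, group, lambda)$crit
  opt <- stats::optimize(function(l10) crit_fn(10^l10),
                         interval = c(-10, 8), tol = 1e-9)
  lambda <- 10^opt$minimum
  crit0 <- crit_fn(0)
  if (crit0 <= opt$objective) lambda <- 0
  pieces <- reml_pieces(X, y, group, lambda)
  n <- length(y)
  p <- ncol(X)
  sigma_e2 <- pieces$q / (n - p)
  sigma_b2 <- lambda * sigma_e2
  se <- sqrt(sigma_e2 * diag(solve(pieces$xtvx)))
  structure(
    list(
      coefficients = data.frame(term = colnames(X), estimate = pieces$beta,
                                se = se, t_value = pieces$beta / se,
                                row.names = NULL),
      varcomp = data.frame(
        term = c("group", "residual"),
        variance = c(sigma_b2, sigma_e2),
        sd = sqrt(c(sigma_b2, sigma_e2))
      ),
      lambda = lambda,
      reml_criterion = pieces$crit,
      df_residual = n - p,
      n_groups = nlevels(group),
      criterion_fn = crit_fn,
      method = "reml"
    ),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit, %d coefficient(s), residual df = %d\n",
              toupper(x$method), nrow(x$coefficients), x$df_residual))
  print(cbind(x$coefficients[1],
              round(x$coefficients[-1], 4)), row.names = FALSE)
  if (!is.null(x$r_squared)) {
    cat(sprintf("R-squared = %.4f, F(%d, %d) = %.2f\n", x$r_squared,
                x$f_df[1], x$f_df[2], x$f_statistic))
  }
  if (!is.null(x$varcomp)) {
    cat("Variance components:\n")
    print(cbind(x$varcomp[1], round(x$varcomp[-1], 6)), row.names = FALSE)
  }
  invisible(x)
}

#' Gliding-proportion regression for the wind-tunnel experiment
#'
#' Fits `gliding_prop ~ logger_shape * wind_angle + bird` by OLS with
#' references cube shape, +2 degrees wind and the first bird, one
#' observation per flight session.
#'
#' @param flights data frame with one row per flight session: columns
#'   `gliding_prop`, `logger_shape`, `wind_angle`, `bird`.
#' @param ref_bird reference level for the bird factor (default the
#'   first level).
#' @return A `model_fit` from [fit_ols()].
#' @export
fit_gliding_model <- function(flights, ref_bird = NULL) {
  stopifnot(all(c("gliding_prop", "logger_shape", "wind_angle", "bird")
                %in% names(flights)))
  flights$wind_angle <- factor(flights$wind_angle)
  refs <- list(logger_shape = "cube",
               wind_angle = levels(flights$wind_angle)[1],
               bird = ref_bird %||% sort(unique(as.character(flights$bird)))[1])
  d <- build_design(flights,
                    gliding_prop ~ logger_shape * wind_angle + bird,
                    ref_levels = refs)
  fit_ols(d$X, d$y)
}

#' Assemble the log10 daily-distance design table
#'
#' Log-transforms daily flight distances (base 10) and attaches the
#' attachment-position and activity factors; zero-distance days cannot be
#' log-transformed and are excluded (their count is reported in attribute
#' `n_excluded`).
#'
#' @param daily a `daily_summary` (or a row-bound set of them) with
#'   columns `bird`, `path_km`, `day_type`, and either an `attachment`
#'   column or attribute.
#' @return Data frame with `bird`, `log10_km`, `activity` (factor,
#'   reference `stopover`) and `attachment` (factor, reference
#'   `wing_loop`).
#' @export
log10_transform <- function(daily) {
  stopifnot(all(c("bird", "path_km", "day_type") %in% names(daily)))
  attach_col <- daily$attachment %||%
    rep(attr(daily, "attachment") %||% NA_character_, nrow(daily))
  keep <- daily$path_km > 0
  out <- data.frame(
    bird = daily$bird[keep],
    log10_km = log10(daily$path_km[keep]),
    activity = factor(daily$day_type[keep],
                      levels = c("stopover", "migration")),
    attachment = factor(attach_col[keep], levels = c("wing_loop", "leg_loop")),
    stringsAsFactors = FALSE
  )
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Daily-distance mixed model for the field study
#'
#' Fits `log10(distance) ~ attachment * activity + (1 | bird)` by REML
#' with references wing-loop harness and stopover days.
#'
#' @param design_table output of [log10_transform()].
#' @return A `model_fit` from [fit_lmm_ranint()].
#' @export
fit_distance_model <- function(design_table) {
  d <- build_design(design_table, log10_km ~ attachment * activity,
                    ref_levels = list(attachment = "wing_loop",
                                      activity = "stopover"))
  fit_lmm_ranint(d$X, d$y, design_table$bird)
}
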