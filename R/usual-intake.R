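#' @importFrom generics tidy glance
NULL

# Box-Cox transform and inverse; lambda 0 is the log.
bc_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}
bc_inverse <- function(z, lambda) {
  if (abs(lambda) < 1e-12) exp(z) else (lambda * z + 1)^(1 / lambda)
}

# Profile log-likelihood of the Box-Cox model given fixed effects in X.
bc_loglik <- function(y, lambda, X) {
  z <- bc_transform(y, lambda)
  fit <- stats::lm.fit(X, z)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  -n / 2 * log(rss / n) + (lambda - 1) * sum(log(y))
}

#' Fit a usual-intake (habitual intake) model
#'
#' Converts repeated short-term intake measurements into the ingredients of a
#' habitual-intake estimate, in the style of the amount part of the Multiple
#' Source Method: (1) transform intakes towards normality with a Box-Cox
#' power chosen by maximum likelihood over a coarse grid (0 = log); (2) remove
#' an optional weekday/weekend fixed effect, re-centring at the 4/7-3/7 week
#' composition; (3) decompose the variance into between-person and
#' within-person (day-to-day) components with the one-way random-effects
#' ANOVA method-of-moments estimators. All participants are treated as
#' consumers; zero intakes are handled by a small positive offset (half the
#' smallest positive value) before transforming.
#'
#' @param data Daily-intake tibble (e.g. from [daily_intake()]), one row per
#'   participant-day, with a `participant_id` column.
#' @param value Name of the intake column to model (string), e.g. `"added_g"`.
#' @param day_class Optional name of a two-level `weekday`/`weekend` column;
#'   `NULL` drops the effect.
#' @param lambda_grid Box-Cox exponents searched; default
#'   `c(-1, -0.5, 0, 1/3, 0.5, 1)`.
#' @param weekend_share Long-run share of weekend days; default 3/7 (Friday
#'   through Sunday).
#' @return An object of class `usual_intake_model`.
#' @export
fit_usual_intake <- function(data, value, day_class = "day_class",
                             lambda_grid = c(-1, -0.5, 0, 1 / 3, 0.5, 1),
                             weekend_share = 3 / 7) {
  data <- as_tibble(data)
  stopifnot(value %in% names(data), "participant_id" %in% names(data))
  y_raw <- data[[value]]
  if (any(is.na(y_raw)) || any(y_raw < 0)) {
    abort("intake values must be non-negative and non-missing")
  }

  offset <- 0
  if (any(y_raw <= 0)) {
    pos <- y_raw[y_raw > 0]
    if (length(pos) == 0) abort("all intakes are zero; nothing to model")
    offset <- min(pos) / 2
    inform(sprintf(
      "zero intakes present: adding offset %.4g (half the smallest positive value)",
      offset))
  }
  y <- y_raw + offset

  use_dc <- !is.null(day_class) && day_class %in% names(data) &&
    length(unique(data[[day_class]])) > 1
  weekend <- if (use_dc) as.numeric(data[[day_class]] == "weekend") else NULL
  X <- if (use_dc) cbind(1, weekend) else matrix(1, nrow = length(y))

  ll <- vapply(lambda_grid, function(l) bc_loglik(y, l, X), 0)
  lambda <- lambda_grid[[which.max(ll)]]
  z <- bc_transform(y, lambda)

  beta_weekend <- 0
  if (use_dc) {
    fit <- stats::lm.fit(X, z)
    beta_weekend <- unname(fit$coefficients[[2]])
    # centre at the 4/7 weekday - 3/7 weekend composition of a week
    z <- z - beta_weekend * (weekend - weekend_share)
  }

  id <- data$participant_id
  k <- length(unique(id))
  N <- length(z)
  grp_mean <- tapply(z, id, mean)
  grp_n <- tapply(z, id, length)
  if (sum(grp_n >= 2) == 0) {
    abort(paste0("within-person variance is unidentifiable: no participant ",
                 "has two or more observation days"))
  }
  grand <- mean(z)
  ssw <- sum((z - grp_mean[id])^2)
  dfw <- N - k
  sigma2_within <- ssw / dfw
  ssb <- sum(grp_n * (grp_mean - grand)^2)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(grp_n^2) / N) / (k - 1)
  sigma2_between <- (msb - sigma2_within) / n0
  if (sigma2_between < 0) {
    warn(sprintf(
      "negative between-person moment estimate (%.4g) clamped to 0",
      sigma2_between))
    sigma2_between <- 0
  }

  structure(
    list(value = value,
         transform = if (abs(lambda) < 1e-12) "log" else "box_cox",
         lambda = lambda, offset = offset,
         mu = grand,
         sigma2_between = sigma2_between,
         sigma2_within = sigma2_within,
         beta_weekend = beta_weekend, weekend_share = weekend_share,
         mean_observed = mean(y_raw),
         n_participants = k, n_obs = N,
         lambda_grid = lambda_grid, loglik = ll),
    class = "usual_intake_model")
}

#' @export
print.usual_intake_model <- function(x, ...) {
  cat("<usual_intake_model> ", x$value, "\n", sep = "")
  cat(sprintf("  transform: %s (lambda = %.3g), offset = %.4g\n",
              x$transform, x$lambda, x$offset))
  cat(sprintf("  mu = %.4g  sigma2_between = %.4g  sigma2_within = %.4g\n",
              x$mu, x$sigma2_between, x$sigma2_within))
  cat(sprintf("  weekend effect = %.4g  (%d participants, %d days)\n",
              x$beta_weekend, x$n_participants, x$n_obs))
  invisible(x)
}

#' Predict habitual intakes
#'
#' On the transformed scale each participant's mean is shrunk towards the
#' population mean with the factor
#' `sigma2_between / (sigma2_between + sigma2_within / n_i)`, then
#' back-transformed. A smearing-style correction rescales the back-transformed
#' values by `mean(observed) / mean(back-transformed)` so the population mean
#' on the original scale is preserved exactly.
#'
#' @param object A fitted `usual_intake_model`.
#' @param newdata Daily-intake tibble containing `participant_id`, the
#'   modelled value column, and (if used in fitting) the day-class column.
#' @param day_class Name of the day-class column; `NULL` if unused.
#' @param ... Unused.
#' @return Tibble `participant_id, n_days, shrinkage, habitual`.
#' @export
predict.usual_intake_model <- function(object, newdata,
                                       day_class = "day_class", ...) {
  stopifnot(object$value %in% names(newdata),
            "participant_id" %in% names(newdata))
  y_raw <- newdata[[object$value]]
  if (any(is.na(y_raw))) abort("intake values must be non-missing")
  y <- y_raw + object$offset
  z <- bc_transform(y, object$lambda)
  if (object$beta_weekend != 0 && !is.null(day_class) &&
      day_class %in% names(newdata)) {
    weekend <- as.numeric(newdata[[day_class]] == "weekend")
    z <- z - object$beta_weekend * (weekend - object$weekend_share)
  }
  id <- newdata$participant_id
  grp_mean <- tapply(z, id, mean)
  grp_n <- tapply(z, id, length)
  if (any(grp_n == 0)) abort("participant with zero observation days")

  s2b <- object$sigma2_between
  s2w <- object$sigma2_within
  denom <- s2b + s2w / as.numeric(grp_n)
  shrink <- ifelse(denom > 0, s2b / denom, 1)
  h <- object$mu + shrink * (as.numeric(grp_mean) - object$mu)
  hab <- bc_inverse(h, object$lambda) - object$offset
  hab <- pmax(hab, 0)
  m <- mean(hab)
  scale <- if (m > 0) mean(y_raw) / m else 1
  tibble(participant_id = names(grp_mean),
         n_days = as.integer(grp_n),
         shrinkage = as.numeric(shrink),
         habitual = hab * scale)
}

#' @export
tidy.usual_intake_model <- function(x, ...) {
  tibble(term = c("lambda", "offset", "mu", "sigma2_between", "sigma2_within",
                  "beta_weekend"),
         estimate = c(x$lambda, x$offset, x$mu, x$sigma2_between,
                      x$sigma2_within, x$beta_weekend))
}

#' @export
glance.usual_intake_model <- function(x, ...) {
  s2b <- x$sigma2_between
  s2w <- x$sigma2_within
  tibble(value = x$value, transform = x$transform, lambda = x$lambda,
         sigma2_between = s2b, sigma2_within = s2w,
         variance_ratio = if (s2w > 0) s2b / s2w else NA_real_,
         icc = if (s2b + s2w > 0) s2b / (s2b + s2w) else NA_real_,
         shrinkage_2day = if (s2b + s2w / 2 > 0) s2b / (s2b + s2w / 2) else 1,
         n_participants = x$n_participants, n_obs = x$n_obs)
}

#' @export
generics::tidy

#' @export
generics::glance

#' Habitual intakes for all pipeline nutrients
#'
#' Convenience wrapper fitting one usual-intake model per nutrient column and
#' returning one habitual value per participant and nutrient.
#'
#' @param daily Daily-intake tibble from [daily_intake()].
#' @param values Columns to adjust; default
#'   `c("added_g", "free_g", "total_g", "energy_kJ")`.
#' @param ... Passed to [fit_usual_intake()].
#' @return Tibble `participant_id` plus one habitual column per nutrient;
#'   the fitted models are attached as attribute `"models"`.
#' @export
usual_intakes <- function(daily,
                          values = c("added_g", "free_g", "total_g", "energy_kJ"),
                          ...) {
  models <- list()
  out <- NULL
  for (v in values) {
    m <- fit_usual_intake(daily, v, ...)
    models[[v]] <- m
    pred <- predict(m, daily)
    pred <- select(pred, "participant_id", habitual = "habitual")
    names(pred)[2] <- v
    out <- if (is.null(out)) pred else left_join(out, pred, by = "participant_id")
  }
  attr(out, "models") <- models
  out
}
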