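#' Ordinary least-squares fit of heave amplitude on wingbeat frequency
#'
#' @param data Data frame of intervals (or cycles).
#' @param amplitude,frequency Column names of the response and predictor.
#' @return An object of class `wb_linfit` with `slope`, `intercept`,
#'   `p_value` (two-sided, on the slope), `r_squared`, `n` and the underlying
#'   `lm` fit.
#' @export
fit_amplitude_frequency <- function(data,
                                    amplitude = "mean_heave_amplitude",
                                    frequency = "mean_frequency") {
  stopifnot(all(c(amplitude, frequency) %in% names(data)))
  d <- data.frame(a = data[[amplitude]], f = data[[frequency]])
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 observations for the amplitude-frequency fit")
  if (var(d$f) == 0) stop("wingbeat frequency has zero variance: slope is undefined")
  fit <- lm(a ~ f, data = d)
  # an exactly linear input is legitimate (R^2 = 1); silence the advisory
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = sm$coefficients[2, 4],
                 r_squared = sm$r.squared,
                 n = nrow(d),
                 fit = fit),
            class = "wb_linfit")
}

#' @export
print.wb_linfit <- function(x, ...) {
  cat(sprintf("<wb_linfit> amplitude = %.4g + %.4g * frequency  (p = %.3g, R^2 = %.3g, n = %d)\n",
              x$intercept, x$slope, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.wb_linfit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Mixed model of heave amplitude on frequency and its flight-mode interaction
#'
#' Fits `amplitude ~ WBF + WBF:covariate` with a random intercept per
#' individual and a continuous-time first-order autoregressive (CAR1)
#' residual correlation indexed by interval time within individual,
#' estimated by REML via [nlme::lme()]. A positive interaction means birds
#' raise amplitude more than frequency as the covariate (climb rate or
#' airspeed) increases. Marginal and conditional R-squared follow the
#' variance-partition formula for mixed models: the fixed-effect variance is
#' the variance of the fixed-effect predictor, and the denominators add the
#' random-intercept and residual variances.
#'
#' When the response is (numerically) an exact linear function of the fixed
#' effects, the mixed model is degenerate (zero residual variance) and the
#' fit falls back to ordinary least squares with zero variance components, a
#' case flagged by `degenerate = TRUE`.
#'
#' @param data Interval data, time-ordered within individual.
#' @param covariate Which flight-state covariate interacts with frequency:
#'   `"v_z"` (climb rate) or `"airspeed"`.
#' @param response,frequency,individual,time Column names.
#' @return An object of class `wb_lmm`: fixed-effect table (`estimate`,
#'   `se`, `t`, `p` per term), `sd_intercept`, `sigma`, `phi` (CAR1
#'   parameter), `r2_marginal`, `r2_conditional`, `n`, `n_individuals`,
#'   `singular`/`degenerate` flags and the underlying model.
#' @export
fit_lmm_interaction <- function(data, covariate = c("v_z", "airspeed"),
                                response = "mean_heave_amplitude",
                                frequency = "mean_frequency",
                                individual = "individual",
                                time = "start") {
  covariate <- match.arg(covariate)
  need <- c(response, frequency, covariate, individual, time)
  stopifnot(all(need %in% names(data)))
  d <- data.frame(amp = data[[response]], wbf = data[[frequency]],
                  cov = data[[covariate]], id = factor(data[[individual]]),
                  tt = data[[time]])
  d <- d[complete.cases(d), , drop = FALSE]
  d <- d[order(d$id, d$tt), , drop = FALSE]
  if (nlevels(droplevels(d$id)) < 2) stop("need at least 2 individuals for the random intercept")

  ols <- lm(amp ~ wbf + wbf:cov, data = d)
  degenerate <- suppressWarnings(summary(ols)$sigma) < 1e-8 * max(1, sd(d$amp))
  if (degenerate) {
    sm <- suppressWarnings(summary(ols)$coefficients)
    fixed <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        t = sm[, 3], p = sm[, 4], row.names = NULL)
    res <- list(fixed = fixed, sd_intercept = 0,
                sigma = suppressWarnings(summary(ols)$sigma),
                phi = 0, r2_marginal = 1, r2_conditional = 1,
                n = nrow(d), n_individuals = nlevels(droplevels(d$id)),
                df = ols$df.residual,
                singular = TRUE, degenerate = TRUE, model = ols,
                covariate = covariate)
    class(res) <- "wb_lmm"
    return(res)
  }

  mod <- nlme::lme(amp ~ wbf + wbf:cov, random = ~ 1 | id,
                   correlation = nlme::corCAR1(form = ~ tt | id),
                   data = d, method = "REML",
                   control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                              returnObject = TRUE))
  tt <- summary(mod)$tTable
  fixed <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                      se = tt[, "Std.Error"], t = tt[, "t-value"],
                      p = tt[, "p-value"], row.names = NULL)
  vc <- nlme::VarCorr(mod)
  sd_id <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  sigma <- mod$sigma
  phi <- unname(coef(mod$modelStruct$corStruct, unconstrained = FALSE))
  X <- model.matrix(~ wbf + wbf:cov, d)
  var_f <- var(as.numeric(X %*% nlme::fixef(mod)))
  var_r <- sd_id^2
  var_e <- sigma^2
  tot <- var_f + var_r + var_e
  singular <- var_r < 1e-10 * tot
  res <- list(fixed = fixed, sd_intercept = sd_id, sigma = sigma, phi = phi,
              r2_marginal = var_f / tot,
              r2_conditional = (var_f + var_r) / tot,
              n = nrow(d), n_individuals = nlevels(droplevels(d$id)),
              df = unname(tt["wbf:cov", "DF"]),
              singular = singular, degenerate = FALSE, model = mod,
              covariate = covariate)
  if (singular) {
    warning("random-intercept variance is estimated at (near) zero; ",
            "the random effect may be unidentifiable in these data")
  }
  class(res) <- "wb_lmm"
  res
}

#' @export
print.wb_lmm <- function(x, ...) {
  cat(sprintf("<wb_lmm> amplitude ~ WBF + WBF:%s | random intercept per individual, CAR1 errors\n",
              x$covariate))
  cat(sprintf("  n = %d intervals, %d individuals%s\n", x$n, x$n_individuals,
              if (isTRUE(x$degenerate)) " [degenerate: OLS fallback]" else ""))
  print(x$fixed, digits = 4)
  cat(sprintf("  random intercept sd = %.4g | residual sd = %.4g | phi (CAR1) = %.4g\n",
              x$sd_intercept, x$sigma, x$phi))
  cat(sprintf("  R^2 marginal = %.3g, conditional = %.3g\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @export
coef.wb_lmm <- function(object, ...) {
  setNames(object$fixed$estimate, object$fixed$term)
}

#' Wald confidence intervals for the fixed effects of a `wb_lmm`
#'
#' @param object A `wb_lmm` fit.
#' @param parm Terms to include (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix with `lower` and `upper` columns.
#' @export
confint.wb_lmm <- function(object, parm = NULL, level = 0.95, ...) {
  fx <- object$fixed
  if (!is.null(parm)) fx <- fx[fx$term %in% parm, , drop = FALSE]
  q <- qt(1 - (1 - level) / 2, df = object$df)
  out <- cbind(lower = fx$estimate - q * fx$se,
               upper = fx$estimate + q * fx$se)
  rownames(out) <- fx$term
  out
}

#' Coefficient of variation of wingbeat frequency
#'
#' Sample standard deviation divided by the mean, pooled across all supplied
#' values (typically all individuals of a species).
#'
#' @param frequencies Numeric vector (>= 2 values, positive mean).
#' @return The CV (dimensionless).
#' @export
species_cv <- function(frequencies) {
  frequencies <- frequencies[!is.na(frequencies)]
  if (length(frequencies) < 2) stop("need at least 2 values for a CV")
  m <- mean(frequencies)
  if (m <= 0) stop("CV undefined for non-positive mean")
  sd(frequencies) / m
}

#' Residual wing loading
#'
#' Wing loading is body mass per unit wing area; to assess its role
#' independent of size, each species' residual from the ordinary
#' least-squares regression of log(wing loading) on log(body mass) is used.
#' Residuals are invariant to multiplicative unit changes of either variable
#' (the log shift is absorbed by the intercept).
#'
#' @param records Data frame with positive `mass` and `wing_area` columns
#'   (any consistent units).
#' @param mass,wing_area Column names.
#' @return `records` with `wing_loading` and `residual_wing_loading` columns
#'   added.
#' @export
residual_wing_loading <- function(records, mass = "mass", wing_area = "wing_area") {
  stopifnot(all(c(mass, wing_area) %in% names(records)))
  m <- records[[mass]]; a <- records[[wing_area]]
  if (any(!is.finite(m)) || any(!is.finite(a)) || any(m <= 0) || any(a <= 0)) {
    stop("mass and wing area must be positive")
  }
  if (nrow(records) < 2) stop("need at least 2 records to fit the allometric line")
  records$wing_loading <- m / a
  records$residual_wing_loading <-
    unname(resid(lm(log(records$wing_loading) ~ log(m))))
  records
}

#' Correlate species kinematic variability with morphology
#'
#' Pearson product-moment correlation between species-level coefficients of
#' variation (of wingbeat frequency) and a morphological predictor, with a
#' two-sided p-value. `r_squared` is the squared correlation; the adjusted
#' value from the corresponding univariate linear model is reported as
#' `r_squared_adj`.
#'
#' @param summaries Data frame with `species` and `cv_frequency` columns.
#' @param records Data frame with `species` and the predictor column (e.g.
#'   from [residual_wing_loading()]).
#' @param predictor One of `"mass"`, `"wingspan"`, `"residual_wing_loading"`
#'   (or any column of `records`).
#' @return An object of class `wb_cor`: `rho`, `r_squared`, `r_squared_adj`,
#'   `p_value`, `n`.
#' @export
correlate_cv_morphology <- function(summaries, records,
                                    predictor = "residual_wing_loading") {
  stopifnot("species" %in% names(summaries), "cv_frequency" %in% names(summaries),
            "species" %in% names(records), predictor %in% names(records))
  d <- merge(summaries[, c("species", "cv_frequency")],
             records[, c("species", predictor)], by = "species")
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 matched species")
  if (var(d$cv_frequency) == 0 || var(d[[predictor]]) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  ct <- cor.test(d$cv_frequency, d[[predictor]], method = "pearson")
  rho <- unname(ct$estimate)
  n <- nrow(d)
  structure(list(rho = rho, r_squared = rho^2,
                 r_squared_adj = 1 - (1 - rho^2) * (n - 1) / (n - 2),
                 p_value = ct$p.value, n = n, predictor = predictor),
            class = "wb_cor")
}

#' @export
print.wb_cor <- function(x, ...) {
  cat(sprintf("<wb_cor> Pearson rho(CV_f, %s) = %.3f (R^2 = %.3f, adj %.3f, p = %.3f, n = %d)\n",
              x$predictor, x$rho, x$r_squared, x$r_squared_adj, x$p_value, x$n))
  invisible(x)
}

#' Relative flapping power proxy
#'
#' Mechanical power in flapping flight scales with the cube of both wingbeat
#' amplitude and frequency, so `(A * f)^3` serves as a relative power proxy
#' (arbitrary positive constant omitted; use for comparisons only).
#'
#' @param amplitude Wingbeat amplitude (any non-negative proxy).
#' @param frequency Wingbeat frequency (Hz, non-negative).
#' @return Relative power, same shape as the inputs.
#' @export
power_proxy <- function(amplitude, frequency) {
  if (any(amplitude < 0, na.rm = TRUE) || any(frequency < 0, na.rm = TRUE)) {
    stop("amplitude and frequency must be non-negative")
  }
  (amplitude * frequency)^3
}

#' Simulate interval-level kinematic data with known mixed-model structure
#'
#' Generates per-individual interval series from the generating model
#' `amplitude = b0 + b_wbf * WBF + b_int * WBF * covariate + u_i + e_t`,
#' with `u_i ~ N(0, sd_intercept^2)` and `e_t` a continuous-time AR(1)
#' process (`cor(e_s, e_t) = phi^|s - t|`) of marginal standard deviation
#' `sigma`. Used as the recovery oracle for [fit_lmm_interaction()].
#'
#' @param n_individuals,n_intervals Grid size.
#' @param beta0,beta_wbf,beta_int Generating fixed effects.
#' @param sd_intercept Random-intercept standard deviation.
#' @param phi CAR1 correlation at lag 1 time unit, in `[0, 1)`.
#' @param sigma Marginal residual standard deviation.
#' @param wbf_mean,wbf_sd,cov_sd Distributions of the frequency and covariate
#'   draws.
#' @param dt Time spacing between consecutive intervals.
#' @param seed Optional seed.
#' @return Data frame with `individual`, `start`, `mean_frequency`, `v_z`,
#'   `mean_heave_amplitude`.
#' @export
simulate_kinematic_intervals <- function(n_individuals = 10, n_intervals = 200,
                                         beta0 = 0, beta_wbf = 1, beta_int = 0.05,
                                         sd_intercept = 0.3, phi = 0.5,
                                         sigma = 0.2,
                                         wbf_mean = 5, wbf_sd = 0.4,
                                         cov_sd = 1, dt = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_individuals), function(i) {
    tt <- seq(0, by = dt, length.out = n_intervals)
    wbf <- rnorm(n_intervals, wbf_mean, wbf_sd)
    cv <- rnorm(n_intervals, 0, cov_sd)
    rho <- phi^dt
    e <- numeric(n_intervals)
    e[1] <- rnorm(1, 0, sigma)
    for (k in seq_len(n_intervals - 1)) {
      e[k + 1] <- rho * e[k] + rnorm(1, 0, sigma * sqrt(1 - rho^2))
    }
    u <- rnorm(1, 0, sd_intercept)
    data.frame(individual = sprintf("id%02d", i), start = tt,
               mean_frequency = wbf, v_z = cv,
               mean_heave_amplitude = beta0 + beta_wbf * wbf +
                 beta_int * wbf * cv + u + e)
  })
  do.call(rbind, out)
}
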