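#' Psychophysical power law
#'
#' Mean estimated numerosity as a power function of physical numerosity:
#' `psi = c * phi^n`, equivalently `log(psi) = n*log(phi) + log(c)`.
#'
#' @param phi physical numerosity, `> 0` (vectorised).
#' @param c multiplicative constant, `> 0`.
#' @param n exponent.
#' @return Predicted mean estimate `psi`.
#' @examples
#' power_law(20, c = 1, n = 1)     # veridical observer
#' power_law(10, c = 2, n = 0.8)   # compressive estimation
#' @export
power_law <- function(phi, c = 1, n = 1) {
  if (any(phi <= 0)) stop("phi must be > 0")
  if (c <= 0) stop("c must be > 0")
  c * phi^n
}

#' Observer parameters for simulated numerosity estimation
#'
#' The generative model behind [simulate_estimates()]: estimates follow a
#' power law of numerosity with multiplicative lognormal noise of constant
#' coefficient of variation (scalar variability), a per-condition gain, and
#' integer rounding with a floor of 1 (typed numeral responses).
#'
#' @param c,n power-law constant and exponent.  The defaults (`c = 1.9`,
#'   `n = 0.8`) give mild overestimation of small numerosities shading into
#'   underestimation of large ones over the 10--30 range.
#' @param cv coefficient of variation of the multiplicative noise
#'   (SD/mean of repeated estimates at fixed numerosity); 0.33 is a typical
#'   human level for estimation well beyond the subitizing range.
#' @param condition_gain named multiplicative gains per motion condition;
#'   the default makes first-order estimates slightly higher.
#' @param exponent_offset named per-condition additive offsets to the
#'   exponent `n` (default zero for every condition in `condition_gain`); a
#'   positive first-order offset reproduces a condition-by-numerosity
#'   interaction.
#' @param subject_sd length-2 numeric: between-subject SDs of `log(c)` and
#'   of `n` (default `c(0, 0)`, identical subjects).
#' @return Object of class `observer_params`.
#' @export
observer_params <- function(c = 1.9, n = 0.8, cv = 0.33,
                            condition_gain = c(first_order = 1.1,
                                               second_order = 1.0),
                            exponent_offset = NULL,
                            subject_sd = c(0, 0)) {
  if (cv < 0) stop("cv must be >= 0")
  if (c <= 0) stop("c must be > 0")
  if (any(condition_gain <= 0)) stop("condition gains must be > 0")
  if (is.null(exponent_offset)) {
    exponent_offset <- stats::setNames(rep(0, length(condition_gain)),
                                       names(condition_gain))
  }
  if (!all(names(condition_gain) %in% names(exponent_offset)))
    stop("exponent_offset must name every condition in condition_gain")
  out <- list(c = c, n = n, cv = cv, condition_gain = condition_gain,
              exponent_offset = exponent_offset, subject_sd = subject_sd)
  class(out) <- "observer_params"
  out
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("Observer: psi = %.3g * phi^%.3g, cv = %.2f; gains %s\n",
              x$c, x$n, x$cv,
              paste(names(x$condition_gain), x$condition_gain,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# lognormal sigma giving a multiplicative noise term exp(e) with the
# requested coefficient of variation: cv = sqrt(exp(sigma^2) - 1)
.cv_to_sigma <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a table of numerosity estimates
#'
#' Draws estimates `psi = gain * c * phi^(n + offset) * exp(eps)` with
#' `eps ~ N(0, sigma^2)` and `sigma` chosen so the multiplicative noise has
#' the configured coefficient of variation
#' (`cv = sqrt(exp(sigma^2) - 1)`), then rounds to the nearest integer with
#' a floor of 1.  A mean-bar-height covariate is drawn
#' per trial as the mean of `phi` i.i.d. draws from the two bar heights; it
#' has no effect on the estimates unless `height_exponent` is non-zero.
#'
#' @param numerosities integer vector of physical numerosities (default
#'   10:30).
#' @param subjects number of simulated subjects.
#' @param reps repetitions of each numerosity per condition.
#' @param params an [observer_params()].
#' @param seed RNG seed; the table is reproducible given the seed.
#' @param conditions character vector of condition labels (must name entries
#'   of `params$condition_gain`).
#' @param bar_heights_deg the two bar heights the covariate is drawn from.
#' @param height_exponent exponent on (mean bar height / reference height);
#'   default 0 (bar height does not drive the estimates).
#' @return A data frame of class `estimate_table` with columns
#'   `subject, condition, numerosity, bar_height, estimate, trial`.
#' @examples
#' tab <- simulate_estimates(10:30, subjects = 3, reps = 2, seed = 1)
#' head(tab)
#' @export
simulate_estimates <- function(numerosities = 10:30, subjects = 11L,
                               reps = 6L, params = observer_params(),
                               seed = 1L,
                               conditions = c("first_order", "second_order"),
                               bar_heights_deg = c(2.08, 3.12),
                               height_exponent = 0) {
  if (reps < 1) stop("reps must be >= 1")
  stopifnot(all(conditions %in% names(params$condition_gain)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sigma <- .cv_to_sigma(params$cv)
  ref_h <- mean(bar_heights_deg)
  rows <- vector("list", subjects)
  for (s in seq_len(subjects)) {
    log_c_s <- log(params$c) + stats::rnorm(1, 0, params$subject_sd[1])
    n_s <- params$n + stats::rnorm(1, 0, params$subject_sd[2])
    per_cond <- lapply(conditions, function(cond) {
      phi <- rep(numerosities, each = reps)
      trial <- stats::ave(phi, phi, FUN = seq_along)
      hbar <- vapply(phi, function(k)
        mean(sample(bar_heights_deg, k, replace = TRUE)), numeric(1))
      mu <- params$condition_gain[[cond]] * exp(log_c_s) *
        phi^(n_s + params$exponent_offset[[cond]]) *
        (hbar / ref_h)^height_exponent
      eps <- stats::rnorm(length(phi), 0, sigma)
      est <- pmax(1, round(mu * exp(eps)))
      data.frame(subject = s, condition = cond, numerosity = phi,
                 bar_height = hbar, estimate = est, trial = trial)
    })
    rows[[s]] <- do.call(rbind, per_cond)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("estimate_table", "data.frame")
  out
}

#' Fit the psychophysical power law to an estimate table
#'
#' Ordinary least squares of `log(estimate)` on `log(numerosity)`; the slope
#' is the exponent `n` and the intercept is `log(c)`.
#'
#' @param table an estimate table (data frame with `numerosity` and
#'   `estimate` columns), e.g. from [simulate_estimates()].
#' @return List of class `power_law_fit` with `c`, `n`, their standard
#'   errors (`se_log_c`, `se_n`), and the fit's `r_squared`.
#' @export
fit_power_law <- function(table) {
  if (length(unique(table$numerosity)) < 2)
    stop("need at least 2 distinct numerosities to fit the power law")
  fit <- stats::lm(log(estimate) ~ log(numerosity), data = table)
  cf <- summary(fit)$coefficients
  out <- list(c = exp(cf[1, 1]), n = cf[2, 1],
              se_log_c = cf[1, 2], se_n = cf[2, 2],
              r_squared = summary(fit)$r.squared)
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: psi = %.4g * phi^%.4g (se_n %.3g), R^2 = %.3f\n",
              x$c, x$n, x$se_n, x$r_squared))
  invisible(x)
}

#' Write / read an estimate table as CSV
#'
#' @param table an `estimate_table`.
#' @param path file path.
#' @export
write_estimates_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_csv
#' @export
read_estimates_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "condition", "numerosity", "bar_height",
              "estimate", "trial")
  missing <- setdiff(needed, names(out))
  if (length(missing))
    stop("estimate table is missing columns: ", paste(missing, collapse = ", "))
  class(out) <- c("estimate_table", "data.frame")
  out
}
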