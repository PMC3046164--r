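#' Scalar-variability diagnostics for an estimate table
#'
#' Scalar variability is the signature of magnitude estimation: the standard
#' deviation of repeated estimates grows in direct proportion to their mean,
#' so the coefficient of variation (CV) is flat.  Per condition this report
#' computes, for each numerosity, the group mean estimate and its standard
#' error, then
#' * regresses log SE on log mean estimate (slope near 1 under scalar
#'   variability, near 0 under additive constant-SD noise), with the
#'   correlation of the two log variables,
#' * fits the linear SE-on-mean regression and reports its adjusted R^2,
#' * regresses the per-(subject, numerosity) CVs, pooled over subjects, on
#'   the numerosity's group mean estimate (R^2 near 0 when the CV is flat),
#'   and reports the mean CV,
#' * tests the per-numerosity bias (subject mean estimate minus numerosity)
#'   with one-sample t tests, uncorrected and Bonferroni-adjusted.
#'
#' @param table an estimate table (see [simulate_estimates()]).
#' @param se_method `"between"` (default): SE of a numerosity is the SD of
#'   the subjects' per-numerosity means divided by sqrt(subjects);
#'   `"within"`: SD of all estimates at that numerosity over sqrt(count).
#' @return Object of class `scalar_var_report`: per condition, the summary
#'   statistics above plus the per-numerosity table.  Cells with a single
#'   observation are excluded from the CV analysis with a warning; zero
#'   SEs make the log-log fit degenerate, which is reported (`slope = NA`)
#'   rather than an error.
#' @export
scalar_variability_report <- function(table, se_method = c("between", "within")) {
  se_method <- match.arg(se_method)
  conds <- unique(table$condition)
  out <- list(se_method = se_method, per_condition = list())
  for (cond in conds) {
    d <- table[table$condition == cond, ]
    cell <- stats::aggregate(estimate ~ subject + numerosity, data = d,
                             function(v) c(m = mean(v), s = stats::sd(v),
                                           k = length(v)))
    cm <- data.frame(subject = cell$subject, numerosity = cell$numerosity,
                     mean = cell$estimate[, "m"], sd = cell$estimate[, "s"],
                     k = cell$estimate[, "k"])
    if (any(cm$k < 2)) {
      warning(sprintf("%s: %d cells with a single observation excluded from the CV analysis",
                      cond, sum(cm$k < 2)))
    }
    # group-level per-numerosity means and SEs
    phis <- sort(unique(cm$numerosity))
    grp <- do.call(rbind, lapply(phis, function(phi) {
      sub_means <- cm$mean[cm$numerosity == phi]
      all_est <- d$estimate[d$numerosity == phi]
      se <- if (se_method == "between")
        stats::sd(sub_means) / sqrt(length(sub_means))
      else stats::sd(all_est) / sqrt(length(all_est))
      data.frame(numerosity = phi, mean = mean(sub_means), se = se,
                 n_subjects = length(sub_means))
    }))
    # log SE vs log mean (scalar-variability slope), and linear SE ~ mean
    ok <- is.finite(grp$se) & grp$se > 0
    if (sum(ok) >= 3) {
      lfit <- stats::lm(log(se) ~ log(mean), data = grp[ok, ])
      slope <- unname(stats::coef(lfit)[2])
      r_loglog <- stats::cor(log(grp$mean[ok]), log(grp$se[ok]))
    } else {
      slope <- NA_real_
      r_loglog <- NA_real_
    }
    sfit <- stats::lm(se ~ mean, data = grp)
    adj_r2_se <- summary(sfit)$adj.r.squared
    # pooled CV ~ estimate level: per-(subject, numerosity) CVs regressed on
    # the numerosity's group mean estimate.  Using the group mean (not the
    # cell's own mean) as the regressor keeps the two sides free of shared
    # sampling noise, which would otherwise induce a spurious association
    # even under perfectly flat CV.
    cv_cells <- cm[cm$k >= 2, ]
    cv_cells$cv <- cv_cells$sd / cv_cells$mean
    cv_cells$level <- grp$mean[match(cv_cells$numerosity, grp$numerosity)]
    if (nrow(cv_cells) >= 3 && stats::sd(cv_cells$cv) > 0) {
      cvfit <- stats::lm(cv ~ level, data = cv_cells)
      cv_r2 <- summary(cvfit)$r.squared
    } else {
      cv_r2 <- NA_real_
    }
    mean_cv <- mean(cv_cells$cv)
    # per-numerosity bias: subject means vs true numerosity
    bias <- do.call(rbind, lapply(phis, function(phi) {
      diffs <- cm$mean[cm$numerosity == phi] - phi
      if (length(diffs) >= 2 && stats::sd(diffs) > 0) {
        tt <- stats::t.test(diffs)
        data.frame(numerosity = phi, bias = mean(diffs),
                   t = unname(tt$statistic), p = tt$p.value)
      } else {
        data.frame(numerosity = phi, bias = mean(diffs),
                   t = NA_real_, p = NA_real_)
      }
    }))
    bias$p_bonferroni <- pmin(1, bias$p * nrow(bias))
    out$per_condition[[cond]] <- list(
      slope = slope, r_loglog = r_loglog, adj_r2_se = adj_r2_se,
      cv_r2 = cv_r2, mean_cv = mean_cv,
      by_numerosity = grp, bias = bias)
  }
  class(out) <- "scalar_var_report"
  out
}

#' @export
print.scalar_var_report <- function(x, ...) {
  cat("Scalar-variability report (SE method:", x$se_method, ")\n")
  for (cond in names(x$per_condition)) {
    p <- x$per_condition[[cond]]
    cat(sprintf("  %s: log SE ~ log mean slope %.3f (r = %.3f); SE~mean adj R^2 %.3f\n",
                cond, p$slope, p$r_loglog, p$adj_r2_se))
    cat(sprintf("    CV ~ mean pooled R^2 %.4f; mean CV %.3f\n",
                p$cv_r2, p$mean_cv))
  }
  invisible(x)
}

#' Per-subject multiple regression on log numerosity and log bar height
#'
#' Regresses log estimated numerosity on log numerosity and log mean bar
#' height for one subject and condition.  All three log variables are
#' z-scored first, so the coefficients are standardized.
#'
#' @param table an estimate table.
#' @param subject subject identifier.
#' @param condition condition label.
#' @return Object of class `subject_regression`: adjusted R^2, overall
#'   F-test p value, standardized coefficients with t statistics and p
#'   values for log numerosity (`num`) and log bar height (`height`), and
#'   the residual degrees of freedom.
#' @export
per_subject_regression <- function(table, subject, condition) {
  d <- table[table$subject == subject & table$condition == condition, ]
  if (nrow(d) < 10)
    stop(sprintf("need >= 10 rows for subject %s / %s, got %d",
                 subject, condition, nrow(d)))
  z <- function(v) (v - mean(v)) / stats::sd(v)
  for (col in c("numerosity", "bar_height")) {
    if (stats::sd(log(d[[col]])) == 0)
      stop(sprintf("constant predictor: log(%s) has zero variance", col))
  }
  dd <- data.frame(y = z(log(d$estimate)),
                   num = z(log(d$numerosity)),
                   height = z(log(d$bar_height)))
  fit <- stats::lm(y ~ num + height, data = dd)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  out <- list(
    subject = subject, condition = condition,
    adj_r_squared = sm$adj.r.squared,
    p_overall = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                 lower.tail = FALSE)),
    coef = data.frame(
      term = c("num", "height"),
      beta = unname(sm$coefficients[c("num", "height"), "Estimate"]),
      t = unname(sm$coefficients[c("num", "height"), "t value"]),
      p = unname(sm$coefficients[c("num", "height"), "Pr(>|t|)"])),
    df_residual = fit$df.residual,
    n = nrow(d))
  class(out) <- "subject_regression"
  out
}

#' @export
print.subject_regression <- function(x, ...) {
  cat(sprintf("Subject %s / %s: adj R^2 = %.3f, overall p = %.3g (df = %d)\n",
              x$subject, x$condition, x$adj_r_squared, x$p_overall,
              x$df_residual))
  print(x$coef, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Two-factor repeated-measures ANOVA on log estimates
#'
#' Classical two-way within-subjects ANOVA: repetitions are collapsed to
#' per-(subject, condition, numerosity) cell means, log-transformed, and
#' each effect (motion order, numerosity, their interaction) is tested
#' against its own subject-by-effect interaction error term.  With 11
#' subjects, 2 conditions and 21 numerosities the degrees of freedom are
#' (1, 10) for the condition effect and (20, 200) for numerosity and for
#' the interaction.  No sphericity correction is applied.
#'
#' @param table an estimate table; the design must be complete (every
#'   subject observed in every condition-by-numerosity cell).
#' @param log_transform log-transform the cell means first (default `TRUE`).
#' @return Object of class `rm_anova`: a data frame with one row per effect
#'   (`condition`, `numerosity`, `condition:numerosity`) holding sums of
#'   squares, df, F, p and partial eta squared
#'   (`SS_effect / (SS_effect + SS_error)`).
#' @export
rm_anova_2way <- function(table, log_transform = TRUE) {
  cell <- stats::aggregate(estimate ~ subject + condition + numerosity,
                           data = table, FUN = mean)
  subs <- sort(unique(cell$subject))
  conds <- sort(unique(cell$condition))
  phis <- sort(unique(cell$numerosity))
  full <- expand.grid(subject = subs, condition = conds, numerosity = phis,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$condition, d$numerosity)
  missing <- setdiff(key(full), key(cell))
  if (length(missing))
    stop("incomplete design; missing cells (subject condition numerosity): ",
         paste(utils::head(missing, 10), collapse = "; "),
         if (length(missing) > 10) " ..." else "")
  y <- if (log_transform) log(cell$estimate) else cell$estimate
  S <- length(subs); a <- length(conds); b <- length(phis)
  ms <- tapply(y, cell$subject, mean)[as.character(cell$subject)]
  ma <- tapply(y, cell$condition, mean)[cell$condition]
  mb <- tapply(y, cell$numerosity, mean)[as.character(cell$numerosity)]
  mab <- tapply(y, list(cell$condition, cell$numerosity), mean)[
    cbind(cell$condition, as.character(cell$numerosity))]
  mas <- tapply(y, list(cell$condition, cell$subject), mean)[
    cbind(cell$condition, as.character(cell$subject))]
  mbs <- tapply(y, list(cell$numerosity, cell$subject), mean)[
    cbind(as.character(cell$numerosity), as.character(cell$subject))]
  m <- mean(y)
  ss <- function(v) sum(v^2)
  SS_A  <- ss(ma - m)
  SS_B  <- ss(mb - m)
  SS_AB <- ss(mab - ma - mb + m)
  SS_AS <- ss(mas - ma - ms + m)
  SS_BS <- ss(mbs - mb - ms + m)
  SS_ABS <- ss(y - mab - mas - mbs + ma + mb + ms - m)
  eff <- data.frame(
    effect = c("condition", "numerosity", "condition:numerosity"),
    ss = c(SS_A, SS_B, SS_AB),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    ss_error = c(SS_AS, SS_BS, SS_ABS),
    df2 = c((a - 1) * (S - 1), (b - 1) * (S - 1), (a - 1) * (b - 1) * (S - 1)))
  eff$F <- (eff$ss / eff$df1) / (eff$ss_error / eff$df2)
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff$partial_eta_sq <- eff$ss / (eff$ss + eff$ss_error)
  out <- list(effects = eff, n_subjects = S, n_conditions = a,
              n_numerosities = b, log_transform = log_transform)
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects, %d x %d design%s)\n",
              x$n_subjects, x$n_conditions, x$n_numerosities,
              if (x$log_transform) ", log cell means" else ""))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-22s F(%d,%d) = %.2f, p = %.3g, partial eta^2 = %.2f\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i],
                e$partial_eta_sq[i]))
  invisible(x)
}

#' Cross-condition agreement for one subject
#'
#' Averages the repetitions of each numerosity within each condition, then
#' computes the Pearson correlation between the two conditions' per-
#' numerosity mean estimates.
#'
#' @param table an estimate table containing exactly two conditions for the
#'   subject.
#' @param subject subject identifier.
#' @return List with `r`, the correlation test `p` value and `n_numerosities`;
#'   `r` is `NA` (with a warning) if either condition has zero variance.
#' @export
condition_correlation <- function(table, subject) {
  d <- table[table$subject == subject, ]
  conds <- unique(d$condition)
  if (length(conds) != 2)
    stop("subject must have exactly two conditions, found ", length(conds))
  cm <- stats::aggregate(estimate ~ condition + numerosity, data = d, FUN = mean)
  wide <- stats::reshape(cm, idvar = "numerosity", timevar = "condition",
                         direction = "wide")
  v1 <- wide[[2]]; v2 <- wide[[3]]
  keep <- stats::complete.cases(v1, v2)
  v1 <- v1[keep]; v2 <- v2[keep]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero variance in one condition; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n_numerosities = length(v1)))
  }
  ct <- stats::cor.test(v1, v2)
  list(r = unname(ct$estimate), p = ct$p.value, n_numerosities = length(v1))
}
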