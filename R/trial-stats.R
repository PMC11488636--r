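# Trial-level inference: ANCOVA for the immediate effect, REML mixed model
# with compound symmetry for follow-up, repeated-measures ANOVA for training
# modulation, learning contrasts, FDR, and ARR/NNT.

#' Pre-to-post symptom reduction
#'
#' @param pre_mean,post_mean group means.
#' @return `pre_mean - post_mean` (positive = improvement).
#' @export
reduction_delta <- function(pre_mean, post_mean) {
  check_scalar(pre_mean, "pre_mean")
  check_scalar(post_mean, "post_mean")
  pre_mean - post_mean
}

clinical_wide <- function(table, instrument, timepoints) {
  d <- table[table$instrument == instrument &
               table$timepoint %in% timepoints, ]
  if (!nrow(d)) stop_param("no rows for instrument ", instrument)
  w <- stats::reshape(d[c("subject_id", "group", "timepoint", "score")],
                      idvar = c("subject_id", "group"),
                      timevar = "timepoint", direction = "wide")
  names(w) <- sub("^score\\.", "", names(w))
  w
}

#' ANCOVA for the immediate treatment effect
#'
#' Linear model `post ~ pre + group` on listwise-complete cases; the group
#' effect is tested adjusted for the pre-treatment score. Partial eta squared
#' is `SS_group / (SS_group + SS_residual)`.
#'
#' @param table an `efp_clinical` long table (see
#'   [generate_clinical_cohort()]).
#' @param instrument instrument to analyse (default the clinician interview
#'   total, `"CAPS5"`).
#' @return object of class `efp_ancova`: list with `F`, `df` (c(1, n-3)),
#'   `p` (two-tailed), `partial_eta_sq`, `adjusted_group_means`, `n`.
#' @export
ancova_immediate <- function(table, instrument = "CAPS5") {
  w <- clinical_wide(table, instrument, c("pre", "post"))
  w <- w[stats::complete.cases(w[c("pre", "post")]), ]
  if (any(table(w$group) < 3) || length(unique(w$group)) < 2)
    stop_param("each group needs at least 3 complete pre/post cases")
  w$group <- factor(w$group, levels = c("control", "test"))
  fit <- stats::lm(post ~ pre + group, data = w)
  an <- stats::anova(fit)
  ssg <- an["group", "Sum Sq"]
  sse <- an["Residuals", "Sum Sq"]
  df <- c(1, nrow(w) - 3)
  if (ssg + sse < 1e-12) {          # covariate absorbs everything
    f <- 0; p <- 1; eta <- 0
  } else {
    f <- (ssg / df[1]) / (sse / df[2])
    p <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
    eta <- ssg / (ssg + sse)
  }
  pre_bar <- mean(w$pre)
  adj <- vapply(levels(w$group), function(g)
    stats::predict(fit, data.frame(pre = pre_bar, group = factor(g,
      levels = levels(w$group)))), numeric(1))
  structure(list(F = f, df = df, p = p, partial_eta_sq = eta,
                 adjusted_group_means = adj, n = nrow(w),
                 instrument = instrument),
            class = "efp_ancova")
}

timepoint_code <- function(tp) {
  match(tp, cohort_timepoints()) - 1L
}

#' Intention-to-treat mixed model for the follow-up trajectory
#'
#' REML linear mixed model `score ~ group * time` with a subject random
#' intercept -- the compound-symmetry covariance structure (equal variances,
#' equal positive pairwise covariances across the repeated measures).
#' Missing observations are handled by the likelihood, not imputed. Time is
#' a numeric covariate coding the five assessments 0..4 (a categorical
#' option is available for sensitivity).
#'
#' @param table an `efp_clinical` long table.
#' @param instrument which self-report instrument (e.g. `"PCL5"`).
#' @param time_coding `"numeric"` (default) or `"categorical"`.
#' @param subset_complete restrict to completers (per-protocol) instead of
#'   all randomized subjects (intention-to-treat).
#' @return object of class `efp_mixed`: list with `fixed` (data.frame of
#'   F/df/p per effect), `interaction_estimate` (slope-difference
#'   coefficient with SE, numeric coding only), `sigma_between`,
#'   `sigma_within`, `loglik_REML`, `converged`, `n_subjects`, `n_obs`.
#' @export
mixed_model_followup <- function(table, instrument = "PCL5",
                                 time_coding = c("numeric", "categorical"),
                                 subset_complete = FALSE) {
  time_coding <- match.arg(time_coding)
  d <- table[table$instrument == instrument, ]
  d <- d[!is.na(d$score), ]
  if (!nrow(d)) stop_param("no observations for instrument ", instrument)
  obs_per_subj <- table(d$subject_id)
  if (subset_complete) {
    keep <- names(obs_per_subj)[obs_per_subj == length(cohort_timepoints())]
    d <- d[d$subject_id %in% keep, ]
    obs_per_subj <- table(d$subject_id)
  }
  if (mean(obs_per_subj >= 2) < 0.8)
    stop_param("fewer than 80% of subjects have >= 2 observed timepoints")
  d$group <- factor(d$group, levels = c("control", "test"))
  d$time <- timepoint_code(d$timepoint)
  if (time_coding == "categorical") d$time <- factor(d$time)
  fit <- tryCatch(
    nlme::lme(score ~ group * time, random = ~ 1 | subject_id, data = d,
              method = "REML", na.action = stats::na.omit),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "efp_mixed"))
  }
  an <- stats::anova(fit, type = "marginal")
  fixed <- data.frame(effect = rownames(an), numDF = an$numDF,
                      denDF = an$denDF, F = an[["F-value"]],
                      p = an[["p-value"]], row.names = NULL)
  fixed <- fixed[fixed$effect != "(Intercept)", ]
  vc <- nlme::VarCorr(fit)
  sig_b <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
  sig_w <- suppressWarnings(as.numeric(vc["Residual", "Variance"]))
  inter <- NULL
  if (time_coding == "numeric") {
    tt <- summary(fit)$tTable
    rn <- grep(":time$", rownames(tt), value = TRUE)
    if (length(rn) == 1)
      inter <- c(estimate = unname(tt[rn, "Value"]),
                 se = unname(tt[rn, "Std.Error"]),
                 p = unname(tt[rn, "p-value"]))
  }
  structure(list(fixed = fixed, interaction_estimate = inter,
                 sigma_between = sig_b, sigma_within = sig_w,
                 loglik_REML = as.numeric(stats::logLik(fit)),
                 converged = TRUE,
                 n_subjects = length(unique(d$subject_id)),
                 n_obs = nrow(d), instrument = instrument,
                 time_coding = time_coding),
            class = "efp_mixed")
}

#' Two-way within-subject (repeated-measures) ANOVA: condition x session
#'
#' Classical sums-of-squares partition for a complete balanced
#' subject x condition x session table (one observation per cell): each
#' within-subject effect is tested against its own subject-interaction error
#' term. Subjects with incomplete tables are dropped and counted. With a
#' single session the condition F equals the squared paired t statistic.
#'
#' @param blocks data.frame with columns `subject`, `condition` (two
#'   levels, e.g. Watch/Regulate), `session`, `value` (per-subject
#'   per-session condition means).
#' @return list with `F_condition`, `F_session`, `F_interaction`, their
#'   dfs and p-values, `partial_eta_sq` per effect, and `n_dropped`.
#' @export
rm_anova_condition_session <- function(blocks) {
  stopifnot(all(c("subject", "condition", "session", "value") %in%
                  names(blocks)))
  blocks$subject <- as.character(blocks$subject)
  blocks$condition <- factor(as.character(blocks$condition))
  blocks$session <- factor(blocks$session)
  a <- nlevels(blocks$condition)
  b <- nlevels(blocks$session)
  if (a != 2) stop_param("exactly two conditions are required")
  cnt <- table(blocks$subject)
  complete <- names(cnt)[cnt == a * b]
  n_dropped <- sum(cnt != a * b)
  blocks <- blocks[blocks$subject %in% complete, ]
  n <- length(complete)
  if (n < 2) stop_param("at least 2 subjects with complete tables required")
  y <- blocks$value
  m <- mean(y)
  mc <- tapply(y, blocks$condition, mean)
  ms <- tapply(y, blocks$session, mean)
  mi <- tapply(y, blocks$subject, mean)
  mcs <- tapply(y, list(blocks$condition, blocks$session), mean)
  mci <- tapply(y, list(blocks$condition, blocks$subject), mean)
  msi <- tapply(y, list(blocks$session, blocks$subject), mean)
  ss_c <- b * n * sum((mc - m)^2)
  ss_s <- a * n * sum((ms - m)^2)
  ss_cs <- n * sum((sweep(sweep(mcs, 1, mc), 2, ms) + m)^2)
  ss_ci <- b * sum((sweep(sweep(mci, 1, mc), 2, mi) + m)^2)
  ss_si <- a * sum((sweep(sweep(msi, 1, ms), 2, mi) + m)^2)
  cell <- function(cc, ss, ii)
    mcs[cbind(cc, ss)] + mci[cbind(cc, ii)] + msi[cbind(ss, ii)] -
      mc[cc] - ms[ss] - mi[ii] + m
  resid3 <- y - cell(as.integer(blocks$condition),
                     as.integer(blocks$session),
                     match(blocks$subject, complete))
  ss_csi <- sum(resid3^2)
  df_c <- a - 1; df_s <- b - 1; df_cs <- df_c * df_s
  df_ci <- df_c * (n - 1); df_si <- df_s * (n - 1); df_csi <- df_cs * (n - 1)
  f_c <- (ss_c / df_c) / (ss_ci / df_ci)
  f_s <- (ss_s / df_s) / (ss_si / df_si)
  f_cs <- if (df_csi > 0) (ss_cs / df_cs) / (ss_csi / df_csi) else NA_real_
  list(F_condition = f_c, df_condition = c(df_c, df_ci),
       p_condition = stats::pf(f_c, df_c, df_ci, lower.tail = FALSE),
       F_session = f_s, df_session = c(df_s, df_si),
       p_session = stats::pf(f_s, df_s, df_si, lower.tail = FALSE),
       F_interaction = f_cs, df_interaction = c(df_cs, df_csi),
       p_interaction = if (is.na(f_cs)) NA_real_ else
         stats::pf(f_cs, df_cs, df_csi, lower.tail = FALSE),
       partial_eta_sq = c(condition = ss_c / (ss_c + ss_ci),
                          session = ss_s / (ss_s + ss_si),
                          interaction = if (df_csi > 0)
                            ss_cs / (ss_cs + ss_csi) else NA_real_),
       n_subjects = n, n_dropped = n_dropped)
}

#' Paired learning contrast: first five vs last five sessions
#'
#' Two-tailed paired t-test of each subject's mean success over sessions
#' 1-5 against sessions 6-10 (means are taken over the sessions available in
#' each half; subjects missing an entire half are excluded and counted).
#'
#' @param session_success numeric matrix, subjects x 10 sessions (NAs
#'   allowed), or a list of per-subject 10-vectors.
#' @return list with `t`, `df`, `p`, `mean_first5`, `mean_last5`,
#'   `n_subjects`, `n_excluded`, `degenerate` (TRUE when the paired
#'   differences have zero variance).
#' @export
paired_learning_test <- function(session_success) {
  if (is.list(session_success))
    session_success <- do.call(rbind, session_success)
  m <- as.matrix(session_success)
  first <- rowMeans(m[, 1:5, drop = FALSE], na.rm = TRUE)
  last <- rowMeans(m[, 6:10, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(first) & is.finite(last)
  n_excluded <- sum(!ok)
  first <- first[ok]; last <- last[ok]
  if (length(first) < 2)
    stop_param("at least 2 subjects with both halves are required")
  d <- first - last
  if (stats::sd(d) == 0) {
    # identical halves: no effect and no uncertainty (t = 0, p = 1);
    # a constant non-zero difference has zero variance and no valid t
    zero_diff <- all(d == 0)
    return(list(t = if (zero_diff) 0 else NA_real_,
                df = length(d) - 1,
                p = if (zero_diff) 1 else NA_real_,
                mean_first5 = mean(first), mean_last5 = mean(last),
                n_subjects = length(d), n_excluded = n_excluded,
                degenerate = !zero_diff))
  }
  tt <- stats::t.test(first, last, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_first5 = mean(first), mean_last5 = mean(last),
       n_subjects = length(d), n_excluded = n_excluded, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (monotone step-up, capped at 1).
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_param("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = centre - half, upper = centre + half)
}

#' Absolute risk reduction and number needed to treat
#'
#' `ARR = loss_test/n_test - loss_control/n_control` for a favourable binary
#' outcome (here: loss of PTSD diagnosis), with a Newcombe hybrid-score 95%
#' interval (Wilson limits per group, combined). `NNT = 1/ARR`; when the ARR
#' is not positive the NNT is flagged "not beneficial" rather than reported.
#'
#' @param loss_test,loss_control favourable-outcome counts per arm.
#' @param n_test,n_control arm sizes.
#' @param conf confidence level.
#' @param ci_method `"newcombe"` (default) or `"wald"`.
#' @return object of class `efp_nnt`: list with `p_test`, `p_control`,
#'   `arr`, `ci_arr`, `nnt`, `ci_nnt`, `beneficial`.
#' @export
arr_and_nnt <- function(loss_test, n_test, loss_control, n_control,
                        conf = 0.95, ci_method = c("newcombe", "wald")) {
  ci_method <- match.arg(ci_method)
  if (loss_test > n_test || loss_control > n_control ||
      min(loss_test, loss_control) < 0)
    stop_param("counts must be non-negative and at most the group size")
  p1 <- loss_test / n_test
  p2 <- loss_control / n_control
  arr <- p1 - p2
  if (ci_method == "newcombe") {
    c1 <- wilson_ci(loss_test, n_test, conf)
    c2 <- wilson_ci(loss_control, n_control, conf)
    ci <- c(lower = arr - sqrt((p1 - c1["lower"])^2 +
                                 (c2["upper"] - p2)^2),
            upper = arr + sqrt((c1["upper"] - p1)^2 +
                                 (p2 - c2["lower"])^2))
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- sqrt(p1 * (1 - p1) / n_test + p2 * (1 - p2) / n_control)
    ci <- c(lower = arr - z * se, upper = arr + z * se)
  }
  names(ci) <- c("lower", "upper")
  beneficial <- arr > 0
  nnt <- if (beneficial) 1 / arr else NA_real_
  ci_nnt <- if (beneficial && all(ci > 0)) {
    out <- sort(1 / ci); names(out) <- c("lower", "upper"); out
  } else c(lower = NA_real_, upper = NA_real_)
  structure(list(p_test = p1, p_control = p2, arr = arr, ci_arr = ci,
                 nnt = nnt, ci_nnt = ci_nnt, beneficial = beneficial,
                 conf = conf, ci_method = ci_method),
            class = "efp_nnt")
}

#' Number needed to treat from an absolute risk reduction
#'
#' @param arr absolute risk reduction (proportion, > 0).
#' @return `1 / arr`.
#' @export
nnt_from_arr <- function(arr) {
  check_scalar(arr, "arr")
  if (arr <= 0) stop_param("`arr` must be positive for an NNT")
  unname(1 / arr)
}

#' Sample size for a between-group F test at a given partial eta squared
#'
#' Utility reproducing an a-priori power analysis: the smallest total N for
#' which a one-way F test (df1 = groups - 1) with noncentrality
#' `N * eta / (1 - eta)` reaches the requested power.
#'
#' @param partial_eta_sq assumed effect size.
#' @param alpha significance level.
#' @param power target power.
#' @param n_groups number of groups.
#' @return integer total sample size.
#' @export
required_sample_size <- function(partial_eta_sq = 0.16, alpha = 0.05,
                                 power = 0.8, n_groups = 2) {
  f2 <- partial_eta_sq / (1 - partial_eta_sq)
  df1 <- n_groups - 1
  for (n in seq(df1 + 2, 10000)) {
    df2 <- n - n_groups
    pow <- stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2,
                     ncp = f2 * n, lower.tail = FALSE)
    if (pow >= power) return(n)
  }
  stop_param("no sample size below 10000 reaches the requested power")
}
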