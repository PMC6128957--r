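#' Two-sample normal-approximation sample size with dropout inflation
#'
#' Per-group sample size for detecting a mean difference `delta` between two
#' arms with common SD `sd` by a two-sided test at level `alpha` and the
#' requested power, using the normal-approximation formula
#' `n0 = 2 * ((z_{1-alpha/2} + z_power) * sd / delta)^2`,
#' then inflated by `1 / (1 - dropout)` and rounded. With the defaults
#' (delta 50 m of 6-minute walk distance, SD 60 m, alpha 0.05, power 80%,
#' 20% dropout, 3 arms) this gives 28 per group and 84 in total.
#'
#' @param delta Smallest mean difference to detect (same units as `sd`).
#' @param sd Common outcome standard deviation (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param dropout Anticipated dropout fraction in \[0, 1).
#' @param n_groups Number of trial arms sized at `n_per_group` each.
#' @param rounding `"nearest"` (default) rounds the dropout-inflated n to the
#'   nearest integer; `"ceiling"` always rounds up.
#' @return A one-row tibble: `n_unadjusted` (analytic n before dropout,
#'   rounded to nearest), `n_per_group`, `n_total`.
#' @export
#' @examples
#' sample_size() # 28 per group, 84 total
sample_size <- function(delta = 50, sd = 60, alpha = 0.05, power = 0.80,
                        dropout = 0.20, n_groups = 3,
                        rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!is.finite(delta) || delta == 0) {
    abort("`delta` must be nonzero (a zero difference needs infinite n).")
  }
  if (sd <= 0) abort("`sd` must be positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (power <= 0 || power >= 1) abort("`power` must lie in (0, 1).")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must lie in [0, 1).")
  n0 <- 2 * ((qnorm(1 - alpha / 2) + qnorm(power)) * sd / abs(delta))^2
  n_infl <- n0 / (1 - dropout)
  n_per_group <- if (rounding == "nearest") round(n_infl) else ceiling(n_infl)
  tibble::tibble(
    n_unadjusted = round(n0),
    n_per_group = as.integer(n_per_group),
    n_total = as.integer(n_per_group * n_groups)
  )
}

#' Monte-Carlo power of the two-sample t-test
#'
#' Simulates `reps` two-arm trials with normal outcomes (true mean
#' difference `delta`, common SD `sd`, `n_per_group` per arm), tests each
#' with the pooled-variance two-sided two-sample t-test at level `alpha`,
#' and returns the rejection fraction.
#'
#' @param n_per_group Patients per arm (>= 2).
#' @param delta True mean difference.
#' @param sd Common SD (> 0).
#' @param alpha Two-sided significance level.
#' @param reps Number of simulated trials (default 10000).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return The rejection fraction in \[0, 1\].
#' @export
#' @examples
#' empirical_power(23, delta = 50, sd = 60, reps = 2000, seed = 1)
empirical_power <- function(n_per_group, delta = 50, sd = 60, alpha = 0.05,
                            reps = 10000, seed = NULL) {
  if (n_per_group < 2 || n_per_group != round(n_per_group)) {
    abort("`n_per_group` must be an integer >= 2.")
  }
  if (sd <= 0) abort("`sd` must be positive.")
  if (reps < 1) abort("`reps` must be >= 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- as.integer(n_per_group)
  x <- matrix(rnorm(reps * n, mean = delta, sd = sd), nrow = reps)
  y <- matrix(rnorm(reps * n, mean = 0, sd = sd), nrow = reps)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n - 1)
  v2 <- rowSums((y - m2)^2) / (n - 1)
  sp2 <- (v1 + v2) / 2
  tstat <- (m1 - m2) / sqrt(sp2 * 2 / n)
  crit <- stats::qt(1 - alpha / 2, df = 2 * n - 2)
  mean(abs(tstat) > crit)
}

#' Stratified permuted-block 1:1:1 randomization
#'
#' Assigns each rostered patient to a trial arm within strata formed by site
#' and the baseline FEV1 %predicted and CAT classes (cut at 50% predicted
#' and a CAT of 10 by default). Within each site-by-stratum cell, arms are
#' issued in permuted blocks of one slot per arm, so completed blocks are
#' exactly 1:1:1 and cell arm counts never differ by more than one.
#'
#' @param roster Data frame with `patient_id`, `site`, `fev1_pct_pred`,
#'   `cat`.
#' @param arms Character vector of arm labels.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param fev1_cut,cat_cut Stratification cut-points.
#' @return A tibble: `patient_id`, `site`, `stratum`, `arm`.
#' @export
randomize <- function(roster, arms = c("fixed", "fixed-interactive", "control"),
                      seed = NULL, fev1_cut = 50, cat_cut = 10) {
  need <- c("patient_id", "site", "fev1_pct_pred", "cat")
  if (!is.data.frame(roster) || !all(need %in% names(roster))) {
    abort("`roster` needs columns patient_id, site, fev1_pct_pred, cat.")
  }
  if (anyNA(roster[need])) {
    abort("Stratification variables must not contain NA.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  out <- roster |>
    tibble::as_tibble() |>
    dplyr::mutate(
      stratum = paste0(
        "FEV1", ifelse(.data$fev1_pct_pred < fev1_cut, "<", ">="), fev1_cut,
        ":CAT", ifelse(.data$cat < cat_cut, "<", ">="), cat_cut
      ),
      .row = dplyr::row_number()
    )
  assigned <- out |>
    dplyr::group_by(.data$site, .data$stratum) |>
    dplyr::group_modify(function(df, key) {
      n_blocks <- ceiling(nrow(df) / length(arms))
      seq_arms <- unlist(lapply(seq_len(n_blocks), function(b) sample(arms)))
      df$arm <- seq_arms[seq_len(nrow(df))]
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)
  dplyr::select(assigned, "patient_id", "site", "stratum", "arm")
}

#' One-way analysis of variance of a baseline characteristic
#'
#' Compares one baseline variable across trial arms with a standard one-way
#' between-groups ANOVA, as used to check baseline comparability of the
#' arms. Returns the F test plus per-group descriptives.
#'
#' @param data Data frame holding the value and grouping columns.
#' @param value Name of the numeric outcome column (string).
#' @param group Name of the grouping column (string).
#' @return An object of class `pw_anova`; see [tidy()] and [glance()]
#'   methods, and `$groups` for per-group n/mean/sd.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' tidy(baseline_anova(d, "y", "g")) # F = 13.5 on (1, 4) df
baseline_anova <- function(data, value, group) {
  if (!all(c(value, group) %in% names(data))) {
    abort("`value` and `group` must name columns of `data`.")
  }
  df <- data.frame(y = data[[value]], g = factor(data[[group]]))
  df <- df[complete.cases(df), ]
  counts <- table(df$g)
  if (length(counts) < 2) abort("Need at least two groups.")
  if (any(counts < 2)) abort("Every group needs at least two observations.")
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  groups <- df |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y), sd = sd(.data$y),
                     .groups = "drop") |>
    dplyr::rename(group = "g")
  structure(
    list(
      variable = value,
      effects = tibble::tibble(
        term = "group",
        df = an$Df[1], df_resid = an$Df[2],
        sumsq = an$`Sum Sq`[1], sumsq_resid = an$`Sum Sq`[2],
        statistic = an$`F value`[1], p.value = an$`Pr(>F)`[1]
      ),
      groups = groups,
      n = nrow(df)
    ),
    class = "pw_anova"
  )
}

#' Repeated-measures ANOVA of visit outcomes
#'
#' Mixed between-within analysis of an outcome measured at visits V1/V2/V3:
#' patients are the random blocks, trial arm is the between-subject factor
#' and visit the within-subject factor. Only complete cases (patients with
#' the outcome at every visit) enter; no sphericity correction is applied.
#' Per-arm change scores from baseline (V2-V1, V3-V1) are reported
#' alongside the F tests.
#'
#' @param outcomes Long data frame with one row per patient and visit.
#' @param value Name of the outcome column (string), e.g. `"cat"`.
#' @param arm,visit,id Names of the arm, visit and patient-id columns.
#' @return An object of class `pw_rm_anova` with `$effects` (arm, visit and
#'   arm-by-visit F tests), `$changes` (per-arm mean change scores), and
#'   `$n_complete`; see [tidy()] and [glance()].
#' @export
rm_anova <- function(outcomes, value, arm = "arm", visit = "visit",
                     id = "patient_id") {
  need <- c(value, arm, visit, id)
  if (!all(need %in% names(outcomes))) {
    abort("`outcomes` must contain the value, arm, visit and id columns.")
  }
  df <- data.frame(
    y = outcomes[[value]],
    arm = factor(outcomes[[arm]]),
    visit = factor(outcomes[[visit]]),
    id = factor(outcomes[[id]])
  )
  if (nlevels(df$visit) < 2) abort("Need at least two visits.")
  # complete cases: patients observed at every visit
  wide <- tidyr::pivot_wider(tibble::as_tibble(df), names_from = "visit",
                             values_from = "y")
  keep <- wide$id[complete.cases(wide)]
  df <- df[df$id %in% keep & !is.na(df$y), ]
  df$id <- droplevels(df$id)
  per_arm <- table(dplyr::distinct(df, .data$id, .data$arm)$arm)
  if (any(per_arm < 2)) abort("Need >= 2 complete cases per arm.")
  fit <- aov(y ~ arm * visit + Error(id), data = df)
  sm <- summary(fit)
  between <- sm[["Error: id"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  row_of <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    tibble::tibble(
      term = name, df = tab$Df[i],
      df_resid = tab$Df[trimws(rownames(tab)) == "Residuals"],
      sumsq = tab$`Sum Sq`[i],
      sumsq_resid = tab$`Sum Sq`[trimws(rownames(tab)) == "Residuals"],
      statistic = tab$`F value`[i], p.value = tab$`Pr(>F)`[i]
    )
  }
  effects <- dplyr::bind_rows(
    row_of(between, "arm"),
    row_of(within, "visit"),
    row_of(within, "arm:visit")
  )
  visits <- levels(df$visit)
  base <- visits[1]
  changes <- df |>
    tidyr::pivot_wider(names_from = "visit", values_from = "y") |>
    tidyr::pivot_longer(dplyr::all_of(setdiff(visits, base)),
                        names_to = "visit", values_to = "y") |>
    dplyr::group_by(.data$arm, .data$visit) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_change = mean(.data$y - .data[[base]]),
      sd_change = sd(.data$y - .data[[base]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(contrast = paste0(.data$visit, "-", base), .after = "arm") |>
    dplyr::select(-"visit")
  structure(
    list(variable = value, effects = effects, changes = changes,
         n_complete = length(unique(df$id))),
    class = "pw_rm_anova"
  )
}

#' @export
print.pw_anova <- function(x, ...) {
  cat("One-way ANOVA of", x$variable, "(", x$n, "observations )\n")
  e <- x$effects
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              e$df, e$df_resid, e$statistic, e$p.value))
  print(x$groups)
  invisible(x)
}

#' @export
print.pw_rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA of", x$variable,
      "(", x$n_complete, "complete cases )\n")
  print(x$effects)
  cat("Change scores from baseline:\n")
  print(x$changes)
  invisible(x)
}

#' Tidy an ANOVA result
#'
#' @param x A `pw_anova` or `pw_rm_anova`.
#' @param ... Unused.
#' @return A tibble with one row per tested effect: `term`, `df`,
#'   `df_resid`, `sumsq`, `sumsq_resid`, `statistic`, `p.value`.
#' @method tidy pw_anova
#' @export
tidy.pw_anova <- function(x, ...) x$effects

#' @rdname tidy.pw_anova
#' @method tidy pw_rm_anova
#' @export
tidy.pw_rm_anova <- function(x, ...) x$effects

#' One-row summary of an ANOVA result
#'
#' @param x A `pw_anova` or `pw_rm_anova`.
#' @param ... Unused.
#' @return A one-row tibble with the analysed variable, sample size and the
#'   headline p-value (the group effect, or the arm-by-visit interaction).
#' @method glance pw_anova
#' @export
glance.pw_anova <- function(x, ...) {
  tibble::tibble(variable = x$variable, n = x$n,
                 statistic = x$effects$statistic, p.value = x$effects$p.value)
}

#' @rdname glance.pw_anova
#' @method glance pw_rm_anova
#' @export
glance.pw_rm_anova <- function(x, ...) {
  i <- x$effects$term == "arm:visit"
  tibble::tibble(variable = x$variable, n_complete = x$n_complete,
                 statistic = x$effects$statistic[i],
                 p.value = x$effects$p.value[i])
}
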