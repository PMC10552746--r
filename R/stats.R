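# Component-window ROI statistics on tsVEPs: one-sample t tests with
# Cohen's d and Bonferroni correction, the 2 (stimulus) x 5 (region)
# repeated-measures ANOVA with Mauchly's sphericity test and
# Greenhouse-Geisser correction, and per-region simple effects.

#' Default region-of-interest map
#'
#' Five scalp regions of three electrodes each, ordered posterior to
#' anterior.
#'
#' @return named list: region -> channel labels.
#' @export
default_roi_map <- function() {
  list(
    occipital = c("O1", "Oz", "O2"),
    parieto_occipital = c("POz", "PO3", "PO4"),
    parietal = c("P1", "Pz", "P2"),
    central = c("C1", "Cz", "C2"),
    frontal = c("F1", "Fz", "F2")
  )
}

#' Default component windows
#'
#' Early negative (100-140 ms), intermediate positive (150-200 ms) and late
#' (250-320 ms) component windows over which tsVEP amplitude is averaged.
#'
#' @return named list: label -> `c(start, end)` in ms.
#' @export
default_windows <- function() {
  list(early = c(100, 140), mid = c(150, 200), late = c(250, 320))
}

validate_roi_map <- function(roi_map, channels) {
  all_ch <- unlist(roi_map)
  if (anyDuplicated(all_ch))
    abort_config("a channel appears in more than one region")
  missing <- setdiff(all_ch, channels)
  if (length(missing) > 0)
    abort_config(paste("ROI channels missing from montage:",
                       paste(missing, collapse = ", ")))
  invisible(roi_map)
}

#' Mean tsVEP amplitude per region over a component window
#'
#' Averages the waveform over the region's channels and over the lag
#' samples whose centers lie in `[start, end]` inclusive (100-140 ms at
#' 100 Hz covers 5 samples).
#'
#' @param tsvep a `tsvep` or `trf_kernel`.
#' @param roi_map named list region -> channels (default
#'   [default_roi_map()]).
#' @param window `c(start, end)` in ms.
#' @return named numeric vector, one mean per region.
#' @export
roi_window_mean <- function(tsvep, roi_map = default_roi_map(),
                            window = c(100, 140)) {
  validate_roi_map(roi_map, tsvep$channels)
  sel <- tsvep$lag_ms >= window[1] & tsvep$lag_ms <= window[2]
  if (!any(sel)) abort_config("component window contains no lag samples")
  vapply(roi_map, function(chs) {
    mean(tsvep$weights[sel, tsvep$channels %in% chs, drop = FALSE])
  }, numeric(1))
}

#' One-sample t test with Cohen's d
#'
#' Two-sided test of the subject-level component amplitudes against `mu0`
#' (default 0). Cohen's d is `mean / SD`, identically `t / sqrt(n)`; the
#' identity is asserted internally.
#'
#' @param values one amplitude per subject.
#' @param mu0 null value.
#' @return list of class `ttest_result`: `mean`, `se`, `t`, `df`, `p_raw`,
#'   `cohens_d`, `n`.
#' @export
one_sample_component_test <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2) abort_contract("at least 2 subjects are required")
  sdv <- stats::sd(values)
  if (sdv == 0) abort_contract("zero variance across subjects; t undefined")
  tt <- stats::t.test(values, mu = mu0)
  d <- (mean(values) - mu0) / sdv
  stopifnot(abs(d - unname(tt$statistic) / sqrt(n)) < 1e-9)
  structure(
    list(mean = mean(values), se = sdv / sqrt(n),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_raw = tt$p.value, cohens_d = d, n = n),
    class = "ttest_result")
}

#' Cohen's d from a one-sample t statistic
#'
#' For a one-sample t test, `d = mean / SD = t / sqrt(n)`.
#'
#' @param t t statistic.
#' @param n sample size.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, p * family_size)`.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param family_size number of tests in the family; must be at least
#'   `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1))
    abort_contract("p-values must lie in [0, 1]")
  if (family_size < length(p_values))
    abort_contract("family_size must be at least the number of p-values")
  pmin(1, p_values * family_size)
}

# subjects x stimulus x region array -> long data.frame
rm_long <- function(values) {
  dn <- dimnames(values)
  stim_lv <- dn[[2]] %||% paste0("s", seq_len(dim(values)[2]))
  reg_lv <- dn[[3]] %||% paste0("r", seq_len(dim(values)[3]))
  expand <- expand.grid(subject = seq_len(dim(values)[1]),
                        stimulus = stim_lv, region = reg_lv,
                        KEEP.OUT.ATTRS = FALSE)
  expand$value <- as.vector(values)
  expand
}

#' Two-way repeated-measures ANOVA (stimulus x region)
#'
#' Within-subjects ANOVA for a complete balanced subjects x 2 (stimulus) x
#' k (region) design, via the multivariate linear-model route
#' (`car::Anova`, type III). Mauchly's test is run on every effect with
#' more than one numerator df; when it rejects at `alpha_sphericity` (and
#' `gg = "auto"`), the Greenhouse-Geisser corrected p-value replaces the
#' uncorrected one. Two-level effects are spherical by construction
#' (epsilon = 1). Partial eta squared is `SS_effect / (SS_effect +
#' SS_error)`.
#'
#' @param values numeric array subjects x stimulus(2) x region, with
#'   dimnames for the factor levels; no missing cells.
#' @param gg `"auto"` (correct when Mauchly p < alpha), `"always"`, or
#'   `"never"`.
#' @param alpha_sphericity Mauchly rejection level (default 0.05).
#' @return object of class `rm_anova_result`: a data frame `effects` with
#'   columns `effect`, `F`, `df_num`, `df_den`, `p_uncorrected`,
#'   `gg_epsilon`, `p_gg`, `p` (the one selected by the correction rule),
#'   `mauchly_w`, `mauchly_p`, `partial_eta_sq`, `gg_applied`.
#' @export
rm_anova_2x5 <- function(values, gg = c("auto", "always", "never"),
                         alpha_sphericity = 0.05) {
  gg <- match.arg(gg)
  if (length(dim(values)) != 3)
    abort_contract("values must be a subjects x stimulus x region array")
  if (any(!is.finite(values)))
    abort_contract("missing cells are not allowed in the repeated-measures design")
  if (dim(values)[1] < 3) abort_contract("at least 3 subjects are required")

  dn <- dimnames(values)
  stim_lv <- dn[[2]] %||% paste0("s", seq_len(dim(values)[2]))
  reg_lv <- dn[[3]] %||% paste0("r", seq_len(dim(values)[3]))
  Y <- matrix(values, nrow = dim(values)[1])  # cols ordered stim within region
  idata <- expand.grid(stimulus = factor(stim_lv, levels = stim_lv),
                       region = factor(reg_lv, levels = reg_lv))
  mod <- stats::lm(Y ~ 1)
  av <- car::Anova(mod, idata = idata, idesign = ~ stimulus * region,
                   type = 3)
  # summary warns when HF epsilon caps at 1 or when tiny cohorts leave the
  # error SSP singular; both are handled explicitly below
  sm <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- sm$univariate.tests
  keep <- rownames(uni) != "(Intercept)"
  uni <- uni[keep, , drop = FALSE]
  eff <- data.frame(
    effect = rownames(uni),
    F = uni[, "F value"],
    df_num = uni[, "num Df"],
    df_den = uni[, "den Df"],
    p_uncorrected = uni[, "Pr(>F)"],
    partial_eta_sq = uni[, "Sum Sq"] / (uni[, "Sum Sq"] + uni[, "Error SS"]),
    gg_epsilon = 1, p_gg = uni[, "Pr(>F)"],
    mauchly_w = NA_real_, mauchly_p = NA_real_,
    row.names = NULL)
  if (!is.null(sm$pval.adjustments) && nrow(sm$pval.adjustments) > 0) {
    adj <- sm$pval.adjustments
    m <- match(rownames(adj), eff$effect)
    ok <- !is.na(m)
    eff$gg_epsilon[m[ok]] <- adj[ok, "GG eps"]
    eff$p_gg[m[ok]] <- adj[ok, "Pr(>F[GG])"]
  }
  if (!is.null(sm$sphericity.tests) && nrow(sm$sphericity.tests) > 0) {
    sph <- sm$sphericity.tests
    m <- match(rownames(sph), eff$effect)
    ok <- !is.na(m)
    eff$mauchly_w[m[ok]] <- sph[ok, "Test statistic"]
    eff$mauchly_p[m[ok]] <- sph[ok, "p-value"]
  }
  # two-level effects are spherical by construction
  eff$gg_epsilon[eff$df_num == 1] <- 1
  eff$p_gg[eff$df_num == 1] <- eff$p_uncorrected[eff$df_num == 1]
  eff$gg_applied <- switch(gg,
    auto = !is.na(eff$mauchly_p) & eff$mauchly_p < alpha_sphericity &
      !is.na(eff$p_gg),
    always = !is.na(eff$mauchly_p) & !is.na(eff$p_gg) & eff$df_num > 1,
    never = rep(FALSE, nrow(eff)))
  eff$p <- ifelse(eff$gg_applied, eff$p_gg, eff$p_uncorrected)
  structure(list(effects = eff, n_subjects = dim(values)[1]),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("<rm_anova_result> n = %d subjects\n", x$n_subjects))
  print(x$effects[, c("effect", "F", "df_num", "df_den", "p",
                      "gg_epsilon", "partial_eta_sq")], digits = 4)
  invisible(x)
}

#' Simple effects of stimulus within each region
#'
#' For every region, a one-way repeated-measures F test of the two-level
#' stimulus factor, computed as the squared paired t statistic (the two
#' quantities are algebraically identical for two levels; the identity is
#' asserted internally).
#'
#' @param values subjects x stimulus(2) x region array.
#' @return data frame with one row per region: `region`, `difference`
#'   (level 1 minus level 2 mean), `F`, `df_num`, `df_den`, `p`.
#' @export
simple_effects <- function(values) {
  if (dim(values)[2] != 2)
    abort_contract("simple effects are defined for a 2-level stimulus factor")
  reg_lv <- dimnames(values)[[3]] %||% paste0("r", seq_len(dim(values)[3]))
  n <- dim(values)[1]
  out <- lapply(seq_along(reg_lv), function(r) {
    diffs <- values[, 1, r] - values[, 2, r]
    if (stats::sd(diffs) == 0) {
      Fv <- 0; p <- 1
    } else {
      tt <- stats::t.test(values[, 1, r], values[, 2, r], paired = TRUE)
      Fv <- unname(tt$statistic)^2
      p <- tt$p.value
      # F of the one-way RM ANOVA equals t^2 for two levels
      ssb <- n * (mean(diffs) / 2)^2 * 2
      sse <- sum((diffs / 2 - mean(diffs) / 2)^2) * 2
      Fref <- ssb / (sse / (n - 1))
      stopifnot(abs(Fv - Fref) < 1e-9 * max(1, Fv))
    }
    data.frame(region = reg_lv[r], difference = mean(diffs),
               F = Fv, df_num = 1, df_den = n - 1, p = p)
  })
  do.call(rbind, out)
}

#' Component-window statistics report for a tsVEP cohort
#'
#' Orchestrates the statistical sequence: for each contrast, region and
#' component window, a one-sample t test of the subject-level window means
#' against zero with Cohen's d and Bonferroni correction over the regions
#' scanned per (contrast, window); then, per window, the 2 x 5
#' repeated-measures ANOVA over stimulus contrast and region, with simple
#' effects of stimulus within each region (labelled with whether the
#' interaction was significant).
#'
#' @param tsveps named list of contrasts (e.g. `foreground`, `background`),
#'   each a list of per-subject `tsvep` objects.
#' @param roi_map named list region -> channels.
#' @param windows named list of `c(start, end)` ms windows.
#' @param bonferroni_family family size for the t-test correction; default
#'   the number of regions.
#' @param alpha significance level used to label interactions.
#' @return object of class `stat_report`: data frames `t_tests`
#'   (contrast, region, window, mean, se, t, df, p_raw, p_adj, cohens_d),
#'   `anova` (window, effect, F, dfs, p, gg_epsilon, partial_eta_sq) and
#'   `simple_effects` (window, region, difference, F, dfs, p,
#'   interaction_significant), plus `window_means`, the subjects x
#'   contrast x region array per window.
#' @export
build_stat_report <- function(tsveps, roi_map = default_roi_map(),
                              windows = default_windows(),
                              bonferroni_family = length(roi_map),
                              alpha = 0.05) {
  contrasts <- names(tsveps)
  n_sub <- length(tsveps[[1]])
  if (n_sub < 2) abort_contract("at least 2 subjects are required")
  regions <- names(roi_map)

  window_means <- lapply(windows, function(win) {
    arr <- array(NA_real_,
                 dim = c(n_sub, length(contrasts), length(regions)),
                 dimnames = list(NULL, contrasts, regions))
    for (ci in seq_along(contrasts))
      for (si in seq_len(n_sub))
        arr[si, ci, ] <- roi_window_mean(tsveps[[ci]][[si]], roi_map, win)
    arr
  })

  t_rows <- list(); anova_rows <- list(); simple_rows <- list()
  for (wname in names(windows)) {
    arr <- window_means[[wname]]
    for (ci in seq_along(contrasts)) {
      res <- lapply(regions, function(r)
        one_sample_component_test(arr[, ci, r]))
      p_adj <- bonferroni_adjust(vapply(res, `[[`, numeric(1), "p_raw"),
                                 bonferroni_family)
      t_rows[[length(t_rows) + 1]] <- data.frame(
        contrast = contrasts[ci], region = regions, window = wname,
        mean = vapply(res, `[[`, numeric(1), "mean"),
        se = vapply(res, `[[`, numeric(1), "se"),
        t = vapply(res, `[[`, numeric(1), "t"),
        df = vapply(res, `[[`, numeric(1), "df"),
        p_raw = vapply(res, `[[`, numeric(1), "p_raw"),
        p_adj = p_adj,
        cohens_d = vapply(res, `[[`, numeric(1), "cohens_d"))
    }
    if (length(contrasts) == 2 && n_sub >= 3) {
      av <- rm_anova_2x5(arr)
      anova_rows[[length(anova_rows) + 1]] <-
        cbind(window = wname,
              av$effects[, c("effect", "F", "df_num", "df_den", "p",
                             "gg_epsilon", "mauchly_p", "partial_eta_sq")])
      inter_p <- av$effects$p[av$effects$effect == "stimulus:region"]
      se <- simple_effects(arr)
      se$interaction_significant <- inter_p < alpha
      simple_rows[[length(simple_rows) + 1]] <- cbind(window = wname, se)
    }
  }
  structure(
    list(t_tests = do.call(rbind, t_rows),
         anova = if (length(anova_rows)) do.call(rbind, anova_rows),
         simple_effects = if (length(simple_rows)) do.call(rbind, simple_rows),
         window_means = window_means),
    class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report>\nOne-sample t tests (vs 0):\n")
  print(x$t_tests, digits = 3, row.names = FALSE)
  if (!is.null(x$anova)) {
    cat("\nRepeated-measures ANOVA:\n")
    print(x$anova, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
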