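## Dose-response statistics: baseline normalization of longitudinal MEA
## metrics, the normality/homogeneity/ANOVA/Dunnett testing chain for dose
## groups, and direction-of-effect classification over dose and time.

#' Normalize longitudinal metrics to their pre-dose baseline
#'
#' For every (compound, dose, metric) series the relative value at time `t`
#' is `value(t) / value(0)`.  A baseline of 0 followed by 0 gives a
#' relative value of 0 (complete, sustained silence); a baseline of 0
#' followed by activity is undefined and excluded with a warning.
#'
#' @param timeline `data.frame` with columns `compound`, `dose`,
#'   `timepoint` (hours; 0 is the baseline), `metric`, `value`.  Extra
#'   columns are carried through.
#' @return The rows with `timepoint > 0`, with a `relative` column added;
#'   undefined rows are dropped.
#' @export
normalize_to_baseline <- function(timeline) {
  need <- c("compound", "dose", "timepoint", "metric", "value")
  stop_if(!is.data.frame(timeline) || !all(need %in% names(timeline)),
          "`timeline` needs columns %s", paste(need, collapse = ", "))
  key <- interaction(timeline$compound, timeline$dose, timeline$metric,
                     drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    rows <- timeline[key == k, , drop = FALSE]
    base_rows <- rows[rows$timepoint == 0, , drop = FALSE]
    stop_if(nrow(base_rows) == 0, "missing 0 h baseline for series %s", k)
    base <- mean(base_rows$value)
    later <- rows[rows$timepoint > 0, , drop = FALSE]
    if (nrow(later) == 0) next
    if (base == 0) {
      later$relative <- ifelse(later$value == 0, 0, NA_real_)
      if (any(is.na(later$relative))) {
        warning("series ", k, ": activity after a zero baseline; ",
                "relative value undefined, excluded")
        later <- later[!is.na(later$relative), , drop = FALSE]
      }
    } else {
      later$relative <- later$value / base
    }
    out[[k]] <- later
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided Dunnett many-to-one comparisons
#'
#' Compares every dose group against the shared control using the pooled
#' one-way ANOVA error.  Adjusted p-values are computed from the exact
#' multivariate-t distribution of the maximum absolute statistic
#' (equicorrelated only when balanced; the general correlation
#' `rho_ij = lambda_i lambda_j`, `lambda_i = 1 / sqrt(1 + n0/n_i)`, is used
#' so unbalanced designs are handled).
#'
#' @param value Numeric response vector.
#' @param group Factor (or coercible) of group labels.
#' @param control Label of the control group (default: first factor level).
#' @return `data.frame` with one row per non-control group: `group`,
#'   `estimate` (difference of means vs control), `t`, `df`, `p_adj`.
#' @export
dunnett_test <- function(value, group, control = NULL) {
  group <- as.factor(group)
  if (is.null(control)) control <- levels(group)[1]
  stop_if(!(control %in% levels(group)), "control group '%s' not found",
          control)
  group <- stats::relevel(group, ref = control)
  n <- tapply(value, group, length)
  stop_if(any(n < 2), "every group needs >= 2 replicates")
  means <- tapply(value, group, mean)
  k <- nlevels(group)
  N <- length(value)
  df <- N - k
  sse <- sum(tapply(value, group, function(v) sum((v - mean(v))^2)))
  s2 <- sse / df
  others <- levels(group)[-1]
  lam <- 1 / sqrt(1 + n[control] / n[others])
  corr <- outer(lam, lam)
  diag(corr) <- 1
  est <- means[others] - means[control]
  se <- sqrt(s2 * (1 / n[others] + 1 / n[control]))
  tt <- est / se
  p_adj <- vapply(abs(tt), function(q) {
    if (!is.finite(q)) return(if (s2 == 0 && q == Inf) 0 else NA_real_)
    1 - mvtnorm::pmvt(lower = rep(-q, k - 1), upper = rep(q, k - 1),
                      corr = corr, df = df)[1]
  }, numeric(1))
  data.frame(group = others, estimate = as.numeric(est),
             t = as.numeric(tt), df = df,
             p_adj = pmin(pmax(as.numeric(p_adj), 0), 1),
             row.names = NULL)
}

#' Normality, homogeneity, ANOVA and Dunnett chain for dose groups
#'
#' For each endpoint: Shapiro-Wilk normality per dose group, Bartlett's
#' homogeneity test across groups, one-way ANOVA, and two-sided Dunnett
#' comparisons of every dose against the dose-0 control, with significance
#' flags at 0.05 and 0.01.  Normality or homogeneity rejections are
#' reported as flags; the parametric chain still runs.  Endpoints in which
#' every observation is identical are returned with a `degenerate` status
#' and no tests.
#'
#' @param table `data.frame` with columns `dose` (numeric; 0 present as the
#'   control), `value`, and optionally `endpoint` (tested separately) and
#'   `compound`.
#' @param alpha Significance level for the flags (a second flag is always
#'   reported at 0.01).
#' @return List of class `stat_result` with one element per endpoint:
#'   `endpoint`, `anova_F`, `anova_p`, `normality_p` (per group),
#'   `homogeneity_p`, `dunnett` (from [dunnett_test()], plus `sig_05`,
#'   `sig_01`), `status` (`"ok"` or `"degenerate"`).
#' @export
test_dose_groups <- function(table, alpha = 0.05) {
  need <- c("dose", "value")
  stop_if(!is.data.frame(table) || !all(need %in% names(table)),
          "`table` needs columns dose, value")
  if (!("endpoint" %in% names(table))) table$endpoint <- "endpoint"
  stop_if(!any(table$dose == 0), "a dose-0 control group is required")
  res <- lapply(split(table, table$endpoint), function(df) {
    g <- factor(df$dose)
    stop_if(nlevels(g) < 2, "need >= 2 dose groups")
    stop_if(any(tapply(df$value, g, length) < 2),
            "every dose group needs >= 2 replicates")
    if (stats::var(df$value) == 0) {
      return(list(endpoint = df$endpoint[1], status = "degenerate",
                  anova_F = NA_real_, anova_p = NA_real_,
                  normality_p = NULL, homogeneity_p = NA_real_,
                  dunnett = NULL))
    }
    norm_p <- tapply(df$value, g, function(v) {
      if (length(v) < 3 || stats::var(v) == 0) NA_real_
      else stats::shapiro.test(v)$p.value
    })
    hom_p <- if (all(tapply(df$value, g, stats::var) > 0)) {
      stats::bartlett.test(df$value, g)$p.value
    } else NA_real_
    fit <- stats::aov(value ~ g, data = df)
    an <- summary(fit)[[1]]
    dn <- dunnett_test(df$value, g, control = "0")
    dn$sig_05 <- dn$p_adj <= alpha
    dn$sig_01 <- dn$p_adj <= 0.01
    list(endpoint = df$endpoint[1], status = "ok",
         anova_F = an$`F value`[1], anova_p = an$`Pr(>F)`[1],
         normality_p = as.numeric(norm_p), homogeneity_p = hom_p,
         dunnett = dn)
  })
  structure(res, class = "stat_result")
}

#' Classify effect direction over dose and time
#'
#' A normalized (relative-to-baseline) value above `1 + margin` is called
#' excitatory, below `1 - margin` inhibitory, otherwise none.  Per
#' (compound, dose, metric) the ordered directions over timepoints are
#' collapsed into a trajectory label such as `"inhibition->excitation"`.
#'
#' @param relative Output of [normalize_to_baseline()] (needs `compound`,
#'   `dose`, `timepoint`, `metric`, `relative`).
#' @param margin Half-width of the "no effect" band around 1 (default 0.2).
#' @return List with `calls` (per-row `direction` added) and `trajectories`
#'   (`compound`, `dose`, `metric`, `trajectory`).
#' @export
classify_effects <- function(relative, margin = 0.2) {
  need <- c("compound", "dose", "timepoint", "metric", "relative")
  stop_if(!is.data.frame(relative) || !all(need %in% names(relative)),
          "`relative` needs columns %s", paste(need, collapse = ", "))
  check_number(margin, "margin", lower = 0)
  dir_of <- function(r) {
    if (r > 1 + margin) "excitatory"
    else if (r < 1 - margin) "inhibitory"
    else "none"
  }
  relative$direction <- vapply(relative$relative, dir_of, character(1))
  key <- interaction(relative$compound, relative$dose, relative$metric,
                     drop = TRUE)
  word <- c(excitatory = "excitation", inhibitory = "inhibition",
            none = "none")
  traj <- do.call(rbind, lapply(split(relative, key), function(df) {
    df <- df[order(df$timepoint), , drop = FALSE]
    dirs <- tapply(df$direction, df$timepoint, function(d) {
      names(which.max(table(factor(d, levels = names(word)))))
    })
    lab <- if (all(dirs == "none")) "none" else
      paste(word[rle(as.character(dirs))$values], collapse = "->")
    data.frame(compound = df$compound[1], dose = df$dose[1],
               metric = df$metric[1], trajectory = lab)
  }))
  rownames(traj) <- NULL
  list(calls = relative, trajectories = traj)
}
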