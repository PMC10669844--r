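# Phase 7: carrageenan paw-edema statistics.  Edema is expressed as the
# percent increase of paw thickness over the pre-induction baseline; group
# contrasts against the carrageenan control use one-way ANOVA with Dunnett
# adjustment, the latter by Monte-Carlo sampling of the max-|t| null.

#' Edema percentage
#'
#' `100 * (M_f - M_i) / M_i`: percent change of the paw measurement over the
#' pre-induction baseline.  Negative values (paw below baseline) are valid.
#'
#' @param M_i Baseline paw measurement(s), mm; must be positive.
#' @param M_f Post-induction measurement(s), mm.
#' @return Numeric percentage(s).
#' @export
edema_percent <- function(M_i, M_f) {
  if (any(M_i <= 0)) stop("baseline measurement M_i must be positive")
  (M_f - M_i) / M_i * 100
}

#' Per-group edema summary at one timepoint
#'
#' @param records Long edema tibble with columns `group`, `mouse`, `time`
#'   and `edema_pct` (see [generate_edema()]).
#' @param timepoint Time (h) to summarise.
#' @return Tibble per group: `mean`, `sem` (sample sd / sqrt(n)), `n`.
#' @export
group_summary <- function(records, timepoint) {
  sub <- records[records$time == timepoint, ]
  if (nrow(sub) == 0) stop("no measurements at time ", timepoint)
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$group),
    mean = mean(.data$edema_pct),
    sem = stats::sd(.data$edema_pct) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop"
  )
  if (any(out$n < 2)) {
    stop("group(s) with fewer than 2 mice: ",
         paste(out$group[out$n < 2], collapse = ", "))
  }
  out
}

#' Monte-Carlo sample of the Dunnett max-|t| null
#'
#' Draws the joint null distribution of the largest absolute Dunnett
#' t-statistic for a one-way layout: group means `N(0, 1/n_i)`, a shared
#' `chi^2_df / df` variance, and contrasts of each treatment against the
#' control.
#'
#' @param n_treat Vector of treatment group sizes.
#' @param n_control Control group size.
#' @param df Error degrees of freedom.
#' @param mc_draws Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of `mc_draws` max-|t| values.
#' @export
dunnett_null_sample <- function(n_treat, n_control, df, mc_draws = 1e5,
                                seed = 1L) {
  k <- length(n_treat)
  with_local_seed(seed, {
    m0 <- stats::rnorm(mc_draws, sd = sqrt(1 / n_control))
    s2 <- stats::rchisq(mc_draws, df) / df
    tmax <- numeric(mc_draws)
    for (i in seq_len(k)) {
      mi <- stats::rnorm(mc_draws, sd = sqrt(1 / n_treat[i]))
      ti <- (mi - m0) / sqrt(s2 * (1 / n_treat[i] + 1 / n_control))
      tmax <- pmax(tmax, abs(ti))
    }
    tmax
  })
}

#' One-way ANOVA with Dunnett contrasts against a control
#'
#' The F statistic is the standard between/within mean-square ratio.  Each
#' treatment is compared two-sidedly against the control with the pooled-sd
#' t statistic; family-wise adjusted p-values are
#' `P(max-|t| >= |t_i|)` under the Monte-Carlo null of
#' [dunnett_null_sample()] (seeded, reproducible).
#'
#' @param data Data frame with a grouping column and a response column.
#' @param response,group Column names (strings).
#' @param control Level of `group` used as control.
#' @param alpha Significance level for the `significant` column.
#' @param mc_draws Monte-Carlo draws for the null.
#' @param seed Integer seed for the null sample.
#' @param null_sample Optional precomputed max-|t| sample (from
#'   [dunnett_null_sample()] with matching design) reused instead of fresh
#'   draws.
#' @return List: `F`, `df_between`, `df_within`, `p_anova`, and `contrasts`
#'   tibble (`group`, `diff`, `t`, `p_raw` two-sided unadjusted, `p_adj`,
#'   `significant`).
#' @export
anova_dunnett <- function(data, response = "edema_pct", group = "group",
                          control, alpha = 0.05, mc_draws = 1e5, seed = 1L,
                          null_sample = NULL) {
  y <- data[[response]]
  g <- as.character(data[[group]])
  stopifnot(control %in% g)
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  levels <- names(sizes)
  k <- length(levels)
  if (k < 2) stop("need a control plus at least one treatment group")
  N <- length(y)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df_b <- k - 1
  df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  Fstat <- ms_b / ms_w
  p_anova <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)

  treat <- setdiff(levels, control)
  n0 <- as.numeric(sizes[control])
  nt <- as.numeric(sizes[treat])
  diff <- as.numeric(means[treat] - means[control])
  se <- sqrt(ms_w * (1 / nt + 1 / n0))
  tstat <- diff / se
  p_raw <- 2 * stats::pt(abs(tstat), df_w, lower.tail = FALSE)
  if (is.null(null_sample)) {
    null_sample <- dunnett_null_sample(nt, n0, df_w, mc_draws, seed)
  }
  p_adj <- vapply(abs(tstat), function(tt) mean(null_sample >= tt),
                  numeric(1))
  p_adj <- pmax(p_adj, p_raw)  # adjustment can never beat the raw p
  list(
    F = Fstat, df_between = df_b, df_within = df_w, p_anova = p_anova,
    contrasts = tibble::tibble(
      group = treat, diff = diff, t = tstat, p_raw = p_raw, p_adj = p_adj,
      significant = p_adj < alpha
    )
  )
}
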