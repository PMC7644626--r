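# Small phenotype statistics around the screen: Smurf summaries, fold
# changes and two-sample tests, Kaplan-Meier survival with log-rank, and
# 2^-ddCt qPCR fold changes. The replication unit for Smurf dispersion and
# t-tests is the vial, not the fly.

#' Summarise Smurf proportions per group
#'
#' Per-vial proportions `n_smurf / n_total`, with mean and SD taken across
#' vials (the replication unit). The SD is undefined (NA) for groups with a
#' single vial.
#'
#' @param phen a [phenotype_table()] or data.frame with `n_smurf`/`n_total`.
#' @param group_cols columns defining groups (default
#'   `c("line_id", "dose_gy")` intersected with what is present; no match =
#'   one overall group).
#' @return data.frame of class `smurf_summary`: group columns plus
#'   `n_vials`, `mean_proportion`, `sd_proportion`. Per-vial proportions are
#'   attached as attribute `"proportions"` (a list per group).
#' @export
smurf_summary <- function(phen, group_cols = c("line_id", "dose_gy")) {
  phen <- as.data.frame(phen)
  if (nrow(phen) == 0) stop_radgut("empty phenotype group")
  if (!all(c("n_smurf", "n_total") %in% names(phen)))
    stop_radgut("need n_smurf and n_total columns")
  group_cols <- intersect(group_cols, names(phen))
  prop <- phen$n_smurf / phen$n_total
  key <- if (length(group_cols))
    interaction(phen[group_cols], drop = TRUE, lex.order = TRUE)
  else factor(rep("all", nrow(phen)))
  split_prop <- split(prop, key)
  idx <- match(names(split_prop), as.character(key))
  out <- if (length(group_cols)) phen[idx, group_cols, drop = FALSE]
         else data.frame(group = names(split_prop))
  out$n_vials <- lengths(split_prop)
  out$mean_proportion <- vapply(split_prop, mean, numeric(1))
  out$sd_proportion <- vapply(split_prop, function(p)
    if (length(p) < 2) NA_real_ else stats::sd(p), numeric(1))
  rownames(out) <- NULL
  attr(out, "proportions") <- split_prop
  class(out) <- c("smurf_summary", "data.frame")
  out
}

#' Fold change of two means
#'
#' @param treated treated-group mean.
#' @param control control-group mean; must be > 0.
#' @return `treated / control`.
#' @export
fold_change <- function(treated, control) {
  if (any(control <= 0)) stop_radgut("fold change undefined: control mean must be > 0")
  treated / control
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch-Satterthwaite) test by default, as figure-legend
#' "t-test" comparisons rarely justify pooled variances; `pooled = TRUE`
#' gives the classic equal-variance test.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param pooled use pooled variance (default FALSE).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop_radgut("each group needs at least 2 values")
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`;
#' censored records leave the risk set without a step. The median is the
#' first event time with `S(t) <= 0.5`, undefined (NA) if the curve never
#' reaches 0.5.
#'
#' @param tab a [survival_table()].
#' @param group optional group label to subset to.
#' @return list of class `km_curve`: `time`, `n_risk`, `n_event`, `surv`
#'   (event times only), `median`, `n`.
#' @export
km_estimate <- function(tab, group = NULL) {
  tab <- survival_table(as.data.frame(tab))
  if (!is.null(group)) {
    tab <- tab[tab$group == group, , drop = FALSE]
    if (nrow(tab) == 0) stop_radgut("no records for group '%s'", group)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = tab)
  keep <- fit$n.event > 0
  out <- list(time = fit$time[keep], n_risk = fit$n.risk[keep],
              n_event = fit$n.event[keep], surv = fit$surv[keep],
              n = nrow(tab))
  out$median <- if (any(out$surv <= 0.5)) out$time[which(out$surv <= 0.5)[1L]]
                else NA_real_
  class(out) <- "km_curve"
  out
}

#' Evaluate a KM curve at given times
#'
#' @param curve a `km_curve`.
#' @param t times.
#' @return `S(t)` (right-continuous step function, `S(0) = 1`).
#' @export
km_surv_at <- function(curve, t) {
  s <- c(1, curve$surv)
  s[findInterval(t, curve$time) + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, %d event times, median = %s\n", x$n,
              length(x$time), if (is.na(x$median)) "undefined" else x$median))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank comparison.
#'
#' @param tab a [survival_table()].
#' @param groups optional length-2 vector of group labels; default all
#'   groups present (must be exactly 2).
#' @return list with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(tab, groups = NULL) {
  tab <- survival_table(as.data.frame(tab))
  if (!is.null(groups)) tab <- tab[tab$group %in% groups, , drop = FALSE]
  gl <- unique(tab$group)
  if (length(gl) != 2) stop_radgut("log-rank needs exactly 2 groups, got %d", length(gl))
  if (sum(tab$event) == 0) stop_radgut("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = tab)
  list(chisq = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Relative qPCR fold change (2^-ddCt)
#'
#' `ddCt = (Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control`;
#' fold = `2^-ddCt`. Vectors of replicate Ct values are averaged first.
#' Normalisation to the reference gene makes the fold invariant to any
#' constant shift applied to all Cts.
#'
#' @param ct_target_treated,ct_ref_treated Ct values in the treated
#'   condition (target and reference gene).
#' @param ct_target_control,ct_ref_control Ct values in the control
#'   condition.
#' @return fold change (1 = no change; 2 = doubling of relative abundance).
#' @examples
#' ddct_fold_change(24, 20, 25, 20)  # one cycle lower in treated: fold 2
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts) | cts <= 0))
    stop_radgut("Ct values must be finite and positive")
  ddct <- (mean(ct_target_treated) - mean(ct_ref_treated)) -
    (mean(ct_target_control) - mean(ct_ref_control))
  2^(-ddct)
}
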