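# Survival screen for hub genes: median-split groups, Kaplan-Meier
# curves, log-rank test and a single-covariate proportional-hazards
# hazard ratio (Efron ties), via the survival package.

#' Split subjects into high/low expression groups
#'
#' High iff expression strictly exceeds the `cutoff_quantile` quantile
#' (default the median, i.e. a 50% cut); subjects tied with the cutoff go
#' to the low group, so the split is deterministic.
#'
#' @param surv_table data.frame as from [read_survival_table()].
#' @param gene gene column to split on.
#' @param cutoff_quantile quantile in (0, 1), default 0.5.
#' @return factor with levels `low`, `high`, one per subject.
#' @export
dichotomize <- function(surv_table, gene, cutoff_quantile = 0.5) {
  if (!gene %in% names(surv_table))
    stop("gene '", gene, "' not in the survival table")
  v <- surv_table[[gene]]
  if (any(is.na(v))) stop("missing expression for gene '", gene, "'")
  if (length(unique(v)) < 2)
    stop("all expression values identical for '", gene,
         "': degenerate split")
  cut <- stats::quantile(v, cutoff_quantile, names = FALSE)
  factor(ifelse(v > cut, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates; censored subjects leave the risk set without a
#' probability step.
#'
#' @param surv_table data.frame with `time_months` and `event`.
#' @param groups factor of group labels, one per subject.
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_estimate <- function(surv_table, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) == 0)
    stop("every group must contain at least one subject")
  fit <- survival::survfit(
    survival::Surv(surv_table$time_months, surv_table$event) ~ groups)
  if (nlevels(droplevels(groups)) == 1) {
    strata_lab <- rep(levels(droplevels(groups)), length(fit$time))
  } else {
    strata_lab <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata_lab, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Mantel-Haenszel statistic accumulated over event times, referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param surv_table data.frame with `time_months` and `event`.
#' @param groups two-level factor.
#' @return list with `chisq` and `p`.
#' @export
logrank_test <- function(surv_table, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("log-rank test needs exactly two groups")
  if (sum(surv_table$event) == 0) stop("no events: log-rank undefined")
  sd <- survival::survdiff(
    survival::Surv(surv_table$time_months, surv_table$event) ~ groups)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Hazard ratio from a single-covariate proportional-hazards fit
#'
#' Partial-likelihood fit of high vs low group (Efron tie handling);
#' returns the hazard ratio of the `high` group relative to `low` with a
#' 95% Wald confidence interval and p-value. Complete separation (all
#' events in one group before any in the other) leaves the partial
#' likelihood monotone; the fit is then flagged and the unbounded CI side
#' reported as infinite.
#'
#' @param surv_table data.frame with `time_months` and `event`.
#' @param groups factor with levels `low`, `high`.
#' @return list with `hr`, `ci` (length-2), `p`, `flagged`.
#' @export
hazard_ratio <- function(surv_table, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("hazard ratio needs exactly two groups")
  if (any(tapply(surv_table$event, groups, sum) == 0))
    warning("a group has zero events; the hazard ratio is unstable")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(surv_table$time_months, surv_table$event) ~ groups,
      ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || abs(beta) > 15) flagged <- TRUE
  ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  if (flagged) ci[if (beta > 0) 2 else 1] <- Inf
  list(hr = exp(beta), ci = ci,
       p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
       flagged = flagged)
}

#' Survival screen across a gene list
#'
#' For each gene: median split, log-rank test, proportional-hazards
#' hazard ratio, per-group median survival. A gene is `significant` when
#' the log-rank p or the hazard-ratio p is at most 0.05 (non-strict, so a
#' p of exactly 0.05 counts). Genes missing from the table yield a
#' flagged NA row and the screen continues.
#'
#' @param surv_table data.frame as from [read_survival_table()].
#' @param genes character vector of gene columns to screen.
#' @param cutoff_quantile split quantile (default 0.5).
#' @param alpha significance level for the dual criterion (default 0.05).
#' @return data.frame, one row per gene in input order: `gene`,
#'   `logrank_p`, `hazard_ratio`, `hr_ci_low`, `hr_ci_high`, `hr_p`,
#'   `median_surv_low`, `median_surv_high`, `significant`, `flagged`.
#' @export
screen_genes <- function(surv_table, genes, cutoff_quantile = 0.5,
                         alpha = 0.05) {
  if (!length(genes))
    return(data.frame(gene = character(), logrank_p = numeric(),
                      hazard_ratio = numeric(), hr_ci_low = numeric(),
                      hr_ci_high = numeric(), hr_p = numeric(),
                      median_surv_low = numeric(),
                      median_surv_high = numeric(),
                      significant = logical(), flagged = logical()))
  rows <- lapply(genes, function(g) {
    if (!g %in% names(surv_table)) {
      warning("gene '", g, "' missing from the survival table")
      return(data.frame(gene = g, logrank_p = NA_real_,
                        hazard_ratio = NA_real_, hr_ci_low = NA_real_,
                        hr_ci_high = NA_real_, hr_p = NA_real_,
                        median_surv_low = NA_real_,
                        median_surv_high = NA_real_,
                        significant = NA, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    grp <- dichotomize(surv_table, g, cutoff_quantile)
    lr <- logrank_test(surv_table, grp)
    hr <- hazard_ratio(surv_table, grp)
    med <- vapply(c("low", "high"), function(lv) {
      fit <- survival::survfit(survival::Surv(
        surv_table$time_months[grp == lv],
        surv_table$event[grp == lv]) ~ 1)
      unname(summary(fit)$table["median"])
    }, 0)
    data.frame(gene = g, logrank_p = lr$p, hazard_ratio = hr$hr,
               hr_ci_low = hr$ci[1], hr_ci_high = hr$ci[2], hr_p = hr$p,
               median_surv_low = med[["low"]],
               median_surv_high = med[["high"]],
               significant = lr$p <= alpha || hr$p <= alpha,
               flagged = hr$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
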