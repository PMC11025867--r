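# Survival screening: median-expression dichotomization, Kaplan-Meier
# curves, two-group log-rank test and univariate Cox regression.  The
# estimators are provided by the survival package; this module fixes the
# conventions (median ties to "low", Breslow tie handling) and exposes a
# per-gene screening table.

#' Dichotomize samples at the median
#'
#' Values strictly above the median are labelled `high`; values at or
#' below the median are `low`.  Ties at the median therefore fall into
#' the low group, so hazard ratios read as the risk of high expression.
#'
#' @param x Numeric vector (one value per sample).
#' @return Factor with levels `low`, `high`, same length as `x`.
#' @export
dichotomize_by_median <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  if (max(x) == min(x)) {
    stop("all values identical: median split would produce one group")
  }
  med <- stats::median(x)
  factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored); events at a
#'   tied time are handled before censorings at that time.
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`: the step function coordinates at each distinct observed
#'   time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least 1 record")
  if (any(time <= 0)) stop("times must be positive")
  stopifnot(all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time,
             n_risk = fit$n.risk,
             n_event = fit$n.event,
             n_censor = fit$n.censor,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with hypergeometric variance at each
#' distinct event time, referred to a chi-square distribution with 1 df.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level grouping factor.
#' @return List with `chisq`, `p`, and the per-group observed/expected
#'   event counts `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Univariate Cox proportional hazards regression
#'
#' Partial likelihood with Breslow tie handling; the hazard ratio and
#' its 95% confidence interval come from the observed information.
#' Non-convergence (e.g. monotone likelihood) is reported with a
#' warning and flagged in the result.
#'
#' @param time,event As in [km_estimate()].
#' @param covariate Numeric per-sample covariate (must vary).
#' @return List with `beta`, `se`, `hr`, `ci_low`, `ci_high`, `wald_p`,
#'   `converged`.
#' @export
cox_univariate <- function(time, event, covariate) {
  if (sum(event) < 1) stop("need at least one event")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|out of iterations", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (!converged) {
    warning("Cox fit did not converge (monotone likelihood?); ",
            "estimate reported anyway")
  }
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  z <- beta / se
  list(beta = beta,
       se = se,
       hr = exp(beta),
       ci_low = exp(beta - stats::qnorm(0.975) * se),
       ci_high = exp(beta + stats::qnorm(0.975) * se),
       wald_p = 2 * stats::pnorm(-abs(z)),
       converged = converged)
}

#' Survival screen over a set of genes
#'
#' For every gene: median-dichotomize its expression over the samples
#' with survival records, compare the two groups by log-rank test and
#' fit a univariate Cox model on the high/low indicator (so the hazard
#' ratio is high-versus-low).  Genes whose expression cannot be split
#' (all values identical) are reported with `NA` statistics.
#'
#' @param expr Gene x sample expression matrix.
#' @param survdata data.frame `sample_id`, `time`, `event`.
#' @param genes Genes to screen (default: all rows of `expr`).
#' @param alpha Significance level on the log-rank p-value.
#' @return data.frame `gene`, `n_high`, `n_low`, `logrank_chisq`,
#'   `logrank_p`, `hr`, `ci_low`, `ci_high`, `wald_p`, `significant`.
#' @export
screen_survival <- function(expr, survdata, genes = rownames(expr),
                            alpha = 0.05) {
  survdata <- survdata[!is.na(survdata$time) & !is.na(survdata$event), ,
                       drop = FALSE]
  shared <- intersect(colnames(expr), survdata$sample_id)
  survdata <- survdata[match(shared, survdata$sample_id), , drop = FALSE]
  rows <- lapply(genes, function(g) {
    na_row <- data.frame(gene = g, n_high = NA_integer_,
                         n_low = NA_integer_, logrank_chisq = NA_real_,
                         logrank_p = NA_real_, hr = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         wald_p = NA_real_, significant = FALSE,
                         stringsAsFactors = FALSE)
    if (!g %in% rownames(expr)) return(na_row)
    x <- expr[g, shared]
    grp <- tryCatch(dichotomize_by_median(x), error = function(e) NULL)
    if (is.null(grp)) return(na_row)
    lr <- logrank_test(survdata$time, survdata$event, grp)
    cx <- tryCatch(
      suppressWarnings(cox_univariate(survdata$time, survdata$event,
                                      as.numeric(grp == "high"))),
      error = function(e) NULL)
    data.frame(gene = g,
               n_high = sum(grp == "high"),
               n_low = sum(grp == "low"),
               logrank_chisq = lr$chisq,
               logrank_p = lr$p,
               hr = if (is.null(cx)) NA_real_ else cx$hr,
               ci_low = if (is.null(cx)) NA_real_ else cx$ci_low,
               ci_high = if (is.null(cx)) NA_real_ else cx$ci_high,
               wald_p = if (is.null(cx)) NA_real_ else cx$wald_p,
               significant = lr$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
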