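# Multivariable logistic models for POD: the seven BS modelling strategies
# (continuous BSR, raw duration, binary indicator, sensitivity restriction
# to measurable BS, per-agent subgroups, interaction model) as thin, classed
# wrappers around stats::glm with Wald odds-ratio reporting.

or_table <- function(fit, conf_level = 0.95) {
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    term = names(cf),
    estimate = unname(cf),
    odds_ratio = exp(unname(cf)),
    ci_lo = exp(unname(cf) - z * se),
    ci_hi = exp(unname(cf) + z * se),
    p_value = 2 * pnorm(-abs(unname(cf) / se)),
    stringsAsFactors = FALSE)
}

fit_logistic <- function(formula, data, model_name, conf_level = 0.95) {
  if (length(unique(data$pod)) < 2L)
    stop("outcome has a single class in this subset; model '",
         model_name, "' cannot be fitted")
  n0 <- nrow(data)
  data <- data[stats::complete.cases(data), , drop = FALSE]
  dropped <- n0 - nrow(data)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # huge Wald SEs are the other face of separation
  if (any(sqrt(diag(vcov(fit))) > 50)) sep <- TRUE
  structure(list(
    model_name = model_name,
    fit = fit,
    coefficients = or_table(fit, conf_level),
    n = nrow(data),
    n_dropped = dropped,
    converged = fit$converged && !sep,
    separation = sep,
    conf_level = conf_level), class = "pod_model")
}

#' Fit a multivariable logistic model of postoperative delirium
#'
#' The predictor set is anesthetic agent (sevoflurane vs propofol), age, ASA
#' class, surgery duration in hours, postoperative care location, plus the
#' chosen burst-suppression representation. With `subset = "bs_only"` the
#' model is restricted to patients with measurable BS (`bs_duration > 0`)
#' and uses `log(1 + bs_duration)` as the dose variable (raw seconds with
#' `dose_log = FALSE`); per-agent subsets drop the agent term.
#'
#' @param cohort a cohort table (see [validate_cohort()]).
#' @param bs_mode burst-suppression representation: `"binary"` (`any_bs`),
#'   `"continuous_bsr"`, `"raw_duration"`, or `"none"`.
#' @param subset `"all"`, `"sevoflurane"`, `"propofol"` or `"bs_only"`.
#' @param covariates include age, ASA, surgery duration and care location
#'   (default TRUE).
#' @param dose_log log-transform the duration dose in the `bs_only` model.
#' @param conf_level Wald CI level.
#' @return An object of class `"pod_model"`: the glm fit, an odds-ratio
#'   table with Wald CIs and p-values, `n` used (after listwise deletion,
#'   counted in `n_dropped`), and a convergence/separation flag.
#' @examples
#' coh <- simulate_cohort(cohort_sim_spec(n = 4000, seed = 7))
#' fit_pod_model(coh, bs_mode = "binary")
#' @export
fit_pod_model <- function(cohort,
                          bs_mode = c("binary", "continuous_bsr",
                                      "raw_duration", "none"),
                          subset = c("all", "sevoflurane", "propofol",
                                     "bs_only"),
                          covariates = TRUE, dose_log = TRUE,
                          conf_level = 0.95) {
  bs_mode <- match.arg(bs_mode)
  subset <- match.arg(subset)
  cohort <- validate_cohort(cohort)
  data <- switch(subset,
    all = cohort,
    sevoflurane = cohort[cohort$agent == "sevoflurane", , drop = FALSE],
    propofol = cohort[cohort$agent == "propofol", , drop = FALSE],
    bs_only = cohort[cohort$bs_duration > 0, , drop = FALSE])
  terms <- character()
  if (subset %in% c("all", "bs_only")) terms <- c(terms, "agent")
  if (subset == "bs_only") {
    data$bs_dose <- if (dose_log) log1p(data$bs_duration) else
      data$bs_duration
    terms <- c(terms, "bs_dose")
  } else {
    terms <- c(terms, switch(bs_mode,
                             binary = "any_bs",
                             continuous_bsr = "bsr",
                             raw_duration = "bs_duration",
                             none = NULL))
  }
  if (covariates)
    terms <- c(terms, "age", "asa", "surgery_duration", "care_location")
  if (!length(terms)) stop("model has no predictors")
  fml <- as.formula(paste("pod ~", paste(terms, collapse = " + ")))
  nm <- if (subset == "bs_only") "bs_only" else
    paste0(bs_mode, if (subset != "all") paste0("_", subset))
  fit_logistic(fml, data, model_name = nm, conf_level = conf_level)
}

#' Fit the anesthetic-by-burst-suppression interaction model
#'
#' Logistic model with main effects for sevoflurane and any BS plus their
#' product term, optionally adjusted for the standard covariates. The four
#' conditional odds ratios relative to the propofol / no-BS reference cell
#' are derived from the coefficients — `(1, exp(b_bs), exp(b_sevo),
#' exp(b_sevo + b_bs + b_int))` — with Wald CIs from the corresponding
#' linear combinations, alongside the interaction OR `exp(b_int)` itself.
#' By construction `OR(sevo+BS) = OR(sevo) * OR(bs) * OR(interaction)`.
#'
#' @param cohort a cohort table; all four agent-by-BS cells must be
#'   non-empty.
#' @param covariates include age, ASA, surgery duration and care location.
#' @param conf_level Wald CI level.
#' @return A `"pod_model"` with an extra element `conditional_or`: a data
#'   frame of the four cells with OR and CI.
#' @examples
#' coh <- simulate_cohort(cohort_sim_spec(n = 20000, seed = 11))
#' fit_interaction_model(coh)$conditional_or
#' @export
fit_interaction_model <- function(cohort, covariates = TRUE,
                                  conf_level = 0.95) {
  cohort <- validate_cohort(cohort)
  cells <- table(agent = cohort$agent, any_bs = cohort$any_bs)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("empty agent-by-BS cell: ",
         rownames(cells)[empty[1L]], " / any_bs=",
         colnames(cells)[empty[2L]])
  }
  terms <- c("agent * any_bs",
             if (covariates) c("age", "asa", "surgery_duration",
                               "care_location"))
  fml <- as.formula(paste("pod ~", paste(terms, collapse = " + ")))
  m <- fit_logistic(fml, cohort, model_name = "interaction",
                    conf_level = conf_level)
  cf <- coef(m$fit)
  V <- vcov(m$fit)
  nm_sevo <- "agentsevoflurane"
  nm_bs <- "any_bsTRUE"
  nm_int <- "agentsevoflurane:any_bsTRUE"
  z <- qnorm(1 - (1 - conf_level) / 2)
  combo <- function(terms) {
    w <- setNames(numeric(length(cf)), names(cf))
    w[terms] <- 1
    est <- sum(w * cf)
    se <- sqrt(drop(t(w) %*% V %*% w))
    c(or = exp(est), lo = exp(est - z * se), hi = exp(est + z * se))
  }
  rows <- rbind(
    propofol_no_bs = c(or = 1, lo = NA_real_, hi = NA_real_),
    propofol_bs = combo(nm_bs),
    sevoflurane_no_bs = combo(nm_sevo),
    sevoflurane_bs = combo(c(nm_sevo, nm_bs, nm_int)))
  m$conditional_or <- data.frame(
    cell = rownames(rows), odds_ratio = rows[, "or"],
    ci_lo = rows[, "lo"], ci_hi = rows[, "hi"],
    stringsAsFactors = FALSE, row.names = NULL)
  m$interaction_or <- combo(nm_int)
  m
}

#' @export
print.pod_model <- function(x, digits = 3, ...) {
  cat("<pod_model> '", x$model_name, "', n = ", x$n,
      if (x$n_dropped) paste0(" (", x$n_dropped, " dropped)"), "\n",
      sep = "")
  if (!x$converged)
    cat("  WARNING: ", if (x$separation)
      "possible complete/quasi-complete separation; " else "",
      "estimates unreliable\n", sep = "")
  tab <- x$coefficients
  tab[-1L] <- lapply(tab[-1L], signif, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$conditional_or)) {
    cat("  conditional ORs vs propofol/no-BS:\n")
    co <- x$conditional_or
    co[-1L] <- lapply(co[-1L], signif, digits = digits)
    print(co, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.pod_model <- function(object, ...) {
  list(model_name = object$model_name,
       coefficients = object$coefficients,
       conditional_or = object$conditional_or,
       n = object$n, converged = object$converged,
       glm_summary = summary(object$fit))
}

#' @export
coef.pod_model <- function(object, ...) coef(object$fit)

#' @export
confint.pod_model <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object$fit)
  se <- sqrt(diag(vcov(object$fit)))
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(lower = cf - z * se, upper = cf + z * se)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.pod_model <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) predict(object$fit, type = type)
  else predict(object$fit, newdata = newdata, type = type)
}

#' @export
plot.pod_model <- function(x, ...) {
  tab <- x$coefficients[x$coefficients$term != "(Intercept)", ]
  k <- nrow(tab)
  plot(NULL, xlim = range(c(tab$ci_lo, tab$ci_hi, 1), finite = TRUE),
       ylim = c(0.5, k + 0.5), log = "x", yaxt = "n",
       xlab = "odds ratio (log scale)", ylab = "",
       main = paste0("POD model '", x$model_name, "'"), ...)
  axis(2, at = seq_len(k), labels = tab$term, las = 1, cex.axis = 0.7)
  abline(v = 1, lty = 2, col = "grey50")
  segments(tab$ci_lo, seq_len(k), tab$ci_hi, seq_len(k))
  points(tab$odds_ratio, seq_len(k), pch = 16)
  invisible(x)
}
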