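# Cohort-level statistics: contingency analysis of POD incidence by agent
# (chi-square, relative risk, Cohen's h, two-proportion power), rank-sum
# group comparison, and the log-scale transform used for duration plots.

#' Validate a patient cohort table
#'
#' Checks the column set and the structural invariants: `any_bs` is exactly
#' `bs_duration > 0`, `bsr` lies in \[0, 100\], ASA class in 1–4, agent in
#' propofol/sevoflurane.
#'
#' @param cohort a data frame (see [simulate_cohort()] for the schema).
#' @return The validated cohort, with `agent` and `care_location` coerced to
#'   factors.
#' @export
validate_cohort <- function(cohort) {
  need <- c("agent", "pod", "age", "asa", "surgery_duration",
            "bs_duration", "bsr", "any_bs", "care_location")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  cohort$agent <- factor(as.character(cohort$agent),
                         levels = c("propofol", "sevoflurane"))
  if (anyNA(cohort$agent)) stop("agent must be propofol or sevoflurane")
  cohort$care_location <- factor(as.character(cohort$care_location),
                                 levels = c("recovery", "pacu_icu"))
  if (!all(cohort$asa %in% 1:4)) stop("asa must be in 1..4")
  if (any(cohort$bsr < -1e-9 | cohort$bsr > 100 + 1e-9))
    stop("bsr must lie in [0, 100]")
  if (any(cohort$bs_duration < 0)) stop("bs_duration must be >= 0")
  if (!all(cohort$any_bs == (cohort$bs_duration > 0)))
    stop("any_bs must equal (bs_duration > 0)")
  cohort
}

#' Read a cohort CSV
#'
#' @param path CSV with the [validate_cohort()] column schema;
#'   `surgery_duration` in hours (use `minutes = TRUE` for tables stored in
#'   minutes).
#' @param minutes convert `surgery_duration` from minutes to hours.
#' @return A validated `pod_cohort` data frame.
#' @export
read_cohort <- function(path, minutes = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (minutes) df$surgery_duration <- df$surgery_duration / 60
  df <- validate_cohort(df)
  class(df) <- c("pod_cohort", "data.frame")
  df
}

#' Cohen's h effect size for two proportions
#'
#' `|2*asin(sqrt(p1)) - 2*asin(sqrt(p2))|`, the arcsine-transformed
#' difference of two proportions. Symmetric in its arguments.
#'
#' @param p1,p2 proportions in \[0, 1\].
#' @return Non-negative effect size (at most pi).
#' @examples
#' cohens_h(56 / 126, 42 / 139)  # 0.295
#' @export
cohens_h <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)))
}

#' Power of the two-sample proportions z-test (normal approximation)
#'
#' Power to detect `p1 != p2` with arm sizes `n1`, `n2` at level `alpha`:
#' the rejection threshold uses the pooled standard error under H0,
#' `se0 = sqrt(pbar*(1-pbar)*(1/n1+1/n2))` with
#' `pbar = (n1*p1 + n2*p2)/(n1+n2)`, and the power is evaluated under H1
#' with the unpooled standard error
#' `se1 = sqrt(p1*(1-p1)/n1 + p2*(1-p2)/n2)`:
#' `power = Phi((|p1-p2| - z*se0)/se1) + Phi((-|p1-p2| - z*se0)/se1)`
#' with `z = qnorm(1 - alpha/tails)`. At `p1 == p2` this returns `alpha`.
#'
#' @param p1,p2 arm proportions.
#' @param n1,n2 arm sizes (>= 2).
#' @param alpha significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Achieved power (1 − beta).
#' @export
two_proportion_power <- function(p1, p2, n1, n2, alpha = 0.05, tails = 2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 2, n2 >= 2,
            tails %in% c(1, 2))
  z <- qnorm(1 - alpha / tails)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (se1 == 0) return(as.numeric(abs(p1 - p2) > 0))
  d <- abs(p1 - p2)
  pnorm((d - z * se0) / se1) + pnorm((-d - z * se0) / se1)
}

#' Contingency analysis of POD incidence by anesthetic agent
#'
#' From a cohort table (or directly from a 2x2 count matrix with rows
#' `sevoflurane`/`propofol` and columns `pod`/`no_pod`): per-arm incidences,
#' Pearson chi-square without continuity correction (df = 1), relative risk
#' (sevoflurane vs propofol) with a log-scale Wald 95% CI, Cohen's h, and
#' the achieved two-proportion power at alpha = 0.05 two-sided.
#'
#' @param x a cohort data frame with `agent` and `pod`, or a 2x2 numeric
#'   matrix of counts.
#' @param yates apply the Yates continuity correction (default FALSE; the
#'   uncorrected test is the package convention).
#' @param conf_level CI level for the relative risk.
#' @return An object of class `"bs_contingency"`.
#' @examples
#' counts <- matrix(c(56, 70, 42, 97), nrow = 2, byrow = TRUE,
#'                  dimnames = list(c("sevoflurane", "propofol"),
#'                                  c("pod", "no_pod")))
#' incidence_table(counts)
#' @export
incidence_table <- function(x, yates = FALSE, conf_level = 0.95) {
  if (is.matrix(x)) {
    if (!all(dim(x) == 2L)) stop("count matrix must be 2x2")
    counts <- x
    if (is.null(rownames(counts)))
      rownames(counts) <- c("sevoflurane", "propofol")
    if (is.null(colnames(counts)))
      colnames(counts) <- c("pod", "no_pod")
  } else {
    x <- validate_cohort(x)
    if (any(table(x$agent) == 0L))
      stop("both anesthetic arms must be present")
    counts <- rbind(
      sevoflurane = c(pod = sum(x$agent == "sevoflurane" & x$pod),
                      no_pod = sum(x$agent == "sevoflurane" & !x$pod)),
      propofol = c(pod = sum(x$agent == "propofol" & x$pod),
                   no_pod = sum(x$agent == "propofol" & !x$pod)))
  }
  if (any(rowSums(counts) == 0)) stop("empty anesthetic arm")
  n1 <- sum(counts["sevoflurane", ]); n2 <- sum(counts["propofol", ])
  p1 <- counts["sevoflurane", "pod"] / n1
  p2 <- counts["propofol", "pod"] / n2
  ct <- suppressWarnings(chisq.test(counts, correct = yates))
  rr <- p1 / p2
  # log-scale Wald CI for the risk ratio
  se_log <- sqrt((1 - p1) / (p1 * n1) + (1 - p2) / (p2 * n2))
  z <- qnorm(1 - (1 - conf_level) / 2)
  res <- list(
    counts = counts,
    incidence = c(sevoflurane = 100 * p1, propofol = 100 * p2,
                  overall = 100 * sum(counts[, "pod"]) / sum(counts)),
    chi_square = unname(ct$statistic),
    p_value = unname(ct$p.value),
    relative_risk = unname(rr),
    rr_ci = exp(log(rr) + c(-1, 1) * z * se_log),
    cohens_h = cohens_h(p1, p2),
    achieved_power = two_proportion_power(p1, p2, n1, n2),
    yates = yates, conf_level = conf_level)
  class(res) <- "bs_contingency"
  res
}

#' @export
print.bs_contingency <- function(x, ...) {
  cat("<bs_contingency> POD incidence by anesthetic agent\n")
  print(x$counts)
  cat("  incidence: sevoflurane ", format(x$incidence[["sevoflurane"]],
                                          digits = 3),
      "%, propofol ", format(x$incidence[["propofol"]], digits = 3),
      "%, overall ", format(x$incidence[["overall"]], digits = 3), "%\n",
      "  chi-square (df=1", if (x$yates) ", Yates", ") = ",
      format(x$chi_square, digits = 4), ", p = ",
      format(x$p_value, digits = 3), "\n",
      "  RR (sevo vs prop) = ", format(x$relative_risk, digits = 4),
      " [", format(x$rr_ci[1L], digits = 4), ", ",
      format(x$rr_ci[2L], digits = 4), "]\n",
      "  Cohen's h = ", format(x$cohens_h, digits = 3),
      ", achieved power = ", format(x$achieved_power, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Two-group rank-sum comparison (Mann–Whitney U)
#'
#' Two-sided Mann–Whitney U test with tie correction under the normal
#' approximation (no continuity correction), the convention used for the
#' skewed BS-duration comparisons.
#'
#' @param a,b numeric samples.
#' @return List with `u` (the U statistic for `a`), `p_value`, and the
#'   group medians.
#' @export
group_compare <- function(a, b) {
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       median_a = median(a), median_b = median(b))
}

#' Log-scale transform for burst-suppression durations
#'
#' `log(1 + x)`: zero maps to zero and order is preserved, which keeps the
#' many zero-duration patients on the plot axis.
#'
#' @param x durations in seconds (>= 0).
#' @return Transformed values.
#' @export
log_scale_duration <- function(x) {
  if (any(x < 0)) stop("durations must be >= 0")
  log1p(x)
}
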