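#' Welch two-sample t test from summary statistics
#'
#' The Welch (unequal-variance) t test computed directly from printed
#' group summaries (mean, SD, n) with Welch-Satterthwaite degrees of
#' freedom — the form in which demographic tables are usually reported,
#' allowing published p values to be recomputed without raw data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @examples
#' # age at follow-up vs controls from a published demographics table
#' welch_from_summary(75.73, 7.25, 40, 74.78, 4.95, 45)$p  # ~0.49
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    stop_gm("welch_from_summary: need n >= 2 per group",
            class = "gmprog_insufficient_data_error")
  se2 <- sd1^2 / n1 + sd2^2 / n2
  if (se2 == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
  tt <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Demographic and cognitive group comparisons
#'
#' The standard cohort-description tests: sex composition by 2x2
#' chi-squared with Yates continuity correction, and age / CDR / MMSE /
#' MoCA by two-tailed Welch two-sample t tests, for HC vs AD-T1 and HC vs
#' AD-T2. Missing scores are dropped pairwise (complete-case per
#' variable).
#'
#' @param phenotypes phenotype table as from [generate_phenotypes()].
#' @return Data frame: `variable, comparison, statistic, df, p`.
#' @export
cohort_demographic_tests <- function(phenotypes) {
  grp <- function(g, tp) phenotypes[phenotypes$group == g &
                                    phenotypes$timepoint == tp, , drop = FALSE]
  hc <- grp("HC", "T1")
  if (nrow(hc) < 2)
    stop_gm("cohort_demographic_tests: HC group degenerate (n < 2)",
            class = "gmprog_insufficient_data_error")
  out <- list()
  for (tp in c("T1", "T2")) {
    ad <- grp("AD", tp)
    if (nrow(ad) < 2)
      stop_gm("cohort_demographic_tests: AD-", tp, " group degenerate (n < 2)",
              class = "gmprog_insufficient_data_error")
    comp <- paste0("HC_vs_AD", tp)
    tab <- rbind(AD = c(M = sum(ad$sex == "M"), F = sum(ad$sex == "F")),
                 HC = c(M = sum(hc$sex == "M"), F = sum(hc$sex == "F")))
    cs <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    out[[length(out) + 1]] <- data.frame(
      variable = "sex", comparison = comp,
      statistic = unname(cs$statistic), df = unname(cs$parameter),
      p = cs$p.value, stringsAsFactors = FALSE)
    for (v in c("age", "CDR", "MMSE", "MoCA")) {
      x <- ad[[v]][!is.na(ad[[v]])]
      y <- hc[[v]][!is.na(hc[[v]])]
      res <- if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
        list(statistic = 0, parameter = length(x) + length(y) - 2, p.value = 1)
      } else {
        tt <- stats::t.test(x, y, var.equal = FALSE)
        list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
             p.value = tt$p.value)
      }
      out[[length(out) + 1]] <- data.frame(
        variable = v, comparison = comp,
        statistic = res$statistic, df = res$parameter, p = res$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
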