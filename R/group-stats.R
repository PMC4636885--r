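# Statistical decision tree over the 3-treatment x 3-temperature design.
#
# Replicate-level responses (one value per biological replicate, n = 3
# per cell) are first checked for normality (Shapiro-Wilk on residuals
# from the cell means — with n = 3 per cell, per-cell testing is
# impossible) and homogeneity of variance (Bartlett across the nine
# cells). If both pass at alpha, a balanced fixed-effects two-way ANOVA
# with interaction is fitted and Tukey HSD is run on significant
# effects; otherwise each factor is tested marginally with
# Kruskal-Wallis (which cannot assess interactions) and significant
# factors are followed up with pairwise Wilcoxon rank-sum tests
# (Holm-adjusted). alpha = 0.05 a priori.

.TREATMENTS <- c("US+UCA", "US", "UCA")
.TEMPERATURES <- c("37", "39.5", "42")

#' Validate and normalize a replicate table
#'
#' Checks the closed factor sets (treatments US+UCA/US/UCA, temperatures
#' 37/39.5/42 degC) and returns a data.frame with `treatment` and
#' `temperature` as factors and a numeric `response`.
#'
#' @param records data.frame with columns `treatment`, `temperature`,
#'   `replicate`, `response`.
#' @return normalized data.frame.
#' @export
asReplicateTable <- function(records) {
  need <- c("treatment", "temperature", "response")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' must be a data.frame with columns treatment, temperature, response")
  tr <- as.character(records$treatment)
  te <- as.character(records$temperature)
  if (!all(tr %in% .TREATMENTS))
    stop("treatment levels must be among: ", paste(.TREATMENTS, collapse = ", "))
  if (!all(te %in% .TEMPERATURES))
    stop("temperature levels must be among: ", paste(.TEMPERATURES, collapse = ", "))
  if (!is.numeric(records$response) || any(!is.finite(records$response)))
    stop("'response' must be finite numeric")
  data.frame(treatment = factor(tr, levels = .TREATMENTS),
             temperature = factor(te, levels = .TEMPERATURES),
             replicate = if ("replicate" %in% names(records))
               records$replicate else seq_len(nrow(records)),
             response = as.numeric(records$response))
}

#' Check distributional assumptions and choose the branch
#'
#' Shapiro-Wilk on residuals from the cell (treatment x temperature)
#' means, Bartlett's test across the cells; the parametric branch is
#' taken iff both p-values exceed `alpha`.
#'
#' @param records a replicate table (see [asReplicateTable()]).
#' @param alpha significance level (default 0.05).
#' @return list with `shapiroP`, `bartlettP`, `branch`.
#' @export
checkAssumptions <- function(records, alpha = 0.05) {
  d <- asReplicateTable(records)
  cell <- interaction(d$treatment, d$temperature, drop = TRUE)
  if (nlevels(cell) < 2) stop("need at least 2 groups")
  if (any(tabulate(cell) < 3))
    stop("need at least 3 observations per cell")
  res <- d$response - ave(d$response, cell)
  if (all(abs(res) < .Machine$double.eps^0.5 * max(1, abs(d$response))))
    stop("degenerate data: responses constant within every cell")
  shapiroP <- shapiro.test(res)$p.value
  bartlettP <- bartlett.test(d$response, cell)$p.value
  list(shapiroP = shapiroP, bartlettP = bartlettP,
       branch = if (shapiroP > alpha && bartlettP > alpha)
         "parametric" else "nonparametric")
}

#' Two-way ANOVA with Tukey HSD follow-up
#'
#' Balanced fixed-effects two-way ANOVA with interaction
#' (`response ~ treatment * temperature`; balance makes the
#' sum-of-squares type immaterial). Tukey HSD tables are produced for
#' significant effects only. Unbalanced designs are refused.
#'
#' @param records a replicate table.
#' @param alpha significance level.
#' @return list with `pTreatment`, `pTemperature`, `pInteraction` and
#'   `tukey` (named list of data.frames for significant effects).
#' @export
twoWayAnova <- function(records, alpha = 0.05) {
  d <- asReplicateTable(records)
  cell <- interaction(d$treatment, d$temperature, drop = FALSE)
  counts <- tabulate(cell, nbins = nlevels(cell))
  if (length(unique(counts)) != 1L || counts[1] < 2)
    stop("unsupported design: need a balanced layout with n >= 2 per cell")
  fit <- aov(response ~ treatment * temperature, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  p <- tab[["Pr(>F)"]]
  names(p) <- rownames(tab)
  # zero residual variance drives F -> Inf; report p = 0 for effects
  # with positive sum of squares
  if (!is.na(tab["Residuals", "Sum Sq"]) &&
      tab["Residuals", "Sum Sq"] <= .Machine$double.eps * sum(tab[["Sum Sq"]])) {
    ss <- tab[["Sum Sq"]]
    p <- ifelse(ss > .Machine$double.eps * sum(ss), 0, NA_real_)[seq_along(p)]
    names(p) <- rownames(tab)
  }
  out <- list(pTreatment = unname(p["treatment"]),
              pTemperature = unname(p["temperature"]),
              pInteraction = unname(p["treatment:temperature"]))
  sig <- c("treatment", "temperature",
           "treatment:temperature")[c(out$pTreatment, out$pTemperature,
                                      out$pInteraction) < alpha]
  sig <- sig[!is.na(sig)]
  out$tukey <- list()
  if (length(sig) &&
      tab["Residuals", "Sum Sq"] > .Machine$double.eps * sum(tab[["Sum Sq"]])) {
    hsd <- TukeyHSD(fit, which = sig)
    out$tukey <- lapply(hsd, function(m) {
      df <- as.data.frame(m)
      df$comparison <- rownames(m)
      rownames(df) <- NULL
      df[, c("comparison", "diff", "lwr", "upr", "p adj")]
    })
  }
  out
}

#' Kruskal-Wallis tests with pairwise Wilcoxon follow-up
#'
#' Applies the Kruskal-Wallis rank-sum test separately to each factor
#' (data pooled over the other factor; interactions cannot be assessed
#' on this branch). Significant factors are followed up with pairwise
#' Wilcoxon rank-sum tests, Holm-adjusted.
#'
#' @param records a replicate table.
#' @param alpha significance level.
#' @return list with `pTreatment`, `pTemperature` and `wilcoxon` (named
#'   list of pairwise tables for significant factors).
#' @export
nonparametricTests <- function(records, alpha = 0.05) {
  d <- asReplicateTable(records)
  if (length(unique(d$response)) == 1L)
    stop("degenerate ranks: all responses are tied")
  pT <- kruskal.test(response ~ treatment, data = d)$p.value
  pK <- kruskal.test(response ~ temperature, data = d)$p.value
  out <- list(pTreatment = pT, pTemperature = pK, wilcoxon = list())
  for (fac in c("treatment", "temperature")) {
    pv <- if (fac == "treatment") pT else pK
    if (!is.na(pv) && pv < alpha) {
      pw <- suppressWarnings(
        pairwise.wilcox.test(d$response, d[[fac]],
                             p.adjust.method = "holm"))
      tab <- as.data.frame(as.table(pw$p.value))
      tab <- tab[!is.na(tab$Freq), ]
      names(tab) <- c("group1", "group2", "pAdjusted")
      rownames(tab) <- NULL
      out$wilcoxon[[fac]] <- tab
    }
  }
  out
}

#' Run the full statistical decision tree
#'
#' Chains [checkAssumptions()], then either [twoWayAnova()] (parametric
#' branch) or [nonparametricTests()] (nonparametric branch; interaction
#' reported as not assessed), recording every decision.
#'
#' @param records a replicate table.
#' @param alpha significance level (0.05 a priori).
#' @return a [StatReport-class].
#' @examples
#' tab <- generateExperiment(groupSpecPreset("transfection"), seed = 1)
#' runDecisionTree(tab)
#' @export
runDecisionTree <- function(records, alpha = 0.05) {
  chk <- checkAssumptions(records, alpha)
  if (chk$branch == "parametric") {
    a <- twoWayAnova(records, alpha)
    new("StatReport", shapiroP = chk$shapiroP, bartlettP = chk$bartlettP,
        branch = "parametric", pTreatment = a$pTreatment,
        pTemperature = a$pTemperature, pInteraction = a$pInteraction,
        posthoc = a$tukey, alpha = alpha)
  } else {
    np <- nonparametricTests(records, alpha)
    new("StatReport", shapiroP = chk$shapiroP, bartlettP = chk$bartlettP,
        branch = "nonparametric", pTreatment = np$pTreatment,
        pTemperature = np$pTemperature, pInteraction = NA_real_,
        posthoc = np$wilcoxon, alpha = alpha)
  }
}
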