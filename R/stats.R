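## Cohort-level statistics: nested linear/quadratic age models with ANOVA
## selection, FDR across the nine regional outcomes, repeatability and
## correlation summaries, and the compartment arithmetic used to interpret
## water-fraction changes.

#' Fit the nested linear and quadratic age models for one outcome
#'
#' Ordinary least squares of
#' LM: wf = b0 + b1 age + b2 sex + b3 volume and
#' QM: wf = b0 + b1 age + b2 age^2 + b3 sex + b4 volume
#' on one (ROI, water fraction) outcome of a regional table.
#'
#' @param table regional table (columns age_years, sex, normalized_volume
#'   and the water-fraction columns; long format with a roi column).
#' @param roi which ROI ("wm", "cortex", "deepgm").
#' @param wf which outcome ("mwf", "iewf", "csff").
#' @return list with elements \code{lm}, \code{qm} (both \code{lm} fits),
#'   \code{roi}, \code{wf}, \code{n}.
#' @export
fitLmQm <- function(table, roi, wf = c("mwf", "iewf", "csff")) {
  wf <- match.arg(wf)
  d <- table[table$roi == roi, , drop = FALSE]
  if (nrow(d) < 6L) stop("need at least 6 subjects for the 5-parameter QM")
  if (anyNA(d[, c("age_years", "sex", "normalized_volume", wf)]))
    stop("missing covariate or outcome values")
  if (length(unique(d$sex)) < 2L)
    stop("design is rank-deficient: column 'sex' has a single level")
  d$.y <- d[[wf]]
  lmFit <- stats::lm(.y ~ age_years + sex + normalized_volume, data = d)
  qmFit <- stats::lm(.y ~ age_years + I(age_years^2) + sex +
                       normalized_volume, data = d)
  for (f in list(lmFit, qmFit))
    if (anyNA(stats::coef(f))) {
      bad <- names(stats::coef(f))[is.na(stats::coef(f))][1L]
      stop("design is rank-deficient: column '", bad, "'")
    }
  list(lm = lmFit, qm = qmFit, roi = roi, wf = wf, n = nrow(d))
}

#' Select between the linear and quadratic age models
#'
#' Nested-model ANOVA F-test for the age-squared term: the quadratic model
#' is selected iff the F-test p-value is below \code{alpha}; otherwise the
#' most parsimonious (linear) model is kept. The degenerate case of a
#' perfect fit under both models (both residual sums of squares ~0, F
#' undefined) resolves to the linear model. The reported age p-value is
#' the ANOVA p of the age-squared term under QM and the Wald p of the age
#' coefficient under LM; all three candidate p-values are returned.
#'
#' @param fits result of \code{\link{fitLmQm}} (the fits must share data).
#' @param alpha selection level (default 0.05).
#' @return list with \code{model} ("LM" or "QM"), \code{coefficients}
#'   (of the selected model, with standard errors), \code{anovaF},
#'   \code{anovaP}, \code{agePLm}, \code{agePQmWald}, \code{ageP}
#'   (the selected model's age p-value), \code{n}, \code{roi}, \code{wf}.
#' @export
selectModel <- function(fits, alpha = 0.05) {
  lmFit <- fits$lm; qmFit <- fits$qm
  if (!isTRUE(all.equal(stats::model.response(stats::model.frame(lmFit)),
                        stats::model.response(stats::model.frame(qmFit)))))
    stop("LM and QM fits do not share the same data")
  rssL <- sum(stats::resid(lmFit)^2)
  rssQ <- sum(stats::resid(qmFit)^2)
  n <- fits$n
  dfQ <- n - length(stats::coef(qmFit))
  tiny <- .Machine$double.eps * max(1, sum(lmFit$model$.y^2))
  if (rssQ < tiny && rssL < tiny) {
    ## both models interpolate exactly: parsimony keeps the linear model
    F <- NA_real_; p <- NA_real_
    useQm <- FALSE
  } else if (rssQ < tiny) {
    ## only the quadratic model is exact: F is formally infinite
    F <- Inf; p <- 0
    useQm <- TRUE
  } else {
    F <- (rssL - rssQ) / (rssQ / dfQ)
    p <- stats::pf(F, 1, dfQ, lower.tail = FALSE)
    useQm <- !is.na(p) && p < alpha
  }
  sel <- if (useQm) qmFit else lmFit
  cf <- summary(sel)$coefficients
  agePLm <- summary(lmFit)$coefficients["age_years", "Pr(>|t|)"]
  agePQmWald <- summary(qmFit)$coefficients["I(age_years^2)", "Pr(>|t|)"]
  list(model = if (useQm) "QM" else "LM", coefficients = cf,
       anovaF = F, anovaP = p, agePLm = agePLm, agePQmWald = agePQmWald,
       ageP = if (useQm) p else agePLm,
       n = n, roi = fits$roi, wf = fits$wf)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values for the family of age p-values (one per
#' regional outcome). Order-preserving, elementwise >= the raw values.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values.
#' @export
fdrAdjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Bland-Altman repeatability summary
#'
#' Bias (mean of scan1 - scan2), sd of the differences and 95\% limits of
#' agreement bias +/- 1.96 sd.
#'
#' @param scan1,scan2 paired repeated measurements (length >= 2).
#' @return list with \code{bias}, \code{sd}, \code{loa} (numeric(2)),
#'   \code{n}.
#' @export
blandAltman <- function(scan1, scan2) {
  if (length(scan1) != length(scan2)) stop("pairs must have equal length")
  if (length(scan1) < 2L) stop("need at least 2 pairs")
  d <- scan1 - scan2
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       n = length(d))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged), with a two-sided
#' p-value from the t approximation t = rho sqrt((n-2)/(1-rho^2)). With
#' |rho| = 1 the p-value is 0; zero variance in either rank vector yields
#' an NA correlation with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance in ranks; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
       n = n)
}

#' CSF volume fraction from CSFF and tissue water content
#'
#' V_CSF = water content x CSFF: converts the CSF fraction of the water
#' signal into a CSF fraction of tissue volume, given the tissue's water
#' content (g water per mL tissue).
#'
#' @param csff CSF water fraction in [0, 1].
#' @param waterContent tissue water content in [0, 1] (g/mL).
#' @param percent if TRUE return percent rounded to 1 decimal (the
#'   reporting convention); otherwise the full-precision fraction.
#' @return V_CSF as fraction or formatted percent.
#' @export
csffToVcsf <- function(csff, waterContent, percent = FALSE) {
  if (any(csff < 0 | csff > 1) || any(waterContent < 0 | waterContent > 1))
    stop("csff and waterContent must lie in [0, 1]")
  v <- waterContent * csff
  if (percent) round(100 * v, 1) else v
}

#' Water-fraction shift from a compartmental water-content change
#'
#' Given initial compartment water contents (myelin water,
#' intra/extra-cellular water, CSF; g/mL) and a new intra/extra-cellular
#' content, recomputes the three fractions and returns the change in each,
#' in percentage points (full precision; round to 1 decimal for
#' reporting). Illustrates that a loss of intra/extra-cellular water alone
#' changes CSFF only via the shrinking denominator.
#'
#' @param contents numeric(3): initial (MW, IEW, CSF) water contents, g/mL.
#' @param newIew replacement intra/extra-cellular content, g/mL.
#' @return named numeric(3): deltaMwf, deltaIewf, deltaCsff in percentage
#'   points.
#' @export
compartmentShift <- function(contents, newIew) {
  stopifnot(length(contents) == 3L)
  if (any(contents < 0) || newIew < 0) stop("contents must be >= 0")
  newContents <- c(contents[1L], newIew, contents[3L])
  if (sum(newContents) == 0) stop("new total water content is 0")
  if (sum(contents) == 0) stop("initial total water content is 0")
  old <- contents / sum(contents)
  new <- newContents / sum(newContents)
  d <- 100 * (new - old)
  c(deltaMwf = d[1L], deltaIewf = d[2L], deltaCsff = d[3L])
}

#' Age-association report across all nine regional outcomes
#'
#' Runs \code{\link{fitLmQm}} and \code{\link{selectModel}} for every
#' (ROI, water fraction) pair and adjusts the nine selected-model age
#' p-values by Benjamini-Hochberg FDR. The FDR family is exactly these
#' nine p-values; the raw LM-Wald and QM-Wald alternatives are reported
#' alongside.
#'
#' @param table regional table as produced by \code{\link{simulateCohort}}.
#' @param alpha model-selection level.
#' @return data.frame with one row per outcome: roi, wf, model, n, anova_f,
#'   anova_p, age_p_lm, age_p_qm_wald, age_p, age_p_fdr.
#' @export
ageAssociationReport <- function(table, alpha = 0.05) {
  grid <- expand.grid(roi = .TISSUE_ROIS, wf = .WF_NAMES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- selectModel(fitLmQm(table, grid$roi[i], grid$wf[i]), alpha)
    data.frame(roi = sel$roi, wf = sel$wf, model = sel$model, n = sel$n,
               anova_f = sel$anovaF, anova_p = sel$anovaP,
               age_p_lm = sel$agePLm, age_p_qm_wald = sel$agePQmWald,
               age_p = sel$ageP)
  })
  rep <- do.call(rbind, rows)
  rep$age_p_fdr <- fdrAdjust(rep$age_p)
  rep
}
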