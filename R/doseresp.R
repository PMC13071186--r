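## Probit concentration-mortality analysis: binomial-probit ML fit on log10
## dose, Pearson goodness of fit, and LC_p with delta-method confidence
## limits on the log10 scale.

nonEstimableError <- function(msg) {
  stop(structure(class = c("ethotox_nonestimable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Fit a probit concentration-mortality model
#'
#' Maximum-likelihood binomial regression of mortality on log10 dose with a
#' probit link: probit(p) = a + b * log10(dose). With zero control mortality
#' this is the standard GLM fit; with \code{controlMortality > 0} the
#' Abbott-corrected response p = c + (1 - c) * Phi(a + b x) is fitted by
#' direct likelihood maximisation. Dose groups with 0% or 100% kill enter
#' through the exact binomial likelihood (no empirical-probit transform).
#' Pearson chi-square goodness of fit is reported on #doses - 2 df.
#'
#' @param dose concentrations (> 0), e.g. ppm.
#' @param n number exposed per concentration.
#' @param dead number dead per concentration.
#' @param controlMortality natural response proportion in [0, 1) (default 0).
#' @return A \code{ProbitFit}.
#' @examples
#' doses <- c(156.25, 312.5, 625, 1250, 2500, 5000, 10000)
#' dead <- c(1, 3, 5, 11, 17, 25, 29)
#' fit <- fitProbit(doses, rep(30, 7), dead)
#' lc(fit, 0.5)
#' @export
fitProbit <- function(dose, n, dead, controlMortality = 0) {
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(dead < 0 | dead > n)) stop("need 0 <= dead <= n", call. = FALSE)
  if (length(unique(dose)) < 2)
    stop("need at least 2 distinct doses", call. = FALSE)
  if (controlMortality < 0 || controlMortality >= 1)
    stop("controlMortality must lie in [0, 1)", call. = FALSE)
  if (!any(dead > 0)) nonEstimableError("no mortality at any dose")
  if (!any(dead < n)) nonEstimableError("complete kill at every dose")
  x <- log10(dose)
  dat <- data.frame(dose = dose, n = n, dead = dead, logDose = x)

  if (controlMortality == 0) {
    fit <- suppressWarnings(
      glm(cbind(dead, n - dead) ~ logDose, family = binomial(link = "probit"),
          data = dat))
    if (!fit$converged || abs(coef(fit)[2]) > 1e3)
      nonEstimableError("probit fit did not converge (separation?)")
    ab <- unname(coef(fit))
    V <- unname(vcov(fit))
    pHat <- pnorm(ab[1] + ab[2] * x)
  } else {
    cc <- controlMortality
    nll <- function(theta) {
      p <- cc + (1 - cc) * pnorm(theta[1] + theta[2] * x)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(dead * log(p) + (n - dead) * log(1 - p))
    }
    start <- unname(coef(suppressWarnings(
      glm(cbind(dead, n - dead) ~ logDose,
          family = binomial(link = "probit"), data = dat))))
    opt <- optim(start, nll, method = "BFGS", hessian = TRUE)
    if (opt$convergence != 0)
      nonEstimableError("Abbott-corrected probit fit did not converge")
    ab <- opt$par
    V <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 2, 2))
    pHat <- cc + (1 - cc) * pnorm(ab[1] + ab[2] * x)
  }
  expDead <- n * pHat
  denom <- n * pHat * (1 - pHat)
  ok <- denom > 0
  chisq <- sum((dead[ok] - expDead[ok])^2 / denom[ok])
  new("ProbitFit", coef = c(a = ab[1], b = ab[2]), vcov = V,
      chisq = chisq, df = max(length(unique(dose)) - 2, 0), data = dat,
      controlMortality = controlMortality)
}

#' Construct a probit line through two lethal-concentration anchors
#'
#' Solves the intercept and slope of probit(p) = a + b * log10(dose) exactly
#' through two (p, LC_p) pairs; useful for consistency checks among reported
#' LC values. The covariance is zero (a deterministic line).
#'
#' @param p1,p2 mortality fractions in (0, 1).
#' @param lc1,lc2 corresponding concentrations.
#' @return A \code{ProbitFit}.
#' @examples
#' line <- probitFromLC(0.10, 395, 0.50, 1992)
#' lc(line, 0.30)$lc
#' @export
probitFromLC <- function(p1, lc1, p2, lc2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, lc1 > 0, lc2 > 0, p1 != p2)
  x1 <- log10(lc1); x2 <- log10(lc2)
  b <- (qnorm(p2) - qnorm(p1)) / (x2 - x1)
  a <- qnorm(p1) - b * x1
  new("ProbitFit", coef = c(a = a, b = b), vcov = matrix(0, 2, 2),
      chisq = NA_real_, df = 0,
      data = data.frame(dose = c(lc1, lc2), n = NA, dead = NA,
                        logDose = c(x1, x2)),
      controlMortality = 0)
}

#' Lethal concentration LC_p with confidence limits
#'
#' LC_p = 10^((probit(p) - a) / b). Confidence limits are delta-method on the
#' log10 scale: var(x_p) = g' V g with g = (-1/b, -x_p/b), then
#' 10^(x_p +/- z * se).
#'
#' @param fit a \code{ProbitFit}.
#' @param p mortality fraction in (0, 1); vectorised.
#' @param level confidence level (default 0.95).
#' @return data.frame with p, lc, lower, upper (concentration units of the
#'   fit).
#' @export
lc <- function(fit, p, level = 0.95) {
  stopifnot(is(fit, "ProbitFit"))
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  a <- fit@coef[1]; b <- fit@coef[2]
  if (b <= 0) stop("slope must be positive for LC estimation", call. = FALSE)
  xp <- (qnorm(p) - a) / b
  z <- qnorm(1 - (1 - level) / 2)
  se <- vapply(xp, function(x) {
    g <- c(-1 / b, -x / b)
    v <- drop(t(g) %*% fit@vcov %*% g)
    if (is.na(v) || v < 0) NA_real_ else sqrt(v)
  }, numeric(1))
  data.frame(p = p, lc = 10^xp,
             lower = 10^(xp - z * se), upper = 10^(xp + z * se))
}

#' Log-likelihood of a probit fit at given parameters
#'
#' Exact binomial log-likelihood (up to the combinatorial constant) of the
#' fitted data at \code{(a, b)}; used e.g. to confirm the optimum against a
#' parameter-grid search.
#'
#' @param fit a \code{ProbitFit}.
#' @param a,b intercept and slope; default the fitted values.
#' @return Log-likelihood value.
#' @export
probitLogLik <- function(fit, a = fit@coef[1], b = fit@coef[2]) {
  stopifnot(is(fit, "ProbitFit"))
  d <- fit@data
  cc <- fit@controlMortality
  p <- cc + (1 - cc) * pnorm(a + b * d$logDose)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(d$dead * log(p) + (d$n - d$dead) * log(1 - p))
}

#' Read a bioassay CSV (dose, n, dead)
#'
#' @param path 3-column CSV with headers dose, n, dead.
#' @return data.frame.
#' @export
readBioassay <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose", "n", "dead")
  if (!all(need %in% names(d)))
    stop("bioassay CSV needs columns dose, n, dead", call. = FALSE)
  d[, need]
}

#' Write a probit fit summary as JSON
#'
#' Coefficients, covariance, goodness of fit and an LC table.
#'
#' @param fit a \code{ProbitFit}.
#' @param path output JSON path.
#' @param p LC fractions to tabulate (default 0.10, 0.30, 0.50).
#' @return Invisibly, \code{path}.
#' @export
writeProbitSummary <- function(fit, path, p = c(0.10, 0.30, 0.50)) {
  tab <- lc(fit, p)
  jsonlite::write_json(
    list(a = unname(fit@coef[1]), b = unname(fit@coef[2]),
         vcov = fit@vcov, chisq = fit@chisq, df = fit@df,
         control_mortality = fit@controlMortality,
         lc = tab),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
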