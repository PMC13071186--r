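## Nonparametric comparison chain for behavioural features: Shapiro-Wilk
## normality gate, Kruskal-Wallis omnibus test, Dunn post hoc z tests with
## Holm's step-down familywise correction (within one feature).

#' Shapiro-Wilk normality gate
#'
#' Tests each group's sample for normality; the analysis chain switches to
#' nonparametric tests when any group rejects at \code{alpha}. Constant
#' (degenerate) samples cannot be tested and are flagged as non-normal.
#'
#' @param samples named list of numeric vectors, one per group (each n >= 3).
#' @param alpha rejection level (default 0.05).
#' @return List: \code{shapiroP} (named vector, NA for degenerate groups),
#'   \code{degenerate} (logical vector), \code{useNonparametric} (flag).
#' @export
normalityGate <- function(samples, alpha = 0.05) {
  if (any(vapply(samples, length, integer(1)) < 3))
    stop("each group needs n >= 3", call. = FALSE)
  pv <- vapply(samples, function(x) {
    if (length(unique(x)) == 1) return(NA_real_)
    shapiro.test(x)$p.value
  }, numeric(1))
  degen <- is.na(pv)
  list(shapiroP = pv, degenerate = degen,
       useNonparametric = any(degen) || any(pv < alpha, na.rm = TRUE))
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction, p from the chi-square distribution on
#' k - 1 df (delegated to \code{stats::kruskal.test}). Identical values in
#' every observation give H = 0, p = 1.
#'
#' @param samples list of numeric vectors, one per group.
#' @return List: H, p, df.
#' @export
kruskalWallis <- function(samples) {
  if (length(samples) < 2) stop("need >= 2 groups", call. = FALSE)
  if (sum(lengths(samples)) < 5) stop("need total n >= 5", call. = FALSE)
  pooled <- unlist(samples, use.names = FALSE)
  if (length(unique(pooled)) == 1)
    return(list(H = 0, p = 1, df = length(samples) - 1))
  kt <- kruskal.test(samples)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn post hoc test with Holm correction
#'
#' Pairwise z statistics from the pooled ranks with tie correction:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)),
#' T = sum(t^3 - t) / (12 (N - 1)) over tie groups; two-sided p values,
#' Holm's step-down adjustment over all pairwise comparisons within the
#' feature.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param method p adjustment method (default \code{"holm"}).
#' @return data.frame: group1, group2, z, p, p_adj.
#' @export
dunnHolm <- function(samples, method = "holm") {
  k <- length(samples)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("g", seq_len(k))
  ns <- lengths(samples)
  pooled <- unlist(samples, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  grp <- rep(names(samples), ns)
  rbar <- tapply(rk, grp, mean)[names(samples)]
  ties <- table(pooled)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(samples), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    sePool <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / ns[i1] + 1 / ns[i2]))
    z[j] <- if (sePool > 0) (rbar[i1] - rbar[i2]) / sePool else 0
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = p.adjust(p, method = method), row.names = NULL)
}

#' Full comparison chain for one feature
#'
#' Shapiro-Wilk gate, Kruskal-Wallis omnibus, and Dunn + Holm post hoc table.
#'
#' @param values numeric feature values.
#' @param groups group labels (same length).
#' @param alpha gate level (default 0.05).
#' @return List of class \code{"groupComparison"}: gate, kw, dunn.
#' @export
groupComparison <- function(values, groups, alpha = 0.05) {
  samples <- split(values, groups)
  gate <- normalityGate(samples, alpha)
  kw <- kruskalWallis(samples)
  dn <- dunnHolm(samples)
  structure(list(gate = gate, kw = kw, dunn = dn), class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat("Shapiro-Wilk p:",
      paste(sprintf("%s=%.3g", names(x$gate$shapiroP), x$gate$shapiroP),
            collapse = ", "),
      if (x$gate$useNonparametric) "-> nonparametric chain\n" else "\n")
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.3g\n",
              x$kw$H, as.integer(x$kw$df), x$kw$p))
  print(x$dunn, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare all features of a feature table across groups
#'
#' Runs \code{\link{groupComparison}} per feature and returns a tidy long
#' table (feature, test, statistic, p, comparison, adjusted p).
#'
#' @param tbl feature table (one row per individual).
#' @param features feature column names (default
#'   \code{\link{classifierFeatures}}).
#' @param group grouping column name (default \code{"group"}).
#' @return data.frame in long format.
#' @export
compareFeatures <- function(tbl, features = classifierFeatures(),
                            group = "group") {
  out <- lapply(features, function(f) {
    gc <- groupComparison(tbl[[f]], tbl[[group]])
    kwRow <- data.frame(feature = f, test = "kruskal_wallis",
                        statistic = gc$kw$H, p = gc$kw$p,
                        comparison = "omnibus", p_adj = NA_real_)
    dunnRows <- data.frame(feature = f, test = "dunn",
                           statistic = gc$dunn$z, p = gc$dunn$p,
                           comparison = paste(gc$dunn$group1, "vs",
                                              gc$dunn$group2),
                           p_adj = gc$dunn$p_adj)
    rbind(kwRow, dunnRows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
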