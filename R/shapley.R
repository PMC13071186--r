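## Exact Shapley feature attributions by full coalition enumeration.
##
## Value function: v(S) = mean over background rows of f(hybrid), where the
## hybrid takes the explained sample's values on features in S and the
## background row's values elsewhere. phi_i is the Shapley value of feature i
## under v; by construction sum(phi) = f-mean(full sample) - v(empty set)
## (efficiency), up to floating point.

#' Exact Shapley attributions
#'
#' Enumerates all 2^d feature coalitions (no sampling), evaluating the model
#' on background-completed hybrids; feasible for d <= 15. The model function
#' must accept a numeric matrix and return one numeric output per row (a
#' probability-like score for classifiers).
#'
#' @param predictFun function(matrix) -> numeric vector.
#' @param x samples to explain: numeric vector (one sample) or matrix.
#' @param background background matrix (non-empty) defining the baseline.
#' @param chunkRows cap on hybrid rows evaluated per call block (memory
#'   control; default 262144).
#' @return List of class \code{"shapExplanation"}: \code{phi} (samples x
#'   features), \code{baseline} (v of the empty coalition), \code{prediction}
#'   (v of the full coalition per sample).
#' @examples
#' f <- function(m) 2 * m[, 1] - 3 * m[, 2]
#' bg <- matrix(rnorm(20), 10, 2)
#' ex <- exactShapley(f, c(1, 1), bg)
#' rowSums(ex$phi) - (ex$prediction - ex$baseline)  # efficiency ~ 0
#' @export
exactShapley <- function(predictFun, x, background, chunkRows = 262144) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("background must be non-empty", call. = FALSE)
  d <- ncol(x)
  if (d != ncol(background))
    stop("x and background must have the same number of features",
         call. = FALSE)
  if (d > 15)
    stop("exact enumeration supports at most 15 features; ",
         "use a sampling approximation for wider inputs", call. = FALSE)
  nB <- nrow(background)
  nMask <- bitwShiftL(1L, d)
  masks <- 0:(nMask - 1)
  ## membership matrix: bit j of each mask
  member <- matrix(FALSE, nMask, d)
  for (j in seq_len(d))
    member[, j] <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L

  sizes <- rowSums(member)
  w <- exp(lfactorial(sizes) + lfactorial(d - 1 - sizes) - lfactorial(d))

  masksPerChunk <- max(1L, chunkRows %/% nB)
  phi <- matrix(0, nrow(x), d,
                dimnames = list(NULL, colnames(x)))
  baseline <- NA_real_
  prediction <- numeric(nrow(x))
  for (si in seq_len(nrow(x))) {
    v <- numeric(nMask)
    for (start in seq(1L, nMask, by = masksPerChunk)) {
      idx <- start:min(start + masksPerChunk - 1L, nMask)
      big <- background[rep(seq_len(nB), times = length(idx)), , drop = FALSE]
      mem <- member[idx, , drop = FALSE]
      for (j in seq_len(d)) {
        rows <- rep(mem[, j], each = nB)
        if (any(rows)) big[rows, j] <- x[si, j]
      }
      preds <- predictFun(big)
      v[idx] <- colMeans(matrix(preds, nrow = nB))
    }
    for (j in seq_len(d)) {
      bit <- bitwShiftL(1L, j - 1L)
      without <- which(!member[, j])
      phi[si, j] <- sum(w[without] * (v[without + bit] - v[without]))
    }
    baseline <- v[1]
    prediction[si] <- v[nMask]
  }
  structure(list(phi = phi, baseline = baseline, prediction = prediction),
            class = "shapExplanation")
}

#' @export
print.shapExplanation <- function(x, ...) {
  cat(sprintf("Exact Shapley explanation: %d sample(s), %d features, baseline %.4f\n",
              nrow(x$phi), ncol(x$phi), x$baseline))
  print(head(x$phi, 3), digits = 3)
  invisible(x)
}
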