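# Information-theoretic primitives. All measures are computed in bits
# (log base 2) on the non-missing (complete-case) part of their inputs;
# missing values never form a probability mass.

# empirical class counts of the non-missing values of x
value_counts <- function(x) {
  v <- x[!is.na(x)]
  if (!length(v)) return(integer(0))
  table(as.character(v))
}

#' Shannon entropy of a value vector
#'
#' \eqn{H(X) = -\sum_c p_c \log_2 p_c} over the distinct non-missing values
#' of `x`, with empirical probabilities. Missing values are excluded; an
#' empty or all-missing vector has entropy 0. Entropy is zero iff the vector
#' holds at most one distinct non-missing value.
#'
#' @param x vector (categorical or numeric), `NA` marking missing.
#' @return entropy in bits (non-negative scalar).
#' @export
entropy <- function(x) {
  cnt <- value_counts(x)
  if (length(cnt) <= 1) return(0)
  p <- as.numeric(cnt) / sum(cnt)
  -sum(p * log2(p))
}

#' Information content of a discrete vector
#'
#' \eqn{IC(X) = -\sum_i \log_2 p(x_i)} summed over the non-missing
#' *elements* (not distinct values), so that \eqn{IC(X) = n\,H(X)} where
#' `n` is the number of non-missing elements.
#'
#' @param x vector treated as categorical, `NA` marking missing.
#' @return information content in bits.
#' @export
information_content_discrete <- function(x) {
  cnt <- value_counts(x)
  if (!length(cnt)) return(0)
  n <- sum(cnt)
  p <- as.numeric(cnt) / n
  -sum(as.numeric(cnt) * log2(p))
}

#' Information content of a continuous vector via adaptive KDE
#'
#' Estimates the density at each observation with a Gaussian kernel density
#' estimator using adaptive (Abramson-style) per-point bandwidths seeded by
#' a Silverman pilot bandwidth, and returns
#' \eqn{-\sum_i \log_2 \hat p(x_i)}. Densities are floored at `1e-12`
#' before taking logs.
#'
#' @param x numeric vector with at least 5 non-missing values; must not be
#'   constant.
#' @param adaptivity Abramson sensitivity exponent alpha (default 0.5);
#'   0 gives a fixed-bandwidth estimator.
#' @return information content in bits.
#' @export
information_content_continuous <- function(x, adaptivity = 0.5) {
  v <- parse_num(x)
  v <- v[!is.na(v)]
  if (length(v) < 5) {
    stop("continuous IC requires >= 5 non-missing values; ",
         "use information_content_discrete() for small samples",
         call. = FALSE)
  }
  s <- stats::sd(v)
  iqr <- stats::IQR(v)
  if (s == 0) {
    stop("degenerate (constant) numeric vector: density is not estimable",
         call. = FALSE)
  }
  n <- length(v)
  spread <- min(s, if (iqr > 0) iqr / 1.34 else s)
  h0 <- 0.9 * spread * n^(-1 / 5)
  # pilot (fixed-bandwidth, leave-in) density at the observations
  d <- outer(v, v, "-")
  pilot <- rowMeans(stats::dnorm(d / h0)) / h0
  pilot <- pmax(pilot, 1e-300)
  g <- exp(mean(log(pilot)))
  lambda <- (pilot / g)^(-adaptivity)
  # Abramson: bandwidth attached to each data point j
  hj <- h0 * lambda
  dens <- rowMeans(stats::dnorm(sweep(d, 2, hj, "/")) /
                     matrix(hj, n, n, byrow = TRUE))
  dens <- pmax(dens, 1e-12)
  -sum(log2(dens))
}

# equal-frequency discretisation of a numeric vector into <= bins classes
equal_freq_bin <- function(v, bins) {
  qs <- stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7)
  brk <- unique(qs)
  if (length(brk) < 2) return(rep(1L, length(v)))
  as.integer(cut(v, breaks = brk, include.lowest = TRUE))
}

# treat as continuous (needs discretisation) if numeric-valued with more
# distinct values than the bin budget
prepare_discrete <- function(x, bins) {
  if (is.numeric(x) && length(unique(x[!is.na(x)])) > bins) {
    out <- rep(NA_integer_, length(x))
    obs <- !is.na(x)
    out[obs] <- equal_freq_bin(x[obs], bins)
    return(out)
  }
  x
}

#' Mutual information of two vectors
#'
#' Plug-in mutual information from the joint contingency table of the
#' complete cases (both values non-missing), in bits. Continuous inputs
#' (numeric vectors with more distinct values than the bin budget) are
#' first discretised into equal-frequency bins; the number of bins is
#' `min(bins, floor(sqrt(n)))` where `n` is the number of complete cases.
#' This is a declared estimator choice, not an exact quantity, for
#' continuous data.
#'
#' @param x,y vectors of equal length, `NA` marking missing.
#' @param bins maximum bin count for continuous inputs (default 10).
#' @return mutual information in bits (non-negative up to float noise).
#' @export
mutual_information <- function(x, y, bins = 10) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  cc <- !is.na(x) & !is.na(y)
  n <- sum(cc)
  if (n == 0) stop("no complete cases", call. = FALSE)
  b <- max(2L, min(bins, floor(sqrt(n))))
  xv <- prepare_discrete(x[cc], b)
  yv <- prepare_discrete(y[cc], b)
  tab <- table(as.character(xv), as.character(yv))
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (pxy[i, j] > 0) {
        mi <- mi + pxy[i, j] * log2(pxy[i, j] / (px[i] * py[j]))
      }
    }
  }
  max(mi, 0)
}

#' Mutual information content
#'
#' Mutual information of `x` and `y` multiplied by the number of complete
#' cases: \eqn{MIC = MI(X;Y) \times n}. Comparable against the discrete
#' information content of an input (also an element-wise sum) to detect
#' information loss during variable merging: an input's information is fully
#' retained in a merged variable iff its MIC with the merged variable equals
#' its IC.
#'
#' @inheritParams mutual_information
#' @return mutual information content in bits.
#' @export
mutual_information_content <- function(x, y, bins = 10) {
  n <- sum(!is.na(x) & !is.na(y))
  mutual_information(x, y, bins = bins) * n
}

#' Symmetric uncertainty
#'
#' \eqn{SU(X,Y) = 2\,(H(X)+H(Y)-H(X,Y)) / (H(X)+H(Y))}, computed on the
#' complete cases, where \eqn{H(X,Y)} is the entropy of the paired value
#' vector. Lies in \[0, 1\]: 1 means fully redundant, 0 independent. If
#' \eqn{H(X)+H(Y) = 0} the result is 0 by convention.
#'
#' @param x,y vectors of equal length, `NA` marking missing.
#' @return symmetric uncertainty in \[0, 1\].
#' @export
symmetric_uncertainty <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  cc <- !is.na(x) & !is.na(y)
  if (!sum(cc)) stop("no complete cases", call. = FALSE)
  xv <- as.character(x[cc])
  yv <- as.character(y[cc])
  hx <- entropy(xv)
  hy <- entropy(yv)
  if (hx + hy == 0) return(0)
  hxy <- entropy(paste(xv, yv, sep = "\x1f"))
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  min(max(su, 0), 1)
}

#' Min-max normalisation
#'
#' Rescales the non-missing values of a numeric vector to \[0, 1\]:
#' \eqn{X_{norm} = (X - \min X) / (\max X - \min X)}. Missing values are
#' preserved in place.
#'
#' @param x numeric vector (or character parseable as numbers).
#' @param name optional variable name used in error messages.
#' @return numeric vector in \[0, 1\] with `NA` preserved.
#' @export
min_max_normalise <- function(x, name = deparse(substitute(x))) {
  v <- parse_num(x)
  if (any(is.na(v) & !is.na(x))) {
    stop(sprintf("'%s' contains non-numeric values", name), call. = FALSE)
  }
  obs <- v[!is.na(v)]
  if (!length(obs)) return(v)
  r <- range(obs)
  if (r[1] == r[2]) {
    stop(sprintf("cannot min-max normalise constant variable '%s'", name),
         call. = FALSE)
  }
  (v - r[1]) / (r[2] - r[1])
}
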