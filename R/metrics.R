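#' @include AllClasses.R
NULL

.as_fraction_vector <- function(x) {
  if (is(x, "MixtureSpec")) unname(x@fractions) else as.numeric(x)
}

.check_pair <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("truth and prediction must have equal length")
  if (length(y) < 1) stop("empty fraction vectors")
  list(y = y, yhat = yhat)
}

#' Root mean square error between fraction vectors
#'
#' `RMSE(y, yhat) = sqrt(sum((yhat_i - y_i)^2) / n)`.
#'
#' @param y Ground-truth fraction vector (or [MixtureSpec-class]).
#' @param yhat Predicted fraction vector (or [MixtureSpec-class]).
#' @return Non-negative numeric; 0 iff the vectors are identical.
#' @export
rmse <- function(y, yhat) {
  p <- .check_pair(.as_fraction_vector(y), .as_fraction_vector(yhat))
  sqrt(mean((p$yhat - p$y)^2))
}

# population (1/n) moments shared by both concordance coefficients
.pop_moments <- function(y, yhat) {
  n <- length(y)
  mu_y <- mean(y); mu_h <- mean(yhat)
  list(mu_y = mu_y, mu_h = mu_h,
       var_y = sum((y - mu_y)^2) / n,
       var_h = sum((yhat - mu_h)^2) / n,
       cov = sum((y - mu_y) * (yhat - mu_h)) / n)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC(y, yhat) = 2 cov(y, yhat) / (var_y + var_yhat + (mu_y - mu_yhat)^2)`
#' with population (1/n) moments. Measures agreement along the identity
#' line.
#'
#' Degenerate cases: both vectors constant and equal gives 1; a zero
#' denominator with unequal vectors gives 0.
#'
#' @inheritParams rmse
#' @param sample_moments Use (n-1) denominators instead of the default
#'   population moments.
#' @return Numeric in `[-1, 1]`.
#' @export
linCCC <- function(y, yhat, sample_moments = FALSE) {
  p <- .check_pair(.as_fraction_vector(y), .as_fraction_vector(yhat))
  m <- .pop_moments(p$y, p$yhat)
  adj <- if (sample_moments) length(p$y) / (length(p$y) - 1) else 1
  denom <- adj * (m$var_y + m$var_h) + (m$mu_y - m$mu_h)^2
  if (denom == 0) return(if (identical(p$y, p$yhat)) 1 else 0)
  2 * adj * m$cov / denom
}

#' Modified concordance correlation coefficient
#'
#' Lin's CCC with the mean-shift penalty `(mu_y - mu_yhat)^2` replaced by
#' the full mean squared error `sum((yhat_i - y_i)^2) / n`. Because the two
#' means are (nearly) equal whenever both vectors lie on the simplex, the
#' plain CCC under-penalises within-sample errors; the modified form
#' restores that penalty. Since `MSE >= (mu_y - mu_yhat)^2`, the modified
#' coefficient never exceeds the plain one when the covariance is
#' positive, and equals 1 iff `y == yhat` (non-constant).
#'
#' @inheritParams linCCC
#' @return Numeric in `[-1, 1]`.
#' @export
modifiedCCC <- function(y, yhat, sample_moments = FALSE) {
  p <- .check_pair(.as_fraction_vector(y), .as_fraction_vector(yhat))
  m <- .pop_moments(p$y, p$yhat)
  adj <- if (sample_moments) length(p$y) / (length(p$y) - 1) else 1
  mse <- mean((p$yhat - p$y)^2)
  denom <- adj * (m$var_y + m$var_h) + mse
  if (denom == 0) return(if (identical(p$y, p$yhat)) 1 else 0)
  2 * adj * m$cov / denom
}

#' Evaluate predicted against true compositions
#'
#' Computes RMSE, Lin's CCC and the modified CCC either per sample (within
#' each sample's fraction vector across cell types) or per cell type
#' (within each type's fraction vector across samples).
#'
#' @param truth,predicted Numeric matrices `n_samples x K` with matching
#'   dimnames, or lists of [MixtureSpec-class].
#' @param group_by `"sample"` (default) or `"cell_type"`.
#' @return A data.frame of per-group metrics with a summary attribute
#'   `means` (the column means).
#' @export
evaluateFractions <- function(truth, predicted,
                              group_by = c("sample", "cell_type")) {
  group_by <- match.arg(group_by)
  to_mat <- function(x) {
    if (is.list(x)) do.call(rbind, lapply(x, .as_fraction_vector)) else
      as.matrix(x)
  }
  yt <- to_mat(truth); yp <- to_mat(predicted)
  stopifnot(all(dim(yt) == dim(yp)))
  if (group_by == "cell_type") {
    yt <- t(yt); yp <- t(yp)
    nm <- if (is.list(truth)) cellTypes(truth[[1]]) else colnames(to_mat(truth))
    if (is.null(nm)) nm <- paste0("type", seq_len(nrow(yt)))
  } else {
    nm <- rownames(yt)
    if (is.null(nm)) nm <- paste0("sample", seq_len(nrow(yt)))
  }
  out <- data.frame(
    group = nm,
    rmse = vapply(seq_len(nrow(yt)), function(i)
      rmse(yt[i, ], yp[i, ]), numeric(1)),
    ccc = vapply(seq_len(nrow(yt)), function(i)
      linCCC(yt[i, ], yp[i, ]), numeric(1)),
    modified_ccc = vapply(seq_len(nrow(yt)), function(i)
      modifiedCCC(yt[i, ], yp[i, ]), numeric(1)))
  attr(out, "means") <- c(rmse = mean(out$rmse), ccc = mean(out$ccc),
                          modified_ccc = mean(out$modified_ccc))
  out
}
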