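#' Sample skewness (Fisher-Pearson moment coefficient)
#'
#' `g1 = m3 / m2^(3/2)` with central moments `m_k = mean((x - mean(x))^k)`.
#' A zero-variance sample is declared symmetric (skewness 0) with a warning.
#'
#' @param values Numeric vector with at least 3 values.
#' @return Skewness as a single number.
#' @export
sample_skewness <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) .stopf("skewness needs at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) {
    .warnf("zero-variance sample declared symmetric (skewness 0)")
    return(0)
  }
  mean((values - m)^3) / m2^(3 / 2)
}

#' Yeo-Johnson power transformation
#'
#' The two-branch monotone transform:
#' for `x >= 0`, `((x+1)^lambda - 1)/lambda` (`lambda != 0`) or `log(x+1)`
#' (`lambda == 0`); for `x < 0`, `-(((-x+1)^(2-lambda) - 1)/(2-lambda))`
#' (`lambda != 2`) or `-log(-x+1)` (`lambda == 2`). Strictly monotone for any
#' `lambda`, and the identity at `lambda = 1` for non-negative input.
#'
#' @param x Numeric vector.
#' @param lambda Transformation parameter.
#' @return Transformed vector.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-12) out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  else out[pos] <- log1p(x[pos])
  if (abs(lambda - 2) > 1e-12) out[!pos] <- -(((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda))
  else out[!pos] <- -log1p(-x[!pos])
  out
}

# Maximum-likelihood lambda for the Yeo-Johnson transform (profile
# log-likelihood of a normal model on the transformed scale).
.fit_yj_lambda <- function(x, interval = c(-5, 5)) {
  n <- length(x)
  ll <- function(lambda) {
    y <- yeo_johnson(x, lambda)
    s2 <- mean((y - mean(y))^2)
    if (!is.finite(s2) || s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
  }
  stats::optimize(ll, interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

#' Fit a per-feature normalization plan on training rows
#'
#' Implements the skewness-branched scheme: features with sample skewness in
#' `[-0.5, 0.5]` (boundary inclusive) are robustly normalized by removing the
#' training median and scaling to the training interquartile range; features
#' with `|skewness| > 0.5` receive a Yeo-Johnson power transformation with
#' maximum-likelihood lambda, followed by standardization to training
#' mean 0 / sd 1 so both branches land on comparable scales. All constants
#' are estimated on the supplied (training) rows only.
#'
#' Degenerate cases: a constant feature gets an identity transform with a
#' warning; a zero IQR falls back to unit scale with a warning.
#'
#' @param train_table Data frame of training rows.
#' @param features Character vector of columns to normalize (default: all
#'   numeric columns except `label`).
#' @return A `normalization_plan`: per-feature list of branch and constants.
#' @export
fit_normalization_plan <- function(train_table, features = NULL) {
  if (is.null(features))
    features <- setdiff(names(train_table)[vapply(train_table, is.numeric, TRUE)],
                        c("label", "t_stage", "n_stage"))
  plan <- lapply(features, function(f) {
    x <- train_table[[f]]
    if (length(unique(x)) == 1L) {
      .warnf("feature '%s' is constant on the training rows; identity transform", f)
      return(list(branch = "identity"))
    }
    sk <- suppressWarnings(sample_skewness(x))
    if (abs(sk) <= 0.5) {
      iqr <- stats::IQR(x)
      med <- stats::median(x)
      if (iqr <= 0) {
        .warnf("feature '%s' has zero IQR; centring only (unit scale)", f)
        iqr <- 1
      }
      list(branch = "robust", median = med, iqr = iqr, skewness = sk)
    } else {
      lam <- .fit_yj_lambda(x)
      y <- yeo_johnson(x, lam)
      s <- stats::sd(y)
      if (!is.finite(s) || s <= 0) s <- 1
      list(branch = "yeo_johnson", lambda = lam, mean = mean(y), sd = s, skewness = sk)
    }
  })
  names(plan) <- features
  structure(plan, class = "normalization_plan")
}

#' Apply a fitted normalization plan
#'
#' Transforms rows (training or test) using the plan's training constants
#' only; no statistic of the supplied table is computed.
#'
#' @param plan A `normalization_plan` from [fit_normalization_plan()].
#' @param table Data frame containing every planned column.
#' @return The table with planned columns transformed.
#' @export
apply_normalization_plan <- function(plan, table) {
  stopifnot(inherits(plan, "normalization_plan"))
  missing <- setdiff(names(plan), names(table))
  if (length(missing) > 0)
    .stopf("table lacks planned column(s): %s", paste(missing, collapse = ", "))
  for (f in names(plan)) {
    p <- plan[[f]]
    x <- table[[f]]
    table[[f]] <- switch(p$branch,
      identity = x,
      robust = (x - p$median) / p$iqr,
      yeo_johnson = (yeo_johnson(x, p$lambda) - p$mean) / p$sd)
  }
  table
}

#' @export
print.normalization_plan <- function(x, ...) {
  br <- vapply(x, `[[`, "", "branch")
  cat(sprintf("<normalization_plan> %d features: %d robust, %d Yeo-Johnson, %d identity\n",
              length(x), sum(br == "robust"), sum(br == "yeo_johnson"),
              sum(br == "identity")))
  invisible(x)
}

#' Serialize / restore a normalization plan
#'
#' Plans are written as JSON so a run's normalization constants can be
#' audited and replayed.
#' @param plan A `normalization_plan`.
#' @param path JSON file path.
#' @return `read_normalization_plan()` returns the plan.
#' @export
write_normalization_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization_plan
#' @export
read_normalization_plan <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "normalization_plan")
}
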