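# Lin's concordance correlation coefficient (CCC) for validating an estimate
# series against an external reference series.
#
# CCC penalises both loss of correlation and location/scale shift:
#   rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2),
# computed by default with population (1/n) moments as in Lin (1989).
# Confidence intervals use the Fisher z transform with Lin's asymptotic
# variance (with the 2000 erratum correction).

#' Align two labelled series into pairs
#'
#' Inner-joins two `label,value` series on their labels; pairs where either
#' side is missing (`NA`) are dropped and reported.
#'
#' @param reference,candidate Data frames with columns `label` and `value`,
#'   or named numeric vectors.
#' @return A `paired_series` object: list with `labels`, `x` (reference),
#'   `y` (candidate), `dropped` (labels present on only one side or with a
#'   missing value), `n`.
#' @export
align_series <- function(reference, candidate) {
  ref <- as_label_value(reference)
  cand <- as_label_value(candidate)
  joined <- dplyr::inner_join(ref, cand, by = "label",
                              suffix = c("_ref", "_cand"))
  complete <- !is.na(joined$value_ref) & !is.na(joined$value_cand)
  dropped <- sort(unique(c(
    setdiff(ref$label, cand$label), setdiff(cand$label, ref$label),
    joined$label[!complete]
  )))
  joined <- joined[complete, , drop = FALSE]
  if (nrow(joined) < 2) {
    stop("insufficient pairs: need at least 2 aligned, non-missing pairs",
         call. = FALSE)
  }
  structure(list(labels = joined$label, x = joined$value_ref,
                 y = joined$value_cand, dropped = dropped,
                 n = nrow(joined)),
            class = "paired_series")
}

as_label_value <- function(s) {
  if (is.numeric(s) && !is.null(names(s))) {
    s <- tibble::tibble(label = names(s), value = unname(s))
  }
  stopifnot(is.data.frame(s), all(c("label", "value") %in% names(s)))
  tibble::tibble(label = as.character(s$label),
                 value = suppressWarnings(as.numeric(s$value)))
}

ccc_moments <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  div <- if (moments == "population") n else n - 1
  list(n = n, mx = mx, my = my,
       sx2 = sum((x - mx)^2) / div,
       sy2 = sum((y - my)^2) / div,
       sxy = sum((x - mx) * (y - my)) / div)
}

#' Lin's concordance correlation coefficient
#'
#' @param x A `paired_series` from [align_series()], or a numeric vector
#'   (reference values).
#' @param y Candidate values when `x` is a vector.
#' @param moments `"population"` (1/n, the Lin (1989) convention, default) or
#'   `"sample"` (1/(n-1)) second moments.
#' @return The CCC, a scalar in `[-1, 1]`.
#' @export
lins_ccc <- function(x, y = NULL, moments = c("population", "sample")) {
  v <- paired_values(x, y)
  m <- ccc_moments(v$x, v$y, match.arg(moments))
  denom <- m$sx2 + m$sy2 + (m$mx - m$my)^2
  if (denom == 0) {
    stop("CCC undefined: both series are constant with equal means",
         call. = FALSE)
  }
  2 * m$sxy / denom
}

paired_values <- function(x, y) {
  if (inherits(x, "paired_series")) return(list(x = x$x, y = x$y))
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in series", call. = FALSE)
  list(x = x, y = y)
}

#' Confidence interval for Lin's CCC
#'
#' Fisher z-transform interval: `z = atanh(ccc)` with standard error from
#' Lin's asymptotic variance, back-transformed. A CCC of exactly +/-1
#' (or fewer than 3 pairs) yields the degenerate interval `[ccc, ccc]`.
#'
#' @inheritParams lins_ccc
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
ccc_confidence_interval <- function(x, y = NULL, level = 0.95,
                                    moments = c("population", "sample")) {
  moments <- match.arg(moments)
  v <- paired_values(x, y)
  p <- lins_ccc(v$x, v$y, moments)
  m <- ccc_moments(v$x, v$y, moments)
  n <- m$n
  if (abs(p) >= 1 - 1e-15 || n < 3) {
    return(c(lower = p, upper = p))
  }
  r <- m$sxy / sqrt(m$sx2 * m$sy2)  # Pearson correlation
  u <- (m$my - m$mx) / (m$sx2 * m$sy2)^0.25  # standardised location shift
  var_p <- ((1 - r^2) * p^2 * (1 - p^2) / r^2 +
              2 * p^3 * (1 - p) * u^2 / r -
              p^4 * u^4 / (2 * r^2)) / (n - 2)
  se_z <- sqrt(var_p) / (1 - p^2)
  z <- atanh(p)
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = tanh(z - q * se_z), upper = tanh(z + q * se_z))
}

#' Interpret a CCC value
#'
#' Bands: below 0.90 poor; 0.90 to below 0.95 moderate; 0.95 to below 0.99
#' substantial; 0.99 and above almost perfect.
#'
#' @param ccc CCC value(s) in `[-1, 1]`.
#' @return Character vector of band names (`"poor"`, `"moderate"`,
#'   `"substantial"`, `"almost_perfect"`).
#' @export
interpret_ccc <- function(ccc) {
  stopifnot(all(ccc >= -1 & ccc <= 1))
  dplyr::case_when(
    ccc >= 0.99 ~ "almost_perfect",
    ccc >= 0.95 ~ "substantial",
    ccc >= 0.90 ~ "moderate",
    .default = "poor"
  )
}

#' Concordance between two estimate series
#'
#' Aligns two labelled series and returns Lin's CCC with its confidence
#' interval and interpretation band.
#'
#' @inheritParams align_series
#' @param level Confidence level for the interval.
#' @param moments Moment convention, see [lins_ccc()].
#' @return A `concordance_result`: list with `ccc`, `ci_lower`, `ci_upper`,
#'   `level`, `n`, `interpretation`, `dropped`.
#' @export
concordance <- function(reference, candidate, level = 0.95,
                        moments = c("population", "sample")) {
  moments <- match.arg(moments)
  s <- align_series(reference, candidate)
  ccc <- lins_ccc(s, moments = moments)
  ci <- ccc_confidence_interval(s, level = level, moments = moments)
  structure(
    list(ccc = ccc, ci_lower = unname(ci["lower"]),
         ci_upper = unname(ci["upper"]), level = level, n = s$n,
         interpretation = interpret_ccc(ccc), dropped = s$dropped),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, digits = 2, ...) {
  cat(sprintf("Lin's CCC: %.*f (%d%% CI: %.*f-%.*f), n = %d, %s\n",
              digits, x$ccc, round(100 * x$level), digits, x$ci_lower,
              digits, x$ci_upper, x$n,
              gsub("_", " ", x$interpretation)))
  if (length(x$dropped)) {
    cat("dropped (unmatched or missing):", paste(x$dropped, collapse = ", "),
        "\n")
  }
  invisible(x)
}
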