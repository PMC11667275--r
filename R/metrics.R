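#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Probability that a randomly chosen event subject scores higher than a
#' randomly chosen non-event subject, ties counted one half.
#'
#' @param y binary outcome (0/1).
#' @param scores numeric risk scores or probabilities.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y, scores) {
  y <- as.integer(y)
  ok <- !is.na(y) & !is.na(scores)
  y <- y[ok]; scores <- scores[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes are required")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nagelkerke variation explained
#'
#' `R2 = [1 - exp((2/n)(LL0 - LL1))] / [1 - exp((2/n) LL0)]`, reported in
#' percent.
#'
#' @param loglik log-likelihood of the fitted model.
#' @param null_loglik log-likelihood of the intercept-only model on the same
#'   rows.
#' @param n number of observations.
#' @return percent of variation explained.
#' @export
nagelkerke_r2 <- function(loglik, null_loglik, n) {
  if (loglik < null_loglik - 1e-6)
    stop("model log-likelihood below the null: models are not nested on these rows")
  cox_snell <- 1 - exp((2 / n) * (null_loglik - loglik))
  maxr2 <- 1 - exp((2 / n) * null_loglik)
  100 * cox_snell / maxr2
}

#' Cox calibration intercept and slope
#'
#' The slope is the coefficient of the predicted log-odds in a logistic
#' refit; the intercept is from a logistic fit with the predicted log-odds as
#' fixed offset. A perfectly calibrated model has intercept 0, slope 1.
#'
#' @param y binary outcome.
#' @param p predicted probabilities in (0, 1).
#' @return list with `intercept`, `slope` and a `degenerate` flag (set when
#'   the predictions carry no variation, where the slope is undefined and
#'   reported as 0).
#' @export
cox_calibration <- function(y, p) {
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  lp <- stats::qlogis(p)
  if (stats::sd(lp) < 1e-12) {
    ic <- stats::glm(y ~ 1, offset = lp, family = stats::binomial())
    return(list(intercept = unname(stats::coef(ic)[1]), slope = 0,
                degenerate = TRUE))
  }
  sl <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
  ic <- suppressWarnings(stats::glm(y ~ 1, offset = lp,
                                    family = stats::binomial()))
  list(intercept = unname(stats::coef(ic)[1]),
       slope = unname(stats::coef(sl)[2]),
       degenerate = FALSE)
}

#' Classification metrics at a probability threshold
#'
#' @param y binary outcome.
#' @param p predicted probabilities.
#' @param threshold classification threshold; predictions `>= threshold`
#'   count as positive.
#' @return list with the 2x2 counts and `sensitivity`, `specificity`, `ppv`,
#'   `npv` (NaN with `undefined` flag naming the metric when a margin is
#'   empty).
#' @export
classification_metrics <- function(y, p, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  pos <- p >= threshold
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  fn <- sum(!pos & y == 1); tn <- sum(!pos & y == 0)
  ratio <- function(a, b) if (a + b == 0) NaN else a / (a + b)
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = ratio(tp, fn), specificity = ratio(tn, fp),
              ppv = ratio(tp, fp), npv = ratio(tn, fn))
  out$undefined <- names(which(vapply(out[c("sensitivity", "specificity",
                                            "ppv", "npv")], is.nan,
                                      logical(1))))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, applied per table of p-values.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' @param counts 2x2 matrix or length-4 vector `c(a, b, c, d)` laid out as
#'   rows exposure, columns event: `a` exposed/event, `b` exposed/no event,
#'   `c` unexposed/event, `d` unexposed/no event.
#' @param conf confidence level.
#' @return list with `or`, `ci`, and `corrected` (TRUE when a zero cell
#'   forced the Haldane-Anscombe +0.5 correction).
#' @export
odds_ratio_2x2 <- function(counts, conf = 0.95) {
  x <- as.numeric(counts)
  if (length(x) != 4L || any(x < 0)) stop("counts must be 4 non-negative numbers")
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  or <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), corrected = corrected)
}
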