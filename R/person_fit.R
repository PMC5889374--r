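#' Standardized log-likelihood person-fit statistic
#'
#' For a binary vector `u` with model probabilities `p`, computes the
#' log-likelihood `l0 = sum(u log p + (1-u) log(1-p))`, its model-implied
#' expectation `E[l0] = sum(p log p + (1-p) log(1-p))` and variance
#' `Var[l0] = sum(p (1-p) logit(p)^2)`, and the standardization
#' `lz = (l0 - E[l0]) / sqrt(Var[l0])`. Under the model, lz is
#' asymptotically standard normal; large negative values flag vectors far
#' less likely than the model expects (misfit).
#'
#' @param u Binary response/score vector.
#' @param p Model probabilities for each entry, already clipped away from
#'   0 and 1 (see [prob_correct()]).
#' @return List with components `l0`, `e_l0`, `var_l0`, `lz`.
#' @examples
#' lz_statistic(c(1, 1), c(0.8, 0.8))
#' @export
lz_statistic <- function(u, p) {
  if (length(u) != length(p)) stop("u and p must have equal length")
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0,1)")
  logit <- log(p / (1 - p))
  l0 <- sum(u * log(p) + (1 - u) * log(1 - p))
  e0 <- sum(p * log(p) + (1 - p) * log(1 - p))
  v0 <- sum(p * (1 - p) * logit^2)
  if (v0 < 1e-12) {
    stop("degenerate variance: Var[l0] < 1e-12 (all probabilities ~0.5?)")
  }
  list(l0 = l0, e_l0 = e0, var_l0 = v0, lz = (l0 - e0) / sqrt(v0))
}

#' Per-rater lz over a full exam
#'
#' One lz per rater (station), computed over the rater's entire assessment
#' vector: that station's checklist probabilities for every examinee,
#' crossed with the given abilities (true or estimated, per the caller's
#' configuration).
#'
#' @param scores Examinee x item score matrix (as from an `"osce_exam"`).
#' @param bank The `"item_params"` bank.
#' @param theta Ability vector used to build the probability grid.
#' @param D Logistic scaling constant.
#' @return Data frame of class `"lz_result"` with one row per station:
#'   `station`, `l0`, `e_l0`, `var_l0`, `lz`.
#' @export
rater_lz <- function(scores, bank, theta, D = 1.702) {
  p <- prob_matrix(theta, bank, D = D)
  stations <- sort(unique(bank$station))
  out <- data.frame(station = stations, l0 = NA_real_, e_l0 = NA_real_,
                    var_l0 = NA_real_, lz = NA_real_)
  for (k in seq_along(stations)) {
    cols <- station_cols(bank, stations[k])
    r <- lz_statistic(as.vector(scores[, cols, drop = FALSE]),
                      as.vector(p[, cols, drop = FALSE]))
    out$l0[k] <- r$l0; out$e_l0[k] <- r$e_l0
    out$var_l0[k] <- r$var_l0; out$lz[k] <- r$lz
  }
  class(out) <- c("lz_result", "data.frame")
  out
}

#' Flag raters from their lz scores
#'
#' Misfit lives in the lower tail of lz (a likelihood smaller than the model
#' expects), so the default flags raters with `lz < qnorm(alpha)` (-1.645 at
#' alpha 0.05, -2.326 at 0.01). Upper and two-sided conventions are
#' available for comparison.
#'
#' @param lz Numeric vector of lz scores (or an `"lz_result"` data frame).
#' @param alpha Type I error level.
#' @param tail `"lower"` (default), `"upper"`, or `"two_sided"`.
#' @return Logical vector of flags.
#' @export
classify_raters <- function(lz, alpha = 0.05,
                            tail = c("lower", "upper", "two_sided")) {
  tail <- match.arg(tail)
  if (is.data.frame(lz)) lz <- lz$lz
  if (!length(lz)) stop("no lz scores supplied")
  switch(tail,
         lower = lz < stats::qnorm(alpha),
         upper = lz > stats::qnorm(1 - alpha),
         two_sided = abs(lz) > stats::qnorm(1 - alpha / 2))
}
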