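#' Two-parameter logistic probability of a correct (pass) score
#'
#' `P(theta) = 1 / (1 + exp(-D * a * (theta - b)))`, clipped into
#' `[eps, 1 - eps]` so downstream logarithms are always finite. `D = 1.702`
#' makes the logistic curve nearly coincide with the normal ogive, which is
#' what keeps the CTT conversion in [ctt_to_2pl()] marginally consistent.
#'
#' All arguments recycle, so `theta` may be a vector against scalar item
#' parameters or vice versa.
#'
#' @param theta Latent ability (latent-trait units).
#' @param a Discrimination (slope).
#' @param b Difficulty (location).
#' @param D Logistic scaling constant.
#' @param eps Probability clipping constant.
#' @return Probability (or vector of probabilities) in `[eps, 1 - eps]`.
#' @examples
#' prob_correct(1, a = 1, b = 0, D = 1)  # 0.731...
#' @export
prob_correct <- function(theta, a, b, D = 1.702, eps = 1e-6) {
  p <- stats::plogis(D * a * (theta - b))
  pmin(pmax(p, eps), 1 - eps)
}

# 48 x 120 probability matrix: examinees (rows) crossed with bank items
# (columns, station-major order). Kept internal; all heavy loops use it.
prob_matrix <- function(theta, bank, D = 1.702, eps = 1e-6) {
  z <- D * outer(theta, bank$b, `-`)
  p <- stats::plogis(sweep(z, 2L, bank$a, `*`))
  pmin(pmax(p, eps), 1 - eps)
}

#' Simulate binary checklist scores under the 2PL
#'
#' Draws every examinee x item entry independently as
#' Bernoulli(`prob_correct(theta_j, item_i)`). Columns follow the bank's
#' row order (station-major: station 1 items 1..10, station 2 items 1..10,
#' ...), so a 12-station x 10-item bank yields a `length(theta) x 120`
#' matrix; the column block for station s is a rater's scoring of every
#' examinee on that station's checklist.
#'
#' @param theta Vector of true abilities.
#' @param bank An `"item_params"` data frame.
#' @param D Logistic scaling constant.
#' @param seed Optional integer seed (set just before drawing); `NULL` uses
#'   the current RNG state.
#' @return Integer matrix of 0/1 scores, `length(theta)` rows,
#'   `nrow(bank)` columns named `s<station>_i<item>`.
#' @export
simulate_responses <- function(theta, bank, D = 1.702, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- prob_matrix(theta, bank, D = D)
  u <- matrix(as.integer(stats::runif(length(p)) < p), nrow = nrow(p))
  colnames(u) <- sprintf("s%d_i%d", bank$station, bank$item)
  u
}

#' Maximum-likelihood ability estimates from binary scores
#'
#' Maximizes the 2PL log-likelihood over `theta` in `[-bound, bound]` for
#' each row of `scores`. The 2PL log-likelihood is strictly concave in theta
#' for any mix of positive and negative slopes, so a damped Newton iteration
#' started at 0 finds the global maximum; patterns whose likelihood is
#' monotone in theta (e.g. all-1 responses on a positively discriminating
#' bank) land on the corresponding bound rather than erroring, because the
#' person-fit statistic must remain computable for every examinee.
#'
#' @param scores Binary vector of length `nrow(bank)`, or a matrix with one
#'   row per examinee and `nrow(bank)` columns.
#' @param bank An `"item_params"` data frame covering every scored item.
#' @param bound Search bound on |theta|.
#' @param D Logistic scaling constant.
#' @return Numeric vector of estimates, one per examinee.
#' @export
estimate_theta <- function(scores, bank, bound = 4, D = 1.702) {
  u <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1L)
  if (ncol(u) != nrow(bank)) {
    stop(sprintf("response vector length (%d) does not match bank size (%d)",
                 ncol(u), nrow(bank)))
  }
  a <- bank$a
  a2 <- a^2
  theta <- rep(0, nrow(u))
  for (iter in seq_len(60L)) {
    p <- prob_matrix(theta, bank, D = D)
    grad <- D * as.vector((u - p) %*% a)
    hess <- D^2 * as.vector((p * (1 - p)) %*% a2)
    step <- grad / pmax(hess, 1e-10)
    step <- pmin(pmax(step, -1), 1)   # damping keeps early steps sane
    theta <- pmin(pmax(theta + step, -bound), bound)
    # converged, or pinned at a bound the gradient still pushes against
    pinned <- (theta >= bound & grad > 0) | (theta <= -bound & grad < 0)
    if (all(abs(step) < 1e-10 | pinned)) break
  }
  theta
}
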