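#' OSCE design constants
#'
#' The examination layout the simulator emulates: one rater per station
#' (raters nested in stations), every examinee scored at every station, so
#' each rater produces `n_examinees * items_per_station` binary checklist
#' entries (480 under the defaults).
#'
#' @param n_examinees Examinees per administration.
#' @param n_stations Stations (= raters).
#' @param items_per_station Checklist items per station.
#' @return List of class `"osce_design"`.
#' @export
osce_design <- function(n_examinees = 48, n_stations = 12,
                        items_per_station = 10) {
  structure(list(n_examinees = as.integer(n_examinees),
                 n_stations = as.integer(n_stations),
                 items_per_station = as.integer(items_per_station)),
            class = "osce_design")
}

#' Generate an unbiased OSCE cohort
#'
#' Draws true abilities i.i.d. N(0,1) and simulates every rater's checklist
#' scores from the 2PL bank. The returned exam carries its bias ground truth
#' (initially empty) so that [inject_bias()] and the study harness can audit
#' exactly which raters were manipulated.
#'
#' @param bank An `"item_params"` data frame matching the design
#'   (`n_stations * items_per_station` rows).
#' @param design An [osce_design()].
#' @param D Logistic scaling constant.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return List of class `"osce_exam"`: `scores` (examinee x item matrix),
#'   `theta` (true abilities), `design`, `biased_raters` (integer station
#'   ids, empty), `bias_type`, `nominal_rate`, `empirical_bias_count`.
#' @export
generate_cohort <- function(bank, design = osce_design(), D = 1.702,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(bank) == design$n_stations * design$items_per_station)
  theta <- stats::rnorm(design$n_examinees)
  scores <- simulate_responses(theta, bank, D = D)
  structure(list(scores = scores, theta = theta, design = design,
                 biased_raters = integer(0), bias_type = NA_character_,
                 nominal_rate = NA_real_,
                 empirical_bias_count = integer(0)),
            class = "osce_exam")
}

station_cols <- function(bank, station) which(bank$station == station)

#' Inject stringent or lenient rater bias into an exam
#'
#' Picks `n_biased` raters (stations) uniformly without replacement, then
#' within each chosen rater's full assessment vector (all examinees x all
#' checklist items, 480 entries under the default design) picks
#' `round(rate * length)` entry positions uniformly without replacement and
#' overwrites them with 0 (stringent) or 1 (lenient). Positions already
#' holding the target value count toward the nominal selection but not
#' toward the empirical bias count, so the empirical rate is at most the
#' nominal rate — and well below it for easy stations under leniency, where
#' most entries are already 1.
#'
#' @param exam An unbiased `"osce_exam"` (double injection is refused).
#' @param bias_type `"stringent"` (overwrite with 0) or `"lenient"`
#'   (overwrite with 1).
#' @param n_biased Number of biased raters, `1..n_stations`.
#' @param rate Nominal bias rate in (0, 1].
#' @param bank The `"item_params"` bank that generated the exam (used for
#'   the station -> column mapping).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return The exam with modified scores and filled-in ground truth;
#'   `empirical_bias_count` is a named integer vector (one entry per biased
#'   station) of entries actually changed.
#' @export
inject_bias <- function(exam, bias_type = c("stringent", "lenient"),
                        n_biased, rate, bank, seed = NULL) {
  bias_type <- match.arg(bias_type)
  stopifnot(inherits(exam, "osce_exam"))
  if (length(exam$biased_raters) > 0L) {
    stop("exam already contains injected bias; refusing double injection")
  }
  if (!(n_biased >= 1L && n_biased <= exam$design$n_stations)) {
    stop("n_biased must lie in 1..n_stations")
  }
  if (!(rate > 0 && rate <= 1)) stop("rate must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)

  target <- if (bias_type == "stringent") 0L else 1L
  vec_len <- exam$design$n_examinees * exam$design$items_per_station
  n_sel <- round(rate * vec_len)
  stations <- sort(sample.int(exam$design$n_stations, n_biased))
  emp <- integer(n_biased)
  for (k in seq_along(stations)) {
    cols <- station_cols(bank, stations[k])
    block <- exam$scores[, cols, drop = FALSE]
    v <- as.vector(block)
    pos <- sample.int(vec_len, n_sel)
    emp[k] <- sum(v[pos] != target)
    v[pos] <- target
    exam$scores[, cols] <- matrix(v, nrow = nrow(block))
  }
  names(emp) <- stations
  exam$biased_raters <- stations
  exam$bias_type <- bias_type
  exam$nominal_rate <- rate
  exam$empirical_bias_count <- emp
  exam
}

#' Long-format view of a simulated exam
#'
#' One row per examinee x station x item with the score, the examinee's true
#' ability and whether the scoring rater was biased; convenient for export
#' and inspection.
#'
#' @param exam An `"osce_exam"`.
#' @param bank The bank that generated it.
#' @return A data frame with columns `examinee`, `station`, `item`, `score`,
#'   `true_theta`, `rater_biased`.
#' @export
exam_long <- function(exam, bank) {
  n <- exam$design$n_examinees
  data.frame(
    examinee = rep(seq_len(n), times = nrow(bank)),
    station = rep(bank$station, each = n),
    item = rep(bank$item, each = n),
    score = as.vector(exam$scores),
    true_theta = rep(exam$theta, times = nrow(bank)),
    rater_biased = rep(bank$station %in% exam$biased_raters, each = n)
  )
}
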