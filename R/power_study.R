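# Deterministic per-replication seed from root seed, setting index and
# replication index; stays inside the 32-bit integer range so any single
# replication is reproducible in isolation.
child_seed <- function(root_seed, setting_index, rep_index) {
  h <- (as.double(root_seed) %% 2147483647) * 2654435761
  h <- (h + setting_index * 40503 + rep_index * 2654435769) %% 2147483647
  as.integer(h) + 1L
}

#' Run one replication of one study setting
#'
#' Generates an unbiased cohort, injects the setting's bias, re-estimates
#' every examinee's ability from the post-bias scores (unless
#' `theta_mode = "true"`), computes one lz per rater, flags raters at each
#' alpha, and returns the detection rate (flagged among truly biased) and
#' false-positive rate (flagged among unbiased) per alpha.
#'
#' @param bias_type `"stringent"` or `"lenient"`.
#' @param n_biased Number of biased raters (1..n_stations).
#' @param rate Nominal bias rate in (0, 1].
#' @param bank An `"item_params"` data frame.
#' @param seed Integer seed for the whole replication.
#' @param alphas Type I error levels to flag at.
#' @param theta_mode How the abilities entering the lz probability grid are
#'   obtained. `"mle_pre"` (default): maximum-likelihood estimates from the
#'   cohort's pre-manipulation scores, i.e. abilities estimated under the
#'   2PL before any rater is made biased — the configuration whose
#'   false-positive rates sit at the nominal alpha. `"mle_post"`: estimates
#'   from the post-bias scores an administrator would actually observe;
#'   bias then contaminates every examinee's estimate and inflates
#'   false-positive rates among unbiased raters. `"true"`: the simulation's
#'   generating abilities (an upper bound on power).
#' @param tail Flagging convention, see [classify_raters()].
#' @param D Logistic scaling constant.
#' @param design An [osce_design()].
#' @return One-row data frame: the setting descriptors plus, per alpha,
#'   `det_<alpha>` and `fp_<alpha>`, and the mean empirical bias count.
#' @export
run_replication <- function(bias_type, n_biased, rate, bank, seed,
                            alphas = c(0.05, 0.01),
                            theta_mode = c("mle_pre", "mle_post", "true"),
                            tail = "lower", D = 1.702,
                            design = osce_design()) {
  theta_mode <- match.arg(theta_mode)
  set.seed(seed)
  exam <- generate_cohort(bank, design = design, D = D)
  theta <- if (theta_mode == "mle_pre") {
    estimate_theta(exam$scores, bank, D = D)
  }
  exam <- inject_bias(exam, bias_type = bias_type, n_biased = n_biased,
                      rate = rate, bank = bank)
  theta <- switch(theta_mode,
                  mle_pre = theta,
                  mle_post = estimate_theta(exam$scores, bank, D = D),
                  true = exam$theta)
  lz <- tryCatch(rater_lz(exam$scores, bank, theta, D = D),
                 error = function(e) {
                   stop(sprintf("setting %s/n%d/r%.2f seed %d: %s",
                                bias_type, n_biased, rate, seed,
                                conditionMessage(e)))
                 })
  biased <- lz$station %in% exam$biased_raters
  out <- data.frame(bias_type = bias_type, n_biased = as.integer(n_biased),
                    rate = rate, seed = as.integer(seed),
                    mean_empirical_bias = mean(exam$empirical_bias_count))
  for (a in alphas) {
    fl <- classify_raters(lz, alpha = a, tail = tail)
    tag <- sub("^0\\.", "", format(a, nsmall = 2))
    out[[paste0("det_", tag)]] <- mean(fl[biased])
    out[[paste0("fp_", tag)]] <- mean(fl[!biased])
  }
  out
}

#' Run the factorial Monte Carlo power study
#'
#' Crosses bias type x number of biased raters x bias rate (the full default
#' grid is 2 x 6 x 6 = 72 settings) and replicates each setting `reps`
#' times, with a deterministic per-replication seed derived from
#' `root_seed`, the setting index and the replication index.
#'
#' @param bank An `"item_params"` data frame.
#' @param bias_types,n_biased_levels,rate_levels Factor levels of the grid.
#' @param reps Replications per setting.
#' @param root_seed Root seed for the whole study.
#' @inheritParams run_replication
#' @return List of class `"lz_study"`: `outcomes` (one row per setting x
#'   replication), `settings`, `reps`, `root_seed`, `alphas`, `theta_mode`,
#'   `tail`.
#' @export
run_study <- function(bank,
                      bias_types = c("stringent", "lenient"),
                      n_biased_levels = 1:6,
                      rate_levels = seq(0.1, 0.6, by = 0.1),
                      reps = 100, root_seed = 1,
                      alphas = c(0.05, 0.01),
                      theta_mode = c("mle_pre", "mle_post", "true"),
                      tail = "lower", D = 1.702,
                      design = osce_design()) {
  theta_mode <- match.arg(theta_mode)
  stopifnot(reps >= 1)
  settings <- expand.grid(bias_type = bias_types, n_biased = n_biased_levels,
                          rate = rate_levels, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  settings <- settings[order(settings$bias_type, settings$n_biased,
                             settings$rate), , drop = FALSE]
  rows <- vector("list", nrow(settings) * reps)
  idx <- 1L
  for (s in seq_len(nrow(settings))) {
    for (r in seq_len(reps)) {
      row <- run_replication(settings$bias_type[s], settings$n_biased[s],
                             settings$rate[s], bank,
                             seed = child_seed(root_seed, s, r),
                             alphas = alphas, theta_mode = theta_mode,
                             tail = tail, D = D, design = design)
      row$replication <- r
      rows[[idx]] <- row
      idx <- idx + 1L
    }
  }
  outcomes <- do.call(rbind, rows)
  structure(list(outcomes = outcomes, settings = settings, reps = reps,
                 root_seed = root_seed, alphas = alphas,
                 theta_mode = theta_mode, tail = tail),
            class = "lz_study")
}

#' Summarize a power study
#'
#' Per-setting and marginal (by bias type, by rate, by number of biased
#' raters) means and SDs of the per-replication detection rate, plus pooled
#' false-positive means, at each alpha.
#'
#' @param object An `"lz_study"`.
#' @param ... Unused.
#' @return List of data frames: `per_setting`, `by_type`, `by_rate`,
#'   `by_n_biased`, `false_positive`.
#' @export
summary.lz_study <- function(object, ...) {
  oc <- object$outcomes
  det_cols <- grep("^det_", names(oc), value = TRUE)
  fp_cols <- grep("^fp_", names(oc), value = TRUE)
  agg <- function(by) {
    means <- stats::aggregate(oc[det_cols], by = oc[by], FUN = mean)
    sds <- stats::aggregate(oc[det_cols], by = oc[by],
                            FUN = function(x) {
                              if (length(x) > 1L) stats::sd(x) else NA_real_
                            })
    names(sds)[names(sds) %in% det_cols] <- paste0(det_cols, "_sd")
    merge(means, sds, by = by)
  }
  fp <- data.frame(t(colMeans(oc[fp_cols])))
  list(per_setting = agg(c("bias_type", "n_biased", "rate")),
       by_type = agg("bias_type"),
       by_rate = agg("rate"),
       by_n_biased = agg("n_biased"),
       false_positive = fp)
}

#' @export
print.lz_study <- function(x, ...) {
  cat(sprintf(
    "lz power study: %d settings x %d replications (theta: %s, tail: %s)\n",
    nrow(x$settings), x$reps, x$theta_mode, x$tail))
  s <- summary(x)
  cat("\nMean detection rate by bias type:\n")
  print(s$by_type, row.names = FALSE, digits = 3)
  cat("\nMean detection rate by bias rate:\n")
  print(s$by_rate, row.names = FALSE, digits = 3)
  cat("\nPooled false-positive rates:\n")
  print(s$false_positive, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Balanced factorial ANOVA on per-replication detection rates
#'
#' Classical fixed-effects decomposition (all main effects and interactions,
#' every factor crossed) with partial eta squared
#' `SS_effect / (SS_effect + SS_residual)` per effect and Cohen-style size
#' labels. Input must be balanced (equal replications per cell); unbalanced
#' tables are refused rather than silently reweighted.
#'
#' @param outcomes Long data frame, e.g. `study$outcomes`.
#' @param response Name of the response column (default the detection rate
#'   at alpha 0.05).
#' @param factors Character vector of factor column names to cross.
#' @return Data frame of class `"anova_eta"`: one row per effect plus
#'   residual, with `df`, `sum_sq`, `mean_sq`, `F`, `p`, `partial_eta_sq`,
#'   `effect_size`.
#' @export
factorial_anova <- function(outcomes, response = "det_05",
                            factors = c("bias_type", "n_biased", "rate")) {
  stopifnot(response %in% names(outcomes),
            all(factors %in% names(outcomes)))
  d <- outcomes[c(response, factors)]
  for (f in factors) d[[f]] <- factor(d[[f]])
  counts <- table(d[factors])
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced design: unequal replications per cell")
  }
  form <- stats::as.formula(paste(response, "~",
                                  paste(factors, collapse = " * ")))
  fit <- stats::aov(form, data = d)
  tab <- summary(fit)[[1L]]
  eff <- trimws(rownames(tab))
  ss <- tab[["Sum Sq"]]
  df <- tab[["Df"]]
  res_i <- which(eff == "Residuals")
  ss_res <- ss[res_i]
  # a denominator at rounding-noise scale means a constant response
  eta <- ifelse(ss + ss_res > 1e-12, ss / (ss + ss_res), 0)
  eta[res_i] <- NA_real_
  out <- data.frame(effect = eff, df = df, sum_sq = ss,
                    mean_sq = tab[["Mean Sq"]],
                    F = tab[["F value"]], p = tab[["Pr(>F)"]],
                    partial_eta_sq = eta,
                    effect_size = c(classify_effect_size(
                      ifelse(is.na(eta), 0, eta))),
                    row.names = NULL)
  out$effect_size[res_i] <- NA_character_
  class(out) <- c("anova_eta", "data.frame")
  out
}

#' Label a partial eta squared with Cohen's thresholds
#'
#' `< 0.01` negligible, `[0.01, 0.06)` small, `[0.06, 0.14)` medium,
#' `>= 0.14` large.
#'
#' @param eta_p_sq Partial eta squared value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' classify_effect_size(c(0.005, 0.03, 0.06, 0.53))
#' @export
classify_effect_size <- function(eta_p_sq) {
  stopifnot(all(eta_p_sq >= 0 & eta_p_sq <= 1, na.rm = TRUE))
  as.character(cut(eta_p_sq, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf),
                   labels = c("negligible", "small", "medium", "large"),
                   right = FALSE))
}
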