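#' Load the packaged station checklist properties
#'
#' Reads a 12-station x 10-item checklist property table (the packaged bank
#' from a previously administered undergraduate OSCE, or a user-supplied CSV
#' in the same schema) and interprets it under one of three modes.
#'
#' The packaged table carries two rows per item, labelled `D_i` and `P_i`.
#' The caption-level labels are ambiguous: the `P_i` rows contain negative
#' values, impossible for a proportion-correct, while the `D_i` rows all lie
#' in (0,1) and are mostly high, as expected for fairly easy clinical
#' stations. The default mode `"ctt_swapped"` therefore reads `D_i` as the
#' classical difficulty (proportion-correct `p_value`) and `P_i` as the
#' point-biserial discrimination (`r_pb`). Mode `"ctt_literal"` takes the
#' labels at face value (and fails validation on this bank), and
#' `"direct_2pl"` treats the rows as already-transformed 2PL parameters
#' (`a` from `D_i`, `b` from `P_i`).
#'
#' @param path Path to a CSV with columns `station`, `item`, `D_i`, `P_i`.
#'   `NULL` (default) loads the packaged bank.
#' @param mode Interpretation mode; one of `"ctt_swapped"`, `"ctt_literal"`,
#'   `"direct_2pl"`.
#' @param b_max Validation bound on |b| under `"direct_2pl"`.
#' @return Under the two CTT modes, a data frame of class `"ctt_items"` with
#'   columns `station`, `item`, `p_value`, `r_pb`; under `"direct_2pl"`, a
#'   data frame of class `"item_params"` with columns `station`, `item`,
#'   `a`, `b`.
#' @seealso [ctt_to_2pl()], [osce_item_bank()]
#' @export
load_station_checklists <- function(path = NULL,
                                    mode = c("ctt_swapped", "ctt_literal",
                                             "direct_2pl"),
                                    b_max = 5) {
  mode <- match.arg(mode)
  if (is.null(path)) {
    path <- system.file("extdata", "station_checklists.csv",
                        package = "raterfit", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station", "item", "D_i", "P_i")
  if (!all(need %in% names(raw))) {
    stop("checklist CSV must have columns: ", paste(need, collapse = ", "))
  }
  raw <- raw[order(raw$station, raw$item), , drop = FALSE]

  if (mode == "direct_2pl") {
    out <- data.frame(station = as.integer(raw$station),
                      item = as.integer(raw$item),
                      a = as.numeric(raw$D_i),
                      b = as.numeric(raw$P_i))
    bad <- which(!is.finite(out$a) | !is.finite(out$b) | abs(out$b) > b_max)
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf("station %d item %d: invalid 2PL parameters (a=%g, b=%g)",
                   out$station[i], out$item[i], out$a[i], out$b[i]))
    }
    class(out) <- c("item_params", "data.frame")
    return(out)
  }

  if (mode == "ctt_swapped") {
    p <- as.numeric(raw$D_i); r <- as.numeric(raw$P_i)
  } else { # ctt_literal: caption labels at face value
    p <- as.numeric(raw$P_i); r <- as.numeric(raw$D_i)
  }
  out <- data.frame(station = as.integer(raw$station),
                    item = as.integer(raw$item),
                    p_value = p, r_pb = r)
  bad <- which(!(out$p_value > 0 & out$p_value < 1))
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf(
      "station %d item %d: p_value %g outside (0,1) under mode '%s'",
      out$station[i], out$item[i], out$p_value[i], mode))
  }
  bad <- which(!(out$r_pb > -1 & out$r_pb < 1))
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf(
      "station %d item %d: r_pb %g outside (-1,1) under mode '%s'",
      out$station[i], out$item[i], out$r_pb[i], mode))
  }
  class(out) <- c("ctt_items", "data.frame")
  out
}

#' Convert classical item statistics to 2PL parameters
#'
#' Normal-ogive conversion of classical difficulty (proportion-correct p) and
#' point-biserial discrimination (r) into two-parameter-logistic slope and
#' location: `a = r / sqrt(1 - r^2)`, `b = qnorm(1 - p) / r`. With the
#' logistic scaling constant D = 1.702 applied later in [prob_correct()],
#' the marginal proportion-correct over abilities drawn from N(0,1) recovers
#' p up to the ogive/logistic approximation whenever b is not clipped.
#'
#' Near-zero discriminations are floored at `r_min` in absolute value
#' (preserving sign) before transforming, and |b| is clipped at `b_max`, so
#' that extreme p/r combinations cannot produce degenerate slopes or
#' unbounded locations. Negative discriminations are retained as negative
#' slopes; the transform never takes absolute values.
#'
#' @param stats A `"ctt_items"` data frame (see [load_station_checklists()]),
#'   or any data frame with columns `station`, `item`, `p_value`, `r_pb`.
#' @param b_max Clipping bound for |b| (latent-trait units).
#' @param r_min Floor for |r_pb| before transforming.
#' @return Data frame of class `"item_params"` with columns `station`,
#'   `item`, `a`, `b`.
#' @examples
#' ctt_to_2pl(data.frame(station = 1, item = 1, p_value = 0.5, r_pb = 0.6))
#' @export
ctt_to_2pl <- function(stats, b_max = 5, r_min = 0.05) {
  stopifnot(is.data.frame(stats),
            all(c("station", "item", "p_value", "r_pb") %in% names(stats)))
  p <- stats$p_value
  r <- stats$r_pb
  if (any(p <= 0 | p >= 1)) {
    stop("p_value must lie strictly inside (0,1)")
  }
  # floor |r| at r_min, keeping sign (sign 0 treated as positive)
  s <- ifelse(r < 0, -1, 1)
  r <- s * pmax(abs(r), r_min)
  a <- r / sqrt(1 - r^2)
  b <- stats::qnorm(1 - p) / r
  b <- pmin(pmax(b, -b_max), b_max)
  out <- data.frame(station = as.integer(stats$station),
                    item = as.integer(stats$item),
                    a = a, b = b)
  class(out) <- c("item_params", "data.frame")
  out
}

#' Packaged OSCE item bank as 2PL parameters
#'
#' Convenience wrapper: loads the packaged checklist table and, for the CTT
#' interpretation modes, applies [ctt_to_2pl()]. This is the bank used
#' throughout the power study.
#'
#' @inheritParams load_station_checklists
#' @inheritParams ctt_to_2pl
#' @return An `"item_params"` data frame with 120 rows.
#' @export
osce_item_bank <- function(mode = c("ctt_swapped", "ctt_literal",
                                    "direct_2pl"),
                           path = NULL, b_max = 5, r_min = 0.05) {
  mode <- match.arg(mode)
  x <- load_station_checklists(path = path, mode = mode, b_max = b_max)
  if (inherits(x, "item_params")) x else ctt_to_2pl(x, b_max = b_max,
                                                    r_min = r_min)
}
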