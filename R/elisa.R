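#' Serial-dilution amount series
#'
#' Amounts (ng per well) of a stepwise serial dilution:
#' \code{start_ng / factor^k}, k = 0..n_points-1. The default is the 4-fold
#' series starting from 1 ug (1000 ng) per well.
#'
#' @param start_ng starting amount in ng (> 0).
#' @param factor dilution factor (> 1).
#' @param n_points number of dilution points (>= 2).
#' @return numeric vector of amounts, strictly decreasing.
#' @export
make_dilution_series <- function(start_ng = 1000, factor = 4, n_points = 6) {
  if (!is.numeric(start_ng) || start_ng <= 0) stop("start_ng must be > 0", call. = FALSE)
  if (!is.numeric(factor) || factor <= 1) stop("factor must be > 1", call. = FALSE)
  if (!is.numeric(n_points) || n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  start_ng / factor^(seq_len(n_points) - 1)
}

#' ELISA dilution series of one mAb
#'
#' @param mab_id antibody identifier.
#' @param amounts ng per well, strictly decreasing geometric series.
#' @param od_replicates list (one element per amount) of OD readings, or a
#'   matrix with one row per amount.
#' @return validated list of class \code{"elisa_series"}.
#' @export
elisa_series <- function(mab_id, amounts, od_replicates) {
  if (is.matrix(od_replicates))
    od_replicates <- split(od_replicates, row(od_replicates))
  stopifnot(length(amounts) == length(od_replicates))
  if (any(diff(amounts) >= 0))
    stop("amounts must be strictly decreasing", call. = FALSE)
  ratios <- amounts[-length(amounts)] / amounts[-1]
  if (max(ratios) / min(ratios) > 1 + 1e-6)
    stop("amounts must form a constant-ratio dilution series", call. = FALSE)
  if (any(unlist(od_replicates) < 0))
    stop("OD readings must be >= 0", call. = FALSE)
  if (any(lengths(od_replicates) < 1))
    stop("need >= 1 replicate per amount", call. = FALSE)
  structure(list(mab_id = mab_id, amounts = amounts,
                 od_replicates = od_replicates), class = "elisa_series")
}

#' OD detection threshold from negative controls
#'
#' Default rule: mean + \code{n_sd} standard deviations of the
#' no-primary-antibody negative-control readings. A fixed \code{override}
#' (the assay's chosen detection line) takes precedence when supplied.
#'
#' @param negative_control_ods numeric vector of >= 2 control readings.
#' @param n_sd number of standard deviations above the control mean.
#' @param override fixed OD threshold bypassing the control rule.
#' @return OD threshold (scalar).
#' @export
od_threshold_from_controls <- function(negative_control_ods, n_sd = 3,
                                       override = NULL) {
  if (!is.null(override)) return(override)
  if (length(negative_control_ods) < 2)
    stop("need >= 2 negative-control readings", call. = FALSE)
  mean(negative_control_ods) + n_sd * stats::sd(negative_control_ods)
}

#' ELISA binding threshold of one dilution series
#'
#' The binding threshold is the minimum antibody amount (ng) giving detectable
#' binding: mean OD is computed per amount, amounts are scanned in increasing
#' order, and the smallest amount whose mean OD reaches \code{od_threshold} is
#' refined by linear interpolation of mean OD against log10(amount) between
#' the bracketing dilution points. If even the largest amount stays below the
#' threshold the result is right-censored at the maximum amount (reported as
#' \code{">1000"} for the default series); if already the smallest amount is
#' at or above it, the result is left-censored at the minimum amount.
#'
#' @param series an [elisa_series()].
#' @param od_threshold OD detection threshold (> 0), e.g. from
#'   [od_threshold_from_controls()].
#' @return list of class \code{"elisa_threshold"}: \code{mab_id},
#'   \code{threshold_ng} (NA when censored), \code{censored} ("none",
#'   "above", "below"), \code{censor_limit_ng}, \code{display} (e.g.
#'   \code{">1000"}), \code{od_threshold_used}.
#' @export
binding_threshold <- function(series, od_threshold) {
  stopifnot(inherits(series, "elisa_series"))
  if (!is.numeric(od_threshold) || od_threshold <= 0)
    stop("od_threshold must be > 0", call. = FALSE)
  mean_od <- vapply(series$od_replicates, mean, numeric(1))
  ord <- order(series$amounts)                 # increasing amounts
  a <- series$amounts[ord]
  m <- mean_od[ord]

  res <- function(threshold_ng, censored, limit) {
    display <- if (censored == "above") paste0(">", format(limit))
    else if (censored == "below") paste0("<", format(limit))
    else format(signif(threshold_ng, 6))
    structure(list(mab_id = series$mab_id,
                   threshold_ng = if (censored == "none") threshold_ng else NA_real_,
                   censored = censored, censor_limit_ng = limit,
                   display = display, od_threshold_used = od_threshold),
              class = "elisa_threshold")
  }

  above <- m >= od_threshold
  if (!any(above)) return(res(NA_real_, "above", max(a)))
  k <- which(above)[1]                         # lowest crossing amount
  if (sum(diff(above) != 0) > 1)
    warning("non-monotone OD curve with multiple threshold crossings; ",
            "using the crossing at the lowest amount")
  if (k == 1) return(res(NA_real_, "below", min(a)))
  # interpolate log10(amount) linearly in mean OD between the bracket
  la <- log10(a[k - 1]) + (od_threshold - m[k - 1]) / (m[k] - m[k - 1]) *
    (log10(a[k]) - log10(a[k - 1]))
  res(10^la, "none", NA_real_)
}

#' Batch ELISA thresholds from a long-format plate table
#'
#' Parses a plate table (columns \code{mab_id}, \code{amount_ng},
#' \code{replicate}, \code{od}; control rows labeled \code{"no_primary"} carry
#' the negative-control readings) and computes the binding threshold of every
#' mAb.
#'
#' @param plate long-format data.frame as written by the simulator or read by
#'   [read_elisa_plate()].
#' @param od_threshold fixed OD threshold; \code{NULL} derives it from the
#'   \code{"no_primary"} rows via [od_threshold_from_controls()].
#' @param n_sd passed to [od_threshold_from_controls()].
#' @return data.frame: mab_id, threshold_ng, censored, censor_limit_ng,
#'   display, od_threshold_used.
#' @export
elisa_thresholds <- function(plate, od_threshold = NULL, n_sd = 3) {
  stopifnot(all(c("mab_id", "amount_ng", "od") %in% names(plate)))
  if (is.null(od_threshold)) {
    nc <- plate$od[plate$mab_id == "no_primary"]
    if (length(nc) < 2)
      stop("no 'no_primary' negative-control rows; supply od_threshold",
           call. = FALSE)
    od_threshold <- od_threshold_from_controls(nc, n_sd = n_sd)
  }
  mabs <- setdiff(unique(plate$mab_id), c("no_primary", "positive_control"))
  rows <- lapply(mabs, function(id) {
    x <- plate[plate$mab_id == id & !is.na(plate$amount_ng), , drop = FALSE]
    amounts <- sort(unique(x$amount_ng), decreasing = TRUE)
    reps <- lapply(amounts, function(a) x$od[x$amount_ng == a])
    r <- binding_threshold(elisa_series(id, amounts, reps), od_threshold)
    data.frame(mab_id = id, threshold_ng = r$threshold_ng,
               censored = r$censored, censor_limit_ng = r$censor_limit_ng,
               display = r$display, od_threshold_used = r$od_threshold_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
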