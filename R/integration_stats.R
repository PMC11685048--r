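#' Build the per-cell integrated table
#'
#' Left-joins subset labels, clonotype assignments, mutation profiles,
#' index-sort fluorescence and ELISA results onto a base cell-metadata table,
#' all keyed by \code{cell_id}. Any source with duplicate keys is rejected.
#'
#' @param cells base data.frame with a unique \code{cell_id} column (and
#'   typically plate, well, sample).
#' @param ... further data.frames to join, each with a unique \code{cell_id}
#'   column; \code{NULL} entries are skipped. Name the arguments to get named
#'   join counts in the report.
#' @return list with \code{table} (the integrated data.frame) and
#'   \code{report} (per-source matched/unmatched counts).
#' @export
build_integrated_table <- function(cells, ...) {
  stopifnot("cell_id" %in% names(cells))
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell_id in base cell table", call. = FALSE)
  sources <- list(...)
  if (length(sources) && is.null(names(sources)))
    names(sources) <- paste0("source", seq_along(sources))
  out <- cells
  report <- list()
  for (nm in names(sources)) {
    src <- sources[[nm]]
    if (is.null(src)) next
    stopifnot("cell_id" %in% names(src))
    if (anyDuplicated(src$cell_id))
      stop("duplicate cell_id in source '", nm, "'", call. = FALSE)
    out <- merge(out, src, by = "cell_id", all.x = TRUE, sort = FALSE)
    report[[nm]] <- list(matched = sum(src$cell_id %in% cells$cell_id),
                         unmatched = sum(!src$cell_id %in% cells$cell_id))
  }
  out <- out[match(cells$cell_id, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, report = report)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Omnibus Kruskal-Wallis H with tie correction, followed by Dunn's pairwise
#' z-tests on mean ranks (shared tie correction), with the pairwise p-values
#' adjusted over all pairs (Bonferroni by default, the classical Dunn
#' procedure). Pairwise results are meaningful only alongside a significant
#' omnibus test; both are always returned.
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of group membership (>= 2 per group).
#' @param p_adjust_method adjustment for the pairwise p-values
#'   (\code{"bonferroni"}, \code{"holm"}, \code{"none"}, ...).
#' @return list: \code{H}, \code{df}, \code{p_value}, \code{pairwise}
#'   (data.frame group1, group2, z, p, p_adjusted).
#' @export
kruskal_dunn <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("every group needs >= 2 observations; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  k <- nlevels(groups)
  n <- length(values)
  r <- rank(values)
  rsum <- tapply(r, groups, sum)
  ni <- as.vector(sizes)

  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  denom <- 1 - tie_term / (n^3 - n)
  if (denom <= 0) {                       # all observations tied
    H <- 0; p <- 1
    z <- function(i, j) 0
  } else {
    H <- (12 / (n * (n + 1)) * sum(rsum^2 / ni) - 3 * (n + 1)) / denom
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    sigma2 <- (n * (n + 1) / 12 - tie_term / (12 * (n - 1)))
    rbar <- rsum / ni
    z <- function(i, j)
      (rbar[i] - rbar[j]) / sqrt(sigma2 * (1 / ni[i] + 1 / ni[j]))
  }
  pairs <- utils::combn(seq_len(k), 2)
  pw <- data.frame(
    group1 = levels(groups)[pairs[1, ]],
    group2 = levels(groups)[pairs[2, ]],
    z = apply(pairs, 2, function(ij) z(ij[1], ij[2])),
    stringsAsFactors = FALSE)
  pw$p <- 2 * stats::pnorm(-abs(pw$z))
  pw$p_adjusted <- stats::p.adjust(pw$p, method = p_adjust_method)
  list(H = unname(H), df = k - 1, p_value = unname(p), pairwise = pw)
}

#' Semi-log least-squares fit of binding against ELISA threshold
#'
#' Fits \code{y = a + b * log10(x)} by least squares, where x is the ELISA
#' binding threshold (ng) and y the arcsinh-transformed surface binding. The
#' straight-line fit on log10(x) attains the same optimum as an iterative
#' least-squares fit of the same semi-log model, deterministically. Censored
#' thresholds (">max") are handled per \code{censor_policy}: \code{"cap"}
#' replaces them by the censoring limit, \code{"exclude"} drops those rows.
#'
#' @param x threshold amounts in ng (> 0 after the censor policy).
#' @param y arcsinh-scale binding values.
#' @param censored logical vector flagging right-censored x entries
#'   (\code{NULL} = none).
#' @param censor_policy "cap" or "exclude".
#' @param cap_value value substituted for censored entries under "cap".
#' @return list: \code{slope}, \code{intercept}, \code{r_squared}, \code{n},
#'   \code{censor_policy}.
#' @export
semilog_fit <- function(x, y, censored = NULL,
                        censor_policy = c("cap", "exclude"),
                        cap_value = 1000) {
  censor_policy <- match.arg(censor_policy)
  stopifnot(length(x) == length(y))
  if (is.null(censored)) censored <- rep(FALSE, length(x))
  keep <- !is.na(y) & (!is.na(x) | censored)
  x <- x[keep]; y <- y[keep]; censored <- censored[keep]
  if (censor_policy == "cap") {
    x[censored] <- cap_value
  } else {
    x <- x[!censored]; y <- y[!censored]
  }
  if (length(x) < 3) stop("need >= 3 usable points", call. = FALSE)
  if (any(x <= 0)) stop("all x must be > 0", call. = FALSE)
  if (stats::var(y) == 0)
    stop("zero variance in y; R^2 undefined", call. = FALSE)
  fit <- stats::lm(y ~ log10(x))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(x), censor_policy = censor_policy)
}

#' Per-clonotype summaries of size and surface binding
#'
#' @param table integrated cell table with \code{clonotype_id},
#'   \code{sample} and an asinh binding column.
#' @param binding_col name of the asinh binding column.
#' @param background asinh background threshold; members above it count
#'   toward \code{n_above_background}.
#' @return data.frame: clonotype_id, size, mean_binding (over non-missing
#'   values), n_above_background, samples.
#' @export
summarize_clonotypes <- function(table, binding_col = "asinh_OVA-AF647",
                                 background = 1) {
  stopifnot("clonotype_id" %in% names(table), binding_col %in% names(table))
  tab <- table[!is.na(table$clonotype_id), , drop = FALSE]
  out <- do.call(rbind, lapply(split(tab, tab$clonotype_id), function(g) {
    b <- g[[binding_col]]
    data.frame(clonotype_id = g$clonotype_id[1], size = nrow(g),
               mean_binding = if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE),
               n_above_background = sum(b > background, na.rm = TRUE),
               samples = paste(sort(unique(g$sample)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Select candidate clonotypes for mAb production
#'
#' Clonotypes with at least \code{min_size} members and at least one member
#' with surface binding above background qualify; optionally a seeded random
#' subsample of \code{k} candidates is drawn.
#'
#' @param summary data.frame from [summarize_clonotypes()].
#' @param min_size minimum clonotype size.
#' @param k number of candidates to sample (\code{NULL} = return all).
#' @param seed seed for the subsample.
#' @return character vector of clonotype ids.
#' @export
select_clonotypes <- function(summary, min_size = 5, k = NULL, seed = 0L) {
  hits <- summary$clonotype_id[summary$size >= min_size &
                                 summary$n_above_background >= 1]
  if (is.null(k) || length(hits) <= k) return(hits)
  with_seed(seed, sample(hits, k))
}

#' Detect FACS/ELISA discordant outlier cells
#'
#' Cells with no detectable surface binding (asinh value below
#' \code{binding_cutoff}) whose mAbs nevertheless have an uncensored ELISA
#' binding threshold strictly inside \code{range_ng}.
#'
#' @param table data.frame with the binding and threshold columns.
#' @param binding_cutoff asinh background cutoff (default 1).
#' @param range_ng open interval of threshold amounts (ng).
#' @param binding_col,threshold_col,censored_col column names.
#' @return subset of \code{table} holding the outlier rows.
#' @export
detect_outliers <- function(table, binding_cutoff = 1, range_ng = c(10, 100),
                            binding_col = "asinh_OVA-AF647",
                            threshold_col = "threshold_ng",
                            censored_col = "censored") {
  stopifnot(binding_col %in% names(table), threshold_col %in% names(table))
  b <- table[[binding_col]]
  x <- table[[threshold_col]]
  cens <- if (censored_col %in% names(table))
    !(table[[censored_col]] %in% c("none", NA, "")) else rep(FALSE, nrow(table))
  hit <- !is.na(b) & !is.na(x) & !cens &
    b < binding_cutoff & x > range_ng[1] & x < range_ng[2]
  table[hit, , drop = FALSE]
}
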