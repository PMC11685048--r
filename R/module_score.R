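#' Gene-signature module score
#'
#' Scores a gene set per cell against expression-matched control genes: all
#' genes are ranked by mean normalized expression across cells and cut into
#' \code{n_bins} equal-size bins; for every signature gene, \code{n_ctrl}
#' control genes are drawn from its bin (with the given seed); the score of a
#' cell is the mean expression of the signature genes minus the mean
#' expression of the pooled control draw. Scores are location-free: adding a
#' constant to the whole matrix leaves them unchanged.
#'
#' @param norm_matrix normalized gene-by-cell matrix.
#' @param gene_set character vector of signature genes.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes drawn per signature gene (default 100); bins
#'   smaller than \code{n_ctrl} are sampled with replacement (with a warning).
#' @param seed RNG seed for the control draw.
#' @return numeric vector of scores, one per cell (named by cell).
#' @export
module_score <- function(norm_matrix, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 0L) {
  stopifnot(n_bins >= 1)
  genes <- rownames(norm_matrix)
  sig <- intersect(gene_set, genes)
  if (length(sig) == 0)
    stop("no signature gene found in the matrix", call. = FALSE)
  n_bins <- min(n_bins, length(genes))
  gene_means <- Matrix::rowMeans(norm_matrix)
  # equal-size bins over the rank of mean expression (ties broken stably)
  rk <- rank(gene_means, ties.method = "first")
  bin <- ceiling(rk * n_bins / length(genes))
  names(bin) <- genes

  ctrl <- with_seed(seed, {
    unlist(lapply(sig, function(g) {
      # controls are expression-matched non-signature genes from the same bin
      pool <- setdiff(genes[bin == bin[[g]]], sig)
      if (length(pool) == 0)
        stop("no control genes available in the bin of '", g, "'",
             call. = FALSE)
      if (length(pool) < n_ctrl) {
        warning("bin of gene '", g, "' has ", length(pool),
                " genes < n_ctrl = ", n_ctrl, "; sampling with replacement")
        sample(pool, n_ctrl, replace = TRUE)
      } else {
        sample(pool, n_ctrl)
      }
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::colMeans(norm_matrix[sig, , drop = FALSE])
  # control pool keeps duplicates: mean over the drawn multiset
  ctrl_mean <- Matrix::colMeans(norm_matrix[ctrl, , drop = FALSE])
  as.numeric(sig_mean - ctrl_mean) |> stats::setNames(colnames(norm_matrix))
}

#' Score several signatures at once
#'
#' @param norm_matrix normalized gene-by-cell matrix.
#' @param signatures named list of gene sets.
#' @inheritParams module_score
#' @return cells-by-signatures numeric matrix.
#' @export
score_signatures <- function(norm_matrix, signatures, n_bins = 24,
                             n_ctrl = 100, seed = 0L) {
  sc <- vapply(signatures, function(gs)
    module_score(norm_matrix, gs, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
    numeric(ncol(norm_matrix)))
  rownames(sc) <- colnames(norm_matrix)
  sc
}

#' Gating configuration for GC subset assignment
#'
#' Per-signature score thresholds of the sequential gate. The defaults of 0
#' place each gate at the natural signal-above-control boundary; they are meant
#' to be tuned empirically per dataset (see [suggest_gate_thresholds()]).
#'
#' @param thresholds named numeric vector with entries PC, prePC, preMem, LZ,
#'   DZ.
#' @return list of class \code{"gating_config"}.
#' @export
gating_config <- function(thresholds = c(PC = 0, prePC = 0, preMem = 0,
                                         LZ = 0, DZ = 0)) {
  need <- c("PC", "prePC", "preMem", "LZ", "DZ")
  if (!all(need %in% names(thresholds)) || any(!is.finite(thresholds[need])))
    stop("thresholds must be finite and name PC, prePC, preMem, LZ, DZ",
         call. = FALSE)
  structure(list(thresholds = thresholds[need]), class = "gating_config")
}

#' Empirical gate thresholds from score distributions
#'
#' Places each signature's gate at the midpoint of its observed score range —
#' a simple empirical calibration that separates a well-scored positive
#' population from the background bulk when the signature has clear signal.
#' Intended for simulated or strongly structured data; real datasets usually
#' warrant manual tuning.
#'
#' @param scores cells-by-signatures matrix from [score_signatures()].
#' @return a [gating_config()].
#' @export
suggest_gate_thresholds <- function(scores) {
  need <- c("PC", "prePC", "preMem", "LZ", "DZ")
  stopifnot(all(need %in% colnames(scores)))
  thr <- vapply(need, function(s)
    (max(scores[, s]) + min(scores[, s])) / 2, numeric(1))
  gating_config(thr)
}

#' Gate cells into GC subsets from signature scores
#'
#' Sequential rule evaluation: a cell is PC if its PC score exceeds the PC
#' threshold; else prePC, else preMem by the same logic; else LZtoDZ if both
#' the LZ and DZ scores exceed their thresholds; otherwise the larger of the
#' LZ and DZ scores decides (exact ties give "unassigned"). Every cell
#' receives exactly one label.
#'
#' @param scores cells-by-signatures matrix with columns PC, prePC, preMem,
#'   LZ, DZ (and optionally others).
#' @param config a [gating_config()].
#' @return character vector of labels, named by cell.
#' @export
gate_subsets <- function(scores, config = gating_config()) {
  need <- c("PC", "prePC", "preMem", "LZ", "DZ")
  miss <- setdiff(need, colnames(scores))
  if (length(miss))
    stop("missing score column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  t <- config$thresholds
  lab <- rep(NA_character_, nrow(scores))
  lab[scores[, "PC"] > t["PC"]] <- "PC"
  free <- is.na(lab)
  lab[free & scores[, "prePC"] > t["prePC"]] <- "prePC"
  free <- is.na(lab)
  lab[free & scores[, "preMem"] > t["preMem"]] <- "preMem"
  free <- is.na(lab)
  lab[free & scores[, "LZ"] > t["LZ"] & scores[, "DZ"] > t["DZ"]] <- "LZtoDZ"
  free <- is.na(lab)
  lab[free & scores[, "LZ"] > scores[, "DZ"]] <- "LZ"
  lab[free & scores[, "DZ"] > scores[, "LZ"]] <- "DZ"
  lab[is.na(lab)] <- "unassigned"
  stats::setNames(lab, rownames(scores))
}

#' Infer cell-cycle phase from S and G2M signatures
#'
#' S and G2M module scores are computed as in [module_score()]; a cell is
#' assigned the larger-scoring phase if either score is positive, and
#' "G1/quiescent" otherwise. An exact positive tie resolves to "S".
#'
#' @param norm_matrix normalized gene-by-cell matrix.
#' @param s_genes,g2m_genes phase signature gene sets.
#' @inheritParams module_score
#' @return character vector of phases per cell.
#' @export
cell_cycle_phase <- function(norm_matrix, s_genes, g2m_genes, n_bins = 24,
                             n_ctrl = 100, seed = 0L) {
  s <- module_score(norm_matrix, s_genes, n_bins, n_ctrl, seed)
  g <- module_score(norm_matrix, g2m_genes, n_bins, n_ctrl, seed)
  phase <- ifelse(s <= 0 & g <= 0, "G1/quiescent", ifelse(g > s, "G2M", "S"))
  stats::setNames(phase, colnames(norm_matrix))
}
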