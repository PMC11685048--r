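#' Per-cell quality-control metrics
#'
#' Computes, for every cell of a UMI count matrix, the total endogenous UMI
#' count (ERCC spike-ins excluded), the number of endogenous genes detected,
#' the percentage of transcripts from mitochondrial genes, and the ERCC
#' spike-in quantification accuracy — the Pearson correlation, across spike-in
#' species with positive expected concentration, of log1p(observed count)
#' against log10(expected concentration).
#'
#' @param counts gene-by-cell matrix (dense or \pkg{Matrix} sparse); ERCC rows
#'   identified by \code{ercc_prefix}, mitochondrial rows by \code{mito_genes}
#'   or \code{mito_prefix}.
#' @param ercc_expected named numeric vector of expected spike-in
#'   concentrations (names = ERCC row ids). \code{NULL} disables the accuracy
#'   metric (returned as \code{NA}).
#' @param mito_genes explicit character vector of mitochondrial gene ids;
#'   overrides the prefix rule.
#' @param ercc_prefix,mito_prefix row-name prefixes used to identify spike-in
#'   and mitochondrial rows (mouse nomenclature \code{"mt-"} by default).
#' @return data.frame with columns \code{cell_id}, \code{total_umi},
#'   \code{n_genes_detected}, \code{pct_mito}, \code{ercc_accuracy}. Cells
#'   with fewer than 3 detected spike-in species get \code{NA} accuracy (and
#'   will fail any finite accuracy threshold).
#' @export
compute_qc_metrics <- function(counts, ercc_expected = NULL, mito_genes = NULL,
                               ercc_prefix = "ERCC-", mito_prefix = "mt-") {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  rn <- rownames(counts)
  is_ercc <- startsWith(rn, ercc_prefix)
  if (is.null(mito_genes)) mito_genes <- rn[startsWith(rn, mito_prefix)]
  if (!all(mito_genes %in% rn))
    stop("mito_genes must be a subset of the matrix row names", call. = FALSE)
  endo <- counts[!is_ercc, , drop = FALSE]
  total_umi <- Matrix::colSums(endo)
  n_genes <- Matrix::colSums(endo > 0)
  mito_total <- if (length(mito_genes))
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) else 0
  pct_mito <- ifelse(total_umi > 0, 100 * mito_total / total_umi, 0)

  ercc_accuracy <- rep(NA_real_, ncol(counts))
  if (!is.null(ercc_expected) && any(is_ercc)) {
    ids <- intersect(rn[is_ercc], names(ercc_expected)[ercc_expected > 0])
    if (length(ids) >= 3) {
      obs <- as.matrix(counts[ids, , drop = FALSE])
      lexp <- log10(ercc_expected[ids])
      ercc_accuracy <- apply(obs, 2, function(o) {
        if (sum(o > 0) < 3) return(NA_real_)   # too few detected species
        suppressWarnings(stats::cor(log1p(o), lexp))
      })
    }
  }
  data.frame(cell_id = colnames(counts), total_umi = as.numeric(total_umi),
             n_genes_detected = as.integer(n_genes),
             pct_mito = as.numeric(pct_mito),
             ercc_accuracy = as.numeric(ercc_accuracy),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quality-control thresholds
#'
#' The four criteria applied by [filter_cells()]. The numeric defaults are
#' typical for plate-based single-cell protocols and are configuration, not
#' constants; real datasets should tune them per run.
#'
#' @param min_total_umi minimum endogenous UMI total.
#' @param min_genes minimum number of genes detected.
#' @param max_pct_mito maximum percent mitochondrial transcripts.
#' @param min_ercc_accuracy minimum ERCC quantification accuracy (correlation).
#' @return list of class \code{"qc_thresholds"}.
#' @export
qc_thresholds <- function(min_total_umi = 2000, min_genes = 500,
                          max_pct_mito = 20, min_ercc_accuracy = 0.8) {
  stopifnot(is.finite(min_total_umi), is.finite(min_genes),
            is.finite(max_pct_mito), is.finite(min_ercc_accuracy),
            min_ercc_accuracy >= -1, min_ercc_accuracy <= 1)
  structure(list(min_total_umi = min_total_umi, min_genes = min_genes,
                 max_pct_mito = max_pct_mito,
                 min_ercc_accuracy = min_ercc_accuracy),
            class = "qc_thresholds")
}

#' Filter cells on quality-control metrics
#'
#' A cell passes iff all four criteria hold; an undefined (NA) ERCC accuracy
#' fails the accuracy criterion.
#'
#' @param metrics data.frame from [compute_qc_metrics()].
#' @param thresholds a [qc_thresholds()] object.
#' @return data.frame \code{cell_id}, \code{pass}, \code{reasons}
#'   (semicolon-separated failure reasons, empty for passing cells).
#' @export
filter_cells <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(all(c("cell_id", "total_umi", "n_genes_detected", "pct_mito",
                  "ercc_accuracy") %in% names(metrics)))
  fails <- cbind(
    low_umi = metrics$total_umi < thresholds$min_total_umi,
    low_genes = metrics$n_genes_detected < thresholds$min_genes,
    high_mito = metrics$pct_mito > thresholds$max_pct_mito,
    bad_ercc = is.na(metrics$ercc_accuracy) |
      metrics$ercc_accuracy < thresholds$min_ercc_accuracy)
  reasons <- apply(fails, 1, function(f)
    paste(colnames(fails)[which(f)], collapse = ";"))
  data.frame(cell_id = metrics$cell_id, pass = rowSums(fails) == 0,
             reasons = reasons, stringsAsFactors = FALSE, row.names = NULL)
}

#' Log-normalize a UMI count matrix
#'
#' Per-cell library-size normalization followed by a natural-log transform:
#' \code{ln(1 + scale_factor * count / cell_total)}, with cell totals taken
#' over endogenous genes only (ERCC spike-in rows are excluded from both the
#' totals and the output).
#'
#' @param counts gene-by-cell count matrix (QC-passing cells only).
#' @param scale_factor library-size scale factor (default 10,000).
#' @param ercc_prefix prefix identifying spike-in rows to drop.
#' @return normalized matrix (same storage class family as the input) over
#'   endogenous genes.
#' @export
lognormalize <- function(counts, scale_factor = 10000, ercc_prefix = "ERCC-") {
  stopifnot(scale_factor > 0)
  rn <- rownames(counts)
  if (!is.null(rn)) counts <- counts[!startsWith(rn, ercc_prefix), , drop = FALSE]
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0))
    stop("zero-total cell(s): ",
         paste(utils::head(colnames(counts)[totals <= 0], 5), collapse = ", "),
         "; remove them with QC filtering first", call. = FALSE)
  if (inherits(counts, "sparseMatrix")) {
    norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
    norm@x <- log1p(norm@x)
    dimnames(norm) <- dimnames(counts)
    norm
  } else {
    log1p(sweep(as.matrix(counts), 2, totals / scale_factor, "/"))
  }
}
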