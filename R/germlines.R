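#' Bundled germline V-region references
#'
#' Generates the package's invented germline V-segment reference set: in-frame
#' 294-nt (98-codon) sequences with an FR1-CDR1-FR2-CDR2-FR3 layout, named in
#' IMGT style (\code{"IGHV1-sim*01"}, \code{"IGKV1-sim*01"}, ...). The set is a
#' deterministic constant (built from an internal fixed seed) so that allele
#' lookups, mutation planting and mutation counting are reproducible across
#' sessions without any external database download.
#'
#' Region maps use 0-based half-open coordinates with codon layout
#' FR1 1-25, CDR1 26-33, FR2 34-50, CDR2 51-58, FR3 59-98, and a reading-frame
#' offset of 0 (sequences start in frame).
#'
#' @param n_heavy,n_kappa,n_lambda number of IGHV / IGKV / IGLV genes.
#' @param v_length V-region length in nucleotides; must be a multiple of 3.
#' @return A list with elements \code{sequences} (named character vector of
#'   nucleotide sequences), \code{region_maps} (named list, one region map per
#'   allele) and \code{loci} (named character: IGH/IGK/IGL per allele).
#' @export
germline_references <- function(n_heavy = 8, n_kappa = 6, n_lambda = 2,
                                v_length = 294) {
  stopifnot(v_length %% 3 == 0, n_heavy >= 1, n_kappa >= 1, n_lambda >= 0)
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  n_codons <- v_length / 3
  names <- c(sprintf("IGHV%d-sim*01", seq_len(n_heavy)),
             sprintf("IGKV%d-sim*01", seq_len(n_kappa)),
             if (n_lambda > 0) sprintf("IGLV%d-sim*01", seq_len(n_lambda)))
  loci <- c(rep("IGH", n_heavy), rep("IGK", n_kappa), rep("IGL", n_lambda))
  names(loci) <- names
  seqs <- with_seed(902140L, {
    vapply(seq_along(names), function(i)
      paste(sample(codons, n_codons, replace = TRUE), collapse = ""),
      character(1))
  })
  names(seqs) <- names
  rm <- default_region_map(v_length)
  region_maps <- stats::setNames(rep(list(rm), length(names)), names)
  list(sequences = seqs, region_maps = region_maps, loci = loci)
}

#' Default V-region CDR/FW region map
#'
#' @param v_length sequence length in nt (multiple of 3, >= 294 uses the
#'   canonical codon layout truncated/extended on FR3).
#' @return region map list: \code{frame_offset} (0-based nt offset of the
#'   reading frame) and \code{regions} (data.frame name/label/start/end,
#'   0-based half-open).
#' @export
default_region_map <- function(v_length = 294) {
  stopifnot(v_length %% 3 == 0, v_length >= 180)
  # codon boundaries (1-based codons): FR1 1-25, CDR1 26-33, FR2 34-50,
  # CDR2 51-58, FR3 59-end
  b <- c(0, 25, 33, 50, 58) * 3L
  e <- c(b[-1], v_length)
  list(frame_offset = 0L,
       regions = data.frame(
         name = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
         label = c("FW", "CDR", "FW", "CDR", "FW"),
         start = as.integer(b), end = as.integer(e),
         stringsAsFactors = FALSE))
}

#' Look up the germline sequence and region map for a V call
#'
#' Resolves \code{v_call} against a reference set. A call with no allele
#' suffix (no \code{"*"}) resolves to allele \code{*01} of that gene.
#'
#' @param v_call V gene/allele string, e.g. \code{"IGHV1-sim*01"} or
#'   \code{"IGHV1-sim"}.
#' @param references reference set as returned by [germline_references()].
#' @return list with \code{sequence}, \code{region_map}, \code{allele}.
#' @export
infer_germline <- function(v_call, references) {
  stopifnot(is.character(v_call), length(v_call) == 1L)
  allele <- v_call
  if (!grepl("\\*", allele)) allele <- paste0(allele, "*01")
  if (!allele %in% names(references$sequences)) {
    stop("unknown V allele '", v_call, "'; available: ",
         paste(names(references$sequences), collapse = ", "), call. = FALSE)
  }
  list(sequence = unname(references$sequences[[allele]]),
       region_map = references$region_maps[[allele]],
       allele = allele)
}
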