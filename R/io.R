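# Readers and writers for the package's interchange formats. Writers prepend
# a one-line provenance comment ('#' prefix); readers skip comment lines.
# Matrix Market files follow the format's own header instead.

provenance_line <- function(seed = NULL, config_hash = NULL) {
  paste0("# gcmabs ", as.character(utils::packageVersion("gcmabs")),
         if (!is.null(seed)) paste0(" | seed=", seed),
         if (!is.null(config_hash)) paste0(" | config=", config_hash))
}

write_table_prov <- function(df, path, sep = ",", seed = NULL,
                             config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(seed, config_hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_prov <- function(path, sep = ",") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write AIRR rearrangement tables
#'
#' Tab-separated tables using AIRR community field names
#' (\code{cell_id}, \code{sequence_id}, \code{locus}, \code{v_call},
#' \code{j_call}, \code{c_call}, \code{junction}, \code{junction_aa},
#' \code{sequence}, \code{duplicate_count}, \code{productive}, \code{frame}).
#' String and integer fields round-trip bit-exact.
#'
#' @param path file path.
#' @param contigs contig data.frame.
#' @param seed,config_hash optional provenance fields.
#' @return \code{read_airr}: validated data.frame.
#' @export
read_airr <- function(path) {
  x <- read_table_prov(path, sep = "\t")
  need <- c("cell_id", "sequence_id", "locus", "v_call", "j_call", "c_call",
            "junction", "sequence", "duplicate_count", "productive", "frame")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed AIRR header in ", path, ": missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!x$locus %in% c("IGH", "IGK", "IGL")))
    stop("invalid locus at line ",
         which(!x$locus %in% c("IGH", "IGK", "IGL"))[1] + 2L, call. = FALSE)
  if (any(x$duplicate_count < 0))
    stop("negative duplicate_count at line ",
         which(x$duplicate_count < 0)[1] + 2L, call. = FALSE)
  x$c_call[x$c_call == ""] <- NA_character_
  x$productive <- as.logical(x$productive)
  x$frame <- as.logical(x$frame)
  x
}

#' @rdname read_airr
#' @export
write_airr <- function(contigs, path, seed = NULL, config_hash = NULL) {
  write_table_prov(contigs, path, sep = "\t", seed = seed,
                   config_hash = config_hash)
}

#' Read / write a UMI count matrix
#'
#' Matrix Market (\code{matrix.mtx} + \code{genes.tsv} + \code{barcodes.tsv}
#' in one directory) or a single dense CSV with genes as rows. Counts must be
#' non-negative.
#'
#' @param dir directory for the MTX triplet.
#' @param counts gene-by-cell matrix.
#' @return \code{read_counts_mtx}: sparse \code{dgCMatrix} with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop("matrix dimensions disagree with genes/barcodes files", call. = FALSE)
  if (any(m@x < 0)) stop("negative count in matrix", call. = FALSE)
  dimnames(m) <- list(genes, barcodes)
  methods::as(m, "CsparseMatrix")
}

#' @rdname read_counts_mtx
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname read_counts_mtx
#' @param path CSV path (genes as rows, header = cell ids).
#' @export
read_counts_csv <- function(path) {
  x <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                       comment.char = "#")
  m <- as.matrix(x)
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)[1]
    stop("negative count at row ", bad, " of ", path, call. = FALSE)
  }
  m
}

#' @rdname read_counts_mtx
#' @export
write_counts_csv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), as.matrix(counts),
                   check.names = FALSE)
  write_table_prov(df, path)
}

#' Read / write germline references (FASTA + JSON region maps)
#'
#' @param fasta_path FASTA of V-region germline sequences (names = alleles).
#' @param region_map_path JSON file of region maps (0-based half-open
#'   coordinates, one entry per allele).
#' @param references reference set as from [germline_references()].
#' @return \code{read_germlines}: a reference set list.
#' @export
read_germlines <- function(fasta_path, region_map_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  sequences <- stats::setNames(as.character(seqs), names(seqs))
  raw <- jsonlite::read_json(region_map_path, simplifyVector = TRUE)
  region_maps <- lapply(raw$region_maps, function(rm) {
    rm$regions <- as.data.frame(rm$regions, stringsAsFactors = FALSE)
    validate_region_map(rm)
  })
  loci <- unlist(raw$loci)
  list(sequences = sequences, region_maps = region_maps, loci = loci)
}

#' @rdname read_germlines
#' @export
write_germlines <- function(references, fasta_path, region_map_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(references$sequences), fasta_path)
  jsonlite::write_json(
    list(coordinate_system = "0-based half-open",
         region_maps = references$region_maps,
         loci = as.list(references$loci)),
    region_map_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fasta_path)
}

#' Read / write an index-sort fluorescence table
#'
#' CSV with \code{plate}, \code{well} and one column per compensated channel.
#' Wells must fit 96-well geometry (A1-H12) and (plate, well) must be unique.
#'
#' @param path CSV path.
#' @param table index-sort data.frame.
#' @export
read_index_sort <- function(path) {
  x <- read_table_prov(path)
  stopifnot(all(c("plate", "well") %in% names(x)))
  bad <- !is_valid_well(x$well)
  if (any(bad))
    stop("well geometry violation ('", x$well[which(bad)[1]], "') at line ",
         which(bad)[1] + 2L, " of ", path, call. = FALSE)
  if (anyDuplicated(paste(x$plate, x$well)))
    stop("duplicate (plate, well) key in ", path, call. = FALSE)
  x
}

#' @rdname read_index_sort
#' @export
write_index_sort <- function(table, path, seed = NULL, config_hash = NULL) {
  write_table_prov(table, path, seed = seed, config_hash = config_hash)
}

#' Read / write a long-format ELISA plate table
#'
#' Columns: \code{mab_id}, \code{amount_ng}, \code{replicate}, \code{od};
#' control rows use mab_id \code{"no_primary"} / \code{"positive_control"}.
#'
#' @param path CSV path.
#' @param plate plate data.frame.
#' @export
read_elisa_plate <- function(path) {
  x <- read_table_prov(path)
  need <- c("mab_id", "amount_ng", "od")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed ELISA plate header: missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(x$od < 0, na.rm = TRUE))
    stop("negative OD at line ", which(x$od < 0)[1] + 2L, call. = FALSE)
  x
}

#' @rdname read_elisa_plate
#' @export
write_elisa_plate <- function(plate, path, seed = NULL, config_hash = NULL) {
  write_table_prov(plate, path, seed = seed, config_hash = config_hash)
}

#' Read / write signature gene lists (JSON)
#'
#' @param path JSON path.
#' @param signatures named list of gene vectors.
#' @export
read_signatures <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.character)
}

#' @rdname read_signatures
#' @export
write_signatures <- function(signatures, path) {
  jsonlite::write_json(signatures, path, pretty = TRUE)
  invisible(path)
}

#' Write a simulated bundle to disk
#'
#' Writes every component of a [simulate_dataset()] bundle in its interchange
#' format: MTX counts, AIRR contigs, germline FASTA + region-map JSON,
#' index-sort CSV, ELISA plate CSV, signature JSON, ERCC concentrations CSV
#' and ground-truth JSON.
#'
#' @param bundle a \code{gcmabs_bundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- bundle$config$seed
  write_counts_mtx(bundle$counts, file.path(dir, "counts"))
  write_airr(bundle$contigs, file.path(dir, "contigs.tsv"), seed = seed)
  write_germlines(bundle$germlines, file.path(dir, "germlines.fasta"),
                  file.path(dir, "region_maps.json"))
  write_index_sort(bundle$index_sort, file.path(dir, "index_sort.csv"),
                   seed = seed)
  write_elisa_plate(bundle$elisa, file.path(dir, "elisa_plate.csv"),
                    seed = seed)
  write_signatures(c(bundle$signatures, bundle$cc_signatures),
                   file.path(dir, "signatures.json"))
  write_table_prov(data.frame(ercc_id = names(bundle$ercc_expected),
                              concentration = bundle$ercc_expected),
                   file.path(dir, "ercc_expected.csv"), seed = seed)
  write_table_prov(bundle$cell_metadata, file.path(dir, "cell_metadata.csv"),
                   seed = seed)
  jsonlite::write_json(bundle$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Bundled characteristics of recombinant mAbs from OVA-specific GC B cells
#'
#' Loads the package's reference table of 37 recombinant monoclonal
#' antibodies derived from five OVA-specific GC B-cell clonotypes (c179,
#' c248, c127, c87, c184) and their synthesized germline revertants: somatic
#' mutation counts in the CDR and framework regions of the heavy (VH) and
#' kappa light (VK) chains, the ELISA binding threshold in ng (right-censored
#' entries printed as ">1000"), and the OVA-AF647 surface binding on the
#' asinh(MFI/100) scale (not available for germline revertants, which have no
#' parent cell).
#'
#' @return data.frame with numeric \code{threshold_ng}, logical
#'   \code{threshold_censored} parsed from the printed threshold strings, and
#'   the raw \code{elisa_threshold_ng} display column.
#' @export
load_ova_mab_table <- function() {
  path <- system.file("extdata", "ova_gc_mabs.csv", package = "gcmabs",
                      mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$threshold_censored <- startsWith(x$elisa_threshold_ng, ">")
  x$threshold_ng <- suppressWarnings(as.numeric(x$elisa_threshold_ng))
  x$censor_limit_ng <- ifelse(x$threshold_censored,
                              as.numeric(sub("^>", "", x$elisa_threshold_ng)),
                              NA_real_)
  x
}
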