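#' Hyperbolic arcsine transform of fluorescence values
#'
#' \code{asinh(value / cofactor)}; the standard linearizing transform for
#' compensated cytometry data, defined (and odd) for negative values. The
#' default cofactor of 100 matches the reporting convention
#' \code{asinh(MFI/100)} used throughout the package.
#'
#' @param value numeric fluorescence value(s).
#' @param cofactor positive scaling cofactor.
#' @export
asinh_transform <- function(value, cofactor = 100) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be > 0", call. = FALSE)
  asinh(value / cofactor)
}

#' Attach index-sort fluorescence to cells
#'
#' Joins an index-sort table (one row per sorted well, compensated fluorescence
#' channels as columns) onto cells via their (plate, well) coordinates. Each
#' cell gains the raw value and the arcsinh-transformed value
#' (\code{asinh_<channel>}) of every channel. The attachment is lossless: raw
#' values are carried through bit-exact.
#'
#' @param index_table data.frame with \code{plate}, \code{well} and one column
#'   per channel; (plate, well) must be unique and wells must fit 96-well
#'   geometry (A1-H12).
#' @param well_map data.frame mapping cells to wells: \code{cell_id},
#'   \code{plate}, \code{well}.
#' @param cofactor asinh cofactor (per-call override).
#' @return list with \code{cells} (well_map plus raw and transformed channel
#'   columns) and \code{unmapped_wells} (index-table wells with no cell).
#' @export
attach_index_sort <- function(index_table, well_map, cofactor = 100) {
  stopifnot(all(c("plate", "well") %in% names(index_table)),
            all(c("cell_id", "plate", "well") %in% names(well_map)))
  bad <- !is_valid_well(index_table$well)
  if (any(bad))
    stop("invalid well id(s) for 96-well geometry at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(utils::head(index_table$well[bad], 5), collapse = ", "),
         call. = FALSE)
  ikey <- paste(index_table$plate, index_table$well)
  if (anyDuplicated(ikey))
    stop("duplicate (plate, well) in index-sort table", call. = FALSE)
  mkey <- paste(well_map$plate, well_map$well)
  if (anyDuplicated(mkey))
    stop("duplicate cell_id mapping for one well", call. = FALSE)
  if (anyDuplicated(well_map$cell_id))
    stop("duplicate cell_id in well map", call. = FALSE)

  channels <- setdiff(names(index_table), c("plate", "well"))
  hit <- match(mkey, ikey)
  if (anyNA(hit))
    warning(sum(is.na(hit)), " mapped well(s) absent from index-sort table")
  out <- well_map
  for (ch in channels) {
    raw <- index_table[[ch]][hit]
    out[[ch]] <- raw
    out[[paste0("asinh_", ch)]] <- asinh_transform(raw, cofactor)
  }
  list(cells = out, unmapped_wells = index_table[!(ikey %in% mkey),
                                                 c("plate", "well"),
                                                 drop = FALSE])
}
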