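# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. Keeps seeded operations (control-gene
# sampling, simulation) from perturbing user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Translate one codon (3-nt character string) with the standard genetic code.
translate_codon <- function(codon) {
  stopifnot(nchar(codon) == 3L)
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

# Positions are 1-based along the germline; region maps use 0-based half-open
# coordinates. Returns "CDR"/"FW" per position, NA outside mapped regions.
region_labels <- function(region_map, length) {
  lab <- rep(NA_character_, length)
  reg <- region_map$regions
  for (i in seq_len(nrow(reg))) {
    from <- reg$start[i] + 1L
    to <- min(reg$end[i], length)
    if (from <= to) lab[from:to] <- reg$label[i]
  }
  lab
}

validate_region_map <- function(region_map, seq_length = NULL) {
  if (is.null(region_map) || is.null(region_map$regions))
    stop("missing region_map", call. = FALSE)
  reg <- region_map$regions
  stopifnot(all(c("name", "label", "start", "end") %in% names(reg)))
  if (any(!reg$label %in% c("CDR", "FW")))
    stop("region labels must be 'CDR' or 'FW'", call. = FALSE)
  if (any(reg$end <= reg$start)) stop("empty region in region_map", call. = FALSE)
  if (!is.null(seq_length) && max(reg$end) > seq_length)
    stop("region_map extends beyond sequence (length ", seq_length, ")", call. = FALSE)
  invisible(region_map)
}

# 96-well plate geometry: rows A-H, columns 1-12.
valid_wells_96 <- function() {
  as.vector(outer(LETTERS[1:8], 1:12, paste0))
}

is_valid_well <- function(well) well %in% valid_wells_96()
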