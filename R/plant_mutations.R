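#' Plant somatic point mutations into a germline V sequence
#'
#' Introduces exactly \code{n_mut} nucleotide substitutions at distinct random
#' positions of a germline sequence. Each planted mutation is recorded with its
#' position, original and substituted base, CDR/FW region label, and a silent
#' flag computed by translating the germline codon against the codon with that
#' single substitution applied (all other positions germline) in the reading
#' frame given by the region map.
#'
#' @param germline germline nucleotide sequence (character scalar, ACGT).
#' @param region_map region map (see [default_region_map()]); required.
#' @param n_mut number of substitutions to plant; must not exceed sequence
#'   length.
#' @param seed integer seed making the draw reproducible.
#' @return list with \code{sequence} (mutated sequence) and \code{mutations}
#'   (data.frame: position (1-based), from, to, region, silent).
#' @export
plant_mutations <- function(germline, region_map, n_mut, seed = 1L) {
  if (missing(region_map) || is.null(region_map))
    stop("missing region_map", call. = FALSE)
  stopifnot(is.character(germline), length(germline) == 1L)
  len <- nchar(germline)
  validate_region_map(region_map, len)
  if (n_mut < 0 || n_mut > len)
    stop("n_mut must be in [0, sequence length]", call. = FALSE)
  empty <- data.frame(position = integer(0), from = character(0),
                      to = character(0), region = character(0),
                      silent = logical(0), stringsAsFactors = FALSE)
  if (n_mut == 0)
    return(list(sequence = germline, mutations = empty))

  bases <- c("A", "C", "G", "T")
  glchars <- strsplit(toupper(germline), "")[[1]]
  labels <- region_labels(region_map, len)
  offset <- region_map$frame_offset %||% 0L

  drawn <- with_seed(seed, {
    pos <- sort(sample.int(len, n_mut))
    to <- vapply(pos, function(p) sample(setdiff(bases, glchars[p]), 1L),
                 character(1))
    list(pos = pos, to = to)
  })
  pos <- drawn$pos
  to <- drawn$to

  silent <- vapply(seq_along(pos), function(i) {
    p <- pos[i]
    if (p <= offset) return(NA)
    ci <- (p - 1L - offset) %/% 3L           # 0-based codon index
    cstart <- offset + ci * 3L + 1L
    if (cstart + 2L > len) return(NA)        # partial trailing codon
    gl_codon <- paste(glchars[cstart:(cstart + 2L)], collapse = "")
    mt <- glchars[cstart:(cstart + 2L)]
    mt[p - cstart + 1L] <- to[i]
    translate_codon(gl_codon) == translate_codon(paste(mt, collapse = ""))
  }, logical(1))

  mutated <- glchars
  mutated[pos] <- to
  list(sequence = paste(mutated, collapse = ""),
       mutations = data.frame(position = pos, from = glchars[pos], to = to,
                              region = labels[pos], silent = silent,
                              stringsAsFactors = FALSE))
}
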