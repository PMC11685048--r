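#' Consolidate reconstructed BCR contigs into one heavy and one light chain
#'
#' Applies the three-step filtering used for plate-based BCR reconstruction
#' output: (1) contigs of the same V(D)J rearrangement — identical
#' (locus, v_call, j_call, junction) — are merged, keeping the single longest
#' sequence; (2) contigs with no constant region identified in frame
#' (\code{frame} FALSE or \code{c_call} absent) are discarded; (3) if several
#' contigs of the same chain class survive (IGH for heavy; IGK/IGL jointly as
#' light), the contig with the highest expression (\code{duplicate_count}) is
#' retained.
#'
#' @param contigs data.frame of contigs of one cell, with AIRR-style columns
#'   \code{cell_id}, \code{sequence_id}, \code{locus}, \code{v_call},
#'   \code{j_call}, \code{c_call}, \code{junction}, \code{sequence},
#'   \code{duplicate_count}, \code{frame}.
#' @return list of class \code{"chain_selection"}: \code{cell_id},
#'   \code{heavy}/\code{light} (single-row data.frame or \code{NULL}) and
#'   \code{paired} (TRUE iff both present).
#' @export
consolidate_contigs <- function(contigs) {
  if (nrow(contigs) == 0)
    return(structure(list(cell_id = NA_character_, heavy = NULL, light = NULL,
                          paired = FALSE), class = "chain_selection"))
  if (length(unique(contigs$cell_id)) != 1L)
    stop("consolidate_contigs expects contigs of a single cell", call. = FALSE)

  # step 1: merge same-rearrangement contigs, keep longest sequence
  key <- paste(contigs$locus, contigs$v_call, contigs$j_call, contigs$junction,
               sep = "\r")
  len <- nchar(contigs$sequence)
  keep <- unlist(lapply(split(seq_len(nrow(contigs)), key), function(idx)
    idx[which.max(len[idx])]), use.names = FALSE)
  x <- contigs[sort(keep), , drop = FALSE]

  # step 2: require an in-frame constant region
  x <- x[!is.na(x$c_call) & x$c_call != "" & x$frame, , drop = FALSE]

  # step 3: per chain class, keep the highest-expressed survivor
  pick <- function(rows) {
    if (nrow(rows) == 0) return(NULL)
    rows[which.max(rows$duplicate_count), , drop = FALSE]
  }
  heavy <- pick(x[x$locus == "IGH", , drop = FALSE])
  light <- pick(x[x$locus %in% c("IGK", "IGL"), , drop = FALSE])
  structure(list(cell_id = contigs$cell_id[1], heavy = heavy, light = light,
                 paired = !is.null(heavy) && !is.null(light)),
            class = "chain_selection")
}

#' Select paired chains for every cell of a contig table
#'
#' @param contigs AIRR-style contig data.frame covering many cells.
#' @return data.frame of selected contigs, one row per retained chain, with a
#'   \code{chain} column ("heavy"/"light") and a \code{paired} flag per cell.
#' @export
select_chains <- function(contigs) {
  out <- lapply(split(contigs, contigs$cell_id), function(cc) {
    sel <- consolidate_contigs(cc)
    rows <- rbind(
      if (!is.null(sel$heavy)) cbind(sel$heavy, chain = "heavy"),
      if (!is.null(sel$light)) cbind(sel$light, chain = "light"))
    if (!is.null(rows)) rows$paired <- sel$paired
    rows
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group cells into clonotypes from heavy-chain rearrangements
#'
#' Cells are first blocked by (V gene, junction nucleotide length); within a
#' block, pairs whose junctions have nucleotide identity at or above
#' \code{junction_identity_min} are linked, and connected components under
#' single linkage become clonotypes. The V gene is the \code{v_call} with any
#' allele suffix stripped. Clonotype ids (\code{"c1"}, \code{"c2"}, ...) are
#' assigned in order of first appearance after sorting cells by id, so the
#' partition and its labels are independent of input order.
#'
#' @param heavy data.frame with columns \code{cell_id}, \code{v_call},
#'   \code{junction} (one row per cell).
#' @param junction_identity_min minimum junction identity linking two cells.
#' @return list with \code{assignments} (cell_id, clonotype_id, v_gene,
#'   junction, junction_length), \code{clonotypes} (clonotype_id, v_gene,
#'   junction_length, representative_junction, size) and \code{excluded}
#'   (cells lacking a junction).
#' @export
call_clonotypes <- function(heavy, junction_identity_min = 0.8) {
  stopifnot(all(c("cell_id", "v_call", "junction") %in% names(heavy)))
  if (anyDuplicated(heavy$cell_id))
    stop("duplicate cell_id in heavy-chain table", call. = FALSE)
  bad <- is.na(heavy$junction) | heavy$junction == ""
  excluded <- heavy$cell_id[bad]
  h <- heavy[!bad, , drop = FALSE]
  h <- h[order(h$cell_id), , drop = FALSE]
  h$v_gene <- sub("\\*.*$", "", h$v_call)
  h$junction_length <- nchar(h$junction)

  h$clonotype_id <- NA_character_
  blocks <- split(seq_len(nrow(h)), paste(h$v_gene, h$junction_length))
  comp <- integer(nrow(h))
  n_comp <- 0L
  for (idx in blocks) {
    juncs <- h$junction[idx]
    m <- length(idx)
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (m > 1) {
      jm <- do.call(rbind, strsplit(juncs, ""))
      for (a in seq_len(m - 1)) for (b in (a + 1):m) {
        ident <- mean(jm[a, ] == jm[b, ])
        if (ident >= junction_identity_min) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    roots <- vapply(seq_len(m), find, integer(1))
    labs <- match(roots, unique(roots))
    comp[idx] <- n_comp + labs
    n_comp <- n_comp + max(labs)
  }
  # label components in order of first appearance over cells sorted by id
  h$clonotype_id <- paste0("c", match(comp, unique(comp)))

  clono <- do.call(rbind, lapply(split(h, h$clonotype_id), function(g) {
    rep_j <- names(sort(table(g$junction), decreasing = TRUE))[1]
    data.frame(clonotype_id = g$clonotype_id[1], v_gene = g$v_gene[1],
               junction_length = g$junction_length[1],
               representative_junction = rep_j, size = nrow(g),
               stringsAsFactors = FALSE)
  }))
  clono <- clono[order(as.integer(sub("^c", "", clono$clonotype_id))), ,
                 drop = FALSE]
  rownames(clono) <- NULL
  rownames(h) <- NULL
  list(assignments = h[, c("cell_id", "clonotype_id", "v_gene", "junction",
                           "junction_length")],
       clonotypes = clono, excluded = excluded)
}

#' Count somatic mutations of a chain against its germline
#'
#' Aligns the observed sequence to the germline V region with a global
#' end-free (overlap) alignment (match +1, mismatch −1, a gap of length L
#' costs 4 + (L−1)), then counts each aligned substitution once, attributed to
#' the CDR or FW region of its germline position. Silent status is decided by
#' translating the germline codon against the codon with that single
#' substitution applied (other positions germline). Indels set
#' \code{indel_flag} and are not counted as mutations.
#'
#' @param observed observed nucleotide sequence (the reconstructed contig; may
#'   extend past the V region).
#' @param germline germline V-region sequence.
#' @param region_map region map of the germline (see [default_region_map()]).
#' @param min_coverage minimum fraction of the germline that must be aligned.
#' @return list of class \code{"mutation_profile"}: \code{cdr_count},
#'   \code{fw_count}, \code{silent_count}, \code{nonsilent_count},
#'   \code{total_count}, \code{indel_flag}, and \code{mutations} (data.frame
#'   position/from/to/region/silent).
#' @export
count_mutations <- function(observed, germline, region_map,
                            min_coverage = 0.8) {
  validate_region_map(region_map, nchar(germline))
  pal <- overlap_align(observed, germline)
  sstart <- Biostrings::start(Biostrings::subject(pal))
  send <- Biostrings::end(Biostrings::subject(pal))
  covered <- (send - sstart + 1) / nchar(germline)
  if (covered < min_coverage)
    stop("sequence/germline mismatch: alignment covers only ",
         round(100 * covered), "% of the germline", call. = FALSE)

  ap <- strsplit(as.character(Biostrings::alignedPattern(pal)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pal)), "")[[1]]
  # germline position of each aligned column (NA at subject gaps)
  gpos <- sstart - 1L + cumsum(as_ != "-")
  labels <- region_labels(region_map, nchar(germline))
  offset <- region_map$frame_offset %||% 0L
  glchars <- strsplit(toupper(germline), "")[[1]]

  indel <- any(ap == "-") || any(as_ == "-")
  is_sub <- ap != "-" & as_ != "-" & ap != as_
  pos <- gpos[is_sub]
  to <- ap[is_sub]
  keep <- !is.na(labels[pos])
  pos <- pos[keep]; to <- to[keep]

  silent <- vapply(seq_along(pos), function(i) {
    p <- pos[i]
    if (p <= offset) return(NA)
    ci <- (p - 1L - offset) %/% 3L
    cstart <- offset + ci * 3L + 1L
    if (cstart + 2L > length(glchars)) return(NA)
    gl_codon <- paste(glchars[cstart:(cstart + 2L)], collapse = "")
    mt <- glchars[cstart:(cstart + 2L)]
    mt[p - cstart + 1L] <- to[i]
    translate_codon(gl_codon) == translate_codon(paste(mt, collapse = ""))
  }, logical(1))

  muts <- data.frame(position = pos, from = glchars[pos], to = to,
                     region = labels[pos], silent = silent,
                     stringsAsFactors = FALSE)
  structure(list(
    cdr_count = sum(muts$region == "CDR"),
    fw_count = sum(muts$region == "FW"),
    silent_count = sum(muts$silent, na.rm = TRUE),
    nonsilent_count = sum(!muts$silent, na.rm = TRUE),
    total_count = nrow(muts),
    indel_flag = indel,
    mutations = muts), class = "mutation_profile")
}

# Global end-free (overlap) alignment used by count_mutations: match +1,
# mismatch -1, a gap of length L costs 4 + (L - 1).
overlap_align <- function(observed, germline) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(observed),
    subject = Biostrings::DNAString(germline),
    type = "overlap", substitutionMatrix = submat,
    gapOpening = 3, gapExtension = 1)
}

#' Mutation profiles for all selected chains of a dataset
#'
#' Convenience wrapper running [infer_germline()] + [count_mutations()] over a
#' chain-selection table and returning one row per cell with the heavy (VH)
#' and light (VK/VL) region/silence splits.
#'
#' @param selections data.frame from [select_chains()].
#' @param references germline reference set ([germline_references()]).
#' @return data.frame: cell_id, vh_cdr, vh_fw, vh_silent, vh_nonsilent,
#'   vh_total, vl_cdr, vl_fw, vl_silent, vl_nonsilent, vl_total, indel_flag.
#' @export
count_mutations_all <- function(selections, references) {
  cells <- unique(selections$cell_id)
  rows <- lapply(cells, function(cid) {
    sel <- selections[selections$cell_id == cid, , drop = FALSE]
    prof <- function(chain) {
      r <- sel[sel$chain == chain, , drop = FALSE]
      if (nrow(r) == 0) return(NULL)
      g <- infer_germline(r$v_call[1], references)
      count_mutations(r$sequence[1], g$sequence, g$region_map)
    }
    h <- prof("heavy"); l <- prof("light")
    z <- function(p, f) if (is.null(p)) NA_integer_ else p[[f]]
    data.frame(cell_id = cid,
               vh_cdr = z(h, "cdr_count"), vh_fw = z(h, "fw_count"),
               vh_silent = z(h, "silent_count"),
               vh_nonsilent = z(h, "nonsilent_count"),
               vh_total = z(h, "total_count"),
               vl_cdr = z(l, "cdr_count"), vl_fw = z(l, "fw_count"),
               vl_silent = z(l, "silent_count"),
               vl_nonsilent = z(l, "nonsilent_count"),
               vl_total = z(l, "total_count"),
               indel_flag = isTRUE(h$indel_flag) || isTRUE(l$indel_flag),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
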