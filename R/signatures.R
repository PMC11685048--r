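#' Default gene signatures for GC B-cell subsets and cell cycle
#'
#' The six germinal-center subset signatures are the top-5 marker genes of each
#' subset (light zone LZ, dark zone DZ, recycling LZtoDZ, memory-precursor
#' preMem, plasma-cell-precursor prePC, plasma cell PC); the S and G2M
#' signatures carry canonical replication / mitosis genes. These are the
#' default inputs to [module_score()] and [gate_subsets()]; users supply their
#' own lists for real datasets.
#'
#' @return named list of character vectors of gene symbols.
#' @export
default_signatures <- function() {
  list(
    LZ      = c("Fcer2a", "Cd83", "H2-Oa", "Cd86", "Nfkbia"),
    DZ      = c("Gcsam", "Ccnb2", "Hmces", "Pafah1b3", "Stmn1"),
    LZtoDZ  = c("C1qbp", "Pa2g4", "Apex1", "Nop58", "Exosc7"),
    preMem  = c("Serpinb1a", "Capg", "Ms4a4c", "Gpr183", "Btg1"),
    prePC   = c("Sub1", "Pdia4", "Emb", "Glo1", "Polr2h"),
    PC      = c("Sdc1", "Fam46c", "Irf4", "Bst2", "Glipr1"),
    S_phase = c("Mcm3", "Mcm5", "Pcna", "Rrm2", "Slbp"),
    G2M_phase = c("Mki67", "Top2a", "Ube2c", "Birc5", "Cenpa")
  )
}

#' Remove cell-cycle-associated genes from a signature
#'
#' DZ and LZ transcriptional programs are confounded by proliferation; before
#' scoring these signatures, genes on a supplied cell-cycle gene list are
#' removed so that the subset score reflects state, not cycle phase.
#'
#' @param gene_set character vector of signature genes.
#' @param cc_gene_list character vector of cell-cycle-associated genes.
#' @return list with \code{genes} (filtered set) and \code{removed} (genes
#'   that were dropped).
#' @export
remove_cc_genes <- function(gene_set, cc_gene_list) {
  removed <- intersect(gene_set, cc_gene_list)
  list(genes = setdiff(gene_set, cc_gene_list), removed = removed)
}
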