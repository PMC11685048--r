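mk_contig <- function(cell = "cellA", sid, locus = "IGH", v = "IGHV1-sim*01",
                      j = "IGHJ2-sim*01", cc = "IGHG1", junction = "TGTGCGAGA",
                      seq = NULL, expr = 100, frame = TRUE) {
  if (is.null(seq))
    seq <- paste0(strrep("ACGT", 100), junction, strrep("GATC", 20))
  data.frame(cell_id = cell, sequence_id = sid, locus = locus, v_call = v,
             j_call = j, c_call = cc, junction = junction,
             junction_aa = "X", sequence = seq, duplicate_count = expr,
             productive = TRUE, frame = frame, stringsAsFactors = FALSE)
}

test_that("same-rearrangement contigs merge keeping the largest sequence", {
  a <- mk_contig(sid = "s1", seq = paste0(strrep("A", 471), "TGTGCGAGA"))
  b <- mk_contig(sid = "s2", seq = paste0(strrep("A", 501), "TGTGCGAGA"),
                 expr = 10)
  sel <- consolidate_contigs(rbind(a, b))
  expect_identical(sel$heavy$sequence_id, "s2")   # 510 nt beats 480 nt
})

test_that("contigs without an in-frame constant region are discarded", {
  a <- mk_contig(sid = "s1", cc = NA)
  sel <- consolidate_contigs(a)
  expect_null(sel$heavy)
  expect_false(sel$paired)
  b <- mk_contig(sid = "s2", frame = FALSE)
  expect_null(consolidate_contigs(b)$heavy)
})

test_that("among distinct in-frame rearrangements the highest-expressed wins", {
  a <- mk_contig(sid = "k1", locus = "IGK", v = "IGKV1-sim*01", cc = "IGKC",
                 junction = "TGTCAACAG", expr = 120)
  b <- mk_contig(sid = "k2", locus = "IGK", v = "IGKV2-sim*01", cc = "IGKC",
                 junction = "TGTCAGCAA", expr = 45)
  sel <- consolidate_contigs(rbind(a, b))
  expect_identical(sel$light$sequence_id, "k1")
})

test_that("empty input gives an unpaired empty selection; mixed cells are rejected", {
  sel <- consolidate_contigs(mk_contig(sid = "x")[0, ])
  expect_null(sel$heavy); expect_null(sel$light); expect_false(sel$paired)
  two <- rbind(mk_contig(cell = "a", sid = "s1"), mk_contig(cell = "b", sid = "s2"))
  expect_error(consolidate_contigs(two), "single cell")
})

test_that("consolidation never invents sequence and recovers the planted pair", {
  b <- noisy_bundle()
  ch <- select_chains(b$contigs)
  expect_true(all(ch$sequence_id %in% b$contigs$sequence_id))
  expect_true(all(ch$sequence %in% b$contigs$sequence))
  gt <- b$ground_truth$cells
  h <- ch[ch$chain == "heavy", ]
  l <- ch[ch$chain == "light", ]
  expect_identical(h$sequence_id[match(gt$cell_id, h$cell_id)], gt$true_heavy)
  expect_identical(l$sequence_id[match(gt$cell_id, l$cell_id)], gt$true_light)
})

test_that("identical junctions share a clonotype; different lengths never do", {
  h <- data.frame(cell_id = c("a", "b", "c"),
                  v_call = "IGHV1-sim*01",
                  junction = c("TGTGCGAGAGGG", "TGTGCGAGAGGG", "TGTGCGAGAGGGTTT"),
                  stringsAsFactors = FALSE)
  cl <- call_clonotypes(h)
  asg <- cl$assignments
  expect_identical(asg$clonotype_id[asg$cell_id == "a"],
                   asg$clonotype_id[asg$cell_id == "b"])
  expect_false(asg$clonotype_id[asg$cell_id == "c"] ==
                 asg$clonotype_id[asg$cell_id == "a"])
})

test_that("cells missing a junction are excluded and flagged", {
  h <- data.frame(cell_id = c("a", "b"), v_call = "IGHV1-sim*01",
                  junction = c("TGTGCGAGA", NA), stringsAsFactors = FALSE)
  cl <- call_clonotypes(h)
  expect_identical(cl$excluded, "b")
  expect_identical(nrow(cl$assignments), 1L)
})

test_that("the clonotype partition matches a brute-force single-linkage oracle and input order does not matter", {
  b <- small_bundle()
  ch <- select_chains(b$contigs)
  h <- ch[ch$chain == "heavy", c("cell_id", "v_call", "junction")]
  h <- h[seq_len(min(50, nrow(h))), ]
  cl <- call_clonotypes(h)
  mine <- setNames(cl$assignments$clonotype_id, cl$assignments$cell_id)
  oracle <- brute_force_clonotypes(h)
  ord <- sort(names(mine))
  expect_true(same_partition(unname(mine[ord]), unname(oracle[ord])))
  # permuting input rows relabels nothing
  set.seed(4)
  cl2 <- call_clonotypes(h[sample(nrow(h)), ])
  mine2 <- setNames(cl2$assignments$clonotype_id, cl2$assignments$cell_id)
  expect_identical(mine[ord], mine2[ord])
  # partition property: every eligible cell in exactly one clonotype
  expect_identical(sort(cl$assignments$cell_id), ord)
  expect_identical(sum(cl$clonotypes$size), nrow(h))
})

test_that("fully unique junctions give one clonotype per cell", {
  set.seed(9)
  h <- data.frame(cell_id = sprintf("c%02d", 1:12),
                  v_call = "IGHV1-sim*01",
                  junction = vapply(1:12, function(i)
                    paste(sample(c("A", "C", "G", "T"), 36, TRUE),
                          collapse = ""), character(1)),
                  stringsAsFactors = FALSE)
  # random 36-mers: verify pairwise identity below threshold, then count
  oracle <- brute_force_clonotypes(h)
  expect_identical(length(unique(oracle)), nrow(h))
  cl <- call_clonotypes(h)
  expect_identical(nrow(cl$clonotypes), nrow(h))
})

test_that("mutation counting returns all-zero for identical sequences and splits regions/silence correctly", {
  refs <- germline_references()
  g <- refs$sequences[[1]]
  rm <- refs$region_maps[[1]]
  p <- count_mutations(g, g, rm)
  expect_identical(p$total_count, 0L)
  expect_false(p$indel_flag)

  # single silent substitution inside CDR1 (codons 26-33): put a glycine codon
  # at codon 26 and mutate its third base (GGG -> GGA, both Gly)
  pos <- 26 * 3
  g2 <- paste0(substr(g, 1, pos - 3), "GGG", substr(g, pos + 1, nchar(g)))
  obs <- paste0(substr(g2, 1, pos - 1), "A", substr(g2, pos + 1, nchar(g2)))
  p2 <- count_mutations(obs, g2, rm)
  expect_identical(p2$cdr_count, 1L)
  expect_identical(p2$fw_count, 0L)
  expect_identical(p2$silent_count, 1L)
  expect_identical(p2$nonsilent_count, 0L)
})

test_that("planted mutations are recovered with exact region and silence splits", {
  refs <- germline_references()
  g <- refs$sequences[[2]]
  rm <- refs$region_maps[[2]]
  for (seed in c(2, 7, 13)) {
    p <- plant_mutations(g, rm, 7, seed = seed)
    prof <- count_mutations(p$sequence, g, rm)
    expect_identical(prof$total_count, 7L)
    expect_identical(prof$cdr_count, sum(p$mutations$region == "CDR"))
    expect_identical(prof$fw_count, sum(p$mutations$region == "FW"))
    expect_identical(prof$silent_count, sum(p$mutations$silent))
    expect_identical(prof$nonsilent_count, sum(!p$mutations$silent))
    expect_identical(prof$total_count, prof$cdr_count + prof$fw_count)
    expect_identical(prof$total_count, prof$silent_count + prof$nonsilent_count)
  }
})

test_that("alignment scores equal the exhaustive dynamic-programming oracle on short sequences", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (k in 1:25) {
    a <- paste(sample(bases, sample(15:60, 1), TRUE), collapse = "")
    b <- paste(sample(bases, sample(15:60, 1), TRUE), collapse = "")
    expect_identical(Biostrings::score(overlap_align(a, b)),
                     dp_overlap_score(a, b))
  }
})

test_that("indels are flagged but not counted; poor germline coverage errors", {
  refs <- germline_references()
  g <- refs$sequences[[1]]
  rm <- refs$region_maps[[1]]
  obs <- paste0(substr(g, 1, 150), substr(g, 154, nchar(g)))  # 3-nt deletion
  p <- count_mutations(obs, g, rm)
  expect_true(p$indel_flag)
  expect_identical(p$total_count, 0L)
  expect_error(count_mutations(substr(g, 1, 100), g, rm), "mismatch")
})

test_that("germline lookup resolves alleles, default-allele rule and unknown calls", {
  refs <- germline_references()
  hit <- infer_germline("IGHV1-sim*01", refs)
  expect_identical(hit$sequence, unname(refs$sequences[["IGHV1-sim*01"]]))
  # truncated allele suffix resolves to *01
  expect_identical(infer_germline("IGHV1-sim", refs)$allele, "IGHV1-sim*01")
  expect_error(infer_germline("IGHV9-nope*01", refs), "available")
})
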