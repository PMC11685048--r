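test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_ercc = 1), "n_ercc")
  expect_error(sim_config(shm_rate = -1), "shm_rate")
  expect_error(sim_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(sim_config(n_cells_per_subset = c(LZ = 5)), "n_cells_per_subset")
  expect_error(sim_config(clonotype_size_distribution = c(a = 1)),
               "clonotype_size_distribution")
})

test_that("identical seeds give byte-identical bundles", {
  b1 <- simulate_dataset(sim_config(cells_scale = 0.05, seed = 42))
  b2 <- simulate_dataset(sim_config(cells_scale = 0.05, seed = 42))
  expect_identical(b1, b2)
  b3 <- simulate_dataset(sim_config(cells_scale = 0.05, seed = 43))
  expect_false(identical(b1$counts, b3$counts))
})

test_that("zero SHM rate yields germline-identical V sequences everywhere", {
  b <- simulate_dataset(sim_config(cells_scale = 0.05, seed = 5, shm_rate = 0))
  expect_true(is.null(b$ground_truth$mutations) ||
                nrow(b$ground_truth$mutations) == 0L)
  ch <- select_chains(b$contigs)
  prof <- count_mutations_all(ch[seq_len(10), ], b$germlines)
  expect_true(all(prof$vh_total == 0, na.rm = TRUE))
  expect_true(all(prof$vl_total == 0, na.rm = TRUE))
})

test_that("without measurement noise, MFI rank equals true affinity rank and ELISA thresholds fall with affinity", {
  b <- simulate_dataset(sim_config(cells_scale = 0.1, seed = 6,
                                   noise_free = TRUE))
  gt <- b$ground_truth$cells
  mfi <- b$index_sort[["OVA-AF647"]]
  expect_identical(order(mfi), order(gt$affinity))
  te <- b$ground_truth$elisa
  uncens <- te[te$censored == "none", ]
  if (nrow(uncens) >= 2) {
    o <- order(uncens$true_affinity)
    expect_true(all(diff(uncens$true_threshold_ng[o]) <= 0))
  }
})

test_that("clonotype sizes sum to the cell count and cover every cell", {
  for (sc in c(0.05, 0.12)) {
    b <- simulate_dataset(sim_config(cells_scale = sc, seed = 11))
    sizes <- b$ground_truth$clonotype_sizes
    expect_identical(sum(sizes), ncol(b$counts))
    expect_identical(sort(unique(b$ground_truth$cells$clonotype_id)),
                     sort(names(sizes)[sizes > 0]))
  }
  b <- simulate_dataset(sim_config(cells_scale = 0.1, seed = 2,
                                   n_clonotypes = 30L))
  expect_identical(sum(b$ground_truth$clonotype_sizes), ncol(b$counts))
})

test_that("subset markers are elevated in their subset (fold >= 2, zero dropout)", {
  b <- small_bundle()
  keep <- bundle_pass(b)
  norm <- as.matrix(lognormalize(b$counts[, keep]))
  gt <- b$ground_truth$cells
  subset <- gt$subset[match(keep, gt$cell_id)]
  own_only <- c("LZ", "DZ", "prePC", "PC")   # subsets elevating only their own markers
  for (s in own_only) {
    marker_mean <- colMeans(norm[b$signatures[[s]], , drop = FALSE])
    per_subset <- tapply(marker_mean, subset, mean)
    expect_true(all(per_subset[s] > per_subset[setdiff(names(per_subset), s)]),
                label = paste("marker contrast for", s))
  }
})

test_that("each cell carries 1-4 heavy and 1-3 light contigs with one true chain each", {
  b <- noisy_bundle()
  per_cell <- table(b$contigs$cell_id, b$contigs$locus)
  heavy_n <- per_cell[, "IGH"]
  light_n <- rowSums(per_cell[, colnames(per_cell) %in% c("IGK", "IGL"),
                              drop = FALSE])
  expect_true(all(heavy_n >= 1 & heavy_n <= 4))
  expect_true(all(light_n >= 1 & light_n <= 3))
  gt <- b$ground_truth$cells
  expect_true(all(gt$true_heavy %in% b$contigs$sequence_id))
  expect_true(all(gt$true_light %in% b$contigs$sequence_id))
})

test_that("plant_mutations returns exact counts, unique in-bounds positions and codon-consistent silent flags", {
  refs <- germline_references()
  g <- refs$sequences[[1]]
  rm <- refs$region_maps[[1]]

  p0 <- plant_mutations(g, rm, 0)
  expect_identical(p0$sequence, g)
  expect_identical(nrow(p0$mutations), 0L)

  for (seed in 1:10) {
    n <- sample(1:12, 1)
    p <- plant_mutations(g, rm, n, seed = seed)
    expect_identical(nrow(p$mutations), n)
    expect_false(anyDuplicated(p$mutations$position) > 0)
    expect_true(all(p$mutations$position >= 1 &
                      p$mutations$position <= nchar(g)))
    # recompute silent flags independently via full-codon translation
    for (i in seq_len(n)) {
      pos <- p$mutations$position[i]
      ci <- (pos - 1) %/% 3
      gl_codon <- substr(g, ci * 3 + 1, ci * 3 + 3)
      mt <- strsplit(gl_codon, "")[[1]]
      mt[pos - ci * 3] <- p$mutations$to[i]
      same_aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(gl_codon), no.init.codon = TRUE)) ==
        as.character(Biostrings::translate(
          Biostrings::DNAString(paste(mt, collapse = "")), no.init.codon = TRUE))
      expect_identical(p$mutations$silent[i], same_aa)
    }
  }
})

test_that("a third-base GGG to GGA substitution is recorded as silent", {
  g <- paste(rep("GGG", 98), collapse = "")
  rm <- default_region_map(294)
  found <- FALSE
  for (seed in 1:50) {
    p <- plant_mutations(g, rm, 1, seed = seed)
    if (p$mutations$to == "A" && p$mutations$position %% 3 == 0) {
      expect_true(p$mutations$silent)   # GGG -> GGA, both glycine
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("plant_mutations rejects out-of-range requests and missing region maps", {
  refs <- germline_references()
  g <- refs$sequences[[1]]
  expect_error(plant_mutations(g, refs$region_maps[[1]], nchar(g) + 1), "n_mut")
  expect_error(plant_mutations(g, NULL, 1), "region_map")
})
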