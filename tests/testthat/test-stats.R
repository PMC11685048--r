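test_that("integrated table joins on cell_id with per-source accounting", {
  cells <- data.frame(cell_id = c("a", "b", "c"), sample = "d10p")
  labels <- data.frame(cell_id = c("a", "b"), subset = c("LZ", "DZ"))
  stray <- data.frame(cell_id = c("x", "y"), value = 1:2)
  j <- build_integrated_table(cells, labels = labels, stray = stray)
  expect_identical(j$table$cell_id, cells$cell_id)
  expect_identical(j$table$subset, c("LZ", "DZ", NA))
  expect_identical(j$report$labels$matched, 2L)
  expect_identical(j$report$stray$matched, 0L)
  expect_identical(j$report$stray$unmatched, 2L)
  # empty/NULL sources are fine
  j2 <- build_integrated_table(cells, elisa = NULL)
  expect_identical(j2$table, cells)
  dup <- data.frame(cell_id = c("a", "a"), v = 1:2)
  expect_error(build_integrated_table(cells, dup = dup), "duplicate")
})

test_that("integrated table round-trips the simulated ground truth for QC-passing cells", {
  b <- small_bundle()
  keep <- bundle_pass(b)
  gt <- b$ground_truth$cells
  base <- b$cell_metadata[b$cell_metadata$cell_id %in% keep, ]
  ch <- select_chains(b$contigs)
  cl <- call_clonotypes(ch[ch$chain == "heavy", ])
  j <- build_integrated_table(base, clonotypes = cl$assignments)
  expect_identical(nrow(j$table), length(keep))
  tt <- table(gt$clonotype_id[match(j$table$cell_id, gt$cell_id)],
              j$table$clonotype_id)
  expect_true(all(rowSums(tt > 0) == 1))
})

test_that("Kruskal-Wallis H matches hand computation and degenerates gracefully", {
  r <- kruskal_dunn(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                    rep(c("a", "b", "c"), each = 3))
  expect_equal(r$H, 7.2)                         # rank-sum hand computation
  expect_equal(r$df, 2)
  same <- kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_dunn(1:5, c("a", "a", "b", "b", "c")), "offending: c")
})

test_that("H agrees with stats::kruskal.test under ties and monotone transforms", {
  set.seed(12)
  vals <- sample(rep(1:6, each = 4))
  grp <- rep(c("g1", "g2", "g3"), each = 8)
  mine <- kruskal_dunn(vals, grp)
  ref <- kruskal.test(vals, factor(grp))
  expect_equal(mine$H, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  # rank-based: any strictly monotone transform leaves H unchanged
  mono <- kruskal_dunn(exp(vals / 2), grp)
  expect_equal(mono$H, mine$H)
})

test_that("Dunn adjusted p-values dominate raw ones and stay in [0,1]", {
  set.seed(3)
  vals <- c(rnorm(8), rnorm(8, 1), rnorm(8, 2.5))
  grp <- rep(c("a", "b", "c"), each = 8)
  r <- kruskal_dunn(vals, grp)
  expect_true(all(r$pairwise$p_adjusted >= r$pairwise$p - 1e-12))
  expect_true(all(r$pairwise$p_adjusted <= 1))
  expect_identical(nrow(r$pairwise), 3L)
  rh <- kruskal_dunn(vals, grp, p_adjust_method = "holm")
  expect_true(all(rh$pairwise$p_adjusted <= r$pairwise$p_adjusted + 1e-12))
})

test_that("increasing mutation loads across timepoints give a significant omnibus with the extreme pair smallest", {
  b <- small_bundle()
  ch <- select_chains(b$contigs)
  prof <- count_mutations_all(ch, b$germlines)
  gt <- b$ground_truth$cells
  samp <- gt$sample[match(prof$cell_id, gt$cell_id)]
  r <- kruskal_dunn(prof$vh_total, samp)
  expect_lt(r$p_value, 0.05)
  pw <- r$pairwise
  extreme <- pw[(pw$group1 == "d10p" & pw$group2 == "d20s") |
                  (pw$group1 == "d20s" & pw$group2 == "d10p"), ]
  expect_equal(min(pw$p_adjusted), extreme$p_adjusted)
})

test_that("semilog fit recovers exact log-linear data and equals squared Pearson correlation", {
  x <- c(0.5, 2, 8, 32, 128, 512)
  y <- 2.5 - 0.8 * log10(x)
  f <- semilog_fit(x, y)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, -0.8)
  expect_equal(f$intercept, 2.5)

  set.seed(5)
  y2 <- y + rnorm(6, 0, 0.3)
  f2 <- semilog_fit(x, y2)
  expect_equal(f2$r_squared, cor(y2, log10(x))^2)
  # affine rescaling of y leaves R^2 unchanged
  f3 <- semilog_fit(x, 3 * y2 + 1)
  expect_equal(f3$r_squared, f2$r_squared)
  expect_error(semilog_fit(x, rep(1, 6)), "zero variance")
  expect_error(semilog_fit(x[1:2], y2[1:2]), ">= 3")
})

test_that("censor policies cap or exclude right-censored thresholds", {
  x <- c(10, 100, NA, NA, 50)
  cen <- c(FALSE, FALSE, TRUE, TRUE, FALSE)
  y <- c(2, 1, 0.1, 0.05, 1.5)
  fc <- semilog_fit(x, y, censored = cen, censor_policy = "cap")
  expect_identical(fc$n, 5L)
  fe <- semilog_fit(x, y, censored = cen, censor_policy = "exclude")
  expect_identical(fe$n, 3L)
})

test_that("clonotype selection applies the size and binding gates", {
  su <- data.frame(clonotype_id = c("c1", "c2", "c3", "c4"),
                   size = c(4, 6, 8, 5),
                   mean_binding = c(2, 0.2, 1.5, 1.1),
                   n_above_background = c(3, 0, 2, 1))
  expect_identical(select_clonotypes(su), c("c3", "c4"))   # c1 small, c2 dim
  expect_identical(length(select_clonotypes(su, k = 1, seed = 1)), 1L)
  got <- select_clonotypes(su, k = 1, seed = 2)
  expect_identical(got, select_clonotypes(su, k = 1, seed = 2))
})

test_that("simulated qualifying clonotypes are exactly the selected set", {
  b <- small_bundle()
  att <- attach_index_sort(b$index_sort,
                           b$cell_metadata[, c("cell_id", "plate", "well")])
  gt <- b$ground_truth$cells
  tab <- merge(att$cells, gt[, c("cell_id", "clonotype_id", "sample")],
               by = "cell_id")
  su <- summarize_clonotypes(tab)
  hits <- select_clonotypes(su)
  expect_setequal(hits, b$ground_truth$qualifying_clonotypes)
})

test_that("outlier detection is strict on the range and monotone in the cutoff", {
  tab <- data.frame(cell_id = c("a", "b", "c", "d", "e"),
                    `asinh_OVA-AF647` = c(0.2, 0.5, 1.6, 0.3, 0.4),
                    threshold_ng = c(50, 10, 30, NA, 99.9),
                    censored = c("none", "none", "none", "above", "none"),
                    check.names = FALSE)
  out <- detect_outliers(tab)
  expect_identical(out$cell_id, c("a", "e"))   # b on boundary, c bright, d censored
  lo <- detect_outliers(tab, binding_cutoff = 0.3)
  expect_true(all(lo$cell_id %in% out$cell_id))
  expect_identical(nrow(detect_outliers(tab[0, ])), 0L)
})
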