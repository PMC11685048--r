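# Independent reference implementations and shared fixtures.

# Exhaustive affine-gap dynamic-programming aligner (Gotoh), ends-free on both
# sequences: match +1, mismatch -1, a gap of length L costs open + (L-1)*ext.
# Written independently of the package's alignment path; used as the score
# oracle for short sequences.
dp_overlap_score <- function(a, b, match = 1, mismatch = -1,
                             open = 4, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[, 1] <- 0; M[1, ] <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open, Y[i - 1, j] - open, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - open, Y[i, j - 1] - ext)
  }
  max(M[n + 1, ], M[, m + 1], X[n + 1, ], X[, m + 1], Y[n + 1, ], Y[, m + 1])
}

# Brute-force clonotype partition: all pairwise junction identities, explicit
# single-linkage closure within (v_gene, junction length) blocks.
brute_force_clonotypes <- function(heavy, identity_min = 0.8) {
  h <- heavy[order(heavy$cell_id), , drop = FALSE]
  n <- nrow(h)
  vg <- sub("\\*.*$", "", h$v_call)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (vg[i] == vg[j] && nchar(h$junction[i]) == nchar(h$junction[j])) {
      ai <- strsplit(h$junction[i], "")[[1]]
      aj <- strsplit(h$junction[j], "")[[1]]
      linked[i, j] <- mean(ai == aj) >= identity_min
    }
  }
  # transitive closure
  repeat {
    nxt <- linked | (linked %*% linked > 0)
    if (identical(nxt, linked)) break
    linked <- nxt
  }
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      g <- g + 1L
      grp[which(linked[i, ])] <- g
    }
  }
  stats::setNames(grp, h$cell_id)
}

# Kruskal-Wallis H computed from first principles (rank sums, tie correction);
# used both directly and inside the permutation oracle.
kw_H <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rsum <- tapply(r, groups, sum)
  ni <- as.vector(table(groups))
  ties <- table(values)
  denom <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (denom <= 0) return(0)
  (12 / (n * (n + 1)) * sum(rsum^2 / ni) - 3 * (n + 1)) / denom
}

# Two partitions are equal iff their co-membership relations agree.
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  ma <- outer(a, a, "==")
  mb <- outer(b, b, "==")
  identical(ma, mb)
}

# Shared simulated fixtures (built once per test run).
.fixture_env <- new.env()

small_bundle <- function() {
  if (is.null(.fixture_env$small))
    .fixture_env$small <- simulate_dataset(
      sim_config(cells_scale = 0.12, seed = 3, noise_free = TRUE))
  .fixture_env$small
}

noisy_bundle <- function() {
  if (is.null(.fixture_env$noisy))
    .fixture_env$noisy <- simulate_dataset(
      sim_config(cells_scale = 0.12, seed = 8))
  .fixture_env$noisy
}

# QC-passing cells of a bundle, per the generator's own thresholds
bundle_pass <- function(bundle) {
  metrics <- compute_qc_metrics(bundle$counts, bundle$ercc_expected)
  verdict <- filter_cells(metrics, bundle$qc_thresholds)
  verdict$cell_id[verdict$pass]
}

# signature set with cycle genes removed from LZ/DZ, as gating expects
gating_signatures <- function(bundle) {
  sigs <- bundle$signatures
  sigs$LZ <- remove_cc_genes(sigs$LZ, bundle$cc_genes)$genes
  sigs$DZ <- remove_cc_genes(sigs$DZ, bundle$cc_genes)$genes
  sigs
}
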