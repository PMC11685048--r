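#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic dataset generator.
#' Defaults emulate the study design the package targets: a cohort of sorted
#' IgD-negative GC B cells across four immunization timepoints (d10p, d20p,
#' d10s, d20s), six transcriptional subsets with printed-marker structure,
#' clonal BCR lineages carrying somatic hypermutation whose load increases
#' across timepoints, affinity-linked OVA-AF647 index-sort fluorescence, and
#' affinity-linked 4-fold-dilution ELISA saturation curves.
#'
#' @param seed integer seed; the whole bundle is deterministic given the seed.
#' @param n_cells_per_subset named integer vector over subsets LZ, DZ, LZtoDZ,
#'   preMem, prePC, PC. Defaults are the cohort subset sizes (331/300/55/29/27/5).
#' @param cells_scale convenience scalar multiplying all subset sizes.
#' @param n_genes total number of endogenous (non-mito) genes, markers included.
#' @param n_marker_genes_per_subset markers elevated per subset (<= 5 uses the
#'   bundled printed marker names).
#' @param n_ercc,n_mito number of ERCC spike-in and mitochondrial gene rows.
#' @param n_clonotypes number of clonal lineages; \code{NULL} draws sizes from
#'   \code{clonotype_size_distribution} until all cells are covered.
#' @param clonotype_size_distribution named probability vector over lineage
#'   sizes (names are sizes >= 1).
#' @param shm_rate mean substitutions per heavy V region per cell (Poisson);
#'   scaled per sample by \code{shm_sample_multiplier}.
#' @param shm_sample_multiplier named multipliers per sample; defaults increase
#'   d10p -> d20p -> d10s -> d20s.
#' @param sample_proportions sampling probabilities of the four timepoints
#'   (defaults proportional to 145/205/295/124).
#' @param affinity_model list: \code{base_binder}, \code{base_background},
#'   \code{base_germline}, \code{beta_cdr} (log-affinity shift per planted
#'   heavy CDR mutation), \code{p_binder} (probability a lineage is
#'   antigen-binding).
#' @param facs_noise_sd lognormal sd of the MFI noise.
#' @param mfi_scale scale factor from affinity to MFI.
#' @param elisa list: \code{od_max}, \code{hill_like_K_scale},
#'   \code{replicate_noise_sd}, \code{n_dilutions}, \code{n_replicates},
#'   \code{start_ng}, \code{dilution_factor}, \code{negative_control_od},
#'   \code{n_clonotypes} (lineages taken to mAb production).
#' @param dropout_rate per-gene per-cell zero-inflation probability.
#' @param marker_fold fold elevation of subset markers in their subset.
#' @param base_mean_log,base_mean_sdlog lognormal parameters of per-gene base
#'   means.
#' @param nb_size negative binomial dispersion (size) of UMI counts.
#' @param qc_violation_rate fraction of cells planted to violate one QC
#'   criterion.
#' @param noise_free if TRUE, measurement noise is switched off: counts equal
#'   their (rounded) expected values, dropout, FACS and ELISA noise are zero.
#'   Somatic mutations are still drawn (they are signal, not noise).
#' @return validated config list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_subset = c(LZ = 331L, DZ = 300L, LZtoDZ = 55L,
                                              preMem = 29L, prePC = 27L, PC = 5L),
                       cells_scale = 1,
                       n_genes = 600L,
                       n_marker_genes_per_subset = 5L,
                       n_ercc = 12L, n_mito = 5L,
                       n_clonotypes = NULL,
                       clonotype_size_distribution =
                         c(`1` = 0.62, `2` = 0.18, `3` = 0.08,
                           `5` = 0.06, `8` = 0.04, `10` = 0.02),
                       shm_rate = 3,
                       shm_sample_multiplier = c(d10p = 0.5, d20p = 1,
                                                 d10s = 1.5, d20s = 2),
                       sample_proportions = c(d10p = 145, d20p = 205,
                                              d10s = 295, d20s = 124) / 769,
                       affinity_model = list(base_binder = 1,
                                             base_background = 0.02,
                                             base_germline = 0.005,
                                             beta_cdr = 0.12, p_binder = 0.3),
                       facs_noise_sd = 0.3,
                       mfi_scale = 150,
                       elisa = list(od_max = 3, hill_like_K_scale = 350,
                                    replicate_noise_sd = 0.05,
                                    n_dilutions = 6L, n_replicates = 2L,
                                    start_ng = 1000, dilution_factor = 4,
                                    negative_control_od = 0.08,
                                    n_clonotypes = 5L),
                       dropout_rate = 0.1,
                       marker_fold = 4,
                       base_mean_log = log(8), base_mean_sdlog = 1,
                       nb_size = 2,
                       qc_violation_rate = 0.1,
                       noise_free = FALSE) {
  cfg <- as.list(environment())
  cfg$n_cells_per_subset <- round(n_cells_per_subset * cells_scale)
  if (noise_free) {
    cfg$dropout_rate <- 0
    cfg$facs_noise_sd <- 0
    cfg$elisa$replicate_noise_sd <- 0
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a \code{sim_config} list.
#' @export
validate_sim_config <- function(config) {
  fail <- function(field, why) stop("invalid sim_config field '", field, "': ",
                                    why, call. = FALSE)
  req_subsets <- c("LZ", "DZ", "LZtoDZ", "preMem", "prePC", "PC")
  n <- config$n_cells_per_subset
  if (!all(req_subsets %in% names(n)))
    fail("n_cells_per_subset", "must name all of LZ, DZ, LZtoDZ, preMem, prePC, PC")
  if (any(n < 0) || sum(n) < 1) fail("n_cells_per_subset", "counts must be >= 0 and sum >= 1")
  for (f in c("n_genes", "n_marker_genes_per_subset", "n_ercc", "n_mito"))
    if (config[[f]] < 0) fail(f, "must be >= 0")
  if (config$n_genes < 8 * config$n_marker_genes_per_subset + 10)
    fail("n_genes", "too small to hold the marker groups plus background genes")
  if (config$n_ercc < 3) fail("n_ercc", "need >= 3 spike-in species")
  if (config$shm_rate < 0) fail("shm_rate", "must be >= 0")
  if (config$facs_noise_sd < 0) fail("facs_noise_sd", "must be >= 0")
  if (config$dropout_rate < 0 || config$dropout_rate > 1)
    fail("dropout_rate", "must be a probability")
  p <- config$clonotype_size_distribution
  if (is.null(names(p)) || any(is.na(suppressWarnings(as.integer(names(p))))) ||
      any(as.integer(names(p)) < 1) || any(p < 0) || sum(p) <= 0)
    fail("clonotype_size_distribution", "needs named probabilities over sizes >= 1")
  if (abs(sum(config$sample_proportions) - 1) > 1e-8)
    fail("sample_proportions", "must sum to 1")
  el <- config$elisa
  for (f in c("od_max", "hill_like_K_scale", "start_ng", "dilution_factor"))
    if (is.null(el[[f]]) || el[[f]] <= 0) fail(paste0("elisa$", f), "must be > 0")
  if (el$n_dilutions < 2) fail("elisa$n_dilutions", "must be >= 2")
  if (el$replicate_noise_sd < 0) fail("elisa$replicate_noise_sd", "must be >= 0")
  invisible(config)
}

# marker gene names per group, extended with synthetic names when more than
# the five printed markers are requested
sim_marker_genes <- function(k) {
  sig <- default_signatures()
  lapply(stats::setNames(names(sig), names(sig)), function(s) {
    g <- sig[[s]]
    if (k <= length(g)) g[seq_len(k)]
    else c(g, sprintf("%s.sim%d", s, seq_len(k - length(g))))
  })
}

# constant-region and J-segment stubs per locus (deterministic constants)
sim_segment_stubs <- function() {
  with_seed(515001L, {
    bases <- c("A", "C", "G", "T")
    rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    list(J = list(IGH = rand(33), IGK = rand(33), IGL = rand(33)),
         C = list(IGH = rand(60), IGK = rand(60), IGL = rand(60)))
  })
}

#' Simulate a complete synthetic single-cell GC B-cell dataset
#'
#' Generates a bundle with full ground truth: a UMI count matrix with ERCC and
#' mitochondrial rows, an index-sort fluorescence table, an AIRR-style contig
#' table with decoy contigs exercising consolidation, germline references and
#' region maps, ELISA plate tables for the mAb-producing lineages, and the
#' ground-truth record of every planted quantity.
#'
#' @param config a [sim_config()].
#' @return list of class \code{"gcmabs_bundle"} with elements \code{counts}
#'   (sparse gene-by-cell matrix), \code{ercc_expected}, \code{cell_metadata},
#'   \code{contigs}, \code{germlines}, \code{index_sort}, \code{elisa},
#'   \code{signatures}, \code{cc_genes}, \code{qc_thresholds},
#'   \code{ground_truth}, \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  subsets <- c("LZ", "DZ", "LZtoDZ", "preMem", "prePC", "PC")
  nsub <- config$n_cells_per_subset[subsets]
  n_cells <- sum(nsub)

  ## ---- cells: ids, plates/wells, samples, subsets, phases -----------------
  subset <- rep(subsets, times = nsub)
  subset <- sample(subset)                      # shuffle plate layout
  wells <- valid_wells_96()
  plate <- (seq_len(n_cells) - 1L) %/% 96L + 1L
  well <- wells[(seq_len(n_cells) - 1L) %% 96L + 1L]
  cell_id <- paste0("p", plate, ".", well)
  samp <- sample(names(config$sample_proportions), n_cells, replace = TRUE,
                 prob = config$sample_proportions)
  phase_probs <- list(
    LZ = c(`G1/quiescent` = 0.6, S = 0.4, G2M = 0),
    DZ = c(`G1/quiescent` = 0, S = 0.3, G2M = 0.7),
    LZtoDZ = c(`G1/quiescent` = 0, S = 0.7, G2M = 0.3),
    preMem = c(`G1/quiescent` = 1, S = 0, G2M = 0),
    prePC = c(`G1/quiescent` = 0, S = 0.6, G2M = 0.4),
    PC = c(`G1/quiescent` = 1, S = 0, G2M = 0))
  phase <- vapply(subset, function(s) {
    p <- phase_probs[[s]]
    sample(names(p), 1L, prob = p)
  }, character(1))

  ## ---- expression matrix --------------------------------------------------
  markers <- sim_marker_genes(config$n_marker_genes_per_subset)
  marker_genes <- unlist(markers, use.names = FALSE)
  n_filler <- config$n_genes - length(marker_genes)
  genes <- c(marker_genes, sprintf("Gene%04d", seq_len(n_filler)))
  mito_genes <- if (config$n_mito > 0) sprintf("mt-Sim%d", seq_len(config$n_mito)) else character(0)
  ercc_ids <- sprintf("ERCC-%05d", seq_len(config$n_ercc))

  base_mean <- stats::rlnorm(length(genes), config$base_mean_log,
                             config$base_mean_sdlog)
  names(base_mean) <- genes
  base_mean[marker_genes] <- 5      # moderate shared baseline for markers

  # which marker groups are elevated in each subset label
  elevated_groups <- list(
    LZ = "LZ", DZ = "DZ", LZtoDZ = c("LZtoDZ", "LZ", "DZ"),
    preMem = c("preMem", "LZ"), prePC = "prePC", PC = "PC")

  mu <- matrix(base_mean, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, cell_id))
  for (i in seq_len(n_cells)) {
    up <- unlist(markers[elevated_groups[[subset[i]]]], use.names = FALSE)
    if (phase[i] == "S") up <- c(up, markers$S_phase)
    if (phase[i] == "G2M") up <- c(up, markers$G2M_phase)
    mu[up, i] <- mu[up, i] * config$marker_fold
  }

  if (config$noise_free) {
    counts <- round(mu)
  } else {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    if (config$dropout_rate > 0) {
      keep <- matrix(stats::rbinom(length(mu), 1L, 1 - config$dropout_rate),
                     nrow = nrow(mu))
      counts <- counts * keep
    }
  }

  mito_mu <- 60
  mito <- if (config$n_mito > 0) {
    if (config$noise_free)
      matrix(mito_mu, config$n_mito, n_cells, dimnames = list(mito_genes, cell_id))
    else
      matrix(stats::rnbinom(config$n_mito * n_cells, mu = mito_mu,
                            size = config$nb_size),
             config$n_mito, n_cells, dimnames = list(mito_genes, cell_id))
  } else NULL

  ercc_expected <- stats::setNames(0.5 * 2^(seq_len(config$n_ercc) - 1), ercc_ids)
  ercc_lambda <- ercc_expected * 2
  ercc <- if (config$noise_free)
    matrix(rep(round(ercc_lambda), n_cells), config$n_ercc, n_cells,
           dimnames = list(ercc_ids, cell_id))
  else
    matrix(stats::rpois(config$n_ercc * n_cells, rep(ercc_lambda, n_cells)),
           config$n_ercc, n_cells, dimnames = list(ercc_ids, cell_id))

  ## ---- planted QC violations ---------------------------------------------
  n_viol <- round(config$qc_violation_rate * n_cells)
  viol_idx <- if (n_viol > 0) sort(sample.int(n_cells, n_viol)) else integer(0)
  viol_types <- c("low_umi", "high_mito", "bad_ercc", "low_genes")
  qc_violation <- rep("", n_cells)
  if (n_viol > 0)
    qc_violation[viol_idx] <- rep_len(viol_types, n_viol)

  exp_total <- sum(base_mean) + config$n_marker_genes_per_subset * 5 * 3
  qc_thr <- qc_thresholds(
    min_total_umi = round(0.25 * exp_total),
    min_genes = round(0.6 * length(genes)),
    max_pct_mito = 20,
    min_ercc_accuracy = 0.8)

  for (i in viol_idx) {
    switch(qc_violation[i],
      low_umi = {
        tot <- sum(counts[, i])
        counts[, i] <- floor(counts[, i] * min(1, 0.1 * qc_thr$min_total_umi / max(tot, 1)))
      },
      high_mito = {
        if (config$n_mito > 0)
          mito[, i] <- ceiling(0.7 * sum(counts[, i]) / config$n_mito)
      },
      bad_ercc = {
        ercc[, i] <- rev(ercc[, i])
      },
      low_genes = {
        keep_n <- max(3L, round(0.15 * qc_thr$min_genes))
        ord <- order(counts[, i], decreasing = TRUE)
        counts[ord[-seq_len(keep_n)], i] <- 0L
      })
  }

  full_counts <- rbind(counts, if (!is.null(mito)) mito, ercc)
  full_counts <- Matrix::Matrix(full_counts, sparse = TRUE)

  ## ---- clonal structure ---------------------------------------------------
  sizes_avail <- as.integer(names(config$clonotype_size_distribution))
  probs <- config$clonotype_size_distribution / sum(config$clonotype_size_distribution)
  if (!is.null(config$n_clonotypes)) {
    sizes <- sample(sizes_avail, config$n_clonotypes, replace = TRUE, prob = probs)
    while (sum(sizes) < n_cells) sizes <- c(sizes, 1L)
    while (sum(sizes) > n_cells) {
      j <- which.max(sizes)
      if (sizes[j] == 1L) { sizes <- sizes[-j] } else sizes[j] <- sizes[j] - 1L
    }
  } else {
    sizes <- integer(0)
    while (sum(sizes) < n_cells)
      sizes <- c(sizes, sample(sizes_avail, 1L, prob = probs))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_cells)
    sizes <- sizes[sizes > 0]
  }
  n_clone <- length(sizes)
  clone_ids <- sprintf("tc%03d", seq_len(n_clone))
  assignment <- sample(rep(seq_len(n_clone), times = sizes))
  clonotype_id <- clone_ids[assignment]

  refs <- germline_references()
  heavy_alleles <- names(refs$loci)[refs$loci == "IGH"]
  kappa_alleles <- names(refs$loci)[refs$loci == "IGK"]
  lambda_alleles <- names(refs$loci)[refs$loci == "IGL"]
  stubs <- sim_segment_stubs()
  codons_ok <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))

  clone_vh <- sample(heavy_alleles, n_clone, replace = TRUE)
  light_is_kappa <- stats::runif(n_clone) < 0.9 | length(lambda_alleles) == 0
  clone_vl <- ifelse(light_is_kappa,
                     sample(kappa_alleles, n_clone, replace = TRUE),
                     sample(if (length(lambda_alleles)) lambda_alleles else kappa_alleles,
                            n_clone, replace = TRUE))
  clone_jlen <- sample(c(36L, 39L, 42L, 45L), n_clone, replace = TRUE)
  clone_junction <- vapply(clone_jlen, function(l)
    paste(sample(codons_ok, l / 3L, replace = TRUE), collapse = ""), character(1))
  clone_ljunction <- vapply(seq_len(n_clone), function(i)
    paste(sample(codons_ok, 9L, replace = TRUE), collapse = ""), character(1))
  clone_binder <- stats::runif(n_clone) < config$affinity_model$p_binder

  mutate_junction <- function(j, k) {
    if (k == 0) return(j)
    ch <- strsplit(j, "")[[1]]
    pos <- sample.int(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }

  ## ---- per-cell chains, SHM, contigs --------------------------------------
  shm_mult <- config$shm_sample_multiplier[samp]
  contig_rows <- vector("list", n_cells)
  mut_rows <- vector("list", n_cells)
  truth_rows <- vector("list", n_cells)
  affinity <- numeric(n_cells)

  for (i in seq_len(n_cells)) {
    cl <- assignment[i]
    gh <- infer_germline(clone_vh[cl], refs)
    gl <- infer_germline(clone_vl[cl], refs)
    light_locus <- refs$loci[[clone_vl[cl]]]

    n_mut_h <- stats::rpois(1L, config$shm_rate * shm_mult[i])
    n_mut_l <- stats::rpois(1L, 0.7 * config$shm_rate * shm_mult[i])
    ph <- plant_mutations_rng(gh$sequence, gh$region_map, n_mut_h)
    pl <- plant_mutations_rng(gl$sequence, gl$region_map, n_mut_l)

    junc_h <- mutate_junction(clone_junction[cl], sample(0:2, 1L))
    junc_l <- clone_ljunction[cl]
    seq_h <- paste0(ph$sequence, junc_h, stubs$J$IGH, stubs$C$IGH)
    seq_l <- paste0(pl$sequence, junc_l, stubs$J[[light_locus]], stubs$C[[light_locus]])
    expr_h <- if (config$noise_free) 300 else 200 + stats::rpois(1L, 100)
    expr_l <- if (config$noise_free) 250 else 150 + stats::rpois(1L, 80)

    jcall_h <- "IGHJ2-sim*01"
    jcall_l <- paste0(light_locus, "J1-sim*01")
    ccall_h <- "IGHG1"
    ccall_l <- paste0(light_locus, "C")

    mk <- function(sid, locus, v, j, cc, junc, sq, expr, frame) {
      data.frame(cell_id = cell_id[i], sequence_id = sid, locus = locus,
                 v_call = v, j_call = j, c_call = cc, junction = junc,
                 junction_aa = as.character(Biostrings::translate(
                   Biostrings::DNAString(junc), no.init.codon = TRUE)),
                 sequence = sq, duplicate_count = expr, productive = TRUE,
                 frame = frame, stringsAsFactors = FALSE)
    }

    rows <- list(
      mk(paste0(cell_id[i], "_H1"), "IGH", clone_vh[cl], jcall_h, ccall_h,
         junc_h, seq_h, expr_h, TRUE),
      mk(paste0(cell_id[i], "_L1"), light_locus, clone_vl[cl], jcall_l, ccall_l,
         junc_l, seq_l, expr_l, TRUE))

    n_extra_h <- sample(0:3, 1L)
    if (n_extra_h >= 1) {    # fragment of the same rearrangement (merged away)
      frag <- substr(seq_h, 40L, nchar(seq_h) - 10L)
      rows <- c(rows, list(mk(paste0(cell_id[i], "_H2"), "IGH", clone_vh[cl],
                              jcall_h, ccall_h, junc_h, frag, expr_h * 2, TRUE)))
    }
    if (n_extra_h >= 2) {    # no in-frame constant region (discarded)
      junk <- paste(sample(codons_ok, 12L, replace = TRUE), collapse = "")
      bad <- mk(paste0(cell_id[i], "_H3"), "IGH",
                sample(heavy_alleles, 1L), jcall_h, NA_character_,
                junk, paste0(gh$sequence, junk, stubs$J$IGH), expr_h * 3, FALSE)
      rows <- c(rows, list(bad))
    }
    if (n_extra_h >= 3) {    # competing in-frame rearrangement, lower expression
      junk <- paste(sample(codons_ok, 13L, replace = TRUE), collapse = "")
      alt_v <- sample(heavy_alleles, 1L)
      altg <- infer_germline(alt_v, refs)
      rows <- c(rows, list(mk(paste0(cell_id[i], "_H4"), "IGH", alt_v, jcall_h,
                              ccall_h, junk,
                              paste0(altg$sequence, junk, stubs$J$IGH, stubs$C$IGH),
                              max(1, round(expr_h * 0.3)), TRUE)))
    }
    n_extra_l <- sample(0:2, 1L)
    if (n_extra_l >= 1) {
      frag <- substr(seq_l, 40L, nchar(seq_l) - 10L)
      rows <- c(rows, list(mk(paste0(cell_id[i], "_L2"), light_locus, clone_vl[cl],
                              jcall_l, ccall_l, junc_l, frag, expr_l * 2, TRUE)))
    }
    if (n_extra_l >= 2) {
      junk <- paste(sample(codons_ok, 9L, replace = TRUE), collapse = "")
      alt_v <- sample(kappa_alleles, 1L)
      altg <- infer_germline(alt_v, refs)
      rows <- c(rows, list(mk(paste0(cell_id[i], "_L3"), "IGK", alt_v,
                              "IGKJ1-sim*01", "IGKC", junk,
                              paste0(altg$sequence, junk, stubs$J$IGK, stubs$C$IGK),
                              max(1, round(expr_l * 0.3)), TRUE)))
    }
    contig_rows[[i]] <- do.call(rbind, rows)

    muts <- rbind(
      if (nrow(ph$mutations)) cbind(cell_id = cell_id[i], chain = "VH",
                                    ph$mutations, stringsAsFactors = FALSE),
      if (nrow(pl$mutations)) cbind(cell_id = cell_id[i], chain = "VL",
                                    pl$mutations, stringsAsFactors = FALSE))
    mut_rows[[i]] <- muts

    n_cdr_h <- sum(ph$mutations$region == "CDR")
    am <- config$affinity_model
    affinity[i] <- if (clone_binder[cl])
      am$base_binder * exp(am$beta_cdr * n_cdr_h) else am$base_background

    truth_rows[[i]] <- data.frame(
      cell_id = cell_id[i], subset = subset[i], sample = samp[i],
      phase = phase[i], clonotype_id = clonotype_id[i],
      binder = clone_binder[cl], affinity = affinity[i],
      n_mut_vh = n_mut_h, n_mut_vl = n_mut_l,
      true_heavy = paste0(cell_id[i], "_H1"),
      true_light = paste0(cell_id[i], "_L1"),
      qc_violation = qc_violation[i], stringsAsFactors = FALSE)
  }
  contigs <- do.call(rbind, contig_rows)
  rownames(contigs) <- NULL
  mutations_truth <- do.call(rbind, mut_rows)
  truth_cells <- do.call(rbind, truth_rows)

  ## ---- index-sort fluorescence --------------------------------------------
  noise <- if (config$facs_noise_sd > 0)
    exp(stats::rnorm(n_cells, 0, config$facs_noise_sd)) else rep(1, n_cells)
  mfi_ova <- config$mfi_scale * affinity * noise
  index_sort <- data.frame(plate = plate, well = well,
                           `OVA-AF647` = mfi_ova,
                           CD19 = stats::rlnorm(n_cells, log(500), 0.3),
                           GL7 = stats::rlnorm(n_cells, log(300), 0.3),
                           check.names = FALSE, stringsAsFactors = FALSE)

  ## ---- ELISA plates for selected lineages ---------------------------------
  clone_sizes <- as.vector(table(factor(assignment, levels = seq_len(n_clone))))
  above_bg <- tapply(asinh_transform(mfi_ova) > 1, assignment, sum)
  n_above <- rep(0L, n_clone)
  n_above[as.integer(names(above_bg))] <- as.integer(above_bg)
  qualifying <- which(clone_sizes >= 5 & n_above >= 1)
  selected <- qualifying[order(-clone_sizes[qualifying])]
  selected <- utils::head(selected, config$elisa$n_clonotypes)

  el <- config$elisa
  amounts <- make_dilution_series(el$start_ng, el$dilution_factor, el$n_dilutions)
  t_nominal <- el$negative_control_od

  mk_series <- function(mab, clono, aff) {
    K <- el$hill_like_K_scale / aff
    od <- rep(el$od_max * amounts / (amounts + K), each = el$n_replicates)
    if (el$replicate_noise_sd > 0)
      od <- pmax(0, od + stats::rnorm(length(od), 0, el$replicate_noise_sd))
    data.frame(mab_id = mab, clonotype = clono,
               amount_ng = rep(amounts, each = el$n_replicates),
               replicate = rep(seq_len(el$n_replicates), times = length(amounts)),
               od = od, stringsAsFactors = FALSE)
  }
  true_threshold <- function(aff) {
    K <- el$hill_like_K_scale / aff
    astar <- K * t_nominal / (el$od_max - t_nominal)
    if (astar > max(amounts)) list(value = max(amounts), censored = "above")
    else if (astar < min(amounts)) list(value = min(amounts), censored = "below")
    else list(value = astar, censored = "none")
  }

  plate_rows <- list()
  truth_elisa <- list()
  for (cl in selected) {
    members <- which(assignment == cl)
    for (i in members) {
      plate_rows[[length(plate_rows) + 1L]] <-
        mk_series(cell_id[i], clone_ids[cl], affinity[i])
      tt <- true_threshold(affinity[i])
      truth_elisa[[length(truth_elisa) + 1L]] <- data.frame(
        mab_id = cell_id[i], clonotype = clone_ids[cl],
        true_affinity = affinity[i], true_threshold_ng = tt$value,
        censored = tt$censored, stringsAsFactors = FALSE)
    }
    g_aff <- config$affinity_model$base_germline
    gid <- paste0(clone_ids[cl], "_germline")
    plate_rows[[length(plate_rows) + 1L]] <- mk_series(gid, clone_ids[cl], g_aff)
    tt <- true_threshold(g_aff)
    truth_elisa[[length(truth_elisa) + 1L]] <- data.frame(
      mab_id = gid, clonotype = clone_ids[cl], true_affinity = g_aff,
      true_threshold_ng = tt$value, censored = tt$censored,
      stringsAsFactors = FALSE)
  }
  # controls: positive (high-affinity mAb), negative (no primary antibody)
  plate_rows[[length(plate_rows) + 1L]] <- mk_series("positive_control", NA, 5)
  nc_od <- rep(el$negative_control_od, 4L)
  if (el$replicate_noise_sd > 0)
    nc_od <- pmax(0, nc_od + stats::rnorm(4L, 0, el$replicate_noise_sd))
  plate_rows[[length(plate_rows) + 1L]] <- data.frame(
    mab_id = "no_primary", clonotype = NA, amount_ng = NA_real_,
    replicate = 1:4, od = nc_od, stringsAsFactors = FALSE)
  elisa_plate <- do.call(rbind, plate_rows)
  rownames(elisa_plate) <- NULL
  truth_elisa <- if (length(truth_elisa)) do.call(rbind, truth_elisa) else NULL

  sig <- sim_marker_genes(config$n_marker_genes_per_subset)
  cc_genes <- unique(c(sig$S_phase, sig$G2M_phase, "Ccnb2", "Stmn1"))

  structure(list(
    config = config,
    counts = full_counts,
    ercc_expected = ercc_expected,
    cell_metadata = data.frame(cell_id = cell_id, plate = plate, well = well,
                               sample = samp, stringsAsFactors = FALSE),
    contigs = contigs,
    germlines = refs,
    index_sort = index_sort,
    elisa = elisa_plate,
    signatures = sig[c("LZ", "DZ", "LZtoDZ", "preMem", "prePC", "PC")],
    cc_signatures = sig[c("S_phase", "G2M_phase")],
    cc_genes = cc_genes,
    qc_thresholds = qc_thr,
    ground_truth = list(cells = truth_cells, mutations = mutations_truth,
                        elisa = truth_elisa,
                        clonotype_sizes = stats::setNames(clone_sizes, clone_ids),
                        qualifying_clonotypes = clone_ids[qualifying],
                        selected_clonotypes = clone_ids[selected],
                        od_threshold = t_nominal)
  ), class = "gcmabs_bundle")
}

# plant mutations using the current RNG stream (used inside simulate_dataset
# so the whole bundle stays a single seeded stream)
plant_mutations_rng <- function(germline, region_map, n_mut) {
  if (n_mut == 0)
    return(list(sequence = germline,
                mutations = data.frame(position = integer(0), from = character(0),
                                       to = character(0), region = character(0),
                                       silent = logical(0), stringsAsFactors = FALSE)))
  seed <- sample.int(.Machine$integer.max, 1L)
  plant_mutations(germline, region_map, n_mut, seed = seed)
}
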