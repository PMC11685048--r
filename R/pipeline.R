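#' Pipeline configuration
#'
#' Builds (or loads from YAML/JSON) the configuration driving
#' [run_pipeline()]. Any field left NULL falls back to the package default.
#'
#' @param path optional YAML or JSON file with the same field names.
#' @param outdir output directory of all stages.
#' @param seed integer seed recorded in every output's provenance and used by
#'   all seeded stages.
#' @param sim list of [sim_config()] overrides for the simulate stage.
#' @param qc a [qc_thresholds()] list (or field overrides).
#' @param clonotype list: \code{junction_identity_min}.
#' @param gating list: \code{thresholds} (see [gating_config()]) or
#'   \code{auto = TRUE} to calibrate with [suggest_gate_thresholds()].
#' @param elisa list: \code{od_threshold} (NULL = derive from controls),
#'   \code{n_sd}.
#' @param stats list: \code{censor_policy}, \code{dunn_adjust},
#'   \code{background}, \code{min_clonotype_size}.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(path = NULL, outdir = tempfile("gcmabs_run_"),
                            seed = 1L, sim = list(), qc = list(),
                            clonotype = list(junction_identity_min = 0.8),
                            gating = list(auto = TRUE),
                            elisa = list(od_threshold = NULL, n_sd = 3),
                            stats = list(censor_policy = "cap",
                                         dunn_adjust = "bonferroni",
                                         background = 1,
                                         min_clonotype_size = 5)) {
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim, qc = qc,
              clonotype = clonotype, gating = gating, elisa = elisa,
              stats = stats)
  if (!is.null(path)) {
    loaded <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    for (nm in names(loaded)) cfg[[nm]] <- utils::modifyList(
      if (is.list(cfg[[nm]])) cfg[[nm]] else list(), as.list(loaded[[nm]]))
    if (!is.null(loaded$outdir)) cfg$outdir <- loaded$outdir
    if (!is.null(loaded$seed)) cfg$seed <- as.integer(loaded$seed)
  }
  structure(cfg, class = "pipeline_config")
}

stage_outputs <- function(outdir) list(
  simulate = file.path(outdir, c("counts/matrix.mtx", "contigs.tsv",
                                 "index_sort.csv", "elisa_plate.csv")),
  qc = file.path(outdir, c("qc_report.csv", "normalized", "cells_pass.csv")),
  bcr = file.path(outdir, c("chains.csv", "clonotypes.csv", "mutations.csv")),
  annotate = file.path(outdir, "labels.csv"),
  facs = file.path(outdir, "facs.csv"),
  elisa = file.path(outdir, "elisa_results.csv"),
  integrate = file.path(outdir, c("integrated.csv", "stats_report.json")))

stage_deps <- list(simulate = character(0), qc = "simulate",
                   bcr = "simulate", annotate = "qc",
                   facs = "simulate", elisa = "simulate",
                   integrate = c("qc", "bcr", "annotate", "facs", "elisa"))

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing each stage's
#' outputs under \code{config$outdir} and appending an entry (parameters,
#' package version, seed, output hashes) to a JSON manifest. A stage whose
#' outputs already exist is skipped unless \code{force = TRUE}; a stage whose
#' dependency outputs are missing fails with an error naming the stage to run
#' first.
#'
#' @param config a [pipeline_config()].
#' @param stages ordered subset of simulate, qc, bcr, annotate, facs, elisa,
#'   integrate.
#' @param force re-run stages whose outputs already exist.
#' @return invisibly, the manifest (list of stage entries).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "qc", "bcr", "annotate",
                                    "facs", "elisa", "integrate"),
                         force = FALSE) {
  stages <- match.arg(stages, names(stage_deps), several.ok = TRUE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else list()
  outs <- stage_outputs(outdir)

  done <- function(stage) all(file.exists(outs[[stage]]))
  record <- function(stage, params) {
    files <- outs[[stage]][!dir.exists(outs[[stage]])]
    manifest[[stage]] <<- list(
      stage = stage, version = as.character(utils::packageVersion("gcmabs")),
      seed = config$seed, params = params,
      output_md5 = as.list(tools::md5sum(files)),
      time = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  for (stage in stages) {
    for (dep in stage_deps[[stage]]) {
      if (!done(dep))
        stop("stage '", stage, "' requires outputs of stage '", dep,
             "'; run that stage first", call. = FALSE)
    }
    if (!force && done(stage)) next

    switch(stage,
      simulate = {
        sc <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                    config$sim))
        bundle <- simulate_dataset(sc)
        write_bundle(bundle, outdir)
        record(stage, list(sim = config$sim))
      },
      qc = {
        counts <- read_counts_mtx(file.path(outdir, "counts"))
        ercc <- read_table_prov(file.path(outdir, "ercc_expected.csv"))
        ercc_expected <- stats::setNames(ercc$concentration, ercc$ercc_id)
        thr <- do.call(qc_thresholds, config$qc)
        metrics <- compute_qc_metrics(counts, ercc_expected)
        verdict <- filter_cells(metrics, thr)
        write_table_prov(merge(metrics, verdict, by = "cell_id"),
                         file.path(outdir, "qc_report.csv"), seed = config$seed)
        keep <- verdict$cell_id[verdict$pass]
        norm <- lognormalize(counts[, keep, drop = FALSE])
        write_counts_mtx(norm, file.path(outdir, "normalized"))
        write_table_prov(data.frame(cell_id = keep),
                         file.path(outdir, "cells_pass.csv"), seed = config$seed)
        record(stage, config$qc)
      },
      bcr = {
        contigs <- read_airr(file.path(outdir, "contigs.tsv"))
        refs <- read_germlines(file.path(outdir, "germlines.fasta"),
                               file.path(outdir, "region_maps.json"))
        chains <- select_chains(contigs)
        write_table_prov(chains, file.path(outdir, "chains.csv"),
                         seed = config$seed)
        heavy <- chains[chains$chain == "heavy", ]
        cl <- call_clonotypes(heavy,
                              config$clonotype$junction_identity_min %||% 0.8)
        write_table_prov(cl$assignments, file.path(outdir, "clonotypes.csv"),
                         seed = config$seed)
        muts <- count_mutations_all(chains, refs)
        write_table_prov(muts, file.path(outdir, "mutations.csv"),
                         seed = config$seed)
        record(stage, config$clonotype)
      },
      annotate = {
        norm <- read_counts_mtx(file.path(outdir, "normalized"))
        sigs <- read_signatures(file.path(outdir, "signatures.json"))
        cc <- unique(c(sigs$S_phase, sigs$G2M_phase))
        subset_sigs <- sigs[c("LZ", "DZ", "LZtoDZ", "preMem", "prePC", "PC")]
        subset_sigs$LZ <- remove_cc_genes(subset_sigs$LZ, cc)$genes
        subset_sigs$DZ <- remove_cc_genes(subset_sigs$DZ, cc)$genes
        scores <- score_signatures(norm, subset_sigs, seed = config$seed)
        gc_cfg <- if (isTRUE(config$gating$auto)) suggest_gate_thresholds(scores)
        else gating_config(unlist(config$gating$thresholds))
        labels <- gate_subsets(scores, gc_cfg)
        phase <- cell_cycle_phase(norm, sigs$S_phase, sigs$G2M_phase,
                                  seed = config$seed)
        write_table_prov(data.frame(cell_id = colnames(norm), subset = labels,
                                    phase = phase, scores,
                                    check.names = FALSE),
                         file.path(outdir, "labels.csv"), seed = config$seed)
        record(stage, list(gating = gc_cfg$thresholds))
      },
      facs = {
        idx <- read_index_sort(file.path(outdir, "index_sort.csv"))
        meta <- read_table_prov(file.path(outdir, "cell_metadata.csv"))
        att <- attach_index_sort(idx, meta[, c("cell_id", "plate", "well")])
        write_table_prov(att$cells, file.path(outdir, "facs.csv"),
                         seed = config$seed)
        record(stage, list())
      },
      elisa = {
        plate <- read_elisa_plate(file.path(outdir, "elisa_plate.csv"))
        res <- elisa_thresholds(plate,
                                od_threshold = config$elisa$od_threshold,
                                n_sd = config$elisa$n_sd %||% 3)
        write_table_prov(res, file.path(outdir, "elisa_results.csv"),
                         seed = config$seed)
        record(stage, config$elisa)
      },
      integrate = {
        meta <- read_table_prov(file.path(outdir, "cell_metadata.csv"))
        pass <- read_table_prov(file.path(outdir, "cells_pass.csv"))
        labels <- read_table_prov(file.path(outdir, "labels.csv"))
        clono <- read_table_prov(file.path(outdir, "clonotypes.csv"))
        muts <- read_table_prov(file.path(outdir, "mutations.csv"))
        facs <- read_table_prov(file.path(outdir, "facs.csv"))
        elisa <- read_table_prov(file.path(outdir, "elisa_results.csv"))
        names(elisa)[names(elisa) == "mab_id"] <- "cell_id"
        base <- meta[meta$cell_id %in% pass$cell_id, , drop = FALSE]
        joined <- build_integrated_table(
          base, labels = labels, clonotypes = clono, mutations = muts,
          facs = facs[, setdiff(names(facs), c("plate", "well"))],
          elisa = elisa[elisa$cell_id %in% base$cell_id, , drop = FALSE])
        tab <- joined$table
        write_table_prov(tab, file.path(outdir, "integrated.csv"),
                         seed = config$seed)

        st <- config$stats
        report <- list(join_report = joined$report)
        grp_ok <- !is.na(tab$vh_total) & !is.na(tab$sample)
        if (length(unique(tab$sample[grp_ok])) >= 3 &&
            all(table(tab$sample[grp_ok]) >= 2)) {
          report$shm_by_sample <- kruskal_dunn(
            tab$vh_total[grp_ok], tab$sample[grp_ok],
            p_adjust_method = st$dunn_adjust %||% "bonferroni")
        }
        summ <- summarize_clonotypes(tab, background = st$background %||% 1)
        report$candidate_clonotypes <- select_clonotypes(
          summ, min_size = st$min_clonotype_size %||% 5)
        fit_ok <- !is.na(tab[["asinh_OVA-AF647"]]) &
          (!is.na(tab$threshold_ng) | !(tab$censored %in% c(NA, "none")))
        if (sum(fit_ok) >= 3) {
          xx <- ifelse(is.na(tab$threshold_ng), tab$censor_limit_ng,
                       tab$threshold_ng)
          report$semilog_fit <- tryCatch(
            semilog_fit(xx[fit_ok], tab[["asinh_OVA-AF647"]][fit_ok],
                        censored = !(tab$censored[fit_ok] %in% c(NA, "none")),
                        censor_policy = st$censor_policy %||% "cap"),
            error = function(e) list(error = conditionMessage(e)))
          report$outliers <- detect_outliers(tab)$cell_id
        }
        jsonlite::write_json(report, file.path(outdir, "stats_report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             force = TRUE)
        record(stage, st)
      })
  }
  invisible(manifest)
}
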