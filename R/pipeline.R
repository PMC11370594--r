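## End-to-end orchestration: simulate -> encode -> associate -> spatial ->
## heterogeneity -> lineage -> blood-panel, with table validation and a
## JSON run manifest capturing config, seed, and per-stage outputs.

#' Validate the pipeline's delimited tables
#'
#' Schema, range, and referential-integrity checks for \code{cells.csv},
#' \code{blood.csv} and \code{survival.csv} in a directory. Violations are
#' reported with file, column, and (1-based) row index.
#'
#' @param dir Directory holding the tables.
#' @return Data frame: file, column, row, message. Zero rows when clean.
#' @export
validate_tables <- function(dir) {
  bad <- list()
  note <- function(file, column, row, message)
    bad[[length(bad) + 1L]] <<- data.frame(
      file = file, column = column, row = row, message = message,
      stringsAsFactors = FALSE)
  panel <- glycan_panel()
  fcols <- vapply(panel$glycans, frac_col, "")

  cells_path <- file.path(dir, "cells.csv")
  specimens <- character(0)
  if (!file.exists(cells_path)) {
    note("cells.csv", NA, NA, "file missing")
  } else {
    cells <- utils::read.csv(cells_path, check.names = FALSE,
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    for (cl in c("cell_id", "specimen_id", "roi_id", "x_um", "y_um",
                 fcols, "histology"))
      if (!cl %in% names(cells)) note("cells.csv", cl, NA, "column missing")
    for (cl in intersect(fcols, names(cells))) {
      out <- which(!is.na(cells[[cl]]) & (cells[[cl]] < 0 | cells[[cl]] > 1))
      for (r in out) note("cells.csv", cl, r, "fraction outside [0,1]")
    }
    if ("specimen_id" %in% names(cells))
      specimens <- unique(cells$specimen_id)
  }

  blood_path <- file.path(dir, "blood.csv")
  if (file.exists(blood_path)) {
    blood <- utils::read.csv(blood_path, check.names = FALSE,
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    for (cl in c("sample_id", "assay_id", "rfu"))
      if (!cl %in% names(blood)) note("blood.csv", cl, NA, "column missing")
    if ("rfu" %in% names(blood))
      for (r in which(!is.na(blood$rfu) & blood$rfu < 0))
        note("blood.csv", "rfu", r, "negative RFU")
    if (all(c("specimen_id") %in% names(blood)) && length(specimens))
      for (r in which(!is.na(blood$specimen_id) &
                      !blood$specimen_id %in% specimens))
        note("blood.csv", "specimen_id", r, "specimen not in cells.csv")
  }

  surv_path <- file.path(dir, "survival.csv")
  if (file.exists(surv_path)) {
    surv <- utils::read.csv(surv_path, check.names = FALSE,
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    for (cl in c("specimen_id", "time_days", "event"))
      if (!cl %in% names(surv)) note("survival.csv", cl, NA, "column missing")
    if ("time_days" %in% names(surv))
      for (r in which(!is.na(surv$time_days) & surv$time_days < 0))
        note("survival.csv", "time_days", r, "negative time")
    if (all(c("time_days", "progression_days") %in% names(surv)))
      for (r in which(!is.na(surv$progression_days) &
                      surv$progression_days > surv$time_days))
        note("survival.csv", "progression_days", r,
             "progression after survival time")
    if ("specimen_id" %in% names(surv) && length(specimens))
      for (r in which(!surv$specimen_id %in% specimens))
        note("survival.csv", "specimen_id", r, "specimen not in cells.csv")
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(file = character(0), column = character(0),
                  row = integer(0), message = character(0))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in dependency order: simulate (generate and write the cohort),
#' encode (specimen-split threshold fitting, glycan pruning, 4-bit coding),
#' associate (signature discovery on the training split, specimen-bootstrap
#' odds ratios and panel-vs-CA19-9 performance on the test split), spatial
#' (density-overlap ROI segmentation on a capped number of specimens),
#' heterogeneity (cluster/tumor profiles, quadrants, survival comparison),
#' lineage (cluster- and tumor-level graphs), and blood-panel (anchored
#' combination and subtype prediction). Each stage writes its outputs under
#' \code{out_dir} and updates \code{manifest.json} before and after running;
#' a rerun skips completed stages unless \code{force}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param out_dir Output directory.
#' @param train_fraction Fraction of tumor specimens used as the training
#'   split for threshold fitting and discovery.
#' @param n_boot Bootstrap/resampling replicates for the association and
#'   blood stages.
#' @param spatial_max_specimens Cap on specimens segmented spatially.
#' @param force Rerun stages whose outputs already exist.
#' @return The run manifest (list), invisibly; results are in
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir, train_fraction = 0.4,
                         n_boot = 500L, spatial_max_specimens = 4L,
                         force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(mpath) && !force)
    jsonlite::read_json(mpath) else list(seed = config$seed, stages = list())
  manifest$seed <- config$seed
  env <- new.env(parent = emptyenv())

  stage <- function(name, outputs, fun) {
    done <- !is.null(manifest$stages[[name]]$status) &&
      manifest$stages[[name]]$status == "done" &&
      all(file.exists(file.path(out_dir, outputs)))
    manifest$stages[[name]] <<- list(
      status = if (done && !force) "done" else "running",
      started = format(Sys.time()), outputs = outputs)
    write_manifest(manifest, out_dir)
    fun(done && !force)
    manifest$stages[[name]]$status <<- "done"
    manifest$stages[[name]]$finished <<- format(Sys.time())
    manifest$stages[[name]]$digests <<- as.list(
      tools::md5sum(file.path(out_dir, outputs)))
    write_manifest(manifest, out_dir)
  }

  panel <- glycan_panel()
  data_dir <- file.path(out_dir, "data")

  stage("simulate", file.path("data", "cells.csv"), function(skip) {
    env$cohort <- generate_cohort(config)
    if (!skip) write_cohort(env$cohort, data_dir)
    rep <- validate_tables(data_dir)
    if (nrow(rep)) stop("validation failed: ", rep$file[1], " column ",
                        rep$column[1], " row ", rep$row[1], ": ",
                        rep$message[1])
  })

  stage("encode", c("coded.csv", "thresholds.yaml"), function(skip) {
    cells <- env$cohort$cells
    tumors <- unique(cells$specimen_id[grepl("^T", cells$specimen_id)])
    set.seed(config$seed + 1L)
    env$train <- sample(tumors, max(2L, round(train_fraction * length(tumors))))
    cancer <- cells$histology == "PDAC"
    tr <- cells$specimen_id %in% env$train
    pr <- prune_glycans(cells[tr, ], cancer[tr], panel, seed = config$seed)
    thr <- fit_thresholds(cells[tr, ], cancer[tr], panel, seed = config$seed)
    env$thresholds <- thr
    env$codes <- encode_cells(cells, thr, panel)
    env$cancer <- cancer
    if (!skip) {
      coded <- cbind(cells, code = env$codes)
      utils::write.csv(coded, file.path(out_dir, "coded.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
      write_thresholds(thr, file.path(out_dir, "thresholds.yaml"))
      yaml::write_yaml(pr[c("retained", "pruned", "baseline_accuracy")],
                       file.path(out_dir, "pruning.yaml"))
    }
  })

  stage("associate", "associations.csv", function(skip) {
    cells <- env$cohort$cells
    tr <- cells$specimen_id %in% env$train
    disc <- discover_signatures(env$codes[tr], env$cancer[tr],
                                min_cells = 20L)
    env$cancer_codes <- disc$cancer_codes
    te <- !tr
    comp <- roi_composition(env$codes[te], cells$roi_id[te],
                            cells$specimen_id[te], cells$histology[te])
    env$comp_test <- comp
    m <- composition_matrix(comp)
    is_cancer_roi <- comp$histology == "PDAC"
    rows <- lapply(seq_along(disc$cancer_codes), function(i) {
      cd <- disc$cancer_codes[i]
      or <- bootstrap_odds_ratio(m[, cd] > 0.05, is_cancer_roi,
                                 comp$specimen_id, n_boot = n_boot,
                                 seed = config$seed + i)
      data.frame(code = cd, n_cancer = sum(m[is_cancer_roi, cd] > 0.05),
                 n_noncancer = sum(m[!is_cancer_roi, cd] > 0.05),
                 or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
                 p = or$p, seed = config$seed + i, stringsAsFactors = FALSE)
    })
    assoc <- do.call(rbind, rows)
    assoc$q <- fdr_adjust(assoc$p)
    env$associations <- assoc
    env$perf <- panel_performance(comp, is_cancer_roi, disc$cancer_codes,
                                  n_boot = n_boot, seed = config$seed)
    if (!skip)
      utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                       row.names = FALSE)
  })

  stage("spatial", "spatial_rois.csv", function(skip) {
    cells <- env$cohort$cells
    specs <- utils::head(unique(cells$specimen_id[grepl("^T", cells$specimen_id)]),
                         spatial_max_specimens)
    i <- cells$specimen_id %in% specs
    seg <- spatial_segment(cells[i, ], env$codes[i])
    env$spatial <- seg
    if (!skip)
      utils::write.csv(seg$rois, file.path(out_dir, "spatial_rois.csv"),
                       row.names = FALSE)
  })

  stage("heterogeneity", c("clusters.csv", "tumors.csv"), function(skip) {
    cells <- env$cohort$cells
    pd <- cells$histology == "PDAC"
    env$clusters <- cluster_profiles(env$codes[pd], cells$cluster_id[pd],
                                     cells$specimen_id[pd], env$cancer_codes)
    env$tumors <- tumor_profiles(env$codes[pd], cells$cluster_id[pd],
                                 cells$specimen_id[pd], env$cancer_codes)
    sv <- env$cohort$survival
    hu <- env$tumors$quadrant[match(sv$specimen_id, env$tumors$specimen_id)]
    keep <- !is.na(hu)
    env$survival <- survival_compare(sv$time_days[keep], sv$event[keep],
                                     hu[keep] == "heterogeneous-uniform",
                                     sv$progression_days[keep])
    if (!skip) {
      utils::write.csv(env$clusters, file.path(out_dir, "clusters.csv"),
                       row.names = FALSE)
      utils::write.csv(env$tumors, file.path(out_dir, "tumors.csv"),
                       row.names = FALSE)
      utils::write.csv(env$survival$km, file.path(out_dir, "km_curves.csv"),
                       row.names = FALSE)
    }
  })

  stage("lineage", c("lineage_clusters.csv", "lineage_tumors.csv"),
        function(skip) {
    occ_cl <- occurrence_sets(composition_matrix(env$clusters,
                                                 env$cancer_codes))
    occ_tu <- occurrence_sets(composition_matrix(
      within(env$tumors, unit <- specimen_id), env$cancer_codes))
    env$lineage_clusters <- build_lineage_graph(occ_cl)
    env$lineage_tumors <- build_lineage_graph(occ_tu)
    if (!skip) {
      utils::write.csv(lineage_edges(env$lineage_clusters),
                       file.path(out_dir, "lineage_clusters.csv"),
                       row.names = FALSE)
      utils::write.csv(lineage_edges(env$lineage_tumors),
                       file.path(out_dir, "lineage_tumors.csv"),
                       row.names = FALSE)
      write_lineage_dot(env$lineage_clusters,
                        file.path(out_dir, "lineage_clusters.dot"))
    }
  })

  stage("blood_panel", "blood_performance.yaml", function(skip) {
    blood <- env$cohort$blood
    m <- blood_matrix(blood)
    cls <- tapply(blood$class, blood$sample_id, function(v) v[1])[rownames(m)]
    perf <- resampled_performance(m[cls == "case", , drop = FALSE],
                                  m[cls == "control", , drop = FALSE],
                                  n_resample = n_boot, seed = config$seed)
    env$blood_perf <- perf
    case_m <- m[cls == "case", , drop = FALSE]
    spec_of <- tapply(blood$specimen_id, blood$sample_id,
                      function(v) v[1])[rownames(case_m)]
    truth_type <- env$cohort$truth$tumors$type[
      match(spec_of, env$cohort$truth$tumors$specimen_id)]
    thr <- fit_subtype_thresholds(case_m, truth_type)
    env$subtype <- data.frame(sample_id = rownames(case_m),
                              truth = truth_type,
                              predicted = predict_tumor_type(case_m, thr),
                              stringsAsFactors = FALSE)
    if (!skip) {
      yaml::write_yaml(list(
        sensitivity = perf$sensitivity, specificity = perf$specificity,
        comparator = perf$comparator,
        comparator_sensitivity = perf$comparator_sensitivity,
        delta_sensitivity_p = perf$delta_sensitivity_p,
        subtype_thresholds = as.list(thr)),
        file.path(out_dir, "blood_performance.yaml"))
      utils::write.csv(env$subtype, file.path(out_dir, "blood_subtypes.csv"),
                       row.names = FALSE)
    }
  })

  results <- as.list(env)
  manifest$finished <- format(Sys.time())
  write_manifest(manifest, out_dir)
  attr(manifest, "results") <- results
  invisible(manifest)
}
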