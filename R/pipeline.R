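#' Assemble a pipeline configuration
#'
#' Inputs may be given as file paths (read with the package readers) or as
#' the corresponding in-memory objects. Only the QTL catalog, the study
#' table and the genetic maps are mandatory; the physical layer (marker
#' positions, MTA list, gene annotation) is optional and the corresponding
#' stages degrade gracefully when it is absent.
#'
#' @param qtl QTL table path or `qtl_catalog`.
#' @param studies study table path or `study_meta`.
#' @param maps character vector of map file paths, or list of
#'   `genetic_map`s.
#' @param marker_physical optional path or data.frame.
#' @param mta optional path or data.frame.
#' @param gff optional GFF3 path or `GRanges`.
#' @param study_maps optional named `study_id -> map_id` vector; defaults to
#'   cycling studies over the maps in order.
#' @param lod_flagged_studies studies whose missing LOD defaults to 3.
#' @param intervals consensus interval parameters, default `1:3`.
#' @param seed master seed, default 1.
#' @param out_dir optional run directory; when set, every stage output and a
#'   JSON manifest are written there.
#' @param scale_limits,max_extrapolation_cm projection QC (see
#'   [project_catalog()]).
#' @param K_max,restarts,sigma_min meta-analysis settings (see
#'   [meta_qtl()]).
#' @param id_prefix MQTL id prefix, default `"CaMQAST"`.
#' @param breeder_max_interval_bp,breeder_min_pve breeder rule thresholds.
#' @param cg_pve_gate,cg_flank_bp candidate-gene window settings.
#' @param keywords stress keyword list, default [stress_keywords()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(qtl, studies, maps, marker_physical = NULL,
                            mta = NULL, gff = NULL, study_maps = NULL,
                            lod_flagged_studies = character(0),
                            intervals = 1:3, seed = 1, out_dir = NULL,
                            scale_limits = c(0.2, 5),
                            max_extrapolation_cm = 10,
                            K_max = NULL, restarts = 10, sigma_min = 0.1,
                            id_prefix = "CaMQAST",
                            breeder_max_interval_bp = 2e6,
                            breeder_min_pve = 10,
                            cg_pve_gate = 30, cg_flank_bp = 1e6,
                            keywords = stress_keywords()) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.load_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1 && file.exists(x)) reader(x) else x
}

#' Run the full meta-QTL pipeline
#'
#' Executes, in order: catalog curation (validation, LOD defaulting, CI
#' imputation, multi-environment de-duplication), consensus-map
#' construction, QTL projection, mixture meta-analysis, physical anchoring
#' with MTA validation, the breeder rule and candidate-gene mining, and
#' report rendering. Any stage failure halts with the stage name in the
#' error; optional stages without inputs are skipped with a warning and
#' recorded as such in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return an `mqtl_pipeline` list with elements `catalog`, `catalog_summary`,
#'   `consensus`, `projected`, `result` (the [meta_qtl()] `mqtl_result`),
#'   `anchors`, `mta_hits`, `gene_lists`, `manifest`, `config`. When
#'   `config$out_dir` is set, stage outputs and `manifest.json` are written
#'   there (see [render_reports()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  note <- function(stage, status, ...) {
    manifest[[stage]] <<- c(list(stage = stage, status = status), list(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- catalog -------------------------------------------------------------
  catalog <- stage("catalog", {
    cat0 <- .load_input(config$qtl, read_qtl_table)
    studies <- .load_input(config$studies, read_study_table)
    if (length(config$lod_flagged_studies)) {
      cat0 <- suppressWarnings(
        default_lod_threshold(cat0, config$lod_flagged_studies))
    }
    cat0 <- impute_ci(cat0, studies)
    deduped <- dedupe_multi_env(cat0)
    attr(deduped, "studies") <- studies
    deduped
  })
  studies <- attr(catalog, "studies")
  n_rejected <- nrow(attr(catalog, "rejections") %||% data.frame())
  n_dropped <- nrow(attr(catalog, "dropped") %||% data.frame())
  note("catalog", "completed", n_records = nrow(catalog),
       n_rejected = n_rejected, n_dedup_dropped = n_dropped)
  catalog_summary <- summarize_catalog(catalog)

  # --- consensus map -------------------------------------------------------
  consensus <- stage("consensus", {
    maps <- config$maps
    if (is.character(maps)) maps <- lapply(maps, read_genetic_map)
    attr(maps, "ids") <- vapply(maps, function(m) attr(m, "map_id"), "")
    cm <- build_consensus(maps, intervals = config$intervals)
    attr(cm, "source_maps") <- maps
    cm
  })
  note("consensus", "completed", n_markers = nrow(consensus),
       interval_parameter = attr(consensus, "interval_parameter"),
       mean_rmse = attr(consensus, "mean_rmse"))

  # --- projection ----------------------------------------------------------
  projected <- stage("projection", {
    maps <- attr(consensus, "source_maps")
    names(maps) <- vapply(maps, function(m) attr(m, "map_id"), "")
    study_maps <- config$study_maps
    if (is.null(study_maps)) {
      ids <- unique(catalog$study_id)
      study_maps <- setNames(
        names(maps)[(seq_along(ids) - 1) %% length(maps) + 1], ids)
    }
    project_catalog(catalog, maps, consensus, study_maps = study_maps,
                    scale_limits = config$scale_limits,
                    max_extrapolation_cm = config$max_extrapolation_cm)
  })
  note("projection", "completed",
       n_projected = sum(projected$status == "PROJECTED"),
       n_rejected = sum(projected$status == "REJECTED"))

  # --- meta-analysis -------------------------------------------------------
  result <- stage("meta_analysis", {
    meta_qtl(projected, consensus = consensus, seed = config$seed,
             K_max = config$K_max, restarts = config$restarts,
             sigma_min = config$sigma_min, id_prefix = config$id_prefix)
  })
  note("meta_analysis", "completed", n_mqtl = nrow(result$mqtl))

  # --- anchoring / validation / gene mining (optional) ---------------------
  anchors <- NULL
  mta_hits <- NULL
  gene_lists <- NULL
  marker_physical <- .load_input(config$marker_physical, read_marker_physical)
  if (is.null(marker_physical)) {
    warning("no marker physical positions supplied; anchoring skipped")
    note("anchoring", "skipped", reason = "no marker_physical input")
  } else {
    anchors <- stage("anchoring", {
      a <- anchor_mqtl(result$mqtl, marker_physical)
      mtas <- .load_input(config$mta, read_mta_table)
      if (!is.null(mtas)) {
        mta_hits <<- overlap_mta(a, mtas)
        a$n_mta <- attr(mta_hits, "hit_counts")[a$mqtl_id]
      } else {
        a$n_mta <- NA_integer_
      }
      a <- select_breeder_mqtl(a,
                               max_interval_bp = config$breeder_max_interval_bp,
                               min_pve = config$breeder_min_pve)
      cg_window(a, consensus = consensus, pve_gate = config$cg_pve_gate,
                flank_bp = config$cg_flank_bp)
    })
    note("anchoring", "completed", n_validated = sum(anchors$validated),
         n_breeder = sum(anchors$breeder_flag))
    ann <- .load_input(config$gff, read_gene_annotation)
    if (!is.null(ann)) {
      gene_lists <- stage("gene_mining", {
        idx <- which(!is.na(anchors$window_lo_bp))
        gl <- lapply(idx, function(i) {
          genes_in_window(c(anchors$window_lo_bp[i], anchors$window_hi_bp[i]),
                          anchors$chrom[i], ann, keywords = config$keywords)
        })
        names(gl) <- anchors$mqtl_id[idx]
        gl
      })
      note("gene_mining", "completed", n_windows = length(gene_lists),
           n_genes = sum(vapply(gene_lists, nrow, 0L)))
    } else {
      note("gene_mining", "skipped", reason = "no annotation input")
    }
  }

  run <- list(catalog = catalog, catalog_summary = catalog_summary,
              consensus = consensus, projected = projected, result = result,
              anchors = anchors, mta_hits = mta_hits,
              gene_lists = gene_lists, manifest = unname(manifest),
              config = config)
  class(run) <- "mqtl_pipeline"
  if (!is.null(config$out_dir)) {
    paths <- render_reports(run, config$out_dir)
    run$report_paths <- paths
    jsonlite::write_json(run$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run
}

#' @export
print.mqtl_pipeline <- function(x, ...) {
  cat("Meta-QTL pipeline run\n")
  for (m in x$manifest) {
    cat(sprintf("  %-14s %s", m$stage, m$status))
    extra <- m[setdiff(names(m), c("stage", "status"))]
    if (length(extra)) {
      cat("  (", paste(names(extra), unlist(extra), sep = "=",
                       collapse = ", "), ")", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Render the report tables of a pipeline run
#'
#' Writes the standard outputs as CSV: the trait-by-chromosome count table,
#' the consensus-map summary, the MQTL detail table (with a JSON stats
#' sidecar holding the mean PVE and mean CI width computed by
#' [mqtl_table_stats()]), the per-MQTL stress-contribution table, the
#' validated-MQTL table, MQTL-per-chromosome and PVE histogram data, the
#' marker-density profile and the MTA-frequency table. Tables whose stage
#' was skipped come out empty but well-formed.
#'
#' @param run an `mqtl_pipeline` object.
#' @param dir output directory.
#' @param density_bin_cm bin width for the marker-density profile, default 5.
#' @return invisibly, named vector of file paths.
#' @export
render_reports <- function(run, dir, density_bin_cm = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(name, df) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths[name] <<- p
  }
  # trait x chromosome counts
  cat_df <- as.data.frame(run$catalog)
  if (nrow(cat_df)) {
    t1 <- as.data.frame.matrix(table(cat_df$trait, cat_df$lg))
    t1 <- cbind(trait = rownames(t1), t1, total = rowSums(t1))
    rownames(t1) <- NULL
  } else {
    t1 <- data.frame(trait = character(), total = integer())
  }
  put("table1_trait_by_lg.csv", t1)
  put("table2_map_summary.csv", map_summary(run$consensus))
  mq <- as.data.frame(run$result$mqtl)
  put("table3_mqtl.csv", mq)
  st <- mqtl_table_stats(run$result$mqtl)
  jsonlite::write_json(list(n_mqtl = st$n, mean_pve = st$mean_pve,
                            mean_ci_width = st$mean_ci_width),
                       file.path(dir, "table3_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["table3_stats.json"] <- file.path(dir, "table3_stats.json")
  pct_cols <- grep("^pct_", names(mq), value = TRUE)
  put("table4_stress_contributions.csv",
      mq[, c("mqtl_id", "lg", pct_cols), drop = FALSE])
  anc <- if (is.null(run$anchors)) {
    data.frame(mqtl_id = character(), chrom = character(),
               start_bp = numeric(), stop_bp = numeric(),
               interval_bp = numeric(), validated = logical(),
               n_mta = integer(), breeder_flag = logical())
  } else as.data.frame(run$anchors)
  put("table5_validated_mqtl.csv", anc)
  put("fig5a_mqtl_per_lg.csv",
      data.frame(lg = names(table(mq$lg)), n_mqtl = as.integer(table(mq$lg))))
  pve_breaks <- c(0, 10, 20, 30, 40, Inf)
  pve_cut <- cut(mq$pve_pct, pve_breaks, right = FALSE)
  put("fig5c_mqtl_pve_hist.csv",
      data.frame(bin = levels(pve_cut), n = as.integer(table(pve_cut))))
  put("fig3_marker_density.csv",
      density_profile(run$consensus, density_bin_cm))
  mta_freq <- if (is.null(run$mta_hits) || nrow(run$mta_hits) == 0) {
    data.frame(mqtl_id = character(), n_mta = integer())
  } else {
    data.frame(mqtl_id = names(table(run$mta_hits$mqtl_id)),
               n_mta = as.integer(table(run$mta_hits$mqtl_id)))
  }
  put("fig6_mta_frequency.csv", mta_freq)
  if (!is.null(run$gene_lists) && length(run$gene_lists)) {
    gl <- do.call(rbind, Map(function(id, df) {
      if (nrow(df)) cbind(mqtl_id = id, df) else NULL
    }, names(run$gene_lists), run$gene_lists))
    put("candidate_genes.csv", gl %||%
          data.frame(mqtl_id = character(), gene_id = character()))
  }
  put("projection_report.csv", projection_report(run$projected))
  invisible(paths)
}
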