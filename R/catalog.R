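#' @name qtl_catalog
#' @title Multi-study QTL catalogs
#'
#' @description
#' A QTL catalog is a plain `data.frame` (class `qtl_catalog`) with one row
#' per reported QTL and the canonical columns
#' `qtl_id, study_id, trait, stress, lg, peak_cm, ci_lo_cm, ci_hi_cm, lod,
#' r2_pct, flank_left, flank_right, env`. Study-level metadata (population
#' type and size, needed for confidence-interval imputation) live in a
#' companion `study_meta` data.frame with columns
#' `study_id, population_type, population_size`.
#'
#' Stress classes are `DROUGHT`, `HEAT`, `COLD`, `SALINITY`; population types
#' are `F2_3`, `BACKCROSS`, `RIL`, `MAGIC`, `OTHER`.
NULL

.stress_levels <- c("DROUGHT", "HEAT", "COLD", "SALINITY")
.pop_levels    <- c("F2_3", "BACKCROSS", "RIL", "MAGIC", "OTHER")

.norm_stress <- function(x) {
  key <- toupper(trimws(as.character(x)))
  map <- c(D = "DROUGHT", H = "HEAT", C = "COLD", S = "SALINITY",
           DROUGHT = "DROUGHT", HEAT = "HEAT", COLD = "COLD",
           SALINITY = "SALINITY", SALT = "SALINITY")
  out <- unname(map[key])
  out
}

.norm_pop_type <- function(x) {
  key <- toupper(gsub("[^A-Z0-9]", "", toupper(as.character(x))))
  map <- c(F2 = "F2_3", F23 = "F2_3", F2_3 = "F2_3",
           BC = "BACKCROSS", BACKCROSS = "BACKCROSS",
           RIL = "RIL", RILS = "RIL",
           MAGIC = "MAGIC", MAGICF6 = "MAGIC")
  out <- unname(map[key])
  out[is.na(out) & nzchar(key)] <- "OTHER"
  out
}

#' Read a per-study QTL table
#'
#' Reads a delimited QTL table into a validated catalog. Every input row
#' either becomes a catalog record or is logged as a rejection with a reason;
#' nothing is silently dropped. Numeric cells may carry digit-grouping commas
#' (stripped via [parse_grouped_number()]).
#'
#' @param path path to a CSV (or other delimited) file with a header.
#' @param schema optional named character vector mapping canonical column
#'   names (`qtl_id`, `study_id`, `trait`, `stress`, `lg`, `peak_cm`, and the
#'   optional `ci_lo_cm`, `ci_hi_cm`, `lod`, `r2_pct`, `flank_left`,
#'   `flank_right`, `env`) to the file's column names. Defaults to identity.
#' @param sep field separator, default `","`.
#' @return a `qtl_catalog` data.frame. Rejected rows (with `file`, `row`,
#'   `reason`) are attached as `attr(, "rejections")`.
#' @export
read_qtl_table <- function(path, schema = NULL, sep = ",") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  required <- c("qtl_id", "study_id", "trait", "stress", "lg", "peak_cm")
  optional <- c("ci_lo_cm", "ci_hi_cm", "lod", "r2_pct",
                "flank_left", "flank_right", "env")
  cols <- setNames(c(required, optional), c(required, optional))
  if (!is.null(schema)) cols[names(schema)] <- schema
  missing_req <- required[!cols[required] %in% names(raw)]
  if (length(missing_req) > 0) {
    stop("missing mandatory column(s): ",
         paste(cols[missing_req], collapse = ", "))
  }
  get_col <- function(cn) {
    if (cols[[cn]] %in% names(raw)) raw[[cols[[cn]]]] else rep(NA, nrow(raw))
  }
  num <- function(x) suppressWarnings(parse_grouped_number(x))
  rec <- data.frame(
    qtl_id      = as.character(get_col("qtl_id")),
    study_id    = as.character(get_col("study_id")),
    trait       = as.character(get_col("trait")),
    stress      = .norm_stress(get_col("stress")),
    lg          = as.character(get_col("lg")),
    peak_cm     = num(get_col("peak_cm")),
    ci_lo_cm    = num(get_col("ci_lo_cm")),
    ci_hi_cm    = num(get_col("ci_hi_cm")),
    lod         = num(get_col("lod")),
    r2_pct      = num(get_col("r2_pct")),
    flank_left  = as.character(get_col("flank_left")),
    flank_right = as.character(get_col("flank_right")),
    env         = as.character(get_col("env")),
    stringsAsFactors = FALSE
  )
  raw_stress <- as.character(get_col("stress"))
  raw_peak <- as.character(get_col("peak_cm"))

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- msg
  }
  flag(!nzchar(rec$qtl_id) | is.na(rec$qtl_id), "missing qtl_id")
  flag(!nzchar(rec$study_id) | is.na(rec$study_id), "missing study_id")
  flag(is.na(rec$stress) & nzchar(trimws(raw_stress)), "unknown stress class")
  flag(is.na(rec$stress), "missing stress class")
  flag(is.na(rec$peak_cm) & nzchar(trimws(raw_peak)), "unparseable peak position")
  flag(is.na(rec$peak_cm), "missing peak position")
  flag(rec$peak_cm < 0, "negative peak position")
  flag(!is.na(rec$r2_pct) & (rec$r2_pct <= 0 | rec$r2_pct > 100),
       "PVE out of range")
  flag(!is.na(rec$lod) & rec$lod < 0, "negative LOD")
  both_ci <- !is.na(rec$ci_lo_cm) & !is.na(rec$ci_hi_cm)
  flag(both_ci & rec$ci_lo_cm > rec$ci_hi_cm, "inverted confidence interval")
  flag(both_ci & !is.na(rec$peak_cm) &
         (rec$peak_cm < rec$ci_lo_cm | rec$peak_cm > rec$ci_hi_cm),
       "peak outside confidence interval")

  keep <- is.na(reason)
  out <- rec[keep, , drop = FALSE]
  out$ci_source <- ifelse(!is.na(out$ci_lo_cm) & !is.na(out$ci_hi_cm),
                          "reported", "to_impute")
  out$source_file <- rep_len(path, nrow(out))
  out$source_row <- which(keep)
  rownames(out) <- NULL
  rejections <- data.frame(
    file = rep_len(path, sum(!keep)), row = which(!keep),
    qtl_id = rec$qtl_id[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("qtl_catalog", "data.frame")
  attr(out, "rejections") <- rejections
  out
}

#' Read a study-metadata table
#'
#' @param path CSV with columns `study_id`, `population_type`,
#'   `population_size` (and optionally `year`, `mapping_method`).
#' @return a `study_meta` data.frame; population types normalised to
#'   `F2_3`, `BACKCROSS`, `RIL`, `MAGIC`, `OTHER`.
#' @export
read_study_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "population_type", "population_size")
  if (!all(need %in% names(raw))) {
    stop("study table must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    study_id        = as.character(raw$study_id),
    population_type = .norm_pop_type(raw$population_type),
    population_size = suppressWarnings(parse_grouped_number(raw$population_size)),
    stringsAsFactors = FALSE
  )
  if ("year" %in% names(raw)) out$year <- as.integer(raw$year)
  if ("mapping_method" %in% names(raw)) out$mapping_method <- as.character(raw$mapping_method)
  bad <- is.na(out$population_size) | out$population_size < 2
  if (any(bad)) {
    stop("invalid population_size for study: ",
         paste(out$study_id[bad], collapse = ", "))
  }
  class(out) <- c("study_meta", "data.frame")
  out
}

#' Convert a likelihood ratio to a LOD score
#'
#' LOD = likelihood ratio / 4.6, since 2 ln 10 is approximately 4.6; used to
#' harmonise studies that report likelihood-ratio statistics instead of LOD.
#'
#' @param likelihood_ratio non-negative numeric vector.
#' @return LOD scores.
#' @examples
#' lod_from_lr(c(4.6, 13.8))  # 1, 3
#' @export
lod_from_lr <- function(likelihood_ratio) {
  if (any(likelihood_ratio < 0, na.rm = TRUE)) {
    stop("likelihood ratio must be non-negative")
  }
  likelihood_ratio / 4.6
}

#' Fill missing LOD scores with a study's declared threshold
#'
#' Studies that report QTL only above a declared LOD threshold (typically 3)
#' but omit the per-QTL value get that threshold imputed. Records from
#' non-flagged studies are left untouched (with a warning when LOD stays
#' missing).
#'
#' @param catalog a `qtl_catalog`.
#' @param flagged_studies character vector of `study_id`s that declared a
#'   threshold.
#' @param threshold the declared LOD threshold, default 3.
#' @return the catalog with `lod` filled where applicable and a logical
#'   `lod_imputed` column.
#' @export
default_lod_threshold <- function(catalog, flagged_studies, threshold = 3) {
  fill <- is.na(catalog$lod) & catalog$study_id %in% flagged_studies
  catalog$lod[fill] <- threshold
  catalog$lod_imputed <- fill
  left <- is.na(catalog$lod)
  if (any(left)) {
    warning(sum(left), " record(s) still lack a LOD score")
  }
  catalog
}

#' 95% confidence-interval width from population design
#'
#' Applies the population-specific approximation for the 95% CI width (in cM)
#' of a QTL position: `530 / (R2 * N)` for F2:3 and backcross designs and
#' `163 / (R2 * N)` for recombinant inbred lines, with `R2` the explained
#' variance as a proportion and `N` the population size. No constant exists
#' for MAGIC or other designs; those return `NA`.
#'
#' @param population_type `F2_3`, `BACKCROSS`, `RIL`, `MAGIC` or `OTHER`.
#' @param population_size integer N >= 2.
#' @param r2_pct explained variance in percent, in (0, 100].
#' @return CI width in cM, `NA` where undefined.
#' @examples
#' ci_width_95("RIL", 163, 10)   # 10 cM
#' ci_width_95("F2_3", 106, 5)   # 100 cM
#' @export
ci_width_95 <- function(population_type, population_size, r2_pct) {
  const <- c(F2_3 = 530, BACKCROSS = 530, RIL = 163)[population_type]
  width <- unname(const) / ((r2_pct / 100) * population_size)
  width[!is.finite(width)] <- NA_real_
  width
}

#' Impute missing 95% confidence intervals in a catalog
#'
#' Records with reported CI bounds keep them (reported bounds always take
#' precedence). For the rest, the CI width is obtained from [ci_width_95()]
#' and bounds are set to `peak_cm +/- width / 2`, truncated at 0. Records for
#' which no CI can be obtained (MAGIC/OTHER design, or missing R2/N) are
#' flagged `not_projectable`.
#'
#' @param catalog a `qtl_catalog`.
#' @param studies a `study_meta` data.frame.
#' @return the catalog with completed `ci_lo_cm`/`ci_hi_cm`, the imputed
#'   `ci_width_cm`, updated `ci_source` (`reported`/`imputed`/`none`) and a
#'   logical `not_projectable` column.
#' @export
impute_ci <- function(catalog, studies) {
  idx <- match(catalog$study_id, studies$study_id)
  ptype <- studies$population_type[idx]
  psize <- studies$population_size[idx]
  has_ci <- !is.na(catalog$ci_lo_cm) & !is.na(catalog$ci_hi_cm)
  width <- ci_width_95(ptype, psize, catalog$r2_pct)
  can_impute <- !has_ci & !is.na(width)
  catalog$ci_lo_cm[can_impute] <-
    pmax(0, catalog$peak_cm[can_impute] - width[can_impute] / 2)
  catalog$ci_hi_cm[can_impute] <-
    catalog$peak_cm[can_impute] + width[can_impute] / 2
  catalog$ci_source <- ifelse(has_ci, "reported",
                              ifelse(can_impute, "imputed", "none"))
  catalog$ci_width_cm <- catalog$ci_hi_cm - catalog$ci_lo_cm
  catalog$not_projectable <- catalog$ci_source == "none"
  catalog
}

#' Collapse multi-environment duplicates to the highest-PVE record
#'
#' When a study reports the same QTL in several environments, only the
#' instance explaining the most phenotypic variance is retained. Identity is
#' `(study_id, qtl_id)`, falling back to
#' `(study_id, trait, lg, flank_left, flank_right)` for records whose ids
#' differ but whose trait and flanking interval coincide. Ties on `r2_pct`
#' are broken by higher LOD, then by first occurrence. Idempotent.
#'
#' @param catalog a `qtl_catalog`.
#' @return de-duplicated catalog; dropped rows in `attr(, "dropped")`.
#' @export
dedupe_multi_env <- function(catalog) {
  if (nrow(catalog) == 0) return(catalog)
  pick_best <- function(df) {
    r2 <- ifelse(is.na(df$r2_pct), -Inf, df$r2_pct)
    best <- which(r2 == max(r2))
    if (length(best) > 1) {
      lod <- ifelse(is.na(df$lod[best]), -Inf, df$lod[best])
      best <- best[lod == max(lod)]
    }
    best[1]
  }
  collapse <- function(df, key) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(i) {
      i[pick_best(df[i, , drop = FALSE])]
    }), use.names = FALSE)
    sort(keep)
  }
  key1 <- paste(catalog$study_id, catalog$qtl_id, sep = "\r")
  keep1 <- collapse(catalog, key1)
  out <- catalog[keep1, , drop = FALSE]
  # fallback identity: same study, trait, linkage group and flanking interval
  has_flanks <- !is.na(out$flank_left) & !is.na(out$flank_right) &
    nzchar(out$flank_left) & nzchar(out$flank_right)
  key2 <- ifelse(has_flanks,
                 paste(out$study_id, out$trait, out$lg,
                       out$flank_left, out$flank_right, sep = "\r"),
                 paste("row", seq_len(nrow(out))))
  keep2 <- collapse(out, key2)
  dropped <- rbind(catalog[-keep1, , drop = FALSE],
                   out[-keep2, , drop = FALSE])
  out <- out[keep2, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- attr(catalog, "rejections")
  attr(out, "dropped") <- dropped
  out
}

#' Summarise a QTL catalog
#'
#' Counts records per linkage group, trait and stress class, and bins PVE and
#' LOD into the histogram layout used for catalog description (PVE bins
#' `[0,5), [5,10), [10,15), [15,20), [20,25), [25,Inf)`).
#'
#' @param catalog a `qtl_catalog`.
#' @return a `catalog_summary` list with elements `n`, `by_lg`, `by_trait`,
#'   `by_stress`, `pve_hist`, `lod_hist`.
#' @export
summarize_catalog <- function(catalog) {
  pve_breaks <- c(0, 5, 10, 15, 20, 25, Inf)
  pve_labels <- c("[0,5)", "[5,10)", "[10,15)", "[15,20)", "[20,25)", "[25,Inf)")
  lod_breaks <- c(0, 3, 6, 9, 12, 15, Inf)
  lod_labels <- c("[0,3)", "[3,6)", "[6,9)", "[9,12)", "[12,15)", "[15,Inf)")
  count_by <- function(x) {
    tab <- table(x, useNA = "no")
    setNames(as.integer(tab), names(tab))
  }
  bin <- function(x, breaks, labels) {
    x <- x[!is.na(x)]
    setNames(as.integer(table(cut(x, breaks, labels, right = FALSE))), labels)
  }
  out <- list(
    n         = nrow(catalog),
    by_lg     = count_by(catalog$lg),
    by_trait  = count_by(catalog$trait),
    by_stress = count_by(catalog$stress),
    pve_hist  = bin(catalog$r2_pct, pve_breaks, pve_labels),
    lod_hist  = bin(catalog$lod, lod_breaks, lod_labels)
  )
  stopifnot(sum(out$by_lg) == out$n)
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("QTL catalog:", x$n, "records on", length(x$by_lg),
      "linkage group(s)\n")
  cat("  per linkage group: ",
      paste(names(x$by_lg), x$by_lg, sep = "=", collapse = "  "), "\n")
  cat("  per stress class:  ",
      paste(names(x$by_stress), x$by_stress, sep = "=", collapse = "  "), "\n")
  cat("  PVE histogram:     ",
      paste(names(x$pve_hist), x$pve_hist, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Write catalog summary files
#'
#' Writes the count tables as CSV and the histograms as JSON.
#'
#' @param summary a `catalog_summary`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_catalog_summary <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- rbind(
    data.frame(dimension = "lg", level = names(summary$by_lg),
               count = unname(summary$by_lg)),
    data.frame(dimension = "trait", level = names(summary$by_trait),
               count = unname(summary$by_trait)),
    data.frame(dimension = "stress", level = names(summary$by_stress),
               count = unname(summary$by_stress))
  )
  csv <- file.path(dir, "catalog_counts.csv")
  utils::write.csv(counts, csv, row.names = FALSE)
  js <- file.path(dir, "catalog_histograms.json")
  jsonlite::write_json(list(pve = as.list(summary$pve_hist),
                            lod = as.list(summary$lod_hist)),
                       js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv, js))
}
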