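#' Shared-anchor interpolation between a source map and the consensus
#'
#' Internal helper: for one linkage group, returns the shared ("anchor")
#' markers of a source map and the consensus, sorted by source position,
#' with duplicate source positions collapsed.
#' @noRd
.shared_anchors <- function(source_map, consensus, lg) {
  a <- source_map[source_map$lg == lg, , drop = FALSE]
  b <- consensus[consensus$lg == lg, , drop = FALSE]
  shared <- intersect(a$marker, b$marker)
  if (length(shared) == 0) {
    return(data.frame(marker = character(), src = numeric(), dst = numeric()))
  }
  out <- data.frame(marker = shared,
                    src = a$pos_cm[match(shared, a$marker)],
                    dst = b$pos_cm[match(shared, b$marker)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$src, out$marker), , drop = FALSE]
  n_raw <- nrow(out)
  # collapse anchors at identical source positions (a zero-length anchor
  # interval cannot define a scale)
  if (anyDuplicated(out$src)) {
    keep <- !duplicated(out$src)
    dst <- vapply(split(out$dst, out$src), mean, 0)
    out <- out[keep, , drop = FALSE]
    out$dst <- dst[as.character(out$src)]
  }
  rownames(out) <- NULL
  attr(out, "n_raw") <- n_raw
  out
}

#' Find the anchor pair flanking a QTL peak
#'
#' Returns the closest markers shared between the QTL's source map and the
#' consensus that flank the peak on the source map. A peak outside the shared
#' span gets the two nearest anchors on one side and an extrapolation flag.
#'
#' @param peak_cm QTL peak position on the source map.
#' @param source_map the study's `genetic_map`.
#' @param consensus the `consensus_map`.
#' @param lg linkage group of the QTL.
#' @return a list with `left`, `right` (marker names), `src`/`dst` positions
#'   of the pair, and `extrapolated`; or `NULL` when fewer than two shared
#'   markers exist.
#' @export
find_anchor_pair <- function(peak_cm, source_map, consensus, lg) {
  anc <- .shared_anchors(source_map, consensus, lg)
  if (nrow(anc) < 2) return(NULL)
  if (peak_cm < anc$src[1]) {
    i <- 1L; extrap <- TRUE
  } else if (peak_cm > anc$src[nrow(anc)]) {
    i <- nrow(anc) - 1L; extrap <- TRUE
  } else {
    i <- max(which(anc$src <= peak_cm))
    if (i == nrow(anc)) i <- i - 1L  # peak exactly on the last anchor
    extrap <- FALSE
  }
  list(left = anc$marker[i], right = anc$marker[i + 1],
       src = c(anc$src[i], anc$src[i + 1]),
       dst = c(anc$dst[i], anc$dst[i + 1]),
       extrapolated = extrap)
}

# piecewise-linear source->consensus coordinate map over the anchors;
# outside the anchor span the end segment's slope is extended
.pw_transform <- function(anc) {
  function(x) {
    n <- nrow(anc)
    y <- stats::approx(anc$src, anc$dst, xout = x, rule = 1, ties = "ordered")$y
    lo <- x < anc$src[1]
    hi <- x > anc$src[n]
    if (any(lo)) {
      s <- (anc$dst[2] - anc$dst[1]) / (anc$src[2] - anc$src[1])
      y[lo] <- anc$dst[1] + s * (x[lo] - anc$src[1])
    }
    if (any(hi)) {
      s <- (anc$dst[n] - anc$dst[n - 1]) / (anc$src[n] - anc$src[n - 1])
      y[hi] <- anc$dst[n] + s * (x[hi] - anc$src[n])
    }
    y
  }
}

#' Project a QTL catalog onto the consensus map
#'
#' Re-expresses each QTL's peak and 95% CI in consensus coordinates by the
#' homothetic (piecewise-linear) transform defined by the shared anchor
#' markers of its study's map and the consensus: the peak and each CI bound
#' are mapped through their own flanking anchor pair, which preserves
#' monotonicity when a CI spans several anchor intervals.
#'
#' Quality control rejects projections whose local scale ratio (consensus
#' anchor interval / source anchor interval at the peak) falls outside
#' `scale_limits`, or whose peak lies more than `max_extrapolation_cm`
#' outside the shared-anchor span. Projected CI bounds are clipped at 0 and
#' at the consensus linkage-group length.
#'
#' @param catalog a `qtl_catalog` after [impute_ci()].
#' @param maps named list of source `genetic_map`s (names are map ids).
#' @param consensus the `consensus_map`.
#' @param study_maps named character vector mapping `study_id` to a map id;
#'   defaults to using the study id itself.
#' @param scale_limits admissible scale-ratio range, default `c(0.2, 5)`.
#' @param max_extrapolation_cm default 10.
#' @return a `projected_qtl` data.frame: the catalog columns plus
#'   `consensus_peak_cm`, `consensus_ci_lo_cm`, `consensus_ci_hi_cm`,
#'   `anchor_left`, `anchor_right`, `scale_ratio`, `extrapolated`, `status`
#'   (`PROJECTED`/`REJECTED`) and `reason`. A per-reason count table is in
#'   `attr(, "report")`.
#' @export
project_catalog <- function(catalog, maps, consensus, study_maps = NULL,
                            scale_limits = c(0.2, 5),
                            max_extrapolation_cm = 10) {
  if (is.null(names(maps))) {
    names(maps) <- vapply(maps, function(m) attr(m, "map_id") %||% "?", "")
  }
  n <- nrow(catalog)
  out <- catalog
  out$consensus_peak_cm <- NA_real_
  out$consensus_ci_lo_cm <- NA_real_
  out$consensus_ci_hi_cm <- NA_real_
  out$anchor_left <- NA_character_
  out$anchor_right <- NA_character_
  out$scale_ratio <- NA_real_
  out$extrapolated <- FALSE
  out$status <- "REJECTED"
  out$reason <- NA_character_

  lg_len <- vapply(split(consensus$pos_cm, consensus$lg), max, 0)
  anchors_cache <- new.env(parent = emptyenv())

  for (i in seq_len(n)) {
    rec <- catalog[i, ]
    map_id <- if (!is.null(study_maps)) study_maps[[rec$study_id]] else rec$study_id
    src <- maps[[map_id]]
    if (is.null(src)) { out$reason[i] <- "no source map"; next }
    if (!any(src$lg == rec$lg)) { out$reason[i] <- "no source coverage"; next }
    if (isTRUE(rec$not_projectable) ||
        is.na(rec$ci_lo_cm) || is.na(rec$ci_hi_cm)) {
      out$reason[i] <- "no confidence interval"; next
    }
    key <- paste(map_id, rec$lg, sep = "\r")
    anc <- if (!is.null(anchors_cache[[key]])) anchors_cache[[key]] else {
      anchors_cache[[key]] <- .shared_anchors(src, consensus, rec$lg)
    }
    if (nrow(anc) < 2) {
      # >= 2 shared markers collapsed onto one position: the anchor
      # interval is degenerate rather than absent
      out$reason[i] <- if ((attr(anc, "n_raw") %||% 0) >= 2)
        "degenerate interval" else "no anchors"
      next
    }
    pair <- find_anchor_pair(rec$peak_cm, src, consensus, rec$lg)
    if (diff(pair$src) == 0) { out$reason[i] <- "degenerate interval"; next }
    ratio <- diff(pair$dst) / diff(pair$src)
    if (!is.finite(ratio) || ratio <= 0 ||
        ratio < scale_limits[1] || ratio > scale_limits[2]) {
      out$scale_ratio[i] <- ratio
      out$reason[i] <- "distorted interval"; next
    }
    if (pair$extrapolated) {
      dist <- max(anc$src[1] - rec$peak_cm, rec$peak_cm - anc$src[nrow(anc)])
      if (dist > max_extrapolation_cm) {
        out$reason[i] <- "extrapolation too far"; next
      }
    }
    f <- .pw_transform(anc)
    vals <- f(c(rec$peak_cm, rec$ci_lo_cm, rec$ci_hi_cm))
    len <- lg_len[[rec$lg]] %||% NA_real_
    clip <- function(x) if (is.na(len)) pmax(0, x) else pmin(pmax(0, x), len)
    out$consensus_peak_cm[i] <- clip(vals[1])
    out$consensus_ci_lo_cm[i] <- clip(min(vals[2], vals[1]))
    out$consensus_ci_hi_cm[i] <- clip(max(vals[3], vals[1]))
    out$anchor_left[i] <- pair$left
    out$anchor_right[i] <- pair$right
    out$scale_ratio[i] <- ratio
    out$extrapolated[i] <- pair$extrapolated
    out$status[i] <- "PROJECTED"
  }
  class(out) <- c("projected_qtl", "data.frame")
  attr(out, "report") <- projection_report(out)
  out
}

#' Tabulate projection outcomes by reason
#'
#' @param projected a `projected_qtl` data.frame.
#' @return data.frame `status, reason, n`.
#' @export
projection_report <- function(projected) {
  key <- paste(projected$status,
               ifelse(is.na(projected$reason), "", projected$reason), sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(status = vapply(parts, `[`, "", 1),
             reason = vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""),
             n = as.integer(tab), stringsAsFactors = FALSE)
}
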