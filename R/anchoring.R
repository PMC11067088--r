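#' Default stress-related keyword list for candidate-gene flagging
#'
#' Case-insensitive substrings matched against gene functional descriptions
#' to mark genes plausibly involved in abiotic-stress tolerance (heat-shock
#' proteins, hormone pathways, membrane transport, cell-wall and
#' detoxification families).
#'
#' @return character vector of keywords.
#' @export
stress_keywords <- function() {
  c("heat shock", "peroxidase", "aquaporin", "gibberellin", "abscisic",
    "auxin", "IAA", "cytochrome P450", "F-box", "zinc finger", "Casparian",
    "cinnamoyl-CoA", "dnaJ", "trichome birefringence", "potassium channel",
    "UDP-glycosyltransferase")
}

#' Read a marker physical-position table
#'
#' @param path CSV with columns `marker`, `chrom`, `bp` (digit-grouping
#'   commas tolerated).
#' @return data.frame `marker, chrom, bp` (1-based positions).
#' @export
read_marker_physical <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chrom", "bp") %in% names(raw)))
  out <- data.frame(marker = as.character(raw$marker),
                    chrom = as.character(raw$chrom),
                    bp = parse_grouped_number(raw$bp),
                    stringsAsFactors = FALSE)
  if (any(out$bp < 1, na.rm = TRUE)) stop("physical positions must be >= 1")
  out
}

#' Read a marker-trait-association list (BED-like)
#'
#' Four-plus-column whitespace/tab-delimited file: `chrom, start, end, id
#' [, trait]`. Starts follow the BED convention (0-based, half-open) and are
#' converted to 1-based inclusive coordinates on read.
#'
#' @param path file path.
#' @return data.frame `mta_id, chrom, start_bp, end_bp, trait`.
#' @export
read_mta_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(raw) < 4) stop("MTA file needs at least 4 columns")
  trait <- if (ncol(raw) >= 5) as.character(raw[[5]]) else
    rep(NA_character_, nrow(raw))
  trait[!is.na(trait) & !nzchar(trait)] <- NA_character_
  data.frame(mta_id = as.character(raw[[4]]),
             chrom = as.character(raw[[1]]),
             start_bp = parse_grouped_number(raw[[2]]) + 1,
             end_bp = parse_grouped_number(raw[[3]]),
             trait = trait,
             stringsAsFactors = FALSE)
}

#' Physical interval length between two flanking markers
#'
#' Flanking-marker positions arrive in table order, not genomic order, so the
#' interval is the absolute difference (symmetric in its arguments).
#'
#' @param left_bp,right_bp positions in bp.
#' @return `abs(left_bp - right_bp)`.
#' @examples
#' physical_interval(14038103, 13991104)  # 46999
#' @export
physical_interval <- function(left_bp, right_bp) {
  abs(left_bp - right_bp)
}

#' Attach physical coordinates to MQTL via their flanking markers
#'
#' Looks up each MQTL's flanking markers in the physical-position table and
#' records the bp interval. MQTL with one or both markers unlocated are kept
#' but marked not validated (no interval, no downstream windows).
#'
#' @param mqtl an `mqtl_set` (needs `mqtl_id, lg, position_cm, pve_pct,
#'   flank_left, flank_right`).
#' @param marker_physical data.frame from [read_marker_physical()].
#' @return a `physical_anchor` data.frame: `mqtl_id, lg, position_cm,
#'   pve_pct, n_qtl, chrom, start_bp, stop_bp, interval_bp, validated`.
#' @export
anchor_mqtl <- function(mqtl, marker_physical) {
  li <- match(mqtl$flank_left, marker_physical$marker)
  ri <- match(mqtl$flank_right, marker_physical$marker)
  start_bp <- marker_physical$bp[li]
  stop_bp <- marker_physical$bp[ri]
  chrom_l <- marker_physical$chrom[li]
  chrom_r <- marker_physical$chrom[ri]
  validated <- !is.na(start_bp) & !is.na(stop_bp) &
    !is.na(chrom_l) & chrom_l == chrom_r
  out <- data.frame(
    mqtl_id = mqtl$mqtl_id, lg = mqtl$lg,
    position_cm = mqtl$position_cm, pve_pct = mqtl$pve_pct,
    n_qtl = if ("n_qtl" %in% names(mqtl)) mqtl$n_qtl else NA_integer_,
    flank_left = mqtl$flank_left, flank_right = mqtl$flank_right,
    chrom = ifelse(validated, chrom_l, NA_character_),
    start_bp = ifelse(validated, start_bp, NA_real_),
    stop_bp = ifelse(validated, stop_bp, NA_real_),
    interval_bp = ifelse(validated, physical_interval(start_bp, stop_bp),
                         NA_real_),
    validated = validated, stringsAsFactors = FALSE)
  class(out) <- c("physical_anchor", "data.frame")
  out
}

#' Marker-trait associations co-located with anchored MQTL
#'
#' An MTA co-locates with an MQTL when any part of its interval lies within
#' the MQTL's physical interval `[min(start, stop), max(start, stop)]`,
#' closed at both ends.
#'
#' @param anchors a `physical_anchor` data.frame.
#' @param mtas data.frame from [read_mta_table()].
#' @return long data.frame `mqtl_id, mta_id, trait`; per-MQTL hit counts in
#'   `attr(, "hit_counts")`.
#' @export
overlap_mta <- function(anchors, mtas) {
  hits <- list()
  for (i in which(anchors$validated)) {
    lo <- min(anchors$start_bp[i], anchors$stop_bp[i])
    hi <- max(anchors$start_bp[i], anchors$stop_bp[i])
    sel <- mtas$chrom == anchors$chrom[i] &
      mtas$end_bp >= lo & mtas$start_bp <= hi
    if (any(sel)) {
      hits[[length(hits) + 1]] <- data.frame(
        mqtl_id = anchors$mqtl_id[i], mta_id = mtas$mta_id[sel],
        trait = mtas$trait[sel], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(mqtl_id = character(), mta_id = character(),
               trait = character(), stringsAsFactors = FALSE)
  counts <- setNames(integer(nrow(anchors)), anchors$mqtl_id)
  if (nrow(out)) {
    tab <- table(out$mqtl_id)
    counts[names(tab)] <- as.integer(tab)
  }
  attr(out, "hit_counts") <- counts
  out
}

#' Flag breeder's MQTL
#'
#' The marker-assisted-selection shortlist rule: a validated MQTL is flagged
#' when its physical interval is smaller than `max_interval_bp` (default
#' 2 Mb, strict) *and* its PVE exceeds `min_pve` (default 10%, strict). The
#' number of supporting QTL is reported for ranking but not thresholded.
#'
#' @param anchors a `physical_anchor` data.frame.
#' @param max_interval_bp default `2e6`.
#' @param min_pve default 10.
#' @return the anchors with a logical `breeder_flag` column.
#' @export
select_breeder_mqtl <- function(anchors, max_interval_bp = 2e6,
                                min_pve = 10) {
  flag <- anchors$validated &
    !is.na(anchors$interval_bp) & anchors$interval_bp < max_interval_bp &
    !is.na(anchors$pve_pct) & anchors$pve_pct > min_pve
  anchors$breeder_flag <- flag
  anchors
}

#' Candidate-gene windows for high-PVE MQTL
#'
#' Only validated MQTL with PVE above `pve_gate` (default 30%) get a mining
#' window. MQTL whose flanking-marker interval is below `direct_max_bp`
#' (default 2 Mb) use the whole marker interval; wider MQTL use
#' `peak_bp +/- flank_bp` (default 1 Mb each side) around the peak's physical
#' position, obtained by linear cM-to-bp interpolation between the two
#' flanking markers' (cM, bp) pairs. Windows are clipped at 1 and, when
#' `chrom_lengths` is given, at the chromosome end.
#'
#' @param anchors a `physical_anchor` data.frame.
#' @param consensus the `consensus_map` (for the flanking markers' cM
#'   positions); may be `NULL`, in which case wide MQTL centre the window on
#'   the interval midpoint.
#' @param pve_gate default 30.
#' @param direct_max_bp default `2e6`.
#' @param flank_bp default `1e6`.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @return the anchors with `window_lo_bp`, `window_hi_bp` (NA where no
#'   window applies).
#' @export
cg_window <- function(anchors, consensus = NULL, pve_gate = 30,
                      direct_max_bp = 2e6, flank_bp = 1e6,
                      chrom_lengths = NULL) {
  anchors$window_lo_bp <- NA_real_
  anchors$window_hi_bp <- NA_real_
  for (i in seq_len(nrow(anchors))) {
    if (!anchors$validated[i]) next
    if (is.na(anchors$pve_pct[i]) || anchors$pve_pct[i] <= pve_gate) next
    lo <- min(anchors$start_bp[i], anchors$stop_bp[i])
    hi <- max(anchors$start_bp[i], anchors$stop_bp[i])
    if (anchors$interval_bp[i] < direct_max_bp) {
      win <- c(lo, hi)
    } else {
      peak_bp <- (lo + hi) / 2
      if (!is.null(consensus)) {
        cm <- consensus[consensus$lg == anchors$lg[i], , drop = FALSE]
        cm_l <- cm$pos_cm[match(anchors$flank_left[i], cm$marker)]
        cm_r <- cm$pos_cm[match(anchors$flank_right[i], cm$marker)]
        if (!is.na(cm_l) && !is.na(cm_r) && cm_l != cm_r) {
          frac <- (anchors$position_cm[i] - cm_l) / (cm_r - cm_l)
          frac <- min(max(frac, 0), 1)
          peak_bp <- anchors$start_bp[i] +
            frac * (anchors$stop_bp[i] - anchors$start_bp[i])
        }
      }
      win <- c(peak_bp - flank_bp, peak_bp + flank_bp)
    }
    win[1] <- max(1, win[1])
    if (!is.null(chrom_lengths) && anchors$chrom[i] %in% names(chrom_lengths)) {
      win[2] <- min(win[2], chrom_lengths[[anchors$chrom[i]]])
    }
    anchors$window_lo_bp[i] <- win[1]
    anchors$window_hi_bp[i] <- win[2]
  }
  anchors
}

#' Read gene features from a GFF3 annotation
#'
#' Imports the annotation with \pkg{rtracklayer} and keeps `gene` features.
#' The functional description is taken from the `description` attribute,
#' falling back to `Note`.
#'
#' @param path GFF3 file.
#' @return a [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `description`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  desc <- if ("description" %in% names(mc)) as.character(mc$description)
  else rep(NA_character_, length(gr))
  if ("Note" %in% names(mc)) {
    note <- vapply(mc$Note, function(v) {
      if (length(v)) paste(v, collapse = "; ") else NA_character_
    }, "")
    desc <- ifelse(is.na(desc) | !nzchar(desc), note, desc)
  }
  id <- if ("ID" %in% names(mc)) as.character(mc$ID)
  else if ("Name" %in% names(mc)) as.character(mc$Name)
  else paste0("gene", seq_along(gr))
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(gene_id = id,
                                                description = desc)
  out
}

#' Genes within a candidate-gene window
#'
#' Returns annotated genes whose span intersects the window (strand is
#' ignored). Genes with an empty or "uncharacterized" description are
#' dropped, since their role cannot be assessed. Descriptions are matched
#' case-insensitively against `keywords` to flag stress-related candidates.
#'
#' @param window numeric `c(lo_bp, hi_bp)`.
#' @param chrom chromosome name.
#' @param annotation a `GRanges` from [read_gene_annotation()].
#' @param keywords character vector, default [stress_keywords()].
#' @return data.frame `gene_id, chrom, start_bp, end_bp, description,
#'   stress_related`.
#' @export
genes_in_window <- function(window, chrom, annotation,
                            keywords = stress_keywords()) {
  if (!chrom %in% as.character(GenomicRanges::seqnames(annotation))) {
    warning("no annotation for chromosome ", chrom)
    return(data.frame(gene_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      description = character(), stress_related = logical(),
                      stringsAsFactors = FALSE))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(window[1], window[2]))
  hits <- GenomicRanges::findOverlaps(q, annotation, ignore.strand = TRUE)
  g <- annotation[S4Vectors::subjectHits(hits)]
  desc <- S4Vectors::mcols(g)$description
  keep <- !is.na(desc) & nzchar(trimws(desc)) &
    !grepl("uncharacteri[sz]ed", desc, ignore.case = TRUE)
  g <- g[keep]
  desc <- desc[keep]
  pat <- paste(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", keywords),
               collapse = "|")
  data.frame(
    gene_id = S4Vectors::mcols(g)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start_bp = GenomicRanges::start(g), end_bp = GenomicRanges::end(g),
    description = desc,
    stress_related = grepl(pat, desc, ignore.case = TRUE),
    stringsAsFactors = FALSE)
}
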