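#' Create a genetic map object
#'
#' A genetic map is a `data.frame` (class `genetic_map`) with columns
#' `marker`, `lg`, `pos_cm`, sorted by linkage group and position. Positions
#' are non-negative; marker names must be unique within the map (see
#' [rename_redundant_markers()] for the duplicate-name convention).
#'
#' @param marker character marker names.
#' @param lg character linkage-group labels.
#' @param pos_cm numeric centimorgan positions, >= 0.
#' @param map_id identifier for the source study/map.
#' @return a `genetic_map` data.frame with attribute `map_id`.
#' @export
genetic_map <- function(marker, lg, pos_cm, map_id = "map") {
  stopifnot(length(marker) == length(lg), length(lg) == length(pos_cm))
  if (any(pos_cm < 0, na.rm = TRUE)) stop("map positions must be >= 0")
  out <- data.frame(marker = as.character(marker), lg = as.character(lg),
                    pos_cm = as.numeric(pos_cm), stringsAsFactors = FALSE)
  out <- out[order(out$lg, out$pos_cm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "map_id") <- map_id
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Read a genetic map file
#'
#' Tab-delimited, three columns: marker, linkage group, position (cM). A
#' header line is detected automatically (non-numeric third field).
#'
#' @param path file path.
#' @param map_id map identifier; defaults to the file name without extension.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, map_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(map_id)) map_id <- sub("\\.[^.]*$", "", basename(path))
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  raw <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("marker", "lg", "pos_cm"))
  genetic_map(raw$marker, raw$lg, suppressWarnings(parse_grouped_number(raw$pos_cm)),
              map_id = map_id)
}

#' Write a genetic map file
#'
#' @param map a `genetic_map` (or consensus map).
#' @param path output path; tab-delimited marker/lg/pos_cm with header.
#' @return invisibly, `path`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map[, c("marker", "lg", "pos_cm")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map '%s': %d markers, %d linkage group(s)\n",
              attr(x, "map_id") %||% "?", nrow(x), length(unique(x$lg))))
  for (g in unique(x$lg)) {
    p <- x$pos_cm[x$lg == g]
    cat(sprintf("  %s: %d markers, %.2f cM\n", g, length(p), max(p)))
  }
  invisible(x)
}

#' Rename markers mapped to several positions within one map
#'
#' A marker name occurring more than once within a single map gets the
#' suffixes `a`, `b`, `c`, ... appended in order of increasing position, so
#' downstream merging never sees an ambiguous within-map name. Names shared
#' *across* maps (the anchors that drive the merge) are deliberately left
#' unchanged.
#'
#' @param maps a list of `genetic_map` objects.
#' @return the list with renamed maps; a rename log data.frame
#'   (`map_id, lg, old, new, pos_cm`) is attached as `attr(, "renames")`.
#' @export
rename_redundant_markers <- function(maps) {
  logs <- list()
  out <- lapply(maps, function(m) {
    dup_names <- unique(m$marker[duplicated(m$marker)])
    if (length(dup_names) == 0) return(m)
    for (nm in dup_names) {
      idx <- which(m$marker == nm)
      idx <- idx[order(m$pos_cm[idx])]
      new <- paste0(nm, letters[seq_along(idx)])
      logs[[length(logs) + 1]] <<- data.frame(
        map_id = attr(m, "map_id") %||% "?", lg = m$lg[idx],
        old = nm, new = new, pos_cm = m$pos_cm[idx],
        stringsAsFactors = FALSE)
      m$marker[idx] <- new
    }
    m
  })
  attr(out, "renames") <- if (length(logs)) do.call(rbind, logs) else
    data.frame(map_id = character(), lg = character(), old = character(),
               new = character(), pos_cm = numeric())
  out
}
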