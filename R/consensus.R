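#' Pairwise marker-precedence graph for one linkage group
#'
#' Builds the directed weighted graph whose nodes are the distinct markers
#' placed on `lg` by any input map and whose edge `u -> v` carries the number
#' of maps placing `u` strictly before `v`. Pairs with edges in both
#' directions are ordering conflicts between maps.
#'
#' @param maps list of `genetic_map` objects.
#' @param lg linkage-group label.
#' @return an [igraph::graph] with edge attribute `weight`; conflicting
#'   marker pairs as a two-column matrix in `attr(, "conflicts")`, and each
#'   marker's mean position across maps in vertex attribute `mean_pos`.
#' @export
order_graph <- function(maps, lg) {
  edges <- list()
  pos_acc <- list()
  for (m in maps) {
    sub <- m[m$lg == lg, , drop = FALSE]
    if (nrow(sub) < 1) next
    sub <- sub[order(sub$pos_cm), , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      pos_acc[[sub$marker[k]]] <- c(pos_acc[[sub$marker[k]]], sub$pos_cm[k])
    }
    if (nrow(sub) < 2) next
    ij <- which(upper.tri(matrix(0, nrow(sub), nrow(sub))), arr.ind = TRUE)
    strict <- sub$pos_cm[ij[, 2]] > sub$pos_cm[ij[, 1]]
    edges[[length(edges) + 1]] <- data.frame(
      from = sub$marker[ij[strict, 1]], to = sub$marker[ij[strict, 2]],
      stringsAsFactors = FALSE)
  }
  if (length(pos_acc) == 0) stop("no map covers linkage group ", lg)
  nodes <- sort(names(pos_acc))
  el <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  if (nrow(el)) {
    key <- paste(el$from, el$to, sep = "\r")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    el <- data.frame(from = vapply(parts, `[`, "", 1),
                     to = vapply(parts, `[`, "", 2),
                     weight = agg$Freq, stringsAsFactors = FALSE)
  } else {
    el$weight <- numeric()
  }
  g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$mean_pos <- vapply(nodes, function(n) mean(pos_acc[[n]]), 0)
  fwd <- paste(el$from, el$to, sep = "\r")
  rev <- paste(el$to, el$from, sep = "\r")
  confl <- el[fwd %in% rev & el$from < el$to, c("from", "to"), drop = FALSE]
  attr(g, "conflicts") <- as.matrix(confl)
  g
}

# exact minimum-weight feedback arc set by subset DP (Held-Karp style) on a
# weight matrix; returns the vertex order. Feasible for n <= 12.
.fas_exact_order <- function(w) {
  n <- nrow(w)
  full <- bitwShiftL(1L, n) - 1L
  cost <- rep(Inf, full + 1L)
  last <- rep(NA_integer_, full + 1L)
  cost[1L] <- 0
  # backward weight added when v is appended after set S: edges v -> S
  for (S in 1:full) {
    members <- which(bitwAnd(S, bitwShiftL(1L, 0:(n - 1))) > 0)
    for (v in members) {
      Sprev <- bitwAnd(S, bitwNot(bitwShiftL(1L, v - 1L)))
      prev_members <- setdiff(members, v)
      add <- if (length(prev_members)) sum(w[v, prev_members]) else 0
      cand <- cost[Sprev + 1L] + add
      if (cand < cost[S + 1L]) {
        cost[S + 1L] <- cand
        last[S + 1L] <- v
      }
    }
  }
  ord <- integer(n)
  S <- full
  for (k in n:1) {
    v <- last[S + 1L]
    ord[k] <- v
    S <- bitwAnd(S, bitwNot(bitwShiftL(1L, v - 1L)))
  }
  ord
}

# greedy Eades-style ordering for large strongly connected components:
# repeatedly emit the vertex with the highest net agreement (out - in weight).
.fas_greedy_order <- function(w) {
  n <- nrow(w)
  remaining <- seq_len(n)
  ord <- integer(0)
  while (length(remaining) > 1) {
    net <- rowSums(w[remaining, remaining, drop = FALSE]) -
      colSums(w[remaining, remaining, drop = FALSE])
    pick <- remaining[which.max(net)]
    ord <- c(ord, pick)
    remaining <- setdiff(remaining, pick)
  }
  c(ord, remaining)
}

#' Resolve ordering conflicts into a single consensus marker order
#'
#' Decomposes the precedence graph into strongly connected components; within
#' each component a minimum-weight feedback arc set is removed (exactly, by
#' dynamic programming, for components of at most `exact_max` markers;
#' greedily by net agreement above that). The acyclic graph is then
#' linearised by Kahn's algorithm, breaking ties by mean observed position
#' (then by name), which interleaves markers private to different maps
#' sensibly and deterministically.
#'
#' @param graph an [order_graph()].
#' @param exact_max largest component size solved exactly (default 12).
#' @return character vector of marker names in consensus order.
#' @export
resolve_marker_order <- function(graph, exact_max = 12) {
  comp <- igraph::components(graph, mode = "strong")
  names_all <- igraph::V(graph)$name
  mean_pos <- setNames(igraph::V(graph)$mean_pos, names_all)
  # rank within each SCC
  scc_order <- lapply(seq_len(comp$no), function(ci) {
    vs <- names_all[comp$membership == ci]
    if (length(vs) == 1) return(vs)
    sub <- igraph::induced_subgraph(graph, vs)
    w <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                               sparse = FALSE))
    nm <- igraph::V(sub)$name
    ord <- if (length(vs) <= exact_max) .fas_exact_order(w) else
      .fas_greedy_order(w)
    nm[ord]
  })
  rank_in_scc <- unlist(lapply(scc_order, function(v) {
    setNames(seq_along(v), v)
  }))
  # condensation DAG between components
  el <- igraph::as_data_frame(graph, what = "edges")
  cfrom <- comp$membership[el$from]
  cto <- comp$membership[el$to]
  inter <- cfrom != cto
  # Kahn on components, tie-break by mean position of the component
  indeg <- integer(comp$no)
  adj <- vector("list", comp$no)
  for (k in which(inter)) {
    adj[[cfrom[k]]] <- union(adj[[cfrom[k]]], cto[k])
  }
  for (ci in seq_len(comp$no)) for (cj in adj[[ci]]) indeg[cj] <- indeg[cj] + 1L
  comp_pos <- vapply(seq_len(comp$no), function(ci) {
    mean(mean_pos[names_all[comp$membership == ci]])
  }, 0)
  comp_name <- vapply(scc_order, `[`, "", 1)
  avail <- which(indeg == 0L)
  out_comp <- integer(0)
  while (length(avail)) {
    pick <- avail[order(comp_pos[avail], comp_name[avail])][1]
    out_comp <- c(out_comp, pick)
    avail <- setdiff(avail, pick)
    for (cj in adj[[pick]]) {
      indeg[cj] <- indeg[cj] - 1L
      if (indeg[cj] == 0L) avail <- c(avail, cj)
    }
  }
  unlist(scc_order[out_comp], use.names = FALSE)
}

# L1 gap fit: given consensus order and per-map distance constraints
# (a, b, d) meaning sum(gaps[a..b-1]) ~ d, minimise total absolute deviation
# subject to gaps >= 0, by coordinate descent with weighted-median updates.
# Even-sized medians land on interval midpoints (the documented tie rule).
.fit_gaps_l1 <- function(n_gaps, cons, tol = 1e-9, max_pass = 400) {
  if (n_gaps == 0) return(numeric(0))
  g <- numeric(n_gaps)
  cover <- vector("list", n_gaps)
  if (nrow(cons)) {
    # initialise each gap from single-step constraints where available
    for (i in seq_len(n_gaps)) {
      cover[[i]] <- which(cons$a <= i & cons$b > i)
      single <- cons$a == i & cons$b == i + 1
      g[i] <- if (any(single)) median(cons$d[single]) else 0
    }
    for (pass in seq_len(max_pass)) {
      delta <- 0
      spans <- vapply(seq_len(nrow(cons)), function(k) {
        sum(g[cons$a[k]:(cons$b[k] - 1)])
      }, 0)
      for (i in seq_len(n_gaps)) {
        ks <- cover[[i]]
        if (!length(ks)) next
        targets <- cons$d[ks] - (spans[ks] - g[i])
        new <- max(0, median(targets))
        if (new != g[i]) {
          spans[ks] <- spans[ks] + (new - g[i])
          delta <- max(delta, abs(new - g[i]))
          g[i] <- new
        }
      }
      if (delta < tol) break
    }
  }
  g
}

#' Merge one linkage group across maps into consensus positions
#'
#' Implements the candidate-consensus construction: (i) a consensus marker
#' order from [resolve_marker_order()]; (ii) positions minimising the total
#' absolute deviation from every input map's inter-marker distances, subject
#' to monotone non-decreasing positions, where each map contributes distance
#' constraints between markers at most `interval_parameter` apart in its own
#' order; (iii) the first marker anchored at 0 cM.
#'
#' When more than one map covers the group, a map sharing fewer than
#' `min_anchors` markers with the union of the other maps is dropped for this
#' group (logged in `attr(, "dropped_maps")`).
#'
#' @param maps list of `genetic_map` objects (after
#'   [rename_redundant_markers()]).
#' @param lg linkage-group label.
#' @param interval_parameter integer 1..3, the maximum constraint span.
#' @param min_anchors minimum shared markers a map needs, default 2.
#' @return data.frame `marker, lg, pos_cm` in consensus order, with
#'   per-marker contributing map ids in `attr(, "provenance")`.
#' @export
merge_linkage_group <- function(maps, lg, interval_parameter = 2,
                                min_anchors = 2) {
  stopifnot(interval_parameter >= 1)
  subs <- lapply(maps, function(m) {
    s <- m[m$lg == lg, , drop = FALSE]
    s <- s[order(s$pos_cm), , drop = FALSE]
    attr(s, "map_id") <- attr(m, "map_id") %||% "?"
    s
  })
  subs <- subs[vapply(subs, nrow, 0L) > 0]
  if (length(subs) == 0) stop("no map covers linkage group ", lg)
  dropped <- character(0)
  if (length(subs) > 1) {
    keep <- vapply(seq_along(subs), function(i) {
      others <- unique(unlist(lapply(subs[-i], function(s) s$marker)))
      sum(subs[[i]]$marker %in% others) >= min_anchors
    }, TRUE)
    if (all(!keep)) stop("no shared anchor markers on linkage group ", lg)
    dropped <- vapply(subs[!keep], function(s) attr(s, "map_id"), "")
    subs <- subs[keep]
  }
  gmaps <- lapply(subs, function(s) {
    gm <- genetic_map(s$marker, s$lg, s$pos_cm, map_id = attr(s, "map_id"))
    gm
  })
  ord <- if (length(gmaps) == 1) {
    gmaps[[1]]$marker
  } else {
    resolve_marker_order(order_graph(gmaps, lg))
  }
  idx <- setNames(seq_along(ord), ord)
  cons_list <- lapply(subs, function(s) {
    m <- nrow(s)
    if (m < 2) return(NULL)
    res <- list()
    for (span in 1:min(interval_parameter, m - 1)) {
      i <- seq_len(m - span)
      j <- i + span
      a <- pmin(idx[s$marker[i]], idx[s$marker[j]])
      b <- pmax(idx[s$marker[i]], idx[s$marker[j]])
      d <- s$pos_cm[j] - s$pos_cm[i]
      ok <- b > a  # drop degenerate (same consensus slot) pairs
      res[[span]] <- data.frame(a = a[ok], b = b[ok], d = d[ok])
    }
    do.call(rbind, res)
  })
  cons <- do.call(rbind, cons_list)
  if (is.null(cons)) cons <- data.frame(a = integer(), b = integer(), d = numeric())
  g <- .fit_gaps_l1(length(ord) - 1, cons)
  pos <- cumsum(c(0, g))
  out <- data.frame(marker = ord, lg = lg, pos_cm = pos,
                    stringsAsFactors = FALSE)
  prov <- lapply(ord, function(mk) {
    unlist(lapply(subs, function(s) {
      if (mk %in% s$marker) attr(s, "map_id") else NULL
    }))
  })
  names(prov) <- ord
  attr(out, "provenance") <- prov
  attr(out, "dropped_maps") <- dropped
  out
}

#' Root-mean-square error of an input map against a consensus
#'
#' RMSE over shared markers of (input position - consensus position), per
#' linkage group, on raw positions (no per-map rescaling).
#'
#' @param map a `genetic_map`.
#' @param consensus a `consensus_map` (or any `genetic_map`).
#' @return data.frame `map_id, lg, n_shared, rmse`; groups without shared
#'   markers are reported with `rmse = NA`.
#' @export
compute_rmse <- function(map, consensus) {
  out <- lapply(unique(map$lg), function(g) {
    a <- map[map$lg == g, , drop = FALSE]
    b <- consensus[consensus$lg == g, , drop = FALSE]
    shared <- intersect(a$marker, b$marker)
    rmse <- if (length(shared) == 0) NA_real_ else {
      d <- a$pos_cm[match(shared, a$marker)] - b$pos_cm[match(shared, b$marker)]
      sqrt(mean(d^2))
    }
    data.frame(map_id = attr(map, "map_id") %||% "?", lg = g,
               n_shared = length(shared), rmse = rmse,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build candidate consensus maps and pick the best by mean RMSE
#'
#' Runs [merge_linkage_group()] on every linkage group for each interval
#' parameter in `intervals`, yielding one candidate consensus per parameter.
#' For each candidate, per-map RMSE diagnostics are computed; maps whose
#' pooled RMSE exceeds `rmse_factor` times the median across maps are dropped
#' and that candidate re-merged once (the "poorly represented map" rule).
#' The candidate with the least mean RMSE over contributing maps is selected
#' (ties go to the smallest interval parameter).
#'
#' @param maps list of `genetic_map` objects (redundant markers are renamed
#'   internally).
#' @param intervals integer vector of interval parameters, default `1:3`.
#' @param min_anchors per-group anchor requirement, default 2.
#' @param rmse_factor outlier-map threshold, default 3; `Inf` disables.
#' @return the selected `consensus_map`: a `genetic_map` data.frame with
#'   attributes `interval_parameter`, `provenance`, `diagnostics` (per map/LG
#'   RMSE), and `candidates` (mean RMSE per interval parameter).
#' @export
build_consensus <- function(maps, intervals = 1:3, min_anchors = 2,
                            rmse_factor = 3) {
  stopifnot(length(maps) >= 1)
  ids <- vapply(maps, function(m) attr(m, "map_id") %||% "?", "")
  if (anyDuplicated(ids)) stop("map_id values must be unique")
  maps <- rename_redundant_markers(maps)
  lgs <- sort(unique(unlist(lapply(maps, function(m) unique(m$lg)))))

  merge_all <- function(maps, p) {
    per_lg <- lapply(lgs, function(g) {
      covered <- vapply(maps, function(m) any(m$lg == g), TRUE)
      merge_linkage_group(maps[covered], g, interval_parameter = p,
                          min_anchors = min_anchors)
    })
    cons <- do.call(rbind, lapply(per_lg, function(x) {
      data.frame(marker = x$marker, lg = x$lg, pos_cm = x$pos_cm,
                 stringsAsFactors = FALSE)
    }))
    cm <- genetic_map(cons$marker, cons$lg, cons$pos_cm,
                      map_id = "consensus")
    attr(cm, "interval_parameter") <- p
    prov <- do.call(c, lapply(per_lg, function(x) attr(x, "provenance")))
    attr(cm, "provenance") <- prov
    attr(cm, "dropped_maps") <-
      unique(unlist(lapply(per_lg, function(x) attr(x, "dropped_maps"))))
    class(cm) <- c("consensus_map", class(cm))
    cm
  }

  candidates <- lapply(intervals, function(p) {
    cm <- merge_all(maps, p)
    diag <- do.call(rbind, lapply(maps, compute_rmse, consensus = cm))
    pooled <- vapply(split(diag, diag$map_id), function(d) {
      if (all(is.na(d$rmse))) NA_real_ else
        sqrt(sum(d$rmse^2 * d$n_shared, na.rm = TRUE) /
               sum(d$n_shared[!is.na(d$rmse)]))
    }, 0)
    bad <- names(pooled)[!is.na(pooled) &
                           pooled > rmse_factor * median(pooled, na.rm = TRUE) &
                           length(maps) > 2]
    if (length(bad)) {
      kept <- maps[!ids %in% bad]
      cm <- merge_all(kept, p)
      attr(cm, "dropped_maps") <- union(attr(cm, "dropped_maps"), bad)
      diag <- do.call(rbind, lapply(kept, compute_rmse, consensus = cm))
    }
    attr(cm, "diagnostics") <- diag
    attr(cm, "mean_rmse") <- mean(vapply(split(diag, diag$map_id),
                                         function(d) mean(d$rmse, na.rm = TRUE),
                                         0), na.rm = TRUE)
    cm
  })
  select_best_consensus(candidates)
}

#' Select the candidate consensus with the least mean RMSE
#'
#' @param candidates list of candidate consensus maps carrying `mean_rmse`
#'   and `interval_parameter` attributes (as built by [build_consensus()]).
#' @return the winning candidate, with the full candidate comparison table in
#'   `attr(, "candidates")`. Ties resolve to the smallest interval parameter.
#' @export
select_best_consensus <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  tab <- data.frame(
    interval_parameter = vapply(candidates, function(c)
      as.numeric(attr(c, "interval_parameter") %||% NA_real_), 0),
    mean_rmse = vapply(candidates, function(c)
      as.numeric(attr(c, "mean_rmse") %||% NA_real_), 0)
  )
  ord <- order(tab$mean_rmse, tab$interval_parameter)
  best <- candidates[[ord[1]]]
  attr(best, "candidates") <- tab
  best
}

#' Per-linkage-group marker summary of a consensus map
#'
#' Reports marker count, genetic length (cM) and marker density (markers/cM,
#' rounded to 2 decimals) per linkage group, plus a totals row: summed
#' counts, summed lengths, and the average of the per-group unrounded
#' densities (all rounded to 2 decimals).
#'
#' @param x a `consensus_map`/`genetic_map`, or a data.frame with columns
#'   `lg`, `n_markers`, `length_cm` holding pre-computed per-group counts and
#'   lengths.
#' @param ... unused.
#' @return data.frame `lg, n_markers, length_cm, density` whose last row is
#'   the `Total` row.
#' @export
map_summary <- function(x, ...) UseMethod("map_summary")

.map_summary_core <- function(lg, n_markers, length_cm) {
  density <- n_markers / length_cm
  density[!is.finite(density)] <- NA_real_
  rbind(
    data.frame(lg = lg, n_markers = n_markers,
               length_cm = length_cm,
               density = round_half_up(density, 2),
               stringsAsFactors = FALSE),
    data.frame(lg = "Total", n_markers = sum(n_markers),
               length_cm = round_half_up(sum(length_cm), 2),
               density = round_half_up(mean(density, na.rm = TRUE), 2),
               stringsAsFactors = FALSE)
  )
}

#' @rdname map_summary
#' @export
map_summary.genetic_map <- function(x, ...) {
  lgs <- unique(x$lg)
  n <- vapply(lgs, function(g) sum(x$lg == g), 0L)
  len <- vapply(lgs, function(g) max(x$pos_cm[x$lg == g]), 0)
  .map_summary_core(lgs, n, len)
}

#' @rdname map_summary
#' @export
map_summary.data.frame <- function(x, ...) {
  stopifnot(all(c("lg", "n_markers", "length_cm") %in% names(x)))
  .map_summary_core(x$lg, x$n_markers, x$length_cm)
}

#' Marker-density profile along each linkage group
#'
#' Counts markers in half-open bins `[k*bin_cm, (k+1)*bin_cm)`; bin counts
#' conserve the total marker number.
#'
#' @param consensus a `genetic_map`.
#' @param bin_cm positive bin width in cM.
#' @return data.frame `lg, bin_start_cm, bin_end_cm, n_markers`.
#' @export
density_profile <- function(consensus, bin_cm) {
  stopifnot(bin_cm > 0)
  out <- lapply(unique(consensus$lg), function(g) {
    p <- consensus$pos_cm[consensus$lg == g]
    if (length(p) == 0) return(NULL)
    k <- floor(p / bin_cm)
    tab <- table(k)
    data.frame(lg = g, bin_start_cm = as.numeric(names(tab)) * bin_cm,
               bin_end_cm = (as.numeric(names(tab)) + 1) * bin_cm,
               n_markers = as.integer(tab), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
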