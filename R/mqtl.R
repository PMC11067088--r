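#' Percentage contribution of each stress class to an MQTL
#'
#' Shares of member QTL per stress class, as percentages of the member count
#' rounded to 1 decimal; classes with no members are omitted.
#'
#' @param stress character vector of member stress classes.
#' @return named numeric vector of percentages (sums to 100 up to rounding).
#' @examples
#' stress_contributions(c("DROUGHT", "DROUGHT", "SALINITY", "DROUGHT"))
#' @export
stress_contributions <- function(stress) {
  stress <- stress[!is.na(stress)]
  if (length(stress) == 0) return(setNames(numeric(0), character(0)))
  tab <- table(stress)
  raw <- 100 * as.numeric(tab) / length(stress)
  # largest-remainder rounding at 1 decimal so the shares sum to exactly 100
  lo <- floor(raw * 10) / 10
  deficit <- round((100 - sum(lo)) * 10)
  if (deficit > 0) {
    bump <- order(raw - lo, decreasing = TRUE)[seq_len(deficit)]
    lo[bump] <- lo[bump] + 0.1
  }
  setNames(round(lo, 1), names(tab))
}

# drop mixture components with no primary member, reassigning their posterior
# weight to the remaining components (renormalisation); returns the reduced
# posterior/means and a log of merges
.prune_empty_components <- function(mean, posterior, sigma) {
  log <- character(0)
  repeat {
    cls <- max.col(posterior, ties.method = "first")
    counts <- tabulate(cls, ncol(posterior))
    if (all(counts > 0) || ncol(posterior) == 1) break
    k <- which(counts == 0)[1]
    nearest <- setdiff(order(abs(mean - mean[k])), k)[1]
    log <- c(log, sprintf("component at %.3f cM empty; merged into %.3f cM",
                          mean[k], mean[nearest]))
    posterior <- posterior[, -k, drop = FALSE]
    posterior <- posterior / rowSums(posterior)
    mean <- mean[-k]
  }
  list(mean = mean, posterior = posterior, log = log)
}

#' Build MQTL from a fitted mixture and its member QTL
#'
#' Turns each mixture component into a meta-QTL: position is the component
#' mean; the 95% CI is `mean +/- 1.96 / sqrt(sum_i r_ik / sigma_i^2)` with
#' `r_ik` the posterior membership weights; primary members are assigned by
#' maximum posterior; a QTL is additionally a *shared* member of every MQTL
#' whose 95% CI overlaps the QTL's own 95% CI; the MQTL PVE is the mean
#' `r2_pct` of its primary members; flanking markers are the nearest
#' consensus markers outside the CI. Components left without any primary
#' member are merged into their nearest neighbour (K decreases; logged in
#' `attr(, "merged_components")`). Ids are assigned left to right as
#' `<prefix><chromosome number>.<rank>`.
#'
#' @param fit an [mqtl_mixture()] (or the `fit` of a
#'   [select_mqtl_model()]).
#' @param observations the `projected_qtl` rows (status `PROJECTED`) the fit
#'   was computed from, in the same order as `fit$x`.
#' @param lg linkage-group label (e.g. `"CaLG04"`).
#' @param consensus optional `consensus_map` for flanking-marker lookup.
#' @param id_prefix default `"CaMQAST"` (chickpea, meta-QTL, abiotic stress
#'   tolerance).
#' @return an `mqtl_set` data.frame: `mqtl_id, lg, position_cm, ci_lo_cm,
#'   ci_hi_cm, ci_width_cm, n_qtl, n_shared, pve_pct, flank_left,
#'   flank_right` plus one `pct_<stress>` column per stress class. The long
#'   membership table (`mqtl_id, qtl_id, study_id, role`) is in
#'   `attr(, "membership")`.
#' @export
build_mqtl <- function(fit, observations, lg, consensus = NULL,
                       id_prefix = "CaMQAST") {
  stopifnot(nrow(observations) == fit$n)
  pr <- .prune_empty_components(fit$mean, fit$posterior, fit$sigma)
  mean_k <- pr$mean
  post <- pr$posterior
  K <- length(mean_k)
  cls <- max.col(post, ties.method = "first")
  prec <- vapply(seq_len(K), function(k) sum(post[, k] / fit$sigma^2), 0)
  half <- 1.96 / sqrt(prec)
  ci_lo <- mean_k - half
  ci_hi <- mean_k + half

  lg_num <- suppressWarnings(as.integer(gsub("\\D", "", lg)))
  ids <- if (is.na(lg_num)) paste0(id_prefix, lg, ".", seq_len(K)) else
    paste0(id_prefix, lg_num, ".", seq_len(K))

  q_lo <- observations$consensus_ci_lo_cm
  q_hi <- observations$consensus_ci_hi_cm

  flank <- function(lo, hi) {
    if (is.null(consensus)) return(c(NA_character_, NA_character_))
    cm <- consensus[consensus$lg == lg, , drop = FALSE]
    left <- cm$marker[cm$pos_cm < lo]
    right <- cm$marker[cm$pos_cm > hi]
    c(if (length(left)) left[length(left)] else NA_character_,
      if (length(right)) right[1] else NA_character_)
  }

  rows <- vector("list", K)
  membership <- vector("list", K)
  stress_levels <- .stress_levels
  for (k in seq_len(K)) {
    primary <- which(cls == k)
    shared <- which(q_hi >= ci_lo[k] & q_lo <= ci_hi[k])
    r2 <- observations$r2_pct[primary]
    pve <- if (all(is.na(r2))) NA_real_ else mean(r2, na.rm = TRUE)
    fl <- flank(ci_lo[k], ci_hi[k])
    contrib <- stress_contributions(observations$stress[primary])
    pct <- setNames(rep(0, length(stress_levels)),
                    paste0("pct_", tolower(stress_levels)))
    pct[paste0("pct_", tolower(names(contrib)))] <- contrib
    rows[[k]] <- data.frame(
      mqtl_id = ids[k], lg = lg, position_cm = mean_k[k],
      ci_lo_cm = ci_lo[k], ci_hi_cm = ci_hi[k],
      ci_width_cm = ci_hi[k] - ci_lo[k],
      n_qtl = length(primary), n_shared = length(shared),
      pve_pct = pve, flank_left = fl[1], flank_right = fl[2],
      as.list(pct), stringsAsFactors = FALSE)
    extra_shared <- setdiff(shared, primary)
    membership[[k]] <- data.frame(
      mqtl_id = ids[k],
      qtl_id = c(observations$qtl_id[primary], observations$qtl_id[extra_shared]),
      study_id = c(observations$study_id[primary],
                   observations$study_id[extra_shared]),
      role = c(rep("primary", length(primary)),
               rep("shared", length(extra_shared))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mqtl_set", "data.frame")
  attr(out, "membership") <- do.call(rbind, membership)
  attr(out, "merged_components") <- pr$log
  out
}

#' Meta-analyse a projected QTL catalog into MQTL
#'
#' Runs the per-linkage-group mixture meta-analysis over all successfully
#' projected QTL: observation sigmas come from the projected 95% CIs; the
#' number of components is chosen by [select_mqtl_model()] on groups with
#' more than `full_selection_min` QTL, and with `K_max = small_K_max` on
#' smaller groups; [build_mqtl()] assembles the MQTL.
#'
#' @param projected a `projected_qtl` data.frame.
#' @param consensus optional `consensus_map` for flanking markers.
#' @param seed integer seed driving every EM restart (deterministic).
#' @param K_max per-group cap on K, default `min(n distinct, 15)`.
#' @param restarts EM restarts per K, default 10.
#' @param sigma_min sigma floor in cM, default 0.1.
#' @param full_selection_min QTL count above which the full K sweep is used,
#'   default 10.
#' @param small_K_max K cap for small groups, default 4.
#' @param id_prefix MQTL id prefix, default `"CaMQAST"`.
#' @return an object of class `mqtl_result`: list with `mqtl` (the combined
#'   `mqtl_set`), `membership`, `selections` (per-LG
#'   `mqtl_model_selection`s), `n_projected`, `n_used`.
#' @export
meta_qtl <- function(projected, consensus = NULL, seed = 1, K_max = NULL,
                     restarts = 10, sigma_min = 0.1,
                     full_selection_min = 10, small_K_max = 4,
                     id_prefix = "CaMQAST") {
  used <- projected[projected$status == "PROJECTED", , drop = FALSE]
  if (nrow(used) == 0) stop("no projected QTL to meta-analyse")
  lgs <- sort(unique(used$lg))
  sets <- list()
  selections <- list()
  for (g in lgs) {
    obs <- used[used$lg == g, , drop = FALSE]
    obs <- obs[order(obs$consensus_peak_cm, obs$qtl_id), , drop = FALSE]
    x <- obs$consensus_peak_cm
    sigma <- sigma_from_ci(obs$consensus_ci_lo_cm, obs$consensus_ci_hi_cm,
                           sigma_min = sigma_min)
    if (nrow(obs) == 1 || length(unique(x)) == 1) {
      fit <- mqtl_mixture(x, sigma, K = 1)
      selections[[g]] <- NULL
    } else {
      kmax <- if (nrow(obs) > full_selection_min) K_max else
        min(small_K_max, K_max %||% small_K_max)
      sel <- select_mqtl_model(x, sigma, K_max = kmax, restarts = restarts,
                               seed = derive_seed(seed, g))
      selections[[g]] <- sel
      fit <- sel$fit
    }
    sets[[g]] <- build_mqtl(fit, obs, g, consensus = consensus,
                            id_prefix = id_prefix)
  }
  mqtl <- do.call(rbind, sets)
  rownames(mqtl) <- NULL
  class(mqtl) <- c("mqtl_set", "data.frame")
  membership <- do.call(rbind, lapply(sets, attr, "membership"))
  rownames(membership) <- NULL
  out <- list(mqtl = mqtl, membership = membership, selections = selections,
              n_projected = sum(projected$status == "PROJECTED"),
              n_used = nrow(used), seed = seed)
  class(out) <- "mqtl_result"
  out
}

#' Summary statistics of an MQTL table
#'
#' The averaging used in reports: number of MQTL, mean PVE, mean 95% CI
#' width, and per-linkage-group counts.
#'
#' @param mqtl an `mqtl_set` (or any data.frame with `pve_pct`,
#'   `ci_width_cm`, `lg`).
#' @return list `n`, `mean_pve`, `mean_ci_width`, `by_lg`.
#' @export
mqtl_table_stats <- function(mqtl) {
  ciw <- if ("ci_width_cm" %in% names(mqtl)) mqtl$ci_width_cm else
    mqtl$ci_hi_cm - mqtl$ci_lo_cm
  list(n = nrow(mqtl),
       mean_pve = mean(mqtl$pve_pct, na.rm = TRUE),
       mean_ci_width = mean(ciw, na.rm = TRUE),
       by_lg = table(mqtl$lg))
}

#' @export
print.mqtl_result <- function(x, ...) {
  s <- mqtl_table_stats(x$mqtl)
  cat(sprintf("Meta-QTL analysis: %d MQTL from %d projected QTL\n",
              s$n, x$n_used))
  cat(sprintf("  mean PVE %.3f%%, mean 95%% CI width %.3f cM\n",
              s$mean_pve, s$mean_ci_width))
  cat("  per linkage group: ",
      paste(names(s$by_lg), s$by_lg, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.mqtl_result <- function(object, ...) {
  s <- mqtl_table_stats(object$mqtl)
  s$membership_roles <- table(object$membership$role)
  s$mqtl <- object$mqtl
  class(s) <- "summary.mqtl_result"
  s
}

#' @export
print.summary.mqtl_result <- function(x, ...) {
  cat(sprintf("%d MQTL; mean PVE %.3f%%; mean CI width %.3f cM\n",
              x$n, x$mean_pve, x$mean_ci_width))
  print(x$mqtl[, c("mqtl_id", "lg", "position_cm", "ci_lo_cm", "ci_hi_cm",
                   "n_qtl", "pve_pct")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.mqtl_result <- function(x, ...) {
  m <- x$mqtl
  lgs <- unique(m$lg)
  ypos <- match(m$lg, lgs)
  plot(range(c(m$ci_lo_cm, m$ci_hi_cm)), c(0.5, length(lgs) + 0.5),
       type = "n", xlab = "consensus position (cM)", ylab = "",
       yaxt = "n", ...)
  axis(2, at = seq_along(lgs), labels = lgs, las = 1)
  segments(m$ci_lo_cm, ypos, m$ci_hi_cm, ypos, lwd = 3, col = "steelblue")
  points(m$position_cm, ypos, pch = 19)
  invisible(x)
}
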