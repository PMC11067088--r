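# in-code fixtures shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal catalog data.frame with canonical columns; extra args override
make_catalog <- function(n = 3, ...) {
  df <- data.frame(
    qtl_id = sprintf("q%d", seq_len(n)),
    study_id = rep_len("s1", n),
    trait = rep_len("YLD", n),
    stress = rep_len("DROUGHT", n),
    lg = rep_len("CaLG01", n),
    peak_cm = seq(10, by = 10, length.out = n),
    ci_lo_cm = seq(10, by = 10, length.out = n) - 2,
    ci_hi_cm = seq(10, by = 10, length.out = n) + 2,
    lod = rep_len(4, n),
    r2_pct = rep_len(10, n),
    flank_left = rep_len(NA_character_, n),
    flank_right = rep_len(NA_character_, n),
    env = rep_len("E1", n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  class(df) <- c("qtl_catalog", "data.frame")
  df
}

write_catalog_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
  path
}

make_studies <- function(ids = "s1", type = "RIL", size = 163) {
  df <- data.frame(study_id = ids, population_type = type,
                   population_size = size, stringsAsFactors = FALSE)
  class(df) <- c("study_meta", "data.frame")
  df
}

# projected_qtl rows matching a vector of consensus peaks/CIs
make_projected <- function(peak, ci_lo = peak - 2, ci_hi = peak + 2,
                           lg = "CaLG01", r2 = 10, stress = "DROUGHT",
                           status = "PROJECTED") {
  n <- length(peak)
  df <- data.frame(
    qtl_id = paste0("q", seq_len(n)), study_id = "s1", trait = "YLD",
    stress = rep_len(stress, n), lg = lg, peak_cm = peak,
    r2_pct = rep_len(r2, n),
    consensus_peak_cm = peak, consensus_ci_lo_cm = ci_lo,
    consensus_ci_hi_cm = ci_hi, status = rep_len(status, n),
    reason = NA_character_, stringsAsFactors = FALSE)
  class(df) <- c("projected_qtl", "data.frame")
  df
}

# small, fast pipeline configuration for end-to-end tests
small_sim_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_linkage_groups = 3, markers_per_lg = 40,
                    n_maps = 2, n_studies = 6, qtl_per_study = 25,
                    genes_per_mb = 5, ...)
}

# independent brute-force oracle for the K = 2 mixture log-likelihood:
# dense grid over both means, mixing proportion swept at 0.01 resolution
grid_oracle_lnL <- function(x, sigma, mu1_grid, mu2_grid,
                            pi_grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(sigma) == 1) sigma <- rep(sigma, length(x))
  phi1 <- outer(mu1_grid, seq_along(x),
                function(m, i) dnorm(x[i], m, sigma[i]))
  phi2 <- outer(mu2_grid, seq_along(x),
                function(m, i) dnorm(x[i], m, sigma[i]))
  best <- -Inf
  for (p in pi_grid) {
    for (j in seq_along(mu2_grid)) {
      mix <- p * phi1 + (1 - p) * matrix(phi2[j, ], nrow(phi1),
                                         length(x), byrow = TRUE)
      ll <- rowSums(log(mix))
      m <- max(ll)
      if (m > best) best <- m
    }
  }
  best
}
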