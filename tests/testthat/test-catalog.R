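test_that("read_qtl_table ingests valid rows and logs rejections with reasons", {
  path <- write_catalog_csv(make_catalog(3))
  cat3 <- read_qtl_table(path)
  expect_s3_class(cat3, "qtl_catalog")
  expect_equal(nrow(cat3), 3)
  expect_equal(nrow(attr(cat3, "rejections")), 0)

  bad <- make_catalog(3, r2_pct = c(10, 120, 20))
  got <- read_qtl_table(write_catalog_csv(bad))
  expect_equal(nrow(got), 2)
  rej <- attr(got, "rejections")
  expect_equal(rej$reason, "PVE out of range")
  expect_equal(rej$row, 2)

  # peak-only record is accepted and marked for CI imputation
  peak_only <- make_catalog(1, ci_lo_cm = NA, ci_hi_cm = NA)
  got <- read_qtl_table(write_catalog_csv(peak_only))
  expect_equal(got$ci_source, "to_impute")

  # inverted CI and peak outside CI are rejected, not silently fixed
  inv <- make_catalog(2, ci_lo_cm = c(12, 5), ci_hi_cm = c(8, 15),
                      peak_cm = c(10, 30))
  got <- read_qtl_table(write_catalog_csv(inv))
  expect_equal(nrow(got), 0)
  expect_setequal(attr(got, "rejections")$reason,
                  c("inverted confidence interval",
                    "peak outside confidence interval"))
})

test_that("read_qtl_table errors on missing mandatory columns", {
  df <- as.data.frame(make_catalog(2))
  df$peak_cm <- NULL
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_qtl_table(path), "mandatory column")
})

test_that("digit-grouped numbers parse in both western and lakh style", {
  expect_equal(parse_grouped_number(c("1,40,38,103", "46,999", "7.5")),
               c(14038103, 46999, 7.5))
})

test_that("LOD conversion and threshold defaulting follow the stated rules", {
  expect_equal(lod_from_lr(c(4.6, 13.8, 0)), c(1, 3, 0))
  expect_error(lod_from_lr(-1), "non-negative")

  cat3 <- make_catalog(3, lod = c(NA, 5.2, NA),
                       study_id = c("s1", "s1", "s2"))
  out <- suppressWarnings(default_lod_threshold(cat3, "s1"))
  expect_equal(out$lod, c(3, 5.2, NA))
  expect_equal(out$lod_imputed, c(TRUE, FALSE, FALSE))
  expect_warning(default_lod_threshold(cat3, "s1"), "lack a LOD")
})

test_that("CI width formula matches the population-design constants", {
  expect_equal(ci_width_95("RIL", 163, 10), 10)
  expect_equal(ci_width_95("F2_3", 106, 5), 100)
  expect_equal(ci_width_95("RIL", 326, 50), 1)
  expect_true(is.na(ci_width_95("MAGIC", 500, 10)))
  # strictly decreasing in N and R2; doubling N halves the width
  w1 <- ci_width_95("RIL", 200, 10)
  expect_equal(ci_width_95("RIL", 400, 10), w1 / 2)
  expect_lt(ci_width_95("RIL", 200, 20), w1)
  expect_lt(ci_width_95("RIL", 300, 10), w1)
})

test_that("impute_ci completes records and flags the unprojectable", {
  cat4 <- make_catalog(4, ci_lo_cm = c(5, NA, NA, NA),
                       ci_hi_cm = c(15, NA, NA, NA),
                       r2_pct = c(10, 10, 10, NA),
                       peak_cm = c(10, 20, 2, 40),
                       study_id = c("s1", "s1", "s1", "s2"))
  studies <- make_studies(c("s1", "s2"), c("RIL", "MAGIC"), c(163, 500))
  out <- impute_ci(cat4, studies)
  # reported bounds take precedence
  expect_equal(out$ci_lo_cm[1], 5)
  expect_equal(out$ci_source[1], "reported")
  # RIL, N = 163, R2 = 10% -> width 10, peak +/- 5
  expect_equal(out$ci_lo_cm[2], 15)
  expect_equal(out$ci_hi_cm[2], 25)
  # truncation at 0 for a peak near the start
  expect_equal(out$ci_lo_cm[3], 0)
  expect_equal(out$ci_hi_cm[3], 7)
  # MAGIC without explicit CI cannot be completed
  expect_true(out$not_projectable[4])
  expect_false(any(out$not_projectable[1:3]))
})

test_that("multi-environment de-duplication keeps the highest-PVE instance", {
  three_env <- make_catalog(3, qtl_id = "q1", env = c("E1", "E2", "E3"),
                            r2_pct = c(8, 12, 9), peak_cm = 10,
                            ci_lo_cm = 8, ci_hi_cm = 12)
  out <- dedupe_multi_env(three_env)
  expect_equal(nrow(out), 1)
  expect_equal(out$r2_pct, 12)
  expect_equal(nrow(attr(out, "dropped")), 2)

  distinct <- make_catalog(4, qtl_id = paste0("q", 1:4))
  expect_equal(nrow(dedupe_multi_env(distinct)), 4)

  tied <- make_catalog(2, qtl_id = "q1", r2_pct = 10, lod = c(3.1, 2.8))
  expect_equal(dedupe_multi_env(tied)$lod, 3.1)

  # fallback identity: same trait + interval under different ids
  aliased <- make_catalog(2, qtl_id = c("qA", "qB"),
                          flank_left = "TA1", flank_right = "TA2",
                          r2_pct = c(5, 9))
  out <- dedupe_multi_env(aliased)
  expect_equal(nrow(out), 1)
  expect_equal(out$qtl_id, "qB")
})

test_that("de-duplication is idempotent and never grows the catalog", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 30
    cat_n <- make_catalog(n,
                          qtl_id = paste0("q", sample(1:12, n, replace = TRUE)),
                          study_id = sample(c("s1", "s2"), n, replace = TRUE),
                          r2_pct = runif(n, 1, 40),
                          lod = runif(n, 2, 10))
    once <- dedupe_multi_env(cat_n)
    twice <- dedupe_multi_env(once)
    expect_lte(nrow(once), n)
    strip <- function(d) {
      d <- as.data.frame(d)
      attributes(d) <- attributes(d)[c("names", "row.names", "class")]
      d
    }
    expect_equal(strip(twice), strip(once))
  }
})

test_that("catalog summaries count consistently and handle the empty case", {
  cat10 <- make_catalog(10, lg = c(rep("CaLG04", 4), rep("CaLG01", 6)),
                        r2_pct = c(1, 7, 8, 9, 6, 12, 17, 22, 30, 55))
  s <- summarize_catalog(cat10)
  expect_equal(unname(s$by_lg[["CaLG04"]]), 4)
  expect_equal(sum(s$by_lg), s$n)
  expect_equal(unname(s$pve_hist[["[5,10)"]]), 4)
  expect_equal(sum(s$pve_hist), 10)

  empty <- summarize_catalog(make_catalog(0))
  expect_equal(empty$n, 0)
  expect_true(all(empty$pve_hist == 0))

  paths <- write_catalog_summary(s, tempfile("summary"))
  expect_true(all(file.exists(paths)))
})
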