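toy_map <- function(markers, pos, id = "A", lg = "L1") {
  genetic_map(markers, rep(lg, length(markers)), pos, map_id = id)
}

test_that("redundant within-map markers are renamed by position; anchors kept", {
  m <- toy_map(c("TA42", "m2", "TA42"), c(5, 10, 17))
  out <- rename_redundant_markers(list(m))
  expect_equal(out[[1]]$marker, c("TA42a", "m2", "TA42b"))
  expect_equal(out[[1]]$pos_cm, c(5, 10, 17))
  expect_equal(nrow(attr(out, "renames")), 2)

  uniq <- toy_map(c("a", "b"), c(0, 5))
  expect_equal(rename_redundant_markers(list(uniq))[[1]]$marker, c("a", "b"))

  # the same name in two different maps is an anchor, untouched
  two <- rename_redundant_markers(list(toy_map("TA42", 3, "A"),
                                       toy_map("TA42", 8, "B")))
  expect_equal(two[[1]]$marker, "TA42")
  expect_equal(two[[2]]$marker, "TA42")
})

test_that("the order graph records weighted precedence and conflicts", {
  g <- order_graph(list(toy_map(c("m1", "m2"), c(0, 5), "A"),
                        toy_map(c("m1", "m2"), c(0, 7), "B")), "L1")
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 1)
  expect_equal(el$weight, 2)
  expect_equal(nrow(attr(g, "conflicts")), 0)

  g2 <- order_graph(list(toy_map(c("m1", "m2"), c(0, 5), "A"),
                         toy_map(c("m2", "m1"), c(0, 5), "B")), "L1")
  el2 <- igraph::as_data_frame(g2)
  expect_equal(sort(paste(el2$from, el2$to)), c("m1 m2", "m2 m1"))
  expect_equal(el2$weight, c(1, 1))
  expect_equal(nrow(attr(g2, "conflicts")), 1)

  g3 <- order_graph(list(toy_map(c("m1", "m3"), c(0, 9), "A"),
                         toy_map(c("m1", "m2", "m3"), c(0, 4, 9), "B")), "L1")
  el3 <- igraph::as_data_frame(g3)
  expect_setequal(paste(el3$from, el3$to), c("m1 m2", "m2 m3", "m1 m3"))
})

test_that("merging follows the absolute-deviation optimum with midpoint ties", {
  # identical maps reproduce themselves for any interval parameter
  A <- toy_map(c("m1", "m2", "m3"), c(0, 4, 9), "A")
  B <- toy_map(c("m1", "m2", "m3"), c(0, 4, 9), "B")
  for (p in 1:3) {
    cons <- merge_linkage_group(list(A, B), "L1", p)
    expect_equal(cons$marker, c("m1", "m2", "m3"))
    expect_equal(cons$pos_cm, c(0, 4, 9))
  }

  # interleaved marker keeps its distances: unique optimum 0, 5, 10
  cons <- merge_linkage_group(
    list(toy_map(c("m1", "m2"), c(0, 10), "A"),
         toy_map(c("m1", "m3", "m2"), c(0, 5, 10), "B")), "L1", 2)
  expect_equal(cons$marker, c("m1", "m3", "m2"))
  expect_equal(cons$pos_cm, c(0, 5, 10))

  # disagreeing distances resolve to the interval midpoint
  cons <- merge_linkage_group(
    list(toy_map(c("m1", "m2"), c(0, 4), "A"),
         toy_map(c("m1", "m2"), c(0, 6), "B")), "L1", 1)
  expect_equal(cons$pos_cm, c(0, 5))
})

test_that("merging a single map reproduces it up to the zero offset", {
  set.seed(4)
  for (rep in 1:3) {
    pos <- sort(runif(12, 3, 80))
    m <- toy_map(sprintf("m%02d", 1:12), pos, "A")
    cons <- merge_linkage_group(list(m), "L1", 2)
    expect_equal(cons$marker, m$marker)
    expect_equal(cons$pos_cm, pos - pos[1], tolerance = 1e-8)
  }
})

test_that("consensus covers the union of markers and ignores map input order", {
  A <- toy_map(c("a", "b", "c", "d"), c(0, 3, 7, 11), "A")
  B <- toy_map(c("b", "x", "d", "y"), c(3, 5, 11, 15), "B")
  cons_ab <- merge_linkage_group(list(A, B), "L1", 2)
  cons_ba <- merge_linkage_group(list(B, A), "L1", 2)
  expect_setequal(cons_ab$marker, union(A$marker, B$marker))
  expect_equal(cons_ab$marker, cons_ba$marker)
  expect_equal(cons_ab$pos_cm, cons_ba$pos_cm, tolerance = 1e-8)
})

test_that("RMSE diagnostics follow the definition", {
  cons <- toy_map(c("a", "b"), c(0, 10), "cons")
  expect_equal(compute_rmse(toy_map(c("a", "b"), c(0, 10)), cons)$rmse, 0)
  expect_equal(compute_rmse(toy_map("a", 2), cons)$rmse, 2)
  expect_equal(compute_rmse(toy_map(c("a", "b"), c(3, 14)), cons)$rmse,
               sqrt(12.5))
  expect_true(is.na(compute_rmse(toy_map("zz", 4), cons)$rmse))
})

test_that("candidate selection minimises mean RMSE with smallest-interval ties", {
  cand <- function(p, rmse) {
    cm <- toy_map(c("a", "b"), c(0, 10), "cons")
    attr(cm, "interval_parameter") <- p
    attr(cm, "mean_rmse") <- rmse
    cm
  }
  best <- select_best_consensus(list(cand(1, 1.2), cand(2, 0.9), cand(3, 1.5)))
  expect_equal(attr(best, "interval_parameter"), 2)
  expect_equal(attr(select_best_consensus(list(cand(1, 1.2))),
                    "interval_parameter"), 1)
  tie <- select_best_consensus(list(cand(3, 0.8), cand(1, 0.8), cand(2, 0.8)))
  expect_equal(attr(tie, "interval_parameter"), 1)
})

test_that("build_consensus selects a candidate no other candidate beats", {
  set.seed(9)
  true_pos <- sort(runif(25, 0, 90))
  mk <- sprintf("m%02d", 1:25)
  maps <- lapply(1:3, function(i) {
    idx <- sort(sample(25, 18))
    toy_map(mk[idx], pmax(true_pos[idx] + rnorm(18, 0, 0.4), 0),
            paste0("map", i))
  })
  cons <- build_consensus(maps, intervals = 1:3)
  tab <- attr(cons, "candidates")
  expect_true(all(attr(cons, "mean_rmse") <= tab$mean_rmse + 1e-12))
  expect_equal(nrow(tab), 3)
  # positions monotone, all markers exactly once
  expect_true(all(diff(cons$pos_cm) >= -1e-9))
  expect_equal(anyDuplicated(cons$marker), 0)
})

test_that("map summaries compute densities, totals and the mean density", {
  one <- toy_map(sprintf("m%d", 1:10), c(0, seq_len(9) * 5 / 9))
  s <- map_summary(one)
  expect_equal(s$density, c(2, 2))
  expect_equal(s$n_markers, c(10, 10))
  expect_equal(s$length_cm, c(5, 5))

  df <- data.frame(lg = c("L1", "L2"), n_markers = c(20, 30),
                   length_cm = c(10, 6))
  s2 <- map_summary(df)
  expect_equal(s2$density, c(2, 5, 3.5))
  expect_equal(s2$n_markers[3], 50)
})

test_that("density profiles bin half-open and conserve marker counts", {
  m <- toy_map(c("a", "b", "c"), c(0.1, 0.9, 1.5))
  prof <- density_profile(m, 1)
  expect_equal(prof$n_markers, c(2, 1))
  expect_equal(prof$bin_start_cm, c(0, 1))

  u <- toy_map(sprintf("m%03d", 1:100), seq(0, 99.9, length.out = 100))
  prof_u <- density_profile(u, 10)
  expect_equal(prof_u$n_markers, rep(10, 10))
  expect_equal(sum(prof_u$n_markers), 100)
})
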