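# Per-frame observables: complex ratio, aggregation number, contacts,
# composition tables and the assembled time series.

test_that("complex ratio counts molecules in any aggregate", {
  topo <- make_topo(36, 36)
  all_in <- make_aggset(list(1:72))
  expect_equal(complex_ratio(all_in, 72), 1)
  expect_equal(complex_ratio(make_aggset(list(), noise = 1:72), 72), 0)
  aggs <- make_aggset(list(c(1, 2, 37, 38), c(3, 39)), noise = integer(0))
  expect_equal(complex_ratio(aggs, 72), 6 / 72)
  # a pure CM15 dimer counts by default but not under mixed_only
  pure <- make_aggset(list(c(1, 2)), noise = 3:72)
  expect_equal(complex_ratio(pure, 72), 2 / 72)
  expect_equal(complex_ratio(pure, 72, topo, mixed_only = TRUE), 0)
})

test_that("average aggregation number supports both conventions", {
  expect_equal(average_aggregation_number(make_aggset(list(1:72))), 72)
  expect_equal(average_aggregation_number(make_aggset(list(1:2, 3:6))), 3)
  expect_equal(average_aggregation_number(make_aggset(list(),
                                                      noise = 1:5)), 0)
  # 34 + 34 in two aggregates with 4 free: 34 by default, 36 over all
  two <- make_aggset(list(1:34, 35:68), noise = 69:72)
  expect_equal(average_aggregation_number(two), 34)
  expect_equal(average_aggregation_number(two, "all", total = 72), 36)
})

test_that("bilayer contacts count molecules within cutoff once", {
  topo <- make_topo(2, 1, n_lip = 4)
  # lipids on z = 2 and z = 6 planes; CM15 #1 hovers 0.3 nm above a lipid
  fr <- make_frame(c(1, 1, 6.3,   8, 8, 9.5,   5, 5, 9.0,
                     1, 1, 6,     2, 2, 6,     1, 1, 2,    2, 2, 2))
  expect_equal(bilayer_contacts(fr, topo, cutoff = 0.6),
               c(CM15 = 1L, SUR = 0L))
  # everything at least 2 nm away: zero contacts
  fr2 <- make_frame(c(5, 5, 9,   8, 8, 9.5,  5, 5, 8.5,
                      1, 1, 6,   2, 2, 6,    1, 1, 2,   2, 2, 2))
  expect_equal(bilayer_contacts(fr2, topo, cutoff = 0.6),
               c(CM15 = 0L, SUR = 0L))
  # no lipids is a hard error
  topo0 <- make_topo(2, 1)
  fr0 <- make_frame(c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  expect_error(bilayer_contacts(fr0, topo0), "lipid")
})

test_that("composition tables bin aggregates and free molecules", {
  topo <- make_topo(4, 4)  # CM15 1..4, SUR 5..8
  aggs <- make_aggset(list(c(1, 2, 3, 5, 6, 7), c(4, 8)), frame = 1,
                      time = 100, topo = topo)
  tab <- composition_table(aggs, topo)
  expect_equal(tab$n_CM15, c(1L, 3L))
  expect_equal(tab$n_SUR, c(1L, 3L))
  expect_equal(tab$count, c(1L, 1L))
  expect_equal(unique(tab$time_ns), 100)

  all_free <- make_aggset(list(), noise = 1:8)
  tf <- composition_table(all_free, topo)
  # free classes: (n_CM15, n_SUR) = (1, 0) and (0, 1)
  expect_setequal(tf$count, c(4L, 4L))
  expect_equal(sum(tf$count * (tf$n_CM15 + tf$n_SUR)), 8)
})

test_that("composition tables conserve molecules on random partitions", {
  set.seed(33)
  topo <- make_topo(10, 10)
  for (r in 1:20) {
    ids <- sample(20)
    sizes <- c()
    while (sum(sizes) < 16) sizes <- c(sizes, sample(2:5, 1))
    sizes <- sizes[cumsum(sizes) <= 20]
    groups <- list(); used <- 0
    for (s in sizes) { groups <- c(groups, list(ids[(used + 1):(used + s)])); used <- used + s }
    noise <- if (used < 20) ids[(used + 1):20] else integer(0)
    aggs <- make_aggset(groups, noise = noise)
    tab <- composition_table(aggs, topo)
    expect_equal(sum(tab$count * (tab$n_CM15 + tab$n_SUR)), 20)
    # partition conservation
    expect_equal(sum(lengths(aggs$aggregates)) + length(aggs$noise), 20)
    # boundary equivalences
    cr <- complex_ratio(aggs, 20)
    expect_true(cr >= 0 && cr <= 1)
    expect_equal(cr == 1, length(aggs$noise) == 0)
    expect_equal(cr == 0, length(aggs$aggregates) == 0)
    # aggregation number identity
    if (length(aggs$aggregates)) {
      expect_equal(average_aggregation_number(aggs),
                   sum(lengths(aggs$aggregates)) / length(aggs$aggregates),
                   tolerance = 1e-12)
    }
  }
})

test_that("metric time series matches hand-computed per-frame values", {
  topo <- make_topo(3, 3)  # CM15 1..3, SUR 4..6
  mk <- function(xs, idx, t) {
    make_frame(as.vector(t(cbind(xs, 5, 5))), box = c(30, 30, 30),
               index = idx, time = t)
  }
  frames <- list(
    mk(c(1, 2, 10, 11, 20, 25), 1, 0),    # {1,2},{3,4}; free 5,6
    mk(c(1, 2, 3, 11, 20, 25), 2, 10),    # {1,2,3,4}? no: x=1,2,3 adjacent
    mk(c(1, 2, 3, 4, 5, 6), 3, 20)        # all chained: one aggregate
  )
  bun <- bundle(frames, topo)
  m <- metric_time_series(bun, clustering_params())
  expect_equal(m$n_aggregates, c(2, 1, 1))
  expect_equal(m$complex_ratio, c(4 / 6, 3 / 6, 1))
  expect_equal(m$avg_aggregation_number, c(2, 3, 6))
  expect_equal(m$free_CM15, c(0L, 0L, 0L))
  expect_equal(m$free_SUR, c(2L, 3L, 0L))
  expect_true(all(is.na(m$contacts_CM15)))

  # stride subsampling
  bun10 <- bundle(lapply(1:10, function(i) mk(c(1, 2, 3, 4, 5, 6), i,
                                              (i - 1) * 10)), topo)
  expect_equal(nrow(metric_time_series(bun10, stride = 2)), 5)
  expect_warning(m1 <- metric_time_series(bun10, stride = 99), "stride")
  expect_equal(nrow(m1), 1)
})

test_that("metrics are invariant under whole-box translation and reruns are byte-identical", {
  bun <- generate_planted_trajectory(
    synthetic_spec(n_species = c(CM15 = 4, SUR = 4), box = c(18, 18, 18),
                   n_frames = 4, init_clusters = list(c(1, 2, 5, 6)),
                   seed = 2))
  m1 <- metric_time_series(bun, clustering_params())
  shifted <- bun
  for (i in seq_along(shifted$frames)) {
    shifted$frames[[i]]$coords <-
      sweep(shifted$frames[[i]]$coords, 2, c(-2, 1, 3) * c(18, 18, 18), "+")
  }
  m2 <- metric_time_series(shifted, clustering_params())
  num <- vapply(m1, is.numeric, logical(1))
  expect_lt(max(abs(as.matrix(m1[, num]) - as.matrix(m2[, num])),
                na.rm = TRUE), 1e-9)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_metrics(m1, f1)
  write_metrics(metric_time_series(bun, clustering_params()), f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
})
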