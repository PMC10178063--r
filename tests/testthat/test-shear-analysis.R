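scheme <- binning_scheme()

test_that("snap_to_bins widens outward with the edge-tie convention", {
  cases <- list(
    list(lo = 1.26, hi = 1.26, want = c(0.84, 1.26)),  # on-edge point
    list(lo = 0.90, hi = 1.10, want = c(0.84, 1.26)),
    list(lo = 0.00, hi = 0.00, want = c(0.00, 0.42)),
    list(lo = 0.42, hi = 1.26, want = c(0.42, 1.26)),  # endpoints stay
    list(lo = 5.5e-6, hi = 0.42, want = c(0.00, 0.42)),
    list(lo = 1.00, hi = 1.00, want = c(0.84, 1.26)),
    list(lo = 0.50, hi = 2.00, want = c(0.42, 2.10)))
  for (cs in cases) {
    got <- snap_to_bins(cs$lo, cs$hi, scheme)
    expect_equal(c(got$low, got$high), cs$want, tolerance = 1e-12)
    expect_true(got$snapped)
    # snapped interval always contains the raw range
    expect_lte(got$low, cs$lo + 1e-12)
    expect_gte(got$high, cs$hi - 1e-12)
  }
  expect_error(snap_to_bins(1.0, 0.5), "low must not exceed high")
})

test_that("snap_to_bins is monotone in the raw range", {
  set.seed(11)
  for (i in 1:200) {
    lo <- runif(1, 0, 4)
    hi <- lo + runif(1, 0, 2)
    a <- snap_to_bins(lo, hi, scheme)
    b <- snap_to_bins(max(lo - 0.2, 0), hi + 0.3, scheme)  # widened raw
    expect_lte(b$low, a$low)
    expect_gte(b$high, a$high)
  }
})

test_that("interval intersection reproduces the printed worked examples", {
  # two junction ranges of the starter model
  ov <- intersect_intervals(list(si(0.420, 1.260), si(0.840, 2.520)))
  expect_equal(c(ov$low, ov$high), c(0.840, 1.260))
  # intervals touching at a single point: no overlap
  ov <- intersect_intervals(list(si(0.420, 1.260), si(0.840, 2.10),
                                 si(1.260, 4.20)))
  expect_true(is_empty_interval(ov))
  # the high outlier variant
  ov <- intersect_intervals(list(si(0.420, 1.680), si(0.840, 4.20),
                                 si(0.840, 4.20), si(1.260, 4.20)))
  expect_equal(c(ov$low, ov$high), c(1.260, 1.680))
  expect_error(intersect_intervals(list()), "non-empty")
})

test_that("intersection is commutative, associative, idempotent, narrowing", {
  set.seed(7)
  rand_iv <- function() {
    lo <- 0.42 * sample(0:6, 1)
    si(lo, lo + 0.42 * sample(1:4, 1))
  }
  for (i in 1:50) {
    a <- rand_iv(); b <- rand_iv(); cc <- rand_iv()
    ab <- intersect_intervals(list(a, b))
    ba <- intersect_intervals(list(b, a))
    expect_identical(ab, ba)
    abc1 <- intersect_intervals(list(ab, cc))
    abc2 <- intersect_intervals(list(a, intersect_intervals(list(b, cc))))
    expect_identical(abc1, abc2)
    expect_identical(intersect_intervals(list(a, a)), a)
    # adding an interval never widens the result
    if (!is_empty_interval(abc1)) {
      expect_gte(abc1$low, ab$low)
      expect_lte(abc1$high, ab$high)
    }
  }
})

test_that("wall and junction intervals follow the binning and floor rules", {
  sol <- solve_network(build_fixture("1C")$network)
  w1 <- wall_interval(sol, "wall_1", scheme)
  expect_equal(c(w1$low, w1$high), c(0.84, 1.26))
  w2 <- wall_interval(sol, "wall_2", scheme)
  expect_equal(c(w2$low, w2$high), c(0, 0.42))
  expect_lt(attr(w2, "raw_high"), 1e-9)  # near-stagnant connector
  expect_error(wall_interval(sol, "wall_99", scheme), "unknown wall_label")

  # junction hull discards the stagnant branch (incident shear 1.26/1.26/0)
  j1 <- junction_interval(sol, "junction_1", scheme)
  expect_equal(c(j1$low, j1$high), c(0.84, 1.26))
  expect_error(junction_interval(sol, "junction_9", scheme),
               "unknown junction")

  # all incident branches stagnant: nothing is discarded
  quiet <- solve_network(single_pipe_network(inlet_speed = 0),
                         validate = FALSE)
  quiet$network$junction_labels <- c(junction_1 = "out")
  # make the outlet a labelled junction region artificially: both incident
  # shear values are 0, so the interval is the lowest bin
  qi <- junction_interval(quiet, "junction_1", scheme)
  expect_equal(c(qi$low, qi$high), c(0, 0.42))

  # thin-walled junction sits in the high bins
  sol2 <- solve_network(disjoint_junction_network())
  j2 <- junction_interval(sol2, "junction_2", scheme)
  expect_equal(c(j2$low, j2$high), c(3.36, 3.78))
  # mixed junction (thick and thin incident, neither stagnant): hull of bins
  sol2$network$junction_labels <- c(sol2$network$junction_labels,
                                    junction_3 = "x")
  jx <- junction_interval(sol2, "junction_3", scheme)
  expect_equal(c(jx$low, jx$high), c(1.26, 3.78))
})

test_that("printed junction intervals reproduce every overlap row", {
  want <- list("1C" = c(0.840, 1.260), "1D" = c(0.840, 1.260),
               "1E" = c(0.840, 1.260), "1F" = NULL,
               "1G" = c(1.260, 1.680), "2A" = c(0.840, 1.260),
               "2B" = c(0.840, 1.260), "2C" = NULL)
  for (m in names(want)) {
    ov <- junction_overlap_region(printed_region_samples(m), scheme)
    if (is.null(want[[m]])) {
      expect_true(is_empty_interval(ov$interval), label = m)
    } else {
      expect_equal(c(ov$interval$low, ov$interval$high), want[[m]],
                   tolerance = 1e-9, label = m)
    }
  }
  # idempotence: a single junction yields its own interval
  one <- printed_region_samples("1C")
  one <- one[one$region_label == "Junction 1", ]
  ov <- junction_overlap_region(one, scheme)
  expect_equal(c(ov$interval$low, ov$interval$high), c(0.42, 1.26))
})

test_that("physiological classification is a pure threshold check", {
  sol <- solve_network(single_pipe_network())
  fl <- classify_physiological(sol)
  expect_true(all(fl$wss_ok), TRUE)
  expect_true(all(fl$velocity_ok))
  expect_true(all(fl$diameter_ok))

  slow <- solve_network(single_pipe_network(inlet_speed = 0.007))
  fl <- classify_physiological(slow)   # tau = 0.098 Pa, v below range
  expect_false(any(fl$wss_ok))
  expect_false(any(fl$velocity_ok))

  fast <- solve_network(single_pipe_network(inlet_speed = 0.22))
  expect_false(any(classify_physiological(fast)$velocity_ok))
})

test_that("region sample tables ingest, snap, and fail informatively", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "samples.csv")
  writeLines(c("region_label,region_kind,wss_pa",
               "Junction 1,junction,0.9", "Junction 1,junction,1.1",
               "Junction 1,junction,1.2"), p)
  tab <- read_region_samples(p)
  iv <- region_interval(tab, "Junction 1", scheme)
  expect_equal(c(iv$low, iv$high), c(0.84, 1.26))
  expect_equal(attr(iv, "raw_low"), 0.9)
  expect_equal(attr(iv, "raw_high"), 1.2)

  # a single on-edge sample uses the bin-below tie rule
  one <- data.frame(region_label = "J", region_kind = "junction",
                    wss_pa = 1.26)
  iv <- region_interval(one, "J", scheme)
  expect_equal(c(iv$low, iv$high), c(0.84, 1.26))
  expect_error(region_interval(tab, "Junction 9", scheme), "no samples")

  writeLines(c("region_label,region_kind,wss_pa",
               "Junction 1,junction,not_a_number"), p)
  expect_error(read_region_samples(p), "row 2")
  writeLines("region_label,region_kind", p)
  expect_error(read_region_samples(p), "wss_pa")
  writeLines("region_label,region_kind,wss_pa", p)
  expect_error(read_region_samples(p), "no sample rows")
  expect_error(read_region_samples(file.path(tmp, "absent.csv")),
               "no such file")

  # round trip through write_region_samples
  tab2 <- printed_region_samples("2A")
  p2 <- file.path(tmp, "t2a.csv")
  write_region_samples(tab2, p2)
  back <- read_region_samples(p2)
  expect_equal(back$wss_pa, tab2$wss_pa)
})

test_that("synthetic interval recovery succeeds in >= 19/20 seeds", {
  truth <- data.frame(region_label = "R", region_kind = "junction",
                      low = 0.7, high = 1.3)
  want <- snap_to_bins(0.7, 1.3, scheme)
  hits <- 0L
  for (s in 1:20) {
    gen <- generate_region_samples(truth, n_samples = 1000, noise_sd = 0,
                                   seed = s)
    got <- region_interval(gen$samples, "R", scheme)
    if (isTRUE(all.equal(c(got$low, got$high), c(want$low, want$high))))
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("report tables mirror the published layout", {
  sol <- solve_network(build_fixture("1C")$network)
  tab <- report_model_table(sol)
  expect_setequal(tab$location[tab$region_kind == "junction"],
                  c("junction_1", "junction_2"))
  expect_true(all(tab$junction_overlap[tab$region_kind == "junction"] ==
                    "0.840-1.260"))
  expect_true(all(tab$junction_overlap[tab$region_kind == "wall"] == ""))
  # trunk velocity 0.09 m/s falls in the printed 0.055-0.11 bin
  expect_equal(tab$velocity_range[tab$location == "wall_1"], "0.055-0.11")

  # table-driven report with the literal "No overlap"
  rep2c <- report_model_table(printed_region_samples("2C"))
  expect_true(all(rep2c$junction_overlap == "No overlap"))
  rep2a <- report_model_table(printed_region_samples("2A"))
  expect_true(all(rep2a$junction_overlap == "0.840-1.260"))

  # no junction regions anywhere -> error propagated
  walls_only <- printed_region_samples("2A", kinds = "wall")
  expect_error(report_model_table(walls_only), "no junction regions")
})
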