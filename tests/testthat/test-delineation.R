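test_that("background estimate is the global median and resists enrichment", {
  expect_equal(estimate_background(make_track(rep(35, 1000)))$value, 35)

  # 5% of positions four orders of magnitude up do not move the median
  v <- rep(35, 20000)
  v[1:1000] <- 70000
  expect_equal(estimate_background(make_track(v))$value, median(v))
  expect_equal(estimate_background(make_track(v))$value, 35)

  expect_error(estimate_background(make_track(rep(0, 100))),
               "no background signal")

  # masked intervals are excluded
  bg <- estimate_background(make_track(v), mask = data.frame(start = 0, end = 1000))
  expect_equal(bg$value, 35)
  expect_equal(bg$n_positions_used, 19000)
})

test_that("running-median smoothing removes spikes and keeps identities", {
  v <- rep(35, 2000)
  tr <- make_track(v)
  expect_equal(smooth_track(tr, 1)$values, v)
  expect_error(smooth_track(tr, 200), "odd")

  v[1000] <- 1e6
  sm <- smooth_track(make_track(v), 201)
  expect_true(all(sm$values == 35))

  # a step edge moves by less than half a window
  v2 <- c(rep(10, 3000), rep(5000, 3000))
  sm2 <- smooth_track(make_track(v2), 201)
  crossing <- which(sm2$values > 2500)[1]
  expect_lt(abs(crossing - 3001), 101)
  # and agrees with direct runmed
  expect_equal(sm2$values, as.numeric(runmed(v2, 201, endrule = "median")))
})

test_that("segmentation finds cores and flanks as separate abutting segments", {
  p <- segmentation_params()
  # constant track: nothing
  expect_equal(nrow(segment_coverage(make_track(rep(35, 5000)), 35, p)), 0)

  # planted core (fold 2000) with flat flank (fold 28.6) from the analytic profile
  tr <- step_track(60000, bg = 35, cores = list(c(20000, 28000, 70000)),
                   flanks = list(c(28000, 31000, 1000)))
  segs <- segment_coverage(tr, 35, p)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$level, c("enriched", "elevated"))
  expect_equal(segs$start, c(20000, 28000))
  expect_equal(segs$end, c(28000, 31000))
})

test_that("merge_gap bridges internal dips and is honoured exactly", {
  # enriched segment with a 1.2-kb dip to fold 3
  tr <- step_track(60000, bg = 35, cores = list(c(10000, 54597, 70000)))
  tr$values[30001:31200] <- 105  # fold 3
  p2000 <- segmentation_params(merge_gap = 2000)
  p500 <- segmentation_params(merge_gap = 500)
  s2000 <- segment_coverage(tr, 35, p2000)
  s500 <- segment_coverage(tr, 35, p500)
  expect_equal(nrow(s2000[s2000$level == "enriched", ]), 1)
  expect_equal(nrow(s500[s500$level == "enriched", ]), 2)
  # the bridged dip is recorded
  expect_equal(s2000$dips[[1]][[1]], c(30000, 31200))
})

test_that("segments match a brute-force run-length oracle before refinement", {
  p <- segmentation_params(merge_gap = 0, min_peak_len = 1, min_core_len = 100)
  set.seed(30)
  for (trial in 1:5) {
    v <- sample(c(5, 80, 5000), 3000, replace = TRUE,
                prob = c(0.9, 0.06, 0.04))
    segs <- segment_coverage(make_track(v), 5, p)
    # independent scan
    lvl <- ifelse(v / 5 >= p$core_fold, 2L, ifelse(v / 5 >= p$flank_fold, 1L, 0L))
    bnd <- c(0, which(diff(lvl) != 0), length(lvl))
    oracle <- data.frame(start = head(bnd, -1), end = bnd[-1],
                         level = lvl[bnd[-1]])
    oracle <- oracle[oracle$level > 0, ]
    expect_equal(segs$start, oracle$start)
    expect_equal(segs$end, oracle$end)
    expect_equal(segs$level,
                 ifelse(oracle$level == 2, "enriched", "elevated"))
  }
})

test_that("boundary refinement is exact on an ideal step profile", {
  tr <- step_track(60000, bg = 35, cores = list(c(20000, 28000, 70000)))
  p <- segmentation_params()
  sm <- smooth_track(tr, p$smooth_window)
  segs <- segment_coverage(sm, 35, p)
  r <- refine_boundaries(sm, segs[1, ], 35, p)
  expect_equal(r$start, 20000)
  expect_equal(r$end, 28000)
  expect_false(r$flagged)

  # degenerate segment (plateau below background) is flagged, unchanged
  flat <- make_track(rep(35, 10000))
  r2 <- refine_boundaries(flat, list(start = 2000, end = 3000), 35, p)
  expect_true(r2$flagged)
  expect_equal(c(r2$start, r2$end), c(2000, 3000))
})

test_that("classification separates cores, attached flanks, and IS artifacts", {
  p <- segmentation_params()
  tr <- step_track(60000, bg = 35, cores = list(c(20000, 28000, 70000)),
                   flanks = list(c(28000, 31000, 1000)))
  segs <- segment_coverage(tr, 35, p)
  regions <- classify_segments(segs, 35, params = p, track = tr)
  expect_equal(regions$klass, c("core", "flank"))
  expect_equal(regions$attached_core[2], regions$region_id[1])
  # reported coordinates are 1-based inclusive
  expect_equal(regions$start, c(20001, 28001))
  expect_equal(regions$end, c(28000, 31000))

  # a short elevated peak away from the core: artifact, explained by IS
  tr2 <- step_track(60000, bg = 35, cores = list(c(20000, 28000, 70000)),
                    flanks = list(c(5000, 6000, 3500)))
  segs2 <- segment_coverage(tr2, 35, p)
  is_ann <- data.frame(replicon_id = "chr", start = 5000, end = 6000,
                       family = "IS66", id = "IS_1")
  reg2 <- classify_segments(segs2, 35, is_annotations = is_ann, params = p,
                            track = tr2)
  art <- reg2[reg2$klass == "artifact", ]
  expect_equal(nrow(art), 1)
  expect_equal(art$overlapping_is[[1]], "IS_1")
  # without annotations it is still reported, flagged unexplained
  reg3 <- classify_segments(segs2, 35, params = p, track = tr2)
  art3 <- reg3[reg3$klass == "artifact", ]
  expect_equal(length(art3$overlapping_is[[1]]), 0)
  expect_equal(art3$note, "unexplained")
})

test_that("call_prophages recovers planted cores on sampled coverage", {
  g2 <- simulate_genome(
    300000,
    prophage_specs = list(
      prophage_spec(60000, 105000, core_rate = 70000),
      prophage_spec(180000, 228000, core_rate = 70000, flank_side = "right",
                    flank_rate = 1000, flank_extent = 10000)),
    seed = 31)
  prof <- expected_coverage_profile(g2, background_rate = 35)
  rep2 <- call_prophages(simulate_poisson_coverage(prof, seed = 32))
  expect_equal(sum(rep2$regions$klass == "core"), 2)

  # host control: uniform coverage, no calls at all
  host <- simulate_poisson_coverage(make_track(rep(35, 300000)), seed = 33)
  rep0 <- call_prophages(host)
  expect_equal(nrow(rep0$regions), 0)
})

test_that("flanks below core_fold are never absorbed into the core call", {
  g <- fixture_genome_small(core_rate = 5000, flank_rate = 100)
  prof <- expected_coverage_profile(g, background_rate = 5)
  for (seed in 1:5) {
    rep <- call_prophages(simulate_poisson_coverage(prof, seed = seed))
    core <- rep$regions[rep$regions$klass == "core", ]
    expect_equal(nrow(core), 1)
    # flank occupies (28000, 31000]; the core call must not reach into it
    expect_lt(core$end, 28000 + 300)
    flank <- rep$regions[rep$regions$klass == "flank", ]
    expect_equal(nrow(flank), 1)
  }
})

test_that("raising core_fold or merge_gap never increases the call counts", {
  g <- fixture_genome_small(core_rate = 5000, flank_rate = 100)
  prof <- expected_coverage_profile(g, background_rate = 5)
  tr <- simulate_poisson_coverage(prof, seed = 34)
  n_cores <- vapply(c(100, 300, 500, 900), function(cf) {
    rep <- call_prophages(tr, params = segmentation_params(core_fold = cf))
    sum(rep$regions$klass == "core")
  }, numeric(1))
  expect_true(all(diff(n_cores) <= 0))

  bg <- estimate_background(tr)
  sm <- smooth_track(tr, 201)
  n_segs <- vapply(c(0, 200, 1000, 3000), function(mg) {
    nrow(segment_coverage(sm, bg, segmentation_params(merge_gap = mg)))
  }, numeric(1))
  expect_true(all(diff(n_segs) <= 0))
})

test_that("calls are invariant under positive rescaling of the track", {
  g <- fixture_genome_small(core_rate = 5000, flank_rate = 100)
  prof <- expected_coverage_profile(g, background_rate = 5)
  tr <- simulate_poisson_coverage(prof, seed = 35)
  r1 <- call_prophages(tr)
  tr_scaled <- make_track(tr$values * 7.3)
  r2 <- call_prophages(tr_scaled)
  expect_equal(r1$regions$start, r2$regions$start)
  expect_equal(r1$regions$end, r2$regions$end)
  expect_equal(r1$regions$klass, r2$regions$klass)
  expect_equal(r2$background$value, r1$background$value * 7.3)
})

test_that("region BED and JSON reports serialise the call", {
  g <- fixture_genome_small()
  prof <- expected_coverage_profile(g, background_rate = 5)
  rep <- call_prophages(simulate_poisson_coverage(prof, seed = 36))
  bed <- tempfile(fileext = ".bed")
  js <- tempfile(fileext = ".json")
  write_regions_bed(rep, bed)
  write_report_json(rep, js)
  b <- read.table(bed, sep = "\t")
  expect_equal(nrow(b), nrow(rep$regions))
  expect_true(all(b$V5 <= 1000))  # BED score cap
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$coordinate_convention, "1-based inclusive")
  expect_equal(length(parsed$regions), nrow(rep$regions))
})
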