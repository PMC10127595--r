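test_that("simulate_genome plants features at requested coordinates", {
  g <- simulate_genome(
    200000, prophage_specs = list(prophage_spec(100000, 144597, core_rate = 5000)),
    seed = 1)
  expect_equal(nrow(g$prophages), 1)
  expect_equal(g$prophages$end - g$prophages$start, 44597)
  expect_equal(nchar(g$replicons[[1]]$seq), 200000)

  g0 <- simulate_genome(50000, seed = 2)
  expect_equal(nrow(g0$prophages), 0)
  expect_equal(nrow(g0$is_copies), 0)
})

test_that("simulated GC content concentrates at the requested fraction", {
  g <- simulate_genome(1e6, gc = 0.635, seed = 3)
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAString(g$replicons[[1]]$seq), c("G", "C"))
  expect_lt(abs(sum(counts) / 1e6 - 0.635), 0.005)
})

test_that("overlapping or out-of-range prophage specs are rejected with coordinates", {
  specs <- list(prophage_spec(1000, 6000, core_rate = 100),
                prophage_spec(5000, 9000, core_rate = 100))
  expect_error(simulate_genome(20000, prophage_specs = specs), "overlap")
  expect_error(simulate_genome(20000, prophage_specs = specs), "5000")
  expect_error(
    simulate_genome(20000, prophage_specs = list(prophage_spec(15000, 25000))),
    "exceeds")
})

test_that("IS copies of one family share an identical sequence", {
  g <- simulate_genome(
    30000, is_specs = list(is_spec("IS66", 800, c(2000, 9000, 17000))),
    seed = 4)
  s <- g$replicons[[1]]$seq
  copies <- substring(s, g$is_copies$start + 1, g$is_copies$end)
  expect_equal(length(unique(copies)), 1)
  expect_equal(nrow(g$is_copies), 3)
})

test_that("expected profile is exact: background, flat and geometric flanks", {
  g <- fixture_genome_small(core_rate = 5000, flank_rate = 100)
  prof <- expected_coverage_profile(g, background_rate = 5)
  expect_equal(prof$values[1000], 5)
  expect_equal(prof$values[25000], 5000)
  flank <- prof$values[28001:31000]
  expect_equal(unname(flank), rep(100, 3000))

  g2 <- simulate_genome(
    60000, prophage_specs = list(prophage_spec(
      20000, 28000, core_rate = 5000, flank_side = "right",
      flank_rate = 1000, flank_extent = 3000, flank_decay = "geometric",
      decay_per_kb = 0.5)),
    seed = 5)
  prof2 <- expected_coverage_profile(g2, background_rate = 5)
  # value 1 kb from the prophage edge is half the edge value
  expect_equal(prof2$values[28001 + 1000], 500)

  g3 <- simulate_genome(20000, seed = 6)
  prof3 <- expected_coverage_profile(g3, background_rate = 35)
  expect_true(all(prof3$values == 35))
})

test_that("phage read counts follow the Poisson expectation", {
  # core-only genome: expected reads = core_rate * core_len / L
  g <- simulate_genome(
    20000, prophage_specs = list(prophage_spec(5000, 15000, core_rate = 1000)),
    seed = 7)
  p <- read_sim_params(read_length = 100, error_rate = 0,
                       background_rate = 0, seed = 8)
  reads <- simulate_phage_reads(g, p)
  expected <- 1000 * 10000 / 100
  expect_lt(abs(nrow(reads) - expected), 3 * sqrt(expected))
  expect_true(all(reads$label == "core"))

  # every read carries a truth label (conservation)
  expect_equal(sum(table(reads$label)), nrow(reads))
})

test_that("core/background coverage ratio is recovered within 10%", {
  g <- simulate_genome(
    40000, prophage_specs = list(prophage_spec(15000, 25000, core_rate = 2000)),
    seed = 9)
  p <- read_sim_params(read_length = 100, error_rate = 0,
                       background_rate = 1, seed = 10, max_reads = 3e6)
  reads <- simulate_phage_reads(g, p)
  core <- sum(reads$label == "core") * 100 / 10000
  bg <- sum(reads$label == "background") * 100 / 30000
  expect_lt(abs(core / bg - 2000) / 2000, 0.10)
})

test_that("contaminant reads appear at the requested proportion and zero means none", {
  g <- simulate_genome(20000, seed = 11)
  p0 <- read_sim_params(background_rate = 30, contaminant_fraction = 0, seed = 12)
  r0 <- simulate_phage_reads(g, p0)
  expect_false(any(r0$label == "contaminant"))

  p1 <- read_sim_params(background_rate = 30, contaminant_fraction = 0.1, seed = 13)
  r1 <- simulate_phage_reads(g, p1)
  frac <- mean(r1$label == "contaminant")
  expect_lt(abs(frac - 0.1), 0.02)
})

test_that("host-control reads give even coverage at the requested depth", {
  g <- simulate_genome(100000, seed = 14)
  expect_error(simulate_host_reads(g, depth = 0), "> 0")
  reads <- simulate_host_reads(g, depth = 200, read_length = 100,
                               error_rate = 0, seed = 15)
  expect_lt(abs(nrow(reads) - 200000) / 200000, 0.05)
  # windowed (1 kb) coverage CV well under 0.2
  cov <- numeric(100000)
  cnt <- tabulate(reads$src_start + 1L, nbins = 100000)
  cs <- cumsum(cnt)
  cov <- cs - c(rep(0, 100), head(cs, -100))
  wm <- colMeans(matrix(cov[101:99100], nrow = 1000))
  expect_lt(sd(wm) / mean(wm), 0.2)
})

test_that("simulation output is byte-identical for a fixed seed", {
  g1 <- simulate_genome(15000, is_specs = list(is_spec("IS3", 500, 2000)),
                        seed = 16)
  g2 <- simulate_genome(15000, is_specs = list(is_spec("IS3", 500, 2000)),
                        seed = 16)
  expect_identical(g1$replicons[[1]]$seq, g2$replicons[[1]]$seq)

  p <- read_sim_params(background_rate = 20, error_rate = 0.01,
                       contaminant_fraction = 0.05, seed = 17)
  fa1 <- tempfile(fileext = ".fasta"); fa2 <- tempfile(fileext = ".fasta")
  fq1 <- tempfile(fileext = ".fastq"); fq2 <- tempfile(fileext = ".fastq")
  write_genome_fasta(g1, fa1); write_genome_fasta(g2, fa2)
  write_reads_fastq(simulate_phage_reads(g1, p), fq1)
  write_reads_fastq(simulate_phage_reads(g2, p), fq2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(fq1), readLines(fq2))
})

test_that("read-count cap refuses oversized simulations with the computed count", {
  g <- simulate_genome(
    50000, prophage_specs = list(prophage_spec(10000, 40000, core_rate = 70000)),
    seed = 18)
  p <- read_sim_params(background_rate = 35, max_reads = 1e5)
  expect_error(simulate_phage_reads(g, p), "exceeds max_reads")
})

test_that("Poisson-sampled coverage matches the expected profile in 1-kb windows", {
  g <- fixture_genome_small(core_rate = 5000, flank_rate = 100)
  prof <- expected_coverage_profile(g, background_rate = 5)
  tr <- simulate_poisson_coverage(prof, read_length = 100, seed = 19)
  expect_equal(length(tr), 60000)
  # windows fully inside constant regions: mean within 3 SE of expectation
  check_window <- function(from, to, expected) {
    v <- tr$values[(from + 1):to]
    wm <- colMeans(matrix(v, nrow = 1000))
    se <- sqrt(expected * 100 / 1000)
    expect_true(all(abs(wm - expected) < 3 * se + 3 * sqrt(expected / 10)))
  }
  check_window(1000, 19000, 5)      # background
  check_window(21000, 27000, 5000)  # core interior
  check_window(29000, 30000, 100)   # flank interior
})

test_that("featureless coverage has no spurious structure over 20 seeds", {
  prof <- make_track(rep(30, 50000))
  for (seed in 1:20) {
    tr <- simulate_poisson_coverage(prof, seed = seed)
    wm <- colMeans(matrix(tr$values, nrow = 1000))
    expect_lt(max(wm) / median(wm), 3)
  }
})

test_that("growth counts follow the doubling-time and induction kinetics", {
  # two doublings in 14.2 h at g = 7.1 h, noise off
  p <- growth_params(initial_cells = 1e6, doubling_time = 7.1,
                     induction_yield = 0, phage_decay = 0,
                     initial_plps = 1e5,
                     timepoints = c(0, 7.1, 14.2), noise = "none",
                     n_replicates = 1)
  s <- simulate_growth_counts(p)
  expect_equal(s$cells_per_ml[3], 4e6, tolerance = 1e-9)
  # zero yield, zero decay: PLPs constant
  expect_equal(s$plp_per_ml, rep(1e5, 3))
})

test_that("PLP kinetics agree with independent numerical integration", {
  p <- growth_params(initial_cells = 5e6, doubling_time = 7.1,
                     induction_yield = 0.35, phage_decay = 0.05,
                     initial_plps = 5e5, timepoints = c(0, 6, 12, 24, 36, 48),
                     noise = "none", n_replicates = 1)
  s <- simulate_growth_counts(p)
  r <- log(2) / 7.1
  ode <- deSolve::ode(
    y = c(P = 5e5), times = p$timepoints,
    func = function(t, y, parms) list(0.35 * 5e6 * exp(r * t) - 0.05 * y["P"]))
  expect_equal(s$plp_per_ml, unname(ode[, "P"]), tolerance = 1e-6)
  # PLP:cell ratio non-decreasing while growth dominates decay
  ratio <- s$plp_per_ml / s$cells_per_ml
  expect_true(all(diff(ratio) > -1e-9))
})

test_that("carrying-capacity cap holds cells at the cap and slows PLP growth", {
  p <- growth_params(initial_cells = 1e6, doubling_time = 5,
                     induction_yield = 0.2, phage_decay = 0.02,
                     carrying_capacity = 1e7,
                     timepoints = c(0, 12, 24, 48), noise = "none",
                     n_replicates = 1)
  s <- simulate_growth_counts(p)
  expect_true(all(s$cells_per_ml <= 1e7 + 1e-6))
  expect_equal(s$cells_per_ml[4], 1e7)
})
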