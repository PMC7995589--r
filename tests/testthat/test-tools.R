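sim_cfg_small <- function() sim_config(n_variants = 300, seed = 11,
                                       class_counts = c(truncal = 20,
                                                        bottleneck = 20,
                                                        loh = 20,
                                                        unique = 20,
                                                        germline_flat = 20))

# zero-jitter variant for threshold-grid tests: realized AFs stay clear of
# the grid values, so the subset relations are not blurred by read noise
sim_cfg_clean <- function() sim_config(n_variants = 300, seed = 13,
                                       af_noise_sd = 0,
                                       class_counts = c(truncal = 20,
                                                        bottleneck = 20,
                                                        loh = 20,
                                                        unique = 20,
                                                        germline_flat = 20))

test_that("af_slope matches hand computation and an independent OLS fit", {
  expect_equal(af_slope(c(1, 2, 3), c(0, 0.1, 0.3)), 0.15)
  expect_equal(af_slope(c(1, 2, 3), c(0.2, 0.2, 0.2)), 0)
  expect_error(af_slope(c(2, 2), c(0, 1)), "not all be equal")
  set.seed(42)
  for (i in 1:200) {
    t <- sort(runif(5, 0, 10))
    a <- runif(5)
    expect_equal(af_slope(t, a), unname(coef(lm(a ~ t))[2]),
                 tolerance = 1e-9)
  }
})

test_that("bottleneck returns risers above the slope threshold", {
  db <- fixture_db()
  r <- suppressMessages(bottleneck(db))
  ids <- r$variant_id
  expect_true(fixture_id("riser") %in% ids)         # slope 0.175
  expect_false(fixture_id("flat") %in% ids)         # slope 0
  expect_false(fixture_id("loh") %in% ids)
  # truncal-boundary row: slope exactly 0.05 is not "exceeding"
  expect_false(fixture_id("truncal_boundary") %in% ids)
  expect_equal(r$slope[r$variant_id == fixture_id("riser")], 0.175)
})

test_that("germline risers are gated by maxNorm and recoverable", {
  db <- fixture_db()
  # normal AF 0.5 excluded at default maxNorm 0
  r0 <- suppressMessages(bottleneck(db))
  expect_false(fixture_id("germline_riser") %in% r0$variant_id)
  # recovered when maxNorm is raised above the germline AF
  r1 <- suppressMessages(bottleneck(db, tool_params(maxNorm = 0.55)))
  expect_true(fixture_id("germline_riser") %in% r1$variant_id)
  # or when the normal is omitted from the considered samples
  r2 <- suppressMessages(
    bottleneck(db, tool_params(samples = c("T1", "T2", "T3"))))
  expect_true(fixture_id("germline_riser") %in% r2$variant_id)
})

test_that("loh requires het normals and homozygous tumors", {
  db <- fixture_db()
  r <- suppressMessages(loh(db))
  expect_true(fixture_id("loh") %in% r$variant_id)
  expect_false(fixture_id("loh_fail") %in% r$variant_id)  # one tumor het
  expect_false(fixture_id("subthresh") %in% r$variant_id) # normal not het
  expect_error(suppressMessages(
    loh(db, tool_params(samples = c("T1", "T2")))), "normal")
})

test_that("truncal demands presence in all tumors and absence in normals", {
  db <- fixture_db()
  r <- suppressMessages(truncal(db))
  ids <- r$variant_id
  expect_true(fixture_id("truncal") %in% ids)
  expect_true(fixture_id("riser") %in% ids)  # all tumors > 0, normal 0
  expect_false(fixture_id("unique23") %in% ids)       # absent from T1
  expect_false(fixture_id("truncal_boundary") %in% ids)  # normal 0.04 > 0
  r5 <- suppressMessages(truncal(db, tool_params(maxNorm = 0.05)))
  expect_true(fixture_id("truncal_boundary") %in% r5$variant_id)
  # tumors must now strictly exceed 0.05, which drops the low-AF riser
  expect_false(fixture_id("riser") %in% r5$variant_id)
  expect_error(suppressMessages(
    truncal(db, tool_params(samples = c("T1", "T2")))), "normal")
})

test_that("unique returns variants private to the specified samples", {
  db <- fixture_db()
  p <- tool_params(specific = c("T2", "T3"))
  r <- suppressMessages(unique_tool(db, p))
  expect_true(fixture_id("unique23") %in% r$variant_id)
  expect_false(fixture_id("unique_fail") %in% r$variant_id)  # absent in T2
  expect_false(fixture_id("unique_near") %in% r$variant_id)  # T1 leaks 0.04
  r2 <- suppressMessages(
    unique_tool(db, tool_params(specific = c("T2", "T3"),
                                maxOthers = 0.05)))
  expect_true(fixture_id("unique_near") %in% r2$variant_id)
  expect_error(unique_tool(db, tool_params()), "non-empty")
  expect_error(unique_tool(db, tool_params(specific = "GHOST")),
               "unknown sample")
})

test_that("set_somatic flags by depth and normal/tumor AF thresholds", {
  dir <- tempfile(); dir.create(dir)
  db <- file.path(dir, "f.db")
  file.copy(fixture_db(), db)
  n <- suppressMessages(set_somatic(db, minDP = 10, normAF = 0.05,
                                    tumorAF = 0.2))
  v <- fetch_variants(db, columns = "is_somatic")
  flagged <- v$variant_id[v$is_somatic == 1]
  expect_equal(n, length(flagged))
  expect_true(fixture_id("riser") %in% flagged)       # tumor 0.4 >= 0.2
  expect_false(fixture_id("norm_leak") %in% flagged)  # normal 0.06 > 0.05
  expect_false(fixture_id("subthresh") %in% flagged)  # no tumor >= 0.2
  expect_false(fixture_id("loh") %in% flagged)        # germline het
  expect_equal(sort(flagged),
               brute_set_somatic(db, 10, 0.05, 0.2))
  # rerunning overwrites
  expect_message(set_somatic(db, minDP = 10, normAF = 0, tumorAF = 0.5),
                 "overwriting")
})

test_that("set_somatic equals the brute-force rule on a simulated cohort", {
  d <- sim_db("tools", sim_cfg_small())
  dir <- tempfile(); dir.create(dir)
  db <- file.path(dir, "s.db")
  file.copy(d$db, db)
  suppressMessages(set_somatic(db, minDP = 10, normAF = 0.05,
                               tumorAF = 0.2))
  v <- fetch_variants(db, columns = "is_somatic")
  expect_equal(sort(v$variant_id[v$is_somatic == 1]),
               brute_set_somatic(db, 10, 0.05, 0.2))
})

test_that("somatic_only gates tool output and demands prior flagging", {
  dir <- tempfile(); dir.create(dir)
  db <- file.path(dir, "f.db")
  file.copy(fixture_db(), db)
  expect_error(suppressMessages(
    truncal(db, tool_params(somatic_only = TRUE))), "set_somatic")
  suppressMessages(set_somatic(db, minDP = 10, normAF = 0.05,
                               tumorAF = 0.2))
  r <- suppressMessages(truncal(db, tool_params(somatic_only = TRUE)))
  v <- fetch_variants(db, columns = "is_somatic")
  expect_true(all(r$variant_id %in% v$variant_id[v$is_somatic == 1]))
  # plain gate semantics
  expect_equal(somatic_gate(c(1, 0), somatic_only = FALSE), c(TRUE, TRUE))
  expect_equal(somatic_gate(c(1, 0), somatic_only = TRUE), c(TRUE, FALSE))
})

test_that("missing AFs disqualify a variant from every tool", {
  db <- fixture_db()
  for (r in list(suppressMessages(bottleneck(db)),
                 suppressMessages(loh(db)),
                 suppressMessages(truncal(db)),
                 suppressMessages(
                   unique_tool(db, tool_params(specific = c("T1"))))))
    expect_false(fixture_id("missing_af") %in% r$variant_id)
  # but not when the affected sample is excluded from consideration
  r <- suppressMessages(
    bottleneck(db, tool_params(samples = c("T1", "T2", "T3"))))
  expect_true(fixture_id("missing_af") %in% r$variant_id)
})

test_that("every tool matches its brute-force predicate oracle", {
  d <- sim_db("tools", sim_cfg_small())
  params <- list(
    bottleneck = tool_params(),
    loh = tool_params(),
    truncal = tool_params(),
    unique = tool_params(specific = d$sim$unique_target))
  runners <- list(bottleneck = bottleneck, loh = loh, truncal = truncal,
                  unique = unique_tool)
  for (tool in names(params)) {
    got <- suppressMessages(suppressWarnings(
      runners[[tool]](d$db, params[[tool]])))
    expect_equal(sort(unique(got$variant_id)),
                 brute_tool(d$db, tool, params[[tool]]),
                 info = tool)
  }
  # and under non-default thresholds with a depth gate
  p2 <- list(
    bottleneck = tool_params(minSlope = 0.12, minDP = 90),
    loh = tool_params(hetLo = 0.4, hetHi = 0.6, lohTumorDelta = 0.02),
    truncal = tool_params(maxNorm = 0.03, minDP = 90),
    unique = tool_params(specific = d$sim$unique_target, minAF = 0.25,
                         maxOthers = 0.02))
  for (tool in names(p2)) {
    got <- suppressMessages(suppressWarnings(
      runners[[tool]](d$db, p2[[tool]])))
    expect_equal(sort(unique(got$variant_id)),
                 brute_tool(d$db, tool, p2[[tool]]), info = tool)
  }
})

test_that("tightening thresholds never enlarges a tool's result set", {
  d <- sim_db("clean", sim_cfg_clean())
  ids <- function(r) sort(unique(r$variant_id))
  # bottleneck: rising minSlope
  prev <- NULL
  for (s in c(0.01, 0.05, 0.1, 0.2, 0.3)) {
    cur <- ids(suppressMessages(bottleneck(d$db,
                                           tool_params(minSlope = s))))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # truncal: falling maxNorm (grid below the planted tumor AF floor of 0.2,
  # since maxNorm doubles as the tumor presence floor)
  prev <- NULL
  for (m in c(0.15, 0.1, 0.05, 0.01, 0)) {
    cur <- ids(suppressMessages(truncal(d$db, tool_params(maxNorm = m))))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # unique: rising minAF and falling maxOthers
  prev <- NULL
  for (a in c(0, 0.1, 0.2, 0.3, 0.4)) {
    cur <- ids(suppressMessages(unique_tool(
      d$db, tool_params(specific = d$sim$unique_target, minAF = a))))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (m in c(0.2, 0.1, 0.05, 0.01, 0)) {
    cur <- ids(suppressMessages(unique_tool(
      d$db, tool_params(specific = d$sim$unique_target, maxOthers = m))))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("tool output is ordered by numeric-aware contig, then position", {
  db <- fixture_db()
  r <- suppressMessages(bottleneck(db))
  expect_true(fixture_id("riser_chr10") %in% r$variant_id)
  # chr2 rows must precede chr10 rows despite lexicographic order
  rank <- tumorgem:::chrom_rank(r$chrom)
  expect_equal(r$chrom, r$chrom[order(rank, r$start)])
  i2 <- which(r$chrom == "chr2")
  i10 <- which(r$chrom == "chr10")
  expect_true(length(i2) > 0 && length(i10) > 0 && max(i2) < min(i10))
})

test_that("default parameters match the documented tool defaults", {
  p <- tool_params()
  expect_equal(p$minSlope, 0.05)
  expect_equal(p$maxNorm, 0)
  expect_equal(p$minAF, 0)
  expect_equal(p$maxOthers, 0)
  expect_equal(p$minDP, 0L)
  expect_error(tool_params(hetLo = 0.8, hetHi = 0.2))
  expect_error(tool_params(maxNorm = 1.5))
})

test_that("bottleneck needs tumors and at least two time points", {
  dir <- tempfile(); dir.create(dir)
  vcf <- write_fixture_vcf(file.path(dir, "f.vcf"))
  mf <- file.path(dir, "one.manifest")
  writeLines(c("name\tpatient_id\ttime",
               "N1\tp1\t0", "T1\tp1\t1", "T2\tp1\t1", "T3\tp1\t1"), mf)
  db <- file.path(dir, "one.db")
  suppressWarnings(suppressMessages(load_db(vcf, mf, db)))
  # all tumors share one time value: no usable trajectory
  expect_warning(r <- suppressMessages(bottleneck(db)), "time points")
  expect_equal(nrow(r), 0)
  mf2 <- file.path(dir, "nt.manifest")
  writeLines(c("name\tpatient_id\ttime", "N1\tp1\t0"), mf2)
  db2 <- file.path(dir, "nt.db")
  suppressWarnings(suppressMessages(load_db(vcf, mf2, db2)))
  expect_error(suppressMessages(bottleneck(db2)), "tumor")
})

test_that("multi-patient databases are evaluated per patient and tagged", {
  cfg <- sim_config(n_patients = 2, n_variants = 120, seed = 5,
                    af_noise_sd = 0,
                    class_counts = c(truncal = 10, bottleneck = 10,
                                     loh = 10, unique = 10,
                                     germline_flat = 10))
  d <- sim_db("multi", cfg)
  r <- suppressMessages(truncal(d$db))
  expect_setequal(unique(r$patient_id), c("p1", "p2"))
  tt <- d$sim$truth_table
  planted <- truth_key(tt[tt$class == "truncal", ])
  for (p in c("p1", "p2")) {
    got <- r[r$patient_id == p, ]
    expect_setequal(truth_key(got), planted)
  }
})
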