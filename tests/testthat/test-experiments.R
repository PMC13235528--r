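# Experiment drivers: sweep structure, determinism, OAT search logic and
# artifact export.

test_that("delay sweeps produce one deterministic cell per delay", {
  sw <- run_delay_sweep(delays = c(50, 150))
  expect_s3_class(sw, "sweep_grid")
  expect_length(sw$counts, 2)
  df <- as.data.frame(sw)
  expect_equal(df$delay, c(50, 150))
  expect_true(all(df$spikes >= 0))
  # re-running a cell reproduces its count exactly
  again <- run_delay_sweep(delays = 50)
  expect_identical(again$counts[1], sw$counts[1])
})

test_that("heatmaps sweep parameter paths and respond monotonically to
          the T conductance", {
  g <- run_heatmap(list(name = "CSN.gCaT", values = c(0.4, 0.8)),
                   list(name = "CSN.gH", values = 6), delay = 50)
  expect_equal(dim(g$counts), c(2, 1))
  expect_gte(g$counts[2, 1], g$counts[1, 1])
  expect_error(run_heatmap(list(name = "CSN.gNothing", values = 1),
                           list(name = "delay", values = 50)),
               "unknown")
})

test_that("stimulus marginals hold the other input at its default", {
  m <- run_stimulus_sweeps("duration", values = c(20, 100),
                           marginals = TRUE)
  expect_named(m, c("s1", "s2"))
  expect_length(m$s1$counts, 2)
  # a too-brief first stimulus fails to drive the CSN
  expect_lt(m$s1$counts[1], 4)
  expect_gte(m$s1$counts[2], 4)
})

test_that("OAT search brackets a known acceptance region", {
  # analytic predicate (no simulation): accepted iff value in [0.2, 0.9]
  pred <- function(cfg) {
    v <- cfg$neurons$CSN$gCaT
    v >= 0.2 && v <= 0.9
  }
  r <- run_oat_search("CSN.gCaT", predicate = pred, refine_rel = 0.02)
  expect_s3_class(r, "oat_range")
  expect_equal(r$baseline, 0.4)
  expect_lte(r$min, 0.2 * 1.05); expect_gte(r$min, 0.2 * 0.95)
  expect_lte(r$max, 0.9); expect_gte(r$max, 0.9 * 0.95)
  expect_true(r$min <= r$baseline && r$baseline <= r$max)
  # ill-posed baseline is refused
  expect_error(run_oat_search("CSN.gCaT",
                              predicate = function(cfg) FALSE),
               "baseline")
})

test_that("motif battery tabulates one outcome row per condition", {
  bat <- run_motif_battery(kinds = "inhibitory_excitatory")
  expect_equal(nrow(bat), 4)
  expect_setequal(bat$condition,
                  c("paired", "delayed_50", "overlap", "reversed"))
  expect_true(bat$success[bat$condition == "paired"])
  expect_false(any(bat$success[bat$condition != "paired"]))
})

test_that("run_from_config writes reproducible artifacts with a manifest", {
  d1 <- file.path(tempdir(), "exp1")
  d2 <- file.path(tempdir(), "exp2")
  r1 <- run_from_config(default_network_config(), "delay-sweep", d1,
                        delays = c(50, 150))
  r2 <- run_from_config(default_network_config(), "delay-sweep", d2,
                        delays = c(50, 150))
  expect_true(file.exists(file.path(d1, "results.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_identical(readLines(file.path(d1, "results.csv")),
                   readLines(file.path(d2, "results.csv")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$config_hash,
               config_hash(default_network_config()))
  expect_equal(man$solver$rtol, 1e-6)
  expect_error(run_from_config(default_network_config(), "nope",
                               tempdir()), "unknown experiment")
})
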