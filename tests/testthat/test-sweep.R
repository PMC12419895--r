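test_that("the default design is the full 3 x 8 x 3 factorial", {
  grid <- build_sweep_grid(sweep_spec())
  expect_equal(nrow(grid), 72)
  expect_equal(sort(unique(grid$p0)), c(0.01, 0.05, 0.10))
  expect_equal(sort(unique(grid$N)), c(10L, 50L, 100L))
  pv <- sort(unique(grid$PV))
  expect_length(pv, 8)
  expect_equal(pv, seq(0.2, 1.6, by = 0.2))
  expect_equal(min(pv), 0.2)
  expect_equal(max(pv), 1.6)
  # ids and sub-seeds are unique and deterministic
  expect_equal(anyDuplicated(grid$condition_id), 0)
  expect_equal(anyDuplicated(grid$seed), 0)
  expect_identical(grid$seed, build_sweep_grid(sweep_spec())$seed)
})

test_that("grid cardinality is always the product of the factor lengths", {
  set.seed(77)
  for (i in 1:5) {
    p0s <- sort(runif(sample(1:3, 1), 0.01, 0.4))
    pvs <- seq(0.2, by = 0.2, length.out = sample(1:4, 1))
    ns <- sample(c(5L, 10L, 20L, 40L), sample(1:3, 1))
    spec <- sweep_spec(p0s, pvs, ns)
    expect_equal(nrow(build_sweep_grid(spec)),
                 length(p0s) * length(pvs) * length(ns))
  }
  expect_equal(nrow(build_sweep_grid(sweep_spec(0.1, 0.6, 10L))), 1)
  expect_error(sweep_spec(numeric(0), 0.6, 10), "non-empty")
  expect_error(sweep_spec(0.7, 0.6, 10), "\\(0, 0.5\\)")
})

test_that("shared settings propagate into every cell", {
  spec <- sweep_spec(0.1, c(0.2, 0.4), c(6L, 9L), TMax = 7, RMax = 2,
                     transmission_rule = "site_serving")
  grid <- build_sweep_grid(spec)
  expect_true(all(purrr::map_int(grid$config, "TMax") == 7))
  expect_true(all(purrr::map_chr(grid$config, "transmission_rule") ==
                    "site_serving"))
  expect_equal(grid$M, purrr::map_int(grid$config, "M"))
})

test_that("summaries equal a brute-force recomputation", {
  spec <- sweep_spec(0.1, c(0.4, 1.0), 8L, TMax = 12, RMax = 3, seed = 21)
  traj <- run_sweep(spec)
  sm <- summarize_trajectories(traj, fixation_cutoff = 0.9)

  # brute force with base R
  agg <- aggregate(prop_social ~ condition_id + turn, data = traj, FUN = mean)
  merged <- merge(as.data.frame(sm), agg, by = c("condition_id", "turn"))
  expect_equal(merged$mean_prop_social, merged$prop_social, tolerance = 1e-12)

  finals <- traj[traj$turn == 12, ]
  for (cid in unique(finals$condition_id)) {
    expect_equal(
      unique(sm$fixation_fraction[sm$condition_id == cid]),
      mean(finals$prop_social[finals$condition_id == cid] >= 0.9)
    )
  }
  expect_true(all(sm$mean_prop_social >= 0 & sm$mean_prop_social <= 1))
})

test_that("degenerate trajectories give boundary summaries", {
  flat <- tidyr::expand_grid(round = 1:2, turn = 1:5)
  flat$prop_social <- 0
  sm0 <- summarize_trajectories(flat)
  expect_true(all(sm0$mean_prop_social == 0))
  expect_true(all(sm0$fixation_fraction == 0))
  flat$prop_social <- 1
  sm1 <- summarize_trajectories(flat)
  expect_true(all(sm1$mean_prop_social == 1))
  expect_true(all(sm1$fixation_fraction == 1))
  # one fixed and one extinct round, cutoff 0.9
  mix <- tidyr::expand_grid(round = 1:2, turn = 1:5)
  mix$prop_social <- ifelse(mix$round == 1, 1, 0)
  expect_equal(unique(summarize_trajectories(mix)$fixation_fraction), 0.5)

  ragged <- flat[-1, ]
  expect_error(summarize_trajectories(ragged), "mismatched")
})

test_that("first-passage turns are the earliest crossings", {
  traj <- tibble::tibble(
    round = c(1, 1, 1, 2, 2, 2),
    turn = c(1, 2, 3, 1, 2, 3),
    prop_social = c(0.2, 0.95, 0.97, 0.3, 0.4, 0.5)
  )
  fp <- first_passage(traj, level = 0.9)
  expect_equal(nrow(fp), 1) # round 2 never crosses
  expect_equal(fp$first_passage_turn, 2)
})

test_that("variant runs share the base condition and label rules", {
  cfg <- quick_config(N = 6, TMax = 8, RMax = 2)
  tr <- run_variants(cfg, c("baseline", "three_visits"))
  expect_setequal(unique(tr$variant), c("baseline", "three_visits"))
  expect_equal(nrow(tr), 2 * 2 * 8)
})

test_that("the cli runs a condition reproducibly and logs parameters", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  args <- c("run", "--N", "8", "--TMax", "6", "--RMax", "2", "--PV", "0.8",
            "--seed", "7")
  expect_equal(suppressMessages(cli_main(c(args, "--out", out1))), 0L)
  expect_equal(suppressMessages(cli_main(c(args, "--out", out2))), 0L)
  t1 <- readLines(file.path(out1, "trajectories.csv"))
  expect_identical(t1, readLines(file.path(out2, "trajectories.csv")))
  expect_true(length(t1) == 1 + 2 * 6)
  log <- readLines(file.path(out1, "run.log"))
  expect_true(any(grepl("^M: 2", log)))       # resolved threshold
  expect_true(any(grepl("^seed: 7", log)))
  expect_true(any(grepl("^sd_social:", log))) # calibrated prior spread
})

test_that("cli sweep --dry-run lists all 72 conditions, touching no RNG", {
  set.seed(42); before <- runif(3)
  set.seed(42)
  out <- capture.output(status <- cli_main(c("sweep", "--dry-run")))
  after <- runif(3)
  expect_equal(status, 0L)
  expect_identical(before, after)
  expect_true(any(grepl("72", out)))
  expect_true(sum(grepl("pv", out)) >= 72)
})

test_that("cli rejects unknown keys and bad values by name", {
  expect_equal(suppressMessages(cli_main(c("run", "--bogus", "1"))), 1L)
  expect_message(cli_main(c("run", "--bogus", "1")), "bogus")
  expect_message(cli_main(c("run", "--N", "ten")), "invalid numeric.*'N'")
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 1L)
})

test_that("cli reads a flat yaml config with flag overrides", {
  dir <- withr::local_tempdir()
  cfgfile <- file.path(dir, "cfg.yaml")
  writeLines(c("N: 6", "TMax: 4", "RMax: 2", "PV: 0.4", "seed: 9"), cfgfile)
  expect_equal(
    suppressMessages(cli_main(c("run", "--config", cfgfile, "--TMax", "3",
                                "--out", dir))),
    0L
  )
  traj <- readr::read_csv(file.path(dir, "trajectories.csv"),
                          show_col_types = FALSE)
  expect_equal(max(traj$turn), 3) # flag beat the file
  expect_equal(length(unique(traj$round)), 2)
})

test_that("cli equilibria reports the interior threshold", {
  out <- capture.output(
    status <- cli_main(c("equilibria", "--h", "1", "--s", "2", "--N", "3",
                         "--M", "2"))
  )
  expect_equal(status, 0L)
  expect_true(any(grepl("0.2928", paste(out, collapse = " "))))
  expect_true(any(grepl("unstable", out)))
})
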