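test_that("train/validation splits partition the panel reproducibly", {
  sp <- split_train_validation(800, 400, seed = 1)
  expect_length(sp$train, 400)
  expect_length(sp$validation, 400)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), 1:800)
  expect_identical(sp, split_train_validation(800, 400, seed = 1))
  expect_false(identical(sp$train, split_train_validation(800, 400, seed = 2)$train))

  odd <- split_train_validation(5, 3, seed = 1)
  expect_length(odd$train, 3)
  expect_length(odd$validation, 2)
  expect_error(split_train_validation(10, 10, seed = 1), "strictly between")
  expect_error(split_train_validation(10, 0, seed = 1), "strictly between")
})

test_that("accuracy cells format in the reporting style", {
  expect_equal(format_accuracy_cell(0.9371, 0.0123), "0.94 (0.01)")
  expect_equal(format_accuracy_cell(1.0, 0.0), "1.00 (0.00)")
  expect_equal(format_accuracy_cell(0.005, 0.001), "0.01 (0.00)")
  expect_equal(format_accuracy_cell(0.9371, 0.0123, n_replicates = 1), "0.94")
})

small_scenario <- function(...) {
  scenario_config(n_qtl = 10, h2 = 0.5, panels = c("mp1", "mp5"),
                  models = "rrblup", n_replicates = 2, train_size = 60,
                  master_seed = 77, mcmc = quick_mcmc(), ...)
}

test_that("replicates and scenario runs are fully seed-deterministic", {
  p <- generate_panel(generator_config(n_individuals = 120, n_loci = 150,
                                       seed = 9, n_chromosomes = 3))
  scen <- small_scenario()
  r1 <- run_replicate(p, scen, n_qtl = 10, h2 = 0.5, replicate_index = 1)
  r2 <- run_replicate(p, scen, n_qtl = 10, h2 = 0.5, replicate_index = 1)
  expect_identical(r1, r2)

  t1 <- run_scenario(p, scen)
  t2 <- run_scenario(p, scen)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
})

test_that("aggregate means and SDs are recomputable from replicate values", {
  p <- generate_panel(generator_config(n_individuals = 100, n_loci = 120,
                                       seed = 10, n_chromosomes = 2))
  tab <- run_scenario(p, small_scenario())
  for (i in seq_len(nrow(tab))) {
    reps <- tab$replicates[[i]]
    expect_equal(tab$mean_accuracy[i], mean(reps))
    expect_equal(tab$sd_accuracy[i], sd(reps))
    expect_equal(tab$n_replicates[i], length(reps))
  }
  # single replicate: mean is the value, SD reported as 0
  tab1 <- run_scenario(p, scenario_config(n_qtl = 5, h2 = 0.5, panels = "mp1",
                                          models = "rrblup", n_replicates = 1,
                                          train_size = 50, master_seed = 3,
                                          mcmc = quick_mcmc()))
  expect_equal(tab1$sd_accuracy, 0)
  expect_equal(tab1$mean_accuracy, tab1$replicates[[1]])
  # hand arithmetic for a two-replicate aggregate
  expect_equal(mean(c(0.92, 0.96)), 0.94)
  expect_equal(sd(c(0.92, 0.96)), 0.0283, tolerance = 1e-3)
})

test_that("a noiseless trait with observed QTL is predicted almost perfectly", {
  p <- generate_panel(generator_config(n_individuals = 200, n_loci = 300,
                                       seed = 12, n_chromosomes = 4))
  scen <- scenario_config(n_qtl = 10, h2 = 1, panels = "mp1",
                          models = "rrblup", n_replicates = 1,
                          train_size = 100, master_seed = 5,
                          mcmc = quick_mcmc())
  tab <- run_scenario(p, scen)
  expect_gt(tab$mean_accuracy, 0.99)
})

test_that("observing the causal loci beats excluding them", {
  p <- generate_panel(generator_config(n_individuals = 300, n_loci = 400,
                                       seed = 13, n_chromosomes = 5))
  scen <- scenario_config(n_qtl = 20, h2 = 0.5, panels = c("mp1", "mp5"),
                          models = "rrblup", n_replicates = 5,
                          train_size = 150, master_seed = 8,
                          mcmc = quick_mcmc())
  raw <- tidy(run_scenario(p, scen))
  wide <- tidyr::pivot_wider(raw, names_from = "panel",
                             values_from = "accuracy")
  expect_gte(sum(wide$mp1 > wide$mp5), 4)
})

test_that("accuracy tables tidy, glance and plot", {
  p <- generate_panel(generator_config(n_individuals = 100, n_loci = 100,
                                       seed = 14, n_chromosomes = 2))
  tab <- run_scenario(p, small_scenario())
  td <- tidy(tab)
  expect_equal(nrow(td), 2 * 2)   # 2 panels x 2 replicates
  expect_named(td, c("n_qtl", "h2", "panel", "model", "replicate", "accuracy"))
  gl <- glance(tab)
  expect_equal(gl$n_cells, 2L)
  pl <- autoplot(tab)
  expect_s3_class(pl, "ggplot")
  lines <- format_accuracy_table(tab)
  expect_true(any(grepl("QTL10", lines)))

  mp <- build_panel("mp4", sample_architecture(p, 5, seed = 2), p)
  expect_s3_class(plot_panel_ld(mp, sample_architecture(p, 5, seed = 2), p),
                  "ggplot")
})

test_that("a YAML-configured experiment writes its result files", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "generator:",
    "  n_individuals: 80",
    "  n_loci: 60",
    "  n_chromosomes: 2",
    "  seed: 4",
    "mcmc:",
    "  n_iter: 400",
    "  burn_in: 100",
    "scenario:",
    "  n_qtl: 5",
    "  h2: 0.5",
    "  panels: [mp1, mp4]",
    "  models: [rrblup]",
    "  n_replicates: 2",
    "  train_size: 40",
    "  master_seed: 11"), cfg_file)
  out <- withr::local_tempdir()
  tab <- run_experiment(cfg_file, out, verbose = FALSE)
  expect_s3_class(tab, "accuracy_table")
  expect_true(all(file.exists(file.path(out,
    c("results.csv", "table1.txt", "run.json")))))
  res <- read.csv(file.path(out, "results.csv"))
  expect_equal(nrow(res), 4L)
  cfg_echo <- jsonlite::read_json(file.path(out, "run.json"))
  expect_equal(cfg_echo$scenario$master_seed, 11L)
})
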