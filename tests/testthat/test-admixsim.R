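test_that("config validation enforces the simulation contract", {
  expect_error(sim_config(n_sources = 7), "1..5")
  expect_error(sim_config(admix_generation = 100, total_generations = 100),
               "precede")
  expect_error(sim_config(selfing_rate = 1.2), "selfing")
  cfg <- sim_config()
  expect_equal(cfg$chrom_length, 2e7)          # desk preset
  expect_equal(sim_config(preset = "full")$chrom_length, 1e8)
  expect_equal(cfg$mutation_rate, 1.6e-8)
  expect_equal(cfg$selfing_rate, 0.95)
  expect_equal(cfg$source_ne, 1000)
})

test_that("truth tracts tile every sampled chromosome and seeds reproduce", {
  cfg <- tiny_cfg(seed = 61)
  sim <- simulate_admixture(cfg)
  for (ch in unique(sim$tracts$chromosome)) {
    tr <- sim$tracts[sim$tracts$chromosome == ch, ]
    expect_equal(tr$start[1], 0)
    expect_equal(tr$end[nrow(tr)], cfg$chrom_length)
    if (nrow(tr) > 1) expect_equal(tr$start[-1], tr$end[-nrow(tr)])
  }
  # source samples have single-source truth
  src_acc <- sim$samples$accession[sim$samples$population != "target"]
  for (acc in src_acc) {
    tr <- sim$tracts[sim$tracts$sample == acc, ]
    expect_equal(length(unique(tr$source)), 1L)
  }
  # determinism
  sim2 <- simulate_admixture(tiny_cfg(seed = 61))
  expect_identical(sim$gm$calls, sim2$gm$calls)
  expect_identical(sim$tracts, sim2$tracts)
})

test_that("drift separates sources far beyond within-source diversity", {
  cfg <- tiny_cfg(n_sources = 2, seed = 62)
  sim <- simulate_admixture(cfg)
  grid <- make_windows(c(sim1 = cfg$chrom_length), 1e6)
  wd <- pairwise_window_distances(sim$gm, grid)
  s1 <- grep("^S1", sim$samples$accession, value = TRUE)
  s2 <- grep("^S2", sim$samples$accession, value = TRUE)
  between <- mean(wd$D[s1, s2, ])
  within <- mean(c(wd$D[s1, s1, ], wd$D[s2, s2, ]))
  expect_gt(between, 5 * within)
})

test_that("selfing suppresses heterozygosity", {
  h_selfing <- mean(simulate_admixture(
    tiny_cfg(n_sources = 2, seed = 63))$heterozygosity)
  h_outcross <- mean(simulate_admixture(
    tiny_cfg(n_sources = 2, seed = 63, selfing_rate = 0))$heterozygosity)
  expect_lt(h_selfing, 0.5 * h_outcross)
})

test_that("window truth takes the majority source by bp overlap", {
  grid <- make_windows(c(sim1 = 1e7), 5e6)
  tracts <- data.frame(chrom = "sim1",
                       start = c(0, 1e7), end = c(1e7, 1e7),
                       chromosome = c("xa", "xa"), sample = c("x", "x"),
                       source = c(2L, 2L))[1, ]
  tw <- truth_to_windows(tracts, grid)
  expect_equal(unname(tw$chromosome["xa", ]), c(2L, 2L))

  # switch exactly at the window boundary splits cleanly
  tr2 <- data.frame(chrom = "sim1", start = c(0, 5e6), end = c(5e6, 1e7),
                    chromosome = "ya", sample = "y", source = c(1L, 2L))
  tw2 <- truth_to_windows(tr2, grid)
  expect_equal(unname(tw2$chromosome["ya", ]), c(1L, 2L))
  expect_equal(unname(tw2$share["y", ]), c(1, 1))

  # random tracts against a bp-overlap oracle
  set.seed(64)
  for (r in 1:5) {
    cuts <- sort(runif(3, 0, 1e7))
    srcs <- sample(1:3, 4, replace = TRUE)
    tr3 <- data.frame(chrom = "sim1", start = c(0, cuts),
                      end = c(cuts, 1e7), chromosome = "za", sample = "z",
                      source = srcs)
    tw3 <- truth_to_windows(tr3, grid)
    for (w in 1:2) {
      ov <- sapply(1:3, function(s) {
        rows <- tr3$source == s
        sum(pmax(pmin(tr3$end[rows], grid$end[w]) -
                   pmax(tr3$start[rows], grid$start[w]), 0))
      })
      expect_equal(tw3$chromosome["za", w], which.max(ov))
    }
  }
})

test_that("accuracy evaluation is exact on constructed fits", {
  # two sources, two targets, four windows; hand-built fit object
  accs <- c("S1_01", "S2_01", "T_01", "T_02")
  labels <- rbind(S1_01 = c(1, 1, 1, 1), S2_01 = c(2, 2, 2, 2),
                  T_01 = c(1, 1, 2, 2), T_02 = c(2, 2, 2, 2))
  grid <- make_windows(c(sim1 = 2e7), 5e6)
  fit <- structure(list(labels = labels, grid = grid,
                        dominator = c("S1_01", "S2_01"),
                        mask = matrix(0L, 4, 4)), class = "introblocker")
  tracts <- rbind(
    data.frame(chrom = "sim1", start = c(0, 1e7), end = c(1e7, 2e7),
               chromosome = "T_01a", sample = "T_01", source = c(1L, 2L)),
    data.frame(chrom = "sim1", start = c(0, 1e7), end = c(1e7, 2e7),
               chromosome = "T_01b", sample = "T_01", source = c(1L, 2L)),
    data.frame(chrom = "sim1", start = 0, end = 2e7,
               chromosome = "T_02a", sample = "T_02", source = 1L),
    data.frame(chrom = "sim1", start = 0, end = 2e7,
               chromosome = "T_02b", sample = "T_02", source = 1L))
  sim <- structure(list(
    tracts = tracts,
    samples = data.frame(accession = accs,
                         population = c("source1", "source2",
                                        "target", "target")),
    heterozygosity = setNames(rep(0, 4), accs)), class = "sim_result")
  ev <- evaluate_accuracy(fit, sim)
  # T_01 matches truth everywhere; T_02 carries the wrong source label
  expect_equal(ev$accuracy, 0.5)
  expect_equal(ev$per_individual$accuracy,
               c(1, 0)[match(c("T_01", "T_02"), ev$per_individual$accession)])

  # relabeling truth-equal inference scores 1; het filter excludes
  sim$heterozygosity["T_02"] <- 0.5
  ev2 <- evaluate_accuracy(fit, sim)
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$n_excluded, 1L)
})

test_that("single-source inference is perfect by construction", {
  cfg <- tiny_cfg(n_sources = 1, seed = 65)
  sim <- simulate_admixture(cfg)
  grid <- make_windows(c(sim1 = cfg$chrom_length), 1e6)
  groups <- group_assignment(
    setNames(sim$samples$population, sim$samples$accession),
    c("source1", "target"))
  fit <- introblocker(pairwise_window_distances(sim$gm, grid),
                      groups = groups, seed = 65)
  ev <- evaluate_accuracy(fit, sim)
  expect_equal(ev$accuracy, 1)
})

test_that("simulation outputs round-trip through plain-text files", {
  cfg <- tiny_cfg(seed = 66)
  sim <- simulate_admixture(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_result(sim, dir)
  back <- read_vcf(paths["vcf"])
  expect_identical(back$calls, sim$gm$calls)
  tr <- read.table(paths["tracts"], header = TRUE, sep = "\t")
  expect_equal(nrow(tr), nrow(sim$tracts))
  cfg_lines <- readLines(paths["config"])
  expect_true(any(grepl("selfing_rate = 0.95", cfg_lines)))
})
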