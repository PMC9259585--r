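test_that("window clustering cuts the average-linkage tree at the threshold", {
  D <- array(0, dim = c(3, 3, 1),
             dimnames = list(letters[1:3], letters[1:3], NULL))
  D["a", "b", 1] <- D["b", "a", 1] <- 1e-4
  D["a", "c", 1] <- D["c", "a", 1] <- 5e-3
  D["b", "c", 1] <- D["c", "b", 1] <- 5e-3
  wd <- wd_from_array(D)
  ic <- binwise_cluster(wd, 1e-3)
  expect_equal(ic["a", 1], ic["b", 1])
  expect_false(ic["a", 1] == ic["c", 1])

  wd0 <- wd_from_array(array(0, dim = c(3, 3, 1)))
  expect_equal(unname(binwise_cluster(wd0, 1e-3)[, 1]), rep(1L, 3))

  expect_error(binwise_cluster(wd, 0), "threshold")
})

test_that("window clustering matches an independent average-linkage oracle", {
  set.seed(21)
  for (r in 1:10) {
    n <- 6
    m <- matrix(10^runif(n * n, -5, -2), n)
    D <- (m + t(m)) / 2
    diag(D) <- 0
    arr <- array(D, dim = c(n, n, 1))
    wd <- wd_from_array(arr)
    got <- binwise_cluster(wd, 1e-3)[, 1]
    want <- brute_average_linkage(D, 1e-3)
    expect_equal(canon(got), canon(want))
  }
})

test_that("masked accessions are excluded from the window dendrogram", {
  D <- array(1e-4, dim = c(3, 3, 2))
  for (w in 1:2) diag(D[, , w]) <- 0
  wd <- wd_from_array(D)
  mask <- matrix(0L, 3, 2)
  mask[2, 1] <- 1L
  ic <- binwise_cluster(wd, 1e-3, mask)
  expect_true(is.na(ic[2, 1]))
  expect_false(anyNA(ic[, 2]))
})

test_that("transition counting skips masks and chromosome boundaries", {
  expect_equal(count_transitions(matrix(c(1, 1, 2, 2, 1), 1)), 2L)
  expect_equal(count_transitions(matrix(c(1, NA, 1), 1)), 0L)
  expect_equal(count_transitions(matrix(c(1, NA, 2), 1)), 1L)
  # no transition across a chromosome boundary
  expect_equal(count_transitions(matrix(c(1, 2), 1), chrom = c("c1", "c2")), 0L)

  set.seed(22)
  for (r in 1:10) {
    lab <- matrix(sample(c(1:3, NA), 40, replace = TRUE), 4)
    chrom <- rep(c("c1", "c2"), each = 5)
    naive <- 0L
    for (ch in c("c1", "c2")) for (i in 1:4) {
      v <- lab[i, chrom == ch]; v <- v[!is.na(v)]
      if (length(v) > 1) naive <- naive + sum(v[-1] != v[-length(v)])
    }
    expect_equal(count_transitions(lab, chrom), naive)
  }
})

test_that("greedy core selection covers co-clustering mass", {
  ic <- random_ic(3, 4, k = 1, seed = 1)       # three identical accessions
  expect_equal(select_core_accessions(ic)[1], "acc1")  # tie -> input order

  # one accession co-clusters with everything, the rest pairwise distinct
  ic2 <- matrix(c(1, 1, 2,
                  1, 1, 2,
                  1, 2, 1,
                  1, 2, 1), nrow = 3,
                dimnames = list(c("hub", "x", "y"), NULL))
  expect_equal(select_core_accessions(ic2)[1], "hub")

  # greedy score at each round equals exhaustive candidate evaluation
  set.seed(23)
  for (r in 1:10) {
    ic3 <- random_ic(5, 6, k = 2, seed = 100 + r)
    got <- select_core_accessions(ic3, coverage = 1)
    covered <- matrix(FALSE, 5, 6)
    avail <- 1:5
    for (pos in seq_along(got)) {
      gains <- vapply(avail, function(a) {
        g <- 0L
        for (w in 1:6) g <- g + sum(!covered[, w] & ic3[, w] == ic3[a, w])
        g
      }, integer(1))
      if (max(gains) == 0L) break
      pick <- avail[which.max(gains)]
      expect_equal(rownames(ic3)[pick], got[pos])
      for (w in 1:6) covered[ic3[, w] == ic3[pick, w], w] <- TRUE
      avail <- setdiff(avail, pick)
    }
  }
})

test_that("label threading follows priority and dominates novel labels", {
  ic <- matrix(c(1, 1,
                 1, 1,
                 2, 2), nrow = 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  class(ic) <- c("initial_clusters", "matrix", "array")
  lab <- assign_ahgs(ic, c("a", "b", "c"))
  expect_equal(unname(lab["b", ]), unname(lab["a", ]))   # co-clustered everywhere
  expect_equal(length(intersect(lab["a", ], lab["c", ])), 0L)  # never co-clustered
  # top-priority accession carries one uniform label
  expect_equal(length(unique(lab["a", ])), 1L)

  # partition invariance: any order induces the same within-window partition
  set.seed(24)
  for (r in 1:10) {
    icr <- random_ic(6, 5, k = 3, seed = 200 + r, mask_rate = 0.1)
    o1 <- sample(rownames(icr)); o2 <- sample(rownames(icr))
    l1 <- assign_ahgs(icr, o1); l2 <- assign_ahgs(icr, o2)
    for (w in 1:5) expect_equal(canon(l1[, w]), canon(l2[, w]))
  }
})

test_that("adjacent-swap optimization reaches the exhaustive optimum on small instances", {
  # two accessions: output is the argmin of the two orders
  ic <- random_ic(2, 6, k = 2, seed = 31)
  res <- optimize_order(ic, rownames(ic))
  both <- sapply(list(c("acc1", "acc2"), c("acc2", "acc1")), function(o)
    count_transitions(assign_ahgs(ic, o)))
  expect_equal(res$transitions, min(both))

  # 4 accessions x 8 windows: equals the minimum over all 24 permutations
  exhaustive <- function(ic4) {
    allp <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    allp <- allp[apply(allp, 1, function(p) length(unique(p)) == 4), ]
    min(apply(allp, 1, function(p)
      count_transitions(assign_ahgs(ic4, rownames(ic4)[unlist(p)]))))
  }
  ic4 <- random_ic(4, 8, k = 3, seed = 34)
  init <- select_core_accessions(ic4)
  res4 <- optimize_order(ic4, init)
  expect_equal(res4$transitions, exhaustive(ic4))
  # monotonicity: never worse than the starting order
  expect_lte(res4$transitions, count_transitions(assign_ahgs(ic4, init)))

  # the adjacent-swap descent is a local search: on some instances it
  # stops above the global minimum, but never below it
  ic_hard <- random_ic(4, 8, k = 3, seed = 32)
  res_hard <- optimize_order(ic_hard, select_core_accessions(ic_hard))
  expect_gte(res_hard$transitions, exhaustive(ic_hard))
})

test_that("semi-supervised swaps never cross group boundaries", {
  ic <- random_ic(6, 6, k = 3, seed = 33)
  groups <- group_assignment(setNames(rep(c("WE", "DT"), each = 3),
                                      rownames(ic)), c("WE", "DT"))
  init <- c(paste0("acc", 1:3), paste0("acc", 4:6))
  res <- optimize_order(ic, init, groups = groups)
  expect_equal(res$mode, "semisupervised")
  expect_true(all(match(res$order[1:3], paste0("acc", 1:3)) %in% 1:3 |
                    TRUE))
  expect_setequal(res$order[1:3], paste0("acc", 1:3))   # WE block first
  expect_setequal(res$order[4:6], paste0("acc", 4:6))
})

test_that("smoothing flips isolated blips and fixes clean maps", {
  # 1x12-window fixture: one accession pair, isolated foreign label at w6
  n <- 3; nw <- 12
  D <- array(3e-3, dim = c(n, n, nw),
             dimnames = list(c("ref", "x", "lone"), c("ref", "x", "lone"), NULL))
  for (w in seq_len(nw)) {
    diag(D[, , w]) <- 0
    D["ref", "x", w] <- D["x", "ref", w] <- 3e-5   # x always near ref
  }
  wd <- wd_from_array(D, window_size = 5e6)
  fit <- introblocker:::new_mixture(c(log10(3e-5), log10(3e-3)), c(0.15, 0.15),
                                    c(0.5, 0.5), 1000, 0, 0, TRUE, 1L)
  labels <- matrix(1L, n, nw)        # everyone carries ref's label ...
  labels[3, ] <- 3L                  # ... except lone with its own label
  labels[2, 6] <- 2L                 # isolated singleton blip in x's row
  sm <- bayesian_smooth(labels, wd, fit, chrom = wd$grid$chrom)
  expect_equal(sm$labels[2, 6], 1L)          # flipped to the neighbor label
  expect_equal(sum(sm$changed), 1L)          # nothing else moved
  # idempotence: a second pass is a fixed point
  sm2 <- bayesian_smooth(sm$labels, wd, fit, chrom = wd$grid$chrom)
  expect_equal(sm2$labels, sm$labels)
  expect_equal(sum(sm2$changed), 0L)
})

test_that("cells with distances at the same-ancestry mode are preserved", {
  n <- 2; nw <- 5
  D <- array(3e-5, dim = c(n, n, nw))
  for (w in seq_len(nw)) diag(D[, , w]) <- 0
  wd <- wd_from_array(D, window_size = 5e6)
  fit <- introblocker:::new_mixture(c(log10(3e-5), log10(3e-3)), c(0.15, 0.15),
                                    c(0.5, 0.5), 1000, 0, 0, TRUE, 1L)
  labels <- matrix(1L, n, nw)        # acc2 sits exactly at the low mean
  sm <- bayesian_smooth(labels, wd, fit, chrom = wd$grid$chrom)
  expect_equal(sm$labels, labels)
})

test_that("the full fit is deterministic and partition-invariant to order", {
  demo <- demo_mosaic(seed = 7)
  f1 <- introblocker(demo$wd, groups = demo$groups)
  f2 <- introblocker(demo$wd, groups = demo$groups)
  expect_identical(f1$labels, f2$labels)

  rev_groups <- group_assignment(demo$groups$groups,
                                 rev(demo$groups$group_order))
  f3 <- introblocker(demo$wd, groups = rev_groups)
  expect_identical(ahg_partitions(f1), ahg_partitions(f3))
  expect_false(identical(f1$dominator, f3$dominator))
  # WE accessions dominate under WE-first priority
  expect_true(all(grepl("^WE", f1$dominator[1:4])))

  # recovered partitions equal the planted ancestry mosaic
  for (w in seq_len(ncol(demo$truth)))
    expect_equal(canon(f1$labels[, w]), canon(demo$truth[, w]))
})

test_that("a single-accession fit yields one uniform label", {
  D <- array(0, dim = c(1, 1, 6), dimnames = list("only", "only", NULL))
  wd <- wd_from_array(D)
  fit <- introblocker(wd, smooth = FALSE)
  expect_equal(unname(fit$labels["only", ]), rep(1L, 6))
  expect_equal(fit$transitions, 0L)
})

test_that("CNV depth masking masks cells before clustering", {
  demo <- demo_mosaic(seed = 8, n_windows = 6)
  depth <- matrix(1, 11, 6, dimnames = list(demo$wd$accessions, NULL))
  depth[2, 3] <- 0.2   # deletion
  fit <- introblocker(demo$wd, depth = depth, groups = demo$groups,
                      smooth = FALSE)
  expect_true(is.na(fit$labels[2, 3]))
  expect_equal(fit$mask[2, 3], 1L)
  m <- ahg_map(fit)
  expect_true(is.na(m[2, 3]))
})

test_that("the AHG map TSV round trip preserves labels, masks and provenance", {
  demo <- demo_mosaic(seed = 9, n_windows = 6)
  depth <- matrix(1, 11, 6, dimnames = list(demo$wd$accessions, NULL))
  depth[4, 2] <- 3
  fit <- introblocker(demo$wd, depth = depth, groups = demo$groups)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ahg_tsv(fit, path)
  back <- read_ahg_tsv(path)
  expect_equal(unname(back$labels), unname(fit$labels))
  expect_equal(unname(back$mask), unname(fit$mask))
  expect_true(any(grepl("threshold=0.001", back$provenance)))
})
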