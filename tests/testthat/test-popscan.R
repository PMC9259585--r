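test_that("Shannon index closed forms", {
  expect_equal(shannon_index(c(a = 5)), 0)
  expect_equal(shannon_index(c(5, 5)), 1)
  expect_equal(shannon_index(rep(3, 4)), 2)
  expect_error(shannon_index(integer(0)), "empty")
  # entropy bound: H <= log2(number of labels)
  set.seed(41)
  for (r in 1:10) {
    k <- sample(2:6, 1)
    counts <- sample.int(20, k, replace = TRUE)
    expect_lte(shannon_index(counts), log2(k) + 1e-12)
  }
})

staged_groups <- function(per_group = 3) {
  ids <- paste0(rep(c("WE", "DT", "LR", "CV"), each = per_group),
                seq_len(per_group))
  group_assignment(setNames(rep(c("WE", "DT", "LR", "CV"), each = per_group),
                            ids), c("WE", "DT", "LR", "CV"))
}

test_that("selection scan flags the stated stage inequalities", {
  g <- staged_groups(8)
  # construct one window with H = (3, 1, 1, 1): WE has 8 distinct labels,
  # later stages two labels 50/50
  lab <- matrix(0L, 32, 1, dimnames = list(names(g$groups), NULL))
  lab[1:8, 1] <- 1:8
  lab[9:16, 1] <- rep(9:10, 4)
  lab[17:24, 1] <- rep(11:12, 4)
  lab[25:32, 1] <- rep(13:14, 4)
  st <- selection_scan(lab, g)
  expect_equal(st$H_WE, 3)
  expect_equal(st$H_DT, 1)
  expect_true(st$sel_WE_DT)
  expect_false(st$sel_DT_LR || st$sel_LR_CV)
  expect_false(any(st$fix_WE, st$fix_DT, st$fix_LR, st$fix_CV))

  # all groups fixed on one label: fixation everywhere, no selection
  lab2 <- matrix(1L, 32, 1, dimnames = list(names(g$groups), NULL))
  st2 <- selection_scan(lab2, g)
  expect_true(all(st2$fix_WE, st2$fix_DT, st2$fix_LR, st2$fix_CV))
  expect_false(any(st2$sel_WE_DT, st2$sel_DT_LR, st2$sel_LR_CV))

  # CEB windows are excluded from flags
  st3 <- selection_scan(lab, g, ceb = TRUE)
  expect_false(st3$sel_WE_DT)
})

test_that("selection scan equals a plain recomputation on random fixtures", {
  set.seed(42)
  g <- staged_groups(5)
  lab <- matrix(sample(1:4, 20 * 20, replace = TRUE), 20,
                dimnames = list(names(g$groups), NULL))
  st <- selection_scan(lab, g, stage_thresholds = c(0.5, 0.3, 0.2),
                       fixation_max = 0.4)
  for (w in 1:20) {
    H <- sapply(c("WE", "DT", "LR", "CV"), function(gr) {
      v <- lab[startsWith(rownames(lab), gr), w]
      p <- table(v) / length(v)
      -sum(p * log2(p))
    })
    expect_equal(unname(st$H_WE[w]), unname(H["WE"]))
    expect_equal(unname(st$sel_WE_DT[w]), unname(H["WE"] - H["DT"] > 0.5))
    expect_equal(unname(st$sel_DT_LR[w]), unname(H["DT"] - H["LR"] > 0.3))
    expect_equal(unname(st$fix_CV[w]), unname(H["CV"] < 0.4))
  }
  # flags are invariant to accession order
  perm <- sample(nrow(lab))
  st_p <- selection_scan(lab[perm, ], g, stage_thresholds = c(0.5, 0.3, 0.2),
                         fixation_max = 0.4)
  expect_equal(st_p$sel_WE_DT, st$sel_WE_DT)
})

test_that("CEB scan uses consecutive-stage frequency jumps only", {
  g <- staged_groups(10)
  freqs <- list(c(0.1, 0.6, 0.7, 0.5), c(0.3, 0.3, 0.3, 0.3),
                c(0.0, 0.2, 0.4, 0.4))
  cnv <- matrix(FALSE, 40, 3, dimnames = list(names(g$groups), NULL))
  for (w in seq_along(freqs)) for (gi in 1:4) {
    rows <- (gi - 1) * 10 + seq_len(10)
    cnv[rows[seq_len(round(freqs[[w]][gi] * 10))], w] <- TRUE
  }
  tab <- ceb_scan(cnv, g)
  expect_equal(tab$max_delta, c(0.5, 0, 0.2))
  expect_equal(tab$ceb, c(TRUE, FALSE, FALSE))
  # the overall 0 -> 0.4 drift in window 3 does not qualify
  expect_lt(tab$max_delta[3], 0.4)
})

test_that("contribution and coverage follow the set-sharing definitions", {
  lab <- rbind(d1 = c(1, 1, 2, 9, 9, 9),
               d2 = c(1, 2, 2, 2, 9, 9),
               d3 = c(7, 7, 7, 7, 7, 9),
               r1 = c(1, 1, 2, 2, 5, 5),
               r2 = c(1, 2, 2, 7, 5, 5))
  # single donor identical to single recipient
  solo <- contribution(rbind(a = c(1, 2, 3), b = c(1, 2, 3)), "a", "b")
  expect_equal(solo$contribution, 1)
  expect_equal(solo$coverage, 1)
  # donor sharing nothing
  none <- contribution(rbind(a = c(1, 1), b = c(2, 2)), "a", "b")
  expect_equal(none$contribution, 0)
  expect_equal(none$coverage, 0)

  rep3 <- contribution(lab, c("d1", "d2", "d3"), c("r1", "r2"))
  # hand enumeration: per (recipient, window) shares
  # d1: r1 w1,w2,w3; r2 w1,w3 -> 5/12
  expect_equal(rep3$contribution[1], 5 / 12)
  # d2: r1 w1,w3,w4(2? r1w4=2 yes); r2 w1,w2,w3 -> 6/12
  expect_equal(rep3$contribution[2], 6 / 12)
  # d3: r2 w4 (7) -> 1/12
  expect_equal(rep3$contribution[3], 1 / 12)
  # coverage: windows of donor whose label occurs in any recipient
  expect_equal(rep3$coverage[1], 3 / 6)   # d1 w1,w2,w3
  expect_equal(rep3$coverage[2], 4 / 6)   # d2 w1..w4
  expect_equal(rep3$coverage[3], 1 / 6)   # d3 w4 via r2
  # cumulative under order d1,d2,d3 deduplicates shared cells:
  # d1 takes {r1:w1,w2,w3; r2:w1,w3}; d2 newly adds {r1:w4, r2:w2};
  # d3 newly adds {r2:w4}
  expect_equal(rep3$cumulative, c(5, 7, 8) / 12)
  # bound: total cumulative never exceeds 1
  expect_lte(max(rep3$cumulative), 1)

  expect_error(contribution(lab, "d1", character(0)), "empty")
  expect_error(contribution(lab, "d1", c("d1", "r1")), "disjoint")
})

test_that("pooled AHGs partition by group presence pattern", {
  g <- group_assignment(setNames(c("A", "A", "B", "B"),
                                 c("a1", "a2", "b1", "b2")), c("A", "B"))
  # one label everywhere
  lab <- matrix(1L, 4, 3, dimnames = list(names(g$groups), NULL))
  p <- shared_ahg_partition(lab, g)
  expect_equal(p$pattern, "A+B")
  expect_equal(p$count, 3L)   # one label per window, 3 windows pooled
  # private labels only
  lab2 <- rbind(a1 = c(1, 1), a2 = c(1, 1), b1 = c(2, 2), b2 = c(2, 2))
  p2 <- shared_ahg_partition(lab2, g)
  expect_setequal(p2$pattern, c("A", "B"))
  expect_equal(sum(p2$count), 4L)
  # conservation: counts total the pooled (window, label) set
  set.seed(43)
  lab3 <- matrix(sample(1:3, 4 * 6, replace = TRUE), 4,
                 dimnames = list(names(g$groups), NULL))
  p3 <- shared_ahg_partition(lab3, g)
  pooled <- sum(sapply(1:6, function(w) length(unique(lab3[, w]))))
  expect_equal(sum(p3$count), pooled)
  expect_equal(sum(p3$fraction), 1)
})

test_that("saturation curves flatten for redundant groups", {
  lab <- matrix(1L, 4, 5, dimnames = list(paste0("a", 1:4), NULL))
  sat <- saturation_curve(lab, paste0("a", 1:4), reps = 20, seed = 1)
  expect_true(all(sat$mean == 1))
  expect_true(all(sat$p5 == sat$p95))

  set.seed(44)
  lab2 <- matrix(sample(1:5, 4 * 6, replace = TRUE), 4,
                 dimnames = list(paste0("a", 1:4), NULL))
  sat2 <- saturation_curve(lab2, paste0("a", 1:4), reps = 50, seed = 2)
  # full-size subsets have zero spread and equal the full distinct count
  full <- mean(apply(lab2, 2, function(v) length(unique(v))))
  expect_equal(sat2$mean[4], full)
  expect_equal(sat2$p5[4], sat2$p95[4])
  # size-2 mean equals the exhaustive average over all 6 pairs
  pairs <- combn(4, 2)
  exp2 <- mean(apply(pairs, 2, function(p)
    mean(apply(lab2[p, ], 2, function(v) length(unique(v))))))
  sat_many <- saturation_curve(lab2, paste0("a", 1:4), reps = 4000, seed = 3)
  expect_equal(sat_many$mean[2], exp2, tolerance = 0.02)
  # monotone non-decreasing in subset size
  expect_true(all(diff(sat2$mean) > -1e-9))
})

test_that("AHG distance matrices count differing windows", {
  lab <- rbind(a = c(1, 1, 2, 2), b = c(1, 1, 2, 2), c = c(1, 2, 2, 9))
  d <- ahg_distance_matrix(lab)
  expect_equal(d["a", "b"], 0L)
  expect_equal(d["a", "c"], 2L)
  expect_equal(d, t(d))
  # masked windows are skipped
  lab2 <- lab; lab2["a", 1] <- NA
  expect_equal(ahg_distance_matrix(lab2)["a", "c"], 2L)
  path <- withr::local_tempfile()
  write_phylip_dist(d, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4L)
})
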