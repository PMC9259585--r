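#' Simulation configuration for admixed selfing cohorts
#'
#' Bundles the parameters of the validation simulator.  The defaults are
#' the evaluation conditions for a wheat-like cohort: source populations
#' of 1000 founder chromosomes (500 selfing diploids) diverging from a
#' single ancestral population by pure drift 1e5 years ago, a target
#' population of 1000 chromosomes founded at generation 30 by admixture of
#' the sources with equal probability, 100 generations of forward
#' reproduction with selfing rate 0.95 and recombination 1e-8 per bp per
#' generation, neutral mutations at 1.6e-8 per bp per generation placed on
#' the genealogy, and final samples of 20 chromosomes per source and 100
#' target chromosomes.  One generation equals one year.  The `desk`
#' preset shrinks only the chromosome to 20 Mbp for routine runs; the
#' full-scale 100 Mbp configuration is the `full` preset.
#'
#' @param n_sources number of source populations (1-5).
#' @param source_ne source population size in chromosomes (default 1000).
#' @param divergence_years source divergence time (default 1e5).
#' @param admix_generation target founding generation (default 30).
#' @param total_generations forward span (default 100).
#' @param selfing_rate probability an offspring is selfed (default 0.95).
#' @param recombination_rate per bp per generation (default 1e-8).
#' @param mutation_rate per bp per generation (default 1.6e-8).
#' @param chrom_length chromosome length in bp.
#' @param source_samples sampled chromosomes per source (default 20).
#' @param target_samples sampled target chromosomes (default 100).
#' @param segment_length genealogy segment length in bp (default 1e6):
#'   source-history genealogies are drawn independently per segment (free
#'   recombination between segments, none within a segment's deep
#'   history); forward-phase recombination is continuous.
#' @param seed integer seed.
#' @param preset `"desk"` (20 Mbp) or `"full"` (100 Mbp); an explicit
#'   `chrom_length` overrides the preset.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sources = 2, source_ne = 1000,
                       divergence_years = 1e5, admix_generation = 30,
                       total_generations = 100, selfing_rate = 0.95,
                       recombination_rate = 1e-8, mutation_rate = 1.6e-8,
                       chrom_length = NULL, source_samples = 20,
                       target_samples = 100, segment_length = 1e6,
                       seed = 1, preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (is.null(chrom_length))
    chrom_length <- if (preset == "desk") 2e7 else 1e8
  if (n_sources < 1 || n_sources > 5) stop("n_sources must be in 1..5")
  if (admix_generation >= total_generations)
    stop("admix_generation must precede total_generations")
  if (selfing_rate < 0 || selfing_rate > 1) stop("selfing_rate must be in [0,1]")
  if (source_samples > source_ne || target_samples > source_ne)
    stop("cannot sample more chromosomes than the population holds")
  structure(list(n_sources = n_sources, source_ne = source_ne,
                 divergence_years = divergence_years,
                 admix_generation = admix_generation,
                 total_generations = total_generations,
                 selfing_rate = selfing_rate,
                 recombination_rate = recombination_rate,
                 mutation_rate = mutation_rate,
                 chrom_length = chrom_length,
                 source_samples = source_samples,
                 target_samples = target_samples,
                 segment_length = segment_length, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("admixture simulation: %d source(s) (Ne %d chrom, ",
                     "split %g yr), %.0f Mbp, selfing %.2f, admix gen %d/%d\n"),
              x$n_sources, x$source_ne, x$divergence_years,
              x$chrom_length / 1e6, x$selfing_rate, x$admix_generation,
              x$total_generations))
  invisible(x)
}

# ---- forward tract phase -------------------------------------------------

# a chromosome is a tract list: bp = 0-based segment starts (first 0),
# f = founder chromosome ids per tract
new_founder_pop <- function(n_chrom, first_id) {
  lapply(seq_len(n_chrom), function(i) list(bp = 0, f = first_id + i - 1L))
}

meiosis <- function(c1, c2, k, L, start_first) {
  if (k == 0L) return(if (start_first) c1 else c2)
  cuts <- sort(runif(k, 0, L))
  use1 <- if (start_first) seq_len(k + 1L) %% 2L == 1L
          else seq_len(k + 1L) %% 2L == 0L
  segs <- c(0, cuts)
  ends <- c(cuts, L)
  bp <- vector("list", k + 1L); f <- vector("list", k + 1L)
  for (j in seq_len(k + 1L)) {
    src <- if (use1[j]) c1 else c2
    i1 <- findInterval(segs[j], src$bp)
    i2 <- findInterval(ends[j] - 1e-9, src$bp)
    nb <- src$bp[i1:i2]; nb[1] <- segs[j]
    bp[[j]] <- nb; f[[j]] <- src$f[i1:i2]
  }
  bp <- unlist(bp); f <- unlist(f)
  keep <- c(TRUE, f[-1L] != f[-length(f)])
  list(bp = bp[keep], f = f[keep])
}

next_generation <- function(pop, L, r, selfing) {
  nc <- length(pop)
  n_ind <- nc %/% 2L
  newpop <- vector("list", nc)
  selfed <- runif(n_ind) < selfing
  p1 <- sample.int(n_ind, n_ind, replace = TRUE)
  p2 <- sample.int(n_ind, n_ind, replace = TRUE)
  ks <- rpois(nc, r * L)
  sf <- runif(nc) < 0.5
  for (i in seq_len(n_ind)) {
    a <- p1[i]
    b <- if (selfed[i]) a else p2[i]
    newpop[[2L * i - 1L]] <- meiosis(pop[[2L * a - 1L]], pop[[2L * a]],
                                     ks[2L * i - 1L], L, sf[2L * i - 1L])
    newpop[[2L * i]] <- meiosis(pop[[2L * b - 1L]], pop[[2L * b]],
                                ks[2L * i], L, sf[2L * i])
  }
  newpop
}

forward_phase <- function(cfg) {
  L <- cfg$chrom_length
  r <- cfg$recombination_rate
  ns <- cfg$n_sources
  nc <- cfg$source_ne
  pops <- lapply(seq_len(ns), function(s)
    new_founder_pop(nc, (s - 1L) * nc + 1L))
  target <- NULL
  for (g in seq_len(cfg$total_generations)) {
    pops <- lapply(pops, next_generation, L = L, r = r,
                   selfing = cfg$selfing_rate)
    if (g == cfg$admix_generation) {
      # found the target from whole migrant individuals: each founder is a
      # copy of an individual from a uniformly chosen source population
      # (the way a forward simulator moves migrants); cross-source
      # genomes then arise only through the outcrossing fraction of the
      # selfing reproduction mode
      n_ind <- nc %/% 2L
      src <- sample.int(ns, n_ind, replace = TRUE)
      ind <- sample.int(n_ind, n_ind, replace = TRUE)
      target <- vector("list", nc)
      for (i in seq_len(n_ind)) {
        target[[2L * i - 1L]] <- pops[[src[i]]][[2L * ind[i] - 1L]]
        target[[2L * i]] <- pops[[src[i]]][[2L * ind[i]]]
      }
    } else if (g > cfg$admix_generation) {
      target <- next_generation(target, L, r, cfg$selfing_rate)
    }
  }
  list(sources = pops, target = target)
}

# ---- deep-history coalescent with mutations ------------------------------

# structured coalescent for one genomic segment: tips are the used founder
# chromosomes per source; within-source Kingman (haploid rate
# choose(k,2)/Ne) until the divergence time, then a single ancestral pool.
# Returns mutation positions (0-based within segment) and a logical
# allele matrix tips x mutations.
coalescent_segment <- function(used_by_source, ne, t_div, mu, seg_len) {
  tips <- unlist(used_by_source, use.names = FALSE)
  n_tips <- length(tips)
  tip_index <- seq_len(n_tips)
  groups <- rep(seq_along(used_by_source),
                lengths(used_by_source))
  carriers <- list(); lens <- numeric(0)
  finish_branch <- function(tipset, len) {
    carriers[[length(carriers) + 1L]] <<- tipset
    lens[length(lens) + 1L] <<- len
  }
  # per-source phase
  survivors <- list(); survivor_birth <- numeric(0)
  for (s in seq_along(used_by_source)) {
    lin <- lapply(tip_index[groups == s], function(i) i)
    birth <- rep(0, length(lin))
    t <- 0
    while (length(lin) > 1L) {
      rate <- length(lin) * (length(lin) - 1) / 2 / ne
      t_next <- t + rexp(1, rate)
      if (t_next > t_div) break
      t <- t_next
      ij <- sample.int(length(lin), 2L)
      finish_branch(lin[[ij[1]]], t - birth[ij[1]])
      finish_branch(lin[[ij[2]]], t - birth[ij[2]])
      merged <- c(lin[[ij[1]]], lin[[ij[2]]])
      lin <- lin[-ij]; birth <- birth[-ij]
      lin[[length(lin) + 1L]] <- merged
      birth[length(birth) + 1L] <- t
    }
    survivors <- c(survivors, lin)
    survivor_birth <- c(survivor_birth, birth)
  }
  # ancestral pool from t_div
  lin <- survivors; birth <- survivor_birth
  t <- t_div
  while (length(lin) > 1L) {
    rate <- length(lin) * (length(lin) - 1) / 2 / ne
    t <- t + rexp(1, rate)
    ij <- sample.int(length(lin), 2L)
    finish_branch(lin[[ij[1]]], t - birth[ij[1]])
    finish_branch(lin[[ij[2]]], t - birth[ij[2]])
    merged <- c(lin[[ij[1]]], lin[[ij[2]]])
    lin <- lin[-ij]; birth <- birth[-ij]
    lin[[length(lin) + 1L]] <- merged
    birth[length(birth) + 1L] <- t
  }
  # mutations per terminated branch (the root branch carries none)
  n_mut <- rpois(length(lens), lens * mu * seg_len)
  total <- sum(n_mut)
  if (total == 0L)
    return(list(pos = integer(0),
                alleles = matrix(FALSE, n_tips, 0,
                                 dimnames = list(tips, NULL))))
  pos <- sample.int(seg_len, total, replace = TRUE) - 1L
  alleles <- matrix(FALSE, n_tips, total, dimnames = list(tips, NULL))
  col <- 0L
  for (b in seq_along(n_mut)) {
    if (n_mut[b] == 0L) next
    idx <- col + seq_len(n_mut[b])
    alleles[carriers[[b]], idx] <- TRUE
    col <- col + n_mut[b]
  }
  # collapse position collisions and sort
  ord <- order(pos)
  pos <- pos[ord]; alleles <- alleles[, ord, drop = FALSE]
  dup <- duplicated(pos)
  list(pos = pos[!dup], alleles = alleles[, !dup, drop = FALSE])
}

# ---- simulation driver ---------------------------------------------------

#' Simulate an admixed selfing cohort with exact truth ancestry
#'
#' Three stages: (1) a forward tract simulation of the source populations
#' and of the target population founded by their admixture, with selfing
#' and recombination, in which every chromosome is an exact mosaic of
#' founder chromosomes; (2) a backward structured coalescent per genomic
#' segment that completes the deep genealogical history of the founder
#' chromosomes used by the sampled individuals (pure-drift divergence of
#' the sources from one ancestral population) and places neutral mutations
#' on the genealogy; (3) sampling and genotype extraction, collapsing each
#' sampled individual's two chromosomes to biallelic dosages.  Truth
#' ancestry tracts of every sampled chromosome are returned exactly (each
#' tract's source population is that of the founder chromosome it copies).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A `sim_result` list: `gm` ([genotype_matrix()] of the sampled
#'   individuals, segregating sites only), `tracts` (data.frame `chrom`,
#'   `start`, `end`, `chromosome`, `sample`, `source`; 0-based half-open,
#'   tiling every sampled chromosome), `samples` (data.frame `accession`,
#'   `population`), `heterozygosity` (named per-individual het call
#'   fraction), and `config`.
#' @export
simulate_admixture <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$chrom_length
  ns <- cfg$n_sources
  fw <- forward_phase(cfg)

  # sample individuals (chromosome pairs)
  n_src_ind <- cfg$source_samples %/% 2L
  n_tgt_ind <- cfg$target_samples %/% 2L
  n_ind_pop <- cfg$source_ne %/% 2L
  sampled <- list(); samples <- list()
  for (s in seq_len(ns)) {
    ids <- sort(sample.int(n_ind_pop, n_src_ind))
    for (j in seq_along(ids)) {
      acc <- sprintf("S%d_%02d", s, j)
      sampled[[length(sampled) + 1L]] <-
        list(acc = acc, pop = paste0("source", s),
             chroms = fw$sources[[s]][c(2L * ids[j] - 1L, 2L * ids[j])])
    }
  }
  ids <- sort(sample.int(n_ind_pop, n_tgt_ind))
  for (j in seq_along(ids)) {
    acc <- sprintf("T_%02d", j)
    sampled[[length(sampled) + 1L]] <-
      list(acc = acc, pop = "target",
           chroms = fw$target[c(2L * ids[j] - 1L, 2L * ids[j])])
  }
  accs <- vapply(sampled, `[[`, character(1), "acc")
  pops <- vapply(sampled, `[[`, character(1), "pop")

  founder_source <- function(f) (f - 1L) %/% cfg$source_ne + 1L

  # truth tracts (merge adjacent same-source tracts)
  tracts <- list()
  for (i in seq_along(sampled)) for (h in 1:2) {
    tr <- sampled[[i]]$chroms[[h]]
    src <- founder_source(tr$f)
    keep <- c(TRUE, src[-1L] != src[-length(src)])
    starts <- tr$bp[keep]; srcs <- src[keep]
    tracts[[length(tracts) + 1L]] <- data.frame(
      chrom = "sim1", start = starts, end = c(starts[-1L], L),
      chromosome = paste0(accs[i], c("a", "b")[h]), sample = accs[i],
      source = srcs)
  }
  tracts <- do.call(rbind, tracts)

  # used founders per source across all sampled chromosomes
  used_f <- sort(unique(unlist(lapply(sampled, function(x)
    c(x$chroms[[1]]$f, x$chroms[[2]]$f)))))
  used_by_source <- split(used_f, founder_source(used_f))

  # per-segment coalescent + genotype extraction
  n_seg <- ceiling(L / cfg$segment_length)
  calls_list <- vector("list", n_seg)
  pos_list <- vector("list", n_seg)
  n_chrom_samp <- 2L * length(sampled)
  for (g in seq_len(n_seg)) {
    seg_start <- (g - 1L) * cfg$segment_length
    seg_len <- min(cfg$segment_length, L - seg_start)
    cs <- coalescent_segment(used_by_source, cfg$source_ne,
                             cfg$divergence_years, cfg$mutation_rate,
                             seg_len)
    if (!length(cs$pos)) next
    fmap <- integer(max(used_f)); fmap[used_f] <- seq_along(used_f)
    gpos <- seg_start + cs$pos           # 0-based global
    hap <- matrix(0L, n_chrom_samp, length(gpos))
    for (i in seq_along(sampled)) for (h in 1:2) {
      rows <- fmap[sampled[[i]]$chroms[[h]]$f[
        findInterval(gpos, sampled[[i]]$chroms[[h]]$bp)]]
      hap[2L * (i - 1L) + h, ] <- cs$alleles[cbind(rows, seq_along(gpos))]
    }
    calls_list[[g]] <- hap[seq(1, n_chrom_samp, 2), , drop = FALSE] +
      hap[seq(2, n_chrom_samp, 2), , drop = FALSE]
    pos_list[[g]] <- gpos
  }
  calls <- do.call(cbind, calls_list)
  pos <- unlist(pos_list)
  rownames(calls) <- accs
  # keep segregating sites only
  seg_sites <- colSums(calls) > 0L & colSums(calls) < 2L * nrow(calls)
  calls <- calls[, seg_sites, drop = FALSE]
  pos <- pos[seg_sites]
  het <- rowMeans(calls == 1L)
  gm <- genotype_matrix(calls, rep("sim1", length(pos)), pos + 1L)

  structure(list(gm = gm, tracts = tracts,
                 samples = data.frame(accession = accs, population = pops),
                 heterozygosity = het, config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("simulated cohort: %d accessions (%d source pops), %d sites, %.0f Mbp\n",
              nrow(x$gm$calls), x$config$n_sources, ncol(x$gm$calls),
              x$config$chrom_length / 1e6))
  invisible(x)
}

#' Write simulation outputs to plain-text files
#'
#' @param res a [simulate_admixture()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "cohort.vcf")
  write_vcf(res$gm, vcf, provenance = sprintf("simulate_admixture seed=%d n_sources=%d",
                                              res$config$seed, res$config$n_sources))
  tr <- file.path(dir, "truth_tracts.tsv")
  write.table(res$tracts, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  cf <- file.path(dir, "config.txt")
  writeLines(paste(names(res$config), unlist(res$config), sep = " = "), cf)
  invisible(c(vcf = vcf, tracts = tr, config = cf))
}

#' Collapse truth tracts to window-level majority labels
#'
#' Labels each window of each sampled chromosome (and of each individual,
#' pooling its two chromosomes) with the source population covering the
#' most bp, recording the coverage share of the majority source.
#'
#' @param res a [simulate_admixture()] result (or its `tracts` frame).
#' @param grid a [make_windows()] grid for the simulated chromosome.
#' @return List: `chromosome` (matrix sampled chromosomes x windows),
#'   `individual` (matrix samples x windows), `share` (majority coverage
#'   share, same shape as `individual`).
#' @export
truth_to_windows <- function(res, grid) {
  tracts <- if (inherits(res, "sim_result")) res$tracts else res
  win_overlap <- function(df) {
    # bp of each source in each window
    nw <- nrow(grid)
    srcs <- sort(unique(df$source))
    m <- matrix(0, length(srcs), nw, dimnames = list(srcs, NULL))
    for (k in seq_len(nrow(df))) {
      ov_s <- pmax(grid$start, df$start[k])
      ov_e <- pmin(grid$end, df$end[k])
      ov <- pmax(ov_e - ov_s, 0)
      m[as.character(df$source[k]), ] <-
        m[as.character(df$source[k]), ] + ov
    }
    m
  }
  per_chrom <- split(tracts, tracts$chromosome)
  nw <- nrow(grid)
  cm <- matrix(NA_integer_, length(per_chrom), nw,
               dimnames = list(names(per_chrom), window_names(grid)))
  ov_list <- lapply(per_chrom, win_overlap)
  for (i in seq_along(ov_list)) {
    m <- ov_list[[i]]
    cm[i, ] <- as.integer(rownames(m))[apply(m, 2, which.max)]
  }
  samples <- vapply(per_chrom, function(df) df$sample[1], character(1))
  uniq <- unique(samples)
  im <- matrix(NA_integer_, length(uniq), nw,
               dimnames = list(uniq, window_names(grid)))
  sh <- matrix(NA_real_, length(uniq), nw, dimnames = dimnames(im))
  for (u in uniq) {
    m <- Reduce(`+`, lapply(which(samples == u), function(i) {
      full <- matrix(0, max(tracts$source), nw)
      mm <- ov_list[[i]]
      full[as.integer(rownames(mm)), ] <- mm
      full
    }))
    best <- apply(m, 2, which.max)
    im[u, ] <- as.integer(best)
    sh[u, ] <- m[cbind(best, seq_len(nw))] / colSums(m)
  }
  list(chromosome = cm, individual = im, share = sh)
}

#' Evaluate inference accuracy against simulated truth
#'
#' Runs the accuracy metric of the simulation study: individuals with an
#' overall heterozygous call fraction above `het_filter` are excluded
#' (inconsistent with self-pollinating reproduction), and for each
#' retained target individual each window counts as correct when its
#' inferred AHG label is shared with — or dominated by — an accession of
#' the true (majority) source population in that window.  Accuracy is
#' correct windows over evaluated windows; relabeling of source ids
#' cannot change it because correctness is via population membership.
#'
#' @param fit an [introblocker()] fit on the simulated cohort (built in
#'   semi-supervised mode with the sources prioritized over the target).
#' @param res the [simulate_admixture()] result.
#' @param het_filter heterozygosity exclusion bound (default 0.1).
#' @return List: `accuracy`, `n_retained`, `n_excluded`, `per_individual`
#'   data.frame (`accession`, `correct`, `evaluated`, `accuracy`).
#' @export
evaluate_accuracy <- function(fit, res, het_filter = 0.1) {
  truth <- truth_to_windows(res, fit$grid)
  targets <- res$samples$accession[res$samples$population == "target"]
  retained <- targets[res$heterozygosity[targets] <= het_filter]
  if (!length(retained)) stop("no target individuals pass the het filter")
  src_pop <- res$samples$population
  names(src_pop) <- res$samples$accession
  lab <- fit$labels
  nw <- ncol(lab)
  # which source population(s) share each label in each window
  dom_pop <- src_pop[fit$dominator]      # NA for target-dominated labels
  per <- lapply(retained, function(acc) {
    correct <- 0L; evaluated <- 0L
    for (w in seq_len(nw)) {
      L <- lab[acc, w]
      if (is.na(L)) next
      tru <- paste0("source", truth$individual[acc, w])
      evaluated <- evaluated + 1L
      ok <- (!is.na(dom_pop[L]) && dom_pop[L] == tru)
      if (!ok) {
        sharers <- rownames(lab)[!is.na(lab[, w]) & lab[, w] == L]
        ok <- any(src_pop[sharers] == tru, na.rm = TRUE)
      }
      if (ok) correct <- correct + 1L
    }
    data.frame(accession = acc, correct = correct, evaluated = evaluated,
               accuracy = correct / evaluated)
  })
  per <- do.call(rbind, per)
  list(accuracy = sum(per$correct) / sum(per$evaluated),
       n_retained = length(retained),
       n_excluded = length(targets) - length(retained),
       per_individual = per)
}

#' Run the full simulation-inference-evaluation experiment
#'
#' Convenience wrapper reproducing the validation protocol end to end:
#' simulate a cohort, compute binwise distances, infer AHGs in
#' semi-supervised mode with source populations prioritized over the
#' admixed target, and score the accuracy against the truth tracts.
#'
#' @param n_sources source population count.
#' @param reps replicate simulations (default 10).
#' @param seed base seed; replicate `r` uses
#'   `seed * 1000 + n_sources * 100 + r`.
#' @param window_size analysis window (default 5 Mbp).
#' @param cfg_args further arguments passed to [sim_config()].
#' @return Data.frame with one row per replicate: `n_sources`, `rep`,
#'   `seed`, `accuracy`, `n_retained`.
#' @export
simulation_accuracy <- function(n_sources, reps = 10, seed = 1,
                                window_size = 5e6, cfg_args = list()) {
  res <- lapply(seq_len(reps), function(r) {
    rep_seed <- seed * 1000L + n_sources * 100L + r
    cfg <- do.call(sim_config, c(list(n_sources = n_sources,
                                      seed = rep_seed), cfg_args))
    sim <- simulate_admixture(cfg)
    grid <- make_windows(c(sim1 = cfg$chrom_length), window_size)
    groups <- group_assignment(
      setNames(sim$samples$population, sim$samples$accession),
      c(paste0("source", seq_len(n_sources)), "target"))
    wd <- pairwise_window_distances(sim$gm, grid)
    fit <- introblocker(wd, groups = groups, seed = rep_seed)
    ev <- evaluate_accuracy(fit, sim)
    data.frame(n_sources = n_sources, rep = r, seed = rep_seed,
               accuracy = ev$accuracy, n_retained = ev$n_retained)
  })
  do.call(rbind, res)
}
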