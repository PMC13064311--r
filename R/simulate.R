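# ---- internal state helpers ---------------------------------------------
# A population state is a list:
#   haps   : list per chromosome of raw matrix (2N x S), 0/1 alleles
#   pos    : list per chromosome of integer positions
#   fixed  : list per chromosome of positions fixed for the derived allele
#   deme   : integer deme id per individual (0-based)
#   famid  : integer parent-pair id per individual
#   kinship: pedigree kinship matrix (or NULL)
#   ped_f  : pedigree inbreeding coefficient per individual

empty_state <- function(n_ind, n_chrom, n_demes = 1, deme = NULL) {
  list(haps = replicate(n_chrom, matrix(as.raw(0), 2 * n_ind, 0), simplify = FALSE),
       pos = replicate(n_chrom, integer(0), simplify = FALSE),
       fixed = replicate(n_chrom, integer(0), simplify = FALSE),
       deme = if (is.null(deme)) rep(0L, n_ind) else as.integer(deme),
       famid = -seq_len(n_ind),
       kinship = diag(0.5, n_ind),
       ped_f = rep(0, n_ind))
}

# draw the ancestral population at neutral mutation-drift equilibrium:
# site frequencies from the standard neutral SFS (P(i copies) ~ 1/i),
# alleles assigned at linkage equilibrium (LD then builds up during burn-in)
equilibrium_state <- function(n_ind, n_chrom, chrom_len, mu) {
  st <- empty_state(n_ind, n_chrom)
  nh <- 2L * n_ind
  theta <- 4 * n_ind * mu
  wt <- 1 / seq_len(nh - 1)
  for (c in seq_len(n_chrom)) {
    es <- theta * chrom_len[c] * sum(wt)
    S <- rpois(1, es)
    if (S == 0) next
    pos <- sample.int(chrom_len[c], S)
    cnt <- sample.int(nh - 1, S, replace = TRUE, prob = wt)
    m <- matrix(as.raw(0), nh, S)
    for (j in seq_len(S)) m[sample.int(nh, cnt[j]), j] <- as.raw(1)
    st$haps[[c]] <- m
    st$pos[[c]] <- as.integer(pos)
  }
  st
}

run_wf <- function(state, n_gens, n_out, chrom_len, mu, rec, mig = 0, sib = 0,
                   sweep = NULL, track_ped = TRUE) {
  if (n_gens == 0 && identical(as.integer(n_out), as.integer(tabulate(state$deme + 1L))))
    return(state)
  n_gens <- max(n_gens, 1L)  # a size change alone still takes one generation
  sw_chrom <- -1L; sw_pos <- 0; sw_s <- 0; sw_h <- 0.5
  if (!is.null(sweep)) {
    sw_chrom <- sweep$chrom - 1L; sw_pos <- sweep$pos; sw_s <- sweep$s
    sw_h <- if (is.null(sweep$h)) 0.5 else sweep$h
  }
  kin <- if (track_ped && !is.null(state$kinship)) state$kinship else matrix(0, 0, 0)
  res <- wf_evolve_cpp(state$haps, state$pos, as.numeric(chrom_len), state$fixed,
                       state$deme, as.integer(n_out), as.integer(n_gens),
                       mu, rec, mig, sib, sw_chrom, sw_pos, sw_s, sw_h,
                       track_ped, kin, state$famid)
  list(haps = res$haps, pos = lapply(res$pos, as.integer),
       fixed = lapply(res$fixed, as.integer),
       deme = res$deme, famid = res$famid,
       kinship = if (track_ped) res$kinship else NULL,
       ped_f = res$ped_f, sweep_freq = res$sweep_freq)
}

inject_sweep <- function(state, chrom, pos) {
  while (pos %in% c(state$pos[[chrom]], state$fixed[[chrom]])) pos <- pos + 1L
  m <- state$haps[[chrom]]
  col <- matrix(as.raw(0), nrow(m), 1)
  col[sample.int(nrow(m), 1), 1] <- as.raw(1)
  state$haps[[chrom]] <- cbind(m, col)
  state$pos[[chrom]] <- c(state$pos[[chrom]], as.integer(pos))
  state$sweep_pos_actual <- pos
  state
}

# ---- configuration -------------------------------------------------------

#' Simulation configuration
#'
#' Describes a rooted population tree evolved forward in time under the
#' Wright-Fisher model with mutation, recombination, optional bottlenecks,
#' biased full-sib mating and a hard selective sweep.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (recycled).
#' @param mutation_rate per bp per generation.
#' @param recombination_rate per bp per generation.
#' @param n_ancestral diploid size of the root population.
#' @param burn_in generations of root evolution before the first split.
#' @param init "equilibrium" (neutral SFS start) or "monomorphic".
#' @param populations list of population descriptors, each a list with
#'   \code{name}, \code{N} (diploid size), \code{t_start} (generations before
#'   present at which it splits from its parent), \code{parent} (name or
#'   "ancestral"), and optionally \code{sample_size} (default 0, internal
#'   node), \code{sib_mating} (probability an offspring's parents are full
#'   sibs, default 0), \code{bottleneck} (list \code{size}, \code{start},
#'   \code{end} in generations before present) and \code{sweep} (list
#'   \code{chrom}, \code{pos}, \code{s}, \code{h}, \code{start},
#'   \code{min_freq}, \code{max_retries}).
#' @param missing_prob per-call missingness probability applied to the output
#'   genotype matrix (default 0).
#' @param error_prob per-call symmetric genotype error probability (default 0).
#' @param seed optional RNG seed recorded in the output.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_chromosomes = 1, chrom_length = 1e6,
                       mutation_rate = 1e-8, recombination_rate = 1e-8,
                       n_ancestral = 100, burn_in = 1000, init = "equilibrium",
                       populations = list(), missing_prob = 0, error_prob = 0,
                       seed = NULL) {
  stopifnot(mutation_rate >= 0, recombination_rate >= 0, n_ancestral >= 2,
            burn_in >= 0, missing_prob >= 0, error_prob >= 0,
            init %in% c("equilibrium", "monomorphic"))
  chrom_length <- rep(as.integer(chrom_length), length.out = n_chromosomes)
  populations <- lapply(populations, function(p) {
    if (is.null(p$parent)) p$parent <- "ancestral"
    if (is.null(p$sample_size)) p$sample_size <- 0
    p
  })
  names(populations) <- vapply(populations, `[[`, "", "name")
  for (p in populations) {
    stopifnot(p$N >= 2, p$t_start >= 0)
    if (p$sample_size > p$N) stop("sample size exceeds population size for ", p$name)
    if (!is.null(p$sweep)) {
      stopifnot(p$sweep$s >= 0, p$sweep$chrom <= n_chromosomes,
                p$sweep$pos <= chrom_length[p$sweep$chrom], p$sweep$start <= p$t_start)
    }
    par <- if (is.null(p$parent)) "ancestral" else p$parent
    if (par != "ancestral") {
      if (!par %in% names(populations)) stop("unknown parent: ", par)
      if (populations[[par]]$t_start < p$t_start)
        stop("parent ", par, " starts after child ", p$name)
    }
  }
  structure(list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                 mutation_rate = mutation_rate, recombination_rate = recombination_rate,
                 n_ancestral = n_ancestral, burn_in = burn_in, init = init,
                 populations = populations, missing_prob = missing_prob,
                 error_prob = error_prob, seed = seed),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [sim_config()].
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sim_config, y)
}

# population size at time t (generations before present), honouring bottleneck
size_at <- function(node, t) {
  if (!is.null(node$bottleneck) &&
      t <= node$bottleneck$start && t > node$bottleneck$end)
    return(node$bottleneck$size)
  node$N
}

sib_of <- function(node) if (is.null(node$sib_mating)) 0 else node$sib_mating

# evolve one population from time `from` down to `to`, cutting at bottleneck
# boundaries and handling the sweep (with bounded retries)
evolve_node <- function(state, node, from, to, cfg) {
  cuts <- sort(unique(c(
    to, from,
    if (!is.null(node$bottleneck)) c(node$bottleneck$start, node$bottleneck$end),
    if (!is.null(node$sweep)) node$sweep$start)), decreasing = TRUE)
  cuts <- cuts[cuts <= from & cuts >= to]
  for (i in seq_len(length(cuts) - 1)) {
    t1 <- cuts[i]; t2 <- cuts[i + 1]
    sweep_pos_keep <- state$sweep_pos_actual
    # the sweep segment is the one starting exactly at the sweep's start time
    # (the cut list always contains that boundary)
    sweep_now <- !is.null(node$sweep) && t1 == node$sweep$start && t2 < t1
    if (sweep_now) {
      min_freq <- if (is.null(node$sweep$min_freq)) 0.8 else node$sweep$min_freq
      retries <- if (is.null(node$sweep$max_retries)) 20 else node$sweep$max_retries
      saved <- state
      for (r in seq_len(retries + 1)) {
        st <- inject_sweep(saved, node$sweep$chrom, node$sweep$pos)
        sw <- list(chrom = node$sweep$chrom, pos = st$sweep_pos_actual,
                   s = node$sweep$s, h = node$sweep$h)
        st <- run_wf(st, t1 - t2, size_at(node, t1), cfg$chrom_length,
                     cfg$mutation_rate, cfg$recombination_rate,
                     sib = sib_of(node), sweep = sw)
        st$sweep_pos_actual <- sw$pos
        if (!is.na(st$sweep_freq) && st$sweep_freq >= min_freq) break
        if (r == retries + 1)
          stop("sweep allele failed to reach frequency ", min_freq,
               " within the retry budget")
      }
      state <- st
    } else {
      state <- run_wf(state, t1 - t2, size_at(node, t1), cfg$chrom_length,
                      cfg$mutation_rate, cfg$recombination_rate, sib = sib_of(node))
      state$sweep_pos_actual <- sweep_pos_keep
    }
  }
  state
}

# ---- the simulator -------------------------------------------------------

#' Forward Wright-Fisher simulation of a population tree
#'
#' Deterministic given the seed. Returns phased haplotypes, the genotype
#' matrix, the population map and a truth record (sweep interval, per-sample
#' pedigree inbreeding, achieved sweep frequency); the ancestral allele is
#' known by construction (simulation starts from ancestral alleles, so 0/ref
#' is ancestral at every site).
#'
#' @param config a [sim_config()].
#' @return list with \code{hs} ([haplo_set()]), \code{gm} ([geno_matrix()]),
#'   \code{pmap} ([pop_map()]), \code{truth} (list) and \code{config}.
#' @export
simulate_wf <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  pops <- cfg$populations
  if (!length(pops)) stop("no populations configured")
  t_root <- max(vapply(pops, `[[`, 0, "t_start"))
  # ancestral root
  state <- if (cfg$init == "equilibrium")
    equilibrium_state(cfg$n_ancestral, cfg$n_chromosomes, cfg$chrom_length,
                      cfg$mutation_rate)
  else empty_state(cfg$n_ancestral, cfg$n_chromosomes)
  if (cfg$burn_in > 0)
    state <- run_wf(state, cfg$burn_in, cfg$n_ancestral, cfg$chrom_length,
                    cfg$mutation_rate, cfg$recombination_rate)

  samples <- list()   # per sampled population: list(state, ids)
  truth_sweep <- NULL

  descend <- function(state, node_name, node, t_now) {
    kids <- names(pops)[vapply(pops, function(p) p$parent == node_name, TRUE)]
    kids <- kids[order(-vapply(pops[kids], `[[`, 0, "t_start"))]
    for (kid in kids) {
      tk <- pops[[kid]]$t_start
      if (t_now > tk) {
        state <- evolve_node(state, node, t_now, tk, cfg)
        t_now <- tk
      }
      kid_state <- run_wf(state, 1, size_at(pops[[kid]], tk), cfg$chrom_length,
                          cfg$mutation_rate, cfg$recombination_rate)
      # pedigree inbreeding is reported relative to the population's founders
      kid_state$kinship <- diag(0.5, length(kid_state$deme))
      kid_state$ped_f <- rep(0, length(kid_state$deme))
      descend(kid_state, kid, pops[[kid]], max(t_now - 1, 0))
    }
    if (!is.null(node) && !is.null(node$sample_size) && node$sample_size > 0) {
      state <- evolve_node(state, node, t_now, 0, cfg)
      n_ind <- length(state$deme)
      ids <- sort(sample.int(n_ind, node$sample_size))
      samples[[node_name]] <<- list(state = state, ids = ids)
      if (!is.null(node$sweep)) {
        g <- node$sweep$start
        # physical footprint of the swept haplotype: recombination erodes it
        # over ~1/(2 r g) bp on each flank (g generations since sweep start)
        halfw <- min(round(1 / (2 * max(cfg$recombination_rate, 1e-12) * g)),
                     500000,
                     cfg$chrom_length[node$sweep$chrom] %/% 2)
        pos_actual <- if (!is.null(state$sweep_pos_actual)) state$sweep_pos_actual else node$sweep$pos
        truth_sweep <<- list(
          population = node_name, chrom = node$sweep$chrom, pos = pos_actual,
          interval = c(max(1, pos_actual - halfw),
                       min(cfg$chrom_length[node$sweep$chrom], pos_actual + halfw)),
          achieved_freq = state$sweep_freq)
      }
    }
    invisible(NULL)
  }
  # root may have multiple children splitting at t_root or later
  root_node <- list(name = "ancestral", N = cfg$n_ancestral, sample_size = 0)
  descend(state, "ancestral", root_node, t_root)
  if (!length(samples)) stop("no population has sample_size > 0")
  assemble_simulation(samples, truth_sweep, cfg)
}

assemble_simulation <- function(samples, truth_sweep, cfg) {
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  pop_names <- names(samples)
  sample_names <- unlist(lapply(pop_names, function(pn)
    sprintf("%s_%02d", pn, seq_along(samples[[pn]]$ids))))
  n_tot <- length(sample_names)
  hap_blocks <- list()
  var_blocks <- list()
  for (c in seq_len(cfg$n_chromosomes)) {
    union_pos <- sort(unique(unlist(lapply(samples, function(sl)
      c(sl$state$pos[[c]], sl$state$fixed[[c]])))))
    if (!length(union_pos)) next
    H <- matrix(0L, 2L * n_tot, length(union_pos))
    row0 <- 0L
    for (pn in pop_names) {
      sl <- samples[[pn]]
      rows <- as.vector(rbind(2L * sl$ids - 1L, 2L * sl$ids))
      hsub <- sl$state$haps[[c]][rows, , drop = FALSE]
      at <- match(sl$state$pos[[c]], union_pos)
      block <- matrix(0L, length(rows), length(union_pos))
      if (length(at)) block[, at] <- as.integer(hsub != as.raw(0))
      fx <- match(sl$state$fixed[[c]], union_pos)
      if (length(fx)) block[, fx] <- 1L
      H[row0 + seq_along(rows), ] <- block
      row0 <- row0 + length(rows)
    }
    cs <- colSums(H)
    seg <- cs > 0 & cs < nrow(H)
    if (!any(seg)) next
    hap_blocks[[length(hap_blocks) + 1]] <- H[, seg, drop = FALSE]
    var_blocks[[length(var_blocks) + 1]] <- data.frame(
      chrom = chrom_names[c], pos = union_pos[seg], stringsAsFactors = FALSE)
  }
  if (!length(hap_blocks)) {
    variants <- data.frame(chrom = character(), pos = integer(), ref = character(),
                           alt = character(), ancestral = character(),
                           stringsAsFactors = FALSE)
    haps <- matrix(0L, 2L * n_tot, 0)
  } else {
    haps <- do.call(cbind, hap_blocks)
    variants <- do.call(rbind, var_blocks)
    bases <- c("A", "C", "G", "T")
    variants$ref <- sample(bases, nrow(variants), replace = TRUE)
    variants$alt <- vapply(variants$ref, function(r)
      sample(setdiff(bases, r), 1), "")
    variants$ancestral <- "ref"
    variants$id <- paste0(variants$chrom, "_", variants$pos)
  }
  pmap <- pop_map(sample_names, rep(pop_names, vapply(samples, function(s)
    length(s$ids), 0L)))
  hs <- haplo_set(haps, variants, sample_names)
  gm <- hs_to_gm(hs)
  # optional genotyping noise on the genotype matrix only
  if (cfg$error_prob > 0 && n_variants(gm) > 0) {
    flip <- which(runif(length(gm$calls)) < cfg$error_prob)
    if (length(flip)) {
      cur <- gm$calls[flip]
      gm$calls[flip] <- ifelse(is.na(cur), cur,
                               (cur + 1L + (runif(length(flip)) < 0.5)) %% 3L)
    }
  }
  if (cfg$missing_prob > 0 && n_variants(gm) > 0) {
    drop <- which(runif(length(gm$calls)) < cfg$missing_prob)
    gm$calls[drop] <- NA_integer_
  }
  ped_f <- unlist(lapply(pop_names, function(pn)
    samples[[pn]]$state$ped_f[samples[[pn]]$ids]))
  names(ped_f) <- sample_names
  truth <- list(sweep = truth_sweep,
                ped_f = ped_f,
                ancestral = "ref",
                seed = cfg$seed)
  if (!is.null(truth_sweep)) truth$sweep$chrom_name <- chrom_names[truth_sweep$chrom]
  list(hs = hs, gm = gm, pmap = pmap, truth = truth, config = cfg)
}

#' Two-deme island-model simulation
#'
#' Symmetric migration between two demes of equal diploid size, neutral
#' mutation, starting monomorphic. Used for calibration checks of the
#' FST estimator.
#'
#' @param n_diploid diploid size of each deme.
#' @param migration_rate per-gene per-generation probability of drawing a
#'   parent from the other deme.
#' @param n_gens generations to run.
#' @param n_sample diploid samples drawn from each deme.
#' @param chrom_length chromosome length (bp).
#' @param mutation_rate,recombination_rate per bp per generation.
#' @return list with \code{gm} and \code{pmap} (populations "deme1"/"deme2").
#' @export
simulate_island <- function(n_diploid = 200, migration_rate = 0.00125,
                            n_gens = 2000, n_sample = 20, chrom_length = 1e6,
                            mutation_rate = 1e-7, recombination_rate = 1e-7) {
  st <- empty_state(2 * n_diploid, 1,
                    deme = rep(0:1, each = n_diploid))
  st$kinship <- NULL
  st <- run_wf(st, n_gens, c(n_diploid, n_diploid), chrom_length,
               mutation_rate, recombination_rate, mig = migration_rate,
               track_ped = FALSE)
  ids <- c(sample(which(st$deme == 0L), n_sample), sample(which(st$deme == 1L), n_sample))
  samples <- list(deme1 = list(state = st, ids = ids[seq_len(n_sample)]),
                  deme2 = list(state = st, ids = ids[n_sample + seq_len(n_sample)]))
  cfg <- sim_config(n_chromosomes = 1, chrom_length = chrom_length,
                    mutation_rate = mutation_rate, recombination_rate = 0,
                    n_ancestral = 2 * n_diploid, burn_in = 0)
  out <- assemble_simulation(samples, NULL, cfg)
  list(gm = out$gm, pmap = out$pmap)
}

#' Six-population study-design fixture
#'
#' Emulates a resequencing study design with six chicken-like populations:
#' a high-diversity wild outgroup, a focal dual-purpose population carrying a
#' hard selective sweep at a known locus, two intermediate commercial
#' broiler-like lines, and two strongly bottlenecked, partially sib-mated
#' layer-like lines with long runs of homozygosity and slow LD decay.
#' Sample sizes are 49 (focal), 25 (outgroup), 20/20 (broilers) and 23/24
#' (layers). The genome is eight chromosomes of 3 Mb with scaled-up per-bp
#' mutation and recombination rates, so orderings (not absolute values) of
#' the study statistics are reproduced at desk scale.
#'
#' @param seed RNG seed.
#' @param out_prefix if non-NULL, write \code{<prefix>.vcf},
#'   \code{<prefix>.popmap.tsv} and \code{<prefix>.truth.json}.
#' @return as [simulate_wf()].
#' @export
emulate_study <- function(seed, out_prefix = NULL) {
  cfg <- sim_config(
    n_chromosomes = 8, chrom_length = 3e6,
    mutation_rate = 3e-7, recombination_rate = 5e-8,
    n_ancestral = 125, burn_in = 250, init = "equilibrium",
    populations = list(
      list(name = "junglefowl", parent = "ancestral", t_start = 280, N = 125,
           sample_size = 25),
      list(name = "domestic", parent = "ancestral", t_start = 280, N = 80),
      list(name = "dual_purpose", parent = "domestic", t_start = 200, N = 100,
           sample_size = 49,
           sweep = list(chrom = 2, pos = 1500000, s = 3, h = 0.5, start = 12,
                        min_freq = 0.9, max_retries = 20)),
      list(name = "commercial", parent = "domestic", t_start = 200, N = 80),
      list(name = "broiler_a", parent = "commercial", t_start = 150, N = 60,
           sample_size = 20, sib_mating = 0.02),
      list(name = "broiler_b", parent = "commercial", t_start = 150, N = 60,
           sample_size = 20, sib_mating = 0.02),
      list(name = "layer_anc", parent = "commercial", t_start = 150, N = 60),
      list(name = "layer_brown", parent = "layer_anc", t_start = 100, N = 60,
           sample_size = 23, sib_mating = 0.3,
           bottleneck = list(size = 12, start = 20, end = 3)),
      list(name = "layer_white", parent = "layer_anc", t_start = 100, N = 60,
           sample_size = 24, sib_mating = 0.3,
           bottleneck = list(size = 12, start = 20, end = 3))),
    seed = seed)
  res <- simulate_wf(cfg)
  if (!is.null(out_prefix)) {
    write_dataset(res$gm, res$pmap, out_prefix, hs = res$hs)
    jsonlite::write_json(res$truth, paste0(out_prefix, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
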