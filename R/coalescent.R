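#' Simulation parameters
#'
#' Parameters shared by all generators: sample size per population, region
#' length and per-generation mutation/recombination rates. Defaults follow
#' common practice for human data (mu = 1.2e-8 per bp per generation,
#' r = 1e-8 per bp per generation, 20 kb regions).
#'
#' @param n_haplotypes_per_pop even positive integer (diploid pairing).
#' @param region_length region length in bp (>= 1).
#' @param mutation_rate per-bp per-generation mutation rate (>= 0).
#' @param recombination_rate per-bp per-generation recombination rate (>= 0).
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_haplotypes_per_pop = 60L, region_length = 20000L,
                       mutation_rate = 1.2e-8, recombination_rate = 1e-8) {
  n <- as.integer(n_haplotypes_per_pop)
  if (n < 2L || n %% 2L != 0L)
    stop("n_haplotypes_per_pop must be even and >= 2 (diploid pairing)")
  if (region_length < 1) stop("region_length must be >= 1")
  if (mutation_rate < 0 || recombination_rate < 0)
    stop("rates must be >= 0")
  structure(list(n_haplotypes_per_pop = n,
                 region_length = as.integer(region_length),
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate),
            class = "sim_params")
}

#' Demographic model
#'
#' Piecewise-constant population sizes per population plus population split
#' events (looking backwards in time, lineages of `derived` move into
#' `ancestral` at `time`). Times are in generations before present; sizes
#' are diploid effective sizes.
#'
#' @param populations character vector of population labels.
#' @param epochs named list (one entry per population) of data.frames with
#'   columns `time` (epoch start, generations ago; first row must be 0,
#'   strictly increasing) and `size` (> 0).
#' @param splits `NULL` for a single population, else a data.frame with
#'   columns `time`, `derived`, `ancestral`; every population must reach a
#'   single common ancestor through the splits.
#' @return a `demography_model` list.
#' @export
demography_model <- function(populations, epochs, splits = NULL) {
  populations <- as.character(populations)
  if (!all(populations %in% names(epochs)))
    stop("every population needs an epochs entry")
  for (p in populations) {
    e <- epochs[[p]]
    if (e$time[1] != 0 || any(diff(e$time) <= 0))
      stop("epoch times for ", p, " must start at 0 and increase strictly")
    if (any(e$size <= 0)) stop("population sizes must be > 0")
  }
  if (length(populations) > 1L) {
    if (is.null(splits) || nrow(splits) < length(populations) - 1L)
      stop("populations never coalesce: missing split events")
    # union-find over split events: all populations must join one root
    anc <- stats::setNames(populations, populations)
    find <- function(x) { while (anc[[x]] != x) x <- anc[[x]]; x }
    sp <- splits[order(splits$time), , drop = FALSE]
    for (i in seq_len(nrow(sp))) {
      a <- find(sp$derived[i]); b <- find(sp$ancestral[i])
      if (a == b) stop("split ", i, " merges an already-merged population")
      anc[[a]] <- b
    }
    roots <- unique(vapply(populations, find, ""))
    if (length(roots) != 1L)
      stop("populations never coalesce under the given splits")
    splits <- sp
  }
  structure(list(populations = populations, epochs = epochs,
                 splits = splits),
            class = "demography_model")
}

#' Single-population constant-size model
#'
#' @param size diploid effective population size.
#' @param label population label.
#' @return a `demography_model`.
#' @export
constant_demography <- function(size = 10000, label = "pop1") {
  demography_model(label,
                   stats::setNames(list(data.frame(time = 0, size = size)),
                                   label))
}

#' Default three-population demography
#'
#' African population at constant size with an out-of-Africa bottleneck and
#' recovery for the two non-African populations, read from the editable
#' config shipped with the package (`inst/extdata/demography_default.tsv`).
#'
#' @param path override for the demography config file.
#' @return a `demography_model` with populations YRI, CEU and CHBJPT.
#' @export
default_demography <- function(path = system.file(
    "extdata", "demography_default.tsv", package = "sweepscan")) {
  read_demography(path)
}

#' Read a demography config file
#'
#' Tab-separated with columns `record` (`epoch` or `split`), `population`,
#' `time`, `size` (epochs) and `ancestral` (splits).
#'
#' @param path file path.
#' @return a `demography_model`.
#' @export
read_demography <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  ep <- d[d$record == "epoch", , drop = FALSE]
  sp <- d[d$record == "split", , drop = FALSE]
  pops <- unique(ep$population)
  epochs <- lapply(split(ep, ep$population), function(x)
    data.frame(time = x$time, size = x$size)[order(x$time), ])
  splits <- if (nrow(sp)) {
    data.frame(time = sp$time, derived = sp$population,
               ancestral = sp$ancestral, stringsAsFactors = FALSE)
  }
  demography_model(pops, epochs[pops], splits)
}

# diploid size of `pop` at time t (generations ago)
.size_at <- function(demography, pop, t) {
  e <- demography$epochs[[pop]]
  e$size[findInterval(t, e$time)]
}

# Structured Kingman coalescent over piecewise-constant sizes and splits.
# `lineages`: data.frame(id, pop, node_time, entry_time) — lineages become
# available for coalescence at entry_time; their branch starts at node_time.
# Returns list(parent, time) vectors indexed by node id (vectors are grown
# past the input ids for internal nodes) plus the root id.
.coalesce <- function(lineages, demography, max_id) {
  n_extra <- nrow(lineages)  # at most n-1 internal nodes
  parent <- rep(NA_integer_, max_id + n_extra)
  ntime <- rep(NA_real_, max_id + n_extra)
  ntime[lineages$id] <- lineages$node_time
  next_id <- max_id + 1L

  # boundary times: epoch changes, splits, pending entries
  btimes <- sort(unique(c(
    unlist(lapply(demography$epochs, function(e) e$time)),
    if (!is.null(demography$splits)) demography$splits$time,
    lineages$entry_time)))

  # resolve the population a lineage belongs to at time t (apply past splits)
  pop_at <- function(pop, t) {
    sp <- demography$splits
    if (is.null(sp)) return(pop)
    for (i in seq_len(nrow(sp)))
      if (sp$time[i] <= t && pop == sp$derived[i]) pop <- sp$ancestral[i]
    pop
  }

  t <- 0
  ord <- order(lineages$entry_time)
  pending <- lineages[ord, , drop = FALSE]
  active_id <- integer(0); active_pop <- character(0)

  admit <- function() {
    while (nrow(pending) && pending$entry_time[1] <= t) {
      active_id <<- c(active_id, pending$id[1])
      active_pop <<- c(active_pop, pop_at(pending$pop[1], t))
      pending <<- pending[-1, , drop = FALSE]
    }
  }
  admit()

  while (length(active_id) + nrow(pending) > 1L) {
    ks <- table(active_pop)
    sizes <- vapply(names(ks), function(p) .size_at(demography, p, t), 0)
    rates <- as.numeric(ks) * (as.numeric(ks) - 1) / 2 / (2 * sizes)
    rtot <- sum(rates)
    nb <- btimes[btimes > t]
    b <- if (length(nb)) nb[1] else Inf
    if (rtot <= 0) {
      if (!is.finite(b))
        stop("configuration error: lineages can never coalesce")
      t <- b
    } else {
      dt <- stats::rexp(1, rtot)
      if (t + dt >= b && is.finite(b)) {
        t <- b
      } else {
        t <- t + dt
        p <- names(ks)[sample.int(length(ks), 1L, prob = rates)]
        in_p <- which(active_pop == p)
        pair <- in_p[sample.int(length(in_p), 2L)]
        node <- next_id; next_id <- next_id + 1L
        ntime[node] <- t
        parent[active_id[pair]] <- node
        active_id <- c(active_id[-pair], node)
        active_pop <- c(active_pop[-pair], p)
        next
      }
    }
    # at a boundary: apply splits due at exactly t, admit pending lineages
    sp <- demography$splits
    if (!is.null(sp)) {
      for (i in which(sp$time == t))
        active_pop[active_pop == sp$derived[i]] <- sp$ancestral[i]
    }
    admit()
  }
  list(parent = parent[seq_len(next_id - 1L)],
       time = ntime[seq_len(next_id - 1L)],
       root = active_id[1])
}

# leaf sets (integer vectors of leaf ids) for every node of a tree given by
# parent/time arrays; relies on children having smaller ids than parents
# among internal nodes, and on leaves being 1..n_leaves.
.leaf_sets <- function(parent, n_leaves) {
  n_nodes <- length(parent)
  sets <- vector("list", n_nodes)
  for (i in seq_len(n_leaves)) sets[[i]] <- i
  for (i in seq_len(n_nodes)) {
    p <- parent[i]
    if (!is.na(p)) sets[[p]] <- c(sets[[p]], sets[[i]])
  }
  sets
}

# drop infinite-sites mutations on a tree for a block [start, end] (bp);
# returns list(positions, carriers = list of leaf-id vectors)
.drop_mutations <- function(tree, n_leaves, mu, start, end) {
  blen <- tree$time[tree$parent] - tree$time
  blen[is.na(blen)] <- 0       # root
  total <- sum(blen)
  width <- end - start + 1
  m <- stats::rpois(1, mu * width * total)
  m <- min(m, width)           # infinite sites on an integer grid
  if (m == 0L)
    return(list(positions = integer(0), carriers = list()))
  branch <- sample.int(length(blen), m, replace = TRUE, prob = blen)
  pos <- start - 1L + sample.int(width, m)   # unique by construction
  ord <- order(pos)
  sets <- .leaf_sets(tree$parent, n_leaves)
  list(positions = as.integer(pos[ord]),
       carriers = lapply(branch[ord], function(b) sets[[b]]))
}

# assemble a haplotype_matrix from per-site carrier lists
.build_matrix <- function(n_hap, positions, carriers, demography, params,
                          pop_of_hap) {
  ord <- order(positions)
  positions <- positions[ord]; carriers <- carriers[ord]
  m <- matrix(0L, nrow = n_hap, ncol = length(positions))
  for (j in seq_along(carriers)) m[carriers[[j]], j] <- 1L
  # drop sites fixed derived in nobody/everybody? keep: fixed sites can
  # arise under sweeps (DAF 1) and are legitimate rows of a VCF
  pops <- demography$populations
  samples <- unlist(lapply(pops, function(p)
    rep(sprintf("%s_s%03d", p, seq_len(sum(pop_of_hap == p) / 2)),
        each = 2)))
  sm <- data.frame(haplotype = seq_len(n_hap), sample = samples,
                   population = pop_of_hap, stringsAsFactors = FALSE)
  nts <- c("A", "C", "G", "T")
  anc <- sample(nts, length(positions), replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(nts, a), 1L), "")
  haplotype_matrix(m, positions, sm,
                   polarized = rep(TRUE, length(positions)),
                   region = c(1L, params$region_length),
                   anc_allele = anc, der_allele = unname(der))
}

# number of quasi-independent recombination blocks for a region: one block
# per ~10 units of scaled recombination rate rho = 4*Nref*r*L, capped
.n_blocks <- function(params, demography) {
  nref <- demography$epochs[[demography$populations[1]]]$size[1]
  rho <- 4 * nref * params$recombination_rate * params$region_length
  max(1L, min(100L, as.integer(round(rho / 10))))
}

#' Simulate a neutral dataset
#'
#' Coalescent simulation under the given demography with infinite-sites
#' mutation. Recombination is approximated by simulating quasi-independent
#' genealogies for contiguous blocks of roughly 10 units of scaled
#' recombination rate each (an `ms`-style independent-loci approximation;
#' see the methods vignette). Allele 0 is the true ancestral state.
#'
#' @param params a [sim_params()] object.
#' @param demography a [demography_model()].
#' @param seed integer seed; identical params + seed give identical output.
#' @return a [haplotype_matrix()] containing all populations.
#' @export
simulate_neutral <- function(params, demography, seed) {
  set.seed(seed)
  pops <- demography$populations
  n_per <- params$n_haplotypes_per_pop
  n_hap <- n_per * length(pops)
  pop_of_hap <- rep(pops, each = n_per)
  lineages <- data.frame(id = seq_len(n_hap), pop = pop_of_hap,
                         node_time = 0, entry_time = 0,
                         stringsAsFactors = FALSE)
  nb <- .n_blocks(params, demography)
  bounds <- unique(as.integer(round(seq(1, params$region_length + 1,
                                        length.out = nb + 1))))
  positions <- integer(0); carriers <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    tree <- .coalesce(lineages, demography, n_hap)
    mut <- .drop_mutations(tree, n_hap, params$mutation_rate,
                           bounds[b], bounds[b + 1L] - 1L)
    positions <- c(positions, mut$positions)
    carriers <- c(carriers, mut$carriers)
  }
  .build_matrix(n_hap, positions, carriers, demography, params, pop_of_hap)
}

#' Sweep model
#'
#' A hard selective sweep on a new derived allele in one population.
#'
#' @param position focal variant position (bp within the region).
#' @param selection_coefficient s > 0 (dimensionless).
#' @param target_daf frequency the derived allele reached, in (0, 1].
#' @param onset_time generations ago at which the sweep ended (the derived
#'   class' common ancestor is at most this old).
#' @param population label of the swept population (default: first).
#' @return a `sweep_model` list.
#' @export
sweep_model <- function(position = 10000L, selection_coefficient = 0.05,
                        target_daf = 0.8, onset_time = 1000,
                        population = NULL) {
  if (selection_coefficient <= 0)
    stop("selection_coefficient must be > 0 (s = 0 is the neutral model; ",
         "use simulate_neutral)")
  if (target_daf <= 0 || target_daf > 1)
    stop("target_daf must be in (0, 1]")
  structure(list(position = as.integer(position),
                 selection_coefficient = selection_coefficient,
                 target_daf = target_daf, onset_time = onset_time,
                 population = population),
            class = "sweep_model")
}

#' Simulate a dataset carrying a hard sweep
#'
#' The focal variant is forced to a realized derived allele frequency of
#' `round(target_daf * n) / n` in the swept population. Haplotypes carrying
#' the derived allele descend from a recent common ancestor: their
#' genealogy is a compressed coalescent (effective size t_s / 4, truncated
#' at `onset_time`) with sweep duration t_s = 2 ln(2 N s) / s — a
#' star-genealogy approximation of the frequency trajectory. Other
#' populations, and the ancestral-allele class, follow the neutral
#' demography. No recombination within sweep regions (single genealogy).
#'
#' @inheritParams simulate_neutral
#' @param sweep a [sweep_model()].
#' @return a [haplotype_matrix()]; the focal site is flagged in attribute
#'   `focal_site` (column index) and carries id position `sweep$position`.
#' @export
simulate_sweep <- function(params, demography, sweep, seed) {
  set.seed(seed)
  pops <- demography$populations
  focal_pop <- if (is.null(sweep$population)) pops[1] else sweep$population
  if (!focal_pop %in% pops) stop("unknown focal population ", focal_pop)
  if (sweep$position < 1 || sweep$position > params$region_length)
    stop("sweep position outside region")
  n_per <- params$n_haplotypes_per_pop
  n_hap <- n_per * length(pops)
  pop_of_hap <- rep(pops, each = n_per)
  n_d <- as.integer(round(sweep$target_daf * n_per))
  if (sweep$target_daf * n_per < 2)
    stop("derived class too small: target_daf x n < 2")

  focal_rows <- which(pop_of_hap == focal_pop)
  derived_ids <- focal_rows[seq_len(n_d)]
  anc_ids <- setdiff(seq_len(n_hap), derived_ids)

  n0 <- .size_at(demography, focal_pop, 0)
  s <- sweep$selection_coefficient
  t_s <- 2 * log(2 * n0 * s) / s
  n_sweep <- max(t_s / 4, 1e-6)

  # derived-class subtree: compressed constant-size coalescent, truncated
  # at the sweep onset (residual lineages merge star-like at onset_time)
  sub <- .coalesce(
    data.frame(id = seq_len(n_d), pop = "sweep", node_time = 0,
               entry_time = 0),
    constant_demography(n_sweep, "sweep"), n_d)
  over <- !is.na(sub$time) & sub$time > sweep$onset_time
  sub$time[over] <- sweep$onset_time

  # graft: relabel subtree nodes into the global id space
  n_sub <- length(sub$parent)
  map <- integer(n_sub)
  map[seq_len(n_d)] <- derived_ids
  if (n_sub > n_d) map[(n_d + 1L):n_sub] <- n_hap + seq_len(n_sub - n_d)
  parent <- rep(NA_integer_, n_hap + (n_sub - n_d))
  ntime <- rep(NA_real_, length(parent))
  for (i in seq_len(n_sub)) {
    ntime[map[i]] <- sub$time[i]
    if (!is.na(sub$parent[i])) parent[map[i]] <- map[sub$parent[i]]
  }
  sub_root <- map[sub$root]

  if (length(anc_ids)) {
    main_lin <- data.frame(
      id = c(anc_ids, sub_root),
      pop = c(pop_of_hap[anc_ids], focal_pop),
      node_time = c(rep(0, length(anc_ids)), ntime[sub_root]),
      entry_time = c(rep(0, length(anc_ids)), sweep$onset_time),
      stringsAsFactors = FALSE)
    main <- .coalesce(main_lin, demography, length(parent))
    grow <- length(main$parent) - length(parent)
    if (grow > 0L) {
      parent <- c(parent, rep(NA_integer_, grow))
      ntime <- c(ntime, rep(NA_real_, grow))
    }
    set_p <- which(!is.na(main$parent))
    parent[set_p] <- main$parent[set_p]
    set_t <- which(!is.na(main$time) & is.na(ntime))
    ntime[set_t] <- main$time[set_t]
  }
  tree <- list(parent = parent, time = ntime)

  mut <- .drop_mutations(tree, n_hap, params$mutation_rate,
                         1L, params$region_length)
  # the focal sweep mutation: carried by the whole derived class
  positions <- c(mut$positions, sweep$position)
  carriers <- c(mut$carriers, list(derived_ids))
  dup <- duplicated(positions, fromLast = TRUE)  # focal wins collisions
  positions <- positions[!dup]; carriers <- carriers[!dup]
  hm <- .build_matrix(n_hap, positions, carriers, demography, params,
                      pop_of_hap)
  attr(hm, "focal_site") <- match(sweep$position, hm$positions)
  attr(hm, "focal_population") <- focal_pop
  hm
}
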