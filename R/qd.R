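#' @title MAP-Elites exploration of strand-subset space
#' @name qd_explore
#' @description Steady-state MAP-Elites over genomes (strand-subset
#'   membership vectors), with feature descriptors (k strands, log10 number
#'   of reactions, number of structures) and MSS or ERT fitness.
NULL

#' Descriptor (grid axis) configuration
#'
#' Defaults follow the 3 x 50 x 55 grid: 3 strand-count bins over 1..7
#' ([1-2], [3-4], [5-7]), 50 bins over log10(#reactions + 1) in [0, 4], and
#' 55 bins over #structures in [0, 2750]. Out-of-range values clamp to the
#' boundary bins.
#'
#' @param k_edges upper-inclusive strand-count bin edges.
#' @param rxn_bins,rxn_range bins and range for log10(#reactions + 1).
#' @param struct_bins,struct_range bins and range for #structures.
#' @return a `descriptor_config`.
#' @export
descriptor_config <- function(k_edges = c(2L, 4L, 7L),
                              rxn_bins = 50L, rxn_range = c(0, 4),
                              struct_bins = 55L, struct_range = c(0, 2750)) {
  stopifnot(all(diff(k_edges) > 0), rxn_bins >= 1, struct_bins >= 1,
            diff(rxn_range) > 0, diff(struct_range) > 0)
  structure(list(k_edges = as.integer(k_edges),
                 rxn_bins = as.integer(rxn_bins),
                 rxn_range = as.numeric(rxn_range),
                 struct_bins = as.integer(struct_bins),
                 struct_range = as.numeric(struct_range)),
            class = "descriptor_config")
}

#' Total number of bins of a descriptor grid
#' @param cfg a [descriptor_config()].
#' @return integer (8250 under defaults).
#' @export
grid_n_bins <- function(cfg) {
  length(cfg$k_edges) * cfg$rxn_bins * cfg$struct_bins
}

clamp_bin <- function(value, range, nbins) {
  b <- floor((value - range[1]) / (range[2] - range[1]) * nbins)
  max(0L, min(nbins - 1L, as.integer(b)))
}

#' Feature descriptors of an evaluated genome
#'
#' @param g a `dsd_genome`.
#' @param metrics output of [crn_metrics()] for the genome's CRN.
#' @param cfg a [descriptor_config()].
#' @return integer vector `(k_bin, rxn_bin, struct_bin)`, 0-based.
#' @export
compute_descriptors <- function(g, metrics, cfg = descriptor_config()) {
  k <- sum(g$bits)
  k_bin <- findInterval(k, cfg$k_edges + 1L)   # 0-based via edge shift
  k_bin <- max(0L, min(length(cfg$k_edges) - 1L, k_bin))
  rxn_bin <- clamp_bin(log10(metrics$n_reactions + 1), cfg$rxn_range,
                       cfg$rxn_bins)
  struct_bin <- clamp_bin(metrics$n_structures, cfg$struct_range,
                          cfg$struct_bins)
  c(k_bin = k_bin, rxn_bin = rxn_bin, struct_bin = struct_bin)
}

#' Random bit-flip mutation of a genome
#'
#' Flips 1-3 uniformly chosen bits, then repairs: above-cap selections are
#' trimmed by clearing random set bits; an empty selection gets one random
#' bit set. Uses the current RNG state (seed at the call site).
#'
#' @param g a `dsd_genome`.
#' @return a valid mutated `dsd_genome`.
#' @export
mutate_genome <- function(g) {
  bits <- g$bits
  n <- length(bits)
  nflip <- sample.int(3L, 1L)
  flip <- sample.int(n, min(nflip, n))
  bits[flip] <- !bits[flip]
  k <- sum(bits)
  if (k == 0) {
    bits[sample.int(n, 1L)] <- TRUE
  } else if (k > g$max_strands) {
    on <- which(bits)
    bits[sample(on, k - g$max_strands)] <- FALSE
  }
  new_genome(bits, g$max_strands)
}

bin_key <- function(d) paste(d, collapse = "_")

new_elite_grid <- function(cfg, fitness_name) {
  structure(list(bins = list(), cfg = cfg, fitness_name = fitness_name,
                 evals = 0L, meta = list()),
            class = "elite_grid")
}

#' Offer a candidate to an elite grid
#'
#' Accepted iff the bin is empty or the candidate's fitness is strictly
#' greater than the incumbent's (ties keep the incumbent, for
#' reproducibility).
#'
#' @param grid an `elite_grid`.
#' @param candidate list with fields `genome`, `fitness`, `descriptors` and
#'   (optionally) `metrics`.
#' @return list `(grid, accepted)`.
#' @export
place_elite <- function(grid, candidate) {
  key <- bin_key(candidate$descriptors)
  inc <- grid$bins[[key]]
  accepted <- is.null(inc) || candidate$fitness > inc$fitness
  if (accepted) grid$bins[[key]] <- candidate
  list(grid = grid, accepted = accepted)
}

# Evaluate one genome: enumerate its CRN and compute metrics + descriptors.
evaluate_genome <- function(g, library, fitness_name, params, cfg) {
  strands <- genome_to_strands(g, library)
  crn <- enumerate_crn(strands, library$spec$domain_lengths, params)
  metrics <- crn_metrics(crn)
  list(genome = g,
       genome_bits = paste(as.integer(g$bits), collapse = ""),
       fitness = metrics[[tolower(fitness_name)]],
       descriptors = compute_descriptors(g, metrics, cfg),
       metrics = metrics,
       truncated = crn$truncated)
}

random_genome <- function(n, max_strands) {
  k <- sample.int(max_strands, 1L)
  bits <- rep(FALSE, n)
  bits[sample.int(n, min(k, n))] <- TRUE
  new_genome(bits, max_strands)
}

#' Run MAP-Elites over a strand library
#'
#' Steady-state loop: initialize with `init_size` random genomes, then until
#' the evaluation budget is exhausted, pick a uniform random elite, mutate
#' it ([mutate_genome()]) and offer the evaluated mutant to the grid.
#' Evaluations are cached by genome bitstring, and each cache hit still
#' counts against the budget. Fully reproducible from `seed`.
#'
#' @param library a `strand_library`.
#' @param fitness_name "MSS" or "ERT".
#' @param budget total evaluations (>= `init_size`).
#' @param cfg a [descriptor_config()].
#' @param params an [enum_params()].
#' @param seed integer seed.
#' @param init_size random initial population (default 100).
#' @param max_strands selection cap per genome (default 7).
#' @param exhaustive evaluate every non-empty subset of at most
#'   `max_strands` strands exactly once instead of the stochastic loop.
#' @return an `elite_grid`; `meta` records the run configuration and an
#'   audit log of per-evaluation best fitness.
#' @export
run_map_elites <- function(library, fitness_name = c("MSS", "ERT"),
                           budget = 1000L, cfg = descriptor_config(),
                           params = enum_params(), seed = 1L,
                           init_size = 100L, max_strands = 7L,
                           exhaustive = FALSE) {
  fitness_name <- match.arg(fitness_name)
  n <- length(library$strands)
  grid <- new_elite_grid(cfg, fitness_name)
  cache <- new.env(parent = emptyenv())
  eval_cached <- function(g) {
    key <- paste(as.integer(g$bits), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cand <- evaluate_genome(g, library, fitness_name, params, cfg)
    cache[[key]] <- cand
    cand
  }
  if (exhaustive) {
    count <- 0L
    for (k in seq_len(min(max_strands, n))) {
      sel <- utils::combn(n, k)
      for (cidx in seq_len(ncol(sel))) {
        bits <- rep(FALSE, n)
        bits[sel[, cidx]] <- TRUE
        cand <- eval_cached(new_genome(bits, max_strands))
        grid <- place_elite(grid, cand)$grid
        count <- count + 1L
      }
    }
    grid$evals <- count
    grid$meta <- list(mode = "exhaustive", max_strands = max_strands,
                      library = library$spec$name)
    return(grid)
  }
  stopifnot(budget >= init_size)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  log_best <- numeric(budget)
  evals <- 0L
  while (evals < min(init_size, budget)) {
    cand <- eval_cached(random_genome(n, max_strands))
    grid <- place_elite(grid, cand)$grid
    evals <- evals + 1L
    log_best[evals] <- max(vapply(grid$bins, `[[`, numeric(1), "fitness"))
  }
  while (evals < budget) {
    parent_key <- sample(names(grid$bins), 1L)
    parent <- grid$bins[[parent_key]]$genome
    cand <- eval_cached(mutate_genome(parent))
    grid <- place_elite(grid, cand)$grid
    evals <- evals + 1L
    log_best[evals] <- max(vapply(grid$bins, `[[`, numeric(1), "fitness"))
  }
  grid$evals <- evals
  grid$meta <- list(mode = "map-elites", seed = seed, budget = budget,
                    init_size = init_size, max_strands = max_strands,
                    batch_size = 1L, library = library$spec$name,
                    best_fitness_log = log_best)
  grid
}

#' Aggregate elite grids from independent runs
#'
#' @param grids list of `elite_grid` objects with identical descriptor
#'   configs and fitness names.
#' @return the per-bin best-fitness aggregate `elite_grid`.
#' @export
aggregate_grids <- function(grids) {
  stopifnot(length(grids) >= 1)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(g$cfg, ref$cfg) || !identical(g$fitness_name,
                                                 ref$fitness_name)) {
      stop("grids have mismatched descriptor configs or fitness names")
    }
  }
  out <- new_elite_grid(ref$cfg, ref$fitness_name)
  for (g in grids) {
    for (key in names(g$bins)) {
      out <- place_elite(out, g$bins[[key]])$grid
    }
    out$evals <- out$evals + g$evals
  }
  out$meta <- list(mode = "aggregate", n_runs = length(grids))
  out
}

#' Coverage / intersection report for elite grids
#'
#' @param a an `elite_grid`.
#' @param b optional second grid of the same shape.
#' @return list with `n_filled`, `pct_filled` (over the grid's total bin
#'   count) and, when `b` is given, `n_intersection` (bins filled in both).
#' @export
grid_report <- function(a, b = NULL) {
  total <- grid_n_bins(a$cfg)
  out <- list(n_filled = length(a$bins),
              pct_filled = 100 * length(a$bins) / total)
  if (!is.null(b)) {
    if (!identical(a$cfg, b$cfg)) stop("grid shapes differ")
    out$n_intersection <- length(intersect(names(a$bins), names(b$bins)))
  }
  out
}

#' Flatten an elite grid to a data frame
#'
#' @param grid an `elite_grid`.
#' @return data.frame with bin indices, fitness, genome bitstring and the
#'   CRN feature values.
#' @export
grid_to_dataframe <- function(grid) {
  if (length(grid$bins) == 0) {
    return(data.frame(k_bin = integer(0), rxn_bin = integer(0),
                      struct_bin = integer(0), fitness = numeric(0),
                      genome = character(0), n_reactions = integer(0),
                      n_structures = integer(0)))
  }
  rows <- lapply(grid$bins, function(e) {
    data.frame(k_bin = e$descriptors[[1]], rxn_bin = e$descriptors[[2]],
               struct_bin = e$descriptors[[3]], fitness = e$fitness,
               genome = e$genome_bits,
               n_reactions = e$metrics$n_reactions,
               n_structures = e$metrics$n_structures)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$k_bin, out$rxn_bin, out$struct_bin), , drop = FALSE]
}

#' Save an elite grid as JSON (plus optional CSV flat table)
#'
#' @param grid an `elite_grid`.
#' @param path JSON output path.
#' @param csv optional CSV path for [grid_to_dataframe()].
#' @return invisibly `path`.
#' @export
write_grid_json <- function(grid, path, csv = NULL) {
  doc <- list(fitness_name = grid$fitness_name, evals = grid$evals,
              cfg = grid$cfg[c("k_edges", "rxn_bins", "rxn_range",
                               "struct_bins", "struct_range")],
              meta = grid$meta[setdiff(names(grid$meta),
                                       "best_fitness_log")],
              bins = lapply(grid$bins, function(e) {
                list(genome = e$genome_bits, fitness = e$fitness,
                     descriptors = as.integer(e$descriptors),
                     metrics = e$metrics)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(csv)) {
    utils::write.csv(grid_to_dataframe(grid), csv, row.names = FALSE)
  }
  invisible(path)
}
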