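#' @title Sequence optimization against a CRN of interest
#' @name seq_opt
#' @description Optimize the nucleotide assignment of a library's base
#'   domains so that as many enumerated structures as possible are
#'   reproduced as well-formed minimum-free-energy folds, by elitist GA or
#'   random search, with re-evaluation at a larger folding size cap.
NULL

#' Optimization configuration
#'
#' @param algorithm "ga" (elitist, mutation-only) or "random".
#' @param budget total objective evaluations.
#' @param population GA population size.
#' @param elite_keep GA elites kept per generation.
#' @param runs independent repetitions (seeded `seed + run - 1`).
#' @param seed base integer seed.
#' @param opt_fold_size folding size cap during optimization (default 3).
#' @param reeval_fold_size cap for final re-evaluation (default 8).
#' @param hybridization_fraction forwarded to [fold_params()].
#' @return an `opt_config`.
#' @export
opt_config <- function(algorithm = c("ga", "random"), budget = 1000L,
                       population = 32L, elite_keep = 8L, runs = 10L,
                       seed = 1L, opt_fold_size = 3L, reeval_fold_size = 8L,
                       hybridization_fraction = 0.5) {
  algorithm <- match.arg(algorithm)
  stopifnot(budget >= population, population >= elite_keep, elite_keep >= 1,
            runs >= 1)
  structure(list(algorithm = algorithm, budget = as.integer(budget),
                 population = as.integer(population),
                 elite_keep = as.integer(elite_keep),
                 runs = as.integer(runs), seed = as.integer(seed),
                 opt_fold_size = as.integer(opt_fold_size),
                 reeval_fold_size = as.integer(reeval_fold_size),
                 hybridization_fraction = hybridization_fraction),
            class = "opt_config")
}

#' Draw a uniform random sequence assignment
#'
#' Uniform random base per position of each base domain; complement
#' sequences are derived as reverse complements. Uses the current RNG
#' state.
#'
#' @param domain_lengths named integer vector of base-domain lengths.
#' @return a [seq_assignment()].
#' @export
random_assignment <- function(domain_lengths) {
  seqs <- vapply(domain_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  seq_assignment(seqs, domain_lengths)
}

#' Mutate a sequence assignment
#'
#' Picks 1-3 distinct positions across the concatenation of the base-domain
#' sequences and changes each to a different base; complements follow
#' automatically. Uses the current RNG state.
#'
#' @param assignment a [seq_assignment()].
#' @return the mutated `seq_assignment`.
#' @export
mutate_assignment <- function(assignment) {
  concat <- strsplit(paste(assignment$seqs, collapse = ""), "")[[1]]
  total <- length(concat)
  npos <- sample.int(3L, 1L)
  pos <- sample.int(total, min(npos, total))
  for (p in pos) {
    concat[p] <- sample(setdiff(c("A", "C", "G", "T"), concat[p]), 1L)
  }
  lens <- assignment$domain_lengths
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seqs <- vapply(seq_along(lens), function(i) {
    paste(concat[starts[i]:ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- names(lens)
  seq_assignment(seqs, lens)
}

assignment_key <- function(assignment) {
  paste(assignment$seqs, collapse = "|")
}

# Objective: number of enumerated structures (within the folding size cap)
# reproduced as well-formed MFE folds under `assignment`.
overlap_objective <- function(assignment, crn, strands, fp) {
  wf <- wellformed_structures(strands, assignment, fp)
  match_overlap(wf, crn, fp)
}

#' Optimize a sequence assignment for a CRN
#'
#' Random search evaluates `budget` independent draws. The GA is elitist
#' (mu + lambda, mutation-only): the `elite_keep` best assignments are kept
#' and the population refilled by mutating uniformly chosen elites. The
#' objective is the overlap count at `opt_fold_size`
#' (see [match_overlap()]). Objective values are cached by assignment, and
#' the best-so-far score is monotone non-decreasing.
#'
#' @param crn a `dsd_crn`.
#' @param strands the CRN's initial strands (list of token vectors).
#' @param domain_lengths named integer vector of base-domain lengths.
#' @param cfg an [opt_config()].
#' @param run run index (seeds `cfg$seed + run - 1`).
#' @return list with `best` (assignment), `best_score`, `best_report` and
#'   `history` (data.frame: eval, score, best_so_far).
#' @export
optimize_sequences <- function(crn, strands, domain_lengths,
                               cfg = opt_config(), run = 1L) {
  fp <- fold_params(cfg$opt_fold_size, cfg$hybridization_fraction)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed + run - 1L)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  history <- data.frame(eval = integer(0), score = numeric(0),
                        best_so_far = numeric(0))
  best <- NULL
  evaluate <- function(assignment) {
    key <- assignment_key(assignment)
    rep <- cache[[key]]
    if (is.null(rep)) {
      rep <- overlap_objective(assignment, crn, strands, fp)
      cache[[key]] <- rep
    }
    n_eval <<- n_eval + 1L
    score <- rep$n_overlap
    if (is.null(best) || score > best$score) {
      best <<- list(assignment = assignment, score = score, report = rep)
    }
    history[nrow(history) + 1L, ] <<- c(n_eval, score, best$score)
    score
  }
  if (cfg$algorithm == "random") {
    while (n_eval < cfg$budget) {
      evaluate(random_assignment(domain_lengths))
    }
  } else {
    pop <- list()
    for (i in seq_len(min(cfg$population, cfg$budget))) {
      a <- random_assignment(domain_lengths)
      pop[[i]] <- list(assignment = a, score = evaluate(a), born = i)
    }
    while (n_eval < cfg$budget) {
      # elitist survival: best elite_keep, earlier-evaluated wins ties
      ord <- order(-vapply(pop, `[[`, numeric(1), "score"),
                   vapply(pop, `[[`, numeric(1), "born"))
      elites <- pop[ord[seq_len(min(cfg$elite_keep, length(pop)))]]
      pop <- elites
      while (length(pop) < cfg$population && n_eval < cfg$budget) {
        parent <- elites[[sample.int(length(elites), 1L)]]
        child <- mutate_assignment(parent$assignment)
        pop[[length(pop) + 1L]] <- list(assignment = child,
                                        score = evaluate(child),
                                        born = n_eval)
      }
    }
  }
  list(best = best$assignment, best_score = best$score,
       best_report = best$report, history = history,
       config = cfg, run = run, evals = n_eval)
}

#' Re-evaluate an optimized assignment at the larger folding cap
#'
#' @param assignment a [seq_assignment()] (typically the best of
#'   [optimize_sequences()]).
#' @param crn the `dsd_crn` it was optimized for.
#' @param strands the CRN's initial strands.
#' @param cfg an [opt_config()] (uses `reeval_fold_size`).
#' @return a `match_report` at `reeval_fold_size`.
#' @export
reevaluate_overlap <- function(assignment, crn, strands,
                               cfg = opt_config()) {
  fp <- fold_params(cfg$reeval_fold_size, cfg$hybridization_fraction)
  overlap_objective(assignment, crn, strands, fp)
}

#' Run both optimizers over several runs and select the better
#'
#' Runs `cfg$runs` repetitions of the configured algorithm (or of both when
#' `algorithm = "both"`), re-evaluates each run's best at the large cap and
#' returns the per-algorithm best plus the selected algorithm (higher
#' re-evaluated proportion).
#'
#' @param crn a `dsd_crn`.
#' @param strands the CRN's initial strands.
#' @param domain_lengths base-domain lengths.
#' @param cfg an [opt_config()].
#' @return list keyed by algorithm with the winning run, plus `selected`.
#' @export
compare_optimizers <- function(crn, strands, domain_lengths,
                               cfg = opt_config()) {
  out <- list()
  for (alg in c("random", "ga")) {
    acfg <- cfg
    acfg$algorithm <- alg
    best_run <- NULL
    for (run in seq_len(cfg$runs)) {
      res <- optimize_sequences(crn, strands, domain_lengths, acfg, run)
      if (is.null(best_run) || res$best_score > best_run$best_score) {
        best_run <- res
      }
    }
    best_run$reeval <- reevaluate_overlap(best_run$best, crn, strands, acfg)
    out[[alg]] <- best_run
  }
  out$selected <- if (out$ga$reeval$proportion > out$random$reeval$proportion)
    "ga" else "random"
  out
}
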