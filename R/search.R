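#' Configuration of the evolutionary search
#'
#' Defaults follow the search design: initial model sizes drawn uniformly
#' from `center - delta` to `center + delta` (3 +/- 2, i.e. 1 to 5 SNPs);
#' expert knowledge used for 50% of initial SNP picks; any-point crossover
#' used 90% of the time inside generational tasks (mutation otherwise, at a
#' fixed 0.5% per-SNP rate); rank/crowding tournaments of size 3 and a
#' parsimony tournament of size 6; a steady-state client population that
#' launches generational tasks and absorbs their subpopulations. The
#' client-side mutation rate is dataset-size dependent: 0.5% per SNP for
#' 1000-SNP datasets and 5% for 100-SNP datasets (`NULL` = choose by SNP
#' count). Termination is by evaluation budget only; models may grow past
#' 5 SNPs through crossover but are truncated at `max_model_size`.
#'
#' @param init_size_center,init_size_delta Initial model size distribution.
#' @param ek_seed_prob Probability that an initial SNP pick follows the
#'   expert-knowledge lookup table instead of being uniform.
#' @param steady_state_pop Client (steady-state) population size.
#' @param task_pop Generational task population size.
#' @param task_generations Generations per task.
#' @param n_tasks_per_round Tasks launched per client round.
#' @param crossover_prob_task Probability a task child comes from
#'   crossover (otherwise mutation of a uniformly drawn model).
#' @param per_snp_mutation_rate Client-side per-SNP mutation rate;
#'   `NULL` = 0.005 for datasets with >= 550 SNPs, 0.05 otherwise.
#' @param task_mutation_rate Per-SNP mutation rate on the task mutation
#'   path (fixed 0.5%).
#' @param tournament_size_rank,tournament_size_parsimony Tournament sizes.
#' @param evaluation_budget Total number of distinct model evaluations.
#' @param max_model_size Hard cap on model order (3^K cells).
#' @return A `search_config` list.
#' @export
search_config <- function(init_size_center = 3L,
                          init_size_delta = 2L,
                          ek_seed_prob = 0.5,
                          steady_state_pop = 200L,
                          task_pop = 50L,
                          task_generations = 25L,
                          n_tasks_per_round = 4L,
                          crossover_prob_task = 0.9,
                          per_snp_mutation_rate = NULL,
                          task_mutation_rate = 0.005,
                          tournament_size_rank = 3L,
                          tournament_size_parsimony = 6L,
                          evaluation_budget = 50000L,
                          max_model_size = 10L) {
  cfg <- list(
    init_size_center = as.integer(init_size_center),
    init_size_delta = as.integer(init_size_delta),
    ek_seed_prob = ek_seed_prob,
    steady_state_pop = as.integer(steady_state_pop),
    task_pop = as.integer(task_pop),
    task_generations = as.integer(task_generations),
    n_tasks_per_round = as.integer(n_tasks_per_round),
    crossover_prob_task = crossover_prob_task,
    per_snp_mutation_rate = per_snp_mutation_rate,
    task_mutation_rate = task_mutation_rate,
    tournament_size_rank = as.integer(tournament_size_rank),
    tournament_size_parsimony = as.integer(tournament_size_parsimony),
    evaluation_budget = as.integer(evaluation_budget),
    max_model_size = as.integer(max_model_size)
  )
  probs <- c(cfg$ek_seed_prob, cfg$crossover_prob_task, cfg$task_mutation_rate,
             cfg$per_snp_mutation_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  sizes <- c(cfg$init_size_center, cfg$steady_state_pop, cfg$task_pop,
             cfg$n_tasks_per_round, cfg$tournament_size_rank,
             cfg$tournament_size_parsimony, cfg$evaluation_budget,
             cfg$max_model_size)
  if (any(sizes < 1L) || cfg$init_size_delta < 0L || cfg$task_generations < 0L) {
    abort("Invalid search_config: sizes must be >= 1 (delta and generations >= 0).")
  }
  structure(cfg, class = "search_config")
}

client_mutation_rate <- function(config, n_snps) {
  if (!is.null(config$per_snp_mutation_rate)) return(config$per_snp_mutation_rate)
  if (n_snps >= 550L) 0.005 else 0.05
}

# ---- variation operators -------------------------------------------------

#' Sample an initial candidate model ("sensible initialization")
#'
#' Model size is drawn uniformly from
#' `[init_size_center - init_size_delta, init_size_center + init_size_delta]`
#' (clipped to at least 1 and at most the SNP count / `max_model_size`).
#' The first SNP is uniform; each subsequent SNP follows the
#' expert-knowledge lookup table with probability `ek_seed_prob` (the best
#' partner of the previously selected SNP, skipping duplicates), otherwise
#' it is uniform among unused SNPs.
#'
#' @param ek An `ek_table`, or `NULL` for pure uniform sampling.
#' @param n_snps Total number of SNPs.
#' @param config A [search_config()].
#' @param ek_seed_prob Override of `config$ek_seed_prob` (the random-search
#'   baseline passes 0).
#' @return An integer vector of distinct SNP indices.
#' @export
sample_initial_model <- function(ek, n_snps, config = search_config(),
                                 ek_seed_prob = config$ek_seed_prob) {
  if (n_snps < 2L) abort("Need at least 2 SNPs.")
  lo <- max(1L, config$init_size_center - config$init_size_delta)
  hi <- min(config$init_size_center + config$init_size_delta,
            n_snps, config$max_model_size)
  k <- if (lo >= hi) lo else (lo:hi)[sample.int(hi - lo + 1L, 1L)]
  model <- integer(k)
  model[1L] <- sample.int(n_snps, 1L)
  if (k > 1L) {
    for (j in 2:k) {
      pick <- NA_integer_
      if (!is.null(ek) && runif(1) < ek_seed_prob) {
        cand <- ek$best_partner[model[j - 1L]]
        if (!cand %in% model[seq_len(j - 1L)]) pick <- cand
      }
      if (is.na(pick)) {
        pool <- setdiff(seq_len(n_snps), model[seq_len(j - 1L)])
        pick <- pool[sample.int(length(pool), 1L)]
      }
      model[j] <- pick
    }
  }
  model
}

#' Any-point crossover of two parent models
#'
#' Independent cut points are chosen uniformly in `[0, length]` of each
#' parent's SNP list and the tails are swapped, so children can be longer
#' or shorter than either parent (growth beyond 5 SNPs happens here).
#' Duplicate SNPs within a child are removed keeping the first occurrence;
#' an empty child is repaired to a single random SNP from either parent;
#' children are truncated at `max_size`.
#'
#' @param a,b Integer vectors of distinct SNP indices (non-empty).
#' @param max_size Truncation cap.
#' @return A list of two children.
#' @export
any_point_crossover <- function(a, b, max_size = 10L) {
  la <- length(a); lb <- length(b)
  if (!la || !lb) abort("Parents must be non-empty.")
  ca <- sample.int(la + 1L, 1L) - 1L
  cb <- sample.int(lb + 1L, 1L) - 1L
  c1 <- c(a[seq_len(ca)], if (cb < lb) b[(cb + 1L):lb])
  c2 <- c(b[seq_len(cb)], if (ca < la) a[(ca + 1L):la])
  fix <- function(x) {
    x <- unique(x)
    if (!length(x)) {
      pool <- c(a, b)
      x <- pool[sample.int(length(pool), 1L)]
    }
    if (length(x) > max_size) x <- x[seq_len(max_size)]
    x
  }
  list(fix(c1), fix(c2))
}

#' Per-SNP mutation of a model
#'
#' Each position is independently replaced, with probability `rate`, by a
#' uniformly drawn SNP not already in the model. Model size is unchanged.
#'
#' @param model Integer vector of distinct SNP indices.
#' @param n_snps Total number of SNPs.
#' @param rate Per-SNP mutation probability.
#' @return The mutated model.
#' @export
mutate_model <- function(model, n_snps, rate) {
  if (rate < 0 || rate > 1) abort("`rate` must lie in [0, 1].")
  if (rate == 0) return(model)
  hits <- which(runif(length(model)) < rate)
  for (j in hits) {
    pool <- setdiff(seq_len(n_snps), model)
    if (!length(pool)) break
    model[j] <- pool[sample.int(length(pool), 1L)]
  }
  model
}

# ---- evaluation with cache + budget --------------------------------------

model_key <- function(m) paste(sort.int(m), collapse = ",")

# Closure-based evaluator: scores batches of models through the QMDR
# kernel, caching by SNP set so re-evaluations are free; only cache misses
# consume the evaluation budget. Models that cannot be scored within the
# remaining budget are reported as unscored.
make_evaluator <- function(dataset, ek, budget) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evals <- 0L
  list(
    evaluate = function(models) {
      keys <- model_keys_cpp(models)
      vals <- mget(keys, envir = cache, ifnotfound = list(NULL))
      miss <- which(vapply(vals, is.null, TRUE))
      # dedupe misses within the batch
      miss <- miss[!duplicated(keys[miss])]
      allowed <- max(0L, min(length(miss), budget - evals))
      if (allowed > 0L) {
        todo <- miss[seq_len(allowed)]
        sc <- score_models(dataset, models[todo], ek)
        rows <- lapply(seq_len(allowed), function(r) sc[r, ])
        names(rows) <- keys[todo]
        list2env(rows, cache)
        evals <<- evals + allowed
        vals <- mget(keys, envir = cache, ifnotfound = list(NULL))
      }
      found <- !vapply(vals, is.null, TRUE)
      out <- matrix(NA_real_, length(models), 4,
                    dimnames = list(NULL, c("t_statistic", "interaction_info",
                                            "size", "valid")))
      if (any(found)) {
        out[found, ] <- matrix(unlist(vals[found], use.names = FALSE),
                               ncol = 4, byrow = TRUE)
      }
      out
    },
    evals = function() evals,
    exhausted = function() evals >= budget
  )
}

# ---- internal population representation ----------------------------------
# A population is a list: models (list of integer vectors) and score
# columns t, ig, size, valid plus rank/crowding, all parallel vectors.

new_population <- function(models, scores) {
  list(models = models,
       keys = model_keys_cpp(models),
       t = scores[, "t_statistic"],
       ig = scores[, "interaction_info"],
       size = scores[, "size"],
       valid = scores[, "valid"],
       rank = NULL, crowd = NULL)
}

pop_size <- function(pop) length(pop$models)

pop_subset <- function(pop, idx) {
  list(models = pop$models[idx], keys = pop$keys[idx], t = pop$t[idx],
       ig = pop$ig[idx], size = pop$size[idx], valid = pop$valid[idx],
       rank = pop$rank[idx], crowd = pop$crowd[idx])
}

pop_bind <- function(a, b) {
  list(models = c(a$models, b$models), keys = c(a$keys, b$keys),
       t = c(a$t, b$t), ig = c(a$ig, b$ig),
       size = c(a$size, b$size), valid = c(a$valid, b$valid),
       rank = NULL, crowd = NULL)
}

pop_rank <- function(pop) {
  rc <- rank_and_crowd(pop$t, pop$ig, pop$size)
  pop$rank <- rc$rank
  pop$crowd <- rc$crowding
  pop
}

# NSGA-II environmental selection: rank the combined population once, keep
# `n` models by ascending rank breaking the last front by descending
# crowding distance, and carry those rank/crowding values into the next
# generation's tournaments (as in canonical NSGA-II; removing dominated
# models cannot change the ranks of the survivors).
pop_truncate <- function(pop, n) {
  pop <- pop_rank(pop)
  if (pop_size(pop) <= n) return(pop)
  pop_subset(pop, truncate_idx_cpp(pop$rank, pop$crowd, n))
}

tour_rc <- function(rank, crowd, size) {
  ent <- sample.int(length(rank), size, replace = TRUE)
  r <- rank[ent]
  best <- which(r == min(r))
  if (length(best) > 1L) {
    cw <- crowd[ent[best]]
    best <- best[cw == max(cw)]
    if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  }
  ent[best]
}

tour_pars <- function(model_size, size) {
  ent <- sample.int(length(model_size), size, replace = TRUE)
  s <- model_size[ent]
  best <- which(s == min(s))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  ent[best]
}

# ---- generational evolutionary task --------------------------------------

#' Run one generational evolutionary task
#'
#' Inside a task, children are bred by any-point crossover 90% of the time
#' (first parent from a size-6 parsimony tournament, second from a size-3
#' rank/crowding tournament) and by mutation of a uniformly drawn model
#' otherwise; each generation the parents and children are re-ranked by
#' NSGA-II and truncated elitistically back to the task population size.
#' Evaluation is cached: only previously unseen SNP sets consume budget.
#'
#' @param seed_pop A list of scored seed models (integer vectors).
#' @param seed_scores Matrix of their scores (from the evaluator).
#' @param evaluator An evaluator closure from the running search.
#' @param n_snps Total SNP count.
#' @param config A [search_config()].
#' @return A list: `pop` (internal population), `exhausted` flag.
#' @keywords internal
run_evolutionary_task <- function(seed_pop, seed_scores, evaluator, n_snps,
                                  config) {
  pop <- pop_rank(new_population(seed_pop, seed_scores))
  exhausted <- FALSE
  gens <- config$task_generations
  if (gens == 0L) return(list(pop = pop, exhausted = FALSE))
  for (g in seq_len(gens)) {
    children <- breed_children_cpp(
      pop$models, pop$rank, pop$crowd, as.integer(pop$size),
      config$task_pop, n_snps, config$crossover_prob_task,
      config$task_mutation_rate, config$tournament_size_parsimony,
      config$tournament_size_rank, config$max_model_size, FALSE
    )
    sc <- evaluator$evaluate(children)
    ok <- !is.na(sc[, 1L])
    if (!all(ok)) exhausted <- TRUE
    if (any(ok)) {
      kids_pop <- new_population(children[ok], sc[ok, , drop = FALSE])
      pop <- pop_truncate(pop_bind(pop, kids_pop), config$task_pop)
    }
    if (exhausted) break
  }
  list(pop = pop, exhausted = exhausted)
}

# ---- running Pareto archive ----------------------------------------------

archive_update <- function(archive, pop, cap = 1000L) {
  u <- pop_bind(archive, pop)
  keep <- !duplicated(u$keys)
  u <- pop_subset(u, keep)
  nd <- nondominated_idx(u$t, u$ig, u$size)
  u <- pop_subset(u, nd)
  if (pop_size(u) > cap) {
    cr <- crowding_core(u$t, u$ig, u$size)
    u <- pop_subset(u, order(-cr)[seq_len(cap)])
  }
  u$rank <- rep.int(0L, pop_size(u))
  u$crowd <- NULL
  u
}

empty_pop <- function() {
  list(models = list(), keys = character(0), t = numeric(0), ig = numeric(0),
       size = numeric(0), valid = numeric(0), rank = integer(0),
       crowd = numeric(0))
}

# ---- top-level searches --------------------------------------------------

search_result <- function(engine, front_pop, dataset, evaluations, history,
                          seed, config, n_front_final_pop, n_front_archive) {
  ord <- order(-front_pop$t)
  front_pop <- pop_subset(front_pop, ord)
  front <- tibble::tibble(
    snps = front_pop$models,
    snp_ids = purrr::map_chr(front_pop$models,
                             ~ paste(dataset$snp_ids[.x], collapse = ",")),
    t_statistic = front_pop$t,
    interaction_info = front_pop$ig,
    size = as.integer(front_pop$size),
    valid = front_pop$valid == 1,
    pareto_rank = 0L
  )
  structure(
    list(
      engine = engine,
      pareto_front = front,
      evaluations = evaluations,
      history = history,
      seed = seed,
      config = config,
      n_front_final_pop = n_front_final_pop,
      n_front_archive = n_front_archive
    ),
    class = "mdr_search_result"
  )
}

#' @export
print.mdr_search_result <- function(x, ...) {
  cat(sprintf(
    "<mdr_search_result> engine = %s, %d evaluations, Pareto front of %d models (best t = %.3f)\n",
    x$engine, x$evaluations, nrow(x$pareto_front),
    if (nrow(x$pareto_front)) max(x$pareto_front$t_statistic) else NA_real_
  ))
  invisible(x)
}

#' Evolutionary multiobjective search for interacting SNP sets
#'
#' The full search: build the pairwise expert-knowledge table, initialize a
#' steady-state client population by sensible initialization, then
#' repeatedly (a) breed task seed models at the client (two size-3
#' rank/crowding tournaments; the second winner is mutated at the
#' dataset-size-dependent rate before any-point crossover), (b) run
#' generational evolutionary tasks seeded with those offspring, and (c)
#' merge the returned subpopulations into the steady-state population with
#' NSGA-II truncation, until the evaluation budget is consumed. The result
#' is the rank-0 front of the union of the final population and the running
#' nondominated archive. Fully reproducible from `seed`.
#'
#' @param dataset A quantitative [genotype_dataset()].
#' @param config A [search_config()].
#' @param seed Integer seed (the only source of randomness).
#' @param ek Optional precomputed [build_expert_knowledge()] table.
#' @param verbose Print a per-round progress line.
#' @return An `mdr_search_result`: `pareto_front` tibble, `evaluations`
#'   (total model evaluations consumed, `<= evaluation_budget`), `history`
#'   tibble per round, `seed`, `config`.
#' @export
run_mdr_search <- function(dataset, config = search_config(), seed = NULL,
                           ek = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "search_config"))
  if (dataset$phenotype_kind != "quantitative") {
    abort("The search requires a quantitative phenotype.")
  }
  if (config$evaluation_budget < config$steady_state_pop) {
    abort("`evaluation_budget` must be at least `steady_state_pop`.")
  }
  runner <- function() {
    if (is.null(ek)) ek <- build_expert_knowledge(dataset)
    n_snps <- dataset$n_snps
    evaluator <- make_evaluator(dataset, ek, config$evaluation_budget)
    mut_rate <- client_mutation_rate(config, n_snps)

    init <- purrr::map(seq_len(config$steady_state_pop),
                       ~ sample_initial_model(ek, n_snps, config))
    sc <- evaluator$evaluate(init)
    ok <- !is.na(sc[, 1L])
    pop <- pop_rank(new_population(init[ok], sc[ok, , drop = FALSE]))
    archive <- archive_update(empty_pop(), pop_subset(pop, pop$rank == 0L))

    history <- list()
    round <- 0L
    while (!evaluator$exhausted()) {
      round <- round + 1L
      before <- evaluator$evals()
      for (task in seq_len(config$n_tasks_per_round)) {
        if (evaluator$exhausted()) break
        # breed task seeds at the client (steady-state rule)
        seeds <- breed_children_cpp(
          pop$models, pop$rank, pop$crowd, as.integer(pop$size),
          config$task_pop, n_snps, 1.0, mut_rate,
          config$tournament_size_parsimony, config$tournament_size_rank,
          config$max_model_size, TRUE
        )
        task_seed <- sample.int(.Machine$integer.max, 1L)
        sc <- evaluator$evaluate(seeds)
        ok <- !is.na(sc[, 1L])
        if (!any(ok)) break
        task_res <- withr::with_seed(
          task_seed,
          run_evolutionary_task(seeds[ok], sc[ok, , drop = FALSE],
                                evaluator, n_snps, config)
        )
        pop <- pop_truncate(pop_bind(pop, task_res$pop),
                            config$steady_state_pop)
      }
      archive <- archive_update(archive, pop_subset(pop, pop$rank == 0L))
      history[[round]] <- tibble::tibble(
        round = round,
        evaluations = evaluator$evals(),
        best_t = max(pop$t),
        front_size = sum(pop$rank == 0L)
      )
      if (verbose) {
        inform(sprintf("round %d: %d evaluations, best t = %.3f, front size %d",
                       round, evaluator$evals(), max(pop$t),
                       sum(pop$rank == 0L)))
      }
      if (evaluator$evals() == before) break  # no progress possible
    }
    final_front <- pop_subset(pop, pop$rank == 0L)
    union_front <- archive_update(archive, final_front)
    search_result("evolutionary", union_front, dataset, evaluator$evals(),
                  dplyr::bind_rows(history), seed, config,
                  n_front_final_pop = pop_size(final_front),
                  n_front_archive = pop_size(archive))
  }
  if (is.null(seed)) runner() else withr::with_seed(seed, runner())
}

#' Matched-budget random-search baseline
#'
#' Evaluates `budget` models drawn from the same initial-sampling
#' distribution as the evolutionary search but with the expert-knowledge
#' path disabled (`ek_seed_prob = 0`, pure uniform), and returns the
#' Pareto front of everything evaluated. This is the comparison engine for
#' the simulation study: same scoring, same number of fitness evaluations,
#' no evolution.
#'
#' @inheritParams run_mdr_search
#' @param budget Number of model evaluations (defaults to
#'   `config$evaluation_budget` so budgets are matched).
#' @return An `mdr_search_result` with `engine = "random"`.
#' @export
run_random_search <- function(dataset, config = search_config(), seed = NULL,
                              budget = config$evaluation_budget, ek = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  budget <- as.integer(budget)
  if (budget < 1L) abort("`budget` must be >= 1.")
  runner <- function() {
    if (is.null(ek)) ek <- build_expert_knowledge(dataset)
    n_snps <- dataset$n_snps
    evaluator <- make_evaluator(dataset, ek, budget)
    archive <- empty_pop()
    batch_size <- 1000L
    while (!evaluator$exhausted()) {
      before <- evaluator$evals()
      draws <- purrr::map(seq_len(batch_size),
                          ~ sample_initial_model(ek, n_snps, config,
                                                 ek_seed_prob = 0))
      sc <- evaluator$evaluate(draws)
      ok <- !is.na(sc[, 1L])
      if (any(ok)) {
        archive <- archive_update(
          archive, new_population(draws[ok], sc[ok, , drop = FALSE])
        )
      }
      if (evaluator$evals() == before) break  # only duplicates remain
    }
    search_result("random", archive, dataset, evaluator$evals(),
                  tibble::tibble(), seed, config,
                  n_front_final_pop = 0L,
                  n_front_archive = pop_size(archive))
  }
  if (is.null(seed)) runner() else withr::with_seed(seed, runner())
}
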