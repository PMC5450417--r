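# NSGA-II machinery on the three search objectives:
# maximize t_statistic, maximize interaction_info, minimize size.

# Internal core: 0-based Pareto ranks from three objective vectors.
# Model a dominates b iff a >= b on t and ig, a <= b on size, and strictly
# better on at least one; equal-objective duplicates never dominate each
# other and therefore share a rank.
nds_ranks <- function(t_stat, ig, size) {
  n <- length(t_stat)
  if (n == 0L) return(integer(0))
  if (anyNA(t_stat) || anyNA(ig) || anyNA(size)) {
    abort("All models must be scored before ranking.")
  }
  nds_rank_cpp(as.numeric(t_stat), as.numeric(ig), as.numeric(size))
}

# Internal core: NSGA-II crowding distance for models sharing one front.
# Per objective, boundary models get +Inf; interior models accumulate the
# normalized gap between their neighbours; a zero objective range
# contributes 0.
crowding_core <- function(t_stat, ig, size) {
  n <- length(t_stat)
  if (n == 0L) abort("Empty front.")
  crowding_cpp(as.numeric(t_stat), as.numeric(ig), as.numeric(size))
}

# rank + crowding for a whole population (crowding computed per front)
rank_and_crowd <- function(t_stat, ig, size) {
  if (anyNA(t_stat) || anyNA(ig) || anyNA(size)) {
    abort("All models must be scored before ranking.")
  }
  rank_and_crowd_cpp(as.numeric(t_stat), as.numeric(ig), as.numeric(size))
}

check_scores <- function(scores) {
  need <- c("t_statistic", "interaction_info", "size")
  if (!all(need %in% names(scores))) {
    abort(sprintf("`scores` must contain columns %s.", paste(need, collapse = ", ")))
  }
  invisible(scores)
}

#' Nondominated (Pareto) sorting of scored models
#'
#' Assigns the standard NSGA-II front ranks under the three objectives:
#' maximize the t-statistic, maximize the mean interaction information,
#' minimize model size. Rank 0 is the Pareto front.
#'
#' @param scores A data frame with columns `t_statistic`,
#'   `interaction_info` and `size` (one row per scored model).
#' @return The input as a tibble with a `pareto_rank` column (0-based).
#' @export
#' @examples
#' nondominated_sort(tibble::tibble(
#'   t_statistic = c(3, 2), interaction_info = c(0.2, 0.1), size = c(2, 3)
#' ))
nondominated_sort <- function(scores) {
  check_scores(scores)
  out <- tibble::as_tibble(scores)
  out$pareto_rank <- nds_ranks(scores$t_statistic, scores$interaction_info,
                               scores$size)
  out
}

#' NSGA-II crowding distance within one front
#'
#' @param front A data frame of models sharing a Pareto rank, with columns
#'   `t_statistic`, `interaction_info`, `size`.
#' @return The input as a tibble with a `crowding` column (boundary models
#'   per objective get `Inf`).
#' @export
crowding_distance <- function(front) {
  check_scores(front)
  if (nrow(front) == 0L) abort("Empty front.")
  out <- tibble::as_tibble(front)
  out$crowding <- crowding_core(front$t_statistic, front$interaction_info,
                                front$size)
  out
}

#' Tournament selection by Pareto rank and crowding distance
#'
#' Draws `size` entrants uniformly with replacement and returns the one
#' with the lowest Pareto rank, ties broken by highest crowding distance,
#' remaining ties broken at random.
#'
#' @param pop A data frame with columns `pareto_rank` and `crowding`.
#' @param size Tournament size (default 3).
#' @return The index (row number) of the winning model.
#' @export
tournament_rank_crowding <- function(pop, size = 3L) {
  n <- nrow(pop)
  if (is.null(n) || n == 0L) abort("Empty population.")
  ent <- sample.int(n, size, replace = TRUE)
  win <- ent[order(pop$pareto_rank[ent], -pop$crowding[ent], runif(size))][1L]
  win
}

#' Parsimony tournament selection by model size
#'
#' Draws `size` entrants uniformly with replacement and returns the one
#' with the smallest model order (number of SNPs), ties broken at random.
#' Pairing this with [tournament_rank_crowding()] applies parsimony
#' pressure without a priori limits on model order.
#'
#' @param pop A data frame with a `size` column.
#' @param size Tournament size (default 6).
#' @return The index (row number) of the winning model.
#' @export
tournament_parsimony <- function(pop, size = 6L) {
  n <- nrow(pop)
  if (is.null(n) || n == 0L) abort("Empty population.")
  ent <- sample.int(n, size, replace = TRUE)
  ent[order(pop$size[ent], runif(size))][1L]
}

# Keep only nondominated rows (rank 0) of a score table; used for the
# running Pareto archive. Returns row indices.
nondominated_idx <- function(t_stat, ig, size) {
  which(nds_ranks(t_stat, ig, size) == 0L)
}
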