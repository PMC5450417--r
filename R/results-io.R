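#' Write search results to disk
#'
#' Writes the Pareto front as a flat TSV (one row per model: SNP ids,
#' t-statistic, mean interaction information, size, Pareto rank) and,
#' alongside it, a JSON file (`<path>.json`) carrying the models, a
#' configuration echo, the seed and the evaluation count, so a result can
#' be reloaded with identical objective values.
#'
#' @param result An `mdr_search_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_search_results <- function(result, path) {
  stopifnot(inherits(result, "mdr_search_result"))
  if (nrow(result$pareto_front) == 0L) abort("Refusing to write an empty front.")
  flat <- result$pareto_front |>
    dplyr::select("snp_ids", "t_statistic", "interaction_info", "size",
                  "pareto_rank")
  readr::write_tsv(flat, path, progress = FALSE)
  payload <- list(
    engine = result$engine,
    models = purrr::pmap(result$pareto_front, function(snps, snp_ids,
                                                       t_statistic,
                                                       interaction_info, size,
                                                       valid, pareto_rank) {
      list(snps = snps, snp_ids = snp_ids, t_statistic = t_statistic,
           interaction_info = interaction_info, size = size, valid = valid,
           pareto_rank = pareto_rank)
    }),
    evaluations = result$evaluations,
    seed = result$seed,
    config = unclass(result$config),
    n_front_final_pop = result$n_front_final_pop,
    n_front_archive = result$n_front_archive
  )
  jsonlite::write_json(payload, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Read back search results written by [write_search_results()]
#'
#' @param path The TSV path given to [write_search_results()].
#' @return A list with `front` (tibble identical in objective values to the
#'   written front) and `meta` (the JSON payload).
#' @export
read_search_results <- function(path) {
  front <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  front$size <- as.integer(front$size)
  front$pareto_rank <- as.integer(front$pareto_rank)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = FALSE)
  }
  list(front = front, meta = meta)
}

#' Write a simulation-study result table
#'
#' Long-format TSV, one row per cell per engine, the canonical artifact of
#' the experiment module (heatmaps are rendered from it).
#'
#' @param experiment An `epistasis_experiment` from [run_grid()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_experiment_results <- function(experiment, path) {
  stopifnot(inherits(experiment, "epistasis_experiment"))
  readr::write_tsv(experiment$cells, path, progress = FALSE)
  invisible(path)
}
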