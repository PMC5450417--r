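# Simulation-study harness: per-cell detection success for the
# evolutionary search and the matched-budget random baseline.

success_criteria <- c("front_union_contains_all", "best_model_contains_all",
                      "best_model_exact")

#' Did a search identify the planted functional SNPs?
#'
#' Three criteria of increasing strictness:
#' * `front_union_contains_all` - every functional SNP appears in at least
#'   one Pareto-front model (gene/pathway-level identification; default).
#' * `best_model_contains_all` - the front model with the highest
#'   t-statistic contains all functional SNPs.
#' * `best_model_exact` - that model's SNP set equals the functional set.
#'
#' @param result An `mdr_search_result`.
#' @param truth The [truth_set()] of the same dataset.
#' @param dataset The [genotype_dataset()] the search ran on (maps SNP
#'   indices back to ids).
#' @param criterion One of the three criteria above.
#' @return Logical scalar (an empty front warns and returns `FALSE`).
#' @export
is_success <- function(result, truth, dataset,
                       criterion = success_criteria) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(result, "mdr_search_result"), inherits(truth, "truth_set"))
  front <- result$pareto_front
  if (nrow(front) == 0L) {
    warn("Empty Pareto front; scoring as failure.")
    return(FALSE)
  }
  target <- truth$functional_snp_ids
  if (criterion == "front_union_contains_all") {
    found <- unique(dataset$snp_ids[unlist(front$snps)])
    return(all(target %in% found))
  }
  best <- front$snps[[which.max(front$t_statistic)]]
  best_ids <- dataset$snp_ids[best]
  if (criterion == "best_model_contains_all") {
    all(target %in% best_ids)
  } else {
    setequal(target, best_ids)
  }
}

derive_seed <- function(seed, i, j = 0L) {
  # double arithmetic: products can exceed .Machine$integer.max
  as.integer((as.numeric(seed) * 10007 + as.numeric(i) * 101 + j) %% 2147483629)
}

#' Run one simulation-study cell
#'
#' Simulates `spec$replicates` datasets (seeds derived from `seed`), runs
#' the evolutionary search and the random baseline on each with identical
#' evaluation budgets, and records success under all three criteria per
#' replicate.
#'
#' @param spec A [simulation_spec()].
#' @param config A [search_config()] shared by both engines.
#' @param criterion The headline criterion for the summary rates.
#' @param seed Integer root seed for the cell.
#' @param engines Which engines to run.
#' @param verbose Print a line per replicate.
#' @return A list of class `cell_result`: `summary` (tibble, one row per
#'   engine with `success_rate` = successes / replicates exactly),
#'   `detail` (tibble, one row per replicate per engine), `spec`,
#'   `criterion`, `budget`, `seed`.
#' @export
run_cell <- function(spec, config = search_config(),
                     criterion = success_criteria, seed = 1L,
                     engines = c("evolutionary", "random"),
                     verbose = FALSE) {
  criterion <- match.arg(criterion)
  engines <- match.arg(engines, several.ok = TRUE)
  stopifnot(inherits(spec, "simulation_spec"), inherits(config, "search_config"))
  rows <- list()
  for (r in seq_len(spec$replicates)) {
    sim <- simulate_epistasis(spec, seed = derive_seed(seed, r, 1L))
    ek <- build_expert_knowledge(sim$dataset)
    for (engine in engines) {
      res <- if (engine == "evolutionary") {
        run_mdr_search(sim$dataset, config, seed = derive_seed(seed, r, 2L),
                       ek = ek)
      } else {
        run_random_search(sim$dataset, config, seed = derive_seed(seed, r, 3L),
                          budget = config$evaluation_budget, ek = ek)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r,
        engine = engine,
        evaluations = res$evaluations,
        front_size = nrow(res$pareto_front),
        best_t = if (nrow(res$pareto_front)) max(res$pareto_front$t_statistic) else NA_real_,
        front_union_contains_all = is_success(res, sim$truth, sim$dataset,
                                              "front_union_contains_all"),
        best_model_contains_all = is_success(res, sim$truth, sim$dataset,
                                             "best_model_contains_all"),
        best_model_exact = is_success(res, sim$truth, sim$dataset,
                                      "best_model_exact")
      )
      if (verbose) {
        inform(sprintf("replicate %d [%s]: %d evals, success = %s", r, engine,
                       res$evaluations,
                       rows[[length(rows)]][[criterion]]))
      }
    }
  }
  detail <- dplyr::bind_rows(rows)
  summary <- detail |>
    dplyr::group_by(.data$engine) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      successes = sum(.data[[criterion]]),
      success_rate = sum(.data[[criterion]]) / dplyr::n(),
      mean_evaluations = mean(.data$evaluations),
      .groups = "drop"
    )
  structure(
    list(summary = summary, detail = detail, spec = spec,
         criterion = criterion, budget = config$evaluation_budget,
         seed = seed),
    class = "cell_result"
  )
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf(
    "<cell_result> %d genes, maf %g, h2 %g, sd %g, n %d, %d SNPs; criterion %s\n",
    x$spec$n_genes, x$spec$maf, x$spec$heritability, x$spec$trait_sd,
    x$spec$n_samples, x$spec$n_total_snps, x$criterion
  ))
  print(x$summary)
  invisible(x)
}

cell_tag <- function(spec) {
  sprintf("g%d_maf%g_h%g_sd%g_n%d_m%d", spec$n_genes, spec$maf,
          spec$heritability, spec$trait_sd, spec$n_samples, spec$n_total_snps)
}

spec_summary_cols <- function(spec) {
  tibble::tibble(
    n_genes = spec$n_genes, maf = spec$maf, heritability = spec$heritability,
    trait_sd = spec$trait_sd, n_samples = spec$n_samples,
    n_total_snps = spec$n_total_snps
  )
}

#' Run a grid of simulation-study cells
#'
#' Runs [run_cell()] for every spec in `specs` and collects a long-format
#' table (one row per cell per engine) suitable for heatmap rendering.
#' When `checkpoint_dir` is given, each completed cell's detail table is
#' written there as TSV and already-checkpointed cells are skipped on
#' rerun, so an interrupted grid resumes to the identical final table.
#'
#' @param specs A list of [simulation_spec()]s.
#' @param config A [search_config()].
#' @param criterion Headline success criterion.
#' @param seed Root seed; cell c uses a derived seed.
#' @param checkpoint_dir Optional directory for per-cell checkpoints.
#' @param engines Engines to run.
#' @param verbose Passed to [run_cell()].
#' @return An object of class `epistasis_experiment`: `cells` (long summary
#'   tibble), `detail`, `criterion`, `budget`, `seed`.
#' @export
run_grid <- function(specs, config = search_config(),
                     criterion = success_criteria, seed = 1L,
                     checkpoint_dir = NULL,
                     engines = c("evolutionary", "random"),
                     verbose = FALSE) {
  criterion <- match.arg(criterion)
  engines <- match.arg(engines, several.ok = TRUE)
  if (!length(specs)) abort("`specs` must be non-empty.")
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  details <- purrr::imap(specs, function(spec, ci) {
    cell_seed <- derive_seed(seed, 1000L + ci)
    ckpt <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, paste0(cell_tag(spec), ".tsv"))
    }
    if (!is.null(ckpt) && file.exists(ckpt)) {
      detail <- readr::read_tsv(ckpt, show_col_types = FALSE, progress = FALSE)
    } else {
      cell <- run_cell(spec, config, criterion, seed = cell_seed,
                       engines = engines, verbose = verbose)
      detail <- cell$detail
      if (!is.null(ckpt)) readr::write_tsv(detail, ckpt, progress = FALSE)
    }
    dplyr::bind_cols(spec_summary_cols(spec)[rep(1L, nrow(detail)), ], detail)
  })
  detail <- dplyr::bind_rows(details)
  cells <- detail |>
    dplyr::group_by(.data$n_genes, .data$maf, .data$heritability,
                    .data$trait_sd, .data$n_samples, .data$n_total_snps,
                    .data$engine) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      successes = sum(.data[[criterion]]),
      success_rate = sum(.data[[criterion]]) / dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(cells = cells, detail = detail, criterion = criterion,
         budget = config$evaluation_budget, seed = seed),
    class = "epistasis_experiment"
  )
}

#' @export
print.epistasis_experiment <- function(x, ...) {
  cat(sprintf("<epistasis_experiment> %d cells, criterion %s, budget %d\n",
              nrow(x$cells), x$criterion, x$budget))
  print(x$cells, n = 20)
  invisible(x)
}

#' Preset simulation grids
#'
#' `grid-100` is the 100-SNP version of the full simulation-study grid
#' (2 and 4 genes; MAF 0.2, 0.4; heritability 0.001, 0.01, 0.1, 0.2;
#' trait SD 0.05, 0.1, 0.2, 0.3; n 2000, 8000); `grid-1000` is the same at
#' 1000 total SNPs. `smoke` is a 2-cell grid for quick checks.
#'
#' @param preset Preset name.
#' @param replicates Replicates per cell.
#' @return A list of [simulation_spec()]s.
#' @export
grid_preset <- function(preset = c("grid-100", "grid-1000", "smoke"),
                        replicates = 10L) {
  preset <- match.arg(preset)
  if (preset == "smoke") {
    return(list(
      simulation_spec(2L, 0.4, 0.2, 0.05, 500L, 20L, replicates),
      simulation_spec(2L, 0.4, 0.1, 0.05, 500L, 20L, replicates)
    ))
  }
  m <- if (preset == "grid-100") 100L else 1000L
  grid <- expand.grid(
    n_genes = c(2L, 4L), maf = c(0.2, 0.4),
    heritability = c(0.001, 0.01, 0.1, 0.2),
    trait_sd = c(0.05, 0.1, 0.2, 0.3),
    n_samples = c(2000L, 8000L),
    KEEP.OUT.ATTRS = FALSE
  )
  purrr::pmap(grid, function(n_genes, maf, heritability, trait_sd, n_samples) {
    simulation_spec(n_genes, maf, heritability, trait_sd, n_samples, m,
                    replicates)
  })
}
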