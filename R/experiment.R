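# The full experiment grid: stimulus levels x aging presets x replicates,
# each replicate simulated, analysed for pairwise TE, and summarised as a
# quartile-criterion bipartite network with its F/M centrality ratio.

#' Define an experiment plan
#'
#' The reference study design crosses four stimulus levels (0, 0.2, 0.4,
#' 0.8) with the three aging presets, ten replicates each. Any scale
#' parameter can be reduced for quicker runs.
#'
#' @param stimuli Numeric vector of stimulus levels.
#' @param presets Character vector of aging presets.
#' @param replicates Replicates per condition (>= 1).
#' @param base_seed Base RNG seed; every (condition, replicate) derives a
#'   distinct seed from it.
#' @param grid_rows,grid_cols,n_iterations Scale of each run.
#' @param bins,min_samples TE estimation settings (see [pairwise_te()]).
#' @param ... Further arguments passed to [simulation_params()].
#' @return A list of class `experiment_plan`.
#' @export
experiment_plan <- function(stimuli = c(0, 0.2, 0.4, 0.8),
                            presets = c("N", "A1", "A2"),
                            replicates = 10L,
                            base_seed = 1L,
                            grid_rows = 100L, grid_cols = 100L,
                            n_iterations = 1000L,
                            bins = 20L, min_samples = 50L, ...) {
  stopifnot(replicates >= 1L)
  structure(
    list(stimuli = stimuli, presets = presets,
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         n_iterations = as.integer(n_iterations),
         bins = as.integer(bins), min_samples = as.integer(min_samples),
         extra = list(...)),
    class = "experiment_plan"
  )
}

condition_seed <- function(plan, cond_index) {
  plan$base_seed + 1000L * cond_index
}

#' Run the full experiment
#'
#' For every (stimulus, preset) condition: simulates the replicates,
#' computes pairwise macrophage-to-fibroblast transfer entropy per
#' replicate, pools the defined TE values into the condition's quartile edge
#' criterion, builds one bipartite network and one F/M ratio per replicate,
#' and assembles a master table. A failing condition is recorded and the
#' remaining conditions proceed. The result is fully reproducible from the
#' plan (including `base_seed`).
#'
#' @param plan An [experiment_plan()].
#' @param out_dir Optional directory; when given, the master table, the
#'   per-condition TE tables and F/M summaries are written as CSV.
#' @param verbose Print one line per condition as it completes.
#' @return An object of class `inflammation_experiment` with elements
#'   `plan`, `conditions` (per-condition list: params, courses tibble,
#'   te tibble, networks = [condition_summary()] result, error message or
#'   NULL, plus `pooled_te`: the condition-level TE table with triples
#'   pooled across replicates) and `master` (tibble: stimulus, preset,
#'   replicate, seed, final_score, peak_score, mean_te, pooled_te, n_edges,
#'   f_sum, m_sum, fm_ratio).
#' @export
run_experiment <- function(plan, out_dir = NULL, verbose = FALSE) {
  grid <- expand.grid(preset = plan$presets, stimulus = plan$stimuli,
                      stringsAsFactors = FALSE)
  conditions <- list()
  master <- list()
  for (k in seq_len(nrow(grid))) {
    S <- grid$stimulus[k]; preset <- grid$preset[k]
    label <- sprintf("S%g_%s", S, preset)
    res <- tryCatch({
      params <- do.call(simulation_params, c(
        list(stimulus = S, preset = preset,
             grid_rows = plan$grid_rows, grid_cols = plan$grid_cols,
             n_iterations = plan$n_iterations,
             seed = condition_seed(plan, k)),
        plan$extra))
      sims <- run_replicates(params, plan$replicates,
                             base_seed = condition_seed(plan, k))
      te_tables <- lapply(sims, function(s) {
        pairwise_te(s$tracks, bins = plan$bins,
                    min_samples = plan$min_samples)
      })
      pooled_te <- pairwise_te(lapply(sims, function(s) s$tracks),
                               bins = plan$bins,
                               min_samples = plan$min_samples)
      nets <- condition_summary(te_tables)
      courses <- purrr::imap(sims, function(s, i) {
        dplyr::mutate(s$course, replicate = i)
      }) |> purrr::list_rbind()
      te_long <- purrr::imap(te_tables, function(x, i) {
        dplyr::mutate(tibble::as_tibble(x), replicate = i)
      }) |> purrr::list_rbind()
      rows <- purrr::imap(sims, function(s, i) {
        te <- te_tables[[i]]$te
        nr <- nets$replicates[nets$replicates$replicate == i, ]
        tibble::tibble(
          stimulus = S, preset = preset, replicate = i, seed = s$seed,
          final_score = s$course$score[nrow(s$course)],
          peak_score = max(s$course$score),
          mean_te = mean(te, na.rm = TRUE),
          pooled_te = mean(pooled_te$te, na.rm = TRUE),
          n_edges = nr$n_edges, f_sum = nr$f_sum, m_sum = nr$m_sum,
          fm_ratio = nr$fm_ratio)
      }) |> purrr::list_rbind()
      list(params = params, courses = courses, te = te_long,
           pooled_te = pooled_te, networks = nets, error = NULL, rows = rows)
    }, error = function(e) {
      list(params = NULL, courses = NULL, te = NULL, pooled_te = NULL,
           networks = NULL, error = conditionMessage(e), rows = NULL)
    })
    conditions[[label]] <- res[setdiff(names(res), "rows")]
    if (!is.null(res$rows)) master[[label]] <- res$rows
    if (verbose) {
      msg <- if (is.null(res$error)) {
        sprintf("mean F/M %.3f", res$networks$mean_fm)
      } else paste("ERROR:", res$error)
      message(sprintf("[%s] %s", label, msg))
    }
  }
  master <- purrr::list_rbind(master)
  out <- structure(list(plan = plan, conditions = conditions, master = master),
                   class = "inflammation_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.inflammation_experiment <- function(x, ...) {
  cat("<inflammation_experiment>\n")
  cat(sprintf("  %d conditions x %d replicates (%d x %d grid, %d iterations)\n",
              length(x$conditions), x$plan$replicates,
              x$plan$grid_rows, x$plan$grid_cols, x$plan$n_iterations))
  failed <- names(Filter(function(c) !is.null(c$error), x$conditions))
  if (length(failed)) cat("  failed:", paste(failed, collapse = ", "), "\n")
  print(glance(x))
  invisible(x)
}

#' Per-replicate master table of an experiment
#'
#' @param x An `inflammation_experiment`.
#' @param ... Unused.
#' @return The master tibble, one row per (condition, replicate).
#' @method tidy inflammation_experiment
#' @export
tidy.inflammation_experiment <- function(x, ...) x$master

#' Per-condition summary of an experiment
#'
#' @param x An `inflammation_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per condition: mean final and peak
#'   inflammation scores, mean defined TE, mean F/M ratio and its standard
#'   error over replicates.
#' @method glance inflammation_experiment
#' @export
glance.inflammation_experiment <- function(x, ...) {
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  }
  x$master |>
    dplyr::group_by(.data$stimulus, .data$preset) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      mean_final_score = mean(.data$final_score),
      mean_peak_score = mean(.data$peak_score),
      mean_te = mean(.data$mean_te, na.rm = TRUE),
      pooled_te = mean(.data$pooled_te),
      mean_fm = mean(.data$fm_ratio, na.rm = TRUE),
      se_fm = se(.data$fm_ratio),
      .groups = "drop")
}

#' Write experiment artefacts as CSV
#'
#' Writes the master table plus, per condition, the TE long table, the
#' replicate network summaries and the pooled betweenness values.
#'
#' @param experiment An `inflammation_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(experiment$master, file.path(dir, "master.csv"),
                   row.names = FALSE)
  utils::write.csv(glance(experiment), file.path(dir, "condition_summary.csv"),
                   row.names = FALSE)
  for (label in names(experiment$conditions)) {
    cond <- experiment$conditions[[label]]
    if (!is.null(cond$error)) next
    utils::write.csv(cond$te, file.path(dir, paste0("te_", label, ".csv")),
                     row.names = FALSE)
    utils::write.csv(cond$networks$betweenness,
                     file.path(dir, paste0("betweenness_", label, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Report tables of an experiment
#'
#' Recomputes presentation tables from the archived intermediates: the mean
#' inflammation course with standard error per condition, the per-condition
#' TE distribution summaries, the pooled betweenness values per part, and
#' the F/M ratio table.
#'
#' @param experiment An `inflammation_experiment`.
#' @return A list of tibbles: `course`, `te_distribution`, `betweenness`,
#'   `fm`, and `missing` (labels of failed conditions).
#' @export
experiment_report <- function(experiment) {
  ok <- Filter(function(c) is.null(c$error), experiment$conditions)
  condition_tbl <- function(f) {
    purrr::imap(ok, f) |> purrr::list_rbind()
  }
  course <- condition_tbl(function(c, label) {
    c$courses |>
      dplyr::group_by(.data$t) |>
      dplyr::summarise(
        mean_score = mean(.data$score),
        se_score = if (dplyr::n() > 1L) {
          stats::sd(.data$score) / sqrt(dplyr::n())
        } else 0,
        .groups = "drop") |>
      dplyr::mutate(condition = label,
                    stimulus = c$params$stimulus,
                    preset = c$params$aging$preset)
  })
  te_distribution <- condition_tbl(function(c, label) {
    dplyr::mutate(c$te, condition = label, stimulus = c$params$stimulus,
                  preset = c$params$aging$preset)
  })
  betweenness <- condition_tbl(function(c, label) {
    dplyr::mutate(c$networks$betweenness, condition = label,
                  stimulus = c$params$stimulus,
                  preset = c$params$aging$preset)
  })
  fm <- condition_tbl(function(c, label) {
    tibble::tibble(condition = label, stimulus = c$params$stimulus,
                   preset = c$params$aging$preset,
                   mean_fm = c$networks$mean_fm, se_fm = c$networks$se_fm)
  })
  missing <- names(Filter(function(c) !is.null(c$error),
                          experiment$conditions))
  if (length(missing)) {
    warning("conditions missing from the report: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  list(course = course, te_distribution = te_distribution,
       betweenness = betweenness, fm = fm, missing = missing)
}
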