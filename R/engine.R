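# Simulation engine. Per iteration: motile cells update one at a time in a
# seeded random permutation (activation, Beta-gated synthesis, chemotactic
# movement, aging), then the epithelium updates, removed slots are refilled
# on the repopulation schedule, and finally both cytokine fields take one
# diffusion-decay step. Identical (params, seed) gives a bit-identical run.

#' Run one inflammation simulation
#'
#' Executes the full agent-based model for `params$n_iterations` iterations
#' on an initially healthy (all-alive) epithelium with zero cytokine,
#' macrophages and fibroblasts placed uniformly at random on distinct sites.
#' Records per-iteration motile-cell tracks, the inflammation score (dead
#' epithelial cell count) and grid-mean cytokine concentrations.
#'
#' @param params A [simulation_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return An object of class `inflammation_sim`: a list with
#' \describe{
#'   \item{tracks}{tibble (t, slot_id, kind, segment, row, col), one row per
#'     living motile cell per iteration, t = 0 .. n_iterations. `segment`
#'     numbers the disjoint cell lifetimes occupying a slot.}
#'   \item{course}{tibble (t, score, mean_tnf, mean_tgf).}
#'   \item{tnf, tgf}{final concentration matrices.}
#'   \item{epithelium}{final [epithelium()] state.}
#'   \item{params, seed}{the configuration used.}
#' }
#' @examples
#' sim <- simulate_inflammation(
#'   simulation_params(stimulus = 0.4, preset = "N", grid_rows = 30,
#'                     grid_cols = 30, n_iterations = 50, seed = 1))
#' max(sim$course$score)
#' @export
simulate_inflammation <- function(params, seed = NULL) {
  validate_params(params)
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  set.seed(seed)

  nr <- params$grid_rows; nc <- params$grid_cols
  n_m <- params$n_macrophages; n_f <- params$n_fibroblasts
  n_cells <- n_m + n_f
  aging <- params$aging
  temp <- params$chemotaxis_temperature
  vel <- params$cell_velocity
  tim <- params$cell_lifetime
  n_iter <- params$n_iterations

  tnf <- matrix(0, nr, nc)
  tgf <- matrix(0, nr, nc)
  epi <- epithelium(nr, nc)

  # cell state vectors; macrophages first, slots numbered within kind
  kind <- rep(c(1L, 2L), c(n_m, n_f))       # 1 macrophage, 2 fibroblast
  slot <- c(seq_len(n_m), seq_len(n_f))
  start <- sample.int(nr * nc, n_cells)     # distinct initial sites
  crow <- ((start - 1L) %% nr) + 1L
  ccol <- ((start - 1L) %/% nr) + 1L
  activated <- rep(FALSE, n_cells)
  mobile <- rep(TRUE, n_cells)
  alive <- rep(TRUE, n_cells)
  age <- rep(0L, n_cells)
  lifespan <- rep(tim, n_cells)
  segment <- rep(1L, n_cells)
  occ <- matrix(FALSE, nr, nc)
  occ[cbind(crow, ccol)] <- TRUE

  # per-iteration records (t = 0 .. n_iter)
  rec_row <- matrix(NA_integer_, n_iter + 1L, n_cells)
  rec_col <- matrix(NA_integer_, n_iter + 1L, n_cells)
  rec_seg <- matrix(NA_integer_, n_iter + 1L, n_cells)
  score <- integer(n_iter + 1L)
  mean_tnf <- numeric(n_iter + 1L)
  mean_tgf <- numeric(n_iter + 1L)
  rec_row[1L, ] <- crow; rec_col[1L, ] <- ccol; rec_seg[1L, ] <- segment

  nb_max <- function(f, r, c) {
    max(f[max(1L, r - 1L):min(nr, r + 1L), max(1L, c - 1L):min(nc, c + 1L)])
  }

  for (t in seq_len(n_iter)) {
    for (i in sample.int(n_cells)) {
      if (!alive[i]) next
      r <- crow[i]; c <- ccol[i]

      if (!activated[i]) {
        if (kind[i] == 1L) {
          p <- macrophage_activation_prob(params$stimulus, nb_max(tnf, r, c),
                                          initial = t == 1L)
        } else {
          p <- fibroblast_activation_prob(nb_max(tnf, r, c))
        }
        if (p > 0 && stats::runif(1L) < p) {
          activated[i] <- TRUE
          if (kind[i] == 2L) {          # settles at the injury site
            mobile[i] <- FALSE
            remaining <- lifespan[i] - age[i]
            lifespan[i] <- age[i] + as.integer(floor(0.25 * remaining))
          }
        }
      }

      if (activated[i]) {
        if (kind[i] == 1L) {
          if (tnf_release(tgf[r, c], aging)) tnf[r, c] <- tnf[r, c] + 1
        } else {
          if (tgf_release(tnf[r, c], aging)) tgf[r, c] <- tgf[r, c] + 1
        }
      }

      if (mobile[i]) {
        f <- if (kind[i] == 1L) tnf else tgf
        for (s in seq_len(vel)) {
          pos <- chemotaxis_step(crow[i], ccol[i], f, occ, temp)
          if (pos[1L] != crow[i] || pos[2L] != ccol[i]) {
            occ[crow[i], ccol[i]] <- FALSE
            occ[pos[1L], pos[2L]] <- TRUE
            crow[i] <- pos[1L]; ccol[i] <- pos[2L]
          }
        }
      }

      age[i] <- age[i] + 1L
      if (age[i] >= lifespan[i]) {      # lifespan exhausted: slot falls empty
        alive[i] <- FALSE
        occ[crow[i], ccol[i]] <- FALSE
      }
    }

    epi <- update_epithelium(epi, tnf, tgf, aging)

    if (t %% params$repopulation_interval == 0L && any(!alive)) {
      for (i in which(!alive)) {
        free <- which(!occ)
        if (!length(free)) break        # refill deferred to next interval
        site <- free[sample.int(length(free), 1L)]
        crow[i] <- ((site - 1L) %% nr) + 1L
        ccol[i] <- ((site - 1L) %/% nr) + 1L
        occ[site] <- TRUE
        alive[i] <- TRUE
        activated[i] <- FALSE
        mobile[i] <- TRUE
        age[i] <- 0L
        lifespan[i] <- tim
        segment[i] <- segment[i] + 1L
      }
    }

    tnf <- field_step(tnf, params$tnf)
    tgf <- field_step(tgf, params$tgf)

    k <- t + 1L
    live <- alive
    rec_row[k, live] <- crow[live]
    rec_col[k, live] <- ccol[live]
    rec_seg[k, live] <- segment[live]
    score[k] <- inflammation_score(epi)
    mean_tnf[k] <- mean(tnf)
    mean_tgf[k] <- mean(tgf)
  }

  keep <- !is.na(rec_row)
  tracks <- tibble::tibble(
    t = rep(0:n_iter, times = n_cells)[as.vector(keep)],
    slot_id = rep(slot, each = n_iter + 1L)[as.vector(keep)],
    kind = c("macrophage", "fibroblast")[rep(kind, each = n_iter + 1L)[as.vector(keep)]],
    segment = as.vector(rec_seg)[as.vector(keep)],
    row = as.vector(rec_row)[as.vector(keep)],
    col = as.vector(rec_col)[as.vector(keep)]
  )
  tracks <- dplyr::arrange(tracks, .data$kind, .data$slot_id, .data$t)

  structure(
    list(tracks = tracks,
         course = tibble::tibble(t = 0:n_iter, score = score,
                                 mean_tnf = mean_tnf, mean_tgf = mean_tgf),
         tnf = tnf, tgf = tgf, epithelium = epi,
         params = params, seed = seed),
    class = "inflammation_sim"
  )
}

#' Run replicate simulations
#'
#' Repeats [simulate_inflammation()] with seeds `base_seed + 0 ...
#' base_seed + n - 1`.
#'
#' @param params A [simulation_params()] object.
#' @param n_replicates Number of independent runs.
#' @param base_seed First seed.
#' @return A list of `inflammation_sim` objects.
#' @export
run_replicates <- function(params, n_replicates, base_seed = params$seed) {
  stopifnot(n_replicates >= 1L)
  lapply(seq_len(n_replicates) - 1L, function(k) {
    simulate_inflammation(params, seed = base_seed + k)
  })
}

#' @export
print.inflammation_sim <- function(x, ...) {
  cat("<inflammation_sim>\n")
  cat(sprintf("  S = %g, preset %s, %d x %d grid, %d iterations, seed %d\n",
              x$params$stimulus, x$params$aging$preset, x$params$grid_rows,
              x$params$grid_cols, x$params$n_iterations, x$seed))
  cat(sprintf("  final score %d (peak %d); %d track records\n",
              x$course$score[nrow(x$course)], max(x$course$score),
              nrow(x$tracks)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the inflammation time course
#'
#' @param x An `inflammation_sim`.
#' @param ... Unused.
#' @return The course tibble (t, score, mean_tnf, mean_tgf).
#' @method tidy inflammation_sim
#' @export
tidy.inflammation_sim <- function(x, ...) x$course

#' One-row summary of a simulation run
#'
#' @param x An `inflammation_sim`.
#' @param ... Unused.
#' @return A tibble with stimulus, preset, seed, peak and final inflammation
#'   score, and peak grid-mean cytokine concentrations.
#' @method glance inflammation_sim
#' @export
glance.inflammation_sim <- function(x, ...) {
  tibble::tibble(
    stimulus = x$params$stimulus,
    preset = x$params$aging$preset,
    seed = x$seed,
    peak_score = max(x$course$score),
    final_score = x$course$score[nrow(x$course)],
    peak_mean_tnf = max(x$course$mean_tnf),
    peak_mean_tgf = max(x$course$mean_tgf)
  )
}

#' Write a run archive
#'
#' Dumps a simulation to a directory as plain-text artefacts: the resolved
#' YAML config, the track table and the inflammation course as CSV, and the
#' final cytokine fields as CSV matrices, so the analysis stage is fully
#' decoupled from the simulator.
#'
#' @param sim An `inflammation_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_archive <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- sim$params; p$seed <- sim$seed
  write_sim_config(p, file.path(dir, "config.yaml"))
  utils::write.csv(sim$tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(sim$course, file.path(dir, "course.csv"), row.names = FALSE)
  utils::write.table(sim$tnf, file.path(dir, "tnf_final.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$tgf, file.path(dir, "tgf_final.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a track table written by [write_run_archive()]
#'
#' Accepts any CSV with columns t, slot_id, kind, segment, row, col --
#' including externally produced tracking tables -- and returns it as the
#' tibble the analysis functions expect.
#'
#' @param path CSV file path.
#' @return A track tibble.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "slot_id", "kind", "segment", "row", "col")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("track table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df[need])
}
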