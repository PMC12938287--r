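#' Aging presets for the inflammation model
#'
#' Returns the parameter set describing one of the three aging conditions of
#' the model: `"N"` (normal), `"A1"` (moderate aging) and `"A2"` (severe
#' aging). Aging is encoded as (i) enhanced TNF synthesis (Beta-gate
#' parameters `tnf_synth_alpha`/`tnf_synth_beta` shifted toward higher
#' draws), (ii) increased apoptosis sensitivity (lower `apoptosis_threshold`),
#' (iii) impaired regeneration (lower `mitosis_prob`, longer `healing_time`)
#' and (iv) prolonged fibrosis (`fibrosis_duration`).
#'
#' @param name One of `"N"`, `"A1"`, `"A2"`.
#'
#' @return An object of class `aging_params`: a named list with fields
#'   `preset`, `tnf_synth_alpha`, `tnf_synth_beta`, `tgf_synth_alpha`,
#'   `tgf_synth_beta`, `apoptosis_threshold` (TNF level above which an
#'   epithelial cell dies), `mitosis_prob` (per-iteration regrowth
#'   probability once healing time has elapsed), `healing_time` (iterations
#'   of TGF exposure required before regrowth is possible) and
#'   `fibrosis_duration` (iterations a fibrosis mark persists). Collagen
#'   damage uses probability Nc/9, with Nc the number of fibrosis sites in
#'   the 3x3 Moore block around an epithelial cell.
#'
#' @examples
#' aging_preset("A2")$apoptosis_threshold  # 0.4
#' @export
aging_preset <- function(name) {
  presets <- list(
    N  = list(tnf_synth_alpha = 1.0, tnf_synth_beta = 3.0,
              apoptosis_threshold = 0.8, mitosis_prob = 0.20,
              healing_time = 5L, fibrosis_duration = 50L),
    A1 = list(tnf_synth_alpha = 1.2, tnf_synth_beta = 2.5,
              apoptosis_threshold = 0.6, mitosis_prob = 0.16,
              healing_time = 6L, fibrosis_duration = 75L),
    A2 = list(tnf_synth_alpha = 1.5, tnf_synth_beta = 2.0,
              apoptosis_threshold = 0.4, mitosis_prob = 0.10,
              healing_time = 8L, fibrosis_duration = 100L)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown aging preset: ", deparse(substitute(name)),
         " (expected one of \"N\", \"A1\", \"A2\")", call. = FALSE)
  }
  p <- presets[[name]]
  structure(
    list(preset = name,
         tnf_synth_alpha = p$tnf_synth_alpha,
         tnf_synth_beta = p$tnf_synth_beta,
         tgf_synth_alpha = 2.0,
         tgf_synth_beta = 1.0,
         apoptosis_threshold = p$apoptosis_threshold,
         mitosis_prob = p$mitosis_prob,
         healing_time = p$healing_time,
         fibrosis_duration = p$fibrosis_duration),
    class = "aging_params"
  )
}

#' Cytokine diffusion/degradation parameters
#'
#' @param diffusion Diffusion constant D (lattice units^2 per iteration).
#'   The explicit 5-point scheme with dt = 1 requires D <= 1/4.
#' @param degradation First-order degradation constant K per iteration.
#' @return An object of class `cytokine_params` with fields `diffusion` and
#'   `degradation`.
#' @export
cytokine_params <- function(diffusion, degradation) {
  structure(list(diffusion = as.numeric(diffusion),
                 degradation = as.numeric(degradation)),
            class = "cytokine_params")
}

#' Full simulation configuration
#'
#' Bundles the aging preset, cytokine constants, motile-cell parameters and
#' run control (grid, iterations, seed) into a validated configuration
#' object. Defaults are the model's reference values: 20 macrophages and 20
#' fibroblasts, cell lifetime 20 iterations, velocity 3 sites/iteration,
#' repopulation every 5 iterations, D_TNF = 0.07, D_TGF = 0.10,
#' K_TNF = 1e-3, K_TGF = 1e-5.
#'
#' @param stimulus Mechanical stimulus S in \[0, 1\]; biases the initial
#'   activation probability of macrophages. S = 0 triggers no inflammation.
#' @param preset Aging preset label (`"N"`, `"A1"`, `"A2"`) or an
#'   `aging_params` object.
#' @param grid_rows,grid_cols Lattice dimensions.
#' @param n_iterations Number of iterations to simulate.
#' @param n_macrophages,n_fibroblasts Fixed population sizes.
#' @param cell_lifetime Motile-cell lifespan in iterations (tim).
#' @param cell_velocity Moore sub-steps per iteration.
#' @param repopulation_interval Iterations between population refills (epop).
#' @param tnf,tgf `cytokine_params` for the two species.
#' @param chemotaxis_temperature Softmax temperature of the biased walk;
#'   lower values give stronger chemotactic bias.
#' @param seed Integer RNG seed; a run is bit-reproducible given
#'   (params, seed).
#'
#' @return A validated object of class `sim_params`.
#' @examples
#' p <- simulation_params(stimulus = 0.4, preset = "N", seed = 1)
#' p$aging$apoptosis_threshold
#' @export
simulation_params <- function(stimulus = 0,
                              preset = "N",
                              grid_rows = 100L,
                              grid_cols = 100L,
                              n_iterations = 1000L,
                              n_macrophages = 20L,
                              n_fibroblasts = 20L,
                              cell_lifetime = 20L,
                              cell_velocity = 3L,
                              repopulation_interval = 5L,
                              tnf = cytokine_params(0.07, 1e-3),
                              tgf = cytokine_params(0.10, 1e-5),
                              chemotaxis_temperature = 1,
                              seed = 1L) {
  aging <- if (inherits(preset, "aging_params")) preset else aging_preset(preset)
  params <- structure(
    list(stimulus = as.numeric(stimulus),
         aging = aging,
         grid_rows = as.integer(grid_rows),
         grid_cols = as.integer(grid_cols),
         n_iterations = as.integer(n_iterations),
         n_macrophages = as.integer(n_macrophages),
         n_fibroblasts = as.integer(n_fibroblasts),
         cell_lifetime = as.integer(cell_lifetime),
         cell_velocity = as.integer(cell_velocity),
         repopulation_interval = as.integer(repopulation_interval),
         tnf = tnf,
         tgf = tgf,
         chemotaxis_temperature = as.numeric(chemotaxis_temperature),
         seed = as.integer(seed)),
    class = "sim_params"
  )
  validate_params(params)
}

fail_field <- function(field, msg) {
  stop("invalid simulation parameter `", field, "`: ", msg, call. = FALSE)
}

check_cytokine <- function(ck, label) {
  if (!inherits(ck, "cytokine_params")) {
    fail_field(label, "must be a cytokine_params object")
  }
  if (!is.finite(ck$diffusion) || ck$diffusion < 0) {
    fail_field(paste0(label, "$diffusion"), "must be a non-negative number")
  }
  if (!is.finite(ck$degradation) || ck$degradation < 0) {
    fail_field(paste0(label, "$degradation"), "must be a non-negative number")
  }
  if (ck$diffusion < ck$degradation) {
    fail_field(paste0(label, "$diffusion"),
               "diffusion constant must be at least the degradation constant")
  }
  # explicit forward-Euler 5-point stencil stability with dt = 1
  if (ck$diffusion > 0.25) {
    fail_field(paste0(label, "$diffusion"),
               sprintf("explicit scheme unstable: D = %g exceeds 1/4", ck$diffusion))
  }
  if (ck$degradation > 1) {
    fail_field(paste0(label, "$degradation"),
               "degradation constant above 1 makes concentrations negative")
  }
  invisible(ck)
}

#' Validate a simulation configuration
#'
#' Checks every invariant of a [simulation_params()] object (probabilities in
#' \[0, 1\], positive counts, diffusion stability bound D <= 1/4, population
#' fitting on the grid) and returns the object unchanged if all hold.
#'
#' @param params A `sim_params` object.
#' @return `params`, unchanged.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "sim_params")) {
    stop("`params` must be a sim_params object", call. = FALSE)
  }
  a <- params$aging
  if (!inherits(a, "aging_params")) fail_field("aging", "must be aging_params")
  for (f in c("tnf_synth_alpha", "tnf_synth_beta",
              "tgf_synth_alpha", "tgf_synth_beta")) {
    if (!is.finite(a[[f]]) || a[[f]] <= 0) {
      fail_field(paste0("aging$", f), "Beta parameters must be > 0")
    }
  }
  if (!is.finite(a$apoptosis_threshold) ||
      a$apoptosis_threshold <= 0 || a$apoptosis_threshold > 1) {
    fail_field("aging$apoptosis_threshold", "must lie in (0, 1]")
  }
  if (!is.finite(a$mitosis_prob) || a$mitosis_prob < 0 || a$mitosis_prob > 1) {
    fail_field("aging$mitosis_prob", "must be a probability in [0, 1]")
  }
  if (a$healing_time < 1L) fail_field("aging$healing_time", "must be >= 1")
  if (a$fibrosis_duration < 1L) fail_field("aging$fibrosis_duration", "must be >= 1")

  if (!is.finite(params$stimulus) || params$stimulus < 0 || params$stimulus > 1) {
    fail_field("stimulus", "must lie in [0, 1]")
  }
  for (f in c("grid_rows", "grid_cols", "n_iterations", "n_macrophages",
              "n_fibroblasts", "cell_lifetime", "cell_velocity",
              "repopulation_interval")) {
    if (is.na(params[[f]]) || params[[f]] < 1L) {
      fail_field(f, "must be a positive integer")
    }
  }
  if (params$n_macrophages + params$n_fibroblasts >=
      params$grid_rows * params$grid_cols) {
    fail_field("n_macrophages",
               "total motile-cell population must be below the number of grid sites")
  }
  check_cytokine(params$tnf, "tnf")
  check_cytokine(params$tgf, "tgf")
  if (!is.finite(params$chemotaxis_temperature) ||
      params$chemotaxis_temperature <= 0) {
    fail_field("chemotaxis_temperature", "must be > 0")
  }
  if (is.na(params$seed)) fail_field("seed", "must be an integer")
  params
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  stimulus S = %g, aging preset %s\n", x$stimulus, x$aging$preset))
  cat(sprintf("  grid %d x %d, %d iterations, seed %d\n",
              x$grid_rows, x$grid_cols, x$n_iterations, x$seed))
  cat(sprintf("  %d macrophages + %d fibroblasts, lifetime %d, velocity %d, repop every %d\n",
              x$n_macrophages, x$n_fibroblasts, x$cell_lifetime,
              x$cell_velocity, x$repopulation_interval))
  cat(sprintf("  TNF: D = %g, K = %g; TGF: D = %g, K = %g\n",
              x$tnf$diffusion, x$tnf$degradation,
              x$tgf$diffusion, x$tgf$degradation))
  invisible(x)
}

#' @export
print.aging_params <- function(x, ...) {
  cat(sprintf("<aging_params> preset %s\n", x$preset))
  cat(sprintf("  TNF gate Beta(%g, %g), TGF gate Beta(%g, %g)\n",
              x$tnf_synth_alpha, x$tnf_synth_beta,
              x$tgf_synth_alpha, x$tgf_synth_beta))
  cat(sprintf("  apoptosis threshold %g, mitosis prob %g, healing time %d, fibrosis %d\n",
              x$apoptosis_threshold, x$mitosis_prob,
              x$healing_time, x$fibrosis_duration))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#'
#' The config file mirrors the nested structure of [simulation_params()], so
#' any valid configuration round-trips exactly. Every pipeline run can dump
#' the fully-resolved configuration it used.
#'
#' @param params A `sim_params` object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a validated `sim_params`.
#' @export
write_sim_config <- function(params, path) {
  validate_params(params)
  x <- list(
    stimulus = params$stimulus,
    aging = unclass(params$aging),
    grid_rows = params$grid_rows,
    grid_cols = params$grid_cols,
    n_iterations = params$n_iterations,
    n_macrophages = params$n_macrophages,
    n_fibroblasts = params$n_fibroblasts,
    cell_lifetime = params$cell_lifetime,
    cell_velocity = params$cell_velocity,
    repopulation_interval = params$repopulation_interval,
    tnf = unclass(params$tnf),
    tgf = unclass(params$tgf),
    chemotaxis_temperature = params$chemotaxis_temperature,
    seed = params$seed
  )
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  aging <- structure(
    list(preset = x$aging$preset,
         tnf_synth_alpha = as.numeric(x$aging$tnf_synth_alpha),
         tnf_synth_beta = as.numeric(x$aging$tnf_synth_beta),
         tgf_synth_alpha = as.numeric(x$aging$tgf_synth_alpha),
         tgf_synth_beta = as.numeric(x$aging$tgf_synth_beta),
         apoptosis_threshold = as.numeric(x$aging$apoptosis_threshold),
         mitosis_prob = as.numeric(x$aging$mitosis_prob),
         healing_time = as.integer(x$aging$healing_time),
         fibrosis_duration = as.integer(x$aging$fibrosis_duration)),
    class = "aging_params")
  simulation_params(
    stimulus = x$stimulus,
    preset = aging,
    grid_rows = x$grid_rows,
    grid_cols = x$grid_cols,
    n_iterations = x$n_iterations,
    n_macrophages = x$n_macrophages,
    n_fibroblasts = x$n_fibroblasts,
    cell_lifetime = x$cell_lifetime,
    cell_velocity = x$cell_velocity,
    repopulation_interval = x$repopulation_interval,
    tnf = cytokine_params(x$tnf$diffusion, x$tnf$degradation),
    tgf = cytokine_params(x$tgf$diffusion, x$tgf$degradation),
    chemotaxis_temperature = x$chemotaxis_temperature,
    seed = x$seed
  )
}
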