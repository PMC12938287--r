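# Information flow from migration dynamics. A cell's heading change between
# consecutive displacement vectors (the turning angle, in [0, 2pi)) is the
# raw signal; angles are discretised into equal bins and all information
# measures are histogram plug-in estimates in bits (log base 2).

#' Turning angles of motile-cell tracks
#'
#' For each slot and lifetime segment, computes the signed angle from the
#' previous displacement vector P(t-1) to the current one P(t)
#' (counter-clockwise, column = x, row = y), mapped to \[0, 2pi). An angle is
#' defined at iteration t only when both displacements exist (consecutive
#' iterations within one segment) and neither is zero; zero-displacement
#' steps are skipped, and segments are never bridged.
#'
#' @param tracks A track tibble (t, slot_id, kind, segment, row, col), as
#'   produced by [simulate_inflammation()] or [read_tracks()].
#' @return A tibble (slot_id, kind, segment, t, angle), t being the
#'   iteration of the later endpoint of P(t).
#' @examples
#' tr <- tibble::tibble(t = 0:2, slot_id = 1L, kind = "macrophage",
#'                      segment = 1L, row = c(0, 0, 1), col = c(0, 1, 1))
#' turning_angles(tr)$angle  # pi/2
#' @export
turning_angles <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$kind, .data$slot_id, .data$segment) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::reframe(segment_angles(.data$t, .data$row, .data$col)) |>
    dplyr::select("slot_id", "kind", "segment", "t", "angle")
}

segment_angles <- function(t, row, col) {
  n <- length(t)
  if (n < 3L) return(tibble::tibble(t = integer(), angle = numeric()))
  dx <- diff(col); dy <- diff(row)
  step_ok <- diff(t) == 1L & (dx != 0 | dy != 0)
  # angle k sits between displacement k-1 and k, assigned to iteration t[k+1]
  ok <- step_ok[-length(step_ok)] & step_ok[-1L]
  if (!any(ok)) return(tibble::tibble(t = integer(), angle = numeric()))
  i <- which(ok)
  theta <- atan2(dx[i] * dy[i + 1L] - dy[i] * dx[i + 1L],
                 dx[i] * dx[i + 1L] + dy[i] * dy[i + 1L]) %% (2 * pi)
  tibble::tibble(t = t[i + 2L], angle = theta)
}

#' Discretise angles into equal bins over \[0, 2pi)
#'
#' With the default 20 bins the bin width is pi/10 (about 0.314 rad). The
#' boundary value 2pi maps to the last bin.
#'
#' @param theta Numeric vector of angles in \[0, 2pi\].
#' @param bins Number of bins (>= 2), default 20.
#' @return Integer symbols in 0 .. bins - 1 (NA preserved).
#' @export
bin_angles <- function(theta, bins = 20L) {
  stopifnot(bins >= 2L)
  pmin(as.integer(floor(theta / (2 * pi / bins))), bins - 1L)
}

#' Spatial Shannon entropy of a cell configuration
#'
#' Partitions the grid into equal rectangular blocks (10 x 10 sites by
#' default) and computes H = -sum p_b log2 p_b over the block-occupancy
#' fractions of one cell kind at each recorded iteration. A tightly
#' clustered population gives low entropy; a uniform spread over B blocks
#' approaches log2 B bits.
#'
#' @param tracks Track tibble.
#' @param grid_rows,grid_cols Grid dimensions the tracks live on.
#' @param block_rows,block_cols Block dimensions in sites.
#' @param kind Cell kind to profile (default `"macrophage"`).
#' @return A tibble (t, entropy) in bits.
#' @export
configuration_entropy <- function(tracks, grid_rows, grid_cols,
                                  block_rows = 10L, block_cols = 10L,
                                  kind = "macrophage") {
  kb <- ceiling(grid_cols / block_cols)
  tracks |>
    dplyr::filter(.data$kind == !!kind) |>
    dplyr::mutate(block = (ceiling(.data$row / block_rows) - 1L) * kb +
                    ceiling(.data$col / block_cols)) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(entropy = entropy_from_counts(table(.data$block)))
}

# H in bits from a vector of non-negative counts
entropy_from_counts <- function(n) {
  n <- n[n > 0]
  N <- sum(n)
  if (N == 0) return(0)
  log2(N) - sum(n * log2(n)) / N
}

#' Z-score standardisation
#'
#' Centres and scales to population mean 0, standard deviation 1 (the
#' divisor is the population sigma, not n - 1).
#'
#' @param x Numeric vector with non-zero variance.
#' @return Standardised vector.
#' @export
zscore <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a degenerate (constant) series", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Compact joint encoding of aligned integer symbol vectors: returns counts
# of each observed tuple. Inputs must be NA-free.
joint_counts <- function(...) {
  cols <- list(...)
  code <- 0
  for (v in cols) {
    v <- as.integer(v)
    v <- v - min(v)
    code <- code * (max(v) + 1L) + v
  }
  tabulate(match(code, unique(code)))
}

#' Plug-in information measures on discrete symbol series
#'
#' Histogram (plug-in) estimators in bits over aligned integer symbol
#' vectors: Shannon entropy H(X), mutual information
#' I(X;Y) = H(X) + H(Y) - H(X,Y), and conditional mutual information
#' I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z). All are non-negative up to
#' floating-point error.
#'
#' @param x,y,z Equal-length integer vectors (factors/symbols).
#' @return A scalar in bits.
#' @export
symbol_entropy <- function(x) {
  x <- x[!is.na(x)]
  entropy_from_counts(joint_counts(x))
}

#' @rdname symbol_entropy
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  entropy_from_counts(joint_counts(x)) + entropy_from_counts(joint_counts(y)) -
    entropy_from_counts(joint_counts(x, y))
}

#' @rdname symbol_entropy
#' @export
conditional_mutual_information <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("`x`, `y` and `z` must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y) & !is.na(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  entropy_from_counts(joint_counts(x, z)) +
    entropy_from_counts(joint_counts(y, z)) -
    entropy_from_counts(joint_counts(z)) -
    entropy_from_counts(joint_counts(x, y, z))
}

#' Transfer entropy between two symbol series
#'
#' The plug-in transfer entropy from `source` to `target`:
#' T = I(target_t ; source_(t-1) | target_(t-1)), estimated from the
#' histogram of (target_t, target_(t-1), source_(t-1)) triples. The two
#' series must be aligned on the same time index; time points where either
#' symbol is NA contribute no triple. T quantifies, in bits, how much the
#' source's previous heading reduces uncertainty about the target's next
#' heading beyond the target's own past.
#'
#' @param source,target Aligned integer symbol vectors (NA = undefined).
#' @param min_samples Minimum number of complete triples; below it the
#'   estimate is reported missing (`NA`) rather than as an unreliable
#'   number. Default 50.
#' @return Transfer entropy in bits, or `NA_real_` if there are fewer than
#'   `min_samples` triples.
#' @export
transfer_entropy <- function(source, target, min_samples = 50L) {
  if (length(source) != length(target)) {
    stop("`source` and `target` must have equal length", call. = FALSE)
  }
  n <- length(target)
  if (n < 2L) return(NA_real_)
  xt <- target[-1L]                 # target_t
  ztm1 <- target[-n]                # target_(t-1)
  ytm1 <- source[-n]                # source_(t-1)
  te_from_triples(xt, ztm1, ytm1, min_samples)
}

te_from_triples <- function(xt, ztm1, ytm1, min_samples) {
  ok <- !is.na(xt) & !is.na(ztm1) & !is.na(ytm1)
  if (sum(ok) < min_samples) return(NA_real_)
  conditional_mutual_information(xt[ok], ytm1[ok], ztm1[ok])
}

# Per-run symbol arrays: one (n_iterations + 1) x n_slots integer matrix per
# cell kind, NA where the turning angle is undefined at that iteration.
angle_symbol_arrays <- function(tracks, bins) {
  ang <- turning_angles(tracks)
  ang$symbol <- bin_angles(ang$angle, bins)
  tmax <- max(tracks$t)
  m_slots <- sort(unique(tracks$slot_id[tracks$kind == "macrophage"]))
  f_slots <- sort(unique(tracks$slot_id[tracks$kind == "fibroblast"]))
  if (!length(m_slots) || !length(f_slots)) {
    stop("tracks must contain both macrophages and fibroblasts", call. = FALSE)
  }
  sym_matrix <- function(kind_label, slots) {
    m <- matrix(NA_integer_, tmax + 1L, length(slots))
    a <- ang[ang$kind == kind_label, ]
    if (nrow(a)) {
      m[cbind(a$t + 1L, match(a$slot_id, slots))] <- a$symbol
    }
    m
  }
  list(macro = sym_matrix("macrophage", m_slots),
       fibro = sym_matrix("fibroblast", f_slots),
       m_slots = m_slots, f_slots = f_slots)
}

#' Pairwise macrophage-fibroblast transfer entropy
#'
#' For every (macrophage slot, fibroblast slot) pair, aligns the two cells'
#' discretised turning-angle series on common iterations, pools triples
#' across lifetime segments, and computes the plug-in transfer entropy with
#' the macrophage as source by default (the pipeline's T M->F: the degree of
#' influence a macrophage exerts on a fibroblast's heading). Pairs with
#' fewer than `min_samples` complete triples are reported missing.
#'
#' When `tracks` is a list of track tables (replicate runs of one
#' condition), triples are pooled across replicates for each slot pair
#' before the estimate, giving the condition-level TE matrix. Pooling is how
#' the joint angle histograms reach useful occupancy: plug-in estimates from
#' a few hundred triples over a 20^3-cell alphabet are dominated by
#' small-sample bias, so single-run matrices should be compared only at
#' matched sample sizes.
#'
#' @param tracks Track tibble from one run, or a list of track tibbles from
#'   replicate runs.
#' @param bins Number of angle bins (default 20).
#' @param min_samples Minimum pooled triples per pair (default 50).
#' @param source Which kind acts as the information source,
#'   `"macrophage"` (default) or `"fibroblast"`; the other kind is the
#'   target whose next heading is predicted.
#' @return A tibble of class `te_table` with columns m_slot, f_slot, te
#'   (bits, NA if missing) and n_triples.
#' @export
pairwise_te <- function(tracks, bins = 20L, min_samples = 50L,
                        source = c("macrophage", "fibroblast")) {
  source <- match.arg(source)
  if (inherits(tracks, "data.frame")) tracks <- list(tracks)
  arrays <- lapply(tracks, angle_symbol_arrays, bins = bins)
  m_slots <- arrays[[1L]]$m_slots
  f_slots <- arrays[[1L]]$f_slots
  for (a in arrays) {
    if (!identical(a$m_slots, m_slots) || !identical(a$f_slots, f_slots)) {
      stop("replicate track tables must share the same slot ids", call. = FALSE)
    }
  }

  pair_triples <- function(a, si, ti) {
    src <- if (source == "macrophage") a$macro[, si] else a$fibro[, si]
    tgt <- if (source == "macrophage") a$fibro[, ti] else a$macro[, ti]
    n <- length(tgt)
    list(xt = tgt[-1L], ztm1 = tgt[-n], ytm1 = src[-n])
  }
  src_slots <- if (source == "macrophage") m_slots else f_slots
  tgt_slots <- if (source == "macrophage") f_slots else m_slots
  grid <- expand.grid(si = seq_along(src_slots), ti = seq_along(tgt_slots))
  res <- lapply(seq_len(nrow(grid)), function(k) {
    tr <- lapply(arrays, pair_triples, si = grid$si[k], ti = grid$ti[k])
    xt <- unlist(lapply(tr, `[[`, "xt"))
    ztm1 <- unlist(lapply(tr, `[[`, "ztm1"))
    ytm1 <- unlist(lapply(tr, `[[`, "ytm1"))
    ok <- !is.na(xt) & !is.na(ztm1) & !is.na(ytm1)
    c(n = sum(ok), te = te_from_triples(xt, ztm1, ytm1, min_samples))
  })
  res <- do.call(rbind, res)
  out <- tibble::tibble(
    m_slot = if (source == "macrophage") src_slots[grid$si] else tgt_slots[grid$ti],
    f_slot = if (source == "macrophage") tgt_slots[grid$ti] else src_slots[grid$si],
    te = res[, "te"],
    n_triples = as.integer(res[, "n"])
  )
  out <- dplyr::arrange(out, .data$m_slot, .data$f_slot)
  class(out) <- c("te_table", class(out))
  attr(out, "bins") <- bins
  attr(out, "source") <- source
  attr(out, "n_runs") <- length(arrays)
  out
}

#' Reshape a pairwise TE table to a matrix
#'
#' @param te_tbl A `te_table` from [pairwise_te()].
#' @return A numeric matrix, rows = macrophage slots, cols = fibroblast
#'   slots, NA for missing pairs.
#' @export
te_matrix <- function(te_tbl) {
  m_slots <- sort(unique(te_tbl$m_slot))
  f_slots <- sort(unique(te_tbl$f_slot))
  m <- matrix(NA_real_, length(m_slots), length(f_slots),
              dimnames = list(paste0("M", m_slots), paste0("F", f_slots)))
  m[cbind(match(te_tbl$m_slot, m_slots), match(te_tbl$f_slot, f_slots))] <- te_tbl$te
  m
}
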