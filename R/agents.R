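# Agent rules: activation, Beta-gated cytokine synthesis, chemotactic biased
# random walk with collision avoidance, and the epithelial tissue layer
# (apoptosis / healing / fibrosis). All stochastic decisions use R's RNG so a
# run is reproducible from its seed.

#' Macrophage activation probability
#'
#' At the first iteration an unactivated macrophage activates with
#' probability S (the mechanical stimulus); afterwards with probability
#' min(1, TNF), where TNF is the highest concentration in its Moore
#' neighbourhood. With S = 0 and no TNF the probability is identically 0, so
#' no inflammation can ever be triggered.
#'
#' @param stimulus Mechanical stimulus S in \[0, 1\].
#' @param local_tnf Local (neighbourhood-maximum) TNF concentration.
#' @param initial `TRUE` at the first iteration of a run.
#' @return Activation probability in \[0, 1\].
#' @export
macrophage_activation_prob <- function(stimulus, local_tnf, initial = FALSE) {
  if (initial) stimulus else min(1, local_tnf)
}

#' Fibroblast activation probability
#'
#' A fibroblast activates with probability min(1, TNF). On activation it
#' settles at the injury site (stops migrating) and its remaining lifespan is
#' reduced by 75%.
#'
#' @param local_tnf Local (neighbourhood-maximum) TNF concentration.
#' @return Activation probability in \[0, 1\].
#' @export
fibroblast_activation_prob <- function(local_tnf) min(1, local_tnf)

#' Beta-gated cytokine release decisions
#'
#' An activated macrophage releases one unit of TNF when a draw from
#' Beta(alpha3, beta3) is at least the local TGF concentration (TGF inhibits
#' TNF synthesis); an activated fibroblast releases one unit of TGF when a
#' draw from Beta(alpha4, beta4) is at most the local TNF concentration (TNF
#' promotes TGF synthesis). Local concentrations are read at the cell's own
#' site.
#'
#' @param local_tgf,local_tnf Concentration at the cell's site.
#' @param aging An [aging_preset()] object supplying the Beta parameters.
#' @return `TRUE` if a unit deposit is released this iteration.
#' @export
tnf_release <- function(local_tgf, aging) {
  stats::rbeta(1L, aging$tnf_synth_alpha, aging$tnf_synth_beta) >= local_tgf
}

#' @rdname tnf_release
#' @export
tgf_release <- function(local_tnf, aging) {
  stats::rbeta(1L, aging$tgf_synth_alpha, aging$tgf_synth_beta) <= local_tnf
}

# Moore offsets (8 neighbours), row/col deltas.
MOORE_DR <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
MOORE_DC <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)

#' One chemotactic sub-step of a motile cell
#'
#' Considers the cell's current site plus its in-grid, unoccupied Moore
#' neighbours and samples the next site with probability proportional to
#' exp(concentration / temperature) (softmax). When all candidate
#' concentrations are equal -- in particular on a zero field -- the choice is
#' uniform, i.e. a pure random walk. A fully enclosed cell stays in place.
#'
#' @param row,col Current position.
#' @param field Concentration matrix the walk is biased toward (TNF for
#'   macrophages, TGF for fibroblasts).
#' @param occupied Logical matrix of motile-cell occupancy; the cell's own
#'   site is ignored.
#' @param temperature Softmax temperature (> 0); default 1.
#' @return Integer vector `c(row, col)` of the chosen site.
#' @export
chemotaxis_step <- function(row, col, field, occupied,
                            temperature = 1) {
  rr <- row + MOORE_DR
  cc <- col + MOORE_DC
  ok <- rr >= 1L & rr <= nrow(field) & cc >= 1L & cc <= ncol(field)
  rr <- rr[ok]; cc <- cc[ok]
  idx <- (cc - 1L) * nrow(field) + rr
  free <- !occupied[idx]
  rr <- c(row, rr[free]); cc <- c(col, cc[free])
  if (length(rr) == 1L) return(c(row, col))
  conc <- field[(cc - 1L) * nrow(field) + rr]
  w <- exp((conc - max(conc)) / temperature)
  k <- sample.int(length(rr), 1L, prob = w)
  c(rr[k], cc[k])
}

#' Epithelial tissue state
#'
#' Constructs the epithelial layer: an all-alive state matrix plus empty
#' fibrosis counters and healing clocks.
#'
#' @param nrow,ncol Grid dimensions.
#' @return A list of class `epithelium` with integer matrices `state`
#'   (1 alive / 0 dead), `fibrosis` (remaining fibrosis iterations) and
#'   `clock` (accumulated TGF-exposure iterations of dead sites).
#' @export
epithelium <- function(nrow, ncol) {
  z <- matrix(0L, nrow, ncol)
  structure(list(state = matrix(1L, nrow, ncol), fibrosis = z, clock = z),
            class = "epithelium")
}

#' One iteration of epithelial dynamics
#'
#' Applies, in order: (a) apoptosis -- an alive cell whose Moore
#' neighbourhood holds TNF above the preset's apoptosis threshold dies;
#' (b) healing -- a dead cell exposed to TGF (> 0 anywhere in its Moore
#' neighbourhood) accumulates one clock tick; once the clock reaches the
#' healing time it regrows with the preset's mitosis probability per
#' iteration; regrowth ensures at least one fibrosis site in the Moore
#' neighbourhood, seeding a random neighbour for `fibrosis_duration`
#' iterations when none is present; (c) collagen damage -- an alive
#' cell whose 3x3 block contains Nc fibrosis sites dies with probability
#' Nc/9; finally all fibrosis counters decrement.
#'
#' @param epi An [epithelium()] object.
#' @param tnf,tgf Concentration matrices, same shape as the lattice.
#' @param aging An [aging_preset()] object.
#' @return The updated `epithelium`.
#' @export
update_epithelium <- function(epi, tnf, tgf, aging) {
  state <- epi$state; fib <- epi$fibrosis; clock <- epi$clock
  if (!all(dim(tnf) == dim(state)) || !all(dim(tgf) == dim(state))) {
    stop("cytokine fields and epithelium must share the grid shape", call. = FALSE)
  }

  # (a) apoptosis by neighbourhood TNF
  die <- state == 1L & moore_max(tnf) > aging$apoptosis_threshold
  if (any(die)) {
    state[die] <- 0L
    clock[die] <- 0L
  }

  # (b) healing: TGF exposure accumulates; after healing_time, regrowth is
  # Bernoulli(mitosis_prob) each iteration
  exposed <- state == 0L & moore_max(tgf) > 0
  clock[exposed] <- clock[exposed] + 1L
  ready <- which(state == 0L & clock >= aging$healing_time)
  if (length(ready)) {
    heal <- ready[stats::runif(length(ready)) < aging$mitosis_prob]
    if (length(heal)) {
      state[heal] <- 1L
      clock[heal] <- 0L
      nr <- nrow(state)
      for (site in heal) {
        r <- ((site - 1L) %% nr) + 1L
        c <- ((site - 1L) %/% nr) + 1L
        rr <- r + MOORE_DR; cc <- c + MOORE_DC
        ok <- rr >= 1L & rr <= nr & cc <= ncol(state) & cc >= 1L
        nb <- (cc[ok] - 1L) * nr + rr[ok]
        # healing ensures at least one fibrosis site in the neighbourhood:
        # a new one is seeded only where none is present yet
        if (!any(fib[nb] > 0L)) {
          fib[nb[sample.int(length(nb), 1L)]] <- aging$fibrosis_duration
        }
      }
    }
  }

  # (c) collagen damage: P(death) = Nc / 9 from fibrosis sites in the block
  nc <- moore_sum(matrix(as.numeric(fib > 0L), nrow(fib), ncol(fib)))
  risk <- which(state == 1L & nc > 0)
  if (length(risk)) {
    killed <- risk[stats::runif(length(risk)) < nc[risk] / 9]
    if (length(killed)) {
      state[killed] <- 0L
      clock[killed] <- 0L
    }
  }

  fib[fib > 0L] <- fib[fib > 0L] - 1L
  structure(list(state = state, fibrosis = fib, clock = clock),
            class = "epithelium")
}

#' Inflammation score of a tissue state
#'
#' The model's injury readout: the number of dead epithelial cells.
#'
#' @param epi An [epithelium()] object.
#' @return Non-negative integer count of dead sites.
#' @export
inflammation_score <- function(epi) sum(epi$state == 0L)
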