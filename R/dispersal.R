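# Stochastic exploration/colonization kernel: per occupied cell, a drawn
# hop reach d; the species can test every land cell within d adjacency hops
# (jump-dispersal: intervening sea or unsuitable cells do not block).

#' Build a dispersal kernel
#'
#' Two levels are supported: poor dispersers reach at most 2 cells per step,
#' good dispersers at most 4 (about 200 km and 400 km at the ~99 km cell
#' spacing of a resolution-8 grid). Reach probabilities follow an
#' exponential decay `p(d) proportional to exp(-lambda * d)` over
#' `d = 1..max_steps`, with optional probability mass at `d = 0` (no
#' exploration this step). Exact per-distance probabilities can be supplied
#' verbatim via `custom_probs`.
#'
#' @param level `"poor"` (max 2 hops) or `"good"` (max 4 hops).
#' @param decay_lambda Positive decay rate (default `log(2)`: each extra hop
#'   is half as likely). Ignored when `custom_probs` is given.
#' @param p0 Probability of reach 0 (default 0).
#' @param custom_probs Optional numeric vector of length `max_steps + 1`
#'   giving probabilities for `d = 0..max_steps`; must sum to 1 within
#'   1e-9. Supplied values are taken verbatim (e.g. tabulated empirical
#'   kernels); only generated kernels are constrained to the decay shape.
#' @return A `dispersal_kernel`: list with `level`, `max_steps` and
#'   `probs` (named by distance `0..max_steps`).
#' @export
make_kernel <- function(level = c("poor", "good"), decay_lambda = log(2),
                        p0 = 0, custom_probs = NULL) {
  level <- match.arg(level)
  max_steps <- if (level == "poor") 2L else 4L
  if (is.null(custom_probs)) {
    if (decay_lambda <= 0) stop("decay_lambda must be positive")
    if (p0 < 0 || p0 >= 1) stop("p0 must be in [0, 1)")
    w <- exp(-decay_lambda * seq_len(max_steps))
    probs <- c(p0, (1 - p0) * w / sum(w))
  } else {
    if (length(custom_probs) != max_steps + 1) {
      stop("custom_probs must have length max_steps + 1 = ", max_steps + 1,
           " (distances 0..", max_steps, ")")
    }
    if (abs(sum(custom_probs) - 1) > 1e-9) {
      stop("custom_probs must sum to 1 (tolerance 1e-9)")
    }
    if (any(custom_probs < 0)) stop("custom_probs must be non-negative")
    probs <- custom_probs
  }
  names(probs) <- 0:max_steps
  structure(list(level = level, max_steps = max_steps, probs = probs),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat("Dispersal kernel (", x$level, ", max ", x$max_steps, " hops)\n",
      sep = "")
  print(round(x$probs, 4))
  invisible(x)
}

#' Inverse-CDF draw of dispersal reach
#'
#' Maps uniform variates to reach distances through the kernel's inverse
#' cumulative distribution, so draws from two kernels can be coupled through
#' a shared uniform.
#'
#' @param kernel A `dispersal_kernel`.
#' @param u Uniform(0,1) variates.
#' @return Integer reaches in `0..max_steps`, one per element of `u`.
#' @export
kernel_draw <- function(kernel, u) {
  cdf <- cumsum(kernel$probs)
  findInterval(u, cdf[-length(cdf)], rightmost.closed = FALSE) |>
    as.integer()
}

#' Propose colonization candidates for one time step
#'
#' Each occupied cell independently draws a reach `d` from the kernel; all
#' land cells within `d` adjacency hops of it are candidates
#' (jump-dispersal). Returns the union of candidates minus the already
#' occupied cells. Suitability is not tested here: the simulation engine
#' occupies any suitable candidate immediately.
#'
#' @param grid A `nichesim_grid`.
#' @param occupied Non-empty vector of occupied cell ids.
#' @param kernel A `dispersal_kernel`.
#' @return Sorted integer vector of candidate cell ids (possibly empty).
#' @export
propose_colonizations <- function(grid, occupied, kernel) {
  stopifnot(inherits(grid, "nichesim_grid"), inherits(kernel, "dispersal_kernel"))
  if (length(occupied) == 0) stop("occupied set is empty")
  occupied <- sort.int(unique(as.integer(occupied)))
  reach <- kernel_draw(kernel, stats::runif(length(occupied)))
  out <- logical(grid$n_cells)
  for (i in seq_along(occupied)) {
    if (reach[i] == 0) next
    out[neighbors_within(grid, occupied[i], reach[i])] <- TRUE
  }
  out[occupied] <- FALSE
  out[!grid$cells$is_land] <- FALSE
  which(out)
}
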