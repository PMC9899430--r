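#' Construct a population trajectory
#'
#' A trajectory is a tibble with columns `t` (0, 1, ..., n_total) and
#' `value` (log abundance or abundance depending on `scale`), carrying the
#' simulation bookkeeping as attributes: row `t = 0` is the initial
#' condition, and the first `n_discard` post-initial steps are flagged as
#' transient burn-in to be excluded from stationary summaries.
#'
#' @param values Numeric vector of length `n_total + 1`, including the
#'   initial value at position 1.
#' @param scale `"log"` or `"natural"`; natural-scale values must be
#'   strictly positive.
#' @param n_discard Number of leading post-initial steps flagged transient.
#' @param seed RNG seed used to generate the values (NA for external data).
#' @param source Generating model: `"gompertz"`, `"ricker"` or `"external"`.
#' @param params Optional generating parameter object, kept as an attribute.
#' @return A tibble of class `pop_trajectory`.
#' @export
new_trajectory <- function(values, scale = c("log", "natural"), n_discard = 0L,
                           seed = NA_integer_, source = "external",
                           params = NULL) {
  scale <- match.arg(scale)
  if (!is.numeric(values) || length(values) < 2L) {
    stop_invalid_input("`values` must be numeric with the initial value plus >= 1 step.")
  }
  if (!all(is.finite(values))) {
    stop_invalid_input("Trajectory values must all be finite.")
  }
  if (scale == "natural" && any(values <= 0)) {
    stop_invalid_input("Natural-scale trajectory values must be strictly positive.")
  }
  n_total <- length(values) - 1L
  n_discard <- check_count(n_discard, "n_discard", min = 0L)
  if (n_discard > n_total) {
    stop_invalid_input("`n_discard` must be <= the number of simulated steps.")
  }
  source <- match.arg(source, c("gompertz", "ricker", "external"))
  out <- tibble::tibble(t = 0:n_total, value = as.numeric(values))
  structure(
    out,
    scale = scale,
    y0 = values[[1L]],
    n_total = n_total,
    n_discard = n_discard,
    seed = seed,
    source = source,
    params = params,
    class = c("pop_trajectory", class(out))
  )
}

#' @export
print.pop_trajectory <- function(x, ...) {
  cat(sprintf(
    "<pop_trajectory> %s-scale %s trajectory: %d steps (+%d initial), %d flagged transient, seed %s\n",
    attr(x, "scale"), attr(x, "source"), attr(x, "n_total"),
    1L, attr(x, "n_discard"),
    if (is.na(attr(x, "seed"))) "NA" else format(attr(x, "seed"))
  ))
  NextMethod()
}

#' Trajectory values as a plain numeric vector
#'
#' @param traj A [new_trajectory()] object.
#' @return Numeric vector of length `n_total + 1` (initial value first).
#' @export
trajectory_values <- function(traj) {
  stopifnot(inherits(traj, "pop_trajectory"))
  traj$value
}

#' Retained stationary segment of a trajectory
#'
#' Drops the initial value and the `n_discard` leading transient steps,
#' returning the values regarded as draws from the stationary distribution
#' (e.g. the last 100 points of a 300-step run with 200 discarded).
#'
#' @param traj A [new_trajectory()] object.
#' @return Numeric vector of length `n_total - n_discard`.
#' @export
stationary_segment <- function(traj) {
  stopifnot(inherits(traj, "pop_trajectory"))
  n_total <- attr(traj, "n_total")
  n_discard <- attr(traj, "n_discard")
  if (n_discard >= n_total) {
    stop_invalid_input("All steps are flagged transient: the stationary segment is empty.")
  }
  traj$value[(n_discard + 2L):(n_total + 1L)]
}

#' Convert a trajectory between log and natural abundance scales
#'
#' @param traj A [new_trajectory()] object.
#' @param scale Target scale, `"log"` or `"natural"`.
#' @return A trajectory on the requested scale (a no-op if already there).
#' @export
convert_scale <- function(traj, scale = c("log", "natural")) {
  scale <- match.arg(scale)
  cur <- attr(traj, "scale")
  if (cur == scale) return(traj)
  values <- if (scale == "log") log(traj$value) else exp(traj$value)
  new_trajectory(
    values,
    scale = scale,
    n_discard = attr(traj, "n_discard"),
    seed = attr(traj, "seed"),
    source = attr(traj, "source"),
    params = attr(traj, "params")
  )
}
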