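#' Build a sequential depolymerization chain
#'
#' A kinetic chain represents one tracked lineage of enzymatic EPS breakdown:
#' an ordered series of species (substrate, intermediate oligomers, terminal
#' product) of strictly decreasing neutral monoisotopic mass, where each
#' non-terminal stage is cleaved into the next by an irreversible first-order
#' step. The terminal stage is absorbing (rate 0), so total tracked amount is
#' conserved.
#'
#' @param stage_masses Neutral monoisotopic mass per stage, Da, strictly
#'   decreasing; at least two stages.
#' @param rates First-order cleavage rate per stage, per hour. All rates must
#'   be non-negative and exactly the last must be zero.
#' @param initial_amount Substrate amount at time zero, arbitrary signal
#'   units (default 1e6, a typical LC-MS base-peak scale).
#' @return An object of class `kinetic_chain`. Chains whose nonzero rates are
#'   not pairwise distinct are accepted but flagged `degenerate = TRUE`; the
#'   closed-form solution does not apply to them and [simulate_chain()] falls
#'   back to numerical integration.
#' @examples
#' build_chain(c(1600, 800, 221.09), c(0.3, 0.6, 0))
#' @export
build_chain <- function(stage_masses, rates, initial_amount = 1e6) {
  stage_masses <- as.numeric(stage_masses)
  rates <- as.numeric(rates)
  n <- length(stage_masses)
  if (n < 2L) {
    abort("a chain needs at least 2 stages")
  }
  if (length(rates) != n) {
    abort("rates must have one entry per stage")
  }
  if (any(!is.finite(stage_masses)) || any(stage_masses <= 0)) {
    abort("stage masses must be positive and finite")
  }
  if (any(diff(stage_masses) >= 0)) {
    abort("stage masses must be strictly decreasing")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("rates must be non-negative")
  }
  if (rates[n] != 0) {
    abort("the terminal stage must have rate 0")
  }
  if (any(rates[-n] == 0)) {
    abort("only the terminal stage may have rate 0")
  }
  if (!is.numeric(initial_amount) || length(initial_amount) != 1L ||
      initial_amount <= 0) {
    abort("initial_amount must be a single positive number")
  }
  # Closed-form Bateman coefficients divide by pairwise rate differences
  # (including the terminal 0), so equal or near-equal rates are degenerate.
  k_all <- rates
  gaps <- abs(outer(k_all, k_all, "-"))
  diag(gaps) <- Inf
  scale <- max(k_all, 1e-12)
  degenerate <- min(gaps) / scale < 1e-8
  structure(
    list(
      stage_masses = stage_masses,
      rates = rates,
      initial_amount = initial_amount,
      degenerate = degenerate
    ),
    class = "kinetic_chain"
  )
}

#' @export
print.kinetic_chain <- function(x, ...) {
  cat(
    "<kinetic_chain> ", length(x$stage_masses), " stages, masses ",
    paste(signif(x$stage_masses, 6), collapse = " > "), " Da\n",
    "  rates (1/h): ", paste(signif(x$rates, 4), collapse = ", "),
    if (x$degenerate) "  [degenerate: numerical solving]" else "", "\n",
    sep = ""
  )
  invisible(x)
}

# Closed-form solution of the linear first-order chain with pairwise distinct
# rates (terminal rate 0 included): amount in stage i at time t is
#   A0 * prod_{j<i} k_j * sum_{j<=i} exp(-k_j t) / prod_{l<=i, l!=j} (k_l - k_j)
.bateman_amounts <- function(chain, timepoints) {
  k <- chain$rates
  n <- length(k)
  out <- matrix(0, nrow = length(timepoints), ncol = n)
  for (i in seq_len(n)) {
    ki <- k[seq_len(i)]
    coef <- vapply(seq_len(i), function(j) {
      denom <- prod(ki[-j] - ki[j])
      if (i == 1L) 1 else prod(k[seq_len(i - 1L)]) / denom
    }, numeric(1))
    out[, i] <- vapply(timepoints, function(t) {
      sum(coef * exp(-ki * t))
    }, numeric(1)) * chain$initial_amount
  }
  out
}

.ode_amounts <- function(chain, timepoints) {
  k <- chain$rates
  n <- length(k)
  y0 <- c(chain$initial_amount, rep(0, n - 1L))
  deriv <- function(t, y, parms) {
    influx <- c(0, k[-n] * y[-n])
    list(influx - k * y)
  }
  tp <- sort(unique(c(0, timepoints)))
  sol <- deSolve::lsoda(y0, tp, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12 * chain$initial_amount)
  sol[match(timepoints, tp), -1L, drop = FALSE]
}

#' Simulate amount trajectories of a kinetic chain
#'
#' Evaluates the amount in each chain stage at the requested timepoints. For
#' chains whose rates (terminal zero included) are pairwise distinct the
#' closed-form Bateman solution of the linear decay chain is used; degenerate
#' chains are integrated numerically with a stiff ODE solver. In either case
#' the substrate decays monotonically, interior stages rise and fall, the
#' terminal stage accumulates monotonically, and the summed amount equals the
#' initial amount at all times (closed system).
#'
#' @param chain A [build_chain()] object.
#' @param timepoints Numeric vector of times in hours, all non-negative.
#' @param method `"auto"` (Bateman when applicable, else numerical),
#'   `"bateman"` or `"ode"`.
#' @return A tibble with columns `stage` (1-based index), `stage_mass`,
#'   `hours` and `amount`.
#' @examples
#' ch <- build_chain(c(1000, 500, 200), c(1, 2, 0), initial_amount = 1)
#' simulate_chain(ch, 0:24)
#' @export
simulate_chain <- function(chain, timepoints, method = c("auto", "bateman", "ode")) {
  method <- match.arg(method)
  if (!inherits(chain, "kinetic_chain")) {
    abort("chain must be a kinetic_chain (see build_chain())")
  }
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) == 0L || any(!is.finite(timepoints)) ||
      any(timepoints < 0)) {
    abort("timepoints must be non-negative and finite")
  }
  if (method == "bateman" && chain$degenerate) {
    abort("degenerate chain: the closed-form solution does not apply")
  }
  use_ode <- method == "ode" || (method == "auto" && chain$degenerate)
  amounts <- if (use_ode) {
    .ode_amounts(chain, timepoints)
  } else {
    .bateman_amounts(chain, timepoints)
  }
  n <- length(chain$stage_masses)
  tibble(
    stage = rep(seq_len(n), each = length(timepoints)),
    stage_mass = rep(chain$stage_masses, each = length(timepoints)),
    hours = rep(timepoints, times = n),
    amount = as.vector(amounts)
  )
}

#' Peak time of the first intermediate in a three-stage chain
#'
#' For a chain substrate -> intermediate -> terminal with cleavage rates
#' \eqn{k_1 \ne k_2}, the intermediate amount is maximal at
#' \eqn{t^* = \ln(k_2/k_1) / (k_2 - k_1)}.
#'
#' @param k1,k2 First and second cleavage rates, per hour, distinct.
#' @return Peak time in hours.
#' @export
intermediate_peak_time <- function(k1, k2) {
  if (any(k1 <= 0) || any(k2 <= 0)) {
    abort("rates must be positive")
  }
  if (any(k1 == k2)) {
    abort("rates must be distinct (the limit k1 == k2 gives 1/k1)")
  }
  log(k2 / k1) / (k2 - k1)
}
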