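#' Design of a synthetic force-spectroscopy experiment
#'
#' Describes how many bond-lifetime measurements to draw and at which
#' forces. The default emulates a constant-force optical-tweezer campaign
#' on the cadherin-catenin-actin complex: 803 measurements over 12 force
#' levels spanning 0.7-33 pN, with sampling weights that decay toward high
#' force (long waits and rare events make high-force records scarcer). The
#' true per-force counts of the original experiment are unpublished, so
#' the design is explicit configuration, never hard-coded into analyses.
#'
#' @param n_measurements Total number of records.
#' @param force_levels Force levels in pN.
#' @param level_weights Sampling probabilities per level; normalized
#'   internally, must be non-negative and sum to a positive value.
#' @return A list of class `experiment_design`.
#' @examples
#' experiment_design()
#' @export
experiment_design <- function(n_measurements = 803,
                              force_levels = c(0.7, 2, 4, 6, 8, 10, 12,
                                               15.1, 18, 22, 27, 33),
                              level_weights = NULL) {
  stopifnot(n_measurements >= 1, length(force_levels) >= 1,
            all(force_levels >= 0))
  if (is.null(level_weights)) {
    # gentle decay toward high force
    level_weights <- rev(seq(4, 15, length.out = length(force_levels)))
  }
  stopifnot(length(level_weights) == length(force_levels),
            all(level_weights >= 0), sum(level_weights) > 0)
  structure(list(n_measurements = as.integer(n_measurements),
                 force_levels = as.numeric(force_levels),
                 level_weights = level_weights / sum(level_weights)),
            class = "experiment_design")
}

#' Sample a synthetic lifetime dataset from the kinetic model
#'
#' Draws (force, rupture time) records exactly from the two-state kinetic
#' scheme: each record's force comes from the design, the initial
#' conformational basin is Bernoulli in the zero-force equilibrium
#' small-angle probability (the bond equilibrates before loading), and the
#' three-state continuous-time Markov chain small/large/ruptured is then
#' simulated by the Gillespie algorithm with the analytical rates at that
#' force. Marginal lifetimes at each force are therefore distributed
#' exactly as the model's rupture-time density \eqn{-d\Sigma_F/dt}.
#'
#' Gillespie sampling from the analytic rates (rather than Brownian
#' dynamics) deliberately separates "does maximum likelihood invert the
#' model?" from "is the two-state reduction faithful to the landscape?" —
#' the latter is the oracle module's job.
#'
#' @param design An [experiment_design()].
#' @inheritParams transition_rates
#' @param seed Integer RNG seed; a fixed seed reproduces the dataset
#'   exactly.
#' @return A `lifetime_data` tibble (see [lifetime_data()]) with an extra
#'   `basin` column recording the basin at rupture; the design, parameters
#'   and seed are attached as attributes.
#' @examples
#' d <- sample_lifetimes(experiment_design(n_measurements = 50),
#'                       cca_parameters(), seed = 7)
#' head(d)
#' @export
sample_lifetimes <- function(design = experiment_design(), params,
                             env = bond_environment(), seed = 1,
                             measure = "planar",
                             rate_eval = c("average", "minimum"),
                             control = numeric_control()) {
  params <- as_bond_parameters(params)
  rate_eval <- match.arg(rate_eval)
  stopifnot(inherits(design, "experiment_design"))
  set.seed(as.integer(seed))
  n <- design$n_measurements
  lev <- sample.int(length(design$force_levels), n, replace = TRUE,
                    prob = design$level_weights)
  force <- design$force_levels[lev]
  p_s0 <- equilibrium_small_angle_probability(0, params, env, measure,
                                              control)
  rates_by_level <- lapply(design$force_levels, function(f) {
    rate_set(f, params, env, measure, control, rate_eval)
  })
  # per-level exit rates and rupture probabilities, rows = state (S, L)
  exit_rate <- vapply(rates_by_level, function(r)
    c(r[["omega_sl"]] + r[["omega_s_rup"]],
      r[["omega_ls"]] + r[["omega_l_rup"]]), numeric(2))
  p_rupture <- vapply(rates_by_level, function(r)
    c(r[["omega_s_rup"]] / (r[["omega_sl"]] + r[["omega_s_rup"]]),
      r[["omega_l_rup"]] / (r[["omega_ls"]] + r[["omega_l_rup"]])),
    numeric(2))
  state <- ifelse(stats::runif(n) < p_s0, 1L, 2L)  # 1 = small, 2 = large
  t_acc <- numeric(n)
  basin <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  guard <- 0L
  while (any(alive) && guard < 1000000L) {
    guard <- guard + 1L
    ids <- which(alive)
    flat <- cbind(state[ids], lev[ids])
    t_acc[ids] <- t_acc[ids] + stats::rexp(length(ids), exit_rate[flat])
    rupture <- stats::runif(length(ids)) < p_rupture[flat]
    hit <- ids[rupture]
    basin[hit] <- ifelse(state[hit] == 1L, "small", "large")
    alive[hit] <- FALSE
    flip <- ids[!rupture]
    state[flip] <- 3L - state[flip]
  }
  if (any(alive)) {
    stop("Gillespie simulation exceeded the iteration guard; ",
         "rates may be degenerate", call. = FALSE)
  }
  out <- lifetime_data(force, t_acc,
                       provenance = sprintf(
                         "synthetic Gillespie sample, n = %d, seed = %d", n,
                         as.integer(seed)))
  out$basin <- basin
  attr(out, "design") <- design
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  class(out) <- unique(c("lifetime_data", class(out)))
  out
}
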