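#' Per-cycle transition matrix for a treatment arm
#'
#' Builds the 3x3 row-stochastic matrix over states
#' (FFS, PS, Death) for the cycle starting at index `t`. From FFS the
#' cohort can progress (probability from the arm's FFS->PS Weibull over
#' the cycle interval) or die of other causes (background mortality);
#' from PS it can die (PS->death Weibull); death is absorbing and PS
#' cannot return to FFS. If the FFS competing probabilities exceed 1 they
#' are clipped proportionally with a warning.
#'
#' @param arm An [arm_model()].
#' @param settings A [model_settings()].
#' @param t Cycle index, `t >= 0`; the cycle covers model time
#'   `[t, t+1] * cycle_length_years`.
#' @return A 3x3 matrix with dimnames `c("ffs", "ps", "dead")`.
#' @export
build_transition_matrix <- function(arm, settings, t) {
  stopifnot(inherits(arm, "arm_model"), inherits(settings, "model_settings"),
            length(t) == 1L, t >= 0)
  cl <- settings$cycle_length_years
  p_prog <- conditional_event_prob(arm$ffs_model, t * cl, (t + 1) * cl)
  p_bg <- background_mortality_per_cycle(settings)
  if (p_prog + p_bg > 1) {
    warning(sprintf(
      "probability overflow at cycle %d (p_prog + p_bg = %.4f); clipped",
      as.integer(t), p_prog + p_bg), call. = FALSE)
    total <- p_prog + p_bg
    p_prog <- p_prog / total
    p_bg <- p_bg / total
  }
  p_death <- conditional_event_prob(arm$ps_death_model, t * cl, (t + 1) * cl)
  m <- matrix(c(1 - p_prog - p_bg, p_prog, p_bg,
                0, 1 - p_death, p_death,
                0, 0, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("ffs", "ps", "dead"),
                              c("ffs", "ps", "dead")))
  # guard against -eps from floating point
  m[m < 0 & m > -1e-12] <- 0
  m
}

#' Propagate the cohort through the Markov model
#'
#' Starts the whole cohort in FFS and applies the per-cycle transition
#' matrices over the horizon: `occupancy[k+1] = occupancy[k] %*% M(k)`.
#'
#' @param arm An [arm_model()].
#' @param settings A [model_settings()].
#' @return An object of class `cohort_trace`: a list with `occupancy`
#'   (an `(N+1) x 3` matrix of state fractions at cycle boundaries
#'   `0..N`) and `cycle_length_years`.
#' @export
run_cohort <- function(arm, settings) {
  stopifnot(inherits(arm, "arm_model"), inherits(settings, "model_settings"))
  n <- n_cycles(settings)
  occ <- matrix(NA_real_, nrow = n + 1, ncol = 3,
                dimnames = list(NULL, c("ffs", "ps", "dead")))
  occ[1, ] <- c(1, 0, 0)
  for (k in seq_len(n)) {
    m <- build_transition_matrix(arm, settings, k - 1)
    occ[k + 1, ] <- occ[k, , drop = FALSE] %*% m
  }
  structure(list(occupancy = occ,
                 cycle_length_years = settings$cycle_length_years),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat(sprintf("Cohort trace: %d cycles of %.4g years\n", n,
              x$cycle_length_years))
  print(utils::head(as.data.frame(x), 4))
  if (n > 3) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  data.frame(cycle = 0:n,
             time_years = (0:n) * x$cycle_length_years,
             ffs = x$occupancy[, "ffs"],
             ps = x$occupancy[, "ps"],
             dead = x$occupancy[, "dead"])
}

#' Write a cohort trace to CSV
#'
#' Columns `cycle, time_years, ffs, ps, dead`.
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates `n_individuals` independent patient trajectories with
#' per-cycle categorical draws from the same transition matrices the
#' cohort engine uses, and returns the empirical occupancy trace. Used as
#' an independent check that the deterministic cohort propagation is
#' correct: empirical occupancies converge to the cohort trace at the
#' binomial rate `sqrt(p(1-p)/n)`.
#'
#' @param arm An [arm_model()].
#' @param settings A [model_settings()].
#' @param n_individuals Number of simulated patients.
#' @param seed Integer RNG seed (local to this call).
#' @return A `cohort_trace` of empirical state fractions.
#' @export
microsim_oracle <- function(arm, settings, n_individuals, seed) {
  stopifnot(n_individuals >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n_cyc <- n_cycles(settings)
  state <- rep.int(1L, n_individuals)  # 1 ffs, 2 ps, 3 dead
  occ <- matrix(NA_real_, nrow = n_cyc + 1, ncol = 3,
                dimnames = list(NULL, c("ffs", "ps", "dead")))
  occ[1, ] <- c(1, 0, 0)
  for (k in seq_len(n_cyc)) {
    m <- build_transition_matrix(arm, settings, k - 1)
    u <- stats::runif(n_individuals)
    new_state <- state
    ffs <- state == 1L
    if (any(ffs)) {
      cut1 <- m["ffs", "ffs"]
      cut2 <- cut1 + m["ffs", "ps"]
      new_state[ffs] <- ifelse(u[ffs] < cut1, 1L,
                               ifelse(u[ffs] < cut2, 2L, 3L))
    }
    ps <- state == 2L
    if (any(ps)) {
      new_state[ps] <- ifelse(u[ps] < m["ps", "ps"], 2L, 3L)
    }
    state <- new_state
    occ[k + 1, ] <- tabulate(state, nbins = 3L) / n_individuals
  }
  structure(list(occupancy = occ,
                 cycle_length_years = settings$cycle_length_years),
            class = "cohort_trace")
}
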