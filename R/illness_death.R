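# Three-state (healthy S / diseased C / dead D) illness-death engine.
#
# Within a year, hazards are constant, so the (S, C) subsystem follows
#   S' = -(i + m) S + r C
#   C' =  i S - (r + m + f) C
# and is advanced with the exact matrix exponential. The 2x2 exponential
# and its time integral are evaluated with a shared truncated Taylor
# series plus scaling-and-squaring, so the identity E - I = A P holds to
# machine precision and deaths computed from the person-year integral
# conserve total mass exactly.

# Returns list(E = exp(A*dt), P = integral_0^dt exp(A s) ds) for 2x2 A.
expm_with_integral <- function(A, dt = 1) {
  nrm <- max(rowSums(abs(A))) * dt
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))))
  tau <- dt / 2^s
  # P(tau) = tau * sum_k (A tau)^k / (k+1)!
  term <- diag(2)
  P <- term
  k <- 1
  repeat {
    term <- (term %*% A) * (tau / (k + 1))
    P <- P + term
    if (max(abs(term)) < 1e-17 || k > 60) break
    k <- k + 1
  }
  P <- P * tau
  E <- diag(2) + A %*% P
  for (j in seq_len(s)) {       # doubling: P(2t) = (I + E(t)) P(t)
    P <- (diag(2) + E) %*% P
    E <- E %*% E
  }
  list(E = E, P = P)
}

id_generator <- function(i, r, f, m) {
  matrix(c(-(i + m), i, r, -(r + m + f)), 2, 2)
}

#' One-year transition of the illness-death model
#'
#' Advances a state vector one year under constant hazards: incidence
#' `i` (S to C), remission `r` (C to S), background mortality `m` (both
#' states) and excess case mortality `f` (C only), solving the
#' constant-coefficient linear system exactly. Deaths accrue from the
#' within-year person-time integral, so `S + C + D` is conserved to
#' machine precision.
#'
#' @param state Numeric vector `c(S, C, D)` (non-negative).
#' @param i,r,f,m Hazards, per person-year (non-negative).
#' @param dt Step length in years (default 1).
#' @return List: `state` (the new `c(S, C, D)`) and `person_years`
#'   (`c(S, C)` person-time lived over the step).
#' @export
step_year <- function(state, i, r, f, m, dt = 1) {
  if (length(state) != 3L || any(state < 0) || any(!is.finite(state)))
    stop_input("'state' must be non-negative c(S, C, D)")
  for (h in list(i = i, r = r, f = f, m = m))
    if (!is.finite(h) || h < 0) stop_input("hazards must be non-negative and finite")
  EP <- expm_with_integral(id_generator(i, r, f, m), dt)
  x0 <- state[1:2]
  x1 <- as.numeric(EP$E %*% x0)
  py <- as.numeric(EP$P %*% x0)
  deaths <- m * py[1] + (m + f) * py[2]
  list(state = c(S = x1[1], C = x1[2], D = state[3] + deaths),
       person_years = c(S = py[1], C = py[2]))
}

#' Excess case mortality from a relative risk of all-cause death
#'
#' `f(a) = m(a) * (RR - 1)`, so the total hazard among cases is
#' `m + f = RR * m`.
#'
#' @param mortality A `mortality_schedule` (background hazards `m(a)`).
#' @param rr Relative risk of all-cause mortality in cases (>= 1).
#' @return data.frame with columns `age`, `hazard` (the excess hazard).
#' @export
excess_mortality_from_rr <- function(mortality, rr) {
  check_age_table(mortality, "hazard", "mortality")
  check_number(rr, "rr")
  if (rr < 1) stop_input("rr must be >= 1 (protective effects out of scope)")
  data.frame(age = mortality$age, hazard = mortality$hazard * (rr - 1))
}

#' Forward-propagate an illness-death cohort over ages
#'
#' Starting from `initial = c(S, C, D)` at age `age_from`, applies
#' [step_year()] with the age-specific hazards and records prevalence
#' among survivors, `C / (S + C)`, at each age.
#'
#' @param hazards List with age-indexed numeric vectors `incidence`,
#'   `remission`, `excess`, `background`, each of length 101 (ages
#'   0-100), or scalars (recycled).
#' @param initial State vector `c(S, C, D)`.
#' @param age_from,age_to Age range to propagate (`age_from < age_to <= 100`).
#' @return data.frame with columns `age`, `S`, `C`, `D`, `prevalence`.
#' @export
solve_forward <- function(hazards, initial, age_from = 0, age_to = 100) {
  if (!(age_from < age_to && age_to <= 100))
    stop_input("need age_from < age_to <= 100")
  h <- lapply(hazards[c("incidence", "remission", "excess", "background")],
              function(v) rep_len(v, 101))
  ages <- age_from:age_to
  n <- length(ages)
  S <- C <- D <- numeric(n)
  S[1] <- initial[1]; C[1] <- initial[2]; D[1] <- initial[3]
  for (k in seq_len(n - 1)) {
    a <- ages[k]
    st <- step_year(c(S[k], C[k], D[k]),
                    i = h$incidence[a + 1], r = h$remission[a + 1],
                    f = h$excess[a + 1], m = h$background[a + 1])$state
    S[k + 1] <- st[1]; C[k + 1] <- st[2]; D[k + 1] <- st[3]
  }
  alive <- S + C
  if (any(alive <= 0))
    stop_input("cohort extinct at age %d", ages[which(alive <= 0)[1]])
  data.frame(age = ages, S = S, C = C, D = D, prevalence = C / alive)
}

#' Back-calculate internally consistent incidence from prevalence
#'
#' DisMod-2-style consistency fit: given a target age-specific prevalence
#' curve and the remission, excess-mortality and background-mortality
#' hazards, finds the age-specific incidence `i(a)` such that forward
#' propagation of the illness-death model reproduces the target
#' prevalence at every age. Each age is a 1-D bisection on
#' `i(a) in [0, 10]` (tolerance 1e-8); where prevalence declines faster
#' than remission plus mortality allow, incidence is clamped at zero and
#' the age is flagged.
#'
#' @param target A `prevalence_curve` (or data.frame with `age`,
#'   `prevalence` over ages 0-100), values in \[0, 1).
#' @param remission,excess,background Hazard vectors of length 101 (or
#'   scalars, recycled).
#' @param max_incidence Upper bisection bound (default 10/year).
#' @param tol Bisection tolerance on incidence (default 1e-8).
#' @return A `dismod_fit`: list with `incidence` (data.frame `age`,
#'   `incidence`), `target`, `hazards`, `fitted` (achieved prevalence),
#'   `clamped` (ages where the zero clamp bound), and `trajectory`.
#' @examples
#' pop <- make_population(1e6)
#' cv <- make_prevalence_curve("ptsd", 0.05, pop)
#' fit <- fit_incidence(cv, remission = 0.17, excess = 0, background = 0.01)
#' head(coef(fit))
#' @export
fit_incidence <- function(target, remission, excess, background,
                          max_incidence = 10, tol = 1e-8) {
  check_age_table(target, "prevalence", "target")
  p <- target$prevalence
  if (any(p < 0 | p >= 1)) stop_input("target prevalence must lie in [0, 1)")
  r <- rep_len(remission, 101)
  f <- rep_len(excess, 101)
  m <- rep_len(background, 101)
  if (any(c(r, f, m) < 0)) stop_input("hazards must be non-negative")

  inc <- numeric(101)
  clamped <- integer(0)
  S <- 1 - p[1]; C <- p[1]; D <- 0
  traj <- matrix(NA_real_, 101, 3, dimnames = list(NULL, c("S", "C", "D")))
  traj[1, ] <- c(S, C, D)
  prev_after <- function(i, k) {
    st <- step_year(c(S, C, D), i, r[k], f[k], m[k])$state
    st[2] / (st[1] + st[2])
  }
  for (k in 1:100) {
    lo <- 0; hi <- max_incidence
    p_lo <- prev_after(lo, k)
    if (p_lo >= p[k + 1]) {          # prevalence falls too fast: clamp
      inc[k] <- 0
      if (p_lo > p[k + 1] + tol) clamped <- c(clamped, k - 1L)
    } else {
      if (prev_after(hi, k) < p[k + 1])
        stop_input("fit_incidence: no solution below %g/year at age %d",
                   max_incidence, k - 1L)
      iter <- 0
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (prev_after(mid, k) < p[k + 1]) lo <- mid else hi <- mid
        iter <- iter + 1
        if (iter > 200)
          stop_input("fit_incidence: bisection failed to converge at age %d", k - 1L)
      }
      inc[k] <- (lo + hi) / 2
    }
    st <- step_year(c(S, C, D), inc[k], r[k], f[k], m[k])$state
    S <- st[1]; C <- st[2]; D <- st[3]
    traj[k + 1, ] <- st
  }
  inc[101] <- inc[100]  # terminal age carries the last fitted value
  if (length(clamped))
    message("fit_incidence: incidence clamped at 0 for ", length(clamped),
            " age(s): ", paste(utils::head(clamped, 10), collapse = ", "),
            if (length(clamped) > 10) ", ..." else "")
  fitted_prev <- traj[, "C"] / (traj[, "S"] + traj[, "C"])
  structure(list(incidence = data.frame(age = AGES, incidence = inc),
                 target = p,
                 hazards = list(remission = r, excess = f, background = m),
                 fitted = fitted_prev, clamped = clamped,
                 trajectory = data.frame(age = AGES, traj)),
            class = "dismod_fit")
}

#' @export
print.dismod_fit <- function(x, ...) {
  cat("Illness-death consistency fit (incidence back-calculated from prevalence)\n")
  cat(sprintf("  incidence range: %.5f-%.5f /year; %d age(s) clamped at 0\n",
              min(x$incidence$incidence), max(x$incidence$incidence),
              length(x$clamped)))
  cat(sprintf("  max |fitted - target| prevalence: %.2e\n",
              max(abs(x$fitted - x$target))))
  invisible(x)
}

#' @export
summary.dismod_fit <- function(object, ...) {
  res <- object$fitted - object$target
  out <- list(incidence_summary = summary(object$incidence$incidence),
              max_abs_residual = max(abs(res)),
              n_clamped = length(object$clamped),
              clamped_ages = object$clamped)
  class(out) <- "summary.dismod_fit"
  out
}

#' @export
print.summary.dismod_fit <- function(x, ...) {
  cat("Incidence (per person-year):\n")
  print(x$incidence_summary)
  cat(sprintf("Max |prevalence residual|: %.2e; clamped ages: %d\n",
              x$max_abs_residual, x$n_clamped))
  invisible(x)
}

#' @export
coef.dismod_fit <- function(object, ...) {
  stats::setNames(object$incidence$incidence, object$incidence$age)
}

#' @export
fitted.dismod_fit <- function(object, ...) object$fitted

#' @export
residuals.dismod_fit <- function(object, ...) object$fitted - object$target

#' Forward-predict prevalence from a fitted incidence schedule
#'
#' Re-propagates the illness-death model with the fitted incidence,
#' optionally from a different initial state or age range.
#'
#' @param object A `dismod_fit`.
#' @param initial State `c(S, C, D)`; defaults to the fit's starting state.
#' @param age_from,age_to Age range (defaults 0-100).
#' @param ... Unused.
#' @return data.frame as from [solve_forward()].
#' @export
predict.dismod_fit <- function(object, initial = NULL, age_from = 0,
                               age_to = 100, ...) {
  if (is.null(initial))
    initial <- c(1 - object$target[age_from + 1], object$target[age_from + 1], 0)
  solve_forward(list(incidence = object$incidence$incidence,
                     remission = object$hazards$remission,
                     excess = object$hazards$excess,
                     background = object$hazards$background),
                initial, age_from, age_to)
}

#' @export
plot.dismod_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(AGES, x$target, type = "l", xlab = "age",
                 ylab = "prevalence", main = "target vs fitted", ...)
  graphics::lines(AGES, x$fitted, lty = 2, col = 2)
  graphics::legend("topright", c("target", "fitted"), lty = 1:2, col = 1:2,
                   bty = "n")
  graphics::plot(x$incidence$age, x$incidence$incidence, type = "l",
                 xlab = "age", ylab = "incidence (/year)",
                 main = "back-calculated incidence")
  invisible(x)
}
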