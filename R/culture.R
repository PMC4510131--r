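# Virtual culture dynamics: Monod growth, substrate depletion, metabolic
# acidification, and volumetric mixing — the simulator standing in for a live
# vessel.

#' Organism parameters
#'
#' Monod kinetics with a substrate yield and a lumped acid-production
#' coefficient driving the pH readout.
#'
#' @param mu_max Maximum specific growth rate, per hour (> 0).
#' @param Ks Half-saturation (Monod) constant, g/L (> 0).
#' @param yield_Y Cells produced per gram of limiting substrate, CFU/g (> 0).
#' @param q_acid Acid units produced per cell grown (>= 0; 0 disables the pH
#'   dynamics).
#' @param optics An [optical_model_params()] describing how this organism and
#'   its medium appear to the detector.
#' @return An object of class `organism_params`; the doubling time
#'   `ln(2)/mu_max` (hours) is stored as `doubling_time`.
#' @export
organism_params <- function(mu_max, Ks, yield_Y, q_acid = 0, optics) {
  stopifnot(mu_max > 0, Ks > 0, yield_Y > 0, q_acid >= 0,
            inherits(optics, "optical_model_params"))
  structure(list(mu_max = as.numeric(mu_max), Ks = as.numeric(Ks),
                 yield_Y = as.numeric(yield_Y), q_acid = as.numeric(q_acid),
                 optics = optics, doubling_time = log(2) / mu_max),
            class = "organism_params")
}

#' Medium specification
#'
#' @param S0 Limiting-substrate concentration of the fresh medium, g/L (>= 0).
#' @param pH0 pH of the fresh medium.
#' @param buffer_capacity Acid units required to lower the pH by one unit
#'   (> 0); a lumped linear buffer model.
#' @param phenol_red Whether the medium contains phenol red (pH readout).
#' @param pH_floor Lowest pH the lumped model will report (default 4.0, well
#'   below the indicator window).
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(S0, pH0 = 7, buffer_capacity = 1, phenol_red = FALSE,
                        pH_floor = 4) {
  stopifnot(S0 >= 0, buffer_capacity > 0, pH_floor < pH0)
  structure(list(S0 = as.numeric(S0), pH0 = as.numeric(pH0),
                 buffer_capacity = as.numeric(buffer_capacity),
                 phenol_red = isTRUE(phenol_red),
                 pH_floor = as.numeric(pH_floor)),
            class = "medium_spec")
}

#' Culture state
#'
#' The simulator's evolving state. pH is derived, not stored: see
#' [culture_pH()].
#'
#' @param V Liquid volume, mL (> 0).
#' @param X Cell density, CFU/mL (>= 0).
#' @param S Limiting-substrate concentration, g/L (>= 0).
#' @param C_acid Accumulated acid, acid units per mL-free lumped scale (>= 0).
#' @param t Culture time, hours.
#' @return An object of class `culture_state`.
#' @export
culture_state <- function(V, X, S, C_acid = 0, t = 0) {
  stopifnot(V > 0, X >= 0, S >= 0, C_acid >= 0)
  structure(list(t = as.numeric(t), V = as.numeric(V), X = as.numeric(X),
                 S = as.numeric(S), C_acid = as.numeric(C_acid)),
            class = "culture_state")
}

#' Derived culture pH
#'
#' pH = max(pH_floor, pH0 - C_acid / buffer_capacity). Acid is mixed
#' volumetrically and pH recomputed; pH values themselves are never averaged
#' (pH is logarithmic).
#'
#' @param state A [culture_state()].
#' @param medium A [medium_spec()].
#' @return pH units.
#' @export
culture_pH <- function(state, medium) {
  max(medium$pH_floor, medium$pH0 - state$C_acid / medium$buffer_capacity)
}

#' Monod specific growth rate
#'
#' mu(S) = mu_max * S / (Ks + S); bounded by mu_max, zero at S = 0.
#'
#' @param S Substrate concentration, g/L (>= 0).
#' @param org An [organism_params()].
#' @return Specific growth rate, per hour.
#' @export
specific_growth_rate <- function(S, org) {
  if (any(S < 0)) stop("substrate concentration must be >= 0", call. = FALSE)
  org$mu_max * S / (org$Ks + S)
}

# One classical fixed-step RK4 step of the Monod system
#   dX/dt = mu(S) X,  dS/dt = -mu(S) X / Y,  dC/dt = q_acid mu(S) X,
# plus the growth integral dI/dt = mu(S) (used for generation accounting).
# y = c(X, S, C_acid, I); dt in hours. S is clamped at 0 inside the
# derivative evaluations and floored after the step.
.rk4_monod <- function(y, dt, mu_max, Ks, Y, q_acid) {
  deriv <- function(y) {
    S <- max(y[2L], 0)
    mu <- mu_max * S / (Ks + S)
    gX <- mu * y[1L]
    c(gX, -gX / Y, q_acid * gX, mu)
  }
  k1 <- deriv(y)
  k2 <- deriv(y + dt / 2 * k1)
  k3 <- deriv(y + dt / 2 * k2)
  k4 <- deriv(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (y[2L] < 0) y[2L] <- 0
  y
}

#' Advance the culture by one growth step
#'
#' One 4th-order Runge-Kutta step of dX/dt = mu(S) X, dS/dt = -mu(S) X / Y,
#' dC_acid/dt = q_acid mu(S) X. Deterministic fixed step, no adaptive
#' control; substrate is floored at zero.
#'
#' @param state A [culture_state()].
#' @param dt Step size, hours (> 0).
#' @param org An [organism_params()].
#' @param medium A [medium_spec()] (carried for pH derivation; growth itself
#'   does not read it).
#' @return The advanced [culture_state()].
#' @export
step_growth <- function(state, dt, org, medium) {
  stopifnot(inherits(state, "culture_state"), dt > 0)
  y <- .rk4_monod(c(state$X, state$S, state$C_acid, 0), dt,
                  org$mu_max, org$Ks, org$yield_Y, org$q_acid)
  if (any(!is.finite(y))) {
    stop("integration failure: non-finite culture state", call. = FALSE)
  }
  state$t <- state$t + dt
  state$X <- y[1L]
  state$S <- y[2L]
  state$C_acid <- max(y[3L], 0)
  state
}

#' Mix fresh medium into the culture
#'
#' Volumetric mixing: V grows by dV; X, S and C_acid are the volume-weighted
#' averages of culture and fresh medium (fresh medium carries substrate S0 and
#' no cells or acid). pH is derived from the mixed acid load.
#'
#' @param state A [culture_state()].
#' @param dV Volume of fresh medium added, mL (>= 0).
#' @param medium A [medium_spec()].
#' @return The mixed [culture_state()].
#' @export
mix_in <- function(state, dV, medium) {
  stopifnot(inherits(state, "culture_state"), dV >= 0)
  if (dV == 0) return(state)
  V_old <- state$V
  V_new <- V_old + dV
  state$X <- state$X * V_old / V_new
  state$S <- (state$S * V_old + medium$S0 * dV) / V_new
  state$C_acid <- state$C_acid * V_old / V_new
  state$V <- V_new
  state
}

#' Remove well-mixed culture down to a target volume
#'
#' Volume drops to `V_target`; all concentrations (X, S, C_acid, hence pH)
#' are unchanged because removal is of well-mixed liquid.
#'
#' @param state A [culture_state()].
#' @param V_target Target volume, mL (0 < V_target <= V).
#' @return The reduced [culture_state()].
#' @export
draw_off <- function(state, V_target) {
  stopifnot(inherits(state, "culture_state"))
  if (!(V_target > 0 && V_target <= state$V + 1e-12)) {
    stop("fluidics error: draw-off target exceeds current volume",
         call. = FALSE)
  }
  state$V <- min(V_target, state$V)
  state
}
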