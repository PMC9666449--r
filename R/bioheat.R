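#' Pennes bioheat model parameters
#'
#' Tissue and blood constants for
#' `rho C dT/dt = k lap(T) - w_b rho_b C_b (T - T_a) + Q`.
#' Defaults are generic soft-brain values; they are placeholders to be
#' overridden with the constants appropriate to the tissue at hand.
#'
#' @param k_W_mK Tissue thermal conductivity, W m^-1 K^-1.
#' @param rho_kg_m3 Tissue density, kg/m^3.
#' @param C_J_kgK Tissue specific heat, J kg^-1 K^-1.
#' @param w_b_per_s Blood perfusion rate, s^-1.
#' @param rho_b_kg_m3 Blood density, kg/m^3.
#' @param C_b_J_kgK Blood specific heat, J kg^-1 K^-1.
#' @param T_a_C Arterial temperature, degrees C.
#' @param Q_W_m3 Volumetric heat source: 3-D array or scalar, W/m^3.
#' @param dx_m Grid spacing, m (isotropic).
#' @param dim Grid dimensions, used when `Q_W_m3` is scalar.
#' @return An object of class `bioheat_params`.
#' @export
bioheat_params <- function(k_W_mK = 0.51, rho_kg_m3 = 1046,
                           C_J_kgK = 3630, w_b_per_s = 0.0098,
                           rho_b_kg_m3 = 1050, C_b_J_kgK = 3617,
                           T_a_C = 37, Q_W_m3 = 0, dx_m = 1e-3,
                           dim = c(21, 21, 21)) {
  for (nm in c("k_W_mK", "rho_kg_m3", "C_J_kgK", "rho_b_kg_m3",
               "C_b_J_kgK", "dx_m")) {
    stop_if_not_scalar_positive(get(nm), nm)
  }
  if (w_b_per_s < 0) stop("`w_b_per_s` must be >= 0", call. = FALSE)
  if (length(Q_W_m3) == 1) Q_W_m3 <- array(Q_W_m3, dim = dim)
  if (any(!is.finite(Q_W_m3))) stop("`Q_W_m3` must be finite", call. = FALSE)
  structure(
    list(k = k_W_mK, rho = rho_kg_m3, C = C_J_kgK, w_b = w_b_per_s,
         rho_b = rho_b_kg_m3, C_b = C_b_J_kgK, T_a = T_a_C,
         Q = Q_W_m3, dx = dx_m),
    class = "bioheat_params"
  )
}

# second difference with zero-flux (reflected-ghost) boundaries along one
# margin of a 3-D array
lap1 <- function(T, margin) {
  d <- dim(T)
  n <- d[margin]
  idx_up <- c(2:n, n)       # ghost = boundary value
  idx_dn <- c(1, 1:(n - 1))
  slab <- function(i) switch(margin,
                             T[i, , , drop = FALSE],
                             T[, i, , drop = FALSE],
                             T[, , i, drop = FALSE])
  up <- slab(idx_up)
  dn <- slab(idx_dn)
  up + dn - 2 * T
}

#' Explicit finite-difference Pennes bioheat solver
#'
#' Forward-Euler integration of the Pennes equation on a regular 3-D grid
#' with insulated (zero-flux) boundaries, starting from the arterial
#' temperature unless an initial field is given. The explicit stability
#' bound `dt <= dx^2 / (6 kappa)` (with a perfusion correction) is checked;
#' an over-large time step is refused with the required bound in the
#' message.
#'
#' @param params A [bioheat_params()].
#' @param duration_s Simulated time, s.
#' @param dt_s Time step, s; defaults to 90% of the stability bound.
#' @param T_init_C Optional initial temperature field (3-D array, degrees
#'   C).
#' @return A list of class `bioheat_result`: `dT` (final temperature rise
#'   above arterial, 3-D array, K), `max_dT` (maximum over space and time),
#'   `T_final`, `dt_s`, `n_steps`.
#' @export
simulate_bioheat <- function(params, duration_s, dt_s = NULL,
                             T_init_C = NULL) {
  stopifnot(inherits(params, "bioheat_params"))
  stop_if_not_scalar_positive(duration_s, "duration_s")
  kappa <- params$k / (params$rho * params$C)
  decay <- params$w_b * params$rho_b * params$C_b / (params$rho * params$C)
  dt_max <- 1 / (6 * kappa / params$dx^2 + decay)
  if (is.null(dt_s)) dt_s <- 0.9 * dt_max
  if (dt_s > dt_max) {
    stop(sprintf("unstable time step: dt must be <= %.4g s", dt_max),
         call. = FALSE)
  }
  d <- dim(params$Q)
  T <- if (is.null(T_init_C)) array(params$T_a, dim = d) else T_init_C
  stopifnot(identical(dim(T), d))
  n_steps <- max(1L, ceiling(duration_s / dt_s - 1e-9))
  src <- params$Q / (params$rho * params$C)
  max_dT <- max(T - params$T_a)
  for (s in seq_len(n_steps)) {
    lap <- lap1(T, 1) + lap1(T, 2) + lap1(T, 3)
    T <- T + dt_s * (kappa * lap / params$dx^2 -
                       decay * (T - params$T_a) + src)
    m <- max(T - params$T_a)
    if (m > max_dT) max_dT <- m
  }
  structure(
    list(dT = T - params$T_a, max_dT = max_dT, T_final = T,
         dt_s = dt_s, n_steps = n_steps),
    class = "bioheat_result"
  )
}
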