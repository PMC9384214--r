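# Compartment models of plasma insulin / c-peptide accumulation and the
# sigmoid secretion functional that drives them.

#' Sigmoid secretion-functional parameters
#'
#' Parameters of the glucose-dependent secretion functional
#' \deqn{u(g) = K_m / (1 + e^{\alpha (C_0 - g)})}
#' used for both the insulin secretion rate (ISR, uU/ml/min) and the
#' c-peptide secretion rate (CSR, ng/ml/min).
#'
#' @param Km maximum secretion rate (uU/ml/min for insulin, ng/ml/min for
#'   c-peptide); `Km > 0`.
#' @param C0 glucose midpoint, in the glucose unit of the record the
#'   parameters refer to; `C0 > 0`.
#' @param alpha inverse width of the sigmoid (reciprocal glucose units);
#'   `alpha > 0`.
#' @return an object of class `secretion_params`.
#' @seealso [secretion_rate()], [model_params()]
#' @export
secretion_params <- function(Km, C0, alpha) {
  for (nm in c("Km", "C0", "alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single finite positive number", call. = FALSE)
    }
  }
  structure(list(Km = Km, C0 = C0, alpha = alpha), class = "secretion_params")
}

#' Full model parameter vector
#'
#' Combines the secretion-functional parameters with the clearance constants
#' of the chosen compartment model. The single-compartment model has one
#' plasma pool with degradation time `tau_p`; the two-compartment model adds
#' an interstitial pool with degradation time `tau_i` and fixed plasma <->
#' interstitium transport rates `q1`, `q2` (min^-1).
#'
#' @param kind `"single"` or `"two_compartment"`.
#' @param secretion a [secretion_params()] object.
#' @param tau_p plasma degradation time (min), `> 0`.
#' @param tau_i interstitial degradation time (min), required for the
#'   two-compartment model.
#' @param q1,q2 transport rates (min^-1); defaults 0.0473 and 0.0348.
#' @return an object of class `model_params`.
#' @export
model_params <- function(kind = c("single", "two_compartment"), secretion,
                         tau_p, tau_i = NULL, q1 = 0.0473, q2 = 0.0348) {
  kind <- match.arg(kind)
  if (!inherits(secretion, "secretion_params")) {
    stop("'secretion' must be a secretion_params object", call. = FALSE)
  }
  if (!is.numeric(tau_p) || length(tau_p) != 1L || !is.finite(tau_p) || tau_p <= 0) {
    stop("'tau_p' must be a single finite positive number", call. = FALSE)
  }
  if (kind == "two_compartment") {
    if (is.null(tau_i) || !is.finite(tau_i) || tau_i <= 0) {
      stop("two-compartment model requires finite tau_i > 0", call. = FALSE)
    }
    if (!is.finite(q1) || !is.finite(q2) || q1 <= 0 || q2 <= 0) {
      stop("two-compartment model requires q1 > 0 and q2 > 0", call. = FALSE)
    }
  }
  structure(list(kind = kind, secretion = secretion, tau_p = tau_p,
                 tau_i = if (kind == "two_compartment") tau_i else NULL,
                 q1 = q1, q2 = q2),
            class = "model_params")
}

#' Evaluate the sigmoid secretion rate
#'
#' @param g glucose concentration(s); any finite real value, in the same unit
#'   as `p$C0`.
#' @param p a [secretion_params()] object.
#' @return secretion rate(s), strictly increasing in `g` and bounded in
#'   `(0, Km)`.
#' @examples
#' p <- secretion_params(Km = 0.6, C0 = 1000, alpha = 0.01)
#' secretion_rate(1000, p)  # Km / 2 at the midpoint
#' @export
secretion_rate <- function(g, p) {
  if (!inherits(p, "secretion_params")) {
    stop("'p' must be a secretion_params object", call. = FALSE)
  }
  if (!is.numeric(g) || length(g) == 0L || any(!is.finite(g))) {
    stop("'g' must be finite numeric", call. = FALSE)
  }
  p$Km / (1 + exp(p$alpha * (p$C0 - g)))
}

#' Continuous state-space form of a compartment model
#'
#' Writes the model as \eqn{\dot x = A x + B u(g)}, \eqn{y = C x}, where the
#' output `y` is the plasma concentration. For the single-compartment model
#' `A = -1/tau_p`; for the two-compartment model `A` carries the transport
#' rates on the off-diagonal and clearance-plus-transport losses on the
#' diagonal. All eigenvalues of `A` have negative real part (stable
#' degradation).
#'
#' @param mp a [model_params()] object.
#' @return an object of class `state_space` with elements `A`, `B`, `C`.
#' @export
build_state_space <- function(mp) {
  stopifnot(inherits(mp, "model_params"))
  if (mp$kind == "single") {
    A <- matrix(-1 / mp$tau_p, 1L, 1L)
    B <- matrix(1, 1L, 1L)
    C <- matrix(1, 1L, 1L)
  } else {
    A <- matrix(c(-(mp$q1 + 1 / mp$tau_p), mp$q1,
                  mp$q2, -(mp$q2 + 1 / mp$tau_i)), 2L, 2L)
    B <- matrix(c(1, 0), 2L, 1L)
    C <- matrix(c(1, 0), 1L, 2L)
  }
  structure(list(A = A, B = B, C = C, kind = mp$kind), class = "state_space")
}

#' Exact zero-order-hold discretization
#'
#' Converts the continuous system to the discrete recursion
#' \eqn{x_{k+1} = \Phi x_k + \Gamma u_k} with \eqn{\Phi = e^{A T_s}} and
#' \eqn{\Gamma = \int_0^{T_s} e^{A s} ds \, B = A^{-1} (\Phi - I) B}.
#' The secretion input is held constant over each step (zero-order hold).
#'
#' @param ss a [build_state_space()] object.
#' @param Ts step length in minutes (default 0.1).
#' @return an object of class `discrete_system` with `Phi`, `Gamma`, `Ts`.
#' @export
discretize <- function(ss, Ts = 0.1) {
  stopifnot(inherits(ss, "state_space"))
  if (!is.finite(Ts) || Ts <= 0) stop("'Ts' must be > 0", call. = FALSE)
  A <- ss$A
  if (nrow(A) == 1L) {
    Phi <- matrix(exp(A[1L, 1L] * Ts), 1L, 1L)
    Gamma <- (Phi - 1) / A[1L, 1L] * ss$B
  } else {
    Phi <- as.matrix(Matrix::expm(A * Ts))
    Gamma <- solve(A, (Phi - diag(nrow(A))) %*% ss$B)
  }
  structure(list(Phi = Phi, Gamma = Gamma, Ts = Ts, kind = ss$kind),
            class = "discrete_system")
}

#' Equilibrium state at constant glucose
#'
#' Solves \eqn{A x + B u(g_0) = 0}: the fasting steady state used to
#' initialize simulations. For the single model this is
#' `x0 = u(g0) * tau_p`. OGTT subjects are fasted at the first draw, so
#' simulations start from this equilibrium at the baseline glucose.
#'
#' @param mp a [model_params()] object.
#' @param g0 baseline glucose (record units).
#' @return numeric state vector (length 1 or 2).
#' @export
steady_state_init <- function(mp, g0) {
  stopifnot(inherits(mp, "model_params"))
  if (!is.finite(g0)) stop("'g0' must be finite", call. = FALSE)
  u0 <- secretion_rate(g0, mp$secretion)
  ss <- build_state_space(mp)
  as.numeric(solve(ss$A, -ss$B * u0))
}

# Fast scalar propagation: x[k+1] = phi x[k] + gamma u_k, via the C-level
# recursive filter. The secretion input fed through Gamma is the step
# average (u[k] + u[k+1])/2: Phi/Gamma stay the exact matrix-exponential
# pair, and averaging removes the leading quadrature error of holding a
# smoothly varying input constant over the step (exact for inputs linear in
# t). Returns the full state series aligned with u.
.sim_single <- function(u, tau_p, Ts, x0) {
  phi <- exp(-Ts / tau_p)
  gamma <- tau_p * (1 - phi)
  n <- length(u)
  if (n == 1L) return(x0)
  umid <- (u[-n] + u[-1L]) / 2
  c(x0, as.numeric(stats::filter(gamma * umid, phi, method = "recursive",
                                 init = x0)))
}

# Generic (matrix) propagation used for the two-compartment model; same
# step-averaged input convention as .sim_single.
.sim_lin <- function(Phi, Gamma, u, x0) {
  n <- length(u)
  d <- length(x0)
  X <- matrix(0, d, n)
  x <- as.numeric(x0)
  X[, 1L] <- x
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      x <- Phi %*% x + Gamma * ((u[k] + u[k + 1L]) / 2)
      X[, k + 1L] <- x
    }
  }
  X
}

# Plasma output on a uniform grid for glucose series g (same grid).
.sim_plasma_grid <- function(mp, g, Ts, x0 = NULL) {
  u <- secretion_rate(g, mp$secretion)
  if (is.null(x0)) x0 <- steady_state_init(mp, g[1L])
  if (mp$kind == "single") {
    .sim_single(u, mp$tau_p, Ts, x0[1L])
  } else {
    ds <- discretize(build_state_space(mp), Ts)
    .sim_lin(ds$Phi, ds$Gamma, u, x0)[1L, ]
  }
}

#' Simulate the plasma concentration under an interpolated glucose input
#'
#' Iterates the exact discretization at step `Ts` with the secretion input
#' evaluated from the glucose interpolant at every substep (the value fed
#' through `Gamma` over each step is the average of its two endpoint values,
#' which removes the leading hold-quadrature error for smooth inputs), and
#' returns the plasma output at the requested times (nearest grid node; the
#' grid is `Ts`-spaced so the sampling error is at most `Ts/2` minutes).
#'
#' @param mp a [model_params()] object.
#' @param ginput a [interpolate_glucose()] object.
#' @param out_times times (min) at which to report the output; must lie in
#'   the span of `ginput`.
#' @param x0 initial state; defaults to the fasting steady state at the
#'   glucose value at the start of the span.
#' @param Ts internal integration step in minutes (default 0.1).
#' @return a data.frame with columns `time` and `value` (plasma
#'   concentration).
#' @export
simulate_plasma <- function(mp, ginput, out_times = ginput$grid_times,
                            x0 = NULL, Ts = 0.1) {
  stopifnot(inherits(mp, "model_params"), inherits(ginput, "glucose_input"))
  span <- ginput$span
  if (any(out_times < span[1L] - 1e-9 | out_times > span[2L] + 1e-9)) {
    stop("'out_times' must lie within the glucose input span [",
         span[1L], ", ", span[2L], "] min", call. = FALSE)
  }
  n <- round((span[2L] - span[1L]) / Ts)
  tg <- span[1L] + Ts * (0:n)
  g <- ginput$fun(tg)
  y <- .sim_plasma_grid(mp, g, Ts, x0)
  idx <- pmin(n + 1L, pmax(1L, round((out_times - span[1L]) / Ts) + 1L))
  data.frame(time = out_times, value = y[idx])
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> kind:", x$kind, "\n")
  s <- x$secretion
  cat(sprintf("  secretion: Km = %g, C0 = %g, alpha = %g\n", s$Km, s$C0, s$alpha))
  cat(sprintf("  tau_p = %g min", x$tau_p))
  if (x$kind == "two_compartment") {
    cat(sprintf(", tau_i = %g min, q1 = %g, q2 = %g min^-1", x$tau_i, x$q1, x$q2))
  }
  cat("\n")
  invisible(x)
}
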