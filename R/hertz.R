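# Hertz-Sneddon force spectroscopy: forward model, simulation, contact-point
# estimation and nonlinear least-squares fitting of force-distance curves.
#
# Unit conventions used throughout the package:
#   piezo position z        micrometres (um), strictly increasing toward sample
#   force F                 nanonewtons (nN)
#   Young's modulus E       pascals (Pa)
#   spring constant k       N/m  (so F/k is in nm; F_nN / k * 1e-3 gives um)
# 1 Pa * um^2 = 1e-3 nN, hence the prefactor scaling below.

.PA_UM2_NN <- 1e-3

#' Indenter tip model
#'
#' Describes the AFM indenter geometry used by the Hertz-Sneddon contact
#' model. Silicon tips on soft silicon-nitride cantilevers are well
#' approximated by a four-sided pyramid; cone and sphere variants are
#' provided for other probes.
#'
#' @param geometry One of `"pyramid"`, `"cone"`, `"sphere"`.
#' @param half_angle Half-opening angle theta in degrees (cone/pyramid),
#'   `0 < theta < 90`. Default 35, a typical silicon-nitride probe face angle.
#' @param radius Tip radius R in micrometres (sphere only), `R > 0`.
#' @param poisson Poisson ratio nu of the sample, `0 < nu <= 0.5`. Default
#'   0.5, the incompressible-cell convention.
#' @return An object of class `tip_model`.
#' @examples
#' tip_model()                       # 35 degree pyramid, nu = 0.5
#' tip_model("sphere", radius = 2.5)
#' @export
tip_model <- function(geometry = c("pyramid", "cone", "sphere"),
                      half_angle = 35, radius = NULL, poisson = 0.5) {
  geometry <- match.arg(geometry)
  if (!(is.numeric(poisson) && length(poisson) == 1L &&
        poisson > 0 && poisson <= 0.5))
    stop("`poisson` must be in (0, 0.5]")
  if (geometry %in% c("cone", "pyramid")) {
    if (!(is.numeric(half_angle) && length(half_angle) == 1L &&
          half_angle > 0 && half_angle < 90))
      stop("`half_angle` must be in (0, 90) degrees")
  } else {
    if (is.null(radius) || !(is.numeric(radius) && radius > 0))
      stop("spherical tips require `radius` > 0 (um)")
  }
  structure(list(geometry = geometry, half_angle = half_angle,
                 radius = radius, poisson = poisson),
            class = "tip_model")
}

#' @export
print.tip_model <- function(x, ...) {
  par <- if (x$geometry == "sphere") sprintf("R = %g um", x$radius)
         else sprintf("theta = %g deg", x$half_angle)
  cat(sprintf("Indenter: %s (%s, nu = %g)\n", x$geometry, par, x$poisson))
  invisible(x)
}

# Prefactor A such that F[nN] = A * delta[um]^m for indentation delta.
hertz_prefactor <- function(E, tip) {
  red <- E / (1 - tip$poisson^2) * .PA_UM2_NN
  switch(tip$geometry,
    cone    = (2 / pi) * tan(tip$half_angle * pi / 180) * red,
    pyramid = 0.7453 * tan(tip$half_angle * pi / 180) * red,
    sphere  = (4 / 3) * sqrt(tip$radius) * red)
}

hertz_exponent <- function(tip) if (tip$geometry == "sphere") 1.5 else 2

#' AFM acquisition settings
#'
#' Metadata shared by all curves of a force map: the extend ramp, cantilever
#' spring constant, force setpoint and approach speed. Defaults mirror a
#' typical live-cell mapping protocol: 15 um ramp, 1 nN setpoint, 30 um/s
#' approach, and a soft (0.011 N/m) silicon-nitride lever.
#'
#' @param z_min,z_max Ramp range in um (`z` increases toward the sample).
#' @param dz Ramp step in um; default `NULL` derives it from the sampling
#'   rate as `speed / pixel_rate` (14.6 nm at the defaults).
#' @param spring_constant Cantilever stiffness in N/m.
#' @param setpoint Maximum commanded force in nN; the extend segment ends
#'   when this force is reached.
#' @param speed Approach speed in um/s.
#' @param pixel_rate Samples per second along the ramp (Hz).
#' @return A list of class `afm_settings`.
#' @export
afm_settings <- function(z_min = 0, z_max = 15, dz = NULL,
                         spring_constant = 0.011, setpoint = 1, speed = 30,
                         pixel_rate = 2048) {
  if (is.null(dz)) dz <- speed / pixel_rate
  stopifnot(z_max > z_min, dz > 0, spring_constant > 0, setpoint > 0)
  structure(list(z_min = z_min, z_max = z_max, dz = dz,
                 spring_constant = spring_constant,
                 setpoint = setpoint, speed = speed),
            class = "afm_settings")
}

#' Force-distance curve
#'
#' Container for a single AFM approach (and optional retract) record.
#'
#' @param z_extend,force_extend Extend-segment piezo positions (um, strictly
#'   monotonic, increasing toward the sample) and forces (nN); equal length
#'   >= 16.
#' @param spring_constant Cantilever stiffness (N/m), > 0.
#' @param setpoint Maximum commanded force (nN), > 0.
#' @param speed Approach speed (um/s).
#' @param position Optional `(x, y)` map coordinate in um.
#' @param z_retract,force_retract Optional retract segment.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z_extend, force_extend, spring_constant, setpoint,
                        speed = NA_real_, position = c(NA_real_, NA_real_),
                        z_retract = NULL, force_retract = NULL) {
  z_extend <- as.numeric(z_extend); force_extend <- as.numeric(force_extend)
  if (length(z_extend) != length(force_extend) || length(z_extend) < 16L)
    stop("extend arrays must have equal length >= 16")
  dzs <- diff(z_extend)
  if (!(all(dzs > 0) || all(dzs < 0)))
    stop("`z_extend` must be strictly monotonic")
  if (!is.finite(setpoint) || setpoint <= 0) stop("`setpoint` must be > 0")
  if (!is.finite(spring_constant) || spring_constant <= 0)
    stop("`spring_constant` must be > 0")
  structure(list(z_extend = z_extend, force_extend = force_extend,
                 z_retract = z_retract, force_retract = force_retract,
                 spring_constant = spring_constant, setpoint = setpoint,
                 speed = speed, position = position),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "Force-distance curve: %d extend samples, z in [%.3g, %.3g] um, F in [%.3g, %.3g] nN\n",
    length(x$z_extend), min(x$z_extend), max(x$z_extend),
    min(x$force_extend), max(x$force_extend)))
  cat(sprintf("  k = %g N/m, setpoint = %g nN\n", x$spring_constant, x$setpoint))
  invisible(x)
}

# Solve the self-consistent contact force at separations u = z - z0:
#   F = baseline + A * (u - b*F)^m,   b = 1e-3 / k  (um per nN of bending)
# Quadratic geometries (m = 2) have a closed form; m = 3/2 uses Newton.
solve_hertz_force <- function(u, A, m, b, baseline) {
  F <- rep(baseline, length(u))
  pos <- u > 0
  if (!any(pos)) return(F)
  up <- u[pos]
  if (m == 2 && b > 0) {
    # A b^2 F^2 - (2 A b u + 1) F + (A u^2 + baseline) = 0, physical root
    qa <- A * b^2
    qb <- -(2 * A * b * up + 1)
    qc <- A * up^2 + baseline
    disc <- pmax(qb^2 - 4 * qa * qc, 0)
    # smaller root in cancellation-stable form (qa -> 0 as k -> Inf)
    F[pos] <- 2 * qc / (-qb + sqrt(disc))
  } else if (b == 0) {
    F[pos] <- baseline + A * up^m
  } else {
    Fi <- baseline + A * up^m
    for (i in seq_len(60)) {
      d <- pmax(up - b * (Fi - 0), 0)
      g <- baseline + A * d^m - Fi
      gp <- -m * A * b * d^(m - 1) - 1
      step <- g / gp
      Fi <- Fi - step
      Fi[Fi < baseline] <- baseline
      if (max(abs(step)) < 1e-12) break
    }
    F[pos] <- Fi
  }
  F
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate an AFM force-distance curve
#'
#' Forward model of Hertz-Sneddon indentation with cantilever-bending
#' correction: below the contact point the force is the baseline offset; above
#' it the force satisfies `F = baseline + A * delta^m` with indentation
#' `delta = (z - z0) - F / k` (bending subtracted, solved self-consistently).
#' Gaussian force noise is added last. The extend segment terminates at the
#' first sample where the noiseless model reaches the setpoint force.
#'
#' @param E Young's modulus (Pa), > 0.
#' @param tip A [tip_model()].
#' @param z0 Contact point (um), inside the ramp range.
#' @param baseline Force offset (nN).
#' @param noise_sd Gaussian force noise standard deviation (nN), >= 0.
#' @param settings An [afm_settings()] object.
#' @param seed Optional integer; if given the curve is reproducible and the
#'   caller's RNG state is left untouched.
#' @param position Optional `(x, y)` coordinate stored as metadata.
#' @return A [force_curve()].
#' @examples
#' cv <- simulate_force_curve(1000, tip_model("cone"), z0 = 5, seed = 1)
#' @export
simulate_force_curve <- function(E, tip, z0, baseline = 0, noise_sd = 0,
                                 settings = afm_settings(), seed = NULL,
                                 position = c(NA_real_, NA_real_)) {
  stopifnot(is.numeric(E), E > 0, noise_sd >= 0)
  z <- seq(settings$z_min, settings$z_max, by = settings$dz)
  if (z0 < settings$z_min || z0 > settings$z_max)
    stop("`z0` outside the ramp range; inconsistent settings")
  A <- hertz_prefactor(E, tip)
  m <- hertz_exponent(tip)
  b <- 1e-3 / settings$spring_constant
  Fm <- solve_hertz_force(z - z0, A, m, b, baseline)
  hit <- which(Fm >= settings$setpoint)
  if (!length(hit))
    stop("setpoint force not reachable within the z-range; inconsistent settings")
  idx <- seq_len(hit[1L])
  Fobs <- Fm[idx]
  if (noise_sd > 0)
    Fobs <- Fobs + with_local_seed(seed, stats::rnorm(length(idx), 0, noise_sd))
  force_curve(z[idx], Fobs,
              spring_constant = settings$spring_constant,
              setpoint = settings$setpoint, speed = settings$speed,
              position = position)
}

#' Estimate the contact point of a force curve
#'
#' Two-stage heuristic: a ratio-of-variance scan (for every sliding split of
#' the extend segment, the variance of the window after the split divided by
#' the variance before it; the maximising split marks the departure from
#' baseline), followed by a local piecewise least-squares refinement - among
#' candidate contact points near the variance split, the one minimising the
#' residual sum of squares of a flat-baseline-plus-quadratic model. Used to
#' initialise the joint nonlinear fit; never reported as a final contact
#' point.
#'
#' @param curve A [force_curve()].
#' @param window Ratio-of-variance window width in samples
#'   (default `max(8, n/20)`).
#' @return Estimated contact point z0 (um).
#' @seealso [fit_hertz()]
#' @export
estimate_contact_point <- function(curve, window = NULL) {
  z <- curve$z_extend; F <- curve$force_extend
  n <- length(F)
  base_n <- max(10L, n %/% 5L)
  base_mad <- stats::mad(F[seq_len(base_n)])
  rng <- max(F) - min(F)
  if (rng < max(3 * base_mad, 1e-12))
    stop(structure(class = c("mechanocyte_no_contact", "error", "condition"),
                   list(message = "force range below noise floor: no contact detected",
                        call = sys.call(-1))))
  w <- if (is.null(window)) max(8L, n %/% 20L) else as.integer(window)
  idx <- seq.int(w + 1L, n - w)
  if (!length(idx)) return(z[which.max(diff(F)) + 1L])
  eps <- (1e-6 * rng)^2
  rov <- vapply(idx, function(i) {
    stats::var(F[(i + 1L):(i + w)]) / (stats::var(F[(i - w):i]) + eps)
  }, numeric(1))
  j0 <- idx[which.max(rov)]
  # refinement: piecewise flat + quadratic RSS over nearby candidate splits
  dz <- stats::median(diff(z))
  half <- max(4L, min(as.integer(ceiling(0.8 / dz)), n %/% 3L))
  cand <- seq.int(max(j0 - half, 3L), min(j0 + half, n - 3L))
  rss <- vapply(cand, function(j) {
    base <- mean(F[seq_len(j)])
    d <- pmax(z - z[j], 0)
    A <- sum((F - base) * d^2) / max(sum(d^4), 1e-300)
    sum((F - base - A * d^2)^2)
  }, numeric(1))
  z[cand[which.min(rss)]]
}

#' Fit the Hertz-Sneddon model to a force-distance curve
#'
#' Joint nonlinear least squares over the whole extend segment for the
#' parameters `(E, z0, baseline)`. The model is piecewise: baseline force
#' below the contact point `z0`, and `baseline + A(E) * delta^m` above it,
#' where the indentation uses the bending correction
#' `delta = (z - z0) - F/k` with the measured force `F`. The contact model
#' per geometry is `F = (2/pi) * E/(1 - nu^2) * tan(theta) * delta^2` (cone),
#' `F = 0.7453 * E/(1 - nu^2) * tan(theta) * delta^2` (four-sided pyramid),
#' and `F = (4/3) * E/(1 - nu^2) * sqrt(R) * delta^(3/2)` (sphere).
#'
#' E is optimised on the log scale so the fitted modulus is always positive.
#' The contact point is initialised by [estimate_contact_point()]; a curve
#' whose force range never rises above the noise floor raises a no-contact
#' error. Non-convergence is reported through `converged = FALSE`, never as
#' a silent estimate.
#'
#' @param curve A [force_curve()].
#' @param tip A [tip_model()]; default 35 degree pyramid with nu = 0.5.
#' @param options List of fit options: `maxiter` (default 200) and `tol`
#'   (relative convergence tolerance, default 1e-8).
#' @return An object of class `hertz_fit` with elements `E` (Pa), `z0` (um),
#'   `baseline` (nN), `rss` (nN^2), `n_fit`, `converged`, plus the data and
#'   tip for the methods ([predict.hertz_fit()], [plot.hertz_fit()], ...).
#' @examples
#' cv <- simulate_force_curve(1200, tip_model(), z0 = 6, noise_sd = 0.02, seed = 2)
#' fit <- fit_hertz(cv)
#' coef(fit)
#' @export
fit_hertz <- function(curve, tip = tip_model(), options = list()) {
  stopifnot(inherits(curve, "force_curve"), inherits(tip, "tip_model"))
  maxiter <- if (is.null(options$maxiter)) 200L else options$maxiter
  tol <- if (is.null(options$tol)) 1e-8 else options$tol

  z <- curve$z_extend; F <- curve$force_extend
  k <- curve$spring_constant
  m <- hertz_exponent(tip)
  A1 <- hertz_prefactor(1, tip)          # prefactor per unit E
  bend <- F * 1e-3 / k                   # um of cantilever bending

  z0_init <- estimate_contact_point(curve)   # may raise no-contact error
  pre <- z <= z0_init
  b_init <- if (any(pre)) stats::median(F[pre]) else min(F)
  d_end <- max((max(z) - z0_init) - bend[which.max(z)], 1e-3)
  E_init <- max((max(F) - b_init) / (A1 * d_end^m), 1)

  resid_fn <- function(p) {
    E <- exp(p[1L]); z0 <- p[2L]; base <- p[3L]
    delta <- pmax((z - z0) - bend, 0)
    F - (base + A1 * E * delta^m)
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = tol,
                                    ptol = tol, gtol = 0)
  fit <- minpack.lm::nls.lm(par = c(log(E_init), z0_init, b_init),
                            fn = resid_fn, control = ctl)
  p <- fit$par
  conv <- fit$info %in% c(1L, 2L, 3L, 4L) && is.finite(exp(p[1L]))
  res <- resid_fn(p)
  structure(list(E = exp(p[1L]), z0 = p[2L], baseline = p[3L],
                 rss = sum(res^2), n_fit = length(res),
                 converged = conv, info = fit$info,
                 message = fit$message, niter = fit$niter,
                 curve = curve, tip = tip, residuals = res),
            class = "hertz_fit")
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(E = object$E, z0 = object$z0, baseline = object$baseline)
}

#' @export
residuals.hertz_fit <- function(object, ...) object$residuals

#' @export
fitted.hertz_fit <- function(object, ...) {
  object$curve$force_extend - object$residuals
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat("Hertz-Sneddon fit\n")
  cat(sprintf("  E = %.4g Pa, z0 = %.4g um, baseline = %.4g nN\n",
              x$E, x$z0, x$baseline))
  cat(sprintf("  %s (%d points, RSS = %.3g nN^2)\n",
              if (x$converged) "converged" else
                sprintf("NOT converged (info %d: %s)", x$info, x$message),
              x$n_fit, x$rss))
  invisible(x)
}

#' @export
summary.hertz_fit <- function(object, ...) {
  s <- list(coef = coef(object), rss = object$rss, n = object$n_fit,
            sigma = sqrt(object$rss / max(object$n_fit - 3L, 1L)),
            converged = object$converged, tip = object$tip,
            niter = object$niter)
  class(s) <- "summary.hertz_fit"
  s
}

#' @export
print.summary.hertz_fit <- function(x, ...) {
  cat("Hertz-Sneddon model fit\n")
  print(x$tip)
  cat(sprintf("  E        %.6g Pa\n  z0       %.6g um\n  baseline %.6g nN\n",
              x$coef[["E"]], x$coef[["z0"]], x$coef[["baseline"]]))
  cat(sprintf("  residual sd %.3g nN on %d points (%d iterations, %s)\n",
              x$sigma, x$n, x$niter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Predicted force at new piezo positions
#'
#' Evaluates the fitted contact model self-consistently (bending included)
#' at the requested piezo positions.
#'
#' @param object A `hertz_fit`.
#' @param newdata Optional numeric vector of z values (um) or a list/data
#'   frame with a `z` element; defaults to the fitted curve's positions.
#' @param ... Unused.
#' @return Numeric vector of forces (nN).
#' @export
predict.hertz_fit <- function(object, newdata = NULL, ...) {
  z <- if (is.null(newdata)) object$curve$z_extend
       else if (is.numeric(newdata)) newdata
       else newdata$z
  A <- hertz_prefactor(object$E, object$tip)
  solve_hertz_force(z - object$z0, A, hertz_exponent(object$tip),
                    1e-3 / object$curve$spring_constant, object$baseline)
}

#' Simulate curves from a fitted Hertz model
#'
#' Draws new force-distance curves at the fitted `(E, z0, baseline)` with
#' Gaussian force noise equal to the fit's residual standard deviation.
#'
#' @param object A `hertz_fit`.
#' @param nsim Number of curves.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of [force_curve()] objects.
#' @export
simulate.hertz_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cv <- object$curve
  st <- afm_settings(z_min = min(cv$z_extend), z_max = max(cv$z_extend) + 1,
                     dz = stats::median(diff(cv$z_extend)),
                     spring_constant = cv$spring_constant,
                     setpoint = cv$setpoint,
                     speed = if (is.na(cv$speed)) 30 else cv$speed)
  sdn <- sqrt(object$rss / max(object$n_fit - 3L, 1L))
  with_local_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_force_curve(object$E, object$tip, object$z0, object$baseline,
                         noise_sd = sdn, settings = st)))
}

#' @export
plot.hertz_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$z_extend, cv$force_extend, pch = 16, cex = 0.4,
                 col = "grey40", xlab = "piezo position z (um)",
                 ylab = "force (nN)",
                 main = sprintf("Hertz-Sneddon fit: E = %.0f Pa", x$E), ...)
  zz <- seq(min(cv$z_extend), max(cv$z_extend), length.out = 400)
  graphics::lines(zz, predict(x, zz), col = "firebrick", lwd = 2)
  graphics::abline(v = x$z0, lty = 3)
  invisible(x)
}
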