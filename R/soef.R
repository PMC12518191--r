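#' Physical constants for iodine-131
#'
#' The physical half-life of ^131I and the derived decay constant. All
#' kinetic quantities in this package are expressed in hours, so the decay
#' constant is returned in h^-1.
#'
#' @return A list with elements `half_life_d` (8.022 days) and
#'   `lambda_phys` (\eqn{\ln 2 / (8.022 \times 24)} h^-1).
#' @examples
#' i131_constants()$lambda_phys
#' @export
i131_constants <- function() {
  half_life_d <- 8.022
  list(half_life_d = half_life_d,
       lambda_phys = log(2) / (half_life_d * 24))
}

#' Sum-of-exponentials retention model parameters
#'
#' Constructs a validated parameter set for the two sum-of-exponentials
#' functions (SOEFs) used to describe thyroidal ^131I retention as a
#' fraction of the administered activity:
#' \deqn{a_{4c}(t) = \frac{\lambda_1}{\lambda_2+\lambda_1-\lambda_3}
#'   \left(e^{-(\lambda_3+\lambda_{phys})t} -
#'         e^{-(\lambda_1+\lambda_2+\lambda_{phys})t}\right)
#'   + a_1 e^{-(\lambda_1+\lambda_2+\lambda_{phys})t}}
#' and \eqn{a_{3b}(t)}, the same expression without the \eqn{a_1} term.
#' \eqn{\lambda_1,\lambda_2,\lambda_3 \ge 0} are biological uptake/clearance
#' rate constants (h^-1) and \eqn{a_1 \ge 0} is the dimensionless blood-pool
#' background amplitude picked up by the neck measurement. The model
#' `"a3b"` is represented internally as `"a4c"` with \eqn{a_1} structurally
#' fixed at 0, so a single code path serves both.
#'
#' @param lambda1,lambda2,lambda3 Non-negative rate constants in h^-1.
#' @param a1 Non-negative blood-pool amplitude (fraction of administered
#'   activity). Forced to 0 when `model = "a3b"`.
#' @param model `"a4c"` (4 adjustable parameters) or `"a3b"` (3).
#' @return An object of class `soef_params`.
#' @seealso [soef_retention()], [soef_tia()]
#' @examples
#' p <- soef_params(0.04, 0.04, 0.0015, a1 = 0.05)
#' soef_retention(p, c(2, 24, 120))
#' @export
soef_params <- function(lambda1, lambda2, lambda3, a1 = 0,
                        model = c("a4c", "a3b")) {
  model <- match.arg(model)
  lambda1 <- unname(lambda1); lambda2 <- unname(lambda2)
  lambda3 <- unname(lambda3); a1 <- unname(a1)
  vals <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3, a1 = a1)
  if (any(!is.finite(vals)))
    stop("SOEF parameters must be finite", call. = FALSE)
  if (any(vals[1:3] < 0))
    stop("rate constants lambda1, lambda2, lambda3 must be >= 0",
         call. = FALSE)
  if (a1 < 0)
    stop("blood-pool amplitude a1 must be >= 0", call. = FALSE)
  if (model == "a3b") a1 <- 0
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 a1 = a1, model = model),
            class = "soef_params")
}

#' @export
print.soef_params <- function(x, ...) {
  cat(sprintf("SOEF %s: lambda1=%g lambda2=%g lambda3=%g (1/h), a1=%g\n",
              x$model, x$lambda1, x$lambda2, x$lambda3, x$a1))
  invisible(x)
}

# Relative threshold below which |lambda1+lambda2-lambda3| is treated as the
# removable singularity and the limit expression is used instead.
.soef_singular_tol <- 1e-10

# den = lambda1 + lambda2 - lambda3 is singular when it vanishes; the scale
# for "vanishes" is the overall magnitude of the rate constants.
.soef_is_singular <- function(p, lphys) {
  den <- p$lambda2 + p$lambda1 - p$lambda3
  abs(den) < .soef_singular_tol * (p$lambda1 + p$lambda2 + p$lambda3 + lphys)
}

#' Evaluate a sum-of-exponentials retention curve
#'
#' Returns the modelled fraction of administered activity in the thyroid at
#' time `t` hours after administration, including physical decay. Across the
#' removable singularity \eqn{\lambda_1+\lambda_2-\lambda_3 = 0} the first
#' term switches to its limit form
#' \eqn{\lambda_1 t\, e^{-(\lambda_3+\lambda_{phys})t}}, so the function is
#' continuous in the parameters.
#'
#' @param params A [soef_params()] object.
#' @param t Vector of times in hours, all `>= 0`.
#' @return Numeric vector of retention fractions (dimensionless).
#' @export
soef_retention <- function(params, t) {
  stopifnot(inherits(params, "soef_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("t must be finite numeric", call. = FALSE)
  if (any(t < 0))
    stop("t must be >= 0 (hours after administration)", call. = FALSE)
  lp <- i131_constants()$lambda_phys
  slow <- params$lambda3 + lp
  fast <- params$lambda1 + params$lambda2 + lp
  first <- if (.soef_is_singular(params, lp)) {
    params$lambda1 * t * exp(-slow * t)
  } else {
    params$lambda1 / (params$lambda2 + params$lambda1 - params$lambda3) *
      (exp(-slow * t) - exp(-fast * t))
  }
  first + params$a1 * exp(-fast * t)
}

#' Closed-form time-integrated activity of a SOEF
#'
#' Integrates the retention curve analytically over \eqn{[0, \infty)}:
#' \deqn{TIA = \frac{\lambda_1}{\lambda_2+\lambda_1-\lambda_3}
#'   \left(\frac{1}{\lambda_3+\lambda_{phys}} -
#'         \frac{1}{\lambda_1+\lambda_2+\lambda_{phys}}\right)
#'   + \frac{a_1}{\lambda_1+\lambda_2+\lambda_{phys}}}
#' with the limit form \eqn{\lambda_1/(\lambda_3+\lambda_{phys})^2} for the
#' first term at the removable singularity. Units are (fraction of
#' administered activity) x hours; because the administered activity is
#' normalised to 1, no activity-unit conversion is applied.
#'
#' @param params A [soef_params()] object.
#' @return The time-integrated activity in hours (non-negative scalar).
#' @examples
#' soef_tia(soef_params(0.04, 0.04, 0.0015, a1 = 0.05))
#' @export
soef_tia <- function(params) {
  stopifnot(inherits(params, "soef_params"))
  lp <- i131_constants()$lambda_phys
  slow <- params$lambda3 + lp
  fast <- params$lambda1 + params$lambda2 + lp
  first <- if (.soef_is_singular(params, lp)) {
    params$lambda1 / slow^2
  } else {
    params$lambda1 / (params$lambda2 + params$lambda1 - params$lambda3) *
      (1 / slow - 1 / fast)
  }
  first + params$a1 / fast
}

# Vectorised internal forms used by the fitting code: theta is the natural
# scale parameter vector c(lambda1, lambda2, lambda3, a1).
.soef_eval <- function(theta, t, lp = i131_constants()$lambda_phys) {
  slow <- theta[3] + lp
  fast <- theta[1] + theta[2] + lp
  den <- theta[1] + theta[2] - theta[3]
  if (abs(den) < .soef_singular_tol * (sum(theta[1:3]) + lp)) {
    theta[1] * t * exp(-slow * t) + theta[4] * exp(-fast * t)
  } else {
    theta[1] / den * (exp(-slow * t) - exp(-fast * t)) +
      theta[4] * exp(-fast * t)
  }
}

.soef_tia_theta <- function(theta, lp = i131_constants()$lambda_phys) {
  slow <- theta[3] + lp
  fast <- theta[1] + theta[2] + lp
  den <- theta[1] + theta[2] - theta[3]
  first <- if (abs(den) < .soef_singular_tol * (sum(theta[1:3]) + lp))
    theta[1] / slow^2 else theta[1] / den * (1 / slow - 1 / fast)
  first + theta[4] / fast
}
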