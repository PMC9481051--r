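# Two-parameter production-resource curve forms.
#
# Short-term responses (photosynthesis-irradiance, uptake-substrate) follow a
# hyperbolic tangent of a physical capture slope against a biological maximum;
# acclimated responses (division rate against growth irradiance or far-field
# substrate) follow a rectangular hyperbola. The acclimated nutrient form is
# algebraically identical to a Michaelis-Menten curve with half-saturation
# Km_cell = Vm / alpha_v, which is why half-saturation "affinity" readings of
# whole-cell growth curves are physically misleading.

#' Short-term photosynthesis-irradiance curve
#'
#' \eqn{P = P_m \tanh(\alpha_P I_E / P_m)}. The light-saturation index
#' \eqn{I_K^P = P_m/\alpha_P} is derived, never stored; at \eqn{I_E = I_K^P}
#' the tanh form gives \eqn{P = 0.76 P_m}.
#'
#' @param p_max Light-saturated photosynthetic rate \eqn{P_m} (d\eqn{^{-1}}).
#' @param alpha_p Light-limited slope (m\eqn{^2} (mol quanta)\eqn{^{-1}}).
#' @return Object of class `"pi_curve"`.
#' @export
pi_curve <- function(p_max, alpha_p) {
  pd_check_scalar(p_max, "p_max", positive = TRUE)
  pd_check_scalar(alpha_p, "alpha_p", positive = TRUE)
  structure(list(p_max = p_max, alpha_p = alpha_p), class = "pi_curve")
}

#' Acclimated division rate-irradiance curve
#'
#' Rectangular hyperbola
#' \eqn{\mu = \alpha_\mu (I_g - I_r) \mu_m / (\alpha_\mu (I_g - I_r) + \mu_m)}
#' with compensation-like irradiance \eqn{I_r}; \eqn{\mu = 0.5\mu_m} at
#' \eqn{I_g = \mu_m/\alpha_\mu + I_r}.
#'
#' @param mu_max Maximum division rate \eqn{\mu_m} (d\eqn{^{-1}}).
#' @param alpha_mu Low-light slope (rate per mol quanta m\eqn{^{-2}}
#'   d\eqn{^{-1}}).
#' @param i_r Irradiance where production balances maintenance respiration
#'   (mol quanta m\eqn{^{-2}} d\eqn{^{-1}}), \eqn{\ge 0}.
#' @return Object of class `"mu_ig_curve"`.
#' @export
mu_ig_curve <- function(mu_max, alpha_mu, i_r = 0) {
  pd_check_scalar(mu_max, "mu_max", positive = TRUE)
  pd_check_scalar(alpha_mu, "alpha_mu", positive = TRUE)
  pd_check_scalar(i_r, "i_r", nonneg = TRUE)
  structure(list(mu_max = mu_max, alpha_mu = alpha_mu, i_r = i_r),
            class = "mu_ig_curve")
}

#' Short-term uptake-substrate curve
#'
#' \eqn{v = V_m \tanh(\alpha_v S_\infty / V_m)}; the derived saturation index
#' `km_cell(curve)` is \eqn{V_m/\alpha_v}.
#'
#' @param v_max Maximum uptake rate \eqn{V_m} (mmol cell\eqn{^{-1}}
#'   d\eqn{^{-1}}).
#' @param alpha_v Initial slope (dm\eqn{^3} d\eqn{^{-1}} cell\eqn{^{-1}}).
#' @return Object of class `"uptake_curve"`.
#' @export
uptake_curve <- function(v_max, alpha_v) {
  pd_check_scalar(v_max, "v_max", positive = TRUE)
  pd_check_scalar(alpha_v, "alpha_v", positive = TRUE)
  structure(list(v_max = v_max, alpha_v = alpha_v), class = "uptake_curve")
}

#' Derived saturation indices
#'
#' `saturation_index()` returns \eqn{P_m/\alpha_P} or \eqn{\mu_m/\alpha_\mu};
#' `km_cell()` returns \eqn{V_m/\alpha_v}, the emergent half-saturation of the
#' acclimated growth-substrate hyperbola.
#'
#' @param curve A curve object.
#' @return Scalar in the resource units of the curve.
#' @export
saturation_index <- function(curve) {
  if (inherits(curve, "pi_curve")) return(curve$p_max / curve$alpha_p)
  if (inherits(curve, "mu_ig_curve")) return(curve$mu_max / curve$alpha_mu)
  if (inherits(curve, "uptake_curve")) return(curve$v_max / curve$alpha_v)
  pd_stop("no saturation index for this object", "domain_error")
}

#' @rdname saturation_index
#' @export
km_cell <- function(curve) {
  stopifnot(inherits(curve, "uptake_curve"))
  curve$v_max / curve$alpha_v
}

#' Evaluate the short-term photosynthesis-irradiance curve
#'
#' @param curve A [pi_curve()].
#' @param irradiance \eqn{I_E} (mol quanta m\eqn{^{-2}} d\eqn{^{-1}}),
#'   \eqn{\ge 0} (vectorized).
#' @return Photosynthetic rate (d\eqn{^{-1}}), bounded by `p_max`.
#' @export
pi_rate <- function(curve, irradiance) {
  stopifnot(inherits(curve, "pi_curve"))
  if (any(!is.finite(irradiance)) || any(irradiance < 0)) {
    pd_stop("`irradiance` must be non-negative", "domain_error")
  }
  curve$p_max * tanh(curve$alpha_p * irradiance / curve$p_max)
}

#' Acclimated division rate from growth irradiance
#'
#' Rectangular hyperbola in \eqn{I_g - I_r}, clamped to zero below the
#' compensation irradiance (division rates cannot be negative).
#'
#' @param curve A [mu_ig_curve()].
#' @param ig Growth irradiance (mol quanta m\eqn{^{-2}} d\eqn{^{-1}}),
#'   vectorized; values below `i_r` give 0.
#' @return Division rate (d\eqn{^{-1}}), strictly below `mu_max`.
#' @export
mu_from_light <- function(curve, ig) {
  stopifnot(inherits(curve, "mu_ig_curve"))
  x <- pmax(0, ig - curve$i_r) * curve$alpha_mu
  x * curve$mu_max / (x + curve$mu_max)
}

#' Short-term nutrient uptake from far-field substrate
#'
#' @param curve An [uptake_curve()].
#' @param s_inf Far-field substrate concentration (mmol m\eqn{^{-3}}),
#'   \eqn{\ge 0} (vectorized).
#' @return Uptake rate (mmol cell\eqn{^{-1}} d\eqn{^{-1}}).
#' @export
uptake_rate <- function(curve, s_inf) {
  stopifnot(inherits(curve, "uptake_curve"))
  if (any(!is.finite(s_inf)) || any(s_inf < 0)) {
    pd_stop("`s_inf` must be non-negative", "domain_error")
  }
  curve$v_max * tanh(curve$alpha_v * s_inf / curve$v_max)
}

#' Acclimated division rate from far-field substrate
#'
#' \eqn{\mu = \frac{\alpha_v S_\infty V_m}{\alpha_v S_\infty + V_m}\frac{1}{Q}
#'   = \mu_m \frac{S_\infty}{S_\infty + K_{m,cell}}}
#' with \eqn{\mu_m = V_m/Q} and \eqn{K_{m,cell} = V_m/\alpha_v}: the
#' diffusion-shaped acclimated response and its Michaelis-Menten rewriting
#' are the same curve.
#'
#' @param curve An [uptake_curve()].
#' @param q Cell quota for the limiting nutrient (mmol cell\eqn{^{-1}}), > 0.
#' @param s_inf Far-field concentration (mmol m\eqn{^{-3}}), \eqn{\ge 0}
#'   (vectorized).
#' @return Division rate (d\eqn{^{-1}}).
#' @export
mu_from_substrate <- function(curve, q, s_inf) {
  stopifnot(inherits(curve, "uptake_curve"))
  pd_check_scalar(q, "q", positive = TRUE)
  if (any(!is.finite(s_inf)) || any(s_inf < 0)) {
    pd_stop("`s_inf` must be non-negative", "domain_error")
  }
  x <- curve$alpha_v * s_inf
  (x * curve$v_max / (x + curve$v_max)) / q
}

#' Michaelis-Menten equivalent of an acclimated uptake curve
#'
#' @param curve An [uptake_curve()].
#' @param q Cell quota (mmol cell\eqn{^{-1}}).
#' @param m_loss Specific loss rate carried alongside (d\eqn{^{-1}}).
#' @return List with `vm_star` (\eqn{V_m/Q}, d\eqn{^{-1}}), `km`
#'   (\eqn{V_m/\alpha_v}, mmol m\eqn{^{-3}}) and `m_loss`.
#' @export
michaelis_equivalent <- function(curve, q, m_loss = 0) {
  stopifnot(inherits(curve, "uptake_curve"))
  pd_check_scalar(q, "q", positive = TRUE)
  pd_check_scalar(m_loss, "m_loss", nonneg = TRUE)
  list(vm_star = curve$v_max / q, km = km_cell(curve), m_loss = m_loss)
}

# --- fitting ----------------------------------------------------------------

pd_fit_models <- c("pi_tanh", "mu_irradiance", "uptake_tanh", "mu_substrate")

pd_model_fun <- function(model) {
  switch(model,
    pi_tanh       = function(p, x) p[1] * tanh(p[2] * x / p[1]),
    uptake_tanh   = function(p, x) p[1] * tanh(p[2] * x / p[1]),
    mu_irradiance = function(p, x) {
      e <- p[2] * pmax(0, x - p[3])
      e * p[1] / (e + p[1])
    },
    mu_substrate  = function(p, x) p[1] * x / (x + p[2])
  )
}

pd_model_parnames <- function(model) {
  switch(model,
    pi_tanh       = c("p_max", "alpha_p"),
    uptake_tanh   = c("v_max", "alpha_v"),
    mu_irradiance = c("mu_max", "alpha_mu", "i_r"),
    mu_substrate  = c("mu_max", "km_cell")
  )
}

# Deterministic multi-start grid: decade-spaced multiples around crude
# data-derived scales, so fits are reproducible without a seed.
pd_fit_starts <- function(model, x, y) {
  ymax <- max(y)
  if (ymax <= 0) ymax <- 1
  xs <- x[x > 0 & y > 0]
  ys <- y[x > 0 & y > 0]
  slope0 <- if (length(xs)) stats::median(ys / xs) else 1
  if (!is.finite(slope0) || slope0 <= 0) slope0 <- 1
  maxg <- ymax * c(0.5, 1, 2, 5)
  slg <- slope0 * c(0.1, 1, 10)
  if (model == "mu_irradiance") {
    irg <- c(0, min(x), stats::quantile(x, 0.25, names = FALSE))
    g <- expand.grid(maxg, slg, irg, KEEP.OUT.ATTRS = FALSE)
  } else {
    g <- expand.grid(maxg, slg, KEEP.OUT.ATTRS = FALSE)
  }
  if (model == "mu_substrate") {
    # second parameter is a half-saturation, not a slope
    g[[2]] <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)[
      rep(1:3, each = length(maxg))]
  }
  as.matrix(g)
}

#' Least-squares fit of a production-resource curve
#'
#' Fits one of the four two/three-parameter curve forms to `(resource, rate)`
#' data by deterministic multi-start least squares (decade-spaced start grid,
#' Nelder-Mead then BFGS polish); no random numbers are consumed, so the fit
#' is reproducible byte-for-byte.
#'
#' @param model One of `"pi_tanh"` (short-term light response),
#'   `"mu_irradiance"` (acclimated light response, 3 parameters),
#'   `"uptake_tanh"` (short-term uptake), `"mu_substrate"` (acclimated
#'   growth-substrate hyperbola, parameterized as `mu_max`, `km_cell`).
#' @param data Data frame (or 2-column object) with columns `resource`,
#'   `rate`; at least 3 rows, non-negative resources.
#' @return Object of class `"curve_fit"`: `model`, named `par`, `rss`,
#'   `r_squared`, `fitted`, `data`.
#' @examples
#' x <- seq(0.5, 40, length.out = 20)
#' y <- mu_from_light(mu_ig_curve(1.2, 0.05, 0.5), x)
#' fit_curve("mu_irradiance", data.frame(resource = x, rate = y))$par
#' @export
fit_curve <- function(model = pd_fit_models, data) {
  model <- match.arg(model)
  data <- as.data.frame(data)
  if (!all(c("resource", "rate") %in% names(data)) && ncol(data) >= 2) {
    names(data)[1:2] <- c("resource", "rate")
  }
  x <- as.numeric(data$resource)
  y <- as.numeric(data$rate)
  if (length(x) < 3) {
    pd_stop("at least 3 data points are required", "convergence_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0)) {
    pd_stop("resources must be finite and non-negative", "domain_error")
  }
  fun <- pd_model_fun(model)
  npar <- length(pd_model_parnames(model))
  # positive parameters optimized on log scale; i_r stays on natural scale
  to_opt <- function(p) c(log(p[1:2]), if (npar == 3) p[3])
  from_opt <- function(th) c(exp(th[1:2]), if (npar == 3) max(0, th[3]))
  rss_fn <- function(th) {
    r <- y - fun(from_opt(th), x)
    sum(r * r)
  }
  best <- NULL
  for (i in seq_len(nrow(starts <- pd_fit_starts(model, x, y)))) {
    p0 <- starts[i, ]
    if (any(p0[1:2] <= 0)) next
    o <- tryCatch(
      stats::optim(to_opt(p0), rss_fn, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(o) || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    pd_stop("curve fit failed from every start", "convergence_error")
  }
  polish <- tryCatch(
    stats::optim(best$par, rss_fn, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15)),
    error = function(e) best
  )
  if (is.finite(polish$value) && polish$value <= best$value) best <- polish
  par <- from_opt(best$par)
  names(par) <- pd_model_parnames(model)
  fitted <- fun(par, x)
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      model = model, par = par, rss = best$value,
      r_squared = if (tss > 0) 1 - best$value / tss else NA_real_,
      fitted = fitted, data = data.frame(resource = x, rate = y)
    ),
    class = "curve_fit"
  )
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> model = %s, n = %d\n", x$model, nrow(x$data)))
  print(signif(x$par, 6))
  cat(sprintf("RSS = %.6g, R^2 = %.4f\n", x$rss, x$r_squared))
  invisible(x)
}
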