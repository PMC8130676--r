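# Fractional viscoelastic models: single fractional element (springpot) and
# the generalized Kelvin-Voigt model (two springpots in parallel), their
# crossover frequency, joint fitting, and bootstrap confidence intervals.

#' Generalized Kelvin--Voigt modulus
#'
#' G*(omega) = G0 [ (i omega t0)^alpha + (i omega t0)^beta ] with t0 = 1 s,
#' i.e. real part G0 [ w^a cos(pi a/2) + w^b cos(pi b/2) ] and imaginary
#' part with sines. The two springpots enter symmetrically; by convention
#' alpha >= beta so beta controls the low-frequency (solid-like) branch and
#' beta = 0 gives a frequency-independent steady-state elasticity G0.
#'
#' @param omega Angular frequency in rad s^-1 (> 0), vectorized.
#' @param G0 Modulus scale in Pa (> 0).
#' @param alpha,beta Power-law exponents in [0, 1].
#' @param t0 Reference time in s (fixed 1 s).
#' @return Complex modulus in Pa.
#' @export
gkv_modulus <- function(omega, G0, alpha, beta, t0 = 1) {
  if (any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  stopifnot(G0 > 0, alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  w <- omega * t0
  G0 * (complex(modulus = w^alpha, argument = pi * alpha / 2) +
          complex(modulus = w^beta, argument = pi * beta / 2))
}

#' Single fractional element (springpot) modulus
#'
#' G*(omega) = prefactor * (i omega t0)^alpha: a pure power law with
#' constant phase delta = pi alpha / 2. alpha = 0 is a spring, alpha = 1 a
#' Newtonian dashpot.
#'
#' @param omega Angular frequency in rad s^-1 (> 0).
#' @param prefactor Modulus scale in Pa (> 0).
#' @param alpha Exponent in [0, 1].
#' @param t0 Reference time in s (fixed 1 s).
#' @return Complex modulus in Pa.
#' @export
sfe_modulus <- function(omega, prefactor, alpha, t0 = 1) {
  if (any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  stopifnot(prefactor > 0, alpha >= 0, alpha <= 1)
  w <- omega * t0
  prefactor * complex(modulus = w^alpha, argument = pi * alpha / 2)
}

#' Crossover frequency of the generalized Kelvin--Voigt model
#'
#' Closed-form solution of G'(omega) = G''(omega):
#' omega_x = [ (cos(pi b/2) - sin(pi b/2)) / (sin(pi a/2) - cos(pi a/2)) ]
#' ^(1/(a - b)) (with a the larger exponent). A crossover exists only when
#' the bracket is positive, i.e. when the high-frequency branch is
#' fluid-like (alpha > 1/2) and the low-frequency branch solid-like
#' (beta < 1/2).
#'
#' @param alpha,beta GKV exponents in [0, 1], alpha != beta.
#' @param t0 Reference time in s.
#' @return A list with \code{omega_x} (rad s^-1), \code{f_x} (Hz),
#'   \code{defined} (logical) and \code{reason} when undefined.
#' @examples
#' crossover_frequency(0.850, 0.058)$f_x
#' @export
crossover_frequency <- function(alpha, beta, t0 = 1) {
  und <- function(reason) list(omega_x = NA_real_, f_x = NA_real_,
                               defined = FALSE, reason = reason)
  if (alpha == beta) return(und("alpha equals beta: constant G'/G'' ratio"))
  a <- max(alpha, beta); b <- min(alpha, beta)
  num <- cos(pi * b / 2) - sin(pi * b / 2)
  den <- sin(pi * a / 2) - cos(pi * a / 2)
  if (num <= 0 || den <= 0) {
    return(und("no crossover: G' - G'' does not change sign"))
  }
  omega_x <- (num / den)^(1 / (a - b)) / t0
  list(omega_x = omega_x, f_x = omega_x / (2 * pi), defined = TRUE,
       reason = NA_character_)
}

#' Young's modulus from the steady-state shear modulus
#'
#' E = 2 G0 (1 + nu); for an incompressible material (nu = 0.5) E = 3 G0.
#'
#' @param G0 Shear modulus scale in Pa.
#' @param nu Poisson's ratio in (-1, 0.5] (default 0.5).
#' @return Young's modulus in Pa.
#' @export
young_modulus <- function(G0, nu = 0.5) {
  if (any(nu <= -1) || any(nu > 0.5)) {
    stop("Poisson's ratio must lie in (-1, 0.5]", call. = FALSE)
  }
  2 * G0 * (1 + nu)
}

.power_fit <- function(freq_hz, y) {
  # least squares of y = p * omega^a on linear scale, log-space start
  omega <- 2 * pi * freq_hz
  lf <- stats::lm(log(y) ~ log(omega))
  start <- c(log(exp(unname(stats::coef(lf)[1]))), unname(stats::coef(lf)[2]))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) exp(p[1]) * omega^p[2] - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  pred <- exp(fit$par[1]) * omega^fit$par[2]
  list(prefactor = exp(fit$par[1]), exponent = fit$par[2],
       r2 = .r_squared(y, pred))
}

#' Separate power-law (SFE) fits to the storage and loss moduli
#'
#' Fits G'(omega) = G' * omega^alpha' and G''(omega) = G'' * omega^alpha''
#' independently (the phenomenological two-power-law description). Fits with
#' R^2 below \code{r2_min} are flagged \code{retained = FALSE}.
#'
#' @param spectrum Tibble with columns \code{freq_hz}, \code{G1_Pa},
#'   \code{G2_Pa}.
#' @param r2_min Retention threshold on the goodness of fit (default 0.9).
#' @return Tibble with one row per component (\code{storage}, \code{loss}):
#'   \code{prefactor_Pa}, \code{exponent}, \code{r2}, \code{retained}.
#' @export
fit_sfe_separate <- function(spectrum, r2_min = 0.9) {
  stopifnot(all(c("freq_hz", "G1_Pa", "G2_Pa") %in% names(spectrum)))
  purrr::map_dfr(c(storage = "G1_Pa", loss = "G2_Pa"), function(col) {
    ok <- is.finite(spectrum[[col]]) & spectrum[[col]] > 0
    if (sum(ok) < 2) {
      stop("need at least two frequencies with positive modulus per component",
           call. = FALSE)
    }
    ft <- .power_fit(spectrum$freq_hz[ok], spectrum[[col]][ok])
    tibble::tibble(prefactor_Pa = ft$prefactor, exponent = ft$exponent,
                   r2 = ft$r2, retained = ft$r2 >= r2_min)
  }, .id = "component")
}

#' Joint generalized Kelvin--Voigt fit
#'
#' Least squares of the three GKV parameters (G0, alpha, beta) over the
#' concatenated (G', G'') vector, with box bounds 0 <= exponents <= 1 and
#' G0 > 0; the springpot symmetry is used to order alpha >= beta after the
#' fit. R^2 is computed over the concatenated vector; fits below
#' \code{r2_flag} are retained but flagged.
#'
#' @param spectrum Tibble with \code{freq_hz}, \code{G1_Pa}, \code{G2_Pa}.
#' @param weights Optional residual weights (recycled over the concatenated
#'   vector).
#' @param log_residuals Fit in log-modulus space instead of linear (default
#'   FALSE).
#' @param r2_flag Goodness-of-fit floor below which the fit is flagged
#'   (default 0.7).
#' @return An object of class \code{gkv_fit} with elements \code{G0},
#'   \code{alpha}, \code{beta}, \code{r2}, \code{f_x}, \code{E},
#'   \code{converged}, \code{flagged}, \code{n_freq}.
#' @export
fit_gkv <- function(spectrum, weights = NULL, log_residuals = FALSE,
                    r2_flag = 0.7) {
  stopifnot(all(c("freq_hz", "G1_Pa", "G2_Pa") %in% names(spectrum)))
  ok <- is.finite(spectrum$G1_Pa) & is.finite(spectrum$G2_Pa)
  if (sum(ok) < 2) stop("need at least two frequencies", call. = FALSE)
  omega <- 2 * pi * spectrum$freq_hz[ok]
  y <- c(spectrum$G1_Pa[ok], spectrum$G2_Pa[ok])
  w <- if (is.null(weights)) rep(1, length(y)) else rep_len(weights, length(y))
  model <- function(p) {
    G <- gkv_modulus(omega, exp(p[1]), p[2], p[3])
    c(Re(G), Im(G))
  }
  resid_fn <- function(p) {
    m <- model(p)
    if (log_residuals) sqrt(w) * (log(pmax(m, 1e-12)) - log(pmax(y, 1e-12)))
    else sqrt(w) * (m - y)
  }
  G0_seed <- max(mean(abs(y)), 1e-6)
  starts <- list(c(log(G0_seed), 0.8, 0.1), c(log(G0_seed), 0.5, 0.5),
                 c(log(G0_seed), 0.95, 0.02))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = c(log(1e-9), 0, 0),
                         upper = c(log(1e12), 1, 1),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("GKV fit failed to converge", call. = FALSE)
  p <- best$par
  alpha <- max(p[2], p[3]); beta <- min(p[2], p[3])
  G0 <- exp(p[1])
  pred <- model(c(log(G0), alpha, beta))
  r2 <- .r_squared(y, pred)
  structure(list(
    G0 = G0, alpha = alpha, beta = beta, t0 = 1, r2 = r2,
    f_x = crossover_frequency(alpha, beta)$f_x,
    E = young_modulus(G0),
    converged = best$info %in% 1:4,
    flagged = !(best$info %in% 1:4) || r2 < r2_flag,
    n_freq = sum(ok),
    boot_ci = NULL
  ), class = "gkv_fit")
}

#' @export
print.gkv_fit <- function(x, ...) {
  cat(sprintf(
    "<gkv_fit> G0 = %.4g Pa, alpha = %.3f, beta = %.3f (R2 = %.4f%s)\n",
    x$G0, x$alpha, x$beta, x$r2, if (x$flagged) ", flagged" else ""))
  if (!is.na(x$f_x)) cat(sprintf("  crossover f_x = %.4g Hz, E = %.4g Pa\n",
                                 x$f_x, x$E))
  invisible(x)
}

#' Tidy a GKV fit
#'
#' @param x A \code{gkv_fit}.
#' @param ... Unused.
#' @return Tibble with one row per parameter (estimate and, when bootstrap
#'   intervals are attached, the 2 sigma half-width).
#' @export
tidy.gkv_fit <- function(x, ...) {
  est <- c(G0_Pa = x$G0, alpha = x$alpha, beta = x$beta,
           f_x_Hz = x$f_x, E_Pa = x$E)
  out <- tibble::tibble(term = names(est), estimate = unname(est))
  if (!is.null(x$boot_ci)) {
    out$ci2s <- unname(x$boot_ci[out$term])
  }
  out
}

#' Glance at a GKV fit
#'
#' @param x A \code{gkv_fit}.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics.
#' @export
glance.gkv_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, converged = x$converged, flagged = x$flagged,
                 n_freq = x$n_freq)
}

#' Bootstrap 2 sigma confidence intervals over beads
#'
#' Resamples beads with replacement \code{n_boot} times, refits the model on
#' each resample's bead-averaged spectrum, and reports twice the standard
#' deviation of every bootstrap parameter distribution. The resampling unit
#' is the bead, matching per-bead error bars.
#'
#' @param bead_spectra Tibble with columns \code{bead_id}, \code{freq_hz},
#'   \code{G1_Pa}, \code{G2_Pa} (one spectrum per bead, e.g. one analysis
#'   window).
#' @param fit_fn Fitting function taking an aggregated spectrum tibble and
#'   returning a named list/object of parameters; default \code{fit_gkv}.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return Named numeric vector of 2 sigma half-widths for \code{G0_Pa},
#'   \code{alpha}, \code{beta}, \code{f_x_Hz}, \code{E_Pa}.
#' @export
bootstrap_ci <- function(bead_spectra, fit_fn = fit_gkv, n_boot = 100, seed) {
  stopifnot(all(c("bead_id", "freq_hz", "G1_Pa", "G2_Pa") %in%
                  names(bead_spectra)))
  beads <- unique(bead_spectra$bead_id)
  if (length(beads) < 2) {
    warning("fewer than two beads: bootstrap CI undefined", call. = FALSE)
    return(c(G0_Pa = NA_real_, alpha = NA_real_, beta = NA_real_,
             f_x_Hz = NA_real_, E_Pa = NA_real_))
  }
  if (missing(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 5,
                  dimnames = list(NULL, c("G0_Pa", "alpha", "beta",
                                          "f_x_Hz", "E_Pa")))
  by_bead <- split(bead_spectra, bead_spectra$bead_id)
  for (b in seq_len(n_boot)) {
    pick <- sample(beads, length(beads), replace = TRUE)
    agg <- dplyr::bind_rows(by_bead[as.character(pick)]) |>
      dplyr::group_by(.data$freq_hz) |>
      dplyr::summarise(G1_Pa = mean(.data$G1_Pa), G2_Pa = mean(.data$G2_Pa),
                       .groups = "drop")
    ft <- tryCatch(fit_fn(agg), error = function(e) NULL)
    if (is.null(ft)) next
    draws[b, ] <- c(ft$G0, ft$alpha, ft$beta, ft$f_x, ft$E)
  }
  2 * apply(draws, 2, stats::sd, na.rm = TRUE)
}

#' Named model registry
#'
#' @param name Model name: \code{"sfe"}, \code{"gkv"} or
#'   \code{"generalized_maxwell"}.
#' @return The model's modulus function.
#' @export
viscoelastic_model <- function(name = c("gkv", "sfe", "generalized_maxwell")) {
  name <- match.arg(name)
  switch(name,
    gkv = gkv_modulus,
    sfe = sfe_modulus,
    generalized_maxwell = stop(
      "generalized Maxwell model not implemented (supplementary-only form)",
      call. = FALSE)
  )
}
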