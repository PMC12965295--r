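#' Transient-absorption surface
#'
#' A delay x wavelength matrix of absorbance changes with its axes and
#' instrument-response metadata.
#'
#' @param delays strictly increasing numeric vector, ps.
#' @param wavelengths monotone numeric vector, nm.
#' @param dA numeric matrix, `length(delays)` x `length(wavelengths)`, delta OD.
#' @param irf_sigma Gaussian IRF width (standard deviation), ps.
#' @param t0 time zero, ps.
#' @return object of class `ta_surface`.
#' @export
ta_surface <- function(delays, wavelengths, dA, irf_sigma = 0, t0 = 0) {
  delays <- as.numeric(delays)
  wavelengths <- as.numeric(wavelengths)
  dA <- as.matrix(dA)
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  if (length(wavelengths) > 1 && !(all(diff(wavelengths) > 0) ||
                                   all(diff(wavelengths) < 0))) {
    stop("wavelengths must be monotone")
  }
  if (!all(dim(dA) == c(length(delays), length(wavelengths)))) {
    stop("dA must be length(delays) x length(wavelengths)")
  }
  if (irf_sigma < 0) stop("irf_sigma must be >= 0")
  structure(list(delays = delays, wavelengths = wavelengths, dA = dA,
                 irf_sigma = irf_sigma, t0 = t0),
            class = "ta_surface")
}

#' @export
print.ta_surface <- function(x, ...) {
  cat("<ta_surface> ", length(x$delays), " delays (",
      signif(min(x$delays), 3), "-", signif(max(x$delays), 3), " ps) x ",
      length(x$wavelengths), " wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm), IRF sigma ",
      x$irf_sigma, " ps\n", sep = "")
  invisible(x)
}

#' Read / write a TA surface as delimited text
#'
#' Layout: first row holds the wavelengths (nm) with an empty leading cell,
#' first column the delays (ps), body the delta-OD values.
#'
#' @param path file path.
#' @param sep field separator.
#' @param irf_sigma,t0 metadata attached on read.
#' @return [ta_surface()] (read) or `path` invisibly (write).
#' @export
read_ta_surface <- function(path, sep = "\t", irf_sigma = 0, t0 = 0) {
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   check.names = FALSE))
  ta_surface(delays = as.numeric(m[-1, 1]),
             wavelengths = as.numeric(m[1, -1]),
             dA = unname(m[-1, -1, drop = FALSE]),
             irf_sigma = irf_sigma, t0 = t0)
}

#' @rdname read_ta_surface
#' @param surface a [ta_surface()].
#' @export
write_ta_surface <- function(surface, path, sep = "\t") {
  stopifnot(inherits(surface, "ta_surface"))
  m <- rbind(c(NA, surface$wavelengths), cbind(surface$delays, surface$dA))
  utils::write.table(m, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' Exponential decay convolved with a Gaussian IRF
#'
#' Closed form of \eqn{e^{-t/\tau}\,\Theta(t)} convolved with a normalised
#' Gaussian of width `sigma` centred at `t0`:
#' \deqn{\tfrac12 \exp\!\big(\sigma^2/2\tau^2 - (t-t_0)/\tau\big)\,
#'       \mathrm{erfc}\!\big(\sigma/\sqrt2\tau - (t-t_0)/\sqrt2\sigma\big).}
#' For `sigma = 0` this reduces to the step-gated exponential. Evaluated via
#' the scaled complementary error function where the naive product would
#' overflow.
#'
#' @param t times, ps (vectorised).
#' @param tau decay lifetime, ps (> 0).
#' @param t0 time zero, ps.
#' @param sigma Gaussian IRF width, ps (>= 0).
#' @return amplitudes in \eqn{[0, 1]}.
#' @export
irf_decay <- function(t, tau, t0 = 0, sigma = 0) {
  if (tau <= 0) stop("tau must be positive")
  if (sigma < 0) stop("sigma must be >= 0")
  dt <- t - t0
  if (sigma == 0) {
    return(ifelse(dt >= 0, exp(-dt / tau), 0))
  }
  z <- sigma / (sqrt(2) * tau) - dt / (sqrt(2) * sigma)
  out <- numeric(length(dt))
  pos <- z > 0
  if (any(pos)) {
    # exp(a) erfc(z) = erfcx(z) exp(a - z^2), and a - z^2 = -dt^2/(2 sigma^2)
    out[pos] <- 0.5 * .erfcx(z[pos]) * exp(-dt[pos]^2 / (2 * sigma^2))
  }
  if (any(!pos)) {
    a <- sigma^2 / (2 * tau^2) - dt[!pos] / tau
    out[!pos] <- 0.5 * exp(a) * pracma::erfc(z[!pos])
  }
  out
}

# Scaled complementary error function, safe for large arguments where the
# exp(x^2) factor in the direct evaluation overflows (x > ~26.6): switch to
# the asymptotic expansion 1/(x sqrt(pi)) (1 - 1/(2x^2) + 3/(4x^4)), whose
# truncation error there is below 1e-8 relative.
.erfcx <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 1 / (2 * xb^2) + 3 / (4 * xb^4)) / (xb * sqrt(pi))
  }
  out
}

.decay_basis <- function(delays, lifetimes, t0, sigma) {
  vapply(lifetimes, function(tau) irf_decay(delays, tau, t0, sigma),
         numeric(length(delays)))
}

#' Linear (inner) solve for decay-associated spectra
#'
#' Given fixed lifetimes, IRF width, and time zero, the amplitude of each
#' kinetic component at each wavelength — the decay-associated spectrum —
#' is the ordinary least-squares solution per wavelength against the
#' IRF-convolved exponential basis.
#'
#' @param surface a [ta_surface()].
#' @param lifetimes component lifetimes, ps (distinct, positive).
#' @param t0,sigma override the surface metadata.
#' @return list with `dads` (component x wavelength matrix, rows named by
#'   lifetime) and `rss` (total residual sum of squares).
#' @export
dads_linear_solve <- function(surface, lifetimes, t0 = surface$t0,
                              sigma = surface$irf_sigma) {
  stopifnot(inherits(surface, "ta_surface"))
  if (length(lifetimes) >= length(surface$delays)) {
    stop("need fewer components than delay points")
  }
  if (any(lifetimes <= 0)) stop("lifetimes must be positive")
  B <- .decay_basis(surface$delays, lifetimes, t0, sigma)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    stop("rank-deficient component basis (duplicate or indistinguishable ",
         "lifetimes): conditioning error")
  }
  coefs <- qr.coef(qrB, surface$dA)
  if (length(lifetimes) == 1) coefs <- matrix(coefs, nrow = 1)
  fitted <- B %*% coefs
  dads <- matrix(coefs, nrow = length(lifetimes),
                 dimnames = list(signif(lifetimes, 6), NULL))
  list(dads = dads, rss = sum((surface$dA - fitted)^2))
}

#' Global fit of a parallel kinetic model by variable projection
#'
#' Fits \eqn{\Delta A(t,\lambda) = \sum_i \mathrm{DADS}_i(\lambda)\,
#' D(t;\tau_i,t_0,\sigma)} where `D` is the IRF-convolved exponential of
#' [irf_decay()]: nonlinear least squares over the lifetimes (optimised in
#' log space), time zero, and IRF width, with the spectra eliminated at each
#' iterate by the exact inner linear solve of [dads_linear_solve()]. The
#' result is deterministic given the surface and starting values.
#'
#' @param surface a [ta_surface()].
#' @param n_components number of parallel components.
#' @param tau_init starting lifetimes, ps (length `n_components`).
#' @param tau_bounds lifetime box constraints, ps.
#' @param fit_t0,fit_sigma optimise time zero / IRF width (else fixed at the
#'   surface metadata).
#' @param max_iter iteration cap for the Levenberg-Marquardt outer loop.
#' @return object of class `dads_fit`: `lifetimes` (sorted ascending, ps),
#'   `dads` (component x wavelength, same order), `rss`, `t0`, `sigma`,
#'   `n_components`, `converged`, `flags` (per-component: `at_bound`,
#'   `near_zero`), `message`.
#' @export
fit_parallel_model <- function(surface, n_components,
                               tau_init = NULL,
                               tau_bounds = c(1e-3, 1e5),
                               fit_t0 = TRUE, fit_sigma = TRUE,
                               max_iter = 200) {
  stopifnot(inherits(surface, "ta_surface"))
  if (is.null(tau_init)) {
    tau_init <- exp(seq(log(min(diff(surface$delays))),
                        log(max(surface$delays)),
                        length.out = n_components))
  }
  if (length(tau_init) != n_components || any(tau_init <= 0)) {
    stop("tau_init must be ", n_components, " positive lifetimes")
  }
  sigma0 <- max(surface$irf_sigma, 1e-3)
  par <- log(sort(tau_init))
  lower <- rep(log(tau_bounds[1]), n_components)
  upper <- rep(log(tau_bounds[2]), n_components)
  if (fit_t0) {
    par <- c(par, surface$t0)
    lower <- c(lower, surface$t0 - 100)
    upper <- c(upper, surface$t0 + 100)
  }
  if (fit_sigma) {
    par <- c(par, log(sigma0))
    lower <- c(lower, log(1e-4))
    upper <- c(upper, log(1e3))
  }
  unpack <- function(p) {
    taus <- exp(p[seq_len(n_components)])
    i <- n_components
    t0 <- if (fit_t0) p[i <- i + 1] else surface$t0
    sigma <- if (fit_sigma) exp(p[i + 1]) else surface$irf_sigma
    list(taus = taus, t0 = t0, sigma = sigma)
  }
  resid_fn <- function(p) {
    u <- unpack(p)
    B <- .decay_basis(surface$delays, u$taus, u$t0, u$sigma)
    qrB <- qr(B)
    if (qrB$rank < ncol(B)) {
      return(rep(sqrt(mean(surface$dA^2)) * 1e3, length(surface$dA)))
    }
    coefs <- qr.coef(qrB, surface$dA)
    as.numeric(surface$dA - B %*% coefs)
  }
  fit <- minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )
  u <- unpack(fit$par)
  ord <- order(u$taus)
  taus <- u$taus[ord]
  inner <- dads_linear_solve(surface, taus, t0 = u$t0, sigma = u$sigma)
  norms <- sqrt(rowSums(inner$dads^2))
  logt <- log(taus)
  flags <- data.frame(
    lifetime_ps = taus,
    at_bound = logt < log(tau_bounds[1]) + 1e-6 |
      logt > log(tau_bounds[2]) - 1e-6,
    near_zero = norms < 1e-3 * max(norms)
  )
  converged <- fit$info %in% 1:3
  if (!converged) {
    warning("parallel-model fit did not converge in ", max_iter,
            " iterations: ", fit$message)
  }
  structure(
    list(lifetimes = taus, dads = inner$dads, rss = inner$rss,
         t0 = u$t0, sigma = u$sigma, n_components = n_components,
         converged = converged, flags = flags, message = fit$message),
    class = "dads_fit"
  )
}

#' @export
print.dads_fit <- function(x, ...) {
  cat("<dads_fit> ", x$n_components, " components, rss = ",
      signif(x$rss, 5), "\n", sep = "")
  cat("  lifetimes (ps): ", paste(signif(x$lifetimes, 4), collapse = ", "),
      "\n", sep = "")
  cat("  t0 = ", signif(x$t0, 4), " ps, IRF sigma = ", signif(x$sigma, 4),
      " ps", if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  flagged <- x$flags[x$flags$at_bound | x$flags$near_zero, , drop = FALSE]
  if (nrow(flagged) > 0) {
    cat("  flagged components:\n")
    print(flagged)
  }
  invisible(x)
}

#' Plot decay-associated spectra
#'
#' @param x a `dads_fit`.
#' @param wavelengths wavelength axis, nm (defaults to column index).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dads_fit <- function(x, wavelengths = NULL, ...) {
  wl <- if (is.null(wavelengths)) seq_len(ncol(x$dads)) else wavelengths
  graphics::matplot(wl, t(x$dads), type = "l", lty = 1,
                    xlab = "wavelength (nm)", ylab = "DADS amplitude",
                    ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", bty = "n", lty = 1,
                   col = seq_len(nrow(x$dads)),
                   legend = paste0(signif(x$lifetimes, 3), " ps"))
  invisible(x)
}

#' Trapping efficiency from the trapping and intrinsic lifetimes
#'
#' Photochemical quantum efficiency under the simple kinetic picture that
#' excitation decays either by trapping (the dominant antenna-to-trap
#' component) or by intrinsic excited-state decay:
#' \eqn{\phi = 1 - \tau_{trap}/\tau_{intrinsic}}.
#'
#' @param tau_trap trapping time, ps.
#' @param tau_intrinsic intrinsic excited-state lifetime, ps (user-set; not a
#'   fitted quantity).
#' @return fraction in (0, 1).
#' @export
trapping_efficiency <- function(tau_trap, tau_intrinsic) {
  if (tau_trap <= 0) stop("tau_trap must be positive")
  if (tau_trap >= tau_intrinsic) {
    stop("tau_trap must be smaller than tau_intrinsic")
  }
  1 - tau_trap / tau_intrinsic
}

#' Chirp (dispersion) correction of a TA surface
#'
#' Shifts the time axis of every wavelength by a polynomial
#' \eqn{t_0(\lambda) = \sum_j c_j \lambda^j} and re-interpolates the signal
#' onto the common delay grid (linear interpolation, edge values held).
#'
#' @param surface a [ta_surface()].
#' @param coefficients polynomial coefficients `c0, c1, ...` (ascending
#'   powers of wavelength in nm); at most order 5.
#' @return corrected [ta_surface()].
#' @export
dispersion_correct <- function(surface, coefficients) {
  stopifnot(inherits(surface, "ta_surface"))
  if (length(coefficients) > 6) {
    stop("chirp polynomial order > 5 rejected (overfitting guard)")
  }
  t0l <- vapply(surface$wavelengths, function(wl) {
    sum(coefficients * wl^(seq_along(coefficients) - 1))
  }, 0)
  dA <- surface$dA
  for (j in seq_along(surface$wavelengths)) {
    if (t0l[j] == 0) next
    dA[, j] <- stats::approx(x = surface$delays, y = surface$dA[, j],
                             xout = surface$delays + t0l[j],
                             rule = 2)$y
  }
  ta_surface(surface$delays, surface$wavelengths, dA,
             irf_sigma = surface$irf_sigma, t0 = surface$t0)
}
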