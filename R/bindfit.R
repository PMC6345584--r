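# Binding-affinity and lifetime analysis: quadratic mass-action Kd
# fitting of thermophoresis titrations, Poisson-MLE mono-exponential
# lifetime fitting, and FRET efficiency from donor lifetimes.

#' Titration series container
#'
#' @param ligand_conc strictly positive ligand concentrations in mol/L
#'   (at least 6 points); stored sorted ascending.
#' @param response thermophoresis signal at each concentration.
#' @param target_conc constant concentration of the labeled species in
#'   mol/L (default 50e-9).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(ligand_conc, response, target_conc = 50e-9) {
  if (length(ligand_conc) != length(response)) {
    stop("`ligand_conc` and `response` lengths differ", call. = FALSE)
  }
  if (length(ligand_conc) < 6L) {
    stop("at least 6 titration points are required", call. = FALSE)
  }
  if (any(ligand_conc <= 0)) {
    stop("ligand concentrations must be strictly positive", call. = FALSE)
  }
  if (target_conc <= 0) stop("`target_conc` must be > 0", call. = FALSE)
  o <- order(ligand_conc)
  if (any(diff(ligand_conc[o]) == 0)) {
    stop("ligand concentrations must be distinct", call. = FALSE)
  }
  structure(list(ligand_conc = ligand_conc[o], response = response[o],
                 target_conc = target_conc),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d points, L = %.3g..%.3g M, target %.3g M\n",
              length(x$ligand_conc), min(x$ligand_conc), max(x$ligand_conc),
              x$target_conc))
  invisible(x)
}

#' Bound fraction under single-site mass action with ligand depletion
#'
#' The physical root of the quadratic mass-action equilibrium for a
#' labeled target at fixed total concentration `target` titrated with
#' ligand at total concentration `ligand`:
#' `f = ((kd + L + T) - sqrt((kd + L + T)^2 - 4 L T)) / (2 T)`.
#' As `target -> 0` this reduces to the hyperbola `L / (L + kd)`.
#' Strictly increasing in `ligand`, strictly decreasing in `kd`.
#'
#' @param ligand total ligand concentration(s), mol/L (> 0); vectorized.
#' @param kd dissociation constant, mol/L (> 0).
#' @param target total labeled-target concentration, mol/L (> 0).
#' @return Bound fraction(s) in [0, 1].
#' @examples
#' fraction_bound(100e-9, kd = 100e-9, target = 0.1e-9)  # ~0.5
#' @export
fraction_bound <- function(ligand, kd, target) {
  if (any(ligand <= 0) || kd <= 0 || target <= 0) {
    stop("`ligand`, `kd` and `target` must all be > 0", call. = FALSE)
  }
  s <- kd + ligand + target
  disc <- s^2 - 4 * ligand * target
  f <- (s - sqrt(pmax(disc, 0))) / (2 * target)
  pmin(pmax(f, 0), 1)
}

# Residual sum of squares of the binding model at a fixed kd, with the
# two plateaus profiled out by linear least squares.
kd_profile_rss <- function(log10_kd, series) {
  f <- fraction_bound(series$ligand_conc, 10^log10_kd, series$target_conc)
  X <- cbind(1, f)
  fit <- stats::lm.fit(X, series$response)
  list(rss = sum(fit$residuals^2),
       unbound = unname(fit$coefficients[1]),
       bound = unname(fit$coefficients[1] + fit$coefficients[2]))
}

#' Fit a dissociation constant to a titration series
#'
#' Least-squares fit of
#' `response(L) = unbound + (bound - unbound) * fraction_bound(L, kd, T)`
#' over `(kd, unbound, bound)`.  Kd is searched in log10 space on
#' `[1e-10, 1e-3]` mol/L: the two plateaus are profiled out linearly at
#' each candidate kd, the profile is scanned on a fixed grid (including
#' three fixed multi-start anchors), and the best bracket is polished
#' with golden-section optimization.  The procedure is deterministic.
#' A kd landing on a search bound is flagged `unresolved_affinity`.
#'
#' @param series a [titration_series()] object; responses must not all be
#'   equal.
#' @param kd_bounds log-space search bounds in mol/L.
#' @return An object of class `kd_fit` with `print`, `coef`, `predict`
#'   `residuals` and `plot` methods: fields `kd`, `response_unbound`,
#'   `response_bound`, `fraction_bound` (per point), `residual_rms`,
#'   `unresolved_affinity`.
#' @examples
#' tr <- make_titration(binding_truth(kd = 250e-9),
#'                      ligand_concs = 1e-9 * 2^(0:15))
#' fit_kd(tr)$kd
#' @export
fit_kd <- function(series, kd_bounds = c(1e-10, 1e-3)) {
  stopifnot(inherits(series, "titration_series"))
  if (length(unique(series$response)) == 1L) {
    stop("responses are all equal; binding signal absent, fit rejected",
         call. = FALSE)
  }
  lb <- log10(kd_bounds[1]); ub <- log10(kd_bounds[2])
  # coarse deterministic scan (multi-start anchors included in the grid)
  grid <- sort(unique(c(seq(lb, ub, length.out = 71),
                        log10(c(1e-9, 1e-7, 1e-5)))))
  rss <- vapply(grid, function(g) kd_profile_rss(g, series)$rss, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(g) kd_profile_rss(g, series)$rss,
                         lower = lo, upper = hi, tol = 1e-10)
  best <- kd_profile_rss(opt$minimum, series)
  kd <- 10^opt$minimum
  at_bound <- opt$minimum <= lb + 1e-6 || opt$minimum >= ub - 1e-6
  f <- fraction_bound(series$ligand_conc, kd, series$target_conc)
  resid <- series$response - (best$unbound + (best$bound - best$unbound) * f)
  structure(list(kd = kd, response_unbound = best$unbound,
                 response_bound = best$bound, fraction_bound = f,
                 residual_rms = sqrt(mean(resid^2)),
                 unresolved_affinity = at_bound, series = series),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("Quadratic mass-action binding fit\n")
  cat(sprintf("  Kd               : %.4g M (%.4g nM)\n", x$kd, x$kd * 1e9))
  cat(sprintf("  plateaus         : unbound %.4g, bound %.4g\n",
              x$response_unbound, x$response_bound))
  cat(sprintf("  residual RMS     : %.3g (%d points)\n", x$residual_rms,
              length(x$series$ligand_conc)))
  if (x$unresolved_affinity) {
    cat("  flag: Kd at search bound (affinity unresolved by this titration)\n")
  }
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(kd = object$kd, response_unbound = object$response_unbound,
    response_bound = object$response_bound)
}

#' @export
predict.kd_fit <- function(object, ligand = object$series$ligand_conc, ...) {
  f <- fraction_bound(ligand, object$kd, object$series$target_conc)
  object$response_unbound +
    (object$response_bound - object$response_unbound) * f
}

#' @export
residuals.kd_fit <- function(object, ...) {
  object$series$response - predict(object)
}

#' @export
plot.kd_fit <- function(x, ...) {
  graphics::plot(x$series$ligand_conc, x$series$response, log = "x",
                 xlab = "ligand concentration (M)", ylab = "response",
                 main = sprintf("Kd = %.3g nM", x$kd * 1e9), ...)
  ll <- exp(seq(log(min(x$series$ligand_conc)),
                log(max(x$series$ligand_conc)), length.out = 200))
  graphics::lines(ll, predict(x, ll))
  invisible(x)
}

#' Photon-decay histogram container
#'
#' @param bin_centers uniformly spaced bin centers in nanoseconds.
#' @param counts non-negative photon counts per bin.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(bin_centers, counts) {
  if (length(bin_centers) != length(counts)) {
    stop("`bin_centers` and `counts` lengths differ", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  w <- diff(bin_centers)
  if (length(w) && max(abs(w - w[1])) > 1e-9 * w[1]) {
    stop("bins must be uniform", call. = FALSE)
  }
  structure(list(bin_centers = as.numeric(bin_centers),
                 counts = as.numeric(counts)),
            class = "decay_histogram")
}

#' Fit a mono-exponential fluorescence lifetime
#'
#' Poisson maximum-likelihood fit of `counts(t) proportional to
#' exp(-t / tau)` over the tail bins at or beyond `fit_start`, which must
#' lie past the instrument-response region.  For a multinomial/Poisson
#' histogram the likelihood depends on tau only through the bin
#' probabilities normalized over the fitted window, so an exact
#' exponential histogram returns its generating tau to numerical
#' precision.  A histogram whose tail carries no decay information (flat)
#' drives tau to the search bound and is flagged.
#'
#' @param decay a [decay_histogram()] object.
#' @param fit_start fit window start in nanoseconds (default 0.5).
#' @return An object of class `lifetime_fit`: fields `tau` (ns),
#'   `deviance` (per-bin Poisson deviance sum), `n_bins_fit`,
#'   `total_counts_fit`, `tau_at_bound`.
#' @examples
#' d <- make_decay(decay_truth(lifetime_tau = 2.5, total_counts = 1e5))
#' fit_lifetime(d)$tau
#' @export
fit_lifetime <- function(decay, fit_start = 0.5) {
  stopifnot(inherits(decay, "decay_histogram"))
  sel <- decay$bin_centers >= fit_start
  t <- decay$bin_centers[sel]
  cts <- decay$counts[sel]
  if (length(t) < 10L) {
    stop("fewer than 10 bins beyond `fit_start`", call. = FALSE)
  }
  if (sum(cts) < 1000) {
    stop("fewer than 1000 photons in the fit window", call. = FALSE)
  }
  if (sum(cts > 0) < 2L) {
    stop("degenerate histogram: all photons in a single bin", call. = FALSE)
  }
  window <- max(t) - min(t)
  nll <- function(log_tau) {
    tau <- exp(log_tau)
    logp <- -t / tau
    logp <- logp - (min(logp) + log(sum(exp(logp - min(logp)))))  # log-softmax
    -sum(cts * logp)
  }
  opt <- stats::optimize(nll, lower = log(window * 1e-4),
                         upper = log(window * 1e3), tol = 1e-12)
  tau <- exp(opt$minimum)
  at_bound <- opt$minimum >= log(window * 1e3) - 1e-6
  # per-bin Poisson deviance against fitted expectations
  p <- exp(-t / tau); p <- p / sum(p)
  mu <- sum(cts) * p
  dev_terms <- ifelse(cts > 0, cts * log(cts / mu), 0) - (cts - mu)
  structure(list(tau = tau, deviance = 2 * sum(dev_terms),
                 n_bins_fit = length(t), total_counts_fit = sum(cts),
                 tau_at_bound = at_bound, fit_start = fit_start),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat("Mono-exponential lifetime fit (Poisson MLE)\n")
  cat(sprintf("  tau       : %.4g ns\n", x$tau))
  cat(sprintf("  window    : %d bins from %.3g ns, %d photons\n",
              x$n_bins_fit, x$fit_start, x$total_counts_fit))
  cat(sprintf("  deviance  : %.3g\n", x$deviance))
  if (x$tau_at_bound) cat("  flag: tau at search bound (no decay in window)\n")
  invisible(x)
}

#' @export
coef.lifetime_fit <- function(object, ...) c(tau = object$tau)

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_DA / tau_D`, the lifetime-domain FRET efficiency from
#' the donor lifetime with (`tau_da`) and without (`tau_donor`) the
#' acceptor.  Invariant under a common rescaling of both lifetimes
#' (ns vs ps).  A negative efficiency (tau_DA exceeding tau_D) is
#' reported but flagged.
#'
#' @param tau_donor donor-only lifetime, ns (> 0).
#' @param tau_da donor lifetime in presence of acceptor, ns (> 0).
#' @return list with `tau_donor`, `tau_da`, `efficiency`, `negative`
#'   (flag).
#' @examples
#' fret_efficiency(2.5, 2.0)$efficiency  # 0.2
#' @export
fret_efficiency <- function(tau_donor, tau_da) {
  if (tau_donor <= 0 || tau_da <= 0) {
    stop("lifetimes must be positive", call. = FALSE)
  }
  e <- 1 - tau_da / tau_donor
  list(tau_donor = tau_donor, tau_da = tau_da, efficiency = e,
       negative = e < 0)
}
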