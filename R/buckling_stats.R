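# Weighted logistic regression of collision outcomes.
#
# Each head-on collision of a filament of length L (and pre-collision speed
# v0) either buckles (y = 1) or not (y = 0). The buckling probability is
# modelled as p = sig((L - Lc) / dLc) with sig the logistic function; Lc is
# the median critical length of the population and dLc the width of its
# distribution. Individuals observed N_i times are weighted 1/N_i so the fit
# represents the population, not the sampling. The velocity-coupled variant
# replaces Lc by Lc(v0) = (alpha v0)^(-1/3), the theoretical critical length
# under isotropic friction, with alpha = eta / (k B) and k ~ 30.5722 the
# buckling threshold; eta is then the only mechanical unknown.

#' Assign population weights to collision events
#'
#' Adds `N_i` (number of events sharing `individual_id`) and
#' `weight = 1 / N_i`, so each individual contributes unit total weight.
#'
#' @param events data frame with at least `individual_id`.
#' @return the events as a tibble with `N_i` and `weight` columns.
#' @export
assign_weights <- function(events) {
  if (!"individual_id" %in% names(events)) {
    abort("events must have an individual_id column")
  }
  events |>
    as_tibble() |>
    group_by(.data$individual_id) |>
    mutate(N_i = n(), weight = 1 / n()) |>
    ungroup()
}

# weighted Bernoulli log-likelihood for linear predictor x
loglik_logistic <- function(x, y, w) {
  # numerically stable log(sig(x)) and log(1 - sig(x))
  sum(w * (y * -log1p(exp(-x)) + (1 - y) * -log1p(exp(x))))
}

check_events <- function(events, need_speed = FALSE) {
  req <- c("individual_id", "length_um", "buckled")
  if (need_speed) req <- c(req, "speed_um_s")
  miss <- setdiff(req, names(events))
  if (length(miss)) {
    abort(paste("events missing columns:", paste(miss, collapse = ", ")))
  }
  if (!all(events$buckled %in% c(0, 1))) abort("buckled must be 0/1")
  if (any(events$length_um <= 0)) abort("length_um must be > 0")
  if (need_speed && any(events$speed_um_s <= 0)) {
    abort("speed_um_s must be > 0")
  }
  if (!"weight" %in% names(events)) events <- assign_weights(events)
  events
}

new_logistic_fit <- function(model, est, se, vcov, loglik, events, extra = list()) {
  structure(
    c(list(
      model = model, estimate = est, se = se, vcov = vcov,
      loglik = loglik, n_events = nrow(events),
      n_individuals = length(unique(events$individual_id)),
      events = events
    ), extra),
    class = "logistic_fit"
  )
}

#' Length-only logistic regression of buckling outcomes
#'
#' Maximizes the 1/N_i-weighted Bernoulli log-likelihood of
#' p = sig((L - Lc) / dLc) over (Lc, dLc) by quasi-Newton ascent with
#' analytic gradient, dLc parametrized on the log scale, multi-started from
#' three quantile-based seeds. Standard errors come from the observed
#' information matrix at the optimum. Near-perfect separation (fitted
#' dLc below `1e-3 * median(L)`) is flagged and an interval estimate for Lc
#' (the gap between outcome classes) is reported instead of a Wald error.
#'
#' @param events collision events: `individual_id`, `length_um`, `buckled`,
#'   optionally precomputed `weight`.
#' @return an object of class `logistic_fit` with elements `estimate`
#'   (named: `Lc_um`, `dLc_um`), `se`, `vcov`, `loglik`, `separation`.
#' @examples
#' ev <- gen_events(population_spec(truth = list(Lc_um = 161, dLc_um = 35)),
#'   n_events = 388, seed = 1
#' )
#' fit_logistic_length(ev)
#' @export
fit_logistic_length <- function(events) {
  events <- check_events(events)
  L <- events$length_um
  y <- events$buckled
  w <- events$weight
  if (length(unique(y)) < 2) abort("need both outcomes present to fit")

  nll <- function(th) {
    -loglik_logistic((L - th[1]) / exp(th[2]), y, w)
  }
  grad <- function(th) {
    d <- exp(th[2])
    x <- (L - th[1]) / d
    r <- w * (y - plogis(x)) # dll/dx
    -c(sum(r * (-1 / d)), sum(r * (-x)))
  }
  qs <- quantile(L, c(0.35, 0.5, 0.65))
  d0 <- max(diff(quantile(L, c(0.25, 0.75))) / 2, 1e-3 * median(L))
  fits <- lapply(qs, function(q) {
    optim(c(q, log(d0)), nll, grad, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12))
  })
  best <- fits[[which.min(map_dbl(fits, "value"))]]
  Lc <- best$par[1]
  dLc <- exp(best$par[2])

  # width collapse, or the data are perfectly separated in length
  separation <- dLc < 1e-3 * median(L) ||
    max(L[y == 0]) < min(L[y == 1])
  sep_interval <- NULL
  if (separation) {
    sep_interval <- c(
      suppressWarnings(max(L[y == 0 & L < Lc], -Inf)),
      suppressWarnings(min(L[y == 1 & L > Lc], Inf))
    )
    se <- c(Lc_um = NA_real_, dLc_um = NA_real_)
    vc <- matrix(NA_real_, 2, 2)
  } else {
    nll_nat <- function(p) -loglik_logistic((L - p[1]) / p[2], y, w)
    vc <- tryCatch(
      solve(optimHess(c(Lc, dLc), nll_nat)),
      error = function(e) matrix(NA_real_, 2, 2)
    )
    se <- sqrt(pmax(diag(vc), 0))
    names(se) <- c("Lc_um", "dLc_um")
    dimnames(vc) <- list(names(se), names(se))
  }
  new_logistic_fit(
    "length",
    c(Lc_um = Lc, dLc_um = dLc), se, vc, -best$value, events,
    extra = list(separation = separation, separation_interval = sep_interval)
  )
}

#' Velocity-coupled logistic regression
#'
#' Two-regressor fit with the theoretical link
#' `x = (L - (alpha v0)^(-1/3)) / dLc`: the critical length is tied to the
#' pre-collision speed through isotropic friction, and the friction
#' coefficient `eta = alpha * k * B` (k ~ 30.5722) becomes the mechanical
#' parameter of interest. Requires the species bending modulus `B`.
#'
#' @param events collision events including positive `speed_um_s`.
#' @param B bending modulus in N m^2 used to convert alpha to eta.
#' @return a `logistic_fit` (model `"velocity"`) whose `estimate` holds
#'   `alpha` (s um^-4), `dLc_um`, and `eta_nNs_um2`.
#' @export
fit_logistic_velocity <- function(events, B) {
  stopifnot(is.numeric(B), B > 0)
  events <- check_events(events, need_speed = TRUE)
  L <- events$length_um
  v0 <- events$speed_um_s
  y <- events$buckled
  w <- events$weight
  if (length(unique(y)) < 2) abort("need both outcomes present to fit")
  if (sd(v0) < 1e-12 * mean(v0)) {
    warn("all speeds equal: alpha and Lc are aliased; fit is a reparametrized length-only model")
  }

  nll <- function(th) {
    a <- exp(th[1])
    d <- exp(th[2])
    -loglik_logistic((L - (a * v0)^(-1 / 3)) / d, y, w)
  }
  # seed from the length-only fit at the mean speed
  lenfit <- fit_logistic_length(events)
  Lc0 <- unname(lenfit$estimate["Lc_um"])
  a0 <- Lc0^(-3) / mean(v0)
  d0 <- unname(lenfit$estimate["dLc_um"])
  starts <- list(
    c(log(a0), log(d0)),
    c(log(a0 * 2), log(d0)),
    c(log(a0 / 2), log(d0 * 1.5))
  )
  fits <- lapply(starts, function(s) {
    optim(s, nll, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  })
  best <- fits[[which.min(map_dbl(fits, "value"))]]
  alpha <- exp(best$par[1])
  dLc <- exp(best$par[2])
  separation <- dLc < 1e-3 * median(L)

  H <- optimHess(best$par, nll)
  vc_log <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  se_logalpha <- sqrt(pmax(vc_log[1, 1], 0))
  se_logd <- sqrt(pmax(vc_log[2, 2], 0))

  # printed-unit friction coefficient: eta = alpha * k * B
  B_printed <- B * 1e21 # N m^2 -> nN um^2
  eta <- alpha * gamma_c() * B_printed
  est <- c(alpha = alpha, dLc_um = dLc, eta_nNs_um2 = eta)
  se <- c(
    alpha = alpha * se_logalpha, dLc_um = dLc * se_logd,
    eta_nNs_um2 = eta * se_logalpha
  )
  new_logistic_fit(
    "velocity", est, se, vc_log, -best$value, events,
    extra = list(
      separation = separation, B = B,
      median_speed = median(v0)
    )
  )
}

#' Quantiles of the fitted critical-length distribution
#'
#' The length-only model implies a logistic distribution of critical lengths
#' with location Lc and scale dLc; quantile q is
#' `Lc + dLc * log(q / (1 - q))`.
#'
#' @param fit a length-only `logistic_fit`.
#' @param probs probabilities strictly inside (0, 1).
#' @return named numeric vector of lengths (um).
#' @examples
#' \dontrun{
#' logistic_quantiles(fit, c(0.05, 0.25, 0.5, 0.75, 0.95))
#' }
#' @export
logistic_quantiles <- function(fit, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$model != "length") abort("quantiles require a length-only fit")
  if (any(probs <= 0 | probs >= 1)) abort("probs must lie strictly in (0, 1)")
  q <- fit$estimate["Lc_um"] + fit$estimate["dLc_um"] * qlogis(probs)
  setNames(unname(q), paste0("q", probs))
}

#' Predicted buckling probability
#'
#' @param object a `logistic_fit`.
#' @param newdata data frame with `length_um` (and `speed_um_s` for the
#'   velocity model); defaults to the training events.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$events
  L <- newdata$length_um
  if (object$model == "length") {
    plogis((L - object$estimate["Lc_um"]) / object$estimate["dLc_um"])
  } else {
    v0 <- newdata$speed_um_s
    Lcv <- (object$estimate["alpha"] * v0)^(-1 / 3)
    plogis((L - Lcv) / object$estimate["dLc_um"])
  }
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Weighted logistic regression (", x$model, " model)\n", sep = "")
  cat("  events:", x$n_events, " individuals:", x$n_individuals, "\n")
  for (nm in names(x$estimate)) {
    cat(sprintf(
      "  %-12s %.4g (se %.3g)\n", nm, x$estimate[nm],
      if (nm %in% names(x$se)) x$se[nm] else NA
    ))
  }
  cat("  log-likelihood:", format(x$loglik, digits = 6), "\n")
  if (isTRUE(x$separation)) {
    cat("  WARNING: near-perfect separation; Lc interval (",
      x$separation_interval[1], ",", x$separation_interval[2], ") um\n")
  }
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$se[names(x$estimate)])
  )
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(
    model = x$model, logLik = x$loglik, n_events = x$n_events,
    n_individuals = x$n_individuals, separation = isTRUE(x$separation)
  )
}

#' Binned buckling frequencies with the fitted probability curve
#'
#' Weighted buckling frequency in fixed-width length bins, overlaid with the
#' fitted logistic probability (velocity model evaluated at the median
#' speed).
#'
#' @param object a `logistic_fit`.
#' @param bin_width bin width in um.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.logistic_fit <- function(object, bin_width = 25, ...) {
  ev <- object$events
  ev$bin <- floor(ev$length_um / bin_width) * bin_width + bin_width / 2
  bars <- ev |>
    group_by(.data$bin) |>
    summarise(
      freq = sum(.data$weight * .data$buckled) / sum(.data$weight),
      .groups = "drop"
    )
  Lgrid <- tibble(length_um = seq(min(ev$length_um), max(ev$length_um),
    length.out = 200
  ))
  if (object$model == "velocity") Lgrid$speed_um_s <- object$median_speed
  Lgrid$p <- predict(object, Lgrid)
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = bars,
      ggplot2::aes(.data$bin, .data$freq),
      width = bin_width * 0.9, fill = "grey70"
    ) +
    ggplot2::geom_line(
      data = Lgrid,
      ggplot2::aes(.data$length_um, .data$p),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "filament length L (um)", y = "buckling probability",
      title = "Buckling frequency and logistic regression"
    )
}
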