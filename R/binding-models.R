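# Quantitative binding models: 1:1 biolayer-interferometry kinetics with
# a global multi-concentration fit, the single-site ITC isotherm, and a
# two-ligand competitive-displacement equilibrium.

#' 1:1 binding model forward response
#'
#' Closed-form Langmuir 1:1 kinetics. During association at analyte
#' concentration `C`,
#' `R(t) = Rmax * C / (C + KD) * (1 - exp(-(kon * C + koff) * t))` with
#' `KD = koff / kon`; during dissociation the response decays as
#' `R(t) = r0 * exp(-koff * t)` from the phase-start response `r0`.
#'
#' @param kon,koff,rmax Positive kinetic parameters (1/M/s, 1/s, sensor
#'   units).
#' @param C Analyte concentration in molar (association phase).
#' @param t Time in seconds from the start of the phase (non-negative).
#' @param phase `"association"` or `"dissociation"`.
#' @param r0 Response at the start of the dissociation phase.
#' @return Numeric response vector.
#' @examples
#' bli_forward(1e5, 1e-2, 1, C = 1e-7, t = 1e5)  # C = KD: plateau Rmax/2
#' @export
bli_forward <- function(kon, koff, rmax, C, t,
                        phase = c("association", "dissociation"),
                        r0 = NULL) {
  phase <- match.arg(phase)
  stopifnot(kon > 0, koff > 0, rmax > 0)
  if (any(t < 0)) stop("negative time", call. = FALSE)
  if (phase == "association") {
    stopifnot(C >= 0)
    if (C == 0) return(rep(0, length(t)))
    KD <- koff / kon
    rmax * C / (C + KD) * (1 - exp(-(kon * C + koff) * t))
  } else {
    if (is.null(r0)) stop("dissociation needs r0", call. = FALSE)
    r0 * exp(-koff * t)
  }
}

# Model responses for a trace table given parameters; traces must carry
# time (global), concentration, phase. t_assoc_end per concentration is
# the last association time point.
bli_model_responses <- function(traces, kon, koff, rmax) {
  out <- numeric(nrow(traces))
  for (C in unique(traces$concentration)) {
    sel_a <- traces$concentration == C & traces$phase == "association"
    sel_d <- traces$concentration == C & traces$phase == "dissociation"
    t_end <- if (any(sel_a)) max(traces$time[sel_a]) else 0
    if (any(sel_a)) {
      out[sel_a] <- bli_forward(kon, koff, rmax, C, traces$time[sel_a],
                                "association")
    }
    if (any(sel_d)) {
      r_end <- bli_forward(kon, koff, rmax, C, t_end, "association")
      out[sel_d] <- r_end * exp(-koff * (traces$time[sel_d] - t_end))
    }
  }
  out
}

#' Globally fit the 1:1 binding model to BLI traces
#'
#' Least-squares fit of shared `kon`, `koff` and `Rmax` across all traces
#' (association and dissociation phases) by Levenberg-Marquardt on
#' log-scale parameters, with a multi-start grid over
#' `kon in {1e3, 1e5, 1e7}` and `koff in {1e-4, 3e-3, 1e-1}` to avoid
#' local minima. A zero-concentration trace, when present, is used as the
#' reference blank and subtracted point-wise (matched on phase and time)
#' from every other trace before fitting. `KD = koff / kon` is derived,
#' never a free parameter.
#'
#' @param traces Tibble with columns `time`, `response`, `concentration`,
#'   `phase`; at least 2 distinct non-zero concentrations with both
#'   phases.
#' @return An object of class `bli_fit` with elements `kon`, `koff`,
#'   `KD`, `rmax`, `rss`, `conf` (95% half-widths), `data` (blank-
#'   subtracted traces with fitted values), `convergence`.
#' @export
fit_bli <- function(traces) {
  traces <- tibble::as_tibble(traces)
  need <- c("time", "response", "concentration", "phase")
  stopifnot(all(need %in% names(traces)))
  concs <- sort(unique(traces$concentration))
  nz <- concs[concs > 0]
  if (length(nz) < 2) {
    if (length(nz) == 1) {
      warning("single analyte concentration: kon and koff are weakly ",
              "identifiable", call. = FALSE)
    } else {
      stop("need at least one non-zero concentration", call. = FALSE)
    }
  }
  if (!all(c("association", "dissociation") %in% unique(traces$phase))) {
    stop("both association and dissociation phases are required",
         call. = FALSE)
  }
  # blank subtraction
  if (any(traces$concentration == 0)) {
    blank <- traces |>
      dplyr::filter(.data$concentration == 0) |>
      dplyr::group_by(.data$phase, .data$time) |>
      dplyr::summarise(blank = mean(.data$response), .groups = "drop")
    traces <- traces |>
      dplyr::filter(.data$concentration > 0) |>
      dplyr::left_join(blank, by = c("phase", "time")) |>
      dplyr::mutate(
        response = .data$response -
          dplyr::coalesce(.data$blank, 0)) |>
      dplyr::select(-"blank")
  }
  resid_fn <- function(par) {
    p <- exp(par)
    traces$response - bli_model_responses(traces, p[1], p[2], p[3])
  }
  rmax0 <- max(traces$response)
  if (rmax0 <= 0) rmax0 <- 1
  starts <- expand.grid(kon = c(1e3, 1e5, 1e7),
                        koff = c(1e-4, 3e-3, 1e-1))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = log(c(starts$kon[s], starts$koff[s], rmax0)),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("BLI fit failed to converge from every start", call. = FALSE)
  }
  p <- exp(best$par)
  n <- nrow(traces)
  dof <- max(n - 3, 1)
  sigma2 <- best$deviance / dof
  vcov_log <- try(sigma2 * solve(best$hessian), silent = TRUE)
  conf <- if (inherits(vcov_log, "try-error")) {
    c(kon = NA_real_, koff = NA_real_, rmax = NA_real_)
  } else {
    se_log <- sqrt(pmax(diag(vcov_log), 0))
    stats::setNames(1.96 * p * se_log, c("kon", "koff", "rmax"))
  }
  traces$fitted <- bli_model_responses(traces, p[1], p[2], p[3])
  structure(list(
    kon = p[1], koff = p[2], KD = p[2] / p[1], rmax = p[3],
    rss = best$deviance, conf = conf, n = n, data = traces,
    convergence = best$info
  ), class = "bli_fit")
}

#' @export
print.bli_fit <- function(x, ...) {
  cat("Global 1:1 binding fit (biolayer interferometry)\n")
  cat(sprintf("  kon  = %.4g 1/M/s\n  koff = %.4g 1/s\n  KD   = %.4g M\n",
              x$kon, x$koff, x$KD))
  cat(sprintf("  Rmax = %.4g RU, RSS = %.4g over %d points\n",
              x$rmax, x$rss, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.bli_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kon", "koff", "KD", "rmax"),
    estimate = c(x$kon, x$koff, x$KD, x$rmax),
    conf_half_width = c(x$conf[["kon"]], x$conf[["koff"]], NA_real_,
                        x$conf[["rmax"]])
  )
}

#' @exportS3Method generics::glance
glance.bli_fit <- function(x, ...) {
  tibble::tibble(kon = x$kon, koff = x$koff, KD = x$KD, rmax = x$rmax,
                 rss = x$rss, nobs = x$n)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.bli_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time, y = .data$response,
                               colour = factor(.data$concentration))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "time (s)", y = "response (RU)",
                  colour = "analyte (M)",
                  title = sprintf("1:1 global fit: KD = %.3g M",
                                  object$KD)) +
    ggplot2::theme_minimal()
}

# ---- ITC ---------------------------------------------------------------

# Cumulative heat content of the cell after reaching ligand total Xt and
# receptor total Mt (single-site Wiseman isotherm).
itc_q <- function(Ka, dH, n, Mt, Xt, V0) {
  r <- Xt / (n * Mt)
  s <- 1 / (n * Ka * Mt)
  n * Mt * dH * V0 / 2 * (1 + r + s - sqrt((1 + r + s)^2 - 4 * r))
}

#' Single-site ITC isotherm forward model
#'
#' Computes per-injection heats for a 1:1 binding site using the Wiseman
#' isotherm with the standard displacement-style dilution correction:
#' after a cumulative injected volume `v`, receptor and ligand totals are
#' `Mt = M0 * (1 - v / (2 V0))` and `Xt = X0 * (v / V0) * (1 - v / (2 V0))`,
#' and the i-th injection heat is
#' `dQ_i = Q_i - Q_(i-1) + (dV_i / V0) * (Q_i + Q_(i-1)) / 2`.
#'
#' @param Ka Association constant (1/M).
#' @param dH Binding enthalpy (energy/mol; any consistent unit).
#' @param n Stoichiometry.
#' @param cell_conc Receptor concentration in the cell (M).
#' @param syringe_conc Ligand concentration in the syringe (M).
#' @param injection_volumes Vector of injection volumes (L).
#' @param cell_volume Cell volume (L), default 1.4e-3 (a VP-ITC cell).
#' @param noise_sd Gaussian noise added to each heat (same units as the
#'   heats), default 0.
#' @param seed Seed used when `noise_sd > 0`.
#' @return Numeric vector of injection heats.
#' @export
itc_heats <- function(Ka, dH, n, cell_conc, syringe_conc,
                      injection_volumes, cell_volume = 1.4e-3,
                      noise_sd = 0, seed = 1L) {
  stopifnot(Ka > 0, n > 0, cell_conc > 0, syringe_conc > 0,
            all(injection_volumes > 0))
  v <- cumsum(injection_volumes)
  dil <- 1 - v / (2 * cell_volume)
  Mt <- cell_conc * dil
  Xt <- syringe_conc * (v / cell_volume) * dil
  Q <- itc_q(Ka, dH, n, Mt, Xt, cell_volume)
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (injection_volumes / cell_volume) * (Q + Qprev) / 2
  if (noise_sd > 0) {
    scale <- max(abs(dQ))
    dQ <- withr::with_seed(seed,
      dQ + stats::rnorm(length(dQ), 0, noise_sd * scale))
  }
  dQ
}

#' Fit the single-site ITC isotherm
#'
#' Least-squares fit of `(Ka, dH, n)` to per-injection heats using the
#' dilution-corrected Wiseman isotherm (see [itc_heats()]), by
#' Levenberg-Marquardt on `(log Ka, dH, log n)` with a multi-start over
#' `Ka`. Emits a reliability warning when the Wiseman c-value
#' `n * Ka * cell_conc` falls outside `[1, 1000]`, and flags the fit
#' degenerate when the heats are all (near) zero.
#'
#' @param heats Numeric vector of >= 10 injection heats.
#' @param cell_conc,syringe_conc,injection_volumes,cell_volume As in
#'   [itc_heats()].
#' @return An object of class `itc_fit` with `Ka`, `Kd = 1/Ka`, `dH`,
#'   `n`, `rss`, `c_value`, `degenerate`, `data`.
#' @export
fit_itc <- function(heats, cell_conc, syringe_conc, injection_volumes,
                    cell_volume = 1.4e-3) {
  stopifnot(length(heats) >= 10,
            length(injection_volumes) == length(heats),
            cell_conc > 0, syringe_conc > 0)
  if (max(abs(heats)) < .Machine$double.eps^0.5) {
    warning("all injection heats are ~0; dH -> 0 fit is degenerate",
            call. = FALSE)
    return(structure(list(Ka = NA_real_, Kd = NA_real_, dH = 0,
                          n = NA_real_, rss = 0, c_value = NA_real_,
                          degenerate = TRUE,
                          data = tibble::tibble(injection =
                                                  seq_along(heats),
                                                heat = heats,
                                                fitted = 0)),
                     class = "itc_fit"))
  }
  resid_fn <- function(par) {
    Ka <- exp(par[1]); dH <- par[2]; n <- exp(par[3])
    heats - itc_heats(Ka, dH, n, cell_conc, syringe_conc,
                      injection_volumes, cell_volume)
  }
  dH0 <- heats[1] / (syringe_conc * injection_volumes[1])
  best <- NULL
  for (Ka0 in c(1e4, 1e5, 1e6, 1e7)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(log(Ka0), dH0, log(1)),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("ITC fit failed to converge", call. = FALSE)
  Ka <- exp(best$par[1]); dH <- best$par[2]; n <- exp(best$par[3])
  c_value <- n * Ka * cell_conc
  if (c_value < 1 || c_value > 1000) {
    warning(sprintf("Wiseman c-value %.3g outside [1, 1000]; ",
                    c_value),
            "affinity estimate may be unreliable", call. = FALSE)
  }
  fitted <- itc_heats(Ka, dH, n, cell_conc, syringe_conc,
                      injection_volumes, cell_volume)
  structure(list(
    Ka = Ka, Kd = 1 / Ka, dH = dH, n = n, rss = best$deviance,
    c_value = c_value, degenerate = FALSE,
    data = tibble::tibble(injection = seq_along(heats), heat = heats,
                          fitted = fitted)
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("Single-site ITC fit\n")
  if (x$degenerate) {
    cat("  degenerate: all heats ~0, dH -> 0\n")
  } else {
    cat(sprintf("  Ka = %.4g 1/M (Kd = %.4g M)\n  dH = %.4g\n  n = %.3g\n",
                x$Ka, x$Kd, x$dH, x$n))
    cat(sprintf("  c-value = %.3g, RSS = %.4g\n", x$c_value, x$rss))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.itc_fit <- function(x, ...) {
  tibble::tibble(term = c("Ka", "Kd", "dH", "n"),
                 estimate = c(x$Ka, x$Kd, x$dH, x$n))
}

#' @exportS3Method generics::glance
glance.itc_fit <- function(x, ...) {
  tibble::tibble(Ka = x$Ka, Kd = x$Kd, dH = x$dH, n = x$n, rss = x$rss,
                 c_value = x$c_value, degenerate = x$degenerate)
}

#' @exportS3Method ggplot2::autoplot
autoplot.itc_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$injection, y = .data$heat)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "injection", y = "heat",
                  title = if (object$degenerate) "degenerate fit" else
                    sprintf("Kd = %.3g M, n = %.2f", object$Kd,
                            object$n)) +
    ggplot2::theme_minimal()
}

# ---- competitive displacement -----------------------------------------

# Free-receptor mass balance for receptor P with two competing ligands.
free_receptor <- function(p_tot, a_tot, b_tot, kd_a, kd_b) {
  if (p_tot == 0) return(0)
  f <- function(p) {
    p * (1 + a_tot / (kd_a + p) + b_tot / (kd_b + p)) - p_tot
  }
  root <- stats::uniroot(f, c(0, p_tot), tol = p_tot * 1e-15,
                         maxiter = 2000)$root
  # one Newton polish for mass balance at ~1e-9 relative
  for (i in 1:3) {
    fp <- 1 + a_tot * kd_a / (kd_a + root)^2 +
      b_tot * kd_b / (kd_b + root)^2
    root <- root - f(root) / fp
    root <- min(max(root, 0), p_tot)
  }
  root
}

#' Competitive displacement of a reporter ligand
#'
#' Solves the two-ligand, one-site equilibrium for each competitor
#' concentration on a grid: mass balances for receptor, reporter and
#' competitor with dissociation constants `kd_reporter` and
#' `kd_competitor`, solved by robust root-finding on the free-receptor
#' concentration. This models a pull-down or reporter-binding assay being
#' blocked by increasing concentrations of a competing docking peptide.
#'
#' @param kd_reporter,kd_competitor Dissociation constants (M, > 0).
#' @param receptor_total,reporter_total Total concentrations (M).
#' @param competitor_totals Vector of total competitor concentrations (M).
#' @return An object of class `competition_curve`: a tibble with
#'   `competitor`, `free_receptor`, `bound_reporter`, `bound_competitor`,
#'   `fraction_bound` (reporter bound / reporter total).
#' @examples
#' competition_curve(1e-6, 7.2e-6, 1e-6, 1e-6,
#'                   c(0, 1e-6, 1e-5, 1e-4, 2.5e-4))
#' @export
competition_curve <- function(kd_reporter, kd_competitor,
                              receptor_total, reporter_total,
                              competitor_totals) {
  stopifnot(kd_reporter > 0, kd_competitor > 0, receptor_total >= 0,
            reporter_total >= 0, all(competitor_totals >= 0))
  rows <- purrr::map_dfr(competitor_totals, function(b_tot) {
    p <- free_receptor(receptor_total, reporter_total, b_tot,
                       kd_reporter, kd_competitor)
    bound_a <- reporter_total * p / (kd_reporter + p)
    bound_b <- b_tot * p / (kd_competitor + p)
    tibble::tibble(
      competitor = b_tot,
      free_receptor = p,
      bound_reporter = bound_a,
      bound_competitor = bound_b,
      fraction_bound = if (reporter_total > 0) bound_a / reporter_total
                       else NA_real_
    )
  })
  structure(rows, class = c("competition_curve", class(rows)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.competition_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$competitor,
                               y = .data$fraction_bound)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      trans = scales_pseudo_log(),
      name = "competitor (M)") +
    ggplot2::labs(y = "fraction of reporter bound") +
    ggplot2::theme_minimal()
}

# pseudo-log transform without a hard scales dependency at build time
scales_pseudo_log <- function() {
  if (requireNamespace("scales", quietly = TRUE)) {
    scales::pseudo_log_trans(sigma = 1e-8)
  } else {
    "identity"
  }
}
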