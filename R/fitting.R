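#' Stage 1: subthreshold parameters by least squares on dV/dt
#'
#' Ordinary least squares of the observed forward-difference voltage
#' derivative on the subthreshold regressors of the GIF / aGIF equation
#' (voltage, a constant, the injected current, the exponential
#' adaptation basis convolved with the detected spike train, and for the
#' aGIF the two precomputed potassium-current regressors
#' \eqn{m_\infty(V) h (V - E_K)} and \eqn{n_\infty(V)(V - E_K)}),
#' excluding a window around each spike.  The gating curves and
#' inactivation time constant are fixed from voltage clamp, so the
#' maximal conductances enter the regression linearly.
#'
#' @param rec A [recording()].
#' @param kind `"gif"` or `"agif"`.
#' @param k_currents Fixed potassium-current gating for the aGIF
#'   (a [potassium_current_model()]; its `g_A_bar`/`g_K_bar` are ignored
#'   and estimated).
#' @param eta_timescales Adaptation basis time constants, ms.
#' @param window Per-spike exclusion window `(pre, post)`, ms; defaults
#'   to the recording's cell type ([exclusion_window()]).
#' @param spike_threshold Spike-detection threshold, mV.
#' @return An object of class `subthreshold_fit`: estimated `C`, `g_l`,
#'   `E_l`, `eta` weights (and `g_A`, `g_K` for the aGIF), the estimated
#'   post-spike reset voltage, the training R-squared on dV/dt and
#'   bookkeeping needed by [fit_threshold()].
#' @export
fit_subthreshold <- function(rec, kind = c("gif", "agif"),
                             k_currents = potassium_current_model(),
                             eta_timescales = default_filter_timescales(),
                             window = NULL, spike_threshold = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "recording"))
  dt <- rec_dt(rec)
  cell_type <- attr(rec, "cell_type") %||% "5-HT"
  window <- window %||% exclusion_window(cell_type)
  T_ref <- window[2]
  sweeps <- rec_sweeps(rec)

  Xs <- list(); ys <- list(); keeps <- list(); spike_list <- list()
  for (s in seq_along(sweeps)) {
    V <- sweeps[[s]]$V; I <- sweeps[[s]]$I
    n <- length(V)
    spikes <- detect_spikes(V, dt, spike_threshold, min_interval = T_ref)
    spike_list[[s]] <- spikes
    y <- diff(V) / dt
    B <- spike_basis_cpp(spikes, eta_timescales, dt, n)
    k <- seq_len(n - 1)
    X <- cbind(V = V[k], const = 1, I = I[k], -B[k, , drop = FALSE])
    colnames(X) <- c("V", "const", "I", paste0("eta", seq_along(eta_timescales)))
    if (kind == "agif") {
      h <- h_from_v_cpp(V, dt, k_currents$tau_h,
                        k_currents$h_gate$A, k_currents$h_gate$k,
                        k_currents$h_gate$V_star)
      drive <- V - k_currents$E_K
      xA <- -equilibrium_gate(V, k_currents$m_gate) * h * drive
      xK <- -equilibrium_gate(V, k_currents$n_gate) * drive
      X <- cbind(X, IA_reg = xA[k], IK_reg = xK[k])
    }
    keeps[[s]] <- !spike_window_mask(n - 1, spikes, window, dt)
    Xs[[s]] <- X; ys[[s]] <- y
  }
  X <- do.call(rbind, Xs)[unlist(keeps), , drop = FALSE]
  y <- unlist(ys)[unlist(keeps)]

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1, ncol(X))]]
    abort(paste0("rank-deficient subthreshold design; collinear regressors: ",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  Cap <- 1 / beta[["I"]]
  g_l <- -beta[["V"]] * Cap
  E_l <- beta[["const"]] * Cap / g_l
  w <- beta[grep("^eta", names(beta))] * Cap
  est <- list(C = Cap, g_l = g_l, E_l = E_l,
              eta = filter_coeffs(w, eta_timescales))
  if (kind == "agif") {
    est$g_A <- beta[["IA_reg"]] * Cap
    est$g_K <- beta[["IK_reg"]] * Cap
  }

  # reset voltage: mean recorded voltage T_ref after each spike onset
  v_reset <- mean(unlist(lapply(seq_along(sweeps), function(s) {
    V <- sweeps[[s]]$V
    idx <- round((spike_list[[s]] + T_ref) / dt) + 1
    V[idx[idx <= length(V)]]
  })))

  structure(list(kind = kind, estimates = est, V_reset = v_reset,
                 T_ref = T_ref, r_squared = r2, coefficients = beta,
                 spikes = spike_list, window = window, dt = dt,
                 k_currents = if (kind == "agif") k_currents else NULL,
                 cell_type = cell_type,
                 n_retained = length(y), residual_mean = mean(y - fitted)),
            class = "subthreshold_fit")
}

#' @export
print.subthreshold_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<subthreshold_fit:%s> C = %.3g pF, g_l = %.3g nS, E_l = %.3g mV, R^2 = %.3f\n",
              x$kind, e$C, e$g_l, e$E_l, x$r_squared))
  if (x$kind == "agif")
    cat(sprintf("  g_A = %.3g nS, g_K = %.3g nS\n", e$g_A, e$g_K))
  invisible(x)
}

# Assemble a gif_params-family object from a subthreshold fit and
# threshold-stage values (possibly placeholders).
assemble_params <- function(sub, V_T_star = 0, DeltaV = 1,
                            gamma = NULL, theta = NULL) {
  e <- sub$estimates
  gamma <- gamma %||% filter_coeffs(rep(0, length(e$eta$weights)),
                                    e$eta$timescales)
  if (sub$kind == "agif") {
    kc <- sub$k_currents
    kc$g_A_bar <- max(e$g_A, 0)
    kc$g_K_bar <- max(e$g_K, 0)
    p <- agif_params(e$C, e$g_l, e$E_l, e$eta, gamma, V_T_star, DeltaV,
                     sub$V_reset, sub$T_ref, k_currents = kc)
  } else {
    p <- gif_params(e$C, e$g_l, e$E_l, e$eta, gamma, V_T_star, DeltaV,
                    sub$V_reset, sub$T_ref)
  }
  if (!is.null(theta)) {
    p <- igif_params(e$C, e$g_l, e$E_l, e$eta, gamma, V_T_star, DeltaV,
                     sub$V_reset, sub$T_ref,
                     theta_steps = theta$steps, bin_edges = theta$edges,
                     tau_theta = theta$tau_theta)
  }
  p
}

# Newton ascent with backtracking line search for the per-bin Poisson
# log-likelihood  ll(b) = sum y (u + log lam0 dt') - sum lam0 e^u dt',
# u = X b.  Concave in b, so accepted steps never decrease ll.
maximize_spike_likelihood <- function(X, y, dt, lambda_0 = 1,
                                      max_iter = 200, tol = 1e-9) {
  dts <- dt * 1e-3 # per-bin exposure in seconds (intensity in Hz)
  b <- numeric(ncol(X))
  b[2] <- log(sum(y) / (lambda_0 * dts * nrow(X))) # match total count
  loglik <- function(b) {
    u <- drop(X %*% b)
    sum(y * u) - lambda_0 * dts * sum(exp(pmin(u, 700)))
  }
  ll <- loglik(b)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u <- drop(X %*% b)
    mu <- lambda_0 * dts * exp(pmin(u, 700))
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X * mu, X)
    step <- tryCatch(solve(H + diag(1e-10, ncol(X)), grad),
                     error = function(e) grad / max(sum(mu), 1))
    alpha <- 1
    repeat {
      ll_new <- loglik(b + alpha * step)
      if (is.finite(ll_new) && ll_new >= ll) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (!is.finite(ll_new))
      abort(sprintf("non-finite likelihood at iteration %d", it))
    if (alpha < 1e-12) break
    b <- b + alpha * step
    converged <- (ll_new - ll) < tol * (abs(ll) + 1)
    ll <- ll_new
    trace <- c(trace, ll)
    if (converged) break
  }
  list(coef = b, loglik = ll, trace = trace, converged = converged)
}

#' Stage 2: threshold parameters by maximum likelihood
#'
#' Reconstructs the subthreshold voltage with spikes clamped to the data
#' and maximizes the likelihood of the observed spike train under the
#' escape-rate rule over the natural parameters
#' (`1/DeltaV`, `V_T_star/DeltaV`, `gamma_j/DeltaV`, and for the iGIF
#' `theta_j/DeltaV`), by Newton ascent with a backtracking line search
#' (the log-likelihood is concave in these parameters, so accepted
#' iterations never decrease it).  For the iGIF the voltage-bin edges
#' are placed at the quintiles of the subthreshold voltage distribution
#' and `tau_theta` is chosen by grid search over {1, 3, 5, 10, 30, 100}
#' ms maximizing held-out likelihood (final 25% of each sweep).
#'
#' @param sub A [fit_subthreshold()] result.
#' @param rec The same [recording()].
#' @param kind `"gif"`, `"agif"` or `"igif"` (the subthreshold stage of
#'   the iGIF is the plain GIF's).
#' @param gamma_timescales Threshold-movement basis time constants, ms.
#' @param tau_theta_grid Candidate `tau_theta` values, ms (iGIF only).
#' @param n_theta_bins Number of voltage bins for `theta_inf` (iGIF).
#' @return An object of class `threshold_fit` with the fitted
#'   `V_T_star`, `DeltaV`, `gamma` (and `theta` components for iGIF),
#'   the assembled full parameter set (`params`), the log-likelihood
#'   trace and convergence flag.
#' @export
fit_threshold <- function(sub, rec, kind = c("gif", "agif", "igif"),
                          gamma_timescales = default_filter_timescales(),
                          tau_theta_grid = c(1, 3, 5, 10, 30, 100),
                          n_theta_bins = 5) {
  kind <- match.arg(kind)
  stopifnot(inherits(sub, "subthreshold_fit"), inherits(rec, "recording"))
  dt <- sub$dt
  sweeps <- rec_sweeps(rec)
  base <- assemble_params(sub)

  Vhat <- list(); ys <- list(); keeps <- list(); Gs <- list()
  nref <- round(sub$T_ref / dt)
  for (s in seq_along(sweeps)) {
    I <- sweeps[[s]]$I
    n <- length(I)
    spikes <- sub$spikes[[s]]
    sim <- simulate_neuron(base, I, dt = dt, mode = "clamped",
                           spike_times = spikes, record = TRUE)
    Vhat[[s]] <- sim$trace$V
    y <- numeric(n)
    y[round(spikes / dt) + 1] <- 1
    # refractory bins after each spike carry no spiking hazard
    mask <- logical(n)
    for (ts in spikes) {
      a <- round(ts / dt) + 2
      b <- min(n, round(ts / dt) + 1 + nref)
      if (a <= b) mask[a:b] <- TRUE
    }
    ys[[s]] <- y; keeps[[s]] <- !mask
    Gs[[s]] <- spike_basis_cpp(spikes, gamma_timescales, dt, n)
  }

  build_X <- function(theta_edges = NULL, tau_theta = NULL) {
    lapply(seq_along(Vhat), function(s) {
      X <- cbind(V = Vhat[[s]], const = 1, -Gs[[s]])
      colnames(X) <- c("V", "const",
                       paste0("gamma", seq_along(gamma_timescales)))
      if (!is.null(theta_edges)) {
        TH <- theta_basis_cpp(Vhat[[s]], theta_edges, tau_theta, dt)
        colnames(TH) <- paste0("theta", seq_len(ncol(TH)))
        X <- cbind(X, TH)
      }
      X
    })
  }

  theta <- NULL
  if (kind == "igif") {
    vall <- unlist(lapply(seq_along(Vhat), function(s) Vhat[[s]][keeps[[s]]]))
    qs <- quantile(vall, probs = seq(0, 1, length.out = n_theta_bins + 1))
    edges <- as.numeric(qs)
    edges[1] <- edges[1] - 1; edges[length(edges)] <- edges[length(edges)] + 1
    edges <- unique(edges)
    # grid search tau_theta on a within-sweep holdout (final 25%)
    best <- NULL
    for (tt in tau_theta_grid) {
      Xl <- build_X(edges, tt)
      tr_idx <- lapply(Xl, function(X) seq_len(floor(0.75 * nrow(X))))
      Xtr <- do.call(rbind, lapply(seq_along(Xl), function(s) {
        k <- keeps[[s]]; i <- tr_idx[[s]]
        Xl[[s]][intersect(which(k), i), , drop = FALSE]
      }))
      ytr <- unlist(lapply(seq_along(Xl), function(s) {
        k <- keeps[[s]]; i <- tr_idx[[s]]
        ys[[s]][intersect(which(k), i)]
      }))
      fit <- maximize_spike_likelihood(Xtr, ytr, dt)
      Xho <- do.call(rbind, lapply(seq_along(Xl), function(s) {
        k <- keeps[[s]]; i <- setdiff(seq_len(nrow(Xl[[s]])), tr_idx[[s]])
        Xl[[s]][intersect(which(k), i), , drop = FALSE]
      }))
      yho <- unlist(lapply(seq_along(Xl), function(s) {
        k <- keeps[[s]]; i <- setdiff(seq_along(ys[[s]]), tr_idx[[s]])
        ys[[s]][intersect(which(k), i)]
      }))
      u <- drop(Xho %*% fit$coef)
      ll_ho <- sum(yho * u) - dt * 1e-3 * sum(exp(pmin(u, 700)))
      if (is.null(best) || ll_ho > best$ll_ho)
        best <- list(tau_theta = tt, ll_ho = ll_ho)
    }
    theta <- list(edges = edges, tau_theta = best$tau_theta)
  }

  Xl <- build_X(theta$edges, theta$tau_theta)
  X <- do.call(rbind, lapply(seq_along(Xl), function(s)
    Xl[[s]][keeps[[s]], , drop = FALSE]))
  y <- unlist(lapply(seq_along(ys), function(s) ys[[s]][keeps[[s]]]))
  fit <- maximize_spike_likelihood(X, y, dt)

  b <- unname(fit$coef)
  a <- b[1]
  if (a <= 0) warning("fitted 1/DeltaV is not positive; threshold ill-determined")
  DeltaV <- 1 / a
  V_T_star <- -b[2] / a
  gamma_w <- b[grep("^gamma", colnames(X))] / a
  gamma <- filter_coeffs(gamma_w, gamma_timescales)
  theta_out <- NULL
  if (kind == "igif") {
    theta_out <- list(steps = b[grep("^theta", colnames(X))] / a,
                      edges = theta$edges, tau_theta = theta$tau_theta)
  }
  params <- assemble_params(sub, V_T_star, DeltaV, gamma, theta_out)

  structure(list(kind = kind, V_T_star = V_T_star, DeltaV = DeltaV,
                 gamma = gamma, theta = theta_out, params = params,
                 loglik = fit$loglik, loglik_trace = fit$trace,
                 converged = fit$converged, n_spikes = sum(y)),
            class = "threshold_fit")
}

#' Fit a GIF-family model to a recording (both stages)
#'
#' Convenience wrapper running [fit_subthreshold()] then
#' [fit_threshold()] and assembling the full parameter set.
#'
#' @inheritParams fit_subthreshold
#' @param kind `"gif"`, `"agif"` or `"igif"`.
#' @param ... Passed on to [fit_threshold()].
#' @return An object of class `gif_fit` with elements `params`,
#'   `subthreshold`, `threshold`, `r_squared`, `kind`, `cell_type`.
#' @export
fit_gif <- function(rec, kind = c("gif", "agif", "igif"),
                    k_currents = potassium_current_model(),
                    eta_timescales = default_filter_timescales(), ...) {
  kind <- match.arg(kind)
  sub_kind <- if (kind == "agif") "agif" else "gif"
  sub <- fit_subthreshold(rec, sub_kind, k_currents, eta_timescales)
  thr <- fit_threshold(sub, rec, kind, ...)
  structure(list(params = thr$params, subthreshold = sub, threshold = thr,
                 r_squared = sub$r_squared, kind = kind,
                 cell_type = attr(rec, "cell_type") %||% "5-HT"),
            class = "gif_fit")
}

#' @export
print.gif_fit <- function(x, ...) {
  cat(sprintf("<gif_fit:%s> (%s)  training R^2 on dV/dt = %.3f, logLik = %.1f\n",
              x$kind, x$cell_type, x$r_squared, x$threshold$loglik))
  print(x$params)
  invisible(x)
}

#' @export
tidy.gif_fit <- function(x, ...) {
  p <- x$params
  base <- tibble(
    term = c("C", "g_l", "E_l", "V_T_star", "DeltaV", "V_reset", "T_ref"),
    estimate = c(p$C, p$g_l, p$E_l, p$V_T_star, p$DeltaV, p$V_reset, p$T_ref),
    unit = c("pF", "nS", "mV", "mV", "mV", "mV", "ms"))
  filt <- tibble(
    term = c(paste0("eta_w", seq_along(p$eta$weights)),
             paste0("gamma_w", seq_along(p$gamma$weights))),
    estimate = c(p$eta$weights, p$gamma$weights),
    unit = c(rep("pA", length(p$eta$weights)),
             rep("mV", length(p$gamma$weights))))
  out <- dplyr::bind_rows(base, filt)
  if (inherits(p, "agif_params")) {
    out <- dplyr::bind_rows(out, tibble(
      term = c("g_A", "g_K"), unit = "nS",
      estimate = c(p$k_currents$g_A_bar, p$k_currents$g_K_bar)))
  }
  out
}

#' @export
glance.gif_fit <- function(x, ...) {
  tibble(kind = x$kind, cell_type = x$cell_type,
         r_squared = x$r_squared, loglik = x$threshold$loglik,
         n_spikes = x$threshold$n_spikes,
         converged = x$threshold$converged)
}
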