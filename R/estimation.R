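# Maximum-likelihood fitting of the latent probit-threshold model to pilot
# trial data. Each patient contributes the exact mixed density: the marginal
# multivariate-normal density of the continuous components times the
# conditional normal rectangle probability of the observed discrete cells.

#' Fit the latent variable model to pilot trial data
#'
#' Maximizes the joint likelihood of a two-arm trial with mixed
#' continuous/ordinal/binary outcomes under the latent multivariate-normal
#' model, returning \eqn{\hat\theta} with a covariance matrix from the
#' numerically differentiated observed information. This supplies the
#' inputs for composite-endpoint design ([composite_effect()],
#' [delta_method_var()]).
#'
#' Identifiability follows the threshold-model conventions: discrete latent
#' variances are 1; ordinal outcomes have control mean 0 and free
#' thresholds; binary outcomes have the threshold fixed at 0 and free
#' per-arm means; one correlation matrix is shared by the arms. Rows with
#' missing values are dropped (with a message); every ordinal/binary level
#' must be observed at least once per arm, otherwise the corresponding
#' threshold or mean is unidentifiable.
#'
#' @param data Data frame with a 0/1 column `arm` (1 = treatment) and one
#'   column per outcome named as in `spec`. Continuous outcomes are reals,
#'   ordinal are integer levels `0..w`, binary are 0/1.
#' @param spec A [mixed_endpoint()] giving the outcome structure (kinds,
#'   levels); effects in the spec are ignored.
#' @param start Optional named starting values on the natural scale
#'   (defaults are moment-based).
#' @param hessian Compute the observed information and its inverse
#'   (default `TRUE`).
#' @param control Passed to [stats::optim()] (BFGS on an unconstrained
#'   reparameterization: log sd, log threshold gaps, atanh correlations).
#' @return A [latent_fit()] with `theta`, `cov_theta`, `loglik`, `n_T`,
#'   `n_C`, `converged`.
#' @examples
#' spec <- mixed_endpoint(dplyr::bind_rows(
#'   outcome_continuous("y1", effect = 0.5, sd = 1),
#'   outcome_binary("y2", prob_T = 0.6, prob_C = 0.4)
#' ), rho = 0.4)
#' dat <- simulate_trial(spec, n_per_group = 150, seed = 7)
#' fit <- fit_latent_model(dat, spec)
#' tidy(fit)
#' @export
fit_latent_model <- function(data, spec, start = NULL, hessian = TRUE,
                             control = list()) {
  validate_mixed_endpoint(spec)
  oc <- spec$outcomes
  need <- c("arm", oc$name)
  if (!all(need %in% names(data))) {
    lp_abort(paste0("data must contain columns: ",
                    paste(setdiff(need, names(data)), collapse = ", ")),
             class = "lp_error_spec")
  }
  data <- as.data.frame(data)[, need]
  complete <- stats::complete.cases(data)
  if (any(!complete)) {
    rlang::inform(paste0("dropping ", sum(!complete),
                         " rows with missing values"))
    data <- data[complete, , drop = FALSE]
  }
  if (!all(data$arm %in% c(0, 1))) {
    lp_abort("arm must be coded 0 (control) / 1 (treatment)",
             class = "lp_error_spec")
  }
  n_T <- sum(data$arm == 1)
  n_C <- sum(data$arm == 0)
  if (min(n_T, n_C) < 10) {
    lp_abort("each arm needs at least 10 complete observations",
             class = "lp_error_spec")
  }
  for (i in seq_len(spec$K)) {
    if (oc$kind[i] == "continuous") next
    lev <- 0:(oc$n_levels[i] - 1L)
    for (a in c(0, 1)) {
      seen <- unique(data[data$arm == a, oc$name[i]])
      if (!all(seen %in% lev)) {
        lp_abort(paste0("outcome '", oc$name[i], "' has values outside 0..",
                        max(lev)), class = "lp_error_spec")
      }
      missing_lev <- setdiff(lev, seen)
      if (length(missing_lev)) {
        lp_abort(paste0("level ", missing_lev[1], " of outcome '", oc$name[i],
                        "' is never observed in arm ", a,
                        "; the model is unidentifiable"),
                 class = "lp_error_identify")
      }
    }
  }

  template <- theta_template(oc)
  start <- start %||% moment_start(data, oc)
  start <- start[template]
  nll <- make_negloglik(data, oc)
  par0 <- theta_to_unconstrained(start, oc)
  obj <- function(u) nll(unconstrained_to_theta(u, oc, template))
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  opt <- optim(par0, obj, method = "BFGS", control = ctl)
  if (opt$convergence != 0) {
    lp_abort(paste0("latent model fit did not converge (optim code ",
                    opt$convergence, "): ",
                    opt$message %||% "see counts in condition data"),
             class = "lp_error_numeric", optim = opt)
  }
  theta_hat <- unconstrained_to_theta(opt$par, oc, template)
  cov_theta <- NULL
  if (hessian) {
    H <- pracma::hessian(function(th) {
      nll(setNames(th, template))
    }, unlist(theta_hat[template]))
    cov_theta <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (is.null(cov_theta) || any(!is.finite(cov_theta)) ||
        any(diag(cov_theta) <= 0)) {
      rlang::warn("observed information is singular or indefinite; using its PSD pseudo-inverse")
      cov_theta <- psd_project(pracma::pinv((H + t(H)) / 2), tol = 0)
    }
    cov_theta <- (cov_theta + t(cov_theta)) / 2
  }
  latent_fit(theta_hat, oc, cov_theta = cov_theta, n_T = n_T, n_C = n_C,
             loglik = -opt$value, converged = opt$convergence == 0)
}

# moment-based starting values on the natural scale
moment_start <- function(data, oc) {
  clampp <- function(p, n) pmin(pmax(p, 1 / (n + 1)), n / (n + 1))
  th <- list()
  for (i in seq_len(nrow(oc))) {
    y <- oc$name[i]
    yT <- data[data$arm == 1, y]
    yC <- data[data$arm == 0, y]
    if (oc$kind[i] == "continuous") {
      th[[paste0("mu_T.", y)]] <- mean(yT)
      th[[paste0("mu_C.", y)]] <- mean(yC)
      th[[paste0("sigma.", y)]] <- sqrt(
        ((length(yT) - 1) * stats::var(yT) +
           (length(yC) - 1) * stats::var(yC)) /
          (length(yT) + length(yC) - 2))
    } else if (oc$kind[i] == "binary") {
      th[[paste0("mu_T.", y)]] <- qnorm(clampp(mean(yT == 1), length(yT)))
      th[[paste0("mu_C.", y)]] <- qnorm(clampp(mean(yC == 1), length(yC)))
    } else {
      w <- oc$n_levels[i] - 1L
      cumC <- clampp(cumsum(tabulate(yC + 1L, w + 1L))[1:w] / length(yC),
                     length(yC))
      taus <- sort(qnorm(cumC))
      taus <- taus + seq(0, 1e-3, length.out = w)  # break ties
      cumT <- clampp(cumsum(tabulate(yT + 1L, w + 1L))[1:w] / length(yT),
                     length(yT))
      th[[paste0("mu_T.", y)]] <- mean(taus - qnorm(cumT))
      for (j in seq_len(w)) th[[paste0("tau", j, ".", y)]] <- taus[j]
    }
  }
  K <- nrow(oc)
  if (K > 1) {
    num <- data[, oc$name, drop = FALSE]
    r0 <- suppressWarnings(cor(num))
    r0[!is.finite(r0)] <- 0
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        th[[paste0("rho.", oc$name[i], ".", oc$name[j])]] <-
          min(max(r0[i, j], -0.7), 0.7)
      }
    }
  }
  unlist(th)
}

theta_to_unconstrained <- function(theta, oc) {
  u <- as.list(theta)
  for (i in seq_len(nrow(oc))) {
    y <- oc$name[i]
    if (oc$kind[i] == "continuous") {
      u[[paste0("sigma.", y)]] <- log(theta[[paste0("sigma.", y)]])
    } else if (oc$kind[i] == "ordinal") {
      w <- oc$n_levels[i] - 1L
      taus <- vapply(seq_len(w),
                     function(j) theta[[paste0("tau", j, ".", y)]],
                     numeric(1))
      u[[paste0("tau1.", y)]] <- taus[1]
      if (w > 1) {
        for (j in 2:w) u[[paste0("tau", j, ".", y)]] <- log(diff(taus))[j - 1]
      }
    }
  }
  rho_names <- grep("^rho\\.", names(theta), value = TRUE)
  for (nm in rho_names) u[[nm]] <- atanh(theta[[nm]])
  unlist(u)
}

unconstrained_to_theta <- function(u, oc, template) {
  th <- as.list(u)
  names(th) <- names(u)
  for (i in seq_len(nrow(oc))) {
    y <- oc$name[i]
    if (oc$kind[i] == "continuous") {
      th[[paste0("sigma.", y)]] <- exp(u[[paste0("sigma.", y)]])
    } else if (oc$kind[i] == "ordinal") {
      w <- oc$n_levels[i] - 1L
      taus <- numeric(w)
      taus[1] <- u[[paste0("tau1.", y)]]
      if (w > 1) {
        for (j in 2:w) taus[j] <- taus[j - 1] + exp(u[[paste0("tau", j, ".", y)]])
      }
      for (j in seq_len(w)) th[[paste0("tau", j, ".", y)]] <- taus[j]
    }
  }
  for (nm in grep("^rho\\.", names(th), value = TRUE)) th[[nm]] <- tanh(u[[nm]])
  setNames(unlist(th)[template], template)
}

# negative log-likelihood closure on the natural parameter scale
make_negloglik <- function(data, oc) {
  K <- nrow(oc)
  idx_c <- which(oc$kind == "continuous")
  idx_d <- which(oc$kind != "continuous")
  arms <- lapply(c(C = 0, T = 1), function(a) {
    rows <- data$arm == a
    list(
      Xc = as.matrix(data[rows, oc$name[idx_c], drop = FALSE]),
      Ld = as.matrix(data[rows, oc$name[idx_d], drop = FALSE]),
      n = sum(rows)
    )
  })
  big <- 1e10
  function(theta) {
    pars <- tryCatch(arm_params_from_theta(theta, oc),
                     error = function(e) NULL)
    if (is.null(pars)) return(big)
    R <- pars$corr
    if (K > 1 && min_eigenvalue(R) <= 1e-8) {
      return(big + 1e6 * (1e-8 - min_eigenvalue(R)))
    }
    D <- diag(pars$sd, K)
    Sigma <- D %*% R %*% D
    nll <- 0
    for (arm in c("C", "T")) {
      a <- arms[[arm]]
      mu <- if (arm == "T") pars$mu_T else pars$mu_C
      if (length(idx_c)) {
        Scc <- Sigma[idx_c, idx_c, drop = FALSE]
        ll_c <- sum(mvtnorm::dmvnorm(a$Xc, mean = mu[idx_c], sigma = Scc,
                                     log = TRUE))
        if (!is.finite(ll_c)) return(big)
        nll <- nll - ll_c
      }
      if (length(idx_d)) {
        if (length(idx_c)) {
          Scc_inv <- solve(Sigma[idx_c, idx_c, drop = FALSE])
          A <- Sigma[idx_d, idx_c, drop = FALSE] %*% Scc_inv
          cond_cov <- Sigma[idx_d, idx_d, drop = FALSE] -
            A %*% Sigma[idx_c, idx_d, drop = FALSE]
          cond_mean <- matrix(mu[idx_d], nrow = a$n, ncol = length(idx_d),
                              byrow = TRUE) +
            sweep(a$Xc, 2, mu[idx_c]) %*% t(A)
        } else {
          cond_cov <- Sigma[idx_d, idx_d, drop = FALSE]
          cond_mean <- matrix(mu[idx_d], nrow = a$n, ncol = length(idx_d),
                              byrow = TRUE)
        }
        lo <- hi <- matrix(0, a$n, length(idx_d))
        for (jj in seq_along(idx_d)) {
          k <- idx_d[jj]
          cuts <- c(-Inf, pars$thresholds[[k]], Inf)
          lev <- a$Ld[, jj]
          lo[, jj] <- cuts[lev + 1L]
          hi[, jj] <- cuts[lev + 2L]
        }
        if (length(idx_d) == 1L) {
          s <- sqrt(cond_cov[1, 1])
          p <- pnorm((hi[, 1] - cond_mean[, 1]) / s) -
            pnorm((lo[, 1] - cond_mean[, 1]) / s)
          nll <- nll - sum(log(pmax(p, 1e-300)))
        } else if (length(idx_d) == 2L && length(idx_c)) {
          p <- bvn_rect_rows(lo, hi, cond_mean, cond_cov)
          nll <- nll - sum(log(pmax(p, 1e-300)))
        } else {
          sds <- sqrt(diag(cond_cov))
          Rd <- cond_cov / tcrossprod(sds)
          if (min_eigenvalue(Rd) <= 1e-10) return(big)
          ll_d <- 0
          if (!length(idx_c)) {
            # no continuous part: aggregate identical discrete cells
            patt <- apply(a$Ld, 1, paste, collapse = ",")
            cnt <- table(patt)
            for (r in which(!duplicated(patt))) {
              p <- mvn_rectangle((lo[r, ] - cond_mean[r, ]) / sds,
                                 (hi[r, ] - cond_mean[r, ]) / sds,
                                 Rd, algorithm = "miwa")
              ll_d <- ll_d + cnt[[patt[r]]] * log(max(as.numeric(p), 1e-300))
            }
          } else {
            for (r in seq_len(a$n)) {
              p <- mvn_rectangle((lo[r, ] - cond_mean[r, ]) / sds,
                                 (hi[r, ] - cond_mean[r, ]) / sds,
                                 Rd, algorithm = "miwa")
              ll_d <- ll_d + log(max(as.numeric(p), 1e-300))
            }
          }
          nll <- nll - ll_d
        }
      }
    }
    if (!is.finite(nll)) big else nll
  }
}

#' Latent-scale z statistics for the outcome-level tests
#'
#' Computes the per-outcome test statistics \eqn{Z_k = \hat\delta_k /
#' \mathrm{SE}_k} from a fitted latent model or from simulated trial data
#' that carries latent values. In `"nominal"` mode the standard error is
#' the design value \eqn{\sigma_k\sqrt{1/n_T + 1/n_C}} (continuous, known
#' sd) or \eqn{\sqrt{1/n_T + 1/n_C}} (discrete, unit latent variance). In
#' `"model"` mode the standard errors come from the fit's parameter
#' covariance.
#'
#' @param x A [latent_fit()] or a tibble from [simulate_trial()] (with
#'   `.latent_*` columns).
#' @param variance_mode `"nominal"` or `"model"`.
#' @param spec Required when `x` is trial data: the generating
#'   [mixed_endpoint()] (for outcome kinds and continuous sds).
#' @return Tibble with columns `name`, `delta_hat`, `se`, `z`.
#' @export
latent_test_statistics <- function(x, variance_mode = c("nominal", "model"),
                                   spec = NULL) {
  variance_mode <- match.arg(variance_mode)
  if (inherits(x, "latent_fit")) {
    pars <- fit_arm_params(x)
    oc <- x$outcomes
    delta <- pars$mu_T - pars$mu_C
    if (variance_mode == "nominal") {
      se <- pars$sd * sqrt(1 / x$n_T + 1 / x$n_C)
    } else {
      if (is.null(x$cov_theta)) {
        lp_abort("model-based variance needs cov_theta on the fit",
                 class = "lp_error_spec")
      }
      se <- vapply(seq_len(nrow(oc)), function(i) {
        nmT <- paste0("mu_T.", oc$name[i])
        if (oc$kind[i] == "ordinal") {
          sqrt(x$cov_theta[nmT, nmT])
        } else {
          nmC <- paste0("mu_C.", oc$name[i])
          sqrt(x$cov_theta[nmT, nmT] + x$cov_theta[nmC, nmC] -
                 2 * x$cov_theta[nmT, nmC])
        }
      }, numeric(1))
    }
    return(tibble::tibble(name = oc$name, delta_hat = delta, se = se,
                          z = delta / se))
  }
  if (is.null(spec)) {
    lp_abort("supply the generating mixed_endpoint spec for trial data",
             class = "lp_error_spec")
  }
  if (variance_mode == "model") {
    lp_abort("model-based variance requires a latent_fit; fit the model first",
             class = "lp_error_spec")
  }
  oc <- spec$outcomes
  lat_cols <- paste0(".latent_", oc$name)
  if (!all(lat_cols %in% names(x))) {
    lp_abort("trial data must carry .latent_* columns (see simulate_trial)",
             class = "lp_error_spec")
  }
  n_T <- sum(x$arm == 1)
  n_C <- sum(x$arm == 0)
  delta <- vapply(lat_cols, function(cl) {
    mean(x[[cl]][x$arm == 1]) - mean(x[[cl]][x$arm == 0])
  }, numeric(1))
  se <- latent_scales(spec) * sqrt(1 / n_T + 1 / n_C)
  tibble::tibble(name = oc$name, delta_hat = unname(delta), se = se,
                 z = unname(delta) / se)
}
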