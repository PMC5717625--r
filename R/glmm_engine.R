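#' Control parameters for the GLMM fitter
#'
#' @param tol relative penalized log-likelihood tolerance for the inner
#'   penalized-IRLS iterations.
#' @param max_iter maximum inner iterations.
#' @param sigma_interval search interval for the random-intercept standard
#'   deviation.
#' @param singular_tol estimated SDs below this are treated as singular and
#'   refitted at exactly 0 (with a warning).
#' @param agq number of adaptive Gauss-Hermite quadrature points used to
#'   evaluate the marginal likelihood; 1 is the Laplace approximation.
#' @return List of control parameters.
#' @export
glmm_control <- function(tol = 1e-8, max_iter = 500L,
                         sigma_interval = c(1e-4, 10), singular_tol = 1e-3,
                         agq = 1L) {
  stopifnot(tol > 0, max_iter >= 1, sigma_interval[1] > 0,
            sigma_interval[2] > sigma_interval[1], agq >= 1)
  list(tol = tol, max_iter = as.integer(max_iter),
       sigma_interval = sigma_interval, singular_tol = singular_tol,
       agq = as.integer(agq))
}

# effort-standardized rate covariates, written exactly as the node formulas
# use them: pitfall captures per 100 trap-nights, photographs per
# camera-night
.rate_rules <- list(
  rodent_rate   = list(count = "rodents", effort = "trap_nights",   per = 100),
  mulgara_rate  = list(count = "mulgara", effort = "trap_nights",   per = 100),
  dasyurid_rate = list(count = "dasyurids", effort = "trap_nights", per = 100),
  reptile_rate  = list(count = "reptiles", effort = "trap_nights",  per = 100),
  cat_rate      = list(count = "cat",   effort = "camera_nights",   per = 1),
  fox_rate      = list(count = "fox",   effort = "camera_nights",   per = 1),
  dingo_rate    = list(count = "dingo", effort = "camera_nights",   per = 1)
)

#' Effort-standardized rate
#'
#' @param count capture or photograph count.
#' @param effort trap-nights or camera-nights (must be positive).
#' @param per reporting unit (100 for captures per 100 trap-nights, 1 for
#'   photographs per camera-night).
#' @return `count / effort * per`.
#' @export
effort_rate <- function(count, effort, per = 100) {
  if (any(!is.finite(effort)) || any(effort <= 0)) {
    stop("effort must be positive wherever a standardized rate is computed",
         call. = FALSE)
  }
  count / effort * per
}

#' Standardize the predictors of a node
#'
#' Computes any effort-standardized rate predictor the node needs that is
#' not already present (captures per 100 trap-nights; photographs per
#' camera-night), and, when the node is flagged `z_transform`, centres and
#' scales its numeric predictors to unit standard deviation (storing the
#' centres/scales as attributes `z_center` / `z_scale`).
#'
#' @param spec a [node_spec()].
#' @param data analysis table for the node.
#' @return `data` with the required predictor columns.
#' @export
standardize_predictors <- function(spec, data) {
  vars <- unique(unlist(strsplit(spec$predictors, ":", fixed = TRUE)))
  for (v in intersect(vars, names(.rate_rules))) {
    if (v %in% names(data)) next
    rule <- .rate_rules[[v]]
    if (!all(c(rule$count, rule$effort) %in% names(data))) {
      stop("cannot derive '", v, "': need columns '", rule$count, "' and '",
           rule$effort, "'", call. = FALSE)
    }
    data[[v]] <- effort_rate(data[[rule$count]], data[[rule$effort]],
                             rule$per)
  }
  if (spec$z_transform) {
    num_vars <- setdiff(vars, spec$factors)
    centers <- scales <- stats::setNames(numeric(length(num_vars)), num_vars)
    for (v in num_vars) {
      s <- stats::sd(data[[v]], na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        stop("cannot z-transform constant column '", v, "'", call. = FALSE)
      }
      m <- mean(data[[v]], na.rm = TRUE)
      data[[v]] <- (data[[v]] - m) / s
      centers[v] <- m
      scales[v] <- s
    }
    attr(data, "z_center") <- centers
    attr(data, "z_scale") <- scales
  }
  data
}

# family helpers on the linear-predictor scale (canonical links).
# binomial responses are grid-averaged scores: proportion p with prior
# weight m (the denominator), non-integer "successes" accepted via the
# continuous lgamma normalizer.
.fam_mu <- function(family, eta) {
  eta <- pmin(pmax(eta, -30), 30)
  if (family == "poisson") exp(eta) else stats::plogis(eta)
}

.fam_loglik <- function(family, y, eta, m) {
  mu <- .fam_mu(family, eta)
  if (family == "poisson") {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    k <- y * m
    sum(k * log(mu) + (m - k) * log1p(-mu) +
          lgamma(m + 1) - lgamma(k + 1) - lgamma(m - k + 1))
  }
}

.fam_weights <- function(family, eta, m) {
  mu <- .fam_mu(family, eta)
  if (family == "poisson") mu else m * mu * (1 - mu)
}

.fam_workz <- function(family, y, eta, off, m) {
  mu <- .fam_mu(family, eta)
  if (family == "poisson") {
    eta - off + (y - mu) / mu
  } else {
    eta - off + (y - mu) / (mu * (1 - mu))
  }
}

# penalized IRLS over (beta, u) jointly at fixed sigma; monotone in the
# penalized log-likelihood via step-halving. A = [X | Z] dense; the random
# design Z is a group indicator so all linear algebra stays small.
.pirls <- function(family, y, X, group_idx, off, m, sigma, control,
                   theta_start = NULL) {
  n <- length(y)
  p <- ncol(X)
  G <- max(group_idx)
  Z <- matrix(0, n, G)
  Z[cbind(seq_len(n), group_idx)] <- 1
  A <- cbind(X, Z)
  pen <- c(rep(0, p), rep(if (sigma > 0) 1 / sigma^2 else Inf, G))
  use_u <- sigma > 0
  if (!use_u) {
    A <- X
    pen <- rep(0, p)
  }
  q <- ncol(A)
  theta <- if (!is.null(theta_start) && length(theta_start) == q) {
    theta_start
  } else {
    rep(0, q)
  }
  eta <- drop(A %*% theta) + off
  pll_of <- function(theta, eta) {
    upart <- if (use_u) theta[(p + 1):q] else 0
    .fam_loglik(family, y, eta, m) -
      if (use_u) sum(upart^2) / (2 * sigma^2) else 0
  }
  pll <- pll_of(theta, eta)
  trace <- pll
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    w <- .fam_weights(family, eta, m)
    w <- pmax(w, 1e-10)
    zw <- .fam_workz(family, y, eta, off, m)
    Aw <- A * sqrt(w)
    M <- crossprod(Aw)
    diag(M) <- diag(M) + ifelse(is.finite(pen), pen, 0)
    rhs <- crossprod(A, w * zw)
    theta_new <- tryCatch(drop(solve(M, rhs)), error = function(e) {
      drop(qr.coef(qr(M), rhs))
    })
    theta_new[is.na(theta_new)] <- 0
    # step-halve until the penalized log-likelihood does not decrease
    step <- 1
    repeat {
      cand <- theta + step * (theta_new - theta)
      eta_c <- drop(A %*% cand) + off
      pll_c <- pll_of(cand, eta_c)
      if (is.finite(pll_c) && pll_c >= pll - 1e-12) break
      step <- step / 2
      if (step < 1e-8) {
        cand <- theta
        eta_c <- eta
        pll_c <- pll
        break
      }
    }
    done <- abs(pll_c - pll) < control$tol * (abs(pll) + 1)
    theta <- cand
    eta <- eta_c
    pll <- pll_c
    trace <- c(trace, pll)
    if (done) {
      converged <- TRUE
      break
    }
  }
  w <- pmax(.fam_weights(family, eta, m), 1e-10)
  beta <- theta[seq_len(p)]
  u <- if (use_u) theta[(p + 1):q] else rep(0, G)
  list(beta = beta, u = u, eta = eta, w = w, pll = pll, trace = trace,
       converged = converged, A = A, pen = pen, p = p, use_u = use_u)
}

# Gauss-Hermite nodes/weights for exp(-x^2) by Golub-Welsch
.gh_rule <- function(k) {
  if (k == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# marginal log-likelihood with the random intercept integrated out:
# Laplace (agq = 1) or adaptive Gauss-Hermite centred at the conditional
# modes; fit is a .pirls() result at this sigma
.marginal_loglik <- function(family, y, group_idx, off, m, X, fit, sigma,
                             agq = 1L) {
  eta_fixed <- drop(X %*% fit$beta) + off
  if (sigma <= 0) return(.fam_loglik(family, y, eta_fixed, m))
  G <- length(fit$u)
  sg <- as.vector(rowsum(fit$w, group_idx))   # group sums of IRLS weights
  prec <- sg + 1 / sigma^2
  if (agq == 1L) {
    return(.fam_loglik(family, y, fit$eta, m) -
             sum(fit$u^2) / (2 * sigma^2) -
             G * log(sigma) - 0.5 * sum(log(prec)))
  }
  rule <- .gh_rule(agq)
  sd_g <- 1 / sqrt(prec)
  ll <- 0
  for (g in seq_len(G)) {
    idx <- which(group_idx == g)
    ug <- fit$u[g] + sqrt(2) * sd_g[g] * rule$x
    hg <- vapply(seq_along(ug), function(j) {
      .fam_loglik(family, y[idx], eta_fixed[idx] + ug[j], m[idx]) +
        stats::dnorm(ug[j], 0, sigma, log = TRUE)
    }, 0)
    # log of sqrt(2)*sd_g*sum( w_k * exp(x_k^2) * exp(h) )
    lw <- log(rule$w) + rule$x^2 + hg
    mx <- max(lw)
    ll <- ll + log(sqrt(2) * sd_g[g]) + mx + log(sum(exp(lw - mx)))
  }
  ll
}

#' Fit one node's generalized linear mixed model
#'
#' Fits the node's Poisson (log link) or binomial (logit link) model with
#' an optional `log(effort)` offset and a single random intercept on the
#' sampling occasion. Estimation: penalized IRLS over the fixed effects and
#' the per-occasion random intercepts jointly at fixed sigma (monotone in
#' the penalized log-likelihood via step-halving), with the random-
#' intercept standard deviation estimated by maximizing the Laplace
#' marginal log-likelihood in an outer one-dimensional search. At sigma = 0
#' the scheme reduces exactly to iteratively reweighted least squares for
#' the plain generalized linear model. The null model (intercept + offset +
#' random intercept only) is fitted on the identical rows so percentage
#' deviance explained is well defined.
#'
#' Rows with missing values in any used column are dropped listwise (a
#' message reports how many). Wald statistics use the normal tail:
#' `p = 2 * pnorm(-|z|)`.
#'
#' @param spec a [node_spec()].
#' @param data the node's analysis table (rate predictors are derived via
#'   [standardize_predictors()] if absent).
#' @param constrain_sd_zero if `TRUE` the random-intercept SD is fixed at 0
#'   and the fit is a plain GLM via IRLS.
#' @param control a [glmm_control()].
#' @return An object of class `fitted_node`: coefficient table
#'   (`term`, `estimate`, `se`, `z`, `p`), `random_sd`, `loglik`,
#'   `deviance`, `null_deviance`, `n_obs`, `converged`, `singular`, plus
#'   the model frame and design information needed for path
#'   standardization and projection.
#' @export
fit_node <- function(spec, data, constrain_sd_zero = FALSE,
                     control = glmm_control()) {
  stopifnot(inherits(spec, "node_spec"))
  data <- standardize_predictors(spec, as.data.frame(data))
  z_center <- attr(data, "z_center")
  z_scale <- attr(data, "z_scale")
  vars <- unique(unlist(strsplit(spec$predictors, ":", fixed = TRUE)))
  used <- c(spec$response, vars, spec$offset, spec$random)
  missing_col <- setdiff(used, names(data))
  if (length(missing_col)) {
    stop("node '", spec$name, "': missing column(s) ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[used])
  if (any(!keep)) {
    message("node '", spec$name, "': dropping ", sum(!keep),
            " row(s) with missing covariates")
    data <- data[keep, , drop = FALSE]
  }
  for (f in spec$factors) data[[f]] <- factor(data[[f]])
  grp <- factor(data[[spec$random]])
  if (nlevels(grp) < 2L) {
    stop("node '", spec$name, "': random factor needs at least 2 levels",
         call. = FALSE)
  }
  form <- if (length(spec$predictors)) {
    stats::reformulate(spec$predictors)
  } else {
    ~1
  }
  X <- stats::model.matrix(form, data)
  yraw <- data[[spec$response]]
  if (spec$family == "poisson") {
    y <- yraw
    m <- rep(1, length(y))
  } else {
    m <- rep(spec$denominator, length(yraw))
    y <- yraw / m   # proportion in [0, 1]
    if (any(y < 0 | y > 1)) {
      stop("node '", spec$name, "': response outside [0, denominator]",
           call. = FALSE)
    }
  }
  off <- if (!is.null(spec$offset)) {
    eff <- data[[spec$offset]]
    if (any(eff <= 0)) {
      stop("node '", spec$name, "': non-positive effort in offset column",
           call. = FALSE)
    }
    log(eff)
  } else {
    rep(0, length(y))
  }
  gi <- as.integer(grp)

  fit_at <- function(sigma, start = NULL) {
    .pirls(spec$family, y, X, gi, off, m, sigma, control, start)
  }
  obj <- function(log_sigma, start = NULL) {
    s <- exp(log_sigma)
    f <- fit_at(s, start)
    .marginal_loglik(spec$family, y, gi, off, m, X, f, s, control$agq)
  }

  singular <- FALSE
  if (constrain_sd_zero) {
    sigma <- 0
  } else {
    opt <- stats::optimize(obj, interval = log(control$sigma_interval),
                           maximum = TRUE, tol = 1e-7)
    sigma <- exp(opt$maximum)
    if (sigma < control$singular_tol) {
      warning("node '", spec$name,
              "': random-intercept SD estimated at the boundary; ",
              "refitting with SD = 0", call. = FALSE)
      sigma <- 0
      singular <- TRUE
    }
  }
  fit <- fit_at(sigma)
  ll <- .marginal_loglik(spec$family, y, gi, off, m, X, fit, sigma,
                         control$agq)

  # null model (intercept + offset + random intercept) on identical rows
  X0 <- stats::model.matrix(~1, data)
  fit0_at <- function(s) .pirls(spec$family, y, X0, gi, off, m, s, control)
  if (constrain_sd_zero || sigma == 0) {
    sigma0 <- 0
  } else {
    opt0 <- stats::optimize(function(ls) {
      s <- exp(ls)
      f0 <- fit0_at(s)
      .marginal_loglik(spec$family, y, gi, off, m, X0, f0, s, control$agq)
    }, interval = log(control$sigma_interval), maximum = TRUE, tol = 1e-7)
    sigma0 <- exp(opt0$maximum)
    if (sigma0 < control$singular_tol) sigma0 <- 0
  }
  fit0 <- fit0_at(sigma0)
  ll0 <- .marginal_loglik(spec$family, y, gi, off, m, X0, fit0, sigma0,
                          control$agq)

  # covariance of beta from the penalized information at the optimum
  Aw <- fit$A * sqrt(fit$w)
  M <- crossprod(Aw)
  diag(M) <- diag(M) + ifelse(is.finite(fit$pen), fit$pen, 0)
  Vfull <- tryCatch(solve(M), error = function(e) {
    MASS_ginv <- function(mm) {
      s <- svd(mm)
      pos <- s$d > max(s$d) * 1e-12
      s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    }
    MASS_ginv(M)
  })
  p <- ncol(X)
  se <- unname(sqrt(pmax(diag(Vfull)[seq_len(p)], 0)))
  beta <- stats::setNames(fit$beta, colnames(X))
  zstat <- beta / se
  pval <- 2 * stats::pnorm(-abs(zstat))

  structure(list(
    name = spec$name,
    spec = spec,
    coefficients = tibble::tibble(term = colnames(X),
                                  estimate = unname(beta),
                                  se = se, z = unname(zstat),
                                  p = unname(pval)),
    beta = beta,
    vcov_beta = Vfull[seq_len(p), seq_len(p), drop = FALSE],
    random_sd = sigma,
    loglik = ll,
    deviance = -2 * ll,
    null_deviance = -2 * ll0,
    n_obs = length(y),
    n_groups = nlevels(grp),
    converged = fit$converged && fit0$converged && is.finite(ll),
    singular = singular,
    pirls_trace = fit$trace,
    model_frame = data,
    design = X,
    offset_log = off,
    prior_weights = m,
    response_range = range(yraw),
    z_center = z_center,
    z_scale = z_scale
  ), class = "fitted_node")
}

#' @export
print.fitted_node <- function(x, ...) {
  cat(sprintf("fitted_node '%s' (%s%s): n = %d, groups = %d, SD(%s) = %.4f%s\n",
              x$name, x$spec$family,
              if (!is.null(x$spec$denominator))
                paste0("/", x$spec$denominator) else "",
              x$n_obs, x$n_groups, x$spec$random, x$random_sd,
              if (x$singular) " (singular)" else ""))
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("deviance %.2f (null %.2f), %% deviance explained %.1f%%\n",
              x$deviance, x$null_deviance, 100 * deviance_explained(x)))
  invisible(x)
}

#' Proportion of deviance explained by a fitted node
#'
#' `(null deviance - fitted deviance) / null deviance`, where the null
#' model keeps the offset and the random intercept but drops all fixed
#' predictors, and both deviances are `-2 *` the marginal (Laplace)
#' log-likelihood on identical rows. Reported as a percentage in network
#' summaries.
#'
#' @param fit a [fit_node()] result.
#' @return Proportion in `[0, 1]` (up to optimizer tolerance).
#' @export
deviance_explained <- function(fit) {
  stopifnot(inherits(fit, "fitted_node"))
  if (!is.finite(fit$null_deviance) || fit$null_deviance <= 0) {
    stop("null deviance is not positive; deviance explained undefined",
         call. = FALSE)
  }
  (fit$null_deviance - fit$deviance) / fit$null_deviance
}

#' Fit every node of a graph
#'
#' @param graph a [model_graph()].
#' @param frames named list of analysis tables, one per distinct `frame`
#'   referenced by the graph's nodes.
#' @param control a [glmm_control()].
#' @return Named list of `fitted_node` objects (one per graph node).
#' @export
fit_all_nodes <- function(graph, frames, control = glmm_control()) {
  stopifnot(inherits(graph, "model_graph"))
  viol <- validate_graph(graph, lapply(frames, names))
  viol <- viol[!grepl("_rate'", viol)]  # rate columns may be derived at fit time
  if (length(viol)) {
    stop("graph/schema violations:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  lapply(graph$nodes, function(nd) {
    fit_node(nd, frames[[nd$frame]], control = control)
  })
}
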