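#' Range-standardized path coefficient
#'
#' Effect size of one predictor term of a fitted node, on a common unitless
#' scale across families: the response (on its natural scale) is predicted
#' at the predictor's observed minimum and at its observed maximum, holding
#' every other model-matrix column at its observed mean, the random effect
#' at zero and the offset at its mean log-effort; the difference is divided
#' by the observed range of the response. For a categorical predictor the
#' sweep runs over its levels and the coefficient is the spread
#' (max - min) of the level predictions, again over the response range.
#' With a monotone link the sign equals the sign of the raw link-scale
#' coefficient.
#'
#' @param fit a [fit_node()] result.
#' @param predictor one term of the node's formula (e.g. `"seed"`,
#'   `"phase:dingo_rate"`, `"site"`).
#' @param divisor `"observed"` (default) divides by the observed response
#'   range, `"theoretical"` by the family's theoretical range (the binomial
#'   denominator; unavailable for Poisson nodes).
#' @return A single numeric standardized coefficient.
#' @export
standardized_coefficient <- function(fit, predictor,
                                     divisor = c("observed", "theoretical")) {
  stopifnot(inherits(fit, "fitted_node"))
  divisor <- match.arg(divisor)
  if (!predictor %in% fit$spec$predictors) {
    stop("'", predictor, "' is not a term of node '", fit$name, "'",
         call. = FALSE)
  }
  X <- fit$design
  xbar <- colMeans(X)
  off <- mean(fit$offset_log)
  predict_at <- function(xrow) {
    eta <- sum(xrow * fit$beta) + off
    if (fit$spec$family == "poisson") {
      exp(eta)
    } else {
      fit$spec$denominator * stats::plogis(eta)
    }
  }
  resp_range <- if (divisor == "observed") {
    diff(fit$response_range)
  } else {
    if (fit$spec$family != "binomial") {
      stop("theoretical range undefined for a Poisson node", call. = FALSE)
    }
    fit$spec$denominator
  }
  if (!is.finite(resp_range) || resp_range <= 0) {
    stop("response range is zero; standardized coefficient undefined",
         call. = FALSE)
  }

  if (predictor %in% fit$spec$factors) {
    lev_cols <- grep(paste0("^", predictor), colnames(X), value = TRUE)
    preds <- vapply(c("", lev_cols), function(lc) {
      xrow <- xbar
      xrow[lev_cols] <- 0
      if (nzchar(lc)) xrow[lc] <- 1
      predict_at(xrow)
    }, 0)
    return((max(preds) - min(preds)) / resp_range)
  }

  col <- colnames(X)[match(.normalize_term(predictor),
                           .normalize_term(colnames(X)))]
  if (is.na(col)) {
    stop("no model-matrix column for term '", predictor, "'", call. = FALSE)
  }
  xcol <- X[, col]
  if (diff(range(xcol)) == 0) {
    warning("predictor '", predictor, "' is constant; standardized ",
            "coefficient set to 0", call. = FALSE)
    return(0)
  }
  lo <- hi <- xbar
  lo[col] <- min(xcol)
  hi[col] <- max(xcol)
  (predict_at(hi) - predict_at(lo)) / resp_range
}

#' Map a z-transformed fit back to the raw covariate scale
#'
#' For nodes fitted on centred/scaled predictors, returns the
#' coefficient vector (and covariance) re-expressed on the raw covariate
#' scale, using the stored centres and scales. The z-design spans the same
#' column space as the raw design (interactions included), so the mapping
#' is exact.
#'
#' @param fit a [fit_node()] result.
#' @return List with `beta` (named, raw scale) and `vcov`.
#' @export
coef_raw_scale <- function(fit) {
  stopifnot(inherits(fit, "fitted_node"))
  if (is.null(fit$z_center)) {
    return(list(beta = fit$beta, vcov = fit$vcov_beta))
  }
  raw <- fit$model_frame
  for (v in names(fit$z_center)) {
    raw[[v]] <- raw[[v]] * fit$z_scale[[v]] + fit$z_center[[v]]
  }
  form <- stats::reformulate(fit$spec$predictors)
  X_raw <- stats::model.matrix(form, raw)
  X_z <- fit$design
  Tm <- qr.solve(X_raw, X_z)           # X_z = X_raw %*% Tm
  beta_raw <- drop(Tm %*% fit$beta)
  names(beta_raw) <- colnames(X_raw)
  list(beta = beta_raw, vcov = Tm %*% fit$vcov_beta %*% t(Tm))
}

# Wald p-value for one term: normal tail for single columns, joint
# chi-square across the dummy columns of a factor
.term_p_value <- function(fit, predictor) {
  X <- fit$design
  if (predictor %in% fit$spec$factors) {
    cols <- grep(paste0("^", predictor), colnames(X))
    b <- fit$beta[cols]
    V <- fit$vcov_beta[cols, cols, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    return(stats::pchisq(stat, df = length(cols), lower.tail = FALSE))
  }
  col <- match(.normalize_term(predictor), .normalize_term(colnames(X)))
  fit$coefficients$p[col]
}

#' Assemble local fits into the piecewise SEM
#'
#' Collects one path estimate per directed effect of the graph — raw
#' link-scale coefficient, range-standardized coefficient, Wald p-value
#' and a significance flag at the two-sided 0.05 level — together with
#' each node's percentage deviance explained. No global covariance fit is
#' attempted: estimation is purely local, which is what makes mixed
#' models and different dataset lengths per node possible.
#'
#' @param fits named list of [fit_node()] results, one per graph node.
#' @param graph the [model_graph()] the fits were produced from.
#' @param alpha two-sided significance threshold for flagging paths.
#' @return An object of class `sem_result`: `paths` (tibble with `source`,
#'   `target`, `raw`, `standardized`, `p`, `significant`),
#'   `deviance_explained` (named percentages), `fits` (the registry used
#'   by the projection step).
#' @export
assemble <- function(fits, graph, alpha = 0.05) {
  stopifnot(inherits(graph, "model_graph"))
  missing_fit <- setdiff(names(graph$nodes), names(fits))
  if (length(missing_fit)) {
    stop("missing fit for node(s): ", paste(missing_fit, collapse = ", "),
         call. = FALSE)
  }
  paths <- dplyr::bind_rows(lapply(names(graph$nodes), function(nm) {
    fit <- fits[[nm]]
    spec <- graph$nodes[[nm]]
    dplyr::bind_rows(lapply(spec$predictors, function(tm) {
      raw <- if (tm %in% spec$factors) {
        NA_real_
      } else {
        col <- match(.normalize_term(tm),
                     .normalize_term(colnames(fit$design)))
        unname(fit$beta[col])
      }
      p <- .term_p_value(fit, tm)
      tibble::tibble(source = tm, target = nm, raw = raw,
                     standardized = standardized_coefficient(fit, tm),
                     p = p, significant = p < alpha)
    }))
  }))
  dev_ex <- vapply(fits[names(graph$nodes)],
                   function(f) 100 * deviance_explained(f), 0)
  structure(list(paths = paths, deviance_explained = dev_ex,
                 fits = fits[names(graph$nodes)], alpha = alpha,
                 graph = graph),
            class = "sem_result")
}

#' @export
print.sem_result <- function(x, ...) {
  cat(sprintf("sem_result: %d paths, %d significant (p < %g)\n",
              nrow(x$paths), sum(x$paths$significant), x$alpha))
  print(as.data.frame(x$paths), digits = 3)
  invisible(x)
}

#' Render the quantified interaction network
#'
#' Textual analogue of the usual network figure: significant paths with
#' their standardized coefficients (non-significant paths suppressed from
#' the main view but retained in the full path table), and each node's
#' percentage deviance explained.
#'
#' @param sem an [assemble()] result.
#' @return Character vector of report lines (invisibly); also printed.
#' @export
render_network <- function(sem) {
  stopifnot(inherits(sem, "sem_result"))
  sig <- sem$paths[sem$paths$significant, , drop = FALSE]
  lines <- c("Quantified interaction network",
             sprintf("significant paths (p < %g): %d of %d", sem$alpha,
                     nrow(sig), nrow(sem$paths)))
  if (nrow(sig)) {
    ord <- order(-abs(sig$standardized))
    lines <- c(lines, sprintf("  %s -> %s  %+ .3f", sig$source[ord],
                              sig$target[ord], sig$standardized[ord]))
  }
  lines <- c(lines, "deviance explained (%):",
             sprintf("  %-10s %5.1f", names(sem$deviance_explained),
                     sem$deviance_explained))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write / read the path table of an assembled SEM
#'
#' @param sem an [assemble()] result.
#' @param path CSV file.
#' @return `path` (write) or the path tibble (read).
#' @export
write_sem_paths <- function(sem, path) {
  readr::write_csv(sem$paths, path)
  invisible(path)
}

#' @rdname write_sem_paths
#' @export
read_sem_paths <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
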