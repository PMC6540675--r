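# ABC scenario choice, parameter estimation and validation.

normalize_stats <- function(stats, scale) {
  sweep(stats, 2, scale, "/")
}

ref_distances <- function(table, obs) {
  z <- normalize_stats(table$stats, table$scale)
  zo <- obs / table$scale
  sqrt(rowSums(sweep(z, 2, zo, "-")^2))
}

#' ABC scenario choice (direct and logistic estimates)
#'
#' Euclidean distances on MAD-normalized summary statistics.  The direct
#' posterior estimate is the scenario composition of the `n_direct`
#' closest rows (capped at the retained count); the logistic estimate
#' fits a multinomial logistic regression of scenario id on LDA-projected
#' summary statistics over the closest `tolerance_frac` of all rows and
#' evaluates it at the observed point.
#'
#' @param obs named summary vector ([summarize()]).
#' @param table an `abc_reftable`.
#' @param tolerance_frac fraction of rows retained for the regression
#'   (default 0.01).
#' @param n_direct rows used for the direct estimate (default 500).
#' @return object of class `abc_scenario_posterior`: data frame
#'   `posterior` (scenario, direct, logistic, and an approximate 95% CI
#'   for the logistic estimate), `selected` scenario id, `n_retained`.
#' @export
choose_scenario <- function(obs, table, tolerance_frac = 0.01,
                            n_direct = 500) {
  if (tolerance_frac <= 0 || tolerance_frac > 1)
    stop("tolerance_frac must be in (0, 1]")
  n <- nrow(table$stats)
  if (!n) stop("empty reference table")
  obs <- obs[colnames(table$stats)]
  d <- ref_distances(table, obs)
  ord <- order(d)
  n_ret <- max(1L, ceiling(tolerance_frac * n))
  retained <- ord[seq_len(n_ret)]
  scen_levels <- sort(unique(table$scenario))
  # direct estimate
  nd <- min(n_direct, n_ret)
  direct_tab <- table(factor(table$scenario[ord[seq_len(nd)]],
                             levels = scen_levels))
  direct <- as.numeric(direct_tab) / nd
  # logistic estimate on LDA-projected stats
  scen_ret <- factor(table$scenario[retained], levels = scen_levels)
  present <- levels(droplevels(scen_ret))
  z <- normalize_stats(table$stats, table$scale)
  zo <- obs / table$scale
  logi <- rep(NA_real_, length(scen_levels))
  lo <- hi <- rep(NA_real_, length(scen_levels))
  if (length(present) == 1L) {
    logi <- as.numeric(scen_levels == as.integer(present))
    lo <- hi <- logi
    warning("only one scenario among retained rows; logistic estimate ",
            "degenerates to its indicator")
  } else {
    X <- z[retained, , drop = FALSE]
    keep_col <- apply(X, 2, function(x) stats::sd(x) > 0)
    X <- X[, keep_col, drop = FALSE]
    # Epanechnikov weights over distance, as in the standard local
    # logistic model-choice regression
    dmax <- max(d[retained]) * (1 + 1e-12)
    wreg <- if (dmax > 0) 1 - (d[retained] / dmax)^2 else rep(1, n_ret)
    wreg[wreg <= 0] <- 1e-8
    fit <- tryCatch({
      ld <- MASS::lda(X, grouping = droplevels(scen_ret))
      proj <- X %*% ld$scaling
      proj_obs <- matrix(zo[keep_col], 1) %*% ld$scaling
      df <- data.frame(scen = droplevels(scen_ret), proj)
      capture <- utils::capture.output(
        mfit <- nnet::multinom(scen ~ ., data = df, weights = wreg,
                               maxit = 1000, reltol = 1e-12,
                               trace = FALSE))
      newd <- as.data.frame(proj_obs)
      names(newd) <- colnames(proj)
      pr <- stats::predict(mfit, newdata = newd, type = "probs")
      if (is.null(dim(pr))) pr else pr[1, ]
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warning("logistic step failed; reporting the direct estimate")
      logi <- direct
    } else {
      if (length(present) == 2L && length(fit) == 1L)
        fit <- c(1 - fit, fit)   # binary case returns P(second level)
      logi <- rep(0, length(scen_levels))
      names(logi) <- scen_levels
      logi[present] <- as.numeric(fit)
      missing_sc <- setdiff(as.character(scen_levels), present)
      if (length(missing_sc))
        warning("scenario(s) absent from retained set: ",
                paste(missing_sc, collapse = ", "))
      logi <- as.numeric(logi / sum(logi))
      # approximate binomial-style CI at the retained sample size
      se <- sqrt(pmax(logi * (1 - logi), 0) / n_ret)
      lo <- pmax(0, logi - 1.96 * se)
      hi <- pmin(1, logi + 1.96 * se)
    }
  }
  post <- data.frame(scenario = scen_levels, direct = direct,
                     logistic = logi, logistic_lo = lo, logistic_hi = hi)
  sel_prob <- if (all(is.na(logi))) direct else logi
  structure(list(posterior = post,
                 selected = scen_levels[which.max(sel_prob)],
                 selected_direct = scen_levels[which.max(direct)],
                 n_retained = n_ret, n_direct = nd,
                 tolerance_frac = tolerance_frac),
            class = "abc_scenario_posterior")
}

#' @export
print.abc_scenario_posterior <- function(x, ...) {
  cat("ABC scenario choice (", x$n_retained, "retained rows )\n")
  print(round(x$posterior, 4), row.names = FALSE)
  cat("Selected scenario:", x$selected, "(logistic),",
      x$selected_direct, "(direct)\n")
  invisible(x)
}

logit_bounded <- function(x, lo, hi) {
  eps <- 1e-9
  u <- pmin(pmax((x - lo) / (hi - lo), eps), 1 - eps)
  log(u / (1 - u))
}

inv_logit_bounded <- function(y, lo, hi) {
  lo + (hi - lo) / (1 + exp(-y))
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], 1)
}

#' ABC parameter posterior with local-linear adjustment
#'
#' Restricts the reference table to one scenario, retains the closest
#' `tolerance_frac` of its rows, and applies the local-linear regression
#' adjustment with Epanechnikov weights over distance.  Parameters are
#' logit-transformed to their prior bounds before regression and
#' back-transformed afterwards.
#'
#' @param obs named summary vector.
#' @param table an `abc_reftable`.
#' @param scenario scenario id whose parameters to estimate.
#' @param tolerance_frac fraction of the scenario's rows retained.
#' @return object of class `abc_param_posterior`: per-parameter `median`,
#'   `q025`, `q975`, plus the weighted posterior `sample`.
#' @export
estimate_parameters <- function(obs, table, scenario,
                                tolerance_frac = 0.01) {
  rows <- which(table$scenario == scenario)
  if (!length(rows)) stop("scenario absent from table: ", scenario)
  obs <- obs[colnames(table$stats)]
  d_all <- ref_distances(table, obs)
  d <- d_all[rows]
  n_ret <- max(2L, ceiling(tolerance_frac * length(rows)))
  if (n_ret < 200)
    warning("only ", n_ret, " retained rows; parameter posterior will ",
            "be noisy (>= 200 recommended)")
  sel <- rows[order(d)[seq_len(n_ret)]]
  dmax <- max(d_all[sel]) * (1 + 1e-12)
  w <- if (dmax > 0) 1 - (d_all[sel] / dmax)^2 else rep(1, n_ret)
  w[w <= 0] <- min(w[w > 0], 1e-8)
  pnames <- setdiff(scenario_params(scenario), character(0))
  pnames <- intersect(unique(c(pnames)), colnames(table$params))
  z <- normalize_stats(table$stats, table$scale)
  zo <- obs / table$scale
  X <- sweep(z[sel, , drop = FALSE], 2, zo, "-")
  keep_col <- apply(X, 2, function(x) stats::sd(x) > 0)
  X <- X[, keep_col, drop = FALSE]
  out <- list()
  adj_sample <- matrix(NA_real_, n_ret, length(pnames),
                       dimnames = list(NULL, pnames))
  for (pn in pnames) {
    bounds <- table$priors[[pn]]
    theta <- table$params[sel, pn]
    y <- logit_bounded(theta, bounds[1], bounds[2])
    adj <- y
    if (ncol(X) > 0 && stats::sd(y) > 0) {
      fit <- tryCatch(stats::lm.wfit(cbind(1, X), y, w),
                      error = function(e) NULL)
      if (!is.null(fit) && !anyNA(fit$coefficients)) {
        beta <- fit$coefficients[-1]
        adj <- y - as.numeric(X %*% beta)
      } else {
        warning("singular regression design for ", pn,
                "; using unadjusted rejection posterior")
      }
    }
    vals <- inv_logit_bounded(adj, bounds[1], bounds[2])
    adj_sample[, pn] <- vals
    q <- weighted_quantile(vals, w, c(0.025, 0.5, 0.975))
    out[[pn]] <- c(q025 = q[1], median = q[2], q975 = q[3])
  }
  structure(list(scenario = scenario,
                 estimates = do.call(rbind, out),
                 sample = adj_sample, weights = w / sum(w),
                 n_retained = n_ret),
            class = "abc_param_posterior")
}

#' @export
print.abc_param_posterior <- function(x, ...) {
  cat("ABC parameter posterior, scenario", x$scenario,
      "(", x$n_retained, "retained rows )\n")
  est <- x$estimates[, c("median", "q025", "q975"), drop = FALSE]
  colnames(est) <- c("Median", "2.5% quantile", "97.5% quantile")
  print(round(est, 1))
  invisible(x)
}

#' Posterior error rate of scenario choice
#'
#' Simulates `n_pods` pseudo-observed datasets under `target_scenario`
#' with prior-drawn parameters and classifies each against the reference
#' table; the error rate is the fraction not assigned to the target,
#' separately for the direct and logistic estimates.
#'
#' @param table an `abc_reftable`.
#' @param target_scenario scenario id the pods are simulated under.
#' @param n_pods number of pseudo-observed datasets (>= 50).
#' @param seed optional integer seed.
#' @param tolerance_frac,n_direct passed to [choose_scenario()].
#' @return list: `direct` and `logistic` error rates, and `assignments`
#'   (matrix of selected scenarios per pod).
#' @export
posterior_error_rate <- function(table, target_scenario = 6, n_pods = 500,
                                 seed = NULL, tolerance_frac = 0.01,
                                 n_direct = 500) {
  if (n_pods < 50) stop("n_pods must be >= 50")
  if (!is.null(seed)) set.seed(seed)
  cfg <- table$config
  sel <- matrix(NA_integer_, n_pods, 2,
                dimnames = list(NULL, c("direct", "logistic")))
  for (i in seq_len(n_pods)) {
    pars <- sample_prior(target_scenario, table$priors)
    ep <- scenario_epochs(target_scenario, pars)
    raw <- simulate_raw(ep, pars, cfg$n_ind, cfg$n_seq, cfg$n_loci,
                        cfg$L, table$model)
    obs <- summarize_raw(raw$msat, raw$seq, cfg$L)
    ch <- suppressWarnings(choose_scenario(obs, table, tolerance_frac,
                                           n_direct))
    sel[i, "direct"] <- ch$selected_direct
    sel[i, "logistic"] <- ch$selected
  }
  list(direct = mean(sel[, "direct"] != target_scenario),
       logistic = mean(sel[, "logistic"] != target_scenario),
       assignments = sel, target = target_scenario)
}

#' Prior/posterior predictive check of the summary statistics
#'
#' For each statistic, the observed value's quantile within each
#' scenario's simulated marginal; quantiles below 0.005 or above 0.995
#' are flagged as outside the simulated distribution.
#'
#' @param obs named summary vector.
#' @param table an `abc_reftable`.
#' @return data frame: scenario, statistic, quantile, flagged.
#' @export
predictive_check <- function(obs, table) {
  if (!nrow(table$stats)) stop("empty reference table")
  obs <- obs[colnames(table$stats)]
  scen_levels <- sort(unique(table$scenario))
  out <- expand.grid(scenario = scen_levels,
                     statistic = colnames(table$stats),
                     stringsAsFactors = FALSE)
  out$quantile <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- table$stats[table$scenario == out$scenario[r], out$statistic[r]]
    x <- obs[[out$statistic[r]]]
    out$quantile[r] <- (sum(v < x) + 0.5 * sum(v == x)) / length(v)
  }
  out$flagged <- out$quantile < 0.005 | out$quantile > 0.995
  out
}

# ---------------------------------------------------------------------
# The fitted-model interface.

#' Fit the ABC demographic model to observed data
#'
#' Computes the observed summary panel, selects among the demographic
#' scenarios (direct + LDA/logistic estimates), estimates the selected
#' scenario's parameter posterior by local-linear regression adjustment,
#' and runs the predictive check.
#'
#' @param genotypes a [genotype_matrix()] (single population).
#' @param sequences a [dna_alignment()] (same population).
#' @param table an `abc_reftable` built with [build_reference_table()].
#' @param tolerance_frac fraction of rows retained for model choice.
#' @param n_direct rows for the direct estimate.
#' @param param_tolerance_frac fraction of the selected scenario's rows
#'   retained for parameter estimation (default: value that retains at
#'   least 200 rows, bounded below by `tolerance_frac`).
#' @return object of class `gcpop_abc` with `print`, `summary`, `coef`,
#'   `predict`, `plot` and `simulate` methods.
#' @export
abc_fit <- function(genotypes, sequences, table, tolerance_frac = 0.01,
                    n_direct = 500, param_tolerance_frac = NULL) {
  obs <- summarize(genotypes, sequences)
  choice <- choose_scenario(obs, table, tolerance_frac, n_direct)
  n_scen <- sum(table$scenario == choice$selected)
  if (is.null(param_tolerance_frac))
    param_tolerance_frac <- max(tolerance_frac, min(1, 200 / n_scen))
  params <- estimate_parameters(obs, table, choice$selected,
                                param_tolerance_frac)
  structure(list(obs = obs, choice = choice, params = params,
                 check = predictive_check(obs, table),
                 table = table,
                 call = match.call()),
            class = "gcpop_abc")
}

#' @export
print.gcpop_abc <- function(x, ...) {
  cat("ABC demographic fit\n")
  cat("Selected scenario:", x$choice$selected, "\n")
  post <- x$choice$posterior
  cat("Posterior probabilities (logistic):",
      paste(sprintf("S%d=%.3f", post$scenario, post$logistic),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.gcpop_abc <- function(object, ...) {
  cat("ABC demographic inference\n\nScenario choice:\n")
  print(object$choice)
  cat("\nParameter posterior:\n")
  print(object$params)
  nf <- sum(object$check$flagged)
  cat("\nPredictive check:", nf, "of", nrow(object$check),
      "scenario x statistic marginals flag the observation\n")
  invisible(object)
}

#' @export
coef.gcpop_abc <- function(object, ...) {
  stats::setNames(object$params$estimates[, "median"],
                  rownames(object$params$estimates))
}

#' Classify new datasets against the fitted reference table
#'
#' @param object a `gcpop_abc` fit.
#' @param newdata a list with elements `genotypes` and `sequences`, or a
#'   named summary-statistic vector; `NULL` returns the fitted posterior.
#' @param ... unused.
#' @return an `abc_scenario_posterior`.
#' @export
predict.gcpop_abc <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$choice)
  obs <- if (is.numeric(newdata)) newdata
  else summarize(newdata$genotypes, newdata$sequences)
  choose_scenario(obs, object$table, object$choice$tolerance_frac,
                  object$choice$n_direct)
}

#' Posterior predictive simulation
#'
#' Draws parameter vectors from the weighted posterior sample and
#' simulates datasets under the selected scenario, returning their
#' summary panels.
#'
#' @param object a `gcpop_abc` fit.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return matrix `nsim` x statistics.
#' @export
simulate.gcpop_abc <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tab <- object$table
  cfg <- tab$config
  sc <- object$choice$selected
  idx <- sample.int(nrow(object$params$sample), nsim, replace = TRUE,
                    prob = object$params$weights)
  out <- matrix(NA_real_, nsim, ncol(tab$stats),
                dimnames = list(NULL, colnames(tab$stats)))
  for (i in seq_len(nsim)) {
    pars <- object$params$sample[idx[i], ]
    # nuisance mutation parameters redrawn from their priors
    hyper <- vapply(c("mu_msat", "p_geom", "mu_seq"), function(p)
      stats::runif(1, tab$priors[[p]][1], tab$priors[[p]][2]), 1)
    full <- c(pars, hyper)
    if (sc == 7) full <- c(full, N1 = unname(full["N0"]))
    ep <- scenario_epochs(sc, full)
    raw <- simulate_raw(ep, full, cfg$n_ind, cfg$n_seq, cfg$n_loci,
                        cfg$L, tab$model)
    out[i, ] <- summarize_raw(raw$msat, raw$seq, cfg$L)
  }
  out
}

#' Plot an ABC fit
#'
#' Barplot of scenario posterior probabilities and weighted posterior
#' histograms of the selected scenario's parameters.
#'
#' @param x a `gcpop_abc` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.gcpop_abc <- function(x, ...) {
  est <- x$params$estimates
  np <- nrow(est)
  old <- graphics::par(mfrow = c(1, np + 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(x$choice$posterior$logistic,
                    names.arg = x$choice$posterior$scenario,
                    xlab = "scenario", ylab = "posterior probability",
                    main = "scenario choice")
  for (pn in rownames(est)) {
    graphics::hist(x$params$sample[, pn], breaks = 30, main = pn,
                   xlab = pn, ...)
    graphics::abline(v = est[pn, "median"], lwd = 2)
  }
  invisible(x)
}
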