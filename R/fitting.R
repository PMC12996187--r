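#' Fit the self-thinning line by quantile regression
#'
#' Estimates the maximum stand density line \eqn{\ln N = b_0 + b_1 \ln Dg}
#' as the `tau`-quantile (default 0.99) of the log-log density-diameter
#' cloud, i.e. the `(b0, b1)` minimizing the check loss
#' \eqn{\sum_i \rho_\tau(\ln N_i - b_0 - b_1 \ln Dg_i)}.
#'
#' The optimum of this piecewise-linear convex objective passes through two
#' data points, so the solver runs Nelder-Mead from the least-squares line
#' and then polishes exactly by enumerating all lines through pairs of
#' low-residual points (the candidate active set), keeping the line of
#' minimum check loss.
#'
#' @param plots Plot table with columns `n_ha` and `dg_cm` (all positive);
#'   at least 10 plots.
#' @param tau Quantile level in (0, 1), default 0.99.
#' @param registry Registry supplying the reference diameter `d0_cm` carried
#'   into the returned parameter set.
#' @return A list of class `fgym_fit` with `model = "self_thinning"`,
#'   `estimates` (`b0`, `b1`, `d0_cm`), `objective` (check loss),
#'   `below_fraction` (share of points strictly below the line) and
#'   `predicted`/`observed` on the log scale.
#' @export
fit_self_thinning <- function(plots, tau = 0.99, registry = NULL) {
  if (is.null(registry)) registry <- default_registry()
  if (!all(c("n_ha", "dg_cm") %in% names(plots)))
    stop("`plots` must have n_ha and dg_cm columns", call. = FALSE)
  ok <- is.finite(plots$n_ha) & is.finite(plots$dg_cm) &
    plots$n_ha > 0 & plots$dg_cm > 0
  if (sum(ok) < 10) stop("need at least 10 plots with positive N and Dg",
                         call. = FALSE)
  if (tau <= 0 || tau >= 1) stop("`tau` must be in (0, 1)", call. = FALSE)
  x <- log(plots$dg_cm[ok]); y <- log(plots$n_ha[ok])
  if (max(x) - min(x) < 1e-8)
    stop("degenerate design: all Dg (nearly) equal", call. = FALSE)

  loss <- function(b) {
    r <- y - b[1] - b[2] * x
    sum(r * (tau - (r < 0)))
  }
  start <- coef(lm(y ~ x))
  opt <- optim(start, loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  best <- opt$par; best_loss <- opt$value

  # exact vertex polish: the optimal line interpolates two data points
  r <- abs(y - best[1] - best[2] * x)
  cand <- order(r)[seq_len(min(length(x), 40L))]
  for (i in seq_along(cand)) for (j in seq_len(i - 1L)) {
    a <- cand[i]; b <- cand[j]
    if (abs(x[a] - x[b]) < 1e-10) next
    slope <- (y[a] - y[b]) / (x[a] - x[b])
    icpt <- y[a] - slope * x[a]
    l <- loss(c(icpt, slope))
    if (l < best_loss) { best <- c(icpt, slope); best_loss <- l }
  }
  pred <- best[1] + best[2] * x
  structure(list(
    model = "self_thinning",
    estimates = list(b0 = unname(best[1]), b1 = unname(best[2]),
                     d0_cm = registry$self_thinning$d0_cm),
    objective = best_loss,
    tau = tau,
    below_fraction = mean(y < pred),
    observed = y, predicted = pred,
    weighting = sprintf("check loss, tau = %.2f", tau)),
    class = "fgym_fit")
}

# Model functions for the weighted NLS machinery: each entry maps a plot
# table and a named parameter vector to fitted values, and declares its
# response column and which registry section seeds the start values.
.nls_models <- list(
  sci = list(
    response = "th_m", section = "sci", pars = c("a0", "a1", "a2"),
    f = function(d, p) p[["a0"]] * (1 - exp(-p[["a1"]] * d$age_yr))^p[["a2"]]),
  sdi_dynamics = list(
    response = "sdi", section = "sdi_dynamics", pars = c("b2", "b3", "b4"),
    f = function(d, p) (p[["b2"]] + p[["b3"]] * d$sci_m) *
      (1 - exp(-p[["b4"]] * d$age_yr))),
  bas_base = list(
    response = "bas_m2ha", section = "bas_base", pars = c("c", "k"),
    f = function(d, p) p[["c"]] * (1 - exp(-p[["k"]] * d$age_yr))),
  bas_stand = list(
    response = "bas_m2ha", section = "bas_stand",
    pars = c("c0", "c1", "k0", "k1"),
    f = function(d, p) p[["c0"]] * d$sci_m^p[["c1"]] *
      (1 - exp(-p[["k0"]] * (d$sdi / 1000)^p[["k1"]] * d$age_yr))),
  bas_climate = list(
    response = "bas_m2ha", section = "bas_climate",
    pars = c("c0", "sci_exp", "mai_exp", "k0", "k1"),
    f = function(d, p) p[["c0"]] * d$sci_m^p[["sci_exp"]] *
      d$mai^(-p[["mai_exp"]]) *
      (1 - exp(-p[["k0"]] * (d$sdi / 1000)^p[["k1"]] * d$age_yr))),
  bas_stage = list(
    response = "bas_m2ha", section = "bas_stage",
    pars = c("c0", "c01", "c02", "sci_exp", "mai_exp",
             "k0", "k01", "k02", "k1"),
    f = function(d, p) {
      dd <- stage_dummies(d$stage, attr(d, "stage_coding") %||%
                            "non_cumulative")
      (p[["c0"]] + p[["c01"]] * dd$x1 + p[["c02"]] * dd$x2) *
        d$sci_m^p[["sci_exp"]] * d$mai^(-p[["mai_exp"]]) *
        (1 - exp(-(p[["k0"]] + p[["k01"]] * dd$x1 + p[["k02"]] * dd$x2) *
                   (d$sdi / 1000)^p[["k1"]] * d$age_yr))
    }),
  volume = list(
    response = "vol_m3ha", section = "volume", pars = c("d0", "d1", "d2"),
    f = function(d, p) p[["d0"]] * d$bas_m2ha^p[["d1"]] * d$th_m^p[["d2"]])
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted nonlinear least squares with iterated reciprocal weights
#'
#' Fits one equation of the model family by minimizing
#' \eqn{\sum_i w_i (y_i - f(x_i; \theta))^2} with heteroscedasticity weights
#' tied to the model function itself: \eqn{w_i = 1/f(x_i; \hat\theta)}
#' (variance proportional to the mean), updated lazily — each outer iteration
#' re-solves the weighted problem (Levenberg-Marquardt via
#' \pkg{minpack.lm}) with weights frozen at the previous iterate's fitted
#' values, until the relative parameter change falls below `tol` or
#' `max_iter` outer iterations. `weights = "reciprocal_sq"` uses
#' \eqn{1/f^2} (variance proportional to the squared mean) and
#' `weights = "none"` reduces to ordinary nonlinear least squares.
#'
#' @param model Equation identifier: one of `"sci"`, `"sdi_dynamics"`,
#'   `"bas_base"`, `"bas_stand"`, `"bas_climate"`, `"bas_stage"`,
#'   `"volume"`.
#' @param plots Plot table carrying the covariates the equation needs
#'   (`age_yr`, and depending on the model `sci_m`, `sdi`, `mai`, `stage`,
#'   `bas_m2ha`, `th_m`) and its response column.
#' @param start Named start values; defaults to the registry section for the
#'   model (the published values).
#' @param registry Parameter registry used for defaults.
#' @param weights `"reciprocal"` (default), `"reciprocal_sq"` or `"none"`.
#' @param max_iter Maximum outer (weight-update) iterations, default 50.
#' @param tol Relative parameter-change tolerance, default 1e-8.
#' @param n_starts Number of multi-starts; starts beyond the first jitter
#'   `start` multiplicatively (lognormal, sd `jitter_sd`). The best final
#'   fit by unweighted residual sum of squares is kept.
#' @param jitter_sd Log-scale jitter of the additional starts, default 0.2.
#' @param seed Optional seed controlling the jittered starts.
#' @param coding Stage dummy coding for `"bas_stage"`.
#' @return A list of class `fgym_fit`: `estimates`, `std_errors` (from the
#'   final weighted problem; `NA` when the information matrix is singular),
#'   `gof` (via [goodness_of_fit()]), `convergence` (outer iterations, final
#'   objective, per-iteration parameter-change trace), `weighting`,
#'   `observed`, `predicted`.
#' @export
fit_weighted_nls <- function(model, plots, start = NULL, registry = NULL,
                             weights = c("reciprocal", "reciprocal_sq",
                                         "none"),
                             max_iter = 50L, tol = 1e-8, n_starts = 1L,
                             jitter_sd = 0.2, seed = NULL,
                             coding = "non_cumulative") {
  weights <- match.arg(weights)
  if (is.null(registry)) registry <- default_registry()
  if (!model %in% names(.nls_models))
    stop("unknown model id '", model, "'; available: ",
         paste(names(.nls_models), collapse = ", "), call. = FALSE)
  spec <- .nls_models[[model]]
  if (!spec$response %in% names(plots))
    stop("plot table lacks response column '", spec$response, "'",
         call. = FALSE)
  y <- plots[[spec$response]]
  n <- length(y)
  if (n <= length(spec$pars) + 1L)
    stop("need n > k + 1 observations", call. = FALSE)
  if (model == "bas_stage") attr(plots, "stage_coding") <- coding

  if (is.null(start)) start <- registry[[spec$section]]
  start <- unlist(start[spec$pars])
  if (any(is.na(start)))
    stop("start values must name: ", paste(spec$pars, collapse = ", "),
         call. = FALSE)

  starts <- list(start)
  if (n_starts > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (s in seq_len(n_starts - 1L))
      starts[[s + 1L]] <- start * rlnorm(length(start), 0, jitter_sd)
  }

  run_one <- function(th0) {
    th <- th0
    w <- rep(1, n)
    trace <- numeric(0)
    iters <- 0L
    fit <- NULL
    repeat {
      iters <- iters + 1L
      if (weights != "none") {
        fhat <- spec$f(plots, th)
        if (any(!is.finite(fhat)) || any(fhat <= 0)) {
          bad <- which(!is.finite(fhat) | fhat <= 0)[1]
          stop("non-positive fitted value at record ", bad,
               ": reciprocal weight undefined", call. = FALSE)
        }
        w <- if (weights == "reciprocal") 1 / fhat else 1 / fhat^2
      }
      sw <- sqrt(w)
      fit <- minpack.lm::nls.lm(
        par = th,
        fn = function(p) sw * (y - spec$f(plots, p)),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12, ptol = 1e-12))
      th_new <- coef(fit)
      delta <- max(abs(th_new - th) / pmax(abs(th), 1e-12))
      trace <- c(trace, delta)
      th <- th_new
      if (weights == "none" || delta < tol || iters >= max_iter) break
    }
    if (weights != "none" && iters >= max_iter && trace[length(trace)] >= tol)
      warning("weight iteration did not converge in ", max_iter,
              " iterations (last relative change ",
              signif(trace[length(trace)], 3), ")")
    list(th = th, fit = fit, iters = iters, trace = trace,
         sse = sum((y - spec$f(plots, th))^2))
  }

  results <- lapply(starts, function(s) tryCatch(run_one(s),
                                                 error = function(e) e))
  ok <- !vapply(results, inherits, logical(1), "error")
  if (!any(ok)) stop("all starts failed: ",
                     conditionMessage(results[[1]]), call. = FALSE)
  results <- results[ok]
  best <- results[[which.min(vapply(results, `[[`, numeric(1), "sse"))]]

  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(best$th)))
  pred <- spec$f(plots, best$th)
  structure(list(
    model = model,
    estimates = as.list(best$th),
    std_errors = as.list(setNames(se, names(best$th))),
    gof = goodness_of_fit(y, pred, k = length(best$th)),
    convergence = list(iterations = best$iters,
                       objective = best$fit$deviance,
                       trace = best$trace),
    weighting = switch(weights,
                       reciprocal = "w = 1/f(x; theta), lagged",
                       reciprocal_sq = "w = 1/f(x; theta)^2, lagged",
                       none = "unweighted"),
    observed = y, predicted = pred),
    class = "fgym_fit")
}

#' @export
print.fgym_fit <- function(x, ...) {
  cat("<fgym_fit> model:", x$model, "\n")
  est <- unlist(x$estimates)
  cat("  estimates:", paste(names(est), signif(est, 6), sep = " = ",
                            collapse = ", "), "\n")
  if (!is.null(x$gof)) { cat("  "); print(x$gof) }
  if (!is.null(x$weighting)) cat("  weighting:", x$weighting, "\n")
  invisible(x)
}

#' Classify plots into developmental stages
#'
#' Applies the Dg-threshold discrimination rule (see [assign_stage()]) to a
#' plot table.
#'
#' @param plots Plot table with a `dg_cm` column.
#' @return A list with `labels` (integer vector) and `counts` (table of
#'   plots per stage).
#' @export
classify_stage <- function(plots) {
  if (!"dg_cm" %in% names(plots))
    stop("`plots` must have a dg_cm column", call. = FALSE)
  labels <- assign_stage(plots$dg_cm)
  list(labels = labels,
       counts = table(factor(labels, levels = 1:3,
                             labels = paste0("stage", 1:3))))
}

#' Sequential estimation of the whole model family
#'
#' Re-estimates the model family from a plot table in the same order the
#' models depend on one another:
#' \enumerate{
#'   \item Richards mean-height curve (`sci` equation), then per-plot SCI
#'     assignment by the site-index standardization;
#'   \item self-thinning line by `tau`-quantile regression, then per-plot
#'     SDI values; then the SDI dynamics equation;
#'   \item developmental-stage classification from Dg;
#'   \item the four basal-area variants (base, stand, climate, stage) using
#'     the assigned SCI/SDI/stage as fixed covariates (two-stage
#'     estimation);
#'   \item the form-factor volume equation.
#' }
#'
#' Options exist to hold parts fixed at the registry instead of refitting:
#' `sci_source = "column"` trusts an `sci_m` column already present in the
#' table (for instance the generating values of a synthetic table);
#' `stage_source = "column"` likewise trusts an existing `stage` column
#' (externally classified stages) instead of re-deriving stages from Dg; and
#' `self_thinning = "registry"` keeps the published self-thinning slope,
#' which is common practice when the frontier is taken from the literature.
#'
#' @param plots Plot table (columns `plot_id`, `age_yr`, `th_m`, `dg_cm`,
#'   `n_ha`, `bas_m2ha`, `vol_m3ha`, `mai`).
#' @param registry Registry providing start values and fixed constants.
#' @param tau Quantile level for the self-thinning line.
#' @param weights Weighting scheme passed to [fit_weighted_nls()].
#' @param sci_source `"fit"` (default: assign SCI from the fitted height
#'   curve) or `"column"`.
#' @param stage_source `"dg"` (default: classify from Dg thresholds) or
#'   `"column"`.
#' @param self_thinning `"fit"` (default) or `"registry"`.
#' @param bas_variants Which basal-area variants to fit (default all four).
#' @param n_starts,jitter_sd,seed Multi-start controls passed to
#'   [fit_weighted_nls()]; the stage model always uses at least 5 starts
#'   unless `n_starts` is larger.
#' @return A list of class `fgym_pipeline` with `registry` (a new validated
#'   registry carrying the fitted values), `fits` (named list of
#'   `fgym_fit`), `stage_counts`, and `report` (data.frame of fit statistics
#'   per model with basal-area variant improvements).
#' @export
fit_pipeline <- function(plots, registry = NULL, tau = 0.99,
                         weights = "reciprocal",
                         sci_source = c("fit", "column"),
                         stage_source = c("dg", "column"),
                         self_thinning = c("fit", "registry"),
                         bas_variants = c("base", "stand", "climate",
                                          "stage"),
                         n_starts = 1L, jitter_sd = 0.2, seed = NULL) {
  bas_variants <- match.arg(bas_variants, several.ok = TRUE)
  stage_source <- match.arg(stage_source)
  sci_source <- match.arg(sci_source)
  self_thinning <- match.arg(self_thinning)
  if (is.null(registry)) registry <- default_registry()
  validate_plots(plots)
  fits <- list()
  done <- character(0)
  fail <- function(stage_name, e) {
    stop("fit_pipeline failed at '", stage_name, "' (completed: ",
         if (length(done)) paste(done, collapse = ", ") else "none", "): ",
         conditionMessage(e), call. = FALSE)
  }

  # 1. height curve + SCI assignment
  fits$sci <- tryCatch(
    fit_weighted_nls("sci", plots, registry = registry, weights = weights,
                     n_starts = n_starts, jitter_sd = jitter_sd, seed = seed),
    error = function(e) fail("sci", e))
  done <- c(done, "sci")
  sci_pars <- c(fits$sci$estimates,
                reference_age = registry$sci$reference_age)
  plots$sci_m <- if (sci_source == "column") {
    if (is.null(plots$sci_m)) stop("sci_source = 'column' needs an sci_m ",
                                   "column", call. = FALSE)
    plots$sci_m
  } else site_class_index(plots$th_m, plots$age_yr, sci_pars)

  # 2. self-thinning + SDI values + SDI dynamics
  st_pars <- if (self_thinning == "registry") registry$self_thinning else {
    fits$self_thinning <- tryCatch(
      fit_self_thinning(plots, tau = tau, registry = registry),
      error = function(e) fail("self_thinning", e))
    done <- c(done, "self_thinning")
    fits$self_thinning$estimates
  }
  plots$sdi <- stand_density_index(plots$n_ha, plots$dg_cm, st_pars)
  fits$sdi_dynamics <- tryCatch(
    fit_weighted_nls("sdi_dynamics", plots, registry = registry,
                     weights = weights, n_starts = n_starts,
                     jitter_sd = jitter_sd, seed = seed),
    error = function(e) fail("sdi_dynamics", e))
  done <- c(done, "sdi_dynamics")

  # 3. stage classification
  if (stage_source == "column") {
    if (is.null(plots$stage) || !all(plots$stage %in% 1:3))
      stop("stage_source = 'column' needs a stage column in 1:3",
           call. = FALSE)
    cls <- list(labels = plots$stage,
                counts = table(factor(plots$stage, levels = 1:3,
                                      labels = paste0("stage", 1:3))))
  } else {
    cls <- classify_stage(plots)
    plots$stage <- cls$labels
  }

  # 4. BAS variants
  for (m in paste0("bas_", bas_variants)) {
    ns <- if (m == "bas_stage") max(n_starts, 5L) else n_starts
    fits[[m]] <- tryCatch(
      fit_weighted_nls(m, plots, registry = registry, weights = weights,
                       n_starts = ns, jitter_sd = jitter_sd, seed = seed,
                       coding = registry$bas_stage$coding),
      error = function(e) fail(m, e))
    done <- c(done, m)
  }

  # 5. volume
  fits$volume <- tryCatch(
    fit_weighted_nls("volume", plots, registry = registry, weights = weights,
                     n_starts = n_starts, jitter_sd = jitter_sd, seed = seed),
    error = function(e) fail("volume", e))
  done <- c(done, "volume")

  # assemble fitted registry
  new_reg <- unclass(registry)
  new_reg$name <- paste0(registry$name, "-refit")
  new_reg$provenance <- paste0("Refit from ", nrow(plots), " plots; seeded ",
                               "from '", registry$name, "'.")
  new_reg$sci[c("a0", "a1", "a2")] <- fits$sci$estimates[c("a0", "a1", "a2")]
  if (self_thinning == "fit")
    new_reg$self_thinning[c("b0", "b1")] <-
      fits$self_thinning$estimates[c("b0", "b1")]
  new_reg$sdi_dynamics[c("b2", "b3", "b4")] <-
    fits$sdi_dynamics$estimates[c("b2", "b3", "b4")]
  for (m in paste0("bas_", bas_variants)) {
    pars <- .nls_models[[m]]$pars
    new_reg[[m]][pars] <- fits[[m]]$estimates[pars]
  }
  new_reg$volume[c("d0", "d1", "d2")] <-
    fits$volume$estimates[c("d0", "d1", "d2")]
  new_registry <- validate_registry(new_reg)

  gof_row <- function(f) data.frame(model = f$model,
                                    adj_r2 = f$gof$adj_r2,
                                    mae_pct = f$gof$mae_pct,
                                    rmse_pct = f$gof$rmse_pct)
  report <- do.call(rbind, lapply(fits[vapply(fits, function(f)
    !is.null(f$gof), logical(1))], gof_row))
  rownames(report) <- NULL
  base_row <- report[report$model == "bas_stand", ]
  if (nrow(base_row) == 1L) {
    for (m in intersect(c("bas_climate", "bas_stage"), report$model)) {
      i <- report$model == m
      report$d_adj_r2[i] <- report$adj_r2[i] - base_row$adj_r2
      report$d_mae_pct[i] <- report$mae_pct[i] - base_row$mae_pct
      report$d_rmse_pct[i] <- report$rmse_pct[i] - base_row$rmse_pct
    }
  }
  structure(list(registry = new_registry, fits = fits,
                 stage_counts = cls$counts, report = report),
            class = "fgym_pipeline")
}

#' @export
print.fgym_pipeline <- function(x, ...) {
  cat("<fgym_pipeline> fitted registry:", x$registry$name, "\n")
  cat("stage counts:", paste(names(x$stage_counts), x$stage_counts,
                             sep = "=", collapse = " "), "\n")
  print(transform(x$report, adj_r2 = round(adj_r2, 4),
                  mae_pct = round(mae_pct, 2),
                  rmse_pct = round(rmse_pct, 2)), row.names = FALSE)
  invisible(x)
}
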