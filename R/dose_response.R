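# Dose-response model family used for benchmark-dose analysis: five named
# mean functions fitted by least squares under a constant-variance Gaussian
# likelihood. sigma counts as a parameter in the AIC.

dr_models <- list(
  linear = list(
    k = 2,
    fit = function(x, y) {
      co <- stats::coef(stats::lm(y ~ x))
      list(a = unname(co[1]), b = unname(co[2]))
    },
    f = function(x, p) p$a + p$b * x
  ),
  quadratic = list(
    k = 3,
    fit = function(x, y) {
      co <- stats::coef(stats::lm(y ~ x + I(x^2)))
      list(a = unname(co[1]), b = unname(co[2]), c = unname(co[3]))
    },
    f = function(x, p) p$a + p$b * x + p$c * x^2
  ),
  power = list(
    k = 3,
    fit = function(x, y) {
      co <- stats::coef(stats::lm(y ~ x))
      fit <- minpack.lm::nlsLM(y ~ a + b * x^g,
                               start = list(a = unname(co[1]),
                                            b = unname(co[2]), g = 1),
                               lower = c(-Inf, -Inf, 0.1),
                               upper = c(Inf, Inf, 8),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      as.list(stats::coef(fit))
    },
    f = function(x, p) p$a + p$b * x^p$g
  ),
  exponential = list(
    k = 2,
    fit = function(x, y) {
      a0 <- if (abs(mean(y)) > 1e-8) mean(y) else 1e-3
      fit <- minpack.lm::nlsLM(y ~ a * exp(b * x),
                               start = list(a = a0, b = 0.01),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      as.list(stats::coef(fit))
    },
    f = function(x, p) p$a * exp(p$b * x)
  ),
  hill = list(
    k = 4,
    fit = function(x, y) {
      a0 <- mean(y[x == min(x)])
      b0 <- mean(y[x == max(x)]) - a0
      if (abs(b0) < 1e-8) b0 <- 1e-3
      k0 <- stats::median(unique(x[x > 0]))
      fit <- minpack.lm::nlsLM(y ~ a + b * x^n / (k^n + x^n),
                               start = list(a = a0, b = b0, k = k0, n = 1),
                               lower = c(-Inf, -Inf, 1e-6, 0.5),
                               upper = c(Inf, Inf, Inf, 10),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      as.list(stats::coef(fit))
    },
    f = function(x, p) p$a + p$b * x^p$n / (p$k^p$n + x^p$n)
  )
)

gauss_ll <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

# lack-of-fit F test against the saturated per-dose-means model
lack_of_fit_p <- function(x, y, fitted, k) {
  mu <- stats::ave(y, x)
  rss_pe <- sum((y - mu)^2)
  df_pe <- length(y) - length(unique(x))
  rss_m <- sum((y - fitted)^2)
  df_lof <- length(unique(x)) - k
  if (df_pe <= 0 || df_lof <= 0 || rss_pe <= 0) return(NA_real_)
  F <- ((rss_m - rss_pe) / df_lof) / (rss_pe / df_pe)
  stats::pf(max(F, 0), df_lof, df_pe, lower.tail = FALSE)
}

#' Fit the dose-response model family to one gene's series
#'
#' Least-squares fits of linear, quadratic, power, exponential and Hill
#' mean functions under constant variance; AIC per model (sigma counted as
#' a parameter) and a lack-of-fit F-test against the saturated per-dose
#' means. Models whose optimisation fails or that have more mean parameters
#' than distinct doses are skipped with a reason.
#'
#' @param doses,responses Numeric vectors (paired observations). At least 3
#'   distinct doses; replicates required for the lack-of-fit test.
#' @return `dr_fits` list: `fits` (per-model list with `params`, `f`, `rss`,
#'   `aic`, `lof_p`, `sigma`), `skipped` (named reasons), `best`
#'   (name of the lowest-AIC model), `doses`, `responses`.
#' @export
fit_dose_models <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), all(is.finite(responses)))
  nd <- length(unique(doses))
  if (nd < 3) stop("need at least 3 distinct doses")
  n <- length(doses)
  fits <- list()
  skipped <- character()
  for (m in names(dr_models)) {
    mod <- dr_models[[m]]
    if (mod$k >= nd + 1) {
      skipped[m] <- "more parameters than distinct doses"
      next
    }
    p <- tryCatch(mod$fit(doses, responses), error = function(e) NULL)
    if (is.null(p) || any(!is.finite(unlist(p)))) {
      skipped[m] <- "fit failed"
      next
    }
    fitted <- mod$f(doses, p)
    rss <- sum((responses - fitted)^2)
    if (!is.finite(rss)) {
      skipped[m] <- "non-finite residuals"
      next
    }
    kk <- mod$k + 1  # sigma counts as a parameter
    aic <- -2 * gauss_ll(max(rss, 1e-12), n) + 2 * kk
    # small-sample correction: dose series have few observations per
    # parameter, where plain AIC is known to over-select flexible models
    aicc <- if (n - kk - 1 > 0) aic + 2 * kk * (kk + 1) / (n - kk - 1) else Inf
    fx <- local({pp <- p; ff <- mod$f; function(x) ff(x, pp)})
    fits[[m]] <- list(model = m, params = p, f = fx,
                      rss = rss, k = mod$k, n = n, aic = aic, aicc = aicc,
                      sigma = sqrt(max(rss, 0) / max(n - mod$k, 1)),
                      lof_p = lack_of_fit_p(doses, responses, fitted, mod$k))
  }
  if (length(fits) == 0L) stop("all dose-response models failed")
  aiccs <- vapply(fits, `[[`, 0, "aicc")
  structure(list(fits = fits, skipped = skipped,
                 best = names(fits)[which.min(aiccs)],
                 doses = doses, responses = responses),
            class = "dr_fits")
}

#' @export
print.dr_fits <- function(x, ...) {
  aics <- vapply(x$fits, `[[`, 0, "aic")
  cat("dose-response fits (best:", x$best, ")\n")
  print(round(sort(aics), 2))
  invisible(x)
}

# constrained profile log-likelihood at a fixed benchmark dose: one mean
# parameter is eliminated through the benchmark constraint
# |f(bmd) - f(0)| = bmrf * sigma, and the rest (plus log sigma) are
# maximised numerically
profile_ll_at_bmd <- function(fit_obj, model, bmd, s, bmrf) {
  x <- fit_obj$doses; y <- fit_obj$responses
  n <- length(y)
  p0 <- fit_obj$fits[[model]]$params
  sigma0 <- max(fit_obj$fits[[model]]$sigma, 1e-6)
  build <- switch(model,
    linear = list(
      free = c(a = p0$a, lsig = log(sigma0)),
      f = function(th) {
        sg <- exp(th["lsig"])
        b <- s * bmrf * sg / bmd
        list(mu = th["a"] + b * x, sg = sg)
      }),
    quadratic = list(
      free = c(a = p0$a, c = p0$c, lsig = log(sigma0)),
      f = function(th) {
        sg <- exp(th["lsig"])
        b <- (s * bmrf * sg - th["c"] * bmd^2) / bmd
        list(mu = th["a"] + b * x + th["c"] * x^2, sg = sg)
      }),
    power = list(
      free = c(a = p0$a, g = p0$g, lsig = log(sigma0)),
      f = function(th) {
        g <- min(max(th["g"], 0.1), 8)
        sg <- exp(th["lsig"])
        b <- s * bmrf * sg / bmd^g
        list(mu = th["a"] + b * x^g, sg = sg)
      }),
    exponential = list(
      free = c(a = p0$a, lsig = log(sigma0)),
      f = function(th) {
        sg <- exp(th["lsig"])
        val <- 1 + s * bmrf * sg / th["a"]
        if (val <= 0) return(NULL)
        b <- log(val) / bmd
        list(mu = th["a"] * exp(b * x), sg = sg)
      }),
    hill = list(
      free = c(a = p0$a, k = p0$k, nn = p0$n, lsig = log(sigma0)),
      f = function(th) {
        kk <- max(th["k"], 1e-6); nn <- min(max(th["nn"], 0.5), 10)
        sg <- exp(th["lsig"])
        b <- s * bmrf * sg * (kk^nn + bmd^nn) / bmd^nn
        list(mu = th["a"] + b * x^nn / (kk^nn + x^nn), sg = sg)
      }),
    stop("unknown model: ", model))
  negll <- function(th) {
    names(th) <- names(build$free)
    mb <- build$f(th)
    if (is.null(mb) || any(!is.finite(mb$mu))) return(1e10)
    n / 2 * log(2 * pi * mb$sg^2) + sum((y - mb$mu)^2) / (2 * mb$sg^2)
  }
  opt <- tryCatch(stats::optim(build$free, negll, method = "Nelder-Mead",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(opt)) return(-Inf)
  -opt$value
}

#' Benchmark dose with profile-likelihood confidence limits
#'
#' Under the standard-deviation approach, the benchmark response is
#' `bmrf * sigma` (residual SD of the selected model); the BMD is the
#' smallest dose at which the fitted response deviates from the fitted
#' control response by that amount. BMDL and BMDU come from the profile
#' likelihood: the range of benchmark doses whose constrained fit stays
#' within the chi-square cutoff of the two-sided `conf` level.
#'
#' @param fit_obj A [fit_dose_models()] result.
#' @param model Model to use; defaults to the lowest-AIC model.
#' @param bmrf Benchmark response factor (1.349 corresponds to roughly a 10
#'   percent shift of a normal response distribution).
#' @param conf Two-sided confidence level for BMDL/BMDU.
#' @return List: `BMD`, `BMDL`, `BMDU`, `model`, `flags` (character; e.g.
#'   when the response never reaches the benchmark within the dose range).
#' @export
bmd_triple <- function(fit_obj, model = fit_obj$best, bmrf = 1.349,
                       conf = 0.90) {
  stopifnot(inherits(fit_obj, "dr_fits"))
  ft <- fit_obj$fits[[model]]
  if (is.null(ft)) stop("model not fitted: ", model)
  if (bmrf == 0) return(list(BMD = 0, BMDL = 0, BMDU = 0, model = model,
                             flags = character()))
  max_dose <- max(fit_obj$doses)
  f0 <- ft$f(0)
  bmr <- bmrf * ft$sigma
  g <- function(x) abs(ft$f(x) - f0) - bmr
  grid <- seq(0, max_dose, length.out = 400)
  above <- which(g(grid) >= 0)
  if (length(above) == 0L) {
    return(list(BMD = NA_real_, BMDL = NA_real_, BMDU = NA_real_,
                model = model, flags = "benchmark_not_reached"))
  }
  i <- above[1]
  BMD <- if (i == 1L) grid[1] else
    stats::uniroot(g, c(grid[i - 1L], grid[i]))$root
  if (BMD <= 0) BMD <- grid[2] / 10
  s <- sign(ft$f(BMD) - f0)
  ll_hat <- gauss_ll(max(ft$rss, 1e-12), ft$n)
  cut <- stats::qchisq(conf, 1)
  dev <- function(c) 2 * (ll_hat - profile_ll_at_bmd(fit_obj, model, c, s, bmrf))
  # lower limit
  lo <- BMD / 100
  BMDL <- if (dev(lo) < cut) lo else
    tryCatch(stats::uniroot(function(c) dev(c) - cut, c(lo, BMD),
                            tol = BMD * 1e-4)$root,
             error = function(e) lo)
  # upper limit
  hi <- max_dose * 10
  BMDU <- if (dev(hi) < cut) Inf else
    tryCatch(stats::uniroot(function(c) dev(c) - cut, c(BMD, hi),
                            tol = BMD * 1e-4)$root,
             error = function(e) Inf)
  BMDL <- min(BMDL, BMD)
  BMDU <- max(BMDU, BMD)
  flags <- character()
  if (!is.finite(BMDU)) flags <- c(flags, "bmdu_unbounded")
  list(BMD = BMD, BMDL = BMDL, BMDU = BMDU, model = model, flags = flags)
}

#' Benchmark-dose analysis of a multi-gene dose-response table
#'
#' Fits the model family per gene, selects the lowest-AIC model, estimates
#' BMD/BMDL/BMDU, and records the filter cascade flags.
#'
#' @param series Long data.frame: gene_id, dose, replicate, response.
#' @param bmrf,conf Passed to [bmd_triple()].
#' @param lof_alpha,r1,r2,r3 Passed to [filter_dose_dependent()].
#' @return `bmd_result` data.frame: gene_id, model, aic, lof_p, BMD, BMDL,
#'   BMDU, passed, reason.
#' @export
bmd_analysis <- function(series, bmrf = 1.349, conf = 0.90,
                         lof_alpha = 0.01, r1 = 20, r2 = 20, r3 = 40) {
  rows <- lapply(split(series, series$gene_id), function(d) {
    est <- tryCatch({
      fo <- fit_dose_models(d$dose, d$response)
      tri <- bmd_triple(fo, bmrf = bmrf, conf = conf)
      best <- fo$fits[[fo$best]]
      data.frame(gene_id = d$gene_id[1], model = fo$best, aic = best$aic,
                 lof_p = best$lof_p, BMD = tri$BMD, BMDL = tri$BMDL,
                 BMDU = tri$BMDU, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(gene_id = d$gene_id[1], model = NA_character_,
                 aic = NA_real_, lof_p = NA_real_, BMD = NA_real_,
                 BMDL = NA_real_, BMDU = NA_real_, stringsAsFactors = FALSE))
    est
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  flt <- filter_dose_dependent(out, max_dose = max(series$dose),
                               lof_alpha = lof_alpha, r1 = r1, r2 = r2,
                               r3 = r3, return_flags = TRUE)
  out$passed <- flt$passed
  out$reason <- flt$reason
  class(out) <- c("bmd_result", "data.frame")
  out
}

#' Filter cascade for dose-dependent genes
#'
#' Keeps genes with lack-of-fit p above `lof_alpha`, all of BMD/BMDL/BMDU
#' defined and finite, BMD and BMDU within the tested dose range, and
#' confidence-interval ratios not exceeding `BMD/BMDL <= r1`,
#' `BMDU/BMD <= r2`, `BMDU/BMDL <= r3`.
#'
#' @param estimates data.frame with columns gene_id, lof_p, BMD, BMDL, BMDU.
#' @param max_dose Highest tested dose.
#' @param lof_alpha,r1,r2,r3 Filter thresholds.
#' @param return_flags Return per-gene pass flags and reasons instead of the
#'   retained gene set.
#' @return Character vector of retained gene ids, or (with
#'   `return_flags = TRUE`) a list with `passed` and `reason`.
#' @export
filter_dose_dependent <- function(estimates, max_dose, lof_alpha = 0.01,
                                  r1 = 20, r2 = 20, r3 = 40,
                                  return_flags = FALSE) {
  reason <- character(nrow(estimates))
  passed <- rep(TRUE, nrow(estimates))
  fail <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[cond & passed] <<- code
    passed <<- passed & !cond
  }
  defined <- is.finite(estimates$BMD) & is.finite(estimates$BMDL) &
    is.finite(estimates$BMDU)
  fail(!defined, "bmd_undefined")
  fail(!(estimates$lof_p > lof_alpha), "lack_of_fit")
  fail(estimates$BMD > max_dose | estimates$BMDU > max_dose,
       "above_max_dose")
  fail(estimates$BMD / estimates$BMDL > r1, "bmd_bmdl_ratio")
  fail(estimates$BMDU / estimates$BMD > r2, "bmdu_bmd_ratio")
  fail(estimates$BMDU / estimates$BMDL > r3, "bmdu_bmdl_ratio")
  if (return_flags) return(list(passed = passed, reason = reason))
  estimates$gene_id[passed]
}

#' Percentage of dose-dependent genes covered by a target set
#' @param dose_dependent_genes Non-empty character vector.
#' @param target_set Character vector.
#' @return Percentage in `[0, 100]`.
#' @export
target_fraction <- function(dose_dependent_genes, target_set) {
  dose_dependent_genes <- unique(dose_dependent_genes)
  if (length(dose_dependent_genes) == 0L) stop("empty dose-dependent set")
  100 * length(intersect(dose_dependent_genes, target_set)) /
    length(dose_dependent_genes)
}
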