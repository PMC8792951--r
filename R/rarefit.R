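#' Pan/core rarefaction by random genome sampling
#'
#' For each genome count x in 1..N draws up to `n_samples` distinct genome
#' subsets (exhaustive enumeration whenever `choose(N, x) <= n_samples`),
#' and records the pan size (family union) and core size (family
#' intersection) of each subset.
#'
#' @param pan A `pan_matrix` (>= 2 genomes).
#' @param n_samples Random combinations per genome count (default 20,000).
#' @param seed Optional seed for the subset sampling.
#' @return A `rarefaction` tibble (x, sample_id, pan_size, core_size) with a
#'   `medians` attribute tibble (x, pan_median, core_median).
#' @export
rarefy <- function(pan, n_samples = 20000, seed = NULL) {
  N <- ncol(pan)
  assert_that(N >= 2, "need at least 2 genomes")
  assert_that(n_samples >= 1, "n_samples must be >= 1")
  P <- presence_view(pan)
  with_seed(seed, {
    res <- list()
    for (x in seq_len(N)) {
      n_comb <- choose(N, x)
      subsets <- if (n_comb <= n_samples) {
        utils::combn(N, x, simplify = FALSE)
      } else {
        seen <- new.env(hash = TRUE)
        out <- vector("list", n_samples)
        got <- 0L; tries <- 0L
        while (got < n_samples && tries < 5L * n_samples) {
          tries <- tries + 1L
          s <- sort(sample.int(N, x))
          keyname <- paste(s, collapse = ",")
          if (is.null(seen[[keyname]])) {
            seen[[keyname]] <- TRUE
            got <- got + 1L
            out[[got]] <- s
          }
        }
        out[seq_len(got)]
      }
      sizes <- vapply(subsets, function(s) {
        rs <- rowSums(P[, s, drop = FALSE])
        c(sum(rs > 0), sum(rs == length(s)))
      }, numeric(2))
      res[[x]] <- tibble(x = x, sample_id = seq_along(subsets),
                         pan_size = sizes[1, ], core_size = sizes[2, ])
    }
    out <- bind_rows(res)
    med <- out |> group_by(x) |>
      summarise(pan_median = stats::median(pan_size),
                core_median = stats::median(core_size), .groups = "drop")
    structure(out, class = c("rarefaction", class(out)),
              medians = med, n_samples = n_samples, seed = seed)
  })
}

#' Fit a pan- or core-genome growth model to points
#'
#' Least-squares fit of the power law y = a x^gamma + b (pan-genome growth;
#' a positive exponent declares the pan-genome open) or the exponential
#' decay y = a exp(-k x) + b (core-genome shrinkage). Confidence intervals
#' use the linearized (Jacobian) approximation at the optimum.
#'
#' @param x,y Numeric vectors (>= 3 distinct x).
#' @param model "power" or "exponential".
#' @return A `curve_fit` list: model, coefficients, ci_halfwidth (95%),
#'   r_squared, open (power model only), fitted values.
#' @export
fit_growth_curve <- function(x, y, model = c("power", "exponential")) {
  model <- match.arg(model)
  assert_that(length(unique(x)) >= 3, "need >= 3 distinct x values")
  if (stats::sd(y) == 0) {
    warn("constant data: degenerate fit (closed)")
    cf <- if (model == "power") c(a = 0, gamma = 0, b = y[1]) else
      c(a = 0, k = 0, b = y[1])
    return(structure(list(model = model, coef = cf,
                          ci_halfwidth = cf * NA, r_squared = 1,
                          open = FALSE, fitted = rep(y[1], length(x)),
                          x = x, y = y),
                     class = "curve_fit"))
  }
  dat <- data.frame(x = x, y = y)
  if (model == "power") {
    a0 <- (max(y) - min(y)) / (max(x)^0.3 - min(x)^0.3 + 1e-9)
    fit <- minpack.lm::nlsLM(y ~ a * x^gamma + b, data = dat,
                             start = list(a = a0, gamma = 0.3,
                                          b = min(y) - a0),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    a0 <- max(y) - min(y)
    fit <- minpack.lm::nlsLM(y ~ a * exp(-k * x) + b, data = dat,
                             start = list(a = a0, k = 0.1, b = min(y)),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    model = model, coef = cf, ci_halfwidth = 1.96 * se,
    r_squared = max(0, min(1, r2)),
    open = if (model == "power") unname(cf["gamma"] > 0) else NA,
    fitted = stats::fitted(fit), x = x, y = y
  ), class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> %s: %s; R^2 = %.4f\n", x$model,
              paste(sprintf("%s = %.4g +/- %.2g", names(x$coef), x$coef,
                            x$ci_halfwidth), collapse = ", "),
              x$r_squared))
  invisible(x)
}

#' Fit the pan and core accumulation curves of a rarefaction
#'
#' Fits the power law to pan sizes and the exponential decay to core sizes.
#' By default the median size at each genome count is fitted; set
#' `fit_points = "all"` to fit every sampled combination.
#'
#' @param r A [rarefy()] result.
#' @param fit_points "medians" (default) or "all".
#' @return A `pan_curve_fits` list with elements `pan` and `core`
#'   (each a `curve_fit`).
#' @export
fit_curves <- function(r, fit_points = c("medians", "all")) {
  fit_points <- match.arg(fit_points)
  if (fit_points == "medians") {
    med <- attr(r, "medians")
    pan <- fit_growth_curve(med$x, med$pan_median, "power")
    core <- fit_growth_curve(med$x, med$core_median, "exponential")
  } else {
    pan <- fit_growth_curve(r$x, r$pan_size, "power")
    core <- fit_growth_curve(r$x, r$core_size, "exponential")
  }
  structure(list(pan = pan, core = core, fit_points = fit_points),
            class = "pan_curve_fits")
}

#' @export
print.pan_curve_fits <- function(x, ...) {
  cat("pan:  "); print(x$pan)
  cat("core: "); print(x$core)
  cat(sprintf("pan-genome declared %s\n",
              if (isTRUE(x$pan$open)) "open" else "closed/saturating"))
  invisible(x)
}

#' Expected new genes contributed by the (x+1)-th genome
#'
#' The discrete increment a ((x+1)^gamma - x^gamma) of a fitted power-law
#' pan curve; 0 for closed fits (gamma <= 0).
#'
#' @param fit A power-model `curve_fit` or a `pan_curve_fits`.
#' @param x Genome count(s) already sampled.
#' @return Numeric vector of expected new gene counts.
#' @export
new_genes_per_genome <- function(fit, x) {
  if (inherits(fit, "pan_curve_fits")) fit <- fit$pan
  stopifnot(inherits(fit, "curve_fit"))
  assert_that(fit$model == "power", "requires a power-law fit")
  a <- fit$coef[["a"]]; g <- fit$coef[["gamma"]]
  if (g <= 0) return(rep(0, length(x)))
  a * ((x + 1)^g - x^g)
}
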