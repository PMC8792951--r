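#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tibble::as_tibble

#' Tidy a fitted growth curve
#'
#' @param x A `curve_fit`.
#' @param ... Unused.
#' @return Tibble: term, estimate, ci_low, ci_high.
#' @export
tidy.curve_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef),
         ci_low = unname(x$coef - x$ci_halfwidth),
         ci_high = unname(x$coef + x$ci_halfwidth))
}

#' @rdname tidy.curve_fit
#' @export
glance.curve_fit <- function(x, ...) {
  tibble(model = x$model, r_squared = x$r_squared,
         open = if (is.na(x$open)) NA else x$open)
}

#' @rdname tidy.curve_fit
#' @export
tidy.pan_curve_fits <- function(x, ...) {
  bind_rows(pan = tidy(x$pan), core = tidy(x$core), .id = "curve")
}

#' @rdname tidy.curve_fit
#' @export
glance.pan_curve_fits <- function(x, ...) {
  bind_rows(pan = glance(x$pan), core = glance(x$core), .id = "curve")
}

#' Tidy a fitted gain-loss model
#'
#' @param x A `gainloss_model`.
#' @param ... Unused.
#' @return One row per parameter / one-row model summary.
#' @export
tidy.gainloss_model <- function(x, ...) {
  tibble(term = c("gain", "loss", "root_prior"),
         estimate = c(x$gain, x$loss, x$root_prior))
}

#' @rdname tidy.gainloss_model
#' @export
glance.gainloss_model <- function(x, ...) {
  tibble(logLik = x$loglik, rounds_used = x$rounds_used,
         posterior_threshold = x$posterior_threshold)
}

#' Tidy an event profile (per-branch likely events)
#'
#' @param x An `event_profile`.
#' @param ... Unused.
#' @return The per-branch tibble (already tidy); `glance()` gives totals.
#' @export
tidy.event_profile <- function(x, ...) as_tibble(x)

#' @rdname tidy.event_profile
#' @export
glance.event_profile <- function(x, ...) {
  tot <- attr(x, "totals")
  tibble(likely_gains = tot$gains, likely_losses = tot$losses,
         gain_loss_ratio = tot$gain_loss_ratio,
         threshold = attr(x, "threshold"))
}
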