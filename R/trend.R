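#' Size-closure trend fit
#'
#' Least-squares fit of the averaged degree of sutural closure on a skull
#' size proxy, with the Pearson correlation coefficient. The `"linear"`
#' model regresses the closure average on the length itself; the `"log"`
#' model on its natural logarithm (the correlation is base-invariant).
#'
#' @param records specimen metadata with `specimen_id` and the length
#'   variable.
#' @param averages per-specimen averages (see [specimen_averages()]), or a
#'   `character_matrix` from which they are computed.
#' @param model `"linear"` or `"log"`.
#' @param length_var which length column to use (default
#'   `"skull_length_mm"`).
#' @param response which average column to use (default `"closure_avg"`).
#' @return object of class `suture_trend` wrapping the underlying `lm`:
#'   fields `model`, `pearson_r`, `slope`, `intercept`, `n`.
#' @export
suture_trend <- function(records, averages, model = c("linear", "log"),
                         length_var = "skull_length_mm",
                         response = "closure_avg") {
  model <- match.arg(model)
  if (inherits(averages, "character_matrix"))
    averages <- specimen_averages(averages)
  idx <- match(canonical_id(records$specimen_id),
               canonical_id(averages$specimen_id))
  x <- records[[length_var]]
  y <- averages[[response]][idx]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired (length, average) points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in ", if (stats::sd(x) == 0) length_var else response)
  xt <- if (model == "log") log(x) else x
  fit <- stats::lm(y ~ xt)
  r <- stats::cor(xt, y)
  structure(list(model = model, pearson_r = r,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x), lm = fit,
                 data = data.frame(length = x, transformed = xt, average = y),
                 length_var = length_var, response = response),
            class = "suture_trend")
}

#' @export
print.suture_trend <- function(x, ...) {
  cat(sprintf("suture_trend (%s): r = %.2f, n = %d\n",
              x$model, x$pearson_r, x$n))
  cat(sprintf("  %s = %.4g %s %.4g * %s%s\n", x$response, x$intercept,
              if (x$slope >= 0) "+" else "-", abs(x$slope),
              if (x$model == "log") "log " else "", x$length_var))
  invisible(x)
}

#' @export
coef.suture_trend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.suture_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  x <- if (is.list(newdata)) newdata[[object$length_var]] else newdata
  xt <- if (object$model == "log") log(x) else x
  object$intercept + object$slope * xt
}

#' @export
residuals.suture_trend <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.suture_trend <- function(x, ...) {
  graphics::plot(x$data$length, x$data$average,
                 xlab = x$length_var, ylab = x$response,
                 log = if (x$model == "log") "x" else "", ...)
  xs <- seq(min(x$data$length), max(x$data$length), length.out = 100)
  graphics::lines(xs, predict(x, xs))
  graphics::mtext(sprintf("r = %.2f (n = %d, %s model)", x$pearson_r, x$n,
                          x$model), side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}
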