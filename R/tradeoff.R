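# The core statistic: fit a quadratic "vigor curve" through per-genotype
# (mixture, monoculture) performance points and score each genotype by its
# signed orthogonal distance from the curve. Position along the curve is
# general vigor; the perpendicular axis is the group-versus-individual
# (G-I) trade-off, positive above the curve (cooperative: better in
# monoculture than its vigor predicts).

#' Fit the quadratic vigor curve
#'
#' Ordinary least squares of monoculture performance `y` on individual
#' mixture performance `x` and its square, `q(t) = b0 + b1 t + b2 t^2`,
#' with a partial F test of the quadratic term (residual-sum-of-squares
#' comparison against the linear model).
#'
#' @param points data frame with numeric columns `x` and `y` (one row per
#'   genotype), or a matrix-like with those columns.
#' @return An object of class `vigor_fit`: coefficients, `quad_F`,
#'   `quad_df` (1, n-3), `quad_p`, `residual_sd`, and the underlying `lm`.
#' @export
fit_vigor_curve <- function(points) {
  x <- points$x; y <- points$y
  if (length(x) < 4) stop("need at least 4 points to fit the vigor curve")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite performance values")
  if (diff(range(x)) == 0) stop("all x values equal; curve not identifiable")
  quad <- stats::lm(y ~ x + I(x^2))
  lin <- stats::lm(y ~ x)
  n <- length(x)
  rss_q <- sum(stats::resid(quad)^2)
  rss_l <- sum(stats::resid(lin)^2)
  tss <- sum((y - mean(y))^2)
  Fq <- if (rss_l <= 1e-12 * max(tss, .Machine$double.eps)) 0  # exact line
        else (rss_l - rss_q) / (rss_q / (n - 3))
  if (!is.finite(Fq) || Fq < 0) Fq <- 0
  beta <- unname(stats::coef(quad))
  structure(list(coefficients = c(beta0 = beta[1], beta1 = beta[2],
                                  beta2 = beta[3]),
                 quad_F = Fq, quad_df = c(1, n - 3L),
                 quad_p = stats::pf(Fq, 1, n - 3, lower.tail = FALSE),
                 residual_sd = sqrt(rss_q / (n - 3)),
                 lm = quad, n = n),
            class = "vigor_fit")
}

curve_beta <- function(fit) {
  if (inherits(fit, c("vigor_fit", "gi_tradeoff")))
    return(unname(fit$coefficients))
  if (is.numeric(fit) && length(fit) == 3) return(unname(fit))
  stop("'fit' must be a vigor_fit/gi_tradeoff or a length-3 coefficient vector")
}

eval_curve <- function(beta, t) beta[1] + beta[2] * t + beta[3] * t^2

#' Foot point of a performance point on the vigor curve
#'
#' Finds the abscissa `t*` minimizing the squared Euclidean distance
#' `D(t) = (t - x)^2 + (q(t) - y)^2` to the quadratic curve. The
#' stationarity condition `D'(t) = 0` is a cubic, solved analytically; all
#' real roots are compared so the returned minimizer is global, with ties
#' broken toward smaller `t`.
#'
#' @param fit a [fit_vigor_curve()] / [gi_tradeoff()] object, or the numeric
#'   coefficients `(b0, b1, b2)`.
#' @param x,y coordinates of the point(s); vectors are processed elementwise.
#' @return Numeric vector of foot-point abscissas.
#' @export
foot_point <- function(fit, x, y) {
  beta <- curve_beta(fit)
  if (!all(is.finite(beta)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite curve or point")
  b0 <- beta[1]; b1 <- beta[2]; b2 <- beta[3]
  vapply(seq_along(x), function(i) {
    xi <- x[i]; yi <- y[i]
    if (b2 == 0) {
      # curve is a line; perpendicular projection in closed form
      return((xi + b1 * (yi - b0)) / (1 + b1^2))
    }
    # 0.5 D'(t) = (t - x) + (q(t) - y)(b1 + 2 b2 t), a cubic in t
    c0 <- b1 * (b0 - yi) - xi
    c1 <- 1 + 2 * b2 * (b0 - yi) + b1^2
    c2 <- 3 * b1 * b2
    c3 <- 2 * b2^2
    rts <- polyroot(c(c0, c1, c2, c3))
    real <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
    # polish with one Newton step guard via optimize? analytic roots suffice
    D <- (real - xi)^2 + (eval_curve(beta, real) - yi)^2
    dmin <- min(D)
    cand <- sort(real[D <= dmin + 1e-12 * (1 + dmin)])
    cand[1]
  }, numeric(1))
}

#' Signed orthogonal G-I trade-off values
#'
#' For each performance point, the signed Euclidean distance to the fitted
#' vigor curve: positive when the point lies above the curve (monoculture
#' performance exceeding what its vigor position predicts — cooperative),
#' negative below (competitive).
#'
#' @inheritParams fit_vigor_curve
#' @param fit a [fit_vigor_curve()] result (fitted on the same point cloud).
#' @return Data frame: `genotype` (if present in `points`), `x`, `y`,
#'   `t_star`, `gi_value`.
#' @export
gi_values <- function(fit, points) {
  beta <- curve_beta(fit)
  t_star <- foot_point(beta, points$x, points$y)
  qt <- eval_curve(beta, t_star)
  d <- sqrt((t_star - points$x)^2 + (qt - points$y)^2)
  side <- sign(points$y - qt)
  side[d < 1e-9] <- 0
  out <- data.frame(x = points$x, y = points$y, t_star = t_star,
                    gi_value = side * d)
  if (!is.null(points$genotype))
    out <- cbind(genotype = points$genotype, out)
  rownames(out) <- NULL
  out
}

#' Decompose genotype performance into vigor and cooperation
#'
#' The central model of the package. Fits the quadratic vigor curve to the
#' per-genotype performance points and computes every genotype's position
#' along the curve (`t_star`, vigor) and signed orthogonal distance from it
#' (`gi_value`, the G-I trade-off; positive = cooperative). Returns a
#' classed object with the usual accessor methods (`print`, `summary`,
#' `coef`, `predict`, `fitted`, `residuals`, `plot`).
#'
#' @param points data frame with columns `x` (mean individual shoot biomass
#'   across mixtures, grams), `y` (monoculture shoot biomass per individual,
#'   grams), and optionally `genotype`; typically from
#'   [genotype_performance()].
#' @return An object of class `gi_tradeoff`.
#' @examples
#' pts <- data.frame(x = c(0.4, 0.6, 0.8, 1.0, 1.2),
#'                   y = c(0.5, 0.8, 0.9, 1.15, 1.3))
#' fit <- gi_tradeoff(pts)
#' coef(fit)
#' residuals(fit)      # signed orthogonal distances
#' @export
gi_tradeoff <- function(points) {
  points <- as.data.frame(points)
  fit <- fit_vigor_curve(points)
  vals <- gi_values(fit, points)
  structure(list(coefficients = fit$coefficients,
                 quad_F = fit$quad_F, quad_df = fit$quad_df,
                 quad_p = fit$quad_p, residual_sd = fit$residual_sd,
                 lm = fit$lm, n = fit$n, values = vals,
                 call = match.call()),
            class = "gi_tradeoff")
}

#' @export
coef.gi_tradeoff <- function(object, ...) object$coefficients

#' @export
print.gi_tradeoff <- function(x, digits = 4, ...) {
  cat("Group-versus-individual trade-off decomposition\n")
  cat(sprintf("  vigor curve: q(t) = %.4g + %.4g t + %.4g t^2  (n = %d)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3], x$n))
  cat(sprintf("  quadratic term: F(%d, %d) = %.4g, p = %.4g\n",
              x$quad_df[1], x$quad_df[2], x$quad_F, x$quad_p))
  cat(sprintf("  G-I values: range [%.4g, %.4g], sd %.4g\n",
              min(x$values$gi_value), max(x$values$gi_value),
              stats::sd(x$values$gi_value)))
  invisible(x)
}

#' @export
summary.gi_tradeoff <- function(object, ...) {
  structure(list(fit = object,
                 gi_summary = summary(object$values$gi_value),
                 most_cooperative = object$values[
                   order(-object$values$gi_value)[1:min(5, object$n)], ],
                 most_competitive = object$values[
                   order(object$values$gi_value)[1:min(5, object$n)], ]),
            class = "summary.gi_tradeoff")
}

#' @export
print.summary.gi_tradeoff <- function(x, ...) {
  print(x$fit)
  cat("\nG-I value distribution:\n"); print(x$gi_summary)
  cat("\nMost cooperative genotypes:\n")
  print(x$most_cooperative, row.names = FALSE)
  cat("\nMost competitive genotypes:\n")
  print(x$most_competitive, row.names = FALSE)
  invisible(x)
}

#' @export
predict.gi_tradeoff <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$values$x
  else if (is.numeric(newdata)) newdata
  else newdata$x
  eval_curve(unname(object$coefficients), t)
}

#' @export
fitted.gi_tradeoff <- function(object, ...) {
  eval_curve(unname(object$coefficients), object$values$t_star)
}

#' Residuals of a G-I trade-off fit
#'
#' `type = "orthogonal"` (default) returns the signed orthogonal distances —
#' the G-I trade-off values themselves; `type = "vertical"` the ordinary
#' vertical residuals `y - q(x)`.
#'
#' @param object a [gi_tradeoff()] fit.
#' @param type `"orthogonal"` or `"vertical"`.
#' @param ... unused.
#' @export
residuals.gi_tradeoff <- function(object,
                                  type = c("orthogonal", "vertical"), ...) {
  type <- match.arg(type)
  v <- object$values
  r <- switch(type, orthogonal = v$gi_value,
              vertical = v$y - eval_curve(unname(object$coefficients), v$x))
  if (!is.null(v$genotype)) names(r) <- v$genotype
  r
}

#' Plot a G-I trade-off decomposition
#'
#' Scatter of the performance points with the fitted vigor curve and, for
#' each genotype, the orthogonal segment to its foot point. Points above the
#' curve (positive G-I value) are the cooperative genotypes.
#'
#' @param x a [gi_tradeoff()] fit.
#' @param segments draw point-to-curve segments.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gi_tradeoff <- function(x, segments = TRUE, ...) {
  v <- x$values
  graphics::plot(v$x, v$y,
                 xlab = "individual shoot biomass in mixtures [g]",
                 ylab = "monoculture shoot biomass per individual [g]",
                 col = ifelse(v$gi_value >= 0, "firebrick", "steelblue"),
                 pch = 16, ...)
  tt <- seq(min(v$x), max(v$x), length.out = 200)
  graphics::lines(tt, eval_curve(unname(x$coefficients), tt), lwd = 2)
  if (segments)
    graphics::segments(v$x, v$y, v$t_star,
                       eval_curve(unname(x$coefficients), v$t_star),
                       col = "grey60")
  invisible(x)
}
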