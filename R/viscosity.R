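# Viscosity of aqueous sucrose solutions.
#
# A bundled table on a (temperature, weight percent) grid is queried by
# bilinear interpolation. Pure-water values are handbook viscosities at
# 5 C intervals; sucrose rows are generated from a smooth correlation of
# the relative viscosity, ln(eta_rel) = p(w) * (1 + k (20 - T)), with
# p(w) a cubic-in-concentration polynomial anchored to the 20 C
# relative viscosities of 10, 20, 30 and 40 % (w/w) sucrose
# (1.333, 1.941, 3.18 and 6.16) and k = 0.005 per degree C reproducing
# the mild steepening of eta_rel toward low temperature.

.WATER_ETA_CP <- data.frame(
  temp_C = seq(0, 60, 5),
  eta_cP = c(1.787, 1.519, 1.307, 1.139, 1.002, 0.8904, 0.7975, 0.7194,
             0.6529, 0.5960, 0.5468, 0.5040, 0.4665))

.sucrose_poly <- local({
  w <- c(0.10, 0.20, 0.30, 0.40)
  y <- log(c(1.333, 1.941, 3.18, 6.16))
  co <- solve(outer(w, 1:4, `^`), y)
  function(wfrac) as.numeric(outer(wfrac, 1:4, `^`) %*% co)
})

.sucrose_table <- function() {
  Tg <- seq(0, 60, 5)
  wg <- seq(0, 40, 5)
  tab <- outer(Tg, wg, function(T, w) {
    lnr <- .sucrose_poly(w / 100) * (1 + 0.005 * (20 - T))
    rep(.WATER_ETA_CP$eta_cP, length.out = length(T))[match(T, Tg)] * exp(lnr)
  })
  dimnames(tab) <- list(Tg, wg)
  tab
}

.SUCROSE_TAB <- NULL  # built on first use

#' Viscosity of aqueous sucrose at a given temperature and concentration
#'
#' Bilinear interpolation on the bundled sucrose-viscosity table
#' (0-60 C, 0-40 % sucrose by weight). At w = 0 the handbook pure-water
#' viscosities are returned.
#'
#' @param temp_C temperature in Celsius (0-60).
#' @param w_percent sucrose concentration, percent by weight (0-40).
#' @return viscosity in poise.
#' @examples
#' sucroseViscosity(20, 0)    # 0.01002 poise
#' sucroseViscosity(20, 20)   # ~0.0194 poise
#' @export
sucroseViscosity <- function(temp_C, w_percent) {
  if (any(temp_C < 0 | temp_C > 60))
    stop("temperature outside the tabulated range 0-60 C")
  if (any(w_percent < 0 | w_percent > 40))
    stop("sucrose concentration outside the tabulated range 0-40 %")
  if (is.null(.SUCROSE_TAB))
    utils::assignInMyNamespace(".SUCROSE_TAB", .sucrose_table())
  tab <- .SUCROSE_TAB
  Tg <- as.numeric(rownames(tab))
  wg <- as.numeric(colnames(tab))
  out <- mapply(function(T, w) {
    i <- findInterval(T, Tg, rightmost.closed = TRUE)
    j <- findInterval(w, wg, rightmost.closed = TRUE)
    tfrac <- (T - Tg[i]) / diff(Tg)[1]
    wfrac <- (w - wg[j]) / diff(wg)[1]
    i2 <- min(i + 1, length(Tg))
    j2 <- min(j + 1, length(wg))
    if (i2 == i) tfrac <- 0
    if (j2 == j) wfrac <- 0
    (1 - tfrac) * (1 - wfrac) * tab[i, j] +
      tfrac * (1 - wfrac) * tab[i2, j] +
      (1 - tfrac) * wfrac * tab[i, j2] +
      tfrac * wfrac * tab[i2, j2]
  }, temp_C, w_percent)
  out / 100   # cP -> poise
}
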