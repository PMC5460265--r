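#' Physical parameters of the bubble-over-biofilm experiment
#'
#' Bundles the quantities needed for the thin-film estimates: a long air
#' bubble travelling through a shallow rectangular microchannel leaves a
#' residual liquid film on the wall whose thickness, evaporation time and
#' exposure time control whether the film ruptures while the bubble is
#' overhead. All values are SI.
#'
#' @param mu Dynamic viscosity of the liquid (Pa s). Default 1e-3 (water-like
#'   culture medium).
#' @param U Bubble / mean flow speed (m s^-1). Default 250e-6.
#' @param sigma Liquid-air interfacial tension (N m^-1). Default 50e-3; media
#'   conditioned by cells and EPS can be as low as 25e-3.
#' @param H Channel height (m). Default 50e-6.
#' @param L_bubble Bubble length (m). Default 2.5e-3.
#' @param E Evaporation rate of the residual film (kg m^-2 s^-1). Default
#'   5e-5 (room temperature, ~50 % relative humidity). Values outside
#'   [1e-5, 1e-4] trigger a warning, not an error: the humidity-to-rate
#'   conversion is outside the scope of this package and E is a direct input.
#' @param rho Liquid density (kg m^-3). Default 1000.
#' @param Q Volumetric flow rate (m^3 s^-1). Default 5e-11 (3 microlitre/min).
#' @param W Channel width (m). Default 4e-3.
#'
#' @return An object of class \code{physical_params} (a validated list).
#' @examples
#' p <- physical_params()
#' capillary_number(p)
#' @export
physical_params <- function(mu = 1e-3, U = 250e-6, sigma = 50e-3, H = 50e-6,
                            L_bubble = 2.5e-3, E = 5e-5, rho = 1000,
                            Q = 3e-9 / 60, W = 4e-3) {
  p <- list(mu = mu, U = U, sigma = sigma, H = H, L_bubble = L_bubble,
            E = E, rho = rho, Q = Q, W = W)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("physical parameter '", nm, "' must be a finite numeric scalar")
  }
  # L_bubble and U of zero are meaningful limits used in trivial checks;
  # everything else must be strictly positive.
  strict <- setdiff(names(p), c("L_bubble", "U"))
  for (nm in strict) if (p[[nm]] <= 0)
    stop("physical parameter '", nm, "' must be strictly positive")
  if (p$L_bubble < 0 || p$U < 0)
    stop("'L_bubble' and 'U' must be non-negative")
  if (sigma < 1e-3 || sigma > 1e-1)
    stop("'sigma' outside the physically plausible range [1e-3, 1e-1] N m^-1")
  if (E < 1e-5 || E > 1e-4)
    warning("evaporation rate E = ", format(E),
            " kg m^-2 s^-1 is outside the documented 1e-5..1e-4 range")
  structure(p, class = "physical_params")
}

stopifnot_params <- function(p) {
  if (!inherits(p, "physical_params"))
    stop("expected a 'physical_params' object; see physical_params()")
  invisible(p)
}

#' Capillary number of the moving bubble
#'
#' Ca = mu * U / sigma, the ratio of viscous to capillary forces at the
#' bubble interface. For the default parameters Ca is 5e-6 to 1e-5 depending
#' on the interfacial tension.
#'
#' @param p A \code{\link{physical_params}} object.
#' @return Dimensionless capillary number.
#' @export
capillary_number <- function(p) {
  stopifnot_params(p)
  if (p$U <= 0) stop("capillary number requires U > 0")
  p$mu * p$U / p$sigma
}

#' Residual film thickness left by a long bubble
#'
#' For a long bubble in a confined channel at small capillary number, the
#' thickness of the liquid film deposited on the wall scales as
#' h = c * H * Ca^(2/3). The prefactor is of order unity; the classical
#' lubrication value is 1.34, and the default here is 1 (an order-of-magnitude
#' estimate, which keeps h below 0.1 micrometres for the default parameters).
#'
#' @param p A \code{\link{physical_params}} object.
#' @param c Proportionality constant (> 0), default 1.
#' @return Film thickness in metres.
#' @export
film_thickness <- function(p, c = 1) {
  stopifnot_params(p)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a positive scalar")
  Ca <- if (p$U == 0) 0 else capillary_number(p)
  c * p$H * Ca^(2 / 3)
}

#' Time for the residual film to evaporate
#'
#' Simple mass balance: a film of thickness h holds rho*h kilograms of water
#' per square metre, which evaporates at rate E, so t = h * rho / E. A 0.1
#' micrometre film at 5e-5 kg m^-2 s^-1 evaporates in ~2 s.
#'
#' @param h Film thickness (m), >= 0.
#' @param p A \code{\link{physical_params}} object supplying rho and E.
#' @return Evaporation time in seconds.
#' @export
evaporation_time <- function(h, p) {
  stopifnot_params(p)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 0)
    stop("'h' must be a non-negative scalar")
  h * p$rho / p$E
}

#' Time the bubble spends over a fixed point
#'
#' L_bubble / U: the exposure window during which the residual film exists
#' under air. Roughly 10 s for a 2.5 mm bubble at 250 micrometres per second,
#' comfortably longer than the ~2 s evaporation time, which is why the film
#' can rupture while the bubble is still overhead.
#'
#' @param p A \code{\link{physical_params}} object.
#' @return Passage time in seconds.
#' @export
bubble_passage_time <- function(p) {
  stopifnot_params(p)
  if (p$U <= 0) stop("bubble passage time requires U > 0")
  p$L_bubble / p$U
}

#' Mean flow velocity from the volumetric flow rate
#'
#' Q / (W * H) for a rectangular channel of width W and height H.
#'
#' @param p A \code{\link{physical_params}} object.
#' @return Mean velocity in m s^-1.
#' @export
mean_velocity <- function(p) {
  stopifnot_params(p)
  p$Q / (p$W * p$H)
}

#' Wall shear rate in plane-Poiseuille flow
#'
#' 6 * U_mean / H, valid when the channel is much wider than tall (here
#' W/H = 80, so side-wall corrections are negligible). About 30 per second
#' for the default operating point.
#'
#' @param p A \code{\link{physical_params}} object.
#' @param U_mean Mean velocity (m s^-1); defaults to \code{mean_velocity(p)}.
#' @return Shear rate in s^-1.
#' @export
wall_shear_rate <- function(p, U_mean = mean_velocity(p)) {
  stopifnot_params(p)
  if (!is.numeric(U_mean) || length(U_mean) != 1L || U_mean < 0)
    stop("'U_mean' must be a non-negative scalar")
  6 * U_mean / p$H
}

#' All derived hydrodynamic quantities as a one-row data frame
#'
#' @param p A \code{\link{physical_params}} object.
#' @param bretherton_c Prefactor for \code{\link{film_thickness}}.
#' @return A data frame with one row: Ca, film thickness (m), evaporation
#'   time (s), bubble passage time (s), mean velocity (m s^-1) and wall shear
#'   rate (s^-1).
#' @export
physics_report <- function(p = physical_params(), bretherton_c = 1) {
  stopifnot_params(p)
  h <- film_thickness(p, bretherton_c)
  data.frame(
    Ca = capillary_number(p),
    film_thickness_m = h,
    evaporation_time_s = evaporation_time(h, p),
    bubble_passage_time_s = bubble_passage_time(p),
    mean_velocity_m_s = mean_velocity(p),
    wall_shear_rate_per_s = wall_shear_rate(p)
  )
}
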