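# Cell-wall impingement model: dimensionless impact energy, regime
# classification (stick / rebound / spread / splash), and the reference
# (single-event) implementations mirrored by the compiled engine.

#' Thermal context for regime classification
#'
#' The rebound branch activates only above the critical transition
#' temperature `T_c = Tc_star * T_s`; under culture conditions
#' (37 C wall, 100 C saturation, Tc_star = 1) it never fires.
#'
#' @param T_wall Wall temperature, K (default 310.15 = 37 C).
#' @param T_s Saturation temperature, K (default 373.15).
#' @param Tc_star Critical temperature factor, in `[1, 1.5]` (default 1).
#' @export
thermal_context <- function(T_wall = 310.15, T_s = 373.15, Tc_star = 1) {
  if (Tc_star < 1 || Tc_star > 1.5)
    stop("Tc_star must lie in [1, 1.5]")
  if (T_wall <= 0 || T_s <= 0) stop("temperatures must be positive (K)")
  structure(list(T_wall = T_wall, T_s = T_s, Tc_star = Tc_star),
            class = "thermal_context")
}

#' Critical transition temperature
#'
#' `T_c = Tc_star * T_s`.
#' @param thermal A [thermal_context()].
#' @export
critical_temperature <- function(thermal) {
  thermal$Tc_star * thermal$T_s
}

#' Boundary layer thickness at impact
#'
#' `delta_bl = d_p / sqrt(Re)`.
#'
#' @param d_p Particle diameter, m.
#' @param Re Impact Reynolds number, > 0.
#' @export
boundary_layer_thickness <- function(d_p, Re) {
  if (any(Re <= 0)) stop("Re must be > 0")
  d_p / sqrt(Re)
}

#' Dimensionless impact energy
#'
#' Standard spray-impingement form (default):
#' `E^2 = (rho V_pn^2 d / sigma) / (min(h_o/d, 1) + delta_bl/d)`.
#' On a dry wall (`h_o = 0`) only the boundary-layer term remains in the
#' denominator.  `form = "literal"` evaluates the alternative reading
#' `E^2 = (rho V_pn^2 d / sigma) * (1/min(h_o/d, 1) + delta_bl/d)` for
#' sensitivity checks.
#'
#' @param fluid_rho Seeding solution density, kg/m^3.
#' @param V_pn Wall-normal impact speed, m/s.
#' @param d_p Particle diameter, m.
#' @param sigma Surface tension, N/m (cell-phase value by default in the
#'   simulation config).
#' @param h_o Wall film height at the impact element, m.
#' @param delta_bl Boundary layer thickness, m.
#' @param form `"standard"` or `"literal"`.
#' @export
impact_energy <- function(fluid_rho, V_pn, d_p, sigma, h_o, delta_bl,
                          form = c("standard", "literal")) {
  form <- match.arg(form)
  if (any(sigma <= 0) || any(d_p <= 0)) stop("sigma and d_p must be > 0")
  if (any(c(V_pn, h_o, delta_bl) < 0)) stop("inputs must be >= 0")
  base <- fluid_rho * V_pn^2 * d_p / sigma
  hterm <- pmin(h_o / d_p, 1)
  if (form == "standard") {
    br <- hterm + delta_bl / d_p
    if (any(br == 0 & V_pn > 0))
      stop("degenerate impact: zero film height and zero boundary layer")
    E2 <- ifelse(br > 0, base / br, 0)
  } else {
    inv <- ifelse(hterm > 0, 1 / hterm, Inf)
    E2 <- base * (inv + delta_bl / d_p)
    E2[base == 0] <- 0
  }
  sqrt(E2)
}

#' Classify an impingement regime
#'
#' Rebound when the wall is hotter than the critical transition
#' temperature and `E < 57.7`; otherwise stick below `E = 16`, spread for
#' `16 <= E <= 57.7`, splash above 57.7.
#'
#' @param E Impact energy (dimensionless), >= 0.
#' @param thermal A [thermal_context()].
#' @param e_stick,e_splash Regime thresholds (defaults 16 and 57.7).
#' @return Factor with levels stick, rebound, spread, splash.
#' @export
classify_regime <- function(E, thermal = thermal_context(),
                            e_stick = 16, e_splash = 57.7) {
  if (any(E < 0)) stop("E must be >= 0")
  Tc <- critical_temperature(thermal)
  hot <- thermal$T_wall > Tc
  out <- ifelse(hot & E < e_splash, "rebound",
         ifelse(E < e_stick, "stick",
         ifelse(E <= e_splash, "spread", "splash")))
  factor(out, levels = c("stick", "rebound", "spread", "splash"))
}

#' Apply an impingement regime to one particle (reference implementation)
#'
#' Mirrors the compiled engine: stick and spread attach the particle with
#' the wall's (zero) velocity, spread additionally adds the particle
#' volume over the element area to the wall film; rebound reflects the
#' velocity with normal restitution `e_n` and tangential `e_t`; splash
#' breaks the cell into `n_fragments` equal drops, one remaining on the
#' wall as dead matter and the rest leaving with the given speed factor.
#'
#' @param particle List with `position`, `velocity`, `diam`, `status`.
#' @param regime One of `"stick"`, `"rebound"`, `"spread"`, `"splash"`.
#' @param normal Outward unit surface normal at the impact point.
#' @param element_area Surface element area, m^2 (for the film increment).
#' @param e_n,e_t Restitution coefficients (defaults 0.9 and 1).
#' @param n_fragments Number of splash drops (default 6).
#' @param frag_speed_factor Fragment speed as a fraction of impact speed.
#' @return List: updated `particle`, `film_increment` (m), and `fragments`
#'   (data frame, possibly empty).
#' @export
apply_regime <- function(particle, regime, normal, element_area,
                         e_n = 0.9, e_t = 1, n_fragments = 6,
                         frag_speed_factor = 0.8) {
  regime <- match.arg(regime, c("stick", "rebound", "spread", "splash"))
  v <- particle$velocity
  film_inc <- 0
  frags <- data.frame()
  if (regime == "stick") {
    particle$velocity <- c(0, 0, 0)
    particle$status <- "attached"
  } else if (regime == "spread") {
    particle$velocity <- c(0, 0, 0)
    particle$status <- "attached_spread"
    film_inc <- (pi / 6) * particle$diam^3 / element_area
  } else if (regime == "rebound") {
    vn <- sum(v * normal)
    vt <- v - vn * normal
    particle$velocity <- e_t * vt - e_n * vn * normal
    particle$status <- "suspended"
  } else {
    speed <- sqrt(sum(v^2))
    df <- particle$diam / n_fragments^(1 / 3)
    particle$velocity <- c(0, 0, 0)
    particle$status <- "dead_attached"
    particle$diam <- df
    dirs <- matrix(rnorm(3 * (n_fragments - 1)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    flip <- dirs %*% normal < 0
    dirs[flip, ] <- -dirs[flip, , drop = FALSE]
    frags <- data.frame(diam = df,
                        vx = frag_speed_factor * speed * dirs[, 1],
                        vy = frag_speed_factor * speed * dirs[, 2],
                        vz = frag_speed_factor * speed * dirs[, 3])
  }
  list(particle = particle, film_increment = film_inc, fragments = frags)
}

#' Specular reflection at the well boundary (reference implementation)
#'
#' Well walls reflect cells without trapping (only the scaffold traps);
#' restitution 1 by default.
#'
#' @param position,velocity Length-3 numeric (m, m/s), the particle state
#'   exactly at the wall.
#' @param well A [well_domain()].
#' @param restitution Normal restitution (default 1).
#' @return List with reflected `velocity` and the outward `normal` used.
#' @export
reflect_well_wall <- function(position, velocity, well, restitution = 1) {
  cx <- well$diameter / 2; cy <- well$diameter / 2
  r <- sqrt((position[1] - cx)^2 + (position[2] - cy)^2)
  dz_bot <- position[3]; dz_top <- well$depth - position[3]
  dr <- well$diameter / 2 - r
  which_wall <- which.min(c(abs(dr), abs(dz_bot), abs(dz_top)))
  if (which_wall == 1) {
    n <- c((position[1] - cx) / r, (position[2] - cy) / r, 0)
  } else if (which_wall == 2) {
    n <- c(0, 0, -1)
  } else {
    n <- c(0, 0, 1)
  }
  vn <- sum(velocity * n)
  vt <- velocity - vn * n
  list(velocity = vt - restitution * vn * n, normal = n)
}
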