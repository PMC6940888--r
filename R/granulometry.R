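# Feed granulometry from sieve analysis: geometric mean diameter (GMD) and
# geometric standard deviation (GSD) of the particle-size distribution, the
# standard feed-science characterisation of mash and crumble diets.

#' Sieve-analysis stack
#'
#' Ordered sieve apertures (descending, micrometres) with the mass retained
#' on each sieve, plus the mass collected in the pan. The mass retained on
#' sieve i is assigned the class mean diameter `sqrt(a_i * upper_i)`
#' (geometric mean of the bounding apertures); the coarsest sieve's upper
#' bound defaults to `a_1 * sqrt(2)` (a root-2 sieve progression) and the
#' pan class is bounded below by `pan_floor_um`.
#'
#' @param aperture_um Sieve apertures, strictly descending, um.
#' @param mass_g Mass retained on each sieve, g (same length).
#' @param pan_mass_g Mass in the pan, g.
#' @param pan_floor_um Lower diameter bound of the pan class, um.
#' @param top_aperture_um Upper bound of the coarsest class, um; default
#'   `aperture_um[1] * sqrt(2)`.
#' @return A list of class `sieve_stack`.
#' @export
sieve_stack <- function(aperture_um, mass_g, pan_mass_g = 0,
                        pan_floor_um = 38, top_aperture_um = NULL) {
  stopifnot(length(aperture_um) == length(mass_g),
            length(aperture_um) >= 1,
            all(diff(aperture_um) < 0),
            all(aperture_um > 0),
            all(mass_g >= 0), pan_mass_g >= 0, pan_floor_um >= 0)
  total <- sum(mass_g) + pan_mass_g
  if (total <= 0) stop("total retained mass must be positive")
  top <- top_aperture_um %||% (aperture_um[1] * sqrt(2))
  stopifnot(top > aperture_um[1])
  structure(list(aperture_um = aperture_um, mass_g = mass_g,
                 pan_mass_g = pan_mass_g, pan_floor_um = pan_floor_um,
                 top_aperture_um = top),
            class = "sieve_stack")
}

#' Read a sieve stack from a two-column CSV
#'
#' Expects columns `aperture_um` and `mass_g`; a row with aperture 0 (or the
#' smallest aperture equal to 0) is taken as the pan.
#'
#' @param path CSV file path.
#' @param ... Passed to [sieve_stack()] (e.g. `pan_floor_um`).
#' @return A `sieve_stack`.
#' @examples
#' st <- read_sieve_csv(system.file("extdata", "sieve_fine_mash_synthetic.csv",
#'                                  package = "feedkin"))
#' gmd_gsd(st)$gmd_um
#' @export
read_sieve_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  stopifnot(all(c("aperture_um", "mass_g") %in% names(d)))
  d <- d[order(-d$aperture_um), ]
  pan <- d$aperture_um == 0
  sieve_stack(d$aperture_um[!pan], d$mass_g[!pan],
              pan_mass_g = sum(d$mass_g[pan]), ...)
}

#' Geometric mean diameter and geometric standard deviation
#'
#' Mass-weighted log10 statistics of the class mean diameters:
#' `GMD = 10 ^ (sum(W * log10(d)) / sum(W))` and
#' `GSD = 10 ^ sqrt(sum(W * (log10(d) - log10(GMD))^2) / sum(W))`,
#' with `W` the retained masses and `d` the class mean diameters. The GMD
#' is invariant to the logarithm base; the GSD follows the feed-science
#' convention of exponentiating the log10 standard deviation.
#'
#' @param stack A [sieve_stack()].
#' @return List: `gmd_um`, `gsd`, and `classes` (data.frame of class
#'   diameters and weights; the pan row is flagged in `class` when its
#'   configured floor was used).
#' @examples
#' st <- sieve_stack(c(1190, 595, 297), c(10, 40, 30), pan_mass_g = 20)
#' gmd_gsd(st)$gmd_um
#' @export
gmd_gsd <- function(stack) {
  stopifnot(inherits(stack, "sieve_stack"))
  a <- stack$aperture_um
  upper <- c(stack$top_aperture_um, a[-length(a)])
  d <- sqrt(a * upper)
  w <- stack$mass_g
  cls <- rep("sieve", length(a))
  if (stack$pan_mass_g > 0) {
    d_pan <- sqrt(a[length(a)] * stack$pan_floor_um)
    d <- c(d, d_pan); w <- c(w, stack$pan_mass_g)
    cls <- c(cls, "pan (configured floor)")
  }
  occ <- w > 0
  if (any(d[occ] <= 0))
    stop("occupied size class with zero diameter (set a positive pan floor)")
  logd <- log10(d[occ]); wo <- w[occ]
  lg <- sum(wo * logd) / sum(wo)
  ls <- sqrt(sum(wo * (logd - lg)^2) / sum(wo))
  list(gmd_um = 10^lg, gsd = 10^ls,
       classes = data.frame(class = cls, mean_diameter_um = d, mass_g = w))
}
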