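#' Hours of daylight at a date and location
#'
#' Computes the time in hours between sunrise and sunset from the calendar
#' date and geographic coordinates, using the NOAA low-precision solar
#' position equations (Fourier series for the solar declination plus the
#' sunrise hour-angle equation). The solar zenith at rise/set is taken as
#' 90.833 degrees, which accounts for atmospheric refraction and the radius
#' of the solar disc. Day length is evaluated for local solar noon of the
#' date; the result is clipped to exactly 24 during polar day and exactly 0
#' during polar night.
#'
#' Accuracy is a few minutes, which is ample when day length enters
#' regression models in whole hours. Longitude does not affect the
#' sunrise-to-sunset duration at this level of approximation but is part of
#' the location contract and is validated.
#'
#' @param date a `Date` vector (or anything `as.Date` accepts).
#' @param latitude degrees north, in \[-90, 90\].
#' @param longitude degrees east, in \[-180, 180\].
#' @return numeric vector of day lengths in hours, in \[0, 24\].
#' @examples
#' day_length("2004-06-21", 70.05, -126.5)   # polar day: 24
#' day_length("2003-12-21", 70.05, -126.5)   # polar night: 0
#' day_length("2004-03-20", 45, 0)           # near equinox: slightly > 12
#' @export
day_length <- function(date, latitude, longitude) {
  date <- as.Date(date)
  if (anyNA(date)) stop("'date' contains values that are not valid dates")
  if (!is.numeric(latitude) || anyNA(latitude) ||
      any(latitude < -90 | latitude > 90)) {
    stop("'latitude' must be in [-90, 90] degrees north")
  }
  if (!is.numeric(longitude) || anyNA(longitude) ||
      any(longitude < -180 | longitude > 180)) {
    stop("'longitude' must be in [-180, 180] degrees east")
  }

  doy <- as.integer(strftime(date, "%j"))
  year <- as.integer(strftime(date, "%Y"))
  year_len <- ifelse(year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0),
                     366, 365)
  # fractional year at solar noon
  g <- 2 * pi / year_len * (doy - 1 + 0.5)

  decl <- 0.006918 -
    0.399912 * cos(g)     + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.001480 * sin(3 * g)

  phi <- latitude * pi / 180
  cos_zenith <- cos(90.833 * pi / 180)
  cos_ha <- (cos_zenith - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))

  ifelse(cos_ha <= -1, 24,
         ifelse(cos_ha >= 1, 0,
                2 * acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi / 15))
}
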