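# Vegetation indices from 8-day composite surface reflectance:
# NDVI, EVI, LSWI plus QC screening and gap-filling of the index series.

#' Normalized difference vegetation index
#'
#' `NDVI = (rho_nir - rho_red) / (rho_nir + rho_red)`.
#'
#' @param rho_nir,rho_red Surface reflectance of the near-infrared
#'   (841-875 nm) and red bands, dimensionless 0-1.
#' @return NDVI in \[-1, 1\].
#' @export
ndvi <- function(rho_nir, rho_red) {
  denom <- rho_nir + rho_red
  if (any(denom == 0, na.rm = TRUE)) {
    stop_neeflux("undefined_ratio", "NDVI undefined: rho_nir + rho_red = 0")
  }
  (rho_nir - rho_red) / denom
}

#' Enhanced vegetation index
#'
#' `EVI = G (rho_nir - rho_red) / (L + rho_nir + C1 rho_red - C2 rho_blue)`
#' with the standard MODIS coefficients G = 2.5, C1 = 6, C2 = 7.5, L = 1.
#'
#' @param rho_nir,rho_red,rho_blue Band surface reflectances, 0-1.
#' @param g,c1,c2,l EVI coefficients (defaults are the MODIS standard values).
#' @return EVI (dimensionless; not bounded to \[-1, 1\]).
#' @export
evi <- function(rho_nir, rho_red, rho_blue, g = 2.5, c1 = 6, c2 = 7.5, l = 1) {
  denom <- l + rho_nir + c1 * rho_red - c2 * rho_blue
  if (any(denom == 0, na.rm = TRUE)) {
    stop_neeflux("undefined_ratio", "EVI undefined: denominator = 0")
  }
  g * (rho_nir - rho_red) / denom
}

#' Land surface water index
#'
#' `LSWI = (rho_nir - rho_swir) / (rho_nir + rho_swir)` using the
#' 1628-1652 nm shortwave-infrared band.
#'
#' @param rho_nir,rho_swir Band surface reflectances, 0-1.
#' @return LSWI in \[-1, 1\].
#' @export
lswi <- function(rho_nir, rho_swir) {
  denom <- rho_nir + rho_swir
  if (any(denom == 0, na.rm = TRUE)) {
    stop_neeflux("undefined_ratio", "LSWI undefined: rho_nir + rho_swir = 0")
  }
  (rho_nir - rho_swir) / denom
}

#' Build a quality-screened, gap-filled vegetation-index series
#'
#' Computes NDVI, EVI and LSWI for every 8-day composite slot spanned by the
#' input reflectance table. Slots whose record fails QC (or is missing, or has
#' reflectance outside \[0, 1\]) are filled per index by linear interpolation
#' between the nearest valid neighbours; leading/trailing gaps take the
#' nearest valid value. Filled slots are flagged. Direct (QC-passing) values
#' are never altered by the filling step.
#'
#' @param refl Data frame with columns `date` (coercible to `Date`, one row
#'   per 8-day composite), `rho_blue`, `rho_red`, `rho_nir`, `rho_swir`
#'   (reflectance 0-1) and logical `qc_ok`.
#' @param fill `"linear"` (default: interpolate/extend as described) or
#'   `"none"` (leave failing slots as `NA`).
#' @param evi_constants Named list overriding the EVI coefficients
#'   (`g`, `c1`, `c2`, `l`).
#' @return Data frame with one row per 8-day slot of the covered period:
#'   `date`, `ndvi`, `evi`, `lswi`, logical `filled`.
#' @export
build_index_series <- function(refl, fill = c("linear", "none"),
                               evi_constants = list()) {
  fill <- match.arg(fill)
  ec <- utils::modifyList(list(g = 2.5, c1 = 6, c2 = 7.5, l = 1), evi_constants)
  if (is.null(refl) || nrow(refl) == 0) {
    stop_neeflux("empty_input", "no reflectance records supplied")
  }
  need <- c("date", "rho_blue", "rho_red", "rho_nir", "rho_swir", "qc_ok")
  miss <- setdiff(need, names(refl))
  if (length(miss)) {
    stop_neeflux("missing_column",
                 paste("reflectance table missing column(s):",
                       paste(miss, collapse = ", ")))
  }
  refl$date <- as.Date(refl$date)
  refl <- refl[order(refl$date), , drop = FALSE]

  slots <- composite_slots(min(refl$date), max(refl$date))
  i <- match(slots, slot_start(refl$date))

  bands <- c("rho_blue", "rho_red", "rho_nir", "rho_swir")
  in_range <- rowSums(sapply(bands, function(b) {
    is.na(refl[[b]]) | refl[[b]] < 0 | refl[[b]] > 1
  })) == 0
  usable <- refl$qc_ok & in_range &
    (refl$rho_nir + refl$rho_red) > 0 &
    (refl$rho_nir + refl$rho_swir) > 0 &
    (ec$l + refl$rho_nir + ec$c1 * refl$rho_red - ec$c2 * refl$rho_blue) != 0
  if (!any(usable[stats::na.omit(i)])) {
    stop_neeflux("all_bad", "no reflectance record passes quality screening")
  }

  ok <- !is.na(i) & usable[i]
  out <- data.frame(
    date = slots,
    ndvi = NA_real_, evi = NA_real_, lswi = NA_real_,
    filled = !ok
  )
  ri <- i[ok]
  out$ndvi[ok] <- ndvi(refl$rho_nir[ri], refl$rho_red[ri])
  out$evi[ok]  <- evi(refl$rho_nir[ri], refl$rho_red[ri], refl$rho_blue[ri],
                      g = ec$g, c1 = ec$c1, c2 = ec$c2, l = ec$l)
  out$lswi[ok] <- lswi(refl$rho_nir[ri], refl$rho_swir[ri])

  if (fill == "linear") {
    x <- seq_along(slots)
    for (col in c("ndvi", "evi", "lswi")) {
      y <- out[[col]]
      if (anyNA(y)) {
        if (sum(!is.na(y)) == 1) {
          out[[col]] <- rep(y[!is.na(y)], length(y))
        } else {
          # rule = 2: nearest-value extension beyond the first/last valid slot
          out[[col]] <- stats::approx(x[!is.na(y)], y[!is.na(y)], xout = x,
                                      method = "linear", rule = 2)$y
        }
      }
    }
  }
  out
}
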