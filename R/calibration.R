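#' Fit the refractive-index to buoyant-density standard curve
#'
#' Gradient fractions are assayed on a refractometer; buoyant density (BD,
#' g/ml) is then obtained from the refractive index (RI) through a linear
#' standard curve built from serial dilutions of the CsCl solution. This fits
#' density on refractive index by unweighted ordinary least squares.
#'
#' @param standards `data.frame` with numeric columns `refractive_index`
#'   (dimensionless, physically in (1.3, 1.5) for CsCl work) and
#'   `density_g_per_ml` (in (1.0, 2.0)).
#' @return A [CalibrationModel-class] with slots `slope`, `intercept`, `r`
#'   (Pearson correlation) and `n_points`.
#' @examples
#' std <- data.frame(refractive_index = c(1.39, 1.41, 1.43),
#'                   density_g_per_ml = c(1.57278, 1.77882, 1.98486))
#' fitDensityCalibration(std)
#' @export
fitDensityCalibration <- function(standards) {
  standards <- as.data.frame(standards)
  need <- c("refractive_index", "density_g_per_ml")
  if (!all(need %in% colnames(standards)))
    stop("standards must have columns 'refractive_index' and 'density_g_per_ml'")
  ri <- as.numeric(standards$refractive_index)
  bd <- as.numeric(standards$density_g_per_ml)
  if (anyNA(ri) || anyNA(bd)) stop("standards contain missing values")
  if (length(ri) < 2L) stop("degenerate fit: need at least 2 standards")
  if (diff(range(ri)) == 0)
    stop("degenerate fit: all refractive indices identical")
  if (any(ri <= 1.3 | ri >= 1.5))
    warning("refractive index outside the usual CsCl range (1.3, 1.5)")
  if (any(bd <= 1.0 | bd >= 2.0))
    warning("density outside the usual CsCl range (1.0, 2.0) g/ml")
  if (diff(range(bd)) == 0)
    stop("degenerate fit: zero slope (densities do not vary with RI)")
  fit <- lm(bd ~ ri)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope == 0)
    stop("degenerate fit: zero slope (densities do not vary with RI)")
  r <- cor(ri, bd)
  methods::new("CalibrationModel", slope = slope,
               intercept = unname(coef(fit)[1L]),
               r = r, n_points = length(ri))
}

#' The bundled default standard curve
#'
#' The conventional published coefficients BD = 10.302 * RI - 12.747
#' (r = 0.99), for users with no standards table of their own.
#'
#' @return A [CalibrationModel-class].
#' @examples
#' riToBD(1.4040, defaultCalibration())
#' @export
defaultCalibration <- function() {
  methods::new("CalibrationModel", slope = 10.302, intercept = -12.747,
               r = 0.99, n_points = 2L)
}

#' Convert refractive index to buoyant density
#'
#' @param ri numeric vector of refractive indices.
#' @param model a [CalibrationModel-class]; defaults to [defaultCalibration()].
#' @return buoyant densities in g/ml (`slope * ri + intercept`). Values
#'   outside (1.0, 2.0) g/ml trigger a warning, not an error.
#' @export
riToBD <- function(ri, model = defaultCalibration()) {
  stopifnot(methods::is(model, "CalibrationModel"))
  bd <- model@slope * as.numeric(ri) + model@intercept
  if (any(bd <= 1.0 | bd >= 2.0, na.rm = TRUE))
    warning("computed buoyant density outside (1.0, 2.0) g/ml")
  bd
}

#' Convert buoyant density back to refractive index
#'
#' Inverse of [riToBD()]; convenient for placing synthetic standards.
#'
#' @inheritParams riToBD
#' @param bd numeric vector of buoyant densities (g/ml).
#' @return refractive indices.
#' @export
bdToRI <- function(bd, model = defaultCalibration()) {
  stopifnot(methods::is(model, "CalibrationModel"))
  (as.numeric(bd) - model@intercept) / model@slope
}

#' Read a calibration standards table
#'
#' @param path TSV with header columns `refractive_index`, `density_g_per_ml`.
#' @return data.frame of standards.
#' @export
readCalibrationStandards <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("refractive_index", "density_g_per_ml")
  if (!all(need %in% colnames(df)))
    stop("standards file must have header columns: ",
         paste(need, collapse = ", "))
  df
}

#' Serialize a calibration model to YAML
#'
#' @param model a [CalibrationModel-class].
#' @param path output file; written with keys slope, intercept, r, n_points.
#' @return `path`, invisibly.
#' @export
writeCalibrationModel <- function(model, path) {
  stopifnot(methods::is(model, "CalibrationModel"))
  yaml::write_yaml(list(slope = model@slope, intercept = model@intercept,
                        r = model@r, n_points = model@n_points), path)
  invisible(path)
}
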