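#' Default Raman band model for the asphyxia study
#'
#' The thirteen fingerprint-region bands used by the generator, with their
#' vibrational-mode assignments and the physiological driver that scales
#' each band's amplitude: `lactate` bands scale linearly with blood lactate
#' concentration, `oxyHb` bands with the latent blood-oxygenation fraction,
#' `deoxyHb` bands with its complement, and `protein` bands are constant.
#' Line shape is pseudo-Voigt (default mixing 0.5) with a common default
#' width (FWHM, cm^-1).
#'
#' @param fwhm full width at half maximum of every band, cm^-1.
#' @param eta pseudo-Voigt Lorentzian mixing fraction in \[0, 1\].
#'
#' @return `data.frame` with columns `center` (cm^-1), `width` (FWHM,
#'   cm^-1), `amplitude` (base peak height, arbitrary units), `driver`,
#'   `mode`, `molecule`, `eta`.
#' @examples
#' ramanBands()
#' @export
ramanBands <- function(fwhm = 12, eta = 0.5) {
  b <- data.frame(
    center = c(543, 571, 620, 853, 1005, 1053, 1124, 1127, 1222, 1420,
               1459, 1547, 1639),
    amplitude = c(0.45, 0.35, 0.30, 0.60, 0.80, 0.45, 0.40, 0.35, 0.55,
                  0.40, 0.45, 0.60, 0.50),
    driver = c("lactate", "oxyHb", "protein", "lactate", "protein",
               "lactate", "lactate", "deoxyHb", "oxyHb", "lactate",
               "lactate", "deoxyHb", "oxyHb"),
    mode = c("CO2- wagging", "Fe-O2 stretching", "C-C twisting",
             "C-C aliphatic stretching", "phenylalanine breathing",
             "C-CH3 stretching", "CH3 rocking / C-O vibration",
             "C(beta)-methyl vibration", "CH bending", "COO- stretching",
             "CH3 deformation", "C(beta)C(beta) stretching",
             "C(alpha)C(m) asymmetric stretching"),
    molecule = c("lactate", "hemoglobin", "protein denaturation",
                 "lactate", "protein", "lactate", "lactate", "hemoglobin",
                 "hemoglobin", "lactate", "lactate", "hemoglobin",
                 "hemoglobin"),
    stringsAsFactors = FALSE)
  b$width <- fwhm
  b$eta <- eta
  b[, c("center", "width", "amplitude", "driver", "mode", "molecule",
        "eta")]
}

#' Pseudo-Voigt line profile
#'
#' Convex mix of a Lorentzian and a Gaussian of equal FWHM, normalized to
#' unit peak height.
#'
#' @param x evaluation points (cm^-1).
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param eta Lorentzian fraction in \[0, 1\].
#' @return numeric vector, `length(x)`.
#' @export
pseudoVoigt <- function(x, center, fwhm, eta = 0.5) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u <- (x - center) / (fwhm / 2)
  lor <- 1 / (1 + u^2)
  gau <- exp(-log(2) * u^2)
  eta * lor + (1 - eta) * gau
}
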