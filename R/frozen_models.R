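## Published six-variable surface-tension model for binary deep eutectic
## solvents, stored at printed precision. sigma in mN/m, T in kelvin.
M12_COEFFICIENTS <- c(
  "P_VSA_MR_6_pmix"    =   0.405,
  "Eig02_EA(dm)_pmix"  =  -5.034,
  "CATS2D_02_AN_pmix"  = -23.145,
  "BLTF96_pmix"        =   8.835,
  "MATS5s_nmix"        = -25.191,
  "temperature"        =  -0.104
)
M12_INTERCEPT <- 89.611

#' Predict DES surface tension with the frozen M12 model
#'
#' Ready-to-use six-variable linear model for the surface tension of
#' binary deep eutectic solvents:
#' \deqn{\sigma = 89.611 + 0.405\,PVSA\_MR\_6_{pmix}
#'   - 5.034\,Eig02\_EA(dm)_{pmix} - 23.145\,CATS2D\_02\_AN_{pmix}
#'   + 8.835\,BLTF96_{pmix} - 25.191\,MATS5s_{nmix} - 0.104\,T}
#' The five molecular inputs are molar-fraction-weighted mixture
#' descriptors (see [pmix()]/[nmix()]) built from Dragon-style
#' per-component values: a P_VSA-like descriptor on molar refractivity at
#' bin 6, edge-adjacency eigenvalue 2 weighted by dipole moment, the
#' CATS2D acceptor-negative count at lag 2, the Verhaar fish baseline
#' toxicity from MLOGP, and the Moran autocorrelation of lag 5 weighted by
#' intrinsic state. `T` is the measurement temperature in kelvin; the
#' prediction decreases by 0.104 mN/m per kelvin.
#'
#' @param newdata data frame with columns `P_VSA_MR_6_pmix`,
#'   `Eig02_EA(dm)_pmix`, `CATS2D_02_AN_pmix`, `BLTF96_pmix`,
#'   `MATS5s_nmix`, `temperature`.
#' @return Numeric vector of surface tensions (mN/m).
#' @export
predict_sigma_m12 <- function(newdata) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  missing_cols <- setdiff(names(M12_COEFFICIENTS), names(newdata))
  if (length(missing_cols) > 0) {
    stop("missing M12 input column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[, names(M12_COEFFICIENTS), drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite M12 input", call. = FALSE)
  drop(M12_INTERCEPT + x %*% M12_COEFFICIENTS)
}

#' Load the shipped M12 model as a generic linear model
#'
#' Deserializes the bundled model JSON (coefficients at printed precision,
#' standard errors as metadata) into a `linear_model`, so that the generic
#' [predict.linear_model()] machinery and the dedicated
#' [predict_sigma_m12()] shortcut agree exactly.
#'
#' @return A `linear_model`.
#' @export
m12_model <- function() {
  read_model(system.file("extdata", "m12_model.json", package = "mixqspr",
                         mustWork = TRUE))
}
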