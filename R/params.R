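# Dimensionless parameter set ----------------------------------------------

.param_fields <- c("e1", "e2", "e3", "e4", "e5", "Omega", "G1", "G2",
                   "S1", "S2", "Rn", "Pr", "eps", "phi", "We", "alpha", "n")

.preset_default <- list(
  e1 = 0.3, e2 = 0.7, e3 = 0.5, e4 = 0.5, e5 = 0.2,
  Omega = 0.5, G1 = 2, G2 = 1, S1 = 0.7, S2 = 0.3,
  Rn = 0.5, Pr = 1.7, eps = 0.2, phi = 0.15,
  We = 0.2, alpha = 0.1, n = 0.3
)

#' Dimensionless parameters of the peristaltic Carreau model
#'
#' Builds and validates the full set of dimensionless groups governing the
#' flow: the five elastic-wall coefficients `e1`--`e5` (flexural stiffness,
#' longitudinal tension, wall mass per area, viscous damping, spring
#' stiffness), the heat source/sink parameter `Omega`, thermal and solutal
#' Grashof numbers `G1`/`G2`, Soret and Schmidt numbers `S1`/`S2`, the
#' radiation parameter `Rn`, Prandtl number `Pr`, the catheter radius ratio
#' `eps`, wave amplitude ratio `phi`, Weissenberg number `We`, the
#' viscosity-variation coefficient `alpha` (Reynolds viscosity law,
#' truncated to `1 - alpha * H`), and the Carreau power-law index `n`.
#'
#' The defaults are the reference configuration used throughout the
#' package's worked examples and checks.
#'
#' @param e1,e2,e3,e4,e5 Elastic-wall coefficients (dimensionless).
#' @param Omega Heat source/sink parameter, must be `>= 0`.
#' @param G1,G2 Thermal and solutal Grashof numbers.
#' @param S1 Soret number. @param S2 Schmidt number, must be `> 0`.
#' @param Rn Thermal radiation parameter, `> 0`.
#' @param Pr Prandtl number, `> 0`.
#' @param eps Inner (catheter) radius as a fraction of the mean outer
#'   radius; requires `0 < eps < 1 - phi`.
#' @param phi Wave amplitude ratio, `>= 0`.
#' @param We Weissenberg number, `>= 0`.
#' @param alpha Viscosity-variation coefficient; the Maclaurin truncation
#'   of the Reynolds law requires `0 <= alpha < 1`.
#' @param n Carreau power-law index (`n < 1` is shear thinning; `n = 1`
#'   recovers a Newtonian fluid).
#' @return An object of class `carreau_params` (a validated named list).
#' @examples
#' p <- carreau_params()            # reference configuration
#' p2 <- carreau_params(We = 0.05)  # one-off variation
#' @export
carreau_params <- function(e1 = 0.3, e2 = 0.7, e3 = 0.5, e4 = 0.5,
                           e5 = 0.2, Omega = 0.5, G1 = 2, G2 = 1,
                           S1 = 0.7, S2 = 0.3, Rn = 0.5, Pr = 1.7,
                           eps = 0.2, phi = 0.15, We = 0.2,
                           alpha = 0.1, n = 0.3) {
  validate_params(mget(.param_fields))
}

#' Validate a raw parameter mapping
#'
#' Checks that `raw` contains exactly the model's parameter fields, all
#' numeric and finite, and that every physical invariant holds. Violations
#' raise an error naming the offending field.
#'
#' @param raw A named list or named numeric vector with one entry per
#'   parameter field (see [carreau_params()]).
#' @return A `carreau_params` object.
#' @export
validate_params <- function(raw) {
  if (is.numeric(raw) && !is.null(names(raw))) raw <- as.list(raw)
  if (!is.list(raw)) stop("`raw` must be a named list or named numeric vector")
  unknown <- setdiff(names(raw), .param_fields)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.param_fields, names(raw))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  p <- lapply(raw[.param_fields], function(v) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("every parameter must be a single finite number")
    as.numeric(v)
  })
  chk <- function(ok, msg) if (!ok) stop("invalid parameters: ", msg, call. = FALSE)
  chk(p$Pr > 0,    "Pr must be > 0")
  chk(p$Rn > 0,    "Rn must be > 0")
  chk(p$S2 > 0,    "S2 must be > 0")
  chk(p$Omega >= 0, "Omega must be >= 0")
  chk(p$We >= 0,   "We must be >= 0")
  chk(p$alpha >= 0, "alpha must be >= 0")
  chk(p$alpha < 1,  "alpha must be < 1 (Maclaurin truncation of the viscosity law)")
  chk(p$phi >= 0,  "phi must be >= 0")
  chk(p$eps > 0,   "eps must be > 0")
  chk(p$eps < 1 - p$phi,
      "eps must be < 1 - phi (catheter must not touch the deformed wall)")
  structure(p, class = "carreau_params")
}

#' Named parameter presets
#'
#' `"default"` is the reference configuration (see [carreau_params()]);
#' `"newtonian"` is the same geometry and thermal setup with the
#' constitutive nonlinearity switched off (`We = 0`, `alpha = 0`, `n = 1`).
#'
#' @param name Preset name.
#' @return A `carreau_params` object.
#' @export
carreau_preset <- function(name = c("default", "newtonian")) {
  name <- match.arg(name)
  p <- .preset_default
  if (name == "newtonian") {
    p$We <- 0; p$alpha <- 0; p$n <- 1
  }
  validate_params(p)
}

#' Read parameters from a flat YAML or JSON config file
#'
#' The file holds one key per parameter field; keys not in the model are an
#' error. Missing fields are filled from the `"default"` preset, so a
#' config may specify only the values it overrides.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param overrides Optional named list applied on top of the file
#'   (command-line flags take precedence over the config).
#' @return A `carreau_params` object.
#' @export
read_params_config <- function(path, overrides = list()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) raw <- as.list(raw)
  unknown <- setdiff(names(raw), .param_fields)
  if (length(unknown))
    stop("unknown key(s) in config: ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(.preset_default, raw)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), .param_fields)
    if (length(unknown))
      stop("unknown override(s): ", paste(unknown, collapse = ", "))
    p <- utils::modifyList(p, overrides)
  }
  validate_params(p)
}

#' @export
print.carreau_params <- function(x, ...) {
  cat("Peristaltic Carreau model parameters\n")
  cat("  wall:     e1 =", x$e1, " e2 =", x$e2, " e3 =", x$e3,
      " e4 =", x$e4, " e5 =", x$e5, "\n")
  cat("  thermal:  Omega =", x$Omega, " Pr =", x$Pr, " Rn =", x$Rn, "\n")
  cat("  solutal:  S1 =", x$S1, " S2 =", x$S2, "\n")
  cat("  buoyancy: G1 =", x$G1, " G2 =", x$G2, "\n")
  cat("  geometry: eps =", x$eps, " phi =", x$phi, "\n")
  cat("  rheology: We =", x$We, " alpha =", x$alpha, " n =", x$n, "\n")
  invisible(x)
}
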