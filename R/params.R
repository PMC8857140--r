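#' @useDynLib biofilmosc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor lm coef runif setNames
#' @importFrom utils write.csv head tail modifyList packageVersion
NULL

# Master table of model constants.  `default` is in paper units; `per_day`
# marks the diffusivities (mm^2/day in the source table) that the internal
# unit system {mm, hour, mM, mV} divides by 24.  `positive` marks quantities
# whose validity demands strict positivity.  `sens` marks constants included
# in the sensitivity protocol (the reporter constants are excluded: they do
# not feed back on the dynamics).
.param_table <- function() {
  p <- function(name, default, unit, positive, per_day = FALSE, sens = TRUE, desc = "") {
    data.frame(name = name, default = default, unit = unit, positive = positive,
               per_day = per_day, sens = sens, desc = desc, stringsAsFactors = FALSE)
  }
  rbind(
    p("D_G",       0.540,  "mm^2/day", TRUE, TRUE,  TRUE,  "glutamate diffusivity in biofilm"),
    p("D_K",       0.497,  "mm^2/day", TRUE, TRUE,  TRUE,  "potassium diffusivity in biofilm"),
    p("D_G_fl",    0.900,  "mm^2/day", TRUE, TRUE,  TRUE,  "glutamate diffusivity in fluid"),
    p("D_K_fl",    4.97,   "mm^2/day", TRUE, TRUE,  TRUE,  "potassium diffusivity in fluid"),
    p("G0",        30,     "mM",       TRUE, FALSE, TRUE,  "inlet glutamate concentration"),
    p("K0",        8,      "mM",       TRUE, FALSE, TRUE,  "inlet potassium concentration"),
    p("delta_G",   10,     "1/hour",   TRUE, FALSE, TRUE,  "glutamate uptake rate"),
    p("V_th",      -150,   "mV",       FALSE, FALSE, TRUE, "voltage above which uptake shuts off"),
    p("G_max",     20,     "mM",       TRUE, FALSE, TRUE,  "maximum internal glutamate"),
    p("F",         5.6,    "mM/mV",    TRUE, FALSE, TRUE,  "voltage-to-potassium conversion factor"),
    p("g_K",       180,    "1/hour",   TRUE, FALSE, TRUE,  "potassium gate strength"),
    p("g_L",       1.2,    "1/hour",   TRUE, FALSE, TRUE,  "leak gate strength"),
    p("gamma_K",   0.025,  "1/(hour*mM)", TRUE, FALSE, TRUE, "potassium pump strength"),
    p("B_L",       0.5,    "mm",       TRUE, FALSE, TRUE,  "boundary-layer length"),
    p("gamma_G",   1.125,  "1/hour",   TRUE, FALSE, TRUE,  "glutamate consumption rate"),
    p("r_b",       0.1,    "1",        FALSE, FALSE, TRUE, "basal consumption fraction"),
    p("G_u",       18,     "mM",       TRUE, FALSE, TRUE,  "glutamate bound below which cells do not grow"),
    p("eta_V",     20,     "1",        TRUE, FALSE, TRUE,  "voltage influence in grow mode"),
    p("gamma_V",   20,     "1",        TRUE, FALSE, TRUE,  "voltage transition speed in grow mode"),
    p("V_low",     -175,   "mV",       FALSE, FALSE, TRUE, "voltage below which cells do not grow"),
    p("delta_grow", 0.0075, "mm/(mM*hour)", TRUE, FALSE, TRUE, "growth yield"),
    p("eta_K",     30,     "1/hour",   TRUE, FALSE, TRUE,  "acclimation rate to potassium change"),
    p("alpha",     5,      "1/hour",   TRUE, FALSE, TRUE,  "potassium gate opening rate"),
    p("beta",      2.5,    "1/hour",   TRUE, FALSE, TRUE,  "potassium gate closing rate"),
    p("m",         2,      "1",        TRUE, FALSE, TRUE,  "gate-opening Hill exponent"),
    p("G_l",       10,     "mM",       TRUE, FALSE, TRUE,  "glutamate level below which cells hyperpolarize"),
    p("V_K0",      -380,   "mV",       FALSE, FALSE, TRUE, "basal potassium gate reversal potential"),
    p("V_L0",      -156,   "mV",       FALSE, FALSE, TRUE, "basal leak gate reversal potential"),
    p("delta_K",   1,      "mV/mM",    TRUE, FALSE, TRUE,  "potassium gate reversal change"),
    p("delta_L",   60,     "mV/mM",    TRUE, FALSE, TRUE,  "leak gate reversal change"),
    p("alpha_T",   20,     "mM/hour",  TRUE, FALSE, FALSE, "ThT fluorescence strength"),
    p("g_T",       0.3,    "1/mV",     TRUE, FALSE, FALSE, "ThT voltage sensitivity"),
    p("V_0T",      -170,   "mV",       FALSE, FALSE, FALSE, "voltage below which ThT fluoresces"),
    p("gamma_T",   10,     "1/hour",   TRUE, FALSE, FALSE, "ThT decay rate"),
    p("alpha_A",   0.5,    "1/hour",   TRUE, FALSE, FALSE, "APG fluorescence strength"),
    p("gamma_A",   1,      "1/hour",   TRUE, FALSE, FALSE, "APG decay rate"),
    p("K_max",     300,    "mM",       TRUE, FALSE, FALSE, "internal-potassium pump threshold"),
    p("mu",        1,      "1",        TRUE, FALSE, FALSE, "fluid viscosity (2D; rescales pressure only)"),
    p("u0",        90,     "mm/hour",  FALSE, FALSE, FALSE, "inlet centerline fluid speed (2D)")
  )
}

#' Model constants with defaults
#'
#' Returns the full set of model constants, either in "paper" units (the
#' published table mixes per-day diffusivities with per-hour rates) or
#' normalized to the internal unit system \{mm, hour, mM, mV\}.
#'
#' `K_max`, the internal-potassium level at which the active pump switches
#' off, is not tabulated in the source; its default of 300 mM equals the
#' homeostatic initial internal potassium, so the pump sits exactly at its
#' off threshold at the initial condition.  `mu` only rescales the pressure
#' field under the velocity boundary conditions used, and defaults to 1.
#'
#' @param overrides named list of parameter overrides (in `units`).
#' @param units unit system of the returned set (and of `overrides`):
#'   `"internal"` (default) or `"paper"`.
#' @return a named list of class `biofilm_params` with a `units` attribute.
#' @export
#' @examples
#' p <- biofilm_params()
#' p$g_K               # 180 / hour
#' p$D_K               # 0.497 / 24 mm^2/hour
biofilm_params <- function(overrides = list(), units = c("internal", "paper")) {
  units <- match.arg(units)
  load_parameters(overrides, units_of_overrides = "paper") -> p
  if (identical(units, "paper")) denormalize_units(p) else p
}

#' Load parameters with overrides and validation
#'
#' Applies overrides to the published defaults, validates physical sanity
#' (positivity where required, `r_b` in \[0,1\], biofilm diffusivities not
#' exceeding fluid diffusivities under defaults) and normalizes to the
#' internal unit system.
#'
#' @param overrides named list; names must be parameter names.
#' @param units_of_overrides `"paper"` or `"internal"`.
#' @return `biofilm_params` list in internal units.
#' @export
load_parameters <- function(overrides = list(), units_of_overrides = c("paper", "internal")) {
  units_of_overrides <- match.arg(units_of_overrides)
  tab <- .param_table()
  p <- as.list(setNames(tab$default, tab$name))
  attr(p, "units") <- "paper"
  class(p) <- "biofilm_params"
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm)))
      stop("parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, tab$name)
    if (length(unknown)) {
      hint <- vapply(unknown, function(u) {
        cand <- tab$name[agrepl(u, tab$name, max.distance = 2, ignore.case = TRUE)]
        if (length(cand)) paste0(" (did you mean '", cand[[1]], "'?)") else ""
      }, character(1))
      stop("unknown parameter name(s): ",
           paste0("'", unknown, "'", hint, collapse = ", "), call. = FALSE)
    }
    bad <- nm[!vapply(overrides, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))]
    if (length(bad))
      stop("parameter override(s) must be finite numbers: ",
           paste0("'", bad, "'", collapse = ", "), call. = FALSE)
    if (units_of_overrides == "internal") {
      per_day <- tab$name[tab$per_day]
      for (k in intersect(nm, per_day)) overrides[[k]] <- overrides[[k]] * 24
    }
    for (k in nm) p[[k]] <- as.numeric(overrides[[k]])
  }
  validate_params(p)
  normalize_units(p)
}

#' Validate a parameter set
#'
#' Collects all invariant violations and raises a single error listing them.
#' @param p `biofilm_params` (either unit system).
#' @return invisibly `TRUE`.
#' @export
validate_params <- function(p) {
  tab <- .param_table()
  viol <- character(0)
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    v <- p[[nm]]
    if (is.null(v) || !is.finite(v))
      viol <- c(viol, sprintf("%s: missing or non-finite", nm))
    else if (tab$positive[i] && v <= 0)
      viol <- c(viol, sprintf("%s = %g must be strictly positive", nm, v))
  }
  if (!is.null(p$r_b) && is.finite(p$r_b) && (p$r_b < 0 || p$r_b > 1))
    viol <- c(viol, sprintf("r_b = %g must lie in [0, 1]", p$r_b))
  if (!is.null(p$m) && is.finite(p$m) && p$m <= 0)
    viol <- c(viol, sprintf("m = %g must be a positive number", p$m))
  if (!is.null(p$u0) && is.finite(p$u0) && p$u0 < 0)
    viol <- c(viol, sprintf("u0 = %g must be non-negative", p$u0))
  ok <- function(x) !is.null(x) && is.finite(x)
  if (ok(p$D_G) && ok(p$D_G_fl) && p$D_G > p$D_G_fl)
    viol <- c(viol, "D_G must not exceed D_G_fl")
  if (ok(p$D_K) && ok(p$D_K_fl) && p$D_K > p$D_K_fl)
    viol <- c(viol, "D_K must not exceed D_K_fl")
  if (length(viol))
    stop("invalid parameter set:\n  - ", paste(viol, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

#' Normalize a parameter set to internal units
#'
#' Converts the per-day diffusivities to mm^2/hour (division by 24); every
#' other constant is already expressed per hour.  Inverse of
#' [denormalize_units()].
#' @param p `biofilm_params` in paper units.
#' @return `biofilm_params` in internal \{mm, hour, mM, mV\} units.
#' @export
normalize_units <- function(p) {
  if (identical(attr(p, "units"), "internal")) return(p)
  for (k in .param_table()$name[.param_table()$per_day]) p[[k]] <- p[[k]] / 24
  attr(p, "units") <- "internal"
  p
}

#' @rdname normalize_units
#' @export
denormalize_units <- function(p) {
  if (identical(attr(p, "units"), "paper")) return(p)
  for (k in .param_table()$name[.param_table()$per_day]) p[[k]] <- p[[k]] * 24
  attr(p, "units") <- "paper"
  p
}

# Names of constants included in the sensitivity protocol (dynamics-relevant,
# reporter constants excluded).
#' Parameter names reported by the sensitivity analysis
#' @return character vector of 30 parameter names.
#' @export
sensitivity_parameters <- function() {
  tab <- .param_table()
  tab$name[tab$sens]
}

#' @export
print.biofilm_params <- function(x, ...) {
  cat("biofilm model parameters (", attr(x, "units"), " units): ",
      length(unclass(x)), " constants\n", sep = "")
  tab <- .param_table()
  for (nm in tab$name) cat(sprintf("  %-10s %12.6g  %s\n", nm, x[[nm]], tab$desc[tab$name == nm]))
  invisible(x)
}
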