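#' Model parameters
#'
#' Construct the full parameter set of the two-species water-limited
#' vegetation model. Species 1 is the clonal shrub (nonlocal water uptake by
#' laterally extended roots, root-sucker sprouting at a distance); species 2
#' is the sedge (locally confined roots, short-range seed dispersal). Water
#' fields are in kg/m^2 with the convention 1 mm of rainfall = 1 kg/m^2, so
#' the precipitation rate `P` in mm/y enters the water balance unscaled.
#'
#' Defaults are the reference set for the low-altitude shrubland
#' (unchanged values reproduce the reference table exactly).
#'
#' @param P precipitation rate, mm/y.
#' @param E1,E2 lateral root augmentation per unit aboveground biomass, m^2/kg.
#'   The root-zone width of species i grows as `S_i(B) = SG_i * (1 + E_i * B)`.
#' @param K1,K2 maximum standing biomass, kg/m^2.
#' @param M1,M2 biomass decay rate (mortality etc.), 1/y.
#' @param N evaporation rate in bare soil, 1/y.
#' @param Lam1,Lam2 biomass-growth coefficient per unit soil water, (1/mm)/y.
#' @param Gam1,Gam2 water-uptake coefficient per unit biomass, (m^2/kg)/y.
#' @param R1,R2 evaporation reduction by shading, dimensionless, in `[0, 1)`.
#' @param Th1 potential root-sucker growth rate of the shrub, 1/y.
#' @param Th2 potential dispersal rate of the sedge, 1/y.
#' @param DW lateral soil-water diffusion rate, m^2/y.
#' @param SG1 lateral root-system size of shrub seedlings, m.
#' @param SD1 width of the shrub's potential root-sucker distribution, m.
#' @param SD2 characteristic dispersal range of the sedge, m.
#' @param Wstar1,Wstar2 soil-water content at half the potential sucker growth
#'   / dispersal rate, kg/m^2.
#' @param cyperus_local if `TRUE`, the sedge dispersal term is purely local
#'   (unit-mass delta kernel) instead of the fat-tailed kernel of width `SD2`.
#'   Uniform equilibria are unaffected by this switch.
#' @return An object of class `veg_params` (a named list).
#' @export
#' @examples
#' p <- veg_params(P = 1000)
#' p$E1
veg_params <- function(P = 1500,
                       E1 = 16, E2 = 5,
                       K1 = 0.7, K2 = 0.35,
                       M1 = 7.05, M2 = 7.05,
                       N = 15,
                       Lam1 = 0.06, Lam2 = 0.16,
                       Gam1 = 15, Gam2 = 5,
                       R1 = 0.1, R2 = 0.1,
                       Th1 = 3.125, Th2 = 3.125,
                       DW = 0.5,
                       SG1 = 0.5, SD1 = 0.5, SD2 = 0.01,
                       Wstar1 = 0.5, Wstar2 = 2.0,
                       cyperus_local = FALSE) {
  p <- list(P = P, E1 = E1, E2 = E2, K1 = K1, K2 = K2, M1 = M1, M2 = M2,
            N = N, Lam1 = Lam1, Lam2 = Lam2, Gam1 = Gam1, Gam2 = Gam2,
            R1 = R1, R2 = R2, Th1 = Th1, Th2 = Th2, DW = DW,
            SG1 = SG1, SD1 = SD1, SD2 = SD2,
            Wstar1 = Wstar1, Wstar2 = Wstar2,
            cyperus_local = isTRUE(cyperus_local))
  class(p) <- "veg_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  strict_pos <- c("P", "K1", "K2", "M1", "M2", "N", "Lam1", "Lam2",
                  "Gam1", "Gam2", "Th1", "Th2", "DW", "SG1", "SD1", "SD2",
                  "Wstar1", "Wstar2")
  for (nm in strict_pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single strictly positive number")
  }
  for (nm in c("E1", "E2")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("parameter '", nm, "' must be >= 0")
  }
  for (nm in c("R1", "R2")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1)
      stop("parameter '", nm, "' must satisfy 0 <= R < 1")
  }
  invisible(p)
}

#' @export
print.veg_params <- function(x, ...) {
  cat("<veg_params>\n")
  num <- x[vapply(x, is.numeric, logical(1))]
  cat(paste0("  ", format(names(num), width = 7), " = ",
             vapply(num, format, character(1))), sep = "\n")
  cat("  cyperus_local =", x$cyperus_local, "\n")
  invisible(x)
}

# Named presets. "default" is the reference table (low-altitude phenotype,
# P left at 1500 mm/y); "low_altitude" fixes P = 1000 mm/y inside the
# sedge/shrub-pattern bistability range; "high_altitude" is the short-root
# phenotype (E1 = 5, SD1 = 0.01) at P = 1600 mm/y; "weak_feedback" is the
# non-pattern-forming control with root augmentation too weak for patterning
# (E1 = 2, with the accompanying adjustments).
preset_overrides <- list(
  default       = list(),
  low_altitude  = list(P = 1000, E1 = 16, SD1 = 0.5),
  high_altitude = list(P = 1600, E1 = 5, SD1 = 0.01),
  weak_feedback = list(P = 1400, E1 = 2, K1 = 1.75, M1 = 9.05, M2 = 9.05,
                       Lam1 = 0.08, Lam2 = 0.08, Gam1 = 5,
                       SG1 = 0.01, SD1 = 0.1, Wstar2 = 0.5, DW = 1)
)

#' Parameter presets
#'
#' Named parameter presets used throughout the analyses. `preset_params()`
#' builds one in memory; `load_preset()` reads the same preset from the
#' plain-text config shipped in `inst/extdata/presets/` (key: value lines),
#' which serves as the serialized external interface.
#'
#' @param name one of `"default"`, `"low_altitude"`, `"high_altitude"`,
#'   `"weak_feedback"`.
#' @param ... overrides applied on top of the preset (e.g. `P = 1250`).
#' @return A [veg_params] object.
#' @export
preset_params <- function(name = c("default", "low_altitude", "high_altitude",
                                   "weak_feedback"), ...) {
  name <- match.arg(name)
  ov <- modifyList(preset_overrides[[name]], list(...))
  do.call(veg_params, ov)
}

#' @rdname preset_params
#' @param file path to a preset config file; by default resolved from the
#'   package's `extdata/presets` directory by `name`.
#' @export
load_preset <- function(name, file = NULL, ...) {
  if (is.null(file)) {
    file <- system.file("extdata", "presets", paste0(name, ".cfg"),
                        package = "rootpattern", mustWork = TRUE)
  }
  kv <- read_config(file)
  kv$name <- NULL
  ov <- modifyList(kv, list(...))
  do.call(veg_params, ov)
}

#' Read / write key-value config files
#'
#' The config dialect is one `key: value` pair per line; `#` starts a
#' comment; values are parsed as numbers or logicals where possible.
#'
#' @param file path.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) {
      out[[key]] <- num
    } else if (val %in% c("TRUE", "FALSE", "true", "false")) {
      out[[key]] <- as.logical(toupper(val))
    } else {
      out[[key]] <- val
    }
  }
  out
}

#' @rdname read_config
#' @param x a named list (or `veg_params`) to serialize.
#' @export
write_config <- function(x, file) {
  x <- unclass(x)
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 17) else as.character(v)
  }, character(1))
  writeLines(paste0(names(x), ": ", vals), file)
  invisible(file)
}
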