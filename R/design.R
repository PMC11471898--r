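#' @keywords internal
"_PACKAGE"

## Physical constants used throughout the gas and metric computations.
## R in J mol^-1 K^-1; atomic mass of N in g mol^-1.
GAS_CONSTANT <- 8.314
M_NITROGEN <- 14.007

AO_GROUPS <- c("AOA", "AOB", "CMX")

#' Describe a nitrification microcosm incubation
#'
#' A microcosm design captures the serum-bottle geometry, incubation
#' conditions, sampling timepoints, and — centrally — the nested inhibitor
#' scheme: an ordered set of treatments, each silencing a (growing) subset
#' of the ammonia-oxidizer groups AOA, AOB and CMX. The canonical
#' four-treatment design uses no inhibitor (control), 1-octyne (silences
#' AOB), DMPP (silences AOB and CMX) and low-concentration acetylene
#' (silences all three), so that successive treatment differences isolate
#' each group.
#'
#' @param bottle_volume Total serum-bottle volume in mL.
#' @param sample_mass Fresh sample mass in g.
#' @param sample_volume Volume displaced by the sample in mL; the headspace
#'   is `bottle_volume - sample_volume`.
#' @param temperature Incubation temperature in kelvin.
#' @param pressure Headspace pressure in kPa.
#' @param timepoints Destructive sampling times in hours, strictly
#'   increasing and starting at 0.
#' @param inhibitor_scheme Named list mapping treatment name to a character
#'   vector of inhibited groups (subset of `c("AOA","AOB","CMX")`), in
#'   treatment order. Sets must be nested along that order.
#'
#' @return An object of class `microcosm_design`.
#' @examples
#' d <- microcosm_design()
#' validate_design(d)  # character(0): the default design is valid
#' @export
microcosm_design <- function(bottle_volume = 50,
                             sample_mass = 2,
                             sample_volume = 2,
                             temperature = 298.15,
                             pressure = 101.325,
                             timepoints = c(0, 24, 48, 72),
                             inhibitor_scheme = list(
                               control   = character(0),
                               octyne    = "AOB",
                               dmpp      = c("AOB", "CMX"),
                               acetylene = c("AOA", "AOB", "CMX")
                             )) {
  design <- structure(
    list(
      bottle_volume = bottle_volume,
      sample_mass = sample_mass,
      sample_volume = sample_volume,
      temperature = temperature,
      pressure = pressure,
      timepoints = sort(unique(timepoints)),
      incubation_duration = max(timepoints),
      inhibitor_scheme = lapply(inhibitor_scheme, function(g) sort(unique(as.character(g))))
    ),
    class = "microcosm_design"
  )
  design
}

#' Validate a microcosm design
#'
#' Checks geometry (positive masses and volumes, headspace > 0), the
#' timepoint grid (strictly increasing from 0, at least two points) and the
#' inhibitor scheme (known group names, at least two treatments, inhibited
#' sets nested along treatment order). Violations are returned, not raised,
#' so callers can report them all at once.
#'
#' @param design A [microcosm_design()].
#' @return Character vector of violation messages; `character(0)` when the
#'   design satisfies every invariant.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "microcosm_design"))
  v <- character(0)
  if (!is.finite(design$sample_mass) || design$sample_mass <= 0)
    v <- c(v, "sample_mass must be > 0")
  if (!is.finite(design$sample_volume) || design$sample_volume < 0)
    v <- c(v, "sample_volume must be >= 0")
  if (!(design$bottle_volume > design$sample_volume))
    v <- c(v, sprintf("bottle_volume (%g mL) must exceed sample_volume (%g mL)",
                      design$bottle_volume, design$sample_volume))
  if (design$temperature <= 0) v <- c(v, "temperature must be > 0 K")
  if (design$pressure <= 0) v <- c(v, "pressure must be > 0 kPa")
  tp <- design$timepoints
  if (length(tp) < 2) v <- c(v, "at least two timepoints are required")
  if (length(tp) >= 1 && tp[1] != 0) v <- c(v, "timepoints must start at 0")
  if (any(diff(tp) <= 0)) v <- c(v, "timepoints must be strictly increasing")

  scheme <- design$inhibitor_scheme
  if (length(scheme) < 2) {
    v <- c(v, "inhibitor scheme needs >= 2 treatments")
  } else {
    bad <- unlist(lapply(scheme, function(g) setdiff(g, AO_GROUPS)))
    if (length(bad))
      v <- c(v, sprintf("unknown ammonia-oxidizer group(s): %s",
                        paste(unique(bad), collapse = ", ")))
    for (i in seq_len(length(scheme) - 1)) {
      a <- scheme[[i]]; b <- scheme[[i + 1]]
      if (!all(a %in% b))
        v <- c(v, sprintf(
          "inhibitor sets not nested: treatment '%s' {%s} is not a subset of '%s' {%s}",
          names(scheme)[i], paste(a, collapse = ","),
          names(scheme)[i + 1], paste(b, collapse = ",")))
    }
  }
  v
}

#' @export
print.microcosm_design <- function(x, ...) {
  cat("Microcosm design\n")
  cat(sprintf("  bottle %g mL, sample %g g (%g mL), headspace %g mL\n",
              x$bottle_volume, x$sample_mass, x$sample_volume,
              x$bottle_volume - x$sample_volume))
  cat(sprintf("  %g K, %g kPa, sampled at %s h\n",
              x$temperature, x$pressure, paste(x$timepoints, collapse = "/")))
  cat("  treatments:\n")
  for (nm in names(x$inhibitor_scheme)) {
    g <- x$inhibitor_scheme[[nm]]
    cat(sprintf("    %-12s inhibits {%s}\n", nm,
                if (length(g)) paste(g, collapse = ",") else ""))
  }
  invisible(x)
}

#' Read a microcosm design from a YAML config file
#'
#' The config mirrors the [microcosm_design()] arguments; units are fixed
#' (mL, g, kelvin, kPa, hours) and declared in the file for the reader's
#' benefit only.
#'
#' @param path Path to a YAML file.
#' @return A validated `microcosm_design`; invalid configs raise an error
#'   listing every violation.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        c("bottle_volume", "sample_mass", "sample_volume",
                          "temperature", "pressure", "timepoints",
                          "inhibitor_scheme"))]
  if (!is.null(args$timepoints)) args$timepoints <- as.numeric(args$timepoints)
  design <- do.call(microcosm_design, args)
  v <- validate_design(design)
  if (length(v)) stop("invalid design: ", paste(v, collapse = "; "))
  design
}
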