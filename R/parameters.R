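#' Model parameters for the origin-firing lattice simulation
#'
#' Bundles all tunable quantities of the nested replication models MM1-MM5.
#' The genome is a one-dimensional lattice of 1-kb blocks. Origin firing
#' requires an encounter with a limiting trans-acting factor whose copy
#' number grows linearly in time, `N(t) = N0 + J t` (t in rounds); a factor
#' is sequestered by the pair of forks created at firing and released when
#' the forks coalesce with converging neighbours.
#'
#' Model variants activate different parameters:
#' * `MM1`: mean-field firing at probability `Pout` everywhere; constant
#'   fork speed `v`.
#' * `MM2`: MM1, but each active fork independently draws its speed each
#'   round from \{0, 1, 2, 3\} kb/min.
#' * `MM3`: MM1 plus fork-proximal stimulation: the firing probability is
#'   `Plocal` within `d` kb downstream of an active fork.
#' * `MM4`: the genome is segmented so a fraction `theta` of blocks fires
#'   with probability `Pin` and the remainder with `Pout`.
#' * `MM5`: MM3 and MM4 combined (all parameters active).
#'
#' @param N0 Initial number of limiting factors (>= 0).
#' @param J Factor import/activation rate, in factors per simulation round.
#'   (The internal time unit is the round; see `round_minutes`.)
#' @param Pout Per-candidate per-round firing probability outside the
#'   high-probability fraction, in `[0, 1]`.
#' @param Pin Firing probability inside the high-probability fraction.
#' @param Plocal Firing probability within `d` kb downstream of a fork
#'   (MM3/MM5), replacing `Pin`/`Pout` there.
#' @param theta Fraction of the genome carrying `Pin`, in `[0, 1]`.
#' @param d Width of the fork-proximal stimulated zone, kb (integer >= 0).
#' @param v Fork speed in kb per minute (default 0.5).
#' @param variant One of `"MM1"` ... `"MM5"`.
#' @param origin_layout `"continuous"` (every block carries a potential
#'   origin) or `"discrete"` (potential origins are scattered at random).
#' @param mean_origin_spacing Mean spacing of potential origins in kb for
#'   the discrete layout. Defaults to 2.3 kb (discrete) or 1 kb
#'   (continuous).
#' @param round_minutes Minutes of real time per Monte Carlo round. The
#'   default of 2 min follows from symmetric 2-block eye growth per round
#'   at v = 0.5 kb/min.
#'
#' @return An object of class `model_parameters`.
#' @examples
#' p <- model_parameters(N0 = 1231, J = 287, theta = 0.46, Pin = 0.34,
#'                       Plocal = 0.34, Pout = 0.01, d = 138)
#' p
#' @export
model_parameters <- function(N0 = 1000, J = 100, Pout = 0.01, Pin = 0.3,
                             Plocal = 0.3, theta = 0.4, d = 100, v = 0.5,
                             variant = c("MM5", "MM1", "MM2", "MM3", "MM4"),
                             origin_layout = c("discrete", "continuous"),
                             mean_origin_spacing = NULL,
                             round_minutes = 2) {
  variant <- match.arg(variant)
  origin_layout <- match.arg(origin_layout)
  if (is.null(mean_origin_spacing)) {
    mean_origin_spacing <- if (origin_layout == "discrete") 2.3 else 1
  }
  p <- structure(
    list(N0 = N0, J = J, Pout = Pout, Pin = Pin, Plocal = Plocal,
         theta = theta, d = d, v = v, variant = variant,
         origin_layout = origin_layout,
         mean_origin_spacing = mean_origin_spacing,
         round_minutes = round_minutes),
    class = "model_parameters")
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks all structural invariants (probabilities in `[0, 1]`,
#' non-negative counts and distances) and, optionally, the fitting bounds
#' used by the genetic algorithm (`N0` in `[1, 2000]`, `J` in `[0, 4000]`,
#' `d` in `[0, 1000]` kb). Errors name the offending field.
#'
#' @param p A `model_parameters` object.
#' @param fitting_bounds If `TRUE`, additionally require the adjustable
#'   parameters to lie within the optimisation bounds.
#' @return `p`, unchanged, if valid.
#' @export
validate_parameters <- function(p, fitting_bounds = FALSE) {
  stopifnot(inherits(p, "model_parameters"))
  bad <- function(field, msg) {
    abort(sprintf("invalid parameter `%s`: %s", field, msg),
          class = "replifire_invalid_parameter", field = field)
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      bad(field, "must be a single non-missing number")
    v
  }
  for (field in c("Pout", "Pin", "Plocal", "theta")) {
    v <- num1(field)
    if (v < 0 || v > 1) bad(field, "must lie in [0, 1]")
  }
  if (num1("N0") < 0) bad("N0", "must be >= 0")
  if (num1("J") < 0) bad("J", "must be >= 0")
  if (num1("d") < 0) bad("d", "must be >= 0 kb")
  if (num1("v") <= 0) bad("v", "must be > 0 kb/min")
  if (num1("round_minutes") <= 0) bad("round_minutes", "must be > 0 min")
  if (num1("mean_origin_spacing") < 1)
    bad("mean_origin_spacing", "must be >= 1 kb (one block)")
  if (!p$variant %in% paste0("MM", 1:5)) bad("variant", "must be MM1..MM5")
  if (!p$origin_layout %in% c("continuous", "discrete"))
    bad("origin_layout", "must be 'continuous' or 'discrete'")
  if (fitting_bounds) {
    b <- parameter_bounds(p$variant)
    for (i in seq_len(nrow(b))) {
      v <- p[[b$parameter[i]]]
      if (v < b$lower[i] || v > b$upper[i])
        bad(b$parameter[i],
            sprintf("outside fitting bounds [%g, %g]", b$lower[i], b$upper[i]))
    }
  }
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("<model_parameters> variant %s, %s origins (mean spacing %g kb)\n",
              x$variant, x$origin_layout, x$mean_origin_spacing))
  cat(sprintf("  N0 = %g, J = %g/round, Pout = %g, Pin = %g, Plocal = %g\n",
              x$N0, x$J, x$Pout, x$Pin, x$Plocal))
  cat(sprintf("  theta = %g, d = %g kb, v = %g kb/min, %g min/round\n",
              x$theta, x$d, x$v, x$round_minutes))
  invisible(x)
}

#' Adjustable parameters and their optimisation bounds
#'
#' Returns the parameters fitted for a given model variant together with
#' the bounds used by the genetic algorithm.
#'
#' @param variant Model variant, `"MM1"` ... `"MM5"`.
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
parameter_bounds <- function(variant = "MM5") {
  all_bounds <- tibble(
    parameter = c("N0", "J", "Pout", "Pin", "Plocal", "theta", "d"),
    lower = c(1, 0, 0, 0, 0, 0, 0),
    upper = c(2000, 4000, 1, 1, 1, 1, 1000))
  all_bounds[all_bounds$parameter %in% active_parameters(variant), ]
}

#' @rdname parameter_bounds
#' @export
active_parameters <- function(variant = "MM5") {
  switch(variant,
         MM1 = c("N0", "J", "Pout"),
         MM2 = c("N0", "J", "Pout"),
         MM3 = c("N0", "J", "Pout", "Plocal", "d"),
         MM4 = c("N0", "J", "Pout", "Pin", "theta"),
         MM5 = c("N0", "J", "Pout", "Pin", "Plocal", "theta", "d"),
         abort("unknown variant"))
}

#' Read / write parameter sets as YAML or JSON
#'
#' Plain-text round-trip of a `model_parameters` object for provenance
#' and scripting; the format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param p A `model_parameters` object.
#' @param path File path.
#' @return `write_parameters()` returns `path` invisibly;
#'   `read_parameters()` returns a validated `model_parameters`.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "model_parameters"))
  vals <- unclass(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(model_parameters, vals)
}

#' Fork displacement per round, in blocks
#'
#' @param p A `model_parameters` object.
#' @return For constant-speed variants, a single integer; for MM2 the
#'   vector of equiprobable per-round displacements (speeds 0-3 kb/min).
#' @export
speed_choices_blocks <- function(p) {
  if (p$variant == "MM2") {
    as.integer(0:3 * p$round_minutes)
  } else {
    as.integer(round(p$v * p$round_minutes))
  }
}

#' Temporal resolution identities of the lattice model
#'
#' `round_duration()` is the real time represented by one Monte Carlo
#' round, derived from symmetric two-block eye growth at fork speed `v`:
#' `growth_blocks / (2 v)` minutes. `detection_interval()` is the time
#' needed for a new eye to grow from 0 to `max_eye_kb` bidirectionally,
#' `max_eye_kb / (2 v)` minutes -- with the 3-kb upper bound used to call
#' new firing events this is the 3-min window underlying I(f).
#'
#' @param v Fork speed, kb/min.
#' @param growth_blocks Blocks added to an eye per round (2: one per fork).
#' @param max_eye_kb Largest eye still scored as a new firing event, kb.
#' @return Minutes.
#' @export
round_duration <- function(v = 0.5, growth_blocks = 2) growth_blocks / (2 * v)

#' @rdname round_duration
#' @export
detection_interval <- function(v = 0.5, max_eye_kb = 3) max_eye_kb / (2 * v)
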