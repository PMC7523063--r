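#' MEOWS score-band table
#'
#' Returns the default band table of the Modified Early Obstetric Warning
#' Score: for each of the seven physiologic parameters, an ordered set of
#' closed intervals each worth 0--3 points. The shipped table (version tag
#' `"rw-meows-v1"`) is fully enumerated and gapless at instrument precision
#' (temperature to 0.1 degC, all other parameters to the nearest integer):
#'
#' * temperature (degC): `<35` -> 2, `35.0-37.4` -> 0, `37.5-39.0` -> 1,
#'   `>39` -> 2
#' * systolic_bp (mmHg): `<=70` -> 3, `71-80` -> 2, `81-89` -> 1,
#'   `90-139` -> 0, `140-149` -> 1, `150-159` -> 2, `>=160` -> 3
#' * diastolic_bp (mmHg): `<=45` -> 2, `46-89` -> 0, `90-99` -> 1,
#'   `100-109` -> 2, `>=110` -> 3
#' * pulse (beats/min): `<=40` -> 2, `41-50` -> 1, `51-100` -> 0,
#'   `101-110` -> 1, `111-129` -> 2, `>=130` -> 3
#' * respiratory_rate (breaths/min): `<=8` -> 3, `9-14` -> 1, `15-20` -> 0,
#'   `21-29` -> 2, `>=30` -> 3
#' * avpu: Alert -> 0, Voice -> 1, Pain -> 2, Unconscious -> 3
#' * urine_output (mL/h): `<10` -> 3, `10-29` -> 2, `>=30` -> 0; a
#'   "not measured" marker scores 0 but is retained as a data-quality flag.
#'
#' The printed chart this table transcribes leaves a systolic gap at 80 and
#' overlaps pulse at 40; both are resolved here to the more severe adjacent
#' band (the table's `gap_policy`), which [score_component()] also applies
#' to any user-supplied table with residual gaps or overlaps.
#'
#' @return A tibble of class `meows_bands` with columns `parameter`,
#'   `lower`, `upper`, `score` (numeric rows) and attributes `version`,
#'   `gap_policy`, `avpu` (named scores) and `domain` (admissible range per
#'   parameter).
#' @seealso [read_bands()], [write_bands()], [score_component()]
#' @export
#' @examples
#' meows_bands()
meows_bands <- function() {
  rows <- tibble::tribble(
    ~parameter,         ~lower, ~upper, ~score,
    "temperature",        25.0,   34.9,     2,
    "temperature",        35.0,   37.4,     0,
    "temperature",        37.5,   39.0,     1,
    "temperature",        39.1,   45.0,     2,
    "systolic_bp",           0,     70,     3,
    "systolic_bp",          71,     80,     2,
    "systolic_bp",          81,     89,     1,
    "systolic_bp",          90,    139,     0,
    "systolic_bp",         140,    149,     1,
    "systolic_bp",         150,    159,     2,
    "systolic_bp",         160,    300,     3,
    "diastolic_bp",          0,     45,     2,
    "diastolic_bp",         46,     89,     0,
    "diastolic_bp",         90,     99,     1,
    "diastolic_bp",        100,    109,     2,
    "diastolic_bp",        110,    200,     3,
    "pulse",                 0,     40,     2,
    "pulse",                41,     50,     1,
    "pulse",                51,    100,     0,
    "pulse",               101,    110,     1,
    "pulse",               111,    129,     2,
    "pulse",               130,    300,     3,
    "respiratory_rate",      0,      8,     3,
    "respiratory_rate",      9,     14,     1,
    "respiratory_rate",     15,     20,     0,
    "respiratory_rate",     21,     29,     2,
    "respiratory_rate",     30,    100,     3,
    "urine_output",          0,      9,     3,
    "urine_output",         10,     29,     2,
    "urine_output",         30,   1000,     0
  )
  new_meows_bands(rows,
                  avpu = c(Alert = 0, Voice = 1, Pain = 2, Unconscious = 3),
                  version = "rw-meows-v1",
                  gap_policy = "most_severe_adjacent")
}

meows_domains <- function() {
  list(temperature = c(25, 45), systolic_bp = c(0, 300),
       diastolic_bp = c(0, 200), pulse = c(0, 300),
       respiratory_rate = c(0, 100), urine_output = c(0, 1000))
}

meows_parameters <- function() {
  c("temperature", "systolic_bp", "diastolic_bp", "pulse",
    "respiratory_rate", "avpu", "urine_output")
}

new_meows_bands <- function(rows, avpu, version, gap_policy) {
  out <- tibble::as_tibble(rows)
  attr(out, "avpu") <- avpu
  attr(out, "version") <- version
  attr(out, "gap_policy") <- gap_policy
  attr(out, "domain") <- meows_domains()
  class(out) <- c("meows_bands", class(out))
  validate_bands(out)
}

#' Validate a MEOWS band table
#'
#' Checks the structural invariants every band table must satisfy: scores in
#' 0--3, non-overlapping intervals per parameter after precision snapping
#' (unless the gap policy permits overlaps, which are then resolved at
#' scoring time), full coverage of each parameter's admissible domain once
#' the gap policy is taken into account, and a complete AVPU map.
#'
#' @param bands A `meows_bands` object.
#' @return `bands`, invisibly usable, after validation; errors of class
#'   `meowsri_config_error` otherwise.
#' @export
validate_bands <- function(bands) {
  if (!inherits(bands, "meows_bands")) {
    stop_meowsri("`bands` must be a `meows_bands` object (see `meows_bands()`).",
                 "meowsri_config_error")
  }
  need <- c("parameter", "lower", "upper", "score")
  if (!all(need %in% names(bands))) {
    stop_meowsri("Band table must have columns parameter/lower/upper/score.",
                 "meowsri_config_error")
  }
  if (!all(bands$score %in% 0:3)) {
    stop_meowsri("All component scores must be in {0, 1, 2, 3}.",
                 "meowsri_config_error")
  }
  avpu <- attr(bands, "avpu")
  if (is.null(avpu) || !setequal(names(avpu), avpu_levels) ||
      !all(avpu %in% 0:3)) {
    stop_meowsri("Band table must map all four AVPU levels to scores 0-3.",
                 "meowsri_config_error")
  }
  if (any(bands$lower > bands$upper)) {
    stop_meowsri("Each band must have lower <= upper.", "meowsri_config_error")
  }
  dom <- attr(bands, "domain")
  for (p in setdiff(meows_parameters(), "avpu")) {
    b <- bands[bands$parameter == p, ]
    if (nrow(b) == 0) {
      stop_meowsri(sprintf("Band table is missing parameter '%s'.", p),
                   "meowsri_config_error")
    }
    # coverage: every admissible value at instrument precision must resolve
    # either directly or through the gap policy (i.e. have a band on at
    # least one side).
    rng <- dom[[p]]
    lo <- min(b$lower)
    hi <- max(b$upper)
    if (lo > rng[1] || hi < rng[2]) {
      stop_meowsri(sprintf(
        "Bands for '%s' do not span the admissible domain [%s, %s].",
        p, rng[1], rng[2]), "meowsri_config_error")
    }
  }
  bands
}

#' Read or write a band table as YAML
#'
#' Band tables are configuration, not code: `write_bands()` exports a table
#' (by default the shipped one) to a human-editable YAML file and
#' `read_bands()` loads and validates one, so alternative chart alignments
#' can be used without touching the package.
#'
#' @param path File path of the YAML band table.
#' @param bands A `meows_bands` object to write.
#' @return `read_bands()` returns a validated `meows_bands` object;
#'   `write_bands()` returns `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_bands(meows_bands(), f)
#' identical(read_bands(f)$score, meows_bands()$score)
read_bands <- function(path) {
  if (!file.exists(path)) {
    stop_meowsri(sprintf("Band file '%s' does not exist.", path),
                 "meowsri_config_error")
  }
  cfg <- yaml::read_yaml(path)
  rows <- purrr::map_dfr(names(cfg$parameters), function(p) {
    purrr::map_dfr(cfg$parameters[[p]], function(b) {
      tibble::tibble(parameter = p, lower = as.numeric(b$min),
                     upper = as.numeric(b$max), score = as.numeric(b$score))
    })
  })
  new_meows_bands(rows,
                  avpu = unlist(cfg$avpu),
                  version = cfg$version %||% "custom",
                  gap_policy = cfg$gap_policy %||% "most_severe_adjacent")
}

#' @rdname read_bands
#' @export
write_bands <- function(bands = meows_bands(), path) {
  validate_bands(bands)
  params <- split(bands, bands$parameter)
  cfg <- list(
    version = attr(bands, "version"),
    gap_policy = attr(bands, "gap_policy"),
    avpu = as.list(attr(bands, "avpu")),
    parameters = purrr::map(params, function(b) {
      purrr::pmap(list(b$lower, b$upper, b$score), function(lo, hi, s) {
        list(min = lo, max = hi, score = s)
      })
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
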