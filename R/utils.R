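# Internal helpers shared across modules.

MEASURES <- c("mean_difference", "risk_difference", "risk_ratio", "odds_ratio")
TARGETS  <- c("A_GIVEN_NO_B", "A_GIVEN_B", "A_USUAL_PRACTICE", "A_PLUS_B")

#' @noRd
measure_link <- function(measure) {
  switch(measure,
    mean_difference = "identity",
    risk_difference = "identity",
    risk_ratio      = "log",
    odds_ratio      = "logit",
    stop("unknown measure: ", measure)
  )
}

# Effect of group 1 vs group 0 from two outcome means/risks, on the
# measure's natural scale (ratios as ratios, not logs).
#' @noRd
effect_from_means <- function(m1, m0, measure) {
  switch(measure,
    mean_difference = ,
    risk_difference = m1 - m0,
    risk_ratio = {
      if (m0 <= 0 || m1 <= 0 || m0 >= 1 || m1 >= 1)
        stop("risk ratio requires risks strictly inside (0, 1)")
      m1 / m0
    },
    odds_ratio = {
      if (m0 <= 0 || m1 <= 0 || m0 >= 1 || m1 >= 1)
        stop("odds ratio requires risks strictly inside (0, 1)")
      (m1 / (1 - m1)) / (m0 / (1 - m0))
    },
    stop("unknown measure: ", measure)
  )
}

# Natural-scale effect -> link scale (identity, log or log-odds contrast).
#' @noRd
to_link_scale <- function(effect, measure) {
  if (measure_link(measure) == "identity") effect else log(effect)
}

#' @noRd
from_link_scale <- function(x, measure) {
  if (measure_link(measure) == "identity") x else exp(x)
}

#' @noRd
is_binary01 <- function(x) all(x %in% c(0, 1))

# Run code with a local RNG state: seeds deterministically, then restores
# whatever global .Random.seed was in place (no implicit global randomness).
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Read a JSON or YAML config file (format by extension).  The YAML handlers
# keep keys like "n" and "y" as strings instead of YAML-1.1 booleans.
#' @noRd
read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x)
        if (tolower(x) %in% c("true", "yes", "on")) TRUE else x,
      "bool#no" = function(x)
        if (tolower(x) %in% c("false", "no", "off")) FALSE else x))
  } else {
    jsonlite::fromJSON(path)
  }
}

#' @noRd
stop_undefined_estimand <- function(msg) {
  stop(errorCondition(msg, class = c("estimand_undefined", "error")))
}

#' @noRd
check_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok)
    stop(name, " must be a probability in ", if (open) "(0, 1)" else "[0, 1]",
         call. = FALSE)
  invisible(x)
}
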