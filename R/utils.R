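# Internal helpers: classed conditions, scoped RNG, unit conversion.
#
# Canonical internal units are seconds, pA and pC (1 pA integrated over 1 s
# is 1 pC). Femtocoulombs appear only at the reporting boundary for
# miniature-event charges (1 pC = 1000 fC).

rrp_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rrpool_error", "error")))
}

rrp_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "rrpool_warning", "warning")))
}

#' Convert picocoulombs to femtocoulombs
#'
#' Charges are carried internally in pC; miniature-event charges are
#' conventionally reported in fC.
#'
#' @param pc charge in pC.
#' @return charge in fC.
#' @export
pc_to_fc <- function(pc) pc * 1000

#' Convert femtocoulombs to picocoulombs
#'
#' @param fc charge in fC.
#' @return charge in pC.
#' @export
fc_to_pc <- function(fc) fc / 1000

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    rrp_abort("seed must be a single finite number", "rrpool_parameter_error")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# mean/sem with the n = 1 convention: sem is NA, never 0, for a single
# observation.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
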