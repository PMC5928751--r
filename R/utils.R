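#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded simulation helpers do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage-specific child seed from a pipeline seed
#'
#' Deterministic splitting scheme: each (seed, stage, index) triple maps to a
#' distinct 31-bit seed, so a stage can be re-run in isolation and reproduce
#' the in-pipeline result.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @param index optional integer (e.g. participant number).
#' @return integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  h <- Reduce(function(a, ch) (a * 31 + ch) %% 1000003, utf8ToInt(stage), 0)
  as.integer((as.double(seed) * 48271 + h * 1009 + index * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Condition labels of the 2 x 2 audiovisual design
#'
#' Auditory clear/noisy crossed with visual clear/blurred, in the fixed order
#' used by the "+1 +1 -1 -1" clear-vs-noisy contrast.
#' @return character vector of length 4.
#' @export
condition_levels <- function() {
  c("AclearVclear", "AclearVblur", "AnoisyVclear", "AnoisyVblur")
}

#' Auditory / visual factor of a condition label
#' @param condition character vector of condition labels.
#' @return factor-ready character vector ("clear"/"noisy" or "clear"/"blur").
#' @export
auditory_of <- function(condition) {
  ifelse(grepl("^Aclear", condition), "clear", "noisy")
}

#' @rdname auditory_of
#' @export
visual_of <- function(condition) {
  ifelse(grepl("Vclear$", condition), "clear", "blur")
}
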