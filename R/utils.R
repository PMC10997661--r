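# Small shared helpers.

utils::globalVariables(c("count", "mean_attention", "representation",
                         "feature"))

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library internals never
#' disturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Parse a scheme label such as "A+J" into representation codes
#'
#' @param label character scalar, `+`-separated subset of A, P, J, F.
#' @return character vector of unique representation codes.
#' @export
parse_scheme <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  reps <- toupper(trimws(strsplit(label, "+", fixed = TRUE)[[1]]))
  reps <- reps[nzchar(reps)]
  if (length(reps) == 0) stop("empty graph scheme", call. = FALSE)
  bad <- setdiff(reps, c("A", "P", "J", "F"))
  if (length(bad) > 0) {
    stop("unknown representation(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reps)) stop("duplicate representations in scheme",
                                call. = FALSE)
  reps
}

scheme_label <- function(reps) paste(reps, collapse = "+")

#' Default operator: left-hand side unless NULL
#' @param a,b values; `b` is used when `a` is NULL.
#' @return `a` unless it is NULL, else `b`.
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a
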