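#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from one master seed per run;
#' per-stage seeds are derived deterministically from it plus a set of
#' string/integer tags (stage name, blur size, repetition index, ...),
#' so stages are independent yet fully reproducible.
#'
#' @param master integer master seed.
#' @param ... additional tags (character or numeric scalars) identifying
#'   the stage.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "sample", 8L)
#' @export
derive_seed <- function(master, ...) {
  tags <- c(as.character(as.integer(master)), vapply(list(...), as.character, ""))
  h <- 0
  for (tag in tags) {
    for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
    h <- (h * 31 + 7) %% 2147483647
  }
  as.integer(h)
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  code
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stage_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}
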