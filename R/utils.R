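# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All exported generators funnel their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive `n` independent sub-seeds from a master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("perioFD_invalid_argument", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("perioFD_io_error", "error")))
}

is_binary_matrix <- function(x) {
  is.matrix(x) && all(x %in% c(0, 1))
}

assert_binary <- function(x, what = "image") {
  if (!is_binary_matrix(x)) {
    stop_invalid(what, " must be a binary (0/1) matrix")
  }
  invisible(x)
}

# Half-up rounding at `digits` decimals, as spreadsheets and the printed
# tables round (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# md5 of an in-memory object via its canonical JSON serialization.
hash_config <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}
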