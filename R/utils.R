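#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   bind_rows left_join across n
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map2_dbl pmap imap list_rbind
#' @importFrom stats qnorm pnorm rnorm runif quantile setNames uniroot rbinom
NULL

# standard normal upper-quartile point
Z75 <- qnorm(0.75)

abort_config <- function(msg) rlang::abort(msg, class = "foodaidsim_config_error")
abort_input <- function(msg) rlang::abort(msg, class = "foodaidsim_input_error")

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort_input(sprintf("`%s` must be a single number >= %s", name, min))
  }
  invisible(x)
}

# derive a child seed from a parent seed and a stream label; keeps results
# below 2^31 and decorrelated across streams
child_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + s * 16807) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
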