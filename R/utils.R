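#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n pull rename count across all_of
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom stats rnorm runif quantile aov pf qf var sd cor setNames
#' @importFrom utils write.table read.table head combn
NULL

# error with a class so callers can condition on failure kind
ts_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "twinscope_error"))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    ts_abort(sprintf("`%s` must be a single probability in [0, 1], got %s",
                     name, deparse(x)), "config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    ts_abort(sprintf("`%s` must be a single integer >= %d", name, min),
             "config_error")
  }
  invisible(as.integer(x))
}

# normalize an unphased diploid genotype: sort the two alleles -> "A/G"
normalize_gt <- function(gt) {
  out <- vapply(strsplit(gt, "/", fixed = TRUE), function(al) {
    if (length(al) != 2L || anyNA(al)) return(NA_character_)
    paste(sort(al), collapse = "/")
  }, character(1))
  out[is.na(gt)] <- NA_character_
  out
}
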