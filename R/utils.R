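`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
msg <- function(...) message(sprintf(...))

stop_input <- function(...) {
  stop(errorCondition(sprintf(...), class = c("molstack_input_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(sprintf(...), class = c("molstack_config_error", "error")))
}

#' Deterministic string hash
#'
#' Polynomial rolling hash (base 31, modulus 2^31 - 1) reduced to `n_bins`
#' buckets. Used wherever a fingerprint family hashes substructure keys to a
#' fixed width, so bit assignment is identical across runs and platforms.
#'
#' @param x character vector of keys.
#' @param n_bins number of buckets.
#' @param salt string mixed into the key so different families use
#'   independent bit assignments.
#' @return integer vector in `[1, n_bins]`.
#' @keywords internal
hash_bin <- function(x, n_bins, salt = "") {
  mod <- 2147483647
  vapply(paste0(salt, "|", x), function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% mod
    as.integer(h %% n_bins) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

## derive a reproducible child seed from (seed, tag); kept < 2^31
child_seed <- function(seed, tag) {
  (as.numeric(seed) * 7919 + sum(utf8ToInt(as.character(tag)))) %% 2147483647
}
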